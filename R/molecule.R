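# The molecule record: a heavy-atom molecular graph with formal charges and
# stereo descriptors, independent of any particular 3D geometry.

#' Construct a molecule record
#'
#' A molecule is a heavy-atom graph: atomic numbers, a bond table and formal
#' charges, plus optional stereo descriptors and a canonical reference string.
#' Hydrogens are implicit throughout; 3D geometries are carried separately as
#' conformer records (see [conformer_record()]).
#'
#' @param mol_id opaque string identifier.
#' @param elements integer vector of atomic numbers, heavy atoms only.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2 or 3; aromatic rings may be supplied kekulized).
#' @param charges integer vector of formal charges (default all zero).
#' @param chiral integer vector of tetrahedral parity tags: 0 (none/unset),
#'   +1 or -1, following the signed-volume convention of
#'   [assign_stereo_from_3d()].
#' @param ez data.frame of double-bond stereo (columns `i`, `j`, `ni`, `nj`,
#'   `tag`): tag +1 when reference neighbours `ni`, `nj` are cis, -1 trans.
#' @param smiles canonical line-notation reference string, or `NA` until set
#'   by [standardize_molecule()].
#' @return An object of class `cb_molecule`.
#' @export
molecule_record <- function(mol_id, elements, bonds,
                            charges = integer(length(elements)),
                            chiral = integer(length(elements)),
                            ez = NULL, smiles = NA_character_) {
  elements <- as.integer(elements)
  n <- length(elements)
  if (n < 1L) stop("molecule must contain at least one heavy atom")
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond atom index out of range for molecule ", mol_id)
    if (any(bonds$i == bonds$j)) stop("self-bond in molecule ", mol_id)
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- bonds[order(bonds$i, bonds$j), c("i", "j", "order"), drop = FALSE]
    rownames(bonds) <- NULL
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  if (is.null(ez))
    ez <- data.frame(i = integer(), j = integer(), ni = integer(),
                     nj = integer(), tag = integer())
  structure(list(mol_id = as.character(mol_id), elements = elements,
                 bonds = bonds, charges = as.integer(charges),
                 chiral = as.integer(chiral), ez = ez,
                 smiles = smiles),
            class = "cb_molecule")
}

#' @export
print.cb_molecule <- function(x, ...) {
  cat(sprintf("<cb_molecule %s: %d heavy atoms, %d bonds%s>\n",
              x$mol_id, length(x$elements), nrow(x$bonds),
              if (is.na(x$smiles)) "" else paste0(", ", x$smiles)))
  invisible(x)
}

n_heavy_atoms <- function(mol) length(mol$elements)

# igraph view of the molecular graph. Edge attribute `order` keeps the raw
# bond order; `color` holds the normalized integer bond colour in which
# conjugated ring bonds are merged (see .cb_bond_colors), so that the two
# kekule forms of an aromatic ring compare equal.
mol_graph <- function(mol) {
  g <- attr(mol, ".graph")
  if (!is.null(g)) return(g)
  n <- n_heavy_atoms(mol)
  if (nrow(mol$bonds)) {
    g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::E(g)$order <- mol$bonds$order
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  }
  igraph::V(g)$z <- mol$elements
  g
}

mol_with_graph <- function(mol) {
  if (is.null(attr(mol, ".graph"))) attr(mol, ".graph") <- mol_graph(mol)
  mol
}

# Bonds participating in a ring = edges that are not bridges.
ring_bond_mask <- function(mol) {
  g <- mol_graph(mol)
  if (igraph::ecount(g) == 0L) return(logical(0))
  mask <- rep(TRUE, igraph::ecount(g))
  mask[igraph::bridges(g)] <- FALSE
  mask
}

ring_atom_mask <- function(mol) {
  mask <- logical(n_heavy_atoms(mol))
  rb <- ring_bond_mask(mol)
  if (any(rb)) mask[unique(unlist(mol$bonds[rb, c("i", "j")]))] <- TRUE
  mask
}

# Normalized integer bond colours: 10*order, except that ring bonds of order
# 1 or 2 joining two unsaturated atoms collapse to a common "conjugated"
# colour 15. This is a deliberately permissive aromaticity surrogate: it makes
# alternative kekule assignments of the same ring indistinguishable for
# matching, automorphism and fingerprint purposes.
.cb_bond_colors <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(integer(0))
  col <- as.integer(round(mol$bonds$order * 10))
  unsat <- logical(n_heavy_atoms(mol))
  multi <- mol$bonds$order >= 2
  if (any(multi)) unsat[unique(unlist(mol$bonds[multi, c("i", "j")]))] <- TRUE
  rb <- ring_bond_mask(mol)
  conj <- rb & mol$bonds$order <= 2 & unsat[mol$bonds$i] & unsat[mol$bonds$j]
  col[conj] <- 15L
  col
}

# Vertex colours for isomorphism tests: element and formal charge.
.cb_vertex_colors <- function(mol) {
  as.integer(mol$elements * 16L + mol$charges + 8L)
}

adjacency_list <- function(mol) {
  n <- n_heavy_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else sort(v))
}

degree_vec <- function(mol) lengths(adjacency_list(mol))

# Sum of explicit bond orders per atom (conjugated colour counts as its raw
# kekule order), used for implicit-hydrogen bookkeeping.
valence_sum <- function(mol) {
  v <- numeric(n_heavy_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    v[mol$bonds$i[k]] <- v[mol$bonds$i[k]] + mol$bonds$order[k]
    v[mol$bonds$j[k]] <- v[mol$bonds$j[k]] + mol$bonds$order[k]
  }
  v
}

# Default valences used for implicit hydrogen counts during neutralization
# and SMILES-free reasoning. Charge shifts the target valence for N-like and
# O-like centres (ammonium 4, oxide 1, ...).
.cb_default_valence <- c(`5` = 3, `6` = 4, `7` = 3, `8` = 2, `9` = 1,
                         `14` = 4, `15` = 3, `16` = 2, `17` = 1,
                         `34` = 2, `35` = 1, `53` = 1)

implicit_h_count <- function(mol) {
  dv <- .cb_default_valence[as.character(mol$elements)]
  dv[is.na(dv)] <- 0
  target <- dv + ifelse(mol$elements %in% c(7L, 15L), mol$charges,
                        ifelse(mol$elements %in% c(8L, 16L), mol$charges, 0))
  h <- target - valence_sum(mol)
  pmax(0, round(h))
}

# Iterative neighbourhood-refinement ranks (Morgan-style). Not a full
# canonical labelling, but stable and sufficient for deterministic neighbour
# priorities in stereo perception and torsion definitions.
canonical_ranks <- function(mol) {
  cached <- attr(mol, ".ranks")
  if (!is.null(cached)) return(cached)
  n <- n_heavy_atoms(mol)
  adj <- adjacency_list(mol)
  bcol <- .cb_bond_colors(mol)
  bond_col_lookup <- new.env(hash = TRUE)
  for (k in seq_len(nrow(mol$bonds)))
    assign(paste(mol$bonds$i[k], mol$bonds$j[k]), bcol[k], bond_col_lookup)
  get_col <- function(a, b) {
    key <- if (a < b) paste(a, b) else paste(b, a)
    get(key, bond_col_lookup)
  }
  key0 <- paste(mol$elements, lengths(adj), mol$charges, implicit_h_count(mol))
  r <- as.integer(factor(rank(key0, ties.method = "min")))
  for (it in seq_len(n)) {
    keys <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (!length(nb)) return(paste(r[a]))
      nbk <- sort(paste0(sprintf("%04d", vapply(nb, get_col, 0, a = a)),
                         sprintf("%06d", r[nb])))
      paste(r[a], paste(nbk, collapse = "|"))
    }, "")
    rn <- as.integer(factor(keys))
    if (identical(rn, r)) break
    r <- rn
  }
  r
}

mol_with_ranks <- function(mol) {
  if (is.null(attr(mol, ".ranks"))) attr(mol, ".ranks") <- canonical_ranks(mol)
  mol
}
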