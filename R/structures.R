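# Structure curation: standardization, stereo perception from 3D geometry,
# and chirality-aware matching of observed ligands against reference
# structures, with a one-shot bond-order template retry.

#' Canonical SMILES of a molecule
#'
#' Canonicalization is delegated to OpenBabel; when coordinates are supplied,
#' stereochemistry is perceived from the 3D geometry and embedded in the
#' output string.
#'
#' @param mol a `cb_molecule`.
#' @param coords optional N x 3 coordinate matrix used to encode stereo.
#' @return A canonical SMILES string.
#' @export
canonical_smiles <- function(mol, coords = NULL) {
  if (is.null(coords)) coords <- matrix(0, n_heavy_atoms(mol), 3)
  tmp_in <- tempfile(fileext = ".sdf"); tmp_out <- tempfile(fileext = ".smi")
  on.exit(unlink(c(tmp_in, tmp_out)))
  writeLines(.cb_sdf_record(mol, coords), tmp_in)
  status <- system2(.cb_tool("obabel"), c(tmp_in, "-ocan", "-O", tmp_out),
                    stdout = FALSE, stderr = FALSE)
  res <- if (file.exists(tmp_out)) readLines(tmp_out, warn = FALSE) else character(0)
  if (status != 0L || !length(res) || !nzchar(res[1]))
    stop("canonical SMILES generation failed for ", mol$mol_id)
  strsplit(res[1], "\t")[[1]][1]
}

#' Standardize a molecule
#'
#' Keeps the largest connected component, then neutralizes formal charges
#' that can be removed by adding or removing an implicit proton without
#' breaking valence: cations are deprotonated when they carry an implicit
#' hydrogen, anions are protonated. Atoms adjacent to an opposite charge
#' (e.g. the nitro or N-oxide motifs) are left untouched. The canonical
#' reference string is (re)computed. The operation is idempotent.
#'
#' @param raw a `cb_molecule`.
#' @param coords optional coordinates (rows are dropped together with any
#'   discarded fragment atoms); used for the stereo-aware canonical string.
#' @return The standardized `cb_molecule`; when `coords` is given, an
#'   attribute `coords` carries the correspondingly subset matrix.
#' @export
standardize_molecule <- function(raw, coords = NULL) {
  g <- mol_graph(raw)
  comp <- igraph::components(g)
  keep <- seq_len(n_heavy_atoms(raw))
  if (comp$no > 1L) {
    big <- which.max(comp$csize)
    keep <- which(comp$membership == big)
    idx_map <- match(seq_len(n_heavy_atoms(raw)), keep)
    kb <- raw$bonds[raw$bonds$i %in% keep & raw$bonds$j %in% keep, , drop = FALSE]
    kb$i <- idx_map[kb$i]; kb$j <- idx_map[kb$j]
    raw <- molecule_record(raw$mol_id, raw$elements[keep], kb,
                           raw$charges[keep], raw$chiral[keep])
    if (!is.null(coords)) coords <- coords[keep, , drop = FALSE]
  }
  adj <- adjacency_list(raw)
  charges <- raw$charges
  neighbor_charged <- vapply(seq_along(charges), function(a) {
    any(charges[adj[[a]]] * charges[a] < 0)
  }, TRUE)
  imp_h <- implicit_h_count(raw)
  for (a in seq_along(charges)) {
    if (charges[a] == 0L || neighbor_charged[a]) next
    if (charges[a] > 0L && imp_h[a] >= 1L) charges[a] <- 0L
    if (charges[a] < 0L) charges[a] <- 0L
  }
  out <- molecule_record(raw$mol_id, raw$elements, raw$bonds, charges,
                         raw$chiral, raw$ez)
  out$smiles <- canonical_smiles(out, coords)
  if (!is.null(coords)) attr(out, "coords") <- coords
  out
}

# Hash of the chemical environment seen from neighbour `b` of centre `a`,
# walking outward up to `depth` bonds without stepping back through `a`.
# Used to decide whether the branches around a candidate stereocentre are
# distinguishable.
.cb_branch_hash <- function(mol, adj, a, b, depth = 6L) {
  ranks <- canonical_ranks(mol)
  frontier <- b
  blocked <- a
  acc <- integer(0)
  for (d in seq_len(depth)) {
    if (!length(frontier)) break
    acc <- c(acc, d * 1000000L + sort(ranks[frontier]))
    blocked <- c(blocked, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier])), blocked)
  }
  .cb_hash(acc)
}

#' Assign stereo descriptors from a 3D geometry
#'
#' Tetrahedral parity tags are set for atoms with three or four heavy
#' neighbours, no multiple bonds, and pairwise-distinguishable branches.
#' The tag is the sign of the signed volume det(v1, v2, v3) of the bond
#' vectors to the three lowest-index neighbours (the implicit hydrogen, when
#' present, plays the role of the missing fourth substituent). Double-bond
#' E/Z tags are set for acyclic double bonds whose ends each carry at least
#' one additional heavy neighbour.
#'
#' @param mol a `cb_molecule`.
#' @param conf a `cb_conformer` (or plain coordinate matrix) covering all
#'   heavy atoms of `mol`.
#' @return `mol` with `chiral` and `ez` fields populated.
#' @export
assign_stereo_from_3d <- function(mol, conf) {
  coords <- if (inherits(conf, "cb_conformer")) conf$coords else as.matrix(conf)
  n <- n_heavy_atoms(mol)
  if (nrow(coords) != n)
    stop("coordinate/atom count mismatch: ", nrow(coords), " vs ", n)
  adj <- adjacency_list(mol)
  has_multi <- logical(n)
  multi <- mol$bonds$order >= 2
  if (any(multi)) has_multi[unique(unlist(mol$bonds[multi, c("i", "j")]))] <- TRUE
  imp_h <- implicit_h_count(mol)
  chiral <- integer(n)
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    if (has_multi[a]) next
    if (!(length(nb) == 4L || (length(nb) == 3L && imp_h[a] >= 1L))) next
    hashes <- vapply(nb, function(b) .cb_branch_hash(mol, adj, a, b), 0)
    if (anyDuplicated(hashes)) next
    v <- coords[nb[1:3], , drop = FALSE] -
      matrix(coords[a, ], 3, 3, byrow = TRUE)
    vol <- det(v)
    if (abs(vol) < 1e-4) next   # degenerate/planar geometry: leave unset
    chiral[a] <- sign(vol)
  }
  ez <- data.frame(i = integer(), j = integer(), ni = integer(),
                   nj = integer(), tag = integer())
  rb <- ring_bond_mask(mol)
  ranks <- canonical_ranks(mol)
  dbl <- which(mol$bonds$order == 2 & !rb)
  for (k in dbl) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    ni_all <- setdiff(adj[[i]], j); nj_all <- setdiff(adj[[j]], i)
    if (!length(ni_all) || !length(nj_all)) next
    ni <- ni_all[which.max(ranks[ni_all])]
    nj <- nj_all[which.max(ranks[nj_all])]
    ang <- .cb_dihedral(coords[ni, ], coords[i, ], coords[j, ], coords[nj, ])
    if (!is.finite(ang)) next
    ez <- rbind(ez, data.frame(i = i, j = j, ni = ni, nj = nj,
                               tag = if (abs(ang) < 90) 1L else -1L))
  }
  mol$chiral <- chiral
  mol$ez <- ez
  mol
}

#' R/S-style chirality label of a tagged stereocentre
#'
#' Substituent priority is simplified CIP: atomic number of the immediate
#' neighbour first, canonical neighbourhood rank as tie-break, with the
#' implicit hydrogen always lowest.
#'
#' @param mol molecule with `chiral` tags set.
#' @param atom atom index.
#' @param coords coordinate matrix consistent with the tag assignment.
#' @return `"R"`, `"S"`, or `NA` if the atom carries no tag.
#' @export
chirality_label <- function(mol, atom, coords) {
  if (mol$chiral[atom] == 0L) return(NA_character_)
  adj <- adjacency_list(mol)
  nb <- adj[[atom]]
  ranks <- canonical_ranks(mol)
  pri <- order(-mol$elements[nb], -ranks[nb])
  top3 <- nb[pri][1:3]   # implicit H / lowest-priority substituent points away
  v <- coords[top3, , drop = FALSE] - matrix(coords[atom, ], 3, 3, byrow = TRUE)
  # for a tetrahedral centre, det < 0 over the three highest priorities seen
  # in descending order corresponds to a clockwise (R) arrangement
  if (det(v) < 0) "R" else "S"
}

.cb_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.cb_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cb_cross(b1, b2); n2 <- .cb_cross(b2, b3)
  m1 <- .cb_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Does graph mapping sigma (obs index -> ref index) preserve tetrahedral
# parity and E/Z tags? Unspecified centres (tag 0 on either side) match
# anything, mirroring chirality-aware substructure matching semantics.
.cb_stereo_consistent <- function(obs, ref, sigma) {
  adj_o <- adjacency_list(obs)
  for (a in which(obs$chiral != 0L)) {
    b <- sigma[a]
    if (ref$chiral[b] == 0L) next
    nb_o <- adj_o[[a]]
    perm <- rank(sigma[nb_o])   # neighbour order by mapped ref index
    sgn <- .cb_perm_sign(perm)
    if (obs$chiral[a] * sgn != ref$chiral[b]) return(FALSE)
  }
  if (nrow(obs$ez) && nrow(ref$ez)) {
    ref_key <- paste(pmin(ref$ez$i, ref$ez$j), pmax(ref$ez$i, ref$ez$j))
    for (k in seq_len(nrow(obs$ez))) {
      bi <- sigma[obs$ez$i[k]]; bj <- sigma[obs$ez$j[k]]
      m <- match(paste(min(bi, bj), max(bi, bj)), ref_key)
      if (is.na(m)) next
      re <- ref$ez[m, ]
      if (re$i != bi) re <- data.frame(i = re$j, j = re$i, ni = re$nj,
                                       nj = re$ni, tag = re$tag)
      tag <- obs$ez$tag[k]
      if (sigma[obs$ez$ni[k]] != re$ni) tag <- -tag
      if (sigma[obs$ez$nj[k]] != re$nj) tag <- -tag
      if (tag != re$tag) return(FALSE)
    }
  }
  TRUE
}

.cb_perm_sign <- function(perm) {
  n <- length(perm)
  sgn <- 1L
  seen <- logical(n)
  for (s in seq_len(n)) {
    if (seen[s]) next
    len <- 0L; cur <- s
    while (!seen[cur]) { seen[cur] <- TRUE; cur <- perm[cur]; len <- len + 1L }
    if (len %% 2L == 0L) sgn <- -sgn
  }
  sgn
}

# All graph isomorphisms between two molecules, as a list of index maps
# (obs -> ref). Vertex colours always include element + charge; bond colours
# are optional (dropped for the template-assignment fallback).
.cb_isomorphisms <- function(obs, ref, use_bond_colors = TRUE, cap = 10000L) {
  if (n_heavy_atoms(obs) != n_heavy_atoms(ref)) return(list())
  if (!identical(sort(obs$elements), sort(ref$elements))) return(list())
  g1 <- mol_graph(obs); g2 <- mol_graph(ref)
  args <- list(g1, g2, method = "vf2",
               vertex.color1 = .cb_vertex_colors(obs),
               vertex.color2 = .cb_vertex_colors(ref))
  if (use_bond_colors && igraph::ecount(g1) > 0L) {
    args$edge.color1 <- .cb_bond_colors(obs)
    args$edge.color2 <- .cb_bond_colors(ref)
  }
  iso <- do.call(igraph::isomorphisms, args)
  if (length(iso) > cap) iso <- iso[seq_len(cap)]
  lapply(iso, as.integer)
}

#' Match an observed molecule against a reference structure
#'
#' Attempts a chirality-aware graph match between two standardized molecules
#' (element, formal charge and normalized bond order must agree, and every
#' specified stereo descriptor must be preserved). When the direct match
#' fails, bond orders of the observed molecule are re-assigned from the
#' reference template through a plain-connectivity isomorphism and the match
#' is retried exactly once. Failures are reported in the returned object
#' rather than raised, so a batch can drop individual ligands.
#'
#' @param observed,reference standardized `cb_molecule` objects.
#' @return A list of class `cb_match`: `pairs` (two-column matrix of matched
#'   observed/reference indices), `complete` flag, `used_template_retry`
#'   flag, and `reason` on failure.
#' @export
match_to_reference <- function(observed, reference) {
  fail <- function(reason, retry = FALSE) {
    structure(list(pairs = NULL, complete = FALSE,
                   used_template_retry = retry, reason = reason),
              class = "cb_match")
  }
  found <- function(sigma, retry) {
    structure(list(pairs = cbind(observed = seq_along(sigma),
                                 reference = sigma),
                   complete = TRUE, used_template_retry = retry,
                   reason = NA_character_),
              class = "cb_match")
  }
  pick_stereo <- function(obs, iso, retry) {
    for (sigma in iso)
      if (.cb_stereo_consistent(obs, reference, sigma))
        return(found(sigma, retry))
    NULL
  }
  iso <- .cb_isomorphisms(observed, reference)
  hit <- pick_stereo(observed, iso, FALSE)
  if (!is.null(hit)) return(hit)
  # template retry: re-assign bond orders from the reference through a
  # connectivity-only isomorphism, then retry the full match once
  conn <- .cb_isomorphisms(observed, reference, use_bond_colors = FALSE)
  if (!length(conn)) return(fail("no connectivity isomorphism"))
  sigma <- conn[[1]]
  ref_orders <- new.env(hash = TRUE)
  for (k in seq_len(nrow(reference$bonds)))
    assign(paste(reference$bonds$i[k], reference$bonds$j[k]),
           reference$bonds$order[k], ref_orders)
  bonds <- observed$bonds
  for (k in seq_len(nrow(bonds))) {
    a <- sigma[bonds$i[k]]; b <- sigma[bonds$j[k]]
    key <- paste(min(a, b), max(a, b))
    if (exists(key, ref_orders)) bonds$order[k] <- get(key, ref_orders)
  }
  retried <- molecule_record(observed$mol_id, observed$elements, bonds,
                             observed$charges, observed$chiral, observed$ez)
  iso2 <- .cb_isomorphisms(retried, reference)
  hit <- pick_stereo(retried, iso2, TRUE)
  if (!is.null(hit)) return(hit)
  fail(if (length(iso2)) "stereochemistry mismatch" else "no graph match",
       retry = TRUE)
}

#' @export
print.cb_match <- function(x, ...) {
  if (x$complete)
    cat(sprintf("<cb_match: complete, %d atoms%s>\n", nrow(x$pairs),
                if (x$used_template_retry) ", via template retry" else ""))
  else cat(sprintf("<cb_match: FAILED (%s)>\n", x$reason))
  invisible(x)
}
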