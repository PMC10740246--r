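# Hashed circular (Morgan-style) fingerprints and Tanimoto similarity,
# plus Bemis-Murcko scaffold extraction. The fingerprint is a standard
# ECFP-like construction: iterated neighbourhood hashing of atom
# invariants, folded into a fixed-width bit vector.

#' Circular fingerprint of a molecule
#'
#' ECFP-style hashed fingerprint. Initial atom invariants combine element,
#' degree, formal charge, implicit hydrogen count and ring membership
#' (plus the tetrahedral parity tag when `use_chirality` is TRUE); each
#' iteration hashes the sorted (bond colour, neighbour invariant) list into
#' a new invariant. All invariants from radius 0 up to `radius` set bits.
#'
#' @param mol a `cb_molecule`.
#' @param radius neighbourhood radius (3 corresponds to ECFP6).
#' @param n_bits fingerprint width.
#' @param use_chirality include tetrahedral parity in the seed invariant.
#' @return Logical vector of length `n_bits`.
#' @export
morgan_fp <- function(mol, radius = 3L, n_bits = 2048L, use_chirality = TRUE) {
  n <- n_heavy_atoms(mol)
  adj <- adjacency_list(mol)
  bcol <- .cb_bond_colors(mol)
  colmap <- new.env(hash = TRUE)
  for (k in seq_len(nrow(mol$bonds)))
    assign(paste(mol$bonds$i[k], mol$bonds$j[k]), bcol[k], colmap)
  bond_col <- function(a, b)
    get(if (a < b) paste(a, b) else paste(b, a), colmap)
  ring <- ring_atom_mask(mol)
  inv <- vapply(seq_len(n), function(a) {
    .cb_hash(c(mol$elements[a], length(adj[[a]]), mol$charges[a],
               implicit_h_count(mol)[a], as.integer(ring[a]),
               if (use_chirality) mol$chiral[a] + 2L else 0L))
  }, 0)
  bits <- logical(n_bits)
  bits[inv %% n_bits + 1] <- TRUE
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (!length(nb)) return(.cb_hash(c(r, inv[a])))
      pairs <- cbind(vapply(nb, bond_col, 0, a = a), inv[nb])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .cb_hash(c(r, inv[a], t(pairs)))
    }, 0)
    bits[inv %% n_bits + 1] <- TRUE
  }
  bits
}

#' Tanimoto similarity between two bit vectors
#'
#' @param a,b logical vectors of equal length.
#' @return Intersection over union; 0 when both are empty.
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them, keeping atoms
#' double-bonded to a retained atom (exocyclic carbonyls and the like).
#' Acyclic molecules have no ring scaffold; following the package's
#' convention they return the whole molecule, so that every molecule
#' belongs to a well-defined scaffold cluster.
#'
#' @param mol a `cb_molecule`.
#' @return A `cb_molecule` holding the scaffold (atom indices re-numbered).
#' @export
murcko_scaffold <- function(mol) {
  n <- n_heavy_atoms(mol)
  ring <- ring_atom_mask(mol)
  if (!any(ring)) return(mol)
  keep <- rep(TRUE, n)
  repeat {
    deg <- numeric(n)
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (keep[i] && keep[j]) { deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1 }
    }
    prune <- which(keep & !ring & deg <= 1)
    if (!length(prune)) break
    keep[prune] <- FALSE
  }
  # restore substituents attached by a double/triple bond to a kept atom
  repeat {
    added <- FALSE
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] < 2) next
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (keep[i] != keep[j]) { keep[i] <- keep[j] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }
  idx <- which(keep)
  map <- match(seq_len(n), idx)
  kb <- mol$bonds[keep[mol$bonds$i] & keep[mol$bonds$j], , drop = FALSE]
  kb$i <- map[kb$i]; kb$j <- map[kb$j]
  molecule_record(paste0(mol$mol_id, "_scaffold"), mol$elements[idx], kb,
                  mol$charges[idx], mol$chiral[idx])
}
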