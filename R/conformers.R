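# Conformer ensembles: seeded distance-geometry generation, torsion
# manipulation, symmetry-aware overlaid heavy-atom RMSD (ARMSD), the
# ARMSD_bio labelling that the whole package revolves around.

#' Graph automorphisms of a molecule
#'
#' All permutations of the heavy-atom graph preserving element, formal
#' charge and normalized bond colour. Enumeration is capped; if the cap is
#' hit, the truncated list is returned with attribute `capped = TRUE`.
#'
#' @param mol a `cb_molecule`.
#' @param cap maximum number of automorphisms to enumerate.
#' @return List of integer index maps (identity first).
#' @export
molecule_automorphisms <- function(mol, cap = 10000L) {
  cached <- attr(mol, ".autos")
  if (!is.null(cached)) return(cached)
  autos <- .cb_isomorphisms(mol, mol, use_bond_colors = TRUE, cap = cap)
  idx <- which(vapply(autos, function(s) all(s == seq_along(s)), TRUE))
  if (length(idx)) autos <- c(autos[idx], autos[-idx])
  attr(autos, "capped") <- length(autos) >= cap
  autos
}

mol_with_autos <- function(mol, cap = 10000L) {
  if (is.null(attr(mol, ".autos")))
    attr(mol, ".autos") <- molecule_automorphisms(mol, cap)
  mol
}

# Optimal proper-rotation superposition (Kabsch). Reflections are excluded,
# preserving chirality during comparison.
.cb_kabsch_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
}

#' Symmetry-aware overlaid heavy-atom RMSD between two conformers
#'
#' The minimum over graph automorphisms of the heavy-atom RMSD after optimal
#' rigid superposition (proper rotations only). Symmetric in its arguments
#' and invariant under rigid motion of either input.
#'
#' @param a,b `cb_conformer` records (or coordinate matrices) of the same
#'   molecule.
#' @param mol the shared `cb_molecule`; when `NULL`, only the identity atom
#'   mapping is used.
#' @return ARMSD in Angstrom.
#' @export
armsd <- function(a, b, mol = NULL) {
  A <- if (inherits(a, "cb_conformer")) a$coords else as.matrix(a)
  B <- if (inherits(b, "cb_conformer")) b$coords else as.matrix(b)
  if (nrow(A) != nrow(B)) stop("atom-count mismatch: ", nrow(A), " vs ", nrow(B))
  autos <- if (is.null(mol)) list(seq_len(nrow(A)))
           else molecule_automorphisms(mol)
  .cb_armsd_pair_cpp(A, B, autos)
}

#' ARMSD to the closest bioactive conformation
#'
#' @param conf a generated `cb_conformer`.
#' @param bioactive non-empty list of bioactive `cb_conformer` references.
#' @param mol the shared `cb_molecule` (for symmetry-aware comparison).
#' @return Minimum [armsd()] over the bioactive references, in Angstrom.
#' @export
armsd_bio <- function(conf, bioactive, mol = NULL) {
  if (!length(bioactive)) stop("bioactive reference list is empty")
  min(vapply(bioactive, function(b) armsd(conf, b, mol), 0))
}

#' Classify a conformer by its ARMSD_bio
#'
#' Conformers below 1 Angstrom from the closest bioactive conformation are
#' bioactive-like, above 2.5 Angstrom non-bioactive, and intermediate
#' otherwise; both inequalities are strict, so the boundary values
#' themselves are intermediate.
#'
#' @param armsd_bio non-negative ARMSD_bio value(s) in Angstrom.
#' @param bio_like,non_bio class thresholds in Angstrom.
#' @return Character vector in `c("bio_like", "intermediate", "non_bio")`.
#' @export
classify_conformer <- function(armsd_bio, bio_like = 1.0, non_bio = 2.5) {
  if (any(armsd_bio < 0)) stop("ARMSD_bio must be non-negative")
  ifelse(armsd_bio < bio_like, "bio_like",
         ifelse(armsd_bio > non_bio, "non_bio", "intermediate"))
}

#' Label a generated ensemble against its bioactive references
#'
#' Computes ARMSD_bio and the three-way class label for every generated
#' conformer, and flags whether the ensemble retrieves a bioactive
#' conformation (minimum ARMSD_bio below the bioactive-like threshold).
#'
#' @param mol a `cb_molecule`.
#' @param generated non-empty list of generated `cb_conformer`.
#' @param bioactive non-empty list of bioactive `cb_conformer`.
#' @param bio_like,non_bio class thresholds in Angstrom.
#' @return An object of class `cb_ensemble` with fields `mol`, `conformers`,
#'   `bioactive`, `armsd_bio`, `labels`, `retrieved`.
#' @export
build_labelled_ensemble <- function(mol, generated, bioactive,
                                    bio_like = 1.0, non_bio = 2.5) {
  if (!length(generated)) stop("generated conformer list is empty")
  if (!length(bioactive)) stop("bioactive reference list is empty")
  mol <- mol_with_autos(mol)
  ab <- as.numeric(.cb_armsd_min_cpp(lapply(generated, `[[`, "coords"),
                                     lapply(bioactive, `[[`, "coords"),
                                     molecule_automorphisms(mol)))
  structure(list(mol = mol, conformers = generated, bioactive = bioactive,
                 armsd_bio = ab,
                 labels = classify_conformer(ab, bio_like, non_bio),
                 retrieved = min(ab) < bio_like),
            class = "cb_ensemble")
}

#' @export
print.cb_ensemble <- function(x, ...) {
  cat(sprintf(
    "<cb_ensemble %s: %d generated, %d bioactive, %d bio-like / %d non-bio%s>\n",
    x$mol$mol_id, length(x$conformers), length(x$bioactive),
    sum(x$labels == "bio_like"), sum(x$labels == "non_bio"),
    if (x$retrieved) ", retrieved" else ""))
  invisible(x)
}

# ---- torsions -------------------------------------------------------------

#' Rotatable bonds of a molecule
#'
#' Acyclic single bonds whose two ends each carry at least one further heavy
#' neighbour.
#'
#' @param mol a `cb_molecule`.
#' @return data.frame with columns `a`, `b`.
#' @export
rotatable_bonds <- function(mol) {
  deg <- degree_vec(mol)
  rb <- ring_bond_mask(mol)
  keep <- mol$bonds$order == 1 & !rb & deg[mol$bonds$i] >= 2 & deg[mol$bonds$j] >= 2
  data.frame(a = mol$bonds$i[keep], b = mol$bonds$j[keep])
}

#' Torsion quadruples over the rotatable bonds
#'
#' One dihedral (na, a, b, nb) per rotatable bond; the reference neighbours
#' are chosen deterministically, either by highest canonical rank
#' (`"rank"`, the default) or lowest atom index (`"index"`, which is stable
#' across molecules sharing a common atom numbering).
#'
#' @param mol a `cb_molecule`.
#' @param convention `"rank"` or `"index"`.
#' @return data.frame with columns `na`, `a`, `b`, `nb`.
#' @export
torsion_quadruples <- function(mol, convention = c("rank", "index")) {
  convention <- match.arg(convention)
  rot <- rotatable_bonds(mol)
  adj <- adjacency_list(mol)
  ranks <- canonical_ranks(mol)
  pick <- function(nb) {
    if (convention == "rank") nb[order(-ranks[nb], nb)][1] else min(nb)
  }
  na <- integer(nrow(rot)); nbv <- integer(nrow(rot))
  for (k in seq_len(nrow(rot))) {
    na[k] <- pick(setdiff(adj[[rot$a[k]]], rot$b[k]))
    nbv[k] <- pick(setdiff(adj[[rot$b[k]]], rot$a[k]))
  }
  data.frame(na = na, a = rot$a, b = rot$b, nb = nbv)
}

#' Measure a torsion angle
#'
#' @param coords N x 3 coordinate matrix.
#' @param quad one row of [torsion_quadruples()] (or a length-4 index vector).
#' @return Dihedral angle in degrees, in (-180, 180].
#' @export
get_torsion <- function(coords, quad) {
  q <- as.integer(unlist(quad)[1:4])
  .cb_dihedral(coords[q[1], ], coords[q[2], ], coords[q[3], ], coords[q[4], ])
}

#' Set a torsion angle by rotating one side of a rotatable bond
#'
#' Atoms on the `b` side of the (a, b) bond are rotated about the bond axis
#' so the dihedral defined by `quad` becomes `angle_deg`.
#'
#' @param mol molecule supplying connectivity.
#' @param coords N x 3 coordinate matrix.
#' @param quad length-4 torsion definition (na, a, b, nb).
#' @param angle_deg target dihedral in degrees.
#' @return The modified coordinate matrix.
#' @export
set_torsion <- function(mol, coords, quad, angle_deg) {
  q <- as.integer(unlist(quad)[1:4])
  a <- q[2]; b <- q[3]
  g <- mol_graph(mol)
  eid <- igraph::get_edge_ids(g, c(a, b))
  if (eid == 0) stop("atoms ", a, " and ", b, " are not bonded")
  g2 <- igraph::delete_edges(g, eid)
  comp <- igraph::components(g2)
  if (comp$membership[a] == comp$membership[b])
    stop("bond ", a, "-", b, " lies in a ring; torsion cannot be driven")
  side <- setdiff(which(comp$membership == comp$membership[b]), b)
  cur <- get_torsion(coords, q)
  # rotating the b-side by +delta about the a->b axis decreases the
  # measured dihedral under this sign convention
  delta <- (cur - angle_deg) * pi / 180
  u <- coords[b, ] - coords[a, ]
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(delta) * K + (1 - cos(delta)) * (K %*% K)
  if (length(side)) {
    shifted <- sweep(coords[side, , drop = FALSE], 2, coords[b, ])
    coords[side, ] <- sweep(shifted %*% t(R), 2, coords[b, ], "+")
  }
  coords
}

# ---- generation -----------------------------------------------------------

.cb_python_helper <- function() {
  path <- system.file("python", "etkdg_embed.py", package = "confbias")
  if (!nzchar(path)) stop("embedding helper script not found")
  path
}

#' Generate conformer ensembles for a batch of molecules
#'
#' Conformers are embedded with a seeded knowledge-based distance-geometry
#' generator (ETKDG, with experimental torsion terms) and near-duplicate
#' geometries are pruned at 0.05 Angstrom, so rigid molecules yield small
#' ensembles while flexible ones fill the requested budget. The generator's
#' native output order is recorded as `gen_order`. Identical seeds produce
#' bitwise-identical coordinates.
#'
#' @param smiles character vector of input structures.
#' @param mol_ids identifiers, same length as `smiles`.
#' @param max_n maximum ensemble size per molecule.
#' @param seed master seed; per-molecule seeds are derived from it.
#' @return Named list per molecule: `mol` (graph read back from the embedded
#'   geometry, hydrogens stripped) and `conformers`. Molecules that fail to
#'   embed are reported in attribute `failures` and omitted.
#' @export
generate_conformer_ensembles <- function(smiles, mol_ids, max_n = 250L,
                                         seed = 1L) {
  stopifnot(length(smiles) == length(mol_ids), max_n >= 1L)
  job <- tempfile(fileext = ".json"); out <- tempfile(fileext = ".sdf")
  stat <- tempfile(fileext = ".json")
  on.exit(unlink(c(job, out, stat)))
  mols <- lapply(seq_along(smiles), function(k) {
    list(mol_id = mol_ids[k], smiles = smiles[k], max_n = max_n,
         seed = derive_seed(seed, k))
  })
  jsonlite::write_json(list(out = out, status = stat, prune_rms = 0.05,
                            molecules = mols),
                       job, auto_unbox = TRUE)
  status <- system2(.cb_tool("python"), c(.cb_python_helper(), job),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(stat))
    stop("conformer embedding helper failed")
  report <- jsonlite::read_json(stat)
  failures <- Filter(function(r) r$n == 0, report)
  ensembles <- if (file.size(out) > 0) read_sdf_ensembles(out) else list()
  ensembles <- ensembles[intersect(mol_ids, names(ensembles))]
  attr(ensembles, "failures") <- vapply(failures, function(r) r$mol_id, "")
  ensembles
}

#' Generate conformers for one molecule
#'
#' Batch wrapper around [generate_conformer_ensembles()] that maps the
#' generated coordinates back onto the atom order of `mol` through a graph
#' isomorphism.
#'
#' @param mol a `cb_molecule` whose `smiles` field is set.
#' @param max_n maximum ensemble size.
#' @param seed integer seed.
#' @return List of `cb_conformer` in generation order; raises a
#'   generation-failure error if embedding fails.
#' @export
generate_conformers <- function(mol, max_n = 250L, seed = 1L) {
  if (is.na(mol$smiles)) stop("molecule ", mol$mol_id, " carries no SMILES")
  res <- generate_conformer_ensembles(mol$smiles, mol$mol_id, max_n, seed)
  if (!length(res)) stop("conformer generation failed for ", mol$mol_id)
  gen <- res[[1]]
  sigma <- .cb_isomorphisms(mol, gen$mol)
  if (!length(sigma))
    stop("generated structure does not match input graph for ", mol$mol_id)
  s <- sigma[[1]]
  lapply(gen$conformers, function(cf) {
    cf$coords <- cf$coords[s, , drop = FALSE]
    cf
  })
}
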