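# Train/validation/test partitioning: seeded random splits by molecule, and
# scaffold-cluster splits that keep chemically related molecules on one side
# of the partition and weight cluster assignment by conformation counts.

.cb_check_ratios <- function(ratios) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9, all(ratios > 0))
}

#' Random molecule split
#'
#' Shuffles molecule ids with the given seed, then slices the shuffled list
#' by cumulative ratio (floors on the subset boundaries, remainder to
#' test).
#'
#' @param mol_ids character vector of unique molecule ids (at least 3).
#' @param ratios train/validation/test fractions summing to one.
#' @param seed integer seed; identical seeds give identical assignments.
#' @return An object of class `cb_split`: `split_type`, `seed`, and
#'   `assignment`, a named character vector mapping mol_id to
#'   `"train"`/`"val"`/`"test"`.
#' @export
random_split <- function(mol_ids, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  .cb_check_ratios(ratios)
  if (length(mol_ids) < 3L) stop("need at least 3 molecules to split")
  if (anyDuplicated(mol_ids)) stop("duplicate molecule ids")
  shuffled <- with_seed(seed, sample(mol_ids))
  n <- length(shuffled)
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  assignment <- stats::setNames(
    rep(c("train", "val", "test"), c(n_train, n_val, n - n_train - n_val)),
    shuffled)
  structure(list(split_type = "random", seed = as.integer(seed),
                 assignment = assignment[mol_ids]),
            class = "cb_split")
}

#' Cluster scaffold fingerprints at 50 percent minimum similarity
#'
#' Complete-linkage agglomerative clustering on Tanimoto distance
#' (1 - similarity) cut at 0.5. Under complete linkage the cut height
#' bounds the cluster diameter, so every within-cluster pair is at least
#' 50 percent similar.
#'
#' @param fps list of fingerprint bit vectors.
#' @return Integer cluster labels.
#' @export
cluster_scaffold_fps <- function(fps) {
  n <- length(fps)
  if (n == 1L) return(1L)
  mat <- do.call(rbind, lapply(fps, as.numeric))
  inter <- tcrossprod(mat)
  ones <- rowSums(mat)
  union <- outer(ones, ones, "+") - inter
  sim <- ifelse(union > 0, inter / union, 0)
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "complete")
  stats::cutree(hc, h = 0.5 - 1e-9)
}

#' Scaffold-cluster split weighted by conformation counts
#'
#' Pipeline: Bemis-Murcko scaffold per molecule, circular fingerprint
#' (radius 3) of the scaffold, complete-linkage clustering on Tanimoto
#' distance cut at 0.5, then whole clusters are assigned in seeded random
#' order to the training subset until it covers at least `ratios[1]` of the
#' total conformation count, to validation until `ratios[1] + ratios[2]`,
#' and the remainder to test.
#'
#' @param mols list of `cb_molecule`.
#' @param weights per-molecule conformation counts (same order as `mols`).
#' @param ratios cumulative fill targets for train/val/test.
#' @param seed integer seed.
#' @return A `cb_split` whose attribute `clusters` maps mol_id to cluster
#'   label.
#' @export
scaffold_split <- function(mols, weights = NULL, ratios = c(0.8, 0.1, 0.1),
                           seed = 1L) {
  .cb_check_ratios(ratios)
  mol_ids <- vapply(mols, function(m) m$mol_id, "")
  if (anyDuplicated(mol_ids)) stop("duplicate molecule ids")
  if (is.null(weights)) weights <- rep(1, length(mols))
  stopifnot(length(weights) == length(mols), all(weights > 0))
  fps <- lapply(mols, function(m) morgan_fp(murcko_scaffold(m)))
  clusters <- cluster_scaffold_fps(fps)
  ids <- unique(clusters)
  order_ids <- with_seed(seed, sample(ids))
  wt <- vapply(order_ids, function(cl) sum(weights[clusters == cl]), 0)
  total <- sum(wt)
  # keep filling a subset until its cumulative target is reached, then move on
  filled <- 0; stage <- 1L
  targets <- cumsum(ratios) * total
  subset_of <- character(length(order_ids))
  labels <- c("train", "val", "test")
  for (k in seq_along(order_ids)) {
    while (stage < 3L && filled >= targets[stage] - 1e-9) stage <- stage + 1L
    subset_of[k] <- labels[stage]
    filled <- filled + wt[k]
  }
  assignment <- stats::setNames(
    subset_of[match(clusters, order_ids)], mol_ids)
  structure(list(split_type = "scaffold", seed = as.integer(seed),
                 assignment = assignment),
            class = "cb_split", clusters = stats::setNames(clusters, mol_ids))
}

#' @export
print.cb_split <- function(x, ...) {
  tab <- table(factor(x$assignment, c("train", "val", "test")))
  cat(sprintf("<cb_split %s seed %d: train %d / val %d / test %d>\n",
              x$split_type, x$seed, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Write split assignments as TSV
#'
#' @param splits list of `cb_split`.
#' @param path output path.
#' @return The table, invisibly.
#' @export
write_split_table <- function(splits, path) {
  tab <- do.call(rbind, lapply(splits, function(s) {
    data.frame(mol_id = names(s$assignment), split_type = s$split_type,
               seed = s$seed, subset = unname(s$assignment))
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
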