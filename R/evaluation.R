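# Ranking evaluation: regression metrics, BEDROC early enrichment,
# eligibility and hard-subset filters, aggregation and top-fraction
# selection.

#' Regression metrics for predicted vs true ARMSD_bio
#'
#' @param predictions,truths numeric vectors of equal non-zero length.
#' @return List with `rmse` and `r_squared` (the coefficient of
#'   determination about the truth mean). `r_squared` is `NA` with a warning
#'   when the truths have zero variance.
#' @export
regression_metrics <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) > 0)
  rmse <- sqrt(mean((predictions - truths)^2))
  ss_tot <- sum((truths - mean(truths))^2)
  if (ss_tot == 0) {
    warning("zero-variance truths: r_squared undefined")
    return(list(rmse = rmse, r_squared = NA_real_))
  }
  list(rmse = rmse, r_squared = 1 - sum((predictions - truths)^2) / ss_tot)
}

#' Is an ensemble eligible for ranking evaluation?
#'
#' A molecule is evaluated only when it has at least one bioactive-like
#' conformer and is not made up exclusively of bioactive-like conformers
#' (ranking would be pointless in either case).
#'
#' @param ensemble a `cb_ensemble`.
#' @return Logical flag.
#' @export
eligible_for_ranking <- function(ensemble) {
  n_bio <- sum(ensemble$labels == "bio_like")
  n_bio >= 1L && n_bio < length(ensemble$labels)
}

#' Scale a 1-based rank into (0, 1]
#'
#' @param rank 1-based integer rank(s).
#' @param n_conformers ensemble size.
#' @return `rank / n_conformers`.
#' @export
scaled_rank <- function(rank, n_conformers) {
  if (any(rank < 1L | rank > n_conformers))
    stop("rank out of range 1..", n_conformers)
  rank / n_conformers
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Truchon-Bayly formulation on an ordered binary label sequence: with N
#' items and n positives at 1-based ranks r_i,
#' RIE = mean(exp(-alpha r_i / N)) * N * (exp(alpha/N) - 1) / (1 - exp(-alpha)),
#' and BEDROC maps RIE into \[0, 1\] using Ra = n / N.
#'
#' @param ordered_labels logical/0-1 vector in rank order (first = best).
#' @param alpha early-enrichment exponent; 20 concentrates 80\% of the score
#'   mass in the top 8\% of ranks.
#' @return BEDROC in \[0, 1\]; `NA` with a warning when the labels are all
#'   positive or all negative (undefined metric).
#' @export
bedroc <- function(ordered_labels, alpha = 20) {
  y <- as.logical(ordered_labels)
  N <- length(y); n <- sum(y)
  if (n == 0L || n == N) {
    warning("BEDROC undefined: labels are all ",
            if (n == 0L) "negative" else "positive")
    return(NA_real_)
  }
  r <- which(y)
  ra <- n / N
  rie <- mean(exp(-alpha * r / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Cumulative exponential rank-weight fraction
#'
#' Fraction of the BEDROC exponential weight mass contained in the top
#' `top_fraction` of ranks: (1 - exp(-alpha x)) / (1 - exp(-alpha)).
#' Documents the alpha choice (alpha = 20 puts 80\% of the mass in the top
#' 8\%).
#'
#' @param alpha positive exponent.
#' @param top_fraction fraction of the ranked list, in \[0, 1\].
#' @return Weight fraction in \[0, 1\].
#' @export
exponential_weight_fraction <- function(alpha, top_fraction) {
  stopifnot(alpha > 0, all(top_fraction >= 0 & top_fraction <= 1))
  (1 - exp(-alpha * top_fraction)) / (1 - exp(-alpha))
}

#' BEDROC of bioactive-like and of non-bioactive conformers under a ranking
#'
#' Evaluates one ranking twice: positives = bioactive-like conformers
#' (early enrichment) and positives = non-bioactive conformers (early
#' impoverishment when low). Intermediate conformers count as negatives on
#' both sides. A side whose positive set is empty or spans the whole
#' ensemble is reported as `NA`.
#'
#' @param ranking a `cb_ranking` (see [baselines]).
#' @param ensemble the labelled `cb_ensemble` the ranking refers to.
#' @param alpha BEDROC exponent.
#' @return List with `bedroc_bio_like`, `bedroc_non_bio`,
#'   `scaled_rank_first_bio_like`, `scaled_rank_first_non_bio`.
#' @export
bedroc_pair <- function(ranking, ensemble, alpha = 20) {
  labels <- ensemble$labels[match(ranking$order,
                                  vapply(ensemble$conformers,
                                         function(cf) cf$conf_id, 0L))]
  n <- length(labels)
  side <- function(cls) {
    pos <- labels == cls
    if (!any(pos) || all(pos))
      return(list(bedroc = NA_real_, first = NA_real_))
    list(bedroc = suppressWarnings(bedroc(pos, alpha)),
         first = scaled_rank(which(pos)[1], n))
  }
  b <- side("bio_like"); nb <- side("non_bio")
  list(bedroc_bio_like = b$bedroc, bedroc_non_bio = nb$bedroc,
       scaled_rank_first_bio_like = b$first,
       scaled_rank_first_non_bio = nb$first)
}

#' Flag the hard-to-rank subset
#'
#' True for molecules with a full-size generated ensemble and under 5
#' percent bioactive-like conformers, for which chance retrieval in early
#' ranks is unlikely.
#'
#' @param ensemble a `cb_ensemble`.
#' @param max_n required ensemble size.
#' @param frac_threshold bioactive-like fraction bound (strict).
#' @return Logical flag.
#' @export
hard_subset_flag <- function(ensemble, max_n = 250L, frac_threshold = 0.05) {
  n <- length(ensemble$labels)
  n == max_n && mean(ensemble$labels == "bio_like") < frac_threshold
}

#' Bin an MCS size into decades of heavy atoms
#'
#' @param n_heavy non-negative MCS size(s).
#' @return Half-open bin labels such as `"[20, 30["`.
#' @export
mcs_size_bin <- function(n_heavy) {
  stopifnot(all(n_heavy >= 0))
  lo <- 10 * (n_heavy %/% 10)
  sprintf("[%d, %d[", lo, lo + 10)
}

#' Select the top-ranked fraction of a ranking
#'
#' @param ranking a `cb_ranking`.
#' @param fraction in (0, 1]; the selection is `ceiling(fraction * n)`
#'   conformers, at least one.
#' @return Vector of selected `conf_id`s, best first.
#' @export
select_top_fraction <- function(ranking, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(ranking$order)
  ranking$order[seq_len(max(1L, ceiling(fraction * n)))]
}

#' Evaluate a set of rankers over labelled ensembles
#'
#' @param ensembles named list of `cb_ensemble`.
#' @param rankings list of `cb_ranking` covering those ensembles (any
#'   rankers, any subset of molecules).
#' @param alpha BEDROC exponent.
#' @param hard_max_n,hard_frac hard-subset definition.
#' @param groups optional data.frame (`mol_id`, `group`) of class labels.
#' @return Per-molecule data.frame (one row per molecule x ranker) with
#'   BEDROC and scaled-rank metrics, eligibility and hard-subset flags.
#' @export
evaluate_rankings <- function(ensembles, rankings, alpha = 20,
                              hard_max_n = 250L, hard_frac = 0.05,
                              groups = NULL) {
  rows <- lapply(rankings, function(rk) {
    ens <- ensembles[[rk$mol_id]]
    if (is.null(ens)) return(NULL)
    met <- bedroc_pair(rk, ens, alpha)
    data.frame(mol_id = rk$mol_id, ranker = rk$ranker_name,
               bedroc_bio_like = met$bedroc_bio_like,
               bedroc_non_bio = met$bedroc_non_bio,
               scaled_rank_first_bio_like = met$scaled_rank_first_bio_like,
               scaled_rank_first_non_bio = met$scaled_rank_first_non_bio,
               n_conformers = length(ens$labels),
               frac_bio_like = mean(ens$labels == "bio_like"),
               eligible = eligible_for_ranking(ens),
               hard_subset = hard_subset_flag(ens, hard_max_n, hard_frac))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(groups)) out$group <- groups$group[match(out$mol_id, groups$mol_id)]
  out
}

#' Summarize per-molecule metrics into per-split medians
#'
#' Medians are taken over eligible molecules only. With several splits,
#' the across-split mean and standard deviation of the medians are also
#' reported.
#'
#' @param reports data.frame from [evaluate_rankings()], optionally with a
#'   `split` column; rows from different splits are summarized separately.
#' @param group_by optional extra grouping column names (e.g. `"group"`,
#'   `"hard_subset"`).
#' @return List with `medians` (one row per split x ranker x group) and
#'   `across_splits` (mean +/- sd of the medians per ranker x group).
#' @export
summarize_eval <- function(reports, group_by = character(0)) {
  if (!"split" %in% names(reports)) reports$split <- 1L
  metrics <- c("bedroc_bio_like", "bedroc_non_bio",
               "scaled_rank_first_bio_like", "scaled_rank_first_non_bio")
  keys <- c("split", "ranker", group_by)
  el <- reports[reports$eligible, , drop = FALSE]
  if (!nrow(el)) stop("no eligible molecules to summarize")
  fac <- interaction(el[keys], drop = TRUE, lex.order = TRUE)
  med <- do.call(rbind, lapply(split(el, fac), function(d) {
    cbind(d[1, keys, drop = FALSE],
          n_molecules = nrow(d),
          as.data.frame(lapply(d[metrics], stats::median, na.rm = TRUE)))
  }))
  rownames(med) <- NULL
  keys2 <- setdiff(keys, "split")
  fac2 <- interaction(med[keys2], drop = TRUE, lex.order = TRUE)
  across <- do.call(rbind, lapply(split(med, fac2), function(d) {
    out <- d[1, keys2, drop = FALSE]
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    out
  }))
  rownames(across) <- NULL
  list(medians = med, across_splits = across)
}
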