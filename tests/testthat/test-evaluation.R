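# Regression metrics, BEDROC and the evaluation filters.

test_that("regression metrics follow their closed forms", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(rmse = 0, r_squared = 1))
  # constant prediction at the truth mean explains nothing
  expect_equal(regression_metrics(rep(2, 3), c(1, 2, 3))$r_squared, 0)
  m <- regression_metrics(c(1, 2, 5), c(1, 2, 3))
  expect_equal(m$rmse, sqrt(4 / 3))
  expect_equal(m$r_squared, -1)
  expect_warning(regression_metrics(c(1, 2), c(5, 5)), "zero-variance")
})

test_that("eligibility requires some but not only bioactive-like conformers", {
  expect_false(eligible_for_ranking(fake_ensemble(rep("non_bio", 10))))
  expect_false(eligible_for_ranking(fake_ensemble(rep("bio_like", 10))))
  expect_true(eligible_for_ranking(
    fake_ensemble(c(rep("bio_like", 2), rep("non_bio", 8)))))
})

test_that("scaled ranks map 1..n onto (0, 1]", {
  expect_equal(scaled_rank(5, 250), 0.02)
  expect_equal(scaled_rank(250, 250), 1)
  expect_error(scaled_rank(0, 10), "out of range")
  expect_error(scaled_rank(11, 10), "out of range")
  expect_true(all(diff(scaled_rank(1:50, 50)) > 0))
})

test_that("bedroc agrees with a direct-summation oracle", {
  set.seed(42)
  for (k in 1:1000) {
    N <- sample(10:300, 1)
    n <- sample(seq_len(N - 1), 1)
    labels <- logical(N)
    labels[sample(N, n)] <- TRUE
    expect_equal(bedroc(labels), bedroc_oracle(labels), tolerance = 1e-9)
  }
})

test_that("bedroc behaves at the extremes and stays within [0, 1]", {
  perfect <- c(rep(TRUE, 5), rep(FALSE, 95))
  worst <- rev(perfect)
  expect_gt(bedroc(perfect), 0.95)
  expect_lt(bedroc(worst), 0.01)
  set.seed(1)
  for (k in 1:50) {
    labels <- sample(perfect)
    v <- bedroc(labels)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_warning(v <- bedroc(rep(TRUE, 5)), "all positive")
  expect_true(is.na(v))
  expect_warning(bedroc(rep(FALSE, 5)), "all negative")
})

test_that("bedroc never improves when a positive moves to a later rank", {
  # exhaustive over all single-positive-swap neighbours, N <= 7
  for (N in 5:7) {
    for (n in c(1, 2, 3)) {
      set.seed(N * 10 + n)
      labels <- logical(N); labels[sample(N, n)] <- TRUE
      base <- bedroc(labels)
      for (i in which(labels)) for (j in which(!labels)) {
        if (j < i) next
        swapped <- labels; swapped[i] <- FALSE; swapped[j] <- TRUE
        expect_lte(bedroc(swapped), base + 1e-12)
      }
    }
  }
})

test_that("the exponential weight mass is concentrated as advertised", {
  expect_equal(exponential_weight_fraction(20, 0.08), 0.80, tolerance = 0.005)
  expect_equal(exponential_weight_fraction(20, 1), 1)
  # alpha -> 0 approaches uniform weights
  expect_equal(exponential_weight_fraction(1e-9, 0.3), 0.3, tolerance = 1e-6)
  x <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(exponential_weight_fraction(20, x)) > 0))
  expect_true(all(exponential_weight_fraction(30, x) >
                    exponential_weight_fraction(10, x)))
})

test_that("bedroc_pair scores both label classes from one ranking", {
  labels <- c("bio_like", "non_bio", "intermediate", "non_bio", "bio_like",
              "non_bio")
  ens <- fake_ensemble(labels)
  oracle <- ranking_result("fake", "oracle", order(ens$armsd_bio), sort(ens$armsd_bio))
  met <- bedroc_pair(oracle, ens)
  # oracle ranking is maximal for bio-like and minimal for non-bio over all
  # permutations of this 6-conformer ensemble
  perms <- expand.grid(rep(list(1:6), 6))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  all_bio <- apply(perms, 1, function(p) {
    suppressWarnings(bedroc_pair(ranking_result("fake", "x", as.integer(p),
                                                seq_len(6)), ens)$bedroc_bio_like)
  })
  all_non <- apply(perms, 1, function(p) {
    suppressWarnings(bedroc_pair(ranking_result("fake", "x", as.integer(p),
                                                seq_len(6)), ens)$bedroc_non_bio)
  })
  expect_equal(met$bedroc_bio_like, max(all_bio))
  expect_equal(met$bedroc_non_bio, min(all_non))
  # reversed oracle maximizes the non-bio side
  rev_rank <- ranking_result("fake", "rev", rev(oracle$order), seq_len(6))
  expect_equal(bedroc_pair(rev_rank, ens)$bedroc_non_bio, max(all_non))
  expect_equal(met$scaled_rank_first_bio_like, 1 / 6)
})

test_that("hard subset and MCS bins follow their definitions", {
  labs250 <- c(rep("bio_like", 10), rep("non_bio", 240))
  expect_true(hard_subset_flag(fake_ensemble(labs250)))          # 4% of 250
  labs13 <- c(rep("bio_like", 13), rep("non_bio", 237))
  expect_false(hard_subset_flag(fake_ensemble(labs13)))          # 5.2%
  labs180 <- c(rep("bio_like", 2), rep("non_bio", 178))
  expect_false(hard_subset_flag(fake_ensemble(labs180)))         # not full
  expect_identical(mcs_size_bin(30), "[30, 40[")
  expect_identical(mcs_size_bin(0), "[0, 10[")
  expect_false(mcs_size_bin(39) == mcs_size_bin(40))
})

test_that("top-fraction selection uses a ceiling with minimum one", {
  rk <- ranking_result("m", "x", 1:250, seq_len(250))
  expect_length(select_top_fraction(rk, 0.20), 50L)
  expect_length(select_top_fraction(rk, 0.01), 3L)     # ceil(2.5)
  expect_length(select_top_fraction(rk, 1.0), 250L)
  tiny <- ranking_result("m", "x", 1:3, 1:3)
  expect_length(select_top_fraction(tiny, 0.01), 1L)
})

test_that("summaries are medians over eligible molecules, order-invariant", {
  rows <- do.call(rbind, lapply(1:5, function(k) {
    data.frame(mol_id = paste0("m", k), ranker = "r",
               bedroc_bio_like = c(0.1, 0.2, 0.9, 0.4, 0.5)[k],
               bedroc_non_bio = 0.3, scaled_rank_first_bio_like = 0.1,
               scaled_rank_first_non_bio = 0.5, n_conformers = 10,
               frac_bio_like = 0.2, eligible = k != 5, hard_subset = FALSE)
  }))
  s <- summarize_eval(rows)
  expect_equal(s$medians$bedroc_bio_like, median(c(0.1, 0.2, 0.9, 0.4)))
  expect_equal(s$medians$n_molecules, 4L)
  shuffled <- rows[sample(nrow(rows)), ]
  expect_equal(summarize_eval(shuffled)$medians$bedroc_bio_like,
               s$medians$bedroc_bio_like)
  one <- summarize_eval(rows[3, ])
  expect_equal(one$medians$bedroc_bio_like, 0.9)
})
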