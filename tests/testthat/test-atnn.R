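# The distance-only atomistic network: graph construction, basis functions,
# invariances, gradients and the training loop.

desk <- model_config(preset = "desk")

test_that("distance graphs match a brute-force pairwise filter", {
  g <- build_graph(cbind(c(0, 3), 0, 0), c(6L, 6L), cutoff = 10)
  expect_equal(nrow(g$edges), 2L)
  g0 <- build_graph(cbind(c(0, 12), 0, 0), c(6L, 6L), cutoff = 10)
  expect_equal(nrow(g0$edges), 0L)
  set.seed(4)
  coords <- matrix(stats::rnorm(60, sd = 4), 20, 3)
  g <- build_graph(coords, rep(6L, 20), cutoff = 6)
  want <- which(as.matrix(stats::dist(coords)) <= 6 &
                  !diag(TRUE, 20), arr.ind = TRUE)
  got <- paste(g$edges[, 1], g$edges[, 2])
  expect_setequal(got, paste(want[, 1], want[, 2]))
  expect_equal(g$dist, sqrt(rowSums((coords[g$edges[, 1], ] -
                                       coords[g$edges[, 2], ])^2)))
  # single atom: a valid graph with no edges
  g1 <- build_graph(matrix(0, 1, 3), 6L, cutoff = 5)
  expect_equal(nrow(g1$edges), 0L)
})

test_that("radial basis values match a per-component scalar oracle", {
  mu <- seq(0, 10, length.out = 50)
  phi <- rbf_expand(2.0, 50, 10)
  gamma <- 1 / (2 * (mu[2] - mu[1])^2)
  expect_equal(as.numeric(phi), exp(-gamma * (2.0 - mu)^2), tolerance = 1e-12)
  # exactly 1 at a centre
  expect_equal(rbf_expand(mu[7], 50, 10)[7], 1)
  # midway between adjacent centres the two components are equal
  mid <- (mu[3] + mu[4]) / 2
  v <- rbf_expand(mid, 50, 10)
  expect_equal(v[3], v[4])
  # mathematically (0, 1]; components far from their centre underflow to 0
  expect_true(all(phi >= 0 & phi <= 1))
  expect_true(all(rbf_expand(2.0, 50, 10)[1:15] > 0))
})

test_that("the forward pass is invariant to rigid motion and permutation", {
  model <- atnn_init(desk, seed = 2)
  set.seed(10)
  z <- sample(c(6L, 7L, 8L, 16L), 12, replace = TRUE)
  coords <- matrix(stats::rnorm(36, sd = 3), 12, 3)
  y <- atnn_predict(model, list(coords), z)
  moved <- coords %*% random_rotation() +
    matrix(c(5, -3, 2), 12, 3, byrow = TRUE)
  expect_lt(abs(atnn_predict(model, list(moved), z) - y), 1e-5)
  # reflections too: only distances enter
  expect_lt(abs(atnn_predict(model, list(coords %*% diag(c(-1, 1, 1))), z) - y),
            1e-5)
  perm <- sample(12)
  expect_lt(abs(atnn_predict(model, list(coords[perm, ]), z[perm]) - y), 1e-5)
})

test_that("two copies beyond the cutoff give exactly twice the output", {
  tc <- toy$two_copy
  model <- atnn_init(desk, seed = 5)
  y1 <- atnn_predict(model, list(tc$single), tc$z_single)
  y2 <- atnn_predict(model, list(tc$double), tc$z_double)
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})

test_that("unknown atomic numbers raise a vocabulary error", {
  model <- atnn_init(desk, seed = 1)
  expect_error(atnn_predict(model, list(matrix(0, 1, 3)), 99L), "vocabulary")
})

test_that("analytic gradients agree with finite differences", {
  mcfg <- model_config(embed_dim = 6L, n_interactions = 2L, n_rbf = 5L,
                       cutoff = 6, readout_hidden = 4L)
  model <- atnn_init(mcfg, seed = 3)
  set.seed(5)
  samples <- lapply(1:3, function(k)
    confbias:::.cb_prep_sample(sample(c(6L, 7L, 8L), 5, TRUE),
                               matrix(stats::rnorm(15) * 2, 5, 3), mcfg,
                               target = stats::runif(1, 0, 3)))
  batch <- confbias:::.cb_batch(samples)
  bw <- confbias:::.cb_atnn_backward(model, batch)
  eps <- 1e-5
  loss_at <- function(m) mean((confbias:::.cb_atnn_forward(m, batch) -
                                 batch$targets)^2)
  set.seed(17)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      m2 <- model
      m2$params[[nm]][i] <- p[i] + eps; l1 <- loss_at(m2)
      m2$params[[nm]][i] <- p[i] - eps; l0 <- loss_at(m2)
      fd <- (l1 - l0) / (2 * eps)
      an <- bw$grads[[nm]][i]
      # 1e-4 relative agreement on non-negligible components (the floor
      # keeps finite-difference cancellation noise out of the denominator)
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-3), 1e-4)
    }
  }
})

test_that("training learns a smooth geometric target and is reproducible", {
  mcfg <- model_config(embed_dim = 16L, n_interactions = 2L, n_rbf = 10L,
                       cutoff = 8, readout_hidden = 8L)
  # synthetic learnable task: target = scaled mean pairwise distance
  set.seed(11)
  make_sample <- function(k) {
    coords <- matrix(stats::rnorm(15, sd = 1.5), 5, 3)
    confbias:::.cb_prep_sample(rep(6L, 5), coords, mcfg,
                               target = mean(stats::dist(coords)) / 2)
  }
  train <- lapply(1:60, make_sample)
  val <- lapply(1:15, make_sample)
  tcfg <- train_config(learning_rate = 3e-3, max_epochs = 40, patience = 5,
                       batch_size = 16, seed = 9)
  model <- atnn_train(train, val, mcfg, tcfg)
  h <- attr(model, "history")
  # early stopping bookkeeping
  expect_lte(nrow(h), 40L)
  expect_equal(attr(model, "best_epoch"), which.min(h$val_loss))
  expect_lte(nrow(h) - which.min(h$val_loss), 5L)
  # beats the constant-mean predictor on validation data
  targets <- vapply(val, function(s) s$target, 0)
  base_rmse <- sqrt(mean((mean(vapply(train, function(s) s$target, 0)) -
                            targets)^2))
  model_rmse <- sqrt(confbias:::.cb_eval_loss(model, val))
  expect_lt(model_rmse, base_rmse)
  # identical seeds give identical loss histories
  model2 <- atnn_train(train, val, mcfg, tcfg)
  expect_identical(h, attr(model2, "history"))
})

test_that("ranking by prediction sorts ascending with generation-order ties", {
  ens <- fake_ensemble(c("bio_like", "non_bio", "non_bio"))
  model <- atnn_init(desk, seed = 1)
  rk <- predict_and_rank(ens, model)
  expect_setequal(rk$order, 1:3)
  expect_identical(rk$ranker_name, "atnn")
  # all-equal scores keep generation order (same geometry everywhere)
  expect_identical(rk$order, confbias:::.cb_conf_ids(ens)[
    order(rk$scores, seq_len(3))])
})

test_that("checkpoints round-trip through save and load", {
  model <- atnn_init(desk, seed = 4)
  path <- tempfile(fileext = ".rds")
  atnn_save(model, path)
  back <- atnn_load(path)
  expect_equal(back$params, model$params)
  expect_equal(back$config, model$config)
  unlink(path)
})
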