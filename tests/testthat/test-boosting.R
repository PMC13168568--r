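test_that("a realizable target is recovered almost perfectly", {
  inst <- recovery_instance(seed = 21, snr = Inf)
  model <- fit_trf(inst$design, inst$response)
  expect_gte(mean(model$accuracy$accuracy), 0.99)
  truth_eff <- effective_kernel(truth_kernel(inst$truth, "x"),
                                cols = inst$design$cols,
                                basis = inst$design$basis)
  est_eff <- effective_kernel(model)[, 1]
  expect_gte(cor(est_eff, truth_eff), 0.99)
})

test_that("pure-noise responses get near-zero held-out accuracy", {
  accs <- vapply(1:20, function(seed) {
    ps <- normalize_channels(random_predictor_set(seed, n_trials = 6,
                                                  len = 150,
                                                  families = c("f1", "f2")))
    ps <- pad_trials(ps)
    des <- lag_expand(ps)
    set.seed(seed + 500)
    resp <- normalize_channels(source_response(
      matrix(rnorm(nrow(des$X)), ncol = 1), trials = des$trials,
      support = des$support))
    mean(fit_trf(des, resp, keep_log = FALSE)$accuracy$accuracy)
  }, numeric(1))
  expect_lte(mean(accs), 0.02)
})

test_that("boosting matches the least-squares oracle on a small instance", {
  # 2 channels, 10 lags, 500 frames, mild noise, full-rank design;
  # a fine coefficient increment suits this small dense problem
  set.seed(31)
  len <- 100
  ps <- normalize_channels(random_predictor_set(31, n_trials = 5, len = len,
                                                families = c("f1", "f2")))
  des <- lag_expand(ps, lag_min_s = 0, lag_max_s = 0.1)
  expect_equal(ncol(des$X), 20)
  beta_true <- rnorm(20, sd = 0.3)
  y <- drop(des$X %*% beta_true)
  y <- y + rnorm(length(y), sd = 0.1 * sd(y))
  resp <- normalize_channels(source_response(matrix(y, ncol = 1),
                                             trials = des$trials))
  model <- fit_trf(des, resp, step = 0.001, patience = 50, keep_log = FALSE)
  expect_lt(abs(oracle_ls_rmse_ratio(des, resp, model) - 1), 0.10)
})

test_that("prediction follows the forward model exactly", {
  inst <- recovery_instance(seed = 41, snr = 1)
  model <- fit_trf(inst$design, inst$response, keep_log = FALSE)

  # zero kernels and intercepts -> zero prediction
  z <- model
  z$kernels[] <- 0
  z$kernel_mean[] <- 0
  z$intercepts[] <- 0
  z$intercept_mean[] <- 0
  expect_equal(max(abs(predict(z, inst$design))), 0)

  # single unit coefficient at lag 0 of channel f1 -> that basis regressor
  u <- z
  j <- which(inst$design$cols$channel == "f1" &
               inst$design$cols$lag_ms == 0)
  u$kernels[j, , 1] <- 1
  u$kernel_mean <- matrix(apply(u$kernels, c(1, 3), mean),
                          ncol = 1, dimnames = list(NULL, "source1"))
  expect_equal(drop(predict(u, inst$design)), inst$design$X[, j],
               tolerance = 1e-12)

  # arbitrary kernel against the brute-force double-loop oracle, 300 frames
  set.seed(42)
  channels <- cbind(c1 = rnorm(300), c2 = rnorm(300))
  ps <- predictor_set(channels, c("a", "b"))
  des <- lag_expand(ps)
  beta <- rnorm(ncol(des$X), sd = 0.1)
  y <- drop(forward_model(des, beta))
  y_oracle <- oracle_forward(channels, t(matrix(beta, nrow = 75)),
                             unique(des$cols$lag_samples), hamming5())
  expect_lt(max(abs(y - y_oracle)), 1e-9)
})

test_that("accuracy is the proportion of variance explained", {
  x <- rnorm(100)
  expect_equal(accuracy(x, x), 1)
  centred <- x - mean(x)
  expect_equal(accuracy(numeric(100), centred), 0)
  expect_error(accuracy(numeric(5), rep(2, 5)), "zero variance")

  # var(signal) = var(noise): predicting the signal explains half
  set.seed(8)
  n <- 1e4
  sig <- rnorm(n)
  noise <- rnorm(n)
  expect_equal(accuracy(sig, sig + noise), 0.5, tolerance = 0.05)
})

test_that("training error is non-increasing and early stopping returns the minimum", {
  inst <- recovery_instance(seed = 51, snr = 0.5)
  model <- fit_trf(inst$design, inst$response)
  log1 <- model$fit_log[model$fit_log$fold == 1, ]
  expect_true(all(diff(log1$train_sse) <= 1e-8))
  acc1 <- model$accuracy[model$accuracy$fold == 1, ]
  best <- acc1$best_iter
  expect_equal(log1$val_sse[best], min(log1$val_sse))
  expect_true(all(log1$val_sse[log1$iteration > best] >=
                    log1$val_sse[best] - 1e-12))
})

test_that("fold partitions are disjoint and validation sits inside training", {
  n_trials <- 10
  f <- speechtrf:::contiguous_folds(n_trials, 5)
  expect_length(f, n_trials)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(diff(f) >= 0))  # contiguous blocks
  for (k in 1:5) {
    val <- (k %% 5) + 1
    expect_false(val == k)
    expect_true(length(intersect(which(f == k), which(f == val))) == 0)
  }
})

test_that("fitting is deterministic", {
  inst <- recovery_instance(seed = 61, snr = 0.8)
  m1 <- fit_trf(inst$design, inst$response)
  m2 <- fit_trf(inst$design, inst$response)
  expect_identical(m1$fit_log, m2$fit_log)
  expect_identical(m1$kernels, m2$kernels)
})

test_that("too few trials or non-finite input fail fast", {
  ps <- normalize_channels(random_predictor_set(71, n_trials = 3, len = 100))
  des <- lag_expand(ps)
  resp <- source_response(matrix(rnorm(nrow(des$X)), ncol = 1),
                          trials = des$trials)
  expect_error(fit_trf(des, resp), "at least 5")
  ps5 <- normalize_channels(random_predictor_set(71, n_trials = 5, len = 80))
  des5 <- lag_expand(ps5)
  bad <- source_response(matrix(NA_real_, nrow(des5$X), 1),
                         trials = des5$trials)
  expect_error(fit_trf(des5, bad), "Non-finite")
})

test_that("ablating an irrelevant family changes accuracy only by noise", {
  # response generated from f1/f3 only (f2 kernel zeroed)
  ps <- normalize_channels(random_predictor_set(81, n_trials = 8, len = 300))
  ps <- pad_trials(ps)
  des <- lag_expand(ps)
  tr <- ground_truth(des$cols, family_spec = list(
    f1 = list(peak_ms = 100, amplitude = 1),
    f3 = list(peak_ms = 300, amplitude = 0.8)
  ), seed = 81)
  resp <- normalize_channels(
    simulate_responses(des, tr, n_subjects = 1, n_sources = 1, snr = 1, seed = 82)[[1]])
  model <- fit_trf(des, resp, keep_log = FALSE)
  ab_null <- ablate(des, resp, "f2", model)
  expect_lt(abs(ab_null$improvement), 0.02)
  ab_gen <- ablate(des, resp, "f1", model)
  expect_gt(ab_gen$improvement, ab_null$improvement)
  expect_equal(ab_gen$improvement,
               ab_gen$accuracy_full - ab_gen$accuracy_reduced)
  expect_error(ablate(des, resp, "nope", model), "not present")
  expect_error(ablate(des, resp, c("f1", "f2", "f3"), model), "no channels")
})

test_that("tidy and glance expose kernels and accuracies", {
  inst <- recovery_instance(seed = 91, snr = 1)
  model <- fit_trf(inst$design, inst$response, keep_log = FALSE)
  td <- tidy(model)
  expect_equal(nrow(td), nrow(inst$design$cols))
  expect_named(td, c("source", "channel", "family", "lag_ms", "weight"))
  gl <- glance(model)
  expect_equal(gl$folds, 5)
  expect_true(is.numeric(gl$accuracy))
})
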