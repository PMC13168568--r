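test_that("events are impulse-coded at the containing frame", {
  ev <- tibble::tibble(onset_s = 0.50, surprisal_bits = 2.0)
  x <- events_to_impulses(ev, 100, value = "surprisal_bits")
  expect_equal(x[51], 2.0)
  expect_equal(sum(x != 0), 1)

  expect_equal(events_to_impulses(tibble::tibble(onset_s = numeric(0)), 50),
               numeric(50))

  # events in one frame sum
  ev2 <- tibble::tibble(onset_s = c(0.500, 0.504), v = c(1, 2))
  x2 <- events_to_impulses(ev2, 100, value = "v")
  expect_equal(x2[51], 3)

  expect_error(events_to_impulses(tibble::tibble(onset_s = 2), 100),
               "outside the grid")
})

test_that("impulse coding conserves total event value", {
  set.seed(9)
  for (i in 1:5) {
    ev <- tibble::tibble(onset_s = runif(20, 0, 0.99), v = rnorm(20))
    x <- events_to_impulses(ev, 100, value = "v")
    expect_equal(sum(x), sum(ev$v), tolerance = 1e-12)
  }
})

test_that("normalisation z-scores channels and records the transform", {
  ps <- predictor_set(cbind(a = c(1, 2, 3), b = c(0, 1, 0)), c("f", "f"))
  out <- normalize_channels(ps)
  expect_equal(out$channels[, "a"], c(-1, 0, 1))
  expect_equal(colMeans(out$channels), c(a = 0, b = 0), tolerance = 1e-9)
  expect_equal(apply(out$channels, 2, sd), c(a = 1, b = 1), tolerance = 1e-9)
  expect_equal(out$normalization$mean, c(a = 2, b = 1 / 3))

  # idempotence up to numerical tolerance
  out2 <- normalize_channels(out)
  expect_equal(out2$channels, out$channels, tolerance = 1e-9)

  expect_error(
    normalize_channels(predictor_set(cbind(k = rep(1, 5)), "f")),
    "Zero-variance"
  )
})

test_that("padding adds 50 ms before and 700 ms after each trial", {
  ps <- predictor_set(matrix(rnorm(400 * 2), ncol = 2), c("f1", "f2"))
  ps <- normalize_channels(ps)
  out <- pad_trials(ps)
  expect_equal(nrow(out$channels), 475)
  expect_equal(sum(!out$support), 75)
  expect_equal(max(abs(out$channels[!out$support, ])), 0)

  # two trials: both padded, lengths additive
  m <- matrix(rnorm(700), ncol = 1)
  ps2 <- predictor_set(m, "f", trials = tibble::tibble(
    trial = 1:2, start = c(1L, 301L), end = c(300L, 700L)))
  ps2 <- normalize_channels(ps2)
  out2 <- pad_trials(ps2)
  expect_equal(nrow(out2$channels), 700 + 2 * 75)
  expect_equal(out2$trials$end - out2$trials$start + 1L, c(375L, 475L))

  bad <- predictor_set(m, "f", trials = tibble::tibble(
    trial = 1L, start = 5L, end = 4L))
  expect_error(pad_trials(bad), "Zero-length")
})

test_that("padding a response alongside keeps grids aligned", {
  ps <- normalize_channels(
    predictor_set(matrix(rnorm(200), ncol = 2), c("f1", "f2")))
  resp <- source_response(matrix(rnorm(100), ncol = 1))
  both <- pad_trials(ps, resp)
  expect_equal(nrow(both$predictors$channels), nrow(both$response$values))
  expect_equal(both$predictors$trials, both$response$trials)
  resp_bad <- source_response(matrix(rnorm(99), ncol = 1))
  expect_error(pad_trials(ps, resp_bad), "misaligned")
})

test_that("the lag axis has 75 points for [-50, 700) ms at 100 Hz", {
  lags <- lag_axis()
  expect_length(lags, 75)
  expect_equal(lags[1], -50)
  expect_equal(lags[75], 690)
  expect_equal(unique(diff(lags)), 10)
})

test_that("an impulse channel's lag-0 regressor is the centred basis window", {
  x <- numeric(101)
  x[51] <- 1
  ps <- predictor_set(cbind(imp = x), "f")
  des <- lag_expand(ps)
  h <- hamming5()
  col0 <- des$X[, des$cols$lag_ms == 0 & des$cols$channel == "imp"]
  expect_equal(col0[49:53], h, tolerance = 1e-12)
  expect_equal(sum(col0 != 0), 5)
})

test_that("regressors never mix samples across trial boundaries", {
  set.seed(4)
  m <- matrix(rnorm(200), ncol = 1)
  ps <- predictor_set(m, "f", trials = tibble::tibble(
    trial = 1:2, start = c(1L, 101L), end = c(100L, 200L)))
  des <- lag_expand(ps)
  # regressor at max lag for trial 2's first frames depends only on trial 2
  ps_alt <- ps
  ps_alt$channels[1:100, 1] <- rnorm(100)
  des_alt <- lag_expand(ps_alt)
  expect_equal(des$X[101:200, ], des_alt$X[101:200, ])
})

test_that("the lag design reproduces the brute-force forward model", {
  set.seed(7)
  n <- 200
  channels <- cbind(a = rnorm(n), b = rnorm(n))
  ps <- predictor_set(channels, c("fa", "fb"))
  des <- lag_expand(ps)
  beta <- rnorm(ncol(des$X), sd = 0.2)
  y <- drop(forward_model(des, beta))
  beta_mat <- t(matrix(beta, nrow = 75))  # channels x lags
  y_oracle <- oracle_forward(channels, beta_mat,
                             unique(des$cols$lag_samples), hamming5())
  expect_lt(max(abs(y - y_oracle)), 1e-9)
})
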