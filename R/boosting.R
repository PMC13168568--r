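#' Estimate temporal response functions by boosting
#'
#' Greedy coordinate-wise boosting of the lagged design against each
#' response source, minimising the l2 error.  Trials are split into
#' `folds` contiguous blocks for cross-validation.  Within each fold the
#' training portion is further split: one of the remaining folds (the
#' cyclic successor of the test fold) serves as the validation set for
#' early stopping; the rest is the training set.  Starting from all-zero
#' kernels, each iteration adjusts the single (channel, lag) coefficient by
#' `+step` or `-step` that maximally reduces the training l2 error
#' (ties broken toward the lowest channel/lag index), and training stops
#' once the validation error has not improved for `patience` consecutive
#' iterations; the returned kernel per fold is the one at minimum
#' validation error.  Held-out accuracy per fold is the proportion of
#' variance explained on the test block (padding excluded).
#'
#' @param design A `"lag_design"` from [lag_expand()].
#' @param response A `"source_response"` on the same grid and trials.
#' @param folds Number of cross-validation folds (default 5).
#' @param step Coefficient increment in normalised units (default 0.005).
#' @param patience Consecutive validation-error increases before stopping
#'   (default 10).
#' @param max_iter Iteration cap per fold (default 10000).
#' @param keep_log Keep the per-iteration fit log (default `TRUE`; heavy
#'   batch fits may disable it).
#' @param cols Optional integer vector of design columns to use (used by
#'   [ablate()]); default all.
#' @return A list of class `"trf_model"`: per-fold kernels (`kernels`,
#'   columns x folds x sources), their mean (`kernel_mean`), per-fold
#'   `intercepts` (the fit is affine in training-centred coordinates),
#'   `cols` metadata, per-(source, fold) held-out `accuracy`, the fold
#'   table and `fit_log`.
#' @export
fit_trf <- function(design, response, folds = 5, step = 0.005,
                    patience = 10, max_iter = 10000, keep_log = TRUE,
                    cols = NULL) {
  stopifnot(inherits(design, "lag_design"), inherits(response, "source_response"))
  if (nrow(design$X) != nrow(response$values)) {
    abort("Design and response have different lengths.")
  }
  if (!all(is.finite(response$values)) || !all(is.finite(design$X))) {
    abort("Non-finite values in design or response.")
  }
  n_trials <- nrow(design$trials)
  if (n_trials < folds) {
    abort(sprintf("Need at least %d trials (or partitionable segments); got %d.",
                  folds, n_trials))
  }
  idx <- cols %||% seq_len(ncol(design$X))
  p <- length(idx)
  S <- ncol(response$values)
  src_names <- colnames(response$values) %||% paste0("source", seq_len(S))

  fold_of_trial <- contiguous_folds(n_trials, folds)
  fg <- fold_grams(design, fold_of_trial)
  rows_of_fold <- fg$rows
  G_k <- lapply(fg$grams, function(G) G[idx, idx, drop = FALSE])
  s_k <- lapply(fg$colsums, function(s) s[idx])

  kernels <- array(0, dim = c(p, folds, S),
                   dimnames = list(NULL, NULL, src_names))
  intercepts <- matrix(0, folds, S, dimnames = list(NULL, src_names))
  acc <- vector("list", folds * S)
  logs <- list()
  li <- 0L

  for (k in seq_len(folds)) {
    val <- (k %% folds) + 1L
    train <- setdiff(seq_len(folds), c(k, val))
    rows_tr <- unlist(rows_of_fold[train], use.names = FALSE)
    rows_val <- rows_of_fold[[val]]
    rows_te <- rows_of_fold[[k]]
    n_tr <- length(rows_tr)

    # the fit is affine: channels and response are centred over the
    # training rows (rank-1 update of the cached Gram), and the intercept
    # is recovered at prediction time
    mu_tr <- Reduce(`+`, s_k[train]) / n_tr
    G_tr <- Reduce(`+`, G_k[train]) - n_tr * tcrossprod(mu_tr)
    X_val <- sweep(design$X[rows_val, idx, drop = FALSE], 2, mu_tr)
    G_val <- crossprod(X_val)
    X_tr <- design$X[rows_tr, idx, drop = FALSE]
    te_support <- rows_te[design$support[rows_te]]
    X_te <- design$X[te_support, idx, drop = FALSE]

    for (s in seq_len(S)) {
      y <- response$values[, s]
      ybar <- mean(y[rows_tr])
      y_val <- y[rows_val] - ybar
      fit <- boost_coordinates(
        G_tr = G_tr,
        Xty_tr = drop(crossprod(X_tr, y[rows_tr])) - n_tr * mu_tr * ybar,
        yty_tr = sum((y[rows_tr] - ybar)^2),
        G_val = G_val, Xty_val = drop(crossprod(X_val, y_val)),
        yty_val = sum(y_val^2),
        step = step, patience = patience, max_iter = max_iter,
        keep_log = keep_log
      )
      kernels[, k, s] <- fit$beta
      intercepts[k, s] <- ybar - sum(fit$beta * mu_tr)
      y_te <- y[te_support]
      acc[[(k - 1L) * S + s]] <- tibble(
        source = src_names[s], fold = k,
        accuracy = accuracy(drop(X_te %*% fit$beta) + intercepts[k, s], y_te),
        n_iter = fit$n_iter, best_iter = fit$best_iter
      )
      if (keep_log) {
        li <- li + 1L
        logs[[li]] <- dplyr::mutate(fit$log, source = src_names[s], fold = k)
      }
    }
  }

  kernel_mean <- apply(kernels, c(1, 3), mean)
  structure(
    list(
      cols = design$cols[idx, , drop = FALSE],
      col_idx = idx,
      kernels = kernels,
      kernel_mean = matrix(kernel_mean, nrow = p, ncol = S,
                           dimnames = list(NULL, src_names)),
      intercepts = intercepts,
      intercept_mean = colMeans(intercepts),
      accuracy = dplyr::bind_rows(acc),
      fold_of_trial = fold_of_trial,
      trials = design$trials,
      sources = src_names,
      basis = design$basis,
      align = design$align,
      settings = list(folds = folds, step = step, patience = patience,
                      max_iter = max_iter),
      fit_log = if (keep_log) dplyr::bind_rows(logs) else NULL
    ),
    class = "trf_model"
  )
}

# contiguous trial blocks -> fold ids 1..K
contiguous_folds <- function(n_trials, folds) {
  as.integer(ceiling(seq_len(n_trials) * folds / n_trials))
}

# per-fold sample rows and Gram matrices, cached on the design
fold_grams <- function(design, fold_of_trial) {
  key <- paste0("folds_", paste(fold_of_trial, collapse = ""))
  if (!is.null(design$cache[[key]])) return(design$cache[[key]])
  folds <- max(fold_of_trial)
  rows <- lapply(seq_len(folds), function(k) {
    tr <- which(fold_of_trial == k)
    unlist(lapply(tr, function(ti) design$trials$start[ti]:design$trials$end[ti]),
           use.names = FALSE)
  })
  grams <- lapply(rows, function(r) crossprod(design$X[r, , drop = FALSE]))
  colsums <- lapply(rows, function(r) colSums(design$X[r, , drop = FALSE]))
  out <- list(rows = rows, grams = grams, colsums = colsums)
  design$cache[[key]] <- out
  out
}

# greedy +/- step coordinate updates with validation-based early stopping,
# entirely in Gram space (O(p) per iteration)
boost_coordinates <- function(G_tr, Xty_tr, yty_tr, G_val, Xty_val, yty_val,
                              step, patience, max_iter, keep_log = TRUE) {
  p <- length(Xty_tr)
  beta <- numeric(p)
  c_tr <- Xty_tr
  c_val <- Xty_val
  d_tr <- diag(G_tr)
  d_val <- diag(G_val)
  sse_tr <- yty_tr
  sse_val <- yty_val
  best_val <- sse_val
  best_beta <- beta
  best_iter <- 0L
  rising <- 0L  # consecutive iterations with increasing validation error

  log_col <- integer(max_iter)
  log_delta <- numeric(max_iter)
  log_tr <- numeric(max_iter)
  log_val <- numeric(max_iter)
  it <- 0L

  while (it < max_iter) {
    de <- step^2 * d_tr - 2 * step * abs(c_tr)
    j <- which.min(de)
    if (!(de[j] < 0)) break  # no move reduces training error
    it <- it + 1L
    s <- if (c_tr[j] >= 0) 1 else -1
    delta <- s * step
    dval <- -2 * delta * c_val[j] + step^2 * d_val[j]
    beta[j] <- beta[j] + delta
    sse_tr <- sse_tr + de[j]
    sse_val <- sse_val + dval
    c_tr <- c_tr - delta * G_tr[, j]
    c_val <- c_val - delta * G_val[, j]
    if (keep_log) {
      log_col[it] <- j
      log_delta[it] <- delta
      log_tr[it] <- sse_tr
      log_val[it] <- sse_val
    }
    if (sse_val < best_val) {
      best_val <- sse_val
      best_beta <- beta
      best_iter <- it
    }
    if (dval > 0) {
      rising <- rising + 1L
      if (rising >= patience) break
    } else {
      rising <- 0L
    }
  }

  list(
    beta = best_beta, n_iter = it, best_iter = best_iter,
    log = if (keep_log) {
      tibble(iteration = seq_len(it), coordinate = log_col[seq_len(it)],
             delta = log_delta[seq_len(it)], train_sse = log_tr[seq_len(it)],
             val_sse = log_val[seq_len(it)])
    } else NULL
  )
}

#' Effective TRF kernel on the lag axis
#'
#' The boosting coefficients parameterise the TRF in the overlapping
#' Hamming-window basis; the effective kernel — the filter the model
#' actually applies to each channel, and what is usually plotted and
#' compared as "TRF weights" — is the coefficient sequence convolved with
#' the basis window along the lag axis, per channel.
#'
#' @param model A `"trf_model"`, or a numeric coefficient vector (then
#'   `cols` and `basis` are required).
#' @param cols,basis Column metadata and basis window when `model` is a
#'   bare vector (e.g. a ground-truth kernel).
#' @return A matrix (columns = sources) of effective kernel values over the
#'   design columns, or a vector for bare input.
#' @export
effective_kernel <- function(model, cols = NULL, basis = NULL) {
  if (inherits(model, "trf_model")) {
    out <- apply(model$kernel_mean, 2, smooth_kernel_lags,
                 cols = model$cols, h = model$basis)
    return(matrix(out, ncol = length(model$sources),
                  dimnames = list(NULL, model$sources)))
  }
  if (is.null(cols) || is.null(basis)) {
    abort("`cols` and `basis` are required for a bare coefficient vector.")
  }
  smooth_kernel_lags(as.numeric(model), cols, basis)
}

# convolve per-channel coefficient sequences with the basis window
# (centered), in lag space
smooth_kernel_lags <- function(beta, cols, h) {
  out <- numeric(length(beta))
  for (ch in unique(cols$channel)) {
    i <- which(cols$channel == ch)
    s <- as.numeric(stats::filter(beta[i], h, sides = 2))
    s[is.na(s)] <- 0
    out[i] <- s
  }
  out
}

#' Proportion of variance explained
#'
#' \eqn{1 - SS_{res}/SS_{tot}} of the actual signal; may be negative when
#' the prediction is worse than the mean.
#'
#' @param predicted,actual Numeric vectors of equal length.
#' @return A single number (<= 1).
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) != length(actual)) abort("Length mismatch.")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) abort("Actual signal has zero variance.")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Predict responses from a fitted TRF model
#'
#' Linear forward model per source.  On samples belonging to a fold's
#' held-out test trials the fold-specific kernel is used; elsewhere (e.g.
#' on new designs with a different trial count) the mean kernel is used.
#'
#' @param object A `"trf_model"`.
#' @param design A `"lag_design"` with matching channels.
#' @param ... Unused.
#' @return Numeric matrix, samples x sources.
#' @export
predict.trf_model <- function(object, design, ...) {
  stopifnot(inherits(design, "lag_design"))
  if (!identical(design$cols$channel[object$col_idx], object$cols$channel)) {
    abort("Design channels do not match the model.")
  }
  X <- design$X[, object$col_idx, drop = FALSE]
  out <- sweep(X %*% object$kernel_mean, 2, object$intercept_mean, `+`)
  same_trials <- identical(design$trials, object$trials)
  if (same_trials) {
    for (k in seq_len(object$settings$folds)) {
      tr <- which(object$fold_of_trial == k)
      rows <- unlist(lapply(tr, function(ti) {
        design$trials$start[ti]:design$trials$end[ti]
      }), use.names = FALSE)
      out[rows, ] <- sweep(
        X[rows, , drop = FALSE] %*% matrix(object$kernels[, k, ],
                                           nrow = ncol(X)),
        2, object$intercepts[k, ], `+`)
    }
  }
  out
}

#' Feature-family ablation
#'
#' Refits the model on the design with one feature family's channels
#' removed (same folds and hyperparameters) and reports, per source, the
#' accuracy of the full and reduced models and their difference
#' (`improvement = full - reduced`), the contribution of that family to
#' the model accuracy.
#'
#' @param design,response As in [fit_trf()].
#' @param family Feature family tag(s) to remove.
#' @param full_model The fitted full `"trf_model"`.
#' @return A tibble of class `"ablation_result"`: `source`, `family`,
#'   `accuracy_full`, `accuracy_reduced`, `improvement`.
#' @export
ablate <- function(design, response, family, full_model) {
  stopifnot(inherits(full_model, "trf_model"))
  if (!any(design$cols$family %in% family)) {
    abort(sprintf("Family '%s' is not present in the design.",
                  paste(family, collapse = ",")))
  }
  keep <- which(!(design$cols$family %in% family))
  if (length(keep) == 0L) {
    abort("Removing the family leaves no channels.")
  }
  st <- full_model$settings
  reduced <- fit_trf(design, response, folds = st$folds, step = st$step,
                     patience = st$patience, max_iter = st$max_iter,
                     keep_log = FALSE, cols = keep)
  full_acc <- dplyr::summarise(dplyr::group_by(full_model$accuracy, .data$source),
                               accuracy_full = mean(.data$accuracy))
  red_acc <- dplyr::summarise(dplyr::group_by(reduced$accuracy, .data$source),
                              accuracy_reduced = mean(.data$accuracy))
  out <- dplyr::inner_join(full_acc, red_acc, by = "source")
  out$family <- paste(family, collapse = "+")
  out$improvement <- out$accuracy_full - out$accuracy_reduced
  out <- dplyr::ungroup(out)[, c("source", "family", "accuracy_full",
                                 "accuracy_reduced", "improvement")]
  class(out) <- c("ablation_result", class(out))
  out
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d regressors, %d folds, %d source(s)\n",
              nrow(x$cols), x$settings$folds, length(x$sources)))
  acc <- dplyr::summarise(dplyr::group_by(x$accuracy, .data$source),
                          accuracy = mean(.data$accuracy))
  cat(sprintf("  mean held-out accuracy: %s\n",
              paste(sprintf("%s=%.3f", acc$source, acc$accuracy), collapse = ", ")))
  invisible(x)
}

#' @describeIn fit_trf One row per (source, channel, lag): the mean-over-folds
#'   kernel weights.
#' @param x A `"trf_model"`.
#' @param ... Unused.
#' @export
tidy.trf_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$sources), function(s) {
    dplyr::mutate(x$cols, source = x$sources[s],
                  weight = x$kernel_mean[, s])
  })[, c("source", "channel", "family", "lag_ms", "weight")]
}

#' @describeIn fit_trf One row per source: mean and sd of held-out accuracy
#'   across folds.
#' @export
glance.trf_model <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$accuracy, .data$source),
                   accuracy = mean(.data$accuracy),
                   accuracy_sd = sd(.data$accuracy),
                   folds = dplyr::n(), .groups = "drop")
}

#' @describeIn fit_trf Kernel weights over lag, one panel per family.
#' @param object A `"trf_model"`.
#' @export
autoplot.trf_model <- function(object, ...) {
  tidy(object) |>
    dplyr::group_by(.data$family, .data$lag_ms, .data$source) |>
    dplyr::summarise(weight = mean(abs(.data$weight)), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(.data$lag_ms, .data$weight,
                                 colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_y") +
    ggplot2::labs(x = "Lag (ms)", y = "Mean |weight|", colour = "Source")
}
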