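#' TRF weight timecourse
#'
#' Summarises a fitted model's kernel into one non-negative value per lag:
#' the mean (default) or sum over sources and the family's channels of the
#' absolute effective weights (basis-smoothed; see [effective_kernel()]).
#' Lags within the first and last `edge_mask_ms` of the lag window are
#' flagged as masked and excluded from downstream statistics (edge
#' artifacts).
#'
#' @param model A `"trf_model"`.
#' @param family Feature family tag(s) to summarise (default: all).
#' @param edge_mask_ms Width of the edge masks in ms (default 20).
#' @param summary `"mean"` (default, scale-invariant across source counts)
#'   or `"sum"`.
#' @return A tibble with columns `lag_ms`, `weight`, `masked`.
#' @export
weight_timecourse <- function(model, family = NULL, edge_mask_ms = 20,
                              summary = c("mean", "sum")) {
  summary <- match.arg(summary)
  stopifnot(inherits(model, "trf_model"))
  family <- family %||% unique(model$cols$family)
  rows <- model$cols$family %in% family
  if (!any(rows)) abort(sprintf("No channels in family '%s'.",
                                paste(family, collapse = ",")))
  w <- abs(effective_kernel(model)[rows, , drop = FALSE])
  lags <- model$cols$lag_ms[rows]
  agg <- if (summary == "mean") {
    tapply(rowMeans(w), lags, mean)
  } else {
    tapply(rowSums(w), lags, sum)
  }
  lag_ms <- as.numeric(names(agg))
  o <- order(lag_ms)
  lag_ms <- lag_ms[o]
  out <- tibble(lag_ms = lag_ms, weight = as.numeric(agg)[o])
  out$masked <- edge_mask(out$lag_ms, edge_mask_ms)
  out
}

# TRUE for lags inside the first/last edge_mask_ms of the lag window
edge_mask <- function(lag_ms, edge_mask_ms = 20) {
  step <- if (length(lag_ms) > 1) min(diff(sort(lag_ms))) else 10
  lo <- min(lag_ms)
  hi <- max(lag_ms) + step   # right-open window end
  lag_ms < lo + edge_mask_ms | lag_ms >= hi - edge_mask_ms
}

#' One-sample t test of accuracy improvements
#'
#' Tests per-subject source-averaged accuracy deltas against zero
#' (two-sided).
#'
#' @param improvements Numeric vector, one value per subject.
#' @return A tibble with `estimate`, `statistic`, `df`, `p.value`, `n`.
#' @export
#' @examples
#' improvement_ttest(c(1, 2, 3))  # t = 3.464
improvement_ttest <- function(improvements) {
  x <- as.numeric(improvements)
  if (length(x) < 2) abort("Need at least 2 subjects.")
  if (sd(x) == 0) abort("Zero variance in improvements.")
  tt <- t.test(x, mu = 0)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p.value = tt$p.value, n = length(x))
}

# contiguous suprathreshold runs of one sign; returns start/end indices and
# cluster mass (sum of t)
find_clusters <- function(t_vals, threshold) {
  t_vals <- unname(t_vals)
  out <- list()
  for (sgn in c(1, -1)) {
    above <- if (sgn > 0) t_vals > threshold else t_vals < -threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- c(start = starts[i], end = ends[i],
                                   mass = sum(t_vals[starts[i]:ends[i]]))
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(0), end = integer(0), mass = numeric(0)))
  }
  m <- do.call(rbind, out)
  tibble(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
         mass = m[, "mass"])
}

# paired t statistic per column; zero-variance columns give t = 0
paired_t_cols <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  # clamp tiny negative variances from floating cancellation
  s <- sqrt(pmax((colSums(d^2) - n * m^2) / (n - 1), 0))
  t <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  as.numeric(t)
}

#' Cluster-based sign-flip permutation test across lag
#'
#' Paired comparison of two conditions' weight timecourses across subjects.
#' At each lag a paired t statistic is computed on `a - b`; contiguous runs
#' exceeding the cluster-forming threshold (by default the two-sided t
#' critical value at `p < 0.05` for `n - 1` df) form clusters whose mass is
#' the sum of t within the run.  The null distribution is the maximum
#' absolute cluster mass over random sign flips of the subject differences;
#' cluster p values use the add-one convention
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`.  Lags within
#' `edge_mask_ms` of either end of the lag window are excluded.
#'
#' @param a,b Numeric subject x lag matrices (paired rows, same lag axis).
#' @param lags_ms Numeric vector of lag times (ms), one per column.
#' @param n_permutations Number of sign-flip permutations (default 30000).
#' @param alpha Cluster-forming significance level (default 0.05).
#' @param threshold Cluster-forming t threshold; default derived from
#'   `alpha`.
#' @param edge_mask_ms Edge mask width in ms (default 20; 0 disables).
#' @param seed Integer seed for the permutation draws.
#' @return A tibble of class `"cluster_result"` with columns
#'   `cluster_start_ms`, `cluster_end_ms`, `sign`, `mass`, `p`, and
#'   attributes `n_permutations`, `threshold`, `seed`, `lags_ms` (the
#'   analysis axis after masking).
#' @export
cluster_permutation <- function(a, b, lags_ms, n_permutations = 30000,
                                alpha = 0.05, threshold = NULL,
                                edge_mask_ms = 20, seed = NULL) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) abort("Conditions are unpaired: dimensions differ.")
  if (ncol(a) != length(lags_ms)) abort("`lags_ms` must match the columns.")
  n <- nrow(a)
  if (n < 2) abort("Need at least 2 paired subjects.")

  keep <- !edge_mask(lags_ms, edge_mask_ms)
  d <- (a - b)[, keep, drop = FALSE]
  lags <- lags_ms[keep]
  threshold <- threshold %||% qt(1 - alpha / 2, df = n - 1)

  t_obs <- paired_t_cols(d)
  clusters <- find_clusters(t_obs, threshold)
  clusters <- clusters[order(clusters$start), , drop = FALSE]

  result <- tibble(
    cluster_start_ms = lags[clusters$start],
    cluster_end_ms = lags[clusters$end],
    sign = sign(clusters$mass),
    mass = clusters$mass,
    p = rep(NA_real_, nrow(clusters))
  )

  if (nrow(clusters) > 0L) {
    if (!is.null(seed)) set.seed(seed)
    flips <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                    nrow = n_permutations)
    L <- ncol(d)
    ssq <- colSums(d^2)
    M <- flips %*% d / n
    s2 <- pmax(sweep(-n * M^2, 2, ssq, `+`) / (n - 1), 0)
    t_perm <- ifelse(s2 > 0, M / sqrt(s2 / n), 0)
    null_max <- vapply(seq_len(n_permutations), function(i) {
      cl <- find_clusters(t_perm[i, ], threshold)
      if (nrow(cl) == 0L) 0 else max(abs(cl$mass))
    }, numeric(1))
    result$p <- vapply(result$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (1 + n_permutations)
    }, numeric(1))
  }

  attr(result, "n_permutations") <- n_permutations
  attr(result, "threshold") <- threshold
  attr(result, "alpha") <- alpha
  attr(result, "seed") <- seed
  attr(result, "lags_ms") <- lags
  class(result) <- c("cluster_result", class(result))
  result
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations, threshold |t| > %.3f\n",
              nrow(x), attr(x, "n_permutations"), attr(x, "threshold")))
  NextMethod()
}

#' Write a cluster report TSV
#'
#' Columns: `cluster_start_ms`, `cluster_end_ms`, `mass`, `p`,
#' `n_permutations`, `seed`, `threshold`.
#'
#' @param x A `"cluster_result"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(x, path) {
  df <- tibble(
    cluster_start_ms = x$cluster_start_ms, cluster_end_ms = x$cluster_end_ms,
    mass = x$mass, p = x$p,
    n_permutations = attr(x, "n_permutations"),
    seed = attr(x, "seed") %||% NA_integer_,
    threshold = attr(x, "threshold")
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Peak latency within an analysis window
#'
#' Lag of the maximum weight within a named window — early (-50 to 100 ms),
#' mid (100 to 350 ms) or late (350 to 700 ms) — or an explicit
#' `c(lo, hi)` ms range.  Masked lags are excluded; ties resolve to the
#' earliest lag.
#'
#' @param weights Numeric vector of non-negative weights per lag.
#' @param lags_ms Lag times in ms.
#' @param window `"early"`, `"mid"`, `"late"`, or a numeric length-2 range.
#' @param mask Optional logical vector of lags to exclude (e.g. edge mask).
#' @return Peak latency in ms.
#' @export
peak_latency <- function(weights, lags_ms, window = c("early", "mid", "late"),
                         mask = NULL) {
  if (is.character(window)) {
    window <- match.arg(window)
    window <- switch(window, early = c(-50, 100), mid = c(100, 350),
                     late = c(350, 700))
  }
  stopifnot(length(window) == 2, length(weights) == length(lags_ms))
  sel <- lags_ms >= window[1] & lags_ms <= window[2]
  if (!is.null(mask)) sel <- sel & !mask
  if (!any(sel)) abort("Window is empty after masking.")
  w <- weights[sel]
  l <- lags_ms[sel]
  o <- order(l)
  w <- w[o]
  l <- l[o]
  l[which.max(w)]  # which.max returns the first maximum -> earliest lag
}

#' Plot weight timecourses by condition
#'
#' @param df Tibble with columns `lag_ms`, `weight`, `condition`, and
#'   optionally `subject` (averaged with standard-error ribbon).
#' @return A ggplot object.
#' @export
plot_weight_timecourse <- function(df) {
  if ("subject" %in% names(df)) {
    df <- df |>
      dplyr::group_by(.data$condition, .data$lag_ms) |>
      dplyr::summarise(se = sd(.data$weight) / sqrt(dplyr::n()),
                       weight = mean(.data$weight), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(.data$lag_ms, .data$weight,
                                     colour = .data$condition,
                                     fill = .data$condition)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$weight - .data$se,
                                        ymax = .data$weight + .data$se),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Lag (ms)", y = "Mean |weight|")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$lag_ms, .data$weight,
                                     colour = .data$condition)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Lag (ms)", y = "Mean |weight|")
  }
}
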