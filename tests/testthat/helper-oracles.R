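# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths: plain enumeration, double loops and
# closed forms.

# --- cohort enumeration oracle -----------------------------------------

# mass of all entries whose phoneme sequence starts with `prefix`
oracle_prefix_mass <- function(words, freqs, phon, prefix) {
  ok <- vapply(phon, function(p) {
    length(p) >= length(prefix) &&
      (length(prefix) == 0 || all(p[seq_along(prefix)] == prefix))
  }, logical(1))
  sum(freqs[ok])
}

# conditional probability of the i-th phoneme of `word` by enumeration
oracle_cond_prob <- function(words, freqs, phon, word, i) {
  oracle_prefix_mass(words, freqs, phon, word[seq_len(i)]) /
    oracle_prefix_mass(words, freqs, phon, word[seq_len(i - 1)])
}

# entropy (bits) of the next-symbol distribution after `prefix`, with a
# terminal '#' outcome for exhausted entries
oracle_next_entropy <- function(words, freqs, phon, prefix,
                                include_word_end = TRUE) {
  pos <- length(prefix) + 1L
  ok <- vapply(phon, function(p) {
    length(p) >= length(prefix) && all(p[seq_along(prefix)] == prefix)
  }, logical(1))
  nxt <- vapply(phon[ok], function(p) {
    if (length(p) >= pos) p[[pos]] else "#"
  }, character(1))
  f <- freqs[ok]
  if (!include_word_end) {
    f <- f[nxt != "#"]
    nxt <- nxt[nxt != "#"]
    if (length(nxt) == 0) return(0)
  }
  mass <- tapply(f, nxt, sum)
  p <- as.numeric(mass) / sum(f)
  -sum(p * log2(p))
}

# --- forward-model double-loop oracle ----------------------------------

# y(t) = sum_c sum_k beta[c,k] * s_c(t - L_k), with s_c the channel
# convolved with the centered basis window; all loops explicit, one trial
oracle_forward <- function(channels, beta_mat, lag_samples, h) {
  n <- nrow(channels)
  C <- ncol(channels)
  offset <- -(length(h) %/% 2L)
  smooth <- matrix(0, n, C)
  for (ci in seq_len(C)) {
    for (t in seq_len(n)) {
      acc <- 0
      for (j in seq_along(h)) {
        src <- t - (j - 1L + offset)
        if (src >= 1 && src <= n) acc <- acc + h[j] * channels[src, ci]
      }
      smooth[t, ci] <- acc
    }
  }
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (ci in seq_len(C)) {
      for (k in seq_along(lag_samples)) {
        src <- t - lag_samples[k]
        if (src >= 1 && src <= n) {
          y[t] <- y[t] + beta_mat[ci, k] * smooth[src, ci]
        }
      }
    }
  }
  y
}

# --- least-squares oracle ----------------------------------------------

oracle_ls_beta <- function(X, y) {
  X1 <- cbind(1, X)  # affine fit, matching the estimator
  drop(solve(crossprod(X1) + diag(1e-10, ncol(X1)), crossprod(X1, y)))
}

# per-fold held-out RMSE of the boosting fit relative to the exact
# least-squares solve on the same training partition
oracle_ls_rmse_ratio <- function(des, resp, model) {
  yz <- resp$values[, 1]
  folds <- model$settings$folds
  sse_boost <- sse_ls <- 0
  for (k in seq_len(folds)) {
    val <- (k %% folds) + 1
    te_trials <- which(model$fold_of_trial == k)
    tr_trials <- which(!(model$fold_of_trial %in% c(k, val)))
    rows_of <- function(tt) unlist(lapply(tt, function(ti) {
      des$trials$start[ti]:des$trials$end[ti]
    }))
    rows_te <- rows_of(te_trials)
    rows_tr <- rows_of(tr_trials)
    b <- oracle_ls_beta(des$X[rows_tr, ], yz[rows_tr])
    X1te <- cbind(1, des$X[rows_te, ])
    sse_ls <- sse_ls + sum((yz[rows_te] - X1te %*% b)^2)
    bb <- c(model$intercepts[k, 1], model$kernels[, k, 1])
    sse_boost <- sse_boost + sum((yz[rows_te] - X1te %*% bb)^2)
  }
  sqrt(sse_boost / sse_ls)
}

# --- exact sign-flip cluster p -----------------------------------------

# exhaustive 2^n enumeration of sign flips; returns the exact p of the
# largest observed cluster mass
oracle_exact_cluster_p <- function(d, threshold) {
  n <- nrow(d)
  tcol <- function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2, sd)
    ifelse(s > 0, mu / (s / sqrt(n)), 0)
  }
  max_mass <- function(tv) {
    mm <- 0
    for (sgn in c(1, -1)) {
      above <- if (sgn > 0) tv > threshold else tv < -threshold
      r <- rle(as.logical(above))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in which(r$values)) {
        mm <- max(mm, abs(sum(tv[starts[i]:ends[i]])))
      }
    }
    mm
  }
  obs <- max_mass(tcol(d))
  if (obs == 0) return(NA_real_)
  combos <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- apply(combos, 1, function(s) max_mass(tcol(d * s)))
  mean(null >= obs - 1e-12)
}

# --- misc ---------------------------------------------------------------

hamming5 <- function() {
  k <- 0:4
  0.54 - 0.46 * cos(2 * pi * k / 4)
}
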