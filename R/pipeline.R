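#' Default pipeline configuration
#'
#' All defaults follow the analysis conventions used throughout the
#' package: 100 Hz grid, 8 gammatone bands over 20-5000 Hz, lag window
#' `[-50, 700)` ms with a 50 ms Hamming basis, 5-fold cross-validated
#' boosting, 30,000 permutations and 20 ms edge masks.
#'
#' @param ... Named overrides.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    preset = "words_vs_syllables",
    seed = 1L,
    out_dir = NULL,
    # simulation scale
    n_subjects = 15L, n_sources = 4L, n_sequences = 8L, snr = 0.5,
    syllable_ms = 250, syllables_per_sequence = 16L, sample_rate = 16000L,
    # features
    n_bands = 8L, fmin = 20, fmax = 5000, rate = 100L,
    # TRF
    lag_min_s = -0.05, lag_max_s = 0.7, basis_width_s = 0.05,
    folds = 5L, step = 0.005, patience = 10L, max_iter = 10000L,
    # stats
    n_permutations = 30000L, alpha = 0.05, edge_mask_ms = 20,
    ablate_families = c("acoustic_edges", "phoneme")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys take their [default_config()] values.
#'
#' @param path Path to a YAML file.
#' @return A config list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Simulate an experiment bundle from a configuration
#'
#' Wraps [make_experiment()]; when `out_dir` is set, writes the bundle
#' (audio, segmentations, lexicon, predictors, responses, manifest) to
#' disk via [write_bundle()].
#'
#' @param config A config list from [default_config()] / [read_config()].
#' @return A `"trf_experiment"`, invisibly when written to disk.
#' @export
run_simulate <- function(config = default_config()) {
  exp <- make_experiment(
    preset = config$preset, seed = config$seed,
    n_subjects = config$n_subjects, n_sources = config$n_sources,
    n_sequences = config$n_sequences, snr = config$snr,
    syllable_ms = config$syllable_ms,
    syllables_per_sequence = config$syllables_per_sequence,
    sample_rate = config$sample_rate
  )
  if (!is.null(config$out_dir)) {
    write_bundle(exp, config$out_dir)
    return(invisible(exp))
  }
  exp
}

#' Fit TRF models and ablations for a whole experiment
#'
#' For every condition and subject: rebuilds the lag design from the
#' stored predictor set, fits the full boosting model, ablates each
#' configured feature family, and extracts per-family weight timecourses.
#'
#' @param experiment A `"trf_experiment"` (from [run_simulate()] /
#'   [make_experiment()]).
#' @param config A config list (TRF and stats keys are used).
#' @return A list of class `"trf_fit"`: `accuracy` (subject, condition,
#'   source, accuracy), `improvements` (…, family, improvement),
#'   `timecourses` (subject, condition, family, lag_ms, weight, masked),
#'   `config`, `manifest`.
#' @export
run_fit <- function(experiment, config = default_config()) {
  stopifnot(inherits(experiment, "trf_experiment"))
  fams <- config$ablate_families
  acc <- impr <- tcs <- list()
  for (cond in experiment$conditions) {
    for (si in seq_along(experiment$responses[[cond]])) {
      des <- lag_expand(experiment$predictors[[cond]][[si]],
                        lag_min_s = config$lag_min_s,
                        lag_max_s = config$lag_max_s,
                        basis_width_s = config$basis_width_s)
      fams_here <- intersect(fams, unique(des$cols$family))
      if (length(fams_here) < length(fams)) {
        missing <- setdiff(fams, fams_here)
        abort(sprintf("Ablation family '%s' absent from the design.",
                      paste(missing, collapse = ", ")))
      }
      resp <- experiment$responses[[cond]][[si]]
      model <- fit_trf(des, resp, folds = config$folds, step = config$step,
                       patience = config$patience,
                       max_iter = config$max_iter, keep_log = FALSE)
      acc[[length(acc) + 1L]] <- dplyr::mutate(
        glance(model)[, c("source", "accuracy")],
        subject = si, condition = cond, .before = 1
      )
      for (fam in fams_here) {
        ab <- ablate(des, resp, fam, model)
        impr[[length(impr) + 1L]] <- dplyr::mutate(
          tibble::as_tibble(ab), subject = si, condition = cond, .before = 1
        )
      }
      for (fam in unique(des$cols$family)) {
        tc <- weight_timecourse(model, fam,
                                edge_mask_ms = config$edge_mask_ms)
        tcs[[length(tcs) + 1L]] <- dplyr::mutate(
          tc, subject = si, condition = cond, family = fam, .before = 1
        )
      }
    }
  }
  out <- list(accuracy = dplyr::bind_rows(acc),
              improvements = dplyr::bind_rows(impr),
              timecourses = dplyr::bind_rows(tcs),
              config = config, manifest = experiment$manifest)
  class(out) <- "trf_fit"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out$accuracy, file.path(config$out_dir, "accuracy.tsv"))
    readr::write_tsv(out$improvements,
                     file.path(config$out_dir, "improvements.tsv"))
    readr::write_tsv(out$timecourses,
                     file.path(config$out_dir, "timecourses.tsv"))
  }
  out
}

#' @export
print.trf_fit <- function(x, ...) {
  cat(sprintf("<trf_fit> %d subject-condition fits, families: %s\n",
              nrow(dplyr::distinct(x$accuracy, .data$subject, .data$condition)),
              paste(unique(x$improvements$family), collapse = ", ")))
  invisible(x)
}

#' Group-level statistics for a fitted experiment
#'
#' Runs, per feature family: a one-sample t test of the source-averaged
#' accuracy improvements against zero in each condition; a cluster-based
#' sign-flip permutation test of the paired condition difference in weight
#' timecourses; and early/mid/late peak latencies per subject and
#' condition.
#'
#' @param fit A `"trf_fit"` from [run_fit()].
#' @param config A config list (stats keys are used).
#' @return A list of class `"trf_stats"`: `ttests`, `clusters` (named list
#'   of `"cluster_result"` per family), `cluster_table`, `latencies`,
#'   `group_table` (tidy TSV-ready table).
#' @export
run_stats <- function(fit, config = fit$config %||% default_config()) {
  stopifnot(inherits(fit, "trf_fit"))
  conds <- unique(fit$accuracy$condition)
  if (length(conds) != 2) abort("Expected exactly two conditions.")

  subject_impr <- fit$improvements |>
    dplyr::group_by(.data$subject, .data$condition, .data$family) |>
    dplyr::summarise(improvement = mean(.data$improvement), .groups = "drop")
  ttests <- subject_impr |>
    dplyr::group_by(.data$condition, .data$family) |>
    dplyr::group_modify(~ improvement_ttest(.x$improvement)) |>
    dplyr::ungroup()

  families <- unique(fit$timecourses$family)
  lags <- sort(unique(fit$timecourses$lag_ms))
  clusters <- list()
  cluster_rows <- list()
  for (fam in families) {
    tc <- fit$timecourses[fit$timecourses$family == fam, , drop = FALSE]
    wide <- function(cond) {
      d <- tc[tc$condition == cond, , drop = FALSE]
      m <- tapply(d$weight, list(d$subject, d$lag_ms), mean)
      m[, as.character(lags), drop = FALSE]
    }
    a <- wide(conds[1])
    b <- wide(conds[2])
    cl <- cluster_permutation(a, b, lags,
                              n_permutations = config$n_permutations,
                              alpha = config$alpha,
                              edge_mask_ms = config$edge_mask_ms,
                              seed = derive_seed(config$seed %||% 1,
                                                 paste0("cluster_", fam)))
    clusters[[fam]] <- cl
    if (nrow(cl) > 0) {
      cluster_rows[[fam]] <- dplyr::mutate(tibble::as_tibble(cl),
                                           family = fam, .before = 1)
    }
  }
  cluster_table <- dplyr::bind_rows(cluster_rows)

  latencies <- fit$timecourses |>
    dplyr::group_by(.data$subject, .data$condition, .data$family) |>
    dplyr::group_modify(function(d, key) {
      tibble(window = c("early", "mid", "late"),
             peak_ms = vapply(c("early", "mid", "late"), function(w) {
               peak_latency(d$weight, d$lag_ms, w, mask = d$masked)
             }, numeric(1)))
    }) |>
    dplyr::ungroup()

  group_table <- subject_impr |>
    dplyr::left_join(
      tidyr::pivot_wider(latencies, names_from = "window",
                         values_from = "peak_ms",
                         names_prefix = "peak_latency_"),
      by = c("subject", "condition", "family")
    )

  out <- list(ttests = ttests, clusters = clusters,
              cluster_table = cluster_table, latencies = latencies,
              group_table = group_table, config = config)
  class(out) <- "trf_stats"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(ttests, file.path(config$out_dir, "ttests.tsv"))
    if (nrow(cluster_table) > 0) {
      readr::write_tsv(cluster_table, file.path(config$out_dir, "clusters.tsv"))
    }
    readr::write_tsv(group_table, file.path(config$out_dir, "group_table.tsv"))
  }
  out
}

#' @export
print.trf_stats <- function(x, ...) {
  cat("<trf_stats>\n  t tests:\n")
  print(x$ttests)
  cat(sprintf("  clusters: %d across %d families\n",
              nrow(x$cluster_table), length(x$clusters)))
  invisible(x)
}

#' Write an experiment bundle to disk
#'
#' Lays out: `manifest.yaml` (config echo, seeds, ground-truth
#' parameters), `lexicon.tsv`, and per condition the sequence WAVs,
#' TextGrids, event TSVs, the predictor channels and per-subject response
#' TSVs.
#'
#' @param experiment A `"trf_experiment"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(experiment, dir) {
  stopifnot(inherits(experiment, "trf_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(experiment$manifest, file.path(dir, "manifest.yaml"))
  write_lexicon(experiment$lexicon, file.path(dir, "lexicon.tsv"))
  for (cond in experiment$conditions) {
    for (si in seq_along(experiment$streams[[cond]])) {
      cdir <- file.path(dir, cond, sprintf("subj%02d", si))
      dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
      st <- experiment$streams[[cond]][[si]]
      sp <- attr(st, "spec")
      for (i in seq_along(st)) {
        base <- file.path(cdir, sprintf("seq%03d", i))
        write_wav(st[[i]]$audio, path = paste0(base, ".wav"))
        write_events_tsv(st[[i]]$events, paste0(base, "_events.tsv"))
        ev <- st[[i]]$events
        dur <- sp$syllable_ms / 1000 * sp$syllables_per_sequence
        iv <- dplyr::bind_rows(
          tibble(tier = "phoneme", label = ev$label[ev$tier == "phoneme"],
                 start_s = ev$onset_s[ev$tier == "phoneme"]),
          tibble(tier = "word", label = ev$label[ev$tier == "word"],
                 start_s = ev$onset_s[ev$tier == "word"])
        ) |>
          dplyr::group_by(.data$tier) |>
          dplyr::arrange(.data$start_s, .by_group = TRUE) |>
          dplyr::mutate(end_s = dplyr::lead(.data$start_s, default = dur)) |>
          dplyr::ungroup()
        write_textgrid(iv, paste0(base, ".TextGrid"))
      }
      write_predictors_tsv(experiment$predictors[[cond]][[si]],
                           file.path(cdir, "predictors.tsv"))
      df <- tibble::as_tibble(as.data.frame(
        experiment$responses[[cond]][[si]]$values))
      readr::write_tsv(df, file.path(cdir, "response.tsv"))
    }
  }
  invisible(dir)
}
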