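# Praat TextGrid (long text format) reading/writing and the TSV event-table
# alternative.  Segmentations carry phoneme and word interval tiers; interval
# start times are taken as onsets.

#' Read a Praat TextGrid
#'
#' Parses the long ("ooTextFile") TextGrid format, interval tiers only.
#'
#' @param path Path to the TextGrid file.
#' @return A tibble with columns `tier`, `label`, `start_s`, `end_s`.
#' @export
read_textgrid <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!any(grepl("ooTextFile", lines))) abort("Not a Praat TextGrid file.")
  num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  str <- function(l) sub('\\s*"?\\s*$', "", sub('.*=\\s*"', "", l))

  tiers <- list()
  cur_tier <- NULL
  cur <- NULL
  for (l in lines) {
    t <- trimws(l)
    if (grepl("^name\\s*=", t)) {
      cur_tier <- str(t)
    } else if (grepl("^intervals\\s*\\[", t)) {
      if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- cur
      cur <- list(tier = cur_tier)
    } else if (grepl("^xmin\\s*=", t) && !is.null(cur) && is.null(cur$start_s)) {
      cur$start_s <- num(t)
    } else if (grepl("^xmax\\s*=", t) && !is.null(cur) && is.null(cur$end_s)) {
      cur$end_s <- num(t)
    } else if (grepl("^text\\s*=", t) && !is.null(cur)) {
      cur$label <- str(t)
      tiers[[length(tiers) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (length(tiers) == 0L) {
    return(tibble(tier = character(0), label = character(0),
                  start_s = numeric(0), end_s = numeric(0)))
  }
  tibble(
    tier = vapply(tiers, `[[`, character(1), "tier"),
    label = vapply(tiers, `[[`, character(1), "label"),
    start_s = vapply(tiers, `[[`, numeric(1), "start_s"),
    end_s = vapply(tiers, `[[`, numeric(1), "end_s")
  )
}

#' Write a Praat TextGrid (long format)
#'
#' @param intervals A tibble with columns `tier`, `label`, `start_s`, `end_s`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(intervals, path) {
  stopifnot(all(c("tier", "label", "start_s", "end_s") %in% names(intervals)))
  xmin <- min(intervals$start_s)
  xmax <- max(intervals$end_s)
  tiers <- unique(intervals$tier)
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    sprintf("xmin = %.10g", xmin),
    sprintf("xmax = %.10g", xmax),
    "tiers? <exists>",
    sprintf("size = %d", length(tiers)),
    "item []:"
  )
  for (ti in seq_along(tiers)) {
    d <- intervals[intervals$tier == tiers[ti], , drop = FALSE]
    d <- d[order(d$start_s), , drop = FALSE]
    out <- c(out,
      sprintf("    item [%d]:", ti),
      '        class = "IntervalTier"',
      sprintf('        name = "%s"', tiers[ti]),
      sprintf("        xmin = %.10g", xmin),
      sprintf("        xmax = %.10g", xmax),
      sprintf("        intervals: size = %d", nrow(d)))
    for (i in seq_len(nrow(d))) {
      out <- c(out,
        sprintf("        intervals [%d]:", i),
        sprintf("            xmin = %.10g", d$start_s[i]),
        sprintf("            xmax = %.10g", d$end_s[i]),
        sprintf('            text = "%s"', d$label[i]))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Build an event table from segmentation intervals
#'
#' Converts tier intervals (from [read_textgrid()]) into the event-stream
#' form used by [annotate_events()] and [events_to_impulses()]: one row per
#' event with its onset time, tier, label, and the index of the word it
#' belongs to (phonemes are assigned to the latest word starting at or
#' before them).  Empty labels are dropped.
#'
#' @param intervals Tibble with `tier`, `label`, `start_s`, `end_s`.
#' @param phoneme_tier,word_tier Tier names (defaults `"phoneme"`, `"word"`).
#' @return A tibble with columns `onset_s`, `tier`, `label`, `word_index`.
#' @export
segmentation_to_events <- function(intervals, phoneme_tier = "phoneme",
                                   word_tier = "word") {
  keep <- intervals$label != "" & intervals$tier %in% c(phoneme_tier, word_tier)
  d <- intervals[keep, , drop = FALSE]
  words <- d[d$tier == word_tier, , drop = FALSE]
  words <- words[order(words$start_s), , drop = FALSE]
  phons <- d[d$tier == phoneme_tier, , drop = FALSE]
  phons <- phons[order(phons$start_s), , drop = FALSE]
  widx <- function(t) {
    i <- findInterval(t + 1e-9, words$start_s)
    ifelse(i < 1L, NA_integer_, i)
  }
  dplyr::bind_rows(
    tibble(onset_s = words$start_s, tier = "word", label = words$label,
           word_index = seq_len(nrow(words))),
    tibble(onset_s = phons$start_s, tier = "phoneme", label = phons$label,
           word_index = as.integer(widx(phons$start_s)))
  ) |> dplyr::arrange(.data$onset_s)
}

#' Read / write a TSV event table
#'
#' Columns: `onset_s`, `tier`, `label`, `word_index`.
#' @param path File path.
#' @return A tibble (for `read_events_tsv`); `path` invisibly for the writer.
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    onset_s = readr::col_double(),
                    tier = readr::col_character(),
                    label = readr::col_character(),
                    word_index = readr::col_integer()
                  ))
}

#' @rdname read_events_tsv
#' @param events Event tibble to write.
#' @export
write_events_tsv <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}
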