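# End-to-end drivers: recording -> per-channel metrics -> per-subject
# composites -> group comparison tables.

#' Per-channel shape and PAC metrics for one recording
#'
#' Applies the preprocessing chain (optional common average reference, then
#' a zero-phase high-pass) and computes, for each requested channel, the
#' four waveform-shape ratios, the quadrant label and (optionally) the
#' normalized modulation index. Artifact intervals stored in the recording
#' are respected throughout.
#'
#' @param rec an [new_recording()] object.
#' @param channels channels to analyse (default the sensorimotor pair).
#' @param band cycle band, a [band_spec()] (default beta 13-30 Hz).
#' @param reference `"none"` or `"average"`. The common average is the
#'   study-style choice for dense montages; for few-channel synthetic
#'   recordings, where every channel carries the same oscillation, it would
#'   subtract the signal of interest, so the default is `"none"`.
#' @param highpass high-pass cutoff in Hz (`NULL` to skip).
#' @param width sharpness half-window in samples.
#' @param min_cycles minimum valid cycles for defined shape metrics.
#' @param pac compute the modulation index as well?
#' @param phase_band,amp_band PAC bands, [band_spec()] objects.
#' @param n_bins PAC phase-bin count.
#' @return A tibble with one row per channel: `channel`,
#'   `peak_trough_ratio`, `rise_fall_ratio`, `sharpness_ratio`,
#'   `steepness_ratio`, `quadrant`, `n_valid_cycles` and (if requested)
#'   `pac`.
#' @export
analyze_recording <- function(rec, channels = c("C3", "C4"),
                              band = band_spec(),
                              reference = c("none", "average"),
                              highpass = 0.5, width = 3L, min_cycles = 5L,
                              pac = TRUE,
                              phase_band = band_spec(13, 30, 231),
                              amp_band = band_spec(50, 150, 240),
                              n_bins = 18L) {
  stopifnot(inherits(rec, "eeg_recording"))
  reference <- match.arg(reference)
  if (reference == "average") rec <- reference_average(rec)
  if (!is.null(highpass)) rec <- filter_highpass(rec, highpass)
  use <- intersect(channels, good_channels(rec))
  if (length(use) == 0L) cs_abort("none of the requested channels available",
                                  "undefined_metric")
  rows <- purrr::map(use, function(ch) {
    x <- channel_signal(rec, ch)
    sm <- waveform_shape(x, rec$fs, band, rec$artifact_intervals, width,
                         min_cycles)
    out <- dplyr::bind_cols(tibble(channel = ch), sm)
    if (pac) {
      out$pac <- pac_mi(x, rec$fs, phase_band, amp_band, n_bins,
                        rec$artifact_intervals)$mi
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Per-channel metrics for a whole cohort
#'
#' Maps [analyze_recording()] over the rows of a simulated (or assembled)
#' cohort tibble.
#'
#' @param cohort a tibble with columns `subject`, `condition`, `recording`
#'   (list of `eeg_recording`), as returned by [simulate_cohort()].
#' @param ... passed on to [analyze_recording()].
#' @return A tibble with columns `subject`, `condition`, `channel` and the
#'   per-channel metrics.
#' @export
analyze_cohort <- function(cohort, ...) {
  stopifnot(all(c("subject", "condition", "recording") %in% names(cohort)))
  purrr::pmap(cohort[c("subject", "condition", "recording")],
              function(subject, condition, recording) {
                dplyr::bind_cols(
                  tibble(subject = subject, condition = condition),
                  analyze_recording(recording, ...)
                )
              }) |>
    dplyr::bind_rows()
}

#' Composite per-channel metrics into one value per subject
#'
#' Averages each numeric metric over the available channels of the
#' sensorimotor group (or any channel group), so that every subject
#' contributes one value per condition; a subject-condition with a single
#' defined channel keeps that channel's value.
#'
#' @param metrics output of [analyze_cohort()].
#' @param channels channels making up the composite.
#' @param metric_cols metric columns to composite (defaults to all numeric
#'   metric columns present).
#' @return A tibble with one row per subject-condition.
#' @export
composite_metrics <- function(metrics, channels = c("C3", "C4"),
                              metric_cols = intersect(
                                c("peak_trough_ratio", "rise_fall_ratio",
                                  "sharpness_ratio", "steepness_ratio",
                                  "pac"),
                                names(metrics))) {
  metrics |>
    dplyr::filter(.data$channel %in% channels) |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metric_cols),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Compare two conditions metric by metric
#'
#' For paired designs (off vs on medication) applies the Wilcoxon
#' signed-rank test per metric; for unpaired designs (patients vs controls)
#' the rank-sum test. Raw p values are FDR-adjusted across all metrics in
#' the table (one family), and Cohen's d is computed with pooled standard
#' deviation, log-scaling the metrics named in `log_scale` (PAC by
#' default).
#'
#' @param values a tibble with columns `subject`, `condition` and one
#'   column per metric, as from [composite_metrics()].
#' @param conditions length-2 character vector: the condition compared and
#'   the reference (effect signs follow `conditions[1] - conditions[2]`).
#' @param metrics metric columns to test.
#' @param paired paired design?
#' @param log_scale metric names to log-transform for the effect size.
#' @return A `group_comparison` tibble: `metric`, `n`, `statistic`,
#'   `p_raw`, `p_fdr`, `cohens_d`.
#' @export
compare_conditions <- function(values, conditions = c("off", "on"),
                               metrics = intersect(
                                 c("sharpness_ratio", "steepness_ratio",
                                   "pac"),
                                 names(values)),
                               paired = TRUE, log_scale = "pac") {
  stopifnot(length(conditions) == 2L)
  va <- dplyr::filter(values, .data$condition == conditions[1])
  vb <- dplyr::filter(values, .data$condition == conditions[2])
  if (paired) {
    common <- intersect(va$subject, vb$subject)
    va <- va[match(common, va$subject), ]
    vb <- vb[match(common, vb$subject), ]
  }
  rows <- purrr::map(metrics, function(m) {
    a <- va[[m]]
    b <- vb[[m]]
    if (paired) {
      keep <- !is.na(a) & !is.na(b)
      a <- a[keep]
      b <- b[keep]
      tst <- signed_rank_test(a, b)
      n <- tst$n
    } else {
      a <- a[!is.na(a)]
      b <- b[!is.na(b)]
      tst <- rank_sum_test(a, b)
      n <- tst$n_x + tst$n_y
    }
    tibble(metric = m, n = n, statistic = tst$statistic, p_raw = tst$p,
           cohens_d = cohens_d(a, b, log_scale = m %in% log_scale))
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_adjust(out$p_raw)
  out <- out[, c("metric", "n", "statistic", "p_raw", "p_fdr", "cohens_d")]
  class(out) <- c("group_comparison", class(out))
  attr(out, "conditions") <- conditions
  attr(out, "paired") <- paired
  out
}

#' @export
tidy.group_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "group_comparison")
  out
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    n_metrics = nrow(x),
    n_significant_fdr = sum(x$p_fdr < 0.05),
    paired = attr(x, "paired"),
    comparison = paste(attr(x, "conditions"), collapse = " vs ")
  )
}
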