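# Group-level layer: nonparametric paired/unpaired tests, Spearman
# correlation, Benjamini-Hochberg FDR, Cohen's d, the Q4 inclusion rule and
# topographic statistic maps.

#' Wilcoxon signed-rank test (paired)
#'
#' Zero differences are dropped; the reported statistic is the smaller of
#' the positive and negative rank sums (tied ranks averaged). The p value is
#' exact for n <= 25 without ties in the absolute differences, otherwise a
#' normal approximation with continuity correction is used.
#'
#' @param a,b paired numeric vectors (e.g. off and on medication).
#' @return A one-row tibble: `statistic`, `p`, `n` (pairs used), `method`.
#' @export
signed_rank_test <- function(a, b) {
  if (length(a) != length(b)) cs_abort("a and b must be paired", "parameter")
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) cs_abort("all differences are zero", "undefined_test")
  if (n < 5L) cs_abort("need at least 5 nonzero differences", "parameter")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  exact <- n <= 25L && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value
  )
  tibble(statistic = min(w_pos, w_neg), p = p, n = n,
         method = if (exact) "exact" else "normal approximation")
}

#' Wilcoxon rank-sum test (unpaired)
#'
#' Tie-corrected normal-approximation z statistic (positive when `x` tends
#' to exceed `y`) with continuity correction and two-sided p value.
#'
#' @param x,y numeric vectors for the two groups (each n >= 4).
#' @return A one-row tibble: `statistic` (z), `p`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 4L || n2 < 4L) cs_abort("each group needs at least 4 values",
                                   "parameter")
  n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) cs_abort("degenerate rank distribution", "undefined_test")
  num <- w - mu
  z <- (num - sign(num) * 0.5) / sqrt(sigma2)
  tibble(statistic = z, p = 2 * pnorm(-abs(z)), n_x = n1, n_y = n2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a t-approximation p value on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 5 complete pairs).
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 5L) cs_abort("need at least 5 complete pairs", "parameter")
  if (sd(x) == 0 || sd(y) == 0) {
    cs_abort("correlation undefined for a constant vector",
             "undefined_correlation")
  }
  r <- cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  tibble(r = r, p = p, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone and capped at 1, returned in the
#' input order.
#'
#' @param p_raw numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
fdr_adjust <- function(p_raw) {
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    cs_abort("p values must lie in [0, 1]", "parameter")
  }
  p.adjust(p_raw, method = "BH")
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled standard deviation from unbiased variances. With `log_scale =
#' TRUE` both vectors are natural-log transformed first (used for PAC,
#' whose raw distribution is strongly right-skewed).
#'
#' @param a,b numeric vectors (each n >= 2; all positive if `log_scale`).
#' @param log_scale log-transform before computing the effect size.
#' @return A single numeric effect size.
#' @export
cohens_d <- function(a, b, log_scale = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    cs_abort("each group needs at least 2 values", "parameter")
  }
  if (log_scale) {
    if (any(a <= 0) || any(b <= 0)) {
      cs_abort("log scaling requires positive values", "parameter")
    }
    a <- log(a)
    b <- log(b)
  }
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) cs_abort("zero pooled standard deviation", "undefined_effect")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Q4 inclusion rule
#'
#' Retains, per subject, the channels whose waveform falls in quadrant Q4
#' (sharper peaks, steeper decays - the canonical sensorimotor shape) in
#' BOTH conditions; a subject is retained when at least one channel
#' qualifies, and metric values are composited over the retained channels
#' only (a single retained channel contributes its own values).
#'
#' @param metrics a tibble with columns `subject`, `condition`, `channel`,
#'   `quadrant`, plus one or more numeric metric columns named in
#'   `metric_cols`.
#' @param metric_cols names of the metric columns to composite.
#' @return A tibble with columns `subject`, `condition`, `n_channels` and
#'   the composited metrics; subjects failing the criterion are absent (an
#'   empty result is allowed).
#' @export
q4_inclusion <- function(metrics,
                         metric_cols = intersect(
                           c("sharpness_ratio", "steepness_ratio",
                             "peak_trough_ratio", "rise_fall_ratio", "pac"),
                           names(metrics))) {
  stopifnot(all(c("subject", "condition", "channel", "quadrant")
                %in% names(metrics)))
  n_cond <- length(unique(metrics$condition))
  retained <- metrics |>
    dplyr::group_by(.data$subject, .data$channel) |>
    dplyr::filter(dplyr::n() == n_cond && all(.data$quadrant == "Q4")) |>
    dplyr::ungroup()
  retained |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(
      n_channels = dplyr::n(),
      dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Topographic statistic map
#'
#' Rescales per-electrode test evidence for topographic display: electrodes
#' that do not reach significance are set to 0; significant electrodes are
#' rescaled to `100 * score / max(score among significant)`, so the most
#' significant electrode maps to 100. `score` must be on a scale where
#' larger means more significant (e.g. `|z|` or `-log10(p)`); for the
#' signed-rank statistic, whose small values are the significant ones, pass
#' a transformed score.
#'
#' @param score named numeric vector of per-electrode evidence (larger =
#'   more significant).
#' @param significant logical vector marking electrodes that reach the
#'   critical value.
#' @return A tibble with columns `electrode` and `value` in `[0, 100]`.
#' @export
topo_stat_map <- function(score, significant) {
  if (length(score) == 0L) cs_abort("need at least one electrode", "parameter")
  if (length(significant) != length(score)) {
    cs_abort("score and significant must have equal length", "parameter")
  }
  value <- numeric(length(score))
  if (any(significant)) {
    value[significant] <- 100 * score[significant] /
      max(score[significant])
  }
  tibble(electrode = names(score) %||% as.character(seq_along(score)),
         value = value)
}
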