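# One replicate of the full group pipeline: simulate a paired cohort,
# extract per-channel steepness/sharpness, composite over channels, paired
# signed-rank test. Returns p values and observed direction per metric.

cohort_pipeline_rep <- function(seed, off, on, channels = c("C3", "C4"),
                                n_subjects = 15) {
  spec <- cohort_spec(n_subjects = n_subjects, channels = channels,
                      off = off, on = on, seed = seed)
  values <- simulate_cohort(spec) |>
    analyze_cohort(pac = FALSE) |>
    composite_metrics()
  voff <- values[values$condition == "off", ]
  von <- values[values$condition == "on", ]
  von <- von[match(voff$subject, von$subject), ]
  out <- lapply(c("sharpness_ratio", "steepness_ratio"), function(m) {
    tst <- signed_rank_test(voff[[m]], von[[m]])
    tibble::tibble(metric = m, p = tst$p,
                   off_higher = mean(voff[[m]]) > mean(von[[m]]))
  })
  dplyr::bind_rows(out)
}
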