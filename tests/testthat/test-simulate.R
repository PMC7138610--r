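test_that("generation is deterministic for a fixed seed", {
  p <- short_protocol()
  gt <- noisy_gt(seed = 21)
  a <- generate_trial_stack(gt, p, condition_label("V", "on"), 3,
                            dim_px = c(10, 10))
  b <- generate_trial_stack(gt, p, condition_label("V", "on"), 3,
                            dim_px = c(10, 10))
  expect_identical(a$pixels, b$pixels)
  s1 <- generate_spike_counts(gt, p, condition_label("S", "on", "mua"), 6, 5)
  s2 <- generate_spike_counts(gt, p, condition_label("S", "on", "mua"), 6, 5)
  expect_identical(s1$counts, s2$counts)
  # different trials differ
  c2 <- generate_trial_stack(gt, p, condition_label("V", "on"), 4,
                             dim_px = c(10, 10))
  expect_false(identical(a$pixels, c2$pixels))
})

test_that("noise-free ROI average matches the closed-form signal", {
  p <- short_protocol()
  gt <- clean_gt(seed = 2, late_rise = list(onset = 2, slope = 0.003))
  for (cond in list(condition_label("V", "off"), condition_label("V", "on"),
                    condition_label("S", "on"))) {
    st <- generate_trial_stack(gt, p, cond, 1, dim_px = c(12, 12))
    # ROI average of raw pixels is illum_mean_roi * (1 + signal)
    sig <- roi_signal(gt, p, cond)
    # identify roi pixels as those modulated at the end of photostim window
    v <- generate_trial_stack(clean_gt(seed = 2), p, condition_label("V", "off"),
                              1, dim_px = c(12, 12))
    roi <- apply(v$pixels[frame_window(0.2, 1.2, 100), , ], c(2, 3), stats::var) > 1e-12
    tr <- spatial_average(st, roi)
    illum <- spatial_average(v, roi)[1] # first frame is pre-stimulus: signal 0
    expect_lt(max(abs(tr / illum - (1 + sig))), 1e-10)
  }
})

test_that("identity gains reproduce control statistics", {
  p <- short_protocol()
  gt <- clean_gt(seed = 5, g_e = 1, g_s = 1, spont_offset = 0,
                 spont_process = list(std = 0.01, correlation_time = 2))
  v <- generate_roi_traces(gt, p, condition_label("V", "off"), 30)
  vph <- generate_roi_traces(gt, p, condition_label("V", "on"), 30)
  # means differ only by Monte-Carlo error of the spontaneous process
  mc <- gt$spont_process$std / sqrt(30)
  expect_lt(max(abs(colMeans(v) - colMeans(vph))), 6 * mc)
})

test_that("spontaneous condition is the pure gated process", {
  p <- short_protocol()
  gt <- clean_gt(seed = 7, g_s = 0.4, spont_offset = 0,
                 spont_process = list(std = 0.02, correlation_time = 1))
  tr <- generate_roi_traces(gt, p, condition_label("S", "on"), 1,
                            noise_stream = 42L)
  # reconstruct the same OU draw through the public seed contract
  gt0 <- clean_gt(seed = 7, g_s = 1, spont_offset = 0,
                  spont_process = list(std = 0.02, correlation_time = 1))
  base <- generate_roi_traces(gt0, p, condition_label("S", "on"), 1,
                              noise_stream = 42L)
  times <- protocol_times(p)
  gate <- ifelse(times >= 2.5 & times < 2.5 + p$photostim_duration, 0.4, 1)
  expect_equal(as.vector(tr), as.vector(base) * gate, tolerance = 1e-12)
})

test_that("photostimulated spontaneous suppression matches expectation", {
  # time-averaged S_ph level over the photostim window converges to the
  # offset (the OU process is zero mean; the divisive gain acts on variance)
  p <- short_protocol()
  gt <- noisy_gt(seed = 9, g_s = 0.6, spont_offset = -0.03,
                 spont_process = list(std = 0.01, correlation_time = 1))
  tr <- generate_roi_traces(gt, p, condition_label("S", "on", "mua"), 60)
  win <- frame_window(p$photostim_onset,
                      p$photostim_onset + p$photostim_duration, 100)
  avg <- mean(tr[, win])
  expect_lt(abs(avg - (-0.03)), 5e-3)
  # and the variance is suppressed by g_s^2 relative to the pre window
  pre <- frame_window(0, p$photostim_onset, 100)
  ratio <- stats::var(as.vector(tr[, win])) / stats::var(as.vector(tr[, pre]))
  expect_equal(ratio, 0.36, tolerance = 0.08)
})

test_that("spike counts follow the gated Poisson model", {
  p <- short_protocol()
  gt <- noisy_gt(seed = 2, g_s = 0.5, spont_offset = 0)
  # flat 10 Hz unit: mean count per 0.2-s bin is 2 before photostimulation
  gtf <- noisy_gt(seed = 2, g_s = 1, spont_offset = 0,
                  rate_range = c(10, 10))
  scm <- generate_spike_counts(gtf, p, condition_label("S", "off", "mua"),
                               n_units = 1, n_trials = 400)
  expect_equal(mean(scm$counts), 2, tolerance = 0.05)

  # halved gain halves the post/pre mean-count ratio
  scm2 <- generate_spike_counts(gt, p, condition_label("S", "on", "mua"),
                                n_units = 40, n_trials = 40)
  r <- rate_traces(scm2)
  pre <- 1:12    # [0, 2.4) s: clear of the bin straddling photostim onset
  post <- 14:33  # [2.6, 6.6) s
  ratios <- rowMeans(r[, post]) / rowMeans(r[, pre])
  expect_lt(abs(mean(ratios) - 0.5), 0.02)
  expect_error(generate_spike_counts(gt, p, condition_label("S", "off", "mua"),
                                     n_units = 0), "n_units")
})

test_that("late calcium rise is imaging-only (structural dissociation)", {
  p <- short_protocol()
  gt <- clean_gt(seed = 3, g_e = 1, g_s = 1, spont_offset = 0,
                 late_rise = list(onset = 1, slope = 0.05))
  img <- roi_signal(gt, p, condition_label("S", "on"), late = TRUE)
  expect_gt(max(img), 0)
  # spike rates of the same ground truth stay flat
  scm <- generate_spike_counts(gt, p, condition_label("S", "on", "mua"),
                               n_units = 20, n_trials = 40)
  r <- rate_traces(scm)
  pre <- frame_window(0, 2.5, 5)
  late_win <- frame_window(5, 7, 5)
  expect_equal(mean(rowMeans(r[, late_win]) / rowMeans(r[, pre])), 1,
               tolerance = 0.05)
})

test_that("evoked amplitude is nondecreasing in contrast", {
  for (n_exp in c(0.5, 1, 2, 4)) {
    cc <- seq(0.05, 1, length.out = 12)
    expect_true(all(diff(naka_rushton(cc, 1.3, 0.3, n_exp, 0.1)) >= 0))
  }
  # and through the generator's evoked term
  p <- short_contrast_protocol()
  gt <- clean_gt(seed = 1)
  amps <- vapply(c(0.0625, 0.125, 0.25, 0.5, 1), function(co) {
    max(roi_signal(gt, p, condition_label("V", "off", contrast = co)))
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("cohort generation writes a complete, self-describing dataset", {
  p <- short_protocol(n_stim = 2, trial_duration = 6)
  gts <- lapply(1:3, function(s) clean_gt(seed = s, noise_std = 0.002))
  out <- withr::local_tempdir()
  man <- generate_cohort(gts, p, out, n_trials = 2, dim_px = c(8, 8),
                         overwrite = TRUE)
  # 3 subjects x 4 conditions x 2 trials
  expect_equal(nrow(man), 24)
  expect_length(list.files(out, pattern = "\\.tif$", recursive = TRUE), 24)
  rescanned <- scan_cohort(out)
  man_sorted <- man[order(man$subject, man$condition, man$trial), ]
  rownames(man_sorted) <- rownames(rescanned) <- NULL
  expect_equal(rescanned, man_sorted)
  expect_error(generate_cohort(gts, p, out, n_trials = 1), "not empty")
})

test_that("state and drug variants change only the flagged parameters", {
  aw <- ground_truth("awake", seed = 1)
  an <- ground_truth("anesthetized", seed = 1)
  expect_lt(aw$g_e, 1); expect_lt(an$g_e, aw$g_e)  # g_aw < g_an as 1/g_e
  expect_lt(an$spont_offset, aw$spont_offset)
  expect_lt(aw$kernel$peak_delay, an$kernel$peak_delay)
  expect_identical(aw$tuning, an$tuning)
  expect_identical(aw$artifacts, an$artifacts)

  mdl <- apply_drug(an, "MDL")
  expect_equal(mdl$g_e, 0.9)
  expect_lt(mdl$late_rise$slope, an$late_rise$slope)
  expect_equal(mdl$g_s, an$g_s)
  way <- apply_drug(an, "WAY")
  expect_equal(way$g_s, 1)
  expect_equal(way$spont_offset, 0)
  expect_equal(way$g_e, an$g_e)
})
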