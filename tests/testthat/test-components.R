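fake_traceset <- function(means, rate = 100) {
  structure(list(traces = lapply(means, function(v) rbind(v, v)),
                 mean = means, roi_mask = matrix(TRUE, 2, 2),
                 sampling_rate = rate, normalization = list(),
                 stage_log = list()),
            class = "roi_trace_set")
}

test_that("first-peak normalization applies one common scale", {
  p <- short_protocol()
  t <- protocol_times(p)
  v <- 0.04 * calcium_kernel(t - 0.2, 0.25, 0.9)
  ts <- fake_traceset(list(V = v, V_ph = 0.5 * v))
  out <- normalize_to_first_peak(ts, p)
  win <- frame_window(0.2, 1.2, 100)
  expect_equal(max(out$mean$V[win]), 1)
  # ratios between conditions are unchanged by the common scale
  expect_equal(out$mean$V_ph / pmax(out$mean$V, 1e-12),
               (0.5 * v) / pmax(v, 1e-12))
  expect_equal(out$normalization$first_peak, max(v[win]))
  # nonpositive peak is an error
  ts0 <- fake_traceset(list(V = -v))
  expect_error(normalize_to_first_peak(ts0, p), "nonpositive")
})

test_that("peak windows are found on the control kernel maximum", {
  p <- short_protocol()
  gt <- clean_gt()
  tr <- roi_signal(gt, p, condition_label("V", "off"))
  win <- locate_windows(tr, p)
  # generator kernel peaks peak_delay after each onset, within one frame
  expect_equal(win$peak_times, p$stim_onsets + gt$kernel$peak_delay,
               tolerance = 0.011)
  for (i in seq_along(win$w1)) {
    expect_equal(diff(win$w1[[i]]), 0.4)
    expect_equal(diff(win$w2[[i]]), 0.2)
    expect_equal(win$w2[[i]][2], p$stim_onsets[i])  # w2 ends at onset
  }
  expect_equal(win$w_ph, c(2.5, 9.5))
  # flat trace: earliest-sample tie-break plus a warning
  expect_warning(wf <- locate_windows(rep(1, n_frames(p)), p), "flat")
  expect_equal(wf$peak_times, p$stim_onsets)
  # stimulus too close to the trace end truncates w1
  p_end <- protocol_spec(trial_duration = 30, stim_onsets = 29.9,
                         photostim_onset = 2.5, photostim_duration = 16)
  tr_end <- c(rep(0, 2990), seq(0, 1, length.out = 10))
  # both the peak-search window and w1 are truncated at the trace end
  expect_warning(expect_warning(locate_windows(tr_end, p_end), "truncated"),
                 "truncated")
})

test_that("w_red starts at the first significant sample after photostim onset", {
  p <- short_protocol()
  tr <- roi_signal(clean_gt(), p, condition_label("V", "off"))
  mask <- rep(FALSE, n_frames(p))
  mask[301:400] <- TRUE  # 3.0 s - 4.0 s significant
  mask[150:160] <- TRUE  # pre-photostim run must be ignored
  win <- locate_windows(tr, p, sig_mask = mask)
  expect_equal(win$w_red, c(3.0, 4.0))
  expect_true(win$w_red[1] >= win$w_ph[1] && win$w_red[2] <= win$w_ph[2])
})

test_that("metrics follow the amplitude/baseline/magnitude definitions", {
  p <- default_protocol()
  win <- suppressWarnings(locate_windows(rep(0.3, n_frames(p)), p))
  m <- compute_metrics(rep(0.3, n_frames(p)), win)
  expect_equal(m$amplitude, rep(0.3, 10))
  expect_equal(m$baseline, rep(0.3, 10))
  expect_equal(m$magnitude, rep(0, 10))
  # w1 covers 40 frames at 100 samples/s
  expect_length(frame_window(win$w1[[1]][1], win$w1[[1]][2], 100), 40)
  # |0.8 - (-0.2)| = 1.0
  expect_equal(abs(0.8 - (-0.2)), 1.0)
  # magnitude is invariant to adding a constant to the whole trace
  tr <- roi_signal(clean_gt(), p, condition_label("V", "off"))
  w2 <- locate_windows(tr, p)
  m1 <- compute_metrics(tr, w2)
  m2 <- compute_metrics(tr + 0.37, w2)
  expect_equal(m1$magnitude, m2$magnitude, tolerance = 1e-12)
  expect_equal(m2$amplitude, m1$amplitude + 0.37, tolerance = 1e-12)
})

test_that("evoked component isolates the injected evoked waveform", {
  p <- short_protocol()
  # identical V_ph and S_ph trials: component is exactly zero
  x <- matrix(rnorm(5 * 100), 5, 100)
  e0 <- evoked_component(x, x)
  expect_equal(e0$mean, rep(0, 100))
  expect_equal(e0$pairing, "index")
  # shared spontaneous draw cancels exactly in the paired subtraction
  gt <- noisy_gt(seed = 13, spont_process = list(std = 0.02,
                                                 correlation_time = 2))
  vph <- generate_roi_traces(gt, p, condition_label("V", "on"), 8,
                             noise_stream = 5L)
  sph <- generate_roi_traces(gt, p, condition_label("S", "on"), 8,
                             noise_stream = 5L)
  e <- evoked_component(vph, sph)
  injected <- roi_signal(gt, p, condition_label("V", "on")) -
    roi_signal(gt, p, condition_label("S", "on"))
  expect_lt(max(abs(e$mean - injected)), 1e-10)
  # unequal counts fall back to subtracting the S_ph mean
  e2 <- evoked_component(vph, sph[1:5, ])
  expect_equal(e2$pairing, "mean")
  expect_equal(e2$trials[1, ], vph[1, ] - colMeans(sph[1:5, ]))
  expect_error(evoked_component(vph, vph[0, , drop = FALSE]), "no S_ph")
})

test_that("component recovery error shrinks like 1/sqrt(trials)", {
  p <- short_protocol()
  gt <- noisy_gt(seed = 17, spont_process = list(std = 0.05,
                                                 correlation_time = 0.3))
  injected <- roi_signal(gt, p, condition_label("V", "on")) -
    roi_signal(gt, p, condition_label("S", "on"))
  rmse <- vapply(c(8, 128), function(n) {
    vph <- generate_roi_traces(gt, p, condition_label("V", "on"), n,
                               noise_stream = 1L)
    sph <- generate_roi_traces(gt, p, condition_label("S", "on"), n,
                               noise_stream = 2L)
    e <- evoked_component(vph, sph)
    sqrt(mean((e$mean - injected)^2))
  }, numeric(1))
  # 16x the trials: RMSE should drop by about 4, allow wide stochastic slack
  expect_lt(rmse[2], rmse[1] / 2)
})

test_that("MUA normalization follows the spontaneous and evoked rules", {
  p <- default_protocol()
  # constant 5 Hz unit: 1 spike per 0.2-s bin
  counts <- array(1L, dim = c(1, 150, 10))
  scm <- spike_count_matrix(counts, 0.2)
  expect_equal(dim(scm$counts)[2], 150)  # 30 s at 0.2-s bins
  sp <- normalize_mua(scm, p, "spontaneous")
  expect_equal(sp$mean, rep(1, 150))
  ev <- normalize_mua(scm, p, "evoked")
  expect_equal(ev$mean, rep(0, 150))
  # final division by the control first-stimulus amplitude
  counts2 <- counts; counts2[1, 3, ] <- 5L
  ev2 <- normalize_mua(spike_count_matrix(counts2, 0.2), p, "evoked",
                       control_first_amp = 2)
  # 1-s baseline spans bins 1..5 (mean 1.8 with the bin-3 burst of 5)
  expect_equal(ev2$mean[3], (5 - 1.8) / 2, tolerance = 1e-12)
  # zero-baseline units are flagged and excluded
  counts3 <- array(1L, dim = c(2, 150, 4))
  counts3[2, 1:5, ] <- 0L
  counts3[2, 6:150, ] <- 0L
  sp3 <- normalize_mua(spike_count_matrix(counts3, 0.2), p, "spontaneous")
  expect_equal(sp3$excluded, 2)
  expect_equal(nrow(sp3$traces), 1)
})

test_that("separability: V_ph metrics split into evoked and baseline parts", {
  # built as V_ph = E + S with a shared spontaneous process:
  # magnitude(V_ph) matches magnitude(E_ph), amplitude keeps the shift
  p <- short_protocol()
  gt <- noisy_gt(seed = 23, g_e = 0.6, g_s = 0.8, spont_offset = -0.02,
                 late_rise = list(onset = 6, slope = 0),
                 spont_process = list(std = 0.01, correlation_time = 2))
  n <- 40
  vph <- generate_roi_traces(gt, p, condition_label("V", "on"), n,
                             noise_stream = 9L)
  sph <- generate_roi_traces(gt, p, condition_label("S", "on"), n,
                             noise_stream = 9L)
  ctrl <- roi_signal(gt, p, condition_label("V", "off"))
  win <- locate_windows(ctrl, p)
  m_vph <- compute_metrics(colMeans(vph), win)
  m_eph <- compute_metrics(evoked_component(vph, sph)$mean, win)
  # stimuli 2..3 fall inside the photostimulation window
  inside <- 2:3
  expect_equal(mean(m_vph$magnitude[inside]), mean(m_eph$magnitude[inside]),
               tolerance = 0.05)
  shift <- mean(m_vph$amplitude[inside] - m_eph$amplitude[inside])
  expect_lt(abs(shift - gt$spont_offset), abs(0.15 * gt$spont_offset))
})
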