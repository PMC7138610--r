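make_stack <- function(px, cond = condition_label("V", "off"), trial = 1,
                       rate = 100) {
  trial_stack(px, cond, trial, rate)
}

test_that("delta-F/F is exactly zero for blank-identical and constant input", {
  p <- short_protocol(n_stim = 1, trial_duration = 4)
  n <- n_frames(p)
  set.seed(1)
  blank_px <- array(stats::runif(n * 16, 50, 150), dim = c(n, 4, 4))
  blank <- blank_reference(list(make_stack(blank_px)), p)
  # stack identical to the blank
  d <- compute_dff(make_stack(blank_px), blank, p)
  expect_lt(max(abs(d)), 1e-12)
  # any constant stack against a constant blank
  const <- array(7, dim = c(n, 4, 4))
  blank2 <- blank_reference(list(make_stack(array(3, dim = c(n, 4, 4)))), p)
  expect_lt(max(abs(compute_dff(make_stack(const), blank2, p))), 1e-12)
})

test_that("a 10% transient over the pre-stimulus mean gives dff = 0.1", {
  # hand-applied rule: d = F/F_pre; dff = (d - blank)/mean_t(blank)
  p <- short_protocol(n_stim = 1, trial_duration = 4)
  n <- n_frames(p)
  px <- array(200, dim = c(n, 3, 3))
  px[101:110, 2, 2] <- 220  # +10% transient after the pre-stim window
  blank <- blank_reference(list(make_stack(array(100, dim = c(n, 3, 3)))), p)
  d <- compute_dff(make_stack(px), blank, p)
  expect_equal(d[105, 2, 2], 0.1, tolerance = 1e-12)
  expect_lt(max(abs(d[1:100, , ])), 1e-12)
})

test_that("delta-F/F input errors are reported with the offending pixel", {
  p <- short_protocol(n_stim = 1, trial_duration = 4)
  n <- n_frames(p)
  px <- array(1, dim = c(n, 2, 2))
  px[1:20, 2, 1] <- 0  # zero pre-stimulus mean at (2, 1)
  blank <- blank_reference(list(make_stack(array(1, dim = c(n, 2, 2)))), p)
  expect_error(compute_dff(make_stack(px), blank, p), "\\(2, 1\\)")
  small <- array(1, dim = c(n, 3, 3))
  expect_error(compute_dff(make_stack(small), blank, p), "shape mismatch")
})

test_that("spatial high-pass removes DC and attenuates the cutoff to 1/sqrt(2)", {
  expect_lt(max(abs(spatial_filter(matrix(5, 16, 16), smooth_sigma = 0,
                                   cutoff_wavelength = 4))), 1e-12)
  # sinusoid exactly at the cutoff frequency (wavelength 33 px over 66 px)
  h <- w <- 66
  fr <- outer(seq_len(h), rep(1, w)) |> (\(m) sin(2 * pi * 2 * (m - 1) / h))()
  out <- spatial_filter(fr, smooth_sigma = 0, butter_order = 4,
                        cutoff_wavelength = 33)
  atten <- max(abs(out)) / max(abs(fr))
  expect_equal(atten, 1 / sqrt(2), tolerance = 0.01)
  # disabled filters are the identity
  x <- matrix(rnorm(64), 8, 8)
  expect_equal(spatial_filter(x, smooth_sigma = 0, cutoff_wavelength = NULL),
               x, tolerance = 1e-12)
  expect_error(spatial_filter(x, cutoff_wavelength = 2), "cutoff_wavelength")
})

test_that("ROI selection finds the responsive blob with row-major tie-break", {
  g <- function(cx, cy, s, n = 21) {
    m <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - cy)^2 + (j - cx)^2) / (2 * s^2)))
    m
  }
  one <- g(11, 11, 2)
  mask <- select_roi(one, 0.7)
  expect_true(mask[11, 11])
  expect_equal(sum(mask), sum(one >= 0.7 * max(one)))
  # two equal disjoint bumps: the component of the first-scanned maximum wins
  two <- pmax(g(5, 5, 1.5), g(16, 16, 1.5))
  mask2 <- select_roi(two, 0.7)
  expect_true(mask2[5, 5])
  expect_false(mask2[16, 16])
  # threshold 1 keeps only the arg-max pixel
  expect_equal(sum(select_roi(one, 1)), 1)
  expect_error(select_roi(matrix(0, 4, 4)), "no responsive region")
})

test_that("spatial averaging is the unweighted ROI mean", {
  px <- array(0, dim = c(2, 2, 2))
  px[1, , ] <- matrix(c(0, 2, 0, 2), 2, 2)
  px[2, , ] <- 3
  mask <- matrix(TRUE, 2, 2)
  expect_equal(spatial_average(px, mask), c(1, 3))
  expect_error(spatial_average(px, matrix(FALSE, 2, 2)), "empty")
})

test_that("ICA rejection removes a 20-Hz corner artifact, sparing the signal", {
  p <- short_protocol(n_stim = 2, trial_duration = 6)
  gt_art <- noisy_gt(seed = 4,
                     artifacts = list(heartbeat_hz = 10, heartbeat_amp = 0,
                                      respiration_hz = 3, respiration_amp = 0,
                                      photostim_artifact_amp = 0.05,
                                      artifact_corner_fraction = 0.25))
  gt_clean <- noisy_gt(seed = 4)
  conds <- condition_label("V", "on")
  mk <- function(gt) lapply(1:3, function(i)
    generate_trial_stack(gt, p, conds, i, dim_px = c(12, 12))$pixels)
  with_art <- mk(gt_art)
  no_art <- mk(gt_clean)
  res <- remove_artifacts_ica(with_art, p, bands = 20)
  # 20-Hz band power in the corner pixel, during photostimulation
  band_power <- function(px) {
    x <- px[frame_window(3, 6, 100), 12, 1]
    sp <- stats::spec.pgram(stats::ts(x, frequency = 100), plot = FALSE,
                            taper = 0, detrend = TRUE)
    sum(sp$spec[abs(sp$freq - 20) <= 0.5])
  }
  pow_before <- mean(vapply(with_art, band_power, numeric(1)))
  pow_after <- mean(vapply(res$stacks, band_power, numeric(1)))
  expect_gt(pow_before / pow_after, 10)
  # evoked ROI peak changes by < 5%
  roi <- matrix(FALSE, 12, 12); roi[4:9, 4:9] <- TRUE
  peak_of <- function(stks) {
    tr <- colMeans(do.call(rbind, lapply(stks, spatial_average,
                                         roi_mask = roi)))
    max(tr[frame_window(0.2, 1.2, 100)])
  }
  expect_lt(abs(peak_of(res$stacks) - peak_of(with_art)) /
              peak_of(with_art), 0.05)
  expect_true(any(res$report$rejected))

  # no artifact bands requested: pass-through
  res0 <- remove_artifacts_ica(no_art, p, bands = numeric(0))
  expect_identical(res0$stacks, no_art)
  expect_error(remove_artifacts_ica(no_art[1], p), "at least two")
})

test_that("temporal Butterworth reading removes slow drift per pixel", {
  n <- 500
  t <- (0:(n - 1)) / 100
  drift <- 0.5 * t                      # slow ramp, well below 1 Hz
  osc <- sin(2 * pi * 5 * t)            # 5-Hz component, well above cutoff
  px <- array(0, dim = c(n, 2, 2))
  px[, 1, 1] <- drift + osc
  px[, 2, 2] <- drift
  out <- temporal_filter(px, rate = 100, cutoff_hz = 1)
  mid <- 100:400  # avoid filter edge transients
  # oscillation preserved, drift removed
  expect_gt(stats::sd(out[mid, 1, 1]), 0.6)
  expect_lt(stats::sd(out[mid, 2, 2]), 0.02)
  expect_error(temporal_filter(px, 100, 60), "cutoff_hz")
})

test_that("preprocessing pipeline: blank invariant, linearity, stage order", {
  p <- short_protocol(n_stim = 2, trial_duration = 6)
  gt <- noisy_gt(seed = 8, noise_std = 0.003)
  mk <- function(cond, gt, n = 4) lapply(seq_len(n), function(i)
    generate_trial_stack(gt, p, cond, i, dim_px = c(12, 12)))
  stacks <- list(V = mk(condition_label("V", "off"), gt),
                 S = mk(condition_label("S", "off"), gt))
  ts <- preprocess_trials(stacks, p, smooth_sigma = 1)
  # blank-condition trial-averaged trace is zero within noise
  npx <- sum(ts$roi_mask) * n_frames(p) * 4
  expect_lt(abs(mean(ts$mean$S)), max(3 * gt$noise_std / sqrt(npx), 5e-3))
  # doubling the injected evoked amplitude doubles the evoked ROI peak
  gt2 <- noisy_gt(seed = 8, noise_std = 0.003,
                  tuning = list(R_max = 0.2, c50 = 0.25, n = 2, R0 = 0))
  stacks2 <- list(V = mk(condition_label("V", "off"), gt2), S = stacks$S)
  ts2 <- preprocess_trials(stacks2, p, smooth_sigma = 1,
                           roi_mask = ts$roi_mask)
  win <- frame_window(0.2, 1.2, 100)
  r <- max(ts2$mean$V[win]) / max(ts$mean$V[win])
  expect_equal(r, 2, tolerance = 0.05)
  # recorded stage order matches the documented pipeline
  stages <- vapply(ts$stage_log, `[[`, character(1), "stage")
  expect_equal(stages, c("blank_reference", "dff", "spatial_filter",
                         "roi", "spatial_average"))
})
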