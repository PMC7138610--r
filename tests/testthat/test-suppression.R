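test_that("pre/post records and max-rate normalization follow the rules", {
  p <- short_protocol()
  # constant-rate units: pre and post means equal the rate
  tr <- matrix(rep(c(4, 20), each = 50), 2, 50, byrow = TRUE)
  rec <- build_prepost(tr, tr, p, bin_width = 0.2, window_len = 2.5,
                       normalize = FALSE)
  expect_equal(rec$fr_pre, rep(c(4, 20), 2))
  expect_equal(rec$fr_post, rep(c(4, 20), 2))
  # max-pre normalization: the 20-Hz unit maps to 1
  recn <- build_prepost(tr, tr, p, bin_width = 0.2, window_len = 2.5)
  expect_equal(max(recn$fr_pre), 1)
  expect_equal(recn$fr_pre[recn$unit_id == 2 & recn$ph == 0], 1)
  expect_equal(attr(recn, "norm_factor"), 20)
  # a 4-s window does not fit before a 2.5-s photostimulation onset
  expect_error(build_prepost(tr, tr, p, window_len = 4), "window_len")
  expect_error(build_prepost(tr[, 1:20], tr[, 1:20], p, window_len = 2.5),
               "shorter")
})

test_that("rate filters implement the floor-effect exclusions", {
  rec <- data.frame(unit_id = rep(1:4, 2), subject_id = 1,
                    ph = rep(0:1, each = 4),
                    fr_pre = rep(c(0.02, 0.15, 0.95, 1), 2),
                    fr_post = rep(c(0.02, 0.15, 0.95, 1), 2),
                    rate_hz = rep(c(0.5, 3, 19, 25), 2))
  f1 <- filter_units(rec, preset = "band_1_20")  # 1-20 Hz band
  expect_setequal(unique(f1$records$rate_hz), c(3, 19))
  expect_setequal(f1$excluded, c(1, 4))
  f2 <- filter_units(rec)  # default: only < 1 Hz excluded
  expect_setequal(unique(f2$records$rate_hz), c(3, 19, 25))
  rec$rate_hz <- 0.2
  expect_error(filter_units(rec), "all units excluded")
})

test_that("regression recovers exact divisive and subtractive structure", {
  pre <- seq(0.1, 1, 0.1)
  mk <- function(post1) {
    data.frame(unit_id = rep(1:10, 2), subject_id = 1,
               ph = rep(0:1, each = 10), fr_pre = rep(pre, 2),
               fr_post = c(pre, post1), rate_hz = rep(pre * 20, 2))
  }
  fd <- suppressWarnings(fit_suppression(mk(0.5 * pre)))
  expect_equal(unname(fd$coefficients), c(0, 0, 1, -0.5), tolerance = 1e-10)
  fs <- suppressWarnings(fit_suppression(mk(pre - 0.2)))
  expect_equal(unname(fs$coefficients), c(0, -0.2, 1, 0), tolerance = 1e-10)
  # rank-deficient design is reported as such
  bad <- mk(0.5 * pre); bad$fr_pre <- 0.5
  expect_error(fit_suppression(bad), "distinct fr_pre")
})

test_that("OLS estimates agree with an explicit normal-equations oracle", {
  set.seed(42)
  n <- 120
  pre <- runif(2 * n, 0.05, 1)
  ph <- rep(0:1, each = n)
  post <- 0.1 - 0.15 * ph + 0.9 * pre - 0.4 * pre * ph + rnorm(2 * n, 0, 0.05)
  rec <- data.frame(unit_id = rep(seq_len(n), 2), subject_id = 1, ph = ph,
                    fr_pre = pre, fr_post = post, rate_hz = pre * 20)
  fit <- fit_suppression(rec)
  X <- cbind(1, ph, pre, pre * ph)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% post)
  expect_equal(unname(fit$coefficients), as.vector(beta_oracle),
               tolerance = 1e-10)
})

test_that("slope terms are invariant to max-rate normalization", {
  cohort <- simulate_prepost_cohort(1, 40, g_s = 0.7, offset = -0.05,
                                    noise_sd = 0.02, seed = 7)
  rec <- cohort[[1]]
  f_raw <- fit_suppression(rec)
  m <- 3.7
  rec2 <- rec
  rec2$fr_pre <- rec$fr_pre / m
  rec2$fr_post <- rec$fr_post / m
  f_scaled <- fit_suppression(rec2)
  # b3, b4 unchanged; b1, b2 rescale by 1/m
  expect_equal(f_scaled$coefficients[c("b3", "b4")],
               f_raw$coefficients[c("b3", "b4")], tolerance = 1e-10)
  expect_equal(f_scaled$coefficients[c("b1", "b2")],
               f_raw$coefficients[c("b1", "b2")] / m, tolerance = 1e-10)
})

test_that("coefficients identify the generative gain and offset", {
  # b4 -> g_s - 1 and b2 -> offset at low noise and large n
  cohort <- simulate_prepost_cohort(1, 500, g_s = 0.6, offset = -0.1,
                                    noise_sd = 0.01, seed = 11)
  f <- fit_suppression(cohort[[1]])
  expect_lt(abs(f$coefficients["b4"] - (-0.4)), 0.02)
  expect_lt(abs(f$coefficients["b2"] - (-0.1)), 0.02)
  expect_lt(abs(f$coefficients["b3"] - 1), 0.02)
  expect_lt(abs(f$coefficients["b1"]), 0.02)
})

test_that("regression of the control condition is the identity line", {
  cohort <- simulate_prepost_cohort(1, 100, g_s = 1, offset = 0,
                                    noise_sd = 0, seed = 3)
  rec <- cohort[[1]]
  f <- suppressWarnings(fit_suppression(rec[rec$ph == 0, ] |>
                                          (\(d) rbind(d, transform(d, ph = 1L)))()))
  expect_equal(unname(f$coefficients), c(0, 0, 1, 0), tolerance = 1e-10)
})

test_that("classification labels match the coefficient tests", {
  mk_fit <- function(b2, b4) {
    structure(list(coefficients = c(b1 = 0, b2 = b2, b3 = 1, b4 = b4),
                   se = rep(0.01, 4)), class = "suppression_fit")
  }
  jit <- c(-3e-3, 2e-3, -1e-3, 3e-3, -2e-3, 1e-3, -2e-3, 2e-3)
  div <- classify_suppression(lapply(jit, function(e) mk_fit(e, -0.5 + e)))
  expect_equal(div$label, "divisive")
  none <- classify_suppression(lapply(jit, function(e) mk_fit(e, e)))
  expect_equal(none$label, "none")
  mix <- classify_suppression(lapply(jit, function(e)
    mk_fit(-0.1 + e, -0.4 + e)))
  expect_equal(mix$label, "mixed")
  # fewer than three subjects: untested label from point estimates
  two <- classify_suppression(lapply(jit[1:2], function(e) mk_fit(e, -0.5)))
  expect_false(two$tested)
  expect_equal(two$label, "divisive")
})

test_that("Poisson spike-count route recovers divisive suppression", {
  p <- short_protocol()
  gt <- noisy_gt(seed = 31, g_s = 0.6, spont_offset = 0)
  s <- generate_spike_counts(gt, p, condition_label("S", "off", "mua"),
                             n_units = 50, n_trials = 30)
  sph <- generate_spike_counts(gt, p, condition_label("S", "on", "mua"),
                               n_units = 50, n_trials = 30)
  rec <- build_prepost(rate_traces(s), rate_traces(sph), p,
                       bin_width = 0.2, window_len = 2.5)
  f <- fit_suppression(filter_units(rec)$records)
  expect_lt(abs(f$coefficients["b4"] - (-0.4)), 0.06)
  expect_lt(abs(f$coefficients["b3"] - 1), 0.06)
})
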