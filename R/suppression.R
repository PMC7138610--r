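#' Pre/post photostimulation firing-rate records
#'
#' Builds one record per unit per condition from normalized unit traces:
#' the mean rate over a 4-s window ending at photostimulation onset
#' (`fr_pre`) and a 4-s window starting at photostimulation onset
#' (`fr_post`), with a 0/1 photostimulation indicator. Rates are normalized
#' by the maximum pre-window rate over all units of the subject, which
#' rescales intercept-type coefficients but leaves slope-type coefficients
#' unchanged.
#'
#' @param s_traces,sph_traces unit x bin matrices of firing rates (Hz or
#'   ratio-normalized) for the control (S) and photostimulated (S_ph)
#'   spontaneous conditions; rows are matched units.
#' @param protocol a [protocol_spec()].
#' @param bin_width bin width of the traces, s.
#' @param window_len window length, s (must not exceed the photostimulation
#'   onset).
#' @param normalize divide all rates by the maximum pre-window rate.
#' @param subject_id optional subject tag carried into the records.
#' @param base_rates optional per-unit rates in Hz used by [filter_units()];
#'   defaults to the pre-window rate of the control condition.
#' @return Data frame of class `prepost_records`: `unit_id, subject_id, ph,
#'   fr_pre, fr_post, rate_hz`.
#' @export
build_prepost <- function(s_traces, sph_traces, protocol, bin_width = 0.2,
                          window_len = 4, normalize = TRUE,
                          subject_id = 1L, base_rates = NULL) {
  if (window_len > protocol$photostim_onset)
    stop("build_prepost: window_len must not exceed the photostimulation ",
         "onset (", protocol$photostim_onset, " s)", call. = FALSE)
  nb <- ncol(s_traces)
  if (nb * bin_width < protocol$photostim_onset + window_len)
    stop("build_prepost: traces shorter than the post window", call. = FALSE)
  stopifnot(nrow(s_traces) == nrow(sph_traces))
  on <- protocol$photostim_onset
  pre_idx <- frame_window(on - window_len, on, 1 / bin_width, nb)
  post_idx <- frame_window(on, on + window_len, 1 / bin_width, nb)
  pre_s <- rowMeans(s_traces[, pre_idx, drop = FALSE])
  post_s <- rowMeans(s_traces[, post_idx, drop = FALSE])
  pre_p <- rowMeans(sph_traces[, pre_idx, drop = FALSE])
  post_p <- rowMeans(sph_traces[, post_idx, drop = FALSE])
  n <- nrow(s_traces)
  if (is.null(base_rates)) base_rates <- pre_s
  rec <- data.frame(
    unit_id = rep(seq_len(n), 2),
    subject_id = subject_id,
    ph = rep(c(0L, 1L), each = n),
    fr_pre = c(pre_s, pre_p),
    fr_post = c(post_s, post_p),
    rate_hz = rep(base_rates, 2)
  )
  if (normalize) {
    m <- max(rec$fr_pre)
    if (m > 0) {
      rec$fr_pre <- rec$fr_pre / m
      rec$fr_post <- rec$fr_post / m
      attr(rec, "norm_factor") <- m
    }
  }
  class(rec) <- c("prepost_records", class(rec))
  rec
}

#' Filter units by pre-photostimulation firing rate
#'
#' Guards against floor effects: units whose physical pre-photostimulation
#' rate lies outside `[min_rate, max_rate]` are removed. The defaults drop
#' units below 1 Hz; `preset = "band_1_20"` applies the 1-20 Hz band.
#'
#' @param records a `prepost_records` data frame with a `rate_hz` column.
#' @param min_rate,max_rate bounds in Hz.
#' @param preset `"default"` (>= 1 Hz) or `"band_1_20"` (1-20 Hz).
#' @return List with `records` (filtered) and `excluded` (unit ids).
#' @export
filter_units <- function(records, min_rate = 1, max_rate = Inf,
                         preset = c("default", "band_1_20")) {
  preset <- match.arg(preset)
  if (preset == "band_1_20") { min_rate <- 1; max_rate <- 20 }
  keep_units <- unique(records$unit_id[records$rate_hz >= min_rate &
                                         records$rate_hz <= max_rate])
  excluded <- setdiff(unique(records$unit_id), keep_units)
  out <- records[records$unit_id %in% keep_units, ]
  if (nrow(out) == 0)
    stop("filter_units: all units excluded by the rate filter", call. = FALSE)
  list(records = out, excluded = excluded,
       filter = c(min_rate = min_rate, max_rate = max_rate))
}

#' Divisive-versus-subtractive suppression regression
#'
#' Ordinary least squares fit of
#' `fr_post = b1 + b2 * ph + b3 * fr_pre + b4 * fr_pre * ph`:
#' `b2` is the subtractive term (intercept shift under photostimulation) and
#' `b4` the divisive term (slope change). For purely divisive suppression
#' with gain `g_s`, `b4` recovers `g_s - 1`; for purely subtractive
#' suppression, `b2` recovers the shift.
#'
#' @param records a `prepost_records` data frame.
#' @return Object of class `suppression_fit`: list with `coefficients`
#'   (named b1..b4), `se`, `n_records`, `sigma` (residual SD), `r_squared`,
#'   and the underlying `lm` fit.
#' @export
fit_suppression <- function(records) {
  for (p in c(0, 1)) {
    v <- records$fr_pre[records$ph == p]
    if (length(unique(v)) < 2)
      stop("fit_suppression: need >= 2 distinct fr_pre values per ph level",
           call. = FALSE)
  }
  fit <- stats::lm(fr_post ~ ph * fr_pre, data = records)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("fit_suppression: rank-deficient design (collinear ",
         paste(names(cf)[is.na(cf)], collapse = ", "), ")", call. = FALSE)
  sm <- summary(fit)
  b <- c(b1 = unname(cf["(Intercept)"]), b2 = unname(cf["ph"]),
         b3 = unname(cf["fr_pre"]), b4 = unname(cf["ph:fr_pre"]))
  se <- sm$coefficients[, "Std. Error"]
  se <- c(b1 = unname(se["(Intercept)"]), b2 = unname(se["ph"]),
          b3 = unname(se["fr_pre"]), b4 = unname(se["ph:fr_pre"]))
  structure(list(coefficients = b, se = se, n_records = nrow(records),
                 sigma = sm$sigma, r_squared = sm$r.squared, lm = fit),
            class = "suppression_fit")
}

#' @export
print.suppression_fit <- function(x, ...) {
  cat("<suppression_fit>\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Classify suppression as divisive, subtractive, mixed, or none
#'
#' Across subject-level fits, one-sided one-sample t tests (direction
#' "less", the suppressive direction) on the subtractive coefficient `b2`
#' and the divisive coefficient `b4`. The label is `"divisive"` if only
#' `b4` is significantly negative, `"subtractive"` if only `b2`, `"mixed"`
#' if both, `"none"` otherwise. With fewer than three subjects the tests
#' are skipped and the label is taken from the mean point estimates with
#' an `untested` flag.
#'
#' @param fits list of `suppression_fit` objects, one per subject.
#' @param alpha significance level.
#' @param estimate_threshold untested fallback: a coefficient counts as
#'   suppressive when its mean is below `-estimate_threshold`.
#' @return List with `label`, `p_b2`, `p_b4`, `mean_b2`, `mean_b4`,
#'   `sem_b2`, `sem_b4`, `tested`.
#' @export
classify_suppression <- function(fits, alpha = 0.05,
                                 estimate_threshold = 0.05) {
  b2 <- vapply(fits, function(f) f$coefficients["b2"], numeric(1))
  b4 <- vapply(fits, function(f) f$coefficients["b4"], numeric(1))
  tested <- length(fits) >= 3
  if (tested) {
    p2 <- t_test_one_sided(b2, mu = 0, kind = "one_sample", side = "less")$p
    p4 <- t_test_one_sided(b4, mu = 0, kind = "one_sample", side = "less")$p
    sub_sig <- p2 < alpha
    div_sig <- p4 < alpha
  } else {
    p2 <- p4 <- NA_real_
    sub_sig <- mean(b2) < -estimate_threshold
    div_sig <- mean(b4) < -estimate_threshold
  }
  label <- if (div_sig && sub_sig) "mixed"
  else if (div_sig) "divisive"
  else if (sub_sig) "subtractive"
  else "none"
  list(label = label, p_b2 = p2, p_b4 = p4,
       mean_b2 = mean(b2), mean_b4 = mean(b4),
       sem_b2 = stats::sd(b2) / sqrt(length(b2)),
       sem_b4 = stats::sd(b4) / sqrt(length(b4)),
       tested = tested)
}

#' Simulate a cohort of pre/post records with known suppression truth
#'
#' Record-level generator for recovery and classification tests: for each
#' subject, unit pre-rates are drawn uniformly (normalized scale) and the
#' post-rate follows the ground truth `post = g_s * pre + offset` plus
#' Gaussian noise for the photostimulated condition, and `post = pre` plus
#' noise for control. Both `offset` and the noise SD live on the
#' normalized-rate scale of the regression.
#'
#' @param n_subjects,n_units cohort shape.
#' @param g_s true spontaneous gain (divisive truth `b4 = g_s - 1`).
#' @param offset true additive shift (subtractive truth `b2 = offset`).
#' @param noise_sd Gaussian noise SD on the post rates.
#' @param pre_range range of normalized pre rates.
#' @param seed integer seed.
#' @return List of `prepost_records` data frames, one per subject.
#' @export
simulate_prepost_cohort <- function(n_subjects = 8, n_units = 25,
                                    g_s = 0.6, offset = -0.1,
                                    noise_sd = 0.05,
                                    pre_range = c(0.05, 1), seed = 1L) {
  old <- .Random.seed_save()
  set.seed(seed)
  cohort <- lapply(seq_len(n_subjects), function(s) {
    pre <- stats::runif(n_units, pre_range[1], pre_range[2])
    post0 <- pre + stats::rnorm(n_units, 0, noise_sd)
    post1 <- g_s * pre + offset + stats::rnorm(n_units, 0, noise_sd)
    rec <- data.frame(unit_id = rep(seq_len(n_units), 2), subject_id = s,
                      ph = rep(c(0L, 1L), each = n_units),
                      fr_pre = rep(pre, 2), fr_post = c(post0, post1),
                      rate_hz = rep(pre, 2))
    class(rec) <- c("prepost_records", class(rec))
    rec
  })
  .Random.seed_restore(old)
  cohort
}
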