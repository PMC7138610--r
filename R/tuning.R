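#' Naka-Rushton contrast response function
#'
#' `R(c) = R_max * c^n / (c^n + c50^n) + R0`: a saturating contrast-response
#' curve where `c50` is the contrast at half-maximal response and `n`
#' controls the slope at `c50`.
#'
#' @param c contrast fraction(s) in `[0, 1]`.
#' @param R_max maximum response above offset.
#' @param c50 semi-saturation contrast, in `(0, 1]`.
#' @param n exponent, > 0.
#' @param R0 response offset.
#' @return Response value(s).
#' @export
naka_rushton <- function(c, R_max, c50, n, R0 = 0) {
  R_max * c^n / (c^n + c50^n) + R0
}

#' Fit the Naka-Rushton function to contrast-response points
#'
#' Bounded nonlinear least squares with multi-start: initial values
#' `R0 = min(peaks)`, `R_max = max - min`, `c50 = median contrast`, and
#' `n` started from each of {1, 2, 4}; bounds `R_max` in `[0, 10 * range]`,
#' `c50` in `[0.01, 1]`, `n` in `[0.1, 10]`, `R0` free. The best start by
#' residual sum of squares wins.
#'
#' @param contrasts distinct contrast fractions (>= 4 points).
#' @param peaks response peaks, same length.
#' @return Object of class `naka_rushton_fit`: list with `R_max, c50, n,
#'   R0, r_squared, converged, n_points, fitted`. `r_squared` is
#'   `NA` when residual degrees of freedom are 2 or fewer or when the
#'   responses carry no variance (degenerate flat data, flagged by
#'   `degenerate = TRUE`).
#' @export
fit_naka_rushton <- function(contrasts, peaks) {
  if (length(contrasts) < 4)
    stop("fit_naka_rushton: at least 4 (contrast, peak) pairs required",
         call. = FALSE)
  if (anyDuplicated(contrasts))
    stop("fit_naka_rushton: contrasts must be distinct", call. = FALSE)
  stopifnot(length(contrasts) == length(peaks))
  df <- data.frame(c = contrasts, p = peaks)
  rng <- max(peaks) - min(peaks)
  degenerate <- rng == 0
  start_base <- list(R_max = max(rng, 1e-6), c50 = stats::median(contrasts),
                     R0 = min(peaks))
  lower <- c(R_max = 0, c50 = 0.01, n = 0.1, R0 = -Inf)
  upper <- c(R_max = max(10 * rng, 1e-3), c50 = 1, n = 10, R0 = Inf)
  best <- NULL
  for (n0 in c(1, 2, 4)) {
    st <- c(start_base, list(n = n0))[c("R_max", "c50", "n", "R0")]
    fit <- tryCatch(
      minpack.lm::nlsLM(p ~ R_max * c^n / (c^n + c50^n) + R0,
                        data = df, start = st,
                        lower = lower[names(st)], upper = upper[names(st)],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    # best-effort fallback: report the start values, flag non-convergence
    return(structure(list(R_max = start_base$R_max, c50 = start_base$c50,
                          n = 2, R0 = start_base$R0, r_squared = NA_real_,
                          converged = FALSE, degenerate = degenerate,
                          n_points = length(contrasts),
                          fitted = rep(NA_real_, length(contrasts))),
                     class = "naka_rushton_fit"))
  }
  cf <- stats::coef(best$fit)
  fitted_vals <- naka_rushton(contrasts, cf["R_max"], cf["c50"], cf["n"],
                              cf["R0"])
  ss_tot <- sum((peaks - mean(peaks))^2)
  dof <- length(contrasts) - 4  # residual degrees of freedom
  r2 <- if (degenerate || ss_tot == 0 || dof < 1) NA_real_
        else 1 - best$rss / ss_tot
  structure(list(R_max = unname(cf["R_max"]), c50 = unname(cf["c50"]),
                 n = unname(cf["n"]), R0 = unname(cf["R0"]),
                 r_squared = r2, converged = TRUE, degenerate = degenerate,
                 n_points = length(contrasts), fitted = unname(fitted_vals)),
            class = "naka_rushton_fit")
}

#' @export
print.naka_rushton_fit <- function(x, ...) {
  cat(sprintf(
    "<naka_rushton_fit> R_max=%.4g c50=%.4g n=%.3g R0=%.4g R^2=%s%s\n",
    x$R_max, x$c50, x$n, x$R0,
    if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
    if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Max-normalize contrast-response peaks and refit
#'
#' Divides each condition's peak values by that condition's own response at
#' 100% contrast and refits the Naka-Rushton function, testing whether
#' suppressed tuning collapses onto control tuning (contrast normalization:
#' the Naka-Rushton shape parameters `c50` and `n` are invariant to a common
#' multiplicative factor).
#'
#' @param contrasts contrast fractions; must include 1 (100%).
#' @param peaks_by_condition named list of peak vectors (one per condition),
#'   aligned with `contrasts`.
#' @return Named list per condition: `scaled` (peaks after division) and
#'   `fit` (a `naka_rushton_fit` on the scaled peaks).
#' @export
normalize_and_refit <- function(contrasts, peaks_by_condition) {
  i100 <- which(contrasts == 1)
  if (length(i100) != 1)
    stop("normalize_and_refit: a 100%-contrast point is required",
         call. = FALSE)
  lapply(peaks_by_condition, function(p) {
    m <- p[i100]
    if (m == 0)
      stop("normalize_and_refit: zero response at 100% contrast",
           call. = FALSE)
    scaled <- p / m
    list(scaled = scaled, fit = fit_naka_rushton(contrasts, scaled))
  })
}

#' Response-onset latency
#'
#' First time at or after stimulus onset where the trace reaches the mean
#' plus twice the SD of the pre-onset baseline window, sustained for at
#' least two consecutive samples (a persistence rule against single-frame
#' noise). Returns `NA` when the threshold is never crossed.
#'
#' @param trace numeric trace.
#' @param rate sampling rate, samples/s.
#' @param onset stimulus onset, s.
#' @param baseline_window length of the pre-onset baseline, s.
#' @return Latency in seconds after `onset`, or `NA`.
#' @export
response_latency <- function(trace, rate, onset, baseline_window = 0.7) {
  n <- length(trace)
  base_idx <- frame_window(max(onset - baseline_window, 0), onset, rate, n)
  thr <- mean(trace[base_idx]) + 2 * stats::sd(trace[base_idx])
  post <- frame_window(onset, n / rate, rate, n)
  above <- trace[post] >= thr
  ok <- which(above & c(above[-1], FALSE))  # >= 2 consecutive samples
  if (!length(ok)) return(NA_real_)
  (post[ok[1]] - 1) / rate - onset
}

#' Response duration at half-peak
#'
#' Total time within the window during which the trace exceeds half of its
#' peak value (half-open sample counting times the frame period). A
#' nonpositive peak gives duration 0 with a `flagged` attribute.
#'
#' @param trace numeric trace.
#' @param rate sampling rate, samples/s.
#' @param window `c(t0, t1)` window in seconds containing the peak.
#' @return Duration in seconds (attribute `flagged = TRUE` if peak <= 0).
#' @export
response_duration <- function(trace, rate, window) {
  idx <- frame_window(window[1], window[2], rate, length(trace))
  seg <- trace[idx]
  pk <- max(seg)
  if (pk <= 0) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sum(seg > pk / 2) / rate
}
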