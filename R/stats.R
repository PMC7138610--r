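#' One-sided t tests with degenerate-case conventions
#'
#' Thin wrapper around the standard t statistic that fixes the conventions
#' for zero-variance data: zero variance with zero effect gives `p = 1`
#' (statistic 0); zero variance with a nonzero effect in the tested
#' direction gives `p = 0` with a `degenerate` flag.
#'
#' @param x numeric sample (for `paired`, the first member of each pair
#'   unless `y` is `NULL` and `x` is already a difference sample).
#' @param y second sample for `two_sample`/`paired`; `NULL` otherwise.
#' @param mu null value for `one_sample`.
#' @param kind `"one_sample"`, `"two_sample"` (Welch) or `"paired"`.
#' @param side `"less"`, `"greater"` or `"two"`.
#' @return List of class `stat_result`: `statistic, p, n, df, test_name,
#'   side, degenerate`.
#' @export
t_test_one_sided <- function(x, y = NULL, mu = 0,
                             kind = c("one_sample", "two_sample", "paired"),
                             side = c("less", "greater", "two")) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  if (kind == "paired") {
    if (!is.null(y)) { stopifnot(length(x) == length(y)); x <- x - y }
    kind <- "one_sample"
  }
  alt <- switch(side, less = "less", greater = "greater", two = "two.sided")
  degenerate <- FALSE
  if (kind == "one_sample") {
    stopifnot(length(x) >= 2)
    if (stats::sd(x) == 0) {
      eff <- mean(x) - mu
      degenerate <- eff != 0
      stat <- if (eff == 0) 0 else sign(eff) * Inf
      p <- p_from_side(stat, side)
      return(structure(list(statistic = stat, p = p, n = length(x),
                            df = length(x) - 1, test_name = "one-sample t",
                            side = side, degenerate = degenerate),
                       class = "stat_result"))
    }
    ht <- stats::t.test(x, mu = mu, alternative = alt)
    name <- "one-sample t"
  } else {
    stopifnot(length(x) >= 2, length(y) >= 2)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      eff <- mean(x) - mean(y)
      degenerate <- eff != 0
      stat <- if (eff == 0) 0 else sign(eff) * Inf
      p <- p_from_side(stat, side)
      return(structure(list(statistic = stat, p = p,
                            n = c(length(x), length(y)), df = NA,
                            test_name = "two-sample t", side = side,
                            degenerate = degenerate),
                       class = "stat_result"))
    }
    ht <- stats::t.test(x, y, alternative = alt)
    name <- "two-sample t"
  }
  structure(list(statistic = unname(ht$statistic), p = ht$p.value,
                 n = if (is.null(y)) length(x) else c(length(x), length(y)),
                 df = unname(ht$parameter), test_name = name, side = side,
                 degenerate = degenerate),
            class = "stat_result")
}

p_from_side <- function(stat, side) {
  if (stat == 0) return(1)
  hit <- switch(side, less = stat < 0, greater = stat > 0, two = TRUE)
  if (hit) 0 else 1
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s (%s): t=%.3g, p=%.4g%s\n", x$test_name,
              x$side, x$statistic, x$p,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# paired t statistics for each column of a difference matrix (n x k)
col_tstats <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0 & m == 0] <- 0
  t[s == 0 & m != 0] <- sign(m[s == 0 & m != 0]) * Inf
  t
}

#' Max-statistic sign-flip permutation correction
#'
#' Familywise-corrected paired tests over a family of `k` per-stimulus
#' difference samples (`n` pairs each): every pair's sign is flipped
#' independently, and the maximum over the family of the (signed or
#' absolute) t statistic is recorded per permutation. A family member is
#' significant when its observed statistic exceeds the `(1 - alpha)`
#' quantile of that null maximum distribution, which controls the
#' familywise error rate in the strong sense. With `2^n <= max_exact`
#' (default: n <= 12) all sign patterns are enumerated exactly; otherwise
#' `n_perm` Monte-Carlo sign flips are drawn with the given seed.
#'
#' @param D numeric matrix `n_pairs x k` of paired differences (or a vector
#'   for `k = 1`).
#' @param alpha familywise level.
#' @param side `"less"` / `"greater"` (signed statistic) or `"two"`
#'   (absolute statistic).
#' @param n_perm Monte-Carlo permutation count.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @param max_exact largest number of sign patterns enumerated exactly.
#' @return List of class `permutation_result`: `significant` (logical mask,
#'   length k), `p_corrected`, `t_obs`, `exact`, `n_perm_used`, `seed`.
#' @export
permutation_correct <- function(D, alpha = 0.05,
                                side = c("two", "less", "greater"),
                                n_perm = 10000, seed = 1L,
                                max_exact = 4096) {
  side <- match.arg(side)
  if (is.vector(D)) D <- matrix(D, ncol = 1)
  k <- ncol(D)
  if (k == 0) stop("permutation_correct: empty family", call. = FALSE)
  n <- nrow(D)
  stat_fun <- switch(side,
                     two = function(t) abs(t),
                     less = function(t) -t,
                     greater = function(t) t)
  t_obs <- col_tstats(D)
  s_obs <- stat_fun(t_obs)
  exact <- 2^n <= max_exact
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    old <- .Random.seed_save()
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    n_perm, n)
    .Random.seed_restore(old)
  }
  B <- nrow(signs)
  # sum of squares is sign-invariant, so flipped t depends only on the mean
  ss <- colSums(D^2)
  M <- (signs %*% D) / n                      # B x k flipped means
  Svar <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
  Svar[Svar < 0] <- 0
  Tperm <- M / sqrt(Svar / n)
  Tperm[is.nan(Tperm)] <- 0
  Sperm <- stat_fun(Tperm)
  max_null <- apply(Sperm, 1, max)
  # corrected p: fraction of permutation maxima at or above the observed
  # statistic; the per-member (uncorrected) permutation p uses the member's
  # own null and is never larger than the corrected p
  p_corr <- vapply(s_obs, function(s) mean(max_null >= s), numeric(1))
  p_raw <- vapply(seq_len(k), function(j) mean(Sperm[, j] >= s_obs[j]),
                  numeric(1))
  crit <- stats::quantile(max_null, 1 - alpha, type = 1)
  structure(list(significant = s_obs > crit, p_corrected = p_corr,
                 p_raw = p_raw, t_obs = t_obs, exact = exact,
                 n_perm_used = B, seed = if (exact) NA_integer_ else seed,
                 alpha = alpha, side = side),
            class = "permutation_result")
}

#' Onset of significant suppression
#'
#' First post-onset time at which a suppression criterion holds for at
#' least two consecutive bins. Criteria: `"permutation"` runs a
#' familywise-corrected paired test per time bin on a `trials x bins`
#' difference matrix (suppressed minus control, direction "less");
#' `"sd2"` marks bins of a trace falling below the mean minus twice the SD
#' of the pre-photostimulation reference window.
#'
#' @param x for `"permutation"`: matrix `n_pairs x n_bins` of paired
#'   differences per time bin; for `"sd2"`: a numeric trace.
#' @param rate bins per second.
#' @param ph_onset photostimulation onset, s.
#' @param criterion `"permutation"` or `"sd2"`.
#' @param alpha level for the permutation criterion.
#' @param seed permutation seed.
#' @param pre_window reference window length before `ph_onset` for `"sd2"`, s.
#' @return List: `onset` (s after `ph_onset`, or `NA` if never), `mask`
#'   (per-bin criterion), `criterion`.
#' @export
onset_of_significance <- function(x, rate, ph_onset,
                                  criterion = c("permutation", "sd2"),
                                  alpha = 0.05, seed = 1L,
                                  pre_window = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "permutation") {
    stopifnot(is.matrix(x))
    nb <- ncol(x)
    res <- permutation_correct(x, alpha = alpha, side = "less", seed = seed)
    mask <- res$significant
  } else {
    nb <- length(x)
    if (is.null(pre_window)) pre_window <- ph_onset
    pre_idx <- frame_window(max(ph_onset - pre_window, 0), ph_onset, rate, nb)
    thr <- mean(x[pre_idx]) - 2 * stats::sd(x[pre_idx])
    mask <- x < thr
  }
  start <- floor(ph_onset * rate) + 1L
  idx <- seq_len(nb)
  cand <- which(mask & c(mask[-1], FALSE) & idx >= start)
  onset <- if (length(cand)) (cand[1] - 1) / rate - ph_onset else NA_real_
  list(onset = onset, mask = mask, criterion = criterion)
}

#' Two-sample test on detrended traces
#'
#' Removes the least-squares linear trend (slope and intercept) from each
#' trace over a common fitting window, then runs a two-sample t test on the
#' residuals inside a test window. Because detrending removes both slope
#' and intercept, a constant offset between the traces is removed too: the
#' test is sensitive to shape differences (e.g. a mid-window bump), not to
#' level or drift. The test window defaults to the central half of the
#' fitting window; it must be a strict sub-window, because the residuals of
#' each trace average to zero over the full fitting window by construction,
#' so a mean comparison there would be vacuous.
#'
#' @param trace_a,trace_b numeric traces on a common time base.
#' @param rate samples per second.
#' @param window `c(t0, t1)` trend-fitting window, s (>= 3 samples).
#' @param test_window `c(t0, t1)` sub-window whose residuals are compared;
#'   default the central half of `window`.
#' @param side test direction.
#' @return A `stat_result` from [t_test_one_sided()].
#' @export
detrend_compare <- function(trace_a, trace_b, rate, window,
                            test_window = NULL,
                            side = c("two", "less", "greater")) {
  side <- match.arg(side)
  idx <- frame_window(window[1], window[2], rate,
                      min(length(trace_a), length(trace_b)))
  if (length(idx) < 3)
    stop("detrend_compare: window must contain at least 3 samples",
         call. = FALSE)
  if (is.null(test_window)) {
    q <- diff(window) / 4
    test_window <- c(window[1] + q, window[2] - q)
  }
  detrend <- function(y) stats::residuals(stats::lm(y ~ seq_along(y)))
  sub <- frame_window(test_window[1], test_window[2], rate,
                      min(length(trace_a), length(trace_b)))
  sub <- match(intersect(sub, idx), idx)
  if (length(sub) < 2)
    stop("detrend_compare: test window must contain at least 2 samples ",
         "inside the fitting window", call. = FALSE)
  ra <- detrend(trace_a[idx])[sub]
  rb <- detrend(trace_b[idx])[sub]
  # exactly-linear traces leave numerically-zero residuals
  eps <- 1e-10 * (max(abs(c(trace_a[idx], trace_b[idx]))) + 1)
  if (stats::sd(ra) < eps && stats::sd(rb) < eps) {
    return(structure(list(statistic = 0, p = 1,
                          n = c(length(ra), length(rb)), df = NA,
                          test_name = "two-sample t (detrended)",
                          side = side, degenerate = FALSE),
                     class = "stat_result"))
  }
  out <- t_test_one_sided(ra, rb, kind = "two_sample", side = side)
  out$test_name <- "two-sample t (detrended)"
  out
}
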