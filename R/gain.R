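#' Estimate the photostimulation-induced gain
#'
#' The control response is modeled as the photostimulated response scaled by
#' a gain `g >= 1`: `V = g * (E_ph + S_ph)`. `g` is estimated from response
#' magnitudes (amplitude minus baseline), which are invariant to additive
#' baseline shifts and therefore isolate the evoked gain:
#' `g = magnitude(V) / magnitude(V_ph)` per contrast, plus a pooled estimate
#' from the 100%-contrast peak ratio.
#'
#' @param control_metrics `component_metrics` rows of the control condition,
#'   with a `contrast` column when several contrasts are analyzed.
#' @param ph_metrics matching `component_metrics` rows of the photostimulated
#'   condition (same stimuli/contrasts, same order).
#' @return List with `g` (per row; `NA` where the photostimulated magnitude
#'   is nonpositive), `g_pooled` (ratio at 100% contrast, or of the overall
#'   mean magnitudes when no contrast column exists), `contrast`.
#' @export
estimate_gain <- function(control_metrics, ph_metrics) {
  stopifnot(nrow(control_metrics) == nrow(ph_metrics))
  if (any(control_metrics$magnitude <= 0))
    stop("estimate_gain: control magnitudes must be positive", call. = FALSE)
  g <- control_metrics$magnitude / ph_metrics$magnitude
  g[ph_metrics$magnitude <= 0] <- NA_real_
  contrast <- control_metrics$contrast
  if (is.null(contrast)) contrast <- rep(NA_real_, nrow(control_metrics))
  g_pooled <- if (any(contrast == 1, na.rm = TRUE)) {
    i <- which(contrast == 1)[1]
    control_metrics$magnitude[i] / ph_metrics$magnitude[i]
  } else {
    mean(control_metrics$magnitude) / mean(ph_metrics$magnitude)
  }
  list(g = g, g_pooled = g_pooled, contrast = contrast)
}

#' Gain decomposition into evoked and baseline component weights
#'
#' Decomposes the control response as `V = g * E_ph + g * S_ph`: the evoked
#' weight is `g` times the evoked-component magnitude; the baseline weight
#' is `g` times the spontaneous (S_ph) level, both at the control peak time
#' `t_pk` and averaged over the whole photostimulation window. The
#' reconstruction `V_hat = evoked_weight + baseline_weight_at_pk` should
#' recover the control amplitude when the linear model holds.
#'
#' @param g per-contrast gain from [estimate_gain()].
#' @param eph_metrics `component_metrics` of the evoked component (one row
#'   per contrast, aligned with `g`).
#' @param sph_trace trial-averaged S_ph ROI trace.
#' @param protocol a [protocol_spec()].
#' @param peak_times control peak times `t_pk` in seconds, aligned with rows.
#' @param state cortical state tag.
#' @return Object of class `gain_decomposition`: data frame with `contrast,
#'   g, evoked_weight, baseline_weight_pk, baseline_weight_wph,
#'   reconstruction`.
#' @export
component_weights <- function(g, eph_metrics, sph_trace, protocol,
                              peak_times, state = "anesthetized") {
  rate <- protocol$frame_rate
  wph <- c(protocol$photostim_onset,
           protocol$photostim_onset + protocol$photostim_duration)
  sph_wph <- mean(sph_trace[frame_window(wph[1], wph[2], rate,
                                         length(sph_trace))])
  sph_pk <- vapply(peak_times, function(tp) {
    i <- floor(tp * rate) + 1L
    sph_trace[min(max(i, 1L), length(sph_trace))]
  }, numeric(1))
  evoked_weight <- g * eph_metrics$magnitude
  out <- data.frame(
    contrast = if (!is.null(eph_metrics$contrast)) eph_metrics$contrast
               else NA_real_,
    g = g,
    evoked_weight = evoked_weight,
    baseline_weight_pk = g * sph_pk,
    baseline_weight_wph = g * sph_wph,
    reconstruction = evoked_weight + g * sph_pk,
    state = state
  )
  class(out) <- c("gain_decomposition", class(out))
  out
}

#' Compare gain decompositions between cortical states
#'
#' Per-contrast comparison table between the awake and anesthetized
#' regimes: magnitude-suppression differences, spontaneous (S_ph) window
#' averages, baseline weights, and peak times, with two-sample one-sided
#' t tests across subjects where per-subject values are supplied.
#'
#' @param awake,anesthetized lists with elements `decomposition` (a
#'   `gain_decomposition`), `sph_wph` (per-subject S_ph window averages),
#'   `g` (per-subject pooled gains) and `peak_times` (per-subject mean peak
#'   times, s).
#' @param protocol_a,protocol_b the protocols used for the two states
#'   (must match).
#' @return List with the per-contrast `table` and the across-subject `tests`.
#' @export
compare_states <- function(awake, anesthetized,
                           protocol_a = NULL, protocol_b = NULL) {
  if (!is.null(protocol_a) && !is.null(protocol_b) &&
      !identical(unclass(protocol_a), unclass(protocol_b)))
    stop("compare_states: protocols of the two states differ", call. = FALSE)
  da <- awake$decomposition; dn <- anesthetized$decomposition
  stopifnot(nrow(da) == nrow(dn))
  tab <- data.frame(
    contrast = da$contrast,
    g_awake = da$g, g_anesthetized = dn$g,
    evoked_weight_awake = da$evoked_weight,
    evoked_weight_anesthetized = dn$evoked_weight,
    baseline_weight_awake = da$baseline_weight_pk,
    baseline_weight_anesthetized = dn$baseline_weight_pk,
    delta_g = dn$g - da$g,
    delta_baseline_weight = dn$baseline_weight_pk - da$baseline_weight_pk
  )
  tests <- list()
  if (!is.null(awake$g) && !is.null(anesthetized$g))
    tests$gain <- t_test_one_sided(awake$g, anesthetized$g,
                                   kind = "two_sample", side = "less")
  if (!is.null(awake$sph_wph) && !is.null(anesthetized$sph_wph))
    tests$spontaneous <- t_test_one_sided(anesthetized$sph_wph, awake$sph_wph,
                                          kind = "two_sample", side = "less")
  if (!is.null(awake$peak_times) && !is.null(anesthetized$peak_times))
    tests$peak_time <- t_test_one_sided(awake$peak_times,
                                        anesthetized$peak_times,
                                        kind = "two_sample", side = "less")
  list(table = tab, tests = tests)
}
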