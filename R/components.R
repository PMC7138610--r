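#' Normalize a trace set to the first control response peak
#'
#' Every trace in the set is divided by the peak value of the control (V)
#' trial-averaged response to the first visual stimulus, so that conditions
#' stay mutually comparable (a single common scale factor, recorded in
#' `normalization`).
#'
#' @param traces a `roi_trace_set` from [preprocess_trials()].
#' @param protocol a [protocol_spec()].
#' @param control name of the control condition entry (default `"V"`).
#' @return The normalized `roi_trace_set`.
#' @export
normalize_to_first_peak <- function(traces, protocol, control = "V") {
  if (!control %in% names(traces$traces))
    stop("normalize_to_first_peak: control condition '", control,
         "' not present", call. = FALSE)
  v <- traces$mean[[control]]
  win <- frame_window(protocol$stim_onsets[1], protocol$stim_onsets[1] + 1,
                      protocol$frame_rate, length(v))
  peak <- max(v[win])
  if (peak <= 0)
    stop("normalize_to_first_peak: nonpositive first-stimulus peak",
         call. = FALSE)
  traces$traces <- lapply(traces$traces, function(m) m / peak)
  traces$mean <- lapply(traces$mean, function(v) v / peak)
  traces$normalization <- c(traces$normalization,
                            list(first_peak = peak))
  traces
}

#' Stimulus analysis windows
#'
#' Locates, on a control-condition trace, the per-stimulus peak times
#' `t_pk` (maximum within one second after onset, earliest-sample
#' tie-break), and builds the standard windows: `w1 = [t_pk - 0.2,
#' t_pk + 0.2)` around each peak, `w2 = [onset - 0.2, onset)` before each
#' onset, the whole photostimulation window `w_ph`, and (when a
#' significance mask is supplied) `w_red`, the longest contiguous run of
#' corrected-significant suppression starting at the first significant
#' sample after photostimulation onset.
#'
#' Peak times are located once on the control condition and reused for
#' photostimulated conditions, so windows are identical across conditions
#' of one dataset, as required for paired comparisons.
#'
#' @param trace control-condition trial-averaged trace.
#' @param protocol a [protocol_spec()].
#' @param sig_mask optional logical vector per frame (from the statistics
#'   module) marking corrected-significant suppression, used for `w_red`.
#' @return An object of class `stimulus_windows`: list with `peak_times`,
#'   `w1` and `w2` (lists of `c(t0, t1)`), `w_ph`, `w_red` (or `NULL`).
#' @export
locate_windows <- function(trace, protocol, sig_mask = NULL) {
  rate <- protocol$frame_rate
  n <- length(trace)
  peak_times <- numeric(length(protocol$stim_onsets))
  flat <- FALSE
  for (i in seq_along(protocol$stim_onsets)) {
    on <- protocol$stim_onsets[i]
    win <- frame_window(on, on + 1, rate, n)
    seg <- trace[win]
    if (max(seg) == min(seg)) flat <- TRUE
    ipk <- win[which.max(seg)]  # which.max takes the earliest tie
    peak_times[i] <- (ipk - 1) / rate
  }
  if (flat)
    warning("locate_windows: flat response segment; peak set to onset frame",
            call. = FALSE)
  w1 <- lapply(peak_times, function(tp) c(tp - 0.2, tp + 0.2))
  w2 <- lapply(protocol$stim_onsets, function(on) c(on - 0.2, on))
  last_t <- n / rate
  if (any(vapply(w1, function(w) w[2] > last_t, logical(1))))
    warning("locate_windows: peak window extends past trace end; truncated",
            call. = FALSE)
  w_ph <- c(protocol$photostim_onset,
            protocol$photostim_onset + protocol$photostim_duration)
  w_red <- NULL
  if (!is.null(sig_mask)) {
    start <- floor(protocol$photostim_onset * rate) + 1L
    post <- which(sig_mask & seq_len(n) >= start)
    if (length(post)) {
      first <- post[1]
      run_end <- first
      while (run_end < n && isTRUE(sig_mask[run_end + 1])) run_end <- run_end + 1
      w_red <- c((first - 1) / rate, run_end / rate)
      w_red[2] <- min(w_red[2], w_ph[2])  # w_red lies inside w_ph
    }
  }
  structure(list(peak_times = peak_times, w1 = w1, w2 = w2, w_ph = w_ph,
                 w_red = w_red, rate = rate),
            class = "stimulus_windows")
}

window_mean <- function(trace, w, rate) {
  mean(trace[frame_window(w[1], w[2], rate,
                          n_frames = length(trace))])
}

#' Per-stimulus response metrics
#'
#' For each stimulus: amplitude (mean of the trace over the peak window
#' `w1`), baseline (mean over the pre-onset window `w2`), magnitude
#' (absolute difference between amplitude and baseline; a
#' baseline-independent response-gain measure), and the peak time.
#'
#' @param trace a trial-averaged ROI trace (or normalized unit trace).
#' @param windows a `stimulus_windows` from [locate_windows()].
#' @param condition optional [condition_label()] carried into the output.
#' @return Data frame of class `component_metrics` with one row per
#'   stimulus: `stimulus, amplitude, baseline, magnitude, peak_time_s`.
#' @export
compute_metrics <- function(trace, windows, condition = NULL) {
  rate <- windows$rate
  amplitude <- vapply(windows$w1, window_mean, numeric(1),
                      trace = trace, rate = rate)
  baseline <- vapply(windows$w2, window_mean, numeric(1),
                     trace = trace, rate = rate)
  out <- data.frame(stimulus = seq_along(windows$w1),
                    amplitude = amplitude,
                    baseline = baseline,
                    magnitude = abs(amplitude - baseline),
                    peak_time_s = windows$peak_times)
  if (!is.null(condition)) out$condition <- format(condition)
  class(out) <- c("component_metrics", class(out))
  out
}

#' Isolate the evoked component by trialwise subtraction
#'
#' The evoked component `E_ph` is the photostimulated visual response after
#' removal of concurrent spontaneous activity: `E_ph,i = V_ph,i -
#' S_ph,pair(i)`. Trials are paired by index when the two conditions have
#' equal trial counts (conditions were interleaved within trials); otherwise
#' each V_ph trial has the S_ph trial mean subtracted, and the fallback is
#' recorded in the result.
#'
#' @param vph_trials matrix `trials x time` (ROI level) or list of arrays
#'   (pixel level) of the V_ph condition.
#' @param sph_trials same structure for the S_ph condition.
#' @return List with `trials` (same structure as `vph_trials`), `mean`
#'   (trial average), and `pairing` (`"index"` or `"mean"`).
#' @export
evoked_component <- function(vph_trials, sph_trials) {
  if (is.matrix(vph_trials)) {
    if (is.null(sph_trials) || nrow(sph_trials) == 0)
      stop("evoked_component: no S_ph trials", call. = FALSE)
    if (nrow(vph_trials) == nrow(sph_trials)) {
      e <- vph_trials - sph_trials
      pairing <- "index"
    } else {
      e <- sweep(vph_trials, 2, colMeans(sph_trials))
      pairing <- "mean"
    }
    list(trials = e, mean = colMeans(e), pairing = pairing)
  } else {
    if (length(sph_trials) == 0)
      stop("evoked_component: no S_ph trials", call. = FALSE)
    if (length(vph_trials) == length(sph_trials)) {
      e <- Map(function(v, s) v - s, vph_trials, sph_trials)
      pairing <- "index"
    } else {
      smean <- Reduce(`+`, sph_trials) / length(sph_trials)
      e <- lapply(vph_trials, function(v) v - smean)
      pairing <- "mean"
    }
    list(trials = e, mean = Reduce(`+`, e) / length(e), pairing = pairing)
  }
}

#' Normalize multi-unit spike counts
#'
#' Spontaneous conditions: each unit's trial-averaged count trace is divided
#' by its own mean over the first second of recording. Evoked conditions:
#' that 1-s mean is subtracted, and the trace is then divided by the
#' amplitude of the response to the first stimulus in the control (V)
#' condition. Units with a zero 1-s baseline are flagged and excluded from
#' the ratio-normalized output.
#'
#' @param scm a [spike_count_matrix()].
#' @param protocol a [protocol_spec()].
#' @param path `"spontaneous"` (ratio) or `"evoked"` (subtract then scale).
#' @param control_first_amp amplitude of the first-stimulus response in the
#'   control condition (required for the final division of the evoked path;
#'   when `NULL` the division is skipped, e.g. while measuring that
#'   amplitude itself on the control condition).
#' @return List with `traces` (unit x bin matrix of normalized
#'   trial-averaged traces), `mean` (average over units), `excluded`
#'   (unit ids with zero baseline), `bin_width`.
#' @export
normalize_mua <- function(scm, protocol,
                          path = c("spontaneous", "evoked"),
                          control_first_amp = NULL) {
  path <- match.arg(path)
  d <- dim(scm$counts)
  trial_avg <- apply(scm$counts, c(1, 2), mean)  # unit x bin
  nb1s <- max(1L, round(1 / scm$bin_width))
  base <- rowMeans(trial_avg[, seq_len(nb1s), drop = FALSE])
  excluded <- scm$unit_ids[base == 0]
  keep <- base > 0
  if (path == "spontaneous") {
    traces <- trial_avg[keep, , drop = FALSE] / base[keep]
  } else {
    traces <- trial_avg[keep, , drop = FALSE] - base[keep]
    if (!is.null(control_first_amp)) {
      if (control_first_amp <= 0)
        stop("normalize_mua: nonpositive control first-stimulus amplitude",
             call. = FALSE)
      traces <- traces / control_first_amp
    }
  }
  list(traces = traces, mean = colMeans(traces), excluded = excluded,
       bin_width = scm$bin_width,
       times = (seq_len(d[2]) - 1) * scm$bin_width)
}

#' Write component metrics as tidy CSV
#' @param metrics a `component_metrics` data frame (or an rbind of several).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}
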