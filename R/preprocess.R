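#' Pre-stimulus normalization of a raw movie
#'
#' Divides every pixel's time course by that pixel's mean over the initial
#' pre-stimulus window (`pre_record_norm_window`, default 200 ms), removing
#' spatial inhomogeneity in illumination.
#'
#' @param stack a [trial_stack()] or a bare `time x h x w` array.
#' @param protocol a [protocol_spec()].
#' @return A unitless array of the same shape.
#' @keywords internal
prestim_normalize <- function(stack, protocol) {
  px <- if (inherits(stack, "trial_stack")) stack$pixels else stack
  idx <- frame_window(0, protocol$pre_record_norm_window, protocol$frame_rate,
                      dim(px)[1])
  fpre <- apply(px[idx, , , drop = FALSE], c(2, 3), mean)
  if (any(fpre == 0)) {
    bad <- which(fpre == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero pre-stimulus mean at pixel (%d, %d)", bad[1], bad[2]),
         call. = FALSE)
  }
  sweep(px, c(2, 3), fpre, `/`)
}

#' Blank reference from spontaneous trials
#'
#' Averages pre-stimulus-normalized blank (S) movies into the reference used
#' by [compute_dff()]. Normalizing each blank by the same pre-stimulus rule
#' before averaging makes the identity case (stack equal to blank) give a
#' delta-F/F of exactly zero.
#'
#' @param blank_stacks list of [trial_stack()]s from the S condition.
#' @param protocol a [protocol_spec()].
#' @return Array `time x h x w`, the mean normalized blank signal.
#' @export
blank_reference <- function(blank_stacks, protocol) {
  stopifnot(length(blank_stacks) >= 1)
  acc <- NULL
  for (s in blank_stacks) {
    d <- prestim_normalize(s, protocol)
    acc <- if (is.null(acc)) d else acc + d
  }
  acc / length(blank_stacks)
}

#' Relative fluorescence change (delta-F/F)
#'
#' Three steps per pixel: (1) divide by the pixel's pre-stimulus mean,
#' (2) subtract the normalized blank reference frame-by-frame (removing
#' non-neuronal heartbeat/respiration-locked signal), and (3) divide by the
#' pixel's temporal mean of the blank reference, yielding a unitless signal.
#'
#' @param stack a [trial_stack()].
#' @param blank_norm blank reference from [blank_reference()], same shape.
#' @param protocol a [protocol_spec()].
#' @return Unitless `time x h x w` array of delta-F/F.
#' @export
compute_dff <- function(stack, blank_norm, protocol) {
  d <- prestim_normalize(stack, protocol)
  if (!all(dim(d) == dim(blank_norm)))
    stop("compute_dff: shape mismatch between stack and blank reference",
         call. = FALSE)
  bmean <- apply(blank_norm, c(2, 3), mean)
  if (any(bmean == 0)) {
    bad <- which(bmean == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero blank mean at pixel (%d, %d)", bad[1], bad[2]),
         call. = FALSE)
  }
  sweep(d - blank_norm, c(2, 3), bmean, `/`)
}

# Power fraction of a temporal component inside any target band (+- half_bw).
# The denominator is the power above the slow-drift band (>= 0.5 Hz): calcium
# signals concentrate below it, while gated periodic artifacts also carry a
# gate-envelope term there that would otherwise dilute their band fraction.
band_power_fraction <- function(x, rate, bands, half_bw = 0.5) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = rate), plot = FALSE,
                          taper = 0, detrend = TRUE)
  keep <- sp$freq >= 0.5
  total <- sum(sp$spec[keep])
  if (total == 0) return(0)
  inside <- rep(FALSE, length(sp$freq))
  for (b in bands) inside <- inside | abs(sp$freq - b) <= half_bw
  sum(sp$spec[inside & keep]) / total
}

#' ICA-based rejection of periodic artifacts
#'
#' Decomposes each trial movie into temporal independent components,
#' estimates each component's power spectral density, and zeroes components
#' whose power concentrates (above `threshold`) inside any of the target
#' frequency bands (heartbeat, respiration, 20-Hz photostimulation artifact)
#' before back-projection. Applied per trial; the report lists every
#' rejected component with its band attribution.
#'
#' @param stacks list of at least two delta-F/F arrays or [trial_stack()]s.
#' @param protocol a [protocol_spec()].
#' @param bands target frequencies in Hz; an empty vector makes the operation
#'   a no-op.
#' @param n_comp number of temporal components per trial. Few are needed:
#'   the movies carry a handful of genuine sources (evoked response, ongoing
#'   fluctuation, artifact families), and joint-diagonalization ICA degrades
#'   when most extracted components are near-Gaussian noise.
#' @param threshold minimum in-band power fraction for rejection.
#' @return List with `stacks` (cleaned arrays) and `report` (data frame:
#'   trial, model_order, component, band_fraction, rejected, plus a `failed`
#'   flag per trial when no decomposition converged and the trial passed
#'   through unchanged).
#' @export
remove_artifacts_ica <- function(stacks, protocol, bands = c(10, 3, 20),
                                 n_comp = 6, threshold = 0.5) {
  if (length(stacks) < 2)
    stop("remove_artifacts_ica: at least two trials are required",
         call. = FALSE)
  cleaned <- vector("list", length(stacks))
  rep_rows <- list()
  for (i in seq_along(stacks)) {
    px <- if (inherits(stacks[[i]], "trial_stack")) stacks[[i]]$pixels
          else stacks[[i]]
    if (length(bands) == 0) { cleaned[[i]] <- stacks[[i]]; next }
    d <- dim(px)
    X <- matrix(px, d[1], d[2] * d[3])
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    nc_max <- min(n_comp, d[1] - 1, d[2] * d[3])
    # JADE (joint diagonalization) is markedly more stable than fastICA when
    # most retained components are near-Gaussian noise, but which model order
    # isolates a given artifact varies from trial to trial: sweep the order
    # and pool every component whose power concentrates in a target band
    art_cols <- NULL
    any_fit <- FALSE
    for (nc in 2:nc_max) {
      fit <- tryCatch(suppressWarnings(ica::icajade(Xc, nc = nc,
                                                    center = FALSE)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      any_fit <- TRUE
      fracs <- apply(fit$S, 2, band_power_fraction,
                     rate = protocol$frame_rate, bands = bands)
      rej <- fracs >= threshold
      if (any(rej))
        art_cols <- cbind(art_cols, fit$S[, rej, drop = FALSE])
      rep_rows[[length(rep_rows) + 1]] <-
        data.frame(trial = i, model_order = nc,
                   component = seq_along(fracs),
                   band_fraction = fracs, rejected = rej, failed = FALSE)
    }
    if (!any_fit) {
      cleaned[[i]] <- stacks[[i]]
      rep_rows[[length(rep_rows) + 1]] <-
        data.frame(trial = i, model_order = NA, component = NA,
                   band_fraction = NA, rejected = FALSE, failed = TRUE)
      next
    }
    if (is.null(art_cols)) {
      Xhat <- X
    } else {
      # regress the pooled artifact time courses out of every pixel (via an
      # orthonormal basis; this removes all pixel variance aligned with
      # them, including what a mixing-matrix estimate would leave behind)
      Q <- qr.Q(qr(art_cols))
      Xhat <- X - Q %*% crossprod(Q, Xc)
    }
    out <- array(Xhat, dim = d)
    cleaned[[i]] <- if (inherits(stacks[[i]], "trial_stack")) {
      s <- stacks[[i]]; s$pixels <- out; s
    } else out
  }
  list(stacks = cleaned,
       report = if (length(rep_rows)) do.call(rbind, rep_rows)
                else data.frame())
}

# radial spatial-frequency grid (cycles/px) for an h x w frame, FFT order
freq_grid <- function(h, w) {
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[1:h] / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[1:w] / w
  sqrt(outer(fy^2, fx^2, `+`))
}

#' Frame-wise spatial filtering
#'
#' Each frame is Gaussian-smoothed (sigma in pixels) and then high-pass
#' filtered with a 2-D Butterworth magnitude response
#' `|H(f)| = (1 + (f_c / f)^(2 order))^(-1/2)` at radial spatial frequency
#' `f`, with cutoff `f_c = 1 / cutoff_wavelength` cycles/px. Both filters act
#' in the spatial-frequency domain (periodic boundary), so the DC component
#' of every frame is removed exactly by the high-pass stage. `smooth_sigma =
#' 0` disables smoothing and `cutoff_wavelength = NULL` disables the
#' high-pass, making the operation the identity.
#'
#' @param stack delta-F/F array `time x h x w` (or a matrix for one frame).
#' @param smooth_sigma Gaussian sigma in pixels.
#' @param butter_order Butterworth order.
#' @param cutoff_wavelength cutoff wavelength in pixels (> 2), or `NULL`.
#' @return Filtered array of the same shape.
#' @export
spatial_filter <- function(stack, smooth_sigma = 20, butter_order = 4,
                           cutoff_wavelength = 33) {
  one_frame <- is.matrix(stack)
  px <- if (one_frame) array(stack, dim = c(1, dim(stack))) else stack
  d <- dim(px)
  if (!is.null(cutoff_wavelength) && cutoff_wavelength <= 2)
    stop("spatial_filter: cutoff_wavelength must exceed 2 px", call. = FALSE)
  f <- freq_grid(d[2], d[3])
  H <- matrix(1, d[2], d[3])
  if (smooth_sigma > 0)
    H <- H * exp(-2 * pi^2 * smooth_sigma^2 * f^2)
  if (!is.null(cutoff_wavelength)) {
    fc <- 1 / cutoff_wavelength
    Hb <- matrix(0, d[2], d[3])
    nz <- f > 0
    Hb[nz] <- 1 / sqrt(1 + (fc / f[nz])^(2 * butter_order))
    H <- H * Hb
  }
  Ht <- array(rep(as.vector(H), each = d[1]), dim = d)
  out <- Re(batch_fft2(batch_fft2(px) * Ht, inverse = TRUE)) / (d[2] * d[3])
  if (one_frame) out[1, , , drop = TRUE] else out
}

# per-frame 2-D FFT of a time x h x w array, batched over frames via mvfft
batch_fft2 <- function(px, inverse = FALSE) {
  d <- dim(px)
  A <- aperm(px, c(2, 1, 3))
  dim(A) <- c(d[2], d[1] * d[3])
  A <- stats::mvfft(A, inverse = inverse)
  dim(A) <- c(d[2], d[1], d[3])
  A <- aperm(A, c(3, 2, 1))           # w x t x h
  dim(A) <- c(d[3], d[1] * d[2])
  A <- stats::mvfft(A, inverse = inverse)
  dim(A) <- c(d[3], d[1], d[2])
  aperm(A, c(2, 3, 1))
}

#' Temporal Butterworth filtering of a movie
#'
#' The alternative reading of the high-pass Butterworth stage: a 4th-order
#' temporal high-pass applied to every pixel's time course (zero-phase,
#' forward-backward). The spatial interpretation ([spatial_filter()]) is the
#' default throughout the package; this one is provided behind the
#' `butter_domain` flag of [preprocess_trials()].
#'
#' @param stack `time x h x w` array (or [trial_stack()]).
#' @param rate sampling rate, samples/s.
#' @param cutoff_hz cutoff frequency, Hz.
#' @param order filter order.
#' @param type `"high"` or `"low"`.
#' @return Filtered array of the same shape.
#' @export
temporal_filter <- function(stack, rate, cutoff_hz, order = 4,
                            type = c("high", "low")) {
  type <- match.arg(type)
  px <- if (inherits(stack, "trial_stack")) stack$pixels else stack
  d <- dim(px)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("temporal_filter: cutoff_hz must lie in (0, rate/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type)
  X <- matrix(px, d[1], d[2] * d[3])
  for (j in seq_len(ncol(X)))
    X[, j] <- signal::filtfilt(bf, X[, j])
  array(X, dim = d)
}

#' Automated ROI selection from an evoked activity map
#'
#' Thresholds the trial-averaged evoked map at `threshold_frac` times its
#' maximum and returns the 4-connected component that contains the
#' first-scanned (row-major) maximum pixel. With `threshold_frac = 1` the
#' mask reduces to the maximum pixel(s) of that component.
#'
#' @param evoked_map matrix: trial-averaged delta-F/F averaged over a
#'   response window of the control V condition.
#' @param threshold_frac fraction of the map maximum.
#' @return Logical matrix mask.
#' @export
select_roi <- function(evoked_map, threshold_frac = 0.7) {
  m <- max(evoked_map)
  if (m <= 0 || all(evoked_map == 0))
    stop("select_roi: no responsive region (map maximum is not positive)",
         call. = FALSE)
  bin <- evoked_map >= threshold_frac * m
  labels <- EBImage::bwlabel(bin)  # 4-connected components
  peaks <- which(evoked_map == m, arr.ind = TRUE)
  # first-scanned in row-major order: smallest row-major linear index
  rm_index <- (peaks[, 1] - 1) * ncol(evoked_map) + peaks[, 2]
  first <- peaks[which.min(rm_index), , drop = FALSE]
  lab <- labels[first[1, 1], first[1, 2]]
  mask <- labels == lab
  if (!any(mask)) stop("select_roi: empty mask", call. = FALSE)
  mask
}

#' ROI-average a movie into a trace
#'
#' @param stack `time x h x w` array or [trial_stack()].
#' @param roi_mask logical matrix from [select_roi()].
#' @return Numeric vector: per-frame unweighted mean over masked pixels.
#' @export
spatial_average <- function(stack, roi_mask) {
  if (!any(roi_mask)) stop("spatial_average: empty ROI mask", call. = FALSE)
  px <- if (inherits(stack, "trial_stack")) stack$pixels else stack
  d <- dim(px)
  X <- matrix(px, d[1], d[2] * d[3])
  rowMeans(X[, as.vector(roi_mask), drop = FALSE])
}

#' Preprocess a set of trial movies into ROI traces
#'
#' The full preprocessing chain in the fixed order delta-F/F, optional
#' ICA artifact rejection, spatial filtering, ROI averaging. The ROI is
#' selected automatically on the trial-averaged control (V) delta-F/F
#' averaged over a response window after the first stimulus, and the same
#' mask is applied to every condition. The stage log records the order in
#' which stages ran and their parameters.
#'
#' @param stacks_by_condition named list (condition tag) of lists of
#'   [trial_stack()]s; must contain an `S` entry (blank) and a `V` entry
#'   (control) unless `roi_mask` is supplied.
#' @param protocol a [protocol_spec()].
#' @param ica `TRUE` to run [remove_artifacts_ica()] per condition.
#' @param bands artifact bands in Hz for the ICA stage.
#' @param smooth_sigma,butter_order,cutoff_wavelength see [spatial_filter()];
#'   `cutoff_wavelength = NULL` disables the spatial high-pass (appropriate
#'   when the ROI signal itself is spatially broad).
#' @param butter_domain `"space"` (default) applies the Butterworth high-pass
#'   in the spatial-frequency domain; `"time"` applies it along the time axis
#'   instead (see [temporal_filter()]), the alternative reading of the
#'   filtering step.
#' @param temporal_cutoff_hz cutoff for the temporal reading, Hz.
#' @param roi_threshold threshold fraction for [select_roi()].
#' @param roi_mask optional precomputed mask (skips automatic selection).
#' @return A `roi_trace_set`: list with `traces` (named list of trial x time
#'   matrices), `mean` (named list of trial-averaged traces), `roi_mask`,
#'   `sampling_rate`, `normalization` (scale factors applied so far) and
#'   `stage_log`.
#' @export
preprocess_trials <- function(stacks_by_condition, protocol, ica = FALSE,
                              bands = c(10, 3, 20), smooth_sigma = 2,
                              butter_order = 4, cutoff_wavelength = NULL,
                              butter_domain = c("space", "time"),
                              temporal_cutoff_hz = 0.1,
                              roi_threshold = 0.7, roi_mask = NULL) {
  butter_domain <- match.arg(butter_domain)
  stopifnot(is.list(stacks_by_condition), !is.null(names(stacks_by_condition)))
  if (!"S" %in% names(stacks_by_condition))
    stop("preprocess_trials: blank condition 'S' is required", call. = FALSE)
  log <- list()
  blank_norm <- blank_reference(stacks_by_condition[["S"]], protocol)
  log <- c(log, list(list(stage = "blank_reference",
                          n_blank = length(stacks_by_condition[["S"]]))))

  dff <- lapply(stacks_by_condition, function(trials)
    lapply(trials, compute_dff, blank_norm = blank_norm, protocol = protocol))
  log <- c(log, list(list(stage = "dff")))

  ica_report <- NULL
  if (ica) {
    for (nm in names(dff)) {
      res <- remove_artifacts_ica(dff[[nm]], protocol, bands = bands)
      dff[[nm]] <- res$stacks
      res$report$condition <- nm
      ica_report <- rbind(ica_report, res$report)
    }
    log <- c(log, list(list(stage = "ica", bands = bands)))
  }

  if (smooth_sigma > 0 || !is.null(cutoff_wavelength)) {
    dff <- lapply(dff, function(trials)
      lapply(trials, spatial_filter, smooth_sigma = smooth_sigma,
             butter_order = butter_order,
             cutoff_wavelength = if (butter_domain == "space")
               cutoff_wavelength else NULL))
    log <- c(log, list(list(stage = "spatial_filter",
                            smooth_sigma = smooth_sigma,
                            butter_order = butter_order,
                            cutoff_wavelength = cutoff_wavelength,
                            butter_domain = butter_domain)))
  }
  if (butter_domain == "time") {
    dff <- lapply(dff, function(trials)
      lapply(trials, temporal_filter, rate = protocol$frame_rate,
             cutoff_hz = temporal_cutoff_hz, order = butter_order))
    log <- c(log, list(list(stage = "temporal_filter",
                            cutoff_hz = temporal_cutoff_hz,
                            butter_order = butter_order)))
  }

  if (is.null(roi_mask)) {
    vname <- if ("V" %in% names(dff)) "V" else
      grep("^V_c", names(dff), value = TRUE)[1]
    if (is.na(vname) || is.null(dff[[vname]]))
      stop("preprocess_trials: control V condition required for ROI selection",
           call. = FALSE)
    vmean <- Reduce(`+`, dff[[vname]]) / length(dff[[vname]])
    win <- frame_window(protocol$stim_onsets[1],
                        protocol$stim_onsets[1] + 1, protocol$frame_rate,
                        dim(vmean)[1])
    evoked_map <- apply(vmean[win, , , drop = FALSE], c(2, 3), mean)
    roi_mask <- select_roi(evoked_map, roi_threshold)
  }
  log <- c(log, list(list(stage = "roi", n_pixels = sum(roi_mask))))

  traces <- lapply(dff, function(trials)
    do.call(rbind, lapply(trials, spatial_average, roi_mask = roi_mask)))
  log <- c(log, list(list(stage = "spatial_average")))

  structure(list(traces = traces,
                 mean = lapply(traces, colMeans),
                 roi_mask = roi_mask,
                 sampling_rate = protocol$frame_rate,
                 normalization = list(),
                 stage_log = log),
            class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set> %d conditions at %g Hz: %s\n",
              length(x$traces), x$sampling_rate,
              paste(names(x$traces), collapse = ", ")))
  invisible(x)
}
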