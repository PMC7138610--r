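#' Trial protocol description
#'
#' A `protocol_spec` captures the timing of one trial of the four-condition
#' optogenetic design: visual stimulation (V), visual stimulation with
#' photostimulation of serotonergic neurons (V_ph), spontaneous activity (S),
#' and spontaneous activity with photostimulation (S_ph).
#'
#' All times are seconds from the onset of data recording. Analysis windows
#' throughout the package are half-open `[t0, t1)` and are converted to frame
#' indices by flooring `t0 * frame_rate` and ceiling `t1 * frame_rate`.
#'
#' @param frame_rate sampling rate of the movie, samples/s.
#' @param trial_duration total length of one condition recording, s.
#' @param stim_onsets onsets of the visual stimuli, s.
#' @param stim_duration duration of each grating presentation, s.
#' @param photostim_onset onset of the photostimulation train, s.
#' @param photostim_duration duration of the photostimulation train, s.
#' @param photostim_freq pulse frequency of the photostimulation train, Hz.
#' @param pulse_width width of one light pulse, s.
#' @param contrasts grating contrasts as fractions in (0, 1]. In
#'   `single_contrast` mode one trial file exists per contrast and the list
#'   must be strictly decreasing.
#' @param pre_record_norm_window length of the initial pre-stimulus window used
#'   to normalize raw fluorescence, s.
#' @param inter_condition_interval rest time between conditions, s (metadata
#'   only; no analysis depends on it).
#' @param mode `"train"` for the 10-stimulus train design, `"single_contrast"`
#'   for the contrast-series design with one stimulus per trial.
#'
#' @return An object of class `protocol_spec` (a validated list).
#' @seealso [default_protocol()], [contrast_protocol()], [read_protocol()]
#' @export
protocol_spec <- function(frame_rate = 100,
                          trial_duration = 30,
                          stim_onsets = 0.2 + 3 * (0:9),
                          stim_duration = 0.2,
                          photostim_onset = 2.5,
                          photostim_duration = 16,
                          photostim_freq = 20,
                          pulse_width = 0.025,
                          contrasts = 1,
                          pre_record_norm_window = 0.2,
                          inter_condition_interval = 60,
                          mode = c("train", "single_contrast")) {
  mode <- match.arg(mode)
  p <- structure(list(
    frame_rate = as.numeric(frame_rate),
    trial_duration = as.numeric(trial_duration),
    stim_onsets = as.numeric(stim_onsets),
    stim_duration = as.numeric(stim_duration),
    photostim_onset = as.numeric(photostim_onset),
    photostim_duration = as.numeric(photostim_duration),
    photostim_freq = as.numeric(photostim_freq),
    pulse_width = as.numeric(pulse_width),
    contrasts = as.numeric(contrasts),
    pre_record_norm_window = as.numeric(pre_record_norm_window),
    inter_condition_interval = as.numeric(inter_condition_interval),
    mode = mode
  ), class = "protocol_spec")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(is.list(p))
  if (!is.finite(p$frame_rate) || p$frame_rate <= 0)
    stop("protocol validation: frame_rate must be > 0", call. = FALSE)
  if (!is.finite(p$stim_duration) || p$stim_duration <= 0)
    stop("protocol validation: stim_duration must be > 0", call. = FALSE)
  if (p$trial_duration <= 0)
    stop("protocol validation: trial_duration must be > 0", call. = FALSE)
  if (any(p$stim_onsets < 0 | p$stim_onsets >= p$trial_duration))
    stop("protocol validation: stim_onsets must lie inside [0, trial_duration)",
         call. = FALSE)
  if (p$photostim_onset < 0 ||
      p$photostim_onset + p$photostim_duration > p$trial_duration)
    stop("protocol validation: photostimulation window must lie inside ",
         "[0, trial_duration)", call. = FALSE)
  if (any(p$contrasts <= 0 | p$contrasts > 1))
    stop("protocol validation: contrasts must be fractions in (0, 1]",
         call. = FALSE)
  if (anyDuplicated(p$contrasts))
    stop("protocol validation: duplicate contrasts are forbidden", call. = FALSE)
  if (p$mode == "single_contrast" && length(p$contrasts) > 1 &&
      any(diff(p$contrasts) >= 0))
    stop("protocol validation: contrasts must be strictly decreasing in ",
         "single_contrast mode", call. = FALSE)
  invisible(p)
}

#' Default trial protocols
#'
#' `default_protocol()` is the full-field stimulus-train design: 100 Hz
#' acquisition, 30 s per condition, ten 200-ms gratings at 3-s intervals
#' starting 200 ms after recording onset, and a 16-s, 20-Hz photostimulation
#' train starting at 2.5 s. `contrast_protocol()` is the contrast-series
#' design: a single 200-ms grating per trial at one of five contrasts
#' (100, 50, 25, 12.5, 6.25%), with photostimulation starting 700 ms before
#' the visual stimulus and lasting to the end of the trial.
#'
#' @param trial_duration trial length in seconds. The contrast design is
#'   routinely run shorter than the train design in simulation; the analysis
#'   only requires that the stimulus and photostimulation fit in the trial.
#' @return A [protocol_spec()].
#' @export
default_protocol <- function(trial_duration = 30) {
  protocol_spec(trial_duration = trial_duration, mode = "train")
}

#' @rdname default_protocol
#' @param stim_onset onset of the single grating, s.
#' @export
contrast_protocol <- function(trial_duration = 30, stim_onset = 3.2) {
  protocol_spec(
    trial_duration = trial_duration,
    stim_onsets = stim_onset,
    photostim_onset = stim_onset - 0.7,
    photostim_duration = trial_duration - (stim_onset - 0.7),
    contrasts = c(1, 0.5, 0.25, 0.125, 0.0625),
    mode = "single_contrast"
  )
}

#' Read or write a protocol as JSON
#'
#' @param path file path of a JSON protocol description.
#' @return `read_protocol` returns a validated [protocol_spec()];
#'   `write_protocol` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("protocol parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  known <- names(formals(protocol_spec))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("protocol parse error: unknown field(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(protocol_spec, raw)
}

#' @rdname read_protocol
#' @param protocol a [protocol_spec()].
#' @export
write_protocol <- function(protocol, path) {
  validate_protocol(protocol)
  jsonlite::write_json(unclass(protocol), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Condition label
#'
#' Identifies one experimental condition: recording modality, stimulus type
#' (V = visual grating, S = blank screen / spontaneous), photostimulation
#' state, optional antagonist, and (for the contrast design) the grating
#' contrast. A spontaneous (S) condition carries no contrast.
#'
#' @param stimulus `"V"` or `"S"`.
#' @param photostim `"on"` or `"off"`.
#' @param modality `"imaging"` or `"mua"`.
#' @param drug `"none"`, `"MDL"` (5-HT2A antagonist), `"WAY"` (5-HT1A
#'   antagonist) or `"vehicle"`.
#' @param contrast grating contrast fraction, or `NA` for the train design
#'   and for all S conditions.
#' @return An object of class `condition_label`.
#' @export
condition_label <- function(stimulus = c("V", "S"),
                            photostim = c("off", "on"),
                            modality = c("imaging", "mua"),
                            drug = c("none", "MDL", "WAY", "vehicle"),
                            contrast = NA_real_) {
  stimulus <- match.arg(stimulus)
  photostim <- match.arg(photostim)
  modality <- match.arg(modality)
  drug <- match.arg(drug)
  contrast <- as.numeric(contrast)
  if (length(contrast) == 0) contrast <- NA_real_
  if (stimulus == "S" && !is.na(contrast))
    stop("condition validation: spontaneous (S) conditions carry no contrast",
         call. = FALSE)
  structure(list(stimulus = stimulus, photostim = photostim,
                 modality = modality, drug = drug, contrast = contrast),
            class = "condition_label")
}

#' @export
format.condition_label <- function(x, ...) {
  tag <- paste0(x$stimulus, if (x$photostim == "on") "_ph" else "")
  if (!is.na(x$contrast)) tag <- sprintf("%s_c%g", tag, 100 * x$contrast)
  if (x$drug != "none") tag <- paste0(tag, "_", x$drug)
  tag
}

#' @export
print.condition_label <- function(x, ...) {
  cat("<condition>", format(x), sprintf("[%s]\n", x$modality))
  invisible(x)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %s mode: %g Hz, %g s, %d stimuli, photostim %g-%g s\n",
              x$mode, x$frame_rate, x$trial_duration, length(x$stim_onsets),
              x$photostim_onset, x$photostim_onset + x$photostim_duration))
  invisible(x)
}

#' Convert a half-open time window to frame indices
#'
#' Frames are indexed 1-based in R; frame `i` covers time
#' `[(i-1)/rate, i/rate)`. The window `[t0, t1)` maps to frames
#' `floor(t0*rate)+1` through `ceiling(t1*rate)`.
#'
#' @param t0,t1 window bounds in seconds, `t0 < t1`.
#' @param rate sampling rate, samples/s.
#' @param n_frames optional trace length; the window is truncated (with a
#'   warning) if it extends past the end.
#' @return Integer vector of frame indices.
#' @export
frame_window <- function(t0, t1, rate, n_frames = NULL) {
  stopifnot(t1 > t0)
  i0 <- floor(t0 * rate) + 1L
  i1 <- ceiling(t1 * rate)
  if (i0 < 1L) i0 <- 1L
  if (!is.null(n_frames) && i1 > n_frames) {
    warning("analysis window [", t0, ", ", t1, ") truncated at trace end",
            call. = FALSE)
    i1 <- n_frames
  }
  seq.int(i0, i1)
}

#' Time axis of a protocol
#' @param protocol a [protocol_spec()].
#' @return Numeric vector of frame-start times in seconds.
#' @export
protocol_times <- function(protocol) {
  n <- n_frames(protocol)
  (seq_len(n) - 1) / protocol$frame_rate
}

#' @rdname protocol_times
#' @return `n_frames` returns the expected number of frames per trial.
#' @export
n_frames <- function(protocol) {
  as.integer(round(protocol$trial_duration * protocol$frame_rate))
}
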