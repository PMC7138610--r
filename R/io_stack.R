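#' Trial stack container
#'
#' A `trial_stack` holds one raw fluorescence movie for one trial of one
#' condition: a `time x height x width` array of nonnegative values in
#' arbitrary camera units, plus its [condition_label()] and trial index.
#'
#' @param pixels numeric array `time x height x width`, values >= 0.
#' @param condition a [condition_label()].
#' @param trial 1-based trial index.
#' @param frame_rate sampling rate, samples/s.
#' @return An object of class `trial_stack`.
#' @export
trial_stack <- function(pixels, condition, trial, frame_rate) {
  stopifnot(length(dim(pixels)) == 3)
  if (any(pixels < 0))
    stop("trial_stack: negative pixel values", call. = FALSE)
  structure(list(pixels = pixels, condition = condition,
                 trial = as.integer(trial), frame_rate = as.numeric(frame_rate)),
            class = "trial_stack")
}

#' @export
print.trial_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<trial_stack> %s trial %d: %d frames of %dx%d px at %g Hz\n",
              format(x$condition), x$trial, d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

# rebuild a condition_label from sidecar metadata (contrast may be absent)
cond_from_meta <- function(m) {
  condition_label(stimulus = m$stimulus, photostim = m$photostim,
                  modality = m$modality, drug = m$drug,
                  contrast = if (is.null(m$contrast)) NA_real_ else m$contrast)
}

#' Write a trial movie as multi-frame TIFF plus JSON sidecar
#'
#' Movies are stored as 16-bit unsigned grayscale TIFF, one page per frame.
#' Pixel values are scaled into `[0, 1]` by the stack maximum before writing
#' (the scale factor is recorded in the sidecar and undone on read), so the
#' quantization step is about 1.5e-5 of the dynamic range -- far below the
#' photon noise of any real camera, and idempotent: writing what was read
#' back reproduces the file bit for bit. The sidecar (same path with `.json`
#' extension) also records condition, trial index, contrast and frame rate,
#' so each file is self-describing.
#'
#' @param stack a [trial_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_trial_stack <- function(stack, path) {
  stopifnot(inherits(stack, "trial_stack"))
  px <- stack$pixels
  scale <- max(px)
  if (scale <= 0) scale <- 1
  nt <- dim(px)[1]
  # quantize to the 16-bit grid here (writeTIFF truncates): round() makes a
  # write/read/write cycle reproduce the file exactly
  frames <- lapply(seq_len(nt), function(i)
    round(px[i, , , drop = TRUE] / scale * 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L,
                  reduce = FALSE, compression = "none")
  meta <- list(
    condition = unclass(stack$condition),
    trial = stack$trial,
    frame_rate = stack$frame_rate,
    n_frames = nt,
    scale = scale
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a trial movie from TIFF plus sidecar
#'
#' @param path `.tif` path written by [write_trial_stack()].
#' @param protocol optional [protocol_spec()]; when given, the frame count is
#'   checked against `trial_duration * frame_rate`.
#' @return A [trial_stack()].
#' @export
read_trial_stack <- function(path, protocol = NULL) {
  if (!file.exists(path)) stop("trial stack not found: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("sidecar not found: ", sp, call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  nt <- length(frames)
  if (!is.null(protocol) && nt != n_frames(protocol))
    stop(sprintf("frame-count mismatch in %s: %d frames, protocol expects %d",
                 path, nt, n_frames(protocol)), call. = FALSE)
  if (!is.null(meta$n_frames) && nt != meta$n_frames)
    stop(sprintf("frame-count mismatch in %s: %d frames, sidecar says %d",
                 path, nt, meta$n_frames), call. = FALSE)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  px <- array(0, dim = c(nt, h, w))
  for (i in seq_len(nt)) px[i, , ] <- frames[[i]]
  px <- px * meta$scale
  if (any(px < 0))
    stop("negative pixel values in ", path, call. = FALSE)
  cond <- cond_from_meta(meta$condition)
  trial_stack(px, cond, meta$trial, meta$frame_rate)
}

#' Spike-count matrix container
#'
#' Binned multi-unit spike counts: a `unit x bin x trial` integer array with
#' the bin width and unit identifiers.
#'
#' @param counts integer array `unit x bin x trial`, values >= 0.
#' @param bin_width bin width in seconds (0.2 s in the standard design).
#' @param unit_ids character or integer unit identifiers.
#' @param condition a [condition_label()].
#' @param base_rates optional per-unit baseline firing rates in Hz (known for
#'   synthetic data; used by rate filters).
#' @return An object of class `spike_count_matrix`.
#' @export
spike_count_matrix <- function(counts, bin_width = 0.2, unit_ids = NULL,
                               condition = NULL, base_rates = NULL) {
  stopifnot(length(dim(counts)) == 3)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("spike_count_matrix: counts must be nonnegative integers",
         call. = FALSE)
  if (is.null(unit_ids)) unit_ids <- seq_len(dim(counts)[1])
  structure(list(counts = counts, bin_width = as.numeric(bin_width),
                 unit_ids = unit_ids, condition = condition,
                 base_rates = base_rates),
            class = "spike_count_matrix")
}

#' @export
print.spike_count_matrix <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<spike_count_matrix> %d units x %d bins (%g s) x %d trials\n",
              d[1], d[2], x$bin_width, d[3]))
  invisible(x)
}

#' Trial-averaged firing-rate traces of a spike-count matrix
#'
#' @param scm a [spike_count_matrix()].
#' @return Matrix `unit x bin` of firing rates in Hz (counts averaged over
#'   trials, divided by the bin width).
#' @export
rate_traces <- function(scm) {
  apply(scm$counts, c(1, 2), mean) / scm$bin_width
}

#' Write / read spike counts as long-format CSV
#'
#' Columns: `condition, trial, unit, time_s, value`, where `time_s` is the
#' bin start time. A sidecar JSON stores bin width, condition fields and
#' baseline rates.
#'
#' @param scm a [spike_count_matrix()].
#' @param path output `.csv` path.
#' @return `path` invisibly / a [spike_count_matrix()].
#' @export
write_spike_counts <- function(scm, path) {
  stopifnot(inherits(scm, "spike_count_matrix"))
  d <- dim(scm$counts)
  cond_tag <- if (is.null(scm$condition)) "NA" else format(scm$condition)
  df <- data.frame(
    condition = cond_tag,
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    unit = rep(rep(scm$unit_ids, times = d[2]), times = d[3]),
    time_s = rep(rep((seq_len(d[2]) - 1) * scm$bin_width, each = d[1]),
                 times = d[3]),
    value = as.vector(scm$counts)
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(bin_width = scm$bin_width,
               unit_ids = scm$unit_ids,
               condition = if (is.null(scm$condition)) NULL
                           else unclass(scm$condition),
               base_rates = scm$base_rates,
               dim = d)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_spike_counts
#' @export
read_spike_counts <- function(path) {
  if (!file.exists(path)) stop("spike counts not found: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  d <- meta$dim
  counts <- array(as.integer(df$value), dim = d)
  cond <- if (is.null(meta$condition)) NULL else cond_from_meta(meta$condition)
  spike_count_matrix(counts, meta$bin_width, meta$unit_ids, cond,
                     meta$base_rates)
}
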