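#' Ground truth for the synthetic-data generator
#'
#' Collects every parameter of the generative model behind the synthetic
#' trial movies and spike counts, so that analysis results can be checked
#' against known truth. Photostimulation acts through three parameters:
#' a multiplicative gain `g_e` on the evoked response, a multiplicative gain
#' `g_s` on the ongoing (spontaneous) fluctuation process, and an additive
#' shift `spont_offset` of the baseline during the photostimulation window.
#' `g_e = g_s = 1` with `spont_offset = 0` reproduces control statistics.
#'
#' State-dependent defaults encode the two cortical regimes: in the
#' anesthetized state photostimulation is more suppressive (smaller `g_e`,
#' larger negative offset) and the calcium response peaks later than in the
#' awake state.
#'
#' @param state `"anesthetized"` or `"awake"`; selects the default regime.
#' @param g_e evoked gain under photostimulation (1 = no suppression).
#' @param g_s spontaneous gain under photostimulation.
#' @param spont_offset additive baseline shift during photostimulation.
#'   Interpreted in delta-F/F units for imaging and in Hz for spike counts.
#' @param tuning named list `R_max, c50, n, R0` of the contrast-response
#'   function feeding the evoked amplitude (delta-F/F units for `R_max`, `R0`).
#' @param kernel named list `rise_tau, decay_tau` (s) of the calcium impulse
#'   response, a normalized difference of exponentials.
#' @param late_rise named list `onset` (s after photostimulation onset) and
#'   `slope` (delta-F/F per s) of the slow calcium ramp that appears in the
#'   imaging signal (intracellular calcium accumulation) but never in spiking.
#' @param spont_process named list `std` (delta-F/F) and `correlation_time`
#'   (s) of the Ornstein-Uhlenbeck ongoing-activity process.
#' @param artifacts named list `heartbeat_hz, heartbeat_amp, respiration_hz,
#'   respiration_amp, photostim_artifact_amp, artifact_corner_fraction`.
#'   Amplitudes are fractions of the illumination level; the 20-Hz
#'   photostimulation artifact is confined to the lower-left corner block.
#' @param illumination named list `base` (camera units) and `vignette`
#'   (fractional radial falloff) of the spatial gain map.
#' @param noise_std per-pixel Gaussian noise SD as a fraction of `base`.
#' @param rate_range range (Hz) from which per-unit baseline firing rates are
#'   drawn for spike-count generation.
#' @param evoked_rate_gain peak relative rate modulation of a unit at 100%
#'   contrast (unitless; 2 means the rate triples at the response peak).
#' @param seed integer master seed; all per-trial randomness is derived
#'   deterministically from it.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(state = c("anesthetized", "awake"),
                         g_e = NULL, g_s = NULL, spont_offset = NULL,
                         tuning = list(R_max = 0.1, c50 = 0.25, n = 2, R0 = 0),
                         kernel = NULL,
                         late_rise = list(onset = 6, slope = 0.002),
                         spont_process = list(std = 0.01,
                                              correlation_time = 2),
                         artifacts = list(heartbeat_hz = 10,
                                          heartbeat_amp = 0.005,
                                          respiration_hz = 3,
                                          respiration_amp = 0.005,
                                          photostim_artifact_amp = 0.02,
                                          artifact_corner_fraction = 0.25),
                         illumination = list(base = 1000, vignette = 0.3),
                         noise_std = 0.01,
                         rate_range = c(0.5, 25),
                         evoked_rate_gain = 2,
                         seed = 1L) {
  state <- match.arg(state)
  # regime defaults: stronger suppression and a slower calcium kernel under
  # anesthesia, milder suppression and an earlier peak when awake
  if (is.null(g_e)) g_e <- if (state == "anesthetized") 0.52 else 0.78
  if (is.null(g_s)) g_s <- if (state == "anesthetized") 0.6 else 0.65
  if (is.null(spont_offset))
    spont_offset <- if (state == "anesthetized") -0.02 else -0.01
  if (is.null(kernel))
    kernel <- if (state == "anesthetized")
      list(rise_tau = 0.25, decay_tau = 0.9)
    else list(rise_tau = 0.15, decay_tau = 0.7)
  if (g_e < 0 || g_s < 0)
    stop("ground_truth: gains must be nonnegative", call. = FALSE)
  if (g_e > 1 || g_s > 1)
    warning("ground_truth: gain > 1 lies outside the suppressive regime",
            call. = FALSE)
  stopifnot(tuning$R_max >= 0, tuning$n > 0,
            tuning$c50 > 0, tuning$c50 <= 1,
            spont_process$std >= 0, spont_process$correlation_time > 0)
  kernel$peak_delay <- kernel_peak_delay(kernel$rise_tau, kernel$decay_tau)
  structure(list(state = state, g_e = g_e, g_s = g_s,
                 spont_offset = spont_offset, tuning = tuning,
                 kernel = kernel, late_rise = late_rise,
                 spont_process = spont_process, artifacts = artifacts,
                 illumination = illumination, noise_std = noise_std,
                 rate_range = rate_range,
                 evoked_rate_gain = evoked_rate_gain,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> state=%s g_e=%g g_s=%g offset=%g seed=%d\n",
              x$state, x$g_e, x$g_s, x$spont_offset, x$seed))
  invisible(x)
}

#' Antagonist variants of a ground-truth parameter set
#'
#' Encodes the receptor dissociation as alternative ground truth: blocking
#' 5-HT2A receptors (`"MDL"`) largely removes the evoked-gain suppression and
#' attenuates the late calcium rise; blocking 5-HT1A receptors (`"WAY"`)
#' removes the spontaneous suppression (`g_s = 1`, offset 0) while leaving
#' the evoked gain untouched.
#'
#' @param gt a [ground_truth()].
#' @param drug `"MDL"` or `"WAY"`.
#' @return A modified [ground_truth()].
#' @export
apply_drug <- function(gt, drug = c("MDL", "WAY")) {
  drug <- match.arg(drug)
  if (drug == "MDL") {
    gt$g_e <- 0.9
    gt$late_rise$slope <- gt$late_rise$slope * 0.3
  } else {
    gt$g_s <- 1
    gt$spont_offset <- 0
  }
  gt
}

# deterministic 31-bit seed stream derived from the master seed
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1299709 + (as.numeric(p) %% 65521) + 1) %% 2147483647
  as.integer(h)
}

condition_code <- function(condition) {
  2L * (condition$stimulus == "V") + (condition$photostim == "on") +
    4L * match(condition$drug, c("none", "MDL", "WAY", "vehicle")) +
    32L * (!is.na(condition$contrast)) +
    if (!is.na(condition$contrast)) round(1000 * condition$contrast) else 0L
}

#' Calcium impulse-response kernel
#'
#' Difference of exponentials `exp(-t/decay_tau) - exp(-t/rise_tau)`,
#' normalized to unit peak. `kernel_peak_delay` gives the closed-form time
#' of the maximum.
#'
#' @param t times in seconds (>= 0 contributes; t < 0 gives 0).
#' @param rise_tau,decay_tau time constants in s, `rise_tau < decay_tau`.
#' @return Kernel values (unit peak) / peak delay in seconds.
#' @export
calcium_kernel <- function(t, rise_tau, decay_tau) {
  stopifnot(rise_tau > 0, decay_tau > rise_tau)
  k <- ifelse(t >= 0, exp(-t / decay_tau) - exp(-t / rise_tau), 0)
  tp <- kernel_peak_delay(rise_tau, decay_tau)
  kmax <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  k / kmax
}

#' @rdname calcium_kernel
#' @export
kernel_peak_delay <- function(rise_tau, decay_tau) {
  rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

#' Ornstein-Uhlenbeck ongoing-activity process
#'
#' Exact discretization: stationary zero-mean AR(1) with marginal SD `std`
#' and autocorrelation `exp(-dt / tau)` per step.
#'
#' @param n number of samples.
#' @param dt sample interval, s.
#' @param std stationary standard deviation.
#' @param tau correlation time, s.
#' @return Numeric vector of length `n`.
#' @export
ou_process <- function(n, dt, std, tau) {
  if (std == 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov_sd <- std * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, std)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1)) x[i + 1] <- a * x[i] + eps[i]
  x
}

# photostimulation gate: 1 outside the window, `gain` inside (ph conditions)
ph_gate <- function(times, protocol, condition, gain) {
  g <- rep(1, length(times))
  if (condition$photostim == "on") {
    on <- times >= protocol$photostim_onset &
      times < protocol$photostim_onset + protocol$photostim_duration
    g[on] <- gain
  }
  g
}

#' Deterministic ROI signal of the generative model
#'
#' The noise-free, artifact-free population signal for one condition:
#' `evoked(t) * G_e(t) + offset(t) + late(t)`, where `evoked` is the calcium
#' kernel convolved with the stimulus onsets and scaled by the Naka-Rushton
#' response at the condition's contrast, `G_e` switches from 1 to `g_e`
#' during photostimulation, `offset` is the additive baseline shift during
#' photostimulation, and `late` is the slow calcium ramp (imaging only).
#' This closed form is what trial averages of the stochastic generator
#' converge to, and is used directly by recovery tests.
#'
#' @param gt a [ground_truth()].
#' @param protocol a [protocol_spec()].
#' @param condition a [condition_label()].
#' @param late include the late calcium ramp (`TRUE` for imaging).
#' @return Numeric vector over [protocol_times()].
#' @export
roi_signal <- function(gt, protocol, condition, late = TRUE) {
  times <- protocol_times(protocol)
  sig <- numeric(length(times))
  if (condition$stimulus == "V") {
    contr <- if (!is.na(condition$contrast)) condition$contrast else
      protocol$contrasts[1]
    amp <- naka_rushton(contr, gt$tuning$R_max, gt$tuning$c50,
                        gt$tuning$n, gt$tuning$R0)
    evoked <- numeric(length(times))
    for (on in protocol$stim_onsets)
      evoked <- evoked + calcium_kernel(times - on, gt$kernel$rise_tau,
                                        gt$kernel$decay_tau)
    sig <- sig + amp * evoked * ph_gate(times, protocol, condition, gt$g_e)
  }
  if (condition$photostim == "on") {
    ph_on <- times >= protocol$photostim_onset &
      times < protocol$photostim_onset + protocol$photostim_duration
    sig[ph_on] <- sig[ph_on] + gt$spont_offset
    if (late && gt$late_rise$slope != 0) {
      t0 <- protocol$photostim_onset + gt$late_rise$onset
      ramp <- pmax(times - t0, 0) * gt$late_rise$slope
      ramp[!ph_on] <- 0
      sig <- sig + ramp
    }
  }
  sig
}

#' Generate ROI-level delta-F/F trial traces
#'
#' Trace-level short-cut of the movie generator: each trial is the
#' deterministic [roi_signal()] plus the photostimulation-gated spontaneous
#' process `spont(t) * G_s(t)`. Trials are reproducible from the master seed,
#' condition and trial index alone, so the identical spontaneous draw can be
#' shared between conditions by passing the same `noise_stream`, emulating
#' interleaved conditions that ride on a common ongoing process.
#'
#' @inheritParams roi_signal
#' @param n_trials number of trials.
#' @param noise_stream integer tag entering the per-trial seed for the
#'   spontaneous process; conditions generated with the same tag share
#'   spontaneous draws trial-for-trial. Default: a condition-specific tag
#'   (independent draws).
#' @return Matrix `n_trials x n_frames` of delta-F/F traces.
#' @export
generate_roi_traces <- function(gt, protocol, condition, n_trials,
                                noise_stream = NULL) {
  times <- protocol_times(protocol)
  det <- roi_signal(gt, protocol, condition,
                    late = condition$modality == "imaging")
  gs <- ph_gate(times, protocol, condition, gt$g_s)
  if (is.null(noise_stream)) noise_stream <- condition_code(condition)
  out <- matrix(0, n_trials, length(times))
  for (tr in seq_len(n_trials))
    out[tr, ] <- det + spont_draw(gt, protocol, noise_stream, tr) * gs
  out
}

# the spontaneous OU draw for one trial, from the derived seed stream
spont_draw <- function(gt, protocol, noise_stream, trial) {
  old <- .Random.seed_save()
  set.seed(derive_seed(gt$seed, 7L, noise_stream, trial))
  sp <- ou_process(n_frames(protocol), 1 / protocol$frame_rate,
                   gt$spont_process$std, gt$spont_process$correlation_time)
  .Random.seed_restore(old)
  sp
}

# save/restore the global RNG state so derived-seed draws do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# spatial layout shared by all trials of one ground truth
spatial_layout <- function(gt, dim_px) {
  h <- dim_px[1]; w <- dim_px[2]
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r2 <- ((yy - cy) / (h / 2))^2 + ((xx - cx) / (w / 2))^2
  illum <- gt$illumination$base * (1 - gt$illumination$vignette * r2 / 2)
  roi <- (r2 <= 0.35)  # central disk of responsive cortex
  corner <- matrix(FALSE, h, w)
  csh <- max(1L, floor(gt$artifacts$artifact_corner_fraction * h))
  csw <- max(1L, floor(gt$artifacts$artifact_corner_fraction * w))
  corner[(h - csh + 1):h, 1:csw] <- TRUE  # lower-left block
  list(illum = illum, roi = roi, corner = corner)
}

#' Generate a synthetic trial movie
#'
#' One raw-fluorescence movie according to the generative model
#' `pixel(x,y,t) = illum(x,y) * (1 + roi(x,y) * (spont(t) G_s(t) + offset(t)
#' + evoked(t) G_e(t) + late(t))) + artifacts(x,y,t) + noise`, where the
#' heartbeat and respiration artifacts are global sinusoids, the 20-Hz
#' photostimulation artifact is a square wave confined to the lower-left
#' corner block, and noise is i.i.d. Gaussian per pixel (clipped at zero).
#'
#' @inheritParams generate_roi_traces
#' @param trial trial index (enters the derived seed).
#' @param dim_px image size `c(height, width)` in pixels.
#' @return A [trial_stack()].
#' @export
generate_trial_stack <- function(gt, protocol, condition, trial,
                                 dim_px = c(64, 64), noise_stream = NULL) {
  times <- protocol_times(protocol)
  nt <- length(times)
  lay <- spatial_layout(gt, dim_px)
  if (is.null(noise_stream)) noise_stream <- condition_code(condition)
  det <- roi_signal(gt, protocol, condition,
                    late = condition$modality == "imaging")
  gs <- ph_gate(times, protocol, condition, gt$g_s)
  sig <- det + spont_draw(gt, protocol, noise_stream, trial) * gs

  a <- gt$artifacts
  phase_seed <- derive_seed(gt$seed, 11L, condition_code(condition), trial)
  old <- .Random.seed_save()
  set.seed(phase_seed)
  ph_hb <- stats::runif(1, 0, 2 * pi)
  ph_rs <- stats::runif(1, 0, 2 * pi)
  global_art <- a$heartbeat_amp * sin(2 * pi * a$heartbeat_hz * times + ph_hb) +
    a$respiration_amp * sin(2 * pi * a$respiration_hz * times + ph_rs)

  corner_art <- numeric(nt)
  if (condition$photostim == "on" && a$photostim_artifact_amp > 0) {
    on <- times >= protocol$photostim_onset &
      times < protocol$photostim_onset + protocol$photostim_duration
    duty <- (times - protocol$photostim_onset) %% (1 / protocol$photostim_freq)
    sq <- as.numeric(duty < 0.5 / protocol$photostim_freq)
    corner_art <- a$photostim_artifact_amp * sq * on
  }

  h <- dim_px[1]; w <- dim_px[2]
  base <- gt$illumination$base
  px <- array(0, dim = c(nt, h, w))
  noise <- if (gt$noise_std > 0)
    array(stats::rnorm(nt * h * w, 0, gt$noise_std * base), dim = c(nt, h, w))
  else 0
  .Random.seed_restore(old)

  roi_t <- outer(sig, as.numeric(lay$roi))            # nt x (h*w)
  art_t <- outer(global_art, rep(1, h * w)) +
    outer(corner_art, as.numeric(lay$corner))
  frame_gain <- sweep(1 + roi_t + art_t, 2, as.numeric(lay$illum), `*`)
  px[] <- array(frame_gain, dim = c(nt, h, w)) + noise
  px[px < 0] <- 0
  trial_stack(px, condition, trial, protocol$frame_rate)
}

#' Generate synthetic multi-unit spike counts
#'
#' Counts are Poisson samples of an inhomogeneous rate
#' `rate(t) = base_rate * G_s(t) * (1 + evoked_rel(t) * G_e(t)) + offset`,
#' binned at `bin_width`. `evoked_rel` is the calcium kernel convolved with
#' stimulus onsets, scaled so that a 100%-contrast stimulus modulates the
#' rate by `evoked_rate_gain` at its peak. The late calcium ramp never
#' enters the rate: the dissociation between the imaging and spiking signals
#' is structural in the generator. The offset is interpreted in Hz.
#'
#' @inheritParams generate_roi_traces
#' @param n_units number of units; baseline rates are drawn uniformly from
#'   `gt$rate_range`.
#' @param n_trials trials per condition.
#' @param bin_width bin width, s.
#' @return A [spike_count_matrix()] with known `base_rates`.
#' @export
generate_spike_counts <- function(gt, protocol, condition, n_units,
                                  n_trials = 10, bin_width = 0.2) {
  if (n_units < 1) stop("generate_spike_counts: n_units must be >= 1",
                        call. = FALSE)
  nb <- floor(protocol$trial_duration / bin_width)
  tmid <- (seq_len(nb) - 0.5) * bin_width
  ge <- ph_gate(tmid, protocol, condition, gt$g_e)
  gs <- ph_gate(tmid, protocol, condition, gt$g_s)
  offset <- if (condition$photostim == "on")
    gt$spont_offset * (tmid >= protocol$photostim_onset &
                       tmid < protocol$photostim_onset +
                         protocol$photostim_duration)
  else 0

  evoked_rel <- numeric(nb)
  if (condition$stimulus == "V") {
    contr <- if (!is.na(condition$contrast)) condition$contrast else
      protocol$contrasts[1]
    nr1 <- naka_rushton(1, gt$tuning$R_max, gt$tuning$c50, gt$tuning$n,
                        gt$tuning$R0)
    amp <- naka_rushton(contr, gt$tuning$R_max, gt$tuning$c50, gt$tuning$n,
                        gt$tuning$R0) / nr1 * gt$evoked_rate_gain
    for (on in protocol$stim_onsets)
      evoked_rel <- evoked_rel + amp * calcium_kernel(tmid - on,
                                                      gt$kernel$rise_tau,
                                                      gt$kernel$decay_tau)
  }

  old <- .Random.seed_save()
  set.seed(derive_seed(gt$seed, 13L))
  base_rates <- stats::runif(n_units, gt$rate_range[1], gt$rate_range[2])
  set.seed(derive_seed(gt$seed, 17L, condition_code(condition)))
  counts <- array(0L, dim = c(n_units, nb, n_trials))
  for (u in seq_len(n_units)) {
    rate <- pmax(base_rates[u] * gs * (1 + evoked_rel * ge) + offset, 0)
    counts[u, , ] <- stats::rpois(nb * n_trials, rep(rate * bin_width,
                                                     n_trials))
  }
  .Random.seed_restore(old)
  spike_count_matrix(counts, bin_width, seq_len(n_units), condition,
                     base_rates)
}

#' Generate a cohort dataset on disk
#'
#' Writes one movie per subject x condition x trial, a `manifest.csv`
#' listing every file, the protocol, and a `ground_truth.json` sidecar
#' sufficient for parameter-recovery tests.
#'
#' @param gts list of [ground_truth()] objects, one per subject.
#' @param protocol a [protocol_spec()].
#' @param out output directory.
#' @param n_trials trials per condition per subject.
#' @param dim_px image size.
#' @param conditions list of [condition_label()]s; default the four-condition
#'   imaging design (V, V_ph, S, S_ph) in the train protocol, or the full
#'   contrast series in the single-contrast protocol.
#' @param share_spontaneous if `TRUE`, all conditions of one trial index ride
#'   on the same spontaneous draw (useful for noiseless identity checks).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest data frame.
#' @export
generate_cohort <- function(gts, protocol, out, n_trials = 10,
                            dim_px = c(32, 32), conditions = NULL,
                            share_spontaneous = FALSE, overwrite = FALSE) {
  stopifnot(length(gts) >= 1)
  if (dir.exists(out) && length(dir(out)) > 0 && !overwrite)
    stop("output directory ", out, " is not empty (use overwrite = TRUE)",
         call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (is.null(conditions)) conditions <- default_conditions(protocol)
  rows <- list()
  for (s in seq_along(gts)) {
    gt <- gts[[s]]
    sub_dir <- file.path(out, sprintf("sub%02d", s))
    dir.create(sub_dir, showWarnings = FALSE)
    for (cond in conditions) {
      for (tr in seq_len(n_trials)) {
        stream <- if (share_spontaneous) 1L else NULL
        stack <- generate_trial_stack(gt, protocol, cond, tr, dim_px,
                                      noise_stream = stream)
        fname <- sprintf("%s_t%02d.tif", format(cond), tr)
        write_trial_stack(stack, file.path(sub_dir, fname))
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, condition = format(cond), stimulus = cond$stimulus,
          photostim = cond$photostim, drug = cond$drug,
          contrast = cond$contrast, trial = tr,
          file = file.path(sprintf("sub%02d", s), fname))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  write_protocol(protocol, file.path(out, "protocol.json"))
  gt_json <- lapply(seq_along(gts), function(s) {
    g <- unclass(gts[[s]])
    g$kernel$peak_delay <- NULL
    c(list(subject = s), g)
  })
  jsonlite::write_json(gt_json, file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

#' Default condition set of a protocol
#' @param protocol a [protocol_spec()].
#' @param modality `"imaging"` or `"mua"`.
#' @return List of [condition_label()]s.
#' @export
default_conditions <- function(protocol, modality = "imaging") {
  if (protocol$mode == "train") {
    list(condition_label("V", "off", modality),
         condition_label("V", "on", modality),
         condition_label("S", "off", modality),
         condition_label("S", "on", modality))
  } else {
    conds <- list()
    for (co in protocol$contrasts) {
      conds <- c(conds, list(condition_label("V", "off", modality,
                                             contrast = co),
                             condition_label("V", "on", modality,
                                             contrast = co)))
    }
    c(conds, list(condition_label("S", "off", modality),
                  condition_label("S", "on", modality)))
  }
}

#' Re-scan a cohort directory into a manifest
#'
#' Rebuilds the manifest from the sidecar files on disk; used to verify that
#' a written dataset is self-describing.
#'
#' @param root cohort directory written by [generate_cohort()].
#' @return Manifest data frame in the same column order as `manifest.csv`.
#' @export
scan_cohort <- function(root) {
  tifs <- sort(list.files(root, pattern = "\\.tif$", recursive = TRUE))
  rows <- lapply(tifs, function(f) {
    meta <- jsonlite::read_json(sidecar_path(file.path(root, f)),
                                simplifyVector = TRUE)
    cond <- cond_from_meta(meta$condition)
    data.frame(subject = as.integer(sub("sub(\\d+).*", "\\1", f)),
               condition = format(cond), stimulus = cond$stimulus,
               photostim = cond$photostim, drug = cond$drug,
               contrast = cond$contrast, trial = meta$trial, file = f)
  })
  df <- do.call(rbind, rows)
  df[order(df$subject, df$condition, df$trial), ]
}
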