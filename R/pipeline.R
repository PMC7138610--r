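#' Default pipeline configuration
#'
#' Configuration for [run_pipeline()]. The defaults define a small but
#' complete synthetic study: a cohort of subjects recorded with the
#' stimulus-train protocol as full trial movies (exercising the imaging
#' path end-to-end), matched multi-unit spike counts for the suppression
#' regression, and ROI-level contrast-series traces for the tuning and
#' gain-decomposition stages.
#'
#' @param out output directory for result files.
#' @param data_dir directory for the simulated dataset.
#' @param seed master seed; every stochastic stage derives from it.
#' @param n_subjects,n_trials,dim_px cohort shape for the movie dataset.
#' @param n_units,n_mua_trials multi-unit cohort shape.
#' @param states cortical states to simulate (`"anesthetized"`, `"awake"`).
#' @param stages subset of
#'   `c("simulate", "preprocess", "components", "regress", "tuning",
#'   "gain", "report")`.
#' @param smooth_sigma spatial smoothing sigma (px) used in preprocessing
#'   (scaled to the simulated image size rather than the acquisition
#'   default).
#' @param contrast_trials trials per contrast condition for the tuning stage.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out = "results", data_dir = "data", seed = 1L,
                            n_subjects = 3, n_trials = 6,
                            dim_px = c(16, 16), n_units = 24,
                            n_mua_trials = 15,
                            states = "anesthetized",
                            stages = c("simulate", "preprocess",
                                       "components", "regress", "tuning",
                                       "gain", "report"),
                            smooth_sigma = 1, contrast_trials = 20) {
  structure(list(out = out, data_dir = data_dir, seed = as.integer(seed),
                 n_subjects = n_subjects, n_trials = n_trials,
                 dim_px = dim_px, n_units = n_units,
                 n_mua_trials = n_mua_trials, states = states,
                 stages = stages, smooth_sigma = smooth_sigma,
                 contrast_trials = contrast_trials),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with any subset of [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("pipeline config: unknown field(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on a synthetic cohort:
#' `simulate` writes the movie dataset, spike counts and ground truth;
#' `preprocess` turns movies into normalized ROI traces; `components`
#' computes per-stimulus amplitude/baseline/magnitude metrics and the
#' evoked component; `regress` fits the divisive-versus-subtractive
#' suppression regression on the multi-unit data; `tuning` fits
#' Naka-Rushton contrast-response functions (raw and max-normalized);
#' `gain` computes the gain decomposition per state; `report` aggregates a
#' summary with the spontaneous-suppression statistics and the onset of
#' significant suppression. Every stage writes CSV/JSON under `config$out`
#' and the run is byte-reproducible for a fixed seed.
#'
#' @param config a [pipeline_config()], or a path to a JSON config.
#' @return Invisibly, a list with the in-memory results of the stages run.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  log <- list(package = "sertgain",
              version = as.character(utils::packageVersion("sertgain")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = cfg$seed, config = unclass(cfg))

  protocol <- default_protocol()
  cprotocol <- contrast_protocol(trial_duration = 10)

  if ("simulate" %in% cfg$stages) {
    gts <- lapply(seq_len(cfg$n_subjects), function(s)
      ground_truth(state = cfg$states[1],
                   seed = derive_seed(cfg$seed, 101L, s)))
    manifest <- generate_cohort(gts, protocol, cfg$data_dir,
                                n_trials = cfg$n_trials, dim_px = cfg$dim_px,
                                overwrite = TRUE)
    for (s in seq_len(cfg$n_subjects)) {
      for (cond in list(condition_label("S", "off", "mua"),
                        condition_label("S", "on", "mua"),
                        condition_label("V", "off", "mua"))) {
        scm <- generate_spike_counts(gts[[s]], protocol, cond,
                                     n_units = cfg$n_units,
                                     n_trials = cfg$n_mua_trials)
        write_spike_counts(scm, file.path(
          cfg$data_dir, sprintf("sub%02d", s),
          sprintf("mua_%s.csv", format(cond))))
      }
    }
    res$manifest <- manifest
  }

  manifest_path <- file.path(cfg$data_dir, "manifest.csv")
  if (!file.exists(manifest_path) &&
      any(c("preprocess", "components", "report") %in% cfg$stages))
    stop("pipeline stage 'preprocess': missing input manifest.csv ",
         "(run the simulate stage first)", call. = FALSE)

  if (any(c("preprocess", "components", "report") %in% cfg$stages)) {
    manifest <- utils::read.csv(manifest_path)
    protocol <- read_protocol(file.path(cfg$data_dir, "protocol.json"))
    tracesets <- list()
    for (s in unique(manifest$subject)) {
      sub <- manifest[manifest$subject == s, ]
      stacks <- split(sub, sub$condition)
      stacks <- lapply(stacks, function(rows)
        lapply(rows$file, function(f)
          read_trial_stack(file.path(cfg$data_dir, f), protocol)))
      ts <- preprocess_trials(stacks, protocol,
                              smooth_sigma = cfg$smooth_sigma)
      tracesets[[as.character(s)]] <- normalize_to_first_peak(ts, protocol)
    }
    res$tracesets <- tracesets
    # long-format trace CSV (trial-averaged per condition per subject)
    rows <- list()
    for (s in names(tracesets))
      for (cond in names(tracesets[[s]]$mean)) {
        v <- tracesets[[s]]$mean[[cond]]
        rows[[length(rows) + 1]] <- data.frame(
          subject = as.integer(s), condition = cond,
          time_s = (seq_along(v) - 1) / protocol$frame_rate, value = v)
      }
    utils::write.csv(do.call(rbind, rows),
                     file.path(cfg$out, "roi_traces.csv"),
                     row.names = FALSE)
  }

  if ("components" %in% cfg$stages) {
    metrics_rows <- list()
    for (s in names(res$tracesets)) {
      ts <- res$tracesets[[s]]
      win <- locate_windows(ts$mean[["V"]], protocol)
      for (cond in c("V", "V_ph")) {
        m <- compute_metrics(ts$mean[[cond]], win)
        m$condition <- cond; m$subject <- as.integer(s)
        metrics_rows[[length(metrics_rows) + 1]] <- m
      }
      e <- evoked_component(ts$traces[["V_ph"]], ts$traces[["S_ph"]])
      m <- compute_metrics(e$mean, win)
      m$condition <- "E_ph"; m$subject <- as.integer(s)
      metrics_rows[[length(metrics_rows) + 1]] <- m
    }
    res$metrics <- do.call(rbind, metrics_rows)
    utils::write.csv(res$metrics,
                     file.path(cfg$out, "component_metrics.csv"),
                     row.names = FALSE)
  }

  if ("regress" %in% cfg$stages) {
    fits <- list()
    for (s in seq_len(cfg$n_subjects)) {
      sdir <- file.path(cfg$data_dir, sprintf("sub%02d", s))
      if (!file.exists(file.path(sdir, "mua_S.csv")))
        stop("pipeline stage 'regress': missing input mua_S.csv for ",
             sprintf("sub%02d", s), call. = FALSE)
      scm_s <- read_spike_counts(file.path(sdir, "mua_S.csv"))
      scm_p <- read_spike_counts(file.path(sdir, "mua_S_ph.csv"))
      rec <- build_prepost(rate_traces(scm_s), rate_traces(scm_p),
                           protocol, bin_width = scm_s$bin_width,
                           window_len = min(4, protocol$photostim_onset),
                           subject_id = s)
      flt <- filter_units(rec)
      fits[[s]] <- fit_suppression(flt$records)
      utils::write.csv(data.frame(subject = s,
                                  excluded_unit = if (length(flt$excluded))
                                    flt$excluded else NA),
                       file.path(cfg$out,
                                 sprintf("excluded_units_sub%02d.csv", s)),
                       row.names = FALSE)
    }
    cls <- classify_suppression(fits)
    res$suppression <- list(fits = fits, classification = cls)
    write_json_out(list(
      classification = cls[c("label", "p_b2", "p_b4", "mean_b2", "mean_b4",
                             "sem_b2", "sem_b4", "tested")],
      coefficients = lapply(fits, function(f) as.list(f$coefficients)),
      standard_errors = lapply(fits, function(f) as.list(f$se))),
      file.path(cfg$out, "suppression_fit.json"))
  }

  if (any(c("tuning", "gain") %in% cfg$stages)) {
    # ROI-level contrast-series traces per subject and state
    contrast_res <- list()
    for (state in cfg$states) {
      gts <- lapply(seq_len(cfg$n_subjects), function(s)
        ground_truth(state = state, seed = derive_seed(cfg$seed, 211L, s)))
      peaks <- list(V = 0, V_ph = 0, E_ph = 0)
      sph_mean <- 0
      sph_wph <- numeric(cfg$n_subjects)
      pk_times <- numeric(cfg$n_subjects)
      contrasts <- cprotocol$contrasts
      per_subj <- vector("list", cfg$n_subjects)
      for (s in seq_len(cfg$n_subjects)) {
        m <- contrast_metrics(gts[[s]], cprotocol, cfg$contrast_trials)
        per_subj[[s]] <- m
        peaks$V <- peaks$V + m$peaks$V / cfg$n_subjects
        peaks$V_ph <- peaks$V_ph + m$peaks$V_ph / cfg$n_subjects
        peaks$E_ph <- peaks$E_ph + m$peaks$E_ph / cfg$n_subjects
        sph_mean <- sph_mean + m$sph_trace / cfg$n_subjects
        sph_wph[s] <- m$sph_wph
        pk_times[s] <- mean(m$peak_times)
      }
      fits <- lapply(peaks, function(p) fit_naka_rushton(contrasts, p))
      normed <- normalize_and_refit(contrasts, peaks)
      contrast_res[[state]] <- list(contrasts = contrasts, peaks = peaks,
                                    fits = fits, normalized = normed,
                                    sph_trace = sph_mean,
                                    sph_wph = sph_wph,
                                    peak_times = pk_times,
                                    per_subject = per_subj)
    }
    res$contrast <- contrast_res
    if ("tuning" %in% cfg$stages) {
      tun <- lapply(contrast_res, function(cr) {
        list(fits = lapply(cr$fits, unclass_fit),
             normalized = lapply(cr$normalized, function(nf)
               c(list(scaled = nf$scaled), unclass_fit(nf$fit))))
      })
      write_json_out(tun, file.path(cfg$out, "contrast_tuning.json"))
      rows <- list()
      for (state in names(contrast_res)) {
        cr <- contrast_res[[state]]
        for (cond in names(cr$peaks))
          rows[[length(rows) + 1]] <- data.frame(
            state = state, condition = cond, contrast = cr$contrasts,
            peak = cr$peaks[[cond]],
            normalized_peak = cr$normalized[[cond]]$scaled)
      }
      utils::write.csv(do.call(rbind, rows),
                       file.path(cfg$out, "contrast_peaks.csv"),
                       row.names = FALSE)
    }
  }

  if ("gain" %in% cfg$stages) {
    gain_res <- list()
    for (state in names(res$contrast)) {
      cr <- res$contrast[[state]]
      ctrl <- data.frame(magnitude = cr$peaks$V, contrast = cr$contrasts)
      ph <- data.frame(magnitude = cr$peaks$V_ph, contrast = cr$contrasts)
      g <- estimate_gain(ctrl, ph)
      eph <- data.frame(magnitude = cr$peaks$E_ph, contrast = cr$contrasts)
      dec <- component_weights(g$g, eph, cr$sph_trace, cprotocol,
                               peak_times = rep(mean(cr$peak_times),
                                                length(g$g)),
                               state = state)
      gain_res[[state]] <- list(g = g, decomposition = dec,
                                sph_wph = cr$sph_wph, peak_times =
                                  cr$peak_times)
      utils::write.csv(as.data.frame(dec),
                       file.path(cfg$out,
                                 sprintf("gain_decomposition_%s.csv", state)),
                       row.names = FALSE)
    }
    if (length(gain_res) == 2) {
      states <- names(gain_res)
      aw <- if ("awake" %in% states) gain_res$awake else gain_res[[1]]
      an <- if ("anesthetized" %in% states) gain_res$anesthetized
            else gain_res[[2]]
      cmp <- compare_states(
        list(decomposition = aw$decomposition, g = NULL,
             sph_wph = aw$sph_wph, peak_times = aw$peak_times),
        list(decomposition = an$decomposition, g = NULL,
             sph_wph = an$sph_wph, peak_times = an$peak_times))
      write_json_out(list(table = cmp$table,
                          tests = lapply(cmp$tests, function(t)
                            t[c("statistic", "p", "test_name", "side")])),
                     file.path(cfg$out, "state_comparison.json"))
      res$state_comparison <- cmp
    }
    res$gain <- gain_res
  }

  if ("report" %in% cfg$stages) {
    summary <- list(seed = cfg$seed, n_subjects = cfg$n_subjects)
    if (!is.null(res$tracesets)) {
      wph <- c(protocol$photostim_onset,
               protocol$photostim_onset + protocol$photostim_duration)
      sup <- vapply(res$tracesets, function(ts) {
        d <- ts$mean[["S_ph"]] - ts$mean[["S"]]
        mean(d[frame_window(wph[1], wph[2], protocol$frame_rate,
                            length(d))])
      }, numeric(1))
      tt <- t_test_one_sided(sup, mu = 0, kind = "one_sample",
                             side = "less")
      # onset of significant suppression on per-trial paired differences
      s1 <- res$tracesets[[1]]
      nb <- min(nrow(s1$traces$S), nrow(s1$traces$S_ph))
      dmat <- bin_traces(s1$traces$S_ph[seq_len(nb), , drop = FALSE] -
                           s1$traces$S[seq_len(nb), , drop = FALSE],
                         protocol$frame_rate, 0.2)
      ons <- onset_of_significance(dmat, rate = 5,
                                   ph_onset = protocol$photostim_onset,
                                   criterion = "permutation",
                                   seed = derive_seed(cfg$seed, 303L))
      summary$spontaneous_suppression_wph <- list(
        mean = mean(sup), sem = stats::sd(sup) / sqrt(length(sup)),
        p = tt$p)
      summary$suppression_onset_s <- ons$onset
    }
    if (!is.null(res$suppression))
      summary$suppression_classification <-
        res$suppression$classification$label
    if (!is.null(res$contrast))
      summary$tuning <- lapply(res$contrast, function(cr)
        lapply(cr$fits, function(f) f[c("R_max", "c50", "n", "R0",
                                        "r_squared")]))
    res$summary <- summary
    write_json_out(summary, file.path(cfg$out, "summary.json"))
  }

  log$stages_run <- cfg$stages
  write_json_out(log, file.path(cfg$out, "run_log.json"))
  invisible(res)
}

unclass_fit <- function(f)
  f[c("R_max", "c50", "n", "R0", "r_squared", "converged")]

# rebin trial x frame traces to coarser bins (column means per bin)
bin_traces <- function(m, rate, bin_width) {
  k <- round(bin_width * rate)
  nb <- floor(ncol(m) / k)
  out <- matrix(0, nrow(m), nb)
  for (b in seq_len(nb))
    out[, b] <- rowMeans(m[, ((b - 1) * k + 1):(b * k), drop = FALSE])
  out
}

#' Contrast-series component metrics for one subject
#'
#' Generates ROI-level traces for every contrast condition of the
#' single-contrast protocol, and summarizes them into the inputs of the
#' tuning and gain stages: per-contrast peak magnitudes for V, V_ph and the
#' evoked component E_ph, the trial-averaged S_ph trace, its
#' photostimulation-window average, and the control peak times.
#'
#' @param gt a [ground_truth()].
#' @param protocol a single-contrast [protocol_spec()].
#' @param n_trials trials per condition.
#' @return List with `peaks` (named list V/V_ph/E_ph of per-contrast
#'   magnitudes), `amps` (same structure for peak-window amplitudes, which
#'   retain any baseline shift), `sph_trace`, `sph_wph`, `peak_times`,
#'   `contrasts`.
#' @export
contrast_metrics <- function(gt, protocol, n_trials = 20) {
  stopifnot(protocol$mode == "single_contrast")
  contrasts <- protocol$contrasts
  sph <- generate_roi_traces(gt, protocol,
                             condition_label("S", "on"), n_trials)
  s_ctrl <- generate_roi_traces(gt, protocol,
                                condition_label("S", "off"), n_trials)
  peaks <- list(V = numeric(length(contrasts)),
                V_ph = numeric(length(contrasts)),
                E_ph = numeric(length(contrasts)))
  amps <- peaks  # peak-window amplitudes, which keep the baseline shift
  peak_times <- numeric(length(contrasts))
  for (i in seq_along(contrasts)) {
    co <- contrasts[i]
    v <- generate_roi_traces(gt, protocol,
                             condition_label("V", "off", contrast = co),
                             n_trials)
    vph <- generate_roi_traces(gt, protocol,
                               condition_label("V", "on", contrast = co),
                               n_trials)
    win <- locate_windows(colMeans(v), protocol)
    peak_times[i] <- win$peak_times[1]
    eph <- evoked_component(vph, sph)
    mv <- compute_metrics(colMeans(v), win)
    mvp <- compute_metrics(colMeans(vph), win)
    mep <- compute_metrics(eph$mean, win)
    peaks$V[i] <- mv$magnitude[1]
    peaks$V_ph[i] <- mvp$magnitude[1]
    peaks$E_ph[i] <- mep$magnitude[1]
    amps$V[i] <- mv$amplitude[1]
    amps$V_ph[i] <- mvp$amplitude[1]
    amps$E_ph[i] <- mep$amplitude[1]
  }
  wph <- c(protocol$photostim_onset,
           protocol$photostim_onset + protocol$photostim_duration)
  sph_mean <- colMeans(sph)
  sph_wph <- mean(sph_mean[frame_window(wph[1], wph[2],
                                        protocol$frame_rate,
                                        length(sph_mean))]) -
    mean(colMeans(s_ctrl)[frame_window(wph[1], wph[2],
                                       protocol$frame_rate,
                                       length(sph_mean))])
  list(peaks = peaks, amps = amps, sph_trace = sph_mean, sph_wph = sph_wph,
       peak_times = peak_times, contrasts = contrasts)
}
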