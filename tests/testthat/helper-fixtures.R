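# Shared fixtures: small protocols and quiet ground truths so unit tests
# stay fast. The full 30-s / 100-Hz design is exercised where the test is
# about the design itself.

short_protocol <- function(n_stim = 3, trial_duration = 10) {
  protocol_spec(trial_duration = trial_duration,
                stim_onsets = 0.2 + 3 * (seq_len(n_stim) - 1),
                photostim_onset = 2.5,
                photostim_duration = trial_duration - 3)
}

short_contrast_protocol <- function(trial_duration = 10) {
  contrast_protocol(trial_duration = trial_duration)
}

# deterministic regime: no spontaneous fluctuations, artifacts or noise
clean_gt <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(state = "anesthetized", seed = seed,
                   spont_process = list(std = 0, correlation_time = 2),
                   noise_std = 0,
                   late_rise = list(onset = 6, slope = 0),
                   artifacts = list(heartbeat_hz = 10, heartbeat_amp = 0,
                                    respiration_hz = 3, respiration_amp = 0,
                                    photostim_artifact_amp = 0,
                                    artifact_corner_fraction = 0.25))
  do.call(ground_truth, utils::modifyList(defaults, args))
}

# quiet stochastic regime for recovery tests
noisy_gt <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(state = "anesthetized", seed = seed, noise_std = 0.002,
                   artifacts = list(heartbeat_hz = 10, heartbeat_amp = 0,
                                    respiration_hz = 3, respiration_amp = 0,
                                    photostim_artifact_amp = 0,
                                    artifact_corner_fraction = 0.25))
  do.call(ground_truth, utils::modifyList(defaults, args))
}
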