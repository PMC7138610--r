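{
  "frame_rate": 100,
  "trial_duration": 30,
  "stim_onsets": 3.2,
  "stim_duration": 0.2,
  "photostim_onset": 2.5,
  "photostim_duration": 27.5,
  "photostim_freq": 20,
  "pulse_width": 0.025,
  "contrasts": [1, 0.5, 0.25, 0.125, 0.0625],
  "pre_record_norm_window": 0.2,
  "inter_condition_interval": 60,
  "mode": "single_contrast"
}
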