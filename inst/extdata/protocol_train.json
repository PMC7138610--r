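{
  "frame_rate": 100,
  "trial_duration": 30,
  "stim_onsets": [0.2, 3.2, 6.2, 9.2, 12.2, 15.2, 18.2, 21.2, 24.2, 27.2],
  "stim_duration": 0.2,
  "photostim_onset": 2.5,
  "photostim_duration": 16,
  "photostim_freq": 20,
  "pulse_width": 0.025,
  "contrasts": 1,
  "pre_record_norm_window": 0.2,
  "inter_condition_interval": 60,
  "mode": "train"
}
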