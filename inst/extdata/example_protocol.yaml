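# Disks-and-rings protocol example: three disk diameters and the matched
# rings at a shared outer diameter, 2 Hz / 0.8 cpd drifting gratings.
trials: 10
inter_trial_blank_ms: 500
stimuli:
  - shape: blank
    duration_ms: 1500
  - shape: disk
    diameter_deg: 1.0
    temporal_freq_hz: 2
    spatial_freq_cpd: 0.8
    contrast: 1
    duration_ms: 1500
  - shape: disk
    diameter_deg: 2.0
    duration_ms: 1500
  - shape: disk
    diameter_deg: 4.0
    duration_ms: 1500
  - shape: ring
    diameter_deg: 1.0
    outer_diameter_deg: 4.0
    duration_ms: 1500
  - shape: ring
    diameter_deg: 2.0
    outer_diameter_deg: 4.0
    duration_ms: 1500
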