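ions:
- name: ClO4
  charge: -1
- name: S
  charge: -2
sensors:
- id: P1
  primary_ion: ClO4
  e0_mV: 355.0
  slope_mV_per_decade: -57.700000000000003
  log_k_pot:
    S: -1.96
  background_activity_M: 5.2e-06
  noise_sd_mV: 0.5
  drift_sd_mV: 1.0
- id: S1
  primary_ion: S
  e0_mV: -120.0
  slope_mV_per_decade: -33.299999999999997
  log_k_pot:
    ClO4: -2.68
  background_activity_M: 1.3e-05
  noise_sd_mV: 0.5
  drift_sd_mV: 1.0
- id: S2
  primary_ion: S
  e0_mV: -95.0
  slope_mV_per_decade: -30.899999999999999
  log_k_pot:
    ClO4: -3.23
  background_activity_M: 9.799999999999999e-06
  noise_sd_mV: 0.5
  drift_sd_mV: 1.0
- id: S3
  primary_ion: S
  e0_mV: -60.0
  slope_mV_per_decade: -28.899999999999999
  log_k_pot:
    ClO4: -3.75
  background_activity_M: 9.9e-06
  noise_sd_mV: 0.5
  drift_sd_mV: 1.0
- id: G
  primary_ion: S
  e0_mV: -150.0
  slope_mV_per_decade: -44.299999999999997
  log_k_pot:
    ClO4: 1.13
  background_activity_M: 8.3e-06
  noise_sd_mV: 0.5
  drift_sd_mV: 1.0
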