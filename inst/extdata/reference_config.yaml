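# Reference parameter sets for the three transporter systems.
# Times in ns; clustering = number of k-means microstates.
GLUT1-Apo:
  tica_lag_ns: 1.0
  n_components: 3
  clustering: 100
  msm_lag_ns: 5.0
  L_ns: 9.5
  tau_k_ns: 0.4
GLUT9-Apo:
  tica_lag_ns: 0.2
  n_components: 3
  clustering: 100
  msm_lag_ns: 2.0
  L_ns: 9.6
  tau_k_ns: 0.4
GLUT9-API:
  tica_lag_ns: 2.0
  n_components: 3
  clustering: 100
  msm_lag_ns: 2.0
  L_ns: 9.5
  tau_k_ns: 0.1
som_defaults:
  grid: [10, 10]
  cycles: 5000
  cap_angstrom: 12.0
contact_cutoff_angstrom: 4.0
temperature_K: 310.0
frame_interval_ns: 0.1
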