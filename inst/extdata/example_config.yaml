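# Example chamberflux pipeline configuration: simulate a short warming
# campaign (3 chambers, one per treatment), calibrate on day 1, estimate
# the warming effect on day 2.
simulate:
  start: "2009-01-01"
  end: "2009-01-03"
  warming_start: "2009-01-02"
  instrument:
    n_chambers: 3
    co2_noise_sd: 0.5
    dead_band_records: 3
qc:
  dead_band: 3
  passes: 3
  m: 3
  r_threshold: 0.95
  min_points: 10
flux:
  model: linear
  pressure_source: chamber
analysis:
  calibration_window: ["2009-01-01", "2009-01-02"]
  period: ["2009-01-02", "2009-01-03"]
  warming: true
  q10: false
  cv: false
  aggregate: true
  coverage: true
seed: 4
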