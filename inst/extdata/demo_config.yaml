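# Demo configuration: a three-cytokine session per condition, sized so the
# full pipeline (simulate -> report) runs in well under a minute while still
# reproducing the qualitative separability contrast (CH control > CH dss,
# permutation p < 0.05).
seed: 1
population:
  n_neurons: 60
  class_proportions:
    il1b_specific: 0.15
    tnf_specific: 0.25
    il10_responsive: 0.20
    multi_cytokine: 0.25
    non_cytokine: 0.15
  sampling_rate: 20.0
  duration: 1000.0
  latency_max: 100.0
  n_animals: 10
  active_noncytokine: yes
  events:
    time_s: [150.0, 450.0, 750.0]
    stimulus: [IL-1b, TNF, IL-10]
    concentration_ng_per_ml: [200.0, 50.0, 50.0]
conditions: [control, dss]
detection:
  noise_sd_estimator: mad
  onset_k: 3.0
  offset_frac: 0.2
  min_duration: 0.5
  smoothing_window: 5
  peak_prominence_frac: 0.2
  abs_floor: 5.0
assignment:
  window_s: 100.0
  exclude_if_active_at_event: yes
  exclude_saline_responders: no
  baseline_window_s: 50.0
  min_traces_per_animal: 10
separability:
  fence_k: 1.5
  drop_fraction: 0.25
  standardize: yes
  S: 20
  P: 499
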