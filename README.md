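# vagaltrace

Analysis of cytokine-evoked calcium activity in vagal sensory neurons.

Nodose ganglion neurons report visceral immune state to the brain: applying
inflammatory cytokines (IL-1β, TNF, IL-10) to the vagus nerve evokes
discrete calcium transients in distinct neuronal subpopulations, and
colitis-like gut inflammation raises spontaneous baseline activity while
blunting and blurring the cytokine-specific responses. `vagaltrace`
implements the trace-level analysis behind those observations for anyone
working with per-neuron DFF time series and a stimulus log — plus a seeded
synthetic-data generator with full ground truth, so every stage is testable.

The pipeline:

* **Transient detection** on smoothed DFF with robust (MAD) noise
  thresholds, and six per-transient features computed on the raw trace:
  amplitude, duration, rise slope, decay slope, integral, number of peaks.
* **Response assignment** under the 100-s rule: for each application the
  earliest transient with onset in `(t_event, t_event + 100]` is the
  response; one response per trace per event, earlier event wins.
* **Classification** into IL-1β-specific, TNF-specific, IL-10-responsive,
  multi-cytokine, non-cytokine (and optional saline-responder) classes, with
  responder proportions over transient-bearing neurons.
* **Baseline activity**: spontaneously active neuron counts in a 50-s
  event-free window, and per-animal feature summaries (≥10 traces per animal
  flagged otherwise).
* **Cluster separability** of the cytokine groups in z-scored five-feature
  space: per-group Tukey fences (Q1/Q3 ± 1.5·IQR), iterative cross-group
  nearest-neighbor pruning (dropping the 25% most similar points), the
  Calinski-Harabasz index
  `CH = [B/(k−1)] / [W/(n−k)]`
  per condition, and a permutative Mann-Whitney test comparing conditions
  through stratified CH subsamples.

## A worked example

```r
library(vagaltrace)

# a control and a colitis-like session, 60 neurons each, three cytokines
pop <- three_cytokine_population(n_neurons = 60, seed = 1)
ctl <- simulate_population(pop, control_condition(spont_rate = 0))
dss <- simulate_population(pop, dss_condition(spont_rate = 0))

fm <- rbind(
  assemble_feature_matrix(assign_responses(detect_all(ctl), ctl$events), "control"),
  assemble_feature_matrix(assign_responses(detect_all(dss), dss$events), "dss"))
res <- separability_analysis(fm, S = 20, P = 499, seed = 1)
res
#> <separability_result>
#>   CH control = 64.24 vs dss = 21.26
#>   permutative Mann-Whitney: U = 400.0, p = 0.012 (S = 20, m = 5, P = 499)
#>   rows: 159 input -> 141 after fence -> 105 after prune
```

The control condition's cytokine response clusters are far better separated
(CH 64.2) than the colitis-like condition's (CH 21.3) — inflammation
compresses the amplitude differences between cytokines and adds noise — and
the permutation test calls the difference significant (p = 0.012).

Classification on the same session:

```r
cls <- classify_neurons(detect_all(ctl), ctl$events,
                        neuron_ids = ctl$truth$neurons$neuron_id)
round(responder_proportions(cls), 3)
#> il1b_specific    tnf_specific il10_responsive  multi_cytokine    non_cytokine
#>         0.150           0.250           0.200           0.250           0.150
```

which recovers the generating class mix exactly at this noise level.

A command-line wrapper over the same stage functions is installed at
`inst/scripts/vagaltrace` (`simulate`, `detect`, `classify`, `separability`,
`report`, `run-all`), driven by a YAML/JSON config
(`inst/extdata/demo_config.yaml`) and writing a manifest alongside its
artifacts; runs are byte-reproducible for a fixed config.

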