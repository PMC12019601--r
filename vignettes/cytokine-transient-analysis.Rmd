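---
title: "Methods: cytokine-evoked calcium transient analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytokine-evoked calcium transient analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagaltrace)
```

## The analysis problem

Vagal sensory neurons of the nodose ganglion respond to inflammatory
cytokines (IL-1β, TNF, IL-10) applied to the vagus nerve with discrete
calcium transients, and colitis-like gut inflammation both raises their
spontaneous baseline activity and blunts their cytokine-evoked responses.
`vagaltrace` implements the downstream analysis of such recordings, starting
from per-neuron DFF traces (percent fluorescence change over baseline,
sampled on a uniform grid — 20 Hz by default) and a stimulus event log:

1. **Transient detection** and extraction of six response features
   (amplitude, duration, rise slope, decay slope, integral, number of peaks).
2. **Response assignment**: linking transients to cytokine applications
   under a 100-second response window, one response per trace per event.
3. **Neuron classification** into responder subpopulations (IL-1β-specific,
   TNF-specific, IL-10-responsive, multi-cytokine, non-cytokine, optional
   saline responders) and responder proportions.
4. **Baseline activity**: counts of spontaneously active neurons in a 50-s
   event-free window and spontaneous transient amplitudes.
5. **Cluster separability** of the cytokine response groups in five-feature
   space: Tukey-fence outlier removal, iterative cross-group
   nearest-neighbor pruning, the Calinski-Harabasz (CH) index per condition,
   and a permutative Mann-Whitney comparison across conditions.

A synthetic-data generator stands in for raw imaging data: it produces
populations of traces with known ground truth so that every stage can be
validated quantitatively.

## The synthetic generator

### Transient shape model

Real recordings give no closed-form transient shape, so the generator uses a
minimal parametric family able to reproduce all six features: a product of
exponentials
$$g(t) = \left(1 - e^{-t/\tau_r}\right)\, e^{-t/\tau_d}, \qquad t \ge 0,$$
rescaled so its sampled maximum equals the drawn amplitude. Multi-peak
transients superpose delayed copies (delay `duration_mean / 4`) with
geometrically decaying sub-amplitudes (factor 0.6), then rescale the whole
segment. The peak of the unscaled kernel sits at
$t^\* = \tau_r \log(1 + \tau_d/\tau_r)$, which the tests verify against a
dense numerical maximisation.

Per-cytokine kernel defaults encode what distinguishes the cytokines in real
data. The amplitude means are the printed control-condition group means —
IL-1β 22.9, TNF 56.62, IL-10 95.70 %DFF — while the shape parameters
(`rise_tau` 2/4/3 s, `decay_tau` 10/18/28 s, support 40/60/80 s, peak-count
weights) are package defaults chosen once to give each cytokine a distinct
stereotyped time course; they are not measured values. Per-transient
amplitude SDs (4.5/9/14 %DFF, roughly 20% of the mean) are likewise
generator choices: the source reports only animal-level SEMs, not
per-response spreads.

### Conditions

A `condition_spec` carries the disease contrast:

* **control** — spontaneous transients at 0.2 events/min per neuron with
  amplitude 42.66 %DFF (the printed control baseline mean), evoked
  amplitude scales of 1, Gaussian noise SD 2 %DFF.
* **dss** (colitis-like) — spontaneous rate tripled to 0.6 events/min,
  spontaneous amplitude 29.08 %DFF, evoked scales TNF 44.27/56.62 ≈ 0.78
  and IL-10 55.59/95.70 ≈ 0.58 with IL-1β unchanged (the printed group-mean
  ratios), noise SD 3 %DFF (1.5× control).

The spontaneous rates and noise SDs are invented defaults: no event-rate or
noise level is printed for the real recordings. 0.2/min makes roughly 15% of
control neurons active in a 50-s baseline window, a plausible sparse-activity
regime for this preparation; the DSS value encodes "more spontaneously
active neurons" as a 3× rate increase. The DSS condition deliberately models
*only* these phenomenological changes — no receptor-level or transcriptomic
mechanism.

### Populations and ground truth

A `population_spec` fixes the class mix (largest-remainder apportionment, so
realised counts are deterministic; remainder ties go to the class listed
first), the recording grid, and the event schedule. Default proportions are
the published responder breakdown from two-cytokine experiments
(TNF 40.7%, multi-cytokine 28.6%, IL-1β 17.1%, non-cytokine 13.6%);
`three_cytokine_population()` adds an IL-10-responsive class for
three-cytokine sessions. Each responder emits one evoked transient per
responded-to event with latency uniform on `(0, latency_max]`;
`latency_max` defaults to 100 s, the same bound as the assignment window, so
ground truth is recoverable by the 100-s rule. Only the bound is stated for
the real data; the uniform latency law is our choice, made once.

**Conditioning the non-cytokine class on activity.** The imaging pipeline
the analysis emulates only yields ROIs for active neurons, and the
non-cytokine class is defined by activity *unrelated* to the applications. A
plain Poisson process cannot deliver both properties at once — at rates high
enough to make every non-cytokine neuron active, spontaneous transients land
inside assignment windows, where the 100-s rule *correctly* labels them as
responses and the ground-truth label becomes undefined rather than merely
hard to recover. The generator therefore gives each non-cytokine neuron one
guaranteed spontaneous transient placed outside every assignment window
(flag `active_noncytokine`, default on), on top of the ordinary Poisson
process. For the same reason, the ground-truth-recovery experiments in the
test suite run with the spontaneous rate at zero: with spontaneous activity
on, window-coincident transients change the *recoverable* label, which is a
property of the design, not a defect of the implementation. Passing those
tests therefore demonstrates correct detection, assignment and
classification — not robustness to spontaneous confounds, which real data
will have in proportion to their event rate.

Other aspects of real recordings the generator does not emulate: motion
artifacts, photobleaching and slow baseline drift, indicator (GCaMP)
saturation and nonlinearity, correlated noise across neurons, and any
spatial structure.

## Detection and features

Detection runs on a moving-average-smoothed copy (window 5 samples) of each
trace; features are computed on the raw trace. The noise SD is estimated
robustly (1.4826 × MAD of the full trace). A transient starts where the
smoothed trace exceeds `max(onset_k × noise_sd, abs_floor)` with
`onset_k = 3` and `abs_floor = 5` %DFF, and ends where it has fallen below
both that threshold and `offset_frac = 0.2` of its running smoothed maximum,
so re-risings merge into one transient and detected transients are disjoint
and time-ordered. Excursions shorter than 0.5 s are discarded, as are
segments whose smoothed peak never reaches `max(peak_k × noise_sd,
abs_floor)` with `peak_k = 5`: on the slowly decaying tail of a genuine
transient the smoothed trace hovers just below threshold and noise re-crosses
it repeatedly, producing spurious low-amplitude "echo" segments that the
peak criterion removes (without it, precision on synthetic data drops from
~0.99 to ~0.6). All thresholds are package inventions — the source analysis
names no detection criteria — and all are exposed in `detection_params()`.

Feature definitions: amplitude is the maximum raw DFF in the segment (first
sample of a plateau is the peak); duration is onset to offset (not
full-width-half-maximum — the alternative reading is documented here because
the source does not say which it used); rise slope is amplitude over
time-to-peak; decay slope is (offset value − amplitude) over
(offset − peak); the integral is trapezoidal (exact for piecewise-linear
signals, which is why the triangle fixture in the tests has a closed-form
value); `n_peaks` counts local maxima with topographic prominence at least
0.2 × amplitude, with the global maximum always counted so a constant
plateau yields one peak. Segments truncated by the end of the recording are
kept but flagged `censored` and excluded from feature statistics by default.

Two estimator biases worth knowing about: the raw-maximum amplitude is
biased upward by roughly `noise_sd × E[max of the near-peak noise]` (about
+2 to +4 %DFF at the default noise levels, i.e. a few percent of the evoked
amplitudes), and `n_peaks` on raw noisy segments over-counts when
0.2 × amplitude is comparable to noise peak-to-valley excursions. Amplitude
could be de-biased by smoothing, but that would break the exactness of the
closed-form fixtures and bias the peak downward instead; the package keeps
the raw-maximum definition and documents the bias. The parameter-recovery
test therefore runs at noise SD 0.5 %DFF (amplitude/noise ≥ 100, well
inside the regime it targets), a choice made from this bias analysis, not
from test outcomes.

## Assignment and classification

For each event `k` (in time order), the earliest unassigned transient with
onset in `(t_k, t_k + 100]` is the response: half-open at the event (an
onset exactly at the application time is causally ambiguous and excluded),
closed at +100 s. Each transient answers at most one event; when windows
overlap, the earlier event wins — a rule this package declares because the
source does not. A neuron with a transient still ongoing at the application
time gets no response for that event (configurable; the alternative reading
of the source's exclusion phrase — "never responded to an earlier
application" — cannot be right, since multi-cytokine responders exist).

Classification follows the responded-to set: one cytokine maps to the
corresponding specific class, two or more to multi-cytokine, none (with at
least one transient) to non-cytokine, saline-only responders to a separate
label excluded from cytokine proportions only on request. Neurons with no
transients at all are excluded from the proportion denominator, mirroring
the activity-based selection upstream; whether the published percentages
included such neurons is not stated, so the denominator choice is documented
here.

Per-animal summaries average a feature within animals (the unit of group
statistics); animals with fewer than 10 contributing transients are flagged
rather than dropped. Baseline activity counts neurons with at least one
onset in `[0, 50)` s and refuses windows that overlap an event. Group-level
plumbing (`group_tests()`) uses one-way ANOVA with Tukey HSD and the
two-sided Mann-Whitney U test from base R, exact for small untied samples.

## The separability procedure

Responses from both conditions are assembled into a five-feature matrix
(amplitude, duration, rise slope, decay slope, integral) with cytokine group
and condition labels; `n_peaks` is not part of the cluster space.

1. **Tukey fences** (`Q1/Q3 ± 1.5 × IQR`, quartiles by the linear
   interpolation convention at sorted index `(n−1)q`) are applied per
   feature within each cytokine-by-condition cell — never pooled, because
   responses to different cytokines live on different scales. A row is
   removed when any feature is outside its cell's fence; cells with fewer
   than 4 rows pass through with a warning.
2. **Z-scoring** per column over all kept rows, sample (n−1) SD convention.
   The features mix %DFF, s, %DFF/s and %DFF·s, so unscaled Euclidean
   distances would be dominated by the integral; the source states no
   scaling, so standardisation is the default and switchable.
3. **Iterative nearest-neighbor pruning**, per condition: repeatedly remove
   the single point whose Euclidean distance to its nearest surviving
   neighbor in a different cytokine group is smallest, for
   `⌈0.25 × n⌉` removals. Ties (every mutual nearest-neighbor pair is one)
   resolve to the lexicographically smaller group label, then the lower row
   index, making the procedure fully deterministic. A consequence worth
   knowing: removals concentrate in the densest cluster at a group boundary,
   so pruned cell sizes are uneven — downstream subsampling sizes itself on
   the smallest surviving cell.
4. **Calinski-Harabasz index** per condition on the kept rows:
   `CH = [B/(k−1)] / [W/(n−k)]` with between-group dispersion
   `B = Σ_g n_g‖μ_g − μ‖²` and within-group dispersion
   `W = Σ_g Σ_{i∈g} ‖x_i − μ_g‖²`. `W = 0` with `B > 0` returns `Inf` so
   noise-free fixtures remain usable; `B = 0` returns 0. The hot loop is
   implemented in C++ and checked against a literal brute-force evaluation
   of the definition in the tests.
5. **Permutative Mann-Whitney.** A single CH value per condition is not a
   sample, and the source does not say how it was turned into one. The
   package's declared construction: per condition, draw `S` stratified
   subsamples (`m` rows per cytokine group, without replacement within a
   subsample; `m` defaults to 80% of the smallest group-by-condition cell)
   and compute CH on each, giving two samples of `S` values compared with a
   Mann-Whitney U statistic; the null distribution comes from `P`
   permutations of condition labels within cytokine strata, recomputing both
   CH samples and U each time, with the add-one two-sided p-value
   `(1 + #exceedances)/(1 + P)`. All knobs (`S`, `m`, `P`, seed, fence and
   prune settings) are recorded in the result object. The headline CH per
   condition is computed once on all kept rows.

The published headline values (CH 47.11 vs 19.62, p = 0.0019) come from the
in-vivo recordings themselves and additionally depend on unstated choices
(3 vs 5 features, scaling, the permutation scheme), so they are not
reproduction targets; what the package reproduces, robustly across seeds, is
the direction and significance of the contrast — under the condition
defaults above, control CH exceeds DSS CH in effectively all simulated
session pairs and the permutation test rejects in the majority. The 3-D
view of amplitude/duration/rise-slope in the source is treated as
visualisation, not inference; `separability_analysis()` exposes the kept
standardised matrix for external plotting.

## Numerical and design choices

* Quantiles everywhere are R's default type 7, matching the declared
  interpolation convention; equality with a degenerate fence (IQR = 0) keeps
  the row.
* The standardisation example value (±1/√2 for a column `[0, 2]`) fixes the
  sample (n−1) SD convention.
* `W = 0` CH sentinel is `+Inf`, not an error.
* All simulation, subsampling and permutation randomness flows through
  explicit seeds (`with_seed()` restores the caller's RNG state), and the
  pipeline derives per-stage seeds from one master seed so stages can be
  re-run independently; identical configs give byte-identical result files.
* Empty inputs degrade explicitly: empty trace files read as empty lists
  with a warning, zero classified neurons refuse a proportion, degenerate
  groupings refuse a CH value, and insufficient post-pruning cells refuse a
  permutation test naming the required minimum.

### Problem sizes used in the checks

The test suite validates ground-truth recovery on 20 populations of 200
neurons (recall, precision and class accuracy ≥ 0.95; recovered class
fractions within ±0.02 of the generating mix), amplitude recovery on 240
neurons per condition (within 5% of `amplitude_mean × scale` at n > 100
transients per cytokine), permutation-test calibration on 500 null data sets
(type-I error in [0.03, 0.07] at α = 0.05 and a Kolmogorov-Smirnov
uniformity check), and the disease contrast on 100 simulated session pairs
whose class mixes are sized so per-cytokine response counts approximate the
published group sizes (control 153/264/223 and DSS 78/83/80 responses for
IL-1β/TNF/IL-10), at 80% scale. Sample size matters for the permutation
test's power here — post-pruning cell sizes set the subsample size `m`, and
at much smaller sessions the subsampled CH distributions of the two
conditions overlap even when the headline CH values separate cleanly. These
sizes are the package's chosen validation conditions: large enough for the
stated tolerances, small enough to run routinely.

## Known limitations

* Overlapping transients (a spontaneous event riding on an evoked one)
  merge into a single detection; deconvolution is out of scope.
* The amplitude estimator's upward noise bias and `n_peaks` over-counting
  at low amplitude-to-noise ratios, discussed above.
* Classification accuracy against ground truth degrades as the spontaneous
  rate grows, by construction of the 100-s rule, not by implementation.
* The permutation test's subsample scheme (`S`, `m`) is a declared
  construction, not a reproduction of the source's unstated one; its
  calibration is verified under the null, but different (`S`, `m`) choices
  change power.
* CH values depend on the standardisation choice; raw-scale CH is available
  (`standardize = FALSE`) but distances are then dominated by the integral.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(n_neurons = 60, seed = 1)
run_pipeline(cfg, "run1")
# or, from a shell:
#   inst/scripts/vagaltrace run-all --out=run1
```

This simulates a control and a DSS-like session, detects and classifies, and
writes `separability.json` whose CH values and permutation p reproduce the
qualitative disease effect (control CH well above DSS CH, p < 0.05).
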