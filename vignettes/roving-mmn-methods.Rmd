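---
title: "Methods: roving-oddball MMN analysis with Bayesian surprise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: roving-oddball MMN analysis with Bayesian surprise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package models

In an auditory roving-oddball design, tones of two pitches are presented in
consecutive trains of identical stimuli; whenever the pitch changes, the
first tone of the new train is a *Deviant* and the later tones of a train
are *Standards*. Because both pitches occur equally often, each stimulus
type serves as both standard and deviant, which dissociates genuine
predictive-learning effects from rarity effects. Subtracting the ERP to
standards from the ERP to deviants yields the mismatch negativity (MMN), a
frontocentral negative deflection near 200 ms that is widely read as an
index of implicit perceptual learning: the brain's model update when a
prediction fails.

The package implements that whole analysis chain as testable code:

1. **Sequence design** (`generate_sequence()`): pseudo-random train lengths,
   a fixed deviant rate, a constant inter-stimulus interval, and balancing
   of both event counts and mean Bayesian surprise across pitches.
2. **Ideal observer** (`surprise_series()`): a sequential Bayesian learner
   of stimulus probabilities whose per-trial Kullback–Leibler update is the
   Bayesian surprise regressor.
3. **Synthetic data** (`simulate_epochs()`, `simulate_behavior()`):
   multichannel EEG epochs and behavioural recall scores with exactly the
   statistical structure the analysis assumes, so every downstream stage is
   testable without any recording.
4. **ERP core** (`condition_average()`, `mmn_differential()`,
   `negative_peak()`): averaging, the deviant-minus-last-standard
   differential wave, and windowed peak measurement.
5. **Cluster statistics** (`trialwise_correlation()`, `group_t_map()`,
   `cluster_permutation_test()`): point-by-point maps with spatiotemporal
   cluster-based permutation correction.
6. **Behavioural statistics** (`paired_t_dz()`, `benjamini_hochberg()`):
   paired t tests with Cohen's dz and FDR control.
7. **Workbench** (`run_study()`): one-command orchestration of the full
   synthetic study with reproducible seeding and JSON reporting.

## The ideal observer

The observer is a conjugate Beta–Bernoulli learner over stimulus identity
(high vs low pitch). Writing the accumulated pseudo-counts as $(a, b)$ with
prior $(a_0, b_0) = (1, 1)$, observing category $A$ maps the belief
$\mathrm{Beta}(a, b)$ to $\mathrm{Beta}(a + 1, b)$, and the trial's
Bayesian surprise is

$$ BS_t \;=\; D_{KL}\!\left(\mathrm{Beta}(a+1, b) \,\Vert\, \mathrm{Beta}(a, b)\right), $$

computed in closed form from log-Beta and digamma terms (`beta_kl()`),
reported in nats by default (bits = nats / ln 2). This is the standard
"surprise as belief update" construction; the reverse KL direction is
available behind `observer_config(reverse_kl = TRUE)` for comparison.

Two modelling choices deserve flags:

* **Forgetting.** `observer_config(forgetting = λ)` decays the excess
  counts toward the prior before each update, bounding the effective memory
  at $1/(1-λ)$ trials. The default is λ = 1 (no forgetting): plain
  conjugate updating, under which the state is exchangeable in the stream
  order and updates shrink as $\mathcal{O}(1/n)$. Because the true
  forgetting constant of a human listener is not identifiable from the
  design alone, `forgetting_sweep()` reports how the surprise regressor
  changes over a λ grid.
* **Deviants vs standards.** Deviants tend to update the belief more than
  standards because a train inflates the count of its own pitch, so the
  train-terminating deviant usually increments the locally under-counted
  category. With λ = 1 this is a *tendency*, not a theorem: over a long
  balanced run the sign of the count asymmetry at a train's end fluctuates,
  and on a default run roughly a third of the individual deviants carry
  less surprise than their immediately preceding standard, while the mean
  over deviants remains clearly above the mean over standards. The tests
  assert the aggregate ordering and a majority-of-trains version rather
  than a per-train inequality.

Observers restart from the prior at every run boundary; nothing leaks
across runs, and "last standard" bookkeeping restarts likewise.

## Sequence generation

Train lengths are drawn uniformly from the support {3, …, 7} (mean 5, hence
the 80/20 standard/deviant ratio) and nudged by single-notch moves within
the support until they sum to the run length; the number of trains is
`round(deviant_fraction * n_events_per_run)` — 230 for a 1152-event run at
20%. Pitch alternates across trains, so per-pitch deviant counts differ by
at most one by construction. Per-pitch *event* counts are balanced by
greedy swaps of lengths between odd and even train positions, and the mean
surprise gap between pitches is closed by re-permuting the length order
within pitch positions until the gap is at most `balance_tol` (0.05 nats by
default, retry cap 200). A note on reported deviant counts: a fixed count
such as 208 last-standard pairs cannot arise from 20% of 1152; the
`n_trains` override exists for reproducing designs that fix the number of
trains directly, and the default follows the percentage rule.

## The synthetic study generator

Every simulated trial is

$$ x_{c,t}(\text{trial}) \;=\; \underbrace{\sum_k A_k\, w_k(c)\, g_k(t)}_{\text{N1, P2, P3, N4}}
\;+\; \gamma_{\text{cond}}\, (1 + u_s)\, BS_{\text{trial}}\, w_{MMN}(c)\, g_{MMN}(t)\,[\text{deviant}]
\;+\; \varepsilon_{c,t}, $$

with Gaussian time courses $g_k$ (peak latency, width in ms), Gaussian
scalp topographies $w_k$ over a 32-channel 10–20 montage, a subject gain
factor $1 + u_s$, $u_s \sim N(0, 0.2)$, and additive white (default) or
AR(1) noise. Deliberate choices:

* **MMN latency 210 ms, width 18 ms, topography peaking exactly at Fz.**
  At 250 Hz the time grid is anchored at 0 (so t = 0 is always a sample);
  210 ms falls between the 208 and 212 ms samples, so a peak search
  recovers the latency to within one sample by construction, never
  exactly.
* **Gains in µV per nat.** The MMN term scales with the trial's surprise,
  so its microvolt size depends on the observer's surprise scale, which
  with λ = 1 decays over the run. The defaults (other = 600, solo =
  virtual = 300) were calibrated once against the mean deviant surprise of
  a default 1152-event run (≈ 0.005 nats) to give differential-wave peaks
  near −2.8 µV for physical co-presence and −1.4 µV otherwise — the
  empirical MMN range. Early trials have much larger surprise and hence
  unrealistically large single-trial mismatch responses; this is a known,
  documented consequence of the no-forgetting observer, not of the EEG
  model.
* **`mmn_scope`.** By default the mismatch term is added on deviant trials
  only, which is the differential-wave logic. `mmn_scope = "all"` scales
  every trial by its surprise, giving standards signal too — the
  generative assumption under which the trial-by-trial correlation analysis
  has signal across the whole sequence.
* **Noise 2.5 µV per sample.** Chosen as a post-cleaning single-trial
  residual noise level that leaves the group-average peak latency stable
  to about one sample at the study sizes used below.
* **Behaviour.** Block scores are Binomial(16, p) draws with a shared
  subject effect (SD 0.8, logit scale) and a subject-by-condition effect
  (SD 0.6). The shared effect cancels in paired contrasts; the
  condition-specific effect is what limits paired power. These SDs were
  set to reproduce between-subject spreads of roughly 9–10 points out of
  48 per condition, which is what makes a ~3-point video-call-vs-alone
  difference non-significant at n = 18 while a ~4.5-point physical-presence
  difference is usually detected. Because the random effects act on the
  logit scale, the *marginal* condition mean differs from the configured
  proportion by $\mathcal{O}(\sigma^2)$; the configured values are the
  latent (median-subject) proportions.

What the generator does **not** emulate: volume conduction and realistic
forward models, ocular/muscle artifacts, non-stationary noise, latency
jitter across trials and subjects, and any dependence of the behavioural
scores on the EEG. Passing tests therefore demonstrate that the analysis
machinery is correct and calibrated under its own assumptions — not that
those assumptions hold for any particular recording.

## ERP computation

`condition_average()` is a plain pointwise mean over a trial selection
(logical, indices, or a predicate over the trial metadata), with optional
baseline correction subtracting each channel's pre-onset mean. The MMN
differential (`mmn_differential()`) averages all deviants that have a
preceding train in the same run and subtracts the average of the matching
*last standards only* — the event immediately before each such deviant;
corrupting any other standard provably cannot change the result. Because
subtraction is linear, baseline-correcting before or after differencing is
equivalent; the default is off. `negative_peak()` returns the windowed
minimum (default search window 100–300 ms) with ties broken to the
earliest sample, and flags flat windows as degenerate instead of silently
reporting their first sample.

## Cluster-based permutation statistics

Point-by-point maps are Pearson correlations across trials
(`trialwise_correlation()`) or group t statistics (`group_t_map()`:
one-sample against 0, df = n − 1, or paired via within-subject
differences). Points with zero variance are recorded as `NA` — never as
zero — and are excluded from cluster formation.

`cluster_permutation_test()` then:

1. thresholds the group t map two-tailed at `cluster_forming_p` (default
   0.05 — the field's customary cluster-forming threshold; it is a tuning
   parameter, exposed in `cluster_config()`);
2. groups suprathreshold points of equal sign into clusters connected by
   temporal contiguity within a channel and spatial adjacency across
   channels at the same sample (adjacency = montage distance below
   1.3 × the median nearest-neighbour distance by default);
3. discards clusters spanning fewer than `min_adjacent_channels = 2`
   distinct channels, however massive;
4. scores each surviving cluster by its summed t and compares it against
   the permutation distribution of the **maximum** |cluster sum| (95th
   percentile by default) — max-statistic family-wise control. An
   alternative `statistic = "mean"` mode (mean |cluster sum| per
   permutation) is provided because "percentile of the cluster-sum
   distribution" can be read either way in the literature; max is the
   default, standard reading.

Permutations flip the sign of whole subject maps (one-sample) or swap the
two condition labels within subject (paired), which is the exact
exchangeability scheme under a symmetric null. When $2^n$ does not exceed
`n_permutations` the test switches to exhaustive enumeration (with a
message) and p values are exact; otherwise p = (1 + #{null ≥ observed}) /
(1 + n_permutations). Correlation maps enter the group test as raw r by
default; Fisher-z is available and, being monotone and odd, cannot flip
any pointwise t sign.

The connected-component labelling runs in compiled code (`src/`), which
keeps a 500-dataset × 500-permutation null calibration sweep at a few
minutes on one core.

## Validation sizes

The shipped tests and the acceptance script exercise the pipeline at
deliberately desk-scale sizes: latency recovery uses 8 subjects × 384
trials at 250 Hz; the family-wise error sweep uses 12 subjects, 16
channels, 128 samples, 48-event sequences, 500 datasets × 500
permutations; the qualitative contrast pattern uses 6 subjects × 192
events over 15 seeded replicates. These sizes were chosen to estimate each
quantity to its needed precision (one sample of latency; a two-standard-
error margin on a 5% rate) while keeping a full check suite in the
minutes range; the statistical machinery itself is size-agnostic.

## Known limitations

* The observer models *stimulus identity* probabilities; transition or
  alternation observers would need a new observer, though the pluggable
  config keeps downstream stages unchanged.
* With λ = 1, surprise (and hence the simulated mismatch amplitude) decays
  over a run; consecutive-run designs restart it. Fitting λ to data is
  out of scope by design.
* The cluster test assumes subject exchangeability under the null
  (symmetric errors for sign flips); heavy asymmetry would distort its
  level.
* Only the package's own epoch container and delimited tables are read and
  written; binary acquisition formats (EDF, BrainVision) are not parsed —
  convert externally and import via the container.
* p values from random (non-exhaustive) permutations are themselves Monte
  Carlo estimates with resolution 1/(n_permutations + 1).

## A worked mini-study

```{r}
library(rovingmmn)

cfg <- run_config(
  sequence = sequence_config(n_events_per_run = 192, n_runs = 1),
  simulation = simulation_config(n_subjects = 6,
                                 montage = default_montage()[1:16, ],
                                 epoch_window = c(-0.15, 0.362)),
  cluster = cluster_config(n_permutations = 300),
  seed = 2)
res <- run_study(cfg, out_dir = "study_out")
res$summary$contrasts      # cluster windows and p values per contrast
res$behavior               # paired t, dz, FDR flags
```
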