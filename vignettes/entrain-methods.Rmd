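---
title: "Methods: event-train analysis for Pavlovian conditioning recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-train analysis for Pavlovian conditioning recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrain)
```

## Scope and data model

`entrain` analyzes multi-region neural recordings collected while an animal
learns to associate two 10 s conditioned stimuli (a reward-paired R-CS and a
fear-paired F-CS) with their outcomes (water reward, foot shock). The atom of
every analysis is the *event train*: a neuron's spike or calcium-event
timestamps together with its region (`aIC`, `pIC`, `CE_SST`, `CE_PKCd`,
`CEm`), learning stage (`habituation`, `C_early`, `C_late`, `FC`, `recall`)
and treatment label. Event trains are down-sampled to 1 s bins for decoding
and information-flow analyses and to 500 ms bins for trial-aligned PETHs;
both resolutions are first-class (`bin_events()`), with half-open
`[start, end)` bins and 0-based seconds from session start.

Five analysis families sit on top of this representation:

* **PETHs** (`make_peth()`): per-trial `[-8, 18]` s windows around CS onset,
  z-scored per neuron per stage, Gaussian-smoothed, with shock-artifact
  masking and blackout-channel replacement.
* **Behavior** (`score_freezing()`, `classify_episodes()`,
  `classify_cs_trials()`): freezing onsets from a motion-index trace and
  correct/incorrect assignment of episodes and CS trials.
* **Calcium events** (`lowpass()`, `detect_events()`): 0.5 Hz zero-phase
  low-pass filtering of dF/F and MAD-threshold event detection.
* **Decoding** (`decode_single_region()`, `cross_stimulus_transfer()`,
  `discriminate_cs()`, `decode_multi_region()`, `rank_best_neurons()`,
  `contrast_importance()`): the four population-decoding modes with
  shuffled-label controls and random-forest feature importances.
* **Directed information flow** (`discrete_te()`, `pairwise_peak_te()`,
  `region_te()`, `surrogate_test()`, `build_te_network()`): region-level
  transfer-entropy networks with surrogate significance.
* **Spike-field coupling** (`spike_triggered_average()`,
  `spike_field_coherence()`, `compare_sfc()`): STA of a distant LFP around
  local spikes and power-normalized coherence, compared between the 10 s
  pre-CS baseline and the CS.

Because the recordings themselves are not redistributable, the package ships
a synthetic-session generator (`synth_config()`, `generate_session()`) whose
planted structure gives every stage a ground-truth test surface.

## The synthetic-session generator

The generator emulates one recording session of the conditioning task:

* **Populations.** Default neuron counts per region are the per-session
  counts of the study design it emulates: 113 (aIC), 98 (pIC), 48 (CE_SST),
  54 (CE_PKCd), 29 (CEm).
* **Timeline.** `n_trials_per_cs` trials per CS type in blocks of two
  (R, R, F, F, ...), each CS 10 s, onsets at whole seconds with at least
  `min_iti` seconds between trials and a 10 s lead-in. USs follow the
  reinforced CS type of the stage at CS offset (R in `C_early`/`C_late`,
  F in `FC`, none in `habituation`/`recall`).
* **Events.** Per neuron and per 1 s bin, an event is drawn as a Bernoulli
  state at `baseline_rate x bin width`, multiplied during CS and US windows
  by the configured stage-dependent amplitude. The source study reports only
  z-scored responses, so absolute CS/US amplitudes are free parameters; the
  defaults (2x during CS in trained stages, 3x during the US bin) are a
  plausible mid-range modulation chosen once and kept fixed. Event times
  receive uniform sub-bin jitter so 500 ms binning remains meaningful.
* **Coupling.** Each coupling entry `(source, target, excess_prob, lag)`
  OR-gates extra target events: `Y[t+lag] = Base[t+lag] OR
  (X[t] AND Bernoulli(excess_prob))`, with target neurons paired to source
  neurons cyclically. Coupling acts on event *probability*, keeping states
  binary for the transfer-entropy tests. The count-based estimator
  `estimate_excess_prob()` inverts the OR gate,
  `(P(Y|X=1) - P(Y|X=0)) / (1 - P(Y|X=0))`, and converges to
  `excess_prob`.
* **LFP.** 1/f-amplitude background noise plus configured sinusoidal
  components. When a region's component has `kappa > 0`, that region's
  events are placed within their 1 s bin at a von Mises draw around the
  oscillation peak phase instead of uniformly. Placement (rather than
  thinning) preserves bin counts exactly, so rate fidelity and phase
  locking are decoupled.
* **Behavior.** Each trial receives a matching episode (port visit for R,
  freezing onset for F) inside its CS window with probability
  `behavior_correct_prob`, otherwise an episode is placed in an
  inter-trial interval at least 5 s from any CS. The motion-index trace is
  high-motion baseline with near-zero segments during freezing episodes.

Everything is reproducible from the config seed; identical configs yield
identical sessions.

What the generator does *not* emulate: bursting and refractory structure,
non-stationary baseline drift, correlated noise across neurons beyond the
planted coupling, behavior-locked rate changes other than CS/US windows,
electrode artifacts, or miniscope image data. Tests that pass on this
surface therefore demonstrate correctness of the estimators under their
stated assumptions, not robustness to every pathology of real recordings.

## PETH construction

PETHs are built from 500 ms binned matrices. Each neuron is z-scored
against its session-wide (per-stage) mean and SD; zero-variance neurons map
to all-zero rows rather than NaN, so silent units never poison downstream
averages. The "smoothing degree" is interpreted as the SD (in bins) of a
Gaussian kernel truncated at 4 SD — 5 for IC and 8 for CE units by default,
configurable. Smoothing is NA-aware: shock-masked bins stay NA, never leak
into neighbors, and the kernel renormalizes over available samples. Trials
whose window would start before the session are skipped with a warning.
Bins from blacked-out channels are replaced by the population average of
the same (trial, bin) before smoothing.

Label construction (`build_labels()`) defines the decoding tasks: for the
CS task, class 0 is a pre-CS window and class 1 the ten CS bins; for the US
task, class 1 is a post-US window; the three-class task keeps both CS types
separate. The pre-CS window defaults to 10 bins, mirroring the 10 s CS;
the post-US window defaults to 8 bins so an aligned trial ends at +18 s
(US at +10 s, 1 s US duration). Pre-windows overlapping an earlier trial's
stimulus window are truncated, and no bin ever carries two classes.

## Behavior scoring

A freezing episode is a maximal run of frames whose 1 s sliding-window mean
motion stays below threshold, lasting at least 1 s. The window starting at
frame `i` covers `i .. i + w - 1`; a run of `L` below-threshold window
starts is `(L - 1)/fs + 1` seconds immobile. The motion threshold is a free
parameter because its scale is tracker-specific. Correctness is
onset-based: an episode is correct exactly when its onset lies in
`[CS onset, CS onset + 10 s)` of its matching CS type; a CS trial is
correct when it contains at least one correct matching episode. These rules
are checked against brute-force frame-by-frame and interval-membership
oracles in the test suite.

## Calcium event detection

dF/F traces are low-pass filtered at 0.5 Hz with a 4th-order zero-phase
Butterworth design (the source pipeline names no filter family; the order
is configurable). The trace is demeaned before `filtfilt` and the mean
restored, so DC passes with unit gain despite zero initial conditions.
Detection thresholds at `median + 3 x MAD` of the filtered trace, with MAD
scaled by 1.4826 for Gaussian consistency. After a detection, no new event
is accepted until the trace has returned below threshold and `tau_off =
0.2 s` has elapsed — the vendor algorithm behind the original recordings is
unpublished, so the refractory reading of `tau_off` is documented as an
approximation. A constant trace (MAD = 0) yields zero events with a
warning rather than an error.

## Decoding protocols

All four modes share one protocol: z-score features, balance classes by
random under-sampling, stratified 5-fold cross-validation, repeat the whole
procedure (default 40 times), and report the mean held-out accuracy Da.
Under-sampling happens once per iteration *before* the fold split,
following the stated order of the original protocol; z-scoring parameters,
by contrast, are always estimated on the training folds only and applied
unchanged to the held-out fold, which the suite verifies with a
label-leak test. Shuffled-label controls rerun the identical pipeline on
permuted class vectors and must land at chance (0.5 binary, 1/3
three-class).

The original analysis used a multi-layer-perceptron classifier without
specifying its architecture. The package default is a single hidden layer
of 16 logistic units (`nnet`), weight decay 0.1, at most 150 optimizer
iterations — small enough to be stable on a few hundred balanced bins and
fast enough for 40x5 fits; all knobs are exposed. Multi-region decoding
uses a 100-tree random forest (`ranger`) with impurity importances
normalized to sum to 1 over the drawn neurons, and draws its neurons with
per-region counts proportional to the pool composition using
largest-remainder rounding, so exactly `n_total` neurons are taken.

Cross-stimulus transfer fits on one stimulus and evaluates on another;
balancing and scaling are fit on the training set only, and the test set
is under-sampled so chance stays at 1/classes. Conditional CS accuracy in
the three-class task is the fraction of truly-CS bins predicted as the
*correct* CS among truly-CS bins predicted as *either* CS; it is flagged
undefined when no CS bin is predicted as CS. Importance contrasts between
two profiles use a two-sided permutation test over the pooled
per-iteration values (10^4 permutations by default) — the original figures
mark significance without naming a test, so the permutation choice is the
package's own.

## Transfer-entropy networks

`discrete_te()` is a plug-in estimator over empirical joint frequencies,

TE(X→Y) = Σ p(y_{t+1}, y_t^{(k)}, x_t^{(k)}) log2 [ p(y_{t+1} | y_t^{(k)}, x_t^{(k)}) / p(y_{t+1} | y_t^{(k)}) ],

in bits, for arbitrary finite alphabets and history length k. It is exactly
zero when the target's next state is determined by (or independent given)
its own history, nonnegative, and invariant to state relabeling; the suite
pins it against an exhaustive joint-histogram oracle to 1e-10.

Bin counts are clipped to binary states by default (`count >= 1 -> 1`),
matching a discrete-state estimator on sparse 1 s bins; a four-letter
count alphabet (clip at 3) is available. Pairwise TE is computed for every
ordered neuron pair (self-pairs excluded) and every history length in
`k_range`, keeping the per-pair maximum; the default scan is `k = 1` — a
1 s history at 1 s bins. For binary states at k = 1 an algebraically
identical all-pairs path assembles the eight joint counts from four matrix
cross-products, which is what makes surrogate testing affordable.

Region-level TE sorts the pair peaks descending and averages the upper 50%
(ceil(n/2) after a stable sort; 101 pairs keep 51). Significance comes
from surrogates: each neuron's time bins are independently permuted
(destroying all temporal structure, preserving marginal rates; circular
shifts are available as an option), the full pipeline is recomputed per
surrogate, and p is the plain proportion of surrogates at or above the
real value — so p = 0 is possible, and a conservative
`(count + 1)/(n + 1)` companion is stored for downstream use that needs p
bounded away from zero.

`build_te_network()` assembles the region graph: select and concatenate
the analysis bins (CS windows, post-US windows, or onset-bin +/- 2 bins
around behavioral episodes), draw neurons proportionally across regions
(default 500, or all when fewer), compute every ordered region-pair TE
with surrogate p, attach node importances from a matching importance
profile, and expose full and significant-edge (p < 0.05) views.

## Spike-triggered averages and spike-field coherence

The STA averages 200 ms LFP snippets centered on spikes; spikes whose
window crosses the record edge or a condition boundary (preCS = the 10 s
before CS onset, CS = the 10 s stimulus) are excluded. SFC divides the
STA's power spectrum by the mean of the individual snippet power spectra,
frequency by frequency: identical snippets give 1, unlocked spikes give
roughly 1/n_spikes. The phrase behind this normalization admits several
readings; the snippet-power-normalized convention is adopted because it
bounds the result to [0, 1] and behaves as a coherence, and the raw STA
spectrum is kept as a secondary output. Each snippet is Hann-tapered and
zero-padded (default to the next power of two at or above four times the
snippet length, i.e. about 1 Hz resolution at 1 kHz sampling) so that a
33 Hz peak can be localized within +/-2 Hz despite the 200 ms window.
Frequencies whose denominator power is numerically zero (below 1e-12 of
the peak) are flagged NaN rather than reported as unstable ratios.

## Numerical and design choices worth knowing

* Bin edges are half-open everywhere; an event on a boundary belongs to
  the later bin. Summing adjacent 500 ms bins reproduces 1 s binning
  exactly.
* All times are seconds from session start; CS onsets are generated at
  whole seconds so stimulus windows align with analysis bins.
* Ties in best-neuron ranking break by neuron id; ties at the TE top-50%
  cutoff resolve by stable sort (value descending, pair order ascending).
* Every stochastic stage derives its seed from one master seed via
  `derive_seed(master, counter)`, so stages rerun in isolation reproduce
  the full-pipeline result, and `run_pipeline()` manifests are
  byte-identical across runs.
* Problem sizes in the test suite are deliberately modest — e.g. 600-bin
  two-region sessions with 20 neurons per region and 200 surrogates for
  directed-edge recovery, 200 null sessions for calibration, 240-bin
  decoding sets — chosen so the full suite demonstrates each property in
  minutes while keeping comfortable statistical margins.

## Known limitations

* The plug-in TE estimator is biased upward on short series; the surrogate
  test absorbs this bias under the null, but absolute TE values should be
  compared only between conditions with matched bin counts.
* The MLP default is a deliberately small network; for large neuron counts
  or subtle coding, widen the hidden layer and increase `maxit`.
* The refractory reading of `tau_off` and the bounded-noise onset
  convention make event *times* exact only for well-separated transients;
  heavily overlapping transients merge.
* Freezing scoring assumes a uniformly sampled motion index; dropped
  frames must be interpolated upstream.
* The generator's behavior model places at most one episode per trial;
  burst-like repeated port visits are not emulated.
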