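---
title: "Spatiotemporal decomposition and kinematic substates of facial action unit dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal decomposition and kinematic substates of facial action unit dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fexdyn)
```

## The problem

Dynamic facial expressions unfold as coordinated patterns of facial action
units (AUs) — the elementary movements of the Facial Action Coding System,
estimated per video frame by trackers such as OpenFace on a 0–5 intensity
scale. `fexdyn` implements a complete analysis chain for asking three
questions of such recordings:

1. **What moves together?** A non-negative matrix factorization (NMF) of
   the stacked AU timeseries finds a small number of spatiotemporal
   components: AU co-activation profiles (spatial weights `S`) with their
   time courses (temporal weights `T`), `M ≈ T S`.
2. **Is the dynamics diagnostic?** Interpretable timeseries features of
   the per-trial component trajectories, summarised by a train-set PCA,
   feed a random-forest classifier of emotion category, evaluated on a
   held-out set with exact binomial, permutation, and pairwise Fisher
   significance machinery.
3. **What phases does a single expression pass through?** Component
   kinematics (speed, displacement) are segmented by dynamic-time-warping
   (DTW) clustering into substates — relaxed, sustain, transition — which
   are summarised by within-substate speed and by the normalised entropy
   of substate transitions, and characterised with linear mixed-effects
   models.

Because the original video corpus is not bundled, the package ships a
synthetic AU-trial generator with planted ground truth; every recovery
claim in the test suite is made against that ground truth.

## The synthetic generator

`make_ground_truth()` constructs the generative structure the analysis
assumes:

* **Spatial loadings** `S_true` (components × AUs): contiguous disjoint AU
  blocks with within-block loadings ~ U(0.8, 1.2) and cross-loadings
  ~ U(0, 0.05). Block structure mirrors the upper-face / lower-face
  organisation typical of expression components and makes the planted
  components identifiable.
* **Temporal bases** (unit peak, one per component): one inverted-U
  Gaussian bump (centre 0.55, sd 0.22 in warped phase), one shifted bump
  (0.45, sd 0.20), and bimodal Gaussian mixtures (peaks at 0.45 and 0.68,
  sd 0.08) for any further components. The widths are chosen so that the
  rising and falling flanks span the transition phases of the substate
  schedule, the unimodal tops sit inside the sustain phase, and the
  bimodal dip is crossed *during* sustain — i.e. each scheduled substate
  genuinely carries its intended speed signature. This matters: with
  narrow bases, bins labelled "transition" would sit on flat Gaussian
  tails and the planted labels would not correspond to actual movement.
* **Substate schedule**: relaxed (20% of bins, speed scale 0.2) →
  transition (20%, 2.5) → sustain (35%, 0.7) → transition (15%, 2.5) →
  relaxed (10%, 0.2). The schedule is realised by piecewise time-rescaling
  — bases are evaluated on a warped phase whose slope is proportional to
  the segment speed scale — rather than by additive bursts, which keeps
  the low-rank structure exactly recoverable.
* **Mixing gains** per (emotion, condition): each emotion emphasises one
  component strongly (gain 2.0) and one moderately (1.1) against a 0.3
  background, with emotive speech scaled by 1.1. `mixing_scale` widens or
  narrows the emphasis gap; emotion separability is monotone in it.
* **Noise**: additive Gaussian frame noise (default sd 0.05 on the 0–5 AU
  scale, truncated at zero), representing AU-estimation jitter after
  tracking. Subjects get log-normal multiplicative gain perturbations
  (sd 0.15) in `make_dataset()`.

Defaults (240 frames, 100 bins, 18 AUs, three components) match the
dimensions of the motivating production study. What the generator does
*not* emulate: head-pose artefacts, tracking dropouts in bursts,
asymmetric AU onsets, or inter-AU correlations beyond the component
structure — so green recovery tests demonstrate correctness of the
machinery, not performance guarantees on arbitrary real recordings.

## Preprocessing

Trials with mean tracking confidence not strictly above 0.90 are dropped
("over 90%" read literally). A centred moving average (window 3 frames,
truncated at the edges so no padding values are invented) removes tracking
jitter; the choice of a *centred* window avoids the phase lag a causal
filter would add to peak-time features. Each trial is then reduced to 100
time bins by partitioning frames into contiguous, maximally equal groups
(sizes differ by at most one) and averaging — binning preserves channel
means exactly when the frame count is a multiple of the bin count, and
trials shorter than 100 frames are first linearly interpolated up.
`success = 0` frames are linearly interpolated from neighbours rather than
dropped, keeping the time grid regular.

## Decomposition and rank selection

`nmf_fit()` uses the classical Lee–Seung multiplicative updates for the
Frobenius objective from seeded uniform initialisation scaled by the
matrix mean. The updates provably never increase the objective and never
produce negative entries; both properties are asserted in the tests. One
numerical note: multiplicative updates have a slow sublinear tail, so on
exactly low-rank data the relative RSS reaches `1e-6` readily while the
*pointwise* maximum error plateaus near `1e-3` of the data range —
tolerances in the tests reflect this.

The rank is chosen over k = 2..6 by three criteria computed per rank:

* **Cophenetic coefficient** and **consensus silhouette** over restarts:
  each AU channel is assigned to its dominant component (argmax of its
  `S` column); the A×A consensus matrix of co-assignment frequencies is
  clustered (average linkage), and stability is read from the correlation
  between consensus distances and dendrogram cophenetic distances, plus
  the mean silhouette of the k-way cut. Consensus is computed over AU
  channels rather than over the thousands of (trial, bin) rows because
  the object of interest is "groups of AUs with common time courses" and
  the A×A problem is tractable at any data size.
* **Excess explained variance over a block-shuffled null**: within each
  trial and channel, bin blocks (default 10 bins, 10% of the trial) are
  permuted, destroying the coherent spatiotemporal pattern while keeping
  short-range ordering and the exact value multiset. Fitting the same
  ranks to shuffled copies gives a null explained-variance curve; the
  difference is the signal attributable to temporal structure.

The chosen k maximises the mean rank across the three criteria, with ties
broken toward the smaller k. On planted rank-3 data at the default noise
level this recovers k = 3 in ≥ 90% of seeds (20-seed suite); the
acceptance test runs datasets of 24 trials with 8 consensus restarts and
4 null shuffles per rank, sizes chosen to keep a 20-seed suite inside a
few minutes while leaving the selection statistics stable.

Held-out trials are never part of the fit: their temporal weights come
from `nmf_project()`, a per-row non-negative least squares (NNLS) with
`S` frozen — deterministic and optimal per row, unlike running
multiplicative updates with a frozen factor.

## Timeseries features and PCA

`extract_features()` computes a fixed, versioned catalog of 38 features
per component trajectory — location/spread (mean, sd, quantiles, IQR,
range), shape (trapezoid AUC, normalised argmax/argmin, OLS slope, mean
and max absolute second difference), dynamics (mean absolute change, CID
complexity, time-reversal asymmetry, longest monotonic run, zero
crossings of the detrended series, peak count at 0.5·sd prominence),
memory (ACF at lags 1 and 5, first ACF zero crossing), information
(sample entropy m = 2, r = 0.2·sd; permutation entropy order 3), spectral
(centroid, entropy, low-band power below 0.1 cycles/bin), and energy
(RMS, crest factor, half-series energy fractions, Hjorth mobility and
complexity). Thirty-eight per component makes 114 features for a
three-component model. Features undefined on a given series (entropy of a
constant, an ACF that never crosses zero) are imputed with 0 and flagged,
keeping the table dense.

PCA is fitted on training rows only: z-scoring uses training means and
SDs (constant columns are centred and excluded from scaling), loadings
come from the SVD of the standardised table, the retained dimensionality
equals the NMF rank, and each loading's sign is fixed by making its
largest-magnitude entry positive so results are reproducible across
platforms. Applying the PCA to test data reuses the training scaler and
loadings verbatim; the tests assert that mutating test data cannot change
the fit.

## Classification and significance

The stratified 80/20 split uses round-half-up per class, which reproduces
the 61-train / 15-test per-class arithmetic at 76 trials per class. The
random forest is tuned by stratified 5-fold cross-validation over a small
grid (mtry ∈ {1, √p, p} × nodesize ∈ {1, 5, 10} × trees ∈ {250, 500})
maximising balanced accuracy, then refitted at the best setting.

Significance of held-out accuracy is assessed three ways: an exact
upper-tail binomial test against the no-information rate (the majority
class share — 33% on balanced three-class data); a label-permutation test
(default N = 1000) with the add-one estimator so p can never be zero; and
two-sided Fisher exact tests on each 2×2 sub-table of the confusion
matrix restricted to a class pair, Bonferroni-corrected across the three
pairs. Restricting to the pair's sub-table (ignoring third-class
predictions) is the sharpest reading of "pairwise differentiation"; the
enumeration oracle in the tests verifies the Fisher p-values to 1e-10.
One-vs-rest AUC uses the forest's vote fractions as scores.

`grouped_cross_validate()` provides leave-one-stimulus-out and
leave-one-participant-out schemes as plain leave-one-group-out evaluation
with a majority-class baseline.

## Substates

Speed is the bin-wise first difference of a component trajectory divided
by the bin interval; displacement is the trajectory relative to its first
bin. Trials are cut into overlapping windows (10 bins, stride 5) of 2k
channels — absolute speed and displacement per component — and the pooled
windows are clustered by PAM under DTW distance (symmetric step pattern,
Euclidean local cost, no global window). Each bin takes the majority
cluster of the windows covering it, ties resolved toward the earlier
window, and clusters are renamed by ascending mean absolute speed:
relaxed < sustain < transition.

Two scaling decisions matter here. Windows are *not* z-normalised
per window — absolute speed is exactly what distinguishes the substates,
and per-window normalisation would erase it. But the speed and
displacement channel families are each divided by one *dataset-wide*
pooled SD so both families contribute comparably to the DTW cost; without
this the displacement magnitudes (order 1 on the weight scale) numerically
swamp the speeds (order 0.05 per bin) and the clusters collapse into
displacement bands. A single global constant per channel preserves all
between-window and between-trial amplitude differences.

The number of substates is chosen by the mean DTW silhouette over
c = 2..4. Two recovery fixtures back this up. Segmentations of trials
generated from the ground-truth schedule (rest → onset → hold → offset →
rest) reach an adjusted Rand index ≥ 0.6 against the planted labels, with
the residual disagreement concentrated in the ±2–3 bins around segment
boundaries that overlapping windows necessarily blur. For the regime
*count*, the fixture plants exactly one segment per regime (flat relaxed,
raised-cosine transition rise, gentle apex-oscillation sustain), and
c-selection then returns 3 decisively. The distinction is deliberate: in
a full expressive arc the onset and offset transitions — identical in
speed but mirror-imaged in displacement — are genuinely distinct window
shapes under the (speed, displacement) metric, so on such data a 4-way
partition is a defensible clustering and the silhouettes of c = 3 and
c = 4 sit within ~0.01 of each other. A regime-count claim is only
testable on data where the planted count is unambiguous.

A known limitation, deliberately documented rather than patched: when
emotion mixing gains are nearly homogeneous across trials, the NMF factor
pair is identified only up to a rotation within the non-negative cone, so
*fitted* temporal trajectories can be mixtures of the planted bases and
their kinematic regimes blur accordingly. The substate recovery suite
therefore tests the segmentation machinery on planted trajectories; the
full pipeline still applies it to fitted trajectories, as the method
prescribes.

**Transition entropy.** A trial's substate sequence is collapsed to its
run labels; the ordered state-change pairs (s → s′, s ≠ s′) are counted;
and the Shannon entropy of that distribution (bits) is divided by the
maximum theoretical entropy for a three-substate system,
`log2(3·2) = log2 6`. Self-transitions are excluded (this is state-*change*
entropy), the normalisation always uses S = 3 regardless of which
substates a sparse trial visits, and a sequence with no changes scores 0.
Duplicating consecutive labels never alters the value — asserted as a
property test. With this definition a sequence cycling uniformly through
all six ordered transitions scores exactly 1.

## Mixed-effects characterisation

Per-trial substate speeds (and per-trial entropies) are modelled as

```
value ~ emotion * condition * substate + (1 + condition | subject)
```

fitted by REML under sum-to-zero contrasts, with Satterthwaite degrees of
freedom and Type III F tests, and Bonferroni-corrected pairwise contrasts
(simple effects within interaction slices via `emmeans`). Singular or
non-converging fits fall down a fixed ladder — random condition slope →
random intercept → fixed effects only — with a warning at each step.
Entropy is transformed with `log1p` before fitting: a pure `log` is
undefined at the zero entropies that single-substate trials legitimately
produce, and `log1p` agrees with `log` to first order on small values
while remaining defined at 0. Marginal and conditional R² follow the
Nakagawa variance partition, with random-slope contributions evaluated as
the mean per-observation variance `zᵢ' Σ zᵢ`; the implementation is
checked against a direct variance-partition computation in the tests.

Simulation-based acceptance (fixed effects within 2 SE of planted truth
in ≥ 90% of replicates; type-I error for a null emotion effect near
nominal) stands in for coefficient-level replication, which would require
the original recordings.

## Orchestration and reproducibility

`run_pipeline()` executes simulate/ingest → preprocess → split →
decompose (train) → project (test) → features → PCA → classify →
substates → mixed models, writing every intermediate artifact as TSV plus
a JSON manifest and report. The split precedes all fitting, and every
later stage fits on training trials only. Each stage's seed derives from
the single master seed via a stage-name hash, so reruns are bit-identical
and inserting a stage never perturbs the others' streams. The substate
stage caps the trials entering DTW clustering (default 24) because the
pooled-window distance matrix grows quadratically; the cap is a
configuration key.

Problem sizes used by the default test and acceptance runs — 24-trial
datasets for rank selection, 60-trial datasets for classification, twelve
trials for substate clustering, 10–15 subjects for the mixed-model
simulations — were chosen as the smallest designs at which the planted
structure is comfortably identifiable, and are stated in the relevant
tests.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  output_dir = "fexdyn_demo",
  synthetic = list(n_subjects = 6, trials_per_cell = 2),
  seed = 1)
res <- run_pipeline(cfg)
res$selection$chosen_k     # planted rank recovered from the training data
res$report                 # held-out confusion matrix and significance
res$substates$cluster_speed  # relaxed < sustain < transition
```
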