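---
title: "Connectivity dynamics as classification features: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity dynamics as classification features: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

## The problem

Resting-state fMRI connectome classification asks whether the pattern of
temporal coupling between brain regions separates a clinical group (here
autism spectrum disorder, ASD) from typically developing controls (TD).
The input per subject is an L × A matrix of region-mean BOLD values: L
volumes (one per repetition time, TR, typically 1.5–2 s) and A atlas
regions (116 for AAL, 97 for TT).  `dynconn` implements the full journey
from those matrices to a cross-validated diagnostic score and to an
analysis of *which pipeline choices matter*, and pairs it with a
synthetic generator so that every stage has a ground truth to be tested
against.

## Feature representations

**Static FC.**  The full-series sample Pearson correlation for each of
the A(A−1)/2 region pairs.  Correlations are used raw (no Fisher
z-transform): downstream consumers are rank-based or margin-based
classifiers, not parametric tests on the correlations themselves.  A
zero-variance region yields a degenerate correlation, reported as 0 and
flagged — a flat signal is maximally unconnected.

**Dynamic dFC.**  Each pair's coupling is tracked through a sliding
window of width w = 21 TR, stepped by s = 1 TR, with a Gaussian taper
g(t) = exp(−(t−c)² / 2σ²), σ = 3 TR, centred on the window.  The M =
⌊(L−w)/s⌋ + 1 windowed correlations are reduced to the fraction `nst` of
windows with ρ ≥ 0.8 (strong coupling) and the fraction `nwk` with
ρ ≤ 0.25 (weak or no coupling).  These two numbers per pair are the
dynamic feature set: they measure how much of the scan a pair spends
strongly coupled or uncoupled, regardless of when.

Three conventions needed fixing where the mathematics is genuinely
ambiguous, and each is exposed as an option:

* *Window count.*  M counts every fully contained window position,
  M = ⌊(L−w)/s⌋ + 1.  A floor-only reading discards at most one window —
  negligible at M ≈ 150+ — but the inclusive convention wastes no data
  and makes M = 1 for L = w, the natural boundary case.
* *Tapering semantics.*  Segments are mean-centred within the window
  *before* tapering (then the Pearson formula re-centres the tapered
  segments as usual).  Tapering an uncentred segment mixes the window
  mean into the envelope and distorts correlations of signals with
  non-zero local baseline; centring first gives the standard tapered
  correlation estimator.  `center = FALSE` provides the literal
  taper-only variant.
* *Weak criterion sign.*  `nwk` applies ρ ≤ 0.25 to the *signed*
  correlation, so strong anti-correlation counts as "weak/no coupling"
  in the over/under-connectivity sense of the construction.
  `threshold_spec(abs_weak = TRUE)` switches to |ρ| ≤ 0.25 for users who
  read "weak" as small magnitude.

The windowed engine is vectorised (one index-matrix build per pair); its
agreement with a naive slice–centre–taper–correlate loop to 10⁻¹⁰ is a
standing test.

## The synthetic cohort generator

Each targeted region pair alternates between a *connected* state —
bivariate Gaussian draws at correlation ρ\* (`base_corr`, or a per-pair /
per-group override) — and a *disconnected* state of independent draws;
all marginals are unit-variance throughout, and non-targeted regions are
independent noise.  Planting a pair at connected fraction f gives known
ground truth for everything downstream: the full-series correlation
approaches f·ρ\*, and the expected `nst` approaches f.

State sequences are deterministic block cycles by default: time is tiled
with periods of 200 TR containing exactly round(f·200) connected TRs,
with a random phase per subject and pair.  The realised connected
fraction is then *exact* over every full cycle.  The obvious
alternative — geometric dwell times with mean 30 TR — was evaluated and
rejected as the default: at realistic scan lengths (L ≈ 1000–2000) the
realised fraction of a geometric alternation fluctuates by ±0.05–0.13
per subject, and short dwells bias `nst` downward by up to ~0.09 because
windows straddling a state boundary dilute below the strong threshold.
With 200-TR blocks the residual `nst` bias is only the boundary blur:
each connected run loses ≈ 2–3 TR per edge (the taper's effective
half-width) plus ~2 % of deep-connected windows lost to sampling noise of
the tapered correlation (effective sample size ≈ 10.6 of a σ = 3,
w = 21 taper), a total error ≤ 0.04 across f = 0.1–0.9.  Geometric
segments remain available (`segment_mode = "geometric"`) for users who
want irregular dynamics.

Group differences are planted via `group_effect`: affected pairs take
group-specific connected fractions and, optionally, group-specific
connected-state correlations.  Setting f·ρ\* equal across groups (e.g.
0.95 × 0.5 vs 0.5 × 0.95) plants a *purely dynamic* difference — equal
static FC in expectation, opposite window-fraction signatures — which is
the cleanest possible demonstration that the dynamic representation sees
structure the static one cannot.

Demographics are cosmetic (age ~ N(17, 8) truncated at 6 years, ~84 %
male, FIQ ~ N(108, 15), one synthetic site): they make phenotype I/O
realistic but carry no signal.  What the generator does *not* emulate:
hemodynamic autocorrelation, scanner noise spectra, site and motion
effects, heterogeneous effect topographies.  Passing tests on this
generator therefore validate the *machinery* (estimators, selection, CV
bookkeeping, calibration), not clinical performance on real cohorts.

## Feature selection

Stage one keeps the top `ceiling(proportion × p)` features by two-group
ANOVA F (default proportion 0.25 — small enough to bound the RFE cost,
large enough that elimination still has real work to do; constant
features get F = 0 and ties resolve by column order).  Stage two is
recursive feature elimination with stratified k-fold cross-validation
(k = 5, step 2): within each training split, the kernel is refit and the
two lowest-importance features dropped per round (|weights| for the
linear kernels, impurity importance for the tree kernels), while the
held-out fold is scored at every candidate count; the count with the
best mean balanced accuracy wins, ties to the smaller count, and the
final subset is the top of a full-data elimination ranking at that
count.  Eliminating inside each training split — rather than ranking
once on all data — keeps the reported curve honest: on pure-noise data
the best cross-validated score stays near chance instead of inheriting
an optimistic ranking picked on the test folds.

## Classification and evaluation

Six classifiers (linear SVM, ridge-penalised logistic regression, random
forest, histogram gradient-boosted trees, a single-hidden-layer
perceptron with L2 decay, RBF SVM) are tuned by cross-validated random
search over documented spaces (costs and learning rates log-uniform,
tree sizes uniform over standard ranges; 50 draws by default).  Balanced
accuracy — the mean of sensitivity and specificity — is the objective
throughout, and the per-fold identity balanced = (sens + spec)/2 is
asserted in the result structures.  Scale-sensitive classifiers are
standardised with training-fold statistics inside every fold; evaluation
folds use a seed distinct from selection folds.

By default the pipeline follows the sequential protocol: select once,
then cross-validate classifiers on the selected features.  Because the
selection has seen all subjects, those scores carry selection optimism
at small n; the `nested` option reruns the entire selection cascade
inside each training fold of the final evaluation (shared across the
sampled hyper-parameter draws), which is the leakage-free variant — on
null cohorts it is the one that actually scores ≈ 0.5.

## Factorial analysis

All cell scores are logged in a long-format table keyed by
representation, atlas, preprocessing-strategy tag, selection kernel and
classifier.  The three pre-learning factors are tested by a three-factor
ANOVA with sum-to-zero (effects) coding and type-III sums of squares —
the decomposition in which each term is adjusted for all others, and the
one that is invariant to level ordering and row permutation (both
asserted as properties; on balanced grids the main effects also agree
with type-I, a further cross-check, and the single-factor reduction
reproduces the classical one-way F to 10⁻⁸ against a closed-form
oracle).  The full-interaction model is fit first; interactions with
p > 0.001 are then dropped and the model refit.  Scores enter
untransformed: the response of interest is accuracy itself, not a
variance-stabilised version of it.

Region reports parse the canonical feature names: each selected feature
credits one count to both endpoint regions (ties in the ranking break
alphabetically for determinism), and for dynamic features the `_wk` /
`_st` suffix split quantifies whether under- or over-connectivity
carries the selected signal.

## Numerical and degenerate-input conventions

* Zero-variance series or windows: correlation 0 with a `degenerate`
  flag; such windows count toward `nwk`.
* Missing values inside an ROI column: mean-imputed per region with a
  warning; a fully non-finite column is an error (region counts must
  stay aligned across a cohort).
* All randomness flows from explicit integer seeds; a master seed
  derives per-stage and per-subject seeds through a documented string
  hash, so any stage can be rerun in isolation and whole pipelines are
  bit-reproducible.  Seeds are recorded in every result object and
  table.
* Rank-deficient ANOVA designs abort with the list of empty cells; a
  single observed factor level is rejected up front.

## Problem sizes used in the test suite

The suite exercises the pipeline at deliberately small scale, chosen so
each property is measurable with comfortable margins: estimator-recovery
experiments use single pairs at L = 2000 over 20 seeds; oracle
comparisons use 100 random window configurations and 40-sample/6-feature
exhaustive-subset instances; calibration checks use 100-subject permuted
cohorts and 384-row null configuration grids; the planted-dynamics
discrimination cohort is 60 + 60 subjects, 12 regions, L = 400.

## Known limitations

* The generator's pairwise construction cannot place one region in two
  targeted pairs (no joint covariance solver); it rejects such models
  rather than silently producing an infeasible correlation structure.
* The neural-network classifier offers a single hidden layer.
* `evaluate_all` is serial; grid cells are independent and can be
  distributed by the user.
* Harmonisation of heterogeneous TR / scan length across sites is out
  of scope: L and TR are per-subject quantities, never padded or
  truncated.
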