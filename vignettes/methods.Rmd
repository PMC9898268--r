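---
title: "Models and methods behind driftlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind driftlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `driftlearn`, the
assumptions behind them, the numerical choices that were genuinely open,
and what the synthetic-data tests do and do not establish about real data.

## From angles to coordination patterns

**Filtering.** `lowpass_fourier()` is a brick-wall filter: FFT, zero every
bin above the cut-off, inverse FFT. The default cut-off of 8 Hz sits an
order of magnitude above the movement content of interest (cycle rates of
roughly 0.5–1 Hz) and well below sensor noise. A brick-wall filter is
exactly idempotent and exactly preserves in-band sinusoids, which makes it
the easiest filter to reason about in tests; its ringing risk is immaterial
here because everything retained is far from the cut-off.

**Cycle segmentation.** A cycle runs between consecutive maximal knee
flexions. A sample is a boundary if it is a strictly interior local
maximum of the knee angle (ties broken to the earliest index of a plateau)
and at least `min_period = 0.5` s from the previous boundary — cycles in
this task last one to two seconds, so 0.5 s rejects double peaks without
ever merging true cycles. The first and last cycle of every trial are
dropped (push-off and wall-approach artefacts). Each retained cycle is
amplitude-normalized to [0, 1] per cycle and resampled to L = 100 points.
Per-cycle (rather than per-trial) normalization was chosen because the
normalization's purpose is to remove amplitude information and keep shape;
per-trial normalization would leak slow amplitude drift into the shape
features.

**Continuous relative phase.** Each joint's instantaneous phase comes from
the FFT analytic signal of the mean-centered, max-abs-normalized angle
computed on the *whole trial*, then sliced per cycle; computing phase per
cycle would put Hilbert edge transients inside every cycle instead of only
at the two trial ends (which are dropped with the edge cycles). CRP is
elbow phase minus knee phase, wrapped to (−180°, 180°], so anti-phase
reads ±180° and in-phase 0°. Whether the original analyses used Hilbert
phase or an angle/angular-velocity phase plane is not derivable from the
available description; the Hilbert convention is fixed here and tested
against analytically known phase relations (identical signals → 0°,
sign-flipped → 180°, quarter-period lag → −90°).

**Wrap handling in the feature metric.** Curves that hover near ±180° can
cross the wrap line sample-by-sample, and under a plain Euclidean metric a
5° fluctuation then looks like a 360° excursion — enough to split one
coordination pattern into spurious far-apart groups. `crp_matrix()`
therefore unwraps each curve along its own continuity (no ±360° jumps
between neighbouring samples) and recentres its mean into (−180°, 180°]
before clustering. The per-sample wrapped representation is kept everywhere
else.

## The clustering model

`fit_profiles()` implements a discriminative Gaussian mixture of the
Fisher-EM family. Centered curves x ∈ R^L are modelled as

x = U y + ε,  y | k ~ N(μ_k, Σ_k),  ε ~ N(0, β (I − U Uᵀ)),

with U an orthonormal basis of a latent subspace of dimension
d = min(K − 1, L), full per-component covariances Σ_k inside the subspace
and common isotropic noise β outside it. EM alternates responsibilities
(E), the subspace update (F), and Gaussian parameters (M); the best of
`n_init = 10` seeded k-means starts by log-likelihood is returned, and
convergence is a relative log-likelihood change below 1e-8 or 500
iterations.

Three numerical decisions matter and were made deliberately:

* **F-step.** The textbook Fisher criterion maximizes
  tr((UᵀWU)⁻¹UᵀBU) via a generalized eigenproblem with the within-scatter
  W. In high dimension the sampling noise of W tilts the solution off the
  span of the cluster means; the part of the between-cluster energy that
  misses the subspace lands in the isotropic complement and inflates β by
  an order of magnitude, which in turn makes BIC increase monotonically in
  K. The default F-step (`fstep = "svd"`) therefore solves the Fisher
  problem under an isotropic within-scatter — the eigenvectors of the soft
  between-scatter, i.e. the span of the weighted cluster means — which
  cannot leak mean energy. The generalized eigenproblem remains available
  as `fstep = "eig"`.
* **Degeneracy guard.** Latent covariance eigenvalues are clamped from
  below at β: the subspace is supposed to carry at least as much variance
  as the complement it is separated from, and without the clamp a
  component can collapse onto a sub-noise direction and win unbounded
  density. Covariances also receive a small ridge (1e-6).
* **Ascent safeguard.** The F-step is not an exact M-step for the
  likelihood, so monotone ascent is not guaranteed in theory; an iteration
  that would decrease the log-likelihood restores the previous parameters
  and stops. The recorded trace is therefore non-decreasing by
  construction.

**Model selection.** BIC = 2 log L − ν log n (larger better), with ν
counting the orthonormal basis (Ld − d(d+1)/2), latent means (Kd),
covariances (K d(d+1)/2), weights (K − 1) and β (1). `select_k()` picks the
first value of the plateau: the smallest K whose successor has a lower
BIC. If BIC rises through the whole range the maximum is returned with a
warning — that situation means the scan, not the rule, is inadequate.

**When the plateau rule is well-posed.** The selection claim "the plateau
recovers the true number of patterns" holds when within-cluster noise is
approximately white on the L-point grid. With d = K − 1 tied to K, every
extra cluster also buys one more latent dimension, worth roughly
n/2 · (λ/β − 1 − log(λ/β)) in log-likelihood for a direction with variance
λ against noise floor β; if the within-cluster spectrum decays — as it
does for any smooth functional data, including CRP curves computed from
rendered angle traces, whose cycle edges additionally blend neighbouring
patterns — that gain exceeds the BIC penalty for many K beyond the truth
and the BIC rises monotonically. This is a property of the method, not an
implementation artefact, and it is one plausible reading of why cluster
counts selected on real cycle data can exceed the number of
visually distinct patterns: transition and context variants are genuine
structure. Consequently the cluster-count recovery study in the test suite
runs on curve-level synthetic data (templates plus white grid noise, the
`render = "curves"` scenario), and trace-rendered data is used to test the
kinematic chain itself, not K selection.

**Canonical ordering.** Mixture component order is arbitrary (it depends
on the initialization seed), so `assign_labels()` relabels clusters by
ascending circular mean of their mean CRP curve. This replaces an
unreproducible random ordering with a deterministic one; nothing
downstream depends on the order beyond display.

## Drifting Markov models

A DMM of degree d over m patterns is parameterized by d + 1 row-stochastic
support matrices P_0 … P_d at the relative positions i/d; the transition
matrix at position t of a length-n sequence is the Lagrange interpolation
Π_{t/n} = Σ_i P_i L_i(t/n). For d ≤ 1 the interpolant is a convex
combination and automatically stochastic; for d ≥ 2 entries can leave
[0, 1] between the nodes, so evaluated matrices are clipped and
row-renormalized, and the fit penalizes negative interpolants on the data
grid. The order is fixed at 1.

**Estimation.** Maximum likelihood under row-simplex constraints, chosen
because AIC/BIC comparisons downstream require likelihoods. Each source
state's rows across all supports are optimized jointly by BFGS with an
analytic gradient, with the rows kept on the simplex by a softmax
parameterization; the objective is the floored (1e-12) log-likelihood of
the interpolated transition probabilities minus a quadratic penalty on
negative interpolants. The optimizer is initialized at the Laplace-smoothed
(α = 0.5) degree-0 estimate replicated across supports. The returned model
is the best by *exact evaluated* log-likelihood among the optimized fit,
the replicated (unsmoothed) degree-0 estimate, and — for d ≥ 2 — the
embedded degree-1 fit (a linear drift is reproduced exactly by polynomial
interpolation through any set of nodes). The embedding makes the nested
ordering LL(d=3) ≥ LL(d=1) ≥ LL(d=0) hold by construction rather than by
optimizer luck. A closed-form least-squares estimator (indicator
regression on the Lagrange basis, rows projected onto the simplex) is
available as `method = "ls"`.

The degree-0 fit itself is the exact transition-count MLE (uniform rows
for never-observed source states); smoothing applies only to the
initializer, so the classical estimator is recovered without compromise.

**Identifiability caveat.** If the true process's interpolant leaves
[0, 1] (as the strongly concentrated strategy presets do between nodes),
simulation clips it, and the support matrices of the clipped process are
no longer identifiable — a refit can match the data's law with different
supports and a higher likelihood than the nominal truth. Parameter-recovery
tests therefore use `random_smooth_supports()`, whose interpolants stay
essentially interior; at m = 5, d = 3, n = 10,000 the mean absolute support
error is about 0.016.

**Alphabet.** Models are fitted on the global pattern set 1..K* even for
learners who never visited some patterns, so exploration profiles are
comparable across learners; never-visited patterns keep finite likelihood
through the probability floor and are flagged, not zeroed. Plain character
alphabets (e.g. nucleotide sequences read with `read_fasta_sequence()`)
are accepted directly.

## The exploration statistic

`exploration_quantity()` compares the degree-1 and degree-3 descriptions
of the same sequence. The default (`mode = "appearance"`) measures, per
pattern, the mean absolute gap between the two models'
probability-of-appearance trajectories p_t = p_{t−1} Π_{t/n}, as a
percentage; p₀ defaults to the indicator of the first observed label. The
alternative reading — the mean Euclidean distance between the k-th columns
of the two drifting transition matrices, i.e. the probabilities of
transiting *toward* pattern k — is implemented as `mode = "column"`. Both
are symmetric and bounded by 100; the appearance mode also obeys
mean_k Q_k ≤ 200/m because the row gap has total-variation bound 2. The
appearance reading is the default because the statistic is defined in
terms of the two simulated appearance trajectories of the fitted models.

Calibration, verified in the tests: identical models give Q ≡ 0; data from
a homogeneous chain at n = 10,000 gives Q < 2% for every pattern (the two
fits then describe the same linear dynamics); an anchored-local learner at
n = 680 shows a much larger maximal Q than a linear learner at the same
length.

## Learning curves

`fit_exponential()` fits f(t) = a e^{−bt} + c to per-session mean stroke
frequency by Levenberg–Marquardt least squares. Sessions are indexed from
t = 1; a + c is the pre-practice level at t = 0. Initialization is
c₀ = min f, then a log-linear regression of log(f − c₀ + ε) on t for a₀
and b₀; five starts with b₀ jittered by ±50% guard against the flat local
minimum, with bounds b ∈ [0, 10] session⁻¹ and c ∈ [0, max f] Hz. Goodness
of fit is r² = 1 − SS_res/SS_tot and RMSE = √(SS_res/n) — the n (not
n − p) denominator is the convention adopted here and stated because both
exist in the literature. A constant series returns the flagged degenerate
fit (a = 0, b = 0, c = mean). All 16 sessions are used; no exclusion rule
is applied.

## The statistical battery

All tests are written out explicitly so each number can be checked against
an oracle: paired t (with paired Cohen's d and the t-based CI of the mean
difference), unbiased variance, Levene's test with mean centering (the
original Levene; `center = "median"` gives Brown–Forsythe), Pearson and
Spearman correlations (t approximation, midranks for ties), and a two-way
fully within-subject ANOVA. The ANOVA uses the classical decomposition in
which each effect is tested against its own subject-interaction error
term; partial η² = SS_effect/(SS_effect + SS_error). For effects with more
than one numerator df, Greenhouse–Geisser and Huynh–Feldt epsilons are
computed from the covariance of orthonormal contrast scores; the corrected
p uses Greenhouse–Geisser when ε_GG < 0.75 and Huynh–Feldt otherwise, and
two-level effects are exempt (ε = 1). Bonferroni post-hocs run a paired t
per level pair on subject × level means, multiply p by the number of pairs
(capped at 1), and report per-pair t-based CIs — a pooled-error CI
construction would also be defensible; the per-pair choice is stated
rather than hidden. A Shapiro–Wilk screen is reported but never switches
tests automatically: reproducibility is preferred over automation.

## What the synthetic generator emulates — and what it does not

`simulate_learner()` emulates the protocol shape (16 sessions × 5 trials ×
3–17 cycles per trial, two speed conditions, ~11 patterns available) with
a known drifting transition structure per strategy preset and exponential
performance improvement (defaults a = 0.3 Hz, b = 0.2 /session,
c = 0.5 Hz, σ = 0.02 Hz — a ~35% frequency drop to a plausible asymptote
with session-level noise an order of magnitude smaller than the change).
CRP templates default to m − 1 constant levels evenly spaced in
[−140°, 140°] plus one expert-like sweep (−160° → 0° → −160°); the margin
from ±180° prevents phase noise from straddling the wrap line. Rendered
angle traces use a sinusoidal knee, an elbow carrying the labelled cycle's
CRP template as a phase offset, phase noise with the two time scales real
coordination shows (cycle-to-cycle offset plus band-limited within-cycle
wander, total SD 5° by default), 0.5° broadband sensor noise, and
phase-continuous template switches blended over 0.2 s.

The generator does **not** emulate biomechanically realistic swimming
kinematics, inertial-sensor fusion, amplitude variability, or the
heavy-tailed, autocorrelated structure of real motor noise. Passing tests
therefore establish that the chain of estimators is correct and calibrated
under its own assumptions — not that real breaststroke data satisfies
those assumptions. Two honest gaps are documented above: K selection on
trace-rendered features over-counts clusters (colored functional noise),
and strongly clipped drifting processes are not parameter-identifiable.

## Problem sizes and reproducibility

The test suite and acceptance checks run at: n = 10,000 transitions for
DMM recovery and homogeneous-chain calibration; n = 680 cycles for the
strategy comparison (one learner's worth of cycles); 200 seeds for the
noisy learning-curve study; 160 curves per scan point across K = 2..8 for
the 10-seed selection study; and a 2-learner × 2-condition pipeline run
with m = 4 patterns — sizes chosen so each estimate's sampling error is
comfortably below the tested tolerance. Every source of randomness flows
from one integer seed through a splittable helper; rerunning any function
or the whole pipeline with the same seed reproduces results bit for bit,
and the pipeline writes its seed and a config hash into every output
bundle.
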