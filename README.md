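# driftlearn

Quantifying exploration during motor skill learning with drifting Markov
models.

## The problem

When novices learn a new whole-body skill — the motivating case is adults
learning breaststroke swimming over 16 practice sessions — they do not move
smoothly from one fixed movement pattern to a better one. They *explore*:
coordination patterns appear, stabilise for a while, and are abandoned
again. `driftlearn` implements a complete analysis chain that turns raw
joint-angle recordings into a per-pattern, per-learner measure of that
exploration, together with the learning-curve and inferential statistics a
motor-learning study needs:

1. **Kinematics.** Elbow and knee angle time series (100 Hz) are low-pass
   filtered (Fourier brick-wall, 8 Hz), partitioned into movement cycles at
   maximal knee flexions (first and last cycle of each trial dropped),
   amplitude-normalized, and summarised per cycle by the **continuous
   relative phase** CRP(t) = φ_elbow(t) − φ_knee(t) (Hilbert analytic
   phase, degrees, wrapped to (−180°, 180°]), resampled to 100 points.
2. **Coordination profiling.** Cycles are clustered into coordination
   patterns with a discriminative (Fisher-EM style) Gaussian mixture: the
   cluster structure lives in a latent subspace of dimension K − 1 with
   isotropic noise outside it. The number of patterns K is chosen by the
   **BIC plateau rule**: the smallest K whose successor has a lower
   BIC = 2 log L − ν log n.
3. **Drifting Markov models (DMM).** The chronological pattern-label
   sequence x₀…x_n of one learner × speed condition is modelled by an
   order-1 Markov chain whose transition matrix drifts polynomially along
   the sequence: Π_{t/n} = Σᵢ Pᵢ · Lᵢ(t/n), with d + 1 row-stochastic
   support matrices Pᵢ at the nodes i/d and Lᵢ the Lagrange basis.
   Estimation is constrained maximum likelihood; degree 0 reduces exactly
   to the classical transition-count estimate.
4. **Quantity of exploration.** For each pattern k, the distance between
   the degree-1 (linear trend) and degree-3 (flexible) models of the same
   sequence, as a percentage:
   Q_k = 100 · (n+1)⁻¹ Σ_t |p_t^{(3)}(k) − p_t^{(1)}(k)|, where p_t is the
   probability-of-appearance trajectory of each model. Large Q_k means the
   pattern was deeply explored then abandoned (an anchor point); Q_k ≈ 0
   means linear appearance or disappearance.
5. **Learning curves.** Per-session mean stroke frequency is fitted with
   f(t) = a·exp(−b·t) + c (nonlinear least squares); b is the learning
   rate, c the asymptotic performance.
6. **Statistics.** Paired t, mean-centered Levene, two-way within-subject
   ANOVA with Greenhouse–Geisser / Huynh–Feldt sphericity handling and
   partial η², Bonferroni post-hocs, Pearson/Spearman correlations,
   Cohen's d.

A seeded synthetic-learner generator (`simulate_learner()`) renders label
sequences from known drifting transition structures — blind, linear,
anchored-local and hybrid non-local search strategies — plus matching
joint-angle traces and performance series, so every stage can be tested
against ground truth.

## Worked example

The package ships the individual learning rates reported for seven novice
breaststroke swimmers under two speed conditions (`swim_learning_rates`)
and the published BIC scores of the coordination cluster scan
(`coordination_bic`):

```r
library(driftlearn)

low  <- swim_learning_rates$b[swim_learning_rates$speed == "low"]
high <- swim_learning_rates$b[swim_learning_rates$speed == "high"]
paired_t(low, high)
#>   method   statistic    df  p_value effect_size estimate ci_low ci_high
#> 1 paired t     -1.37      6   0.219      -0.519  -0.0736 -0.205  0.0575
levene_mean_centered(list(low, high))
#>   method                 statistic    df   df2 p_value
#> 1 Levene (mean-centered)      6.07     1    12  0.0298
select_k(coordination_bic)
#> [1] 11
```

The learning rates do not differ systematically between conditions
(t(6) = −1.37, p = 0.219), but their dispersion does (F(1,12) = 6.07,
p = 0.030): swimming near maximal speed makes individual learning rates
more heterogeneous. The BIC plateau rule applied to the published cluster
scan selects 11 coordination patterns.

Exploration of a synthetic anchored-local learner over 680 cycles:

```r
sup  <- make_strategy_supports("anchored_local", m = 5, degree = 3)
labs <- simulate_dmm(new_dmm(sup, n = 680), n = 680, initial = 1, seed = 2)
explore_sequence(labs, m = 5)
#> Exploration profile: 5 of 5 patterns visited, SD(Q) = 6.06%
#>   pattern q_percent visited
#> 1       1     7.76  TRUE
#> 2       2    15.7   TRUE
#> 3       3     0.828 TRUE
#> 4       4    14.6   TRUE
#> 5       5     7.03  TRUE
```

Patterns 2 and 4 — the anchors the learner dwelt on and then left — carry
the most exploration, exactly the anchor-point signature the statistic is
designed to expose. A noisy exponential performance series is recovered by
the learning-curve fit:

```r
perf <- gen_performance_series(a = 0.3, b = 0.2, c = 0.5, sigma = 0.02,
                               n_sessions = 16, seed = 2)
fit_exponential(perf)
#> Exponential learning curve: f(t) = 0.2984 * exp(-0.1401 t) + 0.4723
#>   r2 = 0.9130, RMSE = 0.02122 Hz, 16 sessions
```

`run_pipeline(pipeline_config(...))` chains every stage (cluster scan →
plateau selection → labelling → degree-1/degree-3 DMMs → exploration →
learning fits → statistics) on recorded traces or a synthetic scenario and
writes a reproducible report bundle (CSV/TSV/JSON with a seed-stamped
manifest).

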