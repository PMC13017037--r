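---
title: "Trait covariation networks from raw cohort records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait covariation networks from raw cohort records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitnet)
```

`traitnet` implements a complete analysis pipeline for small-cohort studies
of phenotypic trait covariation, of the kind used in fish cognition and
animal-personality research: a cohort of wild-caught individuals is assayed
across life-history, physiological, behavioral and cognitive tests, each
assay is reduced to a scalar trait score, and the covariance structure of
the scores is summarized as a regularized partial-correlation network with
centrality and stability diagnostics. This vignette explains the models and
procedures behind each stage, the tunable parameters and their defaults,
and the design decisions taken where more than one reading was defensible.

## Trait scores

Fourteen scores are derived per subject from the raw trial records:

* **growth** — percent change in body length between the two morphometric
  timepoints, $100\,(L_2 - L_1)/L_1$.
* **basal metabolism** — basal operculum beats per minute divided by body
  weight (bpm/g); ventilation rate is the standard non-invasive proxy for
  metabolic rate in small fish.
* **stress metabolism** — percent elevation of the stress-condition
  ventilation rate over the basal rate, $100\,(V_s - V_b)/V_b$.
* **activity** — distance moved (cm) in the open-field arena.
* **thigmotaxis** — percent time in the outer band of the arena. Its
  chance level follows from the geometry: for a square arena of side $L$
  with an edge band of width $w$, $100\,[L^2 - (L-2w)^2]/L^2$, which is
  39.94% (conventionally 40%) for $L = 40$ cm and $w = 4.5$ cm
  (`chance_level()`).
* **scototaxis** — percent time in the dark half (chance 50%).
* **sociability** — percent time near the mirror stimulus out of the time
  spent outside the central sector (chance 50%).
* **motor / visual lateralization** — the relative index
  $100\,(t_{cw} - t_{ccw})/(t_{cw} + t_{ccw})$ signs the rotation
  preference; the absolute index is its absolute value and measures
  lateralization strength.
* **spatial learning** — days to criterion in the T-maze, where the
  criterion is 10 correct initial choices out of 12 trials over two
  consecutive days.
* **flexibility** — $-(d_{rev} - d_{learn})/d_{learn}$, reversal speed
  corrected for initial learning speed.
* **memory** — $-(d_{mem} - d_{rev})/d_{rev}$, retention after a two-month
  interval, baselined on the reversal phase.

Repeated assays (two trials of each behavioral and lateralization test)
are aggregated by the mean of the two per-trial scores; a `trials =
"first"` switch restricts to the first trial. Note one deliberate
consequence of per-trial aggregation: the absolute lateralization column is
the mean of the per-trial absolute indices, so it is *not* in general the
absolute value of the (signed) relative column — a subject rotating
clockwise in one trial and counterclockwise in the other is strongly
lateralized in both trials yet has a relative score near zero. At the
level of a single trial, `lateralization_indices()` always satisfies
`absolute == |relative|`; under first-trial aggregation the identity also
holds column-wise.

### The days-to-criterion rule

`days_to_criterion()` scans *overlapping* windows of two consecutive days
and returns the first day whose window sum reaches 10. The alternative
reading — disjoint two-day blocks — was rejected because only the
overlapping rule reproduces the published chance-simulation benchmark for
this criterion (see below): the exact success probability of a random
chooser within 8 days is 0.1137 under overlapping windows versus roughly
0.077 under disjoint blocks, and only the former matches the
Monte-Carlo value of ≈11.4%. The minimum achievable value is 2 days.

## The chance-performance null

Whether a cohort's criterion performance could arise from random choice is
judged against a Monte-Carlo null (`simulate_chance_experiment()`): each
replicate simulates the same number of subjects as the real cohort, each
making 6 independent Bernoulli(0.5) choices per day over the observed day
horizon, and records the percentage of simulated subjects reaching the
criterion. With 24 subjects, 8 days and 10,000 replicates the null has
mean ≈ 11.4% and SD ≈ 6.5%. The p-value for an observed count of
successful subjects uses the add-one convention
$(1 + \#\{\text{replicates} \ge \text{observed}\})/(n_{rep} + 1)$, which
never returns exactly zero from a finite run; an observation beyond every
replicate is reported as a bound, e.g. `< 0.0001`.

Two independent checks accompany the simulation. First,
`exact_criterion_probability()` computes the same success probability in
closed form by dynamic programming over the previous day's correct count
(states 0–6, Binomial(6, ½) day draws, absorption when two consecutive
days sum to ≥ 10); at two days this reduces to the binomial tail
$P(\mathrm{Bin}(12, \tfrac12) \ge 10) = 79/4096$. The simulation mean is
required to sit within Monte-Carlo error of the DP value, and the DP value
is provably nondecreasing in the day horizon. Second, the SD of the
per-replicate percentages must agree with the binomial structure
$100\sqrt{p(1-p)/n}$.

A consequence of the monotonicity property is worth recording: any chance
probability quoted for a *shorter* horizon can never exceed one quoted for
a longer horizon under the same criterion rule, which constrains how
far a single windowing convention can be pushed when reconciling published
figures for different phases; this package anchors its validation on the
8-day learning-phase benchmark only.

`criterion_chi_square()` is the conventional goodness-of-fit helper for a
correct/incorrect split against equal expectation (1 df, no continuity
correction). The criterion-level statistic of 10.667 corresponds to the
split (20, 4) — i.e. twenty correct in twenty-four trials — rather than to
10-of-12 (which gives 5.333); the helper is generic and both values are
exercised in the tests.

## Univariate statistics

The univariate layer wraps the standard tests with tidy outputs:
one-sample and paired *t*-tests (`one_sample_t()`, `paired_t()`),
Brown–Forsythe variance homogeneity via `car::leveneTest()`
(median-centered — the robust default, since only the test family, not the
centering, is conventionally fixed), Spearman rank correlation with
average-rank ties and the asymptotic *t* p-value, and the exact binomial
test with Clopper–Pearson interval. All tests are two-sided except the
first-day memory-retention check, which is directional by design
(`alternative = "greater"`). Missing values are dropped pairwise here;
imputation is reserved for the network stage.

**Repeatability** (`repeatability()`) is the intraclass correlation of the
one-way random-intercept model, $R = \sigma^2_s/(\sigma^2_s +
\sigma^2_e)$. For balanced designs the REML variance components coincide
with the closed-form ANOVA estimators ($\hat\sigma^2_e = MS_W$,
$\hat\sigma^2_s = (MS_B - MS_W)/k$ truncated at zero), which the
implementation exploits to make the parametric bootstrap cheap; unbalanced
data fall back to `lme4::lmer()`. The confidence interval is the
percentile interval over 1,000 simulate-and-refit draws from the fitted
model, and the p-value is a likelihood-ratio test of the subject variance
with the usual $\tfrac12\chi^2_1$ boundary correction. Coverage was
verified by simulation: at a true ICC of 0.6 with 24 subjects × 2 trials,
the 95% interval covers the truth in ≥ 90% of replicated designs.

**Learning curves** (`learning_curve_fit()`) model the daily error
probability with a grouped-binomial GLMM,
`cbind(errors, correct) ~ day + (1 | subject)` via `lme4::glmer()`. The
day slope is reported on the log-odds-of-error scale (negative = the
cohort learns) and the day effect is tested by likelihood ratio. Parameter
recovery was checked at a planted slope of −0.4/day.

## Multiple imputation

Missing trait cells are imputed by chained equations with predictive mean
matching (`pmm_impute()`), with the study-standard settings `m = 5`
imputations and `maxit = 50` sweeps. Each incomplete column is regressed
on all other columns at their current values; the regression uses a small
ridge ($10^{-5}$ on the scaled normal equations) so the 24 × 14 case stays
well-posed, and Bayesian draws of the coefficients and error variance
propagate parameter uncertainty. Every missing cell receives the observed
value of a donor sampled uniformly from the `donors = 5` rows with the
closest predicted means — 5 is the canonical PMM donor count, chosen here
because no other value is conventionally fixed. The initial fill draws at
random from each column's observed values. Two consequences are asserted
in the tests: imputed cells always lie in the observed support of their
column, and observed cells are bit-identical across all `m` tables.

Downstream, the `m` completed tables are pooled by Fisher-z averaging of
the Spearman correlations (`correlation_matrix()` on an
`imputation_set`). Averaging on the z scale is the least-surprising
pooling rule for correlations and is exposed rather than hidden: passing a
single completed table instead reproduces the first-table-only analysis.

## Network estimation

The headline network is a **regularized partial-correlation network**:
the graphical lasso is run on the Spearman correlation matrix over a
log-spaced penalty path (100 values from $\lambda_{max}$, the largest
absolute off-diagonal correlation, down to $0.01\,\lambda_{max}$), and the
model is selected by the extended BIC with $\gamma = 0.5$,
$\mathrm{EBIC} = -n(\log\det\Theta - \mathrm{tr}(S\Theta)) + E\log n +
4\gamma E\log p$. Edge weights are the partial correlations
$-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$ — associations corrected for
the influence of all other nodes, which removes chain-induced marginal
correlation (verified against the conditional-independence oracle on
simulated chains). A plain correlation estimator (`estimator = "cor"`)
is retained for the marginal correlation-matrix view; both sit behind one
switch because study descriptions of this analysis family name both, and
the regularized estimator is the headline default. The graphical-lasso
solver is the classic block coordinate descent, implemented in C++; at
zero penalty it reproduces the matrix-inverse partial correlations to
$10^{-6}$ on well-conditioned input, which is asserted in the tests.

Numerical choices: a correlation matrix that is not positive
semi-definite (possible with pairwise-complete Spearman) is repaired by
eigenvalue clipping at $10^{-6}$ followed by rescaling to unit diagonal,
and the repair is logged; numerically tiny negative eigenvalues (above
$-10^{-10}$) are left untouched. The penalty-path solver uses a relative
tolerance of $10^{-7}$ with capped inner iterations — on severely
rank-deficient subsets (far fewer subjects than nodes, as arise in the
case-dropping bootstrap) the unpenalized end of the path converges slowly
and extra precision there has no effect on the EBIC-selected model. Edge
weights below $10^{-10}$ are treated as exact zeros.

The default node set has 12 nodes: the two *relative* lateralization
indices are excluded (as in the standard figure layout of such analyses)
because their absolute counterparts carry the strength information; a
14-node variant is available (`node_set = "14"`).

### Centrality

Three node metrics (`centrality()`): **strength** — the sum of absolute
incident weights; **expected influence** — the signed sum, which
distinguishes positive from negative edges and is carried precisely
because the sign-blind metrics can mask negative interactions; and
**eigenvector centrality** — the principal eigenvector of the absolute
weight matrix scaled to maximum 1 (sign-blind by construction). All three
are verified against brute-force reimplementations on random networks,
including the identities $\sum_i s_i = 2\sum_{i<j}|w_{ij}|$ and
$\sum_i EI_i = 2\sum_{i<j} w_{ij}$.

### Edge stability and the unweighted network

`edge_bootstrap()` resamples subjects with replacement (default 1,000
resamples), re-estimates the network per resample, and summarizes each
edge with its percentile 95% interval and sign-agreement fraction. The
**significance mask** — edges whose interval excludes zero — is the
unweighted network. "Significantly different from zero" is not given an
operational rule in most study descriptions; the bootstrap-CI rule is the
standard choice in this methodology and is what the package uses, with
permutation-style labels mapped onto the same machinery. A resample in
which a trait is constant cannot inform that trait's edges: those edges
are recorded missing for that resample and drop out of the interval
denominator (logged).

### Case-dropping stability (CS-coefficient)

`cs_coefficient()` drops increasing proportions of subjects (grid 0.05 to
0.75 in steps of 0.05, the canonical scheme), recomputes each centrality
metric on subsamples (default 1,000 per proportion), and correlates the
subset centralities with the full-sample ones. The CS-coefficient is the
largest drop proportion at which at least 95% of subsets still correlate
at $r \ge 0.7$; metrics with CS below 0.25 are flagged unreliable. A
subset on which a metric is undefined (an empty network) counts as a
failure, not as missing. `cs_rethreshold()` re-evaluates a stored run at a
different $r$ on identical resamples, which makes the monotonicity of CS
in the threshold directly testable.

## The synthetic cohort generator

Because the original field records are not shipped, every stage is
validated on synthetic cohorts with *known* structure
(`generate_cohort()`). One latent vector per subject is drawn from a
multivariate normal with a configurable 14 × 14 correlation matrix, and
each latent coordinate maps monotonically to its assay's raw observables:

* zone times via logistic squashing to valid fractions of the 30-min
  trial (so component durations can never exceed the total);
* distances and ventilation rates via affine maps clipped at zero;
* lateralization via a logistic magnitude (driven by the "absolute"
  latent) times a tanh direction (driven by the "relative" latent), so
  each index is monotone in its own latent given the other;
* maze performance by giving each subject a logistic daily
  probability-of-correct curve whose slope is log-normal in the phase
  latent with a negative loading (larger latent = slower learner), then
  sampling Bernoulli choices and truncating the phase at the criterion
  day. Reversal starts below chance (the previously rewarded arm is now
  wrong), memory above chance (retention).

Monotone maps preserve rank correlations, which is what makes parameter
recovery well-defined for a Spearman-based pipeline: planted latent
correlations reappear as trait-score Spearman correlations (exactly, up
to the $\frac{6}{\pi}\arcsin(\rho/2)$ normal-scores attenuation, for the
deterministic maps; attenuated further for assays with trial noise, whose
between-trial reliability is set by `trial_icc`, default 0.6). Default
trait locations and spreads are plausible population values for juvenile
tench (e.g. thigmotaxis 78%, basal ventilation ≈ 85 bpm/g, stress
response ≈ 103%); the maze defaults were calibrated once so that
days-to-criterion lands near 4.8 ± 2.1 days with range 2–8 in the
learning phase. Missingness is injected block-wise, mimicking disease
withdrawal rather than cell-wise MCAR: a stage-1 withdrawal loses the
visual lateralization test and both later maze phases, a stage-2
withdrawal loses only the memory phase, with stage-2 twice as likely and
the probabilities scaled so the expected missing-cell fraction of the
scored table equals `missing_rate` (default 6/336 ≈ 1.8%, i.e. about 3
affected subjects in a 24-subject cohort).

Two features of real data are deliberately *not* emulated: invalid trials
(unsolved within the time limit and repeated) are assumed already excluded
upstream, so every simulated day holds exactly 6 valid trials; and no
video, trajectory or arena geometry is synthesized — the generator starts
where tracking software ends, at durations and counts. Passing tests on
synthetic cohorts therefore demonstrate correctness of the scoring,
imputation and network machinery under the stated generative model, not
robustness to tracking artifacts.

One structural property of the scored table matters when interpreting
recovery experiments: the three maze traits are arithmetically coupled
(flexibility is built from the learning and reversal day counts, the
memory index from the reversal count), and the relative and absolute
indices of one lateralization test share raw times. These pairs are
conditionally dependent *by construction*, so a partial-correlation
network correctly finds edges between them even when no latent
correlation was planted; the recovery tests count false positives only
among pairs that are free of such coupling.

## Problem sizes and runtime choices

The test suite exercises the stochastic claims at sizes chosen to balance
statistical resolution against a comfortable default test run: null and
planted-correlation recovery at 500 subjects (5,000 for the deterministic
attenuation check), planted-edge network recovery over 50 seeds at 200
subjects with 150 bootstrap resamples and a 50-value penalty path,
imputation bias over 50 seeds at the 24 × 14 design with the full
`m = 5` / `maxit = 50` settings, repeatability coverage over 100
replicated designs with 1,000 bootstrap draws each, and pipeline
determinism on a 16-subject cohort with reduced bootstrap sizes. The
defaults of the exported functions are the full-size settings (10,000
chance replicates, 1,000 bootstrap resamples); the scaled-down values
appear only inside tests.

## Known limitations

* The PMM implementation is single-level and numeric-only; multilevel or
  passive imputation and imputation of trial-level records are out of
  scope.
* The network is undirected and static; no directed, temporal or
  latent-variable network models are provided.
* With 12 nodes and cohorts of ~24 subjects the EBIC graphical lasso is
  deliberately conservative; empty networks are a legitimate outcome on
  weak data, and the centrality of an empty network is reported as zero
  with a warning rather than as an error.
* p-values in the correlation matrix are unadjusted, matching the
  methodology this pipeline mirrors; multiple-testing control is left to
  the network stage's regularization and bootstrap.
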