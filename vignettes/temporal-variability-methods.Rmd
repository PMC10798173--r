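---
title: "Methods: simulating and analysing temporally variable oddball sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing temporally variable oddball sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and procedures:
what is simulated, what is estimated, which conventions were chosen where
several were defensible, and what the synthetic results do and do not
show about real data.

## The design being simulated

An auditory oddball session consists of 12 blocks of 410 tones presented
about twice per second. The interval between successive tone onsets (the
stimulus-onset asynchrony, SOA) is drawn per trial from a discretized
Gaussian distribution with mean 500 ms and a condition-specific standard
deviation: 0 (periodic), 25, 50, 75, 100, or 150 ms. The support is a
25 ms grid from 100 to 900 ms. Each block contains 56 targets (deviant
with probability 0.5) on which the subject reports standard vs deviant;
targets never occur in the first 10 trials, and 4–10 standards separate
consecutive targets. Two blocks per condition are presented in a
pseudo-randomized order with no immediate condition repeats, giving 112
targets per condition. After each block the subject rates the sequence's
rhythmicity on a 0–10 scale.

## Quantizing the Gaussian

The continuous density is evaluated at each grid point and renormalized
(`soa_distribution()`); the alternative — integrating the density over
25 ms cells — differs negligibly at these widths and loses the clean
symmetry argument. Because the grid is symmetric about 500 ms the
discrete distribution's mean is exactly 500 ms for every condition.
Truncation to [100, 900] shrinks the realized SD below the nominal value
— materially only at 150 ms nominal (realized ≈ 146 ms). All analyses
label conditions by the nominal SD, which is therefore a condition label
rather than a realized moment.

## Target placement: uniform over feasible layouts

The stated constraints are jointly tighter than they first appear: 55
inter-target gaps uniform on \{4..10\} have expected sum 385, which with
56 targets and a 10-trial prefix already exceeds 410 trials in
expectation. Independent uniform gaps are therefore infeasible, and
"uniform" is read as *uniform over the set of feasible layouts*: a
prefix in [10, 16], 55 gaps each in [4, 10], and a tail in [0, 10],
summing with the targets to exactly 410. Layouts are sampled exactly
uniformly by a bounded-parts composition-counting dynamic program with
sequential conditional sampling (`sample_target_gaps()`); uniformity is
verified against exhaustive enumeration on small instances. Under this
conditioning the marginal gap distribution is skewed toward small gaps
(mean ≈ 6.2, not 7) — a property of any generator honouring all the hard
constraints simultaneously. The prefix's upper bound (10 plus one
gap-range width) and the tail bound (one gap maximum) are this package's
choices; nothing in the design pins them down.

## The synthetic observer

The generator plants the effect structure the analyses are meant to
detect, with a *linear-probability* accuracy model:

\[ p = \mathrm{clamp}\big(p_0 + u_s - \beta_g\,\mathrm{STD}_{g} -
\beta_l\,\mathrm{STD}_{l} + \text{tuning}(\bar{\mathrm{SOA}}_l),\;
0.05, 0.95\big), \qquad p \leftarrow (1-\lambda)p + \lambda/2 . \]

Linearity in probability makes the planted slope (default
\(\beta_g\) = 0.6 percentage points per 25 ms of global STD) equal to the
average marginal effect that the logistic mixed model reports on the
response scale, so parameter recovery is a sharp check rather than an
approximate one. Response times are gamma with shape 20 (CV ≈ 22%,
typical for RTs) and mean \(\mu = \mathrm{rt}_0 + v_s +
\gamma_g \mathrm{STD}_g + \gamma_l \mathrm{STD}_l\), default
\(\gamma_g\) = 5 ms per 25 ms. Ratings decline linearly in the condition
STD (default −1 rating unit per 25 ms) with Gaussian noise, clamped to
[0, 10].

Defaults that the design does not determine were fixed once, on
plausibility grounds: baseline accuracy 0.80 and baseline RT 500 ms at
the periodic condition; lapse rate 0.02; between-subject SDs of 0.05
(probability) and 50 ms; rating intercept 9, noise SD 1.5; the local
statistics feeding the generative local terms come from the N = 4
history window. The local-effect slopes default to zero, so the default
cohort carries *global* effects only; the local machinery is exercised by
planting non-zero local slopes.

Two consequences worth knowing: the top clamp of the rating scale makes
the rating a mildly nonlinear function of the STD, so at full cohort
size a likelihood-ratio test can find "extra" explanatory power in the
rating that is really residual nonlinearity of the accuracy–STD
relationship; and because local STD windows inherit their scale from the
condition, the local and global STD predictors are strongly collinear —
confidence intervals in the joint models widen accordingly, exactly as
in the real design.

## Staircase

The SNR calibration simulates a 75-tone periodic stream with a target
every 2–3 tones and a 3-down-1-up transformed rule, whose convergence
point (79.4% correct) matches the task's ~80% working point; the
listener is a cumulative Gaussian over SNR with floor 0.5. The initial
step is 4 dB, halved once after the first two reversals; the converged
SNR is the mean of the last four reversal SNRs. The 4 dB initial step is
what lets a run traverse a realistic start-to-threshold distance
(~10 dB) and still accumulate four reversals within the 75-tone budget;
with a 2 dB step half the runs end short of four reversals. Runs that
still fail to produce four reversals are flagged and return the last
visited SNR.

## Trial-history statistics and 2-D maps

For a target at trial \(i\), the "N previous SOAs" are
\(\mathrm{soa}(i), \ldots, \mathrm{soa}(i-N+1)\) — the window *includes*
the interval immediately preceding the target, so N = 1 reproduces the
last-SOA analysis. Local SDs use the sample (n−1) denominator; a switch
exposes the population convention. Targets are binned by local mean
(centers 400–600 ms) and local SD (centers 10–100 ms) with windows of
half-width 20 ms and 10 ms respectively and *inclusive* boundaries, so
adjacent windows overlap and one trial enters several bins. The center
spacings (10 and 5 ms) are this package's choice; they give at least 50%
overlap between neighbours, matching the premise that adjacent samples
are correlated. Bins with fewer than 5 of a participant's trials are
invalid. Each participant's map is z-scored over their valid bins; maps
with fewer than two valid bins or zero variance are returned all-invalid
with a warning. The group test uses only bins valid for *every*
participant (the permutation machinery needs a complete
participants-by-bins array); per-participant exclusion before a group
intersection is the stricter of the defensible readings, and the
map-building functions accept any `min_count` if a user wants the other.

## Cluster-based sign-flip permutation test

Per bin, a one-sample t-test against zero across participants; bins with
two-sided p ≤ 0.05 are split by sign and grouped under 4-neighbour
(rook) adjacency; a cluster's statistic is its summed t. The null
distribution comes from 1000 whole-map sign flips per participant
(identity included as the first permutation, draws with replacement);
each permutation contributes its single most extreme cluster statistic,
kept with its sign. Observed clusters are significant outside the
2.5th/97.5th percentiles of that signed reference — a two-sided
family-wise 5% test — and p-values are two-sided exceedance ranks with
the +1 finite-sample correction, so no reported p can fall below
1/(n_perm+1). Recording *both* extremes per permutation and pooling them
(a tempting literal reading of "the reference distribution") doubles the
family-wise error to ~10% and is deliberately not the default; the
per-permutation extremes are retained in the result for inspection.
Degenerate zero-variance bins get \(t = \pm\infty\) with the sign of the
mean, a deterministic convention that keeps toy fixtures reproducible.
Sign-flip permutation is exact for symmetric null distributions;
z-scored maps satisfy this to good approximation.

## Mixed models

Accuracy models are binomial-logit GLMMs (lme4, Laplace approximation,
bobyqa); RT models are gamma GLMMs (glmmTMB). The gamma link is log by
default — positive-valued and multiplicatively safe — but the ms-scale
slope statements come from an identity-link fit, started at an ordinary
gamma GLM solution to keep the optimizer in the positive-mean region.
The random structure question (intercept vs intercept+slope) is decided
by likelihood-ratio test, as is the contribution of the rhythmicity
rating. Wald Type II chi-squares (car) assess fixed effects; pairwise
condition contrasts use estimated marginal means with Tukey adjustment
(emmeans) under large-sample (normal) degrees of freedom — the
mixed-model denominator-df question is sidestepped, which for thousands
of trials per condition is immaterial. The "percentage points per 25 ms"
quantity is defined as the average marginal effect of a +25 ms STD
increment on the response-scale probability, averaged over the observed
data with subject effects included — precisely the quantity that equals
the linear-probability generator's planted slope. In the local-vs-global
models (global STD, local STD(N), last SOA, each per +25 ms), odds
ratios follow the convention that OR > 1 means better performance at
*lower* variability, i.e. \(e^{-\beta}\) for the STD terms and
\(e^{+\beta}\) for the last SOA. Fitting a random slope where the
generator planted none puts the fit on the variance boundary; the
singular flag is expected there and the fixed effects remain valid.
Rater exclusion computes each subject's OLS slope of rating on condition
STD and applies Tukey fences (1.5 × IQR beyond the quartiles,
linear-interpolation quantiles); the "regression score" could also be
read as a correlation, but the slope keeps units interpretable and is
the convention here.

## Validation experiments and their sizes

The package validates itself with four experiments (`recover_global_slopes()`,
`staircase_calibration()`, `cluster_fwer()`, `wald_slope_type1()`), run
at these sizes in the test suite and the acceptance script:

* slope recovery: 20 replicate cohorts of 19 subjects × 12 blocks; the
  binomial model's average marginal effect and the identity-gamma slope
  are compared with the planted 0.6 pp and 5 ms per 25 ms;
* staircase calibration: 100 replicate staircases against a known
  listener, expected percent correct at the converged SNR compared with
  the ~80% working point;
* cluster family-wise error: 500 pure-noise datasets (19 participants,
  12 × 10 bins, 1000 permutations each);
* Wald type-I error: 500 null cohorts of 12 subjects × 120 targets.

The harness grid and null-cohort sizes are the package's choices: large
enough for the binomial Monte-Carlo error on a 5% rate to be a fraction
of the tolerance, small enough to keep the experiments at desk scale.

## What passing does not show

The generator plants clean linear effects with Gaussian subject
heterogeneity, no learning or fatigue across blocks, no hazard-rate
structure beyond what the SOA distribution induces, no lapses correlated
with time, and independent trials given the subject. Passing recovery
and error-control tests therefore demonstrates that the *machinery*
measures what it claims under the design's sampling scheme — not that
real listeners obey a linear-probability model, and not that the
original cohort's test statistics can be reproduced, since the human
data are not an input to this package.
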