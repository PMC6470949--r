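---
title: "Modeling swim-training periodization profiles with latent-class mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling swim-training periodization profiles with latent-class mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimperiod)
library(dplyr)
```

## Overview

`swimperiod` analyzes the weekly training of elite swimmers over the 25
weeks preceding each season's best performance. The analysis has four
layers: individualized intensity zoning from blood-lactate tests, the
normalized Total Training Load (TTL) statistic, latent-class linear mixed
model (LCMM) clustering of the TTL trajectories, and statistical
characterization of the resulting periodization profiles. This vignette
explains the models and the choices behind them.

## Load quantification

### Intensity zones

Each season's zones come from an incremental test (six 200 m swims at
increasing speed with capillary lactate after each stage). We model
log(lactate) as piecewise linear in speed between consecutive stages.
This interpolant is monotone wherever the measurements are, is exact at the
observed stages, and makes no parametric assumption about the lactate
curve; a two-parameter exponential, by contrast, cannot pass through three
arbitrary calibration points. Threshold speeds `v2`, `v4`, `v6` are where
the interpolant crosses 2, 4 and 6 mmol·L⁻¹. Crossings outside the observed
range use log-linear extrapolation of the terminal segment and are flagged;
upward extrapolation is capped at twice the final segment's speed range,
beyond which the threshold is reported missing rather than guessed.

Zone boundaries are closed on the upper end of I2 and I3: a speed exactly
at `v4` is classified I2 ("2 to 4 mmol·L⁻¹") and exactly at `v6` is I3
(">4–6"), matching the way the zones are conventionally phrased; maximal
sprint efforts are I5 regardless of speed. Speeds may optionally be shifted
by a user-supplied distance × rest-interval offset table before
classification. The magnitude of such corrections is method-specific and
not something we can supply defensibly, so the hook defaults to no
correction rather than inventing numbers.

### TTL and derived metrics

Within each swimmer-season, each of the five components (MHI, SI, EI in
meters; GC, ST in minutes) is rescaled to percent of its own season-maximum
week, and weekly TTL is the arithmetic mean of the five normalized
components. Two readings of "the five components" are possible — the five
practical categories (MHI/SI/EI/GC/ST) or the five in-water zones plus the
two dryland components. We adopt the five-category reading by default
because those are the declared practical notations of the quantification
scheme; `compute_ttl(mode = "seven_component")` provides the alternative.
A component that is zero for a whole season (e.g. no strength training) is
dropped from the mean and the season flagged; `absent = "fixed"` keeps the
five-way denominator instead.

Weeks are indexed backwards from the best performance (week 1 = final
week), which avoids calendar ambiguity and matches how taper-relative time
is usually displayed. Progressivity compares the mean of the first half
(weeks 25..13, 13 weeks) with the second half (weeks 12..1, 12 weeks);
positive delta means the load grows toward the competition. Week-to-week
variability is the mean absolute TTL change between consecutive weeks.

### Compositions

Mean intensity distributions are compositions (proportions summing to 1)
and are analyzed in isometric log-ratio (ilr) coordinates, which map the
simplex isometrically to Euclidean space so that standard multivariate
tests apply. We use the sequential-binary-partition basis (coordinate j
contrasts the geometric mean of the first j parts against part j+1); all
results that matter (Pillai's trace in particular) are invariant to this
choice, which the test suite verifies against a rotated basis. Zeros are
replaced multiplicatively before transforming, with
δ = 0.65 × the smallest observed non-zero proportion — standard
compositional practice.

## The latent-class linear mixed model

For subject i with TTL vector `y_i` observed at weeks `t`:

* class membership `c_i` is multinomial with probabilities `π_g`
  (intercept-only logits, `ξ_K = 0`);
* given class g, `y_i = X_i β_g + Z_i b_i + ε_i` with `X_i` a natural cubic
  spline basis in `week_before_bp` (intercept + interior knots at equally
  spaced quantiles of the observation times; 0 interior knots degenerates
  to a straight line), `b_i ~ N(0, B_g)` and `ε_i ~ N(0, σ² I)`.

The random-effects design defaults to a random intercept; an
intercept-plus-linear-slope design is available. The covariance search
covers a diagonal or unstructured `B` and a common (`B_g = B`) or
proportional (`B_g = w_g² B`, `w_K = 1` for identifiability) class
structure. "1–15 knots" is read as interior knots; with a random intercept
the diagonal and unstructured covariances coincide and the model grid
deduplicates them.

### Estimation

The marginal likelihood integrates the random effects analytically:
`y_i | g ~ N(X_i β_g, Z_i B_g Z_i' + σ² I)`, combined over classes with
log-sum-exp stabilization. Estimation is EM with the pair (class, random
effect) as missing data, which gives closed-form M-steps: weighted least
squares for `β_g` using the conditional random-effect means, moment updates
for `σ²` and `B` from the conditional second moments, and posterior means
for `π`. Under the proportional structure, `B` and the `w_g` are updated by
a short inner loop of exact conditional maximizations. Every step is an
exact (or generalized) EM step, so the marginal log-likelihood is
non-decreasing across iterations — asserted in the tests at every
iteration of every fit.

Convergence requires relative log-likelihood change below `tol` (default
1e-8) *and* maximum absolute parameter change below 1e-5, within 500 EM
iterations. The best EM solution is then polished by BFGS on the full
marginal likelihood under a log/Cholesky parameterization (logits for `π`,
log-Cholesky for `B`, log for `w` and `σ`), capped at 100 iterations; a
stationary point reached by the polish also counts as convergence, since EM
can stall short of its parameter-change criterion on flat likelihood ridges
(typically when a class is redundant). Variance floors (`σ ≥ 1e-4`, PSD `B`
by construction) prevent degenerate spikes on noise-free inputs.

Initialization fits per-subject least-squares curves, runs K-means on the
coefficients, and seeds additional starts with 20% multiplicative jitter
(default 10 starts; the validation studies use 2–3, which suffices at the
separations involved). After fitting, classes are relabeled by decreasing
mean fitted trajectory level; the likelihood is invariant to relabeling, so
this is purely a reporting convention. Posterior ties in the modal
assignment break toward the lowest class index and are counted.

### Model selection

`model_search()` mirrors the two-stage protocol: within each K the
AIC-minimal converged configuration (knots × covariance × class structure)
is retained, and BIC compares the per-K winners across K. The parameter
count is `(K−1)` logits + `K · p` spline coefficients + covariance
parameters (q, or q(q+1)/2 unstructured) + `(K−1)` proportional scalars +
1 residual SD, and BIC uses the number of *subjects* as N, appropriate for
a subject-level mixture; both counts are exposed in the search table so the
criteria are auditable. The full table is always returned: which K is
scientifically interpretable is a judgement the software should inform, not
make, so nothing beyond the BIC default is automated. Non-converged cells
stay in the table, flagged, and never win.

## The synthetic cohort generator

No training-log cohort of this kind is publicly deposited, so validation
uses `simulate_cohort()`, whose defaults *are* the study conditions for the
sprint stratum: 105 swimmer-seasons, 25 weeks, three classes with
proportions 0.53 / 0.24 / 0.23, relative-performance means 6.0 / 6.8 / 7.4%
(SDs 3.1 / 3.5 / 2.9%), and an in-water composition target of 88 / 8 / 4%
(MHI / SI / EI).

The three archetype mean curves are natural-spline interpolants through
hand-chosen control points: "long" (load peaks 21 and 5 weeks out,
progressive into the second macrocycle), "balanced" (peaks 19 and 10 weeks
out, degressive, high swing) and "stable_flat" (≈60% TTL with one mild peak
8 weeks out). They are qualitative fixtures, not measured data. Noise
levels were fixed a priori at `random_effect_sd = 6` and `residual_sd = 4`
TTL percentage points: an iid residual of SD 4 alone contributes
2σ/√π ≈ 4.5 points of week-to-week variation, placing simulated
variability in the 4–8% range reported for real profiles, and the resulting
class separation is consistent with the near-certain posterior
classification (≥91%) reported for the real cohort. The dryland composition
target (GC, ST) = (0.65, 0.35) and the component maxima (44,000 / 4,000 /
2,000 m·wk⁻¹ in-water, 130 / 70 min·wk⁻¹ dryland) are realistic choices
that reproduce plausible absolute weekly volumes at typical TTL levels.

Weekly volumes are back-computed from the latent TTL so the whole
quantification layer is exercised: the five normalized component series
equal the latent TTL plus mean-zero jitter, each component is anchored at
exactly 100% in one of the five highest-load weeks (the other components
are compensated in that week so the weekly mean is unchanged), and raw
meters/minutes are obtained through the component maxima. Re-running
`compute_ttl()` on the generated logs therefore reproduces the latent TTL
exactly, up to [0, 100] clipping, which is counted and reported. Latent
TTL is truncated to [0, 100] by clipping rather than resampling, because
TTL is a percentage by construction.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: dropout and missed weeks, within-swimmer
correlation across seasons (profiles are known to change from season to
season for most swimmers, and swimmer-seasons are generated independently),
non-Gaussian noise, measurement error in the lactate-based zoning, and any
systematic association between training profile and performance beyond the
class-dependent Pr distributions that are put in by hand.

## Profile characterization

Group comparisons report both one-way ANOVA and Kruskal–Wallis, with
Shapiro–Wilk per group and a Brown–Forsythe variance-homogeneity test
(ANOVA of absolute deviations from group medians, equivalent to Levene's
median-centered test) at α = 0.05 deciding which is marked primary — both
are always computed so the gate is transparent. Paired first/second-half
tests handle their degenerate cases explicitly (all-zero differences: t = 0
and an undefined Wilcoxon reported missing; constant non-zero differences:
unbounded t reported as infinite with a flag). No multiplicity correction
is applied by default, in keeping with the exploratory framing; a
Benjamini–Hochberg adjustment can be applied downstream via `p.adjust`.

Load peaks of a class-mean trajectory are not defined by any standard, so
the detector is deliberately simple and fully configurable: 3-point moving
average smoothing, local maxima with prominence ≥ 2 TTL points, minimum
separation 3 weeks, top two peaks by height, reported in chronological
order.

## Problem sizes used in validation

The test suite validates the likelihood against adaptive quadrature on tiny
instances (2–4 subjects, 3–5 weeks), single-class fits against `lme4`
maximum-likelihood estimates (20–25 subjects), and class recovery and model
selection on ten replicate cohorts of 105 seasons with a K = 1..4 ×
{2, 3, 5}-knot search grid; parameter recovery uses two-class cohorts of
250 seasons over three seeds. These sizes were chosen to exercise every
code path at the cohort scale the method targets while keeping the full
suite comfortably reproducible on a laptop.

## Limitations

* The LCMM assumes Gaussian outcomes and an intercept-only membership
  model; covariate-dependent membership, latent-process link functions and
  joint models are out of scope.
* TTL compresses five heterogeneous components into one mean; two very
  different trainings can share a TTL value.
* Classification-then-testing treats modal classes as known; posterior
  classification uncertainty is reported (mean posterior by class) but not
  propagated into the group tests, which is the standard, slightly
  anti-conservative practice.
* Associations between profiles and performance in either simulated or real
  data are descriptive, not causal.
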