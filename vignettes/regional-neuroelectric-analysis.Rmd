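---
title: "Methods: regional current densities, normative z-scores, and stepwise classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional current densities, normative z-scores, and stepwise classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megdens)
```

This vignette is the package's own account of the statistical model it
implements, the choices that were genuinely open, and what the test suite
does and does not demonstrate.

## The measurement model

The input is a table of per-region counts of validated brief dipole-current
events extracted from an MEG recording by an upstream solver, keyed to an
automated parcellation of 171 regions: 68 cortical parcels, the 68 adjacent
white-matter rims (≤ 5 mm shells paired one-to-one with the parcels), 17
subcortical structures, and 18 deep white-matter tracts. The cortical, rim
and subcortical regions partition the brain volume; the tracts overlap
white matter and are excluded from the partition, but their densities use
the same whole-brain totals.

**Density.** `compute_density()` forms
ρ = (count/count_total) ÷ (vol/vol_total) with `count_total` summed over
the partition regions only. Two exact consequences are tested as
invariants: counts proportional to volumes give ρ = 1 in every region, and
Σ ρ·(vol/vol_total) = 1 over the partition. Because the total is in the
denominator, ρ is invariant to overall solver yield and record length —
which also means a purely multiplicative "session quality" factor cancels
and cannot, on its own, correlate anything between recordings (this matters
for the empty-room model below).

**Atlas and z-scores.** `build_atlas()` stores the per-region mean and
sample SD (n − 1 denominator; the choice is ours — with reference cohorts
of hundreds the distinction is negligible, and the sample SD keeps the
self-z-scored reference at exactly unit variance). `zscore()` applies
z = (ρ − mean)/sd. Counts are non-negative, so on uncorrected densities no
z can fall below the floor −mean/sd, with equality exactly at count zero;
the suite checks this over 10⁴ simulated recordings. The z transformation
assumes approximate normality of reference densities; the floor itself
induces left skew in small regions, and no transformation is applied — the
floor is reported in the atlas (`floor_z`) instead so users can judge how
much sub-mean resolution a region has.

**Empty-room correction.** Solvers validate a non-trivial number of events
from empty-room recordings, and empty-room densities correlate with
same-day subject densities across a cohort. `fit_empty_room_model()`
estimates the per-region Pearson correlation over paired recordings and
`correct_density()` subtracts corr · ρ_empty. When subject and empty-room
densities have equal variance this is exactly the regression residual, so
corrected densities decorrelate from the empty room (tested at n = 600);
outside that regime the correction under- or over-shoots — in our synthetic
cohorts empty-room recordings have smaller totals, hence noisier densities
and larger variance, and the refit residual correlation comes out slightly
negative. That behaviour is inherent to a correlation-weighted (rather than
regression-weighted) correction and is left as is. Each cohort's
correlations are estimated within that cohort by default
(`share_norm_er_model` overrides). Corrected densities may be negative;
the floor property is asserted only pre-correction.

The default pipeline order is correction first, then atlas construction and
z-scoring on corrected densities (`correction_before_atlas = TRUE`). The
alternative order is configurable because the floor diagnostics are only
exact on uncorrected densities.

## Stepwise discriminant classification

`stepwise_lda()` implements classical two-group stepwise linear
discriminant analysis. For two groups Wilks' Λ over a variable set equals
1 − R² of the regression of the group indicator on that set, and the
discriminant partial F equals the regression partial F; the search
therefore runs as symmetric sweeps of the centered cross-product matrix of
[features, indicator], the classical computing scheme. Each step admits the
candidate minimizing Λ if its partial F ≥ `f_to_enter`, then removes any
entered variable whose partial F < `f_to_remove`.

Defaults and their reasons:

* `f_to_enter = 3.84`, `f_to_remove = 2.71` — the long-standing defaults of
  stepwise discriminant programs (χ²₁ critical values at 5% and 10%).
* `tolerance = 0.001` — a candidate must retain at least this fraction of
  its variance after projecting out the entered set. The tolerance is
  computed on the *within-groups* scatter (the discriminant convention):
  this is what guards the within-group covariance inverse used by the
  classification functions, whereas total-scatter tolerance does not.
* `max_regions` (default n/5) — an events-per-variable guard. A fixed
  F-to-enter with many candidates keeps admitting noise variables at small
  n until the error degrees of freedom are exhausted and the within-group
  covariance turns numerically singular; the cap prevents that. In the
  simulated study settings of the test suite the selection stops on its own
  well below the cap.

Classification uses Fisher's linear classification functions with equal
priors by default (keeping both rows of a confusion table symmetric under
unbalanced groups; `priors = "proportional"` is available). A model that
selects nothing falls back to the priors, with the deterministic tie-break
to the first group label under equal priors.

**Jackknife.** `jackknife_classify()` fixes the variable set selected on
the full sample and re-estimates only the classification-function
coefficients with each subject held out. This matches the standard
"leave-one-out classification" of the classical packages, and the suite
verifies it against a brute-force Mahalanobis re-fit. The semantics has a
known consequence the suite also measures: because the variable *set* was
chosen using all labels, selection leakage survives the jackknife, and on
label-exchangeable (null) cohorts with ~85 candidates the jackknifed
accuracy sits near 60% rather than 50% — the classical variable-selection
bias. Users comparing groups should therefore lean on the exact binomial
p-values of a *pre-registered* variable set, or on permutation approaches,
rather than reading a null jackknife table as unbiased.

**Significance.** `binomial_exceedance_p()` sums C(n,k)/2ⁿ over the tail
in log space (log-sum-exp over `lchoose`), exact far below double
underflow of individual terms. Two conventions exist: the default strict
exceedance P(X > correct) reproduces the p-values printed in classical
jackknifed classification tables (verified against nine independent
published rows in the acceptance tests); the inclusive P(X ≥ correct)
convention is available as `convention = "at_least"`. Percentages are
rounded half away from zero to one decimal, matching those tables.

**Scores.** Discriminant "scores" are the canonical variate scaled to unit
pooled within-group variance, oriented so the positive group scores
higher. Group differences are tested with Welch's unequal-variance t and
the Welch–Satterthwaite (conservative) df, one-sided toward the positive
group; Levene's F (center = mean) reports variance heterogeneity.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analyses assume, not raw MEG:

* Per subject, a stable log-activity latent per region:
  log(base) + planted cohort/symptom effect logs + N(0, `subject_noise_sd`)
  with `subject_noise_sd = 0.2` (≈ 20% between-subject regional variation, a
  realistic scale for count-derived physiological measures).
* Recording counts are multinomial over the partition regions with
  probabilities ∝ volume · exp(latent); totals are log-normal with mean
  `total_count_mean = 5e5` (the order of validated events per minute such
  solvers report) and CV 0.3, times a log-normal session-quality factor
  (`session_quality_sd = 0.3`) shared with the same-day empty-room
  recording.
* Dark counts: a share `dark_fraction = 0.05` of each subject recording is
  drawn from the day's dark propensities; the paired empty-room recording
  draws all its counts from them. Because densities are scale invariant, a
  shared factor on totals cannot induce subject↔empty-room density
  correlations; the generator therefore perturbs the dark propensities per
  region and session (`dark_latent_sd = 0.3`), shared between the two
  recordings of the day. This is the package's own mechanism choice; it
  reproduces the positive, mostly moderate correlations such studies plot.
* Follow-up latents correlate with baseline at `retest_rho` (default 0.45,
  a typical long-interval stability for such measures).
* Deep-tract counts are binomially thinned sums over the rims each tract
  overlaps (4 rims per tract, assigned deterministically in table order).
* Survey scores are integers derived from the same latent that decides
  symptom status, so a score ≥ cut-off coincides exactly with the planted
  brain effect. Cut-offs default to 15 (insomnia severity) and 63 (the
  three distress scales), with "positive" defined as score ≥ cut-off.
  Default clinical prevalences (0.47/0.43/0.31/0.46) match the
  screened-positive rates of the study design this emulates.
* One root seed feeds independent named streams (surveys, latents, totals,
  multinomials), so adding a stream never perturbs the others and equal
  spec + seed reproduce cohorts exactly.

What the generator does **not** emulate, hence what passing tests do not
show about real data: no spatial correlation between neighbouring regions
beyond compositional closure; rest and task share the same latent, so
short-term reliability comes out near 1 rather than the ~0.8 of real
recordings; survey scores are noiseless labels of the planted effect;
multiplicative effects on a closed composition slightly depress all other
regions, so cohort effects planted on a few regions leak weak signal
everywhere — visible in full-pipeline runs where non-planted regions enter
the classifier with negative signs.

## Numerical choices

* Chi-square differentials (`pair_chi2`) use the plain Pearson 2-cell
  statistic without continuity correction (counts run to thousands);
  1-df tails are kept as log₁₀ p down to and below 10⁻³⁰⁰ via
  `pchisq(log.p = TRUE)`. Pairs with fewer than 10 total counts are
  reported untestable. Raw counts are used — the statistic needs integers,
  and the empty-room correction produces non-integers.
* The binomial tail and the chi-square statistic are each verified against
  independent oracles (exhaustive coin-sequence enumeration for n ≤ 20;
  brute-force goodness-of-fit on 1000 random instances).
* All TSV writers emit numerics at 17 significant digits, so write→read
  round trips are bit-exact; writes go to a temporary file in the target
  directory and are renamed into place.
* Degenerate cases are explicit: zero-variance regions abort atlas
  construction (naming the region), force corr = 0 with a warning in the
  empty-room model, and mark reliability correlations `NA`.

## Problem sizes in the test suite

The simulated studies are scaled for a desk machine: planted-effect
recovery and null calibration run 20 seeds at n = 100 per group over the
85 cortical + subcortical features; reliability recovery runs 20 seeds of
80 subjects with full follow-up; the floor property uses 10⁴ low-count
recordings; the chi-square null uses 10⁵ pairs. The full suite completes
in well under a minute of compute; `scripts/acceptance.R` runs a complete
synthetic study (150 + 60 subjects) in seconds.

## Known limitations

* The correlation-weighted dark-count correction is only the exact
  regression residual under equal variances; with noisier empty-room
  densities it overcorrects slightly.
* Jackknifed accuracy after full-sample stepwise selection retains
  selection bias (≈ 60% on null cohorts at these candidate counts); see
  above.
* The normative atlas assumes approximate normality of reference densities
  and does not model the floor-induced skew.
* Survey cut-off strictness ("positive" at score ≥ cut-off) is a
  convention; instruments differ in how they phrase the boundary.
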