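---
title: "Saliva/plasma agreement analysis for lipid-peroxidation biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliva/plasma agreement analysis for lipid-peroxidation biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpoagree)
```

## The problem

Blood plasma is the reference medium for quantifying exercise-induced
oxidative damage, but drawing blood around training sessions is invasive.
Saliva can be collected repeatedly and non-invasively, so the practical
question is whether salivary concentrations of lipid-peroxidation (LPO)
products — diene conjugates (DC, primary products absorbing near 232 nm),
triene conjugates (TC, secondary, 278 nm) and Schiff bases (SB, end-stage
aldehyde-amine adducts, 400 nm) — *agree* with the plasmatic ones well
enough to substitute for them. "Agree" is a method-comparison question, not
a correlation question: two assays can correlate strongly while one reads
systematically higher (differential bias) or diverges proportionally with
concentration (proportional bias). This package implements the
quantification arithmetic and the complete agreement-statistics suite for a
repeated design in female athletes: each subject measured in the follicular
(F) and luteal (L) phases of one menstrual cycle, before and after
high-intensity interval exercise.

## Quantification model

Lipids are extracted into two phases — heptane (upper, neutral lipids) and
isopropanol (lower, phospholipids) — and each phase is read at four
wavelengths. The 220 nm absorbance (isolated double bonds) normalises each
phase, and fixed correction coefficients put the three analytes on their
relative-unit scales:

$$\mathrm{DC} = \left(\frac{OD_{232}^{up}}{OD_{220}^{up}} +
  \frac{OD_{232}^{lp}}{OD_{220}^{lp}}\right) \times 0.14,\qquad
  \mathrm{TC} = (\cdot) \times 0.16,\qquad \mathrm{SB} = (\cdot) \times 52.$$

Two consequences are load-bearing and are enforced by tests: each phase
enters only through within-phase ratios, so rescaling all four absorbances
of one phase (a dilution, a path-length change) leaves the result
unchanged; and the formulas are linear in the numerator absorbances, so
each analyte is strictly monotone in its own wavelength.

The equations as printed leave the placement of the coefficient
typographically ambiguous (it trails the second term). We apply it to the
*sum* of the two phase ratios: the three equations are structurally
parallel, and a per-term coefficient would leave the upper-phase term of
each equation uncorrected, making the shared "correction coefficient"
notion meaningless. The coefficients themselves have no published physical
derivation; they are treated as fixed assay constants and are overridable
(`coefficients` argument) for laboratories that calibrate differently.

Negative net absorbances (possible after blank subtraction) are rejected by
default so instrument problems surface; `clamp_negative = TRUE` clamps
numerators to zero with a warning. The normalising 220 nm absorbance must
always be positive. No rounding happens inside any computation.

## Agreement statistics

For each analyte x cycle-phase x timepoint stratum, the paired values are
oriented as x = plasma, y = saliva throughout (so the regression predicts
the salivary level from the plasmatic one, and a positive mean difference
means saliva reads higher).

**Ordinary least products (OLP) regression**, also called geometric-mean or
reduced-major-axis regression, is the appropriate line when *both*
measurements carry error: it minimises the product of vertical and
horizontal residuals, giving the symmetric estimator

$$b = \mathrm{sign}(r)\,\frac{s_y}{s_x},\qquad a = \bar y - b\,\bar x,$$

whose defining property — fitting y-on-x and x-on-y yields reciprocal
slopes — distinguishes it from OLS (tested as an invariant, together with
the exact identities $|b_{OLP}| = |b_{OLS}|/|r|$ and
$|b_{OLP}| \ge |b_{OLS}|$). The analytic confidence interval is the
standard geometric-mean-regression construction: with
$B = F_{1-\alpha;\,1,\,n-2}\,(1-r^2)/(n-2)$, the slope interval is
$b\,(\sqrt{B+1} \mp \sqrt{B})$ (mirrored for negative slopes), and the
intercept interval evaluates $a = \bar y - b^*\bar x$ at the opposing slope
endpoints. The literature does not fix one canonical OLP interval, so a
percentile bootstrap over subject resamples is exposed as an alternative
(`ci_method = "bootstrap"`); the test suite checks that the two
constructions agree in average width at n = 12. Bias classification
follows the interval logic: **differential bias** when the intercept CI
excludes 0, **proportional bias** when the slope CI excludes 1.

**Bland–Altman method of differences.** Differences $d_i = y_i - x_i$ are
summarised by their mean and sample SD (n − 1 denominator everywhere; the
context is inferential). Limits of agreement are fixed at
$\bar d \pm 1.96\,s_d$ — the conventional normal 95% multiplier, not a t
quantile; t quantiles on n − 1 df appear only in the confidence bands:
$\bar d \pm t\,s_d/\sqrt n$ for the mean difference and
$\mathrm{LoA} \pm t\,s_d\sqrt{1/n + 1.96^2/(2(n-1))}$ for each limit.
Differential bias is flagged when the mean-difference CI excludes 0 (the
line of equality falls outside it); proportional bias when the OLS slope of
differences on pair means $(x_i+y_i)/2$ has an interval excluding 0
(equivalently two-sided p < $\alpha$). A zero SD of differences collapses
the limits onto the mean difference; this is reported as a degenerate
result with undefined LoA bands rather than silent NaNs.

Pearson's r (with p from $t = r\sqrt{(n-2)/(1-r^2)}$) is reported per
stratum; Bonferroni adjustment multiplies p by an *explicit* family size
and caps at 1. The family is a parameter (rather than the length of the
p-value vector) because the natural family here — the 3 analytes within
one phase x timepoint stratum — need not equal the number of rows being
adjusted at once; `bonferroni_family = 1` disables adjustment.

## Inference and power

Within-group (post vs pre) comparisons use the paired t-test on
differences, with Cohen's $d_z = \bar d / s_d$ as the effect size — the
paired-design variant, not the pooled-SD between-group d, because only
$d_z$ is coherent with the design's power arithmetic: the t statistic is
$d_z\sqrt n$, so power flows directly from the noncentral t distribution
with df = n − 1 and noncentrality $d\sqrt n$. Two-sided tests are the
default throughout (the conservative choice when sidedness is not
pre-registered).

`power_paired_t()` evaluates $P(|T'| > t_{n-1,1-\alpha/2})$ exactly;
`required_effect_size()` inverts it by bisection on $d \in (0, 10]$ to
within $10^{-6}$ in power (power is strictly increasing in d, so bisection
is safe; the interval bound also guards against unattainable requests).
For the study's configuration — 12 pairs, $\alpha = 0.05$, power 0.80 —
the minimum detectable effect is:

```{r power}
required_effect_size(n = 12, alpha = 0.05, power = 0.80)
power_paired_t(d = 0.89, n = 12, alpha = 0.05)
```

Shapiro–Wilk normality checks *gate* rather than halt: the interval
constructions assume normal differences, but a failed check annotates the
output with a warning instead of aborting, since real field data may fail
the gate while the rest of the report remains useful.

## The synthetic cohort generator

No subject-level data accompany this design, so the generator is the
package's test bed: it emulates the *statistical structure* the analysis
assumes — nothing else. Per analyte, subject and stratum:

* plasma $= \mu_{stratum} + u_i + e$, with a subject random intercept
  $u_i \sim N(0, \mathrm{icc}\cdot\sigma^2)$ shared across the four strata
  (default ICC 0.5 — repeated measures on the same subject should
  correlate, which is what makes paired testing meaningful) and stratum
  noise $e \sim N(0, (1-\mathrm{icc})\sigma^2)$;
* saliva follows the conditional law at correlation $\rho$ with equal
  marginal SD, so the true agreement line is the identity (OLP slope 1,
  intercept 0) until bias is injected as
  $\text{saliva}' = \text{differential} + \text{proportional}\times\text{saliva}$;
* stratum means shift by $d\,\sigma$ for exercise (post > pre, default
  d = 1.5, large enough that pre/post tests at n = 12 are essentially
  always significant) and cycle phase (luteal > follicular, default
  d = 0.5, a direction-only claim at moderate size).

Defaults: 12 subjects; $\rho$ = 0.80 / 0.85 / 0.90 for DC / TC / SB — inside
the 0.77–0.97 band typical of saliva/plasma LPO correlations; scales
DC 0.45 ± 0.12, TC 0.35 ± 0.09, SB 250 ± 60 relative units. The scales are
synthetic order-of-magnitude choices consistent with the analytes'
intercept magnitudes in published agreement tables — they are **not**
measured study values, and nothing downstream depends on them beyond
positivity and feasibility of the OD inversion. Marginals are Gaussian by
default (matching the regime where all measured data pass Shapiro–Wilk); a
`lognormal` switch exists for robustness testing. Negative draws are
rejected and redrawn (count recorded in the `redraws` attribute) rather
than clamped, preserving distributional shape; at the default scales
redraws are essentially never needed. The seed is mandatory and the
generator restores the global RNG state, so cohorts are bit-reproducible
and never perturb the caller's randomness.

`cohort_to_od()` is the exact right-inverse of the quantification: it fixes
both 220 nm absorbances, splits each analyte's ratio-sum
$\mathrm{conc}/k$ between phases by a `split` fraction, and solves for the
numerator absorbances. Implied absorbances above a configurable cap
(default 3.0, beyond plausible spectrophotometer linearity) raise an
infeasible-OD error — with the default SB scale this means choosing
od220 values around 0.3, mirroring how a real assay's normalising
absorbance constrains the measurable ratio range.

What passing tests on this generator do and do not show: they validate the
*statistical machinery* (estimator identities, interval coverage, error
rates, round-trip exactness) under the design's assumed structure; they do
not validate the assay chemistry, the biological effect sizes, or behavior
under non-normal, heteroscedastic or unpaired real-world data.

## Numerical choices and validation scale

* OLP slope CI: F-based analytic formula; bootstrap cross-check in tests.
* LoA multiplier fixed at 1.96; t quantiles only for CI half-widths.
* Sample SD (n − 1) everywhere.
* Bisection tolerance $10^{-6}$ in power, with a $10^{-12}$ width guard.
* Degenerate inputs (zero variance, constant differences, r = 0) raise
  typed errors naming the offending quantity or comparison; they are never
  silent NaNs. Per-stratum failures in the batch suite mark the row and
  continue.
* Ties in stratum ordering: analytes DC, TC, SB, then phase F, L, then
  timepoint pre, post; unknown labels sort last.

The validation suite runs at deliberately chosen problem sizes: 1,000
random OD tuples for formula equivalence ($10^{-12}$), 1,000 random
cohorts for the OD round-trip ($10^{-10}$), 500 random datasets for the
OLP identities ($10^{-10}$), 5,000 simulated no-bias cohorts at n = 12 for
95% ± 2% interval coverage, 20,000 simulated paired tests for size
(0.05 ± 0.005) and power at d = 0.89 (0.80 ± 0.01), and 2,000 replicates
for the small-sample limits-of-agreement containment property.

## Limitations

* The OLP interval construction is one of several in use; at n = 12 the
  bootstrap alternative differs on individual datasets even though the two
  agree on average.
* The pipeline assumes one value per subject x fluid x stratum; replicate
  instrument readings must be averaged upstream.
* Bonferroni is the only multiplicity adjustment offered, matching the
  design's small family; nothing fancier is warranted at 12 strata.
* Non-parametric fallbacks (Wilcoxon) and repeated-measures models across
  the 2 x 2 design are out of scope: strata are analyzed independently.
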