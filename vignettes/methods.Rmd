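---
title: "Cage-level effect-size and decision-tree analysis of chronic feeding trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cage-level effect-size and decision-tree analysis of chronic feeding trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagetrial)
```

## The analysis problem

Chronic rodent feeding studies of whole foods — one-year trials with a
control diet, a comparator variety and a test article at two inclusion
rates, in male and female rats — produce hundreds of endpoint comparisons:
haematology, clinical biochemistry and urinalysis panels at several
sampling months, relative organ weights at necropsy, and weekly body-weight
and feed-consumption series. Two design facts drive everything in this
package:

1. **The cage is the experimental unit.** Animals are housed two per cage
   and share feed; all inference runs on cage means (cage totals for feed
   consumption, which is only recorded jointly). `cage_aggregate()`
   performs this reduction and is the boundary between the raw observation
   layer and every analysis.
2. **Effect sizes, not only p-values.** The primary comparison statistic is
   the standardized effect size (SES), the difference in group means
   divided by the pooled SD of the experimental units, with a 95%
   confidence interval. A CI is judged twice: against zero (statistical
   significance) and against biological relevance limits of ±1.0 SD — the
   effect magnitude the design was powered to detect.

## The SES model

For a treatment and control cell with cage counts $n_T$, $n_C$, means
$\bar{x}_T$, $\bar{x}_C$ and SDs $s_T$, $s_C$,

$$d = \frac{\bar{x}_T - \bar{x}_C}{s_p},\qquad
  s_p = \sqrt{\frac{(n_C-1)s_C^2 + (n_T-1)s_T^2}{n_C+n_T-2}},$$

$$\operatorname{se}(d) = \sqrt{\frac{n_C+n_T}{n_C n_T} +
  \frac{d^2}{2(n_C+n_T-2)}},\qquad
  \mathrm{CI} = d \pm 1.959964\,\operatorname{se}(d).$$

The joint classification against the limits $\pm L$ (default $L = 1$)
yields four cases: **a** (not significant, CI inside the limits), **b**
(significant, CI not entirely outside), **c** (significant and entirely
outside — potentially biologically relevant), **d** (not significant, but
containment in the limits not shown). Containment is open-interval and
"outside" strict, so a CI touching a limit falls to the conservative case
b or d. The four cases are exhaustive and mutually exclusive; the test
suite property-checks this over random intervals.

Two presentation choices were genuinely open and are exposed as options
with these defaults:

* **CI multiplier** — standard-normal $z$ by default (the large-sample
  form of the effect-size literature); `ci = "t"` switches to the
  $t_{n_C+n_T-2}$ quantile.
* **Small-sample bias** — `d` is reported uncorrected by default, because
  the SES is defined as the plain mean difference over the pooled SD;
  `hedges = TRUE` applies the $1 - 3/(4\,\mathrm{df} - 1)$ correction.

Degenerate zero-variance comparisons are returned flagged rather than
raised, so a whole-trial batch (`ses_batch()`) always completes.

### Power and sample size

`ses_power()` computes the power of the two-sided pooled-variance t-test
from the noncentral $t$ with $2n-2$ df and noncentrality $d\sqrt{n/2}$;
`required_n()` inverts it. At $d = 1$, $\alpha = 0.05$ and $n = 20$
experimental units per group the analytic power is ≈ 0.869, which is the
"85% chance of detecting 1.0 SD" design anchor; the acceptance suite
cross-checks this against a million-replicate simulation of the t-test
itself.

## The classical decision tree

`decision_tree_analyze()` reproduces the conventional gated procedure per
endpoint cell, at every level with $\alpha = 0.05$ two-sided:

1. **Gates** (quantitative endpoints only): Lilliefors-corrected
   Kolmogorov–Smirnov normality on the ANOVA residuals pooled across
   groups, and Levene's test (mean-centered by default; median centering —
   Brown–Forsythe — by option). Ordinal endpoints skip the gates.
2. **Parametric branch** (both gates pass): one-way ANOVA; if the omnibus
   F is significant, Dunnett-adjusted and unadjusted post hoc t
   comparisons against control.
3. **Nonparametric branch** otherwise: Kruskal–Wallis; if significant,
   pairwise Wilcoxon rank-sum tests against control.

The per-comparison `significant` flag of the tree is the Dunnett flag on
the parametric path and the Wilcoxon flag on the nonparametric path (the
procedure names ANOVA *with Dunnett* as its parametric arm; the unadjusted
t flags are reported alongside). Post hoc tests are gated on the omnibus
test by default; `run_single_method()` — used for the cross-method
comparison of ANOVA+t, ANOVA+Dunnett and KW+Wilcoxon over all endpoints —
runs ungated so the three methods see identical comparison sets.

Numerical choices:

* **Lilliefors p-values** come from a seeded Monte-Carlo null table of the
  KS statistic (10⁴ draws, cached per sample size; the null distribution is
  distribution-free given $n$). The internal seed is fixed: the table is a
  numerical constant, and user-level RNG state is left untouched. Note the
  table is built for iid samples; applied to ANOVA residuals the gate is
  very slightly conservative (residuals lose four means), which the test
  suite measures rather than assumes. With small interim cells (five cages
  per group) Levene's F is mildly liberal, so the parametric path is taken
  somewhat less often than the naive $(1-\alpha)^2$; the path-fraction
  property test therefore checks internal consistency with the two gates'
  observed rejection rates instead of asserting the naive product.
* **Dunnett adjusted p-values** are computed by deterministic
  Gauss–Legendre product quadrature (64 nodes per coordinate) of the
  control-variate representation of the many-to-one multivariate $t$:
  conditional on the shared control variate and the pooled-variance
  scale, the comparison statistics are independent. Accuracy is ~1e-5;
  tests compare against `mvtnorm::pmvt` and a 10⁶-draw max-|T| Monte-Carlo
  oracle.
* **Zero within-group variance** with unequal centers is reported as a
  capped statistic (`F = Inf`, `p = 0`, degeneracy flag), never an
  exception; all-tied cells give `H = 0`, `p = 1`.
* **Wilcoxon** is exact by enumeration when the combined sample is ≤ 20
  without ties, normal-approximated with tie and continuity corrections
  otherwise (the enumeration sweep up to $n_a + n_b = 12$ is part of the
  acceptance suite).

Assumption tests run per endpoint–gender–time cell (the alternative — once
per endpoint — is not what a cell-wise decision tree implies; this choice
is visible in the per-cell `normality_p`/`homogeneity_p` columns).

## Longitudinal AR(1) REML

Body weight, feed consumption and feed efficiency are cage-level series,
weekly for 13 weeks then biweekly. `fit_gls_ar1()` fits

$$y_{ct} = \beta_0 + \beta_{g(c)} + \beta_w t + e_{ct},\qquad
  \operatorname{cor}(e_{cs}, e_{ct}) = \rho^{|s-t|},$$

by REML: for fixed $\rho$ the model is GLS, and because AR(1) is Markov the
whitening transform is bidiagonal per cage (continuous-lag $\rho^{\Delta t}$
handles the unequal weekly/biweekly spacing); the profiled REML criterion is
then maximized over $\rho \in (-0.99, 0.99)$ by bounded scalar search
(tolerance 1e-6, deterministic). The AR order is read as 1 — the standard
choice for an unnamed "AR covariance" — and the fixed effects default to
group + continuous week with no interaction (`interaction = TRUE` adds it).
Genders can be analysed separately or pooled via `gender_col`.
`lsmeans()` returns model-adjusted group means at a chosen week with
delta-method standard errors; these feed `ses_estimate()` for the
least-square-mean body-weight SES entries. The implementation is
cross-checked against `nlme::gls(corCAR1)` in the test suite, and
`reml_profile()` lets tests verify the returned $\rho$ maximizes the
criterion.

## The synthetic-trial generator

No raw data ship with the package; the generator produces complete trials
with the hierarchical structure the analysis assumes, under the default
design (4 groups × 2 genders × 10 cages × 2 animals; panels at months 3, 6,
12 with 10 animals per group at interim months; weekly weights for 13 weeks
then biweekly to week 53).

For an endpoint with control mean $\mu$, cage-mean SD $\sigma$ and
within-cage share $w$, an animal value in a cage of $m$ animals is

$$y = \mu + \delta\sigma + u_{cage} + \varepsilon,\quad
  u \sim N(0, (1-w)\sigma^2),\quad
  \varepsilon \sim N(0, w\sigma^2 m),$$

so the cage mean has variance exactly $\sigma^2$ and the effect $\delta$ is
expressed on the cage-mean SD scale — the directly recoverable quantity of
the SES analysis, which is also the scale of the design's power statement.
Between- and within-cage shares are not identifiable from published
summary tables, so $w = 0.5$ is a documented convention. Default endpoint
means and SDs are anchored to control values typical of year-old Wistar
rats; growth asymptotes are calibrated to terminal control weights of
~594 g (males) and ~365 g (females). One global seed drives a per-endpoint
hash-derived stream, so trials are byte-reproducible and adding endpoints
never perturbs existing draws. Cage effects are drawn independently per
(cage, endpoint, time); panel endpoints carry no cross-time correlation —
longitudinal correlation lives in `simulate_growth()` (per-animal asymptote
variation) and `simulate_linear_panel()` (explicit AR(1) errors).

What passing tests on these data do and do not show: they demonstrate that
the estimators are calibrated (type-I error, CI coverage, parameter
recovery) and the pipeline is coherent under the *assumed* hierarchical
normal/lognormal world. They do not validate distributional realism of any
real endpoint, inter-endpoint correlation structure, or time trends in
panel endpoints, and the generator makes no attempt to reproduce actually
measured values of any particular study.

## Concordance accounting

`concordance()` compares methods over the common comparison universe by
binary significant/non-significant status: agreement(A, B) is the percent
of comparisons with identical status — the only reading under which a
near-complete agreement over ~600 comparisons is compatible with each
method flagging ~20. SES significance here means the CI excludes zero
(cases b or c), ignoring relevance. Degenerate cells are excluded from the
universe and listed in the manifest.

## Problem sizes and runtime choices

The default synthetic panel yields 594 endpoint comparisons (3 comparisons
× 2 genders × 99 endpoint–time cells), chosen to match the scale of a full
one-year study. Calibration studies in the tests and the acceptance script
use 2000 replicate cells at 10 cages per group; the Dunnett and power
oracles use 10⁶ Monte-Carlo draws; AR(1) recovery uses 500 replicate panels
of 2 groups × 10 cages × 20 weeks. These sizes keep Monte-Carlo error well
below the property tolerances while completing in minutes on one CPU.

## Known limitations

* No repeated-measures ANOVA, random-slope models or spline growth curves;
  the longitudinal model is fixed-effects GLS with AR(1) errors.
* No family-level corrections beyond Dunnett, matching the procedure it
  reimplements; no equivalence-testing (TOST) reinterpretation of the
  relevance limits.
* Ordinal (urinalysis-like) endpoints are supported by the generator and
  the nonparametric branch but excluded from default comparison counting.
* Units are carried as metadata and never converted; feed consumption is
  stored per cage-period as a total and per-animal feed is never imputed.
* Early sacrifice is represented simply as absent records after the kill
  date; cage values fall back to the surviving animal.
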