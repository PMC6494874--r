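---
title: "Multilevel meta-analysis of sexual-selection experiments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel meta-analysis of sexual-selection experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexselmeta)
```

## The scientific problem

Experimental evolution studies manipulate the strength of sexual selection
(for example by enforcing random monogamy, or by changing the adult sex
ratio) and, after some generations, measure a fitness component — female
reproductive success, offspring viability, lifespan, immunity, extinction
rate, and so on. Each study contributes one or more treatment comparisons:
a high-sexual-selection group versus a low one. Synthesising these
comparisons asks two questions: does sexual selection change the *mean* of
fitness traits, and does it change their *variance*? Both must be answered
while respecting the data's hierarchy — effect sizes cluster within
studies, fitness components and taxa — and its heteroscedasticity — every
comparison carries its own known sampling variance.

This package implements the full chain: effect-size computation from
heterogeneous study summaries, multilevel random-effects meta-regression by
REML, heterogeneity partitioning, variability meta-analysis, and
publication-bias diagnostics, plus a synthetic-data generator so that every
stage can be validated against known ground truth.

## Effect-size measures

For a comparison with group summaries $(m_h, s_h, n_h)$ and
$(m_l, s_l, n_l)$:

* **Hedges' g.** $d = (m_h - m_l)/s_p$ with
  $s_p^2 = \big[(n_h-1)s_h^2 + (n_l-1)s_l^2\big]/(n_h+n_l-2)$, corrected
  for small-sample bias by $J = 1 - 3/(4\,\mathrm{df} - 1)$,
  $\mathrm{df} = n_h+n_l-2$, so $g = J d$ with sampling variance
  $J^2\!\left[\frac{n_h+n_l}{n_h n_l} + \frac{d^2}{2(n_h+n_l)}\right]$.
  When only a test statistic is reported, $d$ is reconstructed from $t$
  ($d = t\sqrt{(n_h+n_l)/(n_h n_l)}$), from a one-way $F$ with one
  numerator df ($d = \sqrt{F(n_h+n_l)/(n_h n_l)}$, signed by the recorded
  direction), from a 1-df $\chi^2$ through the phi coefficient
  ($r = \sqrt{\chi^2/N}$, $d = 2r/\sqrt{1-r^2}$), or from two proportions
  through the Cox logit transform
  ($d = [\mathrm{logit}(p_h)-\mathrm{logit}(p_l)]/1.65$). A proportion of
  exactly 1 (or 0) would produce an infinite logit; the implementation
  subtracts (or adds) one to the underlying numerator count, which
  requires the group size and errors without it. $F$ with more than one
  numerator df and $\chi^2$ with more than 1 df are rejected outright:
  they have no unique mapping to a two-group difference.
* **lnRR** $= \ln(m_h/m_l)$, variance
  $s_h^2/(n_h m_h^2) + s_l^2/(n_l m_l^2)$; requires positive means.
* **lnCVR** $= \ln\big[(s_h/m_h)/(s_l/m_l)\big]$ — relative variability,
  controlling for the mean–variance relationship. Its variance allows a
  within-group mean–SD correlation $\rho$ (default 0, settable, since the
  appropriate value is rarely reported).
* **lnVR** $= \ln(s_h/s_l) + \frac{1}{2(n_h-1)} - \frac{1}{2(n_l-1)}$ —
  absolute variability, bias-corrected, variance
  $\frac{1}{2(n_h-1)} + \frac{1}{2(n_l-1)}$.

All raw effects are computed as high minus low sexual selection and then
sign-oriented: traits negatively related to fitness (parasite load,
mutation load, extinction risk/rate, male mating latency, senescence rate;
an editable packaged list) have their sign inverted so that positive always
means higher fitness under sexual selection. The ratio measures need full
group summaries; `compute_effect_sizes()` counts and reports skipped
records rather than failing.

## The multilevel model

Effects $y_i$ with known sampling variances $v_i$ follow

$$y = X\beta + \textstyle\sum_l Z_l u_l + \varepsilon,\qquad
  u_l \sim N(0, \sigma^2_l I),\quad \varepsilon_i \sim N(0, v_i),$$

with random levels chosen from study, fitness component (trait), taxon and
an observation-level ("effect") term. The observation-level term carries
residual heterogeneity — heterogeneity not attributable to any grouping —
and is essential in practice: without it, multilevel partitions of
ecological datasets misattribute most of their (typically very large)
heterogeneity. `reml_mv()` maximises the restricted log-likelihood

$$\ell_R(\sigma^2) = -\tfrac12\Big[\ln|V| + \ln|X^\top V^{-1}X| +
  (y - X\hat\beta)^\top V^{-1}(y - X\hat\beta)\Big],\qquad
  V = \mathrm{diag}(v) + \textstyle\sum_l \sigma^2_l Z_l Z_l^\top,$$

over $\log\sigma^2_l$ (floor $10^{-10}$) by quasi-Newton iteration with
restarts from 0.001 and from 0.1× and 1× a method-of-moments start, then a
polish restart from the best optimum. Components that finish at the floor
are reported as exactly zero. A solution is declared converged when the
optimiser reports success or when a restart from the optimum cannot improve
the objective by more than $10^{-6}$ — the latter matters because boundary
estimates routinely make quasi-Newton codes report "singular convergence"
at the true optimum. Inference is Wald-normal ($z = \hat\beta/SE$,
two-sided $p$, CIs at $\pm 1.96\,SE$), with no small-sample adjustment,
matching the convention of the literature this package serves. Setting
`sigma2 = 0` reproduces fixed-effect inverse-variance weighted least
squares exactly, which the tests exploit.

Moderator designs use treatment coding with reference levels *male* (sex)
and *benign* (environment), so a sex-by-environment model has six
coefficients: intercept (male/benign cell), female, both-sexes, stressful,
and the two interactions. `contrast()` computes $L^\top\hat\beta$ with
$SE = \sqrt{L^\top \hat\Sigma_\beta L}$; the standard hypothesis tests
(female vs male per environment, stressful vs benign per sex) are bundled
in `standard_contrasts()`. `predict_levels()` gives per-cell predictions;
`per_trait_models()` fits separate intercept-only models (random: study,
taxon) per fitness component with more than three effects, listing the
rest as skipped.

## Heterogeneity

The multilevel $I^2$ uses the typical sampling variance
$\bar v = (k-1)\sum w_i / [(\sum w_i)^2 - \sum w_i^2]$, $w_i = 1/v_i$, and
expresses each component as
$I^2_l = 100\,\hat\sigma^2_l/(\sum_m \hat\sigma^2_m + \bar v)$, so the
per-level values sum exactly to the total. Confidence intervals, when
requested, come from a seeded parametric bootstrap (resimulate $y$ from
the fitted model, refit, percentile interval); the default is B = 1000 for
reporting, and the construction is labelled in the result since other
authors use posterior or Q-profile intervals. Levels estimated at zero
report $I^2 = 0$ with a degenerate lower bound at 0.

## Publication-bias diagnostics

`egger_test()` implements the classical Egger regression — standardised
effect $y_i/\sqrt{v_i}$ on precision $1/\sqrt{v_i}$, intercept tested with
a two-sided normal $z$ — plus a multilevel variant (the standard error as
a moderator inside the random-effects model) behind a flag, because
published asymmetry tests do not always state which form was used.
`trend_regression()` fits unweighted least squares of effect on
publication year or journal impact factor, dropping rows with a missing
covariate (df = usable records − 2), with a precision-weighted option.
`funnel_table()` exports plot-ready points and pseudo-CI envelopes
($\pm 1.96\,s$ and $\pm 3.09\,s$). One caveat the simulations make vivid:
with strong heterogeneity, Hedges'-g sampling variances depend on the
effect itself, so Egger's test can flag asymmetry without any selective
publication; under a genuinely symmetric funnel its type-I error is
nominal (checked by simulation in the test suite).

## The synthetic-data generator

`simulate_dataset()` draws, per record, a true effect
$\theta_i = x_i^\top\beta + u_{study} + u_{trait} + u_{taxon} + u_{effect}$
and then two-group normal summaries whose standardised difference targets
$\theta_i$: group means are sample means of $n$ normal draws and group SDs
come from the matching scaled-$\chi^2$ distribution, so computed effects
have the correct first-order sampling distribution and the analytic
variance formulas apply. Group SDs are proportional to group means
(SD = CV × mean, CV drawn from `cv_range`), inducing the positive
mean–variance relationship typical of fitness data — this is what makes
lnCVR and lnVR genuinely different measures. The high-group mean is the
exact solution of $(\mu_h-\mu_l)/\sigma_{pool} = \theta_i$ under that CV
link (falling back to a homoscedastic shift for the rare extreme effects
where no solution exists). One global seed drives everything, with a
deterministic per-record seed split so identical configs are byte-identical
and record subsets can be regenerated.

Defaults (group sizes 10–50 per arm, CV 0.2–0.5, baseline means log-uniform
on 5–50, 1–8 effects per study) were chosen once as representative of
invertebrate experimental-evolution studies. `simulate_paperlike()`
produces a dataset with the marginal structure of a complete synthesis:
459 effects from 65 studies (a fixed right-skewed partition, 1–30 per
study), 22 fitness components, 7 taxa, sexes 189/219/51
(male/female/both), environments 92/337/30 (stressful/benign/undefined),
fitness classes 174/141/144 (direct/indirect/ambiguous) and 354 records
with full summaries, the rest carrying a back-computed $t$ statistic. Its
variance components (study 0.55, trait 0.01, taxon 0.03, observation 0.90)
were set to mirror the very high heterogeneity ($I^2 \approx 95\%$)
typical of ecological meta-datasets. Note that these published marginal
counts are mutually inconsistent with the published moderated-subset size
(direct + indirect = 315 < 330), so the generator reproduces the
marginals and lets the subset fall where it falls (≈295); subset counts of
real deposited data are properties of that file, not of the generator.

What the generator does *not* emulate: non-normal outcome distributions,
correlated effect sizes within a shared control group, digitisation error,
selective reporting, or real phylogenetic structure. Passing tests on
synthetic data therefore validate the estimators under the model's own
assumptions; they cannot certify robustness to violations of those
assumptions in real data.

## Numerical choices and validation

* Optimisation on the log-variance scale, relative objective tolerance
  $10^{-12}$, three starts plus a polish restart; boundary components
  reported as 0.
* The balanced single-level case has a closed form
  ($\hat\sigma^2 = \max(0, SS/(k-1) - v)$), which the optimiser must
  reproduce to $10^{-6}$; randomized instances are additionally checked
  against a 20-point grid around the optimum.
* Independent cross-checks: fits agree with `metafor::rma.mv` to about
  six significant figures in $\beta$, $SE$ and $\sigma^2$, and converters
  agree with `metafor::escalc` (exactly for lnRR/lnVR/lnCVR; to ~$10^{-4}$
  for Hedges' g, where metafor applies the exact gamma-ratio correction
  while this package uses the standard $1 - 3/(4\,\mathrm{df}-1)$
  approximation, following the conversion tools used in this literature).
* Monte-Carlo calibration in the test suite uses 200 replicate datasets of
  200 studies × 3 effects for parameter recovery, and 5000 replicates of
  k = 100 for the Egger type-I experiment — sizes chosen to keep the
  Monte-Carlo error a small fraction of the quantities under test while
  the suite stays fast.

## Known limitations

* With the classical Hedges'-g variance formula, $\hat v_i$ depends on
  $\hat d_i^2$; realized large deviations partially inflate their own
  sampling variance, and the formula omits the $df/(df-2)$ inflation of
  the exact variance. The net effect, measured by simulation at group
  sizes of 10–50, is a small downward bias in variance components (about
  −0.0013 on a true $\sigma^2_{study} = 0.04$, i.e. ~3%) that is shared
  exactly by `metafor::rma.mv` on the same data. It shrinks roughly like
  $1/n$ in the group sizes. $\hat\beta$ and its CI coverage are
  unaffected to Monte-Carlo precision.
* Wald-normal inference does not apply small-sample corrections; per-trait
  models with few effects should be read with that in mind.
* The lnCVR mean–SD correlation $\rho$ defaults to 0; if group-level
  replicate data are available, estimating $\rho$ and passing it through
  `compute_effect_sizes(..., rho = )` is preferable.
* No phylogenetic covariance: taxa enter as an exchangeable grouping
  factor only, appropriate when the taxon pool is small and diverse.
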