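---
title: "Heavy-tailed random effects for area-level small area estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-tailed random effects for area-level small area estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhstable)
```

## The model

Area-level small area estimation starts from one direct survey estimate per
domain, $y_i$, with a known design-based sampling variance $\psi_i$, and
borrows strength across domains through covariates and random effects:

$$y_i = x_i^\top\beta + v_i + e_i,\qquad e_i \sim N(0, \psi_i),\quad
i = 1,\dots,m.$$

The classical Fay–Herriot choice $v_i \sim N(0, \sigma_v^2)$ shares one
variance across all areas, which is exactly what breaks down when a few
areas behave very differently from the rest: a Gaussian random effect
cannot reach a gross outlier without inflating every other area's
variance. `fhstable` replaces the Gaussian law with a symmetric
$\alpha$-stable one,

$$v_i \sim S(\alpha,\, 0,\, \gamma_1,\, 0),\qquad \alpha \in (0,2],$$

whose tail index $\alpha$ interpolates between the Cauchy ($\alpha=1$) and
the Gaussian ($\alpha=2$). For $\alpha<2$ the variance is infinite and the
tails are polynomial, so a handful of extreme areas costs the model very
little while ordinary areas are shrunk as usual.

Stable laws have no closed-form density; everything here works through two
facts:

1. **Characteristic function.** In the 1-parameterization used throughout
   (`sas_cf()`), $\varphi(w) = \exp(-|\gamma_1 w|^\alpha)$ for the
   symmetric case. A consequence worth stating explicitly because it is a
   common source of confusion: $S(2, 0, \gamma, 0)$ is Gaussian with
   variance $2\gamma^2$, not $\gamma^2$ — the package follows the
   characteristic function, and all scale conversions are documented where
   they occur.
2. **Scale mixture of normals.** If $P$ is positive stable with tail index
   $\alpha/2$, standardized so that $E\,e^{-tP} = e^{-t^{\alpha/2}}$, and
   $Z \sim N(0,\sigma^2)$ independently, then $\sqrt{P}\,Z \sim
   S(\alpha, 0, \sigma/\sqrt2, 0)$. Writing $v_i \mid \lambda_i \sim
   N(0, \lambda_i \gamma)$ with $\gamma = 2\gamma_1^2$ and
   $\lambda_i$ positive stable with index $\alpha/2$ turns the intractable
   model into a conditionally Gaussian one.

The mixture form is a global–local shrinkage prior: $\gamma$ is the global
scale shared by all areas, and the heavy-tailed $\lambda_i$ lets an
individual area escape shrinkage when its data demand it.

Priors: $\beta \sim N(\mu_\beta, \Sigma_\beta)$ with
$\mu_\beta = 0,\ \Sigma_\beta = \mathrm{diag}(10^5)$ (effectively flat),
$\gamma \sim IG(a, b)$, and $\alpha \sim U(0, 2]$. The inverse-Gamma
hyperparameters are unspecified in the design this package follows beyond
"noninformative"; the default $a = b = 0.01$ is the standard weakly
informative choice and both are exposed in `prior_spec()`.

## The sampler

`fit_fhas()` cycles, per sweep, through

* `beta`: a $p$-variate Gaussian full conditional (GLS with a ridge from
  the prior);
* `v`: independent Gaussians with shrinkage weight
  $\delta_i = \lambda_i\gamma/(\lambda_i\gamma + \psi_i)$, mean
  $\delta_i(y_i - x_i^\top\beta)$ and variance $\delta_i\psi_i$;
* `gamma`: $\gamma^{-1} \sim
  \Gamma\!\big(m/2 + a,\ \textstyle\sum_i v_i^2/(2\lambda_i) + b\big)$;
* `lambda`: each $\lambda_i$ exactly, by rejection: propose from the
  positive-stable prior and accept against the likelihood bound
  $N(v\mid 0, s) \le (2\pi v^2)^{-1/2}e^{-1/2}$ (the supremum over the
  variance $s$, attained at $s = v^2$);
* `alpha`: a uniform random-walk Metropolis–Hastings step (half-width
  0.15 by default) with acceptance ratio
  $\prod_i f_{\alpha'/2}(\lambda_i)\,/\,f_{\alpha/2}(\lambda_i)$;
  proposals outside $(0, 2]$ are rejected outright, which implements the
  uniform prior's support.

Setting `prior_spec(alpha_fixed = )` pins the tail index and skips the
Metropolis step — the "known tail index" variant used in the Scenario-3
coverage runs.

All five updates are implemented once, in compiled code; the exported
`update_*()` functions call the same routines the full chain uses, and a
test asserts that one compiled sweep equals the composed single updates
draw for draw under the same seed. The Gaussian (`fit_fh_normal()`) and
Student-t (`fit_t()`) baselines are thin R loops over the same compiled
conditionals with $\lambda_i\gamma$ replaced by $\sigma_v^2$ and
$w_i\sigma^2$ respectively, so the shrinkage code path exists — and is
tested — exactly once.

### Numerical choices

**Positive-stable density.** The Metropolis ratio needs
$f_{\alpha/2}(\lambda)$, which has no closed form. It is evaluated through
the Zolotarev single-integral representation
$$f(x) = \frac{s}{\pi}\, x^{-(1+s)} \int_0^\pi A(u)\,
e^{-A(u)\,x^{-s}}\,du, \qquad s = \frac{a}{1-a},$$
with $A$ the Zolotarev auxiliary function. The integrand is unimodal in
$u$; the implementation locates the mode by bisection on the monotone
$\log A$, brackets the region where the log-integrand is within 60 of its
maximum, and applies Gauss–Legendre quadrature (96 nodes per panel, two
panels split at the mode) with the exponent normalized by the node maximum
so nothing can overflow even when the log-integrand spans thousands of
units. Against the closed-form tail-index-$1/2$ law the error is at
machine precision over $x \in [10^{-3}, 10^2]$ and below $10^{-5}$
relative in the extreme far tail; the density integrates to one within
$10^{-4}$ for $a \in \{0.3, 0.55, 0.9\}$. An early design sketch cached
the density on an $(x, a)$ grid with interpolation; direct evaluation
turned out to cost only microseconds, so the cache was dropped — it would
have added interpolation error to the acceptance ratio for no measurable
speed gain.

**Samplers.** Symmetric stable draws use the Chambers–Mallows–Stuck
construction (`sample_sas()`), positive-stable draws use Kanter's
representation (`sample_positive_stable()`); both consume R's global RNG
stream, so chains are bit-reproducible under `mcmc_control(seed = )`.

**Degeneracies.** Two are handled explicitly. When $|v_i| < 10^{-8}$ the
rejection bound is infinite but the likelihood is flat, so $\lambda_i$ is
drawn from its prior (the exact limit). Small-but-nonzero residuals are
the harder case: the acceptance probability is proportional to $|v_i|$,
so the sampler caps attempts at $10^5$ per area and sweep and then falls
back to an inverse-CDF draw on a 512-point log-spaced grid of the target,
counting and reporting every fallback. At the Gaussian boundary the
mixing law degenerates to a point mass, so the tail index is clamped at
$2 - 10^{-6}$ inside the mixing-density evaluations; the exact
$\alpha = 2$ model is the Gaussian baseline.

**Initialization.** $\beta$ at its GLS estimate, $v = 0$, $\gamma = 1$,
$\lambda = 1$, $\alpha = 1.5$ (or the fixed value). Chain defaults are
20000 sweeps with 10000 burn-in; at $m \le 100$ this runs in seconds and
posterior summaries are stable.

## What the simulator emulates

`generate_scenario()` reproduces a four-scenario comparison design: a
shared mean structure (intercept plus one $N(10, \mathrm{sd}\,2)$
covariate, $\beta = (20, 1)^\top$, sampling variances allocated equally
over the grid $\{0.5, 1, \dots, 5\}$) crossed with four random-effect
laws — Gaussian, $t_3$, symmetric stable $(\alpha = 1.1,\,
\gamma_1 = 1/2)$, and Pareto(5, 2). The printed source for this design
lists an eleven-value variance grid including 0, but a zero-variance area
would make its direct estimate exact, and the direct-estimator error
levels the design reports (ASD $\approx 2.76$, AAD $\approx 1.27$) match
only the ten-value grid, whose analytic anchors are
$\bar\psi = 2.75$ and $\overline{\sqrt{2\psi/\pi}} \approx 1.268$. The
ten-value grid is therefore the default and any grid can be passed
explicitly. The stable scenario's scale is read as $\gamma_1 = 1/2$. The
covariate is drawn fresh for each replicate.

What the simulator does *not* emulate about real survey data: estimated
(not known) sampling variances, design effects and survey weights,
spatial correlation between neighbouring areas, and non-Gaussian sampling
error in small domains. Tests passing under these scenarios show the
sampler targets its posterior and the estimators behave as designed under
the stated laws — not that the model is correct for any particular
survey.

## Evaluation tools

`deviance_measures()` computes AAD/ASD/ARB/ASRB against the truth;
`coverage_rate()` the empirical coverage of equal-tailed credible
intervals; `run_study()` averages everything over replicates with the
direct estimator ($\hat\theta_i = y_i$) as a reference row.

`compute_dic()` uses the *conditional* DIC, with deviance
$D(\beta, v) = -2\sum_i \log N(y_i \mid x_i^\top\beta + v_i, \psi_i)$ and
$p_D = \bar D - D(\bar\beta, \bar v)$. Conditioning on the random effects
is the standard choice when comparing random-effects fits with known
sampling variances; a marginal DIC would differ by a model-dependent
offset, so comparisons between models fitted to the same data are the
meaningful output, not levels.

`loo_cv()` refits the model leaving each area out in turn and predicts
the held-out mean as $x_i^\top E[\beta \mid y_{(-i)}]$, the posterior
predictive mean with the random effect integrated out at its prior
center. The source analysis this follows does not define the held-out
predictor operationally; this choice is the natural one under the model
and is stated here so the resulting CV numbers are interpretable.

## Known limitations

* The degrees-of-freedom posterior of the Student-t baseline is weakly
  identified at $m \le 100$: single replicates generated from $t_3$
  routinely support df anywhere between 2 and 30. The package's tests
  therefore check the df posterior comparatively (paired replicates,
  t-generated versus Gaussian-generated data) rather than asserting
  concentration from one data set.
* Skewed stable laws ($\beta_{\text{skew}} \neq 0$ beyond the totally
  skewed positive branch), multivariate stable effects, spatial
  correlation, and stable-parameter estimation outside the model's
  sampler are out of scope.
* For $\alpha$ fixed very near 2 the mixing variables concentrate at 1
  and the rejection fallback fires more often; this is reported in the
  fit's `lambda_attempts` and is the reason exact-Gaussian comparisons
  should use `fit_fh_normal()`.

## Problem sizes used in the shipped checks

The package's own end-to-end checks run the four-scenario machinery at
$m = 20$ with 20 replicates and 10000-sweep chains (50 replicates for the
MCMC-free direct-estimator anchors), sizes at which the replicate means
are stable to a few percent while a full check run completes on one core
in minutes. Larger designs ($m = 50, 100$, 50 replicates, 20000 sweeps)
are a matter of changing `scenario_config()` and `mcmc_control()`
arguments.
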