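---
title: "Normal inverse Gaussian shrinkage regression: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal inverse Gaussian shrinkage regression: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigreg)
```

## The problem

Drug sensitivity prediction from cancer cell line panels couples a
multivariate response (one sensitivity value per drug, typically log IC50)
to a high-dimensional molecular feature matrix shared across drugs.  Two
structural facts distinguish this from D independent regressions: the
responses share the feature matrix, so regularisation strength can be pooled
across drugs; and external information is often available on both axes —
per-feature co-data such as pathway membership or external p-values, and
per-drug co-data such as developmental stage.  `nigreg` models both.

## Model

For cell lines $i = 1,\dots,n$, drugs $d = 1,\dots,D$ and centred features
$x_i \in R^p$,

$$y_{id} = x_i^\top \beta_d + \varepsilon_{id}, \qquad
  \varepsilon_{id} \sim N(0, \sigma_d^2),$$

with the global–local shrinkage prior

$$\beta_{jd} \mid \gamma_{jd}^2, \tau_d^2, \sigma_d^2
    \sim N(0,\, \gamma_{jd}^2 \tau_d^2 \sigma_d^2), \qquad
  \gamma_{jd}^2 \sim IG(\phi_{jd}, \lambda_{feat}), \qquad
  \tau_d^2 \sim IG(\chi_d, \lambda_{drug}),$$

and the objective Jeffreys prior $\pi(\sigma_d^2) \propto \sigma_d^{-3}$
(derived treating mean and variance jointly unknown, which avoids the
sensitivity of vague inverse-gamma priors in flat-likelihood regimes).
$IG(\phi, \lambda)$ is the inverse Gaussian distribution with mean $\phi$
and shape $\lambda$.  Mixing a normal over an IG variance gives the normal
inverse Gaussian (NIG) marginal: heavier-tailed than Gaussian, with prior
kurtosis (excluding the noise factor)

$$K(\beta_{jd}) = 3\,(1 + \phi_{jd}/\lambda_{feat})(1 + \chi_d/\lambda_{drug}),$$

computed by `nig_prior_moments()`.  In shrinkage-weight form
$\kappa = 1/(1+\gamma^2)$ the implied prior (`dkappa_nig()`) can place mass
near both no-shrinkage ($\kappa = 0$) and full-shrinkage ($\kappa = 1$), the
hallmark of a useful global–local rule.

External covariates enter through reciprocal-linear mean models

$$\phi_{jd} = (c_{jd}^\top \alpha_{feat})^{-1}, \qquad
  \chi_d = (z_d^\top \alpha_{drug})^{-1},$$

with intercepts always included; the intercept is interpretable as the
expected prior precision at zero covariates, and each coefficient as an
additive effect on expected prior precision.  Unpenalized covariates (e.g.
tissue indicators) can be added with a flat prior; they are excluded from
all variance-component updates.

## Variational Bayes E-step

Per drug, the mean-field factorisation
$q(\beta)\,q(\gamma^2)\,q(\tau^2)\,q(\sigma^2)$ has optimal factors

* $q(\beta_d) = N_p(\mu_d, \Sigma_d)$,
* $q(\gamma_{jd}^2) = GIG(-1,\ \lambda_{feat}/\phi_{jd}^2,\ \delta_{jd})$,
* $q(\tau_d^2) = GIG(-(p+1)/2,\ \lambda_{drug}/\chi_d^2,\ \eta_d)$,
* $q(\sigma_d^2) = \text{inverse-gamma}((n+p+1)/2,\ \zeta_d)$,

where the GIG convention throughout the package is
$GIG(p, \nu, \eta) \propto x^{p-1} e^{-(\nu x + \eta/x)/2}$.  This
convention was fixed by consistency with the expectation identities the
coordinate updates require: with it,
$E(1/\gamma^2) = \sqrt{(\lambda/\phi^2)/\delta}\,
K_0(\sqrt{\delta\lambda/\phi^2})/K_1(\sqrt{\delta\lambda/\phi^2})
+ 2/\delta$, which is exactly the form used in `vb_expectations()`, and the
IG prior is the $GIG(-1/2, \lambda/\phi^2, \lambda)$ special case
(`ig_to_gig()`), verified against quadrature in the test suite.

The cyclic updates implemented in `nig_vb()` are, writing
$a = E(1/\sigma^2)$, $b_j = E(1/\gamma_j^2)$, $g = E(1/\tau^2)$:

$$\Sigma = a^{-1}\,(X^\top X + g\,\mathrm{diag}(b))^{-1}, \qquad
  \mu = (X^\top X + g\,\mathrm{diag}(b))^{-1} X^\top y,$$
$$\delta_j = a g (\mu_j^2 + \Sigma_{jj}) + \lambda_{feat}, \qquad
  \eta = a \textstyle\sum_j b_j (\mu_j^2 + \Sigma_{jj}) + \lambda_{drug},$$
$$\zeta = \tfrac12\big[y^\top y - 2 y^\top X \mu + \mathrm{tr}(X^\top X \Sigma)
  + \mu^\top X^\top X \mu + g\,\mathrm{tr}(\mathrm{diag}(b)\Sigma)
  + g\,\mu^\top \mathrm{diag}(b) \mu\big],$$

followed by refreshing $(a, b, g)$ from the factor parameters.  The update
order is $(\mu, \Sigma) \to \delta \to b \to \eta \to g \to \zeta \to a$:
$\delta$ uses the previous $g$, while $\eta$ uses the refreshed $b$ and
$\zeta$ uses the refreshed $(b, g)$, matching the staggering of the
coordinate-ascent derivation.  The placement of $a^{-1}$ (in $\Sigma$ but
not $\mu$) is the unique reading consistent with a Gaussian factor under a
prior variance proportional to $\sigma^2$: the posterior precision of
$\beta$ is $\sigma^{-2}(X^\top X + g\,\mathrm{diag}(b))$, so the mean — a
ratio — is free of $a$.

**Convergence** is declared when the max-norm change of $\mu$ and the
relative changes of $\zeta$ and $\eta$ all fall below `tol_vb`
(default $10^{-6}$), with a hard cap of 1000 cycles.  An evidence lower
bound is not monitored: the fixed-point property is instead verified
directly in the tests (re-applying every update at convergence moves
nothing).

**Linear algebra.**  For $p \lesssim n$ the $p \times p$ system is solved by
Cholesky factorisation.  For $p \gg n$ the same quantities come from the
$n \times n$ dual (Woodbury) system at cost $O(n^2 p)$; only
$\mathrm{diag}(\Sigma)$ is ever needed, and
$\mathrm{tr}(X^\top X A^{-1}) = p - \sum_j d_j (A^{-1})_{jj}$ avoids forming
$\Sigma$.  Both routes are tested for equality.

**Bessel ratios.**  The expectations require
$K_\nu(x)/K_{\nu+1}(x)$ at order $(p+1)/2$, which grows with the number of
features, and at arguments spanning many orders of magnitude.
`besselK_ratio()` uses exponentially scaled Bessel functions so the
$e^{-x}$ factors cancel, starts half-integer orders from the exact closed
form $K_{3/2}/K_{1/2} = 1 + 1/x$, and reaches large orders through the
upward recurrence applied to the ratio sequence, which never overflows
because only ratios are stored.  Accuracy is pinned to adaptive quadrature
of the GIG density at relative tolerance $10^{-8}$ over a parameter grid.

## Empirical Bayes M-step

Hyperparameters maximise the variational expectation of the complete-data
log prior.  Both levels decouple and have closed forms
(`eb_update_alpha()`, `eb_update_lambda()`): with $C$ the feature covariate
matrix stacked drug-major, $e_{jd} = E_q(\gamma_{jd}^2)$ and
$b_{jd} = E_q(\gamma_{jd}^{-2})$,

$$\alpha_{feat} = (C^\top \mathrm{diag}(e) C)^{-1} C^\top 1, \qquad
  \lambda_{feat} = pD\,\big[\textstyle\sum b
    + \alpha^\top C^\top \mathrm{diag}(e) C \alpha
    - 2 \alpha^\top C^\top 1\big]^{-1},$$

and identically at the drug level with $(Z, f_d, g_d, D)$.  The shape
denominator is a sum of expected IG deviances; since posterior expectations
satisfy $b \ge 1/e$, the update is provably positive, and the
implementation treats a nonpositive denominator as an error rather than
clipping it.  With intercept-only designs the update reduces to
$\phi = \overline{e}$ (and $\chi = \overline{f}$), which the tests assert
as an algebraic identity.

The outer loop (`nig_fit()`) alternates full per-drug VB convergence with
the two closed-form updates, warm-starting each drug's state from the
previous outer iteration, and stops when all hyperparameters change by less
than `tol_em = 1e-4` in relative terms (cap 100 outer iterations; on
Scenario-3-like data the cap is typically reached because the feature- and
drug-level means drift slowly in opposite directions along a
near-unidentifiable ridge — the products $\phi_{jd}\chi_d$, which are what
predictions feel, stabilise much earlier).  Variational states are fully
re-converged between EB updates; the alternative of partial E-steps would
blur the monotonicity interpretation of the EM objective.

**Positivity.**  The closed-form $\alpha$ update is unconstrained, so a
linear predictor $c^\top\alpha$ can occasionally go nonpositive, which has
no valid prior mean.  The update itself is kept; the implied means are
clipped into $[10^{-6}, 10^6]$ with a warning before the next VB pass.
This preserves the closed form while guarding validity; in the simulation
experiments clipping occurs rarely and only in early iterations.

**Model variants.**  `nig_control()` exposes which level is updated
(`update_feature`, `update_drug`) and whether external covariates enter
(`use_feature_covars`, `use_drug_covars`), giving the feature-only,
drug-only and both-level variants with or without co-data.  A level that is
not updated is pinned: prior mean fixed (default 1) with a large shape
(`fixed_lambda = 1e6`), which holds its variance components at the prior
mean — the model-side analogue of the simulator fixing
$\gamma^2$ or $\tau^2$ at one.

## Gibbs validation

Because variational approximations can understate posterior spread,
`nig_gibbs()` samples the exact per-drug posterior at fixed hyperparameters
from full conditionals derived by conjugacy (Gaussian for $\beta$, GIG for
$\gamma_j^2$ and $\tau^2$, inverse-gamma for $\sigma^2$; the derivations
mirror the variational factor forms, which is itself a useful consistency
check).  GIG variates are drawn by rejection on the log scale: the density
of $\log X$ is always log-concave, so a flat-center/exponential-tail hat
anchored at the unit-drop points dominates uniformly.  The sampler is
validated against IG prior moments and against conjugate-normal closed
forms with pinned variance components.  On an $n = 50$, $p = 10$ instance
the variational coefficient means sit within three Monte Carlo standard
errors (batch means) of the chain means.

## The simulator, and what passing tests mean

`sim_scenario()` draws from the generative model itself: error variances
inverse-gamma(3, 2) (prior mean and variance one), variance components from
their IG priors with four approximately equal dummy-coded groups per axis,
true coefficients $\alpha = (1, 1, 3, 7)$ at each structured level (prior
means 1, 1/2, 1/4, 1/8), shapes $\lambda = 1$, and default dimensions
$n = 507$, $p = 100$, $D = 251$, the scale of a large cell line panel.  Scenario 1 fixes the drug
level, Scenario 2 the feature level, Scenario 3 draws both, Scenario 4
degrades the co-data by permuting a fraction of external covariate rows.

The default design matrix is synthetic: centred Gaussian with exchangeable
column correlation 0.3, a moderate stand-in for co-expression structure.
Real expression panels differ in ways the generator does not emulate —
blockwise and long-range collinearity, heavy-tailed and skewed feature
distributions, batch structure.  Recovery results under the synthetic
design therefore speak to correctness of the estimation machinery, not to
field performance on real panels; the module accepts a user design matrix
so the same experiments can be rerun on real features.  A `standardize`
flag (default on) scales design columns to unit variance, consistent with
the per-drug centring the model assumes.

The recovery experiments used in the acceptance checks run at a reduced
scale chosen to keep the full suite in the minutes range: $n = 250$,
$p = 100$, $D = 50$, 20 replications with fixed seeds.  At this scale the
both-level Scenario 3 fit shows the same signature as at full scale:
feature-level prior means overestimated, drug-level underestimated, their
ratios and products nearly unbiased (group ratios within a few percent of
the true 0.5 and 0.125).

## Prediction, cross-validation, selection

Point predictions are posterior means, $\hat y = X \hat\beta_d$.  Prediction
error is summarised by PMSE, the per-drug mean squared error averaged over
drugs, with missing response cells excluded pairwise; responses are
standardised per drug inside `nig_cv()` so the empty reference model scores
one.  Cross-validation follows the protocol of estimating hyperparameters
once on all samples and refitting only the per-drug variational states
inside each training fold — per-fold refitting of the states is the only
defensible reading when the hyperparameters are global; a fully nested mode
(`nested = TRUE`) re-estimates the hyperparameters per fold for users who
want strict out-of-sample hyperparameter selection.

`dss_select()` implements decoupled shrinkage and selection as a plain
$\ell_1$ approximation of the dense posterior-mean fitted values followed
by an unpenalised refit on the selected support.  The cited decoupling
idea admits variations (penalised refits, credible-interval screening);
the plain lasso-path variant is used here as the most reproducible
interpretation, and the path point is chosen by nearest support size.

## Numerical and degenerate-input policy

* Constant (zero-variance) feature columns are rejected at load: after
  centring they are identically zero and make the penalized system
  singular in the vanishing-penalty limit.
* Fewer than two observed samples for a drug is an error.
* Nonpositive $\zeta$ (numerically impossible for valid inputs) and
  nonpositive shape-update denominators raise errors, not warnings —
  both indicate inconsistent states upstream.
* Non-convergence of the inner VB loop raises an error carrying the
  iteration trace.
* All simulator randomness flows from one seed through named substreams,
  so components are individually reproducible.

## Limitations

* The model factorises over drugs given the hyperparameters; residual
  cross-drug correlation is not modelled.
* Empirical Bayes point-estimates $\alpha$; hyperparameter uncertainty is
  not propagated into the posterior.
* Joint estimation of both levels is near-unidentifiable in the means
  (only products are well determined), so per-level prior means should be
  interpreted relatively, not absolutely.
* The shrinkage-weight density utilities cover the NIG prior only; no
  Student-t or lasso comparison densities are provided.

## A worked example

```{r example, eval = FALSE}
sim <- sim_scenario(3, n = 120, p = 30, D = 8, seed = 1)
fit <- nig_fit(sim$y, sim$X, sim$feature_covars, sim$drug_covars)
fit

# relative feature-level prior means (true: 0.5, 0.25, 0.125)
a <- fit$alpha_feat
a[1] / (a[1] + a[2:4])

cv <- nig_cv(sim$y, sim$X, sim$feature_covars, sim$drug_covars,
             n_folds = 5, seed = 2)
cv$pmse_mean

sparse <- dss_select(sim$X, fit$beta[, 1], target_size = 10)
sparse$selected
```
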