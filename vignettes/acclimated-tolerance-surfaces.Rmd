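---
title: "Acclimated tolerance surfaces: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acclimated tolerance surfaces: models, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Microbial populations evolving under fluctuating salinity experience
selection not only from the current environment but also from carry-over
(acclimation) effects of recently experienced environments. The natural
experimental readout is an *acclimated tolerance surface*: absolute fitness
(per-capita population growth rate) measured over a grid of acclimation
salinities $S_0$ crossed with assay salinities $S_1$. `acclimtol`
implements the full analysis pipeline for such experiments in the
halotolerant microalga *Dunaliella salina* and similar systems: simulating
autocorrelated salinity regimes, fitting the bivariate tolerance surface by
maximum likelihood from raw flow-cytometry counts, relating the surface's
evolution to the statistical moments of each population's selective regime,
and quantifying the plasticity of intracellular glycerol, the main
osmoregulatory trait.

## Environment process and transfer logistics

Fluctuating regimes are stationary AR(1) series
$$x_{t+1} = \bar S + \rho\,(x_t - \bar S) + \varepsilon_t, \qquad
\varepsilon_t \sim \mathcal N\!\big(0,\ \sigma_S^2 (1-\rho^2)\big),$$
so that the stationary variance equals $\sigma_S^2$ for every
autocorrelation $\rho$ — the standard device for separating the effect of
autocorrelation from that of variance. The reference regime has
$\bar S = 2.4$ M NaCl, $\sigma_S^2 = 1$ M$^2$, and
$\rho \in \{-0.5, 0, 0.5, 0.9\}$. Because media are mixed from 0 M and
4.8 M stocks, simulated values are clipped to $[0, 4.8]$ M *after*
generation; the unclipped latent series is retained (it is the object whose
stationary moments are checked) and the number of clipped steps is
reported. With mean 2.4 and unit variance roughly 1–2% of draws clip; the
realized (clipped) series is what populations actually experienced, so
realized moments are computed from it.

Realized moments use the common estimator conventions: sample variance with
denominator $n-1$, and lag-1 autocorrelation as the Pearson correlation
between the series and its one-step shift. *Predictability* is defined as
$\rho_S^2$, always the square of the realized $\rho_S$, never an
independently estimated quantity. A constant regime has zero variance and
an undefined lag correlation; such populations enter regressions with
$\rho_S = \rho_S^2 = 0$ and are flagged, which keeps the six constant
populations in the moment design without inventing an autocorrelation for
them.

Transfer volumes follow the serial-dilution arithmetic
$V_\text{culture} = N_0 V_\text{total}/N_\text{acclim}$,
$V_\text{hyper} = (S_1 V_\text{total} - S_0 V_\text{culture})/S_\text{hyper}$,
with the hyposaline volume as remainder. A negative volume means the
target salinity is unreachable at that dilution — exactly the mechanism
that removes six of the 81 grid cells (from 0.1 M to 3.7/4.3/4.7 M and
from 4.7 M to 0.1/0.5/1.1 M), leaving the 75-transfer design.

## The tolerance-surface model

Each assay well starts from $N_0$ live cells at acclimation salinity
$S_0$, is transferred to assay salinity $S_1$, and is counted after
$t = 3$ days. Two fitness components are separated:

* an *instantaneous mortality ratio* $d(S_0, S_1)$ — the fraction of
  initial cells dying upon transfer (mortality in this system happens
  within hours, before appreciable growth), modeled on the logit scale as
  $\text{logit}\, d = \delta + \delta_0 S_0 + \delta_1 S_1 +
  \delta_{01} S_0 S_1$ (monotonic: mortality concentrates in low-to-high
  transfers, so no quadratic terms are needed);
* an *apparent growth rate* $r(S_0, S_1)$ of the survivors, a bivariate
  quadratic
  $$r = r_\text{max} - \frac{(S_1-\mu_1)^2}{\sigma_1^2}
        - \frac{(S_0-\mu_0)^2}{\sigma_0^2}
        + \frac{2k\,(S_1-\mu_1)(S_0-\mu_0)}{\sigma_1^2}.$$

Here $r_\text{max}$ (1/day) is the maximal apparent growth rate, $\mu_1$
and $\sigma_1$ (M) the assay-salinity optimum and breadth, $\mu_0$ and
$\sigma_0$ the acclimation optimum and breadth, and $k$ the *acclimation
strength*: the conditional assay optimum at acclimation $S_0$ is
$\mu_1 + k (S_0 - \mu_0)$, so $k$ is the slope by which past salinity
drags the current optimum. The surface has a finite maximum
($r_\text{max}$ at $(\mu_0, \mu_1)$) iff $k^2 < \sigma_1^2/\sigma_0^2$;
the constructor warns when a parameter set violates this. Net growth over
the assay combines both components, $R = \ln(1-d)/t + r$.

### Observation model and likelihood

Flow-cytometry live counts are overdispersed, so the final count $N_t$ is
negative binomial with mean $N_0 (1-d) e^{rt}$ and variance
$\mu + \mu^2/\theta$ (the "nbinom2" convention; $\theta$ = `nb_size`).
Dead-cell fractions are similarly overdispersed: the dead increment
$\max(D_t - D_0, 0)$ is beta-binomial with $\mathrm{round}(N_0)$ trials,
mean $d$, and precision $\phi$, i.e. $\text{Beta}(d\phi, (1-d)\phi)$
mixing. Using the initial live cells as trials follows directly from
defining $d$ as a fraction of initial live cells. $N_0$ is treated as a
known constant per acclimation flask (it is measured directly, twice, with
CV ≈ 0.07), not as a latent variable.

The joint likelihood over all wells is maximized with respect to the 10
surface parameters plus the 2 dispersions. The likelihood is written as a
C++ template differentiated automatically (TMB), so gradients are exact;
the model here contains no random effects, making the fit plain
fixed-effects maximum likelihood. For a single shared surface the breadths
and dispersions are log-transformed and all other parameters are
unconstrained. Optimization runs `nlminb` from a moment-based start (a
quadratic regression of raw log-ratio growth mapped onto the surface
parameters, and a quasibinomial logit regression of raw dead fractions for
the mortality coefficients), plus four jittered restarts, supplying the
exact second-order autodiff Hessian to the optimizer and to a final
damped-Newton polish; convergence is declared when the maximum absolute
gradient on the transformed scale falls below $10^{-5}$. Near the optimum
the objective (magnitude $\sim 10^4$) changes by less than its rounding
floor along a Newton step, so polishing accepts steps on gradient-norm
decrease while forbidding genuine objective increases. Standard errors
come from the inverse observed-information matrix, delta-method-transformed
for $\sigma_0$, $\sigma_1$, and the dispersions.

### Surface summaries

`joint_optimum()` maximizes $R$ over a bounded salinity square with
deterministic multi-starts (center, corners, and the projected growth
optimum), breaking exact ties toward the lexicographically smallest
$(S_0, S_1)$ so results are reproducible; `zero_growth_interval()`
root-finds the positive-net-growth interval along the assay axis, flagging
truncation at the bounds. Both are checked against dense grid oracles in
the tests.

## Regression on environmental moments

Evolution of the surface is modeled by letting every parameter $\theta$ of
population $i$ be linear in the realized moments of its regime:
$$\theta_i = \theta_\text{int} + \theta_\text{mean}\bar S_i
 + \theta_\text{var}\sigma^2_{i,S} + \theta_\rho \rho_{i,S}
 + \theta_{\rho^2}\rho^2_{i,S}.$$
Breadths enter on the $1/\sigma^2$ scale, matching how such estimates are
conventionally reported. The model is fitted as *one joint likelihood*
(50 effects + 2 dispersions) across all populations' counts, not as a
two-stage estimate-then-regress procedure: a joint fit propagates count
noise into effect standard errors coherently and yields one Wald test per
effect. Within the optimizer the $1/\sigma^2$ linear predictors are used
directly in the quadratic form; a non-positive predicted $1/\sigma^2$
simply produces a very poor (but finite) likelihood, so no hard barrier is
needed during optimization — the data-generating side, by contrast,
refuses configurations whose predictions break positivity. Moment
regressors are deliberately *not* standardized: intercepts are then
interpretable as the parameter values at mean 0, variance 0, and zero
autocorrelation.

Nested comparisons (e.g. "is there any effect of autocorrelation and
predictability?") drop whole moment rows across all 10 parameters at once
(`drop =` in `fit_hierarchical()`, df = 10 per row) and are tested with
`likelihood_ratio_test()`. Per-effect Wald tests are Bonferroni-corrected
over the 40 non-intercept comparisons. Per-transfer analyses
(`per_transfer_regression()`) regress each design cell's counts on the
moment regressors through `glmmTMB` negative-binomial (total and apparent
growth, log link with the appropriate offsets, coefficients rescaled per
day) and beta-binomial (mortality) regressions.

## Glycerol plasticity

Glycerol analysis starts from concentration estimates ± SE per population,
compartment (total and extracellular), transfer, and time point, plus cell
density estimates ± SE. Intracellular concentration is the difference
total − extracellular (SEs added in quadrature; negative estimates are
retained and flagged, because truncation would bias downstream pooling),
and per-cell amounts $G = C/N$ carry delta-method errors
$\mathrm{SE}(G) = \sqrt{\sigma_C^2/N^2 + C^2\sigma_N^2/N^4}$.

Measurement error is propagated into inference by simulation: `m` datasets
(reference analysis: 1000) are drawn with every concentration replaced by
$\mathcal N(\text{est}, \text{SE})$, each analyzed identically, and
results pooled. Scalar coefficients pool by Rubin's rules (total variance
= within + $(1+1/m)\times$ between, with Rubin's degrees of freedom).
Multi-coefficient ANOVA terms from the model
`G ~ S0 * S1 * Time * rho2 + rho + mean + var`
pool with the D1 multivariate Wald statistic (the standard approach for
pooled multiparameter tests); each term's test uses its coefficient block
from the full model. With `m = 1` the pooled test reduces exactly to the
ordinary single-dataset Wald F, and the function warns that pooling is
degenerate. Assay salinity can be treated categorically (default, matching
the 3-level design) or continuously, since linear reaction norms can miss
shape changes. The overall magnitude of plasticity is summarized by the
among-assay-environment variance of $G$ (`plasticity_variance()`), which
can itself be regressed on the moments.

## The synthetic-data generator

No experimental dataset is distributed, so `generate_experiment()` creates
complete synthetic experiments with the exact structure the analysis
assumes: 25 populations (6 constant at 0.8/2.4/3.2 M, two each; 19
fluctuating — 5 at $\rho = -0.5$, 0, and 0.5, 4 at 0.9), AR(1) series of
80 transfers (about twice-weekly transfers over the experiment's duration,
≈ 200 generations at 3–4 generations per transfer), the 75-cell design
with 3 replicates, one truncated-normal $N_0$ draw (mean 3911, SD 283)
shared by all wells from the same acclimation flask, negative-binomial
live counts (size 20) and beta-binomial dead increments (precision 10).
The dead-count baseline $D_0$ is emitted as 0, and the likelihood uses the
increment $\max(D_t - D_0, 0)$, so generation and fitting are symmetric;
for the same reason counts live on whatever scale the inputs use (full
wells or a cytometer subsample) without affecting recovery. True surface
parameters follow the bundled reference moment-effect matrix; optional
Normal population scatter around those predictions is available for
two-stage diagnostics but defaults to zero, matching the model fitted.

The dispersion defaults (`nb_size = 20`, `bb_precision = 10`) are
realistic for flow-cytometry counts and overdispersed death fractions in
this system and make the recovery experiments honest: counts carry
substantially more noise than Poisson/binomial sampling alone. What the
generator deliberately does **not** emulate: within-assay population
dynamics beyond the closed-form exponential expectation (no lags or
rebounds), day-of-measurement batch effects, or plate layout. Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the stated model, not robustness to model violations in
real data.

The glycerol generator mirrors the 8-population × 6-transfer × 3-time
design (144 conditions per compartment). Its truth function relaxes
per-cell glycerol exponentially from the acclimation equilibrium toward
the assay equilibrium ($G_\text{eq}(s) = 0.3 + 1.0\,s$ pmol/cell, time
constants 4 h down, 16 h up — the documented asymmetry between rapid
excretion and slower synthesis), adds an extracellular excretion term
after downshifts, and plants moment effects (by default a negative
predictability effect and a negative predictability × assay-salinity
interaction, emulating reduced plasticity under high predictability).
Cell densities sit near $5\times 10^5$ cells/mL with 5% measurement CV
and concentrations carry 8% CV.

## Numerical choices and problem sizes

* Sub-seeds for every stochastic stage derive deterministically from one
  user-supplied master seed; all generators are bit-reproducible.
* Degenerate inputs fail loudly and specifically: unreachable transfer
  salinities name the violated bound, rank-deficient moment designs name
  the collinear columns, fewer than 3 distinct salinities per axis raises
  an identifiability error, and $d = 1$ in net growth is guarded.
* The recovery experiments used in the tests and the acceptance script
  run 20 simulate–refit replicates of the 5-population single-surface
  design (1125 wells each) and 10 replicates of the full 25-population
  hierarchical design (5625 wells each); these sizes give medians stable
  to well within the reported standard errors while each fit completes
  in a few seconds thanks to autodiff (TMBad) gradients and Hessians.

## Known limitations

* Exponential within-assay growth is assumed; systems with pronounced lag
  or rebound dynamics violate this and the surface parameters then absorb
  those dynamics.
* The hierarchical model has no population-level random effects;
  population-to-population scatter beyond the moment regression inflates
  the dispersions instead.
* The quadratic growth surface is symmetric about its optima by
  construction; real tolerance surfaces are often skewed, and the
  published mortality/growth partition captures only part of that
  asymmetry.
* Bonferroni correction over 40 comparisons is conservative given the
  correlation among effect estimates within one joint fit.
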