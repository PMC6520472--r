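---
title: "Bayesian cumulative N2O fluxes and emission factors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian cumulative N2O fluxes and emission factors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2oflux)
```

## The problem

Fertiliser emission factors (EFs) for nitrous oxide are estimated from static
chamber campaigns: a handful of chambers per treatment, sampled on a subset of
days over a ~30-day window after application. Soil N2O fluxes are extremely
skewed in space (chamber-to-chamber) and pulsed in time, so the standard
workflow — average the chambers per day, connect the dots, integrate
trapezoidally — yields a point estimate with no defensible uncertainty.
`n2oflux` implements a space-time log-normal model fitted by MCMC, which
yields a full posterior distribution for the cumulative flux and the EF,
alongside the trapezoidal baseline for comparison.

## The model

**Space.** At a fixed time $t$ after application, plot-level fluxes $F$ are
log-normal: $F \sim \ln N(\mu_{\log,t}, \sigma_{\log}^2)$, with arithmetic
mean $\mu = \exp(\mu_{\log} + \tfrac12 \sigma_{\log}^2)$.

**Time.** The spatial-mean emission rate follows a log-normal *density* in
time, scaled by the total emitted nitrogen:
$$\mu_t = \frac{1}{\sqrt{2\pi}\,k\,t}
  \exp\!\left(-\frac{(\log t - \Delta)^2}{2k^2}\right) N_{in}\,\Omega ,$$
where $\Delta$ is the log of the delay to peak flux (days), $k$ a
dimensionless decay-scale, $N_{in}$ the applied N (kg N ha$^{-1}$) and
$\Omega$ the fraction of it eventually emitted as N2O-N. The two pieces are
tied by the mean-preserving location
$\mu_{\log,t} = \log \mu_t - \tfrac12\sigma_{\log}^2$, so at every time the
spatial distribution has mean exactly $\mu_t$ (`mu_log_at_t()`,
`lognormal_mean()`; tested to machine precision).

**Cumulative flux.** Because $\mu_t$ is a scaled log-normal density, the
cumulative emission to day $t$ is closed-form:
$$F_{cum,t} = \Phi\!\left(\frac{\ln t - \Delta}{k}\right) N_{in}\,\Omega ,$$
monotone, zero at $t=0$, with asymptote $N_{in}\Omega$ (`cumulative_flux()`;
checked against quadrature of $\mu_t$ to $10^{-4}$ relative error and exactly
$\tfrac12 N_{in}\Omega$ at $t = e^\Delta$).

## Likelihood, background and censoring

Three numerical choices were genuinely open; this package's resolutions:

* **Background.** Unfertilised control plots emit too (decomposition,
  deposition). The control-plot mean rate $B$ enters the likelihood as a
  constant offset **on the model mean**:
  $\mu_{\log,t} = \log(\mu_t + B) - \tfrac12\sigma_{\log}^2$, and the
  *measured* flux is the likelihood variate. We deliberately did not subtract
  $B$ from each observation: control-plot scatter means many tail-of-event
  observations land near or below zero after subtraction, and the positive
  remnants masquerade as extreme outliers under a near-zero-mean log-normal —
  in recovery experiments that variant inflated $\Omega$ by two orders of
  magnitude. With the mean-offset form the derived cumulative draws include
  the $B\,t$ contribution, so they are on the same footing as a trapezoid of
  the raw fluxes; the background *cumulative* (trapezoid of the control
  means) is then subtracted once, at the EF stage — mirroring how field
  studies report "cumulative minus background".
* **Censoring.** The log-normal has support $(0,\infty)$ but chamber
  regressions can return zero or slightly negative fluxes. Measured values at
  or below a floor $\epsilon$ (default $10^{-4}$ nmol m$^{-2}$ s$^{-1}$) are
  treated as left-censored and contribute the log-CDF at $\epsilon$, so no
  observation is discarded and the likelihood stays finite.
* **$\sigma_{\log}$** is a free parameter fitted jointly with
  $(\Delta, k, \Omega)$ rather than fixed per event; the data per event (≈ 90
  plot-days) identify it comfortably.

## Priors and sampler

Default priors (all overridable via `prior_spec()`):
$\Omega \sim \ln N(\text{median } 0.01, \text{sdlog } 1.5)$ — centred on the
~1% EF typical of synthetic fertilisers, spanning roughly 0.04–25%;
$\Delta \sim N(\ln 3, 1)$ and $k \sim \ln N(0.7, 0.5)$ — a peak within days
decaying over weeks, as process-based denitrification models produce;
$\sigma_{\log} \sim \ln N(1, 0.5)$ — order-of-magnitude spatial scatter.

The sampler (`sample_posterior()`) is a bespoke random-walk
Metropolis-within-Gibbs on $(\Delta, \log k, \log\Omega, \log\sigma_{\log})$
— on that scale every prior is normal, so no Jacobian bookkeeping. Proposal
scales adapt towards ~44% acceptance **during burn-in only**, keeping the
retained chain a valid Markov chain. Defaults: 2 chains × 10⁴ iterations,
2 000 burn-in (one event fits in a few seconds). Diagnostics: per-block
acceptance rates, the Gelman–Rubin $\hat R$ per parameter (warning above
1.1), and a divergence error if post-adaptation acceptance falls below 1%.
With an empty observation set the likelihood is flat and the sampler returns
the prior — the basis of the prior-recovery test. Seeds are derived
deterministically per chain, so runs are exactly reproducible.

## Trapezoidal baseline

`trapezoid_cumulative()` integrates the per-day spatial mean piecewise
linearly. Plots are averaged per day *before* integration (matching how
n = 4 tables are built); `trapezoid_by_plot()` offers the
integrate-then-average alternative, identical under balanced sampling. Edge
conventions are not recoverable from published tables, so they are explicit
and configurable: the default holds the first measured value over the half
day before the first visit (zero earlier) and holds the last value to the
window end; `"zero"` and `"hold"` variants are provided. The choice is a
second-order effect for daily sampling but is logged per run.

## The synthetic world

`simulate_event()` generates exactly the structure the model assumes: per
plot and day, an independent log-normal pulse draw (mean $\mu_t$ in flux
units) **plus** an independent log-normal background draw; control plots draw
background only. Stated-world defaults: 4 treatment + 4 control plots,
background mean 0.4 nmol m$^{-2}$ s$^{-1}$ (typical of grassland controls),
truth $\Delta = \ln 3$, $k = 0.6$, $\Omega = 0.01$, $\sigma_{\log} = 0.8$,
and the two field sampling schedules (daily-for-two-weeks-then-alternate
days; tapering 3×/2×/1× weekly). Site presets (`site_preset()`) bundle
realistic chamber geometries (38 cm cylinder, 0.22 m headspace; 50 × 50 cm
boxes) and N rates of 60–90 kg N ha$^{-1}$; preset treatment $\Omega$ values
(0.006/0.003/0.0026) echo the mean EFs observed across UK grassland trials.
The chamber-series generator inverts the flux equation
$F = \tfrac{dC}{dt}\,\rho\,V/A$ with optional Gaussian analyser noise, whose
magnitude is a free parameter (no published error model exists for a 3–4
point chamber regression).

What the generator does **not** emulate: diurnal cycles, rainfall-triggered
secondary pulses, plot-level persistence (draws are independent across days,
as the model itself assumes no persistence), or autocorrelated analyser
drift. A green recovery test therefore certifies the estimator under the
model's own assumptions — it does not certify the log-normal temporal shape
against real high-frequency data, where single sharp peaks are known to fit
poorly; the package flags lack of fit (via $\hat R$, acceptance and the
credible ribbon) but deliberately implements no alternative temporal models.

Because the likelihood treats the combined pulse + background as one
log-normal while the generator adds two log-normals, the model is mildly
mis-specified even in-world; the observed effect is slight undercoverage of
the 95% interval for $\Omega$ (≈ 85–100% across seed batches), comfortably
inside the acceptance band (≥ 16/20).

## Emission factors and aggregation

Per event and treatment: EF $= 100\,(F_{cum,30} - B_{cum})/N_{in}$ (%), with
$B_{cum}$ the trapezoid of the control means — computed per posterior draw,
so the EF interval inherits the full posterior. Cross-event aggregation
(`aggregate_efs()`) reports the arithmetic mean, the $n-1$ sample SD and the
median per treatment: the published "±" values for this design match the
sample SD of the per-event EFs (to rounding) even where they are labelled
confidence intervals, so both the mean ± SD and the median are reported.
Pooling (`pooled_posterior_pdf()`) mixes per-event EF draws with equal
weight (thinning longer sets); $P(EF_A > EF_B)$ is computed exactly over the
empirical draw sets by ranking (the expectation under random independent
pairing, with ties counted half), so it needs no pairing RNG. The
method-comparison regression reports the OLS slope, intercept, Pearson $R^2$
*and* the through-origin slope, because published comparison slopes rarely
state which was used; only $R^2$ is treated as a gating quantity.

## Units

One unit constant bridges the chamber scale to the reporting scale:
1 nmol N2O m$^{-2}$ s$^{-1}$ = $2 \times 14.0067 \times 10^{-9} \times 86400
\times 10^{4} \times 10^{-3}$ = 0.0242036 kg N ha$^{-1}$ day$^{-1}$
(`convert_flux_units()`). Model internals run in kg N ha$^{-1}$ day$^{-1}$;
files and observations stay in nmol m$^{-2}$ s$^{-1}$, as produced by
chamber systems. Air density defaults to the ideal-gas value
$\rho = P/(RT)$ with $R = 8.314$ J mol$^{-1}$ K$^{-1}$.

## Known limitations

* The temporal model is a single log-normal pulse; multi-pulse events (e.g.
  rain after a dry spell) are outside its support and will show up as poor
  fit, not as an alternative estimate.
* The background is a constant mean rate; any trend in control emissions over
  the window is absorbed into the pulse.
* $P(EF_A > EF_B)$ from pooled draws compares mixture distributions across
  events, not a hierarchical treatment effect; it answers "a randomly chosen
  event-draw of A exceeds one of B", nothing stronger.
* Serialization uses JSON (not YAML) for configs and sidecars, and CSV for
  draws and tables.
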