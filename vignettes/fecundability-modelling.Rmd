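---
title: "Bayesian modelling of time to pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian modelling of time to pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceive)
```

## The model

Conception is treated as a discrete-time Bernoulli process: a couple with
*intrinsic conception rate* $y \in [0, 1)$ conceives in any given menstrual
cycle with probability $y$, independently across cycles. The probability of
conceiving within $n$ cycles is the geometric CDF

$$P(y, n) = 1 - (1 - y)^n,$$

implemented in `conception_cdf()`, with its inverse
$y = 1 - (1-P)^{1/n}$ in `invert_cdf()`. Because $y$ itself cannot be
measured, it carries a prior distribution $f(y)$: a point mass
(*sterile atom*) at $y = 0$ for couples who cannot conceive spontaneously,
plus a weighted mixture of continuous components — beta distributions
(optionally compressed onto $[0, c]$, $c < 1$) and triangular
distributions. The probability that a couple drawn from $f$ has not
conceived after $n$ cycles is the survival function

$$s(n) = \int_0^1 (1 - y)^n f(y)\,dy, \qquad s(0) = 1,$$

and Bayes' theorem gives the posterior after $n$ cycles of non-conception,

$$f_n(y) = \frac{(1 - y)^n f(y)}{s(n)}.$$

The sterile atom is tilted by a factor of one, so its posterior share
$f_0(\{0\})/s(n)$ grows monotonically: prolonged non-conception is
evidence of low fertility. All clinically interpretable outputs derive
from $f_n$:

* `p_next_cycle()` — the posterior mean of $y$, i.e. the probability of
  conceiving in the next cycle given the information available;
* `p_within(state, k)` — $1 - s(n+k)/s(n)$, the probability of conceiving
  within the next $k$ cycles;
* `rate_percentile()` — quantiles of the mixed discrete–continuous
  posterior, atom included;
* `sterile_proportion()` — the sterile share of the remaining population;
* `metrics_table()` and `cycles_to_threshold()` — the per-cycle panel of
  all of these, and the first cycle count at which a chosen subfertility
  indicator (e.g. posterior mean $< 0.1$, or 12-cycle conception
  probability $< 0.5$) is crossed.

Quantiles include the sterile atom in the "remaining population": once
the sterile share exceeds one half, the posterior median is exactly zero.
This convention is what makes the median a usable screening metric for
strongly selected cohorts.

## Numerical scheme

The continuous part of $f$ is carried on a uniform grid of cells over
$[0, 1)$ (default `grid_size = 8193` cells). Rather than storing density
values and integrating them with a quadrature rule, each cell stores its
**exact probability mass** — computed from the component CDFs
(`pbeta`, or the closed-form triangular CDF) — placed at the cell's
**conditional mean**, computed from the component first moments. This has
three consequences:

* total mass and the prior mean are exact to floating point, for any
  shape parameters, including $\alpha < 1$ or $\beta < 1$ where the
  density is unbounded at an endpoint and density-based quadrature
  degrades badly;
* the Bayes update is a pointwise multiplication of cell masses by
  $(1-y)^n$ (computed as $e^{n\log(1-y)}$ via `log1p` for stability at
  large $n$), so the survival chain identity
  $s(n+k) = s(n)\,(1 - \Pr(\text{conceive} \le k \mid n))$ holds exactly;
* the midpoint-style error in $s(n)$ scales as $O(h^2 n^2)$ with
  $h = 1/\texttt{grid\_size}$, about $10^{-7}$ for $n \le 36$ at the
  default grid — comfortably inside the three published decimals, and
  inside $10^{-6}$ of the conjugate closed form
  $s(n) = B(\alpha, \beta+n)/B(\alpha, \beta)$ for pure beta priors.

Quantiles invert the cumulative cell mass with linear interpolation
inside the crossing cell; ties break toward the smaller rate. The sterile
atom is always carried analytically as a scalar and never smeared onto
the grid, so sterile-proportion metrics involve no discretization error
at all.

Threshold scans use a strict inequality (metric $<$ threshold), evaluate
the state after $n$ elapsed cycles with $n = 0$ allowed (a population can
already satisfy an indicator before its first cycle), and return an `NA`
sentinel rather than an error when a threshold is not reached within the
scan limit, so batch tabulations never abort.

## Example populations

Four bundled presets (`example_prior()`) span the behaviour of interest:

| preset | sterile | continuous part | character |
|---|---|---|---|
| 1 | 5% | Beta(2.3, 3.7) | relatively fertile, heterogeneous |
| 2 | 5% | Beta(1.8, 4.2) | uniformly less fertile than 1 |
| 3 | 1% | Beta(11, 22) | homogeneous, fertile |
| 4 | 5% | 85% Beta(11, 22) + 10% Beta(4, 76) | fertile + subfertile mix |

```{r}
tab <- metrics_table(example_prior("example1"), n_max = 12)
round(tab[tab$cycles_elapsed %in% c(0, 6, 12), ], 3)
```

## Reproductive ageing

The ageing extension gives each couple two latent parameters: a *peak*
rate $p \sim \mathrm{Beta}(3, 10)$ (mean peak rate 0.23) and a *sterility
age* $T$ — the female age at which the couple's rate reaches zero. The
rate at age $a$ is

$$y(a) = p \cdot \min\!\left(1, \max\!\left(0, \frac{T - a}{d}\right)\right),$$

with decline window $d = 12.5$ years: couples are at peak until
$T - 12.5$, decline linearly, and are sterile from $T$ onward. One cycle
is one month; the rate used for a cycle is the rate at the cycle's
starting age.

The distribution of $T$ follows Leridon's demographic estimates of
permanent sterility. Published population summaries pin six points of
that curve — about 1% sterile by age 25, 2% by 30, 5.1% by 35, 16.6% by
40, half between 44 and 45, and all by 59 — but not the yearly values
between them. The package's default schedule
(`sterility_age_anchors()`) therefore interpolates those pinned values
with yearly knots whose increments were calibrated once, by penalized
least squares, against published age-specific fertility metrics for
cohorts starting at ages 25–40; the result is a convex-then-saturating
curve (e.g. ~94% sterile by 50) consistent with Leridon's published
estimates. It is a synthetic reconstruction of an unpublished
table and is documented as such; any anchor set can be supplied instead
via `ageing_spec(anchors = ...)`.

The cohort is discretized on a joint grid (default 513 peak cells ×
monthly sterility ages): each cell advances by the geometric update at
its current rate, weights renormalize among the unpregnant, and age
moves forward a month per cycle. This resolution stabilizes the two
published decimals while keeping a full 4-age tabulation to a few
seconds. `frozen_ageing_delta()` re-runs the scan with every couple's
rate held at its starting-age value, quantifying how much ignoring
ageing *during* the attempt delays a subfertility flag (0–2 cycles
across ages 25–40 and the five standard indicators).

## The cohort simulator

`simulate_cohort()` is an independent stochastic oracle, deliberately
sharing no numerics with the engine: couples are drawn by component
sampling (`rbeta`, closed-form triangular inversion, piecewise-linear
CDF inversion for sterility ages) and then undergo literal per-cycle
Bernoulli trials under a single seeded RNG stream. Agreement between
empirical cohort curves and the engine's survival and conditional
conception probabilities — within binomial sampling error at $10^5$
couples — is asserted in the test suite. What passing shows is that the
deterministic discretization and the generative model agree; it does not
validate the priors against any real cohort, nor the independence
assumptions behind the geometric model (no cycle-to-cycle correlation,
no temporary subfertility episodes).

## Design choices and limitations

* **Endpoint.** Conception means clinical pregnancy, not live birth;
  with miscarriage risk rising at higher ages, the ageing metrics are
  optimistic for live-birth planning.
* **Discrete cycles.** The process is modelled per menstrual cycle; no
  continuous-time refinement is attempted.
* **No fitting.** Preset parameters are illustrative population
  descriptions; the package deliberately provides no optimizer to fit
  priors to time-to-pregnancy data.
* **Quantile convention at coarse grids.** The ageing engine's quantiles
  step on the induced rate values of the joint grid rather than
  interpolating (the induced cells overlap after age scaling), so aged
  medians are resolved to about one peak-cell width; the static engine
  interpolates within cells.
* **Singular densities.** For user-supplied shapes with $\alpha < 1$ or
  $\beta < 1$, cell masses and all probability metrics remain exact, but
  the *density values* reported for plotting are finite point evaluations
  at cell means and do not integrate to the component weight by naive
  quadrature near the singular endpoint.
* **Table sizes used in the tests.** The suite reproduces the published
  per-cycle tables at the default grid (8193 cells), the conjugacy
  closed forms at 32769 cells, Monte-Carlo checks at $10^5$ couples, and
  the ageing tables at 513 × monthly resolution; these sizes were chosen
  as the smallest that stabilize the published precision.
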