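---
title: "Methods: the illness-death model, its prevalence ODE, and the inverse problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the illness-death model, its prevalence ODE, and the inverse problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(previnc)
```

## The model and its assumptions

previnc implements the three-state illness-death model for an irreversible
disease: *nondiseased* → *diseased* at the incidence rate $i(a)$, and death
from either living state at the mortality rates $m_0(a)$ (nondiseased) and
$m_1(a)$ (diseased). All rates are hazards per person-year, indexed by age
$a$ in years on a closed interval $[a_0, \omega]$. The model assumes:

* **a closed population** — no migration in or out;
* **time homogeneity** — rates depend on age only, not calendar time
  (equivalently, the package works along a single cohort's characteristic
  line);
* **irreversibility** — no remission back to the nondiseased state;
* **no duration dependence** — $m_1$ depends on current age, not on time
  since onset;
* **smooth, nonnegative rates**, with nonnegative excess mortality
  $\Delta m = m_1 - m_0 \ge 0$ for the boundedness theory (see below for
  what happens when this is violated).

Counts of susceptibles $S(a)$ and cases $C(a)$ obey the linear system
$dS/da = -(i+m_0)S$, $dC/da = iS - m_1C$; the living population is
$N = S + C$ and the age-specific prevalence is $p = C/N$ (defined as 0
where $N = 0$, so it is total: the prevalence of an extinct cohort is
zero). Under the assumptions above $p$ stays in $[0,1]$ and satisfies the
scalar ODE

$$\frac{dp}{da} = (1-p)\,\{\,i - p\,(m_1 - m_0)\,\},\qquad p(a_0)=p_0 .$$

Two pieces of mortality information pin down the right-hand side. The six
supported combinations (tags of `mortality_input()`) and their ODE classes:

| tag | given | right-hand side | class |
|-----|-------|-----------------|-------|
| `M_M0`  | $m, m_0$ | $(1-p)\{i-(m-m_0)\}$ | linear |
| `M_M1`  | $m, m_1$ | $(1-p)\,i - p\,(m_1-m)$ | linear |
| `M0_M1` | $m_0, m_1$ | $(1-p)\{i-p(m_1-m_0)\}$ | Riccati |
| `M0_R`  | $m_0, R$ | $(1-p)\{i-p\,m_0(R-1)\}$ | Riccati |
| `M1_R`  | $m_1, R$ | $(1-p)\{i-p\,m_1(R-1)/R\}$ | Riccati |
| `M_R`   | $m, R$ | $(1-p)\{i-m\,\mathrm{PAF}(p,R)\}$ | Abelian |

where $m = p\,m_1 + (1-p)\,m_0$ is the general mortality, $R = m_1/m_0$
the relative risk, and $\mathrm{PAF}(p,R) = p(R-1)/(p(R-1)+1)$ the
population attributable fraction (with $\mathrm{EAF}(R) = (R-1)/R$ its
$p=1$ limit). The `M_M1` row as usually written carries a removable
$(1-p)$ factor inside the brace; the package integrates the simplified
algebraic form shown, which avoids a $0/0$ as $p \to 1$. When the
mortality inputs are mutually consistent, all six tags produce the same
solution — the test suite asserts pairwise agreement below $10^{-6}$
sup-norm, and the same consistency for the inverse formulas below
$10^{-8}$.

## Parameters that matter

* **Age domain** (`age_domain(a0, omega, step)`). Ages in years; the grid
  is the closed uniform partition. The theory allows $\omega = \infty$;
  the implementation requires a finite, user-chosen $\omega$, because
  every quantity of interest is evaluated on a grid and Gompertz hazards
  make survival beyond ~110 years numerically nil anyway. Default step
  0.1 years: small enough that interpolation and finite differences are
  never the accuracy bottleneck at desk scale, cheap enough that a
  70-year solve takes milliseconds.
* **Hazards** (`gompertz_rate(beta0, beta1, ...)`,
  `tabulated_rate()`, `function_rate()`, `constant_rate()`). The Gompertz
  form $\exp(\beta_0 + \beta_1 a)$ is the standard two-parameter model of
  adult mortality; $\beta_0$ is the log hazard at age 0 and $\beta_1$ the
  log-linear slope per year (typical adult all-cause values
  $\beta_0 \approx -10$, $\beta_1 \approx 0.1$). Rates are validated
  nonnegative by sampling on the domain grid at construction. Tabulated
  rates interpolate linearly between knots and refuse extrapolation —
  constant extension at the tails would silently misstate old-age
  mortality, the region that drives the prevalence maximum.
* **Solver tolerances** (`rtol = 1e-8`, `atol = 1e-10`). Adaptive
  Runge-Kutta 4(5) (`deSolve::ode(method = "ode45")`), solution sampled on
  the grid. At these tolerances the accuracy overhead relative to looser
  settings is negligible for scalar/2-D systems, and agreement with the
  closed forms is near machine precision.
* **Relative risk `R`**. A positive scalar (age-constant) or an
  age-dependent function; internally a constant is wrapped as a degenerate
  age-independent rate so all six tags share one evaluation contract.

## Numerical choices

* **Quadrature.** The closed forms ($S$, the nested integral for $C$,
  the survival curve, the nondifferential prevalence) use per-interval
  Simpson quadrature with midpoint evaluation: over each grid cell the
  increment is $\tfrac{h}{6}(f_a + 4f_{mid} + f_b)$, accumulated by a
  running sum. This is $O(h^4)$ accurate and $O(n)$ in cost; the nested
  integral reuses the cumulative hazards rather than re-integrating
  (quadratic cost would be prohibitive at step 0.1). The two solution
  routes — closed form vs adaptive ODE — agree to ~$10^{-12}$ relative
  and serve as mutual oracles in the tests.
* **Bound enforcement.** Prevalence solutions may leave $[0,1]$ by
  roundoff; excursions below $10^{-9}$ are clamped silently. Larger
  excursions raise an error, because they indicate inconsistent inputs
  rather than numerical noise. The one sanctioned inconsistency is
  negative excess mortality ($m_1 < m_0$, a "protective" disease): the
  ODE is still perfectly integrable, so the package permits it with a
  warning and downgrades bound enforcement to a warning too.
* **Peak localisation.** The age of the prevalence maximum is the grid
  argmax refined by quadratic interpolation through its two neighbours
  (exact for a locally parabolic curve, i.e. one grid-step-squared
  better than the raw argmax); boundary maxima and flat triples fall
  back to the grid point.
* **Degenerate inputs.** Zero rates, $p_0 \in \{0, 1\}$, empty risk sets
  and extinct cohorts are all defined and tested: $p_0 = 1$ is absorbing
  under nondifferential mortality, $C \equiv 0$ gives $p \equiv 0$, and
  $p = 0$ where $N = 0$ by convention.

## The inverse problem

Solving the prevalence ODE for $i$ gives, e.g. in the vital-statistics
form used with the `M_R` tag,

$$\hat i(a) = \frac{dp/da}{1-p} + m(a)\,\frac{p(R-1)}{p(R-1)+1},$$

so incidence can be estimated from one cross-sectional prevalence curve
plus mortality information — no follow-up study. Design choices:

* **Derivative.** Default second-order central differences (one-sided
  second-order at the two boundary points, which are flagged), exact for
  locally quadratic curves — appropriate for model-generated or smooth
  curves. For noisy empirical curves a smoothing spline
  (`stats::smooth.spline`, smoothness by generalized cross-validation
  unless `spar` is given) is differentiated analytically; the noise
  amplification inherent in the inversion (next section) is why raw
  differences are the wrong default for data.
* **Negative estimates are flagged, not clipped.** A negative $\hat i$
  is informative: it diagnoses mortality assumptions inconsistent with
  the observed prevalence (e.g. an $R$ below the truth). A
  `clip_nonnegative` option exists for presentation.
* **Singularities.** $p \ge 1 - 10^{-9}$ anywhere is an error naming the
  age; $1-p < 10^{-3}$ only sets a `near_singular` flag.
* **Unknown relative risk.** `scenario_sweep()` estimates under several
  $R$ values; because the PAF term is increasing in $R$, the estimate
  under the true $R$ lies pointwise between the extreme-scenario
  estimates wherever $p > 0$ (the *sandwich principle*). The classic
  sweep is $R \in \{0.5, 1, 5\}$.

A round trip — forward solve, then invert — recovers the generating
incidence to below $10^{-4}$ per person-year at step 0.1 on the worked
example, and the error falls further as the grid is refined.

## Ill-posedness of the inversion

The inversion is discontinuous in the data: perturbing a prevalence curve
by $\varepsilon_n \sin(na)$ with $\varepsilon_n = n^{-1/2}$ sends the data
perturbation to zero while the estimated-incidence error grows without
bound, because the derivative term contributes
$\varepsilon_n n \cos(na)/(1-p)$, of amplitude $\sqrt n/(1-p)$.
`illposedness_experiment()` measures exactly this: for each $n$ it inverts
the base and perturbed curves and records the sup-norm difference over
ages where the base prevalence is at most 0.99 (near $p = 1$ the
inversion is singular for reasons unrelated to the perturbation).

Two modes, because the statement is about continuous functions while the
package works on grids:

* **analytic** (default): the sine's derivative enters in closed form;
  the base curve's derivative stays numerical. A fixed grid aliases
  frequencies beyond $\pi/\mathrm{step}$, so this mode is the only
  faithful way to probe the $n \to \infty$ mechanism.
* **numeric**: the perturbed curve is differentiated like any data curve;
  requires $n \cdot \mathrm{step} < \pi$ and illustrates how the blow-up
  manifests in practice.

With the default frequencies $n = 10, 40, 160, 640$ (geometric, ratio 4)
the growth law predicts the error to double per step; the measured ratios
are within a few percent of 2, and the normalised sequence
$\mathrm{error}/\sqrt n$ converges to
$\max_a |\cos(na)|/(1-p(a)) \approx 1/(1-p_{\max})$. The demonstration's
base curve is deliberately low-prevalence (constant incidence 0.002 on
ages 0–100, $p_{\max} \approx 0.18$): at $n = 10$ the coupled amplitude
$\varepsilon_{10} \approx 0.32$ is large, and with a high-prevalence base
the $\varepsilon \sin$ term in the denominator $1 - p - \varepsilon\sin$
would contaminate the leading-order $\sqrt n$ behaviour. Since the
construction is functional-analytic rather than epidemiological, the
experiment does not force the perturbed curve into $[0,1]$ — the public
`perturb_prevalence()`, meant for data-like use, does.

The contrast `forward_stability()` completes the argument: an incidence
perturbation of sup-size $\delta$ moves the prevalence by at most
$O(\delta)$ — the direct problem is stable, the inverse is not. The
practical reading: high-frequency noise in prevalence data is amplified
by the factor $n$ per frequency band, so empirical curves must be
smoothed before inversion, and the smoothing choice dominates the error
budget.

## The microsimulator

`simulate_cohort()` is the stochastic counterpart used to validate the
deterministic theory. Each of $N_0$ individuals enters nondiseased at
$a_0$; the first-event age is drawn from the combined hazard $i + m_0$ by
inversion of the cumulative hazard, tabulated at step 0.01 years and
interpolated linearly — a deterministic-cost scheme with no rejection
loops even in steep Gompertz tails. At the event age $t$ the competing
risks split with probability $i(t)/(i(t)+m_0(t))$ (exact for the
combined-hazard construction); new cases then draw a residual lifetime
from $m_1$ the same way. One root-seeded uniform stream is consumed in
fixed blocks of three draws per individual, so enlarging $N_0$ extends
the cohort without reshuffling earlier individuals, and a fixed seed
reproduces records bit-identically.

Validation checks implemented in the tests:

* `empirical_prevalence()` (with Wilson 95% intervals) converges to the
  scalar-ODE solution: with $N_0 = 10^5$ the sup deviation over ages
  30–90 on the worked example is below 0.01, and the deviation shrinks
  roughly as $N_0^{-1/2}$. Because a sup over a correlated grid is a
  noisy statistic, the scaling check compares the $N_0 = 10^5$ run
  against the *mean* sup over five independent $N_0 = 10^3$ replicates.
* Death counts in an age band reproduce the mixture
  $m = p\,m_1 + (1-p)\,m_0$ within Monte-Carlo error.
* Exponential waiting-time law in the constant-hazard case.

Problem sizes used in the shipped tests — $N_0 = 10^5$ for the headline
comparison, $10^3$–$2\times10^4$ elsewhere, 20–100 randomized rate
configurations for the property suites — were chosen as the smallest
sizes at which the Monte-Carlo and discretisation errors are clearly
separated from the tolerances being asserted.

## The synthetic prevalence fixture

`make_noisy_prevalence_fixture()` generates data-like curves for the
inverse problem. The `t1d_like` template emulates the qualitative age
profile of type-1-diabetes prevalence in young women — steep rise from
birth to about 15, plateau to 20, second rise to 30, plateau by 35, peak
of a few per 1000 — via monotone Hermite interpolation of hand-placed
knots, plus Gaussian noise with binomial scale $\sqrt{p(1-p)/n_{\rm eff}}$
(default $n_{\rm eff} = 10^5$ per age point, the order of magnitude of a
large claims dataset per single age). The template is entirely synthetic:
it reproduces a *shape* described qualitatively in the literature, not
any restricted dataset, and carries no claim about absolute levels. What
the fixture deliberately does not emulate: age-aggregation into integer
bins, calendar-period effects, diagnostic misclassification, and
correlated (non-independent) errors across ages. Passing the
fixture-based tests therefore shows that the spline-smoothed inversion
beats raw differences under independent sampling noise — not that the
pipeline is robust to every artefact of real claims data.

## Serialization and the CLI

Curve CSVs use a fixed dialect (comma, dot decimal, UTF-8, mandatory
`age,value`/`age,p` header, strictly increasing ages) because dialect
ambiguity silently corrupts rates; parse errors cite the line number.
Payload numbers are written at 15 significant digits so a write/read
round trip is lossless to below $10^{-12}$ (log output keeps 10
digits for readability). The `idm` CLI (`inst/cli/idm.R`) is a thin
wrapper over the exported functions: flat YAML config files are merged
under command-line flags, every run echoes its effective settings and
seed, and identical configuration plus seed yields byte-identical output
files.

## Known limitations

* Calendar-time (period/cohort) trends are out of scope: rates depend on
  age only. The age–period generalisation is a PDE whose characteristics
  reduce to this ODE, so the machinery transfers, but it is not
  implemented here.
* No migration and no remission terms; no duration-dependent diseased
  mortality.
* No confidence intervals for estimated incidence — the inversion is a
  plug-in formula, and honest uncertainty would have to propagate both
  sampling noise and the smoothing choice.
* No formal regularisation (Tikhonov or otherwise) of the inverse
  problem; the smoothing spline with GCV is the pragmatic stand-in.
* The finite upper age $\omega$ is the user's responsibility; results
  within a few steps of $\omega$ lean on one-sided differences and are
  flagged.
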