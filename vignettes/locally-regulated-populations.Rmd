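---
title: "Locally regulated spatial populations: model, limits, and genealogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally regulated spatial populations: model, limits, and genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrpop)
```

## The model

`lrpop` simulates and analyses a spatial birth–death point process in which
every demographic rate responds to *local density measured by smoothing*.
The population at time $t$ is a set of individuals at locations $x_i \in
\mathbb{R}^d$ ($d \in \{1,2\}$), encoded as a measure $\eta$ that assigns
mass $1/N$ to each individual, where $N$ is a nominal density scale
(individuals per unit area at reference density one).  Local density at $x$
is the convolution $\rho * \eta(x)$ of that atomic measure with a smoothing
kernel; three kernels $\rho_\gamma, \rho_r, \rho_F$ may differ.

Three rate functions of location $x$ and local density $m$ control the
dynamics, on a time axis scaled by $\theta$:

* **birth**: an individual at $x$ produces a single juvenile at rate
  $\theta\,\gamma(x, \rho_\gamma * \eta(x))$;
* **establishment**: the juvenile lands at $y = x + b(x)/\theta +
  K(x)z/\sqrt\theta$ (Gaussian dispersal, $KK^T = C$, $z$ standard normal)
  and instantly survives with probability $r(y, \rho_r * \eta(y))$, computed
  on the pre-birth population — the parent counts, the juvenile itself does
  not;
* **death**: the per-capita death rate is defined through its deviation from
  $r\gamma$ by a function $F$,
  $$\mu_\theta(x) = r(x,\eta)\,\gamma(x,\eta) - F(x,\eta)/\theta,$$
  so $F$ is (nearly) the net per-capita reproductive rate on the slow
  timescale.  `death_rate()` enforces $\mu_\theta \ge 0$: a parameterisation
  that would make it negative raises an error, it is never clipped.

Adults never move; all spatial mixing happens at birth.  The ratio $\alpha =
\theta/N$ controls whether the high-density limit is deterministic
($\alpha = 0$) or a stochastic measure-valued process ($\alpha > 0$); the
package simulates the finite-$(N,\theta)$ process for any values and solves
the deterministic limits as PDEs.

Named parameterisations are kept in a closed registry (`rate_fn()`), so
configurations serialise losslessly.  Two deserve mention:

* the **logistic preset** $r \equiv 1$, $\gamma \equiv 1$, $F(m) = 1 - m$:
  birth and death balance at density one, and the deterministic limit is a
  reaction–diffusion equation with logistic growth;
* the **porous-medium preset** $r \equiv 1$, $\gamma(m) = m$, $F(m) = 1-m$,
  so $\mu_\theta = (1+1/\theta)m - 1/\theta$: motility rises with crowding
  and the deterministic limit is the porous medium equation with logistic
  growth.  Because $\mu_\theta < 0$ for $m < 1/(\theta+1)$, this preset must
  declare the admissible density range (`m_min = 1/(theta+1)`); the linear
  birth rate is capped (default 20) to keep rates bounded, which is
  immaterial in practice because logistic regulation keeps densities near
  one.

## The individual-based simulators

`gillespie_run()` is the exact event-driven simulation: every rate is
recomputed from the full configuration at every event ($O(n)$ density sums
per event; correctness over speed).  `discrete_step()`/`discrete_run()` is
the synchronous variant: over a step $dt$ (scaled time) each individual
independently reproduces with probability $1 - e^{-\gamma\theta\,dt}$ and
dies with probability $1 - e^{-\mu_\theta\theta\,dt}$, all densities frozen
at the start of the step and all offspring appended after all decisions, so
the step is order-independent.  For the porous-medium preset these reduce to
$p_b(m) = 1 - e^{-m\,d\tau}$ and
$p_d(m) = 1 - e^{-(m(1+1/\theta)-1/\theta)\,d\tau}$ with $d\tau = \theta\,dt$
the step in unscaled time units.

Density evaluation has two flagged modes, recorded in the trajectory
metadata: `"direct"` (exact pairwise sums) and `"fft"` (cloud-in-cell
deposition on a grid plus FFT convolution, error $O(dx^2)$).  The fft mode
makes runs with thousands of individuals affordable; with `fft_dx = 0.05`
and kernels of scale 1 its error is $\sim 10^{-4}$, far below sampling
noise.  Self-counting is deliberate: an individual's own atom contributes
$\rho(0)/N$ to its local density, exactly as the convolution implies; there
is no self-exclusion option.

Periodic boundaries with minimal-image distances are the default domain.
This matches the homogeneous-equilibrium analyses and avoids edge effects;
it does mean kernels are formally wrapped, which is negligible whenever the
kernel scale is small against the domain.

## The lookdown representation

The lookdown construction attaches to each individual a *level*
$u \in [0, N]$ such that, given the spatial configuration, levels are i.i.d.
Uniform$[0,N]$ at all times.  Sampling the $k$ lowest levels in a region is
then a uniform $k$-sample (`sample_k_lowest()`), and genealogies survive the
$N \to \infty$ limit.  The dynamics (`lookdown_run()`, finite-$N$ mode):

* an individual at $x$ with level $u$ proposes births at rate
  $2\theta(1 - u/N)\gamma(x,\eta)$ — implemented by thinning against the
  bound $2\theta\gamma$, accepted with probability $1 - u/N$;
* an accepted, established offspring receives a level $u_1 \sim U[u, N]$,
  and a fair coin $\kappa$ assigns parent and offspring to the two levels
  $u, u_1$ in random order.  The *line of descent* keeps the old (lower)
  level; the Ulam–Harris label of the new level starts a new line; on
  $\kappa = 1$ the line of descent therefore continues in the offspring;
* between events each level follows $\dot u = c\,u^2 - b\,u$ with
  $c = (\theta/N)\gamma \int r\,q_\theta$ and
  $b = \theta\gamma\int(r(y)-r(x))\,q_\theta(x,dy) + F$;
  `evolve_level()` solves this in closed form through the reciprocal
  coordinate $v = 1/u$, which is linear.  Because positions are frozen
  between events, the coefficients are *exactly* piecewise constant and the
  per-piece solution is exact — no time discretisation enters the finite-$N$
  dynamics.  The dispersal integrals use 20-node Gauss–Hermite quadrature,
  collapsing exactly when $r$ is constant;
* a level crossing $N$ is a death.

Projecting (mass $1/N$, ignore levels) recovers the population model in
distribution — tested against `gillespie_run()` by a two-sample KS test on
total mass, alongside a KS test of pooled levels against Uniform$[0,N]$.

In **limit mode** ($N \to \infty$ at fixed $\alpha$), lines of descent move
as diffusions with drift $r\gamma(b + C\,\partial_x \log r)$ and squared
diffusion $r\gamma C$, levels follow
$\dot u = \alpha\gamma r u^2 - (\gamma\mathcal{B}r + F)u$, and new lines
appear above level $u$ as a Poisson process of intensity $2\alpha\gamma r$
per unit level, truncated at `u_max`.  With $\alpha = 0$ no new lines are
ever created.  The truncation is a simulation device: levels are not
monotone in the deterministic case, so lines near `u_max` may re-descend;
doubling `u_max` and comparing sampled-lineage statistics is the recommended
diagnostic, and the package fixes no theoretical bound.

`trace_lineage()` walks a sampled label's ancestry backward through the
event log (the lineage jumps to the parent's location exactly when the
sampled line received the offspring role), and `export_genealogy()`
serialises the ancestry forest of a sample as Newick trees, ultrametric in
model time.

## PDE scaling limits

With $\alpha = 0$ the density solves the nonlocal equation
$$\partial_t\varphi = r\,\mathcal{B}^*(\gamma\varphi) + \varphi F,$$
with $r, \gamma, F$ evaluated at kernel-smoothed densities and
$\mathcal{B}^* = \tfrac12\sum C_{ij}\partial_{ij} - \sum b_i\partial_i$ the
adjoint dispersal generator.  `solve_nonlocal()` computes the three
smoothings by FFT each step (periodic domains) and steps explicitly (Heun).
As kernel widths shrink this approaches the classical equations handled by
`solve_local_rd()` (central differences + upwind drift + Heun) and
`solve_pme_logistic()` ($\partial_t\varphi = \Delta(\varphi^2) +
\varphi(1-\varphi)$, central Laplacian of $\varphi^2$ with adaptive explicit
steps $dt \le 0.2\,dx^2/\max(2\varphi)$).  The empirical convergence is part
of the test suite: the $L^1$ distance at $T=1$ between nonlocal and local
solutions falls roughly like $\epsilon^2$ across widths
$\epsilon \in \{0.8, 0.4, 0.2, 0.1\}$, for both the reaction–diffusion and
porous-medium cases.

All solvers are explicit by design — transparency and testability over
speed — with CFL guards that error (with a suggested step) rather than
silently destabilise: $\sigma^2 dt/dx^2 \le 0.4$ for the linear solvers, the
same bound with the instantaneous $\max r\,\partial_m(m\gamma(m))$ as
effective diffusivity for the nonlocal case.  Negative values produced by
explicit steps are clipped at zero and the clipped mass is tracked; for
pure-diffusion configurations mass is conserved to $10^{-6}$ relative.

Three reference travelling waves (`wave_frame_model()`) anchor the analysis
($\sigma^2 = 2$, $b = 0$):

| model | equation | profile $w$ | speed |
|---|---|---|---|
| `fisher_kpp` | $\varphi_t = \varphi_{xx} + \varphi(1-\varphi)$ | numerically relaxed | $2$ (minimal) |
| `allen_cahn` | $\varphi_t = \varphi_{xx} + \varphi(1-\varphi)(2\varphi-1+s)$ | $(1+e^x)^{-1}$ | $s$ |
| `pme_logistic` | $\varphi_t = (\varphi^2)_{xx} + \varphi(1-\varphi)$ | $(1-e^{x/2})_+$ | $1$ |

The porous-medium profile is an exact solution: substituting
$w = 1 - e^{z/2}$ gives $\partial_t w = \tfrac12 e^{z/2} =
\Delta(w^2) + w(1-w)$ pointwise behind the front, and
`travelling_wave_residual(..., derivatives = "analytic")` verifies this to
floating-point zero.  The minimal-speed Fisher-KPP profile is *selected
dynamically* (relaxation of a Heaviside condition in the co-moving frame,
then recentred at $w(0)=\tfrac12$) rather than found by shooting, mirroring
how the minimal wave is selected by the dynamics; the table is cached per
session.  Front positions are tracked at the 0.5 level (well defined for
both sharp and smooth fronts); `support_edge()` additionally reports the
$10^{-6}$-threshold support edge for sharp fronts.  Speeds are
least-squares slopes of front position against time (`estimate_speed()`).

No preferred scheme exists for the degenerate diffusion of the
porous-medium equation; the explicit central $\varphi^2$ scheme is a
pragmatic choice whose front-location bias we measure (speed $0.9999$
at $dx = 0.1$ against the exact $1$) rather than bound.

## Ancestral lineages

Sampling an individual at the present and following its ancestry backward
gives, in the deterministic limit, a diffusion (there is no coalescence in
that limit).  In the lab frame with isotropic dispersal the generator is
$$\tfrac{\sigma^2}{2} r\gamma\left[\Delta + \left(2\nabla\log(\gamma\varphi)
 - 2b/\sigma^2\right)\cdot\nabla\right],$$
lineages being drawn toward regions of high fecundity at speed set by
$r\gamma$; in the frame of a travelling wave with speed $c$ the drift gains
$+c$.  `lineage_coeffs()` assembles $(a, \mu)$ for the three wave models
(closed forms) or for a stationary lab-frame source; `simulate_lineage()`
integrates $dX = \mu\,ds + \sqrt{2a}\,dW$ by Euler–Maruyama.

For a 1-d generator $a\partial_{xx} + \mu\partial_x$ the *speed measure*
$m \propto a^{-1}\exp(\int \mu/a)$ gives the stationary law when integrable
(`stationary_density()`):

* Fisher-KPP: $m \propto w^2 e^{2x}$ does not decay in the tip — **no
  stationary law**; lineages are pushed into the tip (pulled wave);
* Allen–Cahn: $m_A(x) = e^{sx}(1+e^x)^{-2}/B(s, 2-s)$, maximised behind the
  tip;
* porous-medium: $m_P(\xi) = 3e^\xi(1 - e^{\xi/2})$ on $\xi < 0$ (the
  normalisation is $3$ because $\int_{-\infty}^0 e^\xi(1-e^{\xi/2})d\xi =
  1/3$), entirely behind the sharp front — nonlinear diffusion behaves like
  a pushed wave even with logistic growth.

At the porous-medium front the diffusion coefficient $a = w$ vanishes and
the drift tends to $-1$; simulated paths are reflected at a small offset
($10^{-6}$) behind the front.  Since the speed measure vanishes there, the
boundary handling has vanishing stationary impact (halving the offset
changes nothing measurable).  Log-gradients of $\gamma\varphi$ for numeric
sources use central differences with a $10^{-300}$ floor; requests where the
density is genuinely zero are errors, not clips.

The stationary law of a lab-frame stationary profile with gradient drift is
returned in the reversible closed form
$\pi \propto (\gamma/r)\varphi^2 e^{-2h/\sigma^2}$; only the normalised
density is exposed, since the overall constant is convention-dependent.  The
per-capita long-term **reproductive value** is $\pi/\varphi$ up to
normalisation (`reproductive_value()`).  A consequence worth spelling out:
multiplying both establishment and death by a spatial factor $\lambda(x)$
(i.e. $\tilde r = \lambda r$, $\tilde F = \lambda F$) leaves every
stationary profile unchanged but multiplies $\pi$ by $1/\lambda$ — the
population profile alone cannot identify the demography, while lineage
occupation can, and the test suite demonstrates exactly this with a
two-patch $\lambda$.

## Clumping: the dispersion relation

Linearising the nonlocal equation around a spatially constant equilibrium
$\varphi_0$ (where $F(\varphi_0) = 0$, $F'(\varphi_0) < 0$) and Fourier
transforming gives a per-mode growth rate
$$\lambda(u) = -u^2\sigma^2\varphi_0 r_0\gamma_0'\,\hat\rho_\gamma(u)
 - u^2\sigma^2 r_0\gamma_0 + \varphi_0 F_0'\,\hat\rho_F(u),$$
with $\sigma^2$ the coefficient of $\Delta$ in the smooth-density equation
(half the dispersal variance $C$).  **Normalisation note**: `growth_rate()`
uses the unit-normalised transform $\hat\rho(u) = \int e^{iux}\rho(x)\,dx$
(so $\hat\rho(0) = 1$), under which $\lambda(u)$ is the *exact* exponential
rate of a small single-mode perturbation of `solve_nonlocal()` — the test
suite verifies agreement within a few percent.  `kernel_fourier()` itself
carries a $1/(2\pi)$ prefactor (a common transform convention, and the one
its documented examples use); the two are proportional, so every sign and
band-boundary conclusion is identical under either convention, but only the
unit normalisation makes $\lambda$ a rate.  Where an analytic inequality
for the Gaussian-$\gamma'$ instability threshold has a convention-dependent
constant, the package never uses it: `unstable_band()` decides instability
numerically from $\lambda(u)$.

For a Gaussian competition kernel and constant $\gamma$, $\hat\rho_F > 0$
everywhere and the equilibrium is always stable.  When $\gamma$ *declines*
with density, Gaussian kernels can destabilise even though their transform
never changes sign, but under the unit normalisation this requires the
birth rate to fall steeply: $\varphi_0|\gamma_0'| > \gamma_0$ is necessary
(the destabilising term $-u^2\sigma^2\varphi_0 r_0\gamma_0'\hat\rho_\gamma$
must beat $-u^2\sigma^2 r_0\gamma_0$ where $\hat\rho_\gamma \le 1$), and
then long-range dispersal ($\sigma^2/\epsilon^2$ large) tips the balance at
small $\epsilon u$.  A top-hat kernel of
half-width $\epsilon$ has $\hat\rho_F < 0$ on
$(\pi/\epsilon, 2\pi/\epsilon)$: when dispersal is short relative to the
interaction range ($\sigma^2/\epsilon^2$ small) a band of wavenumbers
inside that interval grows — the population spontaneously forms periodic
clumps with spacing set by the interaction distance.
`predicted_vs_observed_wavelength()` closes the loop: it runs the nonlocal
solver from equilibrium plus $10^{-3}$ white noise until the pattern
saturates and compares the spectral-peak wavelength with $2\pi/u^*$; they
agree within ~15% (nonlinear selection and the integer mode count on a
periodic domain account for the gap, hence the 20% tolerance).

## Synthetic initial conditions

`make_fixture()` generates the three initial conditions used everywhere:
homogeneous Poisson point clouds at a given density (the natural
"statistical equilibrium" start — at density 1 and scale $N$ it emulates a
population at carrying capacity, and realized counts are Poisson, not
fixed), Heaviside blocks (invasion fronts), and sampled closed-form wave
profiles.  These fixtures emulate the *idealised* study conditions:
homogeneous space, Gaussian dispersal, instantaneous establishment, no age
structure, uniparental reproduction.  Passing tests therefore demonstrate
internal consistency of model, limits and genealogies under those
conditions — not agreement with any field data, where mating systems,
heterogeneous habitat and measurement error all intervene.

## Numerical choices and problem sizes

Simulation sizes used by the test suite and the acceptance script were
chosen as the smallest at which the quantities of interest are
statistically resolvable: PDE speed estimates use the stated grids
($dx = 0.2$ / $dt = 0.008$ for Fisher-KPP on $[0,400]$; $dx = 0.1$ adaptive
for the porous-medium run on $[0,200]$); the discrete-time equilibrium run
uses $N = 100$ on a periodic length-50 domain ($\approx 5000$ individuals)
for $T = 50$ unscaled time units; lookdown-versus-direct comparisons use
500 replicates of small populations ($N = 12$, length 3, $\theta = 3$),
where the total-mass law is already sensitive to any bookkeeping error;
lineage stationarity uses 200 paths with a backward horizon of 200 and a
20-unit burn-in.  Random-number use is always through R's global stream;
`set.seed` (or the `--seed` flag of the CLI and acceptance script) makes
every stochastic result reproducible.

Known limitations: the nonlocal solver and the fft density mode are 1-d
(2-d populations are simulated with direct sums only); there is no 2-d
porous-medium solver; implicit time stepping is out of scope; dispersal
covariance is spatially constant in the PDE solvers; coalescent-rate
asymptotics and the stochastic ($\alpha>0$) measure-valued limit itself are
not simulated — the finite-$N$ individual-based model stands in for that
regime.
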