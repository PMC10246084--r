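# lrpop — locally regulated spatial population models

`lrpop` is an R toolkit for a spatial birth–death point process in which
birth, establishment and death all respond to *local population density
measured by convolution with a smoothing kernel*, together with its
high-density scaling limits and the genealogies that run through it.  It is
aimed at population geneticists and spatial ecologists who want to study how
the shape of an expanding wave — pulled or pushed, smooth or sharp-fronted —
controls where ancestral lineages sit and therefore what genealogies look
like.

## The model

Individuals live in continuous space (1-d or 2-d, periodic by default) and
carry mass 1/N, so the population is a measure η with local density
ρ\*η(x).  On a time axis scaled by θ:

- an individual at x gives birth at rate **θ γ(x, ρ_γ\*η(x))** to one
  juvenile, displaced by a Gaussian with mean b/θ and covariance C/θ;
- the juvenile instantly **establishes** with probability
  **r(y, ρ_r\*η(y))** at its landing point y, or dies;
- the death rate is defined through its deviation from rγ,

      μ_θ(x) = r(x,η) γ(x,η) − F(x,η)/θ,

  so F is (nearly) the net per-capita reproductive rate; μ_θ ≥ 0 is enforced,
  never clipped.

The ratio α = θ/N separates deterministic (α → 0) from stochastic limits.
The package provides:

- **`gillespie_run` / `discrete_run`** — exact event-driven and synchronous
  discrete-time individual-based simulation, with direct or FFT-binned
  density evaluation;
- **`lookdown_run`** — the same dynamics with lookdown *levels* (uniform on
  [0, N] given positions), lines of descent under Ulam–Harris labels,
  uniform sampling by lowest levels (`sample_k_lowest`), ancestral lineage
  tracing (`trace_lineage`) and Newick genealogy export
  (`export_genealogy`); a limit mode simulates lines of descent in the
  infinite-density limit;
- **`solve_nonlocal` / `solve_local_rd` / `solve_pme_logistic`** — explicit
  finite-difference solvers for the nonlocal limit
  ∂φ/∂t = r 𝓑\*(γφ) + φF and its classical limits, including the Fisher-KPP
  equation (minimal speed c = 2), the Allen–Cahn equation (speed s, profile
  (1+eˣ)⁻¹) and the porous medium equation with logistic growth
  ∂φ/∂t = Δ(φ²) + φ(1−φ), whose sharp-fronted wave (1 − e^{x/2})₊ travels at
  c = 1; plus front tracking and wave-speed regression;
- **`lineage_coeffs` / `simulate_lineage` / `stationary_density`** — the
  backward-in-time ancestral lineage diffusion
  (σ²/2) rγ [Δ + 2∇log(γφ)·∇] (+ wave-frame drift c), its speed measure
  m ∝ a⁻¹ exp(∫ μ/a), and per-capita reproductive values π/φ;
- **`growth_rate` / `unstable_band` / `predicted_vs_observed_wavelength`** —
  the linear "clumping" dispersion relation
  λ(u) = −u²σ²φ₀r₀γ₀′ρ̂_γ(u) − u²σ²r₀γ₀ + φ₀F₀′ρ̂_F(u) around a constant
  equilibrium, and its confrontation with the nonlinear pattern.

## Worked example

```r
library(lrpop)
set.seed(1)

## 1. a Fisher-KPP invasion front selects the minimal speed 2
dx <- 0.2
xg <- seq(0, 200 - dx, by = dx) + dx/2
phi0 <- density_field(xg, as.numeric(xg < 10), boundary = "neumann")
traj <- solve_local_rd(phi0, rate_fn("logistic_F"), sigma2 = 2,
                       T = 60, dt = 0.008, record_every = 1)
est <- estimate_speed(traj, level = 0.5, t_window = c(20, 60))
cat(sprintf("front speed: %.3f +/- %.4f\n", est$speed, est$se))
#> front speed: 1.963 +/- 0.0010

## 2. top-hat competition with short dispersal destabilises the equilibrium
band <- unstable_band(dispersion_spec(phi0 = 1, F0p = -1, sigma2 = 0.0025,
                                      kernel_F = kernel_spec("tophat", 1)))
band
#> <dispersion_result: 1 unstable band(s), u* = 4.39435 (wavelength 1.42983)>

## 3. in the sharp-fronted porous-medium wave, ancestral lineages
##    equilibrate strictly behind the front
mp <- wave_frame_model("pme_logistic")
sd_p <- stationary_density(mp)
cat(sprintf("mean lineage position behind the front: %.3f\n",
            sum(sd_p$x * sd_p$density) * diff(sd_p$x[1:2])))
#> mean lineage position behind the front: -1.667
```

The estimated front speed of 1.963 is the finite-window, finite-grid value
of the asymptotic minimal speed 2 (convergence to the minimal wave is slow —
longer domains and windows move it to 1.99); the unstable band around
u\* ≈ 4.4 means clumps form spontaneously with spacing ≈ 1.4 interaction
lengths; and the stationary lineage density 3e^ξ(1 − e^{ξ/2}) has mean −5/3,
i.e. the typical ancestor of a front individual sits well behind the front
edge — the porous-medium wave behaves like a pushed wave even though its
growth term is the same logistic one as Fisher-KPP's (where no stationary
law exists and lineages ride the tip).

## Command line

A thin wrapper around the same functions ships in `inst/cli/lrpop.R`:

```sh
Rscript inst/cli/lrpop.R simulate-ibm --config cfg.yaml --out run1 --seed 7
Rscript inst/cli/lrpop.R solve-pde --equation kpp --config cfg.yaml --out traj.tsv --seed 1
Rscript inst/cli/lrpop.R wave-speed --in traj.tsv --level 0.5 --window 20,60
Rscript inst/cli/lrpop.R lookdown --config cfg.yaml --out run2 --seed 7 --sample-k 5 --newick run2.nwk
Rscript inst/cli/lrpop.R dispersion --config cfg.yaml --umax 20 --n 2048 --out disp.tsv
```

Every stochastic command is a pure function of (config, seed); outputs are
headered TSV, Newick, and a JSON metadata sidecar.

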