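# sirsTuring

Turing instability and pattern formation in a stochastic spatiotemporal
SIRS epidemic model with reinfection and saturated incidence.

## The problem

Spatial epidemic models of reaction–diffusion type can destabilise their
spatially homogeneous endemic state purely through the disparity of
diffusion coefficients — the Turing mechanism — and self-organise into
stationary patterns of infection density.  This package analyses that
phenomenon for an SIRS model in which

* recovered individuals lose immunity at rate μ (reinfection), closing the
  S → I → R → S loop;
* the force of infection saturates, β(I) = β₀ I² / (1 + α I²), modelling
  behavioural inhibition of spread at high prevalence;
* the infected density is driven by spatiotemporal Gaussian white noise of
  per-cell intensity C_I.

The governing equations are

    ∂S/∂t = b − dS − β₀SI²/(1+αI²) + μR + D₁∇²S
    ∂I/∂t = β₀SI²/(1+αI²) − (γ+d)I + D₂∇²I + ξ(t,x,y)
    ∂R/∂t = γI − (μ+d)R + D₃∇²R

with no-flux boundaries.  Because linear stability analysis cannot see the
interaction of the quadratic incidence nonlinearity with the noise, the
core of the package is a **second-order (moment-closure) stochastic
stability analysis**: perturbation moments up to second order form a
closed linear system dX/dt = A X per spatial wavenumber k, with A a 9×9
matrix whose entries carry the kinetics coefficients, −k²Dᵢ damping, and
the noise intensity C_I.  The maximal eigenvalue of A over k gives
dispersion curves, Turing thresholds and stability regions in parameter
planes; a 2D explicit Euler–Maruyama integrator produces the corresponding
stationary patterns; diagnostics (grid-convergence studies, dominant
pattern wavenumber) tie the simulations back to the eigenvalue analysis.

It is aimed at researchers in mathematical epidemiology and nonlinear
dynamics who want a reproducible toolkit for noise- and diffusion-driven
instabilities in compartment models with loop closure.

## Worked example

```r
library(sirsTuring)

p <- epidemic_params(alpha = 0.5)       # baseline set, saturation 0.5
select_stable_equilibrium(p)
#> Homogeneous steady state: S0=0.248293 I0=0.300683 R0=0.451024 (stable)

turing_threshold(p)
#> Turing threshold k = 0.5864; unstable band [0.5864, 1.2398]

cfg <- sim_config(nx = 100, ny = 100, t_end = 100, seed = 1)
res <- run_simulation(p, cfg)
res
#> Simulation result: t=100 (t_end reached), 100 x 100 grid
#>   I: mean 0.30037, spatial var 0.01762; 0 clip events

pattern_metrics(res$state$I, cfg$dx)[c("var_I", "k_dominant")]
#> $var_I
#> [1] 0.01762
#> $k_dominant
#> [1] 0.911
```

Reading the numbers: the endemic state (I₀ ≈ 0.30) is stable to
homogeneous perturbations, but susceptible diffusion D₁ = 10 opens an
unstable wavenumber band starting at the Turing threshold k ≈ 0.586.  A
simulation seeded with a tiny random perturbation grows a stationary
pattern (spatial variance 1.8×10⁻², three orders of magnitude above the
initial perturbation variance) whose dominant wavenumber 0.911 lies inside
the predicted band [0.586, 1.240].  Raising saturation to α = 2 with
reinfection μ = 0.1 removes the band and the same simulation decays back
to homogeneity.

A thin command-line wrapper ships in `inst/cli/`:

```sh
sirs-turing threshold --alpha 0.5 --out out/
sirs-turing simulate --alpha 2 --mu 0.1 --nx 100 --t_end 100 --seed 1 --out out/
```

Commands: `equilibrium`, `dispersion`, `threshold`, `diagram`, `simulate`,
`converge`; flat `key = value` config files are supported via `--config`,
with flags taking precedence.  Curves and reports are written as
full-precision delimited text with JSON metadata (parameters and seed), so
every run is reproducible from its own output.

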