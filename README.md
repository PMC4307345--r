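# bioheatmfs

Transient nonlinear bioheat transfer in two-dimensional skin tissue, solved
without a mesh.

Predicting how temperature evolves inside living tissue matters for thermal
therapies (laser surgery, hyperthermia) where clinicians need to heat a
target without burning the healthy tissue around it. The standard model is
the Pennes bioheat equation, a reaction–diffusion PDE in which flowing blood
acts as a distributed heat exchanger:

```
k ∇²T + ρ_b c_b ω_b(T) (T_b − T) + Q_r + Q_m = ρ c ∂T/∂t
```

with tissue conductivity `k`, blood density and specific heat `ρ_b`, `c_b`,
arterial temperature `T_b`, external (e.g. laser) heating `Q_r`, metabolic
heating `Q_m`, and a blood perfusion rate `ω_b` that itself depends on the
local temperature — constant, linear `ω_b = a₁ + a₂T`, or exponential
`ω_b = a₁ e^{a₂T}` — which makes the problem nonlinear.

This package is for computational biophysicists and numerical-methods
researchers who want a compact, fully scriptable implementation of the
meshless operator-splitting approach to this problem:

1. **Operator splitting in time.** The nonlinear perfusion source is
   advanced with the explicit two-step Adams–Bashforth scheme and diffusion
   with the implicit Adams–Moulton (trapezoidal) scheme. In the shifted
   variable `θ = T − T_b` every step reduces to a *modified Helmholtz*
   problem for the half-step average `θ* = (θⁿ⁺¹ + θⁿ)/2`:
   `∇²θ* − λ²θ* = F`, with `λ² = 2ρc/(kΔt)`.
2. **Dual reciprocity + method of fundamental solutions in space.** The
   nonhomogeneous part of `θ*` is interpolated with thin-plate-spline
   radial basis functions `φ(r) = r² ln r`, whose Laplacian particular
   solutions `Φ(r) = r⁴(2 ln r − 1)/32` are known in closed form; the
   homogeneous remainder is a superposition of Laplace fundamental
   solutions `G = −ln r/(2π)` anchored at fictitious sources outside the
   tissue. Collocating the PDE at 63 interior points and the boundary
   conditions at 32 boundary points yields one small dense linear system,
   factored once and reused at every time step.

A completely independent Crank–Nicolson finite-difference solver
(`fd_march()`), validated against closed-form solutions, serves as the
built-in reference, and the analysis layer reproduces the standard
experiments: centerline temperature profiles, steady-state timing, and
sensitivity sweeps over the perfusion coefficients `a₁`, `a₂` with
automatic detection of the common intersection point of the steady curves.

## Worked example

```r
library(bioheatmfs)

cfg <- bioheat_config(
  perfusion = perfusion_model("linear", a1 = 5e-4, a2 = 1e-4),
  stepping  = step_parameters(t_end = 100),
  output    = list(snapshot_times = c(50, 100)))

rec <- march(cfg)
rec
#> Bioheat run: 216 tracked points, 3 snapshots, t up to 100 s
#>   steady state not reached within the simulated window
#>   lambda2 = 1.68e+07 1/m^2, condition estimate 3.9e+10

centerline_profile(rec, 100)[c(1, 31, 61, 91, 121), ]
#>         x      T
#> 1   0.000 25.000
#> 31  0.007 36.471
#> 61  0.015 37.647
#> 91  0.022 37.643
#> 121 0.030 37.000
```

At `t = 100 s` the cold surface (25 °C at `x = 0`) has chilled only the
outer few millimetres; the interior sits slightly above the arterial 37 °C
because metabolic plus imposed heating (`Q_t = 34200 W/m³`) outpaces the
perfusion sink. Cross-checking against the finite-difference reference:

```r
verify_against_reference(cfg)$errors
#>  t=50s t=100s
#> 0.4657 0.1941
```

i.e. the meshless solution with only 95 unknowns tracks the 847-unknown
grid solution to better than 0.5% everywhere on the centerline. A
sensitivity sweep over the perfusion intercept:

```r
sensitivity_sweep(
  bioheat_config(perfusion = perfusion_model("linear", 5e-4, 2e-4)),
  "a1", c(0.005, 0.0005, 0.00005))
#> Sensitivity sweep over a1: 0.005, 5e-04, 5e-05
#>   intersection: x = 11.880 mm, T = 37.370 degC (spread 0.00472 degC)
```

The three steady profiles pivot about a common point close to blood
temperature: below it stronger perfusion warms the tissue, above it
stronger perfusion cools it — the thermoregulatory role of blood flow.

A thin command-line wrapper is installed at `inst/cli/bioheat`
(subcommands `solve`, `reference`, `verify`, `sweep`; see `?run_cli`).

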