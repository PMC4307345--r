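---
title: "Methods: meshless operator-splitting solution of nonlinear bioheat transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meshless operator-splitting solution of nonlinear bioheat transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioheatmfs)
```

## The physical model

The package solves the Pennes bioheat equation in a rectangular
cross-section of skin tissue,

$$ k \nabla^2 T + \rho_b c_b\, \omega_b(T)\,(T_b - T) + Q_r + Q_m
   = \rho c\, \frac{\partial T}{\partial t}, $$

where the perfusion term models the capillary bed as a distributed heat
exchanger at arterial temperature $T_b$. Because vessels dilate as tissue
warms, the perfusion rate $\omega_b$ is itself temperature dependent; the
package implements the three standard laws (constant, linear
$a_1 + a_2 T$, exponential $a_1 e^{a_2 T}$), which makes the reaction term
nonlinear. In the shifted variable $\theta = T - T_b$ the equation becomes

$$ \frac{\partial\theta}{\partial t}
   = \frac{k}{\rho c}\nabla^2\theta + f(\theta), \qquad
   f(\theta) = -\frac{\rho_b c_b}{\rho c}\,\omega_b(\theta + T_b)\,\theta
               + \frac{Q_t}{\rho c}, \quad Q_t = Q_r + Q_m. $$

The domain is the rectangle $[0, L_x]\times[0, L_y]$ with $x$ measured
from the skin surface. The left edge is held at the ambient/surface
temperature $T_s$, the right edge at the body-core temperature $T_c$, and
the top and bottom edges are insulated, which makes the physical solution
one-dimensional in $x$; solving the 2D rectangle keeps the method general
and provides a built-in consistency check (y-invariance, below).

### Assumptions

* a single homogeneous tissue layer (no fat/dermis/epidermis layering);
* constant thermal conductivity (no temperature dependence);
* perfusion responds to temperature instantaneously;
* the tissue starts in thermal equilibrium with the blood,
  $T(\mathbf{x}, 0) = T_b$, unless configured otherwise.

## Time discretisation: operator splitting

The diffusion operator and the nonlinear source are advanced by different
second-order schemes: the source explicitly with the two-step
Adams–Bashforth extrapolation $\tfrac32 f(\theta^n) - \tfrac12
f(\theta^{n-1})$, diffusion implicitly with the Adams–Moulton
(trapezoidal) rule. Adding the two half-updates and introducing the
half-step average $\theta^* = (\theta^{n+1} + \theta^n)/2$ turns each step
into a *modified Helmholtz* boundary-value problem

$$ \nabla^2\theta^* - \lambda^2 \theta^* = F, \qquad
   \lambda^2 = \frac{2\rho c}{k\,\Delta t}, \qquad
   F = -\frac{\rho c}{k}\Big[\tfrac32 f(\theta^n) - \tfrac12
       f(\theta^{n-1})\Big] - \lambda^2\theta^n, $$

after which $\theta^{n+1} = 2\theta^* - \theta^n$. Because $\theta^*$ is
an average, its Dirichlet data are averaged too:
$\theta^* = (\theta_{c} + \theta^n)/2$ on the core edge and
$(\theta_{s} + \theta^n)/2$ on the surface edge, while the insulated edges
keep $\partial\theta^*/\partial n = 0$.

The two-step scheme cannot start itself. The first step uses forward-Euler
extrapolation of the source with backward-Euler diffusion, which is the
same Helmholtz problem with parameter $\rho c/(k\Delta t)$ — exactly half
the marching $\lambda^2$ — and *un-averaged* boundary values. The
first-step scheme is first order, the march second order; the temporal
convergence test (error ratio $\approx 4$ when $\Delta t$ halves) passes
with the bootstrap included, confirming the start-up error does not
degrade the order in practice.

## Space discretisation: dual reciprocity + fundamental solutions

Each Helmholtz problem is solved meshlessly with the splitting
$\theta^* = \theta_p + \theta_h$:

* **Particular solutions by dual reciprocity.** The nonhomogeneous term is
  interpolated over $M$ interior points by first-order thin plate splines
  $\varphi(r) = r^2\ln r$, for which the particular-solution kernel
  $\Phi(r) = r^4 (2\ln r - 1)/32$ satisfies $\nabla^2\Phi = \varphi$
  exactly (this identity is enforced as a finite-difference test, not
  assumed). Both kernels have removable singularities at $r = 0$, where
  the limit value $0$ is used — necessary because the RBF centers *are*
  the interpolation points.
* **Homogeneous solutions by fundamental solutions.** The remainder is a
  superposition of Laplace kernels $G(r) = -\ln r/(2\pi)$ anchored at $N$
  fictitious sources placed outside the domain, so no kernel is ever
  singular inside the closure.

Collocating the PDE at the $M$ interior points and the boundary
conditions at the $N$ boundary points yields one dense square
$(M{+}N)\times(M{+}N)$ system for the coefficient vector
$(\alpha_1,\dots,\alpha_M,\beta_1,\dots,\beta_N)$. Since the fundamental
solutions are harmonic, the PDE rows reduce to
$[\varphi_i - \lambda^2\Phi_i \;|\; -\lambda^2 G_j]$. The matrix depends
only on geometry and $\lambda^2$: it is factored once and reused at every
time step, which is why a ten-thousand-step march takes seconds.

A sign convention note: the insulated-edge rows use the geometric normal
derivative of the representation. For homogeneous Neumann data the overall
sign of those rows is immaterial, so no separate flux-sign convention is
needed.

## Geometry and default parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| $k$ | 0.5 | W/m/K | standard skin conductivity |
| $\rho_b c_b$ | $4.2\times10^6$ | J/m³/K | blood (1000 kg/m³ × 4200 J/kg/K) |
| $\rho c$ (tissue) | $4.2\times10^6$ | J/m³/K | **inferred**: set equal to blood, the usual assumption for water-rich soft tissue; configurable |
| $T_b$, $T_c$, $T_s$ | 37, 37, 25 | °C | arterial / core / surface temperatures |
| $Q_r$, $Q_m$ | 30000, 4200 | W/m³ | imposed (laser) and metabolic heating |
| $L_x \times L_y$ | 30 × 15 | mm | **inferred**: accommodates all standard probe locations (up to 26.25 mm); with insulated horizontal edges the solution is independent of $L_y$ |
| interior grid | 9 × 7 = 63 | — | standard collocation density for this problem |
| boundary points | 9+7+7+9 = 32 | — | corners owned by the Dirichlet (vertical) edges so Dirichlet rows stay well-posed |
| `source_offset` | 1.5 | — | sources at 2.5× the boundary's distance from the centroid; standard fictitious-boundary practice, configurable, condition-monitored |
| $\Delta t$ | 1 | s | resolves the fastest perfusion time scale ($1/\omega_b \gtrsim 200$ s) with large margin; snapshot times of interest are multiples |
| $T(x, 0)$ | $T_b$ | °C | physiological rest state (assumption, configurable) |
| march stop `steady_tol` | $10^{-5}$ | °C/step | conservative stopping rule |
| steady-state *detection* tol | $10^{-4}$ | °C/step | reporting rule used by `steady_state_time()` |

The tissue $\rho c$ and the domain length are the two genuinely open
inputs (they are not part of the standard property table); both are
flagged as inferences here and are plain configuration fields. Note that
steady-state *profiles* are independent of $\rho c$ (it scales only the
transient), and the intersection locations of the sensitivity sweeps are
insensitive to $L_y$ but do depend on $L_x$.

## Numerical choices

* **Conditioning.** Fundamental-solution collocation matrices are
  notoriously ill-conditioned; at $\lambda^2 = 1.68\times10^7$ m⁻² the raw
  matrix has reciprocal condition around $10^{-20}$, which base `solve()`
  rightly refuses. The solver therefore equilibrates rows and columns
  (max-norm scaling) before a LAPACK QR factorisation; the equilibrated
  condition estimate (≈ $4\times10^{10}$ for the default problem) is
  reported in the diagnostics and checked against a configurable warning
  threshold (default $10^{12}$). The unscaled residual
  $\|Ac-b\|_\infty/\|b\|_\infty$ is verified below $10^{-8}$ on every
  solve. Despite the conditioning, accuracy is solver-limited, not
  arithmetic-limited — the standard behaviour of this method.
* **Per-step work.** Both operators (marching and bootstrap) and the
  evaluation matrix at all tracked points are precomputed; each step costs
  one triangular solve plus one small mat-vec.
* **Steady detection.** The march stops when the per-step change stays
  below `steady_tol` for 5 consecutive steps; `steady_state_time()`
  scans the recorded change series for the first time after which it
  stays below the (larger) detection tolerance. Reported steady times
  depend strongly on this tolerance: under the default rule the standard
  linear case settles at roughly 600 s and the exponential case at
  roughly 950 s (the exponential law gives weaker perfusion at these
  coefficients, hence a slower approach). These are detection-rule
  outputs, not physical constants.
* **Intersection finding.** Sweep curves all satisfy the same Dirichlet
  data, so their spread vanishes trivially at the domain ends; the search
  for the common intersection therefore takes the discrete minimiser of
  the max pairwise spread over *interior* samples only and refines it by
  piecewise-linear interpolation between the two neighbouring samples.
  Identical curves are reported as degenerate rather than returning an
  arbitrary point.
* **Degenerate inputs.** $r = 0$ kernel evaluations return their limit
  values; querying the field at a fictitious source is an error; duplicate
  collocation points, non-unit normals and sources inside the domain are
  rejected at construction.

## Verification strategy, and what it does not show

The package carries its own reference: a Crank–Nicolson finite-difference
solver on a 121 × 7 node grid (0.25 mm spacing in $x$) with the same
Adams–Bashforth source treatment. Its discretisation shares nothing with
the collocation solver, so agreement is evidence rather than tautology.
The reference is itself validated against closed forms: a 50-term Fourier
series for the pure-diffusion slab (errors below $10^{-3}$ °C at 0.125 mm
spacing, below 0.1% relative at the default grid) and the cosh/sinh
steady profile for constant perfusion

$$ T(x) = T_\infty + A\cosh(mx) + B\sinh(mx), \quad
   m^2 = \frac{\rho_b c_b \omega_b}{k}, \quad
   T_\infty = T_b + \frac{Q_t}{\rho_b c_b \omega_b}, $$

(itself cross-checked against an independent fine-grid boundary-value
solve). On the standard linear-perfusion problem the meshless solution
agrees with the reference within 0.5% along the centerline at
$t = 50, 80, 100$ s.

The y-invariance property deserves a caveat: the grid solver is exactly
y-invariant under x-only data (to linear-algebra epsilon, $<10^{-6}$ °C),
while the meshless solution is y-invariant only to its spatial
discretisation error — about $10^{-2}$ °C at the 63/32 study resolution.
The test suite asserts both at their respective levels.

What none of this shows: agreement with *real tissue*. All experiments
here are synthetic instances of the Pennes model itself — homogeneous
properties, idealised boundary conditions, smooth perfusion laws. Passing
tests demonstrate that the solver solves the stated model accurately, not
that the model captures layered skin, discrete vasculature, thermoreceptor
feedback, or non-Fourier conduction effects.

## Problem sizes used by the tests

The suite runs the study-scale problems directly (63/32 collocations,
121 × 7 reference grid, marches up to a few thousand 1-second steps) —
small enough that the whole suite completes in well under a minute while
exercising every code path at full scale. The temporal-convergence test
uses $\Delta t \in \{8, 4, 1\}$ s over a 64 s horizon in the
pure-diffusion limit, where the temporal error dominates the (shared)
spatial error.

## Known limitations

* Single-material rectangles only; layered or irregular geometry requires
  domain decomposition, which the method does not provide here.
* Increasing the collocation density or the source offset eventually
  exhausts double precision (the condition estimate warns); this caps the
  attainable spatial accuracy well before machine epsilon.
* The explicit source treatment assumes perfusion time scales slower than
  $\Delta t$; extremely strong perfusion ($\omega_b \Delta t \gtrsim 1$)
  would need smaller steps.
* Steady-state *times* are tolerance-defined diagnostics; only steady
  *profiles* are tolerance-free.
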