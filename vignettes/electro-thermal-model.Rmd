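---
title: "The coupled electro-thermal model behind epsim"
author: "epsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled electro-thermal model behind epsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsim)
```

## The model

Electroporation-based treatments (electrochemotherapy, irreversible
electroporation, gene electrotransfer, H-FIRE) permeabilize cell membranes
wherever the local electric field magnitude exceeds a threshold. Predicting a
treatment outcome therefore reduces to computing the field distribution that
a pulse protocol induces in tissue, together with the temperature it
deposits, and comparing the field against reversible and irreversible
thresholds.

`epsim` solves, on a uniform 3D finite-difference grid:

1. **Charge conservation** for the electrostatic potential,
   $\nabla \cdot (\sigma \nabla \Phi) = 0$, with Dirichlet values on
   electrode nodes (electrodes are treated as perfect conductors) and zero
   normal current on tissue–air surfaces. The field is
   $\mathbf{E} = -\nabla\Phi$, the current density $\mathbf{J} = \sigma
   \mathbf{E}$, and the electrode current is the discrete surface integral
   of $\mathbf{J}$ over the voxel surface of an electrode.
2. **A linear conductivity–temperature law**
   $\sigma = \sigma_b\,(1 + \alpha\,(T - T_0))$, which is the nonlinearity
   coupling the two equations. Field-dependent conductivity sigmoids are a
   deliberate non-goal of this version.
3. **Pennes' bioheat equation**
   $\rho C_p\, \partial T/\partial t = \nabla\cdot(\kappa\nabla T)
   - \rho_b \omega_b C_b (T - T_b) + \sigma|\nabla\Phi|^2 + q^m$,
   with a convective (Robin) condition $-\kappa\nabla T\cdot \hat n =
   h\,(T - T_r)$ on exposed electrode surfaces and zero flux on tissue–air
   surfaces.
4. **A pulse-number-dependent electroporation threshold**
   $E_{thr}(n) = E_\infty + (E_0 - E_\infty)\, e^{-n/\tau}$. The decay of
   the threshold with delivered pulse number is an established experimental
   observation; the three-parameter exponential is this package's
   parameterization of it (the decay variable is pulse number, a proxy for
   exposure time at fixed repetition frequency). A second instance of the
   same type, by default the constant 500 V/cm, models the irreversible
   (lethal) threshold, and "damage" is the union of the irreversible field
   region and thermal excess $T \ge T_{crit}$ (no default is claimed for
   $T_{crit}$; pH-mediated damage is out of scope).

The simulation loop alternates an energized stage (`t_ON`), during which the
potential equation is re-solved every time step with the conductivity
updated from the current temperature (Picard-style one-way coupling per
step, no inner iteration), and a rest stage (`t_OFF`), during which the
applied voltage is zero, the field is identically zero and the potential
solve is bypassed entirely. Zero-voltage instants inside an H-FIRE burst
(the inter-phase delays) bypass the solve the same way while still counting
as part of the energized stage.

## Numerical scheme and its choices

**Spatial discretization.** Node-centered uniform grid, spacing `h` on all
axes; all geometry is converted to SI meters at configuration load (configs
use mm, µs and the field's customary V/cm). Electrode solids (needle
cylinders with arbitrary axis, or axis-aligned plate boxes) are rasterized
by an exact, boundary-inclusive point-membership test at node coordinates;
there is no sub-voxel anti-aliasing, so a refinement by 2 changes a
rasterized electrode volume by at most one surface layer.

**The potential solve.** 7-point variable-coefficient stencil with face
conductivities taken as the *harmonic mean* of the adjacent nodal values.
The harmonic mean is flux-continuous across conductivity jumps and makes
the solver reproduce the series-resistor closed form of layered media
exactly at the stencil level. The zero-flux boundary condition is realized
by omitting the outside face (equivalent to a mirror node). The linear
system is solved by red–black successive over-relaxation, ω = 1.8 by
default, to a relative L2 residual of 1e−6 (both configurable). Within a
pulse the fields change slowly, so each solve is warm-started from the
previous solution; across an H-FIRE polarity flip the warm start is the
previous solution rescaled by the voltage ratio, which is near-exact
because the equation is linear in the applied voltage.

**The thermal step.** Backward Euler with the same relaxation machinery
(inner tolerance 1e−8). Implicit stepping is essential: the rest stage is
covered by a single step of nearly a full pulse period, far beyond any
explicit diffusion stability bound at tissue diffusivities and sub-mm
spacings. For the implicit system the ρCp/dt term dominates the diagonal
and plain Gauss–Seidel (ω = 1) converges fastest, so the thermal solver
uses ω = 1. The diffusion stencil mixes tissue and electrode thermal
conductivities by the same harmonic-mean rule; perfusion and metabolic
terms act in tissue nodes only; Joule heat is deposited in tissue only
(perfect conductors dissipate nothing). The ON stage is subdivided into
1000 steps by default, following the reference discretization for these
protocols; tests and examples reduce this (and coarsen grids) to keep runs
in seconds — the physics checks are grid-converged properties, not
absolute-accuracy claims.

**Electrode current.** Faces between electrode nodes and non-electrode
neighbors contribute the stencil-consistent flux $g\,(\Phi_p - \Phi_q)$
with $g = \sigma_{face} h$, weighted by finite-volume dual areas (half
width at domain boundaries). The stencil consistency gives discrete
conservation — anode and cathode currents agree to ~1e−5 relative on
converged solves — and the dual-area weighting makes the uniform-field
plate limit reproduce $I = \sigma E A$ exactly (e.g. 1.6758 A for 0.504
S/m, 250 V/cm, 19 × 7 mm plates). The returned sign convention is
"positive out of the anode, positive into the cathode", so the two values
agree rather than being negatives of each other.

**Charge accumulation.** Trapezoidal integration of the recorded current
samples. Pulse edges are recorded as two samples at the same instant (one
per side of the jump); the zero-width interval contributes nothing, so Q is
exactly flat through every OFF window and the trapezoid never smears a
pulse edge into the rest stage. Within an ON stage, current is sampled at
every time step.

**Tie-breaks and degenerate inputs.** Waveform segments are left-closed /
right-open, so a boundary instant belongs to the later segment and a pulse
end is already OFF. Threshold comparisons are boundary-inclusive
(`|E| >= E_thr`). H-FIRE bursts are filled with complete
positive–delay–negative–delay cycles; a trailing partial cycle is not
emitted, and the remainder of the energized window is zero-voltage. The
asymmetric-phase amplitude ratio is configurable (`hfire.neg_scale`) and
defaults to 1, since published asymmetric waveforms specify asymmetric
*durations*. Degenerate threshold-fit input (constant thresholds) returns
`E_0 = E_inf` with τ flagged unidentifiable instead of failing.
`threshold_from_area` inverts a staircase function, so when no field level
lands within one voxel-area of the requested area the nearest achievable
level is returned and flagged rather than raising an error.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `domain.spacing_mm` | mm | per scenario | resolution/cost trade-off; presets stay ≤ 61³ nodes |
| `protocol.v_per_cm` | V/cm | per protocol | the field's standard amplitude specification; voltage = (V/D)·gap |
| `tissue.sigma_b` | S/m | 0.504 | baseline conductivity of soft tissue used in the needle-pair literature case |
| `tissue.alpha` | 1/°C | 0.015 | conductivity rise per degree; ~1–2 %/°C is typical of soft tissue |
| `tissue.rho, cp, kappa` | SI | 1060, 3600, 0.512 | liver-like soft tissue placeholders (documented defaults, override from measured data) |
| `blood.omega` | 1/s | 1e−3 | perfusion rate; 0 for ex-vivo / vegetable tissue |
| `env.h` | W/m²K | 10 | natural-convection cooling of exposed electrode metal |
| `thresholds.reversible` | V/cm | 800 → 200, τ = 6 | placeholder decay spanning the protocol field range; calibrate per tissue via `fit_threshold_decay` |
| `thresholds.irreversible` | V/cm | 500 | the published lethal isoline for the H-FIRE well case |
| `solver.tol`, `thermal.implicit_tol` | — | 1e−6, 1e−8 | relative residuals; tighten for convergence studies |
| `thermal.dt_on_divisor` | — | 1000 | ON-stage steps per pulse; reduce for exploratory runs |

Whether the conductivity reference temperature `T0` may differ from the
initial temperature `T_init` is left open by the underlying model
descriptions; `epsim` exposes both and defaults them equal (37 °C for
in-vivo presets, 22 °C for the vegetable-tissue presets, which also zero
perfusion and metabolism).

## What the presets and synthetic fields do and do not show

The seven shipped presets transcribe published protocol parameters (pulse
count, ON length, frequency, V/D ratio, electrode geometry, the 900 V
burst specification, the 500 V/cm irreversible threshold). Domain sizes
and detailed physiology are not printed in the protocol tables, so the
presets carry the placeholder defaults above, each overridable; preset
outputs are therefore demonstrations of the machinery on realistic
configurations, not quantitative reproductions of any specific figure.
Likewise the synthetic oracle fields (`make_synthetic_field`: uniform,
linear, radial 1/r, two-slab) have exact closed forms and exercise the
solver, gradient, level-set and threshold-inversion code paths; passing
those tests demonstrates correctness of the discrete operators, not that
any particular tissue is adequately modeled by a linear σ(T) law, an
isotropic κ, or a spatially uniform threshold.

## Problem sizes used in the tests

The test and verification suite runs plate-capacitor accuracy at
41 × 21 × 21, direct-solve equivalence at 13³ (dense assembly), the energy
audit at 21³ with 2 × 10 ON steps, preset smoke runs at ~1 mm coarsened
spacing with one pulse, and the noisy threshold-recovery study with 100
replicates over pulses 0–32. These sizes were chosen so each check
completes in seconds while remaining in the asymptotic regime the check
addresses (e.g. the gradient-convergence test verifies the 4× error drop
under h → h/2 directly).

## Known limitations

- σ depends on temperature only; field-dependent conductivity sigmoids and
  pore-dynamics/capacitive transients are out of scope.
- No Arrhenius thermal-damage integral; thermal damage is a configurable
  temperature ceiling.
- No pH-front damage model.
- Electrodes are perfect conductors; the metal's internal potential drop
  and contact impedance are neglected.
- The nanosecond voltage ramp of real generators is idealized as a step
  (it is orders of magnitude shorter than any time step used here).
- Uniform grids only; no image-derived geometry.
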