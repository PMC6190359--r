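---
title: "Finite-size acoustic radiation forces: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-size acoustic radiation forces: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arftrace)
```

## The model

A standing acoustic field exerts a time-averaged radiation force (ARF) on a
suspended particle through scattering at its boundary. For a particle much
smaller than the wavelength the classical result expresses the force as the
negative gradient of the radiation potential

$$ F^s = -\nabla U, \qquad
U = V_{BP}\left(\mathrm{Re}(f_1)\,\frac{\beta_f}{2}\langle p^2\rangle
  - \mathrm{Re}(f_2)\,\frac{3\rho_{f0}}{4}\langle v^2\rangle\right), $$

with ideal-fluid monopole and dipole scattering coefficients
$f_1 = 1 - \beta_p/\beta_f$ and
$f_2 = 2(\rho_{p0}-\rho_{f0})/(2\rho_{p0}+\rho_{f0})$. The ideal-fluid
coefficients are appropriate in the high-frequency regime this package
targets: `validity_diagnostics()` reports the viscous and thermal
boundary-layer depths $\delta_v = \sqrt{2\mu/\rho\omega}$ and
$\delta_t = \sqrt{2D_{th}/\omega}$ (standard penetration-depth forms),
which at 100 MHz are tens of nanometres — negligible against a 10 µm cell.
The coefficient object keeps a `Re(·)` accessor so complex-valued viscous
extensions would not change the interface.

When the particle diameter is comparable to the wavelength the point
evaluation fails: different volume elements of the particle sit at
different phases of the field and their elementary forces partially cancel.
Because bio-particles have acoustic impedance close to water's (ratio
≈ 1.125 for the reference cell), the field inside the particle is close to
the incident field, and the ARF is well approximated by the volume average
of the point-force field over the particle ball:

$$ F = \frac{1}{V_{BP}}\int_{V_{BP}} F^s\,dv . $$

On a one-directional field $p = p_{ac}\cos(ky)$ the average is analytic:
the point force $F^s_{1D} = 4\pi\Phi a^3 k E_{ac}\sin(2kh)$ picks up the
modifying factor

$$ f_m(\chi) = \frac{3\left[\sin 2\chi - 2\chi\cos 2\chi\right]}{(2\chi)^3},
\qquad \chi = ka, $$

with $f_m \to 1$ as $\chi \to 0$, $f_m(\pi/6) \approx 0.894$ (a 10 µm
particle at $\lambda$ = 60 µm) and a first zero where $\tan x = x$
($x = 2\chi$), i.e. $D_p/\lambda \approx 0.715$. In multi-directional
fields no constant factor can replace the average — the package therefore
evaluates the volume average by quadrature at every requested position, and
the 1-D closed form doubles as an exact oracle for validating that
quadrature.

## Conventions

* **Origin and sign.** Each zero-phase component has a pressure antinode at
  the origin (cosine convention); nodes sit at $ky = \pi/2 + n\pi$. In
  `closed_form_1d(h, ...)` the offset `h` is the node position minus the
  particle position along the axis, so the returned signed force is the
  axial force component directly, and a positive contrast factor drives the
  particle toward the node.
* **Multi-directional phasing.** Components are mutually in phase in time
  (a single $\cos\omega t$ factor). The relative temporal phasing of
  perpendicular components is genuinely open in the patterning literature;
  the in-phase choice produces the checkerboard node/antinode lattice that
  patterned arrays exhibit, and a per-component spatial phase remains
  available in the wave object.
* **Consistent sound speed.** Tabulated $\beta_f$ and $c_f$ are rounded
  independently (for the water registry they disagree at the $10^{-4}$
  level). All time-averaged quantities and forces therefore use the
  compressibility-consistent speed $c = 1/\sqrt{\rho\beta}$, i.e.
  $1/(\rho\omega^2) = \beta/k^2$. This keeps equipartition
  ($\overline{\rho\langle v^2\rangle} = \overline{\beta\langle p^2\rangle}$
  over a wavelength) and the closed-form/gradient force identities exact to
  machine precision rather than true only to the table's rounding.
* **Units.** Everything is SI; config keys carry unit suffixes
  (`wavelength_m`, `peak_pressure_pa`). There is no conversion layer.
* **Shear-speed table entry.** The reference cell registry stores the
  tabulated transverse wave speed 1.244×10³ m/s verbatim, but that entry is
  dimensionally inconsistent with $\sqrt{G/\rho_0}$ at the tabulated
  $G$ = 1.67×10³ Pa (which gives 1.244 m/s). `shear_speed()` follows the
  formula; the stored constant preserves the table. Neither is used by the
  force model.

## Numerical choices

* **Quadrature.** The volume average uses fixed-order Gauss–Legendre
  product rules: radial × polar with an equally-spaced azimuthal rule
  (exact for trigonometric dependence) for the 3-D ball; an in-plane rule
  with the sphere-chord weight $2\sqrt{a^2-d^2}$ for fields invariant in
  the third dimension. The chord weight has a square-root derivative
  singularity at the rim, so the radial variable is substituted
  $\rho = a\sin\psi$, which restores spectral convergence. For
  single-component (1-D) fields the average reduces exactly to a 1-D rule
  with the cross-section weight $\pi(a^2-u^2)$; `method = "auto"` uses this
  fast path, while tests pin `method = "ball"`/`"disk"` so the full rules
  are exercised against the closed form. Orders are doubled until two
  refinements agree to $10^{-6}$ relative (cap: order 64), with an absolute
  floor of $10^{-9}$ of the characteristic force
  $4\pi|\Phi|a^3kE_{ac}$ so that symmetry points with identically zero
  force count as converged; exceeding the cap raises an error carrying the
  last change and scale.
* **Cancellation.** $f_m$ switches to its Taylor series
  $1 - (2\chi)^2/10 + (2\chi)^4/280$ below $\chi = 10^{-3}$.
* **Root finding.** The zero crossing brackets $\chi \in [2, 2.5]$ (the
  root of $\tan x = x$ on $(\pi, 3\pi/2)$) and calls `uniroot` at
  $10^{-12}$ tolerance.
* **Curve metric.** The normalised L1 distance
  $D = \sum|F - F_{ref}|/\sum|F_{ref}|$ is exposed generically for any pair
  of curves on a shared grid; the default size grid is 20 uniform points on
  $D_p/\lambda \in (0.05, 1]$, a parameter because no canonical sampling
  exists.
* **Tracing.** Quasi-static force balance
  $\dot r = u_{flow} + F/(6\pi\mu a)$: at channel Reynolds numbers below
  ~0.2 and micron scales the Stokes response time
  $\rho_p a^2/\mu \sim 30$ µs is far below transport times, so inertia is
  negligible (an inertial mode with the particle's mass exists for
  sensitivity checks and agrees to well under $10^{-3}\lambda$ on the
  shipped scenarios). Integration is `deSolve::lsoda` (rtol $10^{-8}$)
  with a fixed-step RK4 mode for bit-identical regression runs. Inside the
  integrator the finite-size force uses a fixed order-12 rule — on the
  smooth shipped fields this matches the adaptive result to ~$10^{-10}$
  relative while keeping force evaluations cheap. Gravity and buoyancy are
  not included.
* **Equilibria.** Seeds relax by over-damped descent for 25 e-folding
  times of the linearised node-approach rate $2k\,\mu_{mob}\,4\pi|\Phi|
  a^3kE_{ac}$; end points are de-duplicated and classified stable only if
  the residual force is below $10^{-3}$ of the characteristic force and
  small perturbations along each axis are restoring (saddles and antinodes
  under positive contrast are reported `stable = FALSE`).

## The shipped scenarios

The fixture generator (`generate_fixtures()`) writes the four standard
scenario configs; they are the package's synthetic study conditions, chosen
once:

* **Force curve** — water / 10 µm NIH/3T3 cell, $\lambda$ = 60 µm,
  $p_{ac}$ = 200 kPa, offset $h = \lambda/8$, 20 sizes on (0.05, 1].
* **Separation** — the same field across a 240 µm (4λ) channel with plug
  flow. The channel length is a transit-time parameter: with the antinode
  on the centreline (120 µm = 2λ), the node at 105 µm, outlet cuts at
  108/132 µm and releases at 110/114/118 µm, the lateral dynamics obey
  $d\,\ln\tan(kh)/dt = -2k\,\mu_{mob}F_0 \equiv -r$ with
  $r \approx 141\ \mathrm{s^{-1}}$, so the capture time from offset $h_0$
  to the cut at $h_c$ is $\ln[\tan(kh_0)/\tan(kh_c)]/r$. The farthest
  release needs 0.0189 s; the transit time 0.02 s (200 µm at 10 mm/s) then
  captures all three under the point-force model, while the finite-size
  model (rate scaled by exactly $f_m = 0.894$ on a 1-D field) leaves that
  particle 0.5 µm short of the cut — a 13% margin on both sides of the
  classification, robust to integrator tolerances.
* **Force maps** — two equal perpendicular in-phase components,
  $D_p/\lambda$ = 0.2 and 0.4, one wavelength square at 16 points per
  wavelength.

What these scenarios emulate is the idealised physics of the model itself:
monodisperse spherical particles, a lossless resonant field, no streaming,
no particle–particle or particle–wall interactions, no Brownian motion.
Passing tests therefore demonstrate the numerics (quadrature against the
closed form, force against the potential gradient, classification margins),
not that a physical device will achieve these efficiencies — real devices
add streaming drag, polydispersity, wall lift and acoustic attenuation that
this package deliberately does not model.

## Known limitations

* Ideal-fluid scattering only; at low frequencies (boundary layers
  comparable to the particle) the coefficients need viscous/thermoviscous
  corrections that are out of scope.
* The volume-average model assumes impedance closeness; for dense or stiff
  particles (impedance ratio far from 1) it degrades gracefully but has no
  internal error estimate.
* Secondary radiation (Bjerknes) forces between particles are not
  modelled, although they matter for dense patterning.
* Channel geometry is a straight 2-D idealisation; sheath-flow
  hydrodynamics is reduced to an outlet-cut classification.
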