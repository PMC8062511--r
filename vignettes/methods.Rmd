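---
title: "Reduced-order stent deployment mechanics: model and metric definitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order stent deployment mechanics: model and metric definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentmech)
```

## Scope

`stentmech` compares ring-and-link coronary stent platforms deployed in
left-main-like bifurcation vessels. The full problem — balloon-driven
expansion of a laser-cut stent against a diseased arterial wall — is a
3-D elastoplastic contact problem normally solved with explicit-dynamics
finite elements on patient-specific geometry. This package replaces it
with a reduced-order quasi-static model that preserves the *definitions*
of the performance metrics and the *orderings* between designs,
diameters and plaque stiffnesses, at a cost of seconds per deployment.
Absolute newton/millimetre outputs are not calibrated against bench or
finite-element data and should be read comparatively.

## Materials

Arterial tissue uses an incompressible polynomial hyperelastic strain
energy

$$U = \sum_{i+j \ge 1} C_{ij}\,(I_1-3)^i (I_2-3)^j,$$

with the reduced polynomial form ($j = 0$) for wall and plaque. Along the
incompressible uniaxial path $\lambda_2 = \lambda_3 = \lambda^{-1/2}$ the
nominal stress is the analytic derivative $dU/d\lambda$
(`uniaxial_stress()`), which the test suite checks against a numerical
energy slope. Because stress is linear in the coefficients,
`fit_reduced_polynomial()` is an ordinary least-squares solve.

Plaque adds a perfectly-plastic plateau above 34% engineering strain
(`plaque_material()`): the simplest continuous post-yield extension. The
five stiffness categories (`very_soft` … `very_stiff`) share one base
reduced-polynomial shape scaled by a per-category multiplier, so their
stiffness ordering holds at *every* strain by construction. The
platinum–chromium stent alloy is reduced to a 1-D elastoplastic law
(elastic modulus 203 GPa, yield 480 MPa, piecewise-linear isotropic
hardening), because the solver tracks only the bending fibre of strut
hinges. The delivery balloon is a linear membrane (900 MPa, 0.05 mm).

## Stent lattice

A `stent_design()` is a zigzag-ring/axial-link parametrization: `peaks`
crowns per ring, `rings` rings, `links_total` links distributed
round-robin over ring pairs, strut thickness/width, crimped inner
diameter 0.84 mm. `build_lattice()` realizes it on a cylinder;
`cell_polygons()` extracts every closed cell as a face of the lattice
graph in its cylindrical embedding, and the count is independently
checked against the Euler-formula oracle `edges − vertices`
(`expected_cell_count()`).

Ring counts for the four catalog designs are package defaults chosen so
the crimped length decomposes into rings plus 0.3 mm link gaps with
crown heights in the 1.0–1.4 mm range, **subject to a kinematic validity
constraint**: the strut half-angle $\alpha$ (between a strut leg and the
stent axis) must stay below 45° across the studied deployment range
(3.5–5.0 mm). The straight-leg kinematics used here have circumference
$\propto \sin\alpha$ and ring height $\propto \cos\alpha$, so geometric
quantities that scale with $r \cdot h \propto \sin 2\alpha$ peak at
$\alpha = 45°$; beyond it the model's trends invert, which real
platforms (that foreshorten only a few percent) never approach. The
constraint keeps the proxy inside its faithful regime.

## Synthetic vessel

`generate_bifurcation()` builds a station-based (0.2 mm spacing)
left-main-like geometry: a tapered lumen with a Gaussian mid-segment
eccentric stenosis whose minimal lumen area is exactly
$(1-\text{severity})$ times the local reference area, a side-branch
ostium (wall absent over an arc), and a normal-wall layer 0.1–0.25 mm
thick. Per-seed jitter emulates between-patient variability; geometry is
bitwise deterministic per seed and the generator restores the caller's
RNG state. Plaque is assigned either as one homogeneous category over
the diseased extent or as contiguous heterogeneous zones grouped from
seeded OCT-style morphometrics by a weighted similarity distance, each
zone mapped to a category by an arc-dominance rule.

The wall responds as a laminated thin-walled cylinder
(`radial_response()`): normal layer and plaque layer share the hoop
strain $\varepsilon = u/\bar r$ and the resisting pressure is
$\sum_l \sigma_l(\varepsilon)\, t_l / \bar r$, which reduces to
$p = E t u / r^2$ in the thin linear limit.

## Deployment solver

Each zigzag ring is a chain of $2p$ inextensible strut legs joined by
elastoplastic hinges at the crowns. Opening a ring from radius $r_0$ to
$r$ rotates every hinge by $\theta(r) = 2(\alpha(r) - \alpha_0)$ with
$\sin\alpha = 2 r \sin(\pi/2p)/L$, and the outward radial force follows
from the work balance

$$F(r) = n_h\, M(\theta)\, \frac{d\theta}{dr}.$$

Hinge moments follow a 1-D elastoplastic return map with isotropic
hardening; the test suite closes the work balance
$\int F\,dr = n_h \int M\,d\theta$ to $10^{-6}$ relative. At each
pressure increment the balloon pressure, hinge resistance and vessel
reaction are balanced per ring by monotone bisection, capped by the
balloon radius (sized to the target diameter, semi-compliant above
nominal pressure). Deflation (`recoil()`) solves the stent–vessel
equilibrium at zero balloon pressure, floored by the shrinking balloon
radius — the still-inflated balloon props the stent until it deflates
out of the way — with radii non-increasing. Final states carry per-ring
force residuals, typically at machine precision.

## Metrics

* **MSD** — mean inner stent diameter over rings.
* **CCD** (vessel scaffolding) — each cell is unrolled onto the plane of
  its mean-radius cylinder; the largest inscribed circle of the
  strut-centerline polygon is found by a seeded shrinking pattern search
  (robust to the plateaus and multiple local maxima of the distance
  field, cross-checked against a brute-force grid oracle); the *open*
  cell diameter subtracts the strut width, which is what differentiates
  thin-strut platforms. Cells over the side-branch ostium are excluded.
* **Prolapse** — the wall between struts sags into each open cell as an
  equilibrated membrane. A membrane spanning a half-width $a$ under
  transmural pressure $p$ with tension $T$ sags $p a^2/(2T)$; thin-wall
  equilibrium of the deployed wall gives $T = p\,\bar r$, so the sag is
  $a^2/(2 \bar r)$ — the pressure cancels, making prolapse a purely
  geometric quantity, insensitive to balloon sizing once the wall is
  apposed. Malapposed sections (undisturbed lumen outside the strut
  surface) protrude nothing. Reported as the per-section maximum.
* **SAR** — strut outer surface area over the stented lumen surface, in
  percent.
* **Normalized hoop force** — from a simulated bench crimp
  (`radial_crimp()`: expand, release, compress by 15% of diameter):
  maximum radial force over $2\pi$, per millimetre of nominal length.
* **Radial strength** — total outward contact force per strut area.

## Experiment and statistics

`factorial_design()` defaults are the study conditions: 4 designs × 3
sizing diameters (3.5, 4.5, 5.0 mm) × 6 plaque modes (5 homogeneous
categories + heterogeneous zoning) × 4 geometry seeds = 288 cells.
Failed cells are logged, never silently dropped. `compare_groups()`
gates on a Kolmogorov–Smirnov normality test of the standardized
residuals: one-way ANOVA with Bonferroni pairwise t-tests if normality
is not rejected, otherwise the Friedman rank test on complete seed
blocks with Dunn's Bonferroni-adjusted posthoc; both branches are always
returned. SEM is taken across geometry seeds, the experimental
replicates.

```{r example, eval = FALSE}
fd <- factorial_design()
tab <- run_factorial(fd)            # ~10 min on one CPU
make_report(tab, "report")          # per-metric grouped summaries
compare_groups(tab, "ccd")          # design comparison with posthoc
expansion_difference(tab, "MEGATRON_12", "MEGATRON_9")
```

## Limitations

* The model is ordinal, not calibrated: use it to rank designs and
  conditions, not to predict absolute forces.
* Contact is axisymmetric per ring; strut-level malapposition patterns,
  bending of links and cell distortion at the ostium are not resolved.
* At the 3.5 mm sizing the stent underexpands relative to the proximal
  reference in these vessels, which lowers the membrane prolapse via
  smaller open cells; between the properly sized 4.5 and 5.0 mm
  deployments prolapse is diameter-insensitive, as the membrane
  derivation predicts.
* The straight-leg ring kinematics require the 45° half-angle constraint
  above; designs outside the catalog should be checked against
  `max_expansion_diameter()` before use.
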