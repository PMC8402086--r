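---
title: "Modelling an acoustically actuated spheroid-on-chip: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an acoustically actuated spheroid-on-chip: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the model

A multicellular tumour spheroid (diameter 300 µm) sits in a rectangular
microwell (450 × 380 µm) recessed into the floor of a perfusion
microchannel (2000 × 1000 µm). Culture medium flows through the channel at
1–12 µL/min, carrying oxygen (0.2 mM) and glucose (5 mM); both species
reach the spheroid essentially by diffusion across the almost stagnant
well. A piezoelectric transducer below the well bottom vibrates that wall
with a displacement amplitude of 0.1–0.5 nm at a nominal 1 MHz, producing
acoustic streaming that stirs the well, enhances nutrient transport, and
shrinks the necrotic and quiescent zones of the spheroid.

The package models this in 2D (the device midplane) as four coupled
stages, solved in sequence on a shared triangular mesh:

1. **First-order thermoviscous acoustics** — the linearised compressible
   equations in the frequency domain with the isentropic closure
   $p_1 = c_a^2 \rho_1$, shear and dilatational viscosity, and a one-way
   coupled temperature equation. The dilatational coefficient is taken as
   $\mu_B + \mu/3$, i.e. a viscosity ratio $\beta = \mu_B/\mu + 1/3$, so
   the stress divergence has the standard form
   $\mu\nabla^2 V + (\mu_B + \mu/3)\nabla(\nabla\!\cdot V)$.
2. **Streaming representation** — either the time-averaged second-order
   body force and mass source assembled from the first-order fields
   (`body_force` mode, requiring the viscous boundary layer
   $\delta = \sqrt{2\nu/\omega} \approx 0.47$ µm to be mesh-resolved), or
   the classical Rayleigh limiting velocity
   $u_s = -\tfrac{3}{4\omega}\,\partial_s\langle v_t^2\rangle$ imposed on
   the walls outside the layer (`slip_velocity` mode).
3. **Mean flow** — steady incompressible Navier–Stokes (Taylor–Hood
   P2/P1) combining the parabolic perfusion inlet with the streaming in a
   single solve; the convective term is retained by Picard iteration even
   though chip Reynolds numbers are $O(10^{-2})$.
4. **Species transport** — advection–diffusion in the medium, diffusion
   with a Michaelis–Menten sink $V_{max} c/(c+K_m)$ in the spheroid, and a
   solubility jump $c_{agg} = S\,c_{med}$ with flux continuity at the
   interface. The jump is realised by the substituted variable
   $u = c/S_{dom}$, which is continuous across the interface; the weighted
   weak form makes $D S_{dom} \nabla u$ the conserved flux.

Zones are classified per species and combined: necrotic below
0.002644 mM oxygen (2 mmHg) or 0.2 mM glucose; quiescent below 0.01322 mM
oxygen (10 mmHg) or 0.5 mM glucose; proliferating otherwise. The criteria
are combined with a **union** rule: with standard medium, glucose never
falls below its lethal threshold and yet sizeable necrotic cores exist, so
an intersection rule would classify every point as viable — the union is
the only reading consistent with the reported base-case fractions (and the
combined necrotic fraction then equals the oxygen-only fraction there, as
reported). Quiescent is exclusive of necrotic, so the three fractions
partition the spheroid and sum to 100%.

# Geometry choices the source leaves open

The spheroid placement inside the well is not stated; we centre it in the
well (40 µm clearance below, 75 µm on the sides). Nutrients arrive from
the channel above, so a centred placement still reproduces the
bottom-weighted necrotic core. The well sits at mid-channel-length
(symmetric layout). The volumetric flow rate is converted to a 2D inlet
profile using an out-of-plane depth of 1000 µm — the only transverse
dimension the design provides; both the placement and the depth are
configuration knobs (`chip_geometry()`), and zone fractions shift by a few
percentage points when the spheroid is moved by tens of µm, which should
be kept in mind when comparing absolute fractions.

The printed penetration-depth figure of "0.52 nm" for this system is
dimensionally inconsistent with $\delta=\sqrt{2\nu/\omega}$ and the listed
fluid properties (which give 0.47 µm at 1 MHz, or 0.53 µm for 25 °C
water); the package always computes $\delta$ from the properties and
treats the printed unit as µm.

# The acoustic operating point

The chip's inlet and outlet are acoustically open (stress-free,
pressure-release) boundaries; they reflect rather than absorb, so the chip
is a low-loss resonator whose losses are dominated by the viscous wall
boundary layers. Two consequences drive the whole acoustic branch of the
model:

* **Off resonance nothing happens.** At exactly 1.000 MHz the forced bulk
  response of our discretised geometry is $|V_1| \sim 0.02$ m/s, the slip
  velocity $\sim 10^{-7}$ m/s — four orders below the perfusion scale, with
  no visible effect on transport. A strong streaming response (well
  vortices, multiplied shear stress, doubled proliferating zone, first
  order velocities "of order m/s") is only possible within a linewidth of
  a cavity mode. The physical device is driven at its resonance; the
  nominal 1 MHz labels that operating point. `tracked_acoustics()`
  therefore locates the strongest mode within ±8% of the nominal frequency
  (a single dominant mode, at 0.938 MHz on the reference geometry) and
  operates there. `track_resonance = FALSE` disables this.
* **The on-resonance amplitude is set by boundary-layer dissipation.**
  The bulk (Helmholtz) model carries only the tiny volumetric absorption,
  so the modal amplitude is closed self-consistently: the inverse quality
  factor is computed from the modal field as wall boundary-layer
  dissipation (viscous $\tfrac14\rho_0\omega\delta|v_t|^2$ plus the small
  thermal term of isothermal walls) over stored acoustic energy, and fed
  back as effective absorption until fixed. On the closed benchmark cavity
  this estimate gives $Q = 421$ against $Q \approx 364$ measured from the
  resolved thermoviscous linewidth — agreement to ~16%, which we accept
  without any correction factor.

With this operating point the model yields $|V_1| \approx 1.4$ m/s and
slip velocities up to $\sim$1 mm/s at the largest amplitude (0.5 nm) —
strong enough to mix the well and effectively abolish the necrotic zone,
which overshoots the reference behaviour (necrotic 13.3% retained at
0.5 nm, shear below 0.5 dyne/cm²). Our amplitude sweep shows the reference
endpoint numbers are reproduced at $d_0 \approx 0.3$–0.35 nm instead: at
0.3 nm our combined fractions, shear stress (0.30 dyne/cm² < 0.5) and lift
(just below the net submerged weight) all match the published 0.5 nm
picture. Everything on the acoustic side is therefore consistent up to an
amplitude factor of ~1.5, which is the expected sensitivity to modal
detuning and to the slip-theory idealisation: the response scales as
$[1+(2Q\,\Delta f/f)^2]^{-1/2}$ with $Q \approx 480$, so a detuning of a
mere 0.15% halves it. We deliberately do not rescale anything: amplitudes
are taken exactly as configured at the tracked-mode peak.

# Streaming mode: slip velocity by default

`body_force` mode needs six graded layers inside $\delta \approx 0.5$ µm
along every wall of a 2 mm chip — a mesh and a coupled complex-valued
solve far beyond what the slip model needs, for outer streaming that the
limiting-velocity theory reproduces. Chip runs therefore default to
`slip_velocity`; `body_force` is exercised on the benchmark cavity, where
both the four-vortex Rayleigh pattern, the $d_0^2$ scaling, and the
magnitude (bulk streaming within a factor 1.4 of $\tfrac38 u_1^2/c_a$) are
verified against the classical results, and where the cross-check of the
damping model above ties the two modes together.

# Numerical choices

* **Meshing.** Block-structured conforming triangulation: polar disk in
  the spheroid, radial O-grid between spheroid and well walls, graded
  tensor grid in the channel; geometric near-wall layer stacks
  (`mesh_spec()`). The full protocol resolution ($10\delta$ and $20\delta$
  interior sizes, six layers within $\delta$) yields ~8×10⁴ elements and
  is used for mesh-definition checks; physics runs use the desk scale
  (`desk_mesh_spec()`: 15 µm well / 40 µm channel elements, three layers
  within 5 µm, ~9×10³ elements), at which the convergence study shows the
  spheroid-average oxygen settles to <1%, the maximum shear stress to <3%
  and zone fractions to <1 percentage point under further refinement.
* **Discretisation.** P1 for the scalar/complex acoustic systems (the
  harmonic mass terms regularise the equal-order pairing), Taylor–Hood
  P2/P1 for the mean flow (inf-sup stable), P1 for transport. Complex
  systems solve as 2n-real block systems (sparse LU).
* **Transport stabilisation.** At the desk mesh the cell Péclet number is
  below ~2 for perfusion-only runs and plain Galerkin is used; acoustically
  stirred runs reach cell Péclet ~20 and automatically enable
  streamline(-upwind) diffusion. Crosswind over/undershoots of order
  $10^{-3}$ mM can survive near the under-resolved concentration boundary
  layer at the stirred spheroid surface; the solver aborts only on gross
  (percent-level) bound violations, while the strict maximum-principle
  property is asserted by the test suite.
* **Nonlinear solves.** Damped Newton with a mass-lumped Michaelis–Menten
  term and a C¹ linear extension of the rate below zero concentration
  (restoring, removes the kink that stalls Newton after an undershooting
  step); convergence on relative residual 10⁻³ (scaled by the saturation
  consumption) with a 10⁻⁹ mM step safeguard. Mean flow: Picard on the
  convective term to 10⁻⁶ relative update. First-order acoustics and the
  mean-flow linear solves are direct.
* **Zone quadrature.** Fractions integrate the linearly interpolated
  threshold level-set inside each triangle (convex polygon clipping, both
  species jointly for the union rule), removing the O(h) bias of
  whole-element counting; a constructed half-disc split is recovered to
  0.01%.
* **Ties and degenerate inputs.** Zero actuation short-circuits the
  acoustic stage to exact zeros; zero flow rate gives the pure streaming
  problem; a zero spheroid diameter meshes a plain well. A closed cavity
  gauges pressure by a zero-mean constraint, open chips by the stress-free
  outlet.

# What the generator emulates, and what it does not

All inputs are parameter sets (geometry, material constants, actuation,
perfusion, species), so the scenario builder *is* the data generator; the
study conditions are its defaults, and sweeps enumerate the published
operating points (amplitudes 0–0.5 nm, flow rates 1–12 µL/min, low-glucose
1 mM variant). Passing tests certify the 2D model of the stated
conditions — they do not establish 3D accuracy (the midplane model ignores
out-of-plane gradients and spanwise wall losses), cell-scale biology
(growth, contact necrosis, waste species are out of scope), or transducer
physics (actuation is an imposed wall displacement).

# Known limitations

* The acoustic branch is evaluated at the tracked modal peak; real and
  simulated devices detuned by fractions of a percent respond much more
  weakly. Absolute acoustic quantities (average concentrations, zone
  fractions, shear, lift at a given $d_0$) carry an amplitude uncertainty
  of order 1.5× from this alone, while the non-acoustic branch has no such
  sensitivity.
* Slip theory breaks down within a few $\delta$ of re-entrant corners
  (well opening); the corner slip values are mesh-sensitive but localised.
* Equal-order P1 acoustics exhibits corner pressure spikes at
  actuated/rigid wall junctions (singular solutions); interior fields are
  unaffected and all derived quantities exclude the singular points.
* The 1D/2D transport bridge, the zero-order closed form and the Richardson
  study certify the Michaelis–Menten machinery to well under 1%, so the
  transport side of any discrepancy with published fractions is dominated
  by geometry placement, not by the solver.

# Problem sizes used by the shipped analyses

Chip runs use `desk_mesh_spec()` (~9×10³ elements; a scenario solves in
tens of seconds), the benchmark cavity uses 4 µm interior elements with
six boundary layers (~1.1×10⁴ elements), the radial oracle 4×10³ grid
points, and the convergence study refines the chip mesh by factors 2 and
1.4 above the desk scale. These sizes were chosen so the full study —
sweeps, benchmark and convergence — reruns comfortably on a laptop-class
single core while staying inside the convergence envelope quoted above.
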