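---
title: "chipflow: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipflow: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science and the
numerical decisions behind it: what is modeled, what is assumed, which
parameters matter, and where the design was genuinely open.

## The decomposition model

A microfluidic chip whose layout consists of rectangular channels,
90-degree turns and T- or cross-shaped intersections is treated as two
kinds of regions with different physics budgets.

**Channels** obey the hydraulic analog of Ohm's law. For steady,
pressure-driven laminar flow of a Newtonian fluid through a rectangular
channel, volumetric flow and pressure drop are proportional,
`Q = dP / Rh`, with

```
Rh = 12 eta L / (w h^3 F(h, w)),
F  = 1 - (192 / pi^5) (a/b) sum_{n odd} n^-5 tanh(n pi b / (2 a)),
```

where `a = min(w, h)`, `b = max(w, h)`. Series and parallel channels
compose like resistors, and the two Kirchhoff laws (flow conservation at
junctions; zero pressure drop around loops) determine every flow and
pressure in the network. `solve_network()` implements this as sparse
nodal analysis: node pressures are the potentials, pressure-type
terminals pin them, velocity-type terminals enter as flow sources. The
loop law holds identically in a potential formulation; the junction law
is checked a posteriori and its residual is reported
(`kcl_residual`, relative to the largest flow; the suite requires
`< 1e-12`).

**Intersections** are where streams merge and split, and where particle
routing is decided; no resistor analogy captures them. Each is an
instance of the *unit intersection*: four 200 um arms entering a
1.6 x 1.6 mm footprint, each arm an inlet, an outlet, or unused. Of the
2^4 inlet/outlet role assignments, two (all-inlet, all-outlet) violate
conservation, leaving 14 feasible configurations. An instance is the
configuration plus a signed mean velocity per arm (positive into the
junction, summing to zero).

The package solves instances once, stores them in a library, and answers
chip queries by nearest-match retrieval — the expensive physics is paid
per *library*, not per chip.

## The intersection flow solver

The unit-intersection flow is solved as steady, incompressible
**2D Stokes flow**:

- *Two-dimensional*: the paths compared here are planar; the chip's
  depth dimension enters only through the hydraulic resistance of the
  network solve. A depth-averaged treatment would multiply in a
  Poiseuille factor without changing streamline topology at these
  aspect ratios, so the in-plane model is used throughout and the
  whole-chip oracle is solved with the same physics, making the
  decomposed-vs-direct comparison a like-for-like test of the
  *decomposition*, not of the depth model.
- *Stokes (zero Reynolds number)*: at the envelope's 2 cm/s in 200 um
  water channels, `Re ~ 4`; neglecting inertia keeps the operator
  linear. Linearity is what lets the library normalize velocities
  (below) and is verified by the scale-invariance tests rather than
  assumed silently.

Discretization is a uniform staggered (MAC) grid: `u` on vertical cell
faces, `v` on horizontal faces, pressure at cell centers; centered
second-order differences; no-slip walls enforced by zero normal face
values and reflected tangential ghosts. Arm boundary conditions are
fully developed parabolic profiles (`poiseuille_profile()`) imposed on
every active arm except one *reference outlet* — the arm with the
largest outflow, ties broken N < E < S < W — which instead carries a
traction-free outflow (ghost pressure zero, zero normal gradient). One
free outlet avoids over-determining the pressure and anchors its gauge;
if a solve has no natural outlet at all, the prescribed fluxes are
rescaled to balance exactly and one pressure is pinned. Inlet profiles
are imposed as exact cell averages of the parabola, so the discrete flux
of each arm equals `mean velocity x width` to machine precision.

The saddle-point system is assembled in grid units (pressure scaled by
`spacing / viscosity`, so all matrix entries are O(1)) and solved by a
sparse direct factorization. Discrete divergence of an accepted solve
sits at solver-roundoff level, orders of magnitude below the acceptance
bound `1e-8 x max|u| / spacing`.

The parabolic-inflow assumption mirrors the entrance-length argument:
arm mouths sit 0.7 mm (3.5 widths) from the junction core, and Stokes
channel disturbances decay like `exp(-c x / w)` with `c ~ 4`, so the
profile is fully developed at the mouth to well below tracer tolerance.

**Grid spacings.** Tests and library builds default to 20 um (width/10,
the coarsest spacing the domain constructor accepts); the
decomposed-vs-direct acceptance comparison runs at 4 um (width/50). The
discretization is second order: the Poiseuille recovery test measures
the error shrinking ~4x per halving, which is what justifies running
far coarser than a mesh-converged reference would.

## Particle tracing

Particles are traced as **massless streamline followers**: classical
RK4 on `dX/dt = u(X)` with bilinear interpolation per staggered
component and the time step bounded so no step moves more than half a
grid cell. The justification is quantitative, not rhetorical: the Stokes
relaxation time `tau = d^2 rho_p / (18 eta)` is at most 2.3e-5 s for a
20 um particle in water, far below any flow time scale, and
`trace_particle()` refuses diameters for which `tau >= 1e-4 s` rather
than silently extrapolating the massless model.

Finite size enters in exactly two places, matching wall-stick ("freeze")
semantics: release positions are inset one radius from the walls, and a
trace ends frozen when the center-to-wall distance falls to the radius.
Wall distance is computed against the exact wall segments of the domain
(mouths excluded), not against the raster mask. No lift, wall
hydrodynamics, or Brownian motion is modeled. Whether wall contact
should be measured center-to-wall at one radius or as point contact was
an open choice; the radius rule is used and recorded in trajectory
provenance.

Degenerate cases: a particle that reaches fluid slower than 1e-9 of the
field maximum, or that fails to advance by one grid spacing over 512
steps (orbiting a stagnation point), raises a typed stagnation error
with its last position — determinism is preferred over a perturbation
heuristic at measure-zero events.

## The flow-fraction coordinate

Between intersections the package propagates not positions but the
cumulative flow fraction `q in [0, 1]`: the fraction of the channel's
flow between the particle's streamline and the channel's left bank
(left of the flow direction). Under the parabolic profile
`q(s) = 3 s^2 - 2 s^3` with `s = y / w`, inverted in closed form. By
continuity `q` is conserved along streamlines through straight channels
and 90-degree turns, which is what lets a junction exit position be
carried exactly to the next junction entrance. The left-bank convention
makes `q` frame-independent and continuous through turns; under a
mirror symmetry it transforms as `q -> 1 - q`, which the library
transform machinery applies alongside the geometric reflection.

`q` is evaluated with the analytic parabola at channel cross sections
and with the numeric field inside intersections; the hand-off points are
the arm mouths, where the entrance-length argument declares the profile
developed.

**Polyline stitching.** The drawn path hands off between channel and
junction pieces at 1.5 channel widths from the junction center (the
junction core plus one width of development length). Directly at the
core edge the true streamline still deviates appreciably from its
asymptotic transverse offset — the flow is mid-turn there — so hand-off
at the core edge would leave visible seams; one development length out,
the residual mismatch is below one tracer step (the stitch-gap
invariant the suite checks). This is a rendering
choice only — exit positions and routing are decided by `q`, not by the
polyline.

## The library: sampling, canonicalization, retrieval

`sample_instance()` draws the study conditions for random library
records: a configuration uniform over the 14 feasible patterns, each arm
degraded to unused with probability 0.25 (so T-junctions and straights
arise in small libraries at useful rates while four-arm records remain
the majority), inflow rates uniform on (0, 2] cm/s, `N - 1` of `N`
outlet rates uniform on the same range, and the last outlet balancing
the total, with non-physical draws rejected and resampled. The 0-2 cm/s
range and the balancing rule are the library envelope; 0.25 is the
package's own choice where no canonical value exists.

Records are stored in **canonical form**: velocities divided by total
inflow (exact by Stokes linearity) and reduced modulo the 8 symmetries
of the square, keeping the lexicographically smallest image. The
transform (quarter-turns, optional mirror, scale) inverts exactly and is
returned by every query, so one stored solve serves its whole
symmetry-and-scale orbit. Queries require an *identical* canonical
role pattern — configuration mismatches change the topology of the
streamline split and cannot be meaningfully interpolated — then
minimize Euclidean distance between normalized velocity 4-vectors, with
deterministic tie-breaks (record id, then symmetry order). A missing
configuration raises a typed coverage error advising library
augmentation rather than returning a structurally wrong match. A
`normalize = FALSE` compatibility mode compares raw magnitudes instead,
mimicking a magnitude-keyed database.

Unused arms are masked out of the flow domain (flush wall) rather than
simulated as zero-velocity stubs: chips realize three-arm junctions with
flush walls, and a dead-end stub would introduce a spurious
recirculation pocket that the whole-chip oracle does not have.

Retrieval offers two trajectory modes. **Mode A** (default) re-traces
the query particle on the retrieved velocity field from its actual
entry position — the field is precomputed, so this costs only the
trace, and it is exact at distance zero (verified by the retrieval
fidelity tests). **Mode B** interpolates the exit flow fraction between
the two stored release trajectories bracketing the entry, requiring
both to exit through the same arm and otherwise snapping to the nearer
release with the decision recorded in provenance; it reproduces
pure-lookup behavior at bank resolution (10 uniform releases per inlet
arm per diameter).

The library is one serialized file with a versioned schema — an
embedded single-file database with no server dependency.

## Chip generators as study conditions

The fixture generators encode the reference operating conditions rather
than arbitrary demo values: `make_cascade_chip()` defaults to three
inlets at 3.5 mm/s, 3 mm/s drawn at the East outlet and the South outlet
as the 0 Pa reference, so its junction boundary conditions come out at
3.5/3.5 -> 7 mm/s and 10.5 in / 3 + 7.5 out; `make_h_chip()` defaults to
1 and 2 cm/s inlets, making the left junction's East outflow 3 cm/s.
Channel width defaults to 200 um everywhere (the library envelope).
Channel *height* is a required field that no planar drawing determines;
fixtures default to 100 um. Height only enters the network resistances
(uniform-height chips are insensitive to it in their flow *splits*), so
this choice does not affect the decomposed-vs-direct comparisons.
`make_random_grid_chip()` emulates randomly designed rectilinear chips:
a uniform spanning tree on a grid plus extra edges, stub terminals
guaranteeing solvability, pressure-driven defaults.

What the generated conditions do **not** emulate: fabrication
variability (rounded corners, width tolerances), non-rectangular cross
sections, compliance or transients, solute transport, and any 3D or
inertial particle physics. Passing tests demonstrate the decomposition's
internal consistency under the stated planar Stokes model — they do not
certify agreement with a 3D finite-element or experimental reference.

## Numerical tolerances in one place

| Quantity | Bound | Where |
|---|---|---|
| Junction-law residual (network) | `< 1e-12` rel. | `solve_network()` invariant |
| Mass balance of an instance spec | `< 1e-9` rel. | `unit_intersection_spec()` |
| Arm conservation before a solve | `< 1e-6` rel. | `solve_stokes()` precondition |
| Discrete divergence | `< 1e-8 max|u| / spacing` | acceptance suite |
| Flow-fraction conservation | `< 1e-3` abs. | channels/turns at 10 um grid |
| Decomposed vs direct exit | `<= 1.21 um` | cascade chip, 4 um grid |
| Stitch gap in drawn polylines | `< grid spacing` | simulation invariant |

Problem sizes used by the suite: unit-intersection solves at 20 um for
property tests (1.5-3.8 k fluid cells), 10 um where flow-fraction
accuracy at 1e-3 matters, and the full acceptance comparison at 4 um
(66 k fluid cells for the cascade chip; seconds to tens of seconds per
solve with the sparse direct factorization).

## Known limitations

- Planar Stokes only; the optional convective (finite-Re) correction and
  an inertial drag-ODE particle mode were considered and deliberately
  left out to keep the operator linear and the behavior reproducible —
  the relaxation-time guard documents where the massless model's
  validity ends.
- The library envelope is hard: 200 um widths, T/+ junctions, 90-degree
  turns, 0-2 cm/s, 1-20 um particles. Outside it the simulator aborts
  with a typed error instead of extrapolating (`strict_envelope = FALSE`
  permits relying on Stokes scale invariance for faster-than-envelope
  chips whose *normalized* conditions are covered).
- Exact-match retrieval accuracy degrades gracefully with library
  density; `compare_with_direct()` is provided precisely so users can
  quantify that degradation for their own libraries.
- Decomposition is user-supplied: nodes are typed terminal/turn/
  intersection in the netlist. Recovering the decomposition from raw
  geometry (CAD/GDS import) is out of scope.
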