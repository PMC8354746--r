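---
title: "Modelling coral habitat engineering with WCSPH and the Goldilocks Principle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coral habitat engineering with WCSPH and the Goldilocks Principle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reefsph)
```

## The model

Cold-water corals such as *Lophelia pertusa* feed heterotrophically, and
their prey capture is strongly flow-dependent: too slow and zooplankton
evade the polyps, too fast and the tentacles are swept back. Capture — and
hence growth — is efficient only in an intermediate band of current speeds,
roughly 3–6 cm s⁻¹. `reefsph` couples a two-dimensional weakly compressible
smoothed-particle hydrodynamics (WCSPH) solver to two agent-style rules
built on this "Goldilocks" band:

* **Growth** — at scheduled growth events, every *fluid* particle that lies
  within a proximity radius (1.5·Δx) of the colony (live or dead coral) and
  whose time-averaged local speed falls inside the optimal band is converted
  to a *live coral* particle.
* **Death** — a live coral particle whose neighbourhood offers no in-band
  fluid for K consecutive growth events is converted to *dead framework*,
  permanently. Interior coral, which has no adjacent fluid at all, is
  suboptimal by construction. K = ∞ disables death.

Both rules are in-place phase conversions: the total particle count never
changes, which both mirrors the biology (dead framework persists and still
baffles the flow) and keeps the SPH discretization stable. As the colony
grows it reshapes its own hydrodynamic environment, and the feedback between
flow and growth — not any prescribed branching rule — produces the colony
morphologies and the live:dead composition the model tracks.

## The solver

The fluid obeys the Lagrangian continuity and momentum equations, closed by
the Tait equation of state

$$p = B\left[(\rho/\rho_0)^\gamma - 1\right], \qquad B = \rho_0 c_s^2/\gamma,$$

with $\gamma = 7$ and a reference speed of sound $c_s = 10$ m s⁻¹ — at least
ten times the fastest current in the growth scenario, which keeps density
variations within about 1 % of $\rho_0$ (the weakly compressible regime).
Discrete operators use the Wendland C2 kernel

$$W(q,h) = \frac{7}{4\pi h^2}\,(1-q/2)^4\,(1+2q), \quad q = |r|/h \le 2,$$

whose $1/h^2$ normalisation makes the unity condition
$\int W\,\mathrm{d}r = 1$ hold exactly; symmetry, the delta-limit behaviour
and compact support are enforced as property tests. The momentum equation
combines the symmetric pressure-gradient form, the Morris laminar viscosity
(no artificial viscosity model), and a body-force term. After each
continuity update an Ozbulut-style density filter with ε = 0.01 pulls each
density toward its kernel-weighted neighbourhood, damping the acoustic noise
that the stiff equation of state would otherwise amplify.

Time integration is a Verlet (leapfrog) scheme with a plain Euler corrector
step every `n_euler` steps. The leapfrog's parasitic even–odd mode is
*amplified* by dissipative terms, and with the viscosities used in the
validation cases the scheme diverges within ~100 steps at corrector cadences
of 20–50; cadence 10 is stable across every case in the package, so
`n_euler = 10` is the default (configurable). The adaptive step is the CFL
coefficient (0.25) times the most restrictive of an acoustic cap
$h/(c_s + |v|_{max})$, the standard explicit-diffusion cap
$0.125\,h^2\rho_{min}/\mu$, and a body-force cap $\sqrt{h/|F/\rho|_{max}}$.

### Boundaries

The seabed and the coral are *dynamic boundary particles*: they obey the
same continuity/EOS equations as the fluid (so they push back on
approaching fluid through pressure) but never move. Two refinements matter
in practice:

* Boundary pressures are floored at zero, so a rarefied boundary
  neighbourhood never *attracts* fluid.
* For the viscous term only, boundary particles carry a no-slip ghost
  velocity — the anti-mirror of the Shepard-smoothed adjacent fluid
  velocity about the (static) boundary velocity. Without this the wall
  generates a slip length of about half a particle spacing; with it the
  laminar-channel profile error drops from ~33 % to ~4 % at 10 particles
  per channel height.

The growth scenario drives the flow with a parabolic inlet band on the left
(zero at the seabed, peak at the top — the single stated boundary speed
anchors both the lid and the inlet peak), a constant-velocity lid band along
the top, and an outlet on the right realized as recycling: fluid crossing
the right boundary re-enters at the left with the inlet-profile velocity and
reference density, which keeps the particle count exactly constant. The
water column is initialized *on* the inlet profile; starting from rest
produces a violent impulsive transient (compression at the inlet, a global
acceleration phase) that serves no purpose.

Rarefied pockets inside a convoluted grown colony develop negative
(tensile) pressures whose mutual attraction can collapse particle pairs —
the classic WCSPH tensile instability, which in long death-rule runs ends
with coincident particles and a solver abort. The integration loop applies
an artificial-stress correction: when either member of a pair is under
negative pressure, a repulsive term
$\varepsilon_{ts}\,(|p|/\rho^2)\,[W(r)/W(\Delta x)]^4$ is added to the
pairwise pressure term. The $[W(r)/W(\Delta x)]^4$ factor makes the
correction negligible at normal spacing and strong as $r \to 0$, so
mid-range tensile physics (which holds the sheared layer under the lid
together) is preserved while collapse is blocked. The strength
$\varepsilon_{ts} = 0.05$ is calibrated to the Wendland kernel at
$h = 1.3\Delta x$: 0.2 (a value in circulation for other kernels) is
violently over-repulsive here, while 0.05 leaves the settled channel and
scenario flow fields indistinguishable from the uncorrected ones. Two
simpler tensile controls were evaluated and rejected: a global $p \ge 0$
floor removes the tension that holds the lid shear layer together and
cavitates it, and a constant background pressure exerts spurious
kernel-deficiency forces at open boundaries that drain the outlet column.
The exported `tait_pressure()` and `momentum_rhs()` evaluate the bare
equations; the correction is a property of the integration loop.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Δx (full / reduced scenario) | 0.05 / 0.025 | m | full scale fills 10 × 5 m with 20 000 fluid particles |
| h/Δx | 1.3 | — | common WCSPH practice; the ratio is not a reported quantity, so it is explicit configuration |
| ρ₀ | 1000 | kg m⁻³ | fresh-water reference; 1027 for seawater is one keystroke away and rescales only B |
| c_s | 10 | m s⁻¹ | stated design value; ≥ 10 × the 0.5 m s⁻¹ lid current |
| γ | 7 | — | Tait exponent for water |
| ε | 0.01 | — | density-filter strength, stated value |
| μ (scenario) | 0.5 | Pa s | effective viscosity; see below |
| optimal band | 0.03–0.06 | m s⁻¹ | prey-capture optimum |
| proximity | 1.5·Δx | m | growth/death adjacency radius |
| K | ∞ / 5 / 30 | events | death-rule interval; ∞ disables death |
| settle_steps | 300 | steps | solver steps between growth events |
| avg_window | 150 | steps | trailing window for local speed averaging |

**Effective viscosity.** Molecular seawater viscosity (~1.2 × 10⁻³ Pa s) at
the scenario's scale and speed puts the colony Reynolds number around 10⁵,
far beyond what a 2D laminar solver without a turbulence closure can
resolve at Δx = 2.5 cm. The scenario therefore uses an effective viscosity
of 0.5 Pa s (ν = 5 × 10⁻⁴ m² s⁻¹), which brings the colony Reynolds number
to O(10²) — a steady, resolvable laminar wake that still exhibits the
sheltering and baffling the growth rules feed on. `fluid_properties()`
defaults to the molecular value; the elevated value is a documented
property of the scenario configuration, not of the solver.

## Growth-event scheduling

A growth step fires after `settle_steps` solver steps, provided the domain
kinetic energy is steady (relative change of two consecutive windowed means
below `steady_tol`); if steadiness has not been reached, up to
`max_settle_rounds` additional settling rounds run before the event fires
regardless. Death and growth are evaluated against the *same* pre-event
snapshot and applied simultaneously, so the order of the two rules cannot
matter within an event. Two readings of the death-rule cadence are
possible ("applied at intervals of five growth-steps" can mean evaluated
every event with threshold K, or evaluated only every K events); the
default is a streak threshold evaluated at every event, with
`death_cadence` exposing the alternative. Similarly the growth rule
defaults to converting *every* qualifying particle per event, which is the
mechanism's literal description; `cap_per_event = 1` recovers the stricter
one-particle-per-step reading seen in figure captions.

## Validation cases

The solver's quantitative surface is two closed-form cases:

* **Plane Poiseuille flow** (body-force-driven periodic channel): the
  steady profile is $u(y) = \frac{g}{2\nu}y(H-y)$. At Δx = H/20 the
  relative L2 profile error is ~3 %, and the error decreases monotonically
  along the resolution ladder Δx ∈ {H/5, H/10, H/20}. The same case run at
  2 × 1 m with $c_s$ = 10 × the analytic peak speed measures the
  weak-compressibility design property: maximum density deviation well
  under 1 %.
* **Hydrostatic tank** (gravity, side/bottom walls, free surface):
  initialized on the analytic hydrostatic density profile and settled with
  mild velocity damping; mid-depth pressure agrees with ρ₀gd within a few
  percent and density deviations stay under 1 %.

Periodic wrapping in x exists *only* for these channel cases; the growth
scenario's open boundary is the recycling outlet described above.

## What the reduced scenario does and does not show

The acceptance-scale runs use a 2 × 1 m domain at Δx = 0.025 m (3 200 fluid
particles, ~160-particle hemispherical seed of radius 0.25 m), 300 solver
steps between growth events, and a horizon of 40 growth events for the
no-death run and the death-interval family; the K = 5 run continues to 100
events to capture total colony death. These sizes keep a full
four-scenario suite within a desktop test run while preserving the
qualitative regime of the full 10 × 5 m scenario: the same lid speed,
optimal band, proximity rule, EOS constants, and a seed that spans the same
number of particle spacings as the full-scale one.

Observed phenomenology at this scale, none of it prescribed directly by the
rules: with no death rule the colony grows monotonically into a dense
rugose mound. With K = 5 the interior dies at the fifth event (interior
particles are suboptimal by construction), the colony's own growth then
creates suboptimal sheltering over its flanks, and live cover decays with
fluctuations until total colony death, leaving only dead framework. With
K = 30 a live shell persists over the dead interior — live coral sitting
on dead coral, with the live mean height well above the dead mean height —
and at the matched 40-event horizon the live counts are monotone in K
(5, 61 and 141 for K = 5, 15 and 30), the energetic-reserve relationship.
One scale effect deserves note: in this shallow reduced domain the optimal
band hugs the seabed, so at long horizons every finite-K colony eventually
decays (the K = 30 run too, if continued); the family contrast is
therefore read at the matched mid-run horizon, exactly as the full-scale
panels are compared at matched growth-steps.

The 2D model says nothing about overhang mechanics, light, temperature or
food-supply gradients, and simulated time is iteration count, not physical
time; growth-step indices at reduced scale are not comparable to full-scale
indices, which is why the acceptance checks are structural properties
(monotonicity, extinction, stratification) rather than step numbers.

## Numerical choices and degenerate inputs

* Proximity and adjacency use Euclidean distance between particle centres;
  the neighbor relation is validated against an all-pairs oracle.
* Conversions zero the particle's velocity and keep its last density and
  its mass (masses are ρ₀Δx² forever; total mass is conserved exactly).
* The live:dead ratio is reported as `NA` until the first death, avoiding
  spurious infinities in metrics files.
* Coincident particles (r → 0) abort the run: they indicate a collapsed
  pair, and continuing would divide by zero. Non-finite state likewise
  aborts with the step index.
* Scenario runs cap per-particle speeds at twice the lid speed. A grown
  colony encloses pockets of trapped fluid whose acoustic oscillations can
  occasionally eject a particle at unphysical speed; the cap bounds that
  pathology without touching healthy dynamics, where observed maxima stay
  near 1.1× the lid speed. The cap is off by default in `advance()`.
* `compute_dt` treats zero viscosity and zero body force as inactive
  (infinite) caps.
* The steady-state detector returns `FALSE` for histories shorter than two
  windows, so a scenario can never fire a growth event on an empty buffer.
* Identical configurations produce bit-identical count series; the
  scenario loop contains no randomness. The config hash embedded in every
  output file makes this checkable.
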