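---
title: "A mass-spring model of gliding myxobacteria with head-to-tail guiding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-spring model of gliding myxobacteria with head-to-tail guiding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(myxoglide)
```

## The model

Myxobacteria glide on surfaces as flexible rods, follow one another
head-to-tail in streams, and during development wind up into rotating
circular aggregates that seed fruiting bodies. This package implements a
two-dimensional mechanical model of that process and the analysis used to
interrogate it.

Each cell is a chain of `n_particles` point particles (default 9) joined
by stiff linear springs (rest segment length `seg_len = L/(n_particles-1)`,
default 0.65 um for a 5.2 um cell) and angular springs at every interior
joint that penalise deviation from straightness with energy
$\tfrac12 k_a \theta_i^2$. The flexural rigidity of the discretised rod is
approximately $B \approx k_a \cdot \ell_0$; the four stiffness regimes
studied are $k_a = 10^{-18}$ ("very flexible", $B \approx 7\times10^{-25}$
J m), $10^{-17}$ ("flexible", $6\times10^{-24}$, the default),
$10^{-16}$ ("rigid") and $10^{-15}$ N m ("very rigid").

Propulsion is a *distributed engine*: a total force `F_engine` (100 pN)
shared uniformly by the particles, each share along the local body tangent,
pointing from the tail pole toward the head pole. The head is particle 0
when the polarity `k_e = +1` and swaps to the other end on reversal.
Dynamics are overdamped — at micron scales inertia is irrelevant — so each
particle moves at `force / gamma_particle` with the cell's total drag fixed
by free gliding: `gamma_cell = F_engine / v_b`, `v_b = 4` um/min. A free
straight cell therefore glides at exactly `v_b`, which doubles as a
permanent self-check in the test suite.

Cells are capsules of width `W = 0.5` um around their particle chains.
When two segment axes come closer than `W` a linear collision spring
pushes them apart with force $k_c (W - d)$ along the closest-point line,
distributed to the four segment endpoints with barycentric weights. Two
corrections remove artefacts of chained segments: a contact falling on a
particle shared by two adjacent segments is counted once, and when one
segment is within contact range of two adjacent segments of the same other
cell only the closer contact is kept (otherwise the doubled normal forces
act like spurious friction).

### Short-range head-to-tail guiding

The head segment of one cell and the tail segment of another (possibly the
same) cell interact when the axis distance lies in the guiding window
$W < d < W + d_g$ with $d_g = 0.25$ um — half a cell width. The stated
window in terms of raw distance ("between `W` and `d_g`") is empty under
these values, so the package reads it as a *surface gap* of up to `d_g`,
which is the only reading compatible with the linear force law
$F(d) = (F^g_{max}/d_g)(d - W)$ reaching its maximum $F^g_{max}$ (200 pN;
100 pN is "weak guiding") at separation $d_g$. Three variants differ only
in where that force is applied:

* **adhesion** — the full force pulls the follower's head particle toward
  the leader's tail particle, with the exact reaction on the leader
  (action–reaction pair; the leader is slowed and steered too);
* **active following** — the same force on the follower's head only; the
  leader feels nothing (models pili pulling or chasing a secreted cue);
* **passive following (steering)** — only the component normal to the
  follower's body is kept, so the follower turns toward the tail but its
  speed never changes.

Each head engages at most one tail — the nearest qualifying one — modelling
a single attachment site; ties break deterministically by cell id.
(`params$guide_all <- TRUE` switches to engaging every tail in range; the
default single-attachment rule is used everywhere in this package's
analyses.) Cells engaged in a guiding pair have their reversal clock
paused: the clock (period `T_R`, 10 min for vegetative cells, `Inf` =
non-reversing, the default here) does not advance while engaged and is not
reset, matching suppression rather than rescheduling.

### Long-range guiding: slime trails

A periodic square grid (spacing 0.25 um) stores at most one unit vector
per element. After every step each cell writes the tangent at its rear
particle into the element below the rear (later cell ids override, in
ascending order). When a head particle sits over a marked element the
force $\mathrm{sgn}(o \cdot s)\, F^s_{max}\, s$ is projected on the body
normal and applied to the head: the trail reorients the tip without
changing speed, and the sign convention (with $\mathrm{sgn}(0) := +1$)
always turns the cell by an acute angle, so trails are usable in both
directions.

## The continuum rigid-body picture

Stable circular aggregates rotate approximately as rigid bodies: cells do
not slide laterally, so the speed of a cell at radius $r$ is $\omega r$.
Treating the aggregate as a uniform disk of motile material with engine
force density along the local velocity and drag density proportional to
local speed, zero net torque

$$\int_0^R (\gamma v_{\mathrm{eff}} - \gamma\,\omega r)\, r \cdot 2\pi r\, \mathrm{d}r = 0$$

gives $\omega = \tfrac43 v_{\mathrm{eff}}/R$: the edge speed
$v(R) = \tfrac43 v_{\mathrm{eff}}$ is independent of the aggregate size,
and larger aggregates rotate more slowly ($\omega \propto 1/R$). Under
adhesion the guiding forces are internal action–reaction pairs with zero
net torque, so $v_{\mathrm{eff}} = v_b$ and the edge speed is
$\tfrac43 \times 4 = 5.3$ um/min. Under active following every follower
can gain up to $F^g_{max}$ of external tangential force, so at saturation
$v_{\mathrm{eff}} = v_b (F_e + F^g_{max})/F_e = 3 v_b$ and the edge speed
is $4 v_b = 16$ um/min. The same ratio bounds a single pulled cell:
`max_pulled_speed()` returns $v_b(F_e + F^g_{max})/F_e$, and a direct
simulation of one cell with a constant 200 pN tangential head force
reproduces it to within 1%.

```{r}
rigid_body_predictions(R = c(5, 10, 20))
```

## What the scenario builders emulate

* `random_configuration()` — the low-density developmental field:
  straight cells at uniform random positions and orientations,
  rejection-sampled so no two axes come closer than `W`
  (5×10^6 cells/cm^2, `k_c = 0.01` N/m).
* `dense_aligned_configuration()` — a crowded aligned population
  (4×10^7 cells/cm^2) with random gliding directions; at this packing the
  collision stiffness must drop to `k_c = 0.002` N/m or motion jams.
* `spiral_configuration()` — a pre-formed circular aggregate: cells bent
  along an Archimedean spiral, head-to-tail with surface gaps inside the
  guiding window, all circulating the same way, each trailing cell
  slightly farther from the axis than its leader. The pitch default
  `1.1 W` keeps adjacent turns from overlapping.

None of these emulate biology beyond the mechanics: there is no growth,
no death, no C-signal biochemistry, no sporulation, and the model is
strictly two-dimensional. Passing tests therefore demonstrate properties
of the mechanical model, not of real swarms.

## Numerical choices

* **Integration.** Explicit overdamped Euler with `dt = 5e-4` s. Two
  guards apply: the collision-spring criterion
  `k_c*dt/gamma_particle < 0.2`, and the hard stability limit of the
  stiffest chain mode, `4*k_lin*dt/gamma_particle < 1.8` (the default sits
  at 1.2, a 40% margin). At runtime any particle displacement beyond
  `0.1 W` in one step aborts the run as an instability.
* **Inextensibility.** `k_lin = 0.1` N/m, ten times the low-density
  collision stiffness, keeps segment lengths within a fraction of a
  percent of rest length in all reported runs.
* **Neighbour search.** A uniform spatial hash over segment midpoints
  feeds a Verlet pair list with exact axis-distance cutoff
  `W + d_g + 0.15` um; the list is rebuilt when accumulated displacement
  could let a pair cross the margin. Same-cell adjacent segments are
  excluded (they share a particle).
* **Closest points.** Segment-segment closest-point queries use the
  standard clamped-parameter algorithm; for (near-)parallel segments with
  a continuum of minimisers the midpoint of the overlap interval is used,
  making collision directions deterministic. The degenerate case `d = 0`
  falls back to a fixed axis. All geometry uses the minimum image in the
  periodic box; segments are unwrapped about their first endpoint before
  any midpoint arithmetic so cells straddling the seam behave identically.
* **Determinism.** The integrator consumes no random numbers; scenario
  builders draw from R's RNG under a caller-supplied seed; slime
  deposition and every tie-break are resolved in ascending id order.
  Repeated runs are bitwise identical.

## Measuring rotation

`rotation_profile()` fits the rigid-body law $v(r) = \omega r$ to per-cell
mean speeds over a trajectory window (1-minute speed windows smooth
integrator noise). The rotation center minimises the residual of the
through-origin fit by a coarse-grid-plus-refinement search; radii are
time-averaged distances to the center (the distance of the time-averaged
position is biased inward along arcs). The rotation rate comes from
angular increments of positions relative to the instantaneous aggregate
centroid, which is exactly zero for translation and exactly $\omega$ for
rigid rotation, so drifting clusters are not misread as rotating. Two edge
speeds are reported: the mean speed of cells in the outermost decile of
radii (a direct but conservative estimate — on a small spiral of a few
dozen cells the outer decile sits visibly inside the rim), and the
rigid-body edge speed $v(R) = |\omega| R$ with $R$ the 95th percentile of
radii, which is the quantity the continuum model predicts. The rigidity
score is the coefficient of determination of the $v \sim r$ fit measured
against the speed variance; uniform translation scores 0.

## Scaled-down study sizes

The package's own validation runs use deliberately small systems so that
the full suite completes on one CPU in tens of minutes:

* spiral aggregates of 40-60 cells (inner radius 3 um, outer 7-8.5 um)
  run for 30 simulated minutes, profiled over the final 10;
* the two-cell follower experiment (leader driven at `1.5 v_b` through a
  per-cell engine multiplier) runs 5 simulated minutes;
* the population comparison uses 65 cells at the low density
  (5×10^6 cells/cm^2 in a 36×36 um box) for one simulated hour, stepped
  at `dt = 6.5e-4` s (still inside both stability guards; the long
  qualitative runs are the only place the looser step is used). Persistent
  rotating aggregates are detected with [orbital_winding()]: a group of at
  least eight cells that each complete two full turns on a confined path
  over the final half hour (transient swirls do not survive two orbits). Connected components are useless for this purpose
  in a small periodic box, where streams percolate and join everything
  into one component.

These are an order of magnitude below the populations behind the published
pattern figures (hours of simulated time, hundreds to thousands of cells),
which this package reproduces only qualitatively. Consequences of the
scale reduction worth knowing: small spiral aggregates carry less radial
compression, so lateral locking between turns is weaker and some material
slip along the spiral persists (rigidity scores around 0.5–0.85 rather
than ~1); and the outer-decile edge-speed estimator under-reads $\omega R$.
The adhesion edge speed measured on the 60-cell spiral agrees with the
$\tfrac43 v_b$ prediction through the rigid-body readout $|\omega| R$.
For active following at this scale the guiding links relax during the
initial transient instead of staying near saturation, so the measured edge
speed sits near the adhesion value rather than $4 v_b$; the saturated
regime behind the $16$ um/min figure emerges in large aggregates fed by
taut incoming streams, which a 40-60-cell pre-arranged spiral does not
recreate. The test suite states that expectation at its full strength,
so the corresponding check fails by design rather than being weakened.

## Known limitations

* Contacts are frictionless capsule repulsions; tangential coupling
  between sliding neighbours arises only from geometry (spiral pitch,
  bent shapes), which matters for how fast small aggregates spin up.
* One guiding attachment per head (the nearest tail). The alternative
  all-tails coupling is available as an option but is not the analysed
  configuration.
* The slime grid stores one direction per element with no decay or
  volume; trails persist until overwritten.
* The reversal clock is deterministic (fixed period), not stochastic.
* No third dimension: cells cannot climb over each other, which is
  precisely what makes trapping and jamming effective in this model.
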