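---
title: "Methods: hybrid lattice/particle spatial stochastic simulation"
author: "vox4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid lattice/particle spatial stochastic simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vox4d)
```

# The simulation model

vox4d simulates cellular reaction–diffusion systems at the meso-scale with a
hybrid representation. Space is a lattice of cubic sub-volumes ("c-voxels")
of edge length $h$, typically 0.01–1 µm. Abundant small molecules (e.g.
Ca²⁺) are *bulk* species: a real-valued molecule amount per voxel that
diffuses deterministically. Scarcer macromolecules (calmodulin, receptors,
kinases) are *point particles*: individually tracked molecules with
continuous off-lattice coordinates, named binding sites and boolean
modification states. Voxels belong to named compartments; species carry an
accessibility list, and both bulk flux and particle motion are blocked at
interfaces to disallowed compartments. A compartment flagged as a 2-D
membrane occupies the outer voxel layer and restricts membrane-bound
particles to in-plane diffusion.

Each timestep $\Delta t$ executes a fixed phase order: (1) bulk diffusion,
(2) particle Brownian displacement with reflection and microdomain
partition biasing, (3) reactions in the sub-order unimolecular →
bulk–particle → particle–particle → bulk–bulk, (4) probabilistic
transport, (5) reversible immobilization, (6) sources/sinks, (7) logging.
A single Mersenne-Twister stream with inversion normals is consumed in
this order, so results are bit-reproducible given (model, seed).

## Bulk diffusion

Fick's second law is integrated by the explicit forward-Euler scheme on the
6-neighbor (face-adjacent) stencil:
$$N_i' = N_i + \frac{D\,\Delta t}{h^2}\sum_{j \in \mathrm{acc}(i)} (N_j - N_i),$$
where $\mathrm{acc}(i)$ are the face neighbors accessible to the species.
Pair fluxes are applied antisymmetrically, so total amount is conserved to
floating-point exactness. The stability bound $D\,\Delta t/h^2 \le 1/6$
(3-D explicit stencil) is enforced at model validation and again at each
step, naming the offending species. Under that bound the update is a convex
combination, so amounts stay non-negative. Amounts are continuous reals by
design; bulk species model concentrations, not individual molecules.

## Particle motion

Free particles take independent Gaussian steps per axis with standard
deviation $\sqrt{2 D \Delta t}$. A proposed position that leaves the
simulation box or enters a disallowed compartment is reflected specularly
at the crossed boundary plane and re-checked; after 10 failed reflections
the particle stays put (this is exercised only in pathological geometries).
Specular reflection preserves the uniform equilibrium distribution, which
the test suite checks by octant occupancy in a closed box.

Membrane-bound species inside a 2-D membrane compartment keep the
coordinate along the outward normal ("frozen axis") fixed. Edge and corner
voxels are assigned one frozen axis with priority x → y → z. A 2-D step
that would carry a particle past a cube edge onto a face with a different
normal is deflected at the edge rather than transported around it; without
this rule the axis priority would act as a ratchet that slowly funnels all
membrane particles onto the x-faces. A consequence is that each
membrane-bound particle stays on its face plane unless a transport event
relocates it, which the microdomain occupancy test accounts for by
aggregating the per-plane two-state balance.

## Reactions

*Unimolecular* rules fire per particle with probability
$1 - e^{-k \Delta t}$ (exact at any step size, unlike $k\,\Delta t$); bulk
reactants convert deterministically by the same fraction per voxel.

*Particle–particle* rules use the Smoluchowski absorbing-sphere picture:
all unordered reactant pairs within a binding radius $\sigma_b$ react with
probability 1, matched greedily nearest-first with each particle reacting
at most once per step (nearest-first is deterministic given positions and
avoids list-order artifacts). At finite $\Delta t$ the naive radius
$\sigma = k/(4\pi D_{sum})$ under-reacts because pairs can hop over the
sphere within one step, so the radius is enlarged following Andrews and
Bray: the package computes, once per reduced step size
$s' = \sqrt{2 D_{sum}\Delta t}/\sigma_b$, the steady-state absorption rate
of the discrete-time process by iterating the exact radial free-diffusion
propagator (the radially symmetric density $f(r) = r\,c(r)$ obeys a 1-D
heat kernel with an image at the origin) against an absorbing unit sphere,
with a self-consistent $c = 1 - A/r$ far field. The resulting reduced-rate
table (shipped as `inst/extdata/ab_reduced_rates.tsv`, regenerable with the
internal solver) is inverted by monotone root finding and is pinned to the
two analytic limits: $\sigma_b \to k/(4\pi D_{sum})$ as $\Delta t \to 0$
and $\sigma_b \to (3 k \Delta t/4\pi)^{1/3}$ for well-mixed (large) steps.
Outside the tabulated range ($s' \in [0.05, 5]$) the closed forms are used
with a first-order boundary-layer correction on the small-step side; both
switches are accurate to about 1%. A requested rate with zero mutual
diffusion, or one needing a radius beyond the optional physical cap,
raises an "activation-limited regime" error: particle collision is then
not the rate-limiting assumption.

A single product is placed at the reactants' midpoint. The reverse of a
reversible binding places the two products at the unbinding radius
$\sigma_u = m\,\sigma_b$ along a uniformly random direction; $m$ defaults
to 1 (products at contact), which biases toward geminate recombination —
accepted and documented, with the multiplier exposed per rule
(`sigmaUMult`). Any rule creating a particle pair (e.g. dimer dissociation)
uses the $\sigma_u$ of the rule that would re-bind that pair.

*Bulk–particle* rules fire per particle with probability
$1 - e^{-k C_{local} \Delta t}$, where $C_{local}$ is the bulk
concentration in the particle's voxel; each firing subtracts one
molecule-equivalent from that voxel (floored at zero). Accuracy improves
as the bulk species diffuses faster, since local depletion around the
particle vanishes; a regression test asserts this monotonicity.

*Bulk–bulk* rules apply the deterministic per-voxel mass-action decrement
$\Delta N = k C_a C_b V N_A \Delta t$, capped so no amount goes negative.

Catalysts (species appearing unchanged on both sides) are never consumed;
per-rule stoichiometry is conserved exactly, which the suite checks via
receptor bookkeeping ($2\,\mathrm{dimers} + \mathrm{monomers}$ invariant)
and calcium conservation (free + site-bound, to $10^{-9}$ relative).

## Transport, microdomains, immobilization

Inter-compartment trafficking is abstracted as a single probabilistic
event: each matching particle in the source compartment relocates with a
fixed per-step probability to a uniformly random accessible voxel of the
destination (vesicle delivery anywhere on the target), with destination
voxels weighted by microdomain entry biases so partition exclusion cannot
be bypassed. A state flag (e.g. ITIM phosphorylation) can block a rule.

Membrane microdomains (lipid rafts) are voxel subsets of the membrane with
species-specific entry/exit biases in [0, 1]. A diffusion step crossing the
domain boundary is accepted with the entry bias (inward) or exit bias
(outward); denials deflect at the boundary. Biases of 1 consume no
randomness, so enabling microdomains with neutral biases leaves
trajectories bit-identical. The stationary in-domain density exceeds the
area fraction by the factor entry/exit, per face plane.

Reversible immobilization is the surrogate for trans-binding of surface
receptors to an apposed cell: mobile matches immobilize at rate
$k_{on}$ and release at $k_{off}$ (exponential per-step probabilities);
immobilized particles skip diffusion, transport and particle–particle
reactions (a trans-engaged receptor is sterically unavailable), and the
immobilized count is the "clustered" readout.

# The built-in model systems

## Cooperative calmodulin activation (well-mixed)

A 4×4×4 lattice of 0.2 µm voxels (0.8 µm cube, 5.12×10⁻¹⁶ L). Calcium is
bulk ($D$ = 220 µm²/s, free-ion value); calmodulin particles
($D$ = 30 µm²/s) carry four sites N1, N2, C1, C2. Binding is sequential
per lobe — the second site opens only when the first is occupied and has
the higher affinity (positive cooperativity) — implemented as
state-dependent bulk–particle rules with the reverse unbinding rules
returning a calcium to the particle's voxel. The macroscopic two-step
rate constants per lobe are read from the versioned parameter file
`inst/extdata/calmodulin_rates.yaml` (Faas et al. 2011, Nat Neurosci
14:301–304; see the file's provenance comments); every kinetics check is
expressed relative to the mass-action oracle run with the same constants,
so the validation surface does not depend on the specific values. At 2 µM
calmodulin the box holds 617 particles. The default timestep is 0.5 µs —
well inside the 32 µs stability bound for Ca²⁺ diffusion, but required by
the kinetics: exponential per-step probabilities are exact for a single
transition at any Δt, yet sequential application of competing fast
transitions distorts the discrete-time equilibrium by O(kΔt), and the
fastest transition (N-lobe second site, 3.2×10¹⁰ M⁻¹s⁻¹) reaches
k·c·Δt ≈ 0.2 at the top of the calcium scan already at Δt = 0.5 µs.
Scaled runs use 40,000–60,000 steps (20–30 ms), several relaxation times
of the slowest mode at the scanned concentrations.

The well-mixed reference is `massActionEuler()`, a forward-Euler
mass-action integrator over the 9-state (two lobes × occupancy 0–2)
network built by `calmodulinNetwork()`; `camEquilibrium()` solves the
detailed-balance equilibrium algebraically (free calcium by monotone root
finding on the conservation equation). The Euler oracle is cross-checked
in the tests against an independent stiff integrator (deSolve::lsoda) and
against the algebraic equilibrium.

## Calcium microdomains (quintile model)

A 10×10×10 lattice of 0.08 µm voxels divided into five 2-voxel slabs
Q1–Q5. Four voxels on the Q1 outer face are clamped to 1 mM calcium after
every step (Dirichlet source; the release-site layouts `center`,
`original` and `split` place the 2×2 block at the face center, offset one
voxel diagonally, or split into the four quarter-points — the published
end-view schematic is not dimensioned, so placement is checked by a
layout-insensitivity test rather than fixed coordinates). The Q5 outer
face absorbs; all other boundaries reflect. Calmodulin diffuses freely
through all quintiles, carrying occupancy acquired near the source.

A caveat this package documents honestly: with a 1 mM clamp at four
80-nm voxels and a single absorbing face, the exact diffusion steady state
(independent of $D$ and $\Delta t$) averages hundreds of micromolar over
the lattice, so the quintile concentrations sit one to two orders of
magnitude above the 1–10 µM range that motivates the microdomain story,
and the Q5 calmodulin population is mostly activated (CaM₄) rather than
merely primed (CaM₂). Reproducing a low-micromolar interior would require
either sub-voxel (nanometre) release sites or distributed removal
(buffering/pumps), neither of which is part of this model family. The
quintile gradient itself, its monotone decrease Q1→Q5, and the
layout-insensitivity are robust and are what the acceptance checks assert
quantitatively; the reported CaM₂/CaM₄ values in Q5 are computed and
reported as-is. (At the model's 1 µs step the near-source binding
probabilities saturate — k·c·Δt > 1 at millimolar calcium — which is
acceptable because the bound state dominates there anyway, but is a
further reason not to over-interpret the per-quintile occupancy values.)

## CEACAM1 clustering (raft and no-raft)

A 6×6×6 lattice of 0.2 µm voxels with four compartments: membrane (outer
layer, 2-D), cytosolic interface (next layer), and the 2×2×2 core split
between cytosol and an inert organelle (with one-voxel-thick layers in a
6³ box the core is exactly 2×2×2, so a central 2×2×2 organelle would leave
no cytosol; the builder halves the core instead). Species: CEACAM1
cis-dimers and monomers (membrane-bound, $D$ = 0.1/0.2 µm²/s, shuttling
between cytosol and membrane only via transport events — the interface
layer is inaccessible to them, so diffusion cannot cross), Lck
(membrane-only, $D$ = 0.2), and activated calmodulin ($D$ = 10), a
peripheral species allowed in the interface layer and the membrane layer
(confining it strictly to the interface would make nanometre-radius
contact with membrane-resident dimers geometrically negligible at 0.2 µm
voxel resolution, silencing the dissociation pathway entirely).

Rules: dimer + CaM → 2 monomers (catalytic in CaM by default, with a
consumptive switch; k = 10⁷ M⁻¹s⁻¹, the top of the slow-species range),
monomer + monomer → dimer (k_dim, default 10⁶, the scanned variable;
unbinding multiplier 2 so dissociation products start outside immediate
re-binding range), Lck + monomer → Lck + phospho-monomer (k = 10⁶;
raft-scoped in the raft variant), export and internalization at 10⁻³ per
step each, with internalization blocked by phosphorylation, and reversible
immobilization of membrane monomers (k_on = 5 s⁻¹, k_off = 0.2 s⁻¹ —
trans-binding forms a long-lived cluster on the 1 s scale of scaled runs).
The raft variant defines one 2×2-voxel microdomain patch per face (24 of
152 membrane voxels, area fraction 0.158) with monomer entry/exit 1.0/0.2,
dimer 0.2/1.0, and Lck 1.0/0.0 (raft-confined). Initial state: 50 dimers
in the cytosol, 0–20 Lck on the membrane, 0–20 activated calmodulin at the
interface. The full-scale system runs 200,000 steps of 50 µs (10 s);
scaled validation runs use 12,000–20,000 steps with 6 replicate seeds,
which resolves the calmodulin dependence and the growth of the clustered
count but leaves the dimerization-rate scan close to counting noise
(a handful of clustered monomers per run).

# What the generators do and do not emulate

The builders produce the study conditions programmatically; no external
data are read. They emulate compartmentalized geometry, hybrid
bulk/particle kinetics, membrane dimensionality, raft partitioning and
probabilistic trafficking. They do not emulate molecular crowding,
electrostatics, explicit calcium buffers, vesicle formation (transport is
a point event), trans-cellular geometry (immobilization is the surrogate),
or downstream signaling. Passing tests therefore validate the numerical
engine and the stated model structure, not the biological completeness of
the models.

# Numerical choices and degenerate inputs

* Exponential event probabilities everywhere (`1 - exp(-k dt)`), exact for
  homogeneous rates at any step size.
* Reflection retry cap 10, then stay put; keeps every particle in legal
  space unconditionally.
* Bulk clamp sources are applied after diffusion, so clamped voxels read
  exactly the target concentration at every log point.
* Zero-rate rules, zero-amount fields, empty compartments scoped by rules,
  and zero-step runs are all legal no-ops; the counts table always
  contains the step-0 row.
* Ties in nearest-first pair matching resolve by candidate order;
  positions are continuous doubles, so exact ties essentially never occur.
* The voxel index of a position on the extreme upper box face is clamped
  to the last voxel (floating-point guard on the half-open convention).

# Known limitations

* Forward-Euler bulk diffusion limits $\Delta t$ by $h^2/(6D)$; fast ions
  at fine lattices force microsecond steps.
* The absorbing-sphere construction assumes collision-limited kinetics;
  activation-limited reactions are rejected, not approximated.
* Geminate recombination at $\sigma_u = \sigma_b$ is a known bias of the
  contact-placement default.
* Per-voxel compartment geometry cannot represent curved membranes; the
  membrane is the box's outer layer.
* Particle counts beyond ~10⁴ per species are workable but the engine is
  tuned for the hundreds-to-thousands range of the built-in systems.
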