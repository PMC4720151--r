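---
title: "Qualitative dynamics of B-cell terminal differentiation"
author: "bcellfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative dynamics of B-cell terminal differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcellfate)
```

## The biological system and the model

Mature (Naive) B lymphocytes leave the bone marrow expressing the identity
factors Pax5 and Bach2. Depending on the extracellular signals they receive
— interleukins 2/4 and 21, antigen binding to the B-cell receptor, and
direct T-cell contact through CD40L — they differentiate into germinal
center (GC) cells, memory (Mem) cells, or antibody-secreting plasma cells
(PC). Each fate is characterised by a stationary activation pattern of six
master regulators: Bach2, Bcl6, Blimp1, Irf4, Pax5 and XBP1. The identity
program (Pax5, Bach2, Bcl6) and the plasma-cell program (Blimp1, Irf4,
XBP1) repress each other, so the core behaves as a set of interlocking
mutual-inhibition switches.

`bcellfate` ships this regulatory logic as a packaged 22-node network:
6 core regulators, 5 regulator-free environmental inputs (Ag, CD40L, IL2,
IL4, IL21) and the signal-transduction chains that connect them
(Ag→BCR→ERK, CD40L→CD40→NFkB, IL2→IL2R→STAT5, IL4→IL4R→STAT6,
IL21→IL21R→STAT3). Each of the 17 regulated nodes carries a Boolean rule
over AND/OR/NOT; parsing the rules yields 39 signed interactions, four of
which are structural predictions rather than literature-curated edges
(Pax5→Bcl6, Irf4⊣Pax5, and the Bcl6 and Pax5 self-activations, required
for the observed stationary patterns to exist).

```{r}
net <- load_bcell_network()
net$rules$Bcl6
nrow(extract_interactions(net))
```

## Two dynamical engines over one rule set

Rules are stored as expression trees, not truth tables, so the same object
drives both engines.

**Discrete engine.** All nodes update synchronously,
`x_i(t+1) = F_i(x(t))`. Input nodes have no rule; they decay to 0 on the
next step unless clamped. This convention makes all environmental
stimulation transient (pulses), keeps every attractor free of spurious
frozen inputs, and lets basin fractions over the full state space sum
to 1. Exhaustive attractor search materialises the complete synchronous
successor map bit-parallel (node values of all `2^n` states as logical
vectors, one vectorised rule evaluation per node) and resolves every
trajectory by pointer doubling, which makes the 4,194,304-state wild-type
enumeration a matter of seconds. Enumeration refuses networks beyond 24
free nodes; the guard bounds the successor map's memory, and larger models
should be analysed by trajectory sampling instead.

**Continuous engine.** Each rule is fuzzified structurally — AND→`min`,
OR→`max`, NOT→`1 − x` — giving the regulatory input `omega_i` in `[0,1]`,
and each regulated node follows

    dx_i/dt = f(omega_i; h_i) − gamma_i * x_i

where `f` is a normalised sigmoid fixed at (0,0), (0.5,0.5) and (1,1) for
every gain `h`. Regulator-free inputs carry only the decay term. Because
`f(0)=0` and `f(1)=1` exactly, every binary fixed point of the Boolean
model is automatically an equilibrium of the continuous system at
`gamma = 1` — the property that makes the two engines directly
comparable.

### Parameters

* `h` (gain, default 50, dimensionless): slope of the response around the
  half-activation point. At `h = 50` the sigmoid is practically a step
  function; at small `h` it is nearly linear. Binary equilibria do not
  move with `h`.
* `gamma` (decay rate, default 1, per unit time): a saturated node settles
  at `f(omega)/gamma`, so only `gamma = 1` keeps steady levels on the
  `{0, 1}` corners; `parameter_sweep()` demonstrates the displacement
  (e.g. a fully driven node sits at 0.5 when `gamma = 2`).
* `convergence_tol` (default `1e-10`): relaxation stops when
  `max |dx/dt|` falls below it. The integrator (`deSolve::lsoda`, stiff
  capable) runs at `rtol = 1e-10`, `atol = 1e-12` so that the residual can
  actually reach this level; looser settings leave a residual floor near
  the integrator's own tolerance.
* `merge_tol` (default `1e-6`): converged states closer than this are one
  attractor. With residuals at `1e-10` the clustering is unambiguous.
* Pulse/perturbation duration (default 10 time units): long compared with
  the decay time scale (1), short compared with inter-pulse intervals in
  the differentiation protocol. The published pulse protocol requires only
  "2 or more" units; 10 is comfortably past the threshold and the
  destination attractors are insensitive to the exact value.

## Attractors, basins and what the model reproduces

Exhaustive enumeration finds exactly four fixed points, whose core
patterns `[Bach2, Bcl6, Blimp1, Irf4, Pax5, XBP1]` are the canonical
cell-type signatures: Naive `[1,0,0,0,1,0]`, GC `[1,1,0,0,1,0]`, Mem
`[1,0,0,1,1,0]`, PC `[0,0,1,1,0,1]`, with every signalling and
environment node off. There are no limit cycles in the wild type.

Basin sizes measured over all `2^22` initial states are strongly skewed
toward PC (≈99.1%), with Naive ≈0.18%, GC ≈0.10% and Mem ≈0.65%. The
skew has a structural reason: the Irf4 rule contains a positive self-loop,
so any initial state with Irf4 on can never switch it off, and any
transient activity in the Ag/IL21 branches activates Blimp1; both funnel
trajectories into the plasma-cell basin. The same skew persists if the
five environment nodes are fixed at zero instead (2^17 states, PC
≈96.4%), and in the 64-state core-only subspace the split is
31.25/6.25/12.5/50 — these alternative conventions are all computable
with `enumerate_attractors()` via clamps, and none of them redistributes
the bulk away from PC.

## Intermediate attractors and the knife-edge caveat

Random-start sampling of the continuous system (uniform starts in
`[0,1]^22`) finds only the four binary attractors. The discovery protocol
— clamping each node of each attractor at 0, 0.5 and 1 for 10 units,
releasing, and relaxing — additionally finds intermediate fixed points in
which Bcl6 and/or Irf4 sit at exactly 0.5 on a Bach2+/Pax5+ background,
plus one further state with Bach2, Blimp1, Pax5 and XBP1 all half-active
and Irf4 on. All of them are analytically exact equilibria for *every*
gain: each half-active node's fuzzy input equals 0.5 and the sigmoid fixes
0.5. They are, however, knife-edge states: their stability is one-sided
(the `min`/`max` terms clip the destabilising direction only while the
level is *exactly* 0.5), their basins have zero volume, and they are
reached only by protocols that terminate exactly on them. Consequently,
whether a numerical search retains them depends on sub-`1e-10` integrator
residue in the starting attractor. `perturbation_search()` therefore
perturbs the idealised (merge-grid snapped) attractor states, which makes
the discovery outcome deterministic across seeds and integrators: three
Bcl6/Irf4 intermediates plus the four-node half-active state, eight fixed
points in total. Analyses that discard knife-edge states as numerically
unreachable will count seven.

## Differentiation protocol and fate maps

`simulate_pulses()` reproduces the directional differentiation sequence:
a saturating IL4 (or IL2) pulse moves Naive to GC, CD40L moves GC (or
Naive) to Mem, and Ag (or IL21) moves any precursor to PC. Pulses pin the
node's level and zero its derivative during the window, then release it
into free dynamics — matching how a saturating extracellular
concentration during a brief incubation would behave.

`build_fate_map()` systematises this: every attractor × node ×
perturbation level, with an edge whenever the destination differs from the
source. In discrete mode a perturbation is a single-node flip followed by
free synchronous evolution (the one-step analogue of a brief clamp); in
continuous mode it is the clamp-release-relax protocol at levels
{0, 0.5, 1}.

In the discrete engine the PC vertex has out-degree zero: differentiation
into the plasma-cell fate is irreversible while the precursor fates remain
plastic. In the continuous engine that irreversibility turns out to be
marginal rather than absolute. If Irf4 is clamped to 0 for more than a
fraction of a time unit, Blimp1 (whose only remaining drive is Irf4)
decays below threshold before Irf4 can recover through Blimp1 — at
`gamma = 1` the decay and recovery curves cross 0.5 simultaneously in the
step-function limit — and the cell relaxes to Naive; a sustained Pax5 = 1
clamp likewise de-differentiates PC to Mem. Both transitions were
confirmed with two independent stiff integrators at tight tolerances, so
they are properties of the equations, not numerical artifacts; analyses
run at looser solver settings can resolve the marginal race the other way
and see an absorbing PC state. Instantaneous reset perturbations (set the
level, release immediately) do not rescue absolute irreversibility either,
and additionally fail to relay signalling-cascade perturbations, so the
clamp protocol is kept as the default.

## Mutant scans

`mutant_attractors()`/`mutant_report()` clamp one node at 0
(loss-of-function) or 1 (gain-of-function) and recompute the attractor
landscape, exhaustively in the discrete engine. Labels use the core
signatures with the clamped node excluded from the match; a pattern whose
free core bits match a signature while the clamped bit is forced away is
reported as `<label>-like` (e.g. `[0,0,0,0,1,0]` under a Bach2 clamp is
Naive-like). One mutant state, `[1,1,0,1,1,0]` under constitutive Bcl6,
is mechanically Mem-like under this rule although it is biologically better
read as a centrocyte-like state (Bcl6+ and Irf4+ simultaneously); users
should treat `-like` labels as pattern bookkeeping, not cell-type calls.
Hallmark outcomes: Blimp1 loss abolishes PC (and exposes a
`[0,0,0,1,0,0]` pre-plasma state); Irf4 loss leaves only Naive and GC;
Pax5 loss drives the system to PC or a fully-off state; constitutive
Blimp1 collapses everything onto PC; sustained Ag/BCR/ERK/IL21/IL21R/STAT3
signalling also leaves PC as the only attractor.

## What the synthetic generator does and does not emulate

`generate_random_network()` produces random Boolean networks with named
nodes, declared inputs, fixed in-degree and rules built either as random
AND/OR/NOT trees or as random truth tables materialised in disjunctive
normal form — exactly the structural assumptions the engines make, and
nothing more. It exercises code paths (enumeration vs. a brute-force
oracle, fuzzification corner-consistency, discrete-to-continuous
equilibrium carry-over) on arbitrary instances. It makes no biological
claims: degree distributions, canalisation and redundancy of real
regulatory networks are not modelled, so passing property tests on random
instances validates the *engines*, not the biological fidelity of any
particular network.

## Numerical choices and degenerate inputs

* State encoding uses a fixed byte-wise alphabetical node order, so
  attractor tables and basin counts are reproducible across locales.
* Cycle detection hashes visited states per trajectory; full enumeration
  uses global pointer doubling (`ceil(log2(N)) + 1` squarings bounds any
  transient), and cycles are rotated to start at their smallest encoded
  state so attractor identity is entry-point independent.
* Relaxation integrates in 25-unit chunks, re-checking the exact residual
  `max |dx/dt|` between chunks; non-convergence at `max_time = 500` is
  flagged, never silent.
* Clamps during integration are implemented as zeroed derivative plus
  re-pinned level after each chunk, which prevents drift without forcing
  terms.
* Constant rules (`0`/`1`), self-loops and input-only networks are legal;
  empty clamp sets mean wild type; rules referencing undeclared nodes,
  duplicate targets, and a regulator appearing with both signs in one rule
  are rejected with explicit errors.
* Problem sizes used in the shipped tests: full `2^22` wild-type
  enumeration, `2^21` per mutant clamp for the core mutants and sustained
  signals, 1000 random starts for the continuous attractor search, and
  8–10-node random networks (vs. a per-state brute-force oracle) for the
  property suite.

## Known limitations

* Synchronous updating only; asynchronous or probabilistic schemes can
  change reachability and cycle structure and are out of scope.
* The continuous engine's intermediate attractors are knife-edge states
  (see above); their biological interpretation (e.g. centrocyte-like
  Irf4-intermediate states) should be treated as a hypothesis, not a
  prediction of robust multistability.
* Basin fractions depend on the chosen initial-state convention; the
  package reports the full-state-space convention and exposes clamps for
  alternatives.
* No kinetic calibration: time is in arbitrary units and `h`, `gamma` are
  qualitative knobs, not fitted rates.
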