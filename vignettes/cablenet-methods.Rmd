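---
title: "cablenet: models, numerics and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cablenet: models, numerics and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model it
solves, the numerical schemes and their error behaviour, the parameters
that matter, how the verification harness works, and the design
decisions taken where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The model

A cell is a tree of *Sections* — unbranched conical frusta with explicit
3D endpoints, end radii (μm) and a *Region* label. Sections are
subdivided into `nseg` equal-arc *segments*; each segment's membrane
area is the exact lateral area of its sub-frustum, so discretisation
conserves total area identically (asserted in the tests against random
trees). A child section is electrically attached to the distal end of
its parent.

Each segment carries the current-balance equation

$$C_m \frac{dV}{dt} = -\sum_i g_i(t)\,(V - E_i)\; -\; I_{axial} \;+\;
  I_{inj} \;+\; I_{syn} \;+\; I_{gap},$$

with positive current outward. Axial coupling between adjacent segment
centres is $a = \pi \bar r^2 / (R_a \ell)$ with linearly interpolated
radius $\bar r$, centre distance $\ell$ and cytoplasmic resistivity
$R_a$.

Membrane mechanisms:

* **Leak**: constant specific conductance.
* **α/β-gated channels**: each gating particle $x$ relaxes as
  $dx/dt = \alpha(V)(1-x) - \beta(V)x$ with rates in the classic
  five-parameter form $(A + BV)/(C + \exp((V+D)/E))$ (A in ms⁻¹, B in
  ms⁻¹ mV⁻¹, D and E in mV, C dimensionless). When $C = -1$ the
  denominator vanishes where a consistently parameterised numerator
  does too; `eval_rate()` returns the analytic limit $B\,E$ there
  rather than nudging the voltage, so the classic $V = -40$ mV point of
  the squid sodium activation gate is exact.
* **Double-exponential postsynaptic receptors**:
  $g(t) = \bar g\,N\,(e^{-t/\tau_d} - e^{-t/\tau_r})$ with
  $N = 1/(e^{-t_p/\tau_d} - e^{-t_p/\tau_r})$ and
  $t_p = \frac{\tau_d \tau_r}{\tau_d - \tau_r}\ln\frac{\tau_d}{\tau_r}$,
  so `gbar` is literally the peak conductance — directly interpretable
  and directly testable. Overlapping events sum linearly.
* **Gap junctions**: ohmic, $g_{gj}(V_{other} - V_{self})$.

## 2. Units

Every user-facing parameter is a `quantity`: a magnitude canonicalised
to SI base units at construction plus an integer exponent vector over
(length, mass, time, current, amount) and a display label. Conversion is
a single division by the target unit's scale, so round trips are exact
to machine precision and chains of conversions cannot accumulate error
(property-tested over the whole whitelist at 1e-12). The unit grammar is
a deliberate *whitelist* — products, quotients and integer powers of
named tokens (`mV`, `pA`, `ms`, `um2`, `mS/cm2`, `Ohm*cm`, …, with μ
accepted for `u`) — rather than an arbitrary grammar: scenario files and
summaries must be bit-exact auditable. Temperature, offset and
logarithmic units are out of scope. The canonical-internal-SI choice is
this package's own; nothing upstream prescribes one.

## 3. Numerical schemes

**Voltage update.** Implicit θ-stepping of the linearised membrane
equation on the Hines-ordered segment tree (parents before children),
solved by one O(N) tree-elimination pass per cell per step.

* *Backward Euler* (default): first order, L-stable. Chosen as default
  for robustness under event-driven conductance jumps (synaptic onsets),
  where trapezoidal methods ring.
* *Crank–Nicolson* (`method = "cn"`): second order. The convergence
  tests verify the error against the closed-form RC step response
  shrinks ≈4× per dt halving (BE: ≈2×).

**Gating.** Rush–Larsen exponential update
$x \leftarrow x_\infty + (x - x_\infty)e^{-\Delta t/\tau_x}$ evaluated at
the start-of-step voltage (first-order operator splitting).
Unconditionally stable and keeps $x \in [0, 1]$ by construction.

**Stimulus currents.** The injected current applied during a step is the
*exact average* of the commanded waveform over the step interval
(closed-form for step and ramp protocols, trapezoidal for sine). This
makes the injected charge per step exact for piecewise-linear waveforms
under both schemes; sampling the waveform at the step endpoint instead
would inject one spurious step of charge at a window edge that falls on
a step boundary — an O(dt) artifact that would dominate the
backward-Euler/Crank–Nicolson cross-comparison.

**Synapses.** The double exponential is integrated analytically between
events as two decaying states (rise and decay), incremented when an
event is delivered; no ODE stepping, hence the clamped-conductance test
can demand agreement with `psr_conductance()` at the sample times to
well under 0.5%.

**Events.** A presynaptic detector fires at the first step whose end
voltage reaches threshold from below (strict hysteresis: no retrigger
until the voltage falls below threshold). Delivery time is crossing step
time + synaptic delay, folded *up* to the next step boundary; events
falling beyond the simulation end are dropped and counted in the
metadata. The default trigger threshold is 0 mV (upward crossing) —
the source material says only "triggered by an action potential".

**Gap junctions.** Cross-cell coupling would make the system matrix
non-tree; instead each step performs up to 5 fixed-point sweeps
(tolerance 1e-9 mV) with the neighbour voltage frozen per sweep, keeping
every per-cell solve O(N). For the nS-range junctional conductances of
interest convergence is fast; the coupling-coefficient test
(g/(G+g) = 0.25 for 1 nS against 3 nS leak) passes at 0.5%.

**Initial conditions.** Unless an explicit `initial_voltage` is given,
each segment starts at its conductance-weighted reversal potential with
gate variables at their steady state (evaluated at −65 mV for the
weighting, then settled at the resulting voltage). For a passive cell
this is exactly the leak reversal; for the classic squid soma it lands
within a fraction of a millivolt of the true resting point. Tests that
compare against an independent reference integrator set
`initial_voltage` explicitly so both integrators share one stated
initial condition.

**Recording.** Every request is sampled at every step boundary
including t = 0 (the upstream behaviour — every dt vs. a separate
recording interval — is unspecified; this package records every dt).
Spike times for `Events` recordings are linearly interpolated at the
crossing; spike *counts* use the raw strict-crossing rule, so counts are
grid-robust and times are smooth.

## 4. Channel distribution resolution

Densities are declared as (Channel, Applicator, Targeter) triplets. A
targeter selects sections (`everywhere` / `region(name)` / `section(id)`)
and carries an integer priority defaulting to 1/2/3 in that order — the
"more specific wins" principle made explicit and user-overridable.
For each (section, channel) the single highest-priority matching triplet
determines parameters: defaults, then overrides, then multipliers.
Two matches at equal priority are a hard *ambiguity error* rather than
last-one-wins: silent shadowing of a conductance density is a
correctness hazard in exactly the situations this notation exists for.
Multipliers never stack across triplets — a channel is applied once per
section. Whether the upstream priority scale was numeric or ordinal is
unstated; the integer scheme is this package's choice. Continuously
varying (per-segment) applicators are excluded, mirroring the source's
own "not yet implemented".

## 5. Tag queries

`ALL{…}` is a subset test, `ANY{…}` a nonempty-intersection test;
`NOT` binds tightest, then `AND`, then `OR` (conventional precedence —
the source is silent). Tag comparison is case-insensitive because the
upstream text itself mixes `Conductance` and `CONDUCTANCE`. Automatic
tags per recording: the modality (`Voltage`, `Current`, `CurrentDensity`,
`Conductance`, `ConductanceDensity`, `Event`), the cell name,
`loc:<section>`, the channel name where applicable, and for synapses
`SYNAPTIC`, the template name, `POST:<cell>` and (for spike-triggered
synapses) `PRE:<cell>` — enough to reproduce every printed example
query. Correctness is property-tested against an independent naive tree
evaluator on 10,000 random (query, tag set) pairs, plus De Morgan and
print/re-parse equivalence checks. Tags containing spaces are
unsupported (an apparent upstream "POST:cell 2" is read as a
typesetting artifact).

## 6. Morphology I/O

SWC is the 7-column whitespace format with `#` comments and one root
sample (parent −1). Each consecutive sample pair becomes one frustum
Section, so chains split at branch points automatically; a section takes
the *region of its proximal sample* (this is what makes a 3-sample file
of types 1,3,3 read as soma + dendrite sections). The writer labels
junction samples with the child section's region so read∘write is the
identity on topology, geometry (to the printed 1e-6 μm) and regions —
provided sibling sections at a junction share one region, and the root
sample has a single child (a one-root tree cannot represent several
children of the root sample without re-parenting; `read_swc()` documents
this). A single-sample file becomes a cylinder with L = d = 2r (the
equal-area sphere convention); programmatic somata built from a target
area use L = d = sqrt(A/π) — the upstream helper's geometry for "a
single Section of 1000 μm²" is unstated, so the cylinder rule is a
documented choice here.

## 7. The scenario harness (synthetic verification data)

A scenario file is a human- and machine-readable description of a small
simulation — structured directives with `<PARAM>` placeholders, a units
table, record declarations, a parameter sweep and a table of expected
values in slice notation (`$V[95:100].mean`, half-open windows in ms,
statistics mean/max/min with mean the default). The tolerance is
relative (default 1%) with an absolute floor of 0.01 in the record's
unit, to avoid division blow-ups near zero. Descriptions are structured
keyword directives, not natural language: BDD-style parsing of free text
is out of scope, and the original scenario-repository dialect is not
fully printed anywhere, so this grammar is versioned independently.

`generate_fixture_scenarios()` emits six files whose expectations are
*closed forms, never simulator output*:

1. **passive_step** — settled means at $E + I/G$ (the worked passive
   cell: 1000 μm², 1 μF/cm², 0.3 mS/cm² at −51 mV, so G = 3 nS,
   τ = 10/3 ms; I = 0, 100 pA and one seed-varied amplitude);
2. **passive_ramp** — the ramp response tracks
   $E + (k/G)(t' - \tau)$ after several τ;
3. **input_resistance** — 1200 μm² at 0.27778 mS/cm² is 300 MΩ;
   deflections are $I R_{in}$;
4. **time_constant** — window means of the charging curve over
   [0, τ) and [τ, 2τ) after onset (the mean over the first τ is
   $E + IR/e$);
5. **gap_coupling** — the two-node linear system:
   $u_1 = I(G+g)/(G(G+2g))$, $u_2 = \frac{g}{G+g} u_1$;
6. **psr_peak** — clamped synaptic conductance peaks at `gbar` at
   $t_p$; the tail-window mean is the analytic double-exponential
   integral.

The seed perturbs sweep amplitudes deterministically (same seed ⇒
byte-identical files); the physics of the expectations is recomputed
from the drawn values, never tuned. Window statistics compare the
*left-sampled* trace mean with the *continuous* analytic mean; the
discretisation bias is O(dt/2 · slope) — two orders below the 1%
tolerance for every shipped window, which is why windows start well
after onsets.

What a green harness establishes: the solver reproduces linear membrane
physics, junction coupling and synaptic kinetics to 1% under the
declared sweep. What it does not establish: accuracy of spiking
dynamics (covered separately by the forward-Euler reference comparison
at dt = 0.0005 ms), behaviour on real reconstructed morphologies, or
robustness to stiff channel sets beyond the classic squid trio.

## 8. Other design decisions

* dt defaults to 0.025 ms (the conventional compartmental-modelling
  step; no integration step is stated upstream), duration to 200 ms.
* Axial resistivity defaults to 100 Ω·cm and specific capacitance to
  1 μF/cm² — standard textbook values; both are explicit `add_cell()`
  arguments because the worked example sets capacitance explicitly.
* Voltage clamp is a series conductance (default R_series = 1 MΩ)
  toward the command potential: simple, stable, and its residual error
  (≈ g_leak·R_series relative) is visible and testable rather than
  hidden.
* The five-parameter rate form is adopted because the upstream material
  presupposes α/β rate plots but never prints its rate grammar; the
  classic HH library parameterisation is the de-facto standard.
* `run()` is deterministic given the graph, dt and seed; the seed is
  stored for provenance (the shipped mechanisms draw no random numbers).
* Simulation objects are environments (reference semantics for the
  builder API); distinct simulations share no mutable state — asserted
  by test.

## 9. Known limitations

* Pure-R inner loop: comfortable for the intended few-cell networks at
  dt = 0.025 ms (thousands of steps per second per small cell), not for
  large trees at fine dt.
* Gap-junction fixed-point iteration is accurate for small junctional
  conductances; very strong coupling (g approaching the membrane
  conductance scale times the iteration count) would need a global
  cross-cell solve.
* Crank–Nicolson + voltage-clamp onsets can ring for one sample
  (trapezoidal overshoot); use the default backward Euler for clamp
  protocols.
* The SWC writer cannot represent region changes between siblings at a
  junction, nor multiple children of the root sample (Section 6).
* No NEURON/NeuroML/MODL interchange, populations, calcium dynamics,
  Q10 scaling, Markov channels, variable timesteps or extracellular
  potentials.
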