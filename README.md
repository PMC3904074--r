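# cablenet

Simulation of small networks of multicompartmental conductance-based
neurons, in a single self-contained R package.

## Who this is for

Computational neuroscientists and electrophysiologists who want to build
and verify small biophysical network models — a handful of
morphologically detailed neurons with Hodgkin–Huxley-style channels,
chemical synapses and gap junctions — without an external simulator
toolchain. An entire *in silico* experiment (morphology, channel
distributions, stimuli, recording, plotting, summary documents,
verification against hand calculations) is one short R script.

## The model

Each cell is a tree of unbranched **Sections** (conical frusta carrying
**Region** labels), subdivided into **segments** for spatial accuracy.
Every segment obeys the membrane equation

    C_m dV/dt = - Σ_i g_i (V - E_i) - I_axial + I_inj + I_syn + I_gap

where the sum runs over membrane mechanisms:

* **leak**: constant specific conductance `gbar` with reversal `erev`;
* **α/β-gated channels**: conductance `gbar · Π_k x_k^{p_k}` where each
  gating particle relaxes as `dx/dt = α(V)(1-x) - β(V)x` with the classic
  five-parameter rate form `rate(V) = (A + B·V)/(C + exp((V+D)/E))`
  (removable singularities are evaluated by their analytic limit);
  the classic squid Na (m³h, 120 mS/cm², +50 mV) and K (n⁴, 36 mS/cm²,
  −77 mV) channels ship as library fixtures;
* **double-exponential synapses**: peak-normalised
  `g(t) = gbar·N·(e^{-t/τ_d} - e^{-t/τ_r})`, triggered by explicit spike
  times or presynaptic threshold crossings, delivered after a delay;
* **gap junctions**: ohmic coupling `g_gj (V_other - V_self)`.

Numerics: implicit integration (backward Euler by default,
Crank–Nicolson via `run(sim, method = "cn")`) of the branched cable
equation on a Hines-ordered tree (O(N) per step), Rush–Larsen exponential
updates for gating variables, analytic integration of synaptic states,
and a fixed-point inner iteration for gap-junction coupling. All
parameters are units-aware `quantity` objects (`"0.3 mS/cm2"`,
`"300 MOhm"`, `"1200 um2"`, ...), canonicalised to SI internally.

Recorded traces carry **tags** and are selected with a small query
language — `ALL{...}`, `ANY{...}`, `AND`, `OR`, `NOT` — e.g.
`ALL{CONDUCTANCE,SYNAPTIC,PRE:cell1,POST:cell2} AND ANY{NMDA,AMPA}`.

## Worked example: current injection into a passive cell

A single 1000 μm² compartment (specific capacitance 1 μF/cm², leak
0.3 mS/cm² at −51 mV — total conductance G = 3 nS, τ = C/G = 10/3 ms)
receives a 100 pA step between 50 and 150 ms:

```r
library(cablenet)

sim <- simulation("passive_cell", duration = "200 ms", dt = "0.025 ms")
cell1 <- add_cell(sim, "cell1", build_soma_from_area("1000 um2"),
                  capacitance = "1.0 uF/cm2")
apply_channel(cell1, leak_channel("lk", "0.3 mS/cm2", "-51 mV"))
stim <- create_currentclamp(sim, loc(cell1, "soma"), amplitude = "100 pA",
                            delay = "50 ms", duration = "100 ms")
record(sim, "Voltage", loc(cell1, "soma"))
record(sim, "CurrentDensity", loc(cell1, "soma"), channel = "lk")
record(sim, "Current", stimulus = stim)

results <- run(sim)
print(results)
```

```
<simulation_results: 3 recordings, 8000 steps @ 0.025 ms (be)>
<trace 'rec01_Voltage': 8001 samples [0, 200] ms, unit mV, tags {Voltage,cell1,loc:soma}>
<trace 'rec02_CurrentDensity': 8001 samples [0, 200] ms, unit mA/cm2, tags {CurrentDensity,cell1,loc:soma,lk}>
<trace 'rec03_Current': 8001 samples [0, 200] ms, unit pA, tags {Current,cclamp1,cell1,loc:soma}>
```

The settled plateau matches the closed form E + I/G = −51 + 100/3 mV:

```r
v <- filter_traces(results, "ALL{Voltage}")[[1]]
window_stat(v, 140, 150, "mean")
#> -17.6667 mV
```

Units are converted transparently; the indirect density specification
"a 1200 μm² neuron with 300 MΩ input resistance" becomes

```r
area_specific_conductance("300 MOhm", "1200 um2")
#> 0.277778 mS/cm2
qty_in(qty(0.3, "mS/cm2") * surface_area(cell1$morphology), "nS")
#> 3 nS
```

Plotting and summaries:

```r
tagviewer_render(results, out_path = "passive.svg")     # 3 stacked axes
summarize_simulation(sim, results, "passive.html")      # model tables + figures
```

Channel distributions use (Channel, Applicator, Targeter) triplets with
priority resolution — e.g. potassium at default density everywhere but
twice that in the dendrites:

```r
apply_channel(cell, hh_k_channel())                     # everywhere, priority 1
apply_channel(cell, hh_k_channel(),
              applicator(multipliers = list(gbar = 2)),
              target_region("dendrites"))               # region, priority 2
```

## Verification scenarios

Human/machine-readable scenario files pair a parameterised model
description with a table of hand-calculated expected values
(`$V[95:100].mean` = mean voltage over the half-open window 95–100 ms):

```r
generate_fixture_scenarios("scenarios", seed = 1)   # 6 analytic fixtures
reps <- run_scenario_dir("scenarios")               # all pass at 1% tolerance
attr(reps, "pass")
#> TRUE
```

A command-line front end lives at `inst/cli/cablenet.R`
(`run`, `query`, `plot`, `summarize`, `run-scenarios` subcommands;
nonzero exit on any failing scenario cell, CI-friendly).

## Limitations

See the methods vignette (`vignettes/cablenet-methods.Rmd`) for the
numerical choices, the verification strategy, and what the shipped tests
do and do not establish. Notable non-goals: NEURON/NeuroML/MODL import,
variable-timestep integration, path-distance-dependent channel
densities, calcium dynamics, temperature scaling, extracellular
potentials.
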