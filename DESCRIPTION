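Package: cablenet
Title: Simulation of Small Networks of Multicompartmental Conductance-Based Neurons
Version: 0.1.0
Authors@R: person("Cablenet", "Developers", role = c("aut", "cre"),
    email = "cablenet@example.org")
Description: A self-contained simulator for small networks of
    multicompartmental conductance-based model neurons. Provides a
    declarative object model for morphologies (trees of conical frusta
    with region labels, SWC import/export), Hodgkin-Huxley style membrane
    channels defined by alpha/beta rate equations, priority-based channel
    distribution rules, current/voltage-clamp stimuli, double-exponential
    chemical synapses and gap junctions; an implicit branched-cable
    numerical backend (Hines-ordered backward-Euler or Crank-Nicolson
    solves with Rush-Larsen gating updates); units-aware physical
    quantities; tag-based selection and plotting of recorded traces;
    automatic HTML/Markdown model summaries; and a text-file scenario
    harness that verifies simulator output against hand-calculated
    expectation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
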