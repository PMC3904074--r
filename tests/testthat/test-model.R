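test_that("current-clamp protocols evaluate their closed forms", {
  sim <- simulation("s", "200 ms")
  add_cell(sim, "c", build_soma_from_area("1000 um2"))
  st <- create_currentclamp(sim, loc("c", "soma"), amplitude = "100 pA",
                            delay = "50 ms", duration = "100 ms")
  expect_identical(st$protocol, "step")       # step is the default protocol
  expect_equal(stimulus_current(st, 75), 100)
  expect_equal(stimulus_current(st, c(0, 49.99, 150.1)), c(0, 0, 0))
  ramp <- create_currentclamp(sim, loc("c", "soma"), protocol = "ramp",
                              amplitude0 = "0 pA", amplitude1 = "100 pA",
                              delay = "0 ms", duration = "100 ms")
  expect_equal(stimulus_current(ramp, 50), 50)
  sine <- create_currentclamp(sim, loc("c", "soma"), protocol = "sine",
                              amplitude = "50 pA", freq = "10 Hz", delay = "0 ms")
  expect_equal(stimulus_current(sine, 25), 50, tolerance = 1e-9)  # sin(pi/2)
  expect_equal(stimulus_current(sine, 50), 0, tolerance = 1e-9)   # sin(pi)
})

test_that("missing protocol parameters raise a spec error naming them", {
  sim <- simulation("s")
  add_cell(sim, "c", build_soma_from_area("1000 um2"))
  expect_error(create_currentclamp(sim, loc("c", "soma")),
               "amplitude", class = "cablenet_spec_error")
  expect_error(create_currentclamp(sim, loc("c", "soma"), protocol = "sine",
                                   amplitude = "1 pA"),
               "freq", class = "cablenet_spec_error")
  expect_error(create_currentclamp(sim, loc("c", "soma"), protocol = "ramp",
                                   amplitude0 = "1 pA"),
               "amplitude1", class = "cablenet_spec_error")
})

test_that("component libraries register, forward kwargs and reject dupes", {
  lib <- component_library()
  library_register(lib, "toy", "chl",
                   function(gbar = "1 mS/cm2") leak_channel("lk", gbar, "-60 mV"),
                   kind = "channel")
  default <- library_instantiate(lib, "toy", "chl", kind = "channel")
  expect_qty_equal(get_defaults(default)$gbar, 1, "mS/cm2")
  varied <- library_instantiate(lib, "toy", "chl", kind = "channel",
                                gbar = "2 mS/cm2")
  expect_qty_equal(get_defaults(varied)$gbar, 2, "mS/cm2")
  expect_error(library_register(lib, "toy", "chl", function() NULL,
                                kind = "channel"),
               class = "cablenet_domain_error")
  expect_error(library_instantiate(lib, "nope", "chl", kind = "channel"),
               "toy", class = "cablenet_lookup_error")
  tbl <- library_summary_table(lib)
  expect_identical(nrow(tbl), 1L)
})

test_that("the default library models TTX via include_sodium = FALSE", {
  lib <- default_component_library()
  sim <- simulation("ttx")
  cell <- library_instantiate(lib, "squid_classic", "hh_soma", kind = "cell",
                              sim = sim, name = "c1", include_sodium = FALSE)
  chl_names <- vapply(cell$applications, function(a) a$channel$name, "")
  expect_false("hh_na" %in% chl_names)
  expect_true(all(c("hh_k", "hh_leak") %in% chl_names))
  cell2 <- library_instantiate(lib, "squid_classic", "hh_soma", kind = "cell",
                               sim = sim, name = "c2")
  expect_true("hh_na" %in% vapply(cell2$applications, function(a) a$channel$name, ""))
})

test_that("recordings carry automatic and user tags", {
  sim <- passive_sim()
  c1 <- sim$cells$cell1
  record(sim, "CurrentDensity", loc(c1, "soma"), channel = "lk",
         user_tags = "NMDA")
  res <- run(sim)
  expect_length(res$traces, 2L)
  vt <- res$traces[[1]]
  expect_true(all(c("Voltage", "cell1", "loc:soma") %in% vt$tags))
  cdt <- res$traces[[2]]
  expect_true(all(c("CurrentDensity", "cell1", "lk", "NMDA") %in% cdt$tags))
})

test_that("dangling recording targets are rejected", {
  sim <- passive_sim()
  expect_error(record(sim, "CurrentDensity", loc("cell1", "soma"),
                      channel = "hh_na"),
               class = "cablenet_reference_error")
  expect_error(record(sim, "Voltage", loc("ghost", "soma")),
               class = "cablenet_reference_error")
  expect_error(record(sim, "Current", stimulus = "nope"),
               class = "cablenet_reference_error")
})

test_that("run validates the graph, returns one output per request", {
  empty <- simulation("empty")
  expect_error(run(empty), class = "cablenet_validation_error")
  # worked single-compartment example: voltage + leak current density +
  # injected current -> exactly 3 traces in recording order
  sim <- simulation("listing1", "200 ms")
  c1 <- add_cell(sim, "cell1", build_soma_from_area("1000 um2"),
                 capacitance = "1.0 uF/cm2")
  apply_channel(c1, leak_channel("lk", "0.3 mS/cm2", "-51 mV"))
  st <- create_currentclamp(sim, loc(c1, "soma"), amplitude = "100 pA",
                            delay = "50 ms", duration = "100 ms")
  record(sim, "Voltage", loc(c1, "soma"))
  record(sim, "CurrentDensity", loc(c1, "soma"), channel = "lk")
  record(sim, "Current", stimulus = st)
  res <- run(sim)
  expect_length(res$traces, 3L)
  expect_identical(vapply(res$traces, function(t) t$tags[1], ""),
                   c("Voltage", "CurrentDensity", "Current"))
  expect_identical(res$metadata$steps, 8000L)
})

test_that("runs are deterministic and simulations are independent", {
  s1 <- passive_sim()
  r1 <- run(s1)
  r2 <- run(s1)
  expect_identical(r1$traces[[1]]$values, r2$traces[[1]]$values)
  # a second simulation sharing nothing: mutating it leaves s1 untouched
  s2 <- passive_sim(amp = "200 pA")
  expect_length(s1$stimuli, 1L)
  expect_equal(s1$stimuli[[1]]$params$amp, 100)
  expect_equal(s2$stimuli[[1]]$params$amp, 200)
  r1b <- run(s1)
  expect_identical(r1b$traces[[1]]$values, r1$traces[[1]]$values)
})

test_that("the graph is inert until run", {
  sim <- simulation("inert", "1000000 ms", "0.001 ms")  # absurdly large
  add_cell(sim, "c", build_soma_from_area("1000 um2"))
  st <- create_currentclamp(sim, loc("c", "soma"), amplitude = "1 pA")
  record(sim, "Voltage", loc("c", "soma"))
  expect_s3_class(st, "stimulus")   # construction did no integration
})

test_that("simulations serialise to JSON and rebuild identically", {
  sim <- simulation("roundtrip", "40 ms")
  c1 <- add_cell(sim, "cell1", build_soma_from_area("1000 um2"))
  apply_channel(c1, leak_channel("lk", "0.3 mS/cm2", "-60 mV"))
  apply_channel(c1, hh_k_channel(),
                applicator(multipliers = list(gbar = 0.5)),
                target_region("soma"))
  c2 <- add_cell(sim, "cell2", build_soma_from_area("800 um2"))
  apply_channel(c2, leak_channel("lk", "0.3 mS/cm2", "-60 mV"))
  create_currentclamp(sim, loc(c1, "soma"), amplitude = "50 pA",
                      delay = "5 ms", duration = "20 ms")
  add_gap_junction(sim, "1 nS", loc(c1, "soma"), loc(c2, "soma"))
  add_synapse(sim, psr_template("0.5 ms", "5 ms", "1 nS", "0 mV", name = "ampa"),
              loc(c2, "soma"), trigger_times(c(10, 20)))
  record(sim, "Voltage", loc(c1, "soma"))
  record(sim, "Voltage", loc(c2, "soma"), user_tags = "POSTCELL")
  txt <- sim_to_json(sim)
  sim2 <- sim_from_json(txt)
  r1 <- run(sim)
  r2 <- run(sim2)
  for (i in seq_along(r1$traces)) {
    expect_identical(r1$traces[[i]]$values, r2$traces[[i]]$values)
    expect_setequal(r1$traces[[i]]$tags, r2$traces[[i]]$tags)
  }
})
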