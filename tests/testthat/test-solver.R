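test_that("discretisation conserves area and builds valid Hines trees", {
  sim <- simulation("d")
  c1 <- add_cell(sim, "c", build_soma_from_area("1000 um2"))
  d1 <- discretize(c1, 1L)
  expect_identical(d1$n, 1L)
  expect_equal(d1$area_cm2, 1000 * 1e-8, tolerance = 1e-12)
  # uniform cylinder, nseg 2: equal areas, one axial link
  m <- morphology(list(section("cyl", c(0, 0, 0), c(100, 0, 0), 2, 2, NA, "soma")))
  c2 <- add_cell(sim, "cyl", m)
  d2 <- discretize(c2, 2L)
  expect_identical(d2$n, 2L)
  expect_equal(d2$area_cm2[1], d2$area_cm2[2])
  expect_identical(d2$parent, c(0L, 1L))
  expect_gt(d2$g_ax_uS[2], 0)
  # axial conductance: pi r^2 / (Ra l), l = 50 um between centres
  g_expect <- pi * (2e-4)^2 / (100 * 50e-4) * 1e6
  expect_equal(d2$g_ax_uS[2], g_expect, tolerance = 1e-9)
})

test_that("total segment area equals morphology surface area on random trees", {
  set.seed(21)
  for (i in 1:10) {
    secs <- list(section("s1", c(0, 0, 0), c(20, 0, 0), 5, 4, NA, "soma"))
    for (j in 2:8) {
      parent <- secs[[sample(length(secs), 1)]]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      L <- runif(1, 5, 60)
      secs[[j]] <- section(paste0("s", j), parent$distal,
                           parent$distal + dir * L,
                           runif(1, 0.5, 3), runif(1, 0.5, 3),
                           parent$id, sample(c("dendrite", "axon"), 1))
    }
    m <- morphology(secs)
    sim <- simulation("t")
    cl <- add_cell(sim, "c", m)
    nseg <- setNames(sample(1:5, length(secs), replace = TRUE),
                     vapply(secs, `[[`, "", "id"))
    d <- discretize(cl, nseg)
    expect_equal(sum(d$area_cm2) * 1e8, qty_in(surface_area(m), "um2"),
                 tolerance = 1e-9)
    expect_true(all(d$parent < seq_len(d$n)))   # Hines order
  }
})

test_that("passive step response matches the analytic RC charging curve", {
  sim <- passive_sim("50 ms")
  tr <- run(sim)$traces[[1]]
  expect_equal(tr$values[1], -51)   # starts at the leak reversal
  err_be <- max(abs(tr$values - rc_step_v(tr$times)))
  expect_lt(err_be, 0.05)           # backward Euler, first order
  tr2 <- run(sim, method = "cn")$traces[[1]]
  err_cn <- max(abs(tr2$values - rc_step_v(tr2$times)))
  expect_lt(err_cn, 1e-3)           # Crank-Nicolson, second order
  # at t = tau the deflection is (1 - 1/e) * 100/3 mV = 21.07 mV;
  # interpolate the trace to the exact tau
  v_tau <- stats::approx(tr2$times, tr2$values, xout = 10 / 3)$y
  expect_equal(v_tau + 51, (1 - exp(-1)) * 100 / 3, tolerance = 1e-4)
})

test_that("a cell at its reversal potential stays there without stimulus", {
  sim <- simulation("eq", "50 ms")
  c1 <- add_cell(sim, "c", build_soma_from_area("1000 um2"))
  apply_channel(c1, leak_channel("lk", "0.3 mS/cm2", "-51 mV"))
  record(sim, "Voltage", loc(c1, "soma"))
  tr <- run(sim)$traces[[1]]
  expect_equal(max(abs(tr$values + 51)), 0, tolerance = 1e-12)
})

test_that("membrane charge decays monotonically to the leak equilibrium", {
  m <- morphology(list(section("cab", c(0, 0, 0), c(200, 0, 0), 2, 2, NA, "soma")))
  sim <- simulation("decay", "40 ms")
  c1 <- add_cell(sim, "c", m, initial_voltage = "-20 mV")
  apply_channel(c1, leak_channel("lk", "0.3 mS/cm2", "-60 mV"))
  record(sim, "Voltage", loc(c1, "cab", 0.25))
  record(sim, "Voltage", loc(c1, "cab", 0.75))
  res <- run(sim, nseg = list(c = 2L))
  total <- res$traces[[1]]$values + res$traces[[2]]$values  # equal areas
  excess <- total - 2 * (-60)
  expect_true(all(diff(excess) <= 1e-12))
  expect_equal(excess[length(excess)], 0, tolerance = 1e-3)
})

test_that("gap-junction coupling coefficient equals g/(G+g)", {
  sim <- simulation("gj", "200 ms")
  for (nm in c("cell1", "cell2")) {
    cc <- add_cell(sim, nm, build_soma_from_area("1000 um2"))
    apply_channel(cc, leak_channel("lk", "0.3 mS/cm2", "-60 mV"))
  }
  add_gap_junction(sim, "1 nS", loc("cell1", "soma"), loc("cell2", "soma"))
  create_currentclamp(sim, loc("cell1", "soma"), amplitude = "100 pA",
                      delay = "10 ms", duration = "300 ms")
  record(sim, "Voltage", loc("cell1", "soma"))
  record(sim, "Voltage", loc("cell2", "soma"))
  res <- run(sim)
  u1 <- qty_in(window_stat(res$traces[[1]], 190, 200), "mV") + 60
  u2 <- qty_in(window_stat(res$traces[[2]], 190, 200), "mV") + 60
  expect_equal(u2 / u1, 0.25, tolerance = 5e-3)
  expect_lte(res$metadata$gj_max_iterations, 5L)
})

test_that("voltage clamp holds the commanded potential", {
  sim <- simulation("vc", "50 ms")
  c1 <- add_cell(sim, "c", build_soma_from_area("1000 um2"))
  apply_channel(c1, leak_channel("lk", "0.3 mS/cm2", "-51 mV"))
  vc <- create_voltageclamp(sim, loc(c1, "soma"), "-20 mV", delay = "10 ms")
  record(sim, "Voltage", loc(c1, "soma"))
  record(sim, "Current", stimulus = vc)
  res <- run(sim)
  v <- window_stat(res$traces[[1]], 40, 50)
  expect_equal(qty_in(v, "mV"), -20, tolerance = 0.05)   # 1 MOhm series drop
  # clamp current balances the leak: g_lk (V - E) = 3 nS * 31 mV = 93 pA
  ic <- qty_in(window_stat(res$traces[[2]], 40, 50), "pA")
  expect_equal(ic, 3 * (-20 + 51), tolerance = 0.5)
})

test_that("clamped PSR current equals conductance times driving force", {
  sim <- simulation("psr", "60 ms")
  c1 <- add_cell(sim, "c", build_soma_from_area("1000 um2"))
  apply_channel(c1, leak_channel("lk", "0.3 mS/cm2", "-60 mV"))
  create_voltageclamp(sim, loc(c1, "soma"), "-60 mV")
  tpl <- psr_template("0.5 ms", "5 ms", "2 nS", "0 mV", name = "ampa")
  sy <- add_synapse(sim, tpl, loc(c1, "soma"), trigger_times(20))
  record(sim, "Conductance", synapse = sy)
  record(sim, "Current", synapse = sy)
  record(sim, "Voltage", loc(c1, "soma"))
  res <- run(sim)
  g <- res$traces[[1]]; isyn <- res$traces[[2]]; v <- res$traces[[3]]
  sel <- g$times > 20 & g$times < 50
  g_ref <- psr_conductance(tpl, g$times[sel] - 20)
  expect_lt(max(abs(g$values[sel] - g_ref)) / max(g_ref), 5e-3)
  i_ref <- g$values[sel] * (v$values[sel] - 0)
  expect_lt(max(abs(isyn$values[sel] - i_ref)) / max(abs(i_ref)), 5e-3)
  # tags let the paper's synaptic queries find these traces
  expect_true(all(c("SYNAPTIC", "POST:c", "ampa") %in% g$tags))
})

test_that("threshold crossing detection applies strict hysteresis", {
  t <- seq(0, 10, by = 0.1)
  expect_length(threshold_crossings(t - 5, t, 0), 1L)          # one ramp crossing
  s <- sin(2 * pi * t / 2)                                     # 5 full cycles
  expect_length(threshold_crossings(s, t, 0.5), 5L)
  vstart <- c(5, 4, 6, 3, 7)                                   # starts above
  expect_equal(threshold_crossings(vstart, 1:5, 4.5), c(3, 5))
  expect_length(threshold_crossings(rep(-60, 50), seq_len(50), 0), 0L)
})

test_that("presynaptically triggered EPSPs arrive after the configured delay", {
  sim <- simulation("pair", "60 ms")
  pre <- add_cell(sim, "cell1", build_soma_from_area("1000 um2"),
                  initial_voltage = "-65 mV")
  apply_channel(pre, hh_na_channel()); apply_channel(pre, hh_k_channel())
  apply_channel(pre, hh_leak_channel())
  post <- add_cell(sim, "cell2", build_soma_from_area("1000 um2"))
  apply_channel(post, leak_channel("lk", "0.3 mS/cm2", "-60 mV"))
  create_currentclamp(sim, loc(pre, "soma"), amplitude = "300 pA",
                      delay = "10 ms", duration = "4 ms")
  tpl <- psr_template("0.5 ms", "5 ms", "2 nS", "0 mV", name = "ampa")
  sy <- add_synapse(sim, tpl, loc(post, "soma"),
                    trigger_presyn(loc(pre, "soma"), "0 mV"), delay = "3 ms")
  record(sim, "Events", loc(pre, "soma"))
  record(sim, "Conductance", synapse = sy)
  record(sim, "Voltage", loc(post, "soma"))
  res <- run(sim)
  ev <- res$traces[[1]]
  expect_length(ev$times, 1L)                      # exactly one presynaptic spike
  g <- res$traces[[2]]
  onset <- g$times[min(which(g$values > 1e-9))]
  expect_gte(onset - ev$times[1], 3)               # not before the delay
  expect_lt(onset - ev$times[1], 3 + 3 * 0.025)    # folded to a step boundary
  expect_true("PRE:cell1" %in% g$tags)
  # the EPSP actually depolarises the postsynaptic cell
  vpost <- res$traces[[3]]
  expect_gt(max(vpost$values), -59)
})

test_that("events after the simulation end are dropped and counted", {
  sim <- simulation("drop", "30 ms")
  c1 <- add_cell(sim, "c", build_soma_from_area("1000 um2"))
  apply_channel(c1, leak_channel("lk", "0.3 mS/cm2", "-60 mV"))
  tpl <- psr_template("0.5 ms", "5 ms", "2 nS", "0 mV")
  add_synapse(sim, tpl, loc(c1, "soma"), trigger_times(c(10, 29)),
              delay = "5 ms")
  record(sim, "Voltage", loc(c1, "soma"))
  res <- run(sim)   # the 29 + 5 ms event can never be delivered
  expect_length(res$traces, 1L)
})
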