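# Shared fixtures and independent oracles, all built in code.

# closed-form RC step response: V(t) = E + (I/G)(1 - exp(-t/tau)), t from onset
rc_step_v <- function(t_ms, E_mV = -51, I_pA = 100, G_nS = 3, C_pF = 10) {
  tau <- C_pF / G_nS                       # ms
  E_mV + (I_pA / G_nS) * (1 - exp(-pmax(t_ms, 0) / tau))
}

# the worked passive cell: 1000 um2, 1 uF/cm2, 0.3 mS/cm2 leak at -51 mV
# (G = 3 nS, C = 10 pF, tau = 10/3 ms)
passive_sim <- function(duration = "100 ms", dt = "0.025 ms",
                        amp = "100 pA", delay = "0 ms",
                        stim_duration = "1000 ms") {
  sim <- simulation("passive", duration, dt)
  c1 <- add_cell(sim, "cell1", build_soma_from_area("1000 um2"),
                 capacitance = "1.0 uF/cm2")
  apply_channel(c1, leak_channel("lk", "0.3 mS/cm2", "-51 mV"))
  create_currentclamp(sim, loc(c1, "soma"), amplitude = amp,
                      delay = delay, duration = stim_duration)
  record(sim, "Voltage", loc(c1, "soma"))
  sim
}

# classic squid soma (1000 um2), explicit initial voltage for oracle parity
hh_soma_sim <- function(amp, duration = "120 ms", dt = "0.025 ms",
                        delay = "10 ms", stim_dur = "100 ms") {
  sim <- simulation("hh", duration, dt)
  cc <- add_cell(sim, "c", build_soma_from_area("1000 um2"),
                 initial_voltage = "-65 mV")
  apply_channel(cc, hh_na_channel())
  apply_channel(cc, hh_k_channel())
  apply_channel(cc, hh_leak_channel())
  create_currentclamp(sim, loc(cc, "soma"), amplitude = amp,
                      delay = delay, duration = stim_dur)
  record(sim, "Voltage", loc(cc, "soma"))
  sim
}

# independent forward-Euler reference of the classic squid soma, written
# from the textbook rate formulas (no package code in the dynamics)
fe_hh_spike_count <- function(amp_pA, dt = 0.0005, dur = 120,
                              don = 10, doff = 110, area_um2 = 1000) {
  am <- function(v) if (abs(v + 40) < 1e-9) 1 else 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  bm <- function(v) 4 * exp(-(v + 65) / 18)
  ah <- function(v) 0.07 * exp(-(v + 65) / 20)
  bh <- function(v) 1 / (1 + exp(-(v + 35) / 10))
  an <- function(v) if (abs(v + 55) < 1e-9) 0.1 else 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
  bn <- function(v) 0.125 * exp(-(v + 65) / 80)
  area <- area_um2 * 1e-8                      # cm2
  C <- 1 * area * 1e3                          # nF
  gna <- 120 * area * 1e3; gk <- 36 * area * 1e3; gl <- 0.3 * area * 1e3  # uS
  I <- amp_pA / 1e3                            # nA
  v <- -65
  m <- am(v) / (am(v) + bm(v)); h <- ah(v) / (ah(v) + bh(v))
  n <- an(v) / (an(v) + bn(v))
  K <- round(dur / dt); spikes <- 0L; below <- v < 0; t <- 0
  for (k in seq_len(K)) {
    iion <- gna * m^3 * h * (v - 50) + gk * n^4 * (v + 77) + gl * (v + 54.3)
    ii <- if (t >= don && t < doff) I else 0
    m <- m + dt * (am(v) * (1 - m) - bm(v) * m)
    h <- h + dt * (ah(v) * (1 - h) - bh(v) * h)
    n <- n + dt * (an(v) * (1 - n) - bn(v) * n)
    v <- v + dt * (-iion + ii) / C
    t <- t + dt
    if (below && v >= 0) { spikes <- spikes + 1L; below <- FALSE }
    else if (v < 0) below <- TRUE
  }
  spikes
}

# random tag-query text of bounded depth, over a small tag pool
gen_query_text <- function(depth, tagpool) {
  if (depth == 0L || runif(1) < 0.4) {
    kw <- sample(c("ALL", "ANY"), 1)
    tags <- sample(tagpool, sample(1:3, 1))
    sprintf("%s{%s}", kw, paste(tags, collapse = ","))
  } else {
    op <- sample(c("AND", "OR", "NOT"), 1)
    if (op == "NOT") sprintf("NOT (%s)", gen_query_text(depth - 1L, tagpool))
    else sprintf("(%s) %s (%s)", gen_query_text(depth - 1L, tagpool), op,
                 gen_query_text(depth - 1L, tagpool))
  }
}

# naive independent evaluator of a parsed query tree: explicit loops and
# linear membership scans, no shared logic with query_match()
brute_query_eval <- function(node, tags) {
  lc <- vapply(tags, tolower, "")
  has <- function(tag) {
    t <- tolower(tag)
    found <- FALSE
    for (x in lc) if (identical(x, t)) found <- TRUE
    found
  }
  rec <- function(nd) {
    if (nd$op == "all") {
      ok <- TRUE
      for (tg in nd$tags) if (!has(tg)) ok <- FALSE
      return(ok)
    }
    if (nd$op == "any") {
      ok <- FALSE
      for (tg in nd$tags) if (has(tg)) ok <- TRUE
      return(ok)
    }
    if (nd$op == "not") return(!rec(nd$arg))
    if (nd$op == "and") return(rec(nd$lhs) & rec(nd$rhs))
    if (nd$op == "or") return(rec(nd$lhs) | rec(nd$rhs))
    stop("bad node")
  }
  rec(unclass(node))
}

expect_qty_equal <- function(q, value, unit, tol = 1e-9) {
  expect_equal(qty_in(q, unit), value, tolerance = tol)
}
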