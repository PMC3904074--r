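test_that("tag queries parse, print and reject malformed input", {
  q <- parse_query("ALL{Voltage}")
  expect_s3_class(q, "tag_query")
  expect_identical(unclass(q)$op, "all")
  q2 <- parse_query(
    "ALL{CONDUCTANCE,SYNAPTIC,PRE:cell1,POST:cell2} AND ANY{NMDA,AMPA}")
  expect_identical(unclass(q2)$op, "and")
  expect_identical(unclass(q2)$lhs$tags,
                   c("CONDUCTANCE", "SYNAPTIC", "PRE:cell1", "POST:cell2"))
  expect_error(parse_query("ALL{}"), class = "cablenet_query_error")
  expect_error(parse_query("ALL{A,B"), class = "cablenet_query_error")
  expect_error(parse_query("ALL{A} AND"), class = "cablenet_query_error")
  expect_error(parse_query("(ALL{A}"), class = "cablenet_query_error")
  expect_error(parse_query(""), class = "cablenet_query_error")
  expect_error(parse_query("ALL{A} ALL{B}"), class = "cablenet_query_error")
})

test_that("matching is case-insensitive set logic", {
  expect_true(query_match("ALL{Voltage}", c("voltage", "cell1")))
  expect_false(query_match("ALL{A,B} AND NOT ANY{C}", c("A", "B", "C")))
  expect_true(query_match("NOT ALL{X}", character()))
  expect_true(query_match("ANY{NMDA,AMPA}", c("ampa", "cond")))
  expect_false(query_match("ANY{NMDA,AMPA}", c("gaba")))
  # AND binds tighter than OR
  expect_true(query_match("ALL{a} OR ALL{b} AND ALL{c}", "a"))
  expect_false(query_match("(ALL{a} OR ALL{b}) AND ALL{c}", "a"))
  # NOT binds tightest
  expect_true(query_match("NOT ALL{x} AND ALL{a}", "a"))
})

test_that("query evaluation agrees with a naive tree walker", {
  set.seed(123)
  pool <- c("Voltage", "Current", "cell1", "cell2", "NMDA", "AMPA",
            "SYNAPTIC", "loc:soma")
  for (i in 1:500) {
    txt <- gen_query_text(sample(0:4, 1), pool)
    q <- parse_query(txt)
    tags <- sample(pool, sample(0:5, 1))
    expect_identical(query_match(q, tags), brute_query_eval(q, tags))
  }
})

test_that("De Morgan's laws hold on sampled tag sets", {
  set.seed(9)
  pool <- c("a", "b", "c", "d")
  for (i in 1:50) {
    tags <- sample(pool, sample(0:4, 1))
    expect_identical(
      query_match("NOT (ALL{a} AND ALL{b})", tags),
      query_match("(NOT ALL{a}) OR (NOT ALL{b})", tags))
    expect_identical(
      query_match("NOT (ALL{a} OR ALL{b})", tags),
      query_match("(NOT ALL{a}) AND (NOT ALL{b})", tags))
  }
})

test_that("printing a query and reparsing yields an equivalent tree", {
  set.seed(31)
  pool <- c("Voltage", "cell1", "NMDA", "x_1", "loc:soma")
  for (i in 1:100) {
    txt <- gen_query_text(sample(0:3, 1), pool)
    q1 <- parse_query(txt)
    q2 <- parse_query(format(q1))
    for (j in 1:20) {
      tags <- sample(pool, sample(0:4, 1))
      expect_identical(query_match(q1, tags), query_match(q2, tags))
    }
  }
})

test_that("filter_traces selects in recording order", {
  trs <- list(
    trace(0:2, c(1, 2, 3), "mV", c("Voltage", "cell1"), "v1"),
    trace(0:2, c(1, 2, 3), "pA", c("Current", "cell1"), "i1"),
    trace(0:2, c(1, 2, 3), "mV", c("Voltage", "cell47"), "v47"))
  hit <- filter_traces(trs, "ALL{Voltage}")
  expect_identical(vapply(hit, `[[`, "", "name"), c("v1", "v47"))
  hit2 <- filter_traces(trs, "ALL{Voltage,cell47}")
  expect_identical(vapply(hit2, `[[`, "", "name"), "v47")
  expect_length(filter_traces(trs, "ALL{nonexistent}"), 0L)
})

test_that("spike counting uses strict upward crossings", {
  t <- seq(0, 60, by = 0.05)
  flat <- trace(t, rep(-60, length(t)), "mV")
  expect_identical(spike_count(flat, 0), 0L)
  sine <- trace(t, 30 * sin(2 * pi * t / 20), "mV")   # 3 cycles
  expect_identical(spike_count(sine, 10), 3L)
  # starting above threshold: first sample does not count
  above <- trace(0:6, c(10, 12, -5, 11, -5, 12, 13), "mV")
  expect_identical(spike_count(above, 0), 2L)
  expect_error(spike_count(trace(t, t, "pA")), class = "cablenet_dim_error")
})

test_that("spike times are linearly interpolated", {
  tr <- trace(c(0, 1, 2), c(-10, 10, -10), "mV")
  ev <- spike_times(tr, 0)
  expect_equal(ev$times, 0.5)
  expect_true("Event" %in% ev$tags)
})

test_that("window statistics respect half-open windows and units", {
  t <- seq(0, 100, by = 0.1)
  tr <- trace(t, rep(7, length(t)), "mV", name = "const")
  expect_qty_equal(window_stat(tr, 10, 20, "mean"), 7, "mV", 1e-12)
  ramp <- trace(0:10, 0:10, "pA")
  expect_qty_equal(window_stat(ramp, 0, 5, "max"), 4, "pA")   # sample at 5 excluded
  expect_qty_equal(window_stat(ramp, 0, 5.5, "max"), 5, "pA")
  expect_error(window_stat(tr, 20, 10), class = "cablenet_window_error")
  expect_error(window_stat(tr, 200, 300), class = "cablenet_window_error")
  # settled passive response: mean over [95, 100) within 0.1% of I/G + E
  sim <- passive_sim()
  res <- run(sim)
  m <- qty_in(window_stat(res$traces[[1]], 95, 100), "mV")
  expect_equal(m, -51 + 100 / 3, tolerance = 1e-3)
})

test_that("traces validate their construction invariants", {
  expect_error(trace(c(0, 1, 1), c(1, 2, 3), "mV"),
               class = "cablenet_domain_error")
  expect_error(trace(0:1, 1:3, "mV"), class = "cablenet_domain_error")
  expect_error(trace(0:1, 0:1, "parsecs"), class = "cablenet_parse_error")
})
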