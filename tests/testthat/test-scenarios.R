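scn_dir <- NULL
local_fixture_dir <- function(env = parent.frame()) {
  d <- withr::local_tempdir(.local_envir = env)
  generate_fixture_scenarios(d, seed = 1L)
  d
}

test_that("scenario files parse with all cross-checks", {
  d <- local_fixture_dir()
  s <- parse_scenario(file.path(d, "passive_step.scn"))
  expect_identical(s$name, "passive_step")
  expect_setequal(colnames(s$values), c("A", "VS", "C", "GLK", "EREV", "I"))
  expect_identical(nrow(s$values), nrow(s$expected))
  col <- s$expected_cols[[1]]
  expect_identical(col$sym, "V")
  expect_identical(col$stat, "mean")
  expect_equal(c(col$t0, col$t1), c(245, 250))
  expect_identical(s$tolerance, 0.01)
  expect_identical(s$records$V$modality, "Voltage")
})

test_that("malformed scenarios are rejected with informative errors", {
  d <- withr::local_tempdir()
  base <- c("SCENARIO bad", "DESCRIPTION",
            "  SIMULATION DURATION 100",
            "  CELL cell1 AREA <A>",
            "  CHANNEL leak lk ON cell1 GBAR 0.3 EREV -51",
            "UNITS", "  | A | um2 |", "  | V | mV |",
            "RECORD", "  | $V | Voltage | cell1 | soma |")
  w <- function(lines) {
    f <- file.path(d, "bad.scn"); writeLines(lines, f); f
  }
  # expected row count != parameter sets
  expect_error(parse_scenario(w(c(base,
    "VALUES", "  | A |", "  | 1000 |", "  | 900 |",
    "EXPECTED", "  | $V[90:100].mean |", "  | -51 |"))),
    "parameter sets", class = "cablenet_scenario_error")
  # malformed slice
  expect_error(parse_scenario(w(c(base,
    "VALUES", "  | A |", "  | 1000 |",
    "EXPECTED", "  | $V[100:90].mean |", "  | -51 |"))),
    "slice", class = "cablenet_scenario_error")
  # undeclared placeholder
  expect_error(parse_scenario(w(c(base,
    "VALUES", "  | B |", "  | 1 |",
    "EXPECTED", "  | $V[90:100].mean |", "  | -51 |"))),
    "<A>", class = "cablenet_scenario_error")
  # expected symbol not recorded
  expect_error(parse_scenario(w(c(base,
    "VALUES", "  | A |", "  | 1000 |",
    "EXPECTED", "  | $W[90:100].mean |", "  | -51 |"))),
    "undeclared record", class = "cablenet_scenario_error")
  # record symbol missing from UNITS
  expect_error(parse_scenario(w(c(
    "SCENARIO bad", "DESCRIPTION", "  SIMULATION DURATION 100",
    "  CELL cell1 AREA 1000",
    "  CHANNEL leak lk ON cell1 GBAR 0.3 EREV -51",
    "UNITS", "  | A | um2 |",
    "RECORD", "  | $V | Voltage | cell1 | soma |",
    "VALUES", "  | A |", "  | 1000 |",
    "EXPECTED", "  | $V[90:100].mean |", "  | -51 |"))),
    "UNITS", class = "cablenet_scenario_error")
})

test_that("the passive scenario reproduces equilibrium and step deflection", {
  d <- local_fixture_dir()
  rep <- run_scenario(file.path(d, "passive_step.scn"))
  expect_true(attr(rep, "pass"))
  # row 1 is the I = 0 equilibrium at EREV = -51
  expect_equal(rep$observed[rep$row == 1], -51, tolerance = 1e-6)
  # row 2: E + I/G = -51 + 100/3
  expect_equal(rep$observed[rep$row == 2], -51 + 100 / 3, tolerance = 1e-2)
})

test_that("all generated fixtures pass on the shipped solver", {
  d <- local_fixture_dir()
  reps <- run_scenario_dir(d)
  expect_length(reps, 6L)
  expect_true(attr(reps, "pass"))
  for (r in reps) expect_true(all(r$rel_error < 0.01, na.rm = TRUE))
})

test_that("fixture generation is deterministic in the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- generate_fixture_scenarios(d1, seed = 7L)
  f2 <- generate_fixture_scenarios(d2, seed = 7L)
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})

test_that("parse / format round trip preserves the scenario", {
  d <- local_fixture_dir()
  for (f in list.files(d, full.names = TRUE)) {
    s1 <- parse_scenario(f)
    f2 <- tempfile(fileext = ".scn")
    writeLines(format_scenario(s1), f2)
    s2 <- parse_scenario(f2)
    expect_identical(lapply(s1$directives, `[[`, "text"),
                     lapply(s2$directives, `[[`, "text"))
    expect_identical(s1$units, s2$units)
    expect_equal(s1$values, s2$values)
    expect_equal(s1$expected, s2$expected)
  }
})

test_that("corrupting an expected cell fails exactly that cell", {
  d <- local_fixture_dir()
  s <- parse_scenario(file.path(d, "passive_step.scn"))
  for (cell_i in c(1L, 2L)) {
    s_bad <- s
    tol_abs <- max(s$tolerance * abs(s$expected[cell_i, 1]), 0.01)
    s_bad$expected[cell_i, 1] <- s$expected[cell_i, 1] + 5 * tol_abs
    rep <- run_scenario(s_bad)
    expect_false(attr(rep, "pass"))
    expect_identical(which(!rep$pass), cell_i)
  }
})

test_that("a failing simulation is reported, and the run continues", {
  d <- withr::local_tempdir()
  f <- file.path(d, "broken.scn")
  writeLines(c(
    "SCENARIO broken", "DESCRIPTION",
    "  SIMULATION DURATION 100",
    "  CELL cell1 AREA <A>",
    "  CHANNEL leak lk ON cell1 GBAR 0.3 EREV -51",
    "UNITS", "  | A | um2 |", "  | V | mV |",
    "RECORD", "  | $V | Voltage | cell1 | soma |",
    "VALUES", "  | A |", "  | -1000 |", "  | 1000 |",
    "EXPECTED", "  | $V[90:100].mean |", "  | -51 |", "  | -51 |"), f)
  rep <- run_scenario(f)
  expect_false(attr(rep, "pass"))
  expect_false(rep$pass[1])
  expect_match(rep$note[1], "positive")
  expect_true(rep$pass[2])          # the valid row still ran
})

test_that("backend comparison bounds BE/CN discrepancies", {
  d <- local_fixture_dir()
  f <- file.path(d, "passive_step.scn")
  same <- compare_backends(f, list(list(method = "be", dt = 0.025),
                                   list(method = "be", dt = 0.025)))
  expect_equal(same$max_rel_discrepancy, 0)
  cross <- compare_backends(f, list(list(method = "be", dt = 0.025),
                                    list(method = "cn", dt = 0.025)))
  expect_lt(cross$max_rel_discrepancy, 5e-3)
  refine <- compare_backends(f, list(list(method = "cn", dt = 0.025),
                                     list(method = "cn", dt = 0.0125)))
  expect_lt(refine$max_rel_discrepancy, 1e-4)   # second-order convergence
  expect_error(compare_backends(f, list(list(method = "be"))),
               class = "cablenet_comparison_error")
})
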