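test_that("build_soma_from_area produces an equal-area L = d cylinder", {
  m <- build_soma_from_area("1000 um2")
  s <- m$sections[[1]]
  d_expect <- sqrt(1000 / pi)              # 17.8412 um
  expect_equal(2 * s$r_prox, d_expect, tolerance = 1e-9)
  expect_equal(sqrt(sum((s$distal - s$proximal)^2)), d_expect, tolerance = 1e-9)
  expect_qty_equal(surface_area(m), 1000, "um2", tol = 1e-9)
  m2 <- build_soma_from_area(qty(pi, "um2"))
  expect_equal(2 * m2$sections[[1]]$r_prox, 1, tolerance = 1e-9)
  expect_error(build_soma_from_area("10 mV"), class = "cablenet_dim_error")
  expect_error(build_soma_from_area("-1 um2"), class = "cablenet_domain_error")
})

test_that("surface_area sums frustum lateral areas and filters by region", {
  m <- morphology(list(
    section("a", c(0, 0, 0), c(10, 0, 0), 2, 4, NA, "soma"),
    section("b", c(10, 0, 0), c(10, 1, 0), 1, 1, "a", "dendrite")
  ), "frusta")
  expect_qty_equal(surface_area(m, "soma"), pi * 6 * sqrt(104), "um2", 1e-9) # 192.22
  expect_qty_equal(surface_area(m, "dendrite"), 2 * pi, "um2", 1e-9)
  expect_qty_equal(surface_area(m), pi * 6 * sqrt(104) + 2 * pi, "um2", 1e-9)
  expect_error(surface_area(m, "axon"), class = "cablenet_key_error")
})

test_that("area is invariant under section subdivision", {
  set.seed(3)
  for (i in 1:25) {
    r1 <- runif(1, 0.5, 5); r2 <- runif(1, 0.5, 5); L <- runif(1, 1, 50)
    f <- runif(1, 0.05, 0.95)
    whole <- pi * (r1 + r2) * sqrt(L^2 + (r2 - r1)^2)
    rm <- r1 + (r2 - r1) * f
    a1 <- pi * (r1 + rm) * sqrt((L * f)^2 + (rm - r1)^2)
    a2 <- pi * (rm + r2) * sqrt((L * (1 - f))^2 + (r2 - rm)^2)
    expect_equal(a1 + a2, whole, tolerance = 1e-9)
  }
})

test_that("morphology invariants are enforced", {
  expect_error(morphology(list(
    section("a", c(0, 0, 0), c(1, 0, 0), 1, 1, NA),
    section("a", c(1, 0, 0), c(2, 0, 0), 1, 1, "a")
  )), class = "cablenet_morph_error")                       # duplicate id
  expect_error(morphology(list(
    section("a", c(0, 0, 0), c(1, 0, 0), 1, 1, NA),
    section("b", c(0, 0, 0), c(1, 0, 0), 1, 1, NA)
  )), class = "cablenet_morph_error")                       # two roots
  expect_error(morphology(list(
    section("a", c(0, 0, 0), c(1, 0, 0), 1, 1, "ghost")
  )), class = "cablenet_morph_error")                       # dangling parent
  expect_error(morphology(list(
    section("a", c(0, 0, 0), c(1, 0, 0), 0, 1, NA)
  )), class = "cablenet_morph_error")                       # bad radius
})

test_that("SWC import splits chains and maps type codes to regions", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# toy cell",
               "1 1 0 0 0 5 -1",
               "2 3 10 0 0 2 1",
               "3 3 20 0 0 1 2"), f)
  m <- read_swc(f)
  expect_length(m$sections, 2L)
  expect_identical(unname(vapply(m$sections, `[[`, "", "region")),
                   c("soma", "dendrite"))
  expect_qty_equal(surface_area(m),
                   pi * 7 * sqrt(100 + 9) + pi * 3 * sqrt(100 + 1), "um2", 1e-9)
})

test_that("single-sample SWC becomes an equal-area cylinder L = d = 2r", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines("1 1 0 0 0 6 -1", f)
  m <- read_swc(f)
  expect_length(m$sections, 1L)
  s <- m$sections[[1]]
  expect_equal(sqrt(sum((s$distal - s$proximal)^2)), 12)
  expect_equal(s$r_prox, 6)
  expect_qty_equal(surface_area(m), 4 * pi * 36, "um2", 1e-9)  # sphere area
})

test_that("malformed SWC files are rejected with line numbers", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 2 99"), f)
  expect_error(read_swc(f), "line 2", class = "cablenet_swc_error")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 -2 1"), f)
  expect_error(read_swc(f), class = "cablenet_swc_error")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 2 -1"), f)
  expect_error(read_swc(f), "exactly one root", class = "cablenet_swc_error")
})

test_that("write_swc / read_swc round trip preserves the morphology", {
  f <- withr::local_tempfile(fileext = ".swc")
  # root sample with a single child; branch point downstream with
  # same-region siblings (the class of files the round trip guarantees)
  writeLines(c("1 1 0 0 0 5 -1",
               "2 3 10 0 0 2 1",
               "3 3 20 5 0 1 2",
               "4 3 20 -5 0 1 2"), f)
  m <- read_swc(f)
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f2)
  m2 <- read_swc(f2)
  expect_identical(length(m$sections), length(m2$sections))
  key <- function(mm) {
    secs <- mm$sections[order(names(mm$sections))]
    lapply(secs, function(s) list(round(s$proximal, 6), round(s$distal, 6),
                                  round(c(s$r_prox, s$r_dist), 6), s$region))
  }
  expect_identical(unname(key(m)), unname(key(m2)))
  # topology: same multiset of (parent-exists) relations
  depth <- function(mm) sort(vapply(mm$sections, function(s) {
    d <- 0L; cur <- s
    while (!is.na(cur$parent)) { d <- d + 1L; cur <- mm$sections[[cur$parent]] }
    d
  }, 0L))
  expect_identical(depth(m), depth(m2))
})

test_that("resolve_location maps fractions to half-open segment bins", {
  l <- function(f) morph_location("s", f)
  expect_identical(resolve_location(l(0.5), 1)$segment, 0L)
  expect_identical(resolve_location(l(0.5), 3)$segment, 1L)
  expect_identical(resolve_location(l(1.0), 3)$segment, 2L)
  expect_identical(resolve_location(l(0), 4)$segment, 0L)
  expect_identical(resolve_location(l(0.25), 4)$segment, 1L)  # boundary joins upper bin
  expect_error(morph_location("s", 1.2), class = "cablenet_domain_error")
})
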