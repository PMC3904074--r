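# two-region fixture: soma + two dendrite sections + one apical section
dist_morph <- function() {
  morphology(list(
    section("soma", c(0, 0, 0), c(18, 0, 0), 9, 9, NA, "soma"),
    section("d1", c(18, 0, 0), c(40, 0, 0), 2, 2, "soma", "dendrites"),
    section("d2", c(40, 0, 0), c(80, 0, 0), 1.5, 1, "d1", "dendrites"),
    section("ap", c(18, 0, 0), c(18, 50, 0), 2, 1, "soma", "apicaldendrite")
  ), "dist_fixture")
}

test_that("region multiplier doubles gbar only in the targeted region", {
  m <- dist_morph()
  k <- hh_k_channel()
  apps <- list(
    channel_application(k, apply_uniform(), target_everywhere()),
    channel_application(k, applicator(multipliers = list(gbar = 2)),
                        target_region("dendrites")))
  res <- resolve_distribution(apps, m)
  g0 <- qty_in(get_defaults(k)$gbar, "mS/cm2")
  expect_equal(qty_in(res$soma$hh_k$params$gbar, "mS/cm2"), g0)
  expect_equal(qty_in(res$d1$hh_k$params$gbar, "mS/cm2"), 2 * g0)
  expect_equal(qty_in(res$d2$hh_k$params$gbar, "mS/cm2"), 2 * g0)
  expect_equal(qty_in(res$ap$hh_k$params$gbar, "mS/cm2"), g0)
  # erev untouched by the multiplier
  expect_equal(qty_in(res$d1$hh_k$params$erev, "mV"), -77)
})

test_that("region override beats the everywhere default (30 vs 50 mS/cm2)", {
  m <- dist_morph()
  k <- hh_k_channel()
  apps <- list(
    channel_application(k, applicator(overrides = list(gbar = "30 mS/cm2")),
                        target_everywhere()),
    channel_application(k, applicator(overrides = list(gbar = "50 mS/cm2")),
                        target_region("apicaldendrite")))
  res <- resolve_distribution(apps, m)
  expect_equal(qty_in(res$soma$hh_k$params$gbar, "mS/cm2"), 30)
  expect_equal(qty_in(res$d1$hh_k$params$gbar, "mS/cm2"), 30)
  expect_equal(qty_in(res$ap$hh_k$params$gbar, "mS/cm2"), 50)
})

test_that("a single everywhere triplet applies channel defaults everywhere", {
  m <- dist_morph()
  lk <- leak_channel()
  res <- resolve_distribution(list(channel_application(lk)), m)
  for (sid in names(m$sections)) {
    expect_equal(qty_in(res[[sid]]$leak$params$gbar, "mS/cm2"), 0.3)
  }
})

test_that("sections matched by no triplet carry no channel instance", {
  m <- dist_morph()
  k <- hh_k_channel()
  res <- resolve_distribution(
    list(channel_application(k, targeter = target_region("dendrites"))), m)
  expect_null(res$soma$hh_k)
  expect_false(is.null(res$d1$hh_k))
})

test_that("equal-priority conflicts and unknown targets are hard errors", {
  m <- dist_morph()
  k <- hh_k_channel()
  expect_error(resolve_distribution(list(
    channel_application(k, targeter = target_region("dendrites")),
    channel_application(k, applicator(multipliers = list(gbar = 2)),
                        target_region("dendrites"))
  ), m), class = "cablenet_ambiguity_error")
  expect_error(resolve_distribution(list(
    channel_application(k, targeter = target_region("axon"))
  ), m), class = "cablenet_key_error")
  # section targeter (priority 3) beats region (priority 2): no conflict
  res <- resolve_distribution(list(
    channel_application(k, targeter = target_region("dendrites")),
    channel_application(k, applicator(overrides = list(gbar = "5 mS/cm2")),
                        target_section("d2"))
  ), m)
  expect_equal(qty_in(res$d2$hh_k$params$gbar, "mS/cm2"), 5)
  expect_equal(qty_in(res$d1$hh_k$params$gbar, "mS/cm2"), 36)
})

test_that("applicator and application invariants hold", {
  expect_error(applicator(overrides = list(gbar = "1 mS/cm2"),
                          multipliers = list(gbar = 2)),
               class = "cablenet_domain_error")
  expect_error(channel_application(hh_k_channel(),
                                   applicator(multipliers = list(nosuch = 2))),
               class = "cablenet_key_error")
})

test_that("resolution is order independent", {
  m <- dist_morph()
  k <- hh_k_channel()
  lk <- leak_channel()
  apps <- list(
    channel_application(k, apply_uniform(), target_everywhere()),
    channel_application(k, applicator(multipliers = list(gbar = 2)),
                        target_region("dendrites")),
    channel_application(k, applicator(overrides = list(gbar = "50 mS/cm2")),
                        target_section("d2")),
    channel_application(lk, apply_uniform(), target_everywhere()))
  ref <- distribution_table(resolve_distribution(apps, m), m)
  ref <- ref[order(ref$section, ref$channel, ref$parameter), ]
  set.seed(99)
  for (i in 1:100) {
    perm <- sample(length(apps))
    got <- distribution_table(resolve_distribution(apps[perm], m), m)
    got <- got[order(got$section, got$channel, got$parameter), ]
    rownames(ref) <- rownames(got) <- NULL
    expect_identical(got, ref)
  }
})

test_that("adding a lower-priority triplet never changes claimed sections", {
  m <- dist_morph()
  k <- hh_k_channel()
  high <- list(
    channel_application(k, applicator(overrides = list(gbar = "50 mS/cm2")),
                        target_region("dendrites")))
  before <- resolve_distribution(high, m)
  after <- resolve_distribution(c(high, list(
    channel_application(k, applicator(overrides = list(gbar = "1 mS/cm2")),
                        target_everywhere()))), m)
  for (sid in c("d1", "d2")) {
    expect_equal(qty_in(after[[sid]]$hh_k$params$gbar, "mS/cm2"),
                 qty_in(before[[sid]]$hh_k$params$gbar, "mS/cm2"))
  }
  expect_equal(qty_in(after$soma$hh_k$params$gbar, "mS/cm2"), 1)
})
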