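fx <- fpf_fixture()
res <- triage_fixture()

test_that("P/LP at Panel A halts escalation", {
  for (f in c("F3", "F12", "F13")) {
    o <- res$outcomes[[f]]
    expect_equal(o$tiers_run, "A")
    expect_equal(o$stop_reason, "plp_found_A")
  }
})

test_that("VUS-LP never halts; Panel C is gated on severe TL in an affected", {
  # families with VUS-LP and a severely shortened patient go all the way
  for (f in c("F1", "F9")) {
    o <- res$outcomes[[f]]
    expect_equal(o$tiers_run, c("A", "B", "C"))
    expect_equal(o$stop_reason, "completed_C")
  }
  # VUS only and no severe TL: A then B, then stop
  o <- res$outcomes[["F8"]]
  expect_equal(o$tiers_run, c("A", "B"))
  expect_equal(o$stop_reason, "no_severe_tl")
})

test_that("candidates exclude benign-side classes at every tier", {
  fam <- make_family(ids = c("P1", "R1"), status = c("affected", "unaffected"))
  v <- rbind(make_variant(gene = "RTEL1", consequence = "missense", af = 1e-5,
                          pos = 63690001L, genotypes = c(P1 = "het")),
             make_variant(gene = "RTEL1", consequence = "missense", af = 1e-5,
                          pos = 63690002L, genotypes = c(P1 = "het")))
  cls <- acmg_classifier(class_overrides = stats::setNames(
    c("LB", "VUS"), v$key))
  o <- triage_family(fam, v, read_panels(), tl = NULL, classify_fn = cls)
  expect_equal(length(o$candidates$A), 1L)
  expect_equal(o$candidates$A[[1]]$klass, "VUS")
  # benign calls still count toward the per-case retained-variant workload
  expect_equal(unname(o$per_case_counts$A["P1"]), 2)
})

test_that("families without affected members are rejected", {
  fam <- make_family(ids = "R1", status = "unaffected")
  expect_error(triage_family(fam, fx$variants, fx$panels), "no affected")
})

test_that("asymptomatic carrier detection matches the published families", {
  c12 <- res$outcomes[["F12"]]$candidates$A[[1]]
  expect_setequal(c12$unaffected_carrier_ids, c("F12_R2", "F12_R5"))
  c13 <- res$outcomes[["F13"]]$candidates$A[[1]]
  expect_setequal(c13$unaffected_carrier_ids, c("F13_R1", "F13_R3", "F13_R4"))
  # missing genotypes are flagged untested, not called carriers
  expect_true("F13_R6" %in% c13$untested_ids)

  fam <- make_family(ids = c("P1"), status = "affected")
  got <- detect_asymptomatic_carriers(c(P1 = "het"), fam)
  expect_equal(got$carriers, character())
  got <- detect_asymptomatic_carriers(c(P1 = "het", R1 = "ref"),
                                      make_family(ids = c("P1", "R1"),
                                                  status = c("affected",
                                                             "unaffected")))
  expect_equal(got$carriers, character())
})

test_that("diagnostic yields match the cohort fractions with Wilson CIs", {
  y1 <- diagnostic_yield(res$outcomes, c("P", "LP"))
  expect_equal(y1$k, 3L)
  expect_equal(y1$percent, 23.1)
  expect_true(all(abs(y1$ci - c(0.082, 0.503)) <= 0.001))
  y2 <- diagnostic_yield(res$outcomes, c("P", "LP", "VUS_LP"))
  expect_equal(y2$k, 5L)
  expect_equal(y2$percent, 38.5)
  y0 <- diagnostic_yield(res$outcomes, "VUS_LP")
  expect_equal(y0$k, 2L)
  expect_error(diagnostic_yield(list(), c("P", "LP")), "0 families")
})

test_that("yield is monotone in the relevant-class set", {
  sets <- list("P", c("P", "LP"), c("P", "LP", "VUS_LP"))
  fracs <- vapply(sets, function(s)
    diagnostic_yield(res$outcomes, s)$fraction, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("gating is sound on simulated cohorts", {
  sim <- simulate_cohort(sim_config(n_families = 20, planted_fraction = 0.5,
                                    seed = 99))
  tl <- tl_results(sim$tl_records, sim$tl_reference)
  out <- triage_cohort(sim$pedigree, filter_variants(sim$variants), tl = tl)
  severe_ids <- tl$individual_id[tl$known & tl$severe]
  for (o in out$outcomes) {
    expect_equal(o$tiers_run[1], "A")
    if (identical(o$stop_reason, "plp_found_A"))
      expect_equal(o$tiers_run, "A")
    if ("C" %in% o$tiers_run) {
      fam <- sim$pedigree[sim$pedigree$family_id == o$family_id, ]
      expect_true(any(fam$id[fam$status == "affected"] %in% severe_ids))
    }
  }
})
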