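test_that("Fisher exact enumeration matches hand-checked tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 1, 1, 5), 2, byrow = TRUE)),
               0.0801, tolerance = 1e-4 / 0.0801)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)), 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 2, 0), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("Fisher enumeration agrees with the reference implementation", {
  # exhaustive up to N = 12; the full N <= 30 sweep runs in the acceptance
  # suite
  for (n in 1:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c_ in 0:(n - a - b)) {
      d <- n - a - b - c_
      m <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
      expect_equal(fisher_exact_2x2(m), stats::fisher.test(m)$p.value,
                   tolerance = 1e-9,
                   info = paste(a, b, c_, d))
    }
  }
})

test_that("Welch t behaves on degenerate, shifted and equal-variance input", {
  x <- c(1, 2, 3, 4)
  w <- welch_t_test(x, x)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  # sign convention: first sample smaller -> negative t
  w <- welch_t_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(w$t, 0)
  # with equal n and equal variance, Welch reduces to the pooled t
  set.seed(6)
  a <- rnorm(10)
  b <- a[sample(10)] + 1          # same spread, shifted
  pooled <- function(x, y) {
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  }
  expect_equal(welch_t_test(a, b)$t, pooled(a, b), tolerance = 1e-6)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "nonzero variance")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(7)
  p <- replicate(5000, welch_t_test(rnorm(8), rnorm(8))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("Wilson intervals bracket the point estimate with known endpoints", {
  ci <- wilson_ci(3, 13)
  expect_true(all(abs(ci - c(0.082, 0.503)) <= 0.001))
  expect_equal(wilson_ci(0, 10)[1], 0)
  expect_equal(wilson_ci(10, 10)[2], 1)
  for (k in 0:13) {
    ci <- wilson_ci(k, 13)
    expect_lte(ci[1], k / 13)
    expect_gte(ci[2], k / 13)
  }
  # agrees with the score interval from prop.test without continuity
  # correction
  pt <- stats::prop.test(3, 13, correct = FALSE)$conf.int
  expect_equal(wilson_ci(3, 13), as.numeric(pt), tolerance = 1e-9)
})

test_that("the TL association table reproduces the cohort fractions", {
  res <- triage_fixture()
  ta <- tl_association(res$pedigree, res$outcomes, res$tl, scope = "all")
  expect_equal(unname(ta$table),
               matrix(c(8, 13, 5, 31), 2, byrow = TRUE))
  expect_equal(sum(ta$table[1, ]), 21)   # severe group size
  expect_equal(sum(ta$table[2, ]), 36)   # non-severe group size
  expect_true(ta$fisher_p > 0 && ta$fisher_p <= 1)
  # carriers have shorter telomeres than non-carriers on this cohort
  expect_lt(ta$carrier_mean, ta$noncarrier_mean)
  expect_lt(ta$family_welch$mean_x, ta$family_welch$mean_y)

  # patient scope: 5 of the 5 severe patients carry a relevant variant
  tp <- tl_association(res$pedigree, res$outcomes, res$tl, scope = "patients")
  expect_equal(unname(tp$table[1, ]), c(5, 0))
})

test_that("degenerate TL association scopes fall back to p = 1", {
  ped <- make_family(ids = c("P1", "R1"), status = c("affected", "unaffected"))
  tl_none <- make_tl(character(), numeric())
  expect_warning(ta <- tl_association(ped, list(), tl_none, scope = "patients"),
                 "degenerate")
  expect_equal(ta$fisher_p, 1)

  # everyone a carrier: degenerate column margin
  v <- make_variant(gene = "RTEL1", consequence = "nonsense", af = NA,
                    genotypes = c(P1 = "het", R1 = "het"))
  cls <- acmg_classifier(class_overrides = stats::setNames("P", v$key))
  out <- triage_family(ped, v, read_panels(), classify_fn = cls)
  tl <- make_tl(c("P1", "R1"), c(5, 50))
  expect_warning(ta <- tl_association(ped, list(out), tl, scope = "all"),
                 "degenerate")
  expect_equal(ta$fisher_p, 1)
})

test_that("per-tier summaries use sample SD and flag degenerate cases", {
  mk <- function(counts) list(per_case_counts = list(A = counts))
  s <- tier_variant_summary(list(mk(c(a = 0, b = 1, c = 2))), "A")
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 1)
  expect_equal(c(s$min, s$max), c(0, 2))
  s1 <- tier_variant_summary(list(mk(c(a = 5))), "A")
  expect_equal(s1$sd, 0)
  expect_false(s1$sd_defined)
  s0 <- tier_variant_summary(list(), "C")
  expect_equal(s0$n, 0L)
})
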