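test_that("combining-table examples classify as published", {
  expect_equal(combine_acmg(evidence(c("PVS1", "PM2")))$klass, "LP")
  expect_equal(combine_acmg(evidence("BA1"))$klass, "B")
  expect_equal(combine_acmg(evidence(character()))$klass, "VUS")
  expect_equal(combine_acmg(evidence(c("PVS1", "PS1")))$klass, "P")
  expect_equal(combine_acmg(evidence(c("BS1", "BS2")))$klass, "B")
  expect_equal(combine_acmg(evidence(c("BS1", "BP4")))$klass, "LB")
  # conflicting evidence
  expect_equal(combine_acmg(evidence(c("PVS1", "PM2", "BA1")))$klass, "VUS")
})

test_that("combine_acmg equals the transcription oracle over 2^9 sets", {
  universe <- c("PVS1", "PS1", "PM1", "PM2", "PP1", "PP3", "BA1", "BS1", "BP4")
  for (mask in 0:(2^9 - 1)) {
    codes <- universe[bitwAnd(mask, 2^(0:8)) > 0]
    got <- combine_acmg(evidence(codes))$klass
    expect_equal(got, oracle_combine(codes),
                 info = paste(codes, collapse = "+"))
  }
})

test_that("VUS subclassification follows the stated policy", {
  expect_equal(subclassify_vus(evidence(c("PM2", "PP3")))$klass, "VUS_LP")
  expect_equal(subclassify_vus(evidence("PP3"))$klass, "VUS")
  expect_equal(subclassify_vus(evidence(c("PP3", "PP1")))$klass, "VUS_LP")
  expect_equal(subclassify_vus(evidence(c("BP4", "BP7")))$klass, "VUS_LB")
  expect_equal(subclassify_vus(evidence("BS1"))$klass, "VUS_LB")
  # mixed evidence stays plain VUS
  expect_equal(subclassify_vus(evidence(c("PM2", "BP4")))$klass, "VUS")
  # non-VUS base classes pass through untouched
  expect_equal(subclassify_vus(evidence("PP3"), base_klass = "LP")$klass, "LP")
})

test_that("every assertion set maps to exactly one class, deterministically", {
  set.seed(3)
  codes_all <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PP1", "PP3", "BA1",
                 "BS1", "BP4", "BP7")
  for (i in 1:200) {
    codes <- sample(codes_all, sample(0:6, 1))
    ev <- evidence(unique(codes))
    k1 <- classify_variant(ev)$klass
    k2 <- classify_variant(ev)$klass
    expect_identical(k1, k2)
    expect_true(k1 %in% fpftiers:::.acmg_classes)
  }
})

test_that("classification is monotone along the benign-pathogenic ordering", {
  ordering <- fpftiers:::.acmg_classes  # B < LB < VUS_LB < VUS < VUS_LP < LP < P
  rank <- function(k) match(k, ordering)
  set.seed(4)
  path_codes <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PP1", "PP3")
  benign_codes <- c("BA1", "BS1", "BP4", "BP7")
  for (i in 1:200) {
    codes <- unique(sample(c(path_codes, benign_codes), sample(0:5, 1)))
    base <- rank(classify_variant(evidence(codes))$klass)
    add_p <- setdiff(path_codes, codes)
    if (length(add_p) > 0) {
      more <- classify_variant(evidence(c(codes, sample(add_p, 1))))$klass
      expect_gte(rank(more), base)
    }
    add_b <- setdiff(benign_codes, codes)
    if (length(add_b) > 0) {
      less <- classify_variant(evidence(c(codes, sample(add_b, 1))))$klass
      expect_lte(rank(less), base)
    }
  }
})

test_that("automatic evidence derivation follows the thresholds", {
  lof_gene <- list(category = "telomere", lof_mechanism = TRUE)
  non_lof <- list(category = "non_telomere", lof_mechanism = FALSE)
  severe <- list(known = TRUE, severe = TRUE)

  # novel nonsense in a LOF telomere gene with severe carrier TL
  ev <- derive_auto_evidence(list(consequence = "nonsense", af = NA_real_,
                                  score = NA_real_),
                             lof_gene, carrier_tl = severe)
  expect_setequal(ev$code, c("PVS1", "PM2", "PP4"))
  expect_equal(classify_variant(ev)$klass, "P")  # PVS1 + PM2 + supporting TL

  # common-ish missense with a low score: nothing fires
  ev <- derive_auto_evidence(list(consequence = "missense", af = 0.005,
                                  score = 10), non_lof)
  expect_equal(nrow(ev), 0L)

  # absent AF and a high score
  ev <- derive_auto_evidence(list(consequence = "missense", af = NA_real_,
                                  score = 25), non_lof)
  expect_setequal(ev$code, c("PM2", "PP3"))
  expect_equal(classify_variant(ev)$klass, "VUS_LP")

  # no PVS1 without an established LOF mechanism
  ev <- derive_auto_evidence(list(consequence = "nonsense", af = NA_real_,
                                  score = NA_real_), non_lof)
  expect_false("PVS1" %in% ev$code)
})

test_that("the TL criterion is supporting-only and telomere-genes-only", {
  severe <- list(known = TRUE, severe = TRUE)
  # severe TL alone never suffices to leave VUS
  ev <- derive_auto_evidence(list(consequence = "missense", af = 0.005,
                                  score = 5),
                             list(category = "telomere", lof_mechanism = TRUE),
                             carrier_tl = severe)
  expect_equal(ev$code, "PP4")
  expect_equal(ev$strength_class, "supporting")
  expect_equal(classify_variant(ev)$klass, "VUS")
  # not emitted for non-telomere genes
  ev <- derive_auto_evidence(list(consequence = "missense", af = 0.005,
                                  score = 5),
                             list(category = "non_telomere",
                                  lof_mechanism = FALSE),
                             carrier_tl = severe)
  expect_equal(nrow(ev), 0L)
})

test_that("manual assertions override auto ones; class overrides trump all", {
  auto <- evidence(c("PM2", "PP3"))
  manual <- evidence("PM2", strength_class = "strong", source = "manual")
  merged <- merge_evidence(auto, manual)
  expect_equal(merged$strength_class[merged$code == "PM2"], "strong")
  expect_equal(nrow(merged), 2L)

  clf <- acmg_classifier(class_overrides = c("20:1:C:T" = "LP"))
  got <- clf(list(key = "20:1:C:T", consequence = "missense", af = 0.5,
                  score = 0),
             list(category = "non_telomere", lof_mechanism = FALSE))
  expect_equal(got$klass, "LP")
})
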