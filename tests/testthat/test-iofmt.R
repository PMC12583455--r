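test_that("a biallelic annotated het site parses to one decomposed record", {
  path <- write_mini_vcf(
    "20\t63690050\t.\tC\tT\t.\tPASS\tGENE=RTEL1;CSQ=stop_gained;SCORE=38\tGT\t0/1",
    samples = "P1")
  v <- read_annotated_vcf(path)
  expect_equal(nrow(v), 1L)
  expect_equal(v$gene, "RTEL1")
  expect_equal(v$consequence, "nonsense")
  expect_true(is.na(v$af))          # missing AF key -> absent
  expect_equal(v$score, 38)
  expect_equal(v$genotypes[[1]][["P1"]], "het")
  expect_equal(v$key, "20:63690050:C:T")
})

test_that("multi-allelic sites decompose into one record per alt allele", {
  path <- write_mini_vcf(c(
    "chr1\t100\t.\tA\tC,G\t.\t.\tGENE=TERT,TERT;CSQ=missense,stop_gained;AF=0.001,0.002\tGT\t1/2",
    "1\t200\t.\tT\tG\t.\t.\tGENE=PARN;CSQ=missense;AF=0.5\tGT\t0/0"),
    samples = "S1")
  v <- read_annotated_vcf(path)
  # record count equals the number of (site, alt) pairs
  expect_equal(nrow(v), 3L)
  expect_equal(v$chrom[1:2], c("1", "1"))   # chr prefix normalized
  expect_equal(v$pos[1:2], c(100L, 100L))
  expect_equal(v$ref[1:2], c("A", "A"))
  expect_equal(v$alt[1:2], c("C", "G"))
  expect_equal(v$af[1:2], c(0.001, 0.002))  # per-allele INFO split
  # 1/2 genotype: het for each alt allele separately
  expect_equal(unname(v$genotypes[[1]]["S1"]), "het")
  expect_equal(unname(v$genotypes[[2]]["S1"]), "het")
  expect_equal(unname(v$genotypes[[3]]["S1"]), "ref")
})

test_that("unknown consequence terms map to 'other' with a warning", {
  path <- write_mini_vcf(
    "1\t100\t.\tA\tC\t.\t.\tGENE=TERT;CSQ=weird_term\tGT\t0/1",
    samples = "S1")
  expect_warning(v <- read_annotated_vcf(path), "weird_term")
  expect_equal(v$consequence, "other")
})

test_that("malformed VCFs give parse errors naming the problem", {
  bad1 <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "1\t100\t.\tA\tC"), bad1)
  expect_error(read_annotated_vcf(bad1), "#CHROM")
  bad2 <- write_mini_vcf("1\t100\t.\tA", samples = character())
  expect_error(read_annotated_vcf(bad2), "line 8")
})

test_that("missing genotypes and half-calls are handled", {
  path <- write_mini_vcf(
    "1\t100\t.\tA\tC\t.\t.\tGENE=TERT;CSQ=missense\tGT\t./.\t1|1\t0/1",
    samples = c("A", "B", "C"))
  v <- read_annotated_vcf(path)
  expect_equal(unname(v$genotypes[[1]][c("A", "B", "C")]),
               c("missing", "hom", "het"))
})

test_that("pedigree reading validates ids and maps status codes", {
  path <- write_mini_ped(c("FAM1\tP1\t0\t0\t1\t2",
                           "FAM1\tR1\tP1\t0\t2\t1",
                           "FAM2\tQ1\t0\t0\t0\t0"))
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$status, c("affected", "unaffected", "unknown"))
  expect_equal(ped$sex, c("male", "female", "unknown"))

  single <- read_pedigree(write_mini_ped("F1\tA\t0\t0\t1\t2"))
  expect_equal(sum(single$status == "affected"), 1L)

  expect_error(read_pedigree(write_mini_ped(c("F1\tA\t0\t0\t1\t2",
                                              "F1\tA\t0\t0\t1\t1"))),
               "duplicate")
  expect_error(read_pedigree(write_mini_ped("F1\tA\tX9\t0\t1\t2")), "X9")
})

test_that("the bundled fixture pedigree matches the cohort description", {
  ped <- fpf_fixture()$pedigree
  expect_equal(length(unique(ped$family_id)), 13L)
  expect_equal(sum(ped$status == "affected"), 16L)
  expect_equal(nrow(ped), 61L)
  # families 5, 7 and 12 have two affected members
  two_aff <- names(which(table(ped$family_id[ped$status == "affected"]) == 2))
  expect_setequal(two_aff, c("F5", "F7", "F12"))
})

test_that("bundled panels load and validate", {
  a <- read_panel("bundled:A")
  expect_equal(nrow(a), 14L)
  expect_equal(sum(a$category == "telomere"), 8L)
  expect_setequal(a$symbol[a$category == "telomere"],
                  c("TERC", "TERT", "TINF2", "DKC1", "RTEL1", "PARN",
                    "NAF1", "ZCCHC8"))
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("symbol\tpanel_id\tcategory\tinheritance\tevidence\tlof_mechanism",
               "RTEL1\tA\ttelomere\tAD\tstrong\tTRUE",
               "RTEL1\tA\ttelomere\tAD\tstrong\tTRUE"), dup)
  expect_error(read_panel(dup), "duplicate")
  # a symbol may not appear in two panels
  b_dup <- tempfile(fileext = ".tsv")
  writeLines(c("symbol\tpanel_id\tcategory\tinheritance\tevidence\tlof_mechanism",
               "RTEL1\tB\ttelomere\tAD\tstrong\tTRUE"), b_dup)
  expect_error(read_panels(panel_b = b_dup), "more than one panel")
})

test_that("panels survive a write/read round trip and JSON input works", {
  a <- read_panel("bundled:A")
  tsv <- tempfile(fileext = ".tsv")
  write.table(a, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_panel(tsv), a)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(a, js)
  expect_equal(read_panel(js), a)
})

test_that("TL inputs join records to reference bins and keep unknowns", {
  ref <- tempfile(fileext = ".tsv")
  writeLines(c("age_lo\tage_hi\tmean_ts\tsd_ts",
               "0\t50\t1.3\t0.2", "50\t100\t1.1\t0.2"), ref)
  tl <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tts_ratio\tage_years",
               "A\t1.1\t40", "B\t\t60", "C\t0.9\t70"), tl)
  inp <- read_tl_inputs(tl, ref)
  expect_equal(nrow(inp$records), 3L)       # missing T/S retained
  expect_true(is.na(inp$records$ts_ratio[2]))

  bad_ref <- tempfile(fileext = ".tsv")
  writeLines(c("age_lo\tage_hi\tmean_ts\tsd_ts", "0\t100\t1.3\t0"), bad_ref)
  expect_error(read_tl_inputs(tl, bad_ref), "sd_ts")

  tl2 <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\tts_ratio\tage_years", "A\t1.1\t200"), tl2)
  expect_error(read_tl_inputs(tl2, ref), "outside")
})

test_that("coverage fractions follow depth thresholds and degenerate cases", {
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t0\t10\tGENE1", bed)
  panel <- data.frame(symbol = "GENE1", stringsAsFactors = FALSE)

  depth_all20 <- tempfile()
  writeLines(c("chrom\tpos\tdepth", paste0("1\t", 1:10, "\t20")), depth_all20)
  cov <- coverage_summary(depth_all20, bed, panel)
  expect_equal(cov$fraction_ge_10x, 1)
  expect_equal(cov$fraction_ge_20x, 1)

  depth_half <- tempfile()
  writeLines(c("chrom\tpos\tdepth", paste0("1\t", 1:5, "\t5"),
               paste0("1\t", 6:10, "\t15")), depth_half)
  cov <- coverage_summary(depth_half, bed, panel)
  expect_equal(cov$fraction_ge_10x, 0.5)
  expect_equal(cov$fraction_ge_20x, 0)
  expect_lte(cov$fraction_ge_20x, cov$fraction_ge_10x)

  panel2 <- data.frame(symbol = "ABSENT", stringsAsFactors = FALSE)
  expect_warning(cov2 <- coverage_summary(depth_half, bed, panel2),
                 "no target bases")
  expect_equal(cov2$fraction_ge_10x, 0)
})

test_that("triage reports round-trip and mirror the candidate spectrum", {
  res <- triage_fixture()
  prefix <- file.path(tempfile(), "report")
  paths <- write_triage_report(res$outcomes, prefix)
  tsv <- read.delim(paths[1], stringsAsFactors = FALSE)
  expect_equal(nrow(tsv), 10L)    # one row per family-level candidate
  expect_setequal(names(tsv)[1:3], c("family_id", "patient_ids", "gene"))

  back <- read_triage_report(paths[2])
  expect_equal(back, lapply(res$outcomes, fpftiers:::.canon_outcome),
               ignore_attr = TRUE)

  empty <- write_triage_report(list(), file.path(tempfile(), "empty"))
  expect_equal(nrow(read.delim(empty[1])), 0L)
})
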