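# Bundled cohort fixture: a machine-readable transcription of the
# published 13-family FPF study tables (per-variant records with ACMG
# classes and TL percentile categories, pedigree skeletons, panel
# membership). Individuals named in the tables carry their printed
# attributes; family members beyond those named (relative counts, filler
# TL categories, ages) are synthetic fill chosen to match the printed
# cohort-level totals (61 individuals, 16 affected, 58 TL measurements,
# 21 severe / 36 non-severe with 8 and 5 relevant-variant carriers).

.fixture_patients <- function() {
  # family, id, sex, age; ages/sex from the clinical table where printed
  p <- rbind(
    c("F1",  "F1_P1",  "male",   83), c("F2",  "F2_P1",  "female", 60),
    c("F3",  "F3_P1",  "male",   46), c("F4",  "F4_P1",  "female", 72),
    c("F5",  "F5_P1",  "male",   68), c("F5",  "F5_P2",  "female", 59),
    c("F6",  "F6_P1",  "male",   74), c("F7",  "F7_P1",  "male",   46),
    c("F7",  "F7_P2",  "female", 58), c("F8",  "F8_P1",  "female", 67),
    c("F9",  "F9_P1",  "male",   67), c("F10", "F10_P1", "female", 63),
    c("F11", "F11_P1", "female", 64), c("F12", "F12_P1", "male",   56),
    c("F12", "F12_P2", "female", 64), c("F13", "F13_P1", "male",   56))
  data.frame(family_id = p[, 1], id = p[, 2], sex = p[, 3],
             age_years = as.numeric(p[, 4]), status = "affected",
             stringsAsFactors = FALSE)
}

.fixture_relative_counts <- c(F1 = 4, F2 = 3, F3 = 2, F4 = 3, F5 = 3, F6 = 3,
                              F7 = 3, F8 = 3, F9 = 4, F10 = 3, F11 = 3,
                              F12 = 5, F13 = 6)

.fixture_pedigree <- function() {
  patients <- .fixture_patients()
  rel <- lapply(names(.fixture_relative_counts), function(f) {
    n <- .fixture_relative_counts[[f]]
    ids <- sprintf("%s_R%d", f, seq_len(n))
    data.frame(family_id = f, id = ids,
               sex = rep(c("female", "male"), length.out = n),
               age_years = 30 + 5 * seq_len(n), status = "unaffected",
               stringsAsFactors = FALSE)
  })
  ped <- rbind(patients, do.call(rbind, rel))
  ped$father <- "0"
  ped$mother <- "0"
  ped <- ped[order(match(ped$family_id, names(.fixture_relative_counts))), ]
  rownames(ped) <- NULL
  ped[c("family_id", "id", "father", "mother", "sex", "status", "age_years")]
}

# TL percentile categories; "unknown" and omitted ids reflect individuals
# without a usable TL measurement
.fixture_tl_categories <- function() {
  cat_map <- c(
    # patients (printed where available)
    F1_P1 = "<1", F2_P1 = "25-50", F3_P1 = "<1", F4_P1 = "50-75",
    F5_P1 = "25-50", F5_P2 = "10-25", F6_P1 = "50-75", F7_P1 = "unknown",
    F7_P2 = "10-25", F8_P1 = "25-50", F9_P1 = "<10", F10_P1 = "25-50",
    F11_P1 = "10-25", F12_P1 = "10-25", F12_P2 = "<1", F13_P1 = "<10",
    # relatives named in the text
    F12_R2 = "<1", F12_R3 = "<10", F12_R5 = "25-50",
    F13_R1 = "25-50", F13_R2 = "<10", F13_R3 = "<10", F13_R4 = "10-25",
    F3_R1 = "<10", F3_R2 = "<1",
    F1_R1 = "<1", F9_R1 = "10-25",
    # synthetic fill to the cohort totals (one severe unaffected relative
    # per remaining family, the rest non-severe)
    F2_R1 = "<10", F4_R1 = "<10", F5_R1 = "<10", F6_R1 = "<10",
    F7_R1 = "<10", F8_R1 = "<10", F9_R2 = "<10", F10_R1 = "<10",
    F11_R1 = "<10",
    F1_R2 = "10-25", F1_R3 = "25-50",
    F2_R2 = "50-75", F2_R3 = "10-25",
    F4_R2 = "25-50", F4_R3 = "50-75",
    F5_R2 = "10-25", F5_R3 = "25-50",
    F6_R2 = "50-75", F6_R3 = "10-25",
    F7_R2 = "25-50", F7_R3 = "50-75",
    F8_R2 = "10-25", F8_R3 = "25-50",
    F9_R3 = "50-75",
    F10_R2 = "10-25", F10_R3 = "25-50",
    F11_R2 = "50-75", F11_R3 = "10-25",
    F12_R1 = "25-50", F12_R4 = "50-75",
    F13_R5 = "10-25")
  data.frame(individual_id = names(cat_map), tl_category = unname(cat_map),
             stringsAsFactors = FALSE)
}

# genotype map helper: named vector within the carrying family
.gts <- function(het = character(), ref = character(), missing = character()) {
  stats::setNames(c(rep("het", length(het)), rep("ref", length(ref)),
                    rep("missing", length(missing))),
                  c(het, ref, missing))
}

.fixture_variants <- function() {
  v <- list(
    list(chrom = "20", pos = 63688000L, ref = "C", alt = "T", gene = "RTEL1",
         hgvs_c = "NM_001283009.2:c.2579C>T", hgvs_p = "p.Ser860Phe",
         consequence = "missense", af = NA_real_, score = 26, klass = "VUS_LP",
         genotypes = .gts(het = c("F9_P1", "F9_R1"),
                          ref = c("F9_R2", "F9_R3"), missing = "F9_R4")),
    list(chrom = "20", pos = 63690050L, ref = "C", alt = "T", gene = "RTEL1",
         hgvs_c = "NM_001283009.2:c.2920C>T", hgvs_p = "p.Arg974*",
         consequence = "nonsense", af = 4e-6, score = 38, klass = "P",
         genotypes = c(.gts(het = c("F12_P1", "F12_P2", "F12_R2", "F12_R5"),
                            ref = c("F12_R1", "F12_R3", "F12_R4")),
                       .gts(het = c("F13_P1", "F13_R1", "F13_R3", "F13_R4"),
                            ref = c("F13_R2", "F13_R5"),
                            missing = "F13_R6"))),
    list(chrom = "20", pos = 63690065L, ref = "C", alt = "T", gene = "RTEL1",
         hgvs_c = "NM_001283009.2:c.2935C>T", hgvs_p = "p.Arg979Trp",
         consequence = "missense", af = 8e-6, score = 29, klass = "VUS_LP",
         genotypes = .gts(het = "F1_P1", ref = c("F1_R1", "F1_R2", "F1_R3"),
                          missing = "F1_R4")),
    list(chrom = "20", pos = 63691200L, ref = "C", alt = "A", gene = "RTEL1",
         hgvs_c = "NM_001283009.2:c.3470C>A", hgvs_p = "p.Pro1157His",
         consequence = "missense", af = 2e-5, score = 23, klass = "VUS",
         genotypes = .gts(het = "F8_P1", ref = c("F8_R1", "F8_R2", "F8_R3"))),
    list(chrom = "14", pos = 24710500L, ref = "C", alt = "T", gene = "TINF2",
         hgvs_c = "NM_001099274.3:c.1108C>T", hgvs_p = "p.Pro370Ser",
         consequence = "missense", af = NA_real_, score = 25, klass = "VUS_LP",
         genotypes = .gts(het = c("F1_P1", "F1_R1"), ref = c("F1_R2", "F1_R3"),
                          missing = "F1_R4")),
    list(chrom = "4", pos = 163120000L, ref = "T", alt = "G", gene = "NAF1",
         hgvs_c = "NM_138386.3:c.1104T>G", hgvs_p = "p.Tyr368*",
         consequence = "nonsense", af = NA_real_, score = 36, klass = "LP",
         genotypes = .gts(het = "F3_P1", ref = c("F3_R1", "F3_R2"))),
    list(chrom = "10", pos = 79886000L, ref = "G", alt = "A", gene = "SFTPA2",
         hgvs_c = "NM_001098668.4:c.482G>A", hgvs_p = "p.Arg161His",
         consequence = "missense", af = 1e-5, score = 24, klass = "VUS",
         genotypes = .gts(het = "F11_P1",
                          ref = c("F11_R1", "F11_R2", "F11_R3"))),
    list(chrom = "5", pos = 169600000L, ref = "A", alt = "G", gene = "SPDL1",
         hgvs_c = "NM_017785.5:c.892-2A>G", hgvs_p = NA_character_,
         consequence = "splice_site", af = 3e-5, score = 22, klass = "VUS",
         genotypes = .gts(het = "F6_P1", ref = c("F6_R1", "F6_R2", "F6_R3"))),
    list(chrom = "5", pos = 1270000L, ref = "G", alt = "A", gene = "TERT",
         hgvs_c = "NM_198253.3:c.2885G>A", hgvs_p = "p.Arg962His",
         consequence = "missense", af = 1.2e-5, score = 24, klass = "VUS",
         genotypes = .gts(het = c("F7_P1", "F7_P2"),
                          ref = c("F7_R1", "F7_R2", "F7_R3"))))
  df <- do.call(rbind, lapply(v, function(x)
    data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
               gene = x$gene, hgvs_c = x$hgvs_c, hgvs_p = x$hgvs_p,
               consequence = x$consequence, af = x$af, score = x$score,
               key = variant_key(x$chrom, x$pos, x$ref, x$alt),
               klass = x$klass, stringsAsFactors = FALSE)))
  df$genotypes <- lapply(v, `[[`, "genotypes")
  rownames(df) <- NULL
  df
}

#' The bundled in-study cohort fixture
#'
#' Returns the transcribed 13-family cohort: pedigree (61 individuals, 16
#' affected), the 9 distinct Panel A variants with their curated ACMG
#' classes and per-family genotypes (the recurrent RTEL1 nonsense variant
#' is carried in two families, giving 10 family-level candidate records),
#' the per-individual TL percentile categories (58 measurements), the
#' bundled panels, and a classifier pre-loaded with the curated classes.
#'
#' @return list with `pedigree`, `variants` (including a `klass` column),
#'   `classes` (named vector key -> class), `tl_categories`, `tl`
#'   (TL results), `panels`, `classifier`.
#' @export
fpf_fixture <- function() {
  variants <- .fixture_variants()
  classes <- stats::setNames(variants$klass, variants$key)
  tl_cat <- .fixture_tl_categories()
  list(pedigree = .fixture_pedigree(),
       variants = variants[setdiff(names(variants), "klass")],
       classes = classes,
       tl_categories = tl_cat,
       tl = tl_results_from_categories(tl_cat),
       panels = read_panels(),
       classifier = acmg_classifier(class_overrides = classes))
}

#' Run the triage pipeline on the bundled fixture
#'
#' Convenience wrapper: tier-0 filter, cohort triage with the curated
#' classes, TL gating from the categorical TL table.
#'
#' @return `fpf_triage` object.
#' @export
triage_fixture <- function() {
  fx <- fpf_fixture()
  filtered <- filter_variants(fx$variants, filter_config())
  triage_cohort(fx$pedigree, filtered, panels = fx$panels, tl = fx$tl,
                classify_fn = fx$classifier)
}

#' Materialize the fixture as standard files
#'
#' Writes `cohort.ped`, `cohort.vcf`, `tl_categories.tsv`,
#' `class_overrides.tsv` and the three panel TSVs to `dir`, so the fixture
#' can be run through the file-based pipeline or external tools.
#'
#' @param dir output directory.
#' @return named list of paths.
#' @export
fixture_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- fpf_fixture()
  ped <- fx$pedigree
  paths <- list(ped = file.path(dir, "cohort.ped"),
                vcf = file.path(dir, "cohort.vcf"),
                tl = file.path(dir, "tl_categories.tsv"),
                classes = file.path(dir, "class_overrides.tsv"),
                panel_a = file.path(dir, "panel_a.tsv"),
                panel_b = file.path(dir, "panel_b.tsv"),
                panel_c = file.path(dir, "panel_c.tsv"))
  ped_out <- data.frame(ped$family_id, ped$id, ped$father, ped$mother,
                        match(ped$sex, c("male", "female")),
                        ifelse(ped$status == "affected", 2L, 1L),
                        ped$age_years)
  utils::write.table(ped_out, paths$ped, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .write_vcf(fx$variants, ped$id, paths$vcf)
  utils::write.table(fx$tl_categories, paths$tl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(key = names(fx$classes),
                                class = unname(fx$classes)),
                     paths$classes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (p in c("a", "b", "c"))
    file.copy(.extdata(paste0("panel_", p, ".tsv")),
              paths[[paste0("panel_", p)]], overwrite = TRUE)
  paths
}
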