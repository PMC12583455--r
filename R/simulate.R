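# Synthetic family-cohort generator: autosomal-dominant pedigrees with a
# planted pathogenic variant entering through one founder, rare background
# variants, and carrier-correlated short telomeres, plus a truth file for
# end-to-end recovery tests. Everything the triage pipeline consumes can be
# produced here, with no external data.

#' Simulator configuration
#'
#' Defaults emulate the study design the triage assumes: a cohort of 13
#' multigenerational families ascertained for familial pulmonary fibrosis,
#' a planted pathogenic loss-of-function variant in a telomere-related
#' Panel A gene in a subset of families, Mendelian autosomal-dominant
#' transmission, late-onset incomplete penetrance, and shorter telomeres in
#' carriers (and, attenuated, in offspring of carriers) than in unrelated
#' non-carriers.
#'
#' @param n_families number of families.
#' @param members_min,members_max family size range (founder couple plus
#'   descendants); must allow >= 2 members.
#' @param planted_fraction fraction of families receiving a planted
#'   variant (default 5/13).
#' @param background_rate mean number of rare tier-0-passing background
#'   variants per individual (Poisson).
#' @param background_af_absent_mass probability a background variant has no
#'   population AF record.
#' @param background_consequence consequence class of background variants
#'   (default missense, i.e. non-LOF).
#' @param background_score_max background in-silico scores are drawn
#'   Uniform(0, this); default 15, below the PP3 threshold.
#' @param penetrance probability that a carrier older than
#'   `penetrance_age` is affected; carriers at or below that age are never
#'   affected (late onset). Default 0.6 over age 50.
#' @param penetrance_age age above which penetrance applies.
#' @param tl_carrier_beta,tl_offspring_beta Beta(shape1, shape2) parameters
#'   for carrier and non-carrier-offspring-of-carrier TL percentiles
#'   (scaled to 0-100); unrelated non-carriers are Uniform(0, 100).
#' @param seed mandatory integer seed; identical seeds give byte-identical
#'   outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_families = 13, members_min = 4, members_max = 8,
                       planted_fraction = 5 / 13,
                       background_rate = 1.5,
                       background_af_absent_mass = 0.2,
                       background_consequence = "missense",
                       background_score_max = 15,
                       penetrance = 0.6, penetrance_age = 50,
                       tl_carrier_beta = c(1.2, 8),
                       tl_offspring_beta = c(2, 6),
                       seed) {
  if (missing(seed) || is.null(seed)) .fail("sim_config requires a seed")
  if (members_min < 2 || members_max < members_min)
    .fail("family size range must allow at least 2 members")
  if (planted_fraction < 0 || planted_fraction > 1)
    .fail("planted_fraction must be in [0, 1]")
  if (background_rate < 0) .fail("background_rate must be >= 0")
  .assert_enum(background_consequence, .consequences, "consequence")
  structure(list(n_families = n_families, members_min = members_min,
                 members_max = members_max,
                 planted_fraction = planted_fraction,
                 background_rate = background_rate,
                 background_af_absent_mass = background_af_absent_mass,
                 background_consequence = background_consequence,
                 background_score_max = background_score_max,
                 penetrance = penetrance, penetrance_age = penetrance_age,
                 tl_carrier_beta = tl_carrier_beta,
                 tl_offspring_beta = tl_offspring_beta,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.gene_coords <- function() {
  utils::read.delim(.extdata("gene_coords.tsv"), stringsAsFactors = FALSE)
}

# one family's pedigree skeleton: founder couple, children, grandchildren
.sim_family <- function(family_id, n_members) {
  id <- function(i) sprintf("%s_I%d", family_id, i)
  n_children <- max(2L, min(n_members - 2L, ceiling((n_members - 2L) * 0.6)))
  n_grand <- n_members - 2L - n_children
  rows <- list(
    data.frame(family_id = family_id, id = id(1), father = "0", mother = "0",
               sex = "male", status = "unaffected",
               age_years = round(stats::runif(1, 70, 90)),
               founder = TRUE, parent = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(family_id = family_id, id = id(2), father = "0", mother = "0",
               sex = "female", status = "unaffected",
               age_years = round(stats::runif(1, 70, 90)),
               founder = TRUE, parent = NA_character_,
               stringsAsFactors = FALSE))
  for (i in seq_len(n_children)) {
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = family_id, id = id(2L + i), father = id(1), mother = id(2),
      sex = sample(c("male", "female"), 1),
      status = "unaffected", age_years = round(stats::runif(1, 40, 65)),
      founder = FALSE, parent = id(1), stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_grand)) {
    par <- id(2L + sample.int(n_children, 1))
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = family_id, id = id(2L + n_children + i), father = par,
      mother = "0", sex = sample(c("male", "female"), 1),
      status = "unaffected", age_years = round(stats::runif(1, 15, 39)),
      founder = FALSE, parent = par, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.random_snv <- function(gene_row) {
  pos <- sample(seq.int(gene_row$start + 1L, gene_row$end), 1L)
  ref <- sample(c("A", "C", "G", "T"), 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(chrom = normalize_chrom(gene_row$chrom), pos = pos, ref = ref,
       alt = alt)
}

#' Simulate a family cohort
#'
#' Generates pedigrees, an annotated variant set, TL data and a truth
#' table. The planted variant enters through founder 1 of each planted
#' family and is transmitted het with probability 1/2 per meiosis;
#' penetrance is applied to carriers over the penetrance age, and planted
#' families are guaranteed at least two affected carriers (the oldest
#' carriers are promoted if penetrance left fewer). Non-planted families
#' get their two oldest members marked affected, mirroring ascertainment of
#' familial disease without a Panel A cause. TL percentiles are drawn from
#' the group models in [sim_config()] and converted to T/S ratios through
#' the written control reference, so that re-normalising them recovers the
#' drawn percentiles.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, `cohort.ped`, `cohort.vcf`,
#'   `tl.tsv`, `tl_reference.tsv`, `truth.tsv` and `provenance.json` are
#'   written there and the paths returned in `$files`.
#' @return list with `pedigree`, `variants` (same shape as
#'   [read_annotated_vcf()] output), `tl_records`, `tl_reference`, `truth`
#'   (data.frame `family_id`, `gene`, `key`, `class`), `meioses`
#'   (data.frame per transmission from a carrier parent), `files`,
#'   `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  coords <- .gene_coords()
  panel_a <- read_panel("bundled:A")
  plant_genes <- panel_a$symbol[panel_a$category == "telomere" &
                                  panel_a$lof_mechanism]
  reference <- default_tl_reference()

  n_fam <- config$n_families
  n_planted <- round(config$planted_fraction * n_fam)
  fam_ids <- if (n_fam > 0) sprintf("SIM%02d", seq_len(n_fam)) else character()
  planted_fams <- utils::head(fam_ids, n_planted)

  peds <- list()
  variants <- list()
  truth <- list()
  carrier_of <- list()   # family -> carrier ids of the planted variant

  for (f in fam_ids) {
    n_members <- sample(seq.int(config$members_min, config$members_max), 1L)
    fam <- .sim_family(f, n_members)
    carriers <- character()
    if (f %in% planted_fams) {
      carrier <- stats::setNames(logical(nrow(fam)), fam$id)
      carrier[fam$id[1L]] <- TRUE  # founder 1 introduces the variant
      for (i in seq_len(nrow(fam))[-(1:2)]) {
        par <- fam$parent[i]
        if (!is.na(par) && carrier[par])
          carrier[fam$id[i]] <- stats::runif(1) < 0.5
      }
      carriers <- fam$id[carrier[fam$id]]
      # late-onset incomplete penetrance; ascertainment guarantees >= 2
      # affected carriers in a planted family
      eligible <- carriers[fam$age_years[match(carriers, fam$id)] >
                             config$penetrance_age]
      affected <- eligible[stats::runif(length(eligible)) < config$penetrance]
      if (length(affected) < 2L) {
        ord <- carriers[order(-fam$age_years[match(carriers, fam$id)])]
        affected <- unique(c(affected, utils::head(ord, 2L)))
      }
      if (length(affected) < 2L) {
        # single-carrier family: second affected is a phenocopy, as in
        # ascertainment of familial disease
        others <- setdiff(fam$id, affected)
        ord <- others[order(-fam$age_years[match(others, fam$id)])]
        affected <- c(affected, utils::head(ord, 2L - length(affected)))
      }
      fam$status[fam$id %in% affected] <- "affected"

      gene <- sample(plant_genes, 1L)
      snv <- .random_snv(coords[coords$gene == gene, ])
      key <- variant_key(snv$chrom, snv$pos, snv$ref, snv$alt)
      variants[[length(variants) + 1L]] <- list(
        chrom = snv$chrom, pos = snv$pos, ref = snv$ref, alt = snv$alt,
        gene = gene, hgvs_c = NA_character_, hgvs_p = NA_character_,
        consequence = "nonsense", af = NA_real_,
        score = round(stats::runif(1, 25, 45), 2), key = key,
        carriers = carriers)
      truth[[length(truth) + 1L]] <- data.frame(
        family_id = f, gene = gene, key = key, class = "P",
        stringsAsFactors = FALSE)
    } else {
      ord <- fam$id[order(-fam$age_years)]
      fam$status[fam$id %in% utils::head(ord, 2L)] <- "affected"
    }
    carrier_of[[f]] <- carriers
    peds[[length(peds) + 1L]] <- fam
  }
  ped <- if (length(peds) > 0) do.call(rbind, peds) else
    data.frame(family_id = character(), id = character(), father = character(),
               mother = character(), sex = character(), status = character(),
               age_years = numeric(), founder = logical(), parent = character(),
               stringsAsFactors = FALSE)

  # background variants: singleton het, rare or AF-absent, non-LOF
  for (i in seq_len(nrow(ped))) {
    n_bg <- stats::rpois(1L, config$background_rate)
    for (j in seq_len(n_bg)) {
      g <- coords[sample.int(nrow(coords), 1L), ]
      snv <- .random_snv(g)
      af <- if (stats::runif(1) < config$background_af_absent_mass) NA_real_
      else round(stats::runif(1, 1e-5, 0.0099), 6)
      variants[[length(variants) + 1L]] <- list(
        chrom = snv$chrom, pos = snv$pos, ref = snv$ref, alt = snv$alt,
        gene = g$gene, hgvs_c = NA_character_, hgvs_p = NA_character_,
        consequence = config$background_consequence, af = af,
        score = round(stats::runif(1, 0, config$background_score_max), 2),
        key = variant_key(snv$chrom, snv$pos, snv$ref, snv$alt),
        carriers = ped$id[i])
    }
  }

  all_ids <- ped$id
  var_df <- if (length(variants) == 0L) {
    d <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), gene = character(),
                    hgvs_c = character(), hgvs_p = character(),
                    consequence = character(), af = numeric(),
                    score = numeric(), key = character(),
                    stringsAsFactors = FALSE)
    d$genotypes <- list()
    d
  } else {
    d <- do.call(rbind, lapply(variants, function(v)
      data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                 gene = v$gene, hgvs_c = v$hgvs_c, hgvs_p = v$hgvs_p,
                 consequence = v$consequence, af = v$af, score = v$score,
                 key = v$key, stringsAsFactors = FALSE)))
    d$genotypes <- lapply(variants, function(v) {
      g <- stats::setNames(rep("ref", length(all_ids)), all_ids)
      g[v$carriers] <- "het"
      g
    })
    ord <- order(d$chrom, d$pos, d$alt)
    d <- d[ord, , drop = FALSE]
    rownames(d) <- NULL
    d
  }

  # telomere percentiles by group, converted to T/S via the reference
  planted_carriers <- unlist(carrier_of, use.names = FALSE)
  has_carrier_parent <- !is.na(ped$parent) & ped$parent %in% planted_carriers
  group <- ifelse(ped$id %in% planted_carriers, "carrier",
                  ifelse(has_carrier_parent, "offspring", "unrelated"))
  pct <- numeric(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    pct[i] <- switch(group[i],
      carrier = 100 * stats::rbeta(1, config$tl_carrier_beta[1],
                                   config$tl_carrier_beta[2]),
      offspring = 100 * stats::rbeta(1, config$tl_offspring_beta[1],
                                     config$tl_offspring_beta[2]),
      unrelated = stats::runif(1, 0, 100))
  }
  age <- pmin(ped$age_years, max(reference$age_hi) - 1)
  bin <- vapply(age, function(a)
    which(reference$age_lo <= a & a < reference$age_hi)[1L], integer(1))
  ts <- reference$mean_ts[bin] + stats::qnorm(pct / 100) * reference$sd_ts[bin]
  tl_records <- data.frame(individual_id = ped$id,
                           ts_ratio = round(pmax(ts, 1e-3), 6),
                           age_years = age, stringsAsFactors = FALSE)

  # meioses: transmissions from a carrier parent (planted families)
  meioses <- data.frame(
    family_id = ped$family_id[has_carrier_parent],
    offspring = ped$id[has_carrier_parent],
    carrier = ped$id[has_carrier_parent] %in% planted_carriers,
    stringsAsFactors = FALSE)

  truth_df <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(family_id = character(), gene = character(), key = character(),
               class = character(), stringsAsFactors = FALSE)

  out <- list(pedigree = ped[c("family_id", "id", "father", "mother", "sex",
                               "status", "age_years")],
              variants = var_df, tl_records = tl_records,
              tl_reference = reference, truth = truth_df, meioses = meioses,
              files = NULL, config = config)
  if (!is.null(dir)) out$files <- write_cohort(out, dir)
  out
}

#' Write a simulated cohort to standard files
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (`ped`, `vcf`, `tl`, `tl_reference`,
#'   `truth`, `provenance`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ped = file.path(dir, "cohort.ped"),
                vcf = file.path(dir, "cohort.vcf"),
                tl = file.path(dir, "tl.tsv"),
                tl_reference = file.path(dir, "tl_reference.tsv"),
                truth = file.path(dir, "truth.tsv"),
                provenance = file.path(dir, "provenance.json"))
  ped <- cohort$pedigree
  ped_out <- data.frame(ped$family_id, ped$id, ped$father, ped$mother,
                        match(ped$sex, c("male", "female")),
                        ifelse(ped$status == "affected", 2L,
                               ifelse(ped$status == "unaffected", 1L, 0L)),
                        ped$age_years)
  ped_out[[5]][is.na(ped_out[[5]])] <- 0L
  utils::write.table(ped_out, paths$ped, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .write_vcf(cohort$variants, ped$id, paths$vcf)
  utils::write.table(cohort$tl_records, paths$tl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$tl_reference, paths$tl_reference, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(seed = cohort$config$seed,
                            config = unclass(cohort$config)),
                       paths$provenance, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}

# minimal VCF 4.2 writer for the simulator's annotated variants; the file
# is read back with read_annotated_vcf() in the pipeline and tests
.write_vcf <- function(variants, sample_ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=fpftiers_simulate_cohort",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=SCORE,Number=A,Type=Float,Description=\"In-silico deleteriousness score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")), con)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- c(paste0("GENE=", v$gene), paste0("CSQ=", v$consequence))
    if (!is.na(v$af)) info <- c(info, paste0("AF=", formatC(v$af, format = "fg")))
    if (!is.na(v$score))
      info <- c(info, paste0("SCORE=", formatC(v$score, format = "fg")))
    g <- v$genotypes[[1L]][sample_ids]
    gt <- c(ref = "0/0", het = "0/1", hom = "1/1", missing = "./.")[g]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                       paste(info, collapse = ";"), "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
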