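# Readers/writers for the external formats the pipeline touches:
# annotated multi-sample VCF, 6-column PED, panel TSV/JSON, TL tables,
# per-base depth + BED targets, and the triage reports.

#' Default INFO field mapping for annotated VCFs
#'
#' Names the INFO keys that hold the gene symbol, consequence term,
#' population allele frequency and in-silico deleteriousness score.
#' Annotation pipelines differ (ANNOVAR, VEP, ...), so the mapping is
#' configurable; these defaults match the files written by
#' [simulate_cohort()].
#'
#' @param gene,consequence,af,score,hgvs_c,hgvs_p INFO key names. `hgvs_c`
#'   and `hgvs_p` are optional transcript/protein descriptions.
#' @return named list of INFO keys.
#' @export
vcf_field_map <- function(gene = "GENE", consequence = "CSQ", af = "AF",
                          score = "SCORE", hgvs_c = "HGVSC", hgvs_p = "HGVSP") {
  list(gene = gene, consequence = consequence, af = af, score = score,
       hgvs_c = hgvs_c, hgvs_p = hgvs_p)
}

#' Consequence vocabulary mapping
#'
#' Loads the bundled (or a user-supplied) table mapping annotation terms
#' (e.g. `stop_gained`, `stopgain`) onto the internal consequence
#' vocabulary: nonsense, missense, frameshift, splice_site, inframe_indel,
#' synonymous, other.
#'
#' @param path optional TSV with columns `term`, `consequence`; default is
#'   the bundled table.
#' @return named character vector term -> consequence.
#' @export
consequence_map <- function(path = NULL) {
  path <- path %||% .extdata("consequence_map.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert_enum(tab$consequence, .consequences, "consequence")
  stats::setNames(tab$consequence, tab$term)
}

.map_consequence <- function(terms, map) {
  out <- unname(map[terms])
  unknown <- is.na(out) & !is.na(terms) & nzchar(terms)
  if (any(unknown)) {
    warning("unknown consequence term(s) mapped to 'other': ",
            paste(unique(terms[unknown]), collapse = ", "), call. = FALSE)
    out[unknown] <- "other"
  }
  out[is.na(out)] <- "other"
  out
}

# light structural validation so parse errors can name a line number
.validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0L)
    .fail("malformed VCF header in ", path, ": no #CHROM line found")
  body <- which(!startsWith(lines, "#"))
  body <- body[body > hdr[1L]]
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield < 8L]
  if (length(bad) > 0L)
    .fail("malformed VCF record at line ", bad[1L], " of ", path,
          ": fewer than 8 tab-separated fields")
  invisible(TRUE)
}

# genotype call for one alt-allele index from VCF GT strings
.gt_call <- function(gt, allele_index) {
  gt <- sub(":.*$", "", gt)
  out <- character(length(gt))
  alleles <- strsplit(gt, "[/|]")
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    if (length(a) == 0L || anyNA(a) || any(a == ".") || all(!nzchar(a))) {
      out[i] <- "missing"
    } else {
      n <- sum(a == as.character(allele_index))
      out[i] <- c("ref", "het", "hom")[min(n, 2L) + 1L]
    }
  }
  out
}

#' Read an annotated multi-sample VCF
#'
#' Parses a VCF 4.x file into one record per (site, alternate allele);
#' multi-allelic sites are decomposed, with per-allele INFO values split on
#' commas when their length matches the allele count. Missing INFO keys
#' yield absent (`NA`) fields. Chromosome labels are normalized
#' ("chr1" and "1" compare equal).
#'
#' @param path VCF file (plain text or bgzipped).
#' @param field_map named list from [vcf_field_map()] naming the INFO keys.
#' @param consequence_table optional consequence vocabulary from
#'   [consequence_map()].
#' @return data.frame with one row per alternate allele: `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `hgvs_c`, `hgvs_p`, `consequence`, `af`, `score`,
#'   `key`, and a `genotypes` list-column of named vectors
#'   (individual id -> "ref"/"het"/"hom"/"missing").
#' @export
read_annotated_vcf <- function(path, field_map = vcf_field_map(),
                               consequence_table = consequence_map()) {
  if (!file.exists(path)) .fail("VCF file not found: ", path)
  .validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      hgvs_c = character(), hgvs_p = character(),
                      consequence = character(), af = numeric(),
                      score = numeric(), key = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    empty$genotypes <- list()
    return(empty)
  }

  info_get <- function(key) {
    if (is.null(key)) return(rep(NA_character_, n))
    vcfR::extract.info(vcf, element = key)
  }
  gene <- info_get(field_map$gene)
  csq <- info_get(field_map$consequence)
  af <- info_get(field_map$af)
  score <- info_get(field_map$score)
  hgvs_c <- info_get(field_map$hgvs_c)
  hgvs_p <- info_get(field_map$hgvs_p)

  has_gt <- ncol(vcf@gt) > 1L
  samples <- if (has_gt) colnames(vcf@gt)[-1L] else character()
  gt_raw <- if (has_gt) vcf@gt[, -1L, drop = FALSE] else NULL

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    n_alt <- length(alts)
    split_or_recycle <- function(x) {
      if (is.na(x)) return(rep(NA_character_, n_alt))
      parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
      if (length(parts) == n_alt) parts else rep(x, n_alt)
    }
    af_i <- split_or_recycle(af[i])
    sc_i <- split_or_recycle(score[i])
    gene_i <- split_or_recycle(gene[i])
    csq_i <- split_or_recycle(csq[i])
    sub <- data.frame(
      chrom = normalize_chrom(fix$CHROM[i]), pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts, gene = gene_i,
      hgvs_c = split_or_recycle(hgvs_c[i]), hgvs_p = split_or_recycle(hgvs_p[i]),
      consequence = .map_consequence(csq_i, consequence_table),
      af = suppressWarnings(as.numeric(af_i)),
      score = suppressWarnings(as.numeric(sc_i)),
      stringsAsFactors = FALSE)
    sub$key <- variant_key(sub$chrom, sub$pos, sub$ref, sub$alt)
    sub$genotypes <- lapply(seq_len(n_alt), function(a) {
      if (!has_gt) return(stats::setNames(character(), character()))
      stats::setNames(.gt_call(unname(gt_raw[i, ]), a), samples)
    })
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  bad_af <- !is.na(out$af) & (out$af < 0 | out$af > 1)
  if (any(bad_af)) .fail("allele frequency outside [0,1] for ",
                         out$key[bad_af][1L])
  rownames(out) <- NULL
  out
}

#' Read a PED pedigree file
#'
#' Standard 6-column PED (family, individual, father, mother, sex,
#' phenotype), whitespace- or tab-delimited, with an optional 7th column
#' giving age in years. Phenotype 2 = affected, 1 = unaffected,
#' 0 / -9 = unknown; sex 1 = male, 2 = female, otherwise unknown.
#'
#' @param path PED file.
#' @return data.frame of individuals: `family_id`, `id`, `father`, `mother`,
#'   `sex`, `status`, `age_years`. Split by `family_id` to get families.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) .fail("PED file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 6L) .fail("PED file must have at least 6 columns, found ",
                            ncol(raw))
  ped <- data.frame(
    family_id = as.character(raw[[1L]]), id = as.character(raw[[2L]]),
    father = as.character(raw[[3L]]), mother = as.character(raw[[4L]]),
    sex = c("male", "female")[match(as.character(raw[[5L]]), c("1", "2"))],
    status = c("unaffected", "affected")[match(as.character(raw[[6L]]),
                                               c("1", "2"))],
    stringsAsFactors = FALSE)
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$status[is.na(ped$status)] <- "unknown"
  ped$age_years <- if (ncol(raw) >= 7L)
    suppressWarnings(as.numeric(raw[[7L]])) else NA_real_
  if (anyDuplicated(ped$id))
    .fail("duplicate individual id(s) in PED: ",
          paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- ref != "0" & !(ref %in% ped$id)
    if (any(bad))
      .fail(col, " id(s) not present in pedigree: ",
            paste(unique(ref[bad]), collapse = ", "))
  }
  ped
}

.read_panel_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::fromJSON(path)
    as.data.frame(tab, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}

#' Read a virtual gene panel
#'
#' Panels are TSV or JSON tables with columns `symbol`, `panel_id` (A/B/C),
#' `category` (telomere / non_telomere), `inheritance` (AD/AR/XLR/AD_AR),
#' `evidence` (definite/strong/moderate/limited) and `lof_mechanism`
#' (logical: loss of function is an established disease mechanism).
#' `"bundled:A"` returns the 14-gene diagnostic FPF panel (8 telomere-related
#' genes); `"bundled:B"` and `"bundled:C"` return illustrative default
#' extended-ILD and telomere-maintenance panels.
#'
#' @param source a file path or `"bundled:A"`, `"bundled:B"`, `"bundled:C"`.
#' @return validated data.frame of panel genes.
#' @export
read_panel <- function(source) {
  if (grepl("^bundled:", source)) {
    id <- sub("^bundled:", "", source)
    if (!id %in% .panel_ids) .fail("unknown bundled panel: ", source)
    path <- .extdata(paste0("panel_", tolower(id), ".tsv"))
  } else {
    if (!file.exists(source)) .fail("panel file not found: ", source)
    path <- source
  }
  tab <- .read_panel_table(path)
  need <- c("symbol", "panel_id", "category", "inheritance", "evidence",
            "lof_mechanism")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    .fail("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$symbol))
    .fail("duplicate gene symbol(s) in panel: ",
          paste(unique(tab$symbol[duplicated(tab$symbol)]), collapse = ", "))
  .assert_enum(tab$panel_id, .panel_ids, "panel_id")
  .assert_enum(tab$category, .panel_categories, "category")
  .assert_enum(tab$inheritance, .panel_inheritance, "inheritance")
  .assert_enum(tab$evidence, .panel_evidence, "evidence")
  tab$lof_mechanism <- as.logical(tab$lof_mechanism)
  if (anyNA(tab$lof_mechanism)) .fail("lof_mechanism must be TRUE/FALSE")
  tab[need]
}

#' Load the three panels and check cross-panel consistency
#'
#' @param panel_a,panel_b,panel_c sources understood by [read_panel()].
#' @return named list of panel data.frames (`A`, `B`, `C`); errors if a gene
#'   symbol appears in more than one panel.
#' @export
read_panels <- function(panel_a = "bundled:A", panel_b = "bundled:B",
                        panel_c = "bundled:C") {
  panels <- list(A = read_panel(panel_a), B = read_panel(panel_b),
                 C = read_panel(panel_c))
  all_sym <- unlist(lapply(panels, `[[`, "symbol"), use.names = FALSE)
  if (anyDuplicated(all_sym))
    .fail("gene symbol(s) present in more than one panel: ",
          paste(unique(all_sym[duplicated(all_sym)]), collapse = ", "))
  panels
}

#' Read telomere-length inputs
#'
#' Reads the per-individual T/S ratio table (`individual_id`, `ts_ratio`,
#' `age_years`; empty T/S values are retained and flagged unknown) and the
#' age-binned control reference (`age_lo`, `age_hi`, `mean_ts`, `sd_ts`,
#' bins half-open `[age_lo, age_hi)`).
#'
#' @param tl_path,ref_path TSV files as described.
#' @return list with `records` and `reference` data.frames.
#' @export
read_tl_inputs <- function(tl_path, ref_path) {
  for (p in c(tl_path, ref_path))
    if (!file.exists(p)) .fail("TL input file not found: ", p)
  rec <- utils::read.delim(tl_path, stringsAsFactors = FALSE)
  need <- c("individual_id", "ts_ratio", "age_years")
  if (!all(need %in% names(rec)))
    .fail("TL table must have columns: ", paste(need, collapse = ", "))
  rec$ts_ratio <- suppressWarnings(as.numeric(rec$ts_ratio))
  if (any(!is.na(rec$ts_ratio) & rec$ts_ratio <= 0))
    .fail("T/S ratios must be positive")
  ref <- tl_reference(ref_path)
  with_ts <- !is.na(rec$ts_ratio) & !is.na(rec$age_years)
  outside <- with_ts & !vapply(rec$age_years, function(a) {
    !is.na(a) && any(ref$age_lo <= a & a < ref$age_hi)
  }, logical(1))
  if (any(outside))
    .fail("age(s) outside all reference bins: ",
          paste(rec$individual_id[outside], collapse = ", "))
  list(records = rec, reference = ref)
}

#' Read / validate a TL control reference
#'
#' @param ref a path to a TSV with columns `age_lo`, `age_hi`, `mean_ts`,
#'   `sd_ts`, or an equivalent data.frame.
#' @return validated reference data.frame ordered by `age_lo`.
#' @export
tl_reference <- function(ref) {
  tab <- if (is.data.frame(ref)) ref else
    utils::read.delim(ref, stringsAsFactors = FALSE)
  need <- c("age_lo", "age_hi", "mean_ts", "sd_ts")
  if (!all(need %in% names(tab)))
    .fail("TL reference must have columns: ", paste(need, collapse = ", "))
  if (any(tab$sd_ts <= 0)) .fail("TL reference sd_ts must be > 0")
  if (any(tab$age_hi <= tab$age_lo)) .fail("TL reference bins must be non-empty")
  tab <- tab[order(tab$age_lo), , drop = FALSE]
  if (nrow(tab) > 1L && any(tab$age_lo[-1L] < tab$age_hi[-nrow(tab)]))
    .fail("TL reference bins overlap")
  rownames(tab) <- NULL
  tab
}

#' Panel-gene coverage QC
#'
#' Computes, for each panel gene, the fraction of its target bases covered
#' at depth >= 10 and >= 20. Targets are BED intervals (0-based half-open);
#' a 4th BED column names the gene, otherwise intervals are assigned to
#' genes via the bundled toy gene-coordinate table. Depth is a per-base
#' table with columns `chrom`, `pos` (1-based), `depth`; target bases absent
#' from it count as depth 0.
#'
#' @param depth_path per-base depth TSV (with header).
#' @param targets_bed BED3/BED4 target file.
#' @param panel panel data.frame from [read_panel()].
#' @return data.frame `gene`, `n_target_bases`, `fraction_ge_10x`,
#'   `fraction_ge_20x`.
#' @export
coverage_summary <- function(depth_path, targets_bed, panel) {
  depth <- utils::read.delim(depth_path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "depth") %in% names(depth)))
    .fail("depth table must have columns chrom, pos, depth")
  depth$chrom <- normalize_chrom(depth$chrom)
  bed <- utils::read.table(targets_bed, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$chrom <- normalize_chrom(bed$chrom)
  if (ncol(bed) >= 4L) {
    bed$gene <- as.character(bed[[4L]])
  } else {
    coords <- utils::read.delim(.extdata("gene_coords.tsv"),
                                stringsAsFactors = FALSE)
    coords$chrom <- normalize_chrom(coords$chrom)
    bed$gene <- NA_character_
    for (i in seq_len(nrow(bed))) {
      hit <- which(coords$chrom == bed$chrom[i] &
                     coords$start < bed$end[i] & bed$start[i] < coords$end)
      if (length(hit) > 0L) bed$gene[i] <- coords$gene[hit[1L]]
    }
  }
  depth_key <- paste(depth$chrom, depth$pos)
  out <- lapply(panel$symbol, function(g) {
    iv <- bed[!is.na(bed$gene) & bed$gene == g, , drop = FALSE]
    pos <- unique(unlist(lapply(seq_len(nrow(iv)), function(i) {
      if (iv$end[i] <= iv$start[i]) return(character())
      paste(iv$chrom[i], seq.int(iv$start[i] + 1L, iv$end[i]))
    })))
    n <- length(pos)
    if (n == 0L) {
      warning("no target bases for gene ", g, "; coverage reported as 0",
              call. = FALSE)
      return(data.frame(gene = g, n_target_bases = 0L,
                        fraction_ge_10x = 0, fraction_ge_20x = 0,
                        stringsAsFactors = FALSE))
    }
    d <- depth$depth[match(pos, depth_key)]
    d[is.na(d)] <- 0
    data.frame(gene = g, n_target_bases = n,
               fraction_ge_10x = mean(d >= 10),
               fraction_ge_20x = mean(d >= 20), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# canonical (JSON-stable) form of one candidate record
.canon_candidate <- function(x) {
  list(family_id = as.character(x$family_id),
       panel_id = as.character(x$panel_id),
       key = as.character(x$key), gene = as.character(x$gene),
       hgvs_c = as.character(x$hgvs_c %||% NA_character_),
       hgvs_p = as.character(x$hgvs_p %||% NA_character_),
       consequence = as.character(x$consequence),
       klass = as.character(x$klass),
       triggered = as.character(x$triggered %||% character()),
       patient_ids = as.character(x$patient_ids),
       unaffected_carrier_ids = as.character(x$unaffected_carrier_ids %||% character()),
       untested_ids = as.character(x$untested_ids %||% character()),
       carrier_tl = as.list(stats::setNames(as.numeric(x$carrier_tl),
                                            names(x$carrier_tl))))
}

.canon_outcome <- function(o) {
  list(family_id = as.character(o$family_id),
       tiers_run = as.character(o$tiers_run),
       stop_reason = as.character(o$stop_reason),
       candidates = lapply(o$candidates, function(tier)
         lapply(tier, .canon_candidate)),
       per_case_counts = lapply(o$per_case_counts, function(x)
         as.list(stats::setNames(as.numeric(x), names(x)))))
}

#' Flatten triage outcomes into a candidate table
#'
#' @param outcomes list of tier outcomes from [triage_family()] /
#'   [triage_cohort()].
#' @return data.frame with one row per candidate record, columns mirroring
#'   the published per-variant table: family, patients, gene, HGVS,
#'   consequence, ACMG class, carrier TL percentile(s), tier.
#' @export
candidate_table <- function(outcomes) {
  rows <- list()
  for (o in outcomes) {
    for (tier in names(o$candidates)) {
      for (cand in o$candidates[[tier]]) {
        tl <- cand$carrier_tl
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = cand$family_id,
          patient_ids = paste(cand$patient_ids, collapse = ","),
          gene = cand$gene, key = cand$key,
          hgvs_c = cand$hgvs_c %||% NA_character_,
          hgvs_p = cand$hgvs_p %||% NA_character_,
          consequence = cand$consequence, acmg_class = cand$klass,
          tl_percentiles = paste(
            ifelse(is.na(tl), "NA", formatC(unlist(tl), format = "fg")),
            collapse = ","),
          unaffected_carriers = paste(cand$unaffected_carrier_ids,
                                      collapse = ","),
          tier = tier, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(family_id = character(), patient_ids = character(),
                      gene = character(), key = character(),
                      hgvs_c = character(), hgvs_p = character(),
                      consequence = character(), acmg_class = character(),
                      tl_percentiles = character(),
                      unaffected_carriers = character(), tier = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write triage reports
#'
#' Writes a flat TSV (one row per candidate record) and/or a nested JSON of
#' the full tier outcomes. The JSON round-trips through
#' [read_triage_report()].
#'
#' @param outcomes list of tier outcomes.
#' @param path output path without extension; `.tsv` / `.json` are appended.
#' @param format "tsv", "json" or "both".
#' @return invisibly, the paths written.
#' @export
write_triage_report <- function(outcomes, path, format = c("both", "tsv", "json")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  written <- character()
  if (format %in% c("both", "tsv")) {
    tsv <- paste0(path, ".tsv")
    utils::write.table(candidate_table(outcomes), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, tsv)
  }
  if (format %in% c("both", "json")) {
    js <- paste0(path, ".json")
    jsonlite::write_json(lapply(outcomes, .canon_outcome), js,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
    written <- c(written, js)
  }
  invisible(written)
}

#' Read a JSON triage report back into tier outcomes
#'
#' @param path a `.json` file written by [write_triage_report()].
#' @return list of tier outcomes in canonical form.
#' @export
read_triage_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(o) {
    o$tiers_run <- as.character(unlist(o$tiers_run))
    o$candidates <- lapply(o$candidates, function(tier) lapply(tier, function(x) {
      x$triggered <- as.character(unlist(x$triggered))
      x$patient_ids <- as.character(unlist(x$patient_ids))
      x$unaffected_carrier_ids <- as.character(unlist(x$unaffected_carrier_ids))
      x$untested_ids <- as.character(unlist(x$untested_ids))
      x$carrier_tl <- lapply(x$carrier_tl, function(v)
        if (is.null(v)) NA_real_ else as.numeric(v))
      x$hgvs_c <- if (is.null(x$hgvs_c)) NA_character_ else x$hgvs_c
      x$hgvs_p <- if (is.null(x$hgvs_p)) NA_character_ else x$hgvs_p
      .canon_candidate(x)
    }))
    o$per_case_counts <- lapply(o$per_case_counts, function(x)
      lapply(x, as.numeric))
    .canon_outcome(o)
  })
}
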