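# shared helpers: small in-code VCF/PED/TSV builders

write_mini_vcf <- function(records, samples = character(),
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"a\">",
    "##INFO=<ID=SCORE,Number=A,Type=Float,Description=\"s\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

write_mini_ped <- function(rows, path = tempfile(fileext = ".ped")) {
  writeLines(rows, path)
  path
}

# a tiny deterministic variant data.frame in the package's internal shape
make_variant <- function(gene = "RTEL1", consequence = "missense",
                         af = NA_real_, score = NA_real_, pos = 63690000L,
                         chrom = "20", ref = "C", alt = "T",
                         genotypes = c(P1 = "het")) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   gene = gene, hgvs_c = NA_character_, hgvs_p = NA_character_,
                   consequence = consequence, af = af, score = score,
                   key = variant_key(chrom, pos, ref, alt),
                   stringsAsFactors = FALSE)
  df$genotypes <- list(genotypes)
  df
}

make_family <- function(family_id = "FAM1",
                        ids = c("P1", "R1"),
                        status = c("affected", "unaffected"),
                        ages = rep(60, length(ids))) {
  data.frame(family_id = family_id, id = ids, father = "0", mother = "0",
             sex = "unknown", status = status, age_years = ages,
             stringsAsFactors = FALSE)
}

make_tl <- function(ids, percentiles) {
  data.frame(individual_id = ids, z = stats::qnorm(percentiles / 100),
             percentile = percentiles, severe = percentiles < 10,
             known = !is.na(percentiles), stringsAsFactors = FALSE)
}
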