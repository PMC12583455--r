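#' @keywords internal
"_PACKAGE"

# enum vocabularies used across the package
.consequences <- c("nonsense", "missense", "frameshift", "splice_site",
                   "inframe_indel", "synonymous", "other")
.genotype_levels <- c("ref", "het", "hom", "missing")
.acmg_classes <- c("B", "LB", "VUS_LB", "VUS", "VUS_LP", "LP", "P")
.panel_ids <- c("A", "B", "C")
.panel_categories <- c("telomere", "non_telomere")
.panel_inheritance <- c("AD", "AR", "XLR", "AD_AR")
.panel_evidence <- c("definite", "strong", "moderate", "limited")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix so that "chr1" and "1" compare equal, and
#' maps "chrM"/"MT" to "MT". Used everywhere chromosome labels are joined.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x %in% c("M", "MT", "m")] <- "MT"
  x
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt vectors describing one alternate allele each.
#' @return character vector "chrom:pos:ref:alt" with normalized chromosome.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

# stop with a consistent error class so callers/tests can distinguish
# pipeline validation failures from programming errors
.fail <- function(..., class = "fpftiers_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.assert_enum <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0L)
    .fail("unknown ", what, " value(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "fpftiers")
  if (!nzchar(path)) .fail("bundled file not found: ", file)
  path
}
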