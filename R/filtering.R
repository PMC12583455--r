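# Tier-0 variant filter: population rarity + protein-level consequence,
# applied once before any panel logic.

#' Tier-0 filter configuration
#'
#' Variants are retained when their population allele frequency is absent
#' or strictly below `af_threshold` (strict: AF exactly at the threshold is
#' excluded) AND their consequence is one of `retained_consequences`.
#' Absent AF is treated as absent-from-reference-population, i.e. it passes
#' the rarity test; novel variants must not be dropped.
#'
#' @param af_threshold allele-frequency cut-off in (0, 1]; default 0.01.
#' @param retained_consequences consequence classes kept for analysis;
#'   the default covers the non-synonymous coding spectrum, including
#'   splice-site variants.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(af_threshold = 0.01,
                          retained_consequences = c("nonsense", "missense",
                                                    "frameshift", "splice_site",
                                                    "inframe_indel")) {
  if (!is.numeric(af_threshold) || length(af_threshold) != 1L ||
      is.na(af_threshold) || af_threshold <= 0 || af_threshold > 1)
    .fail("af_threshold must be a single number in (0, 1]")
  .assert_enum(retained_consequences, .consequences, "consequence")
  if (length(retained_consequences) == 0L)
    .fail("retained_consequences must be non-empty")
  structure(list(af_threshold = af_threshold,
                 retained_consequences = unique(retained_consequences)),
            class = "filter_config")
}

#' Apply the tier-0 filter
#'
#' Total and order-preserving: a variant is retained iff
#' `(af absent or af < af_threshold) AND consequence %in%
#' retained_consequences`. The input is not modified.
#'
#' @param variants variant data.frame from [read_annotated_vcf()].
#' @param config a [filter_config()].
#' @return the retained subset of `variants`.
#' @export
filter_variants <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(variants) == 0L) return(variants)
  rare <- is.na(variants$af) | variants$af < config$af_threshold
  kept <- rare & variants$consequence %in% config$retained_consequences
  out <- variants[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}
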