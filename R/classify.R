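# ACMG/AMP evidence derivation and combining-rules classification,
# including the VUS-LP / VUS-LB subclasses and the telomere-length
# supporting criterion for telomere-category panel genes.

.acmg_codes <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                 "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
.strengths <- c("stand_alone", "very_strong", "strong", "moderate", "supporting")

#' Default strength class of an ACMG criterion code
#'
#' @param code character vector of criterion codes (PVS1, PS1..PS4,
#'   PM1..PM6, PP1..PP5, BA1, BS1..BS4, BP1..BP7).
#' @return character vector of strength classes.
#' @export
acmg_default_strength <- function(code) {
  .assert_enum(code, .acmg_codes, "ACMG criterion code")
  out <- rep(NA_character_, length(code))
  out[code == "PVS1"] <- "very_strong"
  out[grepl("^PS", code)] <- "strong"
  out[grepl("^PM", code)] <- "moderate"
  out[grepl("^PP", code)] <- "supporting"
  out[code == "BA1"] <- "stand_alone"
  out[grepl("^BS", code)] <- "strong"
  out[grepl("^BP", code)] <- "supporting"
  out
}

#' Construct evidence assertions
#'
#' @param code criterion codes.
#' @param strength_class optional per-assertion strength overrides; defaults
#'   to [acmg_default_strength()].
#' @param source "auto" (engine-derived) or "manual" (curator-supplied).
#' @return data.frame with one row per assertion; at most one per code.
#' @export
evidence <- function(code, strength_class = NULL, source = "auto") {
  if (length(code) == 0L)
    return(data.frame(code = character(), strength_class = character(),
                      source = character(), stringsAsFactors = FALSE))
  .assert_enum(code, .acmg_codes, "ACMG criterion code")
  strength_class <- strength_class %||% acmg_default_strength(code)
  .assert_enum(strength_class, .strengths, "strength class")
  if (anyDuplicated(code)) .fail("duplicate assertion for code(s): ",
                                 paste(unique(code[duplicated(code)]),
                                       collapse = ", "))
  data.frame(code = code, strength_class = strength_class,
             source = rep(source, length.out = length(code)),
             stringsAsFactors = FALSE)
}

#' Merge manual assertions over automatic ones
#'
#' Manual (curator) assertions take precedence over auto-derived assertions
#' with the same code; family-level human evidence the engine cannot see
#' enters this way.
#'
#' @param auto,manual assertion data.frames from [evidence()].
#' @return merged assertion data.frame.
#' @export
merge_evidence <- function(auto, manual) {
  if (is.null(manual) || nrow(manual) == 0L) return(auto)
  keep <- !(auto$code %in% manual$code)
  out <- rbind(auto[keep, , drop = FALSE], manual)
  rownames(out) <- NULL
  out
}

#' Classification thresholds
#'
#' @param pm2_af allele-frequency bound for PM2 (absent from controls);
#'   absent AF always qualifies. Default 1e-4.
#' @param pp3_score in-silico score (CADD-phred-like) at or above which PP3
#'   fires. Default 20.
#' @param tl_support_code criterion code used for the severe-telomere-
#'   shortening supporting criterion (supporting strength, telomere-category
#'   genes only). Default "PP4".
#' @return list of thresholds.
#' @export
classify_thresholds <- function(pm2_af = 1e-4, pp3_score = 20,
                                tl_support_code = "PP4") {
  .assert_enum(tl_support_code, .acmg_codes, "ACMG criterion code")
  list(pm2_af = pm2_af, pp3_score = pp3_score,
       tl_support_code = tl_support_code)
}

#' Derive automatic ACMG evidence for one variant
#'
#' Emits: PVS1 when the consequence is loss-of-function (nonsense,
#' frameshift, splice site) and loss of function is an established disease
#' mechanism for the gene; PM2 when the population AF is absent or below
#' `pm2_af`; PP3 when the in-silico score reaches `pp3_score`; and the
#' severe-telomere-shortening supporting criterion (supporting strength)
#' when the gene is telomere-category and the carrier shows severe TL
#' shortening. Severe TL alone is never enough to leave VUS.
#'
#' @param variant one-row variant data.frame (or list) with `consequence`,
#'   `af`, `score`.
#' @param panel_gene one-row panel data.frame with `category`,
#'   `lof_mechanism`.
#' @param carrier_tl optional TL result (list/row with `severe`, `known`).
#' @param thresholds a [classify_thresholds()] list.
#' @return assertion data.frame.
#' @export
derive_auto_evidence <- function(variant, panel_gene, carrier_tl = NULL,
                                 thresholds = classify_thresholds()) {
  codes <- character()
  lof <- variant$consequence %in% c("nonsense", "frameshift", "splice_site")
  if (isTRUE(lof) && isTRUE(panel_gene$lof_mechanism)) codes <- c(codes, "PVS1")
  af <- variant$af
  if (is.null(af) || length(af) == 0L || is.na(af) || af < thresholds$pm2_af)
    codes <- c(codes, "PM2")
  score <- variant$score
  if (!is.null(score) && length(score) == 1L && !is.na(score) &&
      score >= thresholds$pp3_score)
    codes <- c(codes, "PP3")
  if (identical(panel_gene$category, "telomere") && !is.null(carrier_tl) &&
      isTRUE(carrier_tl$known) && isTRUE(carrier_tl$severe) &&
      !thresholds$tl_support_code %in% codes)
    codes <- c(codes, thresholds$tl_support_code)
  ev <- evidence(codes)
  # the TL criterion is supporting-level regardless of the code chosen
  ev$strength_class[ev$code == thresholds$tl_support_code] <- "supporting"
  ev
}

# counts of assertions by direction and strength class
.evidence_counts <- function(assertions) {
  path <- grepl("^P", assertions$code)
  s <- assertions$strength_class
  list(pvs = sum(path & s == "very_strong"),
       ps = sum(path & s == "strong"),
       pm = sum(path & s == "moderate"),
       pp = sum(path & s == "supporting"),
       ba = sum(!path & s == "stand_alone"),
       bs = sum(!path & s == "strong"),
       bp = sum(!path & s == "supporting"))
}

#' Combine ACMG evidence into a base classification
#'
#' Implements the published ACMG/AMP combining tables for Pathogenic,
#' Likely Pathogenic, Benign and Likely Benign over assertion strength
#' counts (so curator strength overrides are honoured). When a pathogenic
#' rule and a benign rule fire simultaneously the evidence is conflicting
#' and the result is VUS; when no rule fires the result is VUS. VUS results
#' are usually passed on to [subclassify_vus()]; see [classify_variant()].
#'
#' @param assertions assertion data.frame from [evidence()].
#' @return list with `klass` (one of P, LP, VUS, LB, B) and `triggered`
#'   (the assertion codes).
#' @export
combine_acmg <- function(assertions) {
  n <- .evidence_counts(assertions)
  pathogenic <-
    (n$pvs >= 1 && (n$ps >= 1 || n$pm >= 2 || (n$pm >= 1 && n$pp >= 1) ||
                      n$pp >= 2)) ||
    n$ps >= 2 ||
    (n$ps >= 1 && (n$pm >= 3 || (n$pm >= 2 && n$pp >= 2) ||
                     (n$pm >= 1 && n$pp >= 4)))
  likely_pathogenic <-
    (n$pvs >= 1 && n$pm >= 1) ||
    (n$ps >= 1 && n$pm >= 1) ||
    (n$ps >= 1 && n$pp >= 2) ||
    n$pm >= 3 ||
    (n$pm >= 2 && n$pp >= 2) ||
    (n$pm >= 1 && n$pp >= 4)
  benign <- n$ba >= 1 || n$bs >= 2
  likely_benign <- (n$bs >= 1 && n$bp >= 1) || n$bp >= 2
  path_fires <- pathogenic || likely_pathogenic
  benign_fires <- benign || likely_benign
  klass <- if (path_fires && benign_fires) "VUS"
  else if (pathogenic) "P"
  else if (likely_pathogenic) "LP"
  else if (benign) "B"
  else if (likely_benign) "LB"
  else "VUS"
  list(klass = klass, triggered = assertions$code)
}

#' Subclassify a VUS into VUS-LP / VUS-LB
#'
#' Policy (configurable by replacing this function in the classifier):
#' VUS-LP when there is at least one moderate-or-stronger pathogenic
#' assertion, or at least two supporting pathogenic assertions, and no
#' benign assertion; VUS-LB is the mirror image (any stand-alone/strong
#' benign assertion or two supporting benign, and no pathogenic assertion);
#' otherwise plain VUS.
#'
#' @param assertions assertion data.frame.
#' @param base_klass must be "VUS"; other classes are returned unchanged.
#' @return list with `klass` and `triggered`.
#' @export
subclassify_vus <- function(assertions, base_klass = "VUS") {
  if (!identical(base_klass, "VUS"))
    return(list(klass = base_klass, triggered = assertions$code))
  n <- .evidence_counts(assertions)
  any_path <- (n$pvs + n$ps + n$pm + n$pp) > 0
  any_benign <- (n$ba + n$bs + n$bp) > 0
  klass <- if (((n$pvs + n$ps + n$pm) >= 1 || n$pp >= 2) && !any_benign)
    "VUS_LP"
  else if ((n$ba >= 1 || n$bs >= 1 || n$bp >= 2) && !any_path)
    "VUS_LB"
  else "VUS"
  list(klass = klass, triggered = assertions$code)
}

#' Classify one assertion set (combine + VUS subclassification)
#'
#' @param assertions assertion data.frame.
#' @return list with `klass` (one of B, LB, VUS_LB, VUS, VUS_LP, LP, P) and
#'   `triggered`.
#' @export
classify_variant <- function(assertions) {
  base <- combine_acmg(assertions)
  if (base$klass == "VUS") subclassify_vus(assertions) else base
}

#' Build a classifier function for the triage engine
#'
#' Returns `function(variant, panel_gene, carrier_tl)` -> classification.
#' Automatic evidence is derived per variant, manual curator assertions
#' (keyed by variant key) override auto assertions with the same code, and
#' hard class overrides (curated final classes, e.g. transcribed from a
#' published table) short-circuit the engine entirely.
#'
#' @param thresholds a [classify_thresholds()] list.
#' @param manual optional data.frame `key`, `code`, `strength_class`
#'   (optional), `note` (ignored) of curator assertions.
#' @param class_overrides optional named character vector key -> class.
#' @return classifier closure.
#' @export
acmg_classifier <- function(thresholds = classify_thresholds(), manual = NULL,
                            class_overrides = NULL) {
  if (!is.null(manual)) {
    .assert_enum(manual$code, .acmg_codes, "ACMG criterion code")
    if (is.null(manual$strength_class))
      manual$strength_class <- acmg_default_strength(manual$code)
    manual$strength_class[is.na(manual$strength_class)] <-
      acmg_default_strength(manual$code[is.na(manual$strength_class)])
  }
  if (!is.null(class_overrides))
    .assert_enum(class_overrides, .acmg_classes, "ACMG class")
  function(variant, panel_gene, carrier_tl = NULL) {
    if (!is.null(class_overrides) && variant$key %in% names(class_overrides))
      return(list(klass = unname(class_overrides[[variant$key]]),
                  triggered = character()))
    auto <- derive_auto_evidence(variant, panel_gene, carrier_tl, thresholds)
    man <- NULL
    if (!is.null(manual)) {
      rows <- manual[manual$key == variant$key, , drop = FALSE]
      if (nrow(rows) > 0L)
        man <- evidence(rows$code, rows$strength_class, source = "manual")
    }
    classify_variant(merge_evidence(auto, man))
  }
}

#' Read a curator assertion file
#'
#' TSV with columns `key` (chrom:pos:ref:alt), `code`, optional
#' `strength_class`, optional `note`.
#'
#' @param path TSV path.
#' @return data.frame suitable for [acmg_classifier()]'s `manual` argument.
#' @export
read_curator_file <- function(path) {
  if (!file.exists(path)) .fail("curator file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("key", "code") %in% names(tab)))
    .fail("curator file must have columns key, code")
  tab
}
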