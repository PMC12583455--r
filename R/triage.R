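# The core algorithm: per-family sequential application of Panels A, B, C,
# gated by ACMG class (P/LP halts escalation) and by severe telomere
# shortening in an affected member (Panel C gate), followed by asymptomatic-
# carrier detection and family-level diagnostic yield.

.excluded_classes <- c("B", "LB", "VUS_LB")
.halting_classes <- c("P", "LP")

# carrier status from a genotype call
.is_carrier <- function(gt) gt %in% c("het", "hom")

#' Detect asymptomatic carriers of a candidate variant
#'
#' @param genotypes named genotype vector (individual -> call) of the
#'   candidate variant.
#' @param family one family's pedigree data.frame (rows of
#'   [read_pedigree()] output).
#' @return list with `carriers` (unaffected het/hom ids) and `untested`
#'   (unaffected ids with a missing or absent genotype).
#' @export
detect_asymptomatic_carriers <- function(genotypes, family) {
  unaff <- family$id[family$status == "unaffected"]
  gt <- genotypes[unaff]
  names(gt) <- unaff
  carriers <- unaff[!is.na(gt) & .is_carrier(gt)]
  untested <- unaff[is.na(gt) | gt == "missing"]
  list(carriers = carriers, untested = untested)
}

# most severe TL result among a set of ids; NULL when none known
.worst_tl <- function(ids, tl) {
  if (is.null(tl) || length(ids) == 0L) return(NULL)
  rows <- tl[tl$individual_id %in% ids & tl$known, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  as.list(rows[which.min(rows$percentile), ])
}

.tl_lookup <- function(ids, tl) {
  if (is.null(tl)) return(stats::setNames(rep(NA_real_, length(ids)), ids))
  known <- tl$individual_id[tl$known]
  p <- tl$percentile[match(ids, tl$individual_id)]
  p[!ids %in% known] <- NA_real_
  stats::setNames(p, ids)
}

#' Triage one family through the tiered panels
#'
#' Panel A is always analysed: tier-0-filtered variants in Panel A genes
#' carried (het/hom) by at least one affected member are classified; B, LB
#' and VUS-LB calls are excluded from the candidate list. If any candidate
#' is P or LP the analysis stops (`plp_found_A`). Otherwise Panel B is
#' analysed the same way (`plp_found_B` on success). Panel C is analysed
#' only when no P/LP was found at A or B AND at least one affected member
#' shows severe telomere shortening; otherwise the family stops with
#' `no_severe_tl`. VUS-level findings (including VUS-LP) never halt
#' escalation.
#'
#' @param family one family's pedigree data.frame; must contain at least
#'   one affected member.
#' @param variants tier-0-filtered variant data.frame.
#' @param panels named list of panel data.frames (`A`, `B`, `C`) from
#'   [read_panels()].
#' @param tl optional TL results data.frame ([tl_results()] or
#'   [tl_results_from_categories()]).
#' @param classify_fn classifier from [acmg_classifier()].
#' @return a tier outcome: list with `family_id`, `tiers_run`,
#'   `stop_reason`, `candidates` (per tier), `per_case_counts` (per tier,
#'   per affected case: number of carried panel variants retained for
#'   interpretation).
#' @export
triage_family <- function(family, variants, panels, tl = NULL,
                          classify_fn = acmg_classifier()) {
  affected <- family$id[family$status == "affected"]
  if (length(affected) == 0L)
    .fail("family ", family$family_id[1L], " has no affected member")
  family_id <- family$family_id[1L]

  outcome <- list(family_id = family_id, tiers_run = character(),
                  stop_reason = NA_character_,
                  candidates = list(), per_case_counts = list())

  severe_affected <- FALSE
  if (!is.null(tl)) {
    rows <- tl[tl$individual_id %in% affected & tl$known, , drop = FALSE]
    severe_affected <- any(rows$severe)
  }

  for (tier in c("A", "B", "C")) {
    if (tier == "C" && !severe_affected) {
      outcome$stop_reason <- "no_severe_tl"
      break
    }
    panel <- panels[[tier]]
    outcome$tiers_run <- c(outcome$tiers_run, tier)
    in_panel <- variants$gene %in% panel$symbol
    tier_variants <- variants[in_panel, , drop = FALSE]

    # per-affected-case retained variant counts (carried, post tier-0)
    counts <- vapply(affected, function(id) {
      sum(vapply(tier_variants$genotypes, function(g)
        .is_carrier(g[id] %||% NA_character_), logical(1)))
    }, numeric(1))
    outcome$per_case_counts[[tier]] <- counts

    cands <- list()
    halted <- FALSE
    for (i in seq_len(nrow(tier_variants))) {
      v <- tier_variants[i, , drop = FALSE]
      gts <- v$genotypes[[1L]]
      fam_gts <- gts[names(gts) %in% family$id]
      patient_ids <- affected[.is_carrier(fam_gts[affected])]
      patient_ids <- patient_ids[!is.na(patient_ids)]
      if (length(patient_ids) == 0L) next
      pg <- panel[panel$symbol == v$gene, , drop = FALSE]
      cls <- classify_fn(as.list(v[1L, setdiff(names(v), "genotypes")]),
                         as.list(pg[1L, ]), .worst_tl(patient_ids, tl))
      if (cls$klass %in% .excluded_classes) next
      if (cls$klass %in% .halting_classes) halted <- TRUE
      asym <- detect_asymptomatic_carriers(fam_gts, family)
      cands[[length(cands) + 1L]] <- list(
        family_id = family_id, panel_id = tier, key = v$key,
        gene = v$gene, hgvs_c = v$hgvs_c, hgvs_p = v$hgvs_p,
        consequence = v$consequence, klass = cls$klass,
        triggered = cls$triggered, patient_ids = patient_ids,
        unaffected_carrier_ids = asym$carriers, untested_ids = asym$untested,
        carrier_tl = .tl_lookup(patient_ids, tl))
    }
    outcome$candidates[[tier]] <- cands
    if (halted) {
      outcome$stop_reason <- paste0("plp_found_", tier)
      break
    }
    if (tier == "C") outcome$stop_reason <- "completed_C"
  }
  # a P/LP at tier C still ends as completed_C (C is the final tier)
  if (identical(outcome$stop_reason, "plp_found_C"))
    outcome$stop_reason <- "completed_C"
  outcome
}

#' Family-level diagnostic yield
#'
#' Fraction of families in which at least one candidate record carries a
#' class in `relevant_classes`, with a Wilson score confidence interval.
#' The family is the unit of yield.
#'
#' @param outcomes list of tier outcomes.
#' @param relevant_classes subset of P, LP, VUS_LP.
#' @param n_families denominator; defaults to `length(outcomes)`.
#' @param confidence CI level.
#' @return list `k`, `n`, `fraction`, `percent` (1 decimal), `ci`
#'   (fractions), `ci_percent`.
#' @export
diagnostic_yield <- function(outcomes, relevant_classes = c("P", "LP"),
                             n_families = NULL, confidence = 0.95) {
  .assert_enum(relevant_classes, c("P", "LP", "VUS_LP"), "relevant class")
  n <- n_families %||% length(outcomes)
  if (n == 0L) .fail("diagnostic yield undefined for 0 families")
  hit <- vapply(outcomes, function(o) {
    any(vapply(unlist(o$candidates, recursive = FALSE),
               function(cand) cand$klass %in% relevant_classes, logical(1)))
  }, logical(1))
  k <- sum(hit)
  ci <- wilson_ci(k, n, confidence)
  list(k = k, n = n, fraction = k / n, percent = round(100 * k / n, 1),
       ci = ci, ci_percent = round(100 * ci, 1))
}

#' Triage a whole cohort
#'
#' Runs [triage_family()] for every family in the pedigree and assembles
#' the cohort-level result: candidate table, diagnostic yields for the
#' conservative (P/LP) and extended (P/LP/VUS-LP) relevant-class sets, and
#' (when TL data are present) the TL-carrier association statistics.
#'
#' @param pedigree pedigree data.frame from [read_pedigree()].
#' @param variants tier-0-filtered variant data.frame.
#' @param panels named list from [read_panels()].
#' @param tl optional TL results data.frame.
#' @param classify_fn classifier from [acmg_classifier()].
#' @return object of class `fpf_triage`: list with `outcomes`, `candidates`
#'   (data.frame), `yield_plp`, `yield_plp_vuslp`, `tl_association`
#'   (or NULL), `n_families`, `pedigree`, `tl`.
#' @export
triage_cohort <- function(pedigree, variants, panels = read_panels(),
                          tl = NULL, classify_fn = acmg_classifier()) {
  fams <- split(pedigree, pedigree$family_id)
  outcomes <- lapply(fams, triage_family, variants = variants,
                     panels = panels, tl = tl, classify_fn = classify_fn)
  names(outcomes) <- names(fams)
  res <- list(outcomes = outcomes, candidates = candidate_table(outcomes),
              yield_plp = diagnostic_yield(outcomes, c("P", "LP")),
              yield_plp_vuslp = diagnostic_yield(outcomes,
                                                 c("P", "LP", "VUS_LP")),
              tl_association = NULL, n_families = length(outcomes),
              pedigree = pedigree, tl = tl)
  if (!is.null(tl) && any(tl$known))
    res$tl_association <- tryCatch(
      tl_association(pedigree, outcomes, tl, scope = "all"),
      error = function(e) NULL)
  class(res) <- "fpf_triage"
  res
}

#' @export
print.fpf_triage <- function(x, ...) {
  cat("Tiered virtual-gene-panel triage\n")
  cat(sprintf("  families: %d   candidate records: %d\n",
              x$n_families, nrow(x$candidates)))
  reasons <- vapply(x$outcomes, `[[`, character(1), "stop_reason")
  for (r in sort(unique(reasons)))
    cat(sprintf("  %-14s %d families\n", r, sum(reasons == r)))
  cat(sprintf("  diagnostic yield (P/LP):        %.1f%% (95%% CI %.1f-%.1f)\n",
              x$yield_plp$percent, x$yield_plp$ci_percent[1],
              x$yield_plp$ci_percent[2]))
  cat(sprintf("  diagnostic yield (+VUS-LP):     %.1f%% (95%% CI %.1f-%.1f)\n",
              x$yield_plp_vuslp$percent, x$yield_plp_vuslp$ci_percent[1],
              x$yield_plp_vuslp$ci_percent[2]))
  invisible(x)
}

#' @export
summary.fpf_triage <- function(object, ...) {
  print(object)
  cat("\nPer-tier retained variants per affected case:\n")
  for (tier in c("A", "B", "C")) {
    s <- tier_variant_summary(object$outcomes, tier)
    if (s$n == 0L) next
    cat(sprintf("  Panel %s: mean %.2f (SD %.2f), range %g-%g over %d cases\n",
                tier, s$mean, s$sd, s$min, s$max, s$n))
  }
  if (!is.null(object$tl_association)) {
    ta <- object$tl_association
    cat("\nTL association (all individuals with TL data):\n")
    cat(sprintf("  severe carriers %d/%d vs non-severe carriers %d/%d, Fisher p = %.3g\n",
                ta$table[1, 1], sum(ta$table[1, ]),
                ta$table[2, 1], sum(ta$table[2, ]), ta$fisher_p))
  }
  cat("\nCandidates:\n")
  print(object$candidates[, c("family_id", "gene", "hgvs_c", "acmg_class",
                              "tl_percentiles", "tier")], row.names = FALSE)
  invisible(object)
}
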