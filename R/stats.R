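# Statistical layer: exact two-sided Fisher test by hypergeometric
# enumeration, Welch t, Wilson score interval, the TL-carrier association
# tables, and per-tier descriptive summaries.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood convention: with the
#' margins fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7). A table with an empty row or column has a single
#' attainable configuration and p = 1.
#'
#' @param table 2x2 integer matrix (or vector a, b, c, d by row).
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.integer(table)
  if (length(x) != 4L || any(is.na(x)) || any(x < 0))
    .fail("need a 2x2 table of nonnegative counts")
  if (sum(x) < 1L) .fail("table total must be >= 1")
  m <- if (is.matrix(table)) matrix(x, 2L, 2L)
  else matrix(x, 2L, 2L, byrow = TRUE)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  support <- max(0L, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' computed with `stats::t.test(var.equal = FALSE)`. Sign convention:
#' `t < 0` when `mean(x) < mean(y)`.
#'
#' @param x,y numeric samples of size >= 2; at least one group must have
#'   nonzero variance.
#' @return list `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    .fail("Welch t-test needs at least 2 observations per group")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    .fail("Welch t-test needs nonzero variance in at least one group")
  fit <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param confidence CI level (default 0.95).
#' @return numeric `c(lo, hi)` with `lo <= k/n <= hi`.
#' @export
wilson_ci <- function(k, n, confidence = 0.95) {
  if (n < 1L || k < 0L || k > n) .fail("need 0 <= k <= n, n >= 1")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # boundary cases are exact by construction; avoid float residue
  lo <- if (k == 0L) 0 else max(0, center - half)
  hi <- if (k == n) 1 else min(1, center + half)
  c(lo, hi)
}

# ids carrying a relevant-class candidate (patients and unaffected carriers)
.relevant_carriers <- function(outcomes,
                               relevant = c("P", "LP", "VUS_LP"),
                               telomere_only = FALSE, panels = NULL) {
  ids <- character()
  fams <- character()
  for (o in outcomes) {
    for (cand in unlist(o$candidates, recursive = FALSE)) {
      if (!cand$klass %in% relevant) next
      if (telomere_only && !is.null(panels)) {
        all_panels <- do.call(rbind, panels)
        cat_ <- all_panels$category[match(cand$gene, all_panels$symbol)]
        if (!identical(cat_, "telomere")) next
      }
      ids <- c(ids, cand$patient_ids, cand$unaffected_carrier_ids)
      fams <- c(fams, cand$family_id)
    }
  }
  list(ids = unique(ids), families = unique(fams))
}

#' Telomere-length / carrier-status association
#'
#' Builds the 2x2 table of severe TL shortening (rows: severe vs not)
#' against relevant-variant carrier status (columns: carrier vs not) over
#' the chosen scope, tests it with [fisher_exact_2x2()], and compares TL
#' percentile means between carriers and non-carriers, and between members
#' of families with and without a relevant telomere-gene variant, with
#' [welch_t_test()]. Relevant classes are P, LP and VUS-LP. Only
#' individuals with known TL enter the table.
#'
#' @param pedigree pedigree data.frame.
#' @param outcomes list of tier outcomes.
#' @param tl TL results data.frame.
#' @param scope "patients" (affected only) or "all".
#' @param panels panel list, used to identify telomere-category genes for
#'   the family-level comparison.
#' @return list `table` (2x2 matrix), `fisher_p`, `carrier_mean`,
#'   `noncarrier_mean`, `welch` (or NULL if degenerate),
#'   `family_welch` (or NULL), `scope`.
#' @export
tl_association <- function(pedigree, outcomes, tl,
                           scope = c("all", "patients"),
                           panels = read_panels()) {
  scope <- match.arg(scope)
  ids <- if (scope == "patients")
    pedigree$id[pedigree$status == "affected"] else pedigree$id
  known <- tl[tl$known & tl$individual_id %in% ids, , drop = FALSE]
  if (nrow(known) == 0L) {
    warning("no individuals with known TL in scope; degenerate table",
            call. = FALSE)
    return(list(table = matrix(0L, 2, 2), fisher_p = 1,
                carrier_mean = NA_real_, noncarrier_mean = NA_real_,
                welch = NULL, family_welch = NULL, scope = scope))
  }
  rel <- .relevant_carriers(outcomes)
  carrier <- known$individual_id %in% rel$ids
  severe <- known$severe
  tab <- matrix(c(sum(severe & carrier), sum(severe & !carrier),
                  sum(!severe & carrier), sum(!severe & !carrier)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("severe", "not_severe"),
                                c("carrier", "non_carrier")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    warning("degenerate margin in TL association table; Fisher p = 1",
            call. = FALSE)
  p <- fisher_exact_2x2(tab)
  carrier_mean <- mean(known$percentile[carrier])
  noncarrier_mean <- mean(known$percentile[!carrier])
  welch <- tryCatch(
    welch_t_test(known$percentile[carrier], known$percentile[!carrier]),
    error = function(e) NULL)
  tel <- .relevant_carriers(outcomes, telomere_only = TRUE, panels = panels)
  fam_of <- pedigree$family_id[match(known$individual_id, pedigree$id)]
  in_pos_family <- fam_of %in% tel$families
  family_welch <- tryCatch(
    welch_t_test(known$percentile[in_pos_family],
                 known$percentile[!in_pos_family]),
    error = function(e) NULL)
  list(table = tab, fisher_p = p, carrier_mean = carrier_mean,
       noncarrier_mean = noncarrier_mean, welch = welch,
       family_welch = family_welch, scope = scope)
}

#' Per-tier descriptive summary of retained variant counts
#'
#' Mean, sample SD (n - 1 denominator), and range of the number of
#' variants retained for interpretation per affected case at the given
#' tier, across families that ran the tier.
#'
#' @param outcomes list of tier outcomes.
#' @param tier "A", "B" or "C".
#' @return list `n`, `mean`, `sd`, `min`, `max`, `sd_defined` (`FALSE`
#'   when fewer than 2 cases: SD is then reported as 0).
#' @export
tier_variant_summary <- function(outcomes, tier) {
  counts <- unlist(lapply(outcomes, function(o) o$per_case_counts[[tier]]))
  if (length(counts) == 0L)
    return(list(n = 0L, mean = NA_real_, sd = NA_real_, min = NA_real_,
                max = NA_real_, sd_defined = FALSE))
  sd_def <- length(counts) >= 2L
  list(n = length(counts), mean = mean(counts),
       sd = if (sd_def) stats::sd(counts) else 0,
       min = min(counts), max = max(counts), sd_defined = sd_def)
}
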