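# Telomere-length normalisation: Z-scores against age-matched controls,
# percentile conversion, and the severe-shortening flag that gates Panel C
# and the supporting pathogenic criterion.

#' Telomere-length Z-score
#'
#' Compares an individual's T/S ratio (qPCR telomere-to-single-copy-gene
#' signal) to the age-matched control mean and SD:
#' `z = (ts_ratio - bin_mean) / bin_sd`. Reference bins are half-open
#' `[age_lo, age_hi)`.
#'
#' @param ts_ratio positive T/S ratio (NA allowed: unknown).
#' @param age_years age of the individual.
#' @param reference reference data.frame from [tl_reference()].
#' @return the Z-score, or NA when the T/S ratio is missing or the age
#'   falls outside all reference bins.
#' @export
tl_zscore <- function(ts_ratio, age_years, reference) {
  if (is.na(ts_ratio) || is.na(age_years)) return(NA_real_)
  bin <- which(reference$age_lo <= age_years & age_years < reference$age_hi)
  if (length(bin) == 0L) return(NA_real_)
  bin <- bin[1L]
  (ts_ratio - reference$mean_ts[bin]) / reference$sd_ts[bin]
}

#' Percentile from a Z-score
#'
#' Maps a Z-score to a percentile via the standard normal CDF:
#' `percentile = 100 * pnorm(z)`. The control T/S distribution within an
#' age bin is assumed normal; supply an empirical quantile reference to the
#' pipeline if that assumption is inappropriate.
#'
#' @param z finite Z-score (vectorised).
#' @return percentile in (0, 100).
#' @export
percentile_from_z <- function(z) 100 * stats::pnorm(z)

#' Severe telomere-shortening flag
#'
#' Severe shortening is a percentile strictly below the 10th percentile of
#' age-matched controls.
#'
#' @param percentile percentile in (0, 100) (vectorised, NA allowed).
#' @return logical; NA percentile gives FALSE (unknown is never severe).
#' @export
flag_severe <- function(percentile) !is.na(percentile) & percentile < 10

#' Telomere-length results for a set of individuals
#'
#' @param records data.frame `individual_id`, `ts_ratio`, `age_years`
#'   (from [read_tl_inputs()]).
#' @param reference control reference from [tl_reference()].
#' @return data.frame `individual_id`, `z`, `percentile`, `severe`, `known`.
#'   Individuals whose T/S is missing or whose age is outside all bins are
#'   retained with `known = FALSE`.
#' @export
tl_results <- function(records, reference) {
  z <- mapply(tl_zscore, records$ts_ratio, records$age_years,
              MoreArgs = list(reference = reference))
  p <- ifelse(is.na(z), NA_real_, percentile_from_z(z))
  data.frame(individual_id = records$individual_id, z = as.numeric(z),
             percentile = p, severe = flag_severe(p), known = !is.na(p),
             stringsAsFactors = FALSE)
}

# representative numeric percentile for a printed category; used for group
# means when only categorical TL is available
.tl_category_map <- c("<1" = 0.5, "<10" = 5, "10-25" = 17.5, "25-50" = 37.5,
                      "50-75" = 62.5, "75-90" = 82.5, "90-100" = 95,
                      ">90" = 95)

#' Telomere-length results from printed percentile categories
#'
#' Fixture mode mirroring published per-individual TL tables that report
#' percentile categories ("<1", "<10", "10-25", "25-50", "50-75") instead
#' of raw T/S ratios. Categories "<1" and "<10" are severe; "unknown",
#' empty or NA gives `known = FALSE`. The numeric `percentile` column holds
#' the category midpoint (lower-tail categories use their midpoint as well)
#' so that group means remain computable, and `z` is the matching normal
#' quantile.
#'
#' @param records data.frame `individual_id`, `tl_category`.
#' @return data.frame as in [tl_results()], plus `tl_category`.
#' @export
tl_results_from_categories <- function(records) {
  cat <- trimws(as.character(records$tl_category))
  cat[!nzchar(cat) | tolower(cat) %in% c("na", "unknown")] <- NA
  known_levels <- names(.tl_category_map)
  bad <- !is.na(cat) & !cat %in% known_levels
  if (any(bad)) .fail("unknown TL category value(s): ",
                      paste(unique(cat[bad]), collapse = ", "))
  p <- unname(.tl_category_map[cat])
  data.frame(individual_id = records$individual_id,
             z = stats::qnorm(p / 100), percentile = p,
             severe = !is.na(cat) & cat %in% c("<1", "<10"),
             known = !is.na(cat), tl_category = cat,
             stringsAsFactors = FALSE)
}

#' A default 10-year-bin TL control reference
#'
#' Control mean T/S declines linearly with age; SD constant. This is the
#' reference the cohort simulator writes, and a stand-in for unpublished
#' laboratory control distributions.
#'
#' @param age_max upper age bound covered.
#' @param ts_at_zero mean T/S at age 0.
#' @param slope decline of mean T/S per year of age.
#' @param sd constant within-bin SD.
#' @return reference data.frame (see [tl_reference()]).
#' @export
default_tl_reference <- function(age_max = 100, ts_at_zero = 1.5,
                                 slope = 0.005, sd = 0.15) {
  lo <- seq(0, age_max - 10, by = 10)
  hi <- lo + 10
  tl_reference(data.frame(age_lo = lo, age_hi = hi,
                          mean_ts = ts_at_zero - slope * (lo + 5),
                          sd_ts = sd))
}
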