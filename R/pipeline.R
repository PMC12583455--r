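# End-to-end pipeline: config -> filter -> triage (A -> B -> C) ->
# carriers -> yield -> statistics -> reports, with per-family gating
# decisions logged to stderr.

#' Read a pipeline configuration file
#'
#' JSON or YAML with any of the fields accepted by [run_pipeline()]:
#' `vcf`, `ped`, `tl`, `tl_reference`, `tl_mode` ("ratio" or
#' "percentile-category"), `panel_a`/`panel_b`/`panel_c`, `curator`,
#' `class_overrides`, `filter` (af_threshold, retained_consequences),
#' `thresholds` (pm2_af, pp3_score, tl_support_code), `field_map`,
#' `out_dir`, `report_format`, `seed`.
#'
#' @param path config file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .fail("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .fail("YAML configs require the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' Run the full triage pipeline
#'
#' Reads the inputs, applies the tier-0 filter, triages every family
#' through Panels A/B/C, detects asymptomatic carriers, estimates the
#' diagnostic yields, computes the TL association statistics, and writes
#' TSV/JSON reports to `out_dir`. Every per-family gating decision (tiers
#' entered, stop reason) is logged to stderr.
#'
#' @param config named list (see [read_pipeline_config()]) or a path to a
#'   JSON/YAML config file.
#' @return the `fpf_triage` object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (field in c("vcf", "ped"))
    if (is.null(config[[field]]))
      .fail("pipeline config requires field '", field, "'")
  for (field in c("vcf", "ped", "tl", "tl_reference", "curator",
                  "class_overrides"))
    if (!is.null(config[[field]]) && !file.exists(config[[field]]))
      .fail("configured ", field, " file not found: ", config[[field]])

  fm <- do.call(vcf_field_map, as.list(config$field_map %||% list()))
  variants <- read_annotated_vcf(config$vcf, field_map = fm)
  pedigree <- read_pedigree(config$ped)
  panels <- read_panels(config$panel_a %||% "bundled:A",
                        config$panel_b %||% "bundled:B",
                        config$panel_c %||% "bundled:C")

  tl <- NULL
  if (!is.null(config$tl)) {
    mode <- config$tl_mode %||% "ratio"
    if (mode == "percentile-category") {
      tl <- tl_results_from_categories(
        utils::read.delim(config$tl, stringsAsFactors = FALSE))
    } else {
      ref <- if (is.null(config$tl_reference)) default_tl_reference()
      else tl_reference(config$tl_reference)
      inputs <- read_tl_inputs(config$tl, ref_path_or_df(ref))
      tl <- tl_results(inputs$records, inputs$reference)
    }
  }

  fc <- do.call(filter_config, as.list(config$filter %||% list()))
  filtered <- filter_variants(variants, fc)
  message(sprintf("tier-0 filter: %d of %d variants retained",
                  nrow(filtered), nrow(variants)))

  manual <- if (!is.null(config$curator)) read_curator_file(config$curator)
  overrides <- NULL
  if (!is.null(config$class_overrides)) {
    tab <- utils::read.delim(config$class_overrides, stringsAsFactors = FALSE)
    overrides <- stats::setNames(tab$class, tab$key)
  }
  thr <- do.call(classify_thresholds, as.list(config$thresholds %||% list()))
  classify_fn <- acmg_classifier(thr, manual = manual,
                                 class_overrides = overrides)

  res <- triage_cohort(pedigree, filtered, panels = panels, tl = tl,
                       classify_fn = classify_fn)
  for (o in res$outcomes)
    message(sprintf("family %s: tiers %s, stop=%s, candidates=%d",
                    o$family_id, paste(o$tiers_run, collapse = ">"),
                    o$stop_reason,
                    length(unlist(o$candidates, recursive = FALSE))))

  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_triage_report(res$outcomes, file.path(out_dir, "triage_report"),
                      format = config$report_format %||% "both")
  stats_out <- list(
    yield_plp = res$yield_plp, yield_plp_vuslp = res$yield_plp_vuslp,
    tier_summaries = lapply(stats::setNames(nm = c("A", "B", "C")),
                            function(t) tier_variant_summary(res$outcomes, t)))
  if (!is.null(res$tl_association)) {
    ta <- res$tl_association
    stats_out$tl_association <- list(
      table = as.vector(t(ta$table)), fisher_p = ta$fisher_p,
      carrier_mean = ta$carrier_mean, noncarrier_mean = ta$noncarrier_mean,
      welch = ta$welch, family_welch = ta$family_welch, scope = ta$scope)
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(res)
}

# internal shim: tl_reference() accepts a df, read_tl_inputs wants a path
ref_path_or_df <- function(ref) {
  if (is.data.frame(ref)) {
    tmp <- tempfile(fileext = ".tsv")
    utils::write.table(ref, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    tmp
  } else ref
}
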