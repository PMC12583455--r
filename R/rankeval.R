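# Concordance between external automated prioritizers' ranked variant
# lists and a manually prioritized truth set: top-k sensitivity and PPV,
# per tool and for the tools combined.

#' Evaluate ranked variant lists against a truth set
#'
#' For each tool and each k: a truth pair (patient, variant) is a hit when
#' the variant appears within the top k of that patient's list for the
#' tool. Sensitivity = hits / |truth|; the top-k cumulative percentage is
#' 100 x sensitivity. PPV = hits / denominator, where the denominator is
#' either the number of top-k slots emitted across truth patients
#' (`min(k, list length)` summed; default) or the number of distinct
#' variants proposed within top k across truth patients. The "combined"
#' row counts a hit when either tool ranks the variant within k; its slot
#' denominator sums over tools and its distinct denominator takes the
#' union. Ties in rank are broken by input order. 0/0 ratios are reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param lists data.frame `patient_id`, `tool`, `rank`, `key` (variant key
#'   chrom:pos:ref:alt); rank 1 is the top.
#' @param truth data.frame `patient_id`, `key`.
#' @param k_values integer vector of cut-offs (default 1 and 5).
#' @param ppv_denominator "slots" or "distinct".
#' @return data.frame with one row per (tool, k) plus combined rows:
#'   `tool`, `k`, `hits`, `n_truth`, `sensitivity`, `top_k_pct`, `ppv`,
#'   `ppv_denom`, `degenerate`.
#' @export
evaluate_rankings <- function(lists, truth, k_values = c(1L, 5L),
                              ppv_denominator = c("slots", "distinct")) {
  ppv_denominator <- match.arg(ppv_denominator)
  if (any(k_values < 1L)) .fail("k values must be >= 1")
  need <- c("patient_id", "tool", "rank", "key")
  if (!all(need %in% names(lists)))
    .fail("ranked lists need columns: ", paste(need, collapse = ", "))
  dup <- duplicated(lists[c("patient_id", "tool", "key")])
  if (any(dup))
    .fail("duplicate variant in a ranked list: ",
          paste(lists$key[dup][1L], "for", lists$patient_id[dup][1L]))
  tools <- unique(lists$tool)
  n_truth <- nrow(truth)
  truth_patients <- unique(truth$patient_id)

  top_k <- function(tool, patient, k) {
    l <- lists[lists$tool == tool & lists$patient_id == patient, , drop = FALSE]
    l <- l[order(l$rank), , drop = FALSE]  # stable: ties keep input order
    utils::head(l$key, k)
  }
  rows <- list()
  for (k in k_values) {
    per_tool_hits <- list()
    for (tool in tools) {
      hits <- 0L
      slots <- 0L
      proposed <- character()
      hit_pairs <- logical(n_truth)
      for (p in truth_patients) {
        tk <- top_k(tool, p, k)
        slots <- slots + length(tk)
        proposed <- c(proposed, paste(p, tk))
        idx <- which(truth$patient_id == p)
        hit_pairs[idx] <- truth$key[idx] %in% tk
      }
      hits <- sum(hit_pairs)
      per_tool_hits[[tool]] <- list(hit_pairs = hit_pairs, slots = slots,
                                    proposed = unique(proposed))
      denom <- if (ppv_denominator == "slots") slots else
        length(unique(proposed))
      degenerate <- denom == 0L || n_truth == 0L
      rows[[length(rows) + 1L]] <- data.frame(
        tool = tool, k = k, hits = hits, n_truth = n_truth,
        sensitivity = if (n_truth == 0L) 0 else hits / n_truth,
        top_k_pct = if (n_truth == 0L) 0 else 100 * hits / n_truth,
        ppv = if (denom == 0L) 0 else hits / denom,
        ppv_denom = denom, degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
    if (length(tools) > 1L) {
      union_hits <- Reduce(`|`, lapply(per_tool_hits, `[[`, "hit_pairs"))
      slots <- sum(vapply(per_tool_hits, `[[`, numeric(1), "slots"))
      proposed <- unique(unlist(lapply(per_tool_hits, `[[`, "proposed")))
      denom <- if (ppv_denominator == "slots") slots else length(proposed)
      hits <- sum(union_hits)
      rows[[length(rows) + 1L]] <- data.frame(
        tool = "combined", k = k, hits = hits, n_truth = n_truth,
        sensitivity = if (n_truth == 0L) 0 else hits / n_truth,
        top_k_pct = if (n_truth == 0L) 0 else 100 * hits / n_truth,
        ppv = if (denom == 0L) 0 else hits / denom,
        ppv_denom = denom, degenerate = denom == 0L || n_truth == 0L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(tool = character(), k = integer(), hits = integer(),
                      n_truth = integer(), sensitivity = numeric(),
                      top_k_pct = numeric(), ppv = numeric(),
                      ppv_denom = numeric(), degenerate = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read a ranked-list TSV
#'
#' @param path TSV with columns `patient_id`, `tool`, `rank`, `key` and
#'   optional `score`.
#' @return data.frame.
#' @export
read_ranked_lists <- function(path) {
  if (!file.exists(path)) .fail("ranked-list file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
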