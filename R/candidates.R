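#' Refine disease-unlinked genes to unexploited candidates
#'
#' An unlinked gene is retained as a candidate when it carries a TWAS Z
#' score (any sign; optionally above `min_abs_z` in magnitude) or appears
#' as a disease DEG in at least `min_studies` of the meta-analysis study
#' lists. A gene satisfying both criteria appears once with both reasons
#' recorded. Output is sorted by |ON-score| descending, then gene ID.
#'
#' @param unlinked Character vector of disease-unlinked gene IDs; must be
#'   covered by `integrated` or `onscores`.
#' @param integrated An `"integrated_deg_table"` from
#'   [integrate_disease_degs()].
#' @param onscores An `"on_score_table"` (or data frame with `gene_id`,
#'   `on_score`).
#' @param min_studies Minimum number of study lists reporting the gene for
#'   the multi-study criterion; must be >= 1. Default 2.
#' @param min_abs_z Minimum |Z| for the TWAS criterion; default 0 (mere
#'   presence of a Z score qualifies).
#' @param idmap Optional ID map (or [convert_ids()] output) used to attach
#'   display symbols.
#' @return Data frame of class `"candidate_table"`: `gene_id`, `symbol`,
#'   `on_score`, the per-study `log2fc_*` columns, `twas_z`,
#'   `twas_source`, `n_meta_studies`, `reason` (semicolon-joined subset of
#'   `twas`, `multi_study`).
#' @export
filter_candidates <- function(unlinked, integrated, onscores,
                              min_studies = 2L, min_abs_z = 0,
                              idmap = NULL) {
  if (min_studies < 1L) stop("min_studies must be >= 1")
  unlinked <- unique(as.character(unlinked))
  known <- union(integrated$gene_id, onscores$gene_id)
  unknown <- setdiff(unlinked, known)
  if (length(unknown))
    stop("unlinked genes absent from both the integrated table and the ",
         "score table: ", paste(utils::head(unknown, 5), collapse = ", "))
  fc_cols <- grep("^log2fc_", names(integrated), value = TRUE)
  row <- match(unlinked, integrated$gene_id)
  fc <- integrated[row, fc_cols, drop = FALSE]
  n_meta <- as.integer(rowSums(!is.na(fc)))
  n_meta[is.na(row)] <- 0L
  twas_z <- integrated$twas_z[row]
  has_twas <- !is.na(twas_z) & abs(twas_z) >= min_abs_z
  multi <- n_meta >= min_studies
  keep <- has_twas | multi
  reason <- character(length(unlinked))
  reason[has_twas & multi] <- "twas;multi_study"
  reason[has_twas & !multi] <- "twas"
  reason[!has_twas & multi] <- "multi_study"
  score <- onscores$on_score[match(unlinked, onscores$gene_id)]
  out <- data.frame(
    gene_id = unlinked,
    symbol = rep(NA_character_, length(unlinked)),
    on_score = score,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, fc)
  out$twas_z <- twas_z
  out$twas_source <- integrated$twas_source[row]
  out$n_meta_studies <- n_meta
  out$reason <- reason
  out <- out[keep, , drop = FALSE]
  if (!is.null(idmap)) {
    sym_col <- if ("symbol" %in% names(idmap)) "symbol" else NULL
    key_col <- if ("ensembl_id" %in% names(idmap)) "ensembl_id" else "input_id"
    if (!is.null(sym_col))
      out$symbol <- idmap[[sym_col]][match(out$gene_id, idmap[[key_col]])]
  }
  ord <- order(-abs(ifelse(is.na(out$on_score), 0L, out$on_score)), out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "study_ids") <- attr(integrated, "study_ids")
  class(out) <- c("candidate_table", "data.frame")
  out
}
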