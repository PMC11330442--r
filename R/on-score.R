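#' Pseudocounted expression ratio for one stress/control pair
#'
#' Computes the ON-ratio `(t_stress + 1) / (t_control + 1)` for TPM-scale
#' expression values. The +1 pseudocount keeps the ratio finite and positive
#' for genes that are silent in one or both samples; a gene with zero
#' expression in both members of a pair gets ratio 1 (unchanged).
#'
#' @param t_stress,t_control Non-negative finite numeric vectors (TPM-scale),
#'   recycled to a common length.
#' @return Numeric vector of positive ratios.
#' @examples
#' compute_on_ratio(0, 0)   # 1: pseudocount identity
#' compute_on_ratio(2, 1)   # 1.5
#' @export
compute_on_ratio <- function(t_stress, t_control) {
  if (!is.numeric(t_stress) || !is.numeric(t_control))
    stop("expression values must be numeric")
  if (anyNA(t_stress) || anyNA(t_control) ||
      any(!is.finite(t_stress)) || any(!is.finite(t_control)))
    stop("expression values must be finite and non-missing")
  if (any(t_stress < 0) || any(t_control < 0))
    stop("expression values must be non-negative")
  (t_stress + 1) / (t_control + 1)
}

#' Classify a pair-level ratio as up, down or unchanged
#'
#' A ratio at or above `fold_threshold` is called "up", at or below
#' `1/fold_threshold` "down", otherwise "unchanged". The boundary is
#' inclusive so the pair of cutoffs at \eqn{f} and \eqn{1/f} is exactly
#' symmetric and exact-ratio inputs are classifiable.
#'
#' @param on_ratio Positive numeric vector of pair-level ratios.
#' @param fold_threshold Single number > 1; default 1.5.
#' @return Character vector in `c("up", "down", "unchanged")`.
#' @examples
#' classify_pair(c(1, 1.5, 2/3), 1.5)
#' @export
classify_pair <- function(on_ratio, fold_threshold = 1.5) {
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      !is.finite(fold_threshold) || fold_threshold <= 1)
    stop("fold_threshold must be a single finite number > 1")
  if (any(!is.na(on_ratio) & on_ratio <= 0))
    stop("on_ratio must be positive")
  out <- rep("unchanged", length(on_ratio))
  out[!is.na(on_ratio) & on_ratio >= fold_threshold] <- "up"
  out[!is.na(on_ratio) & on_ratio <= 1 / fold_threshold] <- "down"
  out[is.na(on_ratio)] <- NA_character_
  out
}

#' Vote-counting meta-analysis scores over paired expression
#'
#' For every gene and every stress/control pair, the ON-ratio is computed
#' and classified against `fold_threshold`; the ON-score is then the number
#' of pairs called up minus the number called down, an integer vote-count
#' statistic measuring how consistently a gene is dysregulated under stress
#' across independent datasets.
#'
#' @param expression Numeric matrix (or data frame) of non-negative
#'   TPM-scale values, genes in rows (rownames = gene IDs), samples in
#'   columns.
#' @param pairing Data frame with columns `stress_sample` and
#'   `control_sample` (and optionally `source_study`); each row names one
#'   matched pair of columns of `expression`. No sample may appear twice in
#'   the same role.
#' @param fold_threshold Classification threshold, > 1. Default 1.5.
#' @param missing How to treat an `NA` expression value in a pair:
#'   `"unchanged"` (default) counts the pair as unchanged for that gene,
#'   `"error"` aborts.
#' @return A data frame of class `"on_score_table"` with columns `gene_id`,
#'   `n_up`, `n_down`, `n_unchanged`, `on_score` and `mean_abs_log_ratio`
#'   (mean |log ON-ratio| over pairs, used as a deterministic tie-break in
#'   [select_os_degs()]); attribute `n_pairs` records the pair count.
#' @export
compute_on_scores <- function(expression, pairing, fold_threshold = 1.5,
                              missing = c("unchanged", "error")) {
  missing <- match.arg(missing)
  if (is.data.frame(expression)) expression <- as.matrix(expression)
  if (!is.numeric(expression)) stop("expression must be numeric")
  if (is.null(rownames(expression))) stop("expression must have gene IDs as rownames")
  if (nrow(pairing) < 1L) stop("pairing must contain at least one pair")
  req <- c("stress_sample", "control_sample")
  if (!all(req %in% names(pairing)))
    stop("pairing needs columns stress_sample and control_sample")
  stress <- as.character(pairing$stress_sample)
  control <- as.character(pairing$control_sample)
  missing_samples <- setdiff(c(stress, control), colnames(expression))
  if (length(missing_samples))
    stop("samples in pairing absent from expression matrix: ",
         paste(missing_samples, collapse = ", "))
  if (anyDuplicated(stress) || anyDuplicated(control))
    stop("a sample appears in two pairs in the same role")
  s_mat <- expression[, stress, drop = FALSE]
  c_mat <- expression[, control, drop = FALSE]
  if (missing == "error" && (anyNA(s_mat) || anyNA(c_mat)))
    stop("missing expression value in a paired sample")
  if (any(s_mat < 0, na.rm = TRUE) || any(c_mat < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  ratio <- (s_mat + 1) / (c_mat + 1)
  # NA ratio (missing value, tolerant mode) votes unchanged and contributes
  # nothing to the effect-size tie-break
  up <- ratio >= fold_threshold
  down <- ratio <= 1 / fold_threshold
  up[is.na(up)] <- FALSE
  down[is.na(down)] <- FALSE
  n_up <- as.integer(rowSums(up))
  n_down <- as.integer(rowSums(down))
  n_pairs <- nrow(pairing)
  abslog <- abs(log(ratio))
  abslog[is.na(abslog)] <- 0
  out <- data.frame(
    gene_id = rownames(expression),
    n_up = n_up,
    n_down = n_down,
    n_unchanged = n_pairs - n_up - n_down,
    on_score = n_up - n_down,
    mean_abs_log_ratio = rowMeans(abslog),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_pairs") <- n_pairs
  attr(out, "fold_threshold") <- fold_threshold
  class(out) <- c("on_score_table", "data.frame")
  out
}

#' @export
print.on_score_table <- function(x, ...) {
  cat("ON-score table: ", nrow(x), " genes, ", attr(x, "n_pairs"),
      " pairs, fold threshold ", attr(x, "fold_threshold"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more genes)\n", sep = "")
  invisible(x)
}

# nearest integer, halves away from zero (round() rounds halves to even)
round_half_up <- function(x) floor(x + 0.5)

#' Select the most extreme genes by ON-score
#'
#' Takes the `round(fraction/2 * G)` genes with the highest ON-scores as the
#' up-selection and, disjointly, the same number with the lowest as the
#' down-selection (halves round up, so a 62,266-gene universe at fraction
#' 0.05 yields 1557 genes per direction). Ties at the selection boundary are
#' broken by larger mean |log ON-ratio| first, then lexicographic gene ID,
#' so the selection is deterministic.
#'
#' @param table An `"on_score_table"` from [compute_on_scores()], or any
#'   data frame with columns `gene_id` and `on_score` (an optional
#'   `mean_abs_log_ratio` column refines tie-breaking).
#' @param fraction Total fraction of the universe to select (both
#'   directions combined), in (0, 1]. Default 0.05.
#' @param min_abs_score Optional filter: only genes with |on_score| at or
#'   above this value are eligible. Default 0 (off); if fewer eligible genes
#'   than requested remain, the selection is truncated with a warning.
#' @return List of class `"deg_selection"` with elements `up_genes`,
#'   `down_genes` (character vectors in selection order), `fraction` and
#'   `per_direction`.
#' @export
select_os_degs <- function(table, fraction = 0.05, min_abs_score = 0) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  if (nrow(table) == 0L) stop("empty ON-score table")
  g <- nrow(table)
  m <- as.integer(round_half_up(fraction / 2 * g))
  if (2L * m > g)
    stop("selection of ", 2L * m, " genes exceeds universe of ", g)
  tiebreak <- if ("mean_abs_log_ratio" %in% names(table))
    table$mean_abs_log_ratio else numeric(g)
  ord_up <- order(-table$on_score, -tiebreak, table$gene_id)
  if (min_abs_score > 0)
    ord_up <- ord_up[table$on_score[ord_up] >= min_abs_score]
  up_idx <- utils::head(ord_up, m)
  ord_down <- order(table$on_score, -tiebreak, table$gene_id)
  ord_down <- setdiff(ord_down, up_idx)
  if (min_abs_score > 0)
    ord_down <- ord_down[table$on_score[ord_down] <= -min_abs_score]
  down_idx <- utils::head(ord_down, m)
  if (min_abs_score > 0 && (length(up_idx) < m || length(down_idx) < m))
    warning("fewer genes pass min_abs_score than requested; ",
            "selection truncated")
  out <- list(
    up_genes = table$gene_id[up_idx],
    down_genes = table$gene_id[down_idx],
    fraction = fraction,
    per_direction = m
  )
  class(out) <- "deg_selection"
  out
}

#' @export
print.deg_selection <- function(x, ...) {
  cat("DEG selection: ", length(x$up_genes), " up + ", length(x$down_genes),
      " down (fraction ", x$fraction, ")\n", sep = "")
  invisible(x)
}
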