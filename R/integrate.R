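#' Integrate multi-study disease DEG lists and TWAS evidence
#'
#' Builds the union of all gene IDs across the study DEG lists and the TWAS
#' evidence set, keeping per-source provenance: one log2 fold-change column
#' per study (NA where the study did not report the gene) and TWAS flag,
#' Z score and source columns. TWAS genes count toward the disease-DEG
#' union but remain distinguishable so downstream filters can separate the
#' evidence types. Conflicting fold-change signs across studies are
#' preserved, not reconciled.
#'
#' @param studies Named list of data frames with columns `gene_id` and
#'   `log2fc`; names are the study IDs and must be unique. Duplicate
#'   (gene, study) rows with identical log2fc are deduplicated; conflicting
#'   duplicates are an error.
#' @param twas Optional data frame with columns `gene_id`, `z_score`,
#'   `source_study`.
#' @return Data frame of class `"integrated_deg_table"`: `gene_id`, one
#'   `log2fc_<study>` column per study, `twas_flag`, `twas_z`,
#'   `twas_source`; attribute `study_ids`.
#' @export
integrate_disease_degs <- function(studies, twas = NULL) {
  if (length(studies) == 0L && (is.null(twas) || nrow(twas) == 0L)) {
    out <- data.frame(gene_id = character(), twas_flag = logical(),
                      twas_z = numeric(), twas_source = character(),
                      stringsAsFactors = FALSE)
    attr(out, "study_ids") <- character()
    class(out) <- c("integrated_deg_table", "data.frame")
    return(out)
  }
  ids <- names(studies)
  if (length(studies) && (is.null(ids) || any(ids == "") || anyDuplicated(ids)))
    stop("study IDs must be present and unique")
  studies <- lapply(studies, function(s) {
    s <- unique(s[, c("gene_id", "log2fc")])
    if (anyDuplicated(s$gene_id))
      stop("conflicting duplicate (gene, study) rows: ",
           paste(unique(s$gene_id[duplicated(s$gene_id)]), collapse = ", "))
    s
  })
  universe <- sort(unique(c(unlist(lapply(studies, `[[`, "gene_id"),
                                   use.names = FALSE),
                            if (!is.null(twas)) twas$gene_id)))
  out <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (id in ids) {
    s <- studies[[id]]
    out[[paste0("log2fc_", id)]] <-
      s$log2fc[match(universe, s$gene_id)]
  }
  if (!is.null(twas) && nrow(twas) > 0L) {
    # keep the strongest record per gene when a gene has several
    twas <- twas[order(-abs(twas$z_score)), ]
    twas <- twas[!duplicated(twas$gene_id), ]
    row <- match(universe, twas$gene_id)
    out$twas_flag <- !is.na(row)
    out$twas_z <- twas$z_score[row]
    out$twas_source <- twas$source_study[row]
  } else {
    out$twas_flag <- FALSE
    out$twas_z <- NA_real_
    out$twas_source <- NA_character_
  }
  attr(out, "study_ids") <- ids %||% character()
  class(out) <- c("integrated_deg_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count every Venn region of up to six gene sets
#'
#' Enumerates all `2^k - 1` non-empty membership combinations and counts
#' the genes falling exactly in each; counts sum to the union size.
#'
#' @param sets Named list of up to six character vectors.
#' @return Named integer vector; names join the member set names with
#'   `"&"` (e.g. `"A&B"` is the region in A and B but no other set).
#' @export
venn_region_counts <- function(sets) {
  k <- length(sets)
  if (k < 1L) stop("need at least one set")
  if (k > 6L) stop("more than 6 sets is unsupported")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_len(k))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  pattern <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  counts
}

# crude shape check so that Ensembl-vs-symbol mixups surface as a clear
# message instead of a silently empty intersection
id_shape <- function(ids) {
  shapes <- unique(sub("[0-9]+$", "#", ids))
  utils::head(sort(shapes), 3)
}

#' Intersect the stress-DEG selection with the disease-DEG union
#'
#' Returns the genes selected as stress DEGs (either direction) that also
#' appear in the integrated disease table, annotated with selection
#' direction, ON-score and all per-study / TWAS provenance columns.
#'
#' @param os_sel A `"deg_selection"` from [select_os_degs()].
#' @param pd_table An `"integrated_deg_table"` from
#'   [integrate_disease_degs()].
#' @param onscores Optional `"on_score_table"` supplying `on_score` values.
#' @return Data frame with `gene_id`, `direction`, `on_score` (NA if
#'   `onscores` not given) and the provenance columns of `pd_table`.
#' @export
intersect_os_disease <- function(os_sel, pd_table, onscores = NULL) {
  stopifnot(inherits(os_sel, "deg_selection"))
  os_genes <- c(os_sel$up_genes, os_sel$down_genes)
  if (length(os_genes) == 0L || nrow(pd_table) == 0L)
    stop("both the selection and the disease table must be non-empty")
  common <- intersect(os_genes, pd_table$gene_id)
  if (length(common) == 0L &&
      !identical(id_shape(os_genes), id_shape(pd_table$gene_id)))
    warning("no overlap and gene-ID formats differ between inputs (",
            paste(id_shape(os_genes), collapse = ","), " vs ",
            paste(id_shape(pd_table$gene_id), collapse = ","),
            "); check ID normalization")
  keep <- os_genes[os_genes %in% common]  # preserve selection order
  out <- data.frame(
    gene_id = keep,
    direction = ifelse(keep %in% os_sel$up_genes, "up", "down"),
    stringsAsFactors = FALSE
  )
  out$on_score <- if (!is.null(onscores))
    onscores$on_score[match(keep, onscores$gene_id)]
  else rep(NA_integer_, length(keep))
  prov <- pd_table[match(keep, pd_table$gene_id),
                   setdiff(names(pd_table), "gene_id"), drop = FALSE]
  rownames(prov) <- NULL
  out <- cbind(out, prov)
  attr(out, "study_ids") <- attr(pd_table, "study_ids")
  out
}
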