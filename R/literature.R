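#' Build the PubMed Central search query for a candidate gene
#'
#' Returns the exact query string used for the manual literature search:
#' `"<SYMBOL>[All Fields] AND <disease_term>[All Fields]"`.
#'
#' @param symbol Gene symbol; must be non-empty and contain no whitespace.
#' @param disease_term Disease search term; default `"parkinson"` (PMC
#'   search is case-insensitive; lowercase is the display convention).
#' @return Query string.
#' @examples
#' build_query("NUPR1")
#' @export
build_query <- function(symbol, disease_term = "parkinson") {
  if (length(symbol) != 1L || is.na(symbol) || !nzchar(symbol) ||
      grepl("\\s", symbol))
    stop("symbol must be a single non-empty string without whitespace")
  sprintf("%s[All Fields] AND %s[All Fields]", symbol, disease_term)
}

#' Emit a curation worksheet of literature queries for candidates
#'
#' One row per candidate with its ready-made search query and blank
#' evidence columns for the curator to fill in.
#'
#' @param candidates A `"candidate_table"` from [filter_candidates()].
#' @param disease_term Passed to [build_query()].
#' @return Data frame `gene_id`, `symbol`, `query`, `search_date`,
#'   `n_publications`, `evidence_pmcid`, `evidence_statement`,
#'   `functional_statement` (the last five blank).
#' @export
build_worksheet <- function(candidates, disease_term = "parkinson") {
  sym <- ifelse(is.na(candidates$symbol), candidates$gene_id,
                candidates$symbol)
  data.frame(
    gene_id = candidates$gene_id,
    symbol = sym,
    query = vapply(sym, build_query, character(1),
                   disease_term = disease_term),
    search_date = rep("", length(sym)),
    n_publications = rep(NA_integer_, length(sym)),
    evidence_pmcid = rep("", length(sym)),
    evidence_statement = rep("", length(sym)),
    functional_statement = rep(NA, length(sym)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Adjudicate candidates into unexploited / not-unexploited
#'
#' The literature search and the judgement of "mechanistic evidence" are
#' curator tasks; this function structures and validates the decision. A
#' candidate is unexploited ("yes") exactly when its evidence row carries a
#' functional statement; a gene merely listed among DEGs without functional
#' implications, or with zero search results, is "no". Rows claiming a
#' functional statement must cite an evidence PMCID and at least one
#' publication, otherwise the table is rejected.
#'
#' @param candidates A `"candidate_table"` from [filter_candidates()].
#' @param evidence Data frame keyed by `gene_id` with columns
#'   `functional_statement` (logical), `n_publications`,
#'   `evidence_pmcid`, optionally `evidence_statement`, `search_date`.
#'   Every candidate must have a row.
#' @param disease_term Used to regenerate the query column.
#' @return Data frame in candidate order: `gene_id`, `symbol`,
#'   `unexploited` ("yes"/"no"), `evidence_pmcid`, `evidence_statement`,
#'   `query`, `search_date`, `n_publications`.
#' @export
adjudicate <- function(candidates, evidence, disease_term = "parkinson") {
  if (!all(c("gene_id", "functional_statement") %in% names(evidence)))
    stop("evidence table needs columns gene_id and functional_statement")
  row <- match(candidates$gene_id, evidence$gene_id)
  if (anyNA(row))
    stop("candidate(s) missing from evidence table: ",
         paste(candidates$gene_id[is.na(row)], collapse = ", "))
  ev <- evidence[row, , drop = FALSE]
  fun <- as.logical(ev$functional_statement)
  fun[is.na(fun)] <- FALSE
  npub <- if ("n_publications" %in% names(ev)) ev$n_publications else NA_integer_
  pmcid <- if ("evidence_pmcid" %in% names(ev)) as.character(ev$evidence_pmcid)
           else NA_character_
  no_pmcid <- is.na(pmcid) | pmcid == "" | pmcid == "Not Found"
  bad <- fun & (no_pmcid | (!is.na(npub) & npub == 0))
  if (any(bad))
    stop("functional statement without supporting PMCID/publications for: ",
         paste(candidates$gene_id[bad], collapse = ", "))
  sym <- ifelse(is.na(candidates$symbol), candidates$gene_id,
                candidates$symbol)
  data.frame(
    gene_id = candidates$gene_id,
    symbol = sym,
    unexploited = ifelse(fun, "yes", "no"),
    evidence_pmcid = ifelse(fun, pmcid, "Not Found"),
    evidence_statement = if ("evidence_statement" %in% names(ev))
      ifelse(fun, as.character(ev$evidence_statement), "Not Found")
      else rep("Not Found", length(fun)),
    query = vapply(sym, build_query, character(1),
                   disease_term = disease_term),
    search_date = if ("search_date" %in% names(ev))
      as.character(ev$search_date) else rep(NA_character_, length(fun)),
    n_publications = npub,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
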