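#' Attach all known identifier forms to a gene list
#'
#' Looks each input gene up in the ID map by Ensembl ID, symbol or Entrez
#' ID (in that order) and carries along every available key form. Unmapped
#' genes are retained with a flag, never dropped. When two ID-map rows
#' share a symbol, the row with the lowest-sorting Ensembl ID wins and the
#' collision is recorded.
#'
#' @param genes Character vector of gene identifiers (any key form).
#' @param idmap Data frame with columns `ensembl_id`, `symbol`,
#'   `entrez_id` (fields may be NA; `ensembl_id` must be unique where
#'   present).
#' @return Data frame `input_id`, `ensembl_id`, `symbol`, `entrez_id`,
#'   `unmapped`; attribute `symbol_collisions` lists resolved collisions.
#' @export
convert_ids <- function(genes, idmap) {
  req <- c("ensembl_id", "symbol", "entrez_id")
  if (!all(req %in% names(idmap)))
    stop("idmap needs columns ensembl_id, symbol, entrez_id")
  ens <- idmap$ensembl_id[!is.na(idmap$ensembl_id)]
  if (anyDuplicated(ens)) stop("ensembl_id must be unique in the ID map")
  idmap <- idmap[order(idmap$ensembl_id), , drop = FALSE]
  collided <- unique(idmap$symbol[duplicated(idmap$symbol) &
                                  !is.na(idmap$symbol)])
  row <- match(genes, idmap$ensembl_id)
  # first match wins for symbols: lowest-sorting ensembl ID after the sort
  row[is.na(row)] <- match(genes[is.na(row)], idmap$symbol)
  row[is.na(row)] <- match(genes[is.na(row)], idmap$entrez_id)
  out <- data.frame(
    input_id = genes,
    ensembl_id = idmap$ensembl_id[row],
    symbol = idmap$symbol[row],
    entrez_id = idmap$entrez_id[row],
    unmapped = is.na(row),
    stringsAsFactors = FALSE
  )
  out$ensembl_id[out$unmapped] <- genes[out$unmapped]
  attr(out, "symbol_collisions") <- collided
  out
}

validate_snapshot <- function(snapshot, name = "snapshot") {
  req <- c("gene_key", "disease_id", "pmids", "score")
  if (!all(req %in% names(snapshot)))
    stop(name, " needs columns gene_key, disease_id, pmids, score")
  bad <- which(is.na(snapshot$gene_key) | snapshot$gene_key == "" |
               is.na(snapshot$disease_id) | snapshot$disease_id == "")
  if (length(bad))
    stop("malformed rows in ", name, " (missing gene_key or disease_id) at line",
         if (length(bad) > 1) "s" else "", " ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(snapshot)
}

split_pmids <- function(x) {
  if (length(x) == 0L) return(character())
  out <- unlist(strsplit(x[!is.na(x) & x != ""], ";", fixed = TRUE))
  unique(trimws(out))
}

#' Query one association snapshot for a keyed gene list
#'
#' A snapshot record is a hit for a gene when its `gene_key` equals any of
#' the gene's key forms, its `disease_id` is exactly one of the requested
#' disease IDs, and its score is either absent or at least `min_score`.
#'
#' @param keyed Data frame from [convert_ids()].
#' @param snapshot Data frame `gene_key`, `disease_id`, `pmids`
#'   (semicolon-separated), `score` (NA allowed).
#' @param disease_id Character vector of acceptable disease IDs (exact
#'   match, e.g. one per source ontology).
#' @param min_score Minimum association score; records with no score always
#'   pass. Default 0.
#' @return Data frame of hits: `input_id`, `gene_key`, `disease_id`,
#'   `pmids`, `score`.
#' @export
query_snapshot <- function(keyed, snapshot, disease_id, min_score = 0) {
  if (length(disease_id) == 0L || all(is.na(disease_id) | disease_id == ""))
    stop("disease_id must be non-empty")
  validate_snapshot(snapshot)
  rel <- snapshot[snapshot$disease_id %in% disease_id &
                  (is.na(snapshot$score) | snapshot$score >= min_score), ,
                  drop = FALSE]
  keys <- rbind(
    data.frame(input_id = keyed$input_id, key = keyed$ensembl_id,
               stringsAsFactors = FALSE),
    data.frame(input_id = keyed$input_id, key = keyed$symbol,
               stringsAsFactors = FALSE),
    data.frame(input_id = keyed$input_id, key = keyed$entrez_id,
               stringsAsFactors = FALSE))
  keys <- keys[!is.na(keys$key), , drop = FALSE]
  hit <- merge(keys, rel, by.x = "key", by.y = "gene_key")
  out <- data.frame(input_id = hit$input_id, gene_key = hit$key,
                    disease_id = hit$disease_id, pmids = hit$pmids,
                    score = hit$score, stringsAsFactors = FALSE)
  out[order(out$input_id, out$gene_key), , drop = FALSE]
}

#' Classify genes as disease-linked or disease-unlinked
#'
#' Runs [query_snapshot()] against all five association snapshots and
#' declares a gene linked ("yes") when at least one snapshot yields at
#' least one hit. Evidence PMIDs from all hits are pooled and
#' deduplicated. The linked/unlinked split partitions the input exactly,
#' and the result is independent of snapshot row order and gene order.
#'
#' @param keyed Data frame from [convert_ids()].
#' @param snapshots Named list of exactly five snapshot data frames; names
#'   must be `open_targets`, `disgenet`, `mirtex`, `rnadisease`,
#'   `pubchem`.
#' @param disease_id Disease ID(s) to match exactly.
#' @param min_scores Per-database minimum score: a single number or a
#'   named vector/list keyed by database name. Default 0 (any evidence
#'   counts). A scored hit with zero PMIDs still sets availability to
#'   "yes" but contributes nothing to the PMID list.
#' @return Data frame of class `"link_report"`: `input_id`, `ensembl_id`,
#'   `symbol`, `availability` ("yes"/"no"), `evidence_databases`
#'   (semicolon-joined), `n_pmids_disease`, `pmids_disease`
#'   (semicolon-joined), `unmapped`.
#' @export
classify_linkage <- function(keyed, snapshots, disease_id, min_scores = 0) {
  expected <- snapshot_db_names()
  if (length(snapshots) != 5L || !setequal(names(snapshots), expected))
    stop("snapshots must be a named list of exactly the five databases: ",
         paste(expected, collapse = ", "))
  if (is.numeric(min_scores) && length(min_scores) == 1L && is.null(names(min_scores)))
    min_scores <- stats::setNames(rep(min_scores, 5L), expected)
  min_scores <- unlist(min_scores)
  missing_thr <- setdiff(expected, names(min_scores))
  min_scores[missing_thr] <- 0
  if (any(keyed$unmapped))
    warning(sum(keyed$unmapped), " unmapped gene(s) classified unlinked ",
            "unless a snapshot matches the raw ID")
  hits <- lapply(expected, function(db)
    query_snapshot(keyed, snapshots[[db]], disease_id, min_scores[[db]]))
  names(hits) <- expected
  n <- nrow(keyed)
  evidence <- character(n); pmids <- character(n); npmid <- integer(n)
  for (i in seq_len(n)) {
    id <- keyed$input_id[i]
    dbs <- expected[vapply(hits, function(h) id %in% h$input_id, logical(1))]
    pm <- split_pmids(unlist(lapply(hits[dbs],
                                    function(h) h$pmids[h$input_id == id])))
    evidence[i] <- paste(dbs, collapse = ";")
    pmids[i] <- paste(sort(pm), collapse = ";")
    npmid[i] <- length(pm)
  }
  out <- data.frame(
    input_id = keyed$input_id,
    ensembl_id = keyed$ensembl_id,
    symbol = keyed$symbol,
    availability = ifelse(evidence != "", "yes", "no"),
    evidence_databases = evidence,
    n_pmids_disease = npmid,
    pmids_disease = pmids,
    unmapped = keyed$unmapped,
    stringsAsFactors = FALSE
  )
  class(out) <- c("link_report", "data.frame")
  out
}

#' Count a gene's total literature footprint via gene2pubmed
#'
#' Deduplicates PMIDs per gene through the Entrez key. Genes without an
#' Entrez ID get count 0 and an `entrez_missing` flag.
#'
#' @param keyed Data frame from [convert_ids()].
#' @param gene2pubmed Data frame with columns `entrez_id`, `pmid`.
#' @return Data frame `input_id`, `n_pmids_gene`, `pmids_gene`
#'   (semicolon-joined), `entrez_missing`.
#' @export
count_gene_literature <- function(keyed, gene2pubmed) {
  if (!all(c("entrez_id", "pmid") %in% names(gene2pubmed)))
    stop("gene2pubmed needs columns entrez_id, pmid")
  by_gene <- split(as.character(gene2pubmed$pmid),
                   as.character(gene2pubmed$entrez_id))
  pm <- lapply(keyed$entrez_id, function(e) {
    val <- if (is.na(e)) NULL else by_gene[[as.character(e)]]
    if (is.null(val)) character() else sort(unique(val))
  })
  data.frame(
    input_id = keyed$input_id,
    n_pmids_gene = vapply(pm, length, integer(1)),
    pmids_gene = vapply(pm, paste, character(1), collapse = ";"),
    entrez_missing = is.na(keyed$entrez_id),
    stringsAsFactors = FALSE
  )
}
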