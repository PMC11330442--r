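# Tab-separated readers/writers for every table the pipeline exchanges.
# Numeric columns are serialized with %.17g so a write/read round trip
# reproduces doubles exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a data frame as TSV (full numeric precision)
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by this package
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = NA,
                    na.strings = "NA", quote = "")
}

#' Write / read a paired expression matrix
#'
#' TSV dialect: first column `gene_id`, remaining columns one per sample.
#' @param expression Numeric matrix, gene IDs as rownames.
#' @param path File path.
#' @return `write_expression` returns `path`; `read_expression` returns
#'   the matrix with gene rownames.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression),
                   expression, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  m
}

#' Read a pairing manifest (stress_sample, control_sample, source_study)
#' @param path File path.
#' @return Data frame.
#' @export
read_pairing <- function(path) {
  df <- read_tsv(path)
  if (!all(c("stress_sample", "control_sample") %in% names(df)))
    stop("pairing manifest needs columns stress_sample and control_sample")
  df
}

#' Read one study DEG list (gene_id, log2fc)
#' @param path File path.
#' @return Data frame with columns `gene_id`, `log2fc`.
#' @export
read_study_list <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene_id", "log2fc") %in% names(df)))
    stop("study DEG list needs columns gene_id and log2fc: ", path)
  df
}

#' Read a TWAS evidence table (gene_id, z_score, source_study)
#' @param path File path.
#' @return Data frame.
#' @export
read_twas <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene_id", "z_score") %in% names(df)))
    stop("TWAS table needs columns gene_id and z_score: ", path)
  df$source_study <- as.character(df$source_study %||% NA_character_)
  df
}

#' Read an association snapshot (gene_key, disease_id, pmids, score)
#' @param path File path.
#' @return Data frame, validated (malformed rows are reported with their
#'   line numbers).
#' @export
read_snapshot <- function(path) {
  df <- read_tsv(path)
  df$gene_key <- as.character(df$gene_key)
  df$disease_id <- as.character(df$disease_id)
  df$pmids <- as.character(df$pmids)
  validate_snapshot(df, name = path)
}

#' Read an ID map (ensembl_id, symbol, entrez_id)
#' @param path File path.
#' @return Data frame with character columns.
#' @export
read_idmap <- function(path) {
  df <- read_tsv(path)
  for (col in c("ensembl_id", "symbol", "entrez_id"))
    df[[col]] <- as.character(df[[col]])
  df
}

#' Read / write a one-ID-per-line gene list
#' @param path File path.
#' @param genes Character vector of gene IDs.
#' @return `read_gene_list` returns a character vector; `write_gene_list`
#'   returns `path`.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

# ---- report writers using the Supplementary-Table column conventions ----

#' Write the integrated disease-DEG table
#'
#' Per-study fold-change columns are named
#' `PD_log2(fold change)_<study>`; absent values are rendered "Not Found".
#' @param integrated An `"integrated_deg_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_integrated <- function(integrated, path) {
  out <- data.frame(ENSG = integrated$gene_id, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (id in attr(integrated, "study_ids")) {
    v <- integrated[[paste0("log2fc_", id)]]
    out[[sprintf("PD_log2(fold change)_%s", id)]] <-
      ifelse(is.na(v), "Not Found", fmt_num(v))
  }
  out$TWAS <- ifelse(integrated$twas_flag, "yes", "no")
  out[["TWAS Z score"]] <- ifelse(is.na(integrated$twas_z), "Not Found",
                                  fmt_num(integrated$twas_z))
  write_tsv(out, path)
}

#' Write a linkage report with Supplementary-style column names
#'
#' Columns: `ENSG`, `GeneSymbol`, `availability of associations`,
#' `Evidence`, `NU_PMIDs_PD`, `NU_PMIDs_NCBI`, `PMIDs_PD`, `PMIDs_NCBI`.
#' @param report A `"link_report"` from [classify_linkage()].
#' @param gene_lit Output of [count_gene_literature()] for the same genes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_link_report <- function(report, gene_lit, path) {
  row <- match(report$input_id, gene_lit$input_id)
  out <- data.frame(
    ENSG = report$ensembl_id,
    GeneSymbol = ifelse(is.na(report$symbol), "Not Found", report$symbol),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  out[["availability of associations"]] <- report$availability
  out[["Evidence"]] <- ifelse(report$evidence_databases == "", "Not Found",
                              report$evidence_databases)
  out[["NU_PMIDs_PD"]] <- report$n_pmids_disease
  out[["NU_PMIDs_NCBI"]] <- gene_lit$n_pmids_gene[row]
  out[["PMIDs_PD"]] <- ifelse(report$pmids_disease == "", "Not Found",
                              report$pmids_disease)
  out[["PMIDs_NCBI"]] <- ifelse(gene_lit$pmids_gene[row] == "", "Not Found",
                                gene_lit$pmids_gene[row])
  write_tsv(out, path)
}

#' Write the candidate table in the metadata-table layout
#'
#' Columns: `Ensembl gene ID`, `GeneSymbol`, `ON score`, one
#' `PD_log2(fold change)_<study>` column per study, `TWAS Z score`,
#' `TWAS original paper (PMID)`; absent values are "Not Found".
#' @param candidates A `"candidate_table"` from [filter_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  out <- data.frame(
    `Ensembl gene ID` = candidates$gene_id,
    GeneSymbol = ifelse(is.na(candidates$symbol), "Not Found",
                        candidates$symbol),
    `ON score` = candidates$on_score,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (id in attr(candidates, "study_ids")) {
    v <- candidates[[paste0("log2fc_", id)]]
    out[[sprintf("PD_log2(fold change)_%s", id)]] <-
      ifelse(is.na(v), "Not Found", fmt_num(v))
  }
  out[["TWAS Z score"]] <- ifelse(is.na(candidates$twas_z), "Not Found",
                                  fmt_num(candidates$twas_z))
  out[["TWAS original paper (PMID)"]] <-
    ifelse(is.na(candidates$twas_source), "Not Found",
           candidates$twas_source)
  write_tsv(out, path)
}

#' Write all synthetic inputs and a manifest to a directory
#'
#' Invokes the three generators and writes every file the pipeline reads:
#' expression matrix, pairing manifest, one DEG list per study, TWAS
#' table, the five database snapshots, ID map, gene2pubmed table,
#' literature-evidence table, the ground-truth file (long format: `role`,
#' `gene_id`) and a `manifest.tsv` listing every path with its role, plus
#' a `config.yml` parameter sidecar.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if absent).
#' @return Path of the manifest file, invisibly; the manifest data frame
#'   is attached as attribute `"manifest"`.
#' @export
make_fixture <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  expr <- generate_expression(config)
  st <- generate_pd_studies(config, expr$truth)
  sn <- generate_snapshots(config, st$truth)
  truth <- sn$truth
  p <- function(f) file.path(outdir, f)
  rows <- list()
  add <- function(role, file) rows[[length(rows) + 1L]] <<-
    data.frame(role = role, path = file, stringsAsFactors = FALSE)
  write_expression(expr$expression, p("expression.tsv"))
  add("expression", "expression.tsv")
  write_tsv(expr$pairing, p("pairing.tsv")); add("pairing", "pairing.tsv")
  for (id in names(st$studies)) {
    f <- sprintf("study_%s.tsv", id)
    write_tsv(st$studies[[id]], p(f)); add(paste0("study:", id), f)
  }
  write_tsv(st$twas, p("twas.tsv")); add("twas", "twas.tsv")
  for (db in names(sn$snapshots)) {
    f <- sprintf("snapshot_%s.tsv", db)
    write_tsv(sn$snapshots[[db]], p(f)); add(paste0("snapshot:", db), f)
  }
  write_tsv(sn$idmap, p("idmap.tsv")); add("idmap", "idmap.tsv")
  write_tsv(sn$gene2pubmed, p("gene2pubmed.tsv"))
  add("gene2pubmed", "gene2pubmed.tsv")
  write_tsv(sn$literature, p("literature.tsv"))
  add("literature", "literature.tsv")
  tr <- do.call(rbind, lapply(
    c("planted_up", "planted_down", "twas_genes", "db_linked_genes",
      "functional_literature_genes"),
    function(role) if (length(truth[[role]]))
      data.frame(role = role, gene_id = truth[[role]],
                 stringsAsFactors = FALSE)))
  for (id in names(truth$study_membership)) {
    if (length(truth$study_membership[[id]]))
      tr <- rbind(tr, data.frame(role = paste0("study:", id),
                                 gene_id = truth$study_membership[[id]],
                                 stringsAsFactors = FALSE))
  }
  write_tsv(tr, p("truth.tsv")); add("truth", "truth.tsv")
  yaml::write_yaml(unclass(config), p("config.yml"))
  add("config", "config.yml")
  manifest <- do.call(rbind, rows)
  write_tsv(manifest, p("manifest.tsv"))
  out <- p("manifest.tsv")
  attr(out, "manifest") <- manifest
  invisible(out)
}

#' Read a ground-truth file back into the list form
#' @param path Path of `truth.tsv` from [make_fixture()].
#' @return Named list of gene-ID vectors keyed by role.
#' @export
read_truth <- function(path) {
  df <- read_tsv(path)
  split(df$gene_id, df$role)
}
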