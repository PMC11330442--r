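#' Assemble and validate a pipeline configuration
#'
#' Either pass every input path explicitly, or pass `manifest` (the
#' `manifest.tsv` written by [make_fixture()]) and the paths are filled in
#' from it. Parameters default to the study's conventions: 1.5-fold
#' classification threshold, top 5% selection, candidates need evidence in
#' at least 2 studies or any TWAS Z score, any database score accepted.
#'
#' @param manifest Optional path to a fixture manifest.
#' @param expression,pairing,twas,idmap,gene2pubmed,literature Input file
#'   paths.
#' @param studies Named character vector of study DEG list paths (names =
#'   study IDs).
#' @param snapshots Named character vector of the five snapshot paths.
#' @param disease_ids Disease ID(s) matched exactly in the snapshots.
#' @param outdir Directory for intermediate and final tables.
#' @param fold_threshold,selection_fraction,min_studies,min_scores,min_abs_z
#'   Stage parameters (see the stage functions).
#' @param disease_term Literature search term.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(manifest = NULL,
                            expression = NULL, pairing = NULL,
                            studies = NULL, twas = NULL,
                            snapshots = NULL, idmap = NULL,
                            gene2pubmed = NULL, literature = NULL,
                            disease_ids = "MONDO:0005180",
                            outdir = tempfile("unexploitr_out"),
                            fold_threshold = 1.5,
                            selection_fraction = 0.05,
                            min_studies = 2L, min_scores = 0,
                            min_abs_z = 0,
                            disease_term = "parkinson") {
  truth <- NULL
  if (!is.null(manifest)) {
    mf <- read_tsv(manifest)
    base <- dirname(manifest)
    pick <- function(role) {
      f <- mf$path[mf$role == role]
      if (length(f)) file.path(base, f[1]) else NULL
    }
    multi <- function(prefix) {
      sel <- startsWith(mf$role, prefix)
      stats::setNames(file.path(base, mf$path[sel]),
                      sub(prefix, "", mf$role[sel], fixed = TRUE))
    }
    expression <- expression %||% pick("expression")
    pairing <- pairing %||% pick("pairing")
    if (is.null(studies)) studies <- multi("study:")
    twas <- twas %||% pick("twas")
    if (is.null(snapshots)) snapshots <- multi("snapshot:")
    idmap <- idmap %||% pick("idmap")
    gene2pubmed <- gene2pubmed %||% pick("gene2pubmed")
    literature <- literature %||% pick("literature")
    truth <- pick("truth")
    cfg_file <- pick("config")
    if (!is.null(cfg_file)) {
      sim <- yaml::read_yaml(cfg_file)
      if (!is.null(sim$disease_id)) disease_ids <- sim$disease_id
    }
  }
  cfg <- list(expression = expression, pairing = pairing, studies = studies,
              twas = twas, snapshots = snapshots, idmap = idmap,
              gene2pubmed = gene2pubmed, literature = literature,
              truth = truth, disease_ids = disease_ids, outdir = outdir,
              fold_threshold = fold_threshold,
              selection_fraction = selection_fraction,
              min_studies = as.integer(min_studies),
              min_scores = min_scores, min_abs_z = min_abs_z,
              disease_term = disease_term)
  needed <- c("expression", "pairing", "idmap", "literature")
  for (nm in needed)
    if (is.null(cfg[[nm]])) stop("pipeline_config: missing input '", nm, "'")
  paths <- c(cfg$expression, cfg$pairing, cfg$studies, cfg$twas,
             cfg$snapshots, cfg$idmap, cfg$gene2pubmed, cfg$literature)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  if (cfg$fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (cfg$selection_fraction <= 0 || cfg$selection_fraction > 1)
    stop("selection_fraction must be in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full unexploited-gene discovery pipeline
#'
#' Executes, in order: paired-expression scoring and DEG selection, disease
#' DEG/TWAS integration, intersection, database-linkage classification,
#' candidate refinement, and literature adjudication. Every intermediate
#' table is persisted as TSV in `config$outdir` (with a parameter sidecar)
#' so the run can be inspected or resumed around the manual curation step;
#' the run is deterministic for fixed inputs.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"pipeline_report"`: list with `counts` (named
#'   funnel: universe, os_degs, pd_degs, os_pd_degs, linked, unlinked,
#'   candidates, unexploited), `unexploited_genes`, `paths` of all emitted
#'   tables, and `parameters`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)
  paths <- character()

  expr <- run_stage("os_meta", {
    m <- read_expression(config$expression)
    pairing <- read_pairing(config$pairing)
    list(scores = compute_on_scores(m, pairing, config$fold_threshold),
         n_pairs = nrow(pairing))
  })
  scores <- expr$scores
  write_tsv(as.data.frame(scores)[,
    c("gene_id", "n_up", "n_down", "n_unchanged", "on_score")],
    p("on_scores.tsv"))
  paths["on_scores"] <- p("on_scores.tsv")

  sel <- run_stage("os_meta", select_os_degs(scores, config$selection_fraction))
  write_gene_list(sel$up_genes, p("os_degs_up.txt"))
  write_gene_list(sel$down_genes, p("os_degs_down.txt"))
  paths["os_degs_up"] <- p("os_degs_up.txt")
  paths["os_degs_down"] <- p("os_degs_down.txt")

  integrated <- run_stage("deg_integration", {
    studies <- lapply(config$studies, read_study_list)
    twas <- if (!is.null(config$twas)) read_twas(config$twas) else NULL
    integrate_disease_degs(studies, twas)
  })
  write_integrated(integrated, p("pd_degs.tsv"))
  paths["pd_degs"] <- p("pd_degs.tsv")

  os_pd <- run_stage("deg_integration",
                     intersect_os_disease(sel, integrated, scores))
  write_tsv(os_pd, p("os_pd_degs.tsv"))
  paths["os_pd_degs"] <- p("os_pd_degs.tsv")

  linkage <- run_stage("disease_linker", {
    idmap <- read_idmap(config$idmap)
    keyed <- convert_ids(os_pd$gene_id, idmap)
    snaps <- lapply(config$snapshots, read_snapshot)
    report <- classify_linkage(keyed, snaps, config$disease_ids,
                               config$min_scores)
    lit_counts <- if (!is.null(config$gene2pubmed))
      count_gene_literature(keyed, read_tsv(config$gene2pubmed))
    else data.frame(input_id = keyed$input_id, n_pmids_gene = 0L,
                    pmids_gene = "", entrez_missing = is.na(keyed$entrez_id),
                    stringsAsFactors = FALSE)
    list(keyed = keyed, report = report, lit_counts = lit_counts)
  })
  write_link_report(linkage$report, linkage$lit_counts, p("link_report.tsv"))
  paths["link_report"] <- p("link_report.tsv")
  unlinked <- linkage$report$input_id[linkage$report$availability == "no"]
  write_gene_list(unlinked, p("unlinked_genes.txt"))
  paths["unlinked_genes"] <- p("unlinked_genes.txt")

  candidates <- run_stage("candidate_filter",
    filter_candidates(unlinked, integrated, scores,
                      min_studies = config$min_studies,
                      min_abs_z = config$min_abs_z,
                      idmap = linkage$keyed))
  write_candidate_table(candidates, p("candidates.tsv"))
  paths["candidates"] <- p("candidates.tsv")

  screened <- run_stage("literature_screen", {
    worksheet <- build_worksheet(candidates, config$disease_term)
    write_tsv(worksheet, p("worksheet.tsv"))
    evidence <- read_tsv(config$literature)
    adjudicate(candidates, evidence, config$disease_term)
  })
  paths["worksheet"] <- p("worksheet.tsv")
  write_tsv(screened, p("unexploited.tsv"))
  paths["unexploited"] <- p("unexploited.tsv")
  unexploited <- screened$gene_id[screened$unexploited == "yes"]
  write_gene_list(unexploited, p("unexploited_genes.txt"))
  paths["unexploited_genes"] <- p("unexploited_genes.txt")

  params <- config[c("fold_threshold", "selection_fraction", "min_studies",
                     "min_scores", "min_abs_z", "disease_ids",
                     "disease_term")]
  yaml::write_yaml(params, p("parameters.yml"))
  report <- list(
    counts = c(universe = nrow(scores),
               os_degs = length(sel$up_genes) + length(sel$down_genes),
               pd_degs = nrow(integrated),
               os_pd_degs = nrow(os_pd),
               linked = sum(linkage$report$availability == "yes"),
               unlinked = length(unlinked),
               candidates = nrow(candidates),
               unexploited = length(unexploited)),
    unexploited_genes = unexploited,
    paths = paths,
    parameters = params
  )
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Unexploited-gene discovery funnel\n")
  n <- x$counts
  cat(sprintf("  universe        %7d genes\n", n["universe"]))
  cat(sprintf("  stress DEGs     %7d (top %s)\n", n["os_degs"],
              format(x$parameters$selection_fraction)))
  cat(sprintf("  disease DEGs    %7d (union incl. TWAS)\n", n["pd_degs"]))
  cat(sprintf("  in both         %7d\n", n["os_pd_degs"]))
  cat(sprintf("  linked/unlinked %7d / %d\n", n["linked"], n["unlinked"]))
  cat(sprintf("  candidates      %7d\n", n["candidates"]))
  cat(sprintf("  unexploited     %7d", n["unexploited"]))
  if (length(x$unexploited_genes))
    cat(": ", paste(x$unexploited_genes, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}
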