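#' Configuration for the synthetic-data generators
#'
#' Bundles and validates every parameter of the synthetic inputs: a
#' gene universe with planted up/down-regulated genes whose stress samples
#' carry a multiplicative fold effect in a random subset of pairs, several
#' partially overlapping study DEG lists, sparse TWAS hits, and sparse
#' database/literature annotations. Defaults describe a compact study:
#' 2000 genes, 50 stress/control pairs, 50 genes planted per direction with
#' a 2-fold effect expressed in 80% of pairs under lognormal noise
#' (sd 0.25 on the log scale), and three partially overlapping disease
#' studies.
#'
#' @param n_genes,n_pairs Universe size and number of stress/control pairs.
#' @param n_planted_up,n_planted_down Numbers of genes planted as up-/
#'   down-regulated under stress.
#' @param fold_effect Multiplicative fold effect (> 1) applied to planted
#'   genes in responding pairs (\eqn{\times f} up, \eqn{\div f} down).
#' @param response_prob Probability that a planted gene responds in a given
#'   pair.
#' @param noise_sd SD of the lognormal multiplicative noise applied
#'   independently to every stress and control value (log scale).
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline expression is
#'   `exp(Normal(baseline_log_mean, baseline_log_sd))` (TPM scale).
#' @param n_studies Number of synthetic disease-DEG studies.
#' @param study_capture_prob Probability a true disease gene appears in a
#'   given study list.
#' @param study_fp_count Number of random non-disease genes added to each
#'   study list.
#' @param twas_hit_prob Probability a true disease gene has a TWAS record.
#' @param db_link_prob Probability a true disease gene is registered in at
#'   least one association-database snapshot.
#' @param lit_functional_prob Probability a true disease gene has a
#'   functional statement in the literature-evidence table.
#' @param disease_id Disease identifier used in snapshots and queries.
#' @param seed Integer seed; every generator derives its own stream from it
#'   so modules can be regenerated independently.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000L, n_pairs = 50L,
                              n_planted_up = 50L, n_planted_down = 50L,
                              fold_effect = 2, response_prob = 0.8,
                              noise_sd = 0.25,
                              baseline_log_mean = log(100),
                              baseline_log_sd = 1,
                              n_studies = 3L,
                              study_capture_prob = 0.6,
                              study_fp_count = 20L,
                              twas_hit_prob = 0.2,
                              db_link_prob = 0.5,
                              lit_functional_prob = 0.3,
                              disease_id = "MONDO:0005180",
                              seed = 7L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
    n_planted_up = as.integer(n_planted_up),
    n_planted_down = as.integer(n_planted_down),
    fold_effect = fold_effect, response_prob = response_prob,
    noise_sd = noise_sd,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    n_studies = as.integer(n_studies),
    study_capture_prob = study_capture_prob,
    study_fp_count = as.integer(study_fp_count),
    twas_hit_prob = twas_hit_prob, db_link_prob = db_link_prob,
    lit_functional_prob = lit_functional_prob,
    disease_id = as.character(disease_id),
    seed = as.integer(seed)
  )
  nums <- unlist(cfg[setdiff(names(cfg), "disease_id")])
  if (anyNA(nums) || any(!is.finite(nums)))
    stop("all configuration values must be finite")
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$n_pairs < 1L) stop("n_pairs must be positive")
  if (cfg$n_planted_up < 0L || cfg$n_planted_down < 0L ||
      cfg$n_planted_up + cfg$n_planted_down > cfg$n_genes)
    stop("planted gene counts must be non-negative and sum to at most n_genes")
  if (cfg$fold_effect <= 1) stop("fold_effect must be > 1")
  probs <- c(cfg$response_prob, cfg$study_capture_prob, cfg$twas_hit_prob,
             cfg$db_link_prob, cfg$lit_functional_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$baseline_log_sd < 0) stop("baseline_log_sd must be non-negative")
  if (cfg$n_studies < 1L) stop("n_studies must be positive")
  if (cfg$study_fp_count < 0L) stop("study_fp_count must be non-negative")
  class(cfg) <- "simulation_config"
  cfg
}

# per-generator seed streams derived from the global seed
stream_seed <- function(config, offset)
  (config$seed + offset) %% 2147483647L

synthetic_gene_ids <- function(n) sprintf("ENSG%011d", seq_len(n))

#' Generate paired stress/control expression with planted effects
#'
#' Every gene gets a lognormal baseline; planted genes carry the fold
#' effect (`* fold_effect` up, `/ fold_effect` down) in a
#' Bernoulli(`response_prob`) subset of pairs; every stress and control
#' value then receives independent lognormal noise. All values are
#' positive and the output is bit-reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @return List with `expression` (n_genes x 2*n_pairs matrix, gene IDs as
#'   rownames), `pairing` (data frame `stress_sample`, `control_sample`,
#'   `source_study`) and `truth` (list with `planted_up`, `planted_down`
#'   gene-ID vectors).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stream_seed(config, 0L))
  g <- config$n_genes; p <- config$n_pairs
  genes <- synthetic_gene_ids(g)
  planted <- sample.int(g, config$n_planted_up + config$n_planted_down)
  idx_up <- planted[seq_len(config$n_planted_up)]
  idx_down <- planted[config$n_planted_up + seq_len(config$n_planted_down)]
  baseline <- exp(rnorm(g, config$baseline_log_mean, config$baseline_log_sd))
  effect <- matrix(1, g, p)
  responds <- matrix(runif(length(planted) * p) < config$response_prob,
                     length(planted), p)
  effect[idx_up, ][responds[seq_along(idx_up), , drop = FALSE]] <-
    config$fold_effect
  effect[idx_down, ][responds[length(idx_up) + seq_along(idx_down), ,
                              drop = FALSE]] <- 1 / config$fold_effect
  noise <- function() {
    if (config$noise_sd == 0) matrix(1, g, p)
    else matrix(exp(rnorm(g * p, 0, config$noise_sd)), g, p)
  }
  control <- baseline * noise()
  stress <- baseline * effect * noise()
  stress_names <- sprintf("stress_%03d", seq_len(p))
  control_names <- sprintf("control_%03d", seq_len(p))
  expr <- cbind(stress, control)
  dimnames(expr) <- list(genes, c(stress_names, control_names))
  pairing <- data.frame(
    stress_sample = stress_names,
    control_sample = control_names,
    source_study = sprintf("GSE9%05d", (seq_len(p) - 1L) %/% 10L + 1L),
    stringsAsFactors = FALSE
  )
  list(expression = expr, pairing = pairing,
       truth = list(planted_up = genes[idx_up],
                    planted_down = genes[idx_down]))
}

#' Generate multi-study disease-DEG lists and TWAS evidence
#'
#' Each of `n_studies` lists captures each true disease gene (planted up or
#' down) with probability `study_capture_prob`, assigning it a log2 fold
#' change whose sign matches the planted direction, plus `study_fp_count`
#' random non-disease genes with small noise fold changes. TWAS records are
#' drawn per true gene with probability `twas_hit_prob`.
#'
#' @param config A [simulation_config()].
#' @param truth Ground-truth list from [generate_expression()] (needs
#'   `planted_up`, `planted_down`).
#' @return List with `studies` (named list of data frames `gene_id`,
#'   `log2fc`; names are PMID-like study IDs), `twas` (data frame
#'   `gene_id`, `z_score`, `source_study`) and `truth` augmented with
#'   `study_membership` and `twas_genes`.
#' @export
generate_pd_studies <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(truth$planted_up) && is.null(truth$planted_down))
    stop("ground truth has an empty gene universe")
  set.seed(stream_seed(config, 1L))
  genes <- synthetic_gene_ids(config$n_genes)
  true_genes <- c(truth$planted_up, truth$planted_down)
  dir <- c(rep(1, length(truth$planted_up)), rep(-1, length(truth$planted_down)))
  other <- setdiff(genes, true_genes)
  study_ids <- sprintf("9%07d", seq_len(config$n_studies))
  studies <- vector("list", config$n_studies)
  names(studies) <- study_ids
  for (j in seq_len(config$n_studies)) {
    keep <- runif(length(true_genes)) < config$study_capture_prob
    tg <- true_genes[keep]
    tfc <- dir[keep] * abs(rnorm(sum(keep), log2(config$fold_effect), 0.25))
    nfp <- min(config$study_fp_count, length(other))
    fp <- if (nfp > 0) sample(other, nfp) else character()
    ffc <- rnorm(length(fp), 0, 0.4)
    studies[[j]] <- data.frame(gene_id = c(tg, fp), log2fc = c(tfc, ffc),
                               stringsAsFactors = FALSE)
  }
  hit <- runif(length(true_genes)) < config$twas_hit_prob
  twas <- data.frame(
    gene_id = true_genes[hit],
    z_score = dir[hit] * abs(rnorm(sum(hit), 4, 0.8)),
    source_study = sample(c("93523105", "90824768"), sum(hit), replace = TRUE),
    stringsAsFactors = FALSE
  )
  truth$study_membership <- lapply(studies, function(s) s$gene_id)
  truth$twas_genes <- twas$gene_id
  list(studies = studies, twas = twas, truth = truth)
}

snapshot_db_names <- function()
  c("open_targets", "disgenet", "mirtex", "rnadisease", "pubchem")

#' Generate database snapshots, ID map, gene2pubmed and literature evidence
#'
#' Draws the database-linked subset of the true disease genes with
#' probability `db_link_prob` and registers each linked gene in one or more
#' of the five snapshots (`open_targets`, `disgenet`, `mirtex`,
#' `rnadisease`, `pubchem`) with synthetic evidence PMIDs; each snapshot
#' keys genes in its own vocabulary (Ensembl ID, Entrez ID or symbol) so
#' that ID conversion is exercised. Functional-literature genes, drawn with
#' probability `lit_functional_prob`, get a literature row with a
#' functional statement and PMCID. Decoy rows for an unrelated disease ID
#' are included to exercise exact disease matching.
#'
#' @param config A [simulation_config()].
#' @param truth Ground-truth list (needs `planted_up`, `planted_down`).
#' @return List with `snapshots` (named list of five data frames
#'   `gene_key`, `disease_id`, `pmids`, `score`), `idmap` (data frame
#'   `ensembl_id`, `symbol`, `entrez_id`), `gene2pubmed` (data frame
#'   `entrez_id`, `pmid`), `literature` (one row per gene: `gene_id`,
#'   `symbol`, `n_publications`, `evidence_pmcid`, `evidence_statement`,
#'   `functional_statement`) and `truth` augmented with `db_linked_genes`
#'   and `functional_literature_genes`.
#' @export
generate_snapshots <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stream_seed(config, 2L))
  genes <- synthetic_gene_ids(config$n_genes)
  g <- config$n_genes
  idmap <- data.frame(
    ensembl_id = genes,
    symbol = sprintf("SYN%04d", seq_len(g)),
    entrez_id = as.character(500000L + seq_len(g)),
    stringsAsFactors = FALSE
  )
  # a small fraction of genes lack an Entrez ID (annotation gaps)
  idmap$entrez_id[sample.int(g, max(1L, g %/% 50L))] <- NA_character_
  true_genes <- c(truth$planted_up, truth$planted_down)
  linked <- true_genes[runif(length(true_genes)) < config$db_link_prob]
  dbs <- snapshot_db_names()
  key_for <- function(db, ens) {
    row <- match(ens, idmap$ensembl_id)
    switch(db,
      open_targets = ens,
      disgenet = ifelse(is.na(idmap$entrez_id[row]),
                        idmap$symbol[row], idmap$entrez_id[row]),
      idmap$symbol[row])  # mirtex, rnadisease, pubchem key by symbol
  }
  scored_dbs <- c("open_targets", "disgenet", "rnadisease")
  rows <- list()
  for (gene in linked) {
    in_dbs <- sample(dbs, sample(1:2, 1))
    for (db in in_dbs) {
      pmids <- sample(30000000:30999999, sample(1:3, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        db = db, gene_key = key_for(db, gene),
        disease_id = config$disease_id,
        pmids = paste(pmids, collapse = ";"),
        score = if (db %in% scored_dbs) round(runif(1, 0.3, 1), 3) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  # decoys: random genes linked to an unrelated disease
  n_decoy <- min(20L, g)
  for (gene in sample(genes, n_decoy)) {
    db <- sample(dbs, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      db = db, gene_key = key_for(db, gene), disease_id = "MONDO:0000001",
      pmids = paste(sample(30000000:30999999, 1), collapse = ";"),
      score = NA_real_, stringsAsFactors = FALSE)
  }
  all_rows <- do.call(rbind, rows)
  snapshots <- lapply(dbs, function(db) {
    s <- all_rows[all_rows$db == db, c("gene_key", "disease_id", "pmids", "score")]
    rownames(s) <- NULL
    s
  })
  names(snapshots) <- dbs
  functional <- true_genes[runif(length(true_genes)) < config$lit_functional_prob]
  is_true <- genes %in% true_genes
  is_fun <- genes %in% functional
  n_pub <- rpois(g, ifelse(is_true, 5, 1))
  n_pub[is_fun] <- pmax(n_pub[is_fun], 1L)
  literature <- data.frame(
    gene_id = genes,
    symbol = idmap$symbol,
    n_publications = n_pub,
    evidence_pmcid = ifelse(is_fun, sprintf("PMC%07d", sample.int(9999999, g)),
                            "Not Found"),
    evidence_statement = ifelse(is_fun,
      "synthetic functional statement linking the gene to the disease",
      "Not Found"),
    functional_statement = is_fun,
    stringsAsFactors = FALSE
  )
  with_entrez <- which(!is.na(idmap$entrez_id))
  n_lit <- rpois(length(with_entrez), 3)
  g2p <- data.frame(
    entrez_id = rep(idmap$entrez_id[with_entrez], n_lit),
    pmid = as.character(sample(20000000:20999999, sum(n_lit), replace = TRUE)),
    stringsAsFactors = FALSE
  )
  truth$db_linked_genes <- linked
  truth$functional_literature_genes <- functional
  list(snapshots = snapshots, idmap = idmap, gene2pubmed = g2p,
       literature = literature, truth = truth)
}
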