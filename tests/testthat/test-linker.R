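toy_idmap <- function() {
  data.frame(
    ensembl_id = c("ENSG01", "ENSG02", "ENSG03", "ENSG04"),
    symbol = c("AAA", "BBB", "CCC", NA),
    entrez_id = c("101", "102", NA, "104"),
    stringsAsFactors = FALSE
  )
}

empty_snapshot <- function() {
  data.frame(gene_key = character(), disease_id = character(),
             pmids = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

toy_snapshots <- function(disgenet_rows = NULL, open_targets_rows = NULL) {
  s <- stats::setNames(replicate(5, empty_snapshot(), simplify = FALSE),
                       c("open_targets", "disgenet", "mirtex",
                         "rnadisease", "pubchem"))
  if (!is.null(disgenet_rows)) s$disgenet <- disgenet_rows
  if (!is.null(open_targets_rows)) s$open_targets <- open_targets_rows
  s
}

test_that("ID conversion carries all key forms and keeps unmapped genes", {
  keyed <- convert_ids(c("ENSG01", "BBB", "104", "MISSING"), toy_idmap())
  expect_equal(keyed$symbol[1], "AAA")
  expect_equal(keyed$entrez_id[1], "101")
  expect_equal(keyed$ensembl_id[2], "ENSG02")   # matched via symbol
  expect_equal(keyed$ensembl_id[3], "ENSG04")   # matched via entrez
  expect_true(keyed$unmapped[4])
  expect_equal(keyed$ensembl_id[4], "MISSING")  # original ID preserved
  expect_equal(sum(keyed$unmapped), 1L)
})

test_that("symbol collisions resolve to the lowest-sorting Ensembl ID", {
  im <- rbind(toy_idmap(),
              data.frame(ensembl_id = "ENSG00", symbol = "AAA",
                         entrez_id = "100", stringsAsFactors = FALSE))
  keyed <- convert_ids("AAA", im)
  expect_equal(keyed$ensembl_id, "ENSG00")
  expect_true("AAA" %in% attr(keyed, "symbol_collisions"))
  expect_error(convert_ids("AAA", rbind(toy_idmap(), toy_idmap())),
               "unique")
})

test_that("snapshot queries respect key forms, disease ID and score threshold", {
  keyed <- convert_ids(c("ENSG01", "ENSG02"), toy_idmap())
  snap <- data.frame(gene_key = c("101", "BBB", "101"),
                     disease_id = c("D1", "D1", "D2"),
                     pmids = c("1;2", "3", "4"),
                     score = c(0.9, NA, 0.9), stringsAsFactors = FALSE)
  hit <- query_snapshot(keyed, snap, "D1", min_score = 0.5)
  expect_setequal(hit$input_id, c("ENSG01", "ENSG02"))  # entrez + symbol keys
  expect_equal(nrow(query_snapshot(keyed, snap, "D1", min_score = 0.95)), 1L)
  # score-free record passes any threshold
  expect_equal(query_snapshot(keyed, snap, "D1", 0.95)$input_id, "ENSG02")
  expect_equal(nrow(query_snapshot(keyed, snap, "D3")), 0L)
  expect_error(query_snapshot(keyed, snap, ""), "disease_id")
  bad <- snap; bad$gene_key[2] <- ""
  expect_error(query_snapshot(keyed, bad, "D1"), "line")
})

test_that("snapshot query equals a linear-scan oracle on random data", {
  set.seed(91)
  im <- data.frame(ensembl_id = sprintf("E%02d", 1:20),
                   symbol = sprintf("S%02d", 1:20),
                   entrez_id = as.character(1:20), stringsAsFactors = FALSE)
  keyed <- convert_ids(im$ensembl_id, im)
  for (rep in 1:10) {
    snap <- data.frame(
      gene_key = sample(c(im$ensembl_id, im$symbol, im$entrez_id, "zzz"), 30,
                        replace = TRUE),
      disease_id = sample(c("D1", "D2"), 30, replace = TRUE),
      pmids = as.character(sample(100, 30)),
      score = ifelse(runif(30) < 0.3, NA, round(runif(30), 2)),
      stringsAsFactors = FALSE)
    min_score <- 0.4
    got <- query_snapshot(keyed, snap, "D1", min_score)
    oracle <- character()
    for (i in seq_len(nrow(keyed))) {
      for (j in seq_len(nrow(snap))) {
        keys <- unlist(keyed[i, c("ensembl_id", "symbol", "entrez_id")])
        if (snap$gene_key[j] %in% keys && snap$disease_id[j] == "D1" &&
            (is.na(snap$score[j]) || snap$score[j] >= min_score))
          oracle <- c(oracle, keyed$input_id[i])
      }
    }
    expect_setequal(unique(got$input_id), unique(oracle))
  }
})

test_that("linkage classification partitions genes and dedups shared PMIDs", {
  keyed <- convert_ids(c("ENSG01", "ENSG02", "ENSG03"), toy_idmap())
  snaps <- toy_snapshots(
    disgenet_rows = data.frame(gene_key = "101", disease_id = "D1",
                               pmids = "11;12", score = 0.8,
                               stringsAsFactors = FALSE),
    open_targets_rows = data.frame(gene_key = "ENSG01", disease_id = "D1",
                                   pmids = "12;13", score = NA,
                                   stringsAsFactors = FALSE))
  rep <- classify_linkage(keyed, snaps, "D1")
  g1 <- rep[rep$input_id == "ENSG01", ]
  expect_equal(g1$availability, "yes")
  expect_setequal(strsplit(g1$evidence_databases, ";")[[1]],
                  c("open_targets", "disgenet"))
  expect_equal(g1$n_pmids_disease, 3L)  # 11,12,13 with 12 counted once
  expect_equal(rep$availability[rep$input_id == "ENSG02"], "no")
  expect_equal(sum(rep$availability == "yes") +
                 sum(rep$availability == "no"), 3L)
  expect_error(classify_linkage(keyed, snaps[1:4], "D1"), "five")
})

test_that("raising a score threshold never converts unlinked into linked", {
  set.seed(92)
  im <- data.frame(ensembl_id = sprintf("E%02d", 1:15),
                   symbol = sprintf("S%02d", 1:15),
                   entrez_id = as.character(1:15), stringsAsFactors = FALSE)
  keyed <- convert_ids(im$ensembl_id, im)
  snaps <- toy_snapshots(
    disgenet_rows = data.frame(
      gene_key = sample(im$entrez_id, 10), disease_id = "D1",
      pmids = as.character(1:10), score = round(runif(10), 2),
      stringsAsFactors = FALSE))
  prev_yes <- NULL
  for (thr in c(0, 0.3, 0.6, 0.9, 1)) {
    rep <- classify_linkage(keyed, snaps, "D1", min_scores = thr)
    yes <- rep$input_id[rep$availability == "yes"]
    if (!is.null(prev_yes)) expect_true(all(yes %in% prev_yes))
    prev_yes <- yes
  }
})

test_that("linkage verdicts are independent of row and gene order", {
  set.seed(93)
  im <- data.frame(ensembl_id = sprintf("E%02d", 1:10),
                   symbol = sprintf("S%02d", 1:10),
                   entrez_id = as.character(1:10), stringsAsFactors = FALSE)
  rows <- data.frame(gene_key = sample(im$symbol, 8, TRUE),
                     disease_id = "D1", pmids = as.character(1:8),
                     score = NA, stringsAsFactors = FALSE)
  keyed <- convert_ids(im$ensembl_id, im)
  r1 <- classify_linkage(keyed, toy_snapshots(disgenet_rows = rows), "D1")
  shuffled <- rows[sample(nrow(rows)), ]
  keyed2 <- convert_ids(rev(im$ensembl_id), im)
  r2 <- classify_linkage(keyed2, toy_snapshots(disgenet_rows = shuffled), "D1")
  r2 <- r2[match(r1$input_id, r2$input_id), ]
  expect_equal(r1$availability, r2$availability)
  expect_equal(r1$pmids_disease, r2$pmids_disease)
})

test_that("gene literature counts equal a group-by oracle and dedupe", {
  keyed <- convert_ids(c("ENSG01", "ENSG02", "ENSG03"), toy_idmap())
  g2p <- data.frame(entrez_id = c("101", "101", "101", "102", "101"),
                    pmid = c("1", "2", "3", "9", "2"),
                    stringsAsFactors = FALSE)
  got <- count_gene_literature(keyed, g2p)
  expect_equal(got$n_pmids_gene, c(3L, 1L, 0L))
  expect_true(got$entrez_missing[3])
  set.seed(94)
  big <- data.frame(entrez_id = sample(c("101", "102", "104"), 60, TRUE),
                    pmid = as.character(sample(20, 60, TRUE)),
                    stringsAsFactors = FALSE)
  got2 <- count_gene_literature(convert_ids(c("ENSG01", "ENSG02", "ENSG04"),
                                            toy_idmap()), big)
  oracle <- vapply(c("101", "102", "104"), function(e)
    length(unique(big$pmid[big$entrez_id == e])), integer(1))
  expect_equal(got2$n_pmids_gene, unname(oracle))
})
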