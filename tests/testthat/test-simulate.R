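test_that("configuration rejects invalid parameter combinations", {
  expect_error(simulation_config(n_pairs = 0), "n_pairs")
  expect_error(simulation_config(fold_effect = 1), "fold_effect")
  expect_error(simulation_config(response_prob = 1.2), "probabilities")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(n_genes = 10, n_planted_up = 8,
                                 n_planted_down = 8), "planted")
  expect_error(simulation_config(noise_sd = NaN), "finite")
})

test_that("identical seeds give bit-identical outputs from all generators", {
  cfg <- small_config(seed = 42L)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a, b)
  sa <- generate_pd_studies(cfg, a$truth)
  sb <- generate_pd_studies(cfg, b$truth)
  expect_identical(sa, sb)
  expect_identical(generate_snapshots(cfg, sa$truth),
                   generate_snapshots(cfg, sb$truth))
})

test_that("noise-free fully-responding genes shift by exactly the fold effect", {
  cfg <- small_config(noise_sd = 0, response_prob = 1, fold_effect = 2,
                      seed = 5L)
  ex <- generate_expression(cfg)
  s <- ex$expression[ex$truth$planted_up, ex$pairing$stress_sample]
  co <- ex$expression[ex$truth$planted_up, ex$pairing$control_sample]
  expect_equal(unname(s / co), matrix(2, nrow(s), ncol(s)))
  d <- ex$expression[ex$truth$planted_down, ex$pairing$stress_sample] /
    ex$expression[ex$truth$planted_down, ex$pairing$control_sample]
  expect_equal(unname(d), matrix(0.5, nrow(d), ncol(d)))
  # downstream: every planted gene scores exactly +/- n_pairs
  sc <- compute_on_scores(ex$expression, ex$pairing)
  expect_true(all(sc$on_score[match(ex$truth$planted_up, sc$gene_id)] ==
                    cfg$n_pairs))
  expect_true(all(sc$on_score[match(ex$truth$planted_down, sc$gene_id)] ==
                    -cfg$n_pairs))
})

test_that("mean log2 shift of planted-up genes matches the generative model", {
  cfg <- simulation_config(n_genes = 2000L, n_pairs = 50L, fold_effect = 2,
                           response_prob = 0.8, noise_sd = 0.25, seed = 7L)
  ex <- generate_expression(cfg)
  s <- ex$expression[ex$truth$planted_up, ex$pairing$stress_sample]
  co <- ex$expression[ex$truth$planted_up, ex$pairing$control_sample]
  lr <- log2(s / co)
  se <- sd(lr) / sqrt(length(lr))
  # E[log2 ratio] = response_prob * log2(fold_effect) = 0.8
  expect_lt(abs(mean(lr) - 0.8), 3 * se)
})

test_that("study lists degenerate correctly at extreme capture probabilities", {
  cfg1 <- small_config(study_capture_prob = 1, study_fp_count = 0L)
  ex <- generate_expression(cfg1)
  st <- generate_pd_studies(cfg1, ex$truth)
  truth_set <- sort(c(ex$truth$planted_up, ex$truth$planted_down))
  for (s in st$studies) expect_equal(sort(s$gene_id), truth_set)
  cfg0 <- small_config(study_capture_prob = 0, study_fp_count = 0L)
  st0 <- generate_pd_studies(cfg0, generate_expression(cfg0)$truth)
  for (s in st0$studies) expect_equal(nrow(s), 0L)
})

test_that("per-study capture fraction is binomially consistent and signs match", {
  cfg <- simulation_config(n_genes = 1500L, n_planted_up = 150L,
                           n_planted_down = 150L, n_studies = 3L,
                           study_capture_prob = 0.6, seed = 13L)
  ex <- generate_expression(cfg)
  st <- generate_pd_studies(cfg, ex$truth)
  truth_set <- c(ex$truth$planted_up, ex$truth$planted_down)
  p <- cfg$study_capture_prob
  se <- sqrt(p * (1 - p) / length(truth_set))
  for (s in st$studies) {
    frac <- mean(truth_set %in% s$gene_id)
    expect_lt(abs(frac - p), 3 * se)
    up_fc <- s$log2fc[s$gene_id %in% ex$truth$planted_up]
    down_fc <- s$log2fc[s$gene_id %in% ex$truth$planted_down]
    expect_true(all(up_fc > 0) && all(down_fc < 0))
  }
})

test_that("snapshot linkage honours db_link_prob at its extremes", {
  cfg0 <- small_config(db_link_prob = 0)
  ex <- generate_expression(cfg0)
  sn0 <- generate_snapshots(cfg0, ex$truth)
  truth_set <- c(ex$truth$planted_up, ex$truth$planted_down)
  keyed <- convert_ids(truth_set, sn0$idmap)
  disease_rows <- function(sn) unlist(lapply(sn$snapshots, function(s)
    s$gene_key[s$disease_id == cfg0$disease_id]))
  all_keys <- unlist(keyed[c("ensembl_id", "symbol", "entrez_id")])
  expect_length(intersect(disease_rows(sn0), all_keys), 0)
  cfg1 <- small_config(db_link_prob = 1)
  ex1 <- generate_expression(cfg1)
  sn1 <- generate_snapshots(cfg1, ex1$truth)
  expect_setequal(sn1$truth$db_linked_genes,
                  c(ex1$truth$planted_up, ex1$truth$planted_down))
  rep <- classify_linkage(convert_ids(sn1$truth$db_linked_genes, sn1$idmap),
                          sn1$snapshots, cfg1$disease_id)
  expect_true(all(rep$availability == "yes"))
})

test_that("fixture files round-trip numeric values to full precision", {
  cfg <- small_config(seed = 21L)
  dir <- withr::local_tempdir()
  mf <- make_fixture(cfg, dir)
  ex <- generate_expression(cfg)
  back <- read_expression(file.path(dir, "expression.tsv"))
  expect_identical(back, ex$expression)
  st <- generate_pd_studies(cfg, ex$truth)
  first <- names(st$studies)[1]
  back_study <- read_study_list(file.path(dir, sprintf("study_%s.tsv", first)))
  expect_identical(back_study$log2fc, st$studies[[first]]$log2fc)
  manifest <- read_tsv(mf)
  expect_true(all(file.exists(file.path(dir, manifest$path))))
  roles <- manifest$role
  expect_true(all(c("expression", "pairing", "twas", "idmap", "gene2pubmed",
                    "literature", "truth") %in% roles))
  expect_equal(sum(startsWith(roles, "study:")), cfg$n_studies)
  expect_equal(sum(startsWith(roles, "snapshot:")), 5L)
})
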