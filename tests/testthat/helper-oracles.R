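# Independent oracles used across tests. These deliberately use the
# slowest, most literal formulation of each quantity.

# per-gene recount of pair calls with explicit double loop
recount_oracle <- function(expression, pairing, fold_threshold = 1.5) {
  genes <- rownames(expression)
  out <- data.frame(gene_id = genes, n_up = 0L, n_down = 0L,
                    n_unchanged = 0L, on_score = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    for (j in seq_len(nrow(pairing))) {
      s <- expression[i, pairing$stress_sample[j]]
      cc <- expression[i, pairing$control_sample[j]]
      r <- (s + 1) / (cc + 1)
      if (r >= fold_threshold) out$n_up[i] <- out$n_up[i] + 1L
      else if (r <= 1 / fold_threshold) out$n_down[i] <- out$n_down[i] + 1L
      else out$n_unchanged[i] <- out$n_unchanged[i] + 1L
    }
  }
  out$on_score <- out$n_up - out$n_down
  out
}

random_paired_matrix <- function(n_genes, n_pairs) {
  m <- matrix(rexp(n_genes * 2 * n_pairs, rate = 0.05),
              n_genes, 2 * n_pairs)
  rownames(m) <- sprintf("G%03d", seq_len(n_genes))
  colnames(m) <- c(sprintf("s%02d", seq_len(n_pairs)),
                   sprintf("c%02d", seq_len(n_pairs)))
  list(expression = m,
       pairing = data.frame(stress_sample = sprintf("s%02d", seq_len(n_pairs)),
                            control_sample = sprintf("c%02d", seq_len(n_pairs)),
                            stringsAsFactors = FALSE))
}

# upper-tail hypergeometric values computed once with exact integer
# rational arithmetic (arbitrary precision), frozen here; columns are
# N, K, n, k, P(X >= k)
exact_hypergeom_cases <- function() {
  cases <- list(
    list(10L, 5L, 5L, 5L, "3.968253968253968e-03"),
    list(10L, 5L, 5L, 3L, "5.000000000000000e-01"),
    list(20L, 8L, 10L, 6L, "8.490116694451059e-02"),
    list(37L, 12L, 15L, 9L, "4.551662832105154e-03"),
    list(48L, 20L, 24L, 15L, "3.831810878547779e-03"),
    list(60L, 30L, 30L, 25L, "1.782077736895487e-07"),
    list(60L, 30L, 30L, 15L, "6.017271810907903e-01"),
    list(60L, 10L, 50L, 10L, "1.362479032043704e-01"),
    list(55L, 27L, 13L, 11L, "3.745310359820270e-03"),
    list(60L, 59L, 59L, 58L, "1.000000000000000e+00"),
    list(33L, 1L, 32L, 1L, "9.696969696969697e-01"),
    list(60L, 30L, 1L, 1L, "5.000000000000000e-01"),
    list(44L, 22L, 22L, 0L, "1.000000000000000e+00"),
    list(59L, 17L, 41L, 17L, "5.462329207772015e-04"),
    list(60L, 45L, 50L, 40L, "5.985319959262939e-02"),
    list(8L, 5L, 2L, 1L, "8.928571428571429e-01"),
    list(22L, 4L, 2L, 1L, "3.376623376623377e-01"),
    list(39L, 36L, 22L, 10L, "1.000000000000000e+00"),
    list(59L, 4L, 11L, 1L, "5.724700412632985e-01"),
    list(26L, 18L, 11L, 11L, "4.118993135011442e-03"),
    list(20L, 6L, 1L, 1L, "3.000000000000000e-01"),
    list(54L, 6L, 39L, 3L, "9.561087328012966e-01"),
    list(9L, 1L, 6L, 1L, "6.666666666666666e-01"),
    list(11L, 1L, 2L, 0L, "1.000000000000000e+00"),
    list(13L, 13L, 1L, 1L, "1.000000000000000e+00"),
    list(32L, 31L, 17L, 15L, "1.000000000000000e+00"),
    list(58L, 3L, 50L, 2L, "9.528130671506352e-01"),
    list(26L, 17L, 26L, 15L, "1.000000000000000e+00"),
    list(18L, 17L, 11L, 0L, "1.000000000000000e+00"),
    list(30L, 29L, 25L, 20L, "1.000000000000000e+00")
  )
  do.call(rbind, lapply(cases, function(cs)
    data.frame(N = cs[[1]], K = cs[[2]], n = cs[[3]], k = cs[[4]],
               p = as.numeric(cs[[5]]))))
}

# small synthetic config so fixture-driven tests stay fast
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 300L, n_pairs = 12L, n_planted_up = 15L,
         n_planted_down = 15L, study_fp_count = 8L),
    list(...))
  do.call(simulation_config, args)
}
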