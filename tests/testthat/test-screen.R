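test_that("planted anti-phase genes are candidates and flat genes are not", {
  cfg <- simulation_config(n_genes = 50, n_planted = 6, noise_sd = 0,
                           seed = 15)
  st <- simulate_wer_study(cfg)
  res <- apply_criteria(st$signals$mrna, st$signals$h3k4me3_gene,
                        st$signals$h3k27me3_pro[["2kb"]],
                        st$signals$h3k27me3_gene)
  planted <- st$truth$gene_id[st$truth$is_planted_wer]
  expect_setequal(res$gene_id[res$candidate], planted)
  expect_true(all(!res$crit1[!res$gene_id %in% planted]))
})

test_that("candidate calls equal an independent filter-by-filter recomputation", {
  cfg <- simulation_config(n_genes = 300, n_planted = 12, noise_sd = 0.2,
                           seed = 77)
  st <- simulate_wer_study(cfg)
  crit <- screen_criteria()
  res <- apply_criteria(st$signals$mrna, st$signals$h3k4me3_gene,
                        st$signals$h3k27me3_pro[["2kb"]],
                        st$signals$h3k27me3_gene, crit)
  # brute-force recomputation gene by gene, one threshold at a time
  sm <- st$signals
  nb <- lapply(list(sm$mrna, sm$h3k4me3_gene, sm$h3k27me3_pro[["2kb"]]),
               function(s) nb_seasonal_test(s$counts, s$library_sizes, s$times))
  for (i in seq_len(nrow(res))) {
    g <- res$gene_id[i]
    pass <- TRUE
    for (j in 1:3) {
      s <- list(sm$mrna, sm$h3k4me3_gene, sm$h3k27me3_pro[["2kb"]])[[j]]
      f <- cosinor_fit(s$rpkm[g, ], s$times)
      pass <- pass && f$p_value < 0.05 &&
        amplitude_log2(s$rpkm[g, ]) > 1 &&
        nb[[j]]$fdr[nb[[j]]$gene_id == g] < 0.05
    }
    mon <- function(s) spline_monthly(s$rpkm[g, ], s$times)
    r1 <- spearman_rho(mon(sm$h3k27me3_pro[["2kb"]]), mon(sm$mrna))
    r2 <- spearman_rho(mon(sm$h3k27me3_pro[["2kb"]]), mon(sm$h3k4me3_gene))
    pass <- pass && !is.na(r1) && r1 < 0 && !is.na(r2) && r2 < 0
    pass <- pass && max(sm$h3k27me3_gene$rpkm[g, ]) < 2
    expect_equal(res$candidate[i], pass, info = g)
  }
})

test_that("tightening any threshold never enlarges the candidate set", {
  cfg <- simulation_config(n_genes = 200, n_planted = 15, noise_sd = 0.3,
                           seed = 19)
  st <- simulate_wer_study(cfg)
  base <- screen_criteria()
  loose <- apply_criteria(st$signals$mrna, st$signals$h3k4me3_gene,
                          st$signals$h3k27me3_pro[["2kb"]],
                          st$signals$h3k27me3_gene, base)
  tighter <- list(
    screen_criteria(nb_fdr_max = 0.01),
    screen_criteria(cosinor_p_max = 0.01),
    screen_criteria(amp_log2_min = 2),
    screen_criteria(rho_max = -0.5),
    screen_criteria(k27_low_max_rpkm = 0.5)
  )
  for (crit in tighter) {
    res <- apply_criteria(st$signals$mrna, st$signals$h3k4me3_gene,
                          st$signals$h3k27me3_pro[["2kb"]],
                          st$signals$h3k27me3_gene, crit)
    expect_true(all(res$gene_id[res$candidate] %in%
                      loose$gene_id[loose$candidate]),
                info = "tightened candidate set must be a subset")
  }
})

test_that("multi-window robustness matches set algebra", {
  sets <- list(`1kb` = c("a", "b", "c"), `2kb` = c("b", "c", "d"),
               `3kb` = c("c", "b", "d"))
  expect_equal(multi_window_robust(sets), c("b", "c"))
  expect_equal(multi_window_robust(sets, "at_least_k", k = 2),
               c("b", "c", "d"))
  expect_false("d" %in% multi_window_robust(sets))
  # random sets vs direct enumeration
  set.seed(23)
  for (rep in 1:10) {
    rs <- replicate(3, sample(letters, sample(5:15, 1)), simplify = FALSE)
    expect_equal(multi_window_robust(rs),
                 sort(intersect(intersect(rs[[1]], rs[[2]]), rs[[3]])))
    k2 <- sort(unique(unlist(rs))[sapply(unique(unlist(rs)), function(g)
      sum(sapply(rs, function(s) g %in% s)) >= 2)])
    expect_equal(multi_window_robust(rs, "at_least_k", k = 2), k2)
  }
})

test_that("candidates are ranked ascending by rho with stated tie-breaks", {
  df <- data.frame(gene_id = c("g1", "g2", "g3"),
                   rho_k27_mrna = c(-0.5, -0.9, -0.7),
                   rho_k27_k4 = c(-0.1, -0.2, -0.3))
  r <- rank_candidates(df)
  expect_equal(r$gene_id, c("g2", "g3", "g1"))
  expect_equal(r$rank, 1:3)

  tie <- data.frame(gene_id = c("gB", "gA"),
                    rho_k27_mrna = c(-0.6, -0.6),
                    rho_k27_k4 = c(-0.4, -0.2))
  expect_equal(rank_candidates(tie)$gene_id, c("gB", "gA"))
  tie2 <- data.frame(gene_id = c("gB", "gA"),
                     rho_k27_mrna = c(-0.6, -0.6),
                     rho_k27_k4 = c(-0.4, -0.4))
  expect_equal(rank_candidates(tie2)$gene_id, c("gA", "gB"))

  set.seed(29)
  rnd <- data.frame(gene_id = sprintf("g%02d", 1:50),
                    rho_k27_mrna = round(runif(50, -1, 0), 2),
                    rho_k27_k4 = round(runif(50, -1, 0), 2))
  r <- rank_candidates(rnd)
  o <- rnd[order(rnd$rho_k27_mrna, rnd$rho_k27_k4, rnd$gene_id), ]
  expect_equal(r$gene_id, o$gene_id)
})

test_that("overlap enrichment reproduces Fisher's exact test", {
  # symmetric table
  expect_equal(overlap_enrichment(1, 2, 2, 4), 1)
  # small table vs exhaustive enumeration and vs fisher.test
  p <- overlap_enrichment(2, 5, 6, 14)
  expect_equal(p, oracle_fisher2x2(2, 5, 6, 14), tolerance = 1e-12)
  expect_equal(p, fisher.test(matrix(c(2, 3, 4, 5), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  set.seed(31)
  for (rep in 1:50) {
    N <- sample(10:200, 1); n <- sample(1:(N - 1), 1)
    K <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), 2, byrow = TRUE)
    expect_equal(overlap_enrichment(k, n, K, N),
                 fisher.test(tab)$p.value, tolerance = 1e-9,
                 info = paste(k, n, K, N))
  }
  expect_error(overlap_enrichment(5, 4, 10, 20))
})

test_that("full screen recovers planted genes and reports overlap enrichment", {
  cfg <- simulation_config(n_genes = 150, n_planted = 8, noise_sd = 0.2,
                           overlap_fraction = 0.5, seed = 37)
  st <- simulate_wer_study(cfg)
  scr <- run_wer_screen(st$signals, st$annotation)
  rec <- screen_recovery(scr, st$truth)
  expect_gte(rec$recovery, 0.8)
  expect_lte(rec$false_positive_rate, 0.02)
  expect_false(is.null(scr$overlap_test))
  expect_equal(scr$overlap_test$n_candidates, length(scr$robust))
  expect_gte(scr$overlap_test$p_value, 0)
  expect_lte(scr$overlap_test$p_value, 1)
  expect_equal(scr$ranked$rank, seq_len(nrow(scr$ranked)))
  expect_true(all(diff(scr$ranked$rho_k27_mrna) >= 0))
})
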