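test_that("overlap_fraction is realized exactly, including the extremes", {
  cfg0 <- simulation_config(n_genes = 30, n_planted = 3,
                            overlap_fraction = 0, seed = 5)
  sim0 <- simulate_annotation(cfg0)
  tab0 <- annotation_overlap_table(sim0$annotation, 2)
  expect_equal(sum(tab0$overlapped), 0)

  cfg1 <- simulation_config(n_genes = 10, n_planted = 2,
                            overlap_fraction = 1, seed = 5)
  sim1 <- simulate_annotation(cfg1)
  tab1 <- annotation_overlap_table(sim1$annotation, 2)
  expect_equal(sum(tab1$overlapped), 10)
})

test_that("recorded overlap truth equals an independent interval-intersection scan", {
  cfg <- simulation_config(n_genes = 200, n_planted = 10,
                           overlap_fraction = 0.5, seed = 123)
  sim <- simulate_annotation(cfg)
  expect_equal(sum(sim$truth$overlaps_upstream), 100)
  # independent scan, gene by gene
  scanned <- vapply(seq_len(200), function(i)
    oracle_overlap_bp(sim$annotation, i, 2) > 0, logical(1))
  expect_equal(scanned, sim$truth$overlaps_upstream)
})

test_that("generated signals are positive, anti-phase for planted genes, and reproducible", {
  cfg <- simulation_config(n_genes = 40, n_planted = 8, noise_sd = 0,
                           seed = 21)
  sim <- simulate_annotation(cfg)
  sig <- simulate_seasonal_signals(cfg, sim$truth)
  expect_true(all(sig$mrna$rpkm > 0))
  expect_true(all(sig$h3k27me3_pro[["2kb"]]$rpkm > 0))

  planted <- which(sim$truth$is_planted_wer)
  for (g in planted) {
    rho <- spearman_rho(sig$h3k27me3_pro[["2kb"]]$rpkm[g, ],
                        sig$mrna$rpkm[g, ])
    expect_equal(rho, -1)
    # a random acrophase misses the grid extremes by at most half a month
    amp <- amplitude_log2(sig$mrna$rpkm[g, ], pseudocount = 0)
    expect_lte(amp, 2 * cfg$planted_log2_amplitude + 1e-10)
    expect_gte(amp, 2 * cfg$planted_log2_amplitude * cos(pi / 12))
  }
  # fixed seed reproduces byte-identical output
  sig2 <- simulate_seasonal_signals(cfg, sim$truth)
  expect_identical(sig, sig2)
  st1 <- simulate_wer_study(cfg)
  st2 <- simulate_wer_study(cfg)
  expect_identical(st1, st2)
})

test_that("amplitude of a noiseless unit-log2 sinusoid is 2", {
  cfg <- simulation_config(n_genes = 10, n_planted = 10, noise_sd = 0,
                           planted_log2_amplitude = 1, overlap_fraction = 0,
                           seed = 3)
  sim <- simulate_annotation(cfg)
  # acrophase on the sampled grid: the +/-1 extremes of the log2 cosine
  # are then attained by the sampled series
  sim$truth$true_phase <- rep(cfg$time_points[1:10], length.out = 10)
  sig <- simulate_seasonal_signals(cfg, sim$truth)
  for (g in 1:10)
    expect_equal(amplitude_log2(sig$mrna$rpkm[g, ], pseudocount = 0), 2,
                 tolerance = 1e-10)
})

test_that("cosinor false-positive rate on null genes is binomially consistent with 5%", {
  cfg <- simulation_config(n_genes = 2000, n_planted = 0, noise_sd = 0.2,
                           overlap_fraction = 0, seed = 17)
  sim <- simulate_annotation(cfg)
  sig <- simulate_seasonal_signals(cfg, sim$truth)
  cf <- cosinor_fit_matrix(sig$mrna$rpkm, sig$mrna$times)
  rate <- mean(cf$p_value < 0.05)
  # 3 binomial SDs around the nominal level at n = 2000
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("zero-noise planted genes pass every screening criterion; nulls fail amplitude", {
  cfg <- simulation_config(n_genes = 60, n_planted = 10, noise_sd = 0,
                           seed = 31)
  st <- simulate_wer_study(cfg)
  crit <- screen_criteria()
  res <- apply_criteria(st$signals$mrna, st$signals$h3k4me3_gene,
                        st$signals$h3k27me3_pro[["2kb"]],
                        st$signals$h3k27me3_gene, crit)
  planted <- st$truth$gene_id[st$truth$is_planted_wer]
  expect_true(all(res$candidate[res$gene_id %in% planted]))
  nulls <- setdiff(res$gene_id, planted)
  amp <- vapply(nulls, function(g)
    amplitude_log2(st$signals$mrna$rpkm[g, ]), numeric(1))
  expect_true(all(amp <= crit$amp_log2_min))
  expect_false(any(res$candidate[res$gene_id %in% nulls]))
})

test_that("synthetic GUS images carry exact recorded truth and respect jitter bounds", {
  cfg <- simulation_config(image_width = 100, image_height = 100,
                           image_jitter = 25, seed = 9)
  gi <- simulate_gus_image(cfg, n_stained = 3000, n_unstained = 5000)
  expect_equal(gi$truth$n_stained, 3000L)
  expect_equal(gi$truth$n_unstained, 5000L)
  expect_equal(gi$truth$n_background, 2000L)
  q <- quantify_gus(gi$image)
  expect_equal(q$n_stained, 3000)
  expect_equal(q$n_unstained, 5000)
  expect_equal(q$ratio, 0.6)

  cfg0 <- simulation_config(image_width = 20, image_height = 20,
                            stained_fraction = 0, unstained_fraction = 0.5,
                            seed = 9)
  expect_equal(simulate_gus_image(cfg0)$truth$n_stained, 0L)

  bad <- simulation_config(image_jitter = 60, seed = 9)
  expect_error(simulate_gus_image(bad), "jitter")
})

test_that("sequence pairs follow the recorded edit record", {
  p0 <- simulate_sequence_pair(80, 0, 0, seed = 2)
  expect_identical(p0$seq1, p0$seq2)
  a0 <- global_align(p0$seq1, p0$seq2)
  expect_equal(a0$identity, 100)

  ps <- simulate_sequence_pair(50, substitution_rate = 0.04, seed = 2)
  expect_equal(sum(ps$edits$op == "sub"), 2)
  expect_equal(nchar(ps$seq2), 50)
  as <- global_align(ps$seq1, ps$seq2)
  expect_equal(as$identity, 96.0)

  # alignment can only match the edit record or beat it
  for (seed in 1:5) {
    pm <- simulate_sequence_pair(200, substitution_rate = 0.03,
                                 indel_rate = 0.01, seed = seed)
    am <- global_align(pm$seq1, pm$seq2)
    expect_gte(am$matches, pm$implied_matches)
  }
})

test_that("seasonal matrices round-trip through TSV", {
  cfg <- simulation_config(n_genes = 12, n_planted = 2, seed = 4)
  sim <- simulate_annotation(cfg)
  sig <- simulate_seasonal_signals(cfg, sim$truth)
  f <- tempfile(fileext = ".tsv")
  write_seasonal_tsv(sig$mrna, f)
  back <- read_seasonal_tsv(f, times = sig$mrna$times, assay = "mRNA")
  expect_equal(back$rpkm, sig$mrna$rpkm, tolerance = 1e-12)
})
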