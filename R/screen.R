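#' Screening thresholds and options
#'
#' Bundles the three-criteria thresholds of the WER-promoter screen:
#'
#' * criterion 1 (seasonality): NB-test FDR < `nb_fdr_max`, cosinor p <
#'   `cosinor_p_max`, and log2 peak/trough amplitude > `amp_log2_min`, each
#'   required of all three assays (promoter H3K27me3, genic H3K4me3, mRNA);
#' * criterion 2 (anti-correlation): Spearman rho of promoter H3K27me3 with
#'   mRNA, and with genic H3K4me3, both below `rho_max` (strictly negative
#'   by default), computed on spline-smoothed monthly values;
#' * criterion 3 (low H3K27me3): maximum RPKM of the `low_filter_region`
#'   H3K27me3 series below `k27_low_max_rpkm`.
#'
#' @param nb_fdr_max,cosinor_p_max,amp_log2_min,rho_max,k27_low_max_rpkm
#'   Thresholds; defaults 0.05, 0.05, 1, 0, 2.
#' @param low_filter_region Region the low-H3K27me3 ceiling applies to:
#'   `"gene_body"` (default) or `"promoter"`.
#' @param window_sizes_kb Promoter window sizes screened (default 1, 2, 3).
#' @param robustness_rule `"all_windows"` (candidate in every window's set)
#'   or `"at_least_k"`.
#' @param robustness_k Minimum number of window sets for `"at_least_k"`.
#' @param use_nb_test Include the count-level NB seasonal test in
#'   criterion 1 (requires count matrices; default `TRUE`).
#' @param pseudocount Pseudocount shared by the cosinor log transform and
#'   the amplitude statistic (default 0.01 RPKM).
#' @return List of class `"screen_criteria"`.
#' @export
screen_criteria <- function(nb_fdr_max = 0.05, cosinor_p_max = 0.05,
                            amp_log2_min = 1, rho_max = 0,
                            k27_low_max_rpkm = 2,
                            low_filter_region = c("gene_body", "promoter"),
                            window_sizes_kb = c(1, 2, 3),
                            robustness_rule = c("all_windows", "at_least_k"),
                            robustness_k = 2, use_nb_test = TRUE,
                            pseudocount = 0.01) {
  low_filter_region <- match.arg(low_filter_region)
  robustness_rule <- match.arg(robustness_rule)
  stopifnot(nb_fdr_max > 0, cosinor_p_max > 0, k27_low_max_rpkm > 0)
  structure(as.list(environment()), class = "screen_criteria")
}

#' Per-gene seasonal statistics for one assay matrix
#'
#' Computes, for every gene of a `seasonal_matrix`, the cosinor fit (mesor,
#' amplitude, acrophase, F-test p), the log2 peak/trough amplitude, and
#' (when counts are available and requested) the NB seasonal LRT with BH
#' adjustment.
#'
#' @param sm A `seasonal_matrix` (see [simulate_seasonal_signals()] or
#'   [read_seasonal_tsv()]).
#' @param criteria A [screen_criteria()] (pseudocount and NB switch).
#' @return `data.frame` with columns `gene_id`, `assay`, `window_kind`,
#'   `mesor`, `amplitude`, `acrophase`, `cosinor_p`, `amp_log2`,
#'   `max_rpkm`, `nb_p`, `nb_fdr`.
#' @export
seasonal_stats_table <- function(sm, criteria = screen_criteria()) {
  cf <- cosinor_fit_matrix(sm$rpkm, sm$times, pseudocount = criteria$pseudocount)
  out <- data.frame(
    gene_id = rownames(sm$rpkm), assay = sm$assay,
    window_kind = sm$window_kind,
    mesor = cf$mesor, amplitude = cf$amplitude, acrophase = cf$acrophase,
    cosinor_p = cf$p_value,
    amp_log2 = apply(sm$rpkm, 1, amplitude_log2,
                     pseudocount = criteria$pseudocount),
    max_rpkm = apply(sm$rpkm, 1, max),
    nb_p = NA_real_, nb_fdr = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (criteria$use_nb_test && !is.null(sm$counts)) {
    nb <- nb_seasonal_test(sm$counts, sm$library_sizes, sm$times)
    out$nb_p <- nb$raw_p
    out$nb_fdr <- nb$fdr
  }
  out
}

seasonality_pass <- function(stats, criteria) {
  ok <- stats$cosinor_p < criteria$cosinor_p_max &
    stats$amp_log2 > criteria$amp_log2_min
  if (criteria$use_nb_test && !all(is.na(stats$nb_fdr)))
    ok <- ok & stats$nb_fdr < criteria$nb_fdr_max
  ok
}

spline_monthly_matrix <- function(m, times, grid = seq(0.5, 11.5, by = 1)) {
  t(apply(m, 1, spline_monthly, times = times, grid = grid))
}

#' Apply the three screening criteria at one promoter window size
#'
#' Combines per-assay seasonal statistics, spline-smoothed rank
#' correlations and the low-H3K27me3 ceiling into per-gene pass flags and a
#' candidate call. Genes missing from any assay are dropped with a warning.
#'
#' @param mrna,h3k4me3_gene,h3k27me3_pro `seasonal_matrix` objects for the
#'   three assays (promoter H3K27me3 at the window size being screened).
#' @param h3k27me3_low `seasonal_matrix` whose per-gene maximum RPKM is
#'   ceiling-checked (gene-body H3K27me3 under the default criteria;
#'   pass the promoter matrix itself for `low_filter_region = "promoter"`).
#' @param criteria A [screen_criteria()].
#' @return `data.frame` with one row per gene: seasonality flags per assay,
#'   `rho_k27_mrna`, `rho_k27_k4`, `k27_low_max`, `crit1`..`crit3`,
#'   `candidate`.
#' @export
apply_criteria <- function(mrna, h3k4me3_gene, h3k27me3_pro, h3k27me3_low,
                           criteria = screen_criteria()) {
  screen_window(assay_bundle(mrna, criteria),
                assay_bundle(h3k4me3_gene, criteria),
                h3k27me3_pro, h3k27me3_low, criteria)
}

# precomputed per-assay pieces reused across promoter window sizes
assay_bundle <- function(sm, criteria) {
  list(sm = sm, stats = seasonal_stats_table(sm, criteria),
       monthly = spline_monthly_matrix(sm$rpkm, sm$times))
}

screen_window <- function(bund_m, bund_k4, h3k27me3_pro, h3k27me3_low,
                          criteria) {
  genes <- Reduce(intersect, list(rownames(bund_m$sm$rpkm),
                                  rownames(bund_k4$sm$rpkm),
                                  rownames(h3k27me3_pro$rpkm),
                                  rownames(h3k27me3_low$rpkm)))
  all_genes <- unique(c(rownames(bund_m$sm$rpkm), rownames(bund_k4$sm$rpkm),
                        rownames(h3k27me3_pro$rpkm)))
  if (length(genes) < length(all_genes))
    warning(length(all_genes) - length(genes),
            " gene(s) missing from at least one assay; excluded")
  idx_m <- match(genes, rownames(bund_m$sm$rpkm))
  idx_k4 <- match(genes, rownames(bund_k4$sm$rpkm))
  sub <- function(sm) {
    sm$rpkm <- sm$rpkm[genes, , drop = FALSE]
    if (!is.null(sm$counts)) sm$counts <- sm$counts[genes, , drop = FALSE]
    sm
  }
  h3k27me3_pro <- sub(h3k27me3_pro); h3k27me3_low <- sub(h3k27me3_low)

  st_m <- bund_m$stats[idx_m, , drop = FALSE]
  st_k4 <- bund_k4$stats[idx_k4, , drop = FALSE]
  st_k27 <- seasonal_stats_table(h3k27me3_pro, criteria)

  sm_m <- bund_m$monthly[idx_m, , drop = FALSE]
  sm_k4 <- bund_k4$monthly[idx_k4, , drop = FALSE]
  sm_k27 <- spline_monthly_matrix(h3k27me3_pro$rpkm, h3k27me3_pro$times)
  rho_mrna <- vapply(seq_along(genes), function(i)
    spearman_rho(sm_k27[i, ], sm_m[i, ]), numeric(1))
  rho_k4 <- vapply(seq_along(genes), function(i)
    spearman_rho(sm_k27[i, ], sm_k4[i, ]), numeric(1))

  k27_low_max <- apply(h3k27me3_low$rpkm, 1, max)

  crit1 <- seasonality_pass(st_m, criteria) &
    seasonality_pass(st_k4, criteria) & seasonality_pass(st_k27, criteria)
  crit2 <- !is.na(rho_mrna) & rho_mrna < criteria$rho_max &
    !is.na(rho_k4) & rho_k4 < criteria$rho_max
  crit3 <- k27_low_max < criteria$k27_low_max_rpkm
  data.frame(
    gene_id = genes,
    seasonal_mrna = seasonality_pass(st_m, criteria),
    seasonal_k4 = seasonality_pass(st_k4, criteria),
    seasonal_k27 = seasonality_pass(st_k27, criteria),
    rho_k27_mrna = rho_mrna, rho_k27_k4 = rho_k4,
    k27_low_max = unname(k27_low_max),
    crit1 = crit1, crit2 = crit2, crit3 = crit3,
    candidate = crit1 & crit2 & crit3,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Multi-window robustness of candidate sets
#'
#' A gene is robust when it is selected at every promoter window size
#' (`"all_windows"`, the default: the set intersection) or in at least `k`
#' of the sets (`"at_least_k"`).
#'
#' @param candidate_sets List of character vectors of candidate gene ids,
#'   one per window size.
#' @param rule `"all_windows"` or `"at_least_k"`.
#' @param k Minimum set count for `"at_least_k"`.
#' @return Character vector of robust gene ids (sorted).
#' @export
multi_window_robust <- function(candidate_sets,
                                rule = c("all_windows", "at_least_k"),
                                k = 2) {
  rule <- match.arg(rule)
  if (length(candidate_sets) == 0) return(character())
  if (rule == "all_windows")
    return(sort(Reduce(intersect, candidate_sets)))
  tab <- table(unlist(lapply(candidate_sets, unique)))
  sort(names(tab)[tab >= k])
}

#' Rank candidates by anti-correlation strength
#'
#' Orders candidates ascending by Spearman rho between promoter H3K27me3
#' and mRNA (most negative first); ties are broken by rho between promoter
#' H3K27me3 and genic H3K4me3 (ascending), then by gene id.
#'
#' @param results `data.frame` with columns `gene_id`, `rho_k27_mrna`,
#'   `rho_k27_k4` (e.g. candidate rows of [apply_criteria()] output).
#' @return The same rows, sorted, with a `rank` column added.
#' @export
rank_candidates <- function(results) {
  o <- order(results$rho_k27_mrna, results$rho_k27_k4, results$gene_id)
  out <- results[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fisher exact test for upstream-overlap enrichment
#'
#' Two-sided Fisher exact p-value for the 2x2 table comparing the fraction
#' of candidates whose promoter overlaps the upstream neighbor against the
#' genome-wide fraction: `[[k, n-k], [K-k, (N-n)-(K-k)]]`. The two-sided
#' p-value follows the sum-of-smaller-or-equal-probability convention:
#' the total hypergeometric probability of all tables (with the observed
#' margins) no more likely than the observed one.
#'
#' @param k_candidates_overlapping Overlapped candidates.
#' @param n_candidates Total candidates.
#' @param K_genome_overlapping Overlapped genes genome-wide.
#' @param N_genome Total genes.
#' @return Two-sided p-value.
#' @examples
#' overlap_enrichment(4, 8, 15972, 32367)  # > 0.9999
#' @export
overlap_enrichment <- function(k_candidates_overlapping, n_candidates,
                               K_genome_overlapping, N_genome) {
  k <- k_candidates_overlapping; n <- n_candidates
  K <- K_genome_overlapping; N <- N_genome
  stopifnot(k >= 0, n >= k, K >= k, N >= n, N >= K,
            (N - n) - (K - k) >= 0)
  support <- max(0, n + K - N):min(n, K)
  pr <- dhyper(support, K, N - K, n)
  obs <- dhyper(k, K, N - K, n)
  # relative tolerance guards against ties lost to floating-point rounding
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Run the full WER-promoter screen on seasonal signals
#'
#' Applies the three criteria at every promoter window size, intersects the
#' per-window candidate sets into a robust set, ranks robust candidates by
#' anti-correlation at the 2 kb (or first available) window, and, when an
#' annotation is supplied, tests upstream-overlap enrichment of the robust
#' candidates against the genome background with Fisher's exact test.
#'
#' @param signals A `seasonal_signals` list (see
#'   [simulate_seasonal_signals()]); `h3k27me3_pro` must contain one matrix
#'   per screened window size.
#' @param annotation Optional [gene_model()] table for the overlap test.
#' @param criteria A [screen_criteria()].
#' @return List of class `"wer_screen"`: `per_window` (named list of
#'   [apply_criteria()] tables), `candidate_sets`, `robust`, `ranked`
#'   (ranked robust candidates with rho values), `overlap_test`
#'   (`NULL` without annotation), `criteria`.
#' @export
run_wer_screen <- function(signals, annotation = NULL,
                           criteria = screen_criteria()) {
  keys <- paste0(criteria$window_sizes_kb, "kb")
  missing <- setdiff(keys, names(signals$h3k27me3_pro))
  if (length(missing))
    stop("no promoter H3K27me3 matrix for window(s): ",
         paste(missing, collapse = ", "))
  bund_m <- assay_bundle(signals$mrna, criteria)
  bund_k4 <- assay_bundle(signals$h3k4me3_gene, criteria)
  per_window <- lapply(keys, function(kk) {
    low <- if (criteria$low_filter_region == "gene_body")
      signals$h3k27me3_gene else signals$h3k27me3_pro[[kk]]
    screen_window(bund_m, bund_k4, signals$h3k27me3_pro[[kk]], low, criteria)
  })
  names(per_window) <- keys
  candidate_sets <- lapply(per_window, function(d) d$gene_id[d$candidate])
  robust <- multi_window_robust(candidate_sets, criteria$robustness_rule,
                                criteria$robustness_k)
  ref <- if ("2kb" %in% keys) "2kb" else keys[1]
  ranked <- rank_candidates(
    per_window[[ref]][per_window[[ref]]$gene_id %in% robust, , drop = FALSE])
  overlap_test <- NULL
  if (!is.null(annotation) && length(robust) > 0) {
    ov <- annotation_overlap_table(annotation, size_kb = 2)
    k <- sum(ov$overlapped[ov$gene_id %in% robust])
    K <- sum(ov$overlapped)
    overlap_test <- list(
      k_candidates_overlapping = k, n_candidates = length(robust),
      K_genome_overlapping = K, N_genome = nrow(annotation),
      p_value = overlap_enrichment(k, length(robust), K, nrow(annotation)))
  }
  structure(list(per_window = per_window, candidate_sets = candidate_sets,
                 robust = robust, ranked = ranked,
                 overlap_test = overlap_test, criteria = criteria),
            class = "wer_screen")
}

#' Recovery metrics of a screen run against simulation truth
#'
#' @param screen A `"wer_screen"` result.
#' @param truth Truth table from [simulate_annotation()].
#' @return `list(recovery, false_positive_rate, n_true_positive,
#'   n_false_positive)` where recovery is the fraction of planted genes in
#'   the robust set and the false-positive rate is the fraction of
#'   non-planted genes called robust.
#' @export
screen_recovery <- function(screen, truth) {
  planted <- truth$gene_id[truth$is_planted_wer]
  nulls <- truth$gene_id[!truth$is_planted_wer]
  tp <- sum(planted %in% screen$robust)
  fp <- sum(nulls %in% screen$robust)
  list(recovery = if (length(planted)) tp / length(planted) else NA_real_,
       false_positive_rate = if (length(nulls)) fp / length(nulls) else NA_real_,
       n_true_positive = tp, n_false_positive = fp)
}

#' @export
print.wer_screen <- function(x, ...) {
  cat("WER promoter screen\n")
  for (kk in names(x$per_window))
    cat(sprintf("  %s window: %d candidate(s)\n", kk,
                length(x$candidate_sets[[kk]])))
  cat(sprintf("  robust (%s): %d gene(s)\n", x$criteria$robustness_rule,
              length(x$robust)))
  if (nrow(x$ranked))
    cat("  top candidate:", x$ranked$gene_id[1],
        sprintf("(rho = %.3f)\n", x$ranked$rho_k27_mrna[1]))
  if (!is.null(x$overlap_test))
    cat(sprintf("  upstream-overlap Fisher P = %.4g (%d/%d vs %d/%d)\n",
                x$overlap_test$p_value, x$overlap_test$k_candidates_overlapping,
                x$overlap_test$n_candidates, x$overlap_test$K_genome_overlapping,
                x$overlap_test$N_genome))
  invisible(x)
}
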