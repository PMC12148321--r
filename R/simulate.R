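#' Configuration for the synthetic seasonal study
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe
#' the study design the screen targets: one year of monthly sampling
#' (12 time points at mid-month), a cohort of 1000 genes of which 20 are
#' "planted" week-scale environmental response (WER) genes whose promoter
#' H3K27me3 oscillates in exact anti-phase with mRNA and genic H3K4me3,
#' log-normal measurement noise, and a gene layout in which a set fraction
#' of 2 kb promoter windows is intruded by the upstream neighbor.
#'
#' @param n_genes Number of genes in the cohort.
#' @param n_planted Number of planted WER genes (`<= n_genes`).
#' @param time_points Sampling times in months, strictly increasing
#'   (default mid-months 0.5, 1.5, ..., 11.5 over one year).
#' @param noise_sd SD of additive Gaussian noise on the log2 signal.
#' @param planted_log2_amplitude Half peak-to-trough log2 range of planted
#'   seasonal curves (the screen's amplitude criterion needs > 0.5; the
#'   planted default 1.5 corresponds to an 8-fold seasonal swing).
#' @param mesor_range Interval the per-gene baseline log2 RPKM is drawn from.
#' @param overlap_fraction Fraction of genes whose 2 kb upstream window
#'   overlaps the upstream neighbor's span.
#' @param gene_length Gene span in bp (one length for all genes).
#' @param k27_gene_body_log2_mesor Baseline log2 RPKM of gene-body H3K27me3
#'   (kept low: candidate genes carry the mark at the promoter, not the
#'   gene body).
#' @param count_dispersion Negative-binomial dispersion used when sampling
#'   read counts around RPKM-implied means.
#' @param library_size_range Range mapped-library sizes are drawn from.
#' @param n_replicates Series per gene and time point (default 1).
#' @param image_width,image_height Synthetic GUS image size in pixels.
#' @param stained_fraction,unstained_fraction Pixel-class fractions of the
#'   synthetic GUS image (remainder is background).
#' @param image_jitter Per-channel uniform jitter half-width for image
#'   pixels; must stay below the classifier tolerance.
#' @param stained_ref,unstained_ref Reference RGB triples of the two classes.
#' @param seed RNG seed; fixing it makes every generator byte-reproducible.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 1000, n_planted = 20,
                              time_points = seq(0.5, 11.5, by = 1),
                              noise_sd = 0.2, planted_log2_amplitude = 1.5,
                              mesor_range = c(2, 6), overlap_fraction = 0.5,
                              gene_length = 2000,
                              k27_gene_body_log2_mesor = -2,
                              count_dispersion = 0.05,
                              library_size_range = c(15e6, 25e6),
                              n_replicates = 1,
                              image_width = 100, image_height = 100,
                              stained_fraction = 0.3,
                              unstained_fraction = 0.5,
                              image_jitter = 20,
                              stained_ref = c(90, 120, 120),
                              unstained_ref = c(255, 225, 170),
                              seed = 1) {
  stopifnot(n_planted <= n_genes, n_genes >= 1,
            noise_sd >= 0, planted_log2_amplitude > 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            gene_length > 0, count_dispersion >= 0,
            stained_fraction >= 0, unstained_fraction >= 0,
            stained_fraction + unstained_fraction <= 1,
            n_replicates >= 1)
  if (any(diff(time_points) <= 0))
    stop("time_points must be strictly increasing")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a gene annotation with controlled upstream overlaps
#'
#' Places `n_genes` genes of equal length in tandem on one chromosome. The
#' intergenic gap ahead of each gene is drawn short (< 2 kb, so the upstream
#' neighbor intrudes into the 2 kb promoter window) or long (> 2 kb) to
#' realize exactly `round(overlap_fraction * n_genes)` overlapped genes. The
#' first gene has no upstream neighbor and is never overlapped, except when
#' `overlap_fraction = 1`, where it is placed head-to-head on the minus
#' strand so its upstream window reaches into gene 2.
#'
#' The returned truth table also plants `n_planted` WER genes (uniform
#' random acrophase, amplitude `planted_log2_amplitude`) consumed by
#' [simulate_seasonal_signals()].
#'
#' @param config A [simulation_config()].
#' @return `list(annotation = gene_model, truth = data.frame)` where truth
#'   has columns `gene_id`, `is_planted_wer`, `true_amplitude`,
#'   `true_phase`, `overlaps_upstream`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(is(config, "simulation_config"))
  n <- config$n_genes
  L <- as.integer(config$gene_length)
  with_seed(config$seed, {
    k <- round(config$overlap_fraction * n)
    all_overlap <- k == n
    flags <- logical(n)
    if (all_overlap) {
      flags[] <- TRUE
    } else if (k > 0) {
      if (k > n - 1)
        stop("impossible layout: cannot overlap ", k, " of ", n,
             " tandem genes (the first gene has no upstream neighbor)")
      flags[1 + sample.int(n - 1, k)] <- TRUE
    }
    # gap ahead of gene i (gap[1] is chromosome margin before gene 1)
    gaps <- ifelse(flags, round(runif(n, 100, 1900)), round(runif(n, 2100, 4000)))
    gaps[1] <- if (all_overlap) round(runif(1, 100, 1900)) else 3000
    starts <- cumsum(gaps + L) - L
    strands <- rep("+", n)
    if (all_overlap) {
      # head-to-head first pair: gene 1 on '-', its upstream is gene 2
      strands[1] <- "-"
      gaps[2] <- round(runif(1, 100, 1900))
      starts <- cumsum(gaps + L) - L
    }
    ids <- sprintf("g%04d", seq_len(n))
    ann <- gene_model(ids, "chr1", starts, starts + L, strands)
    planted <- logical(n)
    if (config$n_planted > 0)
      planted[sample.int(n, config$n_planted)] <- TRUE
    truth <- data.frame(
      gene_id = ids,
      is_planted_wer = planted,
      true_amplitude = ifelse(planted, config$planted_log2_amplitude, 0),
      true_phase = ifelse(planted, runif(n, 0, 12), NA_real_),
      overlaps_upstream = flags,
      stringsAsFactors = FALSE
    )
    list(annotation = ann, truth = truth)
  })
}

new_seasonal_matrix <- function(rpkm, counts, library_sizes, times, assay,
                                window_kind) {
  structure(list(rpkm = rpkm, counts = counts, library_sizes = library_sizes,
                 times = times, assay = assay, window_kind = window_kind),
            class = "seasonal_matrix")
}

# One genes x times RPKM matrix (plus NB counts) for one assay.
# Planted rows follow mesor + A*cos(2*pi*(t - phase)/12) on log2 scale
# (phase_shift months added for anti-phase marks); null rows are flat.
gen_assay_matrix <- function(config, truth, phase_shift, assay, window_kind,
                             window_kb, fixed_log2_mesor = NULL) {
  t <- config$time_points
  nt <- length(t) * config$n_replicates
  tt <- rep(t, each = config$n_replicates)
  n <- nrow(truth)
  mesor <- if (is.null(fixed_log2_mesor))
    runif(n, config$mesor_range[1], config$mesor_range[2])
  else rep(fixed_log2_mesor, n)
  amp <- truth$true_amplitude
  phase <- ifelse(is.na(truth$true_phase), 0, truth$true_phase) + phase_shift
  curve <- outer(seq_len(n), tt, function(i, j)
    mesor[i] + amp[i] * cos(2 * pi * (j - phase[i]) / 12))
  log2v <- curve + matrix(rnorm(n * nt, sd = config$noise_sd), n, nt)
  rpkm <- 2^log2v
  dimnames(rpkm) <- list(truth$gene_id, sprintf("t%02d", seq_len(nt)))
  libs <- round(runif(nt, config$library_size_range[1],
                      config$library_size_range[2]))
  mu <- sweep(rpkm * window_kb, 2, libs / 1e6, `*`)
  counts <- matrix(
    if (config$count_dispersion > 0)
      rnbinom(n * nt, mu = mu, size = 1 / config$count_dispersion)
    else rpois(n * nt, lambda = mu),
    n, nt, dimnames = dimnames(rpkm))
  new_seasonal_matrix(rpkm, counts, libs, tt, assay, window_kind)
}

#' Simulate seasonal signal matrices for all assays
#'
#' Generates, for each gene in the truth table, one-year seasonal series of
#' mRNA, genic H3K4me3, promoter H3K27me3 (one matrix per requested promoter
#' window size, sharing the gene's seasonal truth but with independent noise
#' and counts) and gene-body H3K27me3 (flat and low, as expected of
#' promoter-marked candidates). Planted genes follow a first-harmonic cosine
#' on the log2 scale; promoter H3K27me3 is phase-shifted by 6 months
#' (anti-phase). Noise is Gaussian on log2 (log-normal RPKM); read counts
#' are negative-binomially sampled around RPKM-implied means.
#'
#' @param config A [simulation_config()].
#' @param truth Truth table from [simulate_annotation()].
#' @param promoter_windows_kb Promoter window sizes to emit (default 1,2,3).
#' @return List of class `"seasonal_signals"` with elements `mrna`,
#'   `h3k4me3_gene`, `h3k27me3_gene` (each a `seasonal_matrix`) and
#'   `h3k27me3_pro`, a named list of `seasonal_matrix` objects keyed
#'   `"1kb"`, `"2kb"`, ....
#' @export
simulate_seasonal_signals <- function(config, truth,
                                      promoter_windows_kb = c(1, 2, 3)) {
  stopifnot(is(config, "simulation_config"))
  # gene-body H3K27me3 is flat for every gene, planted included: candidate
  # genes carry the seasonal mark at the promoter only
  truth_flat <- truth
  truth_flat$true_amplitude <- 0
  with_seed(config$seed + 1L, {
    out <- list(
      mrna = gen_assay_matrix(config, truth, 0, "mRNA", "gene_body", 2),
      h3k4me3_gene = gen_assay_matrix(config, truth, 0, "H3K4me3",
                                      "genic_1kb", 1),
      h3k27me3_gene = gen_assay_matrix(
        config, truth_flat, 0, "H3K27me3", "gene_body", 2,
        fixed_log2_mesor = config$k27_gene_body_log2_mesor),
      h3k27me3_pro = lapply(
        stats::setNames(promoter_windows_kb,
                        paste0(promoter_windows_kb, "kb")),
        function(w) gen_assay_matrix(config, truth, 6, "H3K27me3",
                                     paste0("promoter_", w, "kb"), w))
    )
    class(out) <- "seasonal_signals"
    out
  })
}

#' Simulate a full synthetic WER study
#'
#' Convenience wrapper: annotation + truth + seasonal signal matrices for
#' promoter windows of 1, 2 and 3 kb.
#'
#' @param config A [simulation_config()].
#' @return `list(config, annotation, truth, signals)`.
#' @export
simulate_wer_study <- function(config = simulation_config()) {
  ann <- simulate_annotation(config)
  sig <- simulate_seasonal_signals(config, ann$truth)
  list(config = config, annotation = ann$annotation, truth = ann$truth,
       signals = sig)
}

#' Write a seasonal matrix as TSV
#'
#' Long or wide layout: wide writes the genes x samples RPKM matrix with a
#' `gene_id` first column; `what = "counts"` writes counts instead.
#'
#' @param sm A `seasonal_matrix`.
#' @param path Output TSV path.
#' @param what `"rpkm"` or `"counts"`.
#' @return Invisibly, `path`.
#' @export
write_seasonal_tsv <- function(sm, path, what = c("rpkm", "counts")) {
  what <- match.arg(what)
  m <- sm[[what]]
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seasonal matrix from TSV (bypass mode)
#'
#' Reads a wide genes x samples TSV written by [write_seasonal_tsv()] (or
#' any precomputed per-window RPKM matrix with a `gene_id` first column).
#'
#' @param path TSV path.
#' @param times Sampling times in months for the value columns.
#' @param assay,window_kind Labels attached to the matrix.
#' @param counts_path Optional TSV of matching integer counts.
#' @param library_sizes Library sizes for the count columns.
#' @return A `seasonal_matrix`.
#' @export
read_seasonal_tsv <- function(path, times, assay = "signal",
                              window_kind = "window", counts_path = NULL,
                              library_sizes = NULL) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stopifnot(length(times) == ncol(m))
  counts <- NULL
  if (!is.null(counts_path)) {
    dc <- read.delim(counts_path, check.names = FALSE)
    counts <- as.matrix(dc[, -1, drop = FALSE])
    rownames(counts) <- dc[[1]]
  }
  new_seasonal_matrix(m, counts, library_sizes, times, assay, window_kind)
}

#' Simulate a GUS-stained tissue image with known pixel counts
#'
#' Builds an RGB image containing three pixel populations at random
#' positions: stained (blue-green reference), unstained (pale reference)
#' and background (far outside both tolerance windows), each with uniform
#' integer per-channel jitter. Because the jitter half-width must stay below
#' the classifier tolerance, the recorded truth counts are unambiguous.
#'
#' @param config A [simulation_config()] (image fields are used), or `NULL`
#'   when explicit counts are given.
#' @param n_stained,n_unstained Optional explicit pixel counts (override
#'   the config fractions).
#' @param tolerance Classifier tolerance the jitter must stay below.
#' @param seed Optional seed override.
#' @return `list(image = height x width x 3 array (0..255),
#'   truth = list(n_stained, n_unstained, n_background))`.
#' @export
simulate_gus_image <- function(config = simulation_config(),
                               n_stained = NULL, n_unstained = NULL,
                               tolerance = 60, seed = NULL) {
  w <- config$image_width; h <- config$image_height
  jit <- config$image_jitter
  if (jit >= tolerance)
    stop("image_jitter must be < tolerance, otherwise truth is ambiguous")
  npix <- w * h
  if (is.null(n_stained)) n_stained <- round(config$stained_fraction * npix)
  if (is.null(n_unstained))
    n_unstained <- round(config$unstained_fraction * npix)
  if (n_stained + n_unstained > npix) stop("more class pixels than pixels")
  n_bg <- npix - n_stained - n_unstained
  background_ref <- c(0, 0, 255)
  with_seed(if (is.null(seed)) config$seed + 2L else seed, {
    block <- function(ref, n) matrix(rep(ref, each = n), n, 3)
    refs <- rbind(block(config$stained_ref, n_stained),
                  block(config$unstained_ref, n_unstained),
                  block(background_ref, n_bg))
    jitter <- matrix(sample(seq(-jit, jit), npix * 3, replace = TRUE),
                     npix, 3)
    px <- pmin(pmax(refs + jitter, 0), 255)
    ord <- sample.int(npix)  # scatter classes across the frame
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) img[, , ch][ord] <- px[, ch]
    list(image = img,
         truth = list(n_stained = as.integer(n_stained),
                      n_unstained = as.integer(n_unstained),
                      n_background = as.integer(n_bg)))
  })
}

#' Write an RGB image array as PNG
#'
#' @param image height x width x 3 array with values in 0..255 (or 0..1).
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(image, path) {
  if (max(image) > 1) image <- image / 255
  png::writePNG(image, path)
  invisible(path)
}

#' Simulate a pair of related nucleotide sequences
#'
#' The second sequence is derived from a random first sequence by a recorded
#' number of substitutions (`round(substitution_rate * length)`, each to a
#' different base) and deletions (`round(indel_rate * length)` events of
#' 1-3 bp at non-overlapping positions). The edit record implies a lower
#' bound on the match count any global aligner can achieve.
#'
#' @param length Length of the first sequence.
#' @param substitution_rate,indel_rate Per-base event rates.
#' @param seed RNG seed.
#' @return `list(seq1, seq2, edits, implied_matches, implied_columns)`.
#' @export
simulate_sequence_pair <- function(length, substitution_rate = 0,
                                   indel_rate = 0, seed = 1) {
  stopifnot(length >= 1, substitution_rate >= 0, indel_rate >= 0)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    s1 <- sample(bases, length, replace = TRUE)
    n_del_events <- round(indel_rate * length)
    deleted <- logical(length)
    edits <- list()
    for (i in seq_len(n_del_events)) {
      len <- sample(1:3, 1)
      free <- which(!deleted)
      free <- free[free <= length - len + 1]
      ok <- free[vapply(free, function(p) !any(deleted[p:(p + len - 1)]),
                        logical(1))]
      if (length(ok) == 0) break
      p <- if (length(ok) == 1) ok else sample(ok, 1)
      deleted[p:(p + len - 1)] <- TRUE
      edits[[length(edits) + 1]] <-
        data.frame(op = "del", pos = p, len = len, from = NA, to = NA)
    }
    n_sub <- round(substitution_rate * length)
    subbable <- which(!deleted)
    n_sub <- min(n_sub, length(subbable))
    s2 <- s1
    if (n_sub > 0) {
      pos <- if (length(subbable) == 1) subbable else sample(subbable, n_sub)
      for (p in pos) {
        new <- sample(setdiff(bases, s1[p]), 1)
        edits[[length(edits) + 1]] <-
          data.frame(op = "sub", pos = p, len = 1L, from = s1[p], to = new)
        s2[p] <- new
      }
    }
    seq2 <- paste(s2[!deleted], collapse = "")
    n_del_bases <- sum(deleted)
    list(seq1 = paste(s1, collapse = ""),
         seq2 = seq2,
         edits = if (length(edits)) do.call(rbind, edits) else
           data.frame(op = character(), pos = integer(), len = integer(),
                      from = character(), to = character()),
         implied_matches = length - n_del_bases - n_sub,
         implied_columns = length)
  })
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
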