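#' Construct a gene model table
#'
#' A gene model holds the minimal strand-aware coordinates needed for
#' promoter/genic window arithmetic. Coordinates are 0-based, half-open
#' (BED convention); the transcription start site (TSS) is the `start`
#' boundary on the plus strand and the `end` boundary on the minus strand.
#'
#' @param gene_id Character vector of gene identifiers (unique).
#' @param chrom Chromosome names.
#' @param start,end Integer 0-based half-open gene spans (`start < end`).
#' @param strand `"+"` or `"-"` per gene.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and a derived `tss` column, classed `"gene_model"`.
#' @examples
#' gene_model("g1", "chr1", 5000, 7000, "+")$tss
#' @export
gene_model <- function(gene_id, chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(gene_id) == length(start), length(start) == length(end))
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (any(start >= end)) stop("gene spans must satisfy start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ann <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = start, end = end, strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  class(ann) <- c("gene_model", "data.frame")
  ann
}

as_gene_model <- function(x) {
  if (!all(c("gene_id", "chrom", "start", "end", "strand") %in% names(x)))
    stop("annotation must have gene_id, chrom, start, end, strand columns")
  gene_model(x$gene_id, x$chrom, x$start, x$end, x$strand)
}

#' Promoter window upstream of the TSS
#'
#' Returns the `size_kb` kilobase window upstream of the TSS in the
#' direction opposite to transcription: `[TSS - 1000*size_kb, TSS)` on the
#' plus strand, `[TSS, TSS + 1000*size_kb)` on the minus strand. Windows
#' are clipped at position 0 and, when `chrom_length` is supplied, at the
#' chromosome end; clipped (including zero-length) windows are flagged.
#'
#' @param gene A single-row [gene_model()] (or a row subset of one).
#' @param size_kb Window size in kb (1, 2 and 3 are the screen's choices;
#'   any positive value is accepted).
#' @param chrom_length Optional chromosome length for right-side clipping.
#' @return `data.frame` with `chrom`, `start`, `end`, `clipped`.
#' @examples
#' g <- gene_model("g", "chr1", 5000, 7000, "+")
#' promoter_window(g, 2)  # [3000, 5000)
#' @export
promoter_window <- function(gene, size_kb = 2, chrom_length = NULL) {
  stopifnot(size_kb > 0)
  len <- as.integer(round(1000 * size_kb))
  up <- ifelse(gene$strand == "+", gene$tss - len, gene$tss)
  dn <- ifelse(gene$strand == "+", gene$tss, gene$tss + len)
  clip_interval(gene$chrom, up, dn, chrom_length)
}

#' Genic window downstream of the TSS
#'
#' The 1 kb window downstream of the TSS in the direction of transcription
#' (used for TSS-proximal H3K4me3). By default the window is a pure 1 kb
#' extent even if the gene is shorter; set `clip_to_gene = TRUE` to truncate
#' it at the gene end.
#'
#' @inheritParams promoter_window
#' @param size_kb Window size in kb (default 1).
#' @param clip_to_gene Truncate at the gene 3' end?
#' @return `data.frame` with `chrom`, `start`, `end`, `clipped`.
#' @export
genic_window <- function(gene, size_kb = 1, clip_to_gene = FALSE,
                         chrom_length = NULL) {
  stopifnot(size_kb > 0)
  len <- as.integer(round(1000 * size_kb))
  up <- ifelse(gene$strand == "+", gene$tss, gene$tss - len)
  dn <- ifelse(gene$strand == "+", gene$tss + len, gene$tss)
  gene_clipped <- rep(FALSE, length(up))
  if (clip_to_gene) {
    up2 <- pmax(up, gene$start)
    dn2 <- pmin(dn, gene$end)
    gene_clipped <- up2 != up | dn2 != dn
    up <- up2; dn <- dn2
  }
  out <- clip_interval(gene$chrom, up, dn, chrom_length)
  out$clipped <- out$clipped | gene_clipped
  out
}

clip_interval <- function(chrom, start, end, chrom_length = NULL) {
  s <- pmax(start, 0L)
  e <- if (is.null(chrom_length)) end else pmin(end, chrom_length)
  e <- pmax(e, s)
  data.frame(chrom = chrom, start = as.integer(s), end = as.integer(e),
             clipped = (s != start) | (e != end) | (e == s),
             stringsAsFactors = FALSE)
}

#' Build a read-interval signal track
#'
#' @param reads `data.frame` of read intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open) and, for multi-sample tracks, a
#'   `sample` column.
#' @param total_mapped_reads Library size(s): a single count, or a named
#'   vector keyed by sample.
#' @return An object of class `"signal_track"`.
#' @export
signal_track <- function(reads, total_mapped_reads) {
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  structure(list(reads = reads, total_mapped_reads = total_mapped_reads),
            class = "signal_track")
}

#' Windowed RPKM from a read track
#'
#' RPKM = (reads overlapping the window) / (window length in kb x mapped
#' reads in millions). A read overlaps if at least one base intersects the
#' window, and is counted once per window.
#'
#' @param track A [signal_track()].
#' @param interval One-row interval `data.frame` (`chrom`, `start`, `end`).
#' @param sample Sample name when the track holds several samples.
#' @return RPKM value (numeric scalar).
#' @export
window_rpkm <- function(track, interval, sample = NULL) {
  stopifnot(is(track, "signal_track"))
  width <- interval$end - interval$start
  if (any(width <= 0)) stop("window_rpkm: zero-length interval")
  reads <- track$reads
  total <- track$total_mapped_reads
  if (!is.null(sample)) {
    reads <- reads[reads$sample == sample, , drop = FALSE]
    if (!is.null(names(total))) total <- total[[sample]]
  }
  if (length(total) != 1) stop("ambiguous library size; give `sample`")
  q <- GenomicRanges::GRanges(interval$chrom,
                              IRanges::IRanges(interval$start + 1, interval$end))
  subj <- GenomicRanges::GRanges(reads$chrom,
                                 IRanges::IRanges(reads$start + 1, reads$end))
  n <- GenomicRanges::countOverlaps(q, subj, minoverlap = 1L)
  as.numeric(n) / ((width / 1000) * (total / 1e6))
}

#' Upstream-neighbor overlap of a promoter window
#'
#' Counts the bases of a gene's `size_kb` upstream promoter window that are
#' covered by the span of any other gene in the annotation. A gene is
#' "overlapped" when at least one base of its promoter window lies inside a
#' neighboring gene.
#'
#' @param gene One-row [gene_model()].
#' @param annotation Full [gene_model()] table (may include `gene`).
#' @param size_kb Promoter window size in kb (default 2).
#' @return `list(overlapped = flag, overlap_bp = count)`.
#' @export
upstream_overlap <- function(gene, annotation, size_kb = 2) {
  win <- promoter_window(gene, size_kb)
  others <- annotation[annotation$gene_id != gene$gene_id &
                         annotation$chrom == gene$chrom, , drop = FALSE]
  if (nrow(others) == 0 || win$end <= win$start)
    return(list(overlapped = FALSE, overlap_bp = 0L))
  cov <- IRanges::reduce(IRanges::IRanges(others$start + 1, others$end))
  hit <- IRanges::intersect(cov, IRanges::IRanges(win$start + 1, win$end))
  bp <- sum(IRanges::width(hit))
  list(overlapped = bp > 0, overlap_bp = as.integer(bp))
}

#' Upstream-overlap status for every gene in an annotation
#'
#' @param annotation A [gene_model()] table.
#' @param size_kb Promoter window size in kb.
#' @return `data.frame(gene_id, overlapped, overlap_bp)`.
#' @export
annotation_overlap_table <- function(annotation, size_kb = 2) {
  win <- promoter_window(annotation, size_kb)
  bp <- rep(0L, nrow(annotation))
  ok <- which(win$end > win$start)
  if (length(ok)) {
    wgr <- GenomicRanges::GRanges(
      win$chrom[ok], IRanges::IRanges(win$start[ok] + 1, win$end[ok]))
    ggr <- GenomicRanges::GRanges(
      annotation$chrom, IRanges::IRanges(annotation$start + 1, annotation$end))
    hits <- GenomicRanges::findOverlaps(wgr, ggr)
    keep <- ok[S4Vectors::queryHits(hits)] != S4Vectors::subjectHits(hits)
    hits <- hits[keep]
    if (length(hits)) {
      ov <- IRanges::pintersect(
        IRanges::ranges(wgr)[S4Vectors::queryHits(hits)],
        IRanges::ranges(ggr)[S4Vectors::subjectHits(hits)])
      # union per promoter window: neighbors may themselves overlap
      spl <- split(ov, S4Vectors::queryHits(hits))
      tot <- vapply(spl, function(r) sum(IRanges::width(IRanges::reduce(r))),
                    integer(1))
      bp[ok[as.integer(names(tot))]] <- tot
    }
  }
  data.frame(gene_id = annotation$gene_id,
             overlapped = bp > 0L,
             overlap_bp = bp,
             stringsAsFactors = FALSE)
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 (1-based closed) is converted to the package's 0-based half-open
#' convention on read; BED is taken as-is. Only `gene`-type GFF3 records are
#' kept when a `type` column is present.
#'
#' @param path File path ending in `.gff3`/`.gff` or `.bed`.
#' @return A [gene_model()] table.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!is.null(df$type) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  id <- if (!is.null(df$ID)) df$ID else if (!is.null(df$name)) df$name
  else paste0("gene", seq_len(nrow(df)))
  # GRanges is 1-based closed regardless of source format
  gene_model(id, as.character(df$seqnames), df$start - 1L, df$end,
             as.character(df$strand))
}

#' Write gene annotation as GFF3 and/or BED6
#'
#' @param annotation A [gene_model()] table.
#' @param gff3,bed Output paths (either may be `NULL` to skip).
#' @return Invisibly, the annotation.
#' @export
write_annotation <- function(annotation, gff3 = NULL, bed = NULL) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1, annotation$end),
    strand = annotation$strand
  )
  gr$ID <- annotation$gene_id
  gr$type <- "gene"
  gr$source <- "werscreen"
  if (!is.null(gff3)) rtracklayer::export(gr, gff3, format = "gff3")
  if (!is.null(bed)) {
    gr2 <- gr
    gr2$name <- annotation$gene_id
    gr2$score <- 0L
    rtracklayer::export(gr2, bed, format = "bed")
  }
  invisible(annotation)
}
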