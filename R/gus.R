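#' Reference colors and tolerance for GUS quantification
#'
#' Defaults follow the colorimetric convention for histochemical GUS
#' staining: stained tissue near RGB (90, 120, 120), unstained tissue near
#' RGB (255, 225, 170), with per-channel absolute deviations of up to 60
#' (inclusive) accepted. With these defaults the two color windows are
#' provably disjoint (the red-channel windows [30, 150] and [195, 255] do
#' not intersect).
#'
#' @param stained_ref,unstained_ref RGB reference triples (0..255).
#' @param tolerance Maximum per-channel absolute deviation (Chebyshev
#'   radius), inclusive.
#' @return List of class `"gus_config"`.
#' @export
gus_config <- function(stained_ref = c(90, 120, 120),
                       unstained_ref = c(255, 225, 170), tolerance = 60) {
  stopifnot(length(stained_ref) == 3, length(unstained_ref) == 3,
            tolerance >= 0, all(stained_ref >= 0), all(stained_ref <= 255),
            all(unstained_ref >= 0), all(unstained_ref <= 255))
  structure(list(stained_ref = stained_ref, unstained_ref = unstained_ref,
                 tolerance = tolerance), class = "gus_config")
}

#' Quantify stained vs unstained tissue area in an RGB image
#'
#' Classifies every pixel by reference-color tolerance windows: a pixel is
#' stained if all three channels deviate at most `tolerance` from the
#' stained reference, unstained likewise for the unstained reference, and
#' background otherwise. Under a custom configuration whose windows
#' overlap, pixels matching both are counted as stained (with a warning).
#' The reported signal is the stained/unstained pixel ratio.
#'
#' @param image height x width x 3 array, 8-bit channels; values in 0..1
#'   (as returned by [png::readPNG()]) are rescaled to 0..255.
#' @param config A [gus_config()].
#' @return List of class `"gus_quant"`: `n_stained`, `n_unstained`,
#'   `n_other`, `ratio` (`NA` and flagged via `ratio_defined` when no
#'   unstained pixels exist).
#' @export
quantify_gus <- function(image, config = gus_config()) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("quantify_gus needs a 3-channel RGB image")
  img <- image[, , 1:3, drop = FALSE]
  if (max(img) <= 1) img <- round(img * 255)
  tol <- config$tolerance
  dev_max <- function(ref) {
    d <- abs(img[, , 1] - ref[1])
    d <- pmax(d, abs(img[, , 2] - ref[2]))
    pmax(d, abs(img[, , 3] - ref[3]))
  }
  in_stained <- dev_max(config$stained_ref) <= tol
  in_unstained <- dev_max(config$unstained_ref) <= tol
  if (any(in_stained & in_unstained))
    warning("pixels match both color windows; counted as stained")
  n_s <- sum(in_stained)
  n_u <- sum(in_unstained & !in_stained)
  n_o <- length(in_stained) - n_s - n_u
  structure(list(n_stained = n_s, n_unstained = n_u, n_other = n_o,
                 ratio = if (n_u > 0) n_s / n_u else NA_real_,
                 ratio_defined = n_u > 0),
            class = "gus_quant")
}

#' Read an RGB image from PNG or TIFF
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @return height x width x 3 array with channels in 0..1.
#' @export
read_gus_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is needed to read TIFF images")
    return(tiff::readTIFF(path))
  }
  stop("unsupported image format: ", ext)
}

#' @export
print.gus_quant <- function(x, ...) {
  cat(sprintf("GUS quantification: %d stained, %d unstained, %d other\n",
              x$n_stained, x$n_unstained, x$n_other))
  cat("stained/unstained ratio:",
      if (x$ratio_defined) sprintf("%.4f", x$ratio) else "undefined", "\n")
  invisible(x)
}
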