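#' Cosinor fit of a seasonal series
#'
#' Least-squares first-harmonic cosinor regression
#' `log2(value + eps) = M + A*cos(2*pi*t/period) + B*sin(2*pi*t/period)`,
#' with an F-test of the joint null `(A, B) = (0, 0)`. `M` is the mesor,
#' `sqrt(A^2 + B^2)` the amplitude and `atan2(B, A)` the acrophase in
#' radians (multiply by `period/(2*pi)` for peak time in months).
#'
#' @param values Non-negative signal values (RPKM or counts).
#' @param times Sampling times in months, same length as `values`.
#' @param period Rhythm period in months (default 12, one year).
#' @param log_transform Fit on `log2(value + pseudocount)` (default) or on
#'   the raw scale.
#' @param pseudocount Added before the log2 transform (default 0.01 RPKM).
#' @return `list` of class `"cosinor_fit"` with elements `mesor`,
#'   `coef_cos`, `coef_sin`, `amplitude`, `acrophase`, `p_value`, `df`.
#' @examples
#' t <- 0:11
#' f <- cosinor_fit(2^(2 + cos(2 * pi * t / 12)), t, pseudocount = 0)
#' f$amplitude  # 1
#' @export
cosinor_fit <- function(values, times, period = 12, log_transform = TRUE,
                        pseudocount = 0.01) {
  stopifnot(length(values) == length(times))
  if (length(values) < 6)
    stop("cosinor_fit needs at least 6 observations")
  if (any(values < 0)) stop("values must be non-negative")
  fit <- cosinor_fit_matrix(matrix(values, nrow = 1), times, period,
                            log_transform, pseudocount)
  out <- as.list(fit[1, c("mesor", "coef_cos", "coef_sin", "amplitude",
                          "acrophase", "p_value")])
  out$df <- c(2, length(values) - 3)
  class(out) <- "cosinor_fit"
  out
}

#' Vectorized cosinor fits for a genes x samples matrix
#'
#' Fits the same cosinor design to every row at once (one QR decomposition
#' shared across genes), which keeps genome-wide screens fast.
#'
#' @param values_matrix genes x samples matrix of non-negative values.
#' @param times Sampling times (months) for the columns.
#' @inheritParams cosinor_fit
#' @return `data.frame` with one row per gene: `mesor`, `coef_cos`,
#'   `coef_sin`, `amplitude`, `acrophase`, `p_value`.
#' @export
cosinor_fit_matrix <- function(values_matrix, times, period = 12,
                               log_transform = TRUE, pseudocount = 0.01) {
  m <- as.matrix(values_matrix)
  nt <- ncol(m)
  stopifnot(length(times) == nt)
  if (nt < 6) stop("cosinor needs at least 6 observations")
  if (length(unique(times %% period)) < 3)
    stop("rank-deficient cosinor design: need >= 3 distinct times mod period")
  y <- if (log_transform) log2(m + pseudocount) else m
  X <- cbind(1, cos(2 * pi * times / period), sin(2 * pi * times / period))
  qrX <- qr(X)
  if (qrX$rank < 3) stop("rank-deficient cosinor design")
  # coefficients and residual sums of squares for all genes at once
  B <- t(qr.coef(qrX, t(y)))                     # genes x 3
  fitted <- B %*% t(X)
  rss1 <- rowSums((y - fitted)^2)
  rss0 <- rowSums((y - rowMeans(y))^2)
  df2 <- nt - 3
  Fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
  p <- pf(Fstat, 2, df2, lower.tail = FALSE)
  amp <- sqrt(B[, 2]^2 + B[, 3]^2)
  # zero residual variance: p = 0 when a real oscillation fits exactly,
  # p = 1 for an exactly constant series
  scale0 <- pmax(rowMeans(abs(y)), 1)^2
  degen <- rss1 <= 1e-18 * scale0
  p[degen & amp^2 > 1e-18 * scale0] <- 0
  p[degen & amp^2 <= 1e-18 * scale0] <- 1
  data.frame(mesor = B[, 1], coef_cos = B[, 2], coef_sin = B[, 3],
             amplitude = amp, acrophase = atan2(B[, 3], B[, 2]),
             p_value = p, row.names = rownames(m))
}

#' Log2 peak-to-trough amplitude of a series
#'
#' The screen's amplitude statistic `log2((max + eps) / (min + eps))`; the
#' seasonality criterion requires it to exceed 1 (a > 2-fold swing). The
#' pseudocount keeps the ratio defined when the minimum RPKM is 0.
#'
#' @param values Non-negative signal values.
#' @param pseudocount Added to max and min (default 0.01 RPKM).
#' @return Log2 ratio (numeric scalar >= 0).
#' @examples
#' amplitude_log2(c(1, 2, 4), pseudocount = 0)  # 2
#' @export
amplitude_log2 <- function(values, pseudocount = 0.01) {
  if (any(values < 0)) stop("values must be non-negative")
  log2((max(values) + pseudocount) / (min(values) + pseudocount))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), as computed
#' by `stats::cor(method = "spearman")`. Returns `NA` when either series is
#' constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Smoothing-spline monthly values of a seasonal series
#'
#' Fits a cubic smoothing spline (generalized cross-validation smoothing
#' unless `lambda`/`spar` is forced) and evaluates it on a monthly grid,
#' mid-month points 0.5..11.5 by default. These smoothed monthly values are
#' what the screen's rank correlations are computed on.
#'
#' @param values Signal values.
#' @param times Sampling times in months (>= 4 distinct values).
#' @param grid Evaluation grid (default `seq(0.5, 11.5, by = 1)`).
#' @param lambda,spar Optional smoothing overrides passed to
#'   [stats::smooth.spline()] (e.g. a tiny `lambda` forces interpolation).
#' @return Numeric vector of length `length(grid)`.
#' @export
spline_monthly <- function(values, times, grid = seq(0.5, 11.5, by = 1),
                           lambda = NULL, spar = NULL) {
  stopifnot(length(values) == length(times))
  if (length(unique(times)) < 4)
    stop("spline_monthly needs at least 4 distinct times")
  args <- list(x = times, y = values, cv = FALSE, all.knots = TRUE,
               keep.data = FALSE)
  if (!is.null(lambda)) args$lambda <- lambda
  if (!is.null(spar)) args$spar <- spar
  fit <- do.call(smooth.spline, args)
  predict(fit, grid)$y
}
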