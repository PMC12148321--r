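# Independent oracles used across the suite. Each is deliberately naive
# (enumeration, double loops, textbook formulas) and shares no code with
# the implementation it checks.

# Best global-alignment score by exhaustive enumeration of all alignment
# paths, tracking the gap state so a gap of length L costs
# open + ext * (L - 1). Feasible for sequences of length <= ~7.
oracle_align_score <- function(s1, s2, match = 5, mismatch = -4,
                               open = 10, ext = 0.5) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  # memoized forward recursion over (i, j, gap state); independent of the
  # implementation (different language, direction and recurrence layout)
  n <- length(a); m <- length(b)
  memo <- new.env(hash = TRUE)
  go <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n && j > m) {
      memo[[key]] <- 0
      return(0)
    }
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + go(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- if (state == "X") ext else open
      best <- max(best, -cost + go(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (state == "Y") ext else open
      best <- max(best, -cost + go(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  go(1, 1, "M")
}

# Spearman's rho through the explicit mid-rank + Pearson product-moment
# formula (tie-corrected by construction of mid-ranks).
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-sided Fisher exact p by enumeration over all tables with the observed
# margins, using binomial coefficients directly (no dhyper).
oracle_fisher2x2 <- function(k, n, K, N) {
  support <- max(0, n + K - N):min(n, K)
  pr <- exp(lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n))
  obs <- pr[support == k]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Vectorized margin-wise version: p-values for every feasible k at fixed
# (n, K, N), used for the exhaustive N <= 60 sweep.
oracle_fisher_all_k <- function(n, K, N) {
  support <- max(0, n + K - N):min(n, K)
  pr <- exp(lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n))
  vapply(seq_along(support),
         function(i) sum(pr[pr <= pr[i] * (1 + 1e-7)]), numeric(1))
}

# Naive RPKM: double loop over reads, >= 1 bp intersection counts once.
oracle_rpkm <- function(reads, start, end, total) {
  hits <- 0L
  for (i in seq_len(nrow(reads)))
    if (reads$start[i] < end && reads$end[i] > start) hits <- hits + 1L
  hits / (((end - start) / 1000) * (total / 1e6))
}

# Naive interval-intersection upstream-overlap scan (O(n^2) pairwise).
oracle_overlap_bp <- function(annotation, gene_idx, size_kb = 2) {
  g <- annotation[gene_idx, ]
  if (g$strand == "+") { ws <- g$tss - 1000 * size_kb; we <- g$tss }
  else { ws <- g$tss; we <- g$tss + 1000 * size_kb }
  ws <- max(ws, 0)
  covered <- logical(max(we - ws, 0))
  for (i in seq_len(nrow(annotation))) {
    if (i == gene_idx) next
    o <- annotation[i, ]
    if (o$chrom != g$chrom) next
    lo <- max(ws, o$start); hi <- min(we, o$end)
    if (hi > lo) covered[(lo - ws + 1):(hi - ws)] <- TRUE
  }
  sum(covered)
}

# Per-pixel double-loop scan for GUS classification.
oracle_gus_counts <- function(image, stained_ref, unstained_ref, tol) {
  img <- image
  if (max(img) <= 1) img <- round(img * 255)
  h <- dim(img)[1]; w <- dim(img)[2]
  ns <- nu <- no <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    px <- img[r, c, ]
    if (all(abs(px - stained_ref) <= tol)) ns <- ns + 1L
    else if (all(abs(px - unstained_ref) <= tol)) nu <- nu + 1L
    else no <- no + 1L
  }
  list(n_stained = ns, n_unstained = nu, n_other = no)
}

# Welch's t p-value with the t CDF evaluated by numerical integration of
# the t density (independent of pt()).
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  dens <- function(u) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + u^2 / df)^(-(df + 1) / 2)
  upper <- integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
  2 * upper
}

# Poisson seasonal LRT with both models fitted by direct likelihood
# optimization (null closed form, full via optim), independent of glm.
oracle_poisson_lrt <- function(y, off, times, period = 12) {
  cx <- cos(2 * pi * times / period); sx <- sin(2 * pi * times / period)
  nll <- function(b) {
    mu <- exp(b[1] + b[2] * cx + b[3] * sx + off)
    -sum(y * log(mu) - mu)
  }
  b0 <- log(sum(y) / sum(exp(off)))
  fit <- optim(c(b0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  ll_full <- -fit$value
  ll_null <- sum(y * (b0 + off)) - sum(exp(b0 + off))
  2 * (ll_full - ll_null)
}
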