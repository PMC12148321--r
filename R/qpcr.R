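#' Relative expression from qPCR Ct values (delta-Ct method)
#'
#' Per-sample expression ratio `E^(Ct_reference - Ct_target)` (target
#' normalized to a reference gene such as PP2AA3), rescaled so that the
#' mean ratio of the baseline group (e.g. the day-0 samples) equals 1.
#'
#' @param ct `data.frame` with columns `sample_id`, `timepoint`,
#'   `ct_target`, `ct_reference` (one row per sample; replicates are rows).
#' @param baseline_group Value of `timepoint` defining the baseline.
#' @param efficiency Amplification efficiency per cycle (default 2,
#'   perfect doubling; must lie in (1, 2]).
#' @return The input with columns `ratio` (raw `E^dCt`) and `rel_expr`
#'   (baseline-normalized) appended.
#' @examples
#' ct <- data.frame(sample_id = 1:4, timepoint = c("0d", "0d", "14dC", "14dC"),
#'                  ct_target = c(24, 24, 23, 23), ct_reference = 24)
#' rel_expression(ct, "0d")$rel_expr  # 1 1 2 2
#' @export
rel_expression <- function(ct, baseline_group, efficiency = 2) {
  stopifnot(all(c("timepoint", "ct_target", "ct_reference") %in% names(ct)),
            efficiency > 1, efficiency <= 2)
  if (any(ct$ct_target <= 0) || any(ct$ct_reference <= 0))
    stop("Ct values must be positive")
  base <- ct$timepoint == baseline_group
  if (!any(base)) stop("empty baseline group: ", baseline_group)
  ct$ratio <- efficiency^(ct$ct_reference - ct$ct_target)
  ct$rel_expr <- ct$ratio / mean(ct$ratio[base])
  ct
}

#' Relative histone-modification level from ChIP-qPCR
#'
#' The mark level at an amplicon, first expressed relative to total histone
#' H3 at the same amplicon, then divided by the same mark/H3 ratio at an
#' internal control locus (ACT2 for H3K4me3, FUS3 for H3K27me3). A value of
#' 1 means the amplicon carries the mark at control-locus level.
#'
#' @param level_mark,level_h3 ChIP DNA quantities of the mark and of H3 at
#'   the amplicon of interest.
#' @param control_mark,control_h3 The same pair at the control locus.
#' @return `list(value, defined)`; `value` is `NA` and `defined` is `FALSE`
#'   when H3 or the control ratio is zero.
#' @export
chip_relative <- function(level_mark, level_h3, control_mark, control_h3) {
  stopifnot(level_mark >= 0, level_h3 >= 0, control_mark >= 0,
            control_h3 >= 0)
  if (level_h3 == 0 || control_h3 == 0 || control_mark == 0)
    return(list(value = NA_real_, defined = FALSE))
  list(value = (level_mark / level_h3) / (control_mark / control_h3),
       defined = TRUE)
}

#' Welch's t-test with multiple-testing correction
#'
#' Two-sided Welch unequal-variance t-test (Welch-Satterthwaite degrees of
#' freedom) between two groups, with the p-value optionally adjusted for a
#' stated family of comparisons: Bonferroni multiplies by `family_size`
#' (capped at 1); Holm is the step-down sequential Bonferroni and, for a
#' vector of raw p-values from the same family, is applied jointly via
#' [adjust_p()].
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param correction `"none"`, `"bonferroni"` or `"holm"`.
#' @param family_size Number of comparisons in the family.
#' @return `list(statistic, df, p_raw, p_adjusted)`.
#' @export
group_compare <- function(x, y, correction = c("none", "bonferroni", "holm"),
                          family_size = 1) {
  correction <- match.arg(correction)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  tt <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  p <- tt$p.value
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = p,
       p_adjusted = adjust_p(p, correction, family_size)[1])
}

#' Adjust a family of p-values
#'
#' Bonferroni and Holm (sequential Bonferroni) via [stats::p.adjust()],
#' with an explicit family size that may exceed the number of p-values
#' supplied.
#'
#' @param p Raw p-values.
#' @param method `"none"`, `"bonferroni"` or `"holm"`.
#' @param family_size Family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
adjust_p <- function(p, method = c("none", "bonferroni", "holm"),
                     family_size = length(p)) {
  method <- match.arg(method)
  if (family_size < length(p)) stop("family_size smaller than family")
  p.adjust(p, method = method, n = family_size)
}

#' Read a long-format qPCR Ct table
#'
#' @param path TSV with columns `sample_id`, `timepoint`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @return `data.frame`.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path)
  need <- c("sample_id", "timepoint", "ct_target", "ct_reference")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df
}
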