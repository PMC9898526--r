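# Statistical conventions of the reporting pipeline.

#' Significance band for a p-value
#'
#' Bands mirror the horizontal-bar convention of the time-course figures:
#' `none` (white) for p > 0.05, `weak` (striped) for 0.01 <= p <= 0.05,
#' `strong` (plain) for p < 0.01. The boundary values p = 0.05 and p = 0.01
#' both fall in `weak` (strict inequality for `strong`).
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of bands.
#' @export
pBand <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .configError("p must be in [0, 1]")
  ifelse(p > 0.05, "none", ifelse(p < 0.01, "strong", "weak"))
}

#' Welch two-sample test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, plus the significance band. Two constant samples
#' with equal means give p = 1 by convention (and p = 0 when the means
#' differ).
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p`, `band`.
#' @export
welchTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    .dataError("each sample needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    return(list(t = if (p == 1) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p = p, band = pBand(p)))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, band = pBand(ht$p.value))
}

#' Per-timepoint Welch comparison of two conditions
#'
#' One Welch test per developmental time present in both conditions (>= 2
#' animals each); no multiple-comparison adjustment is applied, matching
#' the reporting convention (an optional Benjamini-Hochberg column can be
#' requested).
#'
#' @param conditionA,conditionB data.frames with columns `time` and `value`
#'   (one row per animal per time).
#' @param adjust if TRUE, add a `p_adj` (BH) column; bands stay based on
#'   the raw p.
#' @return data.frame with `time`, `t`, `df`, `p`, `band` (empty when no
#'   shared times have enough animals).
#' @export
compareTimecourses <- function(conditionA, conditionB, adjust = FALSE) {
  shared <- intersect(unique(conditionA$time), unique(conditionB$time))
  rows <- lapply(sort(shared), function(t0) {
    va <- conditionA$value[conditionA$time == t0]
    vb <- conditionB$value[conditionB$time == t0]
    if (length(va) < 2 || length(vb) < 2) return(NULL)
    w <- welchTest(va, vb)
    data.frame(time = t0, t = w$t, df = w$df, p = w$p, band = w$band)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(time = numeric(0), t = numeric(0), df = numeric(0),
                      p = numeric(0), band = character(0))
  if (adjust && nrow(out)) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Classical one-way ANOVA
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return list with `F` and `p` (`F = 0`, `p = 1` when every value is
#'   identical).
#' @export
anovaOneway <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    .dataError("need >= 2 groups with n >= 2 each")
  v <- unlist(groups, use.names = FALSE)
  if (var(v) == 0) return(list(F = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- oneway.test(v ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value)
}

#' One-sample t test (two-sided, mean against a reference)
#'
#' @param x numeric sample (n >= 2).
#' @param mu reference mean (default 0).
#' @return list with `t`, `df`, `p`.
#' @keywords internal
oneSampleT <- function(x, mu = 0) {
  if (length(x) < 2) .dataError("n >= 2 required")
  ht <- t.test(x, mu = mu)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
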