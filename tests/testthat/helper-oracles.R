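# Independent reference implementations and geometric fixture builders used
# as oracles across the suite.

# Welch t-test from the textbook formulas (independent of stats::t.test).
bruteWelch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# One-way ANOVA from sums of squares (independent of stats::oneway.test).
bruteAnova <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Closed ring of n points on a circle (no repeated closing point).
circleRing <- function(r, n = 240, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  FoldFront(cbind(center[1] + r * cos(th), center[2] + r * sin(th)), time = 0)
}

# Open arc of radius r concave toward +z, apex at (0, 0), center (0, r),
# uniform arc-length sampling.
openArc <- function(r, span, n = 181, time = NA_real_, center = c(0, r)) {
  s <- seq(-span / 2, span / 2, length.out = n)
  FoldFront(cbind(center[1] + r * sin(s / r), center[2] - r * cos(s / r)),
            time = time)
}

# Mean polygon radius about the centroid (for closed simulated rings).
meanRadius <- function(front) {
  p <- frontPoints(front)
  p <- p[-nrow(p), , drop = FALSE]
  ctr <- colMeans(p)
  mean(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2))
}
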