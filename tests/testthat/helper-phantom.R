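# Shared small phantom and frozen truth values used across test files.

small_geom <- function(grid = c(48, 48, 3), ...) {
  make_geometry(grid, voxel_size = c(3, 3, 5), ...)
}

truth_cortex <- function() default_tissue_params()$cortex
truth_medulla <- function() default_tissue_params()$medulla

# Brute-force inversion-recovery oracle: exhaustive T1 grid with every
# polarity assignment of magnitude data. Independent of the package's
# profiled-optimizer path.
ir_gridsearch_oracle <- function(s_mag, ti, t1_grid = seq(200, 3000, by = 0.5)) {
  ord <- order(ti)
  best <- list(rss = Inf)
  for (k in 0:length(ti)) {
    signs <- rep(1, length(ti))
    signs[ord[seq_len(k)]] <- -1
    s <- signs * s_mag
    for (t1 in t1_grid) {
      g <- 1 - 2 * exp(-ti / t1)
      s0 <- sum(s * g) / sum(g * g)
      if (s0 <= 0) next
      rss <- sum((s - s0 * g)^2)
      if (rss < best$rss) best <- list(rss = rss, t1 = t1, s0 = s0)
    }
  }
  best
}

# Dice overlap of two logical masks.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Explicit sum-of-squares two-way ANOVA oracle for ICC (no aov()).
icc_ss_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  msr <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - gm)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}
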