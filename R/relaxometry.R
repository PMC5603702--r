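# Profiled inversion-recovery residual: for fixed T1 the amplitude S0 is
# the linear least-squares solution, so the fit reduces to a 1D search.
ir_profile_rss <- function(t1, s, ti) {
  g <- 1 - 2 * exp(-ti / t1)
  sg <- sum(s * g); gg <- sum(g * g)
  sum(s * s) - sg * sg / gg
}

fit_t1_voxel <- function(s, ti, t1_bounds) {
  # coarse grid then local refinement guards against local minima
  grid <- exp(seq(log(t1_bounds[1]), log(t1_bounds[2]), length.out = 40))
  rss <- vapply(grid, ir_profile_rss, numeric(1), s = s, ti = ti)
  k <- which.min(rss)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(ir_profile_rss, c(lo, hi), s = s, ti = ti, tol = 1e-4)
  t1 <- opt$minimum
  g <- 1 - 2 * exp(-ti / t1)
  s0 <- sum(s * g) / sum(g * g)
  c(t1 = t1, s0 = s0, rss = max(opt$objective, 0))
}

#' Voxelwise inversion-recovery T1 mapping
#'
#' Fits `S(TI) = S0 (1 - 2 exp(-TI/T1))` per voxel by nonlinear least
#' squares (amplitude profiled out, 1D search over T1). In magnitude mode
#' the signal polarity lost by the magnitude operation is restored by
#' trying every candidate zero-crossing position (points before the
#' crossing negated) and keeping the sign assignment with the lowest
#' residual. Voxels whose fitted T1 falls outside `t1_bounds` — or that
#' carry no signal — are flagged `NA`.
#'
#' @param series an IR [acquisition_series()] with at least 3 distinct TIs.
#' @param magnitude_mode `TRUE` if the data are magnitude images.
#' @param t1_bounds admissible T1 range in ms; defaults to 100–5000 ms to
#'   keep background voxels out of downstream histograms.
#' @param mask optional logical array restricting the fit.
#' @return List of [parameter_map()]s: `t1` (ms) and `s0` (a.u.), each
#'   carrying per-voxel residual norms in `fit_quality`.
#' @export
fit_t1 <- function(series, magnitude_mode = FALSE,
                   t1_bounds = c(100, 5000), mask = NULL) {
  stopifnot(inherits(series, "acquisition_series"), series$modality == "IR")
  ti <- series$encoding$ti_ms
  if (length(unique(ti)) < 3L)
    stop("T1 fitting requires at least 3 distinct inversion times",
         call. = FALSE)
  d <- dim(series$data)[1:3]
  t1_map <- array(NA_real_, d); s0_map <- array(NA_real_, d)
  fq <- array(NA_real_, d)
  vox <- if (is.null(mask)) which(array(TRUE, d)) else which(mask)
  dat <- matrix(series$data, prod(d), length(ti))
  for (v in vox) {
    s <- dat[v, ]
    if (all(s == 0) || any(!is.finite(s))) next
    if (!magnitude_mode) {
      fit <- fit_t1_voxel(s, ti, t1_bounds)
    } else {
      ord <- order(ti)
      best <- NULL
      for (k in 0:length(ti)) {       # k earliest TIs negative
        signs <- rep(1, length(ti))
        signs[ord[seq_len(k)]] <- -1
        cand <- fit_t1_voxel(signs * s, ti, t1_bounds)
        if (cand["s0"] > 0 && (is.null(best) || cand["rss"] < best["rss"]))
          best <- cand
      }
      if (is.null(best)) next
      fit <- best
    }
    t1 <- fit[["t1"]]
    # reject fits pinned to the search bounds (no interior optimum)
    if (t1 <= t1_bounds[1] * 1.001 || t1 >= t1_bounds[2] * 0.999) next
    t1_map[v] <- t1
    s0_map[v] <- fit[["s0"]]
    fq[v] <- sqrt(fit[["rss"]])
  }
  list(t1 = parameter_map(t1_map, "T1", "ms", series$voxel_size,
                          fit_quality = fq),
       s0 = parameter_map(s0_map, "S0", "a.u.", series$voxel_size,
                          fit_quality = fq))
}

#' Voxelwise multi-echo T2*/R2* mapping
#'
#' Log-linear fit of `ln S` against TE (the decay `S(TE) = S0
#' exp(-TE/T2*)` is linear in log space). In weighted mode each echo is
#' weighted by its squared signal amplitude — the first-order noise
#' propagation of the log transform, which down-weights late, noise-floor
#' echoes. Non-positive signals are excluded from the log; a voxel with
#' fewer than 3 usable echoes, or T2* outside `t2_bounds`, is flagged
#' `NA`. R2* is reported in 1/s (`1000/T2*` with T2* in ms).
#'
#' @param series an MFFE [acquisition_series()] with at least 3 echoes.
#' @param weighted use amplitude-squared weights (default `TRUE`).
#' @param t2_bounds admissible T2* range in ms.
#' @param mask optional logical array restricting the fit.
#' @return List of [parameter_map()]s: `t2star` (ms), `r2star` (1/s),
#'   `s0` (a.u.).
#' @export
fit_t2star <- function(series, weighted = TRUE, t2_bounds = c(1, 500),
                       mask = NULL) {
  stopifnot(inherits(series, "acquisition_series"),
            series$modality == "MFFE")
  te <- series$encoding$te_ms
  if (length(te) < 3L)
    stop("T2* fitting requires at least 3 echoes", call. = FALSE)
  d <- dim(series$data)[1:3]
  t2_map <- array(NA_real_, d); s0_map <- array(NA_real_, d)
  fq <- array(NA_real_, d)
  vox <- if (is.null(mask)) which(array(TRUE, d)) else which(mask)
  dat <- matrix(series$data, prod(d), length(te))
  for (v in vox) {
    s <- dat[v, ]
    use <- is.finite(s) & s > 0
    if (sum(use) < 3L) next
    y <- log(s[use]); x <- te[use]
    w <- if (weighted) s[use]^2 else rep(1, sum(use))
    sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    sxx <- sum(w * (x - mx)^2)
    if (sxx == 0) next
    slope <- sum(w * (x - mx) * (y - my)) / sxx
    if (slope >= 0) next
    t2 <- -1 / slope
    if (t2 < t2_bounds[1] || t2 > t2_bounds[2]) next
    t2_map[v] <- t2
    s0_map[v] <- exp(my - slope * mx)
    fq[v] <- sqrt(sum(w * (y - (my + slope * (x - mx)))^2) / sw)
  }
  r2 <- 1000 / t2_map
  list(t2star = parameter_map(t2_map, "T2star", "ms", series$voxel_size,
                              fit_quality = fq),
       r2star = parameter_map(r2, "R2star", "s^-1", series$voxel_size),
       s0 = parameter_map(s0_map, "S0", "a.u.", series$voxel_size))
}
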