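# Unweighted log-linear slope/intercept of ln S on b.
loglin_fit <- function(b, s) {
  y <- log(s)
  mx <- mean(b); my <- mean(y)
  slope <- sum((b - mx) * (y - my)) / sum((b - mx)^2)
  c(slope = slope, intercept = my - slope * mx)
}

#' Voxelwise apparent diffusion coefficient (ADC) mapping
#'
#' Mono-exponential fit `S(b) = S0 exp(-b ADC)` by log-linear regression
#' of `ln S` on b over the frames whose b-value lies in `b_range`. Because
#' the perfusion (pseudodiffusion) component decays within the lowest
#' b-values, the fitted ADC depends on the range used: restricting to low
#' b inflates it relative to the full range.
#'
#' @param series a DWI [acquisition_series()].
#' @param b_range `[b_min, b_max]` of frames entering the fit (inclusive).
#' @param mask optional logical array restricting the fit.
#' @return A [parameter_map()] of ADC in mm^2/s; voxels with non-positive
#'   signal on any used frame, or a negative fitted ADC, are `NA`.
#' @export
fit_adc <- function(series, b_range = c(0, Inf), mask = NULL) {
  stopifnot(inherits(series, "acquisition_series"), series$modality == "DWI")
  b <- series$encoding$b
  use_f <- which(b >= b_range[1] & b <= b_range[2])
  if (length(unique(b[use_f])) < 2L)
    stop("ADC fitting requires at least 2 distinct b-values in range",
         call. = FALSE)
  d <- dim(series$data)[1:3]
  adc <- array(NA_real_, d)
  vox <- if (is.null(mask)) which(array(TRUE, d)) else which(mask)
  dat <- matrix(series$data, prod(d), length(b))
  bb <- b[use_f]
  for (v in vox) {
    s <- dat[v, use_f]
    if (any(!is.finite(s)) || any(s <= 0)) next
    fit <- loglin_fit(bb, s)
    a <- -fit[["slope"]]
    if (a < 0) next                           # non-physical, flag
    adc[v] <- a
  }
  parameter_map(adc, "ADC", "mm^2/s", series$voxel_size)
}

# One-parameter D* objective: residual of the bi-exponential with D, fp,
# S0 fixed, over all b.
ivim_dstar_rss <- function(dstar, b, s, s0, d, fp) {
  pred <- s0 * (fp * exp(-b * dstar) + (1 - fp) * exp(-b * d))
  sum((s - pred)^2)
}

#' Voxelwise segmented IVIM fitting (D, fp, D*)
#'
#' Three-step segmented fit of the bi-exponential intravoxel incoherent
#' motion model `S(b) = S0 (fp exp(-b D*) + (1-fp) exp(-b D))`:
#' \enumerate{
#'   \item tissue diffusion D from a log-linear fit over b-values strictly
#'     above `b_threshold`, where pseudodiffusion is assumed fully decayed;
#'   \item perfusion fraction `fp = 1 - I/S(0)` from the zero intercept I
#'     of that fit and the measured b = 0 signal;
#'   \item pseudodiffusion D* from a one-parameter least-squares fit over
#'     all b with D and fp held fixed.
#' }
#' The D* likelihood is notoriously flat, so the 1D search runs on a
#' coarse grid over `[D, 0.5]` mm^2/s before local refinement. `fp`
#' outside `[0, 1)` is clamped (and the voxel flagged in the returned
#' `clamped` array) rather than rejected, keeping maps dense for
#' histogram analysis.
#'
#' @param series a DWI [acquisition_series()] containing a b = 0 frame and
#'   at least 2 b-values above `b_threshold`.
#' @param b_threshold high-b cutoff in s/mm^2 (strict; default 200).
#' @param mask optional logical array restricting the fit.
#' @return List of [parameter_map()]s `d`, `fp`, `dstar` (sharing one `NA`
#'   pattern) plus a logical array `clamped` marking clamped fp voxels.
#' @export
fit_ivim <- function(series, b_threshold = 200, mask = NULL) {
  stopifnot(inherits(series, "acquisition_series"), series$modality == "DWI")
  b <- series$encoding$b
  hi <- which(b > b_threshold)
  if (length(unique(b[hi])) < 2L)
    stop("segmented IVIM requires at least 2 b-values above the threshold",
         call. = FALSE)
  if (!any(b == 0))
    stop("segmented IVIM requires a b = 0 frame", call. = FALSE)
  d3 <- dim(series$data)[1:3]
  D_map <- array(NA_real_, d3); fp_map <- array(NA_real_, d3)
  ds_map <- array(NA_real_, d3)
  clamped <- array(FALSE, d3)
  vox <- if (is.null(mask)) which(array(TRUE, d3)) else which(mask)
  dat <- matrix(series$data, prod(d3), length(b))
  b_hi <- b[hi]
  for (v in vox) {
    s <- dat[v, ]
    s0m <- mean(s[b == 0])
    if (!is.finite(s0m) || s0m <= 0) next
    sh <- s[hi]
    if (any(!is.finite(sh)) || any(sh <= 0)) next
    fit <- loglin_fit(b_hi, sh)
    D <- -fit[["slope"]]
    if (D < 0) next
    intercept <- exp(fit[["intercept"]])
    fp <- 1 - intercept / s0m
    if (fp < 0 || fp >= 1) {
      fp <- min(max(fp, 0), 1 - 1e-9)
      clamped[v] <- TRUE
    }
    # D* search: coarse log grid then local refinement
    lo <- max(D, 1e-6)
    grid <- exp(seq(log(lo), log(0.5), length.out = 60))
    rss <- vapply(grid, ivim_dstar_rss, numeric(1),
                  b = b, s = s, s0 = s0m, d = D, fp = fp)
    k <- which.min(rss)
    opt <- optimize(ivim_dstar_rss,
                    c(grid[max(1, k - 1)], grid[min(length(grid), k + 1)]),
                    b = b, s = s, s0 = s0m, d = D, fp = fp, tol = 1e-8)
    D_map[v] <- D
    fp_map[v] <- fp
    ds_map[v] <- opt$minimum
  }
  list(d = parameter_map(D_map, "D", "mm^2/s", series$voxel_size),
       fp = parameter_map(fp_map, "fp", "fraction", series$voxel_size),
       dstar = parameter_map(ds_map, "Dstar", "mm^2/s", series$voxel_size),
       clamped = clamped)
}
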