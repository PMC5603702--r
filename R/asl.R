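#' Perfusion-weighted difference map with motion quality control
#'
#' Computes per-pair control-minus-label difference images, estimates each
#' pair's in-plane translation against the first control frame by the
#' integer-voxel cross-correlation peak, excludes pairs moving by more
#' than `motion_threshold` voxels, and averages the retained differences
#' into a single perfusion-weighted map.
#'
#' @param series an ASL [acquisition_series()] with complete label/control
#'   pairs.
#' @param motion_threshold maximum tolerated |shift| in voxels (default 1).
#' @return List: `delta_m` (a [parameter_map()], voxelwise mean of retained
#'   differences) and `qc` (a [qc_report()] with per-pair shifts and
#'   exclusions).
#' @export
compute_delta_m <- function(series, motion_threshold = 1) {
  stopifnot(inherits(series, "acquisition_series"), series$modality == "ASL")
  enc <- series$encoding
  pairs <- sort(unique(enc$pair))
  if (!length(pairs)) stop("no label/control pairs", call. = FALSE)
  d <- dim(series$data)[1:3]
  frame3 <- function(k) array(series$data[, , , k], d)
  ctrl_idx <- vapply(pairs, function(p)
    which(enc$pair == p & enc$type == "control")[1], integer(1))
  lab_idx <- vapply(pairs, function(p)
    which(enc$pair == p & enc$type == "label")[1], integer(1))
  if (any(is.na(ctrl_idx)) || any(is.na(lab_idx)))
    stop("incomplete label/control pair(s)", call. = FALSE)
  ref <- frame3(ctrl_idx[1])
  shifts <- matrix(0, length(pairs), 3,
                   dimnames = list(NULL, c("dx", "dy", "dz")))
  for (i in seq_along(pairs))
    shifts[i, 1:2] <- estimate_shift_2d(ref, frame3(ctrl_idx[i]))
  excluded <- pairs[apply(abs(shifts), 1, max) > motion_threshold]
  keep <- setdiff(seq_along(pairs), match(excluded, pairs))
  if (!length(keep))
    stop("all pairs excluded by motion QC: cannot quantify", call. = FALSE)
  acc <- array(0, d)
  for (i in keep)
    acc <- acc + (frame3(ctrl_idx[i]) - frame3(lab_idx[i]))
  dm <- acc / length(keep)
  list(delta_m = parameter_map(dm, "deltaM", "a.u.", series$voxel_size),
       qc = qc_report(excluded, shifts, length(pairs)))
}

#' Kinetic-model perfusion quantification
#'
#' Inverts the single-compartment kinetic model for tissue perfusion f
#' given the perfusion-weighted difference map, the equilibrium M0 map and
#' the tissue T1 map. The model couples f to the apparent T1
#' (`1/T1app = 1/T1 + f/lambda`), so the scalar equation is solved per
#' voxel by fixed-point iteration: start from the explicit solution with
#' `T1app = T1`, then alternate updating T1app and f until `|df| <
#' 1e-6 |f|` (or 50 iterations). The `T1app = T1blood` singularity is
#' handled by its analytic limit. A negative difference signal yields a
#' negative perfusion estimate, which is preserved (flagged, not clamped).
#'
#' @param delta_m [parameter_map()] of the mean difference signal (a.u.).
#' @param m0 [parameter_map()] of equilibrium magnetization (same grid).
#' @param t1 [parameter_map()] of tissue T1 in ms (same grid).
#' @param params an [asl_model_params()] (PLD and blood T1 in seconds).
#' @param iterate if `FALSE`, stop after the single-pass explicit solution
#'   with `T1app = T1` (differs from the converged solution by under ~2%
#'   at physiological perfusion).
#' @return A [parameter_map()] of f in ml/100 g/min; voxels with
#'   non-positive M0 or missing T1 are `NA`. The logical attribute
#'   `negative` marks voxels with f < 0.
#' @export
quantify_perfusion <- function(delta_m, m0, t1, params = asl_model_params(),
                               iterate = TRUE) {
  stopifnot(inherits(delta_m, "parameter_map"), delta_m$quantity == "deltaM",
            inherits(m0, "parameter_map"), inherits(t1, "parameter_map"),
            t1$quantity == "T1", inherits(params, "asl_model_params"))
  stop_unless_same_grid(delta_m, m0, t1)
  dm <- delta_m$data
  m0v <- m0$data
  t1s <- t1$data / 1000
  lam <- params$lambda_bt
  pld <- params$pld
  r1b <- 1 / params$t1_blood
  bad <- !is.finite(dm) | !is.finite(m0v) | m0v <= 0 | !is.finite(t1s) |
    t1s <= 0
  # kinetic kernel K(T1app): dM = 2 M0 (fu/lambda) K
  kfun <- function(r1app) {
    k <- (exp(-pld * r1app) - exp(-pld * r1b)) / (r1b - r1app)
    sing <- is.finite(r1app) & abs(r1b - r1app) < 1e-9
    k[sing] <- pld * exp(-pld * r1b)
    k
  }
  r1app <- 1 / t1s
  fu <- dm * lam / (2 * m0v * kfun(r1app))      # explicit, T1app = T1
  if (iterate) {
    for (it in 1:50) {
      r1app <- 1 / t1s + fu / lam
      fu_new <- dm * lam / (2 * m0v * kfun(r1app))
      delta <- abs(fu_new - fu)
      fu <- fu_new
      if (all(delta[!bad] <= 1e-6 * pmax(abs(fu[!bad]), 1e-12), na.rm = TRUE))
        break
    }
  }
  f <- fu * 6000                                 # ml/g/s -> ml/100 g/min
  f[bad] <- NA_real_
  out <- parameter_map(f, "f", "ml/100 g/min", delta_m$voxel_size)
  attr(out, "negative") <- is.finite(f) & f < 0
  out
}
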