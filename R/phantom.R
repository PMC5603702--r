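#' Default two-tissue kidney phantom parameters
#'
#' Ground-truth tissue parameters for the synthetic kidney phantom. Cortex
#' values are cohort means for healthy kidney at 3 T: T1 1367 ms, T2*
#' 49.6 ms, IVIM D 1.7e-3 mm^2/s, D* 10.7e-3 mm^2/s, perfusion fraction
#' 0.28, perfusion 255 ml/100 g/min. Medulla relaxation times are the
#' corresponding cohort means (T1 1655 ms, T2* 29.7 ms); medullary
#' diffusion and perfusion are not tabulated for this protocol, so
#' physiologically representative values are used (perfusion well below
#' cortex, slightly lower D and fp).
#'
#' @return Named list with one sublist per tissue (`cortex`, `medulla`,
#'   `vessel`), each holding `T1` (ms), `T2star` (ms), `D`, `Dstar`
#'   (mm^2/s), `fp` (fraction), `f` (ml/100 g/min) and `M0` (a.u.).
#' @export
default_tissue_params <- function() {
  list(
    cortex  = list(T1 = 1367, T2star = 49.6, D = 1.7e-3, Dstar = 10.7e-3,
                   fp = 0.28, f = 255, M0 = 100),
    medulla = list(T1 = 1655, T2star = 29.7, D = 1.6e-3, Dstar = 9.0e-3,
                   fp = 0.20, f = 100, M0 = 100),
    vessel  = list(T1 = 1932, T2star = 60, D = 3.0e-3, Dstar = 50e-3,
                   fp = 0.9, f = 0, M0 = 120)
  )
}

TISSUE_CODES <- c(background = 0L, cortex = 1L, medulla = 2L, vessel = 3L)

#' Build the phantom geometry: tissue label volume and masks
#'
#' Each kidney is an ellipse per slice: the outer annulus is cortex, the
#' inner core is medulla, with an unlabelled transition band between them
#' (standing in for the corticomedullary junction / collecting system).
#' An optional vessel disc supports phase-contrast flow simulation.
#'
#' @param grid integer length-3 grid shape; at least 32 x 32 x 3.
#' @param voxel_size numeric length-3, mm.
#' @param n_kidneys 1 or 2 connected kidney components.
#' @param vessel_radius radius of the vessel disc in voxels; 0 disables it.
#' @param cortex_inner fractional radius where the cortex rim starts
#'   (outer edge is 1).
#' @param medulla_outer fractional radius bounding the medullary core.
#' @return List with `labels` (integer array coded by `TISSUE_CODES`),
#'   `masks` (a [tissue_masks()]), `vessel` (logical array) and
#'   `voxel_size`.
#' @export
make_geometry <- function(grid = c(64, 64, 5), voxel_size = c(3, 3, 5),
                          n_kidneys = 1, vessel_radius = 0,
                          cortex_inner = 0.62, medulla_outer = 0.45) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || grid[1] < 32L || grid[2] < 32L || grid[3] < 3L)
    stop("grid too small to host cortex and medulla (need >= 32x32x3)",
         call. = FALSE)
  labels <- array(0L, grid)
  centers <- if (n_kidneys == 1) list(c(grid[1] / 2, grid[2] / 2)) else
    list(c(grid[1] * 0.28, grid[2] / 2), c(grid[1] * 0.72, grid[2] / 2))
  # semi-axes sized so two kidneys stay disjoint
  ax <- if (n_kidneys == 1) grid[1] * 0.30 else grid[1] * 0.17
  ay <- grid[2] * 0.35
  xs <- seq_len(grid[1]); ys <- seq_len(grid[2])
  for (ctr in centers) {
    r <- outer((xs - ctr[1]) / ax, rep(1, grid[2]))^2 +
         outer(rep(1, grid[1]), (ys - ctr[2]) / ay)^2
    r <- sqrt(r)
    sl <- matrix(0L, grid[1], grid[2])
    sl[r <= 1] <- NA_integer_                      # kidney, as-yet unlabelled
    sl[r <= 1 & r > cortex_inner] <- TISSUE_CODES[["cortex"]]
    sl[r <= medulla_outer] <- TISSUE_CODES[["medulla"]]
    sl[is.na(sl)] <- 0L                            # junction band: unlabelled
    for (z in seq_len(grid[3]))
      labels[, , z] <- pmax(labels[, , z], sl)
    # carry kidney extent so the kidney mask includes the junction band
    kid_sl <- r <= 1
    attr(labels, "kidney") <- if (is.null(attr(labels, "kidney")))
      array(rep(kid_sl, grid[3]), grid) else
      attr(labels, "kidney") | array(rep(kid_sl, grid[3]), grid)
  }
  vessel <- array(FALSE, grid)
  if (vessel_radius > 0) {
    vc <- c(round(grid[1] * 0.1), round(grid[2] * 0.1))
    rd <- outer((xs - vc[1])^2, rep(1, grid[2])) +
          outer(rep(1, grid[1]), (ys - vc[2])^2)
    disc <- sqrt(rd) <= vessel_radius
    for (z in seq_len(grid[3])) {
      sl <- labels[, , z]
      sl[disc & sl == 0L] <- TISSUE_CODES[["vessel"]]
      labels[, , z] <- sl
    }
    vessel <- array(rep(disc, grid[3]), grid)
  }
  kidney <- attr(labels, "kidney")
  attr(labels, "kidney") <- NULL
  masks <- tissue_masks(kidney = kidney,
                        cortex = labels == TISSUE_CODES[["cortex"]],
                        medulla = labels == TISSUE_CODES[["medulla"]],
                        voxel_size = voxel_size)
  if (!any(masks$cortex) || !any(masks$medulla))
    stop("geometry degenerate: empty cortex or medulla", call. = FALSE)
  list(labels = labels, masks = masks, vessel = vessel,
       voxel_size = as.numeric(voxel_size))
}

# Map a per-tissue scalar onto the label volume (background -> `fill`).
tissue_volume <- function(labels, tissue_params, field, fill = 0) {
  out <- array(fill, dim(labels))
  for (tis in names(tissue_params)) {
    code <- TISSUE_CODES[[tis]]
    if (is.null(code)) next
    out[labels == code] <- tissue_params[[tis]][[field]]
  }
  out
}

#' Default inversion times, echo times and b-values
#'
#' The protocol's standard encodings at 3 T: 13 inversion times from 200 to
#' 1500 ms, 12 echoes from 5 ms with 3 ms spacing, and 11 b-values from 0
#' to 500 s/mm^2.
#' @name default_encodings
NULL

#' @rdname default_encodings
#' @export
default_tis <- function() c(200, 300, 400, 500, 600, 700, 800, 900,
                            1000, 1100, 1200, 1300, 1500)

#' @rdname default_encodings
#' @export
default_tes <- function() seq(5, by = 3, length.out = 12)

#' @rdname default_encodings
#' @export
default_bvalues <- function() c(0, 5, 10, 20, 30, 50, 100, 200, 300, 400, 500)

#' Simulate an inversion-recovery series
#'
#' Noiseless forward model `S(TI) = S0 (1 - 2 exp(-TI/T1))` per tissue;
#' magnitude mode returns `|S|`.
#'
#' @param geom geometry from [make_geometry()].
#' @param tissue_params per-tissue parameter list (see
#'   [default_tissue_params()]).
#' @param tis inversion times in ms.
#' @param signed if `FALSE`, return magnitude signal.
#' @return An IR [acquisition_series()].
#' @export
simulate_ir_series <- function(geom, tissue_params = default_tissue_params(),
                               tis = default_tis(), signed = TRUE) {
  stopifnot(all(tis > 0))
  t1 <- tissue_volume(geom$labels, tissue_params, "T1", fill = NA_real_)
  s0 <- tissue_volume(geom$labels, tissue_params, "M0", fill = 0)
  d <- dim(geom$labels)
  dat <- array(0, c(d, length(tis)))
  for (k in seq_along(tis)) {
    fr <- s0 * (1 - 2 * exp(-tis[k] / t1))
    fr[!is.finite(fr)] <- 0
    dat[, , , k] <- if (signed) fr else abs(fr)
  }
  acquisition_series(dat, geom$voxel_size, "IR",
                     data.frame(ti_ms = tis))
}

#' Simulate a multi-echo gradient-echo series
#'
#' Noiseless forward model `S(TE) = S0 exp(-TE/T2*)` per tissue.
#'
#' @inheritParams simulate_ir_series
#' @param tes echo times in ms.
#' @return An MFFE [acquisition_series()].
#' @export
simulate_mffe_series <- function(geom, tissue_params = default_tissue_params(),
                                 tes = default_tes()) {
  stopifnot(all(tes > 0))
  t2s <- tissue_volume(geom$labels, tissue_params, "T2star", fill = NA_real_)
  s0 <- tissue_volume(geom$labels, tissue_params, "M0", fill = 0)
  d <- dim(geom$labels)
  dat <- array(0, c(d, length(tes)))
  for (k in seq_along(tes)) {
    fr <- s0 * exp(-tes[k] / t2s)
    fr[!is.finite(fr)] <- 0
    dat[, , , k] <- fr
  }
  acquisition_series(dat, geom$voxel_size, "MFFE",
                     data.frame(te_ms = tes))
}

#' Simulate a diffusion-weighted series (bi-exponential IVIM forward model)
#'
#' `S(b) = S0 (fp exp(-b D*) + (1 - fp) exp(-b D))`; with `fp = 0` this is
#' the mono-exponential diffusion decay.
#'
#' @inheritParams simulate_ir_series
#' @param bvalues b-values in s/mm^2; the first must be 0.
#' @return A DWI [acquisition_series()].
#' @export
simulate_dwi_series <- function(geom, tissue_params = default_tissue_params(),
                                bvalues = default_bvalues()) {
  stopifnot(all(bvalues >= 0), bvalues[1] == 0)
  D  <- tissue_volume(geom$labels, tissue_params, "D", fill = NA_real_)
  Ds <- tissue_volume(geom$labels, tissue_params, "Dstar", fill = NA_real_)
  fp <- tissue_volume(geom$labels, tissue_params, "fp", fill = 0)
  s0 <- tissue_volume(geom$labels, tissue_params, "M0", fill = 0)
  d <- dim(geom$labels)
  dat <- array(0, c(d, length(bvalues)))
  for (k in seq_along(bvalues)) {
    fr <- s0 * (fp * exp(-bvalues[k] * Ds) + (1 - fp) * exp(-bvalues[k] * D))
    fr[!is.finite(fr)] <- 0
    dat[, , , k] <- fr
  }
  acquisition_series(dat, geom$voxel_size, "DWI",
                     data.frame(b = bvalues))
}

#' Kinetic-model perfusion-weighted signal (forward model)
#'
#' Computes the label/control difference signal predicted by the
#' single-compartment kinetic model at a given tissue perfusion:
#' `dM = 2 M0 (f/lambda) (exp(-PLD/T1app) - exp(-PLD/T1blood)) /
#' (1/T1blood - 1/T1app)` with `1/T1app = 1/T1 + f/lambda`. Perfusion `f`
#' is supplied in ml/100 g/min and converted internally to ml/g/s
#' (divide by 6000).
#'
#' @param f perfusion, ml/100 g/min (vector or array).
#' @param m0 equilibrium magnetization (same shape as `f`).
#' @param t1_s tissue T1 in seconds.
#' @param params an [asl_model_params()].
#' @return Difference signal in the units of `m0`.
#' @export
asl_forward_delta_m <- function(f, m0, t1_s, params) {
  fu <- f / 6000                               # ml/g/s
  r1app <- 1 / t1_s + fu / params$lambda_bt
  r1b <- 1 / params$t1_blood
  pld <- params$pld
  num <- exp(-pld * r1app) - exp(-pld * r1b)
  den <- r1b - r1app
  k <- num / den
  # removable singularity at T1app == T1blood
  sing <- is.finite(den) & abs(den) < 1e-9
  k[sing] <- pld * exp(-pld * r1b)
  2 * m0 * (fu / params$lambda_bt) * k
}

#' Simulate an ASL label/control series with known perfusion truth
#'
#' Control frames carry the M0 baseline; label frames are control minus the
#' kinetic-model difference signal at the tissue's true perfusion. Selected
#' pairs can be given integer in-plane translations to emulate inter-pair
#' motion; both frames of a shifted pair move together.
#'
#' @inheritParams simulate_ir_series
#' @param params an [asl_model_params()].
#' @param n_pairs number of label/control pairs.
#' @param motion optional `n_pairs x 2` matrix of integer (dx, dy) voxel
#'   shifts; `NULL` for none.
#' @param m0_scale global scale applied to the M0 baseline.
#' @return List: `series` (ASL [acquisition_series()], frames ordered
#'   control then label per pair), `delta_m_truth` and `f_truth`
#'   ([parameter_map()]s).
#' @export
simulate_asl_series <- function(geom, tissue_params = default_tissue_params(),
                                params = asl_model_params(),
                                n_pairs = 40, motion = NULL, m0_scale = 1) {
  stopifnot(n_pairs >= 1)
  t1_ms <- tissue_volume(geom$labels, tissue_params, "T1", fill = NA_real_)
  f <- tissue_volume(geom$labels, tissue_params, "f", fill = 0)
  m0 <- tissue_volume(geom$labels, tissue_params, "M0", fill = 0) * m0_scale
  dm <- asl_forward_delta_m(f, m0, t1_ms / 1000, params)
  dm[!is.finite(dm)] <- 0
  if (is.null(motion)) motion <- matrix(0L, n_pairs, 2)
  motion <- matrix(as.integer(round(motion)), n_pairs, 2)
  d <- dim(geom$labels)
  dat <- array(0, c(d, 2L * n_pairs))
  enc <- data.frame(pair = rep(seq_len(n_pairs), each = 2),
                    type = rep(c("control", "label"), n_pairs),
                    pld_ms = params$pld * 1000)
  for (p in seq_len(n_pairs)) {
    ctrl <- shift_volume(m0, motion[p, 1], motion[p, 2])
    lab <- ctrl - shift_volume(dm, motion[p, 1], motion[p, 2])
    dat[, , , 2L * p - 1L] <- ctrl
    dat[, , , 2L * p] <- lab
  }
  series <- acquisition_series(dat, geom$voxel_size, "ASL", enc,
                               field_strength = params$field_strength)
  list(series = series,
       delta_m_truth = parameter_map(dm, "deltaM", "a.u.", geom$voxel_size),
       f_truth = parameter_map(f, "f", "ml/100 g/min", geom$voxel_size))
}

#' Simulate a phase-contrast velocity series over the cardiac cycle
#'
#' Each cardiac phase is a velocity image equal to the waveform value
#' inside the vessel and zero outside. Velocities beyond the encoding
#' limit would alias in a real acquisition; the simulator refuses them.
#'
#' @param vessel logical 3D vessel mask.
#' @param waveform per-phase mean velocity, cm/s.
#' @param venc velocity-encoding limit, cm/s.
#' @param voxel_size numeric length-3, mm.
#' @return A PC [acquisition_series()].
#' @export
simulate_pc_series <- function(vessel, waveform, venc = 100,
                               voxel_size = c(1.2, 1.2, 6)) {
  if (any(abs(waveform) > venc))
    stop("waveform exceeds venc: velocities would alias", call. = FALSE)
  d <- dim(vessel)
  dat <- array(0, c(d, length(waveform)))
  for (k in seq_along(waveform))
    dat[, , , k] <- ifelse(vessel, waveform[k], 0)
  acquisition_series(dat, voxel_size, "PC",
                     data.frame(phase = seq_along(waveform),
                                venc_cms = venc))
}

#' Add Rician noise to a series
#'
#' Each voxel value S is replaced by `sqrt((S + n1)^2 + n2^2)` with
#' `n1, n2 ~ Normal(0, sigma)` — the magnitude-MRI noise model.
#'
#' @param series an [acquisition_series()].
#' @param sigma noise standard deviation (signal units); 0 is the identity.
#' @param seed integer seed for reproducibility.
#' @return The series with noisy data.
#' @export
add_rician_noise <- function(series, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(series)
  if (!is.null(seed)) set.seed(seed)
  n <- length(series$data)
  n1 <- rnorm(n, 0, sigma); n2 <- rnorm(n, 0, sigma)
  series$data <- array(sqrt((as.vector(series$data) + n1)^2 + n2^2),
                       dim(series$data))
  series
}

#' Add Gaussian noise to a series
#'
#' For signed (e.g. real-valued inversion-recovery) data where the
#' magnitude noise model does not apply.
#'
#' @inheritParams add_rician_noise
#' @return The series with noisy data.
#' @export
add_gaussian_noise <- function(series, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(series)
  if (!is.null(seed)) set.seed(seed)
  series$data <- series$data + array(rnorm(length(series$data), 0, sigma),
                                     dim(series$data))
  series
}

#' Simulate a test-retest cohort from variance components
#'
#' Value for subject i in session j is `mu + b_i + w_ij` with
#' `b_i ~ Normal(0, sigma_between^2)` and `w_ij ~ Normal(0,
#' sigma_within^2)` — the two-way random-effects generating model that the
#' repeatability statistics (CoV, ICC) estimate.
#'
#' @param mu named numeric vector of per-quantity population means.
#' @param sigma_between,sigma_within named numeric vectors (same names) of
#'   between-subject and within-subject standard deviations.
#' @param n_subjects,n_sessions design size (both at least 2).
#' @param seed integer seed.
#' @return List with `tables` (per quantity, an `n_subjects x n_sessions`
#'   matrix) and `truth` (data frame of the generating components).
#' @export
simulate_repeatability_cohort <- function(mu, sigma_between, sigma_within,
                                          n_subjects = 11, n_sessions = 3,
                                          seed = NULL) {
  stopifnot(n_subjects >= 2, n_sessions >= 2,
            identical(names(mu), names(sigma_between)),
            identical(names(mu), names(sigma_within)))
  if (!is.null(seed)) set.seed(seed)
  tables <- lapply(names(mu), function(q) {
    b <- rnorm(n_subjects, 0, sigma_between[[q]])
    w <- matrix(rnorm(n_subjects * n_sessions, 0, sigma_within[[q]]),
                n_subjects, n_sessions)
    mu[[q]] + b + w
  })
  names(tables) <- names(mu)
  list(tables = tables,
       truth = data.frame(quantity = names(mu), mu = unname(mu),
                          sigma_between = unname(sigma_between),
                          sigma_within = unname(sigma_within)))
}

#' Study-condition defaults for the repeatability cohort
#'
#' Population means with between-subject standard deviations from the
#' healthy-cohort tables, and within-subject standard deviations implied
#' by the reported intra-subject CoV (CoV/100 x mean).
#'
#' @return List of named vectors `mu`, `sigma_between`, `sigma_within`.
#' @export
default_repeatability_components <- function() {
  mu <- c(cortex_perfusion = 255, cortex_T1 = 1367, medulla_T1 = 1655,
          cortex_T2star = 49.6, cortex_ADC = 2.3, cortex_D = 1.7,
          cortex_Dstar = 10.7, cortex_fp = 28, artery_flow = 373,
          kidney_volume = 367)
  sb <- c(cortex_perfusion = 70, cortex_T1 = 79, medulla_T1 = 76,
          cortex_T2star = 6.6, cortex_ADC = 0.3, cortex_D = 0.3,
          cortex_Dstar = 4.5, cortex_fp = 10, artery_flow = 105,
          kidney_volume = 58)
  cov_pct <- c(cortex_perfusion = 9.3, cortex_T1 = 2.0, medulla_T1 = 1.8,
               cortex_T2star = 4.1, cortex_ADC = 2.9, cortex_D = 9.5,
               cortex_Dstar = 38.8, cortex_fp = 21.5, artery_flow = 14.4,
               kidney_volume = 4.2)
  list(mu = mu, sigma_between = sb, sigma_within = cov_pct / 100 * mu)
}
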