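#' @importFrom stats sd optimize aov t.test anova lm median setNames rnorm
#' @importFrom graphics hist
#' @importFrom mclust Mclust mclustBIC me unmap
#' @importFrom stats kmeans quantile
#' @importFrom tools md5sum
#' @importFrom utils write.csv modifyList packageVersion
NULL

MODALITIES <- c("IR", "MFFE", "DWI", "ASL", "PC")

# canonical units per map quantity; the first entry is the default
QUANTITY_UNITS <- list(
  T1       = c("ms"),
  S0       = c("a.u."),
  T2star   = c("ms"),
  R2star   = c("s^-1"),
  ADC      = c("mm^2/s", "x10^-3 mm^2/s"),
  D        = c("mm^2/s", "x10^-3 mm^2/s"),
  Dstar    = c("mm^2/s", "x10^-3 mm^2/s"),
  fp       = c("fraction", "%"),
  f        = c("ml/100 g/min"),
  deltaM   = c("a.u."),
  M0       = c("a.u."),
  velocity = c("cm/s")
)

encoding_columns <- function(modality) {
  switch(modality,
    IR   = "ti_ms",
    MFFE = "te_ms",
    DWI  = "b",
    ASL  = c("pair", "type", "pld_ms"),
    PC   = c("phase", "venc_cms")
  )
}

#' Construct a validated acquisition series
#'
#' An acquisition series holds a 4D voxel array together with the per-frame
#' encoding values that a fitting routine needs: inversion times for
#' inversion-recovery T1 data, echo times for multi-echo gradient-echo data,
#' b-values for diffusion data, label/control pair structure and post-label
#' delay for arterial spin labelling, and cardiac phase plus velocity
#' encoding for phase-contrast flow data.
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param voxel_size numeric length-3, voxel dimensions in mm.
#' @param modality one of `"IR"`, `"MFFE"`, `"DWI"`, `"ASL"`, `"PC"`.
#' @param encoding data frame with one row per frame. Required columns:
#'   `ti_ms` (IR), `te_ms` (MFFE), `b` (DWI), `pair`/`type`/`pld_ms` (ASL,
#'   `type` is `"label"` or `"control"`), `phase`/`venc_cms` (PC).
#' @param field_strength main field in tesla (1.5 or 3). Required for any
#'   series feeding perfusion quantification; optional otherwise.
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(data, voxel_size, modality, encoding,
                               field_strength = NA_real_) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, frame)", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive lengths in mm",
         call. = FALSE)
  modality <- match.arg(modality, MODALITIES)
  encoding <- as.data.frame(encoding)
  if (nrow(encoding) != dim(data)[4L])
    stop(sprintf(
      "encoding length (%d) does not match frame count (%d)",
      nrow(encoding), dim(data)[4L]), call. = FALSE)
  need <- encoding_columns(modality)
  missing_cols <- setdiff(need, names(encoding))
  if (length(missing_cols))
    stop(sprintf("%s series encoding lacks field(s): %s", modality,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (modality == "ASL") {
    if (!all(encoding$type %in% c("label", "control")))
      stop("ASL encoding `type` must be 'label' or 'control'", call. = FALSE)
  }
  if (!is.na(field_strength) && !field_strength %in% c(1.5, 3.0))
    stop("`field_strength` must be 1.5 or 3.0 tesla", call. = FALSE)
  structure(
    list(data = data, voxel_size = voxel_size, modality = modality,
         encoding = encoding, field_strength = field_strength),
    class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<acquisition_series> %s, %dx%dx%d grid, %d frames, voxels %s mm\n",
              x$modality, d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Construct a validated parameter map
#'
#' A parameter map is a 3D voxel array of one named quantitative MRI
#' quantity. Voxels where a fit failed or fell outside physiological bounds
#' are encoded as `NA` (never silently zeroed); downstream histogram
#' summaries drop them.
#'
#' @param data 3D numeric array.
#' @param quantity one of `r paste(names(QUANTITY_UNITS), collapse = ", ")`.
#' @param units unit string; must be one of the units admissible for the
#'   quantity (e.g. `"ms"` for T1, `"mm^2/s"` or `"x10^-3 mm^2/s"` for ADC).
#' @param voxel_size numeric length-3 voxel dimensions in mm.
#' @param fit_quality optional 3D array of per-voxel residual norms.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(data, quantity, units = NULL, voxel_size,
                          fit_quality = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  quantity <- match.arg(quantity, names(QUANTITY_UNITS))
  allowed <- QUANTITY_UNITS[[quantity]]
  if (is.null(units)) units <- allowed[1L]
  if (!units %in% allowed)
    stop(sprintf("units '%s' not admissible for quantity '%s' (allowed: %s)",
                 units, quantity, paste(allowed, collapse = ", ")),
         call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive lengths in mm",
         call. = FALSE)
  if (!is.null(fit_quality) && !identical(dim(fit_quality), dim(data)))
    stop("`fit_quality` grid does not match `data`", call. = FALSE)
  structure(
    list(data = data, quantity = quantity, units = units,
         voxel_size = voxel_size, fit_quality = fit_quality),
    class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<parameter_map> %s [%s], %dx%dx%d, %d finite voxels\n",
              x$quantity, x$units, d[1], d[2], d[3],
              sum(is.finite(x$data))))
  invisible(x)
}

#' Construct a validated set of tissue masks
#'
#' Binary kidney, cortex and medulla masks sharing one grid. Cortex and
#' medulla must be disjoint and contained in the kidney mask.
#'
#' @param kidney,cortex,medulla logical (or 0/1) 3D arrays on one grid.
#' @param voxel_size numeric length-3 voxel dimensions in mm.
#' @return An object of class `tissue_masks`.
#' @export
tissue_masks <- function(kidney, cortex, medulla, voxel_size) {
  kidney <- array(as.logical(kidney), dim(kidney))
  cortex <- array(as.logical(cortex), dim(cortex))
  medulla <- array(as.logical(medulla), dim(medulla))
  if (!identical(dim(kidney), dim(cortex)) ||
      !identical(dim(kidney), dim(medulla)))
    stop("mask grids differ", call. = FALSE)
  if (any(cortex & medulla))
    stop("cortex and medulla masks overlap", call. = FALSE)
  if (any((cortex | medulla) & !kidney))
    stop("cortex/medulla masks extend outside the kidney mask", call. = FALSE)
  structure(list(kidney = kidney, cortex = cortex, medulla = medulla,
                 voxel_size = as.numeric(voxel_size)),
            class = "tissue_masks")
}

#' Kinetic-model parameters for ASL perfusion quantification
#'
#' Defaults follow common renal practice: blood T1 of 1.55 s at 3 T and
#' 1.36 s at 1.5 T, blood-tissue water partition coefficient 0.8 ml/g for
#' kidney.
#'
#' @param pld post-label delay in seconds (> 0).
#' @param field_strength tesla, 1.5 or 3.
#' @param t1_blood blood T1 in seconds; defaults by field strength.
#' @param lambda_bt blood-tissue partition coefficient, ml/g.
#' @return An object of class `asl_model_params`.
#' @export
asl_model_params <- function(pld = 1.8, field_strength = 3.0,
                             t1_blood = NULL, lambda_bt = 0.8) {
  if (!field_strength %in% c(1.5, 3.0))
    stop("`field_strength` must be 1.5 or 3.0 tesla", call. = FALSE)
  if (is.null(t1_blood))
    t1_blood <- if (field_strength == 3.0) 1.55 else 1.36
  if (!is.numeric(pld) || pld <= 0) stop("`pld` must be > 0 s", call. = FALSE)
  structure(list(pld = pld, t1_blood = t1_blood, lambda_bt = lambda_bt,
                 field_strength = field_strength),
            class = "asl_model_params")
}

#' Motion quality-control report for an ASL pair series
#'
#' @param excluded_pair_indices integer vector of excluded pairs.
#' @param per_pair_shift matrix (n_pairs x 3) of estimated shifts in voxels.
#' @param n_total total number of label/control pairs.
#' @return An object of class `qc_report`, with `n_pairs_used =
#'   n_total - length(excluded_pair_indices)`.
#' @export
qc_report <- function(excluded_pair_indices, per_pair_shift, n_total) {
  excluded_pair_indices <- as.integer(excluded_pair_indices)
  if (length(excluded_pair_indices) &&
      any(excluded_pair_indices < 1L | excluded_pair_indices > n_total))
    stop("excluded pair indices outside 1..n_total", call. = FALSE)
  structure(list(excluded_pair_indices = excluded_pair_indices,
                 per_pair_shift = per_pair_shift,
                 n_total = as.integer(n_total),
                 n_pairs_used = as.integer(n_total) -
                   length(excluded_pair_indices)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d pairs retained; excluded: %s\n",
              x$n_pairs_used, x$n_total,
              if (length(x$excluded_pair_indices))
                paste(x$excluded_pair_indices, collapse = ", ") else "none"))
  invisible(x)
}

# shared grid check used by multi-map operations
stop_unless_same_grid <- function(...) {
  maps <- list(...)
  dims <- lapply(maps, function(m) dim(m$data))
  vox  <- lapply(maps, function(m) m$voxel_size)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])) ||
      !all(vapply(vox, function(v) isTRUE(all.equal(v, vox[[1]])),
                  logical(1))))
    stop("maps do not share a grid (shape and voxel size)", call. = FALSE)
  invisible(TRUE)
}
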