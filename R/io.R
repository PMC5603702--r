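#' @importFrom RNifti readNifti writeNifti pixdim
#' @importFrom jsonlite read_json write_json
NULL

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a 4D acquisition series from NIfTI plus JSON sidecar
#'
#' The sidecar carries everything the NIfTI header cannot: modality, field
#' strength and the per-frame encoding list. Frame count is cross-checked
#' against the encoding length; a mismatch is a format error, not a warning.
#'
#' @param path path to a `.nii`/`.nii.gz` volume.
#' @param sidecar path to the JSON sidecar; defaults to `path` with the
#'   extension swapped for `.json`.
#' @return An [acquisition_series()].
#' @export
read_series <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stop("NIfTI volume not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))   # strip niftiImage attributes
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D volume, got %dD", length(dim(arr))),
         call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("modality", "voxel_size_mm", "encoding"))
    if (is.null(meta[[field]]))
      stop("sidecar missing required field: ", field, call. = FALSE)
  fs <- if (is.null(meta$field_strength_T)) NA_real_ else
    as.numeric(meta$field_strength_T)
  acquisition_series(
    data = arr,
    voxel_size = as.numeric(meta$voxel_size_mm),
    modality = meta$modality,
    encoding = as.data.frame(meta$encoding),
    field_strength = fs)
}

#' Write an acquisition series as NIfTI plus JSON sidecar
#'
#' @param series an [acquisition_series()].
#' @param path output `.nii`/`.nii.gz` path; the sidecar is written next to
#'   it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "acquisition_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  meta <- list(modality = series$modality,
               field_strength_T = series$field_strength,
               voxel_size_mm = series$voxel_size,
               encoding = series$encoding)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(path)
}

#' Write a parameter map as NIfTI plus JSON sidecar
#'
#' Values round-trip bit-exactly (double storage); `NA` voxels are
#' preserved. Quantity and units go in the sidecar, voxel size in the
#' NIfTI header.
#'
#' @param map a [parameter_map()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "parameter_map"))
  img <- RNifti::asNifti(map$data)
  RNifti::pixdim(img) <- c(map$voxel_size, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  meta <- list(quantity = map$quantity, units = map$units,
               voxel_size_mm = map$voxel_size)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a parameter map written by [write_map()]
#'
#' @param path `.nii`/`.nii.gz` path with a JSON sidecar beside it.
#' @param sidecar sidecar path override.
#' @return A [parameter_map()].
#' @export
read_map <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stop("NIfTI volume not found: ", path, call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  arr <- array(as.numeric(arr), dim(arr))   # strip niftiImage attributes
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  parameter_map(arr, quantity = meta$quantity, units = meta$units,
                voxel_size = as.numeric(meta$voxel_size_mm))
}
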