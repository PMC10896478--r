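#' Read a NIfTI volume or 4D series
#'
#' Masks and statistic maps are 3D; BOLD series are 4D with more than one
#' timepoint. A 4D file with a length-1 fourth dimension is rejected as a
#' map-not-series to catch dialect mistakes early.
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param expect `"any"`, `"volume"` (3D) or `"series"` (4D, >= 2 volumes).
#' @return Numeric array with attribute `voxel_size_mm` (length 3).
#' @export
read_volume <- function(path, expect = c("any", "volume", "series")) {
  expect <- match.arg(expect)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  vs <- as.numeric(pix)[seq_len(min(3L, length(pix)))]
  if (length(d) == 4L && d[4] == 1L) {
    if (expect == "series")
      stop("file has a length-1 fourth dimension: this is a 3D map, not a series (",
           paste(d, collapse = "x"), ")")
    a <- array(a, dim = d[1:3])
    d <- dim(a)
  }
  if (expect == "volume" && length(d) != 3L)
    stop("expected a 3D volume, got dimensions ", paste(d, collapse = "x"))
  if (expect == "series" && (length(d) != 4L || d[4] < 2L))
    stop("expected a 4D series with >= 2 volumes, got dimensions ",
         paste(d, collapse = "x"))
  attr(a, "voxel_size_mm") <- rep(vs, length.out = 3)
  a
}

#' Write a volume or series as NIfTI
#'
#' @param data 3D or 4D numeric/logical array.
#' @param path output file (.nii or .nii.gz).
#' @param voxel_size_mm voxel size (scalar or length 3).
#' @param repetition_time_s optional TR recorded in the 4th pixdim slot.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size_mm = 3, repetition_time_s = NULL) {
  vs <- rep(as.numeric(voxel_size_mm), length.out = 3)
  data <- (data + 0)  # logical -> numeric
  img <- RNifti::asNifti(data)
  pix <- c(vs, if (!is.null(repetition_time_s)) repetition_time_s)
  RNifti::pixdim(img) <- pix[seq_len(min(length(dim(data)), length(pix)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask volume as a grid
#'
#' Nonzero voxels (float masks with values {0.0, 1.0} included) are coerced
#' to in-mask.
#'
#' @param path NIfTI mask file.
#' @return A [volume_grid()].
#' @export
read_mask <- function(path) {
  a <- read_volume(path, expect = "volume")
  volume_grid(array(a != 0, dim = dim(a)), attr(a, "voxel_size_mm"))
}

#' Extract masked voxel time courses from a 4D array
#'
#' @param arr4d 4D array (x, y, z, time).
#' @param grid a [volume_grid()] with matching spatial dimensions.
#' @param repetition_time_s TR in seconds.
#' @return A [bold_series()].
#' @export
series_from_array <- function(arr4d, grid, repetition_time_s) {
  d <- dim(arr4d)
  if (length(d) != 4L || !all(d[1:3] == grid$dim))
    stop("series grid ", paste(d[1:3], collapse = "x"), " (voxel ",
         paste(attr(arr4d, "voxel_size_mm"), collapse = "x"),
         " mm) does not match mask grid ", paste(grid$dim, collapse = "x"),
         " (voxel ", paste(grid$voxel_size_mm, collapse = "x"), " mm)")
  m <- matrix(arr4d, prod(d[1:3]), d[4])[grid$idx, , drop = FALSE]
  bold_series(m, repetition_time_s)
}

#' Embed an in-mask map (or series) back into the full grid
#'
#' @param values vector (one map) or voxels x k matrix (k maps / bins /
#'   timepoints, written as the 4th dimension).
#' @param grid a [volume_grid()].
#' @return 3D or 4D array with zeros outside the mask.
#' @export
map_to_array <- function(values, grid) {
  if (is.matrix(values)) {
    out <- array(0, c(grid$dim, ncol(values)))
    for (k in seq_len(ncol(values))) {
      v <- array(0, grid$dim); v[grid$idx] <- values[, k]
      out[, , , k] <- v
    }
    out
  } else {
    out <- array(0, grid$dim)
    out[grid$idx] <- values
    out
  }
}

#' Write a run manifest
#'
#' Records the configuration snapshot, all seeds, per-stage parameters and
#' output files of a pipeline run as JSON, so that a run can be reproduced
#' bit-identically for its deterministic stages.
#'
#' @param manifest named list.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$written <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  manifest$package_version <- as.character(utils::packageVersion("fcsconn"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
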