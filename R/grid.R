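#' Masked volume grid
#'
#' A `volume_grid` couples a boolean 3D grey-matter mask with its voxel size
#' so that in-mask voxels have well-defined spatial (mm) coordinates. All
#' Euclidean distances used by the distance-binned connectivity analysis are
#' computed on these coordinates: voxel index (0-based) times voxel size, in a
#' common reference space shared by all subjects of a cohort.
#'
#' @param mask logical 3D array (`TRUE` = in mask).
#' @param voxel_size_mm voxel edge length in mm; scalar (isotropic) or
#'   length-3 vector, one entry per axis.
#' @return An object of class `volume_grid`: list with elements `mask`,
#'   `dim`, `voxel_size_mm` (length 3), `idx` (linear indices of in-mask
#'   voxels), `ijk` (n_voxels x 3 matrix of 1-based array indices),
#'   `coords_mm` (n_voxels x 3 matrix of mm coordinates) and `n_voxels`.
#' @export
volume_grid <- function(mask, voxel_size_mm = 3) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (is.numeric(mask)) mask <- array(mask != 0, dim = dim(mask))
  if (anyNA(mask)) stop("mask contains NA")
  vs <- as.numeric(voxel_size_mm)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  if (length(vs) != 3L || any(vs <= 0)) stop("voxel_size_mm must be positive (scalar or length 3)")
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty: configuration error")
  ijk <- arrayInd(idx, dim(mask))
  coords <- sweep(ijk - 1, 2L, vs, `*`)
  structure(list(
    mask = mask, dim = dim(mask), voxel_size_mm = vs,
    idx = idx, ijk = ijk, coords_mm = coords, n_voxels = length(idx),
    cache = new.env(parent = emptyenv())  # per-grid memo (distance-bin geometry)
  ), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d grid, voxel %s mm, %d in-mask voxels\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(format(x$voxel_size_mm), collapse = " x "), x$n_voxels))
  invisible(x)
}

#' Build an ellipsoidal grey-matter-like mask
#'
#' Constructs a connected ellipsoidal boolean mask centred in the grid, the
#' synthetic stand-in for a grey-matter probability mask. A voxel (0-based
#' index `v`) is in the mask when
#' `sum(((v - centre) / semi_axes)^2) <= 1` in voxel units.
#'
#' @param config a [simulation_config()] list; uses `grid_shape`,
#'   `voxel_size_mm` and optional `mask_semi_axes` / `mask_center` (voxel
#'   units, 0-based centre). Defaults: centre of grid, semi-axes at 45% of
#'   each grid extent.
#' @return A [volume_grid()]. Attribute `fcs_valid` is `FALSE` when the mask
#'   has fewer than 2 voxels (FCS is undefined there).
#' @export
make_mask <- function(config) {
  shp <- as.integer(config$grid_shape)
  if (length(shp) != 3L || any(shp < 1L)) stop("grid_shape must be 3 positive integers")
  ctr <- config$mask_center
  if (is.null(ctr)) ctr <- (shp - 1) / 2
  ax <- config$mask_semi_axes
  if (is.null(ax)) ax <- pmax(0.45 * shp, 0.5)
  g <- expand.grid(i = 0:(shp[1] - 1), j = 0:(shp[2] - 1), k = 0:(shp[3] - 1))
  r2 <- ((g$i - ctr[1]) / ax[1])^2 + ((g$j - ctr[2]) / ax[2])^2 + ((g$k - ctr[3]) / ax[3])^2
  mask <- array(r2 <= 1, dim = shp)
  if (!any(mask)) stop("mask empty after construction: configuration error")
  grid <- volume_grid(mask, config$voxel_size_mm)
  attr(grid, "fcs_valid") <- grid$n_voxels >= 2L
  grid
}

#' Euclidean distance between two in-mask voxels
#'
#' @param grid a [volume_grid()].
#' @param i,j positions in the grid's in-mask voxel ordering (1..n_voxels).
#' @return Distance in mm; symmetric, zero iff `i == j`.
#' @export
pairwise_distance_mm <- function(grid, i, j) {
  stopifnot(inherits(grid, "volume_grid"))
  n <- grid$n_voxels
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    stop("voxel index outside mask (valid range 1..", n, ")")
  sqrt(sum((grid$coords_mm[i, ] - grid$coords_mm[j, ])^2))
}

## distances from a block of in-mask voxels to all in-mask voxels (mm);
## returns length(block) x n_voxels matrix without forming an n x n object
block_distances_mm <- function(grid, block) {
  a <- grid$coords_mm[block, , drop = FALSE]
  b <- grid$coords_mm
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
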