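## Voxel-wise linear-model inference on FCS map stacks, Gaussian smoothness
## estimation from residual maps, Monte Carlo cluster-extent calibration and
## cluster extraction. The ANCOVA is implemented as a linear model with a
## group contrast (identical inference to a one-way ANCOVA with covariates).

## shared voxel-wise GLM: Y (subjects x voxels), X (subjects x p), one
## contrast column; returns signed t map, df, residual stack
fit_voxelwise_glm <- function(Y, X, contrast_col) {
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("map stack rows (", nrow(Y), ") must match design rows (", n, ")")
  if (n <= p) stop("fewer subjects (", n, ") than model parameters + 1 (", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  ci <- match(contrast_col, colnames(X))
  if (is.na(ci)) stop("contrast column '", contrast_col, "' not in design")
  se <- sqrt(pmax(sigma2 * XtXi[ci, ci], 1e-300))
  tval <- B[ci, ] / se
  ## exact-fit voxels (residual at numerical zero relative to the data scale)
  ## carry no evidence: report t = 0 instead of a 0/0 ratio
  tval[sigma2 <= 1e-20 * pmax(colMeans(Y^2), 1e-300)] <- 0
  list(t = unname(tval), df = df, residuals = resid, coef = B)
}

ancova_design <- function(design, extra = NULL) {
  req <- c("group", "age", "sex", "education")
  if (!all(req %in% names(design)))
    stop("design needs columns: ", paste(req, collapse = ", "))
  grp <- design$group
  if (!is.numeric(grp)) grp <- as.integer(grp %in% c("patient", 1, TRUE, "1"))
  X <- cbind(intercept = 1, group = grp, age = design$age,
             sex = as.numeric(design$sex), education = design$education)
  if (!is.null(extra)) X <- cbind(X, extra)
  X
}

#' Voxel-wise ANCOVA group comparison
#'
#' Per voxel, fits `FCS ~ intercept + group + age + sex + education` by least
#' squares and returns the signed group-effect t statistic (patient minus
#' control; negative t = lower FCS in patients) with `df = n - 5`. The group
#' F statistic is `t^2`.
#'
#' @param maps numeric matrix, subjects x in-mask voxels (one smoothed FCS
#'   map per row, all on one grid).
#' @param design data.frame with `group` (either a 0/1 indicator with 1 =
#'   patient, or labels `"patient"`/`"control"`), `age`, `sex`, `education`.
#' @return Object of class `stat_map`: list with `t`, `f` (= t^2), `df`,
#'   `residuals` (subjects x voxels), `n`.
#' @export
voxelwise_ancova <- function(maps, design) {
  X <- ancova_design(design)
  fit <- fit_voxelwise_glm(maps, X, "group")
  structure(list(t = fit$t, f = fit$t^2, df = fit$df,
                 residuals = fit$residuals, n = nrow(X)),
            class = "stat_map")
}

#' Voxel-wise brain-behaviour regression
#'
#' Per voxel, fits `FCS ~ intercept + score + age + sex + education` within
#' one group (typically the patients) and returns the t statistic of the
#' behavioural-score coefficient; positive t means higher FCS with better
#' performance.
#'
#' @param maps subjects x voxels matrix (e.g. smoothed long-range FCS maps).
#' @param design data.frame with `score`, `age`, `sex`, `education` for the
#'   same subjects.
#' @return A `stat_map` (see [voxelwise_ancova()]) for the score effect.
#' @export
voxelwise_behaviour_regression <- function(maps, design) {
  req <- c("score", "age", "sex", "education")
  if (!all(req %in% names(design)))
    stop("design needs columns: ", paste(req, collapse = ", "))
  if (anyNA(design$score)) stop("behavioural score missing for some subjects")
  X <- cbind(intercept = 1, score = design$score, age = design$age,
             sex = as.numeric(design$sex), education = design$education)
  fit <- fit_voxelwise_glm(maps, X, "score")
  structure(list(t = fit$t, f = fit$t^2, df = fit$df,
                 residuals = fit$residuals, n = nrow(X)),
            class = "stat_map")
}

#' Estimate the Gaussian smoothness of residual maps
#'
#' Classic first-differences estimator: each residual map is standardized to
#' unit variance inside the analysis mask; for each axis the variance of
#' differences between in-mask axis neighbours gives the lag-1
#' autocorrelation `rho = 1 - var(diff)/2`, which for a Gaussian
#' autocorrelation function `exp(-d^2 / (4 sigma^2))` yields
#' `FWHM = voxel * 2 sqrt(log 2) / sqrt(-log rho)`. Estimates are pooled
#' across maps and clipped below at one voxel size (white noise has
#' `rho <= 0` and reports the clip value).
#'
#' @param residual_maps matrix, maps x in-mask voxels (at least 2 maps).
#' @param grid the [volume_grid()] the maps live on.
#' @param mask optional logical vector restricting the estimate to a subset
#'   of in-mask voxels (e.g. a distance-bin mask).
#' @return Numeric length-3 vector of per-axis FWHM (mm), attribute
#'   `clipped` flags axes at the clip value.
#' @export
estimate_smoothness <- function(residual_maps, grid, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"), is.matrix(residual_maps))
  if (nrow(residual_maps) < 2L) stop("need at least 2 residual maps")
  keep <- if (is.null(mask)) rep(TRUE, grid$n_voxels) else mask
  kept <- which(keep)                      # positions in in-mask ordering
  lin <- grid$idx[kept]                    # linear grid indices
  pos_of <- integer(prod(grid$dim))
  pos_of[lin] <- seq_along(lin)
  ijk <- grid$ijk[kept, , drop = FALSE]
  strides <- c(1L, grid$dim[1], grid$dim[1] * grid$dim[2])
  fwhm <- numeric(3)
  clipped <- logical(3)
  rho_clip <- exp(-1 / (4 * fwhm_to_sigma(1)^2))  # lag-1 rho at FWHM = 1 voxel
  for (a in 1:3) {
    nb_pos <- integer(length(lin))
    has_nb <- ijk[, a] < grid$dim[a]
    nb_pos[has_nb] <- pos_of[lin[has_nb] + strides[a]]
    ok <- nb_pos > 0L
    if (sum(ok) < 10L) { fwhm[a] <- grid$voxel_size_mm[a]; clipped[a] <- TRUE; next }
    i1 <- kept[ok]                         # in-mask index of voxel
    i2 <- kept[nb_pos[ok]]                 # in-mask index of +1 axis neighbour
    num <- 0; den <- 0
    for (r in seq_len(nrow(residual_maps))) {
      x <- residual_maps[r, ]
      s <- stats::sd(x[kept])
      if (s < 1e-12) next
      d <- (x[i1] - x[i2]) / s
      num <- num + sum(d^2); den <- den + length(d)
    }
    if (den == 0) { fwhm[a] <- grid$voxel_size_mm[a]; clipped[a] <- TRUE; next }
    rho <- 1 - (num / den) / 2
    if (!is.finite(rho) || rho <= rho_clip) {
      fwhm[a] <- grid$voxel_size_mm[a]; clipped[a] <- TRUE
    } else {
      sigma_vox <- sqrt(-1 / (4 * log(rho)))
      fwhm[a] <- 2 * sqrt(2 * log(2)) * sigma_vox * grid$voxel_size_mm[a]
    }
  }
  attr(fwhm, "clipped") <- clipped
  fwhm
}

#' Cluster-correction parameters
#'
#' @param voxel_p voxel-level two-sided p threshold (default 0.05).
#' @param alpha family-wise error level (default 0.05).
#' @param n_iterations Monte Carlo iterations (default 1000; below 100 is
#'   refused).
#' @param connectivity 6, 18 or 26-neighbour cluster connectivity
#'   (default 26).
#' @export
cluster_correction_params <- function(voxel_p = 0.05, alpha = 0.05,
                                      n_iterations = 1000L, connectivity = 26L) {
  if (voxel_p <= 0 || voxel_p >= 1 || alpha <= 0 || alpha >= 1)
    stop("voxel_p and alpha must lie strictly between 0 and 1")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (n_iterations < 100L)
    warning("n_iterations below 100 gives an unstable extent threshold")
  structure(list(voxel_p = voxel_p, alpha = alpha,
                 n_iterations = as.integer(n_iterations),
                 connectivity = as.integer(connectivity)),
            class = "cluster_correction_params")
}

neighbour_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  g <- switch(as.character(connectivity),
              "6" = g[ord == 1, ], "18" = g[ord <= 2, ], "26" = g)
  ## positive-lexicographic half: each unordered pair visited once
  g[g$dz > 0 | (g$dz == 0 & (g$dy > 0 | (g$dy == 0 & g$dx > 0))), ]
}

## connected components of a set of in-mask voxels; returns integer labels
label_components <- function(sel_ijk, dims, connectivity = 26L) {
  n <- nrow(sel_ijk)
  if (n == 0L) return(integer(0))
  key <- (sel_ijk[, 1] - 1) + dims[1] * ((sel_ijk[, 2] - 1) + dims[2] * (sel_ijk[, 3] - 1))
  off <- neighbour_offsets(connectivity)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(off))) {
    ni <- sel_ijk[, 1] + off$dx[r]
    nj <- sel_ijk[, 2] + off$dy[r]
    nk <- sel_ijk[, 3] + off$dz[r]
    valid <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] & nk >= 1 & nk <= dims[3]
    nkey <- (ni - 1) + dims[1] * ((nj - 1) + dims[2] * (nk - 1))
    m <- match(nkey[valid], key)
    a <- which(valid)[!is.na(m)]
    b <- m[!is.na(m)]
    for (q in seq_along(a)) {
      ra <- find(a[q]); rb <- find(b[q])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Monte Carlo cluster-extent threshold
#'
#' Calibrates the minimum cluster size controlling the family-wise error at
#' `alpha` within an analysis mask (AlphaSim convention): simulate white
#' noise on the grid, smooth it to the supplied smoothness with the same
#' mask-weighted Gaussian smoothing used for the data maps, standardize each
#' in-mask voxel exactly (by the analytic SD of the smoothed field),
#' threshold two-sided at `voxel_p`, record the maximum suprathreshold
#' cluster size (positive and negative excursions labelled separately) under
#' the chosen connectivity, and return the `(1 - alpha)` quantile of the
#' max-size distribution.
#'
#' @param grid the [volume_grid()] defining the analysis mask.
#' @param smoothness_fwhm_mm per-axis (or scalar) Gaussian smoothness of the
#'   null fields, typically from [estimate_smoothness()].
#' @param params a [cluster_correction_params()].
#' @param seed RNG seed (recorded in the result).
#' @param mask optional logical vector (in-mask order) restricting the
#'   analysis to a sub-mask, e.g. a distance-bin mask.
#' @return List: `extent_voxels` (minimum size in voxels; clusters strictly
#'   larger survive), `extent_mm3`, `max_sizes` (the null distribution),
#'   `seed`, `params`, `smoothness_fwhm_mm`.
#' @export
monte_carlo_cluster_threshold <- function(grid, smoothness_fwhm_mm,
                                          params = cluster_correction_params(),
                                          seed = 1L, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  keep <- if (is.null(mask)) rep(TRUE, grid$n_voxels) else mask
  if (!any(keep)) stop("analysis mask is empty")
  zcrit <- stats::qnorm(1 - params$voxel_p / 2)
  ijk_all <- grid$ijk
  set.seed(as.integer(seed %% 2147483629))
  max_sizes <- integer(params$n_iterations)
  for (it in seq_len(params$n_iterations)) {
    z <- smoothed_null_field(grid, smoothness_fwhm_mm)
    z[!keep] <- 0
    mx <- 0L
    for (sgn in c(1, -1)) {
      sel <- which(sgn * z > zcrit)
      if (length(sel)) {
        lab <- label_components(ijk_all[sel, , drop = FALSE], grid$dim,
                                params$connectivity)
        mx <- max(mx, max(tabulate(lab)))
      }
    }
    max_sizes[it] <- mx
  }
  ext <- as.integer(stats::quantile(max_sizes, 1 - params$alpha, type = 1))
  list(extent_voxels = ext,
       extent_mm3 = ext * prod(grid$voxel_size_mm),
       max_sizes = max_sizes, seed = seed, params = params,
       smoothness_fwhm_mm = rep(smoothness_fwhm_mm, length.out = 3))
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Binarizes the t map two-sided at `voxel_p` (using the map's t df), labels
#' connected components (positive and negative excursions separately) and
#' keeps components whose volume is strictly greater than the extent
#' threshold.
#'
#' @param stat a `stat_map` from [voxelwise_ancova()] /
#'   [voxelwise_behaviour_regression()], or a plain numeric z/t vector (then
#'   supply `df = Inf` for z).
#' @param grid the [volume_grid()].
#' @param extent_voxels minimum cluster size in voxels (clusters of exactly
#'   this size are rejected), typically
#'   `monte_carlo_cluster_threshold()$extent_voxels`.
#' @param params a [cluster_correction_params()] (voxel_p, connectivity).
#' @param df t degrees of freedom when `stat` is a plain vector.
#' @param mask optional logical sub-mask (in-mask order).
#' @return `data.frame` with one row per surviving cluster: `cluster`,
#'   `n_voxels`, `volume_mm3`, `peak_stat`, `peak_i/j/k` (1-based array
#'   indices), `peak_x/y/z_mm`, `sign`. Zero rows when nothing survives.
#' @export
extract_clusters <- function(stat, grid, extent_voxels,
                             params = cluster_correction_params(),
                             df = NULL, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  if (inherits(stat, "stat_map")) { tval <- stat$t; df <- stat$df }
  else tval <- as.numeric(stat)
  if (is.null(df)) stop("df required for a plain statistic vector")
  tcrit <- if (is.infinite(df)) stats::qnorm(1 - params$voxel_p / 2)
           else stats::qt(1 - params$voxel_p / 2, df)
  keep <- if (is.null(mask)) rep(TRUE, grid$n_voxels) else mask
  rows <- list()
  cl_id <- 0L
  for (sgn in c(1, -1)) {
    sel <- which(keep & sgn * tval > tcrit)
    if (!length(sel)) next
    lab <- label_components(grid$ijk[sel, , drop = FALSE], grid$dim,
                            params$connectivity)
    for (l in seq_len(max(lab))) {
      vox <- sel[lab == l]
      if (length(vox) <= extent_voxels) next
      pk <- vox[which.max(sgn * tval[vox])]
      cl_id <- cl_id + 1L
      rows[[cl_id]] <- data.frame(
        cluster = cl_id, n_voxels = length(vox),
        volume_mm3 = length(vox) * prod(grid$voxel_size_mm),
        peak_stat = tval[pk],
        peak_i = grid$ijk[pk, 1], peak_j = grid$ijk[pk, 2], peak_k = grid$ijk[pk, 3],
        peak_x_mm = grid$coords_mm[pk, 1], peak_y_mm = grid$coords_mm[pk, 2],
        peak_z_mm = grid$coords_mm[pk, 3],
        sign = if (sgn > 0) "positive" else "negative")
    }
  }
  if (!length(rows))
    return(data.frame(cluster = integer(), n_voxels = integer(),
                      volume_mm3 = numeric(), peak_stat = numeric(),
                      peak_i = integer(), peak_j = integer(), peak_k = integer(),
                      peak_x_mm = numeric(), peak_y_mm = numeric(),
                      peak_z_mm = numeric(), sign = character()))
  do.call(rbind, rows)
}
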