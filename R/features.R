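## Feature reduction for the age model: GM probability maps are smoothed
## (FWHM 3 mm), resampled to a coarse grid (3 mm), masked, centred and
## projected onto principal components.

## Deterministic per-subject step: smooth + resample + flatten. Returns an
## n x nvox matrix; safe to precompute outside cross-validation folds.
feature_rows <- function(gm_maps, fwhm = 3, resample = 3) {
  rows <- lapply(gm_maps, function(m) {
    sm <- if (fwhm > 0) smooth_volume(m, fwhm) else m
    rs <- if (!isTRUE(all.equal(resample, m$voxel_size)))
      resample_volume(sm, voxel_size = resample) else sm
    as.vector(rs$values)
  })
  n <- length(rows)
  if (length(unique(vapply(rows, length, integer(1)))) != 1)
    stop("GM maps must share one geometry")
  matrix(unlist(rows), nrow = n, byrow = TRUE)
}

## Fit mask + centring + PCA on a feature-row matrix (training data only).
fit_reduction_rows <- function(rows, mask = NULL, n_components = "max",
                               fwhm = 3, resample = 3,
                               mask_threshold = 0.01) {
  n <- nrow(rows)
  if (n < 2) stop("need at least 2 subjects")
  if (is.null(mask)) mask <- colMeans(rows) > mask_threshold
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty feature mask")
  xm <- rows[, mask, drop = FALSE]
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  sv <- svd(xc, nu = 0)
  kmax <- min(n - 1, ncol(xm))
  k <- if (identical(n_components, "max")) kmax
       else min(as.integer(n_components), kmax)
  ev <- sv$d^2 / (n - 1)
  basis <- sv$v[, seq_len(k), drop = FALSE]
  structure(list(mask = mask, fwhm = fwhm, resample = resample,
                 pca_mean = mu, pca_basis = basis,
                 explained_variance = ev[seq_len(k)],
                 all_eigenvalues = ev, n_train = n),
            class = "feature_reduction")
}

#' Reduce GM maps to PCA features
#'
#' Smooths each GM probability map (default FWHM 3 mm), resamples to a coarse
#' grid (default 3 mm, trilinear), flattens the masked voxels, centres them,
#' and fits a principal component analysis. The number of components is
#' capped at `n - 1`.
#'
#' @param gm_maps List of `volume_image` GM probability maps sharing one
#'   geometry (at least 2).
#' @param mask Optional logical vector over the resampled voxels; default:
#'   voxels whose mean GM probability exceeds 0.01.
#' @param fwhm Smoothing kernel FWHM in mm.
#' @param resample Target isotropic voxel size in mm.
#' @param n_components Number of components, or `"max"` for `n - 1`.
#' @return A list with `reduction` (a `feature_reduction`: mask, centring
#'   vector, orthonormal component basis, per-component explained variance)
#'   and `features` (the n x k score matrix).
#' @export
reduce_features <- function(gm_maps, mask = NULL, fwhm = 3, resample = 3,
                            n_components = "max") {
  rows <- feature_rows(gm_maps, fwhm, resample)
  red <- fit_reduction_rows(rows, mask, n_components, fwhm, resample)
  list(reduction = red, features = project_rows(red, rows))
}

## Project feature-row matrices onto a fitted reduction.
project_rows <- function(reduction, rows) {
  xm <- rows[, reduction$mask, drop = FALSE]
  sweep(xm, 2, reduction$pca_mean) %*% reduction$pca_basis
}

#' Project new GM maps onto a fitted feature reduction
#' @param object A `feature_reduction`.
#' @param gm_maps List of `volume_image` GM maps (same native geometry as the
#'   training maps).
#' @param ... Unused.
#' @return Score matrix (subjects x components).
#' @export
predict.feature_reduction <- function(object, gm_maps, ...) {
  rows <- feature_rows(gm_maps, object$fwhm, object$resample)
  if (ncol(rows) != length(object$mask))
    stop("GM maps do not match the reduction geometry")
  project_rows(object, rows)
}

#' @export
print.feature_reduction <- function(x, ...) {
  cat(sprintf("feature_reduction: %d masked voxels, %d components (FWHM %g mm, %g mm grid)\n",
              sum(x$mask), ncol(x$pca_basis), x$fwhm, x$resample))
  tv <- sum(x$all_eigenvalues)
  if (tv > 0)
    cat(sprintf("  variance explained by retained components: %.1f%%\n",
                100 * sum(x$explained_variance) / tv))
  invisible(x)
}
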