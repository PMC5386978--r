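## Internal numerics shared across the pipeline: seeded RNG scoping,
## FWHM/sigma conversion, separable Gaussian smoothing, box sums and
## trilinear resampling on axis-aligned grids.

#' Convert a Gaussian kernel full width at half maximum to its sigma
#'
#' @param fwhm Full width at half maximum, in the same units as the result.
#' @return Standard deviation of the Gaussian with that FWHM,
#'   `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a child seed from a master seed
#'
#' Stable integer mixing so that every stage and subject of a run draws from
#' its own reproducible stream, all determined by one master seed. Results
#' stay within the 32-bit signed integer range.
#'
#' @param master Master seed (integer).
#' @param ... Further integer or character components identifying the stream
#'   (stage name, subject index, ...).
#' @return A positive integer seed below 2^31.
#' @export
child_seed <- function(master, ...) {
  parts <- list(...)
  h <- as.double(master) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.double(p)) {
      h <- (h * 48271 + v + 11) %% 2147483647
    }
  }
  as.integer(h %% 2147483562 + 1)
}

## 1D normalized Gaussian kernel matrix (n x n) with edge renormalization;
## sigma in voxel units. Returns identity-like matrix for tiny sigma.
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 1e-8) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

## Separable Gaussian smoothing of a 3D array; sigma_vox length-3 in voxels.
smooth_gauss3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  ## axis 1
  if (sigma_vox[1] > 1e-8) {
    K <- gauss_kernel_matrix(d[1], sigma_vox[1])
    arr <- array(K %*% matrix(arr, d[1], d[2] * d[3]), d)
  }
  ## axis 2
  if (sigma_vox[2] > 1e-8) {
    K <- gauss_kernel_matrix(d[2], sigma_vox[2])
    a <- aperm(arr, c(2, 1, 3))
    a <- array(K %*% matrix(a, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2, 1, 3))
  }
  ## axis 3
  if (sigma_vox[3] > 1e-8) {
    K <- gauss_kernel_matrix(d[3], sigma_vox[3])
    a <- aperm(arr, c(3, 1, 2))
    a <- array(K %*% matrix(a, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
    arr <- aperm(a, c(2, 3, 1))
  }
  arr
}

## Sliding box sum over a cube of half-width r (separable, zero-padded).
box_sum3d <- function(arr, r) {
  d <- dim(arr)
  run1 <- function(m, n) {
    ## m: n x q matrix; running sum over window [i-r, i+r] along rows
    cs <- apply(m, 2, cumsum)
    cs <- rbind(matrix(0, 1, ncol(m)), cs)
    hi <- pmin(seq_len(n) + r, n) + 1L
    lo <- pmax(seq_len(n) - r, 1L)
    cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  a <- array(run1(matrix(arr, d[1], d[2] * d[3]), d[1]), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(run1(matrix(a, d[2], d[1] * d[3]), d[2]), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  a <- array(run1(matrix(a, d[3], d[1] * d[2]), d[3]), c(d[3], d[1], d[2]))
  aperm(a, c(2, 3, 1))
}

## Trilinear interpolation of 3D array `arr` at fractional voxel coordinates
## (1-based). Coordinates outside the grid return `fill`.
interp_trilinear <- function(arr, xi, yi, zi, fill = 0) {
  d <- dim(arr)
  out <- rep(fill, length(xi))
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  if (!any(ok)) return(out)
  x <- xi[ok]; y <- yi[ok]; z <- zi[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  v000 <- arr[idx(x0, y0, z0)];     v100 <- arr[idx(x0 + 1, y0, z0)]
  v010 <- arr[idx(x0, y0 + 1, z0)]; v110 <- arr[idx(x0 + 1, y0 + 1, z0)]
  v001 <- arr[idx(x0, y0, z0 + 1)]; v101 <- arr[idx(x0 + 1, y0, z0 + 1)]
  v011 <- arr[idx(x0, y0 + 1, z0 + 1)]
  v111 <- arr[idx(x0 + 1, y0 + 1, z0 + 1)]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
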