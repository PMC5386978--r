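## Affine registration by intensity: normalized mean-squared difference on
## 2-mm-smoothed images, minimized by coarse search plus Nelder-Mead
## refinement over the transform parameters.

rot3 <- function(rx, ry, rz) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

## Build the fixed-world -> moving-world map from a parameter vector.
affine_from_params <- function(par, dof, c_fixed, c_moving) {
  t <- c(0, 0, 0); R <- diag(3); S <- diag(3); Sh <- diag(3)
  if (dof == "scale-only") {
    S <- diag(rep(exp(par[1]), 3))
  } else if (dof == "rigid") {
    t <- par[1:3]; R <- rot3(par[4], par[5], par[6])
  } else {                                   # full-affine
    t <- par[1:3]; R <- rot3(par[4], par[5], par[6])
    S <- diag(exp(par[7:9]))
    Sh[1, 2] <- par[10]; Sh[1, 3] <- par[11]; Sh[2, 3] <- par[12]
  }
  M <- R %*% S %*% Sh
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- c_moving + t - M %*% c_fixed
  A
}

n_params <- function(dof) switch(dof, "scale-only" = 1L, "rigid" = 6L,
                                 "full-affine" = 12L)

#' Resample a volume through a world-space affine transform
#'
#' @param moving The `volume_image` to resample.
#' @param grid A `volume_image` defining the target geometry.
#' @param transform 4x4 matrix mapping target-grid world coordinates to
#'   moving-image world coordinates (as returned by [affine_register()]).
#' @param fill Value for coordinates outside the moving image.
#' @return The resampled `volume_image` on `grid`'s geometry.
#' @export
resample_with_transform <- function(moving, grid, transform, fill = 0) {
  d <- dim(grid$values)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  w <- cbind(grid$origin[1] + (g$i - 1) * grid$voxel_size[1],
             grid$origin[2] + (g$j - 1) * grid$voxel_size[2],
             grid$origin[3] + (g$k - 1) * grid$voxel_size[3])
  src <- w %*% t(transform[1:3, 1:3]) +
    matrix(transform[1:3, 4], nrow(w), 3, byrow = TRUE)
  xi <- (src[, 1] - moving$origin[1]) / moving$voxel_size[1] + 1
  yi <- (src[, 2] - moving$origin[2]) / moving$voxel_size[2] + 1
  zi <- (src[, 3] - moving$origin[3]) / moving$voxel_size[3] + 1
  volume_image(array(interp_trilinear(moving$values, xi, yi, zi, fill), d),
               grid$voxel_size, grid$origin)
}

#' Affine registration of one volume to another
#'
#' Minimizes the mean-squared difference of intensity-normalized,
#' Gaussian-smoothed images over the transform parameters (coarse grid search
#' followed by Nelder-Mead refinement). The returned 4x4 transform maps
#' fixed-space world coordinates to moving-space world coordinates; applying
#' it resamples the moving image into the fixed grid.
#'
#' @param moving,fixed `volume_image`s with overlapping fields of view.
#' @param dof Degrees of freedom: `"scale-only"` (isotropic scale about the
#'   grid centre), `"rigid"` (translation + rotation) or `"full-affine"`
#'   (translation, rotation, per-axis scale, shear).
#' @param smooth_fwhm FWHM (mm) of the smoothing applied before estimating
#'   the transform.
#' @param max_samples Cost function is evaluated on at most this many evenly
#'   strided voxels of the fixed grid.
#' @param maxit Nelder-Mead iteration cap.
#' @return A list of class `affine_registration`: `transform` (4x4),
#'   `params`, `dof`, `cost`, `converged` (logical; `FALSE` flags optimizer
#'   non-convergence) and `resampled` (the original moving image resampled
#'   into the fixed grid).
#' @export
affine_register <- function(moving, fixed,
                            dof = c("rigid", "scale-only", "full-affine"),
                            smooth_fwhm = 2, max_samples = 20000,
                            maxit = 600) {
  dof <- match.arg(dof)
  msm <- if (smooth_fwhm > 0) smooth_volume(moving, smooth_fwhm) else moving
  fsm <- if (smooth_fwhm > 0) smooth_volume(fixed, smooth_fwhm) else fixed
  norm01 <- function(v) {
    s <- stats::sd(v); if (s < 1e-12) s <- 1
    (v - mean(v)) / s
  }
  msm$values <- array(norm01(as.vector(msm$values)), dim(msm$values))
  fvals <- norm01(as.vector(fsm$values))

  d <- dim(fixed$values)
  stride <- max(1L, floor((prod(d) / max_samples)^(1 / 3)))
  ii <- seq(1L, d[1], by = stride); jj <- seq(1L, d[2], by = stride)
  kk <- seq(1L, d[3], by = stride)
  g <- expand.grid(i = ii, j = jj, k = kk)
  lin <- (g$k - 1) * d[1] * d[2] + (g$j - 1) * d[1] + g$i
  w <- cbind(fixed$origin[1] + (g$i - 1) * fixed$voxel_size[1],
             fixed$origin[2] + (g$j - 1) * fixed$voxel_size[2],
             fixed$origin[3] + (g$k - 1) * fixed$voxel_size[3])
  fsamp <- fvals[lin]

  c_fixed <- fixed$origin + (d - 1) / 2 * fixed$voxel_size
  dm <- dim(moving$values)
  c_moving <- moving$origin + (dm - 1) / 2 * moving$voxel_size

  cost <- function(par) {
    A <- affine_from_params(par, dof, c_fixed, c_moving)
    src <- w %*% t(A[1:3, 1:3]) + matrix(A[1:3, 4], nrow(w), 3, byrow = TRUE)
    xi <- (src[, 1] - moving$origin[1]) / moving$voxel_size[1] + 1
    yi <- (src[, 2] - moving$origin[2]) / moving$voxel_size[2] + 1
    zi <- (src[, 3] - moving$origin[3]) / moving$voxel_size[3] + 1
    mv <- interp_trilinear(msm$values, xi, yi, zi, fill = NA)
    ok <- !is.na(mv)
    if (sum(ok) < length(mv) / 4) return(10 + 10 * (1 - sum(ok) / length(mv)))
    ## squared error after the per-evaluation optimal linear intensity map,
    ## i.e. 1 - r^2: invariant to the differing foreground/background
    ## balance of the two fields of view
    r <- stats::cor(mv[ok], fsamp[ok])
    if (!is.finite(r)) return(10)
    1 - r^2
  }

  p0 <- rep(0, n_params(dof))
  ## coarse initialization
  if (dof == "scale-only") {
    grid_s <- log(seq(0.7, 1.4, by = 0.05))
    cs <- vapply(grid_s, function(s) cost(s), numeric(1))
    p0[1] <- grid_s[which.min(cs)]
  } else {
    step <- 2 * max(fixed$voxel_size)
    tr <- expand.grid(tx = (-2:2) * step, ty = (-2:2) * step,
                      tz = (-2:2) * step)
    cs <- vapply(seq_len(nrow(tr)), function(r) {
      p <- p0; p[1:3] <- as.numeric(tr[r, ]); cost(p)
    }, numeric(1))
    p0[1:3] <- as.numeric(tr[which.min(cs), ])
  }

  if (dof == "scale-only") {
    ## one parameter: bounded Brent search
    opt <- stats::optim(p0, cost, method = "Brent",
                        lower = p0 - 0.2, upper = p0 + 0.2)
    opt2 <- stats::optim(opt$par, cost, method = "Brent",
                         lower = opt$par - 0.05, upper = opt$par + 0.05)
  } else {
    opt <- stats::optim(p0, cost, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    ## a restart from the optimum tightens the solution; a restart that
    ## cannot improve the cost is itself evidence of convergence
    opt2 <- stats::optim(opt$par, cost, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10))
  }
  converged <- opt2$convergence == 0 ||
    abs(opt2$value - opt$value) <= 1e-7 * (abs(opt$value) + 1e-12)
  if (opt2$value < opt$value) opt <- opt2

  A <- affine_from_params(opt$par, dof, c_fixed, c_moving)
  res <- resample_with_transform(moving, fixed, A)
  structure(list(transform = A, params = opt$par, dof = dof,
                 cost = opt$value, converged = converged,
                 resampled = res),
            class = "affine_registration")
}

#' @export
print.affine_registration <- function(x, ...) {
  cat(sprintf("affine_registration (%s): cost %.4g, %s\n", x$dof, x$cost,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$transform, 4))
  invisible(x)
}
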