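## VolumeImage: the universal 3D scalar image carrier. Grids are axis-aligned
## (voxel -> world is origin + (index - 1) * voxel_size); rotations live in
## registration transforms, not in image headers.

#' Construct a 3D volume image
#'
#' @param values Numeric 3D array of voxel intensities; all values must be
#'   finite.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param origin World coordinate (mm) of the centre of voxel `[1,1,1]`.
#' @return An object of class `volume_image` with elements `values`,
#'   `voxel_size` and `origin`.
#' @examples
#' img <- volume_image(array(rnorm(8^3), c(8, 8, 8)), voxel_size = 2)
#' voxel_volume(img)  # 8 mm^3
#' @export
volume_image <- function(values, voxel_size = 1, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3 || any(dim(values) < 1))
    stop("'values' must be a non-empty 3D array")
  if (!all(is.finite(values))) stop("all voxel values must be finite")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = rep(as.numeric(origin), length.out = 3)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_image: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

#' Voxel volume in cubic millimetres
#' @param img A `volume_image`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(img) prod(img$voxel_size)

#' 4x4 voxel-to-world affine of a volume
#' @param img A `volume_image`.
#' @return The 4x4 matrix mapping 1-based voxel indices to mm coordinates.
#' @export
voxel_affine <- function(img) {
  A <- diag(4)
  diag(A)[1:3] <- img$voxel_size
  A[1:3, 4] <- img$origin - img$voxel_size
  A
}

## World coordinates (n x 3 matrix) of every voxel centre.
voxel_coords <- function(img) {
  d <- dim(img$values)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  cbind(img$origin[1] + (g$i - 1) * img$voxel_size[1],
        img$origin[2] + (g$j - 1) * img$voxel_size[2],
        img$origin[3] + (g$k - 1) * img$voxel_size[3])
}

#' Write a volume to a NIfTI-1 file
#' @param img A `volume_image`.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  nii <- RNifti::asNifti(img$values, pixdim = img$voxel_size)
  A <- voxel_affine(img)
  A[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep(1, 3)  # 0-based NIfTI origin
  RNifti::sform(nii) <- structure(A, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a NIfTI-1 file into a volume image
#' @param path File path.
#' @return A `volume_image`. Only axis-aligned geometries are represented;
#'   voxel sizes are taken from the header.
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  A <- RNifti::xform(nii)
  vs <- sqrt(colSums(A[1:3, 1:3]^2))
  origin <- as.numeric(A[1:3, 4])
  volume_image(array(as.numeric(nii), dim(nii)[1:3]), voxel_size = vs,
               origin = origin)
}

#' Gaussian-smooth a volume
#'
#' @param img A `volume_image`.
#' @param fwhm Smoothing kernel full width at half maximum, in mm.
#' @return Smoothed `volume_image` on the same grid.
#' @export
smooth_volume <- function(img, fwhm) {
  sig <- fwhm_to_sigma(fwhm) / img$voxel_size
  volume_image(smooth_gauss3d(img$values, sig), img$voxel_size, img$origin)
}

#' Resample a volume onto a new grid
#'
#' Trilinear interpolation in world space. Either a target `volume_image`
#' (whose grid is reused) or a new isotropic voxel size may be given.
#'
#' @param img A `volume_image`.
#' @param target Optional `volume_image` defining the output grid.
#' @param voxel_size Output isotropic voxel size in mm (used when `target`
#'   is `NULL`); the field of view is preserved.
#' @param fill Value for coordinates outside the input grid.
#' @return The resampled `volume_image`.
#' @export
resample_volume <- function(img, target = NULL, voxel_size = NULL, fill = 0) {
  if (is.null(target)) {
    if (is.null(voxel_size)) stop("give either 'target' or 'voxel_size'")
    vs <- rep(voxel_size, length.out = 3)
    fov <- dim(img$values) * img$voxel_size
    nd <- pmax(1L, as.integer(ceiling(fov / vs)))
    target <- list(values = array(0, nd), voxel_size = vs,
                   origin = img$origin + (vs - img$voxel_size) / 2)
  }
  d <- dim(target$values)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  wx <- target$origin[1] + (g$i - 1) * target$voxel_size[1]
  wy <- target$origin[2] + (g$j - 1) * target$voxel_size[2]
  wz <- target$origin[3] + (g$k - 1) * target$voxel_size[3]
  xi <- (wx - img$origin[1]) / img$voxel_size[1] + 1
  yi <- (wy - img$origin[2]) / img$voxel_size[2] + 1
  zi <- (wz - img$origin[3]) / img$voxel_size[3] + 1
  vals <- interp_trilinear(img$values, xi, yi, zi, fill = fill)
  volume_image(array(vals, d), target$voxel_size, target$origin)
}
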