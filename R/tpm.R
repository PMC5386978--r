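## Tissue probability maps: per-voxel class probabilities for GM, WM, CSF and
## background on a shared grid. Stored as a 4D array [x, y, z, class].

TISSUE_CLASSES <- c("gm", "wm", "csf", "bg")

#' Construct a tissue probability map
#'
#' @param prob 4D array `[x, y, z, class]` with classes ordered GM, WM, CSF,
#'   background. Probabilities are renormalized to sum to one per voxel.
#' @param voxel_size Voxel edge lengths in mm.
#' @param origin World coordinate (mm) of voxel `[1,1,1]`.
#' @return An object of class `tissue_prob_map`.
#' @export
tissue_prob_map <- function(prob, voxel_size = 1, origin = c(0, 0, 0)) {
  prob <- as.array(prob)
  if (length(dim(prob)) != 4 || dim(prob)[4] != 4)
    stop("'prob' must be a 4D array with 4 classes (gm, wm, csf, bg)")
  if (any(prob < -1e-9) || !all(is.finite(prob)))
    stop("probabilities must be finite and non-negative")
  prob[prob < 0] <- 0
  obj <- structure(list(prob = prob,
                        voxel_size = rep(as.numeric(voxel_size),
                                         length.out = 3),
                        origin = rep(as.numeric(origin), length.out = 3),
                        classes = TISSUE_CLASSES),
                   class = "tissue_prob_map")
  normalize_tpm(obj)
}

#' Renormalize a TPM so class probabilities sum to one per voxel
#' @param tpm A `tissue_prob_map`.
#' @return The renormalized `tissue_prob_map`. Voxels with zero total mass
#'   become pure background.
#' @export
normalize_tpm <- function(tpm) {
  d <- dim(tpm$prob)
  tot <- array(0, d[1:3])
  for (c in 1:4) tot <- tot + tpm$prob[, , , c]
  zero <- tot <= 1e-12
  tot[zero] <- 1
  for (c in 1:4) tpm$prob[, , , c] <- tpm$prob[, , , c] / tot
  if (any(zero)) {
    bg <- tpm$prob[, , , 4]
    bg[zero] <- 1
    for (c in 1:3) {
      p <- tpm$prob[, , , c]; p[zero] <- 0; tpm$prob[, , , c] <- p
    }
    tpm$prob[, , , 4] <- bg
  }
  tpm
}

#' @export
print.tissue_prob_map <- function(x, ...) {
  d <- dim(x$prob)
  vol <- prod(x$voxel_size) / 1000
  cat(sprintf("tissue_prob_map: %d x %d x %d voxels, %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size[1]))
  for (c in 1:4)
    cat(sprintf("  %-3s prior mass %.1f ml\n", x$classes[c],
                sum(x$prob[, , , c]) * vol))
  invisible(x)
}

## Extract one class as a volume_image.
tpm_class_volume <- function(tpm, class) {
  c <- match(class, tpm$classes)
  volume_image(tpm$prob[, , , c], tpm$voxel_size, tpm$origin)
}

#' Prior tissue mass of a TPM in millilitres
#' @param tpm A `tissue_prob_map`.
#' @param classes Classes to sum over (default GM+WM+CSF, i.e. brain).
#' @return Total prior mass times voxel volume, in ml.
#' @export
tpm_volume_ml <- function(tpm, classes = c("gm", "wm", "csf")) {
  idx <- match(classes, tpm$classes)
  sum(tpm$prob[, , , idx]) * prod(tpm$voxel_size) / 1000
}

#' Brain mask of a TPM
#' @param tpm A `tissue_prob_map`.
#' @param threshold Non-background prior above which a voxel is brain.
#' @return A binary `volume_image`.
#' @export
tpm_brain_mask <- function(tpm, threshold = 0.5) {
  nb <- tpm$prob[, , , 1] + tpm$prob[, , , 2] + tpm$prob[, , , 3]
  volume_image(array(as.numeric(nb > threshold), dim(nb)),
               tpm$voxel_size, tpm$origin)
}

#' Smooth a TPM and renormalize
#' @param tpm A `tissue_prob_map`.
#' @param fwhm Gaussian kernel FWHM in mm.
#' @return Smoothed, renormalized `tissue_prob_map`; the background class is
#'   recomputed as one minus the tissue classes.
#' @export
smooth_tpm <- function(tpm, fwhm) {
  sig <- fwhm_to_sigma(fwhm) / tpm$voxel_size
  for (c in 1:3)
    tpm$prob[, , , c] <- smooth_gauss3d(tpm$prob[, , , c], sig)
  ts <- tpm$prob[, , , 1] + tpm$prob[, , , 2] + tpm$prob[, , , 3]
  over <- ts > 1
  if (any(over)) {
    for (c in 1:3) {
      p <- tpm$prob[, , , c]
      p[over] <- p[over] / ts[over]
      tpm$prob[, , , c] <- p
    }
    ts[over] <- 1
  }
  tpm$prob[, , , 4] <- 1 - ts
  tpm
}

#' Write a TPM as one NIfTI file per class
#' @param tpm A `tissue_prob_map`.
#' @param prefix Path prefix; files `<prefix>_<class>.nii.gz` are written.
#' @return The four file paths, invisibly.
#' @export
write_tpm <- function(tpm, prefix) {
  paths <- character(4)
  for (c in 1:4) {
    paths[c] <- paste0(prefix, "_", tpm$classes[c], ".nii.gz")
    write_volume(tpm_class_volume(tpm, tpm$classes[c]), paths[c])
  }
  invisible(paths)
}

#' Read a TPM written by [write_tpm()]
#' @param prefix Path prefix used at write time.
#' @return A `tissue_prob_map`.
#' @export
read_tpm <- function(prefix) {
  vols <- lapply(TISSUE_CLASSES, function(cl)
    read_volume(paste0(prefix, "_", cl, ".nii.gz")))
  d <- dim(vols[[1]]$values)
  prob <- array(0, c(d, 4))
  for (c in 1:4) prob[, , , c] <- vols[[c]]$values
  tissue_prob_map(prob, vols[[1]]$voxel_size, vols[[1]]$origin)
}
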