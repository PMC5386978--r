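## Iterative species template construction: a reference TPM is affinely
## rescaled to the expected brain size, then refined by segment -> register ->
## voxel-wise median -> smooth cycles until the template stops changing.

#' Construct a template set
#'
#' @param tpm A `tissue_prob_map`.
#' @param t1_average A `volume_image` intensity average in template space.
#' @param brain_mask A binary `volume_image` (non-background prior > 0.5).
#' @param history Numeric vector of per-iteration change metrics.
#' @return A list of class `template_set`.
#' @export
template_set <- function(tpm, t1_average, brain_mask, history = numeric(0)) {
  stopifnot(inherits(tpm, "tissue_prob_map"),
            inherits(t1_average, "volume_image"),
            all(is.finite(history)), all(history >= 0))
  structure(list(tpm = tpm, t1_average = t1_average, brain_mask = brain_mask,
                 history = history),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  d <- dim(x$tpm$prob)
  cat(sprintf("template_set: %d x %d x %d voxels at %.3g mm, brain %.1f ml\n",
              d[1], d[2], d[3], x$tpm$voxel_size[1], tpm_volume_ml(x$tpm)))
  if (length(x$history))
    cat("  iteration change:", paste(signif(x$history, 3), collapse = " "),
        "\n")
  invisible(x)
}

## Synthesize a T1-like average from a TPM using canonical class means.
tpm_to_t1 <- function(tpm, class_means = c(gm = 0.60, wm = 0.95, csf = 0.25,
                                           bg = 0)) {
  d <- dim(tpm$prob)[1:3]
  v <- array(0, d)
  for (c in 1:4) v <- v + class_means[c] * tpm$prob[, , , c]
  volume_image(v, tpm$voxel_size, tpm$origin)
}

#' Initialize a species template by rescaling a reference TPM
#'
#' Scales the reference isotropically (about its prior centre of mass) so
#' that its non-background prior mass matches the target brain volume within
#' 1%, resamples it onto an isotropic grid of the requested voxel size, and
#' renormalizes. The intensity average is synthesized from the rescaled
#' priors with the canonical T1-like class means.
#'
#' @param reference_tpm The reference `tissue_prob_map` (e.g. a human-scale
#'   atlas).
#' @param target_brain_volume Expected brain volume of the target species,
#'   in ml (~200 ml for the adult baboon).
#' @param voxel_size Output isotropic voxel size in mm.
#' @param margin_mm Padding around the scaled brain, in mm.
#' @return A `template_set`.
#' @export
initialize_template <- function(reference_tpm, target_brain_volume,
                                voxel_size = 0.75, margin_mm = 8) {
  if (target_brain_volume <= 0) stop("target volume must be positive")
  v0 <- tpm_volume_ml(reference_tpm)
  if (v0 <= 0) stop("reference TPM has no brain prior mass")
  s <- (target_brain_volume / v0)^(1 / 3)

  ## centre of prior brain mass of the reference, in world mm
  d0 <- dim(reference_tpm$prob)[1:3]
  nb <- reference_tpm$prob[, , , 1] + reference_tpm$prob[, , , 2] +
    reference_tpm$prob[, , , 3]
  g <- expand.grid(i = seq_len(d0[1]), j = seq_len(d0[2]),
                   k = seq_len(d0[3]))
  wgt <- as.vector(nb) / sum(nb)
  ctr <- c(sum((reference_tpm$origin[1] +
                  (g$i - 1) * reference_tpm$voxel_size[1]) * wgt),
           sum((reference_tpm$origin[2] +
                  (g$j - 1) * reference_tpm$voxel_size[2]) * wgt),
           sum((reference_tpm$origin[3] +
                  (g$k - 1) * reference_tpm$voxel_size[3]) * wgt))

  ## brain extent in the reference, scaled, plus margin -> output FOV
  ext0 <- d0 * reference_tpm$voxel_size
  make_grid <- function(s) {
    fov <- ext0 * s + 2 * margin_mm
    nd <- pmax(8L, as.integer(ceiling(fov / voxel_size)))
    org <- -(nd - 1) / 2 * voxel_size
    list(nd = nd, org = org)
  }
  resample_scaled <- function(s) {
    gr <- make_grid(s)
    prob <- array(0, c(gr$nd, 4))
    tgt <- list(values = array(0, gr$nd),
                voxel_size = rep(voxel_size, 3), origin = gr$org)
    for (c in 1:4) {
      src_img <- tpm_class_volume(reference_tpm, TISSUE_CLASSES[c])
      ## world map: output w -> reference ctr + w / s
      dd <- gr$nd
      gg <- expand.grid(i = seq_len(dd[1]), j = seq_len(dd[2]),
                        k = seq_len(dd[3]))
      wx <- gr$org[1] + (gg$i - 1) * voxel_size
      wy <- gr$org[2] + (gg$j - 1) * voxel_size
      wz <- gr$org[3] + (gg$k - 1) * voxel_size
      xi <- (ctr[1] + wx / s - src_img$origin[1]) / src_img$voxel_size[1] + 1
      yi <- (ctr[2] + wy / s - src_img$origin[2]) / src_img$voxel_size[2] + 1
      zi <- (ctr[3] + wz / s - src_img$origin[3]) / src_img$voxel_size[3] + 1
      fill <- if (c == 4) 1 else 0
      prob[, , , c] <- array(interp_trilinear(src_img$values, xi, yi, zi,
                                              fill = fill), dd)
    }
    tissue_prob_map(prob, voxel_size = rep(voxel_size, 3), origin = gr$org)
  }

  tpm <- resample_scaled(s)
  ## interpolation/truncation can shift the mass slightly; correct the scale
  for (k in 1:4) {
    v <- tpm_volume_ml(tpm)
    if (abs(v - target_brain_volume) <= 0.01 * target_brain_volume) break
    s <- s * (target_brain_volume / v)^(1 / 3)
    tpm <- resample_scaled(s)
  }
  v <- tpm_volume_ml(tpm)
  if (abs(v - target_brain_volume) > 0.01 * target_brain_volume)
    stop("target volume incompatible with the reference grid")

  template_set(tpm, tpm_to_t1(tpm), tpm_brain_mask(tpm),
               history = numeric(0))
}

## Row medians of a numeric matrix (sort-free of extra deps).
row_medians <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nc == 1) return(m[, 1])
  o <- order(row(m), m)
  sorted <- matrix(m[o], nr, nc, byrow = TRUE)
  if (nc %% 2 == 1) sorted[, (nc + 1) / 2]
  else (sorted[, nc / 2] + sorted[, nc / 2 + 1]) / 2
}

#' Refine a template by iterative segmentation and median averaging
#'
#' Each iteration segments every subject with the current TPM, registers the
#' results into template space, takes the voxel-wise median across subjects
#' per tissue class, smooths with a Gaussian kernel (default FWHM 2 mm), and
#' renormalizes; the intensity average is the voxel-wise median of the
#' registered images. The change metric is the mean absolute voxel-wise TPM
#' difference (over the brain mask) between consecutive iterations;
#' iteration stops when it falls below `stop_tol`.
#'
#' @param images List of subject `volume_image`s (artifact-corrected).
#' @param current The starting `template_set`.
#' @param fwhm Smoothing kernel FWHM in mm.
#' @param max_iter Maximum number of iterations.
#' @param stop_tol Change threshold that stops the iteration.
#' @param register Affinely register each subject to the template each
#'   iteration (set `FALSE` for cohorts already in template space).
#' @param dof Registration degrees of freedom.
#' @return The refined `template_set`, with the per-iteration change metric
#'   appended to `history`.
#' @export
iterate_template <- function(images, current, fwhm = 2, max_iter = 6,
                             stop_tol = 1e-3, register = TRUE,
                             dof = "rigid") {
  if (length(images) < 1) stop("need at least one subject")
  tmpl <- current
  d <- dim(tmpl$tpm$prob)[1:3]
  nv <- prod(d)
  for (it in seq_len(max_iter)) {
    posts <- list(); regs <- list()
    for (i in seq_along(images)) {
      res <- tryCatch({
        img <- images[[i]]
        if (register) {
          rg <- affine_register(img, tmpl$t1_average, dof = dof)
          img <- rg$resampled
        }
        seg <- segment_tpm(img, tmpl$tpm)
        list(post = seg$posterior, img = img)
      }, error = function(e) {
        warning(sprintf("subject %d excluded from template iteration: %s",
                        i, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        posts[[length(posts) + 1]] <- res$post
        regs[[length(regs) + 1]] <- res$img
      }
    }
    if (!length(posts)) stop("no subject could be segmented")

    prob <- array(0, c(d, 4))
    for (c in 1:4) {
      m <- vapply(posts, function(p) as.vector(p$prob[, , , c]),
                  numeric(nv))
      prob[, , , c] <- array(row_medians(as.matrix(m)), d)
    }
    new_tpm <- tissue_prob_map(prob, tmpl$tpm$voxel_size, tmpl$tpm$origin)
    new_tpm <- smooth_tpm(new_tpm, fwhm)

    t1m <- vapply(regs, function(im) as.vector(im$values), numeric(nv))
    new_t1 <- volume_image(array(row_medians(as.matrix(t1m)), d),
                           tmpl$tpm$voxel_size, tmpl$tpm$origin)

    mask <- tmpl$brain_mask$values > 0.5
    if (!any(mask)) mask <- array(TRUE, d)
    change <- mean(abs(new_tpm$prob[, , , 1:3][rep(mask, 3)] -
                         tmpl$tpm$prob[, , , 1:3][rep(mask, 3)]))

    tmpl <- template_set(new_tpm, new_t1, tpm_brain_mask(new_tpm),
                         history = c(tmpl$history, change))
    if (change < stop_tol) break
  }
  tmpl
}

#' Write a template set to disk
#' @param template A `template_set`.
#' @param dir Output directory; four TPM class NIfTIs, the T1 average, the
#'   brain mask and a JSON iteration history are written.
#' @return `dir`, invisibly.
#' @export
write_template <- function(template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tpm(template$tpm, file.path(dir, "tpm"))
  write_volume(template$t1_average, file.path(dir, "t1_average.nii.gz"))
  write_volume(template$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  jsonlite::write_json(list(history = template$history),
                       file.path(dir, "history.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
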