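## Tissue segmentation: expectation-maximization for a per-class Gaussian
## intensity mixture with the TPM as a spatially varying prior. The posterior
## at each voxel is proportional to likelihood x prior, renormalized.

#' Segment a volume against a tissue probability map
#'
#' Fits one Gaussian intensity distribution per tissue class (GM, WM, CSF,
#' background) by EM, using the registered TPM as the spatial prior.
#' Convergence is declared when the relative change in log-likelihood falls
#' below `tol`. Absolute class volume is the posterior mass times voxel
#' volume (ml); TIV = GM + WM + CSF.
#'
#' @param img A `volume_image`.
#' @param tpm A `tissue_prob_map` on the same grid as `img`.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @return An object of class `segmentation_result`: `posterior` (a
#'   `tissue_prob_map`), `mu`/`sigma` (class intensity parameters),
#'   `volumes_ml` (named GM/WM/CSF), `tiv_ml`, `fractions` (per TIV, summing
#'   to one), `loglik` (trace) and `converged`.
#' @export
segment_tpm <- function(img, tpm, max_iter = 50, tol = 1e-5) {
  if (!all(dim(img$values) == dim(tpm$prob)[1:3]))
    stop("TPM must be registered to the image geometry")
  y <- as.vector(img$values)
  nv <- length(y)
  prior <- matrix(tpm$prob, nv, 4)
  prior_mass <- colSums(prior)
  active <- prior_mass > nv * 1e-6
  if (!all(active))
    warning(sprintf("dropping empty class(es): %s",
                    paste(TISSUE_CLASSES[!active], collapse = ", ")))
  prior[, !active] <- 0
  tot <- rowSums(prior)
  tot[tot <= 0] <- 1
  prior <- prior / tot

  ## init from confident voxels (class is the prior majority) so that soft
  ## prior boundaries do not drag the initial moments across classes
  maxp <- do.call(pmax, lapply(1:4, function(c) prior[, c]))
  mu <- sig <- rep(NA_real_, 4)
  for (c in which(active)) {
    w <- prior[, c] * (prior[, c] >= maxp - 1e-12)
    if (sum(w) < 10) w <- prior[, c]
    mu[c] <- sum(w * y) / sum(w)
    sig[c] <- sqrt(sum(w * (y - mu[c])^2) / sum(w))
  }
  ## symmetric priors (e.g. flat) give coincident init moments from which EM
  ## cannot separate the classes; spread such groups over quantiles
  act <- which(active)
  if (length(act) > 1) {
    for (i in seq_along(act)) {
      grp <- act[abs(mu[act] - mu[act[i]]) < 1e-8]
      if (length(grp) > 1 && act[i] == grp[1]) {
        qs <- stats::quantile(y[prior[, grp[1]] > 0],
                              probs = (seq_along(grp) - 0.5) / length(grp),
                              names = FALSE)
        mu[grp] <- qs
      }
    }
  }

  ## floor class SDs at 2% of the intensity range: denoised flat regions
  ## otherwise collapse to near-zero variance, and their outlier tail is
  ## then absorbed by a neighbouring class whose variance inflates
  sig_floor <- max(0.02 * (max(y) - min(y)), 1e-8)
  sig <- pmax(sig, sig_floor)

  post <- prior
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## E-step
    dens <- matrix(0, nv, 4)
    for (c in which(active))
      dens[, c] <- prior[, c] * stats::dnorm(y, mu[c], sig[c])
    tot <- rowSums(dens)
    ll <- sum(log(pmax(tot, 1e-300)))
    if (!is.finite(ll)) stop("non-finite likelihood in EM segmentation")
    tot[tot <= 0] <- 1
    post <- dens / tot
    ## flat fallback where no class has support
    none <- rowSums(post) < 1e-12
    if (any(none)) post[none, ] <- prior[none, , drop = FALSE]
    ## M-step
    for (c in which(active)) {
      w <- post[, c]
      sw <- sum(w)
      if (sw > 1e-8) {
        mu[c] <- sum(w * y) / sw
        sig[c] <- max(sqrt(sum(w * (y - mu[c])^2) / sw), sig_floor)
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <=
        tol * abs(ll_trace[it - 1])) {
      converged <- TRUE
      break
    }
  }

  voxml <- voxel_volume(img) / 1000
  vols <- colSums(post)[1:3] * voxml
  names(vols) <- c("gm", "wm", "csf")
  tiv <- sum(vols)
  fr <- if (tiv > 0) vols / tiv else c(gm = 0, wm = 0, csf = 0)
  post_tpm <- tissue_prob_map(array(post, c(dim(img$values), 4)),
                              img$voxel_size, img$origin)
  structure(list(posterior = post_tpm, mu = mu, sigma = sig,
                 volumes_ml = vols, tiv_ml = tiv, fractions = fr,
                 loglik = ll_trace, converged = converged,
                 active = active),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result\n")
  cat(sprintf("  GM %.1f ml  WM %.1f ml  CSF %.1f ml  TIV %.1f ml\n",
              x$volumes_ml["gm"], x$volumes_ml["wm"], x$volumes_ml["csf"],
              x$tiv_ml))
  cat(sprintf("  fractions: GM %.3f  WM %.3f  CSF %.3f\n",
              x$fractions["gm"], x$fractions["wm"], x$fractions["csf"]))
  cat(sprintf("  EM %sconverged in %d iterations\n",
              if (x$converged) "" else "NOT ", length(x$loglik)))
  invisible(x)
}

## Hard labels (1 = gm, 2 = wm, 3 = csf, 4 = bg) from a probability map.
hard_labels <- function(tpm) {
  d <- dim(tpm$prob)
  m <- matrix(tpm$prob, prod(d[1:3]), 4)
  array(max.col(m, ties.method = "first"), d[1:3])
}

#' Dice overlap coefficient per tissue class
#'
#' @param a,b `tissue_prob_map`s or integer label arrays on the same grid.
#' @param classes Class indices to evaluate (default GM, WM, CSF).
#' @return Named numeric vector of Dice coefficients.
#' @export
dice_coefficient <- function(a, b, classes = 1:3) {
  la <- if (inherits(a, "tissue_prob_map")) hard_labels(a) else a
  lb <- if (inherits(b, "tissue_prob_map")) hard_labels(b) else b
  out <- vapply(classes, function(c) {
    ia <- la == c; ib <- lb == c
    s <- sum(ia) + sum(ib)
    if (s == 0) return(NA_real_)
    2 * sum(ia & ib) / s
  }, numeric(1))
  names(out) <- TISSUE_CLASSES[classes]
  out
}

#' Preprocess and segment one subject volume
#'
#' Runs the fixed preprocessing order: slice-gain correction, adaptive
#' non-local-means denoising, affine registration to the template, and EM
#' segmentation against the template TPM.
#'
#' @param img A `volume_image` (subject T1-like scan).
#' @param template A `template_set` (see [initialize_template()]).
#' @param slice_axis Axis of the slice-gain correction.
#' @param denoise Apply the non-local-means filter.
#' @param register Estimate an affine transform to the template (set to
#'   `FALSE` when the scan is already in template space).
#' @param dof Registration degrees of freedom.
#' @param ... Passed on to [segment_tpm()].
#' @return A list of class `preprocessed_subject`: `segmentation`, `image`
#'   (the corrected, registered image in template space), `registration`
#'   (or `NULL`), `gains`.
#' @export
preprocess_subject <- function(img, template, slice_axis = 3, denoise = TRUE,
                               register = TRUE, dof = "rigid", ...) {
  sc <- correct_slice_inhomogeneity(img, axis = slice_axis)
  clean <- sc$image
  if (denoise) clean <- denoise_nlm(clean)
  reg <- NULL
  if (register) {
    reg <- affine_register(clean, template$t1_average, dof = dof)
    if (!reg$converged)
      warning("affine registration did not converge; result is flagged")
    clean <- reg$resampled
  }
  seg <- segment_tpm(clean, template$tpm, ...)
  structure(list(segmentation = seg, image = clean, registration = reg,
                 gains = sc$gains),
            class = "preprocessed_subject")
}
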