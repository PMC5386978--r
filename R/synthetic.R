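## Synthetic cohort generator: seeded 3D brain phantoms (CSF shell, GM
## ribbon, WM core) whose tissue composition follows programmed sex-specific
## aging trajectories, plus the subject metadata table. Every downstream
## stage of the pipeline is testable against this generator's ground truth.

#' Parameters of the synthetic aging model
#'
#' Defaults are calibrated so that a lifespan cohort (ages 4-22 y, 15 female
#' and 14 male) reproduces the reference morphometry of the adult baboon:
#' fractional GM ~ 0.47 (females) / 0.46 (males) declining with age (linearly
#' in females, quadratically in males), fractional WM increasing, fractional
#' CSF increasing in females, and TIV ~ 187 ml (females) / 210 ml (males).
#'
#' @param gm_coef,csf_coef Per-sex polynomial coefficients (intercept, linear,
#'   quadratic) of the fractional GM and CSF trajectories against age in
#'   years. Fractional WM is the complement `1 - gm - csf`.
#' @param tiv_mean,tiv_sd Per-sex mean and SD of total intracranial volume
#'   (ml).
#' @param mnr_gm_offset Fractional-GM decrement applied to females of the
#'   maternal-nutrient-restriction (MNR) group, rebalanced into CSF. The
#'   default equals 2.7 years of the female GM trajectory slope
#'   (2.7 x 0.0055), i.e. an atrophy offset equivalent to +2.7 brain-years.
#' @param frac_noise_sd SD of subject-level fractional-GM noise (a GM-CSF
#'   transfer), giving a feature-space age signal-to-noise ratio of about 2.
#' @param age_range Supported chronological age range in years.
#' @param noise_sd Additive Gaussian intensity noise SD (intensity units;
#'   class means span ~1).
#' @param bias_amp Amplitude of the smooth multiplicative bias field.
#' @param slice_gain_sd SD of log per-slice gain factors (third grid axis).
#' @param grid_dim Voxels per axis of the phantom grid.
#' @param voxel_size Isotropic synthetic voxel size in mm. The default
#'   1.75 mm puts a ~200 ml brain comfortably inside the default 48^3 grid.
#' @param deform_amp,deform_modes Relative amplitude and number of
#'   low-frequency cosine modes of the per-subject shape deformation.
#' @param class_means Mean intensity per tissue class; the default T1-like
#'   ordering is CSF < GM < WM.
#' @return A list of class `aging_params`.
#' @export
aging_params <- function(gm_coef = list(female = c(0.52200, -0.00550, 0),
                                        male   = c(0.48532, -0.00186,
                                                   -0.00008)),
                         csf_coef = list(female = c(0.17700, 0.00350, 0),
                                         male   = c(0.21256, 0.00022,
                                                    0.00006)),
                         tiv_mean = c(female = 186.7, male = 210.4),
                         tiv_sd = c(female = 14.4, male = 14.0),
                         mnr_gm_offset = 2.7 * 0.0055,
                         frac_noise_sd = 0.012,
                         age_range = c(4, 22),
                         noise_sd = 0.02,
                         bias_amp = 0.04,
                         slice_gain_sd = 0.05,
                         grid_dim = 48,
                         voxel_size = 1.75,
                         deform_amp = 0.015,
                         deform_modes = 6,
                         class_means = c(gm = 0.60, wm = 0.95, csf = 0.25,
                                         bg = 0)) {
  stopifnot(frac_noise_sd >= 0, noise_sd >= 0, bias_amp >= 0,
            slice_gain_sd >= 0, all(tiv_sd >= 0), grid_dim >= 16,
            voxel_size > 0, age_range[1] > 0, age_range[2] > age_range[1])
  p <- list(gm_coef = gm_coef, csf_coef = csf_coef, tiv_mean = tiv_mean,
            tiv_sd = tiv_sd, mnr_gm_offset = mnr_gm_offset,
            frac_noise_sd = frac_noise_sd, age_range = age_range,
            noise_sd = noise_sd, bias_amp = bias_amp,
            slice_gain_sd = slice_gain_sd, grid_dim = grid_dim,
            voxel_size = voxel_size, deform_amp = deform_amp,
            deform_modes = deform_modes, class_means = class_means)
  ## trajectories must stay inside (0,1) over the supported range
  for (sex in c("female", "male")) {
    a <- seq(age_range[1], age_range[2], length.out = 50)
    fr <- trajectory_fractions(structure(p, class = "aging_params"), sex, a)
    if (any(fr$gm <= 0 | fr$gm >= 1 | fr$wm <= 0 | fr$csf <= 0))
      stop("trajectory fractions leave (0,1) over the supported age range")
  }
  structure(p, class = "aging_params")
}

polyval3 <- function(coef, x) coef[1] + coef[2] * x + coef[3] * x^2

#' Tissue fractions on the programmed aging trajectory
#'
#' Evaluates the configured sex-specific fractional GM/WM/CSF trajectories at
#' given ages. MNR females receive the programmed fractional-GM decrement,
#' rebalanced into CSF; TIV is unaffected.
#'
#' @param params An [aging_params()] object.
#' @param sex `"female"` or `"male"`.
#' @param age Chronological age(s) in years, within `params$age_range`.
#' @param group `"CTR"` or `"MNR"`.
#' @return A list with numeric vectors `gm`, `wm`, `csf` summing to one.
#' @examples
#' p <- aging_params()
#' trajectory_fractions(p, "female", 9.43)$gm  # ~0.47, the cohort mean
#' @export
trajectory_fractions <- function(params, sex = c("female", "male"), age,
                                 group = c("CTR", "MNR")) {
  sex <- match.arg(sex)
  group <- match.arg(group)
  if (any(age < params$age_range[1] - 1e-9 |
          age > params$age_range[2] + 1e-9))
    stop(sprintf("age outside supported range [%g, %g]",
                 params$age_range[1], params$age_range[2]))
  eff_age <- age
  if (group == "MNR" && sex == "female" && params$mnr_gm_offset != 0) {
    ## the MNR insult is accelerated aging along the female trajectory: the
    ## age advance is chosen so fractional GM drops by exactly mnr_gm_offset
    ## (for the default linear female GM trajectory this is
    ## mnr_gm_offset / |slope| years at any age); CSF takes up most of the
    ## rebalanced mass, WM the small trajectory-consistent remainder
    slope <- params$gm_coef[[sex]][2] + 2 * params$gm_coef[[sex]][3] * age
    if (any(slope >= 0))
      stop("MNR aging offset requires a declining GM trajectory")
    eff_age <- age + params$mnr_gm_offset / abs(slope)
  }
  gm <- polyval3(params$gm_coef[[sex]], eff_age)
  csf <- polyval3(params$csf_coef[[sex]], eff_age)
  wm <- 1 - gm - csf
  if (any(gm <= 0 | wm <= 0 | csf <= 0))
    stop("degenerate tissue fractions at the requested age")
  list(gm = gm, wm = wm, csf = csf)
}

#' Specification of one phantom to render
#'
#' @param id Subject identifier.
#' @param gm,wm,csf Target fractional volumes (per TIV); must be positive and
#'   sum to one within 1e-6.
#' @param tiv Total intracranial volume in ml.
#' @param seed Integer seed controlling all randomness of the rendering.
#' @param params An [aging_params()] object supplying grid and noise
#'   settings.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(id, gm, wm, csf, tiv, seed, params = aging_params()) {
  if (abs(gm + wm + csf - 1) > 1e-6)
    stop("tissue fractions must sum to 1 within 1e-6")
  if (any(c(gm, wm, csf) <= 0)) stop("tissue fractions must be positive")
  structure(list(id = id, gm = gm, wm = wm, csf = csf, tiv = tiv,
                 seed = as.integer(seed), params = params),
            class = "phantom_spec")
}

## Low-frequency random field on given world coordinates: sum of `modes`
## cosine waves with <= 1.5 cycles per field of view, normalized to unit SD.
cosine_field <- function(coords, fov, modes) {
  f <- matrix(0, nrow(coords), 1)
  val <- numeric(nrow(coords))
  for (k in seq_len(modes)) {
    freq <- runif(3, -1.5, 1.5) / fov     # cycles per mm
    phase <- runif(1, 0, 2 * pi)
    val <- val + cos(2 * pi * (coords %*% freq) + phase)
  }
  s <- stats::sd(val)
  if (s < 1e-12) return(val * 0)
  val / s
}

#' Render a brain phantom and its ground-truth tissue map
#'
#' Builds a deformed concentric compartment geometry (WM core, GM ribbon,
#' CSF shell) whose voxel-count fractions match the specification, assigns
#' T1-like class intensities (CSF < GM < WM), and applies a smooth
#' multiplicative bias field, per-slice gain factors, and additive Gaussian
#' noise. Identical seeds give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param render_image If `FALSE`, only the ground-truth tissue map is built
#'   (fast path for feature-level experiments).
#' @return A list with `image` (a `volume_image`, or `NULL`), `truth` (the
#'   ground-truth `tissue_prob_map`), `labels` (integer array, 1 = GM,
#'   2 = WM, 3 = CSF, 4 = background), `gains` (true per-slice gains) and
#'   `spec`.
#' @export
render_phantom <- function(spec, render_image = TRUE) {
  p <- spec$params
  n <- p$grid_dim
  if (n < 16) stop("grid must be at least 16^3 voxels")
  vs <- p$voxel_size
  voxvol <- vs^3
  tiv_vox <- round(spec$tiv * 1000 / voxvol)
  d <- c(n, n, n)
  if (tiv_vox > 0.7 * prod(d))
    stop("geometry error: requested TIV does not fit the grid")
  ax <- (seq_len(n) - (n + 1) / 2) * vs
  cx <- array(rep(ax, times = n * n), d)
  cy <- array(rep(rep(ax, each = n), times = n), d)
  cz <- array(rep(ax, each = n * n), d)
  r <- sqrt(cx^2 + cy^2 + cz^2)

  with_seed(spec$seed, {
    coords <- cbind(as.vector(cx), as.vector(cy), as.vector(cz))
    fov <- n * vs
    if (p$deform_amp > 0 && p$deform_modes > 0) {
      def <- cosine_field(coords, fov, p$deform_modes)
      rho <- as.vector(r) * (1 + p$deform_amp * def)
    } else rho <- as.vector(r)

    ord <- order(rho)
    brain_idx <- ord[seq_len(tiv_vox)]
    ## geometry check: brain must not touch the grid boundary
    gi <- arrayInd(brain_idx, d)
    if (any(gi == 1L | gi == n))
      stop("geometry error: brain region touches the grid boundary")

    n_wm <- round(spec$wm * tiv_vox)
    n_gm <- round(spec$gm * tiv_vox)
    labels <- array(4L, d)
    labels[ord[seq_len(n_wm)]] <- 2L
    labels[ord[(n_wm + 1):(n_wm + n_gm)]] <- 1L
    labels[ord[(n_wm + n_gm + 1):tiv_vox]] <- 3L

    prob <- array(0, c(d, 4))
    for (c in 1:4) prob[, , , c] <- as.numeric(labels == c)
    org <- rep(ax[1], 3)
    truth <- tissue_prob_map(prob, voxel_size = vs, origin = org)

    image <- NULL
    gains <- rep(1, n)
    if (render_image) {
      means <- p$class_means[c("gm", "wm", "csf", "bg")]
      img <- array(means[labels], d)
      if (p$bias_amp > 0) {
        bias <- cosine_field(coords, fov, 3)
        img <- img * (1 + p$bias_amp * array(bias, d))
      }
      if (p$slice_gain_sd > 0) {
        gains <- exp(stats::rnorm(n, 0, p$slice_gain_sd))
        img <- img * array(rep(gains, each = n * n), d)
      }
      if (p$noise_sd > 0)
        img <- img + array(stats::rnorm(prod(d), 0, p$noise_sd), d)
      image <- volume_image(img, voxel_size = vs, origin = org)
    }
    list(image = image, truth = truth, labels = labels, gains = gains,
         spec = spec)
  })
}

#' Generate a synthetic cohort
#'
#' Draws ages uniformly over `age_range` and TIV from the per-sex normal
#' distribution, evaluates the programmed trajectories (plus subject-level
#' fraction noise), and renders one phantom per subject. All randomness
#' derives from `master_seed` via stable per-subject child seeds.
#'
#' @param params An [aging_params()] object.
#' @param n_per_sex Integer vector `c(female, male)`.
#' @param age_range Age range in years (defaults to the supported range).
#' @param group Group label, `"CTR"` or `"MNR"`, applied to all subjects.
#' @param master_seed Integer master seed.
#' @param render_image Render T1-like intensity images (`TRUE`) or only the
#'   ground-truth tissue maps (`FALSE`, fast path).
#' @param dir Optional output directory; when given, per-subject NIfTI
#'   volumes and a `metadata.csv` (columns id, sex, age, group, birth_weight,
#'   weight_at_scan) are written.
#' @param id_prefix Prefix for subject identifiers.
#' @return A list of class `synthetic_cohort` with `metadata` (data frame),
#'   `images` (list of `volume_image` or `NULL`s), `truth` (list of
#'   ground-truth `tissue_prob_map`), and `params`.
#' @export
generate_cohort <- function(params = aging_params(),
                            n_per_sex = c(15, 14),
                            age_range = params$age_range,
                            group = c("CTR", "MNR"),
                            master_seed = 1L,
                            render_image = TRUE,
                            dir = NULL,
                            id_prefix = "S") {
  group <- match.arg(group)
  n_per_sex <- as.integer(rep(n_per_sex, length.out = 2))
  if (sum(n_per_sex) < 1) stop("need at least one subject")
  n <- sum(n_per_sex)
  sex <- rep(c("female", "male"), n_per_sex)

  meta <- with_seed(child_seed(master_seed, "metadata"), {
    age <- stats::runif(n, age_range[1], age_range[2])
    tiv <- stats::rnorm(n, params$tiv_mean[sex], params$tiv_sd[sex])
    gm_noise <- stats::rnorm(n, 0, params$frac_noise_sd)
    bw_mean <- ifelse(sex == "female", 0.87, 0.90) -
      if (group == "MNR") 0.08 else 0
    birth_weight <- stats::rnorm(n, bw_mean, 0.11)
    weight <- stats::rnorm(n, 4 + 2.2 * pmin(age, 10), 1.5)
    data.frame(id = sprintf("%s%03d", id_prefix, seq_len(n)), sex = sex,
               age = age, group = group,
               birth_weight = round(birth_weight, 3),
               weight_at_scan = round(weight, 2),
               tiv_true = tiv, gm_noise = gm_noise,
               stringsAsFactors = FALSE)
  })

  images <- vector("list", n)
  truth <- vector("list", n)
  gm_true <- wm_true <- csf_true <- numeric(n)
  for (i in seq_len(n)) {
    fr <- trajectory_fractions(params, meta$sex[i], meta$age[i], group)
    gm <- fr$gm + meta$gm_noise[i]
    csf <- fr$csf - meta$gm_noise[i]
    sp <- phantom_spec(meta$id[i], gm, 1 - gm - csf, csf, meta$tiv_true[i],
                       seed = child_seed(master_seed, "phantom", i),
                       params = params)
    ph <- render_phantom(sp, render_image = render_image)
    images[[i]] <- ph$image
    truth[[i]] <- ph$truth
    gm_true[i] <- gm; wm_true[i] <- 1 - gm - csf; csf_true[i] <- csf
  }
  meta$gm_frac_true <- gm_true
  meta$wm_frac_true <- wm_true
  meta$csf_frac_true <- csf_true

  out <- structure(list(metadata = meta, images = images, truth = truth,
                        params = params, master_seed = master_seed,
                        group = group),
                   class = "synthetic_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cols <- c("id", "sex", "age", "group", "birth_weight", "weight_at_scan")
    utils::write.csv(meta[, cols], file.path(dir, "metadata.csv"),
                     row.names = FALSE)
    for (i in seq_len(n)) {
      if (!is.null(images[[i]]))
        write_volume(images[[i]], file.path(dir, paste0(meta$id[i], ".nii.gz")))
      write_volume(tpm_class_volume(truth[[i]], "gm"),
                   file.path(dir, paste0(meta$id[i], "_gm.nii.gz")))
    }
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("synthetic_cohort: %d subjects (%d female), ages %.1f-%.1f y, group %s\n",
              nrow(m), sum(m$sex == "female"), min(m$age), max(m$age),
              x$group))
  invisible(x)
}

#' Ground-truth GM probability maps of a synthetic cohort
#' @param cohort A `synthetic_cohort`.
#' @return A list of `volume_image` (one GM probability map per subject).
#' @export
cohort_gm_maps <- function(cohort) {
  lapply(cohort$truth, tpm_class_volume, class = "gm")
}
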