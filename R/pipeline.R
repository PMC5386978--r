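## End-to-end orchestration: simulate -> template -> preprocess -> brainage
## -> stats, with config validation, per-stage child seeds, and a manifest
## recording inputs, parameters, seeds and output hashes.

#' Synthetic human-scale reference tissue probability map
#'
#' A stand-in for a human-scale atlas TPM used to initialize the species
#' template: a large, noise-free three-compartment phantom (brain volume
#' ~1400 ml by default), lightly smoothed into soft probabilities. Entirely
#' synthetic.
#'
#' @param brain_volume_ml Brain (GM+WM+CSF) volume of the reference, in ml.
#' @param grid_dim Voxels per axis.
#' @param voxel_size Voxel size in mm.
#' @param fwhm Softening kernel FWHM in mm.
#' @param seed Seed of the shape deformation.
#' @return A `tissue_prob_map`.
#' @export
synthetic_reference_tpm <- function(brain_volume_ml = 1400, grid_dim = 40,
                                    voxel_size = 4, fwhm = 6, seed = 42) {
  p <- aging_params(grid_dim = grid_dim, voxel_size = voxel_size,
                    noise_sd = 0, bias_amp = 0, slice_gain_sd = 0)
  sp <- phantom_spec("reference", gm = 0.50, wm = 0.33, csf = 0.17,
                     tiv = brain_volume_ml, seed = seed, params = p)
  ph <- render_phantom(sp, render_image = FALSE)
  smooth_tpm(ph$truth, fwhm)
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory of the run.
#' @param seed Master seed; all stage and subject seeds derive from it.
#' @param grid_dim,voxel_size Phantom grid settings (see [aging_params()]).
#' @param n_per_sex Lifespan cohort size `c(female, male)`.
#' @param experiment_n List with per-group `c(female, male)` counts of the
#'   MNR experiment.
#' @return A nested configuration list; see [validate_config()] for the
#'   constraints each block must satisfy.
#' @export
default_config <- function(out_dir = tempfile("primage_run_"), seed = 1,
                           grid_dim = 32, voxel_size = 3,
                           n_per_sex = c(15, 14),
                           experiment_n = list(CTR = c(5, 7),
                                               MNR = c(5, 6))) {
  list(
    seed = seed,
    out_dir = out_dir,
    log_level = "info",
    stages = list(simulate = TRUE, template = TRUE, preprocess = TRUE,
                  brainage = TRUE, stats = TRUE),
    simulate = list(n_per_sex = n_per_sex, age_range = c(4, 22),
                    experiment_age_range = c(4, 7),
                    experiment_n = experiment_n,
                    grid_dim = grid_dim, voxel_size = voxel_size),
    template = list(path = NULL, target_volume = 200, fwhm = 2,
                    max_iter = 2, stop_tol = 1e-3, n_subjects = 8,
                    reference_volume = 1400),
    preprocess = list(slice_axis = 3, denoise = TRUE, register = FALSE,
                      dof = "rigid"),
    brainage = list(fwhm = 3, resample = 3, n_components = "max",
                    pca_per_fold = TRUE),
    stats = list(alpha = 0.05, scores_csv = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Checks types, ranges, path existence and stage dependencies. Never
#' mutates its input and never raises on a bad value: violations are
#' returned as a character vector (empty means valid).
#'
#' @param config A configuration list (see [default_config()]).
#' @return Character vector of violations, each naming the offending field;
#'   `character(0)` if the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  if (!num1(config$seed)) add("seed: must be a single finite number")
  if (!is.character(config$out_dir) || length(config$out_dir) != 1)
    add("out_dir: must be a single path")
  st <- config$stages
  for (s in c("simulate", "template", "preprocess", "brainage", "stats"))
    if (!isTRUE(st[[s]]) && !isFALSE(st[[s]]))
      add(sprintf("stages.%s: must be TRUE or FALSE", s))

  sim <- config$simulate
  if (!is.numeric(sim$n_per_sex) || length(sim$n_per_sex) != 2 ||
      any(sim$n_per_sex < 0) || sum(sim$n_per_sex) < 1)
    add("simulate.n_per_sex: need two non-negative counts summing to >= 1")
  if (!num1(sim$grid_dim) || sim$grid_dim < 16)
    add("simulate.grid_dim: must be >= 16")
  if (!num1(sim$voxel_size) || sim$voxel_size <= 0)
    add("simulate.voxel_size: must be positive")
  if (!is.numeric(sim$age_range) || length(sim$age_range) != 2 ||
      sim$age_range[1] <= 0 || diff(sim$age_range) <= 0)
    add("simulate.age_range: must be an increasing positive range")

  tp <- config$template
  if (!num1(tp$target_volume) || tp$target_volume <= 0)
    add("template.target_volume: must be positive")
  if (!num1(tp$fwhm) || tp$fwhm < 0)
    add("template.fwhm: must be non-negative")
  if (!num1(tp$max_iter) || tp$max_iter < 1)
    add("template.max_iter: must be >= 1")
  if (!is.null(tp$path) && !file.exists(paste0(tp$path, "_gm.nii.gz")))
    add("template.path: TPM files not found at the given prefix")

  ba <- config$brainage
  if (!num1(ba$fwhm) || ba$fwhm < 0)
    add("brainage.fwhm: must be non-negative")
  if (!num1(ba$resample) || ba$resample <= 0)
    add("brainage.resample: must be positive")

  ## stage dependencies
  if (isTRUE(st$preprocess) && !isTRUE(st$template) && is.null(tp$path))
    add("template.path: required when preprocess is enabled without the template stage")
  if (isTRUE(st$brainage) && !isTRUE(st$template) && is.null(tp$path))
    add("template.path: required when brainage is enabled without the template stage")
  if (isTRUE(st$brainage) && !isTRUE(st$simulate))
    add("stages.brainage: requires the simulate stage in this run")
  if (isTRUE(st$stats) && !isTRUE(st$brainage) &&
      is.null(config$stats$scores_csv))
    add("stats.scores_csv: required when stats is enabled without brainage")
  if (!is.null(config$stats$scores_csv) &&
      !file.exists(config$stats$scores_csv))
    add("stats.scores_csv: file does not exist")
  v
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[primage] %s", sprintf(...)))
}

#' Run the brain-age pipeline
#'
#' Executes the enabled stages in flowchart order (simulate -> template ->
#' preprocess -> brainage -> stats) and writes a JSON manifest recording the
#' configuration, seeds, per-stage outputs and MD5 hashes of every output
#' file. Reruns with the same configuration and seed reproduce all numeric
#' outputs bit-identically. A stage failure halts the run with the stage
#' name in the error.
#'
#' @param config A configuration list; see [default_config()] and
#'   [validate_config()].
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "primage",
                   version = as.character(utils::packageVersion("primage")),
                   seed = seed, config = config, stages = list())
  st <- config$stages
  run_stage <- function(name, fun) {
    if (!isTRUE(st[[name]])) return(invisible())
    pipeline_log(config, "stage %s ...", name)
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- c(list(status = "completed"), out)
    invisible()
  }

  env <- new.env()
  run_stage("simulate", function() {
    sim <- config$simulate
    params <- aging_params(grid_dim = sim$grid_dim,
                           voxel_size = sim$voxel_size)
    env$params <- params
    env$lifespan <- generate_cohort(params, sim$n_per_sex, sim$age_range,
                                    "CTR",
                                    master_seed = child_seed(seed, "lifespan"),
                                    dir = file.path(config$out_dir,
                                                    "simulate", "lifespan"),
                                    id_prefix = "L")
    ex <- list()
    for (g in names(sim$experiment_n)) {
      ex[[g]] <- generate_cohort(params, sim$experiment_n[[g]],
                                 sim$experiment_age_range, g,
                                 master_seed = child_seed(seed, "exp", g),
                                 dir = file.path(config$out_dir, "simulate",
                                                 paste0("experiment_", g)),
                                 id_prefix = paste0("E", substr(g, 1, 1)))
    }
    env$experiment <- ex
    list(n_lifespan = nrow(env$lifespan$metadata),
         n_experiment = sum(vapply(ex, function(c) nrow(c$metadata),
                                   numeric(1))))
  })

  run_stage("template", function() {
    tp <- config$template
    if (!is.null(tp$path)) {
      tpm <- read_tpm(tp$path)
      env$template <- template_set(tpm, tpm_to_t1(tpm),
                                   tpm_brain_mask(tpm))
      return(list(source = tp$path))
    }
    ref <- synthetic_reference_tpm(tp$reference_volume,
                                   seed = child_seed(seed, "reference"))
    tmpl <- initialize_template(ref, tp$target_volume,
                                voxel_size = env$params$voxel_size)
    imgs <- env$lifespan$images
    imgs <- imgs[seq_len(min(length(imgs), tp$n_subjects))]
    ## phantoms are rendered in a shared space; grids differ from the
    ## template's, so resample onto the template grid first
    imgs <- lapply(imgs, resample_volume, target = tmpl$t1_average)
    tmpl <- iterate_template(imgs, tmpl, fwhm = tp$fwhm,
                             max_iter = tp$max_iter,
                             stop_tol = tp$stop_tol, register = FALSE)
    env$template <- tmpl
    write_template(tmpl, file.path(config$out_dir, "template"))
    list(iterations = length(tmpl$history),
         final_change = if (length(tmpl$history))
           tmpl$history[length(tmpl$history)] else NA)
  })

  run_stage("preprocess", function() {
    pp <- config$preprocess
    dir.create(file.path(config$out_dir, "preprocess"), recursive = TRUE,
               showWarnings = FALSE)
    do_cohort <- function(cohort, tag) {
      maps <- list(); vols <- list()
      for (i in seq_len(nrow(cohort$metadata))) {
        id <- cohort$metadata$id[i]
        res <- tryCatch(
          preprocess_subject(
            resample_volume(cohort$images[[i]],
                            target = env$template$t1_average),
            env$template, slice_axis = pp$slice_axis,
            denoise = pp$denoise, register = pp$register, dof = pp$dof),
          error = function(e)
            stop(sprintf("subject %s: %s", id, conditionMessage(e)),
                 call. = FALSE))
        seg <- res$segmentation
        maps[[id]] <- tpm_class_volume(seg$posterior, "gm")
        vols[[id]] <- data.frame(id = id,
                                 gm_ml = seg$volumes_ml["gm"],
                                 wm_ml = seg$volumes_ml["wm"],
                                 csf_ml = seg$volumes_ml["csf"],
                                 tiv_ml = seg$tiv_ml,
                                 gm_frac = seg$fractions["gm"],
                                 wm_frac = seg$fractions["wm"],
                                 csf_frac = seg$fractions["csf"])
        jsonlite::write_json(as.list(vols[[id]]),
                             file.path(config$out_dir, "preprocess",
                                       paste0(id, "_volumes.json")),
                             auto_unbox = TRUE, digits = NA)
      }
      list(maps = maps, volumes = do.call(rbind, vols))
    }
    env$seg_lifespan <- do_cohort(env$lifespan, "lifespan")
    env$seg_experiment <- lapply(env$experiment, do_cohort)
    utils::write.csv(env$seg_lifespan$volumes,
                     file.path(config$out_dir, "preprocess",
                               "lifespan_volumes.csv"), row.names = FALSE)
    list(n_segmented = nrow(env$seg_lifespan$volumes) +
           sum(vapply(env$seg_experiment, function(x) nrow(x$volumes),
                      numeric(1))))
  })

  run_stage("brainage", function() {
    ba <- config$brainage
    if (!is.null(env$seg_lifespan)) {
      life <- list(gm_maps = unname(env$seg_lifespan$maps),
                   metadata = env$lifespan$metadata)
      exp_maps <- unlist(lapply(env$seg_experiment, function(x)
        unname(x$maps)), recursive = FALSE)
      exp_meta <- do.call(rbind, lapply(env$experiment,
                                        function(c) c$metadata))
    } else {
      life <- env$lifespan
      exp_maps <- unlist(lapply(env$experiment, cohort_gm_maps),
                         recursive = FALSE)
      exp_meta <- do.call(rbind, lapply(env$experiment,
                                        function(c) c$metadata))
    }
    loo <- loocv_brainage(life, fwhm = ba$fwhm, resample = ba$resample,
                          n_components = ba$n_components,
                          pca_per_fold = ba$pca_per_fold)
    env$loocv <- loo
    test <- list(gm_maps = exp_maps, metadata = exp_meta)
    fitted <- apply_trained_model(life, test, fwhm = ba$fwhm,
                                  resample = ba$resample,
                                  n_components = ba$n_components)
    env$experiment_scores <- fitted$result
    dir.create(file.path(config$out_dir, "brainage"), showWarnings = FALSE)
    utils::write.csv(as.data.frame(loo),
                     file.path(config$out_dir, "brainage",
                               "loocv_scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(fitted$result),
                     file.path(config$out_dir, "brainage",
                               "experiment_scores.csv"), row.names = FALSE)
    acc <- brainage_accuracy(loo)
    list(loocv_mae = acc$mae, loocv_r = acc$r, n = acc$n)
  })

  run_stage("stats", function() {
    sa <- config$stats
    dir.create(file.path(config$out_dir, "stats"), showWarnings = FALSE)
    out <- list()
    if (!is.null(sa$scores_csv)) {
      scores <- utils::read.csv(sa$scores_csv, stringsAsFactors = FALSE)
      res <- brainage_result(scores$id, scores$age, scores$brain_age,
                             metadata = scores)
    } else res <- env$experiment_scores

    ## group contrast table (one row per sex), shaped like the reference
    ## MNR summary
    rows <- list()
    for (sx in unique(res$sex %||% "all")) {
      sub <- if ("sex" %in% colnames(res))
        res[res$sex == sx, , drop = FALSE] else res
      if (length(unique(sub$group)) == 2 && nrow(sub) >= 4) {
        gd <- brainage_group_difference(sub)
        rows[[sx]] <- data.frame(
          variable = "brainage_score", sex = sx,
          mean_CTR = unname(gd$group_means["CTR"]),
          mean_MNR = unname(gd$group_means["MNR"]),
          difference = gd$difference, F = gd$ancova$F, p = gd$ancova$p,
          partial_eta2 = gd$ancova$partial_eta2)
      }
    }
    if (length(rows)) {
      tab2 <- do.call(rbind, rows)
      utils::write.csv(tab2, file.path(config$out_dir, "stats",
                                       "group_contrasts.csv"),
                       row.names = FALSE)
      out$group_contrasts = nrow(tab2)
    }

    ## trajectory fits on the lifespan cohort (fractional volumes vs age)
    if (!is.null(env$lifespan)) {
      meta <- env$lifespan$metadata
      vols <- if (!is.null(env$seg_lifespan)) {
        m <- merge(meta, env$seg_lifespan$volumes, by = "id", sort = FALSE)
        m[, c("sex", "age", "gm_frac", "wm_frac", "csf_frac")]
      } else {
        data.frame(sex = meta$sex, age = meta$age,
                   gm_frac = meta$gm_frac_true,
                   wm_frac = meta$wm_frac_true,
                   csf_frac = meta$csf_frac_true)
      }
      rows <- list()
      for (sx in unique(vols$sex)) for (v in c("gm_frac", "wm_frac",
                                               "csf_frac")) {
        sub <- vols[vols$sex == sx, ]
        if (nrow(sub) >= 4) {
          tf <- fit_trajectory(sub$age, sub[[v]], alpha = sa$alpha,
                               response = v)
          for (f in tf$fits)
            rows[[paste(sx, v, f$order)]] <- data.frame(
              volume = v, sex = sx, order = f$order,
              adjusted_r2 = f$adjusted_r2, F = f$F, p = f$p,
              selected = f$selected)
        }
      }
      if (length(rows)) {
        tab3 <- do.call(rbind, rows)
        utils::write.csv(tab3, file.path(config$out_dir, "stats",
                                         "trajectory_fits.csv"),
                         row.names = FALSE)
        out$trajectory_fits <- nrow(tab3)
      }
    }
    out
  })

  ## manifest with output hashes
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", config$out_dir, "/?"), "", names(h))
  manifest$hashes <- as.list(h)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
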