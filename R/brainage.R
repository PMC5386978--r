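## Brain age estimation: PCA-reduced GM maps feed the RVR age model; the
## BrainAGE score of a subject is estimated brain age minus chronological
## age, so positive scores indicate accelerated structural aging.

#' Assemble a brain-age result table
#'
#' @param id Subject identifiers.
#' @param age Chronological ages (years).
#' @param brain_age Estimated brain ages (years).
#' @param metadata Optional data frame merged in by `id` (sex, group, ...).
#' @return An object of class `brainage_result`: a data frame (`id`, `age`,
#'   `brain_age`, `score`) with cohort attributes `mae`, `r` and `n`. The
#'   score is identically `brain_age - age`.
#' @export
brainage_result <- function(id, age, brain_age, metadata = NULL) {
  stopifnot(length(age) == length(brain_age))
  df <- data.frame(id = as.character(id), age = as.numeric(age),
                   brain_age = as.numeric(brain_age),
                   stringsAsFactors = FALSE)
  df$score <- df$brain_age - df$age
  if (!is.null(metadata)) {
    extra <- metadata[, setdiff(intersect(colnames(metadata),
                                          c("id", "sex", "group",
                                            "birth_weight",
                                            "weight_at_scan")),
                                character(0)), drop = FALSE]
    if ("id" %in% colnames(extra))
      df <- merge(df, extra, by = "id", sort = FALSE)
  }
  structure(df, class = c("brainage_result", "data.frame"),
            mae = mean(abs(df$score)),
            r = if (length(df$age) > 2 && stats::sd(df$brain_age) > 0 &&
                    stats::sd(df$age) > 0)
              stats::cor(df$age, df$brain_age) else NA_real_,
            n = nrow(df))
}

#' Cohort accuracy of a brain-age result
#' @param x A `brainage_result`.
#' @return List with `mae` (mean absolute error, years), `r` (Pearson
#'   correlation between chronological and estimated age) and `n`.
#' @export
brainage_accuracy <- function(x) {
  list(mae = attr(x, "mae"), r = attr(x, "r"), n = attr(x, "n"))
}

#' @export
print.brainage_result <- function(x, ...) {
  cat(sprintf("brainage_result: n = %d, MAE = %.2f y, r = %.3f\n",
              attr(x, "n"), attr(x, "mae"),
              if (is.na(attr(x, "r"))) NA else attr(x, "r")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.brainage_result <- function(object, ...) {
  out <- list(n = attr(object, "n"), mae = attr(object, "mae"),
              r = attr(object, "r"),
              score_mean = mean(object$score),
              score_sd = stats::sd(object$score))
  if ("group" %in% colnames(object))
    out$group_means <- tapply(object$score, object$group, mean)
  structure(out, class = "summary.brainage_result")
}

#' @export
print.summary.brainage_result <- function(x, ...) {
  cat(sprintf("Brain age estimation over %d subjects\n", x$n))
  cat(sprintf("  MAE = %.2f years, r(CA, BA) = %.3f\n", x$mae,
              if (is.na(x$r)) NA else x$r))
  cat(sprintf("  BrainAGE score: mean %.2f, SD %.2f years\n",
              x$score_mean, x$score_sd))
  if (!is.null(x$group_means)) {
    cat("  group mean scores:\n")
    for (g in names(x$group_means))
      cat(sprintf("    %s: %+.2f years\n", g, x$group_means[g]))
  }
  invisible(x)
}

#' Scatter plot of estimated versus chronological age
#' @param x A `brainage_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.brainage_result <- function(x, ...) {
  col <- if ("group" %in% colnames(x))
    ifelse(x$group == "MNR", "firebrick", "steelblue") else "steelblue"
  graphics::plot(x$age, x$brain_age, xlab = "Chronological age (years)",
                 ylab = "Estimated brain age (years)", pch = 19, col = col,
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}

## Resolve a "cohort" argument into gm maps + metadata.
resolve_cohort <- function(cohort, gm_maps = NULL, metadata = NULL) {
  if (inherits(cohort, "synthetic_cohort"))
    return(list(maps = cohort_gm_maps(cohort), meta = cohort$metadata))
  if (is.list(cohort) && !is.null(cohort$gm_maps))
    return(list(maps = cohort$gm_maps, meta = cohort$metadata))
  stop("cohort must be a synthetic_cohort or list(gm_maps=, metadata=)")
}

#' Leave-one-out cross-validated brain age estimation
#'
#' For each subject, the feature reduction (mask, centring, PCA) and the RVR
#' model are fitted on the remaining n - 1 subjects only, and the held-out
#' subject's brain age is predicted — no information from the test subject
#' leaks into the fold. BrainAGE scores, pooled MAE and Pearson r are
#' assembled from the n held-out predictions.
#'
#' @param cohort A `synthetic_cohort` or a `list(gm_maps = , metadata = )`
#'   where `metadata` has columns `id` and `age`.
#' @param fwhm,resample,n_components Feature reduction settings (see
#'   [reduce_features()]).
#' @param pca_per_fold Refit the PCA inside every fold (`TRUE`, the
#'   leakage-safe default) or reuse one global PCA.
#' @param ... Passed to [rvr()].
#' @return A [brainage_result()].
#' @export
loocv_brainage <- function(cohort, fwhm = 3, resample = 3,
                           n_components = "max", pca_per_fold = TRUE, ...) {
  cc <- resolve_cohort(cohort)
  meta <- cc$meta
  n <- nrow(meta)
  if (n < 3) stop("need at least 3 subjects for cross-validation")
  rows <- feature_rows(cc$maps, fwhm, resample)   # deterministic per subject

  global_red <- if (!pca_per_fold)
    fit_reduction_rows(rows, NULL, n_components, fwhm, resample) else NULL

  ba <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      tr <- setdiff(seq_len(n), i)
      red <- if (pca_per_fold)
        fit_reduction_rows(rows[tr, , drop = FALSE], NULL, n_components,
                           fwhm, resample)
      else global_red
      ftr <- project_rows(red, rows[tr, , drop = FALSE])
      fte <- project_rows(red, rows[i, , drop = FALSE])
      fit <- rvr(ftr, meta$age[tr], ...)
      predict(fit, fte)
    }, error = function(e)
      stop(sprintf("LOOCV fold %d (%s) failed: %s", i, meta$id[i],
                   conditionMessage(e)), call. = FALSE))
    ba[i] <- res
  }
  brainage_result(meta$id, meta$age, ba, metadata = meta)
}

#' Train the brain-age model on one cohort and score another
#'
#' One feature reduction and one RVR fit on the full training cohort; every
#' test subject is then projected and scored.
#'
#' @param train,test Cohorts as in [loocv_brainage()]. With `test = train`,
#'   predictions equal the fitted values.
#' @param fwhm,resample,n_components Feature reduction settings.
#' @param ... Passed to [rvr()].
#' @return A list of class `brainage_model_fit`: `model` (the `rvr`),
#'   `reduction`, `train_result` and `result` (the test
#'   [brainage_result()]).
#' @export
apply_trained_model <- function(train, test, fwhm = 3, resample = 3,
                                n_components = "max", ...) {
  trc <- resolve_cohort(train)
  tec <- resolve_cohort(test)
  rows_tr <- feature_rows(trc$maps, fwhm, resample)
  red <- fit_reduction_rows(rows_tr, NULL, n_components, fwhm, resample)
  ftr <- project_rows(red, rows_tr)
  fit <- rvr(ftr, trc$meta$age, ...)
  rows_te <- feature_rows(tec$maps, fwhm, resample)
  fte <- project_rows(red, rows_te)
  ba <- predict(fit, fte)
  structure(list(model = fit, reduction = red,
                 train_result = brainage_result(trc$meta$id, trc$meta$age,
                                                fitted(fit), trc$meta),
                 result = brainage_result(tec$meta$id, tec$meta$age, ba,
                                          tec$meta)),
            class = "brainage_model_fit")
}

#' @export
print.brainage_model_fit <- function(x, ...) {
  cat("brainage_model_fit\n")
  print(x$model)
  print(x$result)
  invisible(x)
}

#' Human-equivalent age of a baboon
#'
#' Baboon chronological age maps to human age by a factor of 3.5 (a baboon
#' lifespan of 4-22 years corresponds to roughly 14-77 human years).
#'
#' @param baboon_age Age(s) in baboon years, non-negative.
#' @return Age(s) in human-equivalent years.
#' @examples
#' human_equivalent_age(c(4, 5, 22))  # 14, 17.5, 77
#' @export
human_equivalent_age <- function(baboon_age) {
  if (any(baboon_age < 0)) stop("age must be non-negative")
  3.5 * baboon_age
}

#' Serialize a trained brain-age model to a directory
#'
#' Writes a JSON description plus plain-text arrays (relevance vectors, PCA
#' basis) so a model can be reloaded without R serialization formats.
#'
#' @param fit A `brainage_model_fit`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_brainage_model <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- fit$model
  jsonlite::write_json(
    list(kernel = "linear", bias = m$bias, beta = m$beta,
         alpha = m$alpha, relevance_index = m$relevance_index,
         kernel_weights = m$kernel_weights,
         reduction = list(fwhm = fit$reduction$fwhm,
                          resample = fit$reduction$resample,
                          n_masked = sum(fit$reduction$mask),
                          explained_variance =
                            fit$reduction$explained_variance)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(m$x_train),
                   file.path(dir, "relevance_vectors.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$reduction$pca_basis),
                   file.path(dir, "pca_basis.csv"), row.names = FALSE)
  utils::write.csv(data.frame(mask = fit$reduction$mask),
                   file.path(dir, "mask.csv"), row.names = FALSE)
  utils::write.csv(data.frame(pca_mean = fit$reduction$pca_mean),
                   file.path(dir, "pca_mean.csv"), row.names = FALSE)
  invisible(dir)
}
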