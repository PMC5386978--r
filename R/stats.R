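## Morphometric statistics layer: linear/quadratic volume trajectory fits
## with model selection, two-group ANOVA from summary statistics, ANCOVA
## with partial eta squared, and BrainAGE group contrasts.

#' Fit linear and quadratic age trajectories to a volume measure
#'
#' Ordinary least squares of the measure on age for each polynomial order,
#' with adjusted R-squared `1 - (1 - R^2) (n - 1) / (n - p - 1)` and the
#' overall F test per model. The selected order is the one with the higher
#' adjusted R-squared among orders whose overall F is significant at
#' `alpha`; ties go to the lower order. With `rule = "nested"`, the
#' quadratic model is selected iff its quadratic term is significant at
#' `alpha` in a nested F test.
#'
#' @param ages Chronological ages in years.
#' @param values Volume measure (absolute ml or fractional).
#' @param orders Polynomial orders to fit.
#' @param alpha Significance level of the selection rule.
#' @param rule Selection rule: `"adjusted_r2"` (default) or `"nested"`.
#' @param response Optional response name carried into the result.
#' @return An object of class `trajectory_fit`: a list with one entry per
#'   order (`coefficients`, `r2`, `adjusted_r2`, `F`, `df`, `p`) plus
#'   `selected` (the chosen order, or `NA` if no model is significant).
#' @export
fit_trajectory <- function(ages, values, orders = c(1, 2), alpha = 0.05,
                           rule = c("adjusted_r2", "nested"),
                           response = "volume") {
  rule <- match.arg(rule)
  n <- length(ages)
  stopifnot(length(values) == n)
  if (n <= max(orders) + 1)
    stop("need n > order + 1 observations")
  if (stats::sd(ages) < 1e-12) stop("degenerate design: constant age")
  fits <- list()
  for (ord in sort(as.integer(orders))) {
    X <- stats::poly(ages, degree = ord, raw = TRUE)
    fit <- stats::lm(values ~ X)
    if (any(is.na(stats::coef(fit))))
      stop("collinear design in trajectory fit")
    sm <- summary(fit)
    Fv <- unname(sm$fstatistic)
    fits[[as.character(ord)]] <- list(
      order = ord,
      coefficients = stats::setNames(as.numeric(stats::coef(fit)),
                                     c("(Intercept)",
                                       paste0("age^", seq_len(ord)))),
      r2 = sm$r.squared,
      adjusted_r2 = sm$adj.r.squared,
      F = Fv[1], df = c(Fv[2], Fv[3]),
      p = stats::pf(Fv[1], Fv[2], Fv[3], lower.tail = FALSE),
      model = fit)
  }
  selected <- NA_integer_
  if (rule == "adjusted_r2") {
    sig <- vapply(fits, function(f) f$p < alpha, logical(1))
    if (any(sig)) {
      cand <- fits[sig]
      adj <- vapply(cand, function(f) f$adjusted_r2, numeric(1))
      best <- which(adj >= max(adj) - 1e-12)[1]   # ties -> lower order
      selected <- as.integer(cand[[best]]$order)
    }
  } else {
    if (all(c("1", "2") %in% names(fits))) {
      cmp <- stats::anova(fits[["1"]]$model, fits[["2"]]$model)
      pq <- cmp$`Pr(>F)`[2]
      selected <- if (is.finite(pq) && pq < alpha) 2L else
        if (fits[["1"]]$p < alpha) 1L else NA_integer_
    }
  }
  for (k in names(fits)) fits[[k]]$selected <- identical(fits[[k]]$order,
                                                         as.integer(selected))
  structure(list(fits = fits, selected = selected, rule = rule,
                 alpha = alpha, response = response, n = n),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory_fit for %s (n = %d, rule = %s)\n", x$response,
              x$n, x$rule))
  for (f in x$fits)
    cat(sprintf("  order %d: adj R2 = %.3f, F(%g, %g) = %.2f, p = %.3g%s\n",
                f$order, f$adjusted_r2, f$df[1], f$df[2], f$F, f$p,
                if (f$selected) "  <- selected" else ""))
  if (is.na(x$selected)) cat("  no significant model\n")
  invisible(x)
}

#' Two-group one-way ANOVA from summary statistics
#'
#' Recomputes the group-difference F statistic from per-group n, mean and SD
#' only: pooled variance
#' `s2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`,
#' `F = (mean_a - mean_b)^2 / (s2 (1/n_a + 1/n_b))` on (1, n_a + n_b - 2)
#' degrees of freedom.
#'
#' @param n_a,mean_a,sd_a First group summary (n >= 2).
#' @param n_b,mean_b,sd_b Second group summary (n >= 2).
#' @return An object of class `group_comparison`: `F`, `df`, `p`,
#'   `partial_eta2` and the group summaries. Zero pooled variance with
#'   unequal means yields `F = Inf` with a warning.
#' @examples
#' # absolute GM volume by sex: females 87.3 +/- 8.6 (n 15),
#' # males 95.9 +/- 8.8 (n 14) -> F ~ 7.0
#' anova_from_summary(15, 87.3, 8.6, 14, 95.9, 8.8)
#' @export
anova_from_summary <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df2 <- n_a + n_b - 2
  s2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df2
  num <- (mean_a - mean_b)^2
  if (s2 <= 0) {
    if (num > 0) {
      warning("zero pooled variance with unequal means; F is infinite")
      Fv <- Inf
    } else Fv <- 0
  } else {
    Fv <- num / (s2 * (1 / n_a + 1 / n_b))
  }
  p <- if (is.finite(Fv)) stats::pf(Fv, 1, df2, lower.tail = FALSE) else 0
  pe2 <- if (is.finite(Fv)) Fv / (Fv + df2) else 1
  structure(list(F = Fv, df = c(1, df2), p = p, partial_eta2 = pe2,
                 factor = "group", covariates = character(0),
                 groups = data.frame(n = c(n_a, n_b),
                                     mean = c(mean_a, mean_b),
                                     sd = c(sd_a, sd_b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s%s): F(%g, %g) = %.2f, p = %.3g, partial eta2 = %.2f\n",
              x$factor,
              if (length(x$covariates))
                paste0(" | ", paste(x$covariates, collapse = ", ")) else "",
              x$df[1], x$df[2], x$F, x$p, x$partial_eta2))
  invisible(x)
}

#' ANCOVA group comparison with an age covariate
#'
#' Fits `value ~ group + age` by least squares and reports the group effect
#' from Type-II sums of squares (group adjusted for age), with partial eta
#' squared `SS_group / (SS_group + SS_residual)`.
#'
#' @param values Response values.
#' @param group Two-level group factor (e.g. CTR/MNR).
#' @param age Covariate; `NULL` reduces to a one-way ANOVA.
#' @return A `group_comparison` (see [anova_from_summary()]).
#' @export
ancova_group <- function(values, group, age = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) < 1))
    stop("need two non-empty groups")
  n <- length(values)
  if (n < 4) stop("need at least 4 observations")
  if (is.null(age)) {
    full <- stats::lm(values ~ group)
    red <- stats::lm(values ~ 1)
    covs <- character(0)
  } else {
    if (stats::sd(age[group == levels(group)[1]]) < 1e-12 &&
        stats::sd(age[group == levels(group)[2]]) < 1e-12)
      stop("confounded design: age is constant within groups")
    full <- stats::lm(values ~ group + age)
    red <- stats::lm(values ~ age)
    covs <- "age"
  }
  if (any(is.na(stats::coef(full)))) stop("singular ANCOVA design")
  ss_res <- sum(stats::residuals(full)^2)
  ss_group <- sum(stats::residuals(red)^2) - ss_res   # Type II SS for group
  df_den <- stats::df.residual(full)
  Fv <- (ss_group / 1) / (ss_res / df_den)
  Fv <- max(Fv, 0)
  structure(list(F = Fv, df = c(1, df_den),
                 p = stats::pf(Fv, 1, df_den, lower.tail = FALSE),
                 partial_eta2 = ss_group / max(ss_group + ss_res, 1e-300),
                 factor = "group", covariates = covs,
                 model = full),
            class = "group_comparison")
}

#' BrainAGE group difference with covariate-adjusted test
#'
#' @param results A [brainage_result()] whose rows carry a `group` column,
#'   or one merged with `metadata`.
#' @param metadata Optional data frame with columns `id`, `group` (and
#'   `age`) if the result lacks them.
#' @param reference Group treated as the reference (difference =
#'   mean(other) - mean(reference)).
#' @return A list of class `brainage_group_diff`: `difference` (years,
#'   mean score of the non-reference group minus the reference group),
#'   `group_means`, and `ancova` (the [ancova_group()] test of the scores
#'   with age as covariate).
#' @export
brainage_group_difference <- function(results, metadata = NULL,
                                      reference = "CTR") {
  df <- as.data.frame(results)
  if (!"group" %in% colnames(df)) {
    if (is.null(metadata) || !all(c("id", "group") %in% colnames(metadata)))
      stop("group labels missing: provide metadata with id and group")
    df <- merge(df, metadata[, c("id", "group")], by = "id", sort = FALSE)
  }
  groups <- unique(df$group)
  if (length(groups) != 2 || !(reference %in% groups))
    stop("need exactly two groups including the reference")
  other <- setdiff(groups, reference)
  gm <- tapply(df$score, df$group, mean)
  diff <- unname(gm[other] - gm[reference])
  anc <- ancova_group(df$score, df$group, age = df$age)
  structure(list(difference = diff, group_means = gm, reference = reference,
                 ancova = anc),
            class = "brainage_group_diff")
}

#' @export
print.brainage_group_diff <- function(x, ...) {
  other <- setdiff(names(x$group_means), x$reference)
  cat(sprintf("BrainAGE group difference: %s - %s = %+.2f years\n",
              other, x$reference, x$difference))
  print(x$ancova)
  invisible(x)
}

#' Bundled reference morphometry of the baboon lifespan cohort
#'
#' Per-sex summary statistics (n, mean, SD) of absolute and fractional brain
#' tissue volumes and age for a healthy adult baboon lifespan cohort (29
#' animals, 15 female, ages 4-22 years). Units: ml for absolute volumes,
#' dimensionless for fractional volumes, years for age.
#'
#' @return Data frame with columns `variable`, `unit`, `sex`, `n`, `mean`,
#'   `sd`.
#' @export
lifespan_summary <- function() {
  utils::read.csv(system.file("extdata", "lifespan_summary.csv",
                              package = "primage"),
                  stringsAsFactors = FALSE)
}

#' Bundled reference morphometry of the MNR experiment
#'
#' Per-sex, per-group summary statistics (n, mean, SD) for young adult baboon
#' offspring of mothers fed ad libitum (CTR) or a 70% diet during pregnancy
#' (MNR), including BrainAGE scores.
#'
#' @return Data frame with columns `variable`, `unit`, `sex`, `group`, `n`,
#'   `mean`, `sd`.
#' @export
mnr_summary <- function() {
  utils::read.csv(system.file("extdata", "mnr_summary.csv",
                              package = "primage"),
                  stringsAsFactors = FALSE)
}
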