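## Relevance vector regression (sparse Bayesian learning) with a linear
## kernel: the age estimator at the centre of the brain-age framework.
## Hyperparameters are re-estimated by the standard fixed-point updates on
## the marginal likelihood; bases whose precision diverges are pruned,
## leaving a sparse set of relevance vectors. No random initialization is
## used, so the fit is deterministic.

#' Fit a linear-kernel relevance vector regression
#'
#' Builds the kernel design `K[i, j] = x_i . x_j` plus a bias column and
#' maximizes the marginal likelihood over per-basis precisions `alpha` and
#' noise precision `beta` by iterative re-estimation. Bases with
#' `alpha > prune_threshold` are pruned (the bias column is never pruned).
#' With `max_iter = 0` the posterior mean at the initial hyperparameters is
#' returned, which equals a kernel ridge regression with per-basis penalties
#' `alpha/beta`.
#'
#' @param x Numeric feature matrix (subjects in rows) or vector (one
#'   feature).
#' @param y Numeric response (chronological age in years).
#' @param max_iter Maximum hyperparameter re-estimation cycles.
#' @param prune_threshold Precision above which a basis is pruned.
#' @param tol Convergence tolerance on the relative marginal-likelihood
#'   change.
#' @param alpha0 Initial per-basis precision (default `1/n^2`).
#' @param beta0 Initial noise precision (default `10/var(y)`).
#' @param update_beta Re-estimate the noise precision (`FALSE` keeps `beta0`
#'   fixed).
#' @return An object of class `rvr` with elements `weights` (posterior mean,
#'   bias first), `relevance_index` (training rows retained as relevance
#'   vectors), `alpha`, `beta`, `bias`, `x_train` (retained training rows),
#'   `fitted.values`, `residuals`, `marginal_loglik`, `converged`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' y <- 5 + 2 * x[, 1] + rnorm(20, 0, 0.1)
#' fit <- rvr(x, y)
#' cor(fitted(fit), y)
#' @export
rvr <- function(x, y, max_iter = 500, prune_threshold = 1e6, tol = 1e-4,
                alpha0 = NULL, beta0 = NULL, update_beta = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(x) != n) stop("nrow(x) must match length(y)")
  if (n < 3) stop("need at least 3 training subjects")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("features and response must be finite")

  vy <- stats::var(y)
  if (vy < 1e-12) {
    ## constant response: the model degenerates to the bias term
    obj <- structure(list(weights = mean(y), relevance_index = integer(0),
                          alpha = numeric(0), beta = Inf, bias = mean(y),
                          x_train = x[0, , drop = FALSE],
                          fitted.values = rep(mean(y), n),
                          residuals = rep(0, n), y = y,
                          marginal_loglik = NA_real_, converged = TRUE,
                          p = ncol(x)),
                     class = "rvr")
    return(obj)
  }

  K <- x %*% t(x)
  Phi <- cbind(1, K)                      # n x (n + 1); column 1 = bias
  m <- ncol(Phi)
  alpha <- rep(if (is.null(alpha0)) 1 / n^2 else alpha0, m)
  beta <- if (is.null(beta0)) 10 / vy else beta0
  keep <- rep(TRUE, m)                    # active bases (bias + kernels)

  posterior <- function(Phi_a, alpha_a, beta) {
    H <- beta * crossprod(Phi_a)
    diag(H) <- diag(H) + alpha_a
    L <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(L)) {                     # ridge-jitter retry once
      diag(H) <- diag(H) + max(diag(H)) * 1e-10 + 1e-12
      L <- tryCatch(chol(H), error = function(e)
        stop("singular system in RVR posterior computation"))
    }
    Sigma <- chol2inv(L)
    mu <- beta * Sigma %*% crossprod(Phi_a, y)
    list(mu = as.numeric(mu), Sigma = Sigma, logdetH = 2 * sum(log(diag(L))))
  }

  ml_old <- -Inf
  converged <- max_iter == 0
  post <- posterior(Phi[, keep, drop = FALSE], alpha[keep], beta)
  if (max_iter > 0) {
    for (it in seq_len(max_iter)) {
      idx <- which(keep)
      Phi_a <- Phi[, idx, drop = FALSE]
      gamma <- 1 - alpha[idx] * diag(post$Sigma)
      mu2 <- post$mu^2
      new_alpha <- ifelse(mu2 > 1e-300, pmax(gamma, 1e-12) / mu2, Inf)
      alpha[idx] <- new_alpha
      if (update_beta) {
        rss <- sum((y - Phi_a %*% post$mu)^2)
        ## cap the noise precision: on noiseless data beta diverges and
        ## swamps the posterior computation
        beta <- min(max((n - sum(gamma)) / max(rss, 1e-300), 1e-12),
                    1e10 / vy)
      }
      ## prune diverged bases, never the bias
      keep <- alpha < prune_threshold & is.finite(alpha)
      keep[1] <- TRUE
      post <- posterior(Phi[, keep, drop = FALSE], alpha[keep], beta)

      ## marginal likelihood (up to constants)
      idx <- which(keep)
      Phi_a <- Phi[, idx, drop = FALSE]
      rss <- sum((y - Phi_a %*% post$mu)^2)
      ml <- 0.5 * (n * log(beta) + sum(log(alpha[idx])) - post$logdetH -
                     beta * rss - sum(alpha[idx] * post$mu^2))
      if (is.finite(ml_old) &&
          abs(ml - ml_old) <= tol * (abs(ml_old) + 1e-10)) {
        converged <- TRUE
        break
      }
      ml_old <- ml
    }
  }

  idx <- which(keep)
  w <- post$mu
  bias <- w[1]
  kern_idx <- idx[idx > 1] - 1L           # training-row indices retained
  kern_w <- w[match(kern_idx + 1L, idx)]
  fitted <- as.numeric(Phi[, idx, drop = FALSE] %*% w)
  structure(list(weights = w, relevance_index = kern_idx,
                 alpha = alpha[idx], beta = beta, bias = bias,
                 kernel_weights = kern_w,
                 x_train = x[kern_idx, , drop = FALSE],
                 Sigma = post$Sigma,
                 fitted.values = fitted, residuals = y - fitted, y = y,
                 marginal_loglik = if (max_iter > 0) ml_old else NA_real_,
                 converged = converged, p = ncol(x)),
            class = "rvr")
}

#' Predict ages from a fitted RVR
#'
#' Prediction is linear in the features: the linear kernel against the
#' retained relevance vectors plus the bias term.
#'
#' @param object An `rvr` fit.
#' @param newdata Feature matrix with the training feature dimension (or a
#'   single feature vector). Omitted: returns fitted values.
#' @param se.fit Also return the posterior predictive standard deviation.
#' @param ... Unused.
#' @return Numeric predictions, or a list with `fit` and `se.fit`.
#' @export
predict.rvr <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
             else as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop(sprintf("feature dimension mismatch: model has %d, newdata has %d",
                 object$p, ncol(newdata)))
  if (length(object$relevance_index) == 0) {
    fit <- rep(object$bias, nrow(newdata))
    if (!se.fit) return(fit)
    return(list(fit = fit, se.fit = rep(0, nrow(newdata))))
  }
  Kx <- newdata %*% t(object$x_train)
  fit <- as.numeric(object$bias + Kx %*% object$kernel_weights)
  if (!se.fit) return(fit)
  Phi_new <- cbind(1, Kx)
  var_f <- rowSums((Phi_new %*% object$Sigma) * Phi_new)
  list(fit = fit, se.fit = sqrt(pmax(var_f + 1 / object$beta, 0)))
}

#' @export
coef.rvr <- function(object, ...) {
  c(bias = object$bias,
    stats::setNames(object$kernel_weights,
                    paste0("rv", object$relevance_index)))
}

#' @export
fitted.rvr <- function(object, ...) object$fitted.values

#' @export
residuals.rvr <- function(object, ...) object$residuals

#' @export
print.rvr <- function(x, ...) {
  cat(sprintf("Relevance vector regression (linear kernel)\n"))
  cat(sprintf("  n = %d, features = %d, relevance vectors = %d\n",
              length(x$y), x$p, length(x$relevance_index)))
  cat(sprintf("  noise SD = %.4g, training RMSE = %.4g\n",
              1 / sqrt(x$beta), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
summary.rvr <- function(object, ...) {
  structure(list(n = length(object$y), p = object$p,
                 n_rv = length(object$relevance_index),
                 noise_sd = 1 / sqrt(object$beta),
                 rmse = sqrt(mean(object$residuals^2)),
                 r = if (stats::sd(object$fitted.values) > 0)
                   stats::cor(object$fitted.values, object$y) else NA_real_,
                 converged = object$converged),
            class = "summary.rvr")
}

#' @export
print.summary.rvr <- function(x, ...) {
  cat("Relevance vector regression (linear kernel)\n")
  cat(sprintf("  n = %d subjects, %d features\n", x$n, x$p))
  cat(sprintf("  relevance vectors retained: %d\n", x$n_rv))
  cat(sprintf("  estimated noise SD: %.4g\n", x$noise_sd))
  cat(sprintf("  training RMSE: %.4g, r(fitted, y) = %.3f\n", x$rmse, x$r))
  cat(sprintf("  hyperparameter optimization %sconverged\n",
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Simulate from the posterior predictive of an RVR fit
#'
#' @param object An `rvr` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param newdata Feature matrix (default: training features' fitted values).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses.
#' @export
simulate.rvr <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  pr <- if (is.null(newdata)) {
    list(fit = object$fitted.values,
         se.fit = rep(1 / sqrt(object$beta), length(object$fitted.values)))
  } else predict(object, newdata, se.fit = TRUE)
  with_seed(seed, {
    out <- replicate(nsim, stats::rnorm(length(pr$fit), pr$fit, pr$se.fit))
    as.data.frame(out)
  })
}
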