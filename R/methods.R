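#' @export
print.blmm <- function(x, digits = 4, ...) {
  cat("Bivariate linear mixed model (", x$error_model, " errors)\n", sep = "")
  cat(sprintf("  outcomes: %s (1), %s (2); %d subjects, %d observations\n",
              x$outcomes[1], x$outcomes[2], x$n_subjects, x$n_obs))
  cat(sprintf("  log-likelihood: %.3f%s\n", x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("Fixed effects:\n")
  print(round(x$fixed, digits))
  cat("Random-effect correlations: intercepts",
      format(ranef_correlations(x)$rho_intercept, digits = 3),
      ", slopes", format(ranef_correlations(x)$rho_slope, digits = 3), "\n")
  invisible(x)
}

#' Summarize a fitted bivariate linear mixed model
#'
#' Produces the conventional two-panel report: fixed effects with standard
#' errors and Wald tests, and variance components (4 random-effect variances,
#' 6 covariances, residual variances) with standard errors from the observed
#' information.
#'
#' @param object a `"blmm"` fit.
#' @param ... unused.
#' @export
summary.blmm <- function(object, ...) {
  se_f <- sqrt(diag(object$fixef_cov))
  zval <- object$fixed / se_f
  fixed <- data.frame(Estimate = object$fixed, `Std.Error` = se_f,
                      z = zval, `p.value` = 2 * stats::pnorm(-abs(zval)),
                      check.names = FALSE)
  se_v <- if (!is.null(object$vc_cov)) sqrt(pmax(diag(object$vc_cov), 0)) else
    rep(NA_real_, length(object$vc))
  vc <- data.frame(Estimate = object$vc, `Std.Error` = se_v, check.names = FALSE)
  rc <- ranef_correlations(object)
  structure(list(fixed = fixed, vc = vc, loglik = object$loglik,
                 rho = c(intercept = rc$rho_intercept, slope = rc$rho_slope),
                 error_model = object$error_model, converged = object$converged,
                 n_subjects = object$n_subjects, n_obs = object$n_obs,
                 outcomes = object$outcomes),
            class = "summary.blmm")
}

#' @export
print.summary.blmm <- function(x, digits = 4, ...) {
  cat("Bivariate linear mixed model (", x$error_model, " errors)\n", sep = "")
  cat(sprintf("  %d subjects, %d observations, log-likelihood %.3f%s\n\n",
              x$n_subjects, x$n_obs, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("Fixed effects:\n")
  print(round(x$fixed, digits))
  cat("\nVariance components:\n")
  print(round(x$vc, digits))
  cat(sprintf("\nRandom-effect correlations: intercepts %.3f, slopes %.3f\n",
              x$rho["intercept"], x$rho["slope"]))
  invisible(x)
}

#' @export
coef.blmm <- function(object, ...) object$fixed

#' @export
logLik.blmm <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' Parameter covariance of a fitted model
#'
#' @param object a `"blmm"` fit.
#' @param which `"fixed"` for the fixed-effect covariance, `"vc"` for the
#'   variance-component covariance (delta method from the log-Cholesky
#'   parameterization), `"all"` for the block-diagonal combination (the two
#'   blocks are asymptotically orthogonal under normality).
#' @param ... unused.
#' @export
vcov.blmm <- function(object, which = c("all", "fixed", "vc"), ...) {
  which <- match.arg(which)
  if (which == "fixed") return(object$fixef_cov)
  if (is.null(object$vc_cov) && which != "fixed")
    stop("fit was computed with se = FALSE; refit with se = TRUE")
  if (which == "vc") return(object$vc_cov)
  nf <- nrow(object$fixef_cov); nv <- nrow(object$vc_cov)
  out <- matrix(0, nf + nv, nf + nv)
  out[seq_len(nf), seq_len(nf)] <- object$fixef_cov
  out[nf + seq_len(nv), nf + seq_len(nv)] <- object$vc_cov
  nm <- c(rownames(object$fixef_cov), rownames(object$vc_cov))
  dimnames(out) <- list(nm, nm)
  out
}

#' Empirical Bayes random-effect predictions
#'
#' Best linear unbiased predictions of each subject's four random effects
#' (intercept and slope deviations for both outcomes),
#' \eqn{\hat b_i = \Sigma Z_i' V_i^{-1} (y_i - X_i \hat\theta)}.
#'
#' @param object a `"blmm"` fit.
#' @param ... unused.
#' @return A data frame with one row per subject and columns `int1`, `int2`,
#'   `slope1`, `slope2`.
#' @export
ranef.blmm <- function(object, ...) {
  prep <- .blmm_prepare(object$data, object$covariates, object$error_model,
                        object$slope_covariates %||% character())
  out <- matrix(NA_real_, length(prep$subjects), 4L,
                dimnames = list(prep$subjects, RE_NAMES))
  for (g in prep$groups) {
    V <- g$Z %*% object$Sigma %*% t(g$Z) + .group_R(g, object$err)
    W <- chol2inv(chol(V))
    SZtW <- object$Sigma %*% crossprod(g$Z, W)
    for (k in seq_along(g$idx)) {
      i <- g$idx[k]
      d <- prep$designs[[i]]
      r <- d$y - drop(d$X %*% object$fixed)
      out[i, ] <- drop(SZtW %*% r)
    }
  }
  data.frame(subject_id = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname ranef.blmm
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' Residuals of a fitted bivariate linear mixed model
#'
#' @param object a `"blmm"` fit.
#' @param type `"marginal"` (response minus population mean) or
#'   `"conditional"` (additionally subtracting the subject's predicted random
#'   effects).
#' @param ... unused.
#' @return The long data frame of the fit with a `residual` column.
#' @export
residuals.blmm <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  prep <- .blmm_prepare(object$data, object$covariates, object$error_model,
                        object$slope_covariates %||% character())
  re <- if (type == "conditional") ranef.blmm(object) else NULL
  rows <- list()
  for (i in seq_along(prep$subjects)) {
    d <- prep$designs[[i]]
    r <- d$y - drop(d$X %*% object$fixed)
    if (type == "conditional")
      r <- r - drop(d$Z %*% as.numeric(re[i, RE_NAMES]))
    rows[[i]] <- data.frame(subject_id = prep$subjects[i],
                            outcome = object$outcomes[d$outcome_idx],
                            time = d$time, residual = r,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Population or subject-level trajectory predictions
#'
#' @param object a `"blmm"` fit.
#' @param times evaluation times (years).
#' @param profile optional named covariate vector; defaults to all-zero
#'   (i.e. the covariate-average profile when covariates are standardized).
#' @param subject optional subject id; when given, the subject's predicted
#'   random effects are added (level-1 prediction).
#' @param ... unused.
#' @return Data frame with columns `time`, `outcome`, `fit`.
#' @export
predict.blmm <- function(object, times = seq(0, 7.5, by = 0.5), profile = NULL,
                         subject = NULL, ...) {
  eff <- .profile_effects(object, profile)
  b <- c(0, 0, 0, 0)
  if (!is.null(subject)) {
    re <- ranef.blmm(object)
    row <- re[re$subject_id == as.character(subject), ]
    if (!nrow(row)) stop("subject not found: ", subject)
    b <- as.numeric(row[1L, RE_NAMES])
  }
  f1 <- eff$int1 + b[1L] + (eff$slope1 + b[3L]) * times
  f2 <- eff$int2 + b[2L] + (eff$slope2 + b[4L]) * times
  data.frame(time = rep(times, 2L),
             outcome = rep(object$outcomes, each = length(times)),
             fit = c(f1, f2), stringsAsFactors = FALSE)
}

#' Parametric simulation from a fitted model
#'
#' Draws new datasets from the fitted joint model at the original design
#' (same subjects, visit times and covariates).
#'
#' @param object a `"blmm"` fit.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A list of `"longitudinal_data"` objects of length `nsim`.
#' @export
simulate.blmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  prep <- .blmm_prepare(object$data, object$covariates, object$error_model,
                        object$slope_covariates %||% character())
  cholS <- chol(object$Sigma + diag(1e-10, 4))
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    d <- object$data$data
    newval <- numeric(nrow(d))
    pos <- 1L
    for (i in seq_along(prep$subjects)) {
      des <- prep$designs[[i]]
      m <- length(des$y)
      b <- drop(crossprod(cholS, stats::rnorm(4)))
      R <- .group_R(list(outcome_idx = des$outcome_idx, cross = des$cross,
                         m = m), object$err)
      e <- drop(crossprod(chol(R), stats::rnorm(m)))
      yi <- drop(des$X %*% object$fixed) + drop(des$Z %*% b) + e
      # rows of d are sorted subject/outcome/time, matching the design order
      newval[pos:(pos + m - 1L)] <- yi
      pos <- pos + m
    }
    d$value <- newval
    xi <- object$data
    xi$data <- d
    out[[s]] <- xi
  }
  out
}

#' Likelihood ratio test for correlated versus independent errors
#'
#' Compares the nested pair of fits that differ only in the same-time residual
#' covariance (`cov12 = 0` versus free): statistic
#' \eqn{2(\ell_{corr} - \ell_{indep})} clipped at 0, 1 degree of freedom,
#' p-value from the upper chi-square tail.
#'
#' @param fit_indep the `"blmm"` fit with `error_model = "independent"`.
#' @param fit_corr the `"blmm"` fit with `error_model = "correlated"`.
#' @return A list of class `"blmm_lrt"` with `statistic`, `df`, `p.value`.
#' @export
lrt_errors <- function(fit_indep, fit_corr) {
  stopifnot(inherits(fit_indep, "blmm"), inherits(fit_corr, "blmm"))
  if (fit_indep$error_model != "independent" || fit_corr$error_model != "correlated")
    stop("arguments must be the independent-error and correlated-error fits, in that order")
  if (fit_indep$n_obs != fit_corr$n_obs ||
      !identical(names(fit_indep$fixed), names(fit_corr$fixed)))
    stop("fits must share the same data and mean structure")
  raw <- 2 * (fit_corr$loglik - fit_indep$loglik)
  if (raw < -1e-6)
    warning("correlated-error fit has lower likelihood than the nested independent fit; ",
            "convergence failure likely (raw statistic ", format(raw, digits = 3), ")")
  stat <- max(raw, 0)
  structure(list(statistic = stat, df = 1L,
                 p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
                 loglik = c(independent = fit_indep$loglik,
                            correlated = fit_corr$loglik)),
            class = "blmm_lrt")
}

#' @export
print.blmm_lrt <- function(x, ...) {
  cat("Likelihood ratio test: correlated vs independent errors\n")
  cat(sprintf("  X^2 = %.3g, df = %d, p = %.3g\n", x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
anova.blmm <- function(object, ...) {
  fits <- list(object, ...)
  fits <- Filter(function(f) inherits(f, "blmm"), fits)
  if (length(fits) != 2L)
    stop("supply exactly two nested blmm fits (independent and correlated errors)")
  em <- vapply(fits, `[[`, "", "error_model")
  lrt_errors(fits[[which(em == "independent")]], fits[[which(em == "correlated")]])
}

#' Serialize a fitted model to JSON
#'
#' Writes the estimates needed to reproduce every correlation summary:
#' fixed effects, the 4x4 random-effects covariance in row-major order over
#' (intercept 1, intercept 2, slope 1, slope 2), residual parameters,
#' log-likelihood and convergence record.
#'
#' @param fit a `"blmm"` fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blmm_json <- function(fit, path) {
  stopifnot(inherits(fit, "blmm"))
  obj <- list(
    package = "blmmcor",
    error_model = fit$error_model,
    outcomes = fit$outcomes,
    covariates = fit$covariates,
    fixed = as.list(fit$fixed),
    sigma_order = RE_NAMES,
    sigma_row_major = as.numeric(t(fit$Sigma)),
    err = fit$err,
    loglik = fit$loglik,
    n_subjects = fit$n_subjects,
    n_obs = fit$n_obs,
    converged = fit$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reload a serialized fit
#'
#' Returns a lightweight `"blmm"` object (class `"blmm_lite"` as well) that
#' supports all correlation summaries but not data-dependent methods
#' (residuals, ranef, bootstrap).
#'
#' @param path JSON file written by [write_blmm_json()].
#' @export
read_blmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Sigma <- matrix(obj$sigma_row_major, 4, 4, byrow = TRUE,
                  dimnames = list(RE_NAMES, RE_NAMES))
  fixed <- unlist(obj$fixed)
  structure(list(fixed = fixed, Sigma = Sigma,
                 err = list(var1 = obj$err$var1, var2 = obj$err$var2,
                            cov12 = obj$err$cov12 %||% 0),
                 loglik = obj$loglik, n_subjects = obj$n_subjects,
                 n_obs = obj$n_obs, converged = obj$converged,
                 error_model = obj$error_model,
                 covariates = obj$covariates %||% character(),
                 outcomes = obj$outcomes),
            class = c("blmm_lite", "blmm"))
}
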