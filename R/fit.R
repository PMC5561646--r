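# Profiled maximum likelihood for the bivariate linear mixed model.
#
# Working parameterization (unconstrained):
#   w[1:4]   log-diagonal of the lower Cholesky factor L of Sigma
#   w[5:10]  free off-diagonal of L, column-major (L21, L31, L41, L32, L42, L43)
#   w[11:12] log residual variances (outcome 1, outcome 2)
#   w[13]    atanh of the same-time residual correlation (correlated model only)
# Fixed effects are profiled out by generalized least squares at every
# evaluation, so the optimizer only sees the 12 (or 13) covariance parameters.

.sigma_from_w <- function(w) {
  L <- matrix(0, 4, 4)
  diag(L) <- exp(w[1:4])
  L[lower.tri(L)] <- w[5:10]
  S <- tcrossprod(L)
  dimnames(S) <- list(RE_NAMES, RE_NAMES)
  S
}

.err_from_w <- function(w, error_model) {
  v1 <- exp(w[11]); v2 <- exp(w[12])
  c12 <- if (error_model == "correlated") tanh(w[13]) * sqrt(v1 * v2) else 0
  list(var1 = v1, var2 = v2, cov12 = c12)
}

.w_from_params <- function(Sigma, err, error_model) {
  S <- Sigma + diag(1e-8 * max(mean(diag(Sigma)), 1), 4)
  L <- t(chol(S))
  w <- c(log(diag(L)), L[lower.tri(L)], log(err$var1), log(err$var2))
  if (error_model == "correlated") {
    rho <- (err$cov12 %||% 0) / sqrt(err$var1 * err$var2)
    rho <- max(min(rho, 0.99), -0.99)
    w <- c(w, atanh(rho))
  }
  w
}

# Profiled negative log-likelihood; with profile = TRUE also returns the GLS
# fixed effects and their information matrix.  reml = TRUE adds the
# restricted-likelihood adjustment 0.5 log|sum_i X_i' V_i^{-1} X_i|.
.blmm_nll <- function(w, prep, profile = FALSE, reml = FALSE) {
  Sigma <- .sigma_from_w(w)
  err <- .err_from_w(w, prep$error_model)
  p <- prep$p
  A <- matrix(0, p, p); u <- numeric(p)
  q <- 0; logdet <- 0; n_tot <- 0
  for (g in prep$groups) {
    V <- g$Z %*% Sigma %*% t(g$Z) + .group_R(g, err)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(if (profile) list(nll = Inf) else 1e10)
    W <- chol2inv(ch)
    ld <- 2 * sum(log(diag(ch)))
    if (g$same_X) {
      XtW <- crossprod(g$X, W)
      A <- A + g$n * (XtW %*% g$X)
      u <- u + XtW %*% g$Sy
      q <- q + sum(W * g$Syy)
      logdet <- logdet + g$n * ld
      n_tot <- n_tot + g$n * g$m
    } else {
      for (j in seq_along(g$X_list)) {
        X <- g$X_list[[j]]; y <- g$y_list[[j]]
        XtW <- crossprod(X, W)
        A <- A + XtW %*% X
        u <- u + XtW %*% y
        q <- q + sum(y * (W %*% y))
      }
      logdet <- logdet + length(g$X_list) * ld
      n_tot <- n_tot + length(g$X_list) * g$m
    }
  }
  theta <- tryCatch(solve(A, u), error = function(e) NULL)
  if (is.null(theta)) return(if (profile) list(nll = Inf) else 1e10)
  quad <- q - sum(u * theta)
  nll <- 0.5 * (n_tot * log(2 * pi) + logdet + quad)
  if (reml) {
    ldA <- determinant(A, logarithm = TRUE)
    if (ldA$sign <= 0) return(if (profile) list(nll = Inf) else 1e10)
    nll <- nll + 0.5 * as.numeric(ldA$modulus) - 0.5 * p * log(2 * pi)
  }
  if (!is.finite(nll)) return(if (profile) list(nll = Inf) else 1e10)
  if (profile) list(nll = nll, theta = drop(theta), A = A) else nll
}

#' Marginal log-likelihood of the bivariate linear mixed model
#'
#' Evaluates the marginal (random effects integrated out) log-likelihood at
#' given parameter values: the sum over subjects of the multivariate-normal
#' log-density with mean \eqn{X_i \theta} and covariance
#' \eqn{Z_i \Sigma Z_i' + R_i}.
#'
#' @param x a `"longitudinal_data"` object.
#' @param fixed named fixed-effect vector in the order `int1, slope1,
#'   <covariates>.1, int2, slope2, <covariates>.2`.
#' @param Sigma 4x4 random-effects covariance over (intercept 1, intercept 2,
#'   slope 1, slope 2); must be symmetric positive semidefinite.
#' @param err list with residual variances `var1`, `var2` and optional
#'   same-time residual covariance `cov12`.
#' @param covariates covariate names entering the fixed-effect design.
#' @return The log-likelihood (a scalar).
#' @export
marginal_loglik <- function(x, fixed, Sigma, err, covariates = character()) {
  stopifnot(inherits(x, "longitudinal_data"))
  .check_sigma(Sigma)
  err <- .check_err(err)
  error_model <- if ((err$cov12 %||% 0) != 0) "correlated" else "independent"
  prep <- .blmm_prepare(x, covariates, error_model)
  if (length(fixed) != prep$p)
    stop("'fixed' must have length ", prep$p, " (", paste(prep$fixed_names, collapse = ", "), ")")
  ll <- 0
  for (g in prep$groups) {
    V <- g$Z %*% Sigma %*% t(g$Z) + .group_R(g, err)
    ch <- tryCatch(chol(V), error = function(e) {
      first <- prep$subjects[g$idx[1L]]
      stop("singular marginal covariance (subject ", first, ")", call. = FALSE)
    })
    W <- chol2inv(ch)
    ld <- 2 * sum(log(diag(ch)))
    if (g$same_X) {
      mu <- drop(g$X %*% fixed)
      q <- sum(W * g$Syy) - 2 * sum((W %*% g$Sy) * mu) + g$n * sum(mu * (W %*% mu))
      ll <- ll - 0.5 * (g$n * (g$m * log(2 * pi) + ld) + q)
    } else {
      for (j in seq_along(g$X_list)) {
        r <- g$y_list[[j]] - drop(g$X_list[[j]] %*% fixed)
        ll <- ll - 0.5 * (g$m * log(2 * pi) + ld + sum(r * (W %*% r)))
      }
    }
  }
  ll
}

.check_sigma <- function(Sigma) {
  if (!is.matrix(Sigma) || any(dim(Sigma) != 4L))
    stop("'Sigma' must be a 4x4 matrix")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    stop("'Sigma' must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(sum(diag(Sigma)), 1))
    stop("'Sigma' must be positive semidefinite")
  invisible(Sigma)
}

.check_err <- function(err) {
  stopifnot(is.list(err), !is.null(err$var1), !is.null(err$var2))
  if (err$var1 <= 0 || err$var2 <= 0) stop("residual variances must be positive")
  err$cov12 <- err$cov12 %||% 0
  if (abs(err$cov12) > sqrt(err$var1 * err$var2))
    stop("|cov12| must not exceed sqrt(var1 * var2)")
  err
}

# Moment-based starting values: per-subject ordinary least-squares lines give
# a (noisy but cheap) estimate of the random-effect covariance; pooled OLS
# residuals give the error variances.  Cross-outcome covariances start at 0.
.blmm_init <- function(prep) {
  n <- length(prep$subjects)
  B <- matrix(NA_real_, n, 4L)
  rss <- c(0, 0); rdf <- c(0, 0)
  for (i in seq_len(n)) {
    d <- prep$designs[[i]]
    for (oc in 1:2) {
      sel <- d$outcome_idx == oc
      t <- d$time[sel]; y <- d$y[sel]
      if (length(unique(t)) >= 2L) {
        cf <- stats::lm.fit(cbind(1, t), y)
        B[i, oc] <- cf$coefficients[1L]
        B[i, oc + 2L] <- cf$coefficients[2L]
        if (length(y) > 2L) {
          rss[oc] <- rss[oc] + sum(cf$residuals^2)
          rdf[oc] <- rdf[oc] + length(y) - 2L
        }
      } else if (length(y)) {
        B[i, oc] <- mean(y)
      }
    }
  }
  evar <- ifelse(rdf > 0, rss / rdf,
                 c(stats::var(B[, 1L], na.rm = TRUE), stats::var(B[, 2L], na.rm = TRUE)) / 2 + 1e-2)
  S <- stats::cov(B, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  # zero the cross-outcome blocks for the start
  S[1L, 2L] <- S[2L, 1L] <- 0
  S[1L, 4L] <- S[4L, 1L] <- 0
  S[2L, 3L] <- S[3L, 2L] <- 0
  S[3L, 4L] <- S[4L, 3L] <- 0
  # floor eigenvalues so the Cholesky start exists
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 1e-3 * max(e$values, 1e-2))
  S <- e$vectors %*% (lam * t(e$vectors))
  list(Sigma = S, err = list(var1 = max(evar[1L], 1e-4),
                             var2 = max(evar[2L], 1e-4), cov12 = 0))
}

#' Control parameters for [blmm()]
#'
#' @param maxit iteration cap for the BFGS optimizer (default 500).
#' @param reltol relative convergence tolerance of the optimizer.
#' @param grad_tol gradient-norm threshold used to declare clean convergence.
#' @param restarts number of Nelder-Mead + BFGS restarts attempted when the
#'   first BFGS pass does not converge.
#' @return A list of class `"blmm_control"`.
#' @export
blmm_control <- function(maxit = 500L, reltol = 1e-12, grad_tol = 1e-4,
                         restarts = 1L) {
  structure(list(maxit = maxit, reltol = reltol, grad_tol = grad_tol,
                 restarts = restarts), class = "blmm_control")
}

#' Fit the bivariate linear mixed model
#'
#' Fits, by maximum likelihood, the joint model in which each of the two
#' longitudinal outcomes follows a linear mixed model with random intercept
#' and slope, and the four random effects are linked through an unstructured
#' 4x4 covariance \eqn{\Sigma}.  Residuals are independent across outcomes,
#' or (with `error_model = "correlated"`) correlated between same-time
#' observations of the two outcomes within a subject.
#'
#' The likelihood is the marginal one (random effects integrated out); fixed
#' effects are profiled out by generalized least squares and the covariance
#' parameters are optimized over an unconstrained log-Cholesky
#' parameterization, so the returned \eqn{\Sigma} is positive semidefinite by
#' construction.  Maximum likelihood (not REML) is used so that likelihood
#' ratio tests between nested error structures (see [lrt_errors()]) are valid;
#' variance estimates are therefore slightly smaller than REML ones in small
#' samples.
#'
#' @param x a `"longitudinal_data"` object.
#' @param covariates names of baseline covariates to adjust for (entering the
#'   mean of both outcomes).
#' @param slope_covariates names of covariates additionally interacting with
#'   time (e.g. a class indicator for class-specific slopes).
#' @param error_model `"independent"` (default) or `"correlated"` residuals.
#' @param method `"ML"` (default; valid likelihood ratio tests) or `"REML"`
#'   (restricted likelihood, comparable to mixed-model software defaults;
#'   slightly larger variance estimates in small samples).
#' @param init optional starting values: a list with `Sigma` (4x4) and `err`
#'   (`var1`, `var2`, optional `cov12`).  Default: moment estimates from
#'   per-subject least-squares lines.
#' @param se compute standard errors (observed information); disable for
#'   speed in simulation loops.
#' @param control a [blmm_control()] list.
#' @return An object of class `"blmm"` with components `fixed`, `Sigma`,
#'   `err`, `loglik`, `vc` (named variance-component vector), `fixef_cov`,
#'   `vc_cov`, `converged`, `n_subjects`, `n_obs`, and the data used.
#'   Non-convergence is flagged (with a warning), not an error.
#' @examples
#' spec <- mixture_presets(n_subjects = 80, p_progressive = 0)
#' sim <- simulate_mixture(spec, seed = 1)
#' fit <- blmm(sim$data, se = FALSE)
#' ranef_correlations(fit)
#' @export
blmm <- function(x, covariates = character(), error_model = c("independent", "correlated"),
                 method = c("ML", "REML"), slope_covariates = character(),
                 init = NULL, se = TRUE, control = blmm_control()) {
  stopifnot(inherits(x, "longitudinal_data"))
  error_model <- match.arg(error_model)
  method <- match.arg(method)
  reml <- method == "REML"
  cl <- match.call()
  miss <- setdiff(union(covariates, slope_covariates), x$covariates)
  if (length(miss)) stop("not a covariate of the dataset: ", paste(miss, collapse = ", "))
  if (nrow(x$subjects) < 2L) stop("need at least 2 subjects")
  prep <- .blmm_prepare(x, covariates, error_model, slope_covariates)

  Xall <- do.call(rbind, lapply(prep$designs, `[[`, "X"))
  if (qr(Xall)$rank < prep$p)
    stop("fixed-effect design is rank deficient (collinear covariates?)")

  if (is.null(init)) init <- .blmm_init(prep)
  w0 <- .w_from_params(init$Sigma, .check_err(init$err), error_model)

  opt <- stats::optim(w0, .blmm_nll, prep = prep, reml = reml, method = "BFGS",
                      control = list(maxit = control$maxit, reltol = control$reltol))
  tries <- 0L
  while (opt$convergence != 0 && tries < control$restarts) {
    tries <- tries + 1L
    nm <- stats::optim(opt$par, .blmm_nll, prep = prep, reml = reml,
                       method = "Nelder-Mead", control = list(maxit = 2000L))
    opt <- stats::optim(nm$par, .blmm_nll, prep = prep, reml = reml,
                        method = "BFGS",
                        control = list(maxit = control$maxit, reltol = control$reltol))
  }
  w <- opt$par
  prof <- .blmm_nll(w, prep, profile = TRUE, reml = reml)
  gr <- .num_grad(function(z) .blmm_nll(z, prep, reml = reml), w)
  grad_norm <- sqrt(sum(gr^2))
  converged <- opt$convergence == 0 && is.finite(prof$nll)
  if (!converged)
    warning("blmm fit did not converge cleanly (optim code ", opt$convergence,
            ", gradient norm ", format(grad_norm, digits = 3), ")")

  Sigma <- .sigma_from_w(w)
  err <- .err_from_w(w, error_model)
  theta <- prof$theta
  names(theta) <- prep$fixed_names
  vc <- .vc_vector(Sigma, err, error_model)

  fixef_cov <- tryCatch(solve(prof$A), error = function(e) matrix(NA_real_, prep$p, prep$p))
  dimnames(fixef_cov) <- list(prep$fixed_names, prep$fixed_names)

  vc_cov <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(w, .blmm_nll, prep = prep, reml = reml),
                  error = function(e) NULL)
    covw <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(covw)) {
      J <- .num_jac(function(z) .vc_vector(.sigma_from_w(z), .err_from_w(z, error_model),
                                           error_model), w)
      vc_cov <- J %*% covw %*% t(J)
      dimnames(vc_cov) <- list(names(vc), names(vc))
    }
  }

  structure(list(
    call = cl, fixed = theta, Sigma = Sigma, err = err, vc = vc,
    loglik = -prof$nll, n_subjects = length(prep$subjects), n_obs = prep$n_obs,
    n_par = prep$p + length(w),
    fixef_cov = fixef_cov, vc_cov = vc_cov,
    converged = converged,
    opt = list(counts = opt$counts, convergence = opt$convergence,
               grad_norm = grad_norm, restarts = tries, w = w),
    method = method, error_model = error_model, covariates = covariates,
    slope_covariates = slope_covariates,
    outcomes = x$outcomes, data = x), class = "blmm")
}

.vc_vector <- function(Sigma, err, error_model) {
  v <- c(var.int1 = Sigma[1, 1], var.int2 = Sigma[2, 2],
         var.slope1 = Sigma[3, 3], var.slope2 = Sigma[4, 4],
         cov.int1.int2 = Sigma[1, 2], cov.int1.slope1 = Sigma[1, 3],
         cov.int1.slope2 = Sigma[1, 4], cov.int2.slope1 = Sigma[2, 3],
         cov.int2.slope2 = Sigma[2, 4], cov.slope1.slope2 = Sigma[3, 4],
         evar.1 = err$var1, evar.2 = err$var2)
  if (error_model == "correlated") v <- c(v, ecov.12 = err$cov12)
  v
}

.num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

.num_jac <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    J[, i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  J
}
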