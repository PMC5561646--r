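# The three correlation summaries of a fitted bivariate linear mixed model,
# plus the naive pointwise Pearson estimator.
#
# Sigma is ordered (int1, int2, slope1, slope2); the index map used below is
#   S[1,1] Var(I1)  S[2,2] Var(I2)  S[3,3] Var(S1)  S[4,4] Var(S2)
#   S[1,2] Cov(I1,I2)  S[1,3] Cov(I1,S1)  S[1,4] Cov(I1,S2)
#   S[2,3] Cov(I2,S1)  S[2,4] Cov(I2,S2)  S[3,4] Cov(S1,S2)

#' Correlation between random effects ("association of evolution")
#'
#' The correlation between the two outcomes' random intercepts and between
#' their random slopes,
#' \deqn{\rho_{int} = Cov(I_1, I_2)/\sqrt{Var(I_1) Var(I_2)}, \quad
#'       \rho_{slope} = Cov(S_1, S_2)/\sqrt{Var(S_1) Var(S_2)},}
#' the plug-in summary of how the evolution of one outcome is associated with
#' the evolution of the other.  Confidence intervals are obtained separately
#' by the clustered empirical bootstrap ([bootstrap_correlations()]).
#'
#' @param object a `"blmm"` fit, or a 4x4 random-effects covariance matrix
#'   ordered (intercept 1, intercept 2, slope 1, slope 2).
#' @return List of class `"ranef_correlations"` with `rho_intercept`,
#'   `rho_slope`.
#' @export
ranef_correlations <- function(object) {
  S <- if (inherits(object, "blmm")) object$Sigma else object
  .check_sigma(S)
  if (any(diag(S)[c(1, 2, 3, 4)] <= 0))
    stop("random-effect variances must be strictly positive")
  structure(list(
    rho_intercept = S[1, 2] / sqrt(S[1, 1] * S[2, 2]),
    rho_slope = S[3, 4] / sqrt(S[3, 3] * S[4, 4])),
    class = "ranef_correlations")
}

#' @export
print.ranef_correlations <- function(x, ...) {
  cat(sprintf("rho_intercept = %.4f, rho_slope = %.4f\n",
              x$rho_intercept, x$rho_slope))
  invisible(x)
}

#' Marginal correlation over time ("evolution of association")
#'
#' Evaluates
#' \deqn{\rho(t) = \frac{Cov(I_1,I_2) + t\,Cov(I_1,S_2) + t\,Cov(I_2,S_1) +
#'   t^2 Cov(S_1,S_2) \,[+ \sigma_{12}]}{\sqrt{Var(I_1) + 2t\,Cov(I_1,S_1) +
#'   t^2 Var(S_1) + \sigma_1^2}\sqrt{Var(I_2) + 2t\,Cov(I_2,S_2) +
#'   t^2 Var(S_2) + \sigma_2^2}},}
#' the model-implied Pearson correlation between the two outcomes at time
#' `t`; the residual covariance \eqn{\sigma_{12}} enters the numerator only
#' under the correlated-error model.  As \eqn{t \to \infty} this converges to
#' the random-slope correlation; at \eqn{t = 0} it reflects mainly the
#' random-intercept correlation diluted by measurement error.
#'
#' @param object a `"blmm"` fit.
#' @param t time(s) in years, `>= 0` (vectorized).
#' @return Numeric vector of correlations, one per time.
#' @export
marginal_correlation <- function(object, t) {
  stopifnot(inherits(object, "blmm"), all(t >= 0))
  S <- object$Sigma; e <- object$err
  num <- S[1, 2] + t * S[1, 4] + t * S[2, 3] + t^2 * S[3, 4] + e$cov12
  v1 <- S[1, 1] + 2 * t * S[1, 3] + t^2 * S[3, 3] + e$var1
  v2 <- S[2, 2] + 2 * t * S[2, 4] + t^2 * S[4, 4] + e$var2
  num / sqrt(v1 * v2)
}

#' Joint moments of outcomes and outcome-1 random coefficients
#'
#' Mean and covariance of the 4-vector
#' \eqn{(Y_1(t), Y_2(t), \gamma_0, \gamma_1)} implied by the fitted model,
#' where \eqn{\gamma_0 = Z\alpha_Z + \alpha_0 + a_0} is the subject's
#' outcome-1 intercept level and \eqn{\gamma_1 = \alpha_1 + a_1} its
#' outcome-1 slope.  This joint normal distribution is the basis of the
#' conditional-correlation parametric bootstrap.
#'
#' @param object a `"blmm"` fit.
#' @param t a single time (years).
#' @param profile optional named covariate vector (defaults to all zeros).
#' @return List with `mean` (length 4) and `cov` (4x4), ordered
#'   (Y1, Y2, gamma0, gamma1).
#' @export
joint_moments <- function(object, t, profile = NULL) {
  stopifnot(inherits(object, "blmm"), length(t) == 1L, t >= 0)
  S <- object$Sigma; e <- object$err
  eff <- .profile_effects(object, profile)
  mu <- c(Y1 = eff$int1 + eff$slope1 * t,
          Y2 = eff$int2 + eff$slope2 * t,
          gamma0 = eff$int1,
          gamma1 = eff$slope1)
  v11 <- S[1, 1] + t^2 * S[3, 3] + 2 * t * S[1, 3] + e$var1
  v22 <- S[2, 2] + t^2 * S[4, 4] + 2 * t * S[2, 4] + e$var2
  v12 <- S[1, 2] + t * S[1, 4] + t * S[2, 3] + t^2 * S[3, 4] + e$cov12
  v13 <- S[1, 1] + t * S[1, 3]
  v14 <- S[1, 3] + t * S[3, 3]
  v23 <- S[1, 2] + t * S[1, 4]
  v24 <- S[2, 3] + t * S[3, 4]
  V <- matrix(c(v11, v12, v13, v14,
                v12, v22, v23, v24,
                v13, v23, S[1, 1], S[1, 3],
                v14, v24, S[1, 3], S[3, 3]), 4, 4,
              dimnames = list(names(mu), names(mu)))
  list(mean = mu, cov = V)
}

#' Conditional marginal correlation given outcome-1 random effects
#'
#' Estimates \eqn{\rho(Y_1(t), Y_2(t) \mid \gamma_0 > c_1, \gamma_1 > c_2)},
#' the correlation between the outcomes at time `t` within the subpopulation
#' whose outcome-1 intercept level exceeds `c1` and slope exceeds `c2` (by
#' default the "stable" clinical stratum: level above -5 dB, decline slower
#' than -0.5 dB/year).  A parametric bootstrap is used: each replicate draws
#' `n_subjects` 4-vectors from the fitted joint normal of
#' \eqn{(Y_1, Y_2, \gamma_0, \gamma_1)} (one draw per covariate profile when
#' profiles are supplied), computes the Pearson correlation among the
#' qualifying draws, and the estimate is the replicate mean with a 2.5/97.5
#' percentile interval.
#'
#' @param object a `"blmm"` fit.
#' @param t a single time (years).
#' @param c1 threshold on the outcome-1 intercept level (default -5).
#' @param c2 threshold on the outcome-1 slope (default -0.5 per year).
#' @param n_subjects cohort size per replicate; defaults to the number of
#'   profiles, or to the fitted cohort size.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param profiles optional data frame of covariate profiles, one row per
#'   subject; each replicate uses every profile exactly once.
#' @param seed optional RNG seed (results are deterministic given it).
#' @param keep_replicates return the replicate correlations.
#' @return List of class `"conditional_correlation"`: `estimate`, `ci`,
#'   `n_boot`, `n_dropped` (replicates with fewer than 3 qualifying draws),
#'   `unreliable` (flag set when more than half the replicates are dropped).
#' @export
conditional_correlation <- function(object, t, c1 = -5, c2 = -0.5,
                                    n_subjects = NULL, n_boot = 10000,
                                    profiles = NULL, seed = NULL,
                                    keep_replicates = FALSE) {
  stopifnot(inherits(object, "blmm"), n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  q <- length(object$covariates)
  if (q && is.null(profiles))
    stop("fit has covariates: supply 'profiles' (one row per subject)")
  if (!is.null(profiles)) {
    profiles <- as.data.frame(profiles)
    n_subjects <- nrow(profiles)
    moms <- lapply(seq_len(n_subjects), function(i)
      joint_moments(object, t, profile = unlist(profiles[i, , drop = FALSE])))
    mu <- t(vapply(moms, `[[`, numeric(4), "mean"))
    V <- moms[[1L]]$cov
  } else {
    if (is.null(n_subjects)) n_subjects <- object$n_subjects
    jm <- joint_moments(object, t)
    mu <- matrix(jm$mean, n_subjects, 4L, byrow = TRUE)
    V <- jm$cov
  }
  if (n_subjects < 2L) stop("need at least 2 subjects per replicate")
  cholV <- chol(V + diag(1e-12, 4))

  reps <- numeric(n_boot)
  dropped <- 0L
  chunk <- max(1L, floor(2e6 / n_subjects))
  done <- 0L
  while (done < n_boot) {
    nb <- min(chunk, n_boot - done)
    ntot <- nb * n_subjects
    draws <- matrix(stats::rnorm(ntot * 4L), ntot, 4L) %*% cholV
    draws <- draws + mu[rep(seq_len(n_subjects), times = nb), ]
    grp <- rep(seq_len(nb), each = n_subjects)
    ok <- draws[, 3L] > c1 & draws[, 4L] > c2
    if (any(ok)) {
      g <- grp[ok]
      y1 <- draws[ok, 1L]; y2 <- draws[ok, 2L]
      sums <- rowsum(cbind(1, y1, y2, y1 * y1, y2 * y2, y1 * y2), g)
      n <- sums[, 1L]
      cxy <- sums[, 6L] - sums[, 2L] * sums[, 3L] / n
      vx <- sums[, 4L] - sums[, 2L]^2 / n
      vy <- sums[, 5L] - sums[, 3L]^2 / n
      r <- ifelse(n >= 3 & vx > 0 & vy > 0, cxy / sqrt(vx * vy), NA_real_)
      full <- rep(NA_real_, nb)
      full[as.integer(rownames(sums))] <- r
    } else full <- rep(NA_real_, nb)
    reps[done + seq_len(nb)] <- full
    done <- done + nb
  }
  dropped <- sum(is.na(reps))
  vals <- reps[!is.na(reps)]
  unreliable <- dropped > n_boot / 2
  if (unreliable)
    warning("more than half of the bootstrap replicates had fewer than 3 qualifying subjects")
  out <- list(estimate = mean(vals),
              ci = stats::quantile(vals, c(0.025, 0.975), names = FALSE),
              t = t, c1 = c1, c2 = c2, n_subjects = n_subjects,
              n_boot = n_boot, n_dropped = dropped, unreliable = unreliable)
  if (keep_replicates) out$replicates <- reps
  structure(out, class = "conditional_correlation")
}

#' @export
print.conditional_correlation <- function(x, ...) {
  cat(sprintf(
    "Conditional correlation at t = %g given gamma0 > %g, gamma1 > %g\n",
    x$t, x$c1, x$c2))
  cat(sprintf("  estimate %.4f, 95%% CI (%.4f, %.4f), %d/%d replicates used%s\n",
              x$estimate, x$ci[1], x$ci[2], x$n_boot - x$n_dropped, x$n_boot,
              if (x$unreliable) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Naive pointwise Pearson correlation at a visit time
#'
#' The cross-sectional Pearson correlation between the two outcomes among
#' subjects observed on both outcomes near time `t` (each outcome's nearest
#' visit within `window` years is used, since the two outcomes may sit on
#' different visit grids).  Returns `NA` when fewer than `min_n` subjects
#' qualify, mirroring the at-least-30-subjects display rule.
#'
#' @param x a `"longitudinal_data"` object.
#' @param t time(s) in years (vectorized).
#' @param window pairing half-width in years (default 0.25).
#' @param min_n minimum number of paired subjects (default 30).
#' @return Numeric vector of correlations (possibly `NA`), with the number of
#'   paired subjects in `attr(, "n")`.
#' @export
pointwise_pearson <- function(x, t, window = 0.25, min_n = 30) {
  stopifnot(inherits(x, "longitudinal_data"))
  d <- x$data
  d1 <- d[as.integer(d$outcome) == 1L, ]
  d2 <- d[as.integer(d$outcome) == 2L, ]
  s1 <- split(d1[c("time", "value")], d1$subject_id)
  s2 <- split(d2[c("time", "value")], d2$subject_id)
  both <- intersect(names(s1), names(s2))
  nearest <- function(s, tt) {
    dt <- abs(s$time - tt)
    k <- which.min(dt)
    if (length(k) && dt[k] <= window) s$value[k] else NA_real_
  }
  out <- numeric(length(t)); nn <- integer(length(t))
  for (j in seq_along(t)) {
    v1 <- vapply(s1[both], nearest, 0, tt = t[j])
    v2 <- vapply(s2[both], nearest, 0, tt = t[j])
    ok <- !is.na(v1) & !is.na(v2)
    nn[j] <- sum(ok)
    out[j] <- if (nn[j] >= min_n && stats::sd(v1[ok]) > 0 && stats::sd(v2[ok]) > 0)
      stats::cor(v1[ok], v2[ok]) else NA_real_
  }
  attr(out, "n") <- nn
  out
}

#' Correlation-versus-time curve
#'
#' Evaluates one of the three correlation summaries on a time grid and
#' returns it in a common tabular form suitable for plotting or export.
#'
#' @param object a `"blmm"` fit (flavors `"marginal"`, `"conditional"`) or a
#'   `"longitudinal_data"` object (flavor `"pointwise"`).
#' @param flavor which summary to compute.
#' @param times evaluation grid (default 0 to 7.5 years, step 0.25).
#' @param ... passed to [conditional_correlation()] (e.g. `c1`, `c2`,
#'   `n_boot`, `seed`, `profiles`) or [pointwise_pearson()] (`window`,
#'   `min_n`).
#' @return Data frame of class `"correlation_curve"` with columns `time`,
#'   `rho`, `ci_lower`, `ci_upper`, `flavor`, `n_eff`.
#' @export
correlation_curve <- function(object, flavor = c("marginal", "conditional", "pointwise"),
                              times = seq(0, 7.5, by = 0.25), ...) {
  flavor <- match.arg(flavor)
  stopifnot(!is.unsorted(times, strictly = TRUE))
  if (flavor == "marginal") {
    stopifnot(inherits(object, "blmm"))
    out <- data.frame(time = times, rho = marginal_correlation(object, times),
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      flavor = flavor, n_eff = object$n_subjects)
  } else if (flavor == "conditional") {
    stopifnot(inherits(object, "blmm"))
    rows <- lapply(times, function(tt) {
      cc <- conditional_correlation(object, tt, ...)
      data.frame(time = tt, rho = cc$estimate, ci_lower = cc$ci[1],
                 ci_upper = cc$ci[2], flavor = flavor,
                 n_eff = cc$n_boot - cc$n_dropped)
    })
    out <- do.call(rbind, rows)
  } else {
    stopifnot(inherits(object, "longitudinal_data"))
    r <- pointwise_pearson(object, times, ...)
    out <- data.frame(time = times, rho = as.numeric(r),
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      flavor = flavor, n_eff = attr(r, "n"))
  }
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Plot correlation curves
#'
#' Draws a correlation-versus-time curve with its pointwise confidence band
#' (if present); further curves can be overlaid with `add = TRUE`, giving the
#' usual marginal / conditional / pointwise overlay.
#'
#' @param x a `"correlation_curve"`.
#' @param add overlay on an existing plot.
#' @param col line color.
#' @param ylim y-axis limits.
#' @param ... passed to [graphics::lines()].
#' @export
plot.correlation_curve <- function(x, add = FALSE, col = 1, ylim = c(-0.2, 1), ...) {
  if (!add) {
    graphics::plot(NA, xlim = range(x$time), ylim = ylim,
                   xlab = "Years since index date", ylab = "Correlation")
    graphics::abline(h = 0, col = "grey80")
  }
  if (x$flavor[1] == "pointwise") {
    graphics::points(x$time, x$rho, col = col, pch = 16, ...)
  } else {
    graphics::lines(x$time, x$rho, col = col, lwd = 2, ...)
    if (any(is.finite(x$ci_lower))) {
      graphics::lines(x$time, x$ci_lower, col = col, lty = 2)
      graphics::lines(x$time, x$ci_upper, col = col, lty = 2)
    }
  }
  invisible(x)
}

# Profile-adjusted intercepts and slopes of both outcomes: the fixed
# intercept plus covariate level effects, and the fixed slope plus any
# covariate-by-time effects.
.profile_effects <- function(object, profile = NULL) {
  th <- object$fixed
  cv <- object$covariates %||% character()
  scv <- object$slope_covariates %||% character()
  need <- union(cv, scv)
  z <- stats::setNames(rep(0, length(need)), need)
  if (!is.null(profile)) {
    stopifnot(all(need %in% names(profile)))
    z[need] <- as.numeric(profile[need])
  }
  off <- function(nms, sfx) {
    if (!length(nms)) return(0)
    sum(z[nms] * th[paste0(nms, sfx)])
  }
  list(int1 = th[["int1"]] + off(cv, ".1"),
       int2 = th[["int2"]] + off(cv, ".2"),
       slope1 = th[["slope1"]] + off(scv, ":t.1"),
       slope2 = th[["slope2"]] + off(scv, ":t.2"))
}
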