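#' Specify a two-class mixture of bivariate linear mixed models
#'
#' Describes the generating model for heterogeneity experiments: a majority
#' "stable" class and a minority "progressive" class that share the
#' random-effects covariance and error law but differ in their fixed
#' intercepts and slopes.  Every subject is observed on both outcomes at
#' every grid time (a fully balanced design).
#'
#' @param fixed_stable,fixed_progressive named numeric vectors
#'   `(int1, int2, slope1, slope2)`: the class-specific fixed intercepts and
#'   slopes of the two outcomes.
#' @param Sigma 4x4 random-effects covariance ordered
#'   (intercept 1, intercept 2, slope 1, slope 2), shared by both classes.
#' @param err_var1,err_var2 residual variances of the two outcomes.
#' @param err_rho same-time residual correlation (default 0, independent
#'   errors).
#' @param p_progressive fraction of subjects in the progressive class.
#' @param times common measurement grid in years.
#' @param n_subjects number of subjects per simulated dataset.
#' @param outcomes labels for the two outcomes.
#' @return List of class `"mixture_spec"`.
#' @seealso [mixture_presets()] for the glaucoma-cohort-derived default
#'   parameter set.
#' @export
mixture_spec <- function(fixed_stable, fixed_progressive, Sigma,
                         err_var1, err_var2, err_rho = 0,
                         p_progressive = 0.05,
                         times = seq(0, 5, by = 0.5), n_subjects = 300,
                         outcomes = c("MD", "VA")) {
  nm <- c("int1", "int2", "slope1", "slope2")
  stopifnot(all(nm %in% names(fixed_stable)), all(nm %in% names(fixed_progressive)),
            err_var1 > 0, err_var2 > 0, abs(err_rho) < 1,
            p_progressive >= 0, p_progressive <= 1,
            length(times) >= 1, !is.unsorted(times, strictly = TRUE),
            n_subjects >= 2)
  .check_sigma(Sigma)
  structure(list(fixed_stable = fixed_stable[nm],
                 fixed_progressive = fixed_progressive[nm],
                 Sigma = Sigma, err_var1 = err_var1, err_var2 = err_var2,
                 err_rho = err_rho, p_progressive = p_progressive,
                 times = times, n_subjects = n_subjects, outcomes = outcomes),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Two-class mixture specification\n")
  cat(sprintf("  stable:      int (%g, %g), slope (%g, %g)\n",
              x$fixed_stable["int1"], x$fixed_stable["int2"],
              x$fixed_stable["slope1"], x$fixed_stable["slope2"]))
  cat(sprintf("  progressive: int (%g, %g), slope (%g, %g)  [fraction %g]\n",
              x$fixed_progressive["int1"], x$fixed_progressive["int2"],
              x$fixed_progressive["slope1"], x$fixed_progressive["slope2"],
              x$p_progressive))
  cat(sprintf("  residual variances %g / %g, residual correlation %g\n",
              x$err_var1, x$err_var2, x$err_rho))
  cat(sprintf("  %d subjects, %d visits on [%g, %g]\n",
              x$n_subjects, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Default mixture parameters from the glaucoma cohort analysis
#'
#' The stated generating world of the heterogeneity experiments: a stable
#' majority with MD/VA intercepts (-2, 53) and slopes (-0.2, -0.4), a
#' rapidly progressing minority with intercepts (-8, 48) and slopes
#' (-2.0, -3.0) (the rounded class-2 and class-4 latent-class profiles of
#' the cohort analysis), a shared random-effects covariance taken from the
#' fully heterogeneity-adjusted fit
#' \deqn{\Sigma = \begin{pmatrix} 1.65 & 1.13 & -0.11 & 0.13 \\
#'   1.13 & 36.5 & 0.4 & -1.13 \\ -0.11 & 0.4 & 0.09 & 0.03 \\
#'   0.13 & -1.13 & 0.03 & 0.81 \end{pmatrix}}
#' over (intercept 1, intercept 2, slope 1, slope 2), residual variances
#' 2.0 and 19.0 with independent errors, a semiannual grid t = 0, 0.5, ..., 5
#' and 300 subjects.  Under this covariance the true random-effect
#' correlations are 0.145 (intercepts) and 0.111 (slopes).
#'
#' @param ... overrides passed to [mixture_spec()] (e.g. `p_progressive`,
#'   `err_rho`, `n_subjects`).
#' @return A `"mixture_spec"`.
#' @export
mixture_presets <- function(...) {
  Sigma <- matrix(c(1.65, 1.13, -0.11, 0.13,
                    1.13, 36.5, 0.40, -1.13,
                    -0.11, 0.40, 0.09, 0.03,
                    0.13, -1.13, 0.03, 0.81), 4, 4, byrow = TRUE,
                  dimnames = list(RE_NAMES, RE_NAMES))
  args <- list(
    fixed_stable = c(int1 = -2, int2 = 53, slope1 = -0.2, slope2 = -0.4),
    fixed_progressive = c(int1 = -8, int2 = 48, slope1 = -2.0, slope2 = -3.0),
    Sigma = Sigma, err_var1 = 2.0, err_var2 = 19.0, err_rho = 0,
    p_progressive = 0.05, times = seq(0, 5, by = 0.5), n_subjects = 300)
  over <- list(...)
  args[names(over)] <- over
  do.call(mixture_spec, args)
}

#' Simulate a dataset from a two-class mixture
#'
#' Generates a balanced bivariate longitudinal dataset: each subject is
#' assigned to the stable or progressive class, receives a 4-vector of random
#' effects from \eqn{N(0, \Sigma)}, and at every grid time both outcomes are
#' observed with (possibly correlated) bivariate normal errors.
#'
#' @param spec a `"mixture_spec"`.
#' @param seed optional RNG seed (draws are deterministic given it).
#' @param fixed_count if `TRUE`, exactly `round(p_progressive * n_subjects)`
#'   subjects are progressive; if `FALSE` (default) class membership is an
#'   independent Bernoulli draw per subject.
#' @return List with `data` (a `"longitudinal_data"` carrying the class
#'   indicator as subject covariate `progressive`) and `groups`
#'   (factor of true class labels).
#' @export
simulate_mixture <- function(spec, seed = NULL, fixed_count = FALSE) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  tms <- spec$times
  k <- length(tms)

  if (fixed_count) {
    n_prog <- round(spec$p_progressive * n)
    prog <- c(rep(TRUE, n_prog), rep(FALSE, n - n_prog))
  } else {
    prog <- stats::runif(n) < spec$p_progressive
  }

  cholS <- chol(spec$Sigma + diag(1e-12, 4))
  B <- matrix(stats::rnorm(n * 4L), n, 4L) %*% cholS
  e12 <- spec$err_rho * sqrt(spec$err_var1 * spec$err_var2)
  Re <- matrix(c(spec$err_var1, e12, e12, spec$err_var2), 2, 2)
  cholE <- chol(Re)
  E <- matrix(stats::rnorm(n * k * 2L), n * k, 2L) %*% cholE

  fs <- spec$fixed_stable; fp <- spec$fixed_progressive
  int1 <- ifelse(prog, fp["int1"], fs["int1"])
  int2 <- ifelse(prog, fp["int2"], fs["int2"])
  sl1 <- ifelse(prog, fp["slope1"], fs["slope1"])
  sl2 <- ifelse(prog, fp["slope2"], fs["slope2"])

  tt <- rep(tms, times = n)
  sub <- rep(seq_len(n), each = k)
  erow <- seq_len(n * k)
  y1 <- int1[sub] + B[sub, 1L] + (sl1[sub] + B[sub, 3L]) * tt + E[erow, 1L]
  y2 <- int2[sub] + B[sub, 2L] + (sl2[sub] + B[sub, 4L]) * tt + E[erow, 2L]

  ids <- sprintf("s%04d", seq_len(n))
  df <- data.frame(
    subject_id = rep(rep(ids, each = k), 2L),
    outcome = rep(spec$outcomes, each = n * k),
    time = rep(tt, 2L),
    value = c(y1, y2),
    progressive = rep(as.numeric(prog)[sub], 2L),
    stringsAsFactors = FALSE)
  data <- longitudinal_data(df, spec$outcomes[1L], spec$outcomes[2L],
                            covariates = "progressive")
  list(data = data,
       groups = factor(ifelse(prog, "progressive", "stable"),
                       levels = c("stable", "progressive")))
}
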