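# Heterogeneity scenario experiments: how much does an unmodeled two-class
# mixture distort each correlation summary when a homogeneous bivariate
# linear mixed model is (mis)fitted to the data?

.scenario_default_levels <- list(
  A = c(0.05, 0.10, 0.15, 0.20),
  B = c(0.50, 0.75, 1.00, 1.25, 1.50),
  C = c(0.0, 0.2, 0.4, 0.6, 0.8))

# Builds the generating spec for one scenario level.
.scenario_spec <- function(scenario, level, base) {
  if (scenario == "A") {
    if (level < 0 || level > 1) stop("Scenario A levels are progressive fractions in [0, 1]")
    sp <- base; sp$p_progressive <- level
  } else if (scenario == "B") {
    if (level <= 0) stop("Scenario B levels are positive slope multipliers")
    sp <- base
    sp$p_progressive <- 0.05
    sp$fixed_progressive[c("slope1", "slope2")] <-
      level * base$fixed_progressive[c("slope1", "slope2")]
  } else if (scenario == "C") {
    if (abs(level) >= 1) stop("Scenario C levels are residual correlations in (-1, 1)")
    sp <- base
    sp$p_progressive <- 0.05
    sp$err_rho <- level
  } else stop("unknown scenario '", scenario, "' (use \"A\", \"B\" or \"C\")")
  sp
}

#' Run a heterogeneity scenario experiment
#'
#' Monte-Carlo study of the distortion of the correlation summaries when the
#' population is a two-class mixture but a homogeneous model is fitted.  Per
#' level of the chosen scenario, `n_replicates` datasets are generated from
#' the mixture, the independent-error bivariate linear mixed model is fitted
#' to each *without* any class covariate, and the random-effect correlations
#' (and optionally the marginal and conditional correlation curves) are
#' recorded; the report gives replicate means with 2.5/97.5 percentile bands.
#'
#' Scenarios:
#' \describe{
#'   \item{A (size of heterogeneity)}{levels are progressive-class fractions
#'     (default 0.05, 0.10, 0.15, 0.20).}
#'   \item{B (magnitude of heterogeneity)}{levels multiply both progressive
#'     slopes, at a fixed 5% progressive fraction (default 0.5 ... 1.5).}
#'   \item{C (correlated errors)}{levels are generating residual correlations
#'     at a 5% progressive fraction; the fit still assumes independent errors
#'     (default 0 ... 0.8).}
#' }
#'
#' Progressive-class sizes are fixed counts (`round(level * n_subjects)`)
#' rather than binomial draws, removing one source of between-replicate
#' variance.  One master seed spawns an independent substream per level and
#' replicate, so any level is reproducible on its own.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param levels scenario levels; defaults above.
#' @param n_replicates datasets per level (500 in the full experiment;
#'   smaller values are fine for exploration).
#' @param seed master RNG seed.
#' @param base_spec the generating `"mixture_spec"` before the scenario
#'   modification (default [mixture_presets()]).
#' @param curves also record marginal and conditional correlation curves per
#'   replicate (slower).
#' @param curve_times time grid used when `curves = TRUE`.
#' @param n_boot_conditional parametric-bootstrap replicates per conditional
#'   curve point when `curves = TRUE`.
#' @param c1,c2 conditioning thresholds for the conditional curve.
#' @return List of class `"scenario_result"`: `summary` (one row per level:
#'   mean and percentile band of each random-effect correlation), per-level
#'   replicate matrices in `replicates`, average curves in `curves` (when
#'   requested), and the run metadata.
#' @examples
#' \donttest{
#' res <- run_scenario("A", levels = 0.2, n_replicates = 5, seed = 1)
#' res$summary
#' }
#' @export
run_scenario <- function(scenario = c("A", "B", "C"), levels = NULL,
                         n_replicates = 500, seed = NULL,
                         base_spec = mixture_presets(), curves = FALSE,
                         curve_times = seq(0, 5, by = 0.5),
                         n_boot_conditional = 500, c1 = -5, c2 = -0.5) {
  scenario <- match.arg(scenario)
  if (is.null(levels)) levels <- .scenario_default_levels[[scenario]]
  stopifnot(n_replicates >= 1)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  set.seed(seed)
  # independent, reproducible substream seeds per (level, replicate)
  seed_mat <- matrix(sample.int(2^31 - 2, length(levels) * n_replicates),
                     nrow = n_replicates)

  rep_list <- list(); curve_list <- list()
  sum_rows <- list()
  for (li in seq_along(levels)) {
    lev <- levels[li]
    sp <- .scenario_spec(scenario, lev, base_spec)
    reps <- matrix(NA_real_, n_replicates, 2L,
                   dimnames = list(NULL, c("rho_intercept", "rho_slope")))
    marg <- if (curves) matrix(NA_real_, n_replicates, length(curve_times)) else NULL
    cond <- if (curves) matrix(NA_real_, n_replicates, length(curve_times)) else NULL
    n_fail <- 0L
    for (r in seq_len(n_replicates)) {
      sim <- simulate_mixture(sp, seed = seed_mat[r, li], fixed_count = TRUE)
      fit <- tryCatch(
        withCallingHandlers(
          blmm(sim$data, error_model = "independent", se = FALSE),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { n_fail <- n_fail + 1L; next }
      rc <- ranef_correlations(fit)
      reps[r, ] <- c(rc$rho_intercept, rc$rho_slope)
      if (curves) {
        marg[r, ] <- marginal_correlation(fit, curve_times)
        cond[r, ] <- vapply(curve_times, function(tt)
          conditional_correlation(fit, tt, c1 = c1, c2 = c2,
                                  n_boot = n_boot_conditional,
                                  seed = seed_mat[r, li] + 1L)$estimate,
          numeric(1))
      }
    }
    if (n_fail > 0.1 * n_replicates)
      warning(sprintf("scenario %s level %g: %d of %d replicate fits failed",
                      scenario, lev, n_fail, n_replicates))
    ok <- stats::complete.cases(reps)
    qs <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975))
    sum_rows[[li]] <- data.frame(
      scenario = scenario, level = lev,
      rho_intercept = mean(reps[ok, 1L]),
      rho_intercept_lo = qs[1L, 1L], rho_intercept_hi = qs[2L, 1L],
      rho_slope = mean(reps[ok, 2L]),
      rho_slope_lo = qs[1L, 2L], rho_slope_hi = qs[2L, 2L],
      n_replicates = sum(ok), n_fail = n_fail)
    rep_list[[as.character(lev)]] <- reps
    if (curves)
      curve_list[[as.character(lev)]] <- data.frame(
        time = curve_times,
        marginal = colMeans(marg[ok, , drop = FALSE]),
        conditional = colMeans(cond[ok, , drop = FALSE]))
  }
  structure(list(summary = do.call(rbind, sum_rows), replicates = rep_list,
                 curves = if (curves) curve_list else NULL,
                 scenario = scenario, levels = levels,
                 n_replicates = n_replicates, seed = seed,
                 base_spec = base_spec),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Heterogeneity scenario %s (%d replicates per level, seed %d)\n",
              x$scenario, x$n_replicates, x$seed))
  s <- x$summary
  fmt <- function(m, lo, hi) sprintf("%.3f (%.3f, %.3f)", m, lo, hi)
  out <- data.frame(level = s$level,
                    `rho intercepts` = fmt(s$rho_intercept, s$rho_intercept_lo,
                                           s$rho_intercept_hi),
                    `rho slopes` = fmt(s$rho_slope, s$rho_slope_lo, s$rho_slope_hi),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' True random-effect correlations of a mixture specification
#'
#' The no-heterogeneity reference values implied by the shared covariance
#' \eqn{\Sigma} of a [mixture_spec()] (0.145 and 0.111 for the default
#' presets).
#'
#' @param spec a `"mixture_spec"`.
#' @export
true_correlations <- function(spec = mixture_presets()) {
  stopifnot(inherits(spec, "mixture_spec"))
  ranef_correlations(spec$Sigma)
}
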