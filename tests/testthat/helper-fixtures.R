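# Shared fixture builders.  Everything is generated in code; no files.

# Minimal valid long data frame: one subject, both outcomes, two visits each.
tiny_long_df <- function() {
  data.frame(
    subject_id = "s1",
    outcome = c("MD", "MD", "VA", "VA"),
    time = c(0, 0.5, 0, 1),
    value = c(-2, -2.5, 51, 50),
    stringsAsFactors = FALSE)
}

# A small homogeneous simulated dataset (stable class only).
small_sim <- function(n = 80, seed = 1, times = seq(0, 5, by = 0.5), p = 0) {
  simulate_mixture(mixture_presets(n_subjects = n, p_progressive = p,
                                   times = times), seed = seed)
}

# A hand-built "fitted model" carrying known parameters, for exercising the
# correlation formulas without an actual optimization.
fake_fit <- function(Sigma = mixture_presets()$Sigma,
                     err = list(var1 = 2, var2 = 19, cov12 = 0),
                     fixed = c(int1 = -2, slope1 = -0.2, int2 = 53, slope2 = -0.4),
                     n_subjects = 300) {
  structure(list(
    fixed = fixed, Sigma = Sigma,
    err = list(var1 = err$var1, var2 = err$var2, cov12 = err$cov12 %||% 0),
    loglik = NA_real_, n_subjects = n_subjects, n_obs = NA_integer_,
    converged = TRUE,
    error_model = if ((err$cov12 %||% 0) != 0) "correlated" else "independent",
    covariates = character(), outcomes = c("MD", "VA")),
    class = c("blmm_lite", "blmm"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sigma used by the primary-analysis arithmetic checks (bivariate column of
# the variance-component table): I1/I2/S1/S2 variances and all covariances.
primary_sigma <- function() {
  matrix(c(5.09, 3.88, 0.63, 1.16,
           3.88, 38.77, 0.67, -0.73,
           0.63, 0.67, 0.29, 0.37,
           1.16, -0.73, 0.37, 1.35), 4, 4, byrow = TRUE,
         dimnames = list(c("int1", "int2", "slope1", "slope2"),
                         c("int1", "int2", "slope1", "slope2")))
}
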