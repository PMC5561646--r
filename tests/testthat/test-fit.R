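# Estimation checks.  Sample sizes are kept moderate so the whole file runs
# in well under a minute; the heavier N = 2000 recovery run lives in the
# acceptance suite.

test_that("fit matches an independent mixed-model implementation (nlme oracle)", {
  sim <- small_sim(n = 60, seed = 7)
  fit <- blmm(sim$data, se = FALSE)
  df <- as.data.frame(sim$data)
  df$o1 <- as.numeric(df$outcome == "MD"); df$o2 <- 1 - df$o1
  lf <- nlme::lme(value ~ 0 + o1 + o1:time + o2 + o2:time,
                  random = ~ 0 + o1 + o2 + o1:time + o2:time | subject_id,
                  weights = nlme::varIdent(form = ~ 1 | outcome),
                  data = df, method = "ML",
                  control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                             opt = "optim"))
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  ef <- nlme::fixef(lf)
  expect_equal(unname(fit$fixed),
               unname(ef[c("o1", "o1:time", "o2", "time:o2")]),
               tolerance = 1e-4)
  vc <- matrix(as.numeric(nlme::getVarCov(lf)), 4, 4)[c(1, 2, 3, 4), c(1, 2, 3, 4)]
  # nlme's own optimizer tolerance limits the agreement on Sigma
  expect_lt(max(abs(fit$Sigma - vc)), 0.05)
})

test_that("data generated with Sigma = 0 yield near-zero fitted covariances", {
  spec <- mixture_presets(n_subjects = 400, p_progressive = 0)
  spec$Sigma <- matrix(0, 4, 4)
  sim <- simulate_mixture(spec, seed = 11)
  fit <- suppressWarnings(blmm(sim$data, se = FALSE))
  # judge on the residual-variance scale: the likelihood is flat in random
  # intercept variances that are a small fraction of the error variance
  sc <- sqrt(c(2, 19, 2, 19))
  expect_lt(max(abs(fit$Sigma / outer(sc, sc))), 0.05)
  expect_equal(unname(fit$fixed), c(-2, -0.2, 53, -0.4), tolerance = 0.1)
  expect_equal(fit$err$var1, 2, tolerance = 0.1)
  expect_equal(fit$err$var2, 19, tolerance = 0.8)
})

test_that("fitted optimum dominates the generating parameters (ML property)", {
  fixed <- c(int1 = -2, slope1 = -0.2, int2 = 53, slope2 = -0.4)
  S <- mixture_presets()$Sigma
  wins <- 0L
  for (r in 1:8) {
    sim <- small_sim(n = 40, seed = 100 + r, times = c(0, 1, 2, 3))
    fit <- suppressWarnings(blmm(sim$data, se = FALSE))
    ll_true <- marginal_loglik(sim$data, fixed, S, list(var1 = 2, var2 = 19))
    expect_true(fit$converged)
    # fitted Sigma must be symmetric PSD on every replicate
    ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(fit$Sigma)))
    if (fit$loglik >= ll_true - 1e-8) wins <- wins + 1L
  }
  expect_gte(wins, 8L * 0.95)
})

test_that("distinct initializations reach the same optimum", {
  sim <- small_sim(n = 50, seed = 13)
  f1 <- blmm(sim$data, se = FALSE)
  truth <- list(Sigma = mixture_presets()$Sigma, err = list(var1 = 2, var2 = 19))
  f2 <- blmm(sim$data, se = FALSE, init = truth)
  set.seed(77)
  pert <- list(Sigma = diag(c(4, 20, 0.5, 2)), err = list(var1 = 5, var2 = 5))
  f3 <- blmm(sim$data, se = FALSE, init = pert)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-4)
  expect_equal(f1$vc, f2$vc, tolerance = 1e-2)
  expect_equal(f1$vc, f3$vc, tolerance = 1e-2)
})

test_that("the correlated-error fit never falls below the nested independent fit", {
  for (rho in c(0, 0.5)) {
    sim <- simulate_mixture(mixture_presets(n_subjects = 60, p_progressive = 0,
                                            err_rho = rho), seed = 21)
    f0 <- blmm(sim$data, se = FALSE)
    f1 <- blmm(sim$data, error_model = "correlated", se = FALSE)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
  }
})

test_that("correlated-error data fitted as independent inflate slope covariances", {
  # the distortion pattern behind the Scenario C experiment: residual
  # correlation ignored by the fit is absorbed into the random effects
  spec <- mixture_presets(n_subjects = 400, p_progressive = 0, err_rho = 0.8)
  sim <- simulate_mixture(spec, seed = 31)
  fit <- blmm(sim$data, se = FALSE)
  truth <- mixture_presets()$Sigma
  expect_gt(fit$Sigma[3, 4], truth[3, 4] + 0.02)   # Cov(S1,S2) pushed up
  rc <- ranef_correlations(fit)
  expect_gt(rc$rho_slope, 0.3)                     # far above the true 0.111
})

test_that("standard errors come from the observed information and REML runs", {
  sim <- small_sim(n = 60, seed = 17)
  fit <- blmm(sim$data)                 # se = TRUE
  expect_true(all(is.finite(sqrt(diag(fit$fixef_cov)))))
  expect_true(all(diag(fit$vc_cov) >= 0))
  expect_equal(dim(vcov(fit)), c(16L, 16L))
  frml <- blmm(sim$data, method = "REML", se = FALSE)
  expect_true(frml$converged)
  # REML and ML agree closely at this size; REML variances are >= typically
  expect_equal(frml$vc, fit$vc, tolerance = 0.08)
})

test_that("rank-deficient designs and undersized data are rejected", {
  sim <- small_sim(n = 10, seed = 19)
  x <- sim$data
  x$subjects$dup <- x$subjects$progressive
  x$covariates <- c("progressive", "dup")
  expect_error(blmm(x, covariates = c("progressive", "dup")), "rank deficient")
  one <- x
  one$data <- one$data[one$data$subject_id == "s0001", ]
  one$subjects <- one$subjects[1, , drop = FALSE]
  expect_error(blmm(one), "at least 2 subjects")
})
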