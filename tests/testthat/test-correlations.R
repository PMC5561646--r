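test_that("random-effect correlations reproduce the preset and primary-analysis arithmetic", {
  # heterogeneity-adjusted covariance preset: 0.145 / 0.111
  rc <- ranef_correlations(mixture_presets()$Sigma)
  # exact arithmetic gives 0.14558 and 0.11111; the published table shows
  # 0.145/0.111 (its 0.145 was evidently computed from unrounded variances)
  expect_equal(rc$rho_intercept, 1.13 / sqrt(1.65 * 36.5), tolerance = 1e-12)
  expect_equal(rc$rho_slope, 0.03 / sqrt(0.09 * 0.81), tolerance = 1e-12)
  expect_lt(abs(rc$rho_intercept - 0.145), 0.001)
  expect_lt(abs(rc$rho_slope - 0.111), 0.001)

  # primary-analysis column: Cov(I1,I2)/sqrt(Var(I1) Var(I2)) = 0.276,
  # consistent with the reported bootstrap-averaged 0.278
  rp <- ranef_correlations(primary_sigma())
  expect_equal(rp$rho_intercept, 3.88 / sqrt(5.09 * 38.77), tolerance = 1e-12)
  expect_equal(round(rp$rho_intercept, 3), 0.276)
  expect_lt(abs(rp$rho_intercept - 0.278), 0.01)

  # diagonal covariance: both correlations vanish
  r0 <- ranef_correlations(diag(c(1, 2, 3, 4)))
  expect_equal(r0$rho_intercept, 0)
  expect_equal(r0$rho_slope, 0)

  expect_error(ranef_correlations(diag(c(0, 1, 1, 1))), "strictly positive")
})

test_that("marginal correlation follows the closed form and its limits", {
  fit <- fake_fit(Sigma = primary_sigma(), err = list(var1 = 2.02, var2 = 19.19))
  # t = 0 hand evaluation: 3.88 / (sqrt(7.11) * sqrt(57.96))
  expect_equal(marginal_correlation(fit, 0),
               3.88 / (sqrt(5.09 + 2.02) * sqrt(38.77 + 19.19)),
               tolerance = 1e-12)
  expect_equal(round(marginal_correlation(fit, 0), 3), 0.191)

  # convergence to the slope correlation far from baseline
  pre <- fake_fit()
  expect_lt(abs(marginal_correlation(pre, 1e4) -
                  ranef_correlations(pre)$rho_slope), 1e-3)

  # exact consistency with the joint-moment matrix at t = 0
  jm <- joint_moments(pre, 0)
  expect_equal(marginal_correlation(pre, 0),
               jm$cov[1, 2] / sqrt(jm$cov[1, 1] * jm$cov[2, 2]), tolerance = 1e-14)

  # no cross-outcome covariance, no residual covariance: zero everywhere
  S0 <- mixture_presets()$Sigma
  S0[1, 2] <- S0[2, 1] <- S0[1, 4] <- S0[4, 1] <- 0
  S0[2, 3] <- S0[3, 2] <- S0[3, 4] <- S0[4, 3] <- 0
  f0 <- fake_fit(Sigma = S0)
  expect_equal(marginal_correlation(f0, c(0, 1, 5, 50)), rep(0, 4))

  # the residual covariance enters only under the correlated-error model
  fc <- fake_fit(err = list(var1 = 2, var2 = 19, cov12 = 1.2))
  fi <- fake_fit()
  expect_equal(marginal_correlation(fc, 1) - marginal_correlation(fi, 1),
               1.2 / sqrt((1.65 + 2 * -0.11 + 0.09 + 2) *
                            (36.5 + 2 * -1.13 + 0.81 + 19)), tolerance = 1e-12)

  # bounds always hold
  expect_true(all(abs(marginal_correlation(pre, seq(0, 100, 0.5))) <= 1))
})

test_that("joint moments match the stated covariance entries", {
  pre <- fake_fit()
  S <- pre$Sigma
  jm0 <- joint_moments(pre, 0)
  expect_equal(jm0$cov[1, 3], S[1, 1])          # nu13(0) = Var(I1)
  expect_equal(jm0$cov[1, 4], S[1, 3])          # nu14(0) = Cov(I1,S1)
  expect_equal(jm0$cov[1, 1], S[1, 1] + 2)      # nu11(0) = Var(I1) + evar1
  expect_equal(jm0$cov[3, 3], S[1, 1])
  expect_equal(jm0$cov[4, 4], S[3, 3])
  expect_equal(unname(jm0$mean), c(-2, 53, -2, -0.2))

  # hand arithmetic at t = 1: nu12(1) = 1.13 + 0.13 + 0.40 + 0.03 = 1.69
  jm1 <- joint_moments(pre, 1)
  expect_equal(jm1$cov[1, 2], 1.69, tolerance = 1e-12)

  # moment matrix against an elementwise simulation at t = 1
  set.seed(5)
  n <- 2e5
  b <- matrix(rnorm(n * 4), n, 4) %*% chol(S)
  e1 <- rnorm(n, 0, sqrt(2)); e2 <- rnorm(n, 0, sqrt(19))
  y1 <- -2 + b[, 1] + (-0.2 + b[, 3]) * 1 + e1
  y2 <- 53 + b[, 2] + (-0.4 + b[, 4]) * 1 + e2
  g0 <- -2 + b[, 1]; g1 <- -0.2 + b[, 3]
  emp <- cov(cbind(y1, y2, g0, g1))
  # entrywise 3-MC-SE bound: Var(s_ij) = (v_ii v_jj + v_ij^2) / n
  V <- jm1$cov
  tolM <- 3 * sqrt((outer(diag(V), diag(V)) + V^2) / n)
  expect_true(all(abs(emp - V) <= tolM))
  # and the marginal correlation formula agrees with the empirical Pearson
  se_r <- (1 - marginal_correlation(pre, 1)^2) / sqrt(n)
  expect_lt(abs(cor(y1, y2) - marginal_correlation(pre, 1)), 3 * se_r + 1e-4)
})

test_that("conditional correlation collapses to the marginal one without truncation", {
  pre <- fake_fit(n_subjects = 300)
  for (tt in c(0, 2)) {
    cc <- conditional_correlation(pre, tt, c1 = -Inf, c2 = -Inf,
                                  n_boot = 3000, seed = 8)
    expect_equal(cc$estimate, marginal_correlation(pre, tt), tolerance = 0.01)
    expect_equal(cc$n_dropped, 0L)
  }
})

test_that("conditional correlation matches a single-pass truncated-normal oracle", {
  pre <- fake_fit(n_subjects = 300)
  tt <- 2
  cc <- conditional_correlation(pre, tt, c1 = -5, c2 = -0.5,
                                n_boot = 4000, seed = 12)
  # brute force: one large draw from the joint normal, truncate, correlate
  set.seed(99)
  jm <- joint_moments(pre, tt)
  n <- 1e6
  dr <- matrix(rnorm(n * 4), n, 4) %*% chol(jm$cov)
  dr <- sweep(dr, 2, jm$mean, "+")
  keep <- dr[, 3] > -5 & dr[, 4] > -0.5
  oracle <- cor(dr[keep, 1], dr[keep, 2])
  # finite-cohort Pearson bias is O(1/n_subjects); allow that plus MC error
  expect_lt(abs(cc$estimate - oracle), 0.01)
  expect_true(cc$ci[1] <= cc$estimate && cc$estimate <= cc$ci[2])
})

test_that("independence of outcome 2 from outcome 1 survives selection", {
  S0 <- mixture_presets()$Sigma
  S0[1, 2] <- S0[2, 1] <- S0[1, 4] <- S0[4, 1] <- 0
  S0[2, 3] <- S0[3, 2] <- S0[3, 4] <- S0[4, 3] <- 0
  f0 <- fake_fit(Sigma = S0, n_subjects = 300)
  cc <- conditional_correlation(f0, 1, n_boot = 2000, seed = 3)
  expect_lt(abs(cc$estimate), 0.01)
})

test_that("replicates with too few qualifying subjects are dropped and flagged", {
  pre <- fake_fit(n_subjects = 10)
  # thresholds excluding essentially everyone
  expect_warning(
    cc <- conditional_correlation(pre, 1, c1 = 5, c2 = 2, n_boot = 200, seed = 4),
    "fewer than 3 qualifying")
  expect_true(cc$unreliable)
  expect_gt(cc$n_dropped, 100)
})

test_that("pointwise Pearson respects the minimum-subject rule and the textbook formula", {
  # perfectly linearly related pairs
  n <- 35
  df <- data.frame(
    subject_id = rep(sprintf("p%02d", 1:n), each = 2),
    outcome = rep(c("MD", "VA"), n),
    time = 1, value = NA_real_)
  vals <- seq_len(n)
  df$value[df$outcome == "MD"] <- vals
  df$value[df$outcome == "VA"] <- 3 * vals + 2
  x <- longitudinal_data(df, "MD", "VA")
  expect_equal(pointwise_pearson(x, 1), 1, tolerance = 1e-12,
               ignore_attr = TRUE)

  # 29 paired subjects: below the default threshold, missing
  x29 <- x
  keep <- !(x29$data$subject_id %in% sprintf("p%02d", 1:6))
  x29$data <- x29$data[keep, ]
  r29 <- pointwise_pearson(x29, 1)
  expect_true(is.na(r29))
  expect_equal(attr(r29, "n"), 29L)

  # random 50-pair fixture against the product-moment formula
  set.seed(6)
  n <- 50
  v1 <- rnorm(n); v2 <- 0.5 * v1 + rnorm(n)
  df2 <- data.frame(
    subject_id = rep(sprintf("q%02d", 1:n), each = 2),
    outcome = rep(c("MD", "VA"), n),
    time = rep(c(2.1, 1.9), n),          # within the 0.25-year window of t = 2
    value = as.vector(rbind(v1, v2)))
  x2 <- longitudinal_data(df2, "MD", "VA")
  num <- sum((v1 - mean(v1)) * (v2 - mean(v2)))
  den <- sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(pointwise_pearson(x2, 2), num / den, tolerance = 1e-12,
               ignore_attr = TRUE)
  # outside the window nothing pairs
  expect_true(is.na(pointwise_pearson(x2, 3)))
})

test_that("correlation curves share a common tabular form", {
  pre <- fake_fit(n_subjects = 50)
  mc <- correlation_curve(pre, "marginal", times = seq(0, 5, 1))
  expect_s3_class(mc, "correlation_curve")
  expect_equal(mc$rho, marginal_correlation(pre, seq(0, 5, 1)))
  cc <- correlation_curve(pre, "conditional", times = c(0, 2), n_boot = 300,
                          seed = 2)
  expect_true(all(cc$ci_lower <= cc$rho & cc$rho <= cc$ci_upper))
  sim <- small_sim(n = 40, seed = 15, times = c(0, 1, 2))
  pc <- correlation_curve(sim$data, "pointwise", times = c(0, 1, 2), min_n = 10)
  expect_equal(names(pc), c("time", "rho", "ci_lower", "ci_upper", "flavor", "n_eff"))
  expect_true(all(abs(pc$rho) <= 1, na.rm = TRUE))
})
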