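test_that("construction and CSV reading validate the long format", {
  x <- longitudinal_data(tiny_long_df(), "MD", "VA")
  expect_s3_class(x, "longitudinal_data")
  expect_equal(nrow(x$subjects), 1L)
  expect_equal(as.integer(table(x$data$outcome)), c(2L, 2L))

  tf <- tempfile(fileext = ".csv")
  write.csv(tiny_long_df(), tf, row.names = FALSE)
  x2 <- read_long_csv(tf, "MD", "VA", quiet = TRUE)
  expect_equal(x2$data$value, x$data$value)

  # error paths: missing column, unknown label, duplicate visit
  bad <- tiny_long_df(); names(bad)[4] <- "measurement"
  expect_error(longitudinal_data(bad, "MD", "VA"), "missing required column")
  expect_error(longitudinal_data(tiny_long_df(), "MD", "IOP"), "unknown outcome")
  dup <- rbind(tiny_long_df(), tiny_long_df()[1, ])
  expect_error(longitudinal_data(dup, "MD", "VA"), "duplicate")
})

test_that("simulator output round-trips through write/read unchanged", {
  sim <- small_sim(n = 12, seed = 3, p = 0.25)
  tf <- tempfile(fileext = ".csv")
  write_long_csv(sim$data, tf)
  back <- read_long_csv(tf, "MD", "VA", covariates = "progressive", quiet = TRUE)
  expect_equal(back$data$value, sim$data$data$value)
  expect_equal(back$data$time, sim$data$data$time)
  expect_equal(back$subjects$progressive, sim$data$subjects$progressive)
})

test_that("covariate standardization uses the n-1 convention and inverts exactly", {
  df <- rbind(
    transform(tiny_long_df(), subject_id = "s1", age = 60),
    transform(tiny_long_df(), subject_id = "s2", age = 70))
  x <- longitudinal_data(df, "MD", "VA", covariates = "age")
  xs <- standardize_covariates(x, "age")
  # two subjects, sd = sqrt(50) with the n-1 denominator -> +-1/sqrt(2)
  expect_equal(sort(xs$subjects$age), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(mean(xs$subjects$age), 0, tolerance = 1e-12)
  expect_equal(var(xs$subjects$age), 1, tolerance = 1e-12)

  # fixed point: standardizing an already standardized covariate is a no-op
  xss <- standardize_covariates(xs, "age")
  expect_equal(xss$subjects$age, xs$subjects$age, tolerance = 1e-12)

  # inverse transform recovers the original values
  back <- unstandardize_covariates(xs)
  expect_equal(back$subjects$age, x$subjects$age, tolerance = 1e-10)

  # degenerate input: zero variance
  df0 <- transform(df, age = 65)
  x0 <- longitudinal_data(df0, "MD", "VA", covariates = "age")
  expect_error(standardize_covariates(x0, "age"), "zero variance")
})

test_that("mean-0/var-1 postcondition holds on simulated covariates", {
  set.seed(42)
  n <- 40
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    transform(tiny_long_df(), subject_id = sprintf("s%02d", i),
              age = rnorm(1, 65, 10), iop = rnorm(1, 22, 5))))
  x <- standardize_covariates(
    longitudinal_data(df, "MD", "VA", covariates = c("age", "iop")))
  for (cv in c("age", "iop")) {
    expect_equal(mean(x$subjects[[cv]]), 0, tolerance = 1e-12)
    expect_equal(var(x$subjects[[cv]]), 1, tolerance = 1e-12)
  }
})

test_that("cohort filter enforces follow-up, per-subject counts, and is idempotent", {
  sim <- small_sim(n = 8, seed = 9)
  x <- sim$data
  # all observations are within 7.5 years: a no-op
  f1 <- apply_cohort_filter(x)
  expect_equal(f1$data$value, x$data$value)
  expect_equal(filter_report(f1)$n_obs_past_followup, 0L)

  # one observation pushed past the cap is removed and reported
  x2 <- x
  x2$data$time[which.max(x2$data$time)] <- 8.0
  f2 <- apply_cohort_filter(x2)
  expect_equal(nrow(f2$data), nrow(x2$data) - 1L)
  expect_equal(filter_report(f2)$n_obs_past_followup, 1L)

  # a subject reduced to a single visit per outcome is excluded
  x3 <- x
  keep <- !(x3$data$subject_id == "s0001" & x3$data$time > 0)
  x3$data <- x3$data[keep, ]
  f3 <- apply_cohort_filter(x3)
  expect_false("s0001" %in% f3$data$subject_id)
  expect_equal(filter_report(f3)$excluded_subjects, "s0001")

  # idempotence
  f2b <- apply_cohort_filter(f2)
  expect_equal(f2b$data, f2$data)
  expect_equal(filter_report(f2b)$n_obs_excluded, filter_report(f2)$n_obs_excluded)

  # sparse visit times are flagged, not deleted (8 subjects < default 30)
  expect_equal(filter_report(f1)$sparse_times$MD, sort(unique(x$data$time)))
  # a 300-subject balanced design has no sparse times
  big <- small_sim(n = 300, seed = 1, times = c(0, 1, 2))
  fb <- apply_cohort_filter(big$data)
  expect_length(filter_report(fb)$sparse_times$MD, 0)
  expect_length(filter_report(fb)$sparse_times$VA, 0)
})
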