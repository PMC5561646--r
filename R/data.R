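#' Construct a longitudinal two-outcome dataset
#'
#' Builds the long-format container used by every other function in the
#' package: one row per subject x outcome x visit, with exactly two declared
#' outcomes (e.g. mean deviation and visual acuity in a glaucoma cohort) and
#' optional subject-level baseline covariates.
#'
#' The two outcomes may sit on different visit grids (e.g. semiannual and
#' annual); no balance between them is required.  Within a subject-outcome
#' pair visit times must be unique; rows are stored sorted by subject,
#' outcome, time.  Covariates must be constant within subject.
#'
#' @param data data frame with columns `subject_id`, `outcome`, `time`,
#'   `value`, plus one column per covariate.
#' @param outcome1,outcome2 names of the two outcome labels in `outcome`.
#'   `outcome1` is the outcome whose random intercept/slope is conditioned on
#'   by [conditional_correlation()].
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return An object of class `"longitudinal_data"`: the validated long data
#'   frame in `$data`, subject-level covariates in `$subjects`, outcome names
#'   in `$outcomes`.
#' @seealso [read_long_csv()], [standardize_covariates()],
#'   [apply_cohort_filter()]
#' @examples
#' d <- data.frame(subject_id = 1, outcome = c("MD", "MD", "VA", "VA"),
#'                 time = c(0, 0.5, 0, 1), value = c(-2, -2.5, 51, 50))
#' longitudinal_data(d, "MD", "VA")
#' @export
longitudinal_data <- function(data, outcome1, outcome2, covariates = character()) {
  req <- c("subject_id", "outcome", "time", "value")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (identical(outcome1, outcome2))
    stop("the two outcome names must differ")
  labs <- unique(as.character(data$outcome))
  unknown <- setdiff(labs, c(outcome1, outcome2))
  if (length(unknown))
    stop("unknown outcome label(s): ", paste(unknown, collapse = ", "),
         " (declared: ", outcome1, ", ", outcome2, ")")
  if (!is.numeric(data$time) || anyNA(data$time))
    stop("'time' must be numeric and non-missing")
  if (any(data$time < 0))
    stop("'time' must be >= 0 (years since index date)")
  if (!is.numeric(data$value) || anyNA(data$value))
    stop("'value' must be numeric and non-missing")

  data$subject_id <- as.character(data$subject_id)
  data$outcome <- factor(as.character(data$outcome), levels = c(outcome1, outcome2))
  key <- paste(data$subject_id, data$outcome, data$time, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- data[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (subject, outcome, time) row: (%s, %s, %g)",
                 dup$subject_id, as.character(dup$outcome), dup$time))
  }
  ord <- order(data$subject_id, as.integer(data$outcome), data$time)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  # subject-level covariate table; covariates must not vary within subject
  sid <- unique(data$subject_id)
  subjects <- data.frame(subject_id = sid, stringsAsFactors = FALSE)
  for (cv in covariates) {
    v <- data[[cv]]
    if (anyNA(v))
      stop("covariate '", cv, "' contains missing values; drop or complete these subjects")
    per <- tapply(v, data$subject_id, function(x) length(unique(x)))
    if (any(per > 1L))
      stop("covariate '", cv, "' varies within subject (must be baseline-constant)")
    subjects[[cv]] <- as.numeric(tapply(v, data$subject_id, `[`, 1L)[sid])
  }

  structure(
    list(data = data[, c("subject_id", "outcome", "time", "value")],
         subjects = subjects,
         outcomes = c(outcome1, outcome2),
         covariates = covariates,
         scaling = NULL),
    class = "longitudinal_data")
}

#' Read a long-format two-outcome CSV
#'
#' Reads a UTF-8 CSV with header columns `subject_id,outcome,time,value`
#' plus optional covariate columns, and validates it via
#' [longitudinal_data()].
#'
#' @param path CSV file path.
#' @param outcome1,outcome2 the two outcome labels expected in the `outcome`
#'   column.
#' @param covariates character vector of covariate column names to attach.
#' @param quiet suppress the per-outcome row-count message.
#' @return A `"longitudinal_data"` object.
#' @export
read_long_csv <- function(path, outcome1, outcome2, covariates = character(),
                          quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  x <- longitudinal_data(df, outcome1, outcome2, covariates)
  if (!quiet) {
    n <- table(x$data$outcome)
    message(sprintf("read %d subjects; %s: %d rows, %s: %d rows",
                    nrow(x$subjects), outcome1, n[[outcome1]], outcome2, n[[outcome2]]))
  }
  x
}

#' Write a longitudinal dataset to CSV
#'
#' Inverse of [read_long_csv()]: writes the long table with covariate columns
#' repeated on every row of a subject.
#'
#' @param x a `"longitudinal_data"` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(x, path) {
  stopifnot(inherits(x, "longitudinal_data"))
  df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.longitudinal_data <- function(x, ...) {
  df <- x$data
  df$outcome <- as.character(df$outcome)
  if (length(x$covariates)) {
    idx <- match(df$subject_id, x$subjects$subject_id)
    for (cv in x$covariates) df[[cv]] <- x$subjects[[cv]][idx]
  }
  df
}

#' @export
print.longitudinal_data <- function(x, ...) {
  n <- table(x$data$outcome)
  cat("Longitudinal two-outcome dataset\n")
  cat(sprintf("  subjects: %d\n", nrow(x$subjects)))
  cat(sprintf("  %s: %d observations, %s: %d observations\n",
              x$outcomes[1], n[[1]], x$outcomes[2], n[[2]]))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (!is.null(x$scaling))
    cat("  standardized:", paste(names(x$scaling$center), collapse = ", "), "\n")
  rep <- attr(x, "filter_report")
  if (!is.null(rep))
    cat(sprintf("  cohort filter applied: %d observations and %d subjects excluded\n",
                rep$n_obs_excluded, rep$n_subjects_excluded))
  invisible(x)
}

#' @export
summary.longitudinal_data <- function(object, ...) {
  d <- object$data
  out <- lapply(split(d, d$outcome), function(s) {
    c(n_obs = nrow(s), n_subjects = length(unique(s$subject_id)),
      t_min = min(s$time), t_max = max(s$time),
      value_mean = mean(s$value), value_sd = stats::sd(s$value))
  })
  res <- do.call(rbind, out)
  class(res) <- c("summary.longitudinal_data", class(res))
  res
}

#' Standardize baseline covariates
#'
#' Centers and scales the named continuous covariates to sample mean 0 and
#' variance 1 *across subjects* (one value per subject, `n - 1` variance
#' denominator), recording the scaling so that effects can be back-transformed
#' to the original units.  Regression coefficients of a model fitted on the
#' standardized data are then effects per 1 SD of the covariate.
#'
#' @param x a `"longitudinal_data"` object.
#' @param which names of covariates to standardize; default all covariates.
#' @return `x` with the named covariates standardized and a `$scaling` record
#'   (`center`, `scale` named vectors).
#' @export
standardize_covariates <- function(x, which = x$covariates) {
  stopifnot(inherits(x, "longitudinal_data"))
  if (!length(which)) return(x)
  miss <- setdiff(which, x$covariates)
  if (length(miss)) stop("not a covariate: ", paste(miss, collapse = ", "))
  center <- scale <- numeric(0)
  for (cv in which) {
    v <- x$subjects[[cv]]
    m <- mean(v); s <- stats::sd(v)   # n - 1 denominator
    if (!is.finite(s) || s < .Machine$double.eps^0.5)
      stop("covariate '", cv, "' has (near-)zero variance across subjects")
    x$subjects[[cv]] <- (v - m) / s
    center[cv] <- m; scale[cv] <- s
  }
  prev <- x$scaling
  if (is.null(prev)) {
    x$scaling <- list(center = center, scale = scale)
  } else {
    prev$center[names(center)] <- center
    prev$scale[names(scale)] <- scale
    x$scaling <- prev
  }
  x
}

#' Undo covariate standardization
#'
#' @param x a `"longitudinal_data"` object previously passed through
#'   [standardize_covariates()].
#' @return `x` with covariates on their original scale and the scaling record
#'   removed.
#' @export
unstandardize_covariates <- function(x) {
  stopifnot(inherits(x, "longitudinal_data"))
  sc <- x$scaling
  if (is.null(sc)) return(x)
  for (cv in names(sc$center))
    x$subjects[[cv]] <- x$subjects[[cv]] * sc$scale[cv] + sc$center[cv]
  x$scaling <- NULL
  x
}

#' Cohort filtering policy
#'
#' The analysis-cohort rules: truncate follow-up, require a minimum number of
#' post-index measurements per outcome for each subject, and flag visit times
#' where either outcome has too few subjects for pointwise (cross-sectional)
#' summaries.
#'
#' @param max_followup maximum follow-up in years; observations beyond it are
#'   removed (default 7.5).
#' @param min_subjects_per_time minimum subjects per visit time for pointwise
#'   analyses; sparser times are flagged, not removed from model fits
#'   (default 30).
#' @param min_obs_per_outcome minimum observations per outcome for a subject
#'   to enter the analysis cohort (default 2).
#' @return A `"cohort_filter_policy"` list.
#' @export
cohort_filter_policy <- function(max_followup = 7.5, min_subjects_per_time = 30,
                                 min_obs_per_outcome = 2) {
  stopifnot(max_followup > 0, min_subjects_per_time > 0, min_obs_per_outcome > 0)
  structure(list(max_followup = max_followup,
                 min_subjects_per_time = min_subjects_per_time,
                 min_obs_per_outcome = min_obs_per_outcome),
            class = "cohort_filter_policy")
}

#' Apply the cohort filter
#'
#' Applies a [cohort_filter_policy()]: removes observations past
#' `max_followup`, removes subjects with fewer than `min_obs_per_outcome`
#' observations in either outcome, and flags (without deleting) visit times
#' at which either outcome has fewer than `min_subjects_per_time` subjects.
#' Filtering is idempotent.
#'
#' @param x a `"longitudinal_data"` object.
#' @param policy a `"cohort_filter_policy"`; default policy if omitted.
#' @return The filtered `"longitudinal_data"`, with an exclusion report in
#'   `attr(, "filter_report")` (counts per rule and the flagged sparse times
#'   per outcome).
#' @export
apply_cohort_filter <- function(x, policy = cohort_filter_policy()) {
  stopifnot(inherits(x, "longitudinal_data"), inherits(policy, "cohort_filter_policy"))
  d <- x$data
  late <- d$time > policy$max_followup
  d <- d[!late, , drop = FALSE]
  if (!nrow(d)) stop("no observations remain after follow-up truncation")

  tab <- table(d$subject_id, d$outcome)
  keep_sub <- rownames(tab)[apply(tab >= policy$min_obs_per_outcome, 1L, all)]
  drop_sub <- setdiff(unique(d$subject_id), keep_sub)
  d <- d[d$subject_id %in% keep_sub, , drop = FALSE]
  if (!nrow(d)) stop("no subjects remain after the minimum-observations rule")

  sparse <- lapply(levels(d$outcome), function(oc) {
    s <- d[d$outcome == oc, ]
    cnt <- tapply(s$subject_id, s$time, function(ids) length(unique(ids)))
    as.numeric(names(cnt))[cnt < policy$min_subjects_per_time]
  })
  names(sparse) <- levels(d$outcome)

  x$data <- d
  rownames(x$data) <- NULL
  x$subjects <- x$subjects[x$subjects$subject_id %in% keep_sub, , drop = FALSE]
  rownames(x$subjects) <- NULL
  report <- list(
    n_obs_excluded = sum(late) +
      (attr(x, "filter_report")$n_obs_excluded %||% 0),
    n_obs_past_followup = sum(late),
    n_subjects_excluded = length(drop_sub) +
      (attr(x, "filter_report")$n_subjects_excluded %||% 0),
    excluded_subjects = drop_sub,
    sparse_times = sparse,
    policy = unclass(policy))
  attr(x, "filter_report") <- report
  x
}

#' Exclusion report of the last cohort filter
#'
#' @param x a filtered `"longitudinal_data"` object.
#' @return The report list, or `NULL` if the data were never filtered.
#' @export
filter_report <- function(x) attr(x, "filter_report")

`%||%` <- function(a, b) if (is.null(a)) b else a
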