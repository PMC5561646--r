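# Design construction for the stacked bivariate model.
#
# Each subject contributes a response vector y_i of length n1 + n2 (outcome-1
# rows first), a fixed-effect design X_i with one (intercept, time, covariates)
# block per outcome, a 4-column random-effect design Z_i over the effects
# (a0, b0, a1, b1) = (int1, int2, slope1, slope2), and a residual pattern that
# marks same-time cross-outcome pairs for the correlated-error model.

RE_NAMES <- c("int1", "int2", "slope1", "slope2")

#' Stacked design matrices for one subject
#'
#' Exposes the internal stacking of the two outcome equations for a single
#' subject: the response vector (outcome-1 rows first), the fixed-effect
#' design (a separate intercept/time/covariate block per outcome), the
#' 4-column random-effect design over (intercept 1, intercept 2, slope 1,
#' slope 2), and the symmetric 0/1 pattern marking same-time cross-outcome
#' residual pairs used by the correlated-error model.
#'
#' @param x a `"longitudinal_data"` object.
#' @param subject subject identifier.
#' @param covariates covariate names entering the fixed-effect design
#'   (baseline level shift of both outcomes).
#' @param slope_covariates covariate names additionally interacting with
#'   time (covariate-specific slopes for both outcomes).
#' @return list with `y`, `X`, `Z`, `cross` (residual pairing pattern),
#'   `outcome_idx` (1/2 per row) and `time`.
#' @export
build_subject_design <- function(x, subject, covariates = character(),
                                 slope_covariates = character()) {
  stopifnot(inherits(x, "longitudinal_data"))
  subject <- as.character(subject)
  d <- x$data[x$data$subject_id == subject, , drop = FALSE]
  if (!nrow(d)) stop("subject not found: ", subject)
  getz <- function(nm) {
    if (!length(nm)) return(numeric(0))
    row <- x$subjects[x$subjects$subject_id == subject, , drop = FALSE]
    stats::setNames(as.numeric(row[1L, nm]), nm)
  }
  .subject_design(d, getz(covariates), covariates,
                  getz(slope_covariates), slope_covariates, x$outcomes)
}

.subject_design <- function(d, z, covariates, zs = numeric(0),
                            slope_covariates = character(), outcomes) {
  oc <- as.integer(d$outcome)           # 1 = outcome1, 2 = outcome2
  ord <- order(oc, d$time)
  d <- d[ord, , drop = FALSE]
  oc <- oc[ord]
  t <- d$time
  m <- length(t)
  q <- length(covariates)
  qs <- length(slope_covariates)
  pb <- 2L + q + qs                      # columns per outcome block
  p <- 2L * pb

  X <- matrix(0, m, p)
  i1 <- oc == 1L
  X[i1, 1L] <- 1; X[i1, 2L] <- t[i1]
  X[!i1, pb + 1L] <- 1; X[!i1, pb + 2L] <- t[!i1]
  if (q) {
    for (k in seq_len(q)) {
      X[i1, 2L + k] <- z[k]
      X[!i1, pb + 2L + k] <- z[k]
    }
  }
  if (qs) {
    for (k in seq_len(qs)) {
      X[i1, 2L + q + k] <- zs[k] * t[i1]
      X[!i1, pb + 2L + q + k] <- zs[k] * t[!i1]
    }
  }
  block <- function(sfx) c(paste0("int", sfx), paste0("slope", sfx),
                           if (q) paste0(covariates, ".", sfx),
                           if (qs) paste0(slope_covariates, ":t.", sfx))
  colnames(X) <- c(block("1"), block("2"))

  Z <- matrix(0, m, 4L, dimnames = list(NULL, RE_NAMES))
  Z[i1, 1L] <- 1; Z[i1, 3L] <- t[i1]
  Z[!i1, 2L] <- 1; Z[!i1, 4L] <- t[!i1]

  # same-subject, same-time, cross-outcome residual pairs
  cross <- outer(t, t, "==") & outer(oc, oc, "!=")
  list(y = d$value, X = X, Z = Z, cross = cross, outcome_idx = oc, time = t)
}

# Prepares per-subject designs and groups subjects that share an identical
# time/outcome structure so the marginal covariance is factorized once per
# group.  Within a group, if every subject also shares the same X (the
# covariate-free balanced case), sufficient statistics (sum of y, sum of
# y y^T) replace the per-subject loop in the likelihood.
.blmm_prepare <- function(x, covariates, error_model,
                          slope_covariates = character()) {
  d <- x$data
  sids <- unique(d$subject_id)
  idx <- match(sids, x$subjects$subject_id)
  Zcov <- if (length(covariates))
    as.matrix(x$subjects[idx, covariates, drop = FALSE]) else
    matrix(0, length(sids), 0L)
  Zscov <- if (length(slope_covariates))
    as.matrix(x$subjects[idx, slope_covariates, drop = FALSE]) else
    matrix(0, length(sids), 0L)

  split_d <- split(d, d$subject_id)[sids]
  designs <- vector("list", length(sids))
  sig <- character(length(sids))
  for (i in seq_along(sids)) {
    di <- split_d[[i]]
    z <- if (length(covariates)) Zcov[i, ] else numeric(0)
    zs <- if (length(slope_covariates)) Zscov[i, ] else numeric(0)
    designs[[i]] <- .subject_design(di, z, covariates, zs, slope_covariates,
                                    x$outcomes)
    sig[i] <- paste(as.integer(di$outcome), di$time, sep = ":", collapse = ";")
  }

  groups <- split(seq_along(sids), sig)
  ginfo <- lapply(groups, function(ii) {
    g1 <- designs[[ii[1L]]]
    same_X <- all(vapply(ii, function(j) identical(designs[[j]]$X, g1$X), TRUE))
    out <- list(idx = ii, Z = g1$Z, cross = g1$cross,
                outcome_idx = g1$outcome_idx, time = g1$time,
                m = length(g1$y), same_X = same_X)
    if (same_X) {
      Y <- vapply(ii, function(j) designs[[j]]$y, numeric(out$m))
      Y <- matrix(Y, nrow = out$m)
      out$X <- g1$X
      out$n <- length(ii)
      out$Sy <- rowSums(Y)
      out$Syy <- tcrossprod(Y)
    } else {
      out$X_list <- lapply(ii, function(j) designs[[j]]$X)
      out$y_list <- lapply(ii, function(j) designs[[j]]$y)
    }
    out
  })

  p <- ncol(designs[[1L]]$X)
  list(subjects = sids, designs = designs, groups = ginfo, p = p,
       fixed_names = colnames(designs[[1L]]$X),
       n_obs = nrow(d), error_model = error_model,
       covariates = covariates, slope_covariates = slope_covariates)
}

# Residual covariance for a group given the error parameters.
.group_R <- function(g, err) {
  v <- ifelse(g$outcome_idx == 1L, err$var1, err$var2)
  R <- diag(v, g$m)
  if (!is.null(err$cov12) && err$cov12 != 0)
    R[g$cross] <- err$cov12
  R
}
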