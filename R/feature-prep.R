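#' Per-modality feature container
#'
#' A subject-by-feature matrix for one imaging modality (e.g. FC edge
#' strengths, FA or GMV voxel values) with provenance flags recording
#' whether covariates have been regressed out and whether the matrix has
#' been normalized for fusion. Flags are monotone: once set they are never
#' unset by package operations.
#'
#' @param modality label, e.g. "FC", "FA", "GMV".
#' @param data numeric matrix \[n_subjects x n_features\], finite.
#' @param feature_ids,subject_ids character labels for columns/rows.
#' @param normalized,residualized provenance flags.
#' @return object of class \code{modality_features}.
#' @export
modality_features <- function(modality, data, feature_ids = colnames(data),
                              subject_ids = rownames(data),
                              normalized = FALSE, residualized = FALSE) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stopf("modality '%s': data must be a finite numeric matrix", modality)
  if (is.null(feature_ids)) feature_ids <- sprintf("f%05d", seq_len(ncol(data)))
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(data)))
  if (anyDuplicated(subject_ids)) stopf("subject_ids must be unique")
  if (length(subject_ids) != nrow(data) || length(feature_ids) != ncol(data))
    stopf("id lengths must match data dimensions")
  dimnames(data) <- list(subject_ids, feature_ids)
  structure(list(modality = modality, data = data,
                 feature_ids = as.character(feature_ids),
                 subject_ids = as.character(subject_ids),
                 normalized = isTRUE(normalized),
                 residualized = isTRUE(residualized)),
            class = "modality_features")
}

#' @export
print.modality_features <- function(x, ...) {
  cat(sprintf("<modality_features> %s: %d subjects x %d features%s%s\n",
              x$modality, nrow(x$data), ncol(x$data),
              if (x$residualized) ", residualized" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Cohort design: groups, nuisance covariates, clinical scores
#'
#' @param subject_ids unique subject labels.
#' @param group factor (or 0/1) with levels control/patient.
#' @param covariates data.frame of nuisance covariates aligned to
#'   \code{subject_ids} (age in years, sex coded 0/1, meanFD in mm; meanFD
#'   is used for FC only).
#' @param clinical data.frame of clinical scores (onset_age, MMSE, HSCT);
#'   missing values allowed.
#' @return object of class \code{cohort_design}.
#' @export
cohort_design <- function(subject_ids, group, covariates = NULL,
                          clinical = NULL) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stopf("subject_ids must be unique")
  group <- as_group_factor(group)
  if (length(group) != length(subject_ids))
    stopf("group length must match subject_ids")
  chk <- function(tab, what) {
    if (is.null(tab)) return(NULL)
    tab <- as.data.frame(tab)
    if (nrow(tab) != length(subject_ids))
      stopf("%s rows must align with subject_ids", what)
    rownames(tab) <- subject_ids
    tab
  }
  structure(list(subject_ids = subject_ids, group = group,
                 covariates = chk(covariates, "covariates"),
                 clinical = chk(clinical, "clinical")),
            class = "cohort_design")
}

#' Vectorize / restore a symmetric matrix
#'
#' The strict upper triangle in row-major order: (1,2), (1,3), ..., (1,R),
#' (2,3), ... The diagonal is excluded; \code{devectorize_symmetric}
#' restores a symmetric matrix with zero diagonal.
#'
#' @param m symmetric numeric matrix (symmetric within 1e-8).
#' @param v numeric vector of length R(R-1)/2 for some integer R >= 2.
#' @return \code{vectorize_symmetric}: numeric vector;
#'   \code{devectorize_symmetric}: symmetric matrix with zero diagonal.
#' @export
vectorize_symmetric <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stopf("input is not symmetric within 1e-8")
  t(m)[lower.tri(m)]          # row-major strict upper triangle
}

#' @rdname vectorize_symmetric
#' @export
devectorize_symmetric <- function(v) {
  L <- length(v)
  R <- (1 + sqrt(1 + 8 * L)) / 2
  if (abs(R - round(R)) > 1e-9 || R < 2)
    stopf("length %d is not R(R-1)/2 for any integer R >= 2", L)
  R <- as.integer(round(R))
  m <- matrix(0, R, R)
  m[lower.tri(m)] <- v        # fills t(upper) in matching row-major order
  m <- t(m)
  m + t(m)
}

#' Functional-connectivity features from regional time series
#'
#' For each subject, computes the region-by-region Pearson correlation
#' matrix, optionally Fisher z-transforms it (with |r| clipped to
#' 1 - 1e-7 so atanh stays finite), and vectorizes the strict upper
#' triangle in row-major order, giving R(R-1)/2 edge features.
#'
#' @param timeseries list (one per subject) of numeric matrices
#'   \[timepoints x regions\], all with the same region count.
#' @param subject_ids optional subject labels.
#' @param fisher_z logical; apply the variance-stabilizing atanh transform
#'   (default TRUE). Raw correlations are kept when FALSE.
#' @return a \code{\link{modality_features}} with modality "FC".
#' @export
compute_fc <- function(timeseries, subject_ids = names(timeseries),
                       fisher_z = TRUE) {
  if (!is.list(timeseries) || !length(timeseries))
    stopf("timeseries must be a non-empty list of matrices")
  R <- ncol(timeseries[[1]])
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d",
                                                   seq_along(timeseries))
  out <- matrix(NA_real_, length(timeseries), R * (R - 1) / 2)
  for (s in seq_along(timeseries)) {
    ts <- as.matrix(timeseries[[s]])
    if (nrow(ts) < 3) stopf("subject %s: need >= 3 timepoints",
                            subject_ids[s])
    if (ncol(ts) != R) stopf("subject %s: region count differs",
                             subject_ids[s])
    sds <- apply(ts, 2, stats::sd)
    if (any(sds == 0))
      stopf("subject %s: constant time series in region(s) %s",
            subject_ids[s], paste(which(sds == 0), collapse = ", "))
    r <- stats::cor(ts)
    if (fisher_z) {
      r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
      r <- atanh(r)
    }
    out[s, ] <- vectorize_symmetric(r)
  }
  idx <- which(upper.tri(diag(R)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  modality_features("FC", out,
                    feature_ids = sprintf("fc_%d_%d", idx[, 1], idx[, 2]),
                    subject_ids = subject_ids)
}

#' Regress nuisance covariates out of every feature
#'
#' Replaces each feature column by its residual from an ordinary
#' least-squares fit on an intercept plus the named covariates, as is
#' standard before fusion (age and sex for all modalities, mean framewise
#' displacement for FC).
#'
#' @param features a \code{\link{modality_features}}.
#' @param design a \code{\link{cohort_design}} with complete covariates.
#' @param covariate_names columns of \code{design$covariates} to remove.
#' @return the residualized \code{modality_features} (flag set).
#' @export
regress_covariates <- function(features, design, covariate_names) {
  stopifnot(inherits(features, "modality_features"),
            inherits(design, "cohort_design"))
  miss <- setdiff(covariate_names, colnames(design$covariates))
  if (length(miss)) stopf("unknown covariates: %s",
                          paste(miss, collapse = ", "))
  C <- as.matrix(design$covariates[features$subject_ids, covariate_names,
                                   drop = FALSE])
  if (any(!is.finite(C))) stopf("covariates contain missing values")
  n <- nrow(C)
  if (n <= ncol(C) + 1)
    stopf("need n_subjects > n_covariates + 1 (%d <= %d)", n, ncol(C) + 1)
  X <- cbind(`(intercept)` = 1, C)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stopf("rank-deficient covariate design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  res <- qr.resid(q, features$data)
  modality_features(features$modality, res, features$feature_ids,
                    features$subject_ids, normalized = features$normalized,
                    residualized = TRUE)
}

#' Normalize a modality for equal contribution in fusion
#'
#' Centers every feature column, then divides the whole matrix by a single
#' scalar so the pooled standard deviation over all entries equals one.
#' One scalar per modality (rather than per-feature scaling) preserves the
#' relative variance structure within the modality while equalising gross
#' scale across modalities.
#'
#' @param features a \code{\link{modality_features}}.
#' @return the normalized \code{modality_features} (flag set).
#' @export
normalize_modality <- function(features) {
  stopifnot(inherits(features, "modality_features"))
  X <- sweep(features$data, 2, colMeans(features$data))
  s <- stats::sd(as.vector(X))
  if (!is.finite(s) || s == 0) stopf("modality '%s' has zero pooled variance",
                                     features$modality)
  modality_features(features$modality, X / s, features$feature_ids,
                    features$subject_ids, normalized = TRUE,
                    residualized = features$residualized)
}
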