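#' Benjamini-Hochberg FDR control
#'
#' Step-up FDR over a family of p-values; returns rejection flags at level
#' \code{alpha} and monotone adjusted q-values.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param alpha FDR level.
#' @return list with \code{reject} (logical) and \code{q} (numeric).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  list(reject = q <= alpha, q = q)
}

#' Two-sample t-test from summary statistics
#'
#' Standard two-sample t statistic computed from group means, SDs and
#' sizes, with a two-sided p-value; both the pooled-variance and Welch
#' variants are available.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param variant "pooled" or "welch".
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2,
                          variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (sd1 <= 0 || sd2 <= 0) stopf("SDs must be positive")
  if (n1 < 2 || n2 < 2) stopf("need n >= 2 per group")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Align component signs to the control > patient convention
#'
#' ICA components have arbitrary sign. For each (component, modality), if
#' the control-group mean loading is below the patient mean, both the
#' loading column and the corresponding map row are negated, so positive
#' map values read as control > patient. Applying the alignment twice is
#' the identity.
#'
#' @param loadings list (per modality) of \[subjects x M\] loading matrices.
#' @param maps list (per modality) of \[M x features\] map matrices.
#' @param group factor control/patient.
#' @return list with flipped \code{loadings}, \code{maps} and the
#'   \code{flipped} logical matrix \[M x K\].
#' @export
align_component_sign <- function(loadings, maps, group) {
  group <- as_group_factor(group)
  if (!all(c("control", "patient") %in% group))
    stopf("both classes must be present")
  K <- length(loadings)
  M <- ncol(loadings[[1]])
  flipped <- matrix(FALSE, M, K)
  for (k in seq_len(K)) for (m in seq_len(M)) {
    a <- loadings[[k]][, m]
    if (mean(a[group == "control"]) < mean(a[group == "patient"])) {
      loadings[[k]][, m] <- -a
      maps[[k]][m, ] <- -maps[[k]][m, ]
      flipped[m, k] <- TRUE
    }
  }
  list(loadings = loadings, maps = maps, flipped = flipped)
}

#' Group comparison of subject loadings
#'
#' Two-sample t-test (control vs patient) on every (component, modality)
#' loading column; p-values are pooled across the whole M x K family and
#' Benjamini-Hochberg adjusted.
#'
#' @param loadings list (per modality) of \[subjects x M\] matrices; list
#'   names are used as modality labels.
#' @param group factor control/patient.
#' @param variant "welch" (default) or "pooled".
#' @param alpha FDR level for the reject flag.
#' @return data.frame with component, modality, t, p, q.
#' @export
group_ttest_loadings <- function(loadings, group,
                                 variant = c("welch", "pooled"),
                                 alpha = 0.05) {
  variant <- match.arg(variant)
  group <- as_group_factor(group)
  if (min(table(group)) < 2) stopf("need >= 2 subjects per class")
  mods <- names(loadings)
  if (is.null(mods)) mods <- paste0("mod", seq_along(loadings))
  rows <- do.call(rbind, lapply(seq_along(loadings), function(k) {
    A <- loadings[[k]]
    do.call(rbind, lapply(seq_len(ncol(A)), function(m) {
      a <- A[, m]
      if (stats::sd(a[group == "control"]) == 0 &&
          stats::sd(a[group == "patient"]) == 0) {
        if (mean(a[group == "control"]) == mean(a[group == "patient"]))
          return(data.frame(component = m, modality = mods[k], t = 0, p = 1))
        stopf("zero within-class variance in component %d (%s)", m, mods[k])
      }
      tt <- stats::t.test(a[group == "control"], a[group == "patient"],
                          var.equal = variant == "pooled")
      data.frame(component = m, modality = mods[k],
                 t = unname(tt$statistic), p = tt$p.value)
    }))
  }))
  fdr <- bh_fdr(rows$p, alpha)
  rows$q <- fdr$q
  rows
}

#' Correlate loadings with the reference signal
#'
#' Pearson correlation of every (component, modality) loading column with
#' the per-subject reference, two-sided p, BH-adjusted over the M x K
#' family.
#'
#' @param loadings list (per modality) of \[subjects x M\] matrices.
#' @param reference per-subject numeric vector.
#' @param alpha FDR level.
#' @return data.frame with component, modality, r_ref, p_ref, q_ref.
#' @export
correlate_with_reference <- function(loadings, reference, alpha = 0.05) {
  ref <- as.numeric(reference)
  if (stats::sd(ref) == 0) stopf("reference is constant")
  mods <- names(loadings)
  if (is.null(mods)) mods <- paste0("mod", seq_along(loadings))
  rows <- do.call(rbind, lapply(seq_along(loadings), function(k) {
    A <- loadings[[k]]
    do.call(rbind, lapply(seq_len(ncol(A)), function(m) {
      ct <- stats::cor.test(A[, m], ref)
      data.frame(component = m, modality = mods[k],
                 r_ref = unname(ct$estimate), p_ref = ct$p.value)
    }))
  }))
  rows$q_ref <- bh_fdr(rows$p_ref, alpha)$q
  rows
}

#' Correlate loadings with clinical scores
#'
#' Pearson correlation between one loading column per modality and each
#' clinical score, dropping missing entries pairwise (scores such as age
#' of onset exist for patients only).
#'
#' @param loadings list (per modality) of loading vectors (or single
#'   columns of a loading matrix).
#' @param clinical data.frame of clinical scores, rows aligned to subjects.
#' @return data.frame with modality, score, n, r, p.
#' @export
correlate_with_clinical <- function(loadings, clinical) {
  mods <- names(loadings)
  if (is.null(mods)) mods <- paste0("mod", seq_along(loadings))
  out <- list()
  for (k in seq_along(loadings)) for (sc in colnames(clinical)) {
    a <- as.numeric(loadings[[k]])
    y <- clinical[[sc]]
    ok <- is.finite(a) & is.finite(y)
    if (sum(ok) < 4) {
      out[[length(out) + 1]] <- data.frame(
        modality = mods[k], score = sc, n = sum(ok),
        r = NA_real_, p = NA_real_)
      next
    }
    ct <- stats::cor.test(a[ok], y[ok])
    out[[length(out) + 1]] <- data.frame(
      modality = mods[k], score = sc, n = sum(ok),
      r = unname(ct$estimate), p = ct$p.value)
  }
  do.call(rbind, out)
}

#' Partial correlation with the group effect removed
#'
#' Residualizes both the loading column and the reference on an intercept
#' plus the group indicator, then correlates the residuals; the p-value
#' uses the t transform with n - 3 degrees of freedom.
#'
#' @param x loading column (numeric).
#' @param reference per-subject reference vector.
#' @param group factor control/patient.
#' @return list with \code{r_partial}, \code{p}, \code{df}.
#' @export
partial_correlation <- function(x, reference, group) {
  group <- as_group_factor(group)
  if (length(unique(group)) < 2) stopf("both classes must be present")
  g <- as.numeric(group == "patient")
  rx <- stats::lm.fit(cbind(1, g), as.numeric(x))$residuals
  ry <- stats::lm.fit(cbind(1, g), as.numeric(reference))$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stopf("degenerate residuals")
  r <- stats::cor(rx, ry)
  df <- length(rx) - 3
  t <- r * sqrt(df / (1 - r^2))
  list(r_partial = r, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Z-score and threshold a component map
#'
#' Standardizes a spatial map to zero mean / unit SD and masks features
#' exceeding the |Z| threshold (2 is customary for voxelwise FA/GMV maps,
#' 3 for dense FC edge maps). After sign alignment, positive Z means
#' control > patient.
#'
#' @param map numeric feature vector.
#' @param threshold positive |Z| cut.
#' @return object of class \code{thresholded_map}: \code{z_map},
#'   \code{threshold}, \code{mask}.
#' @export
zscore_threshold_map <- function(map, threshold) {
  map <- as.numeric(map)
  if (!is.finite(threshold) || threshold <= 0)
    stopf("threshold must be positive")
  s <- stats::sd(map)
  if (!is.finite(s) || s == 0) stopf("map has zero variance")
  z <- (map - mean(map)) / s
  structure(list(z_map = z, threshold = threshold,
                 mask = abs(z) > threshold),
            class = "thresholded_map")
}

#' Spatial similarity of two component maps
#'
#' Pearson correlation across features; the absolute value is reported
#' alongside to absorb ICA sign indeterminacy.
#'
#' @param map_a,map_b numeric vectors over the same feature space.
#' @return list with \code{r} and \code{abs_r}.
#' @export
spatial_similarity <- function(map_a, map_b) {
  a <- as.numeric(map_a); b <- as.numeric(map_b)
  if (length(a) != length(b)) stopf("maps live on different feature spaces")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stopf("constant map")
  r <- stats::cor(a, b)
  list(r = r, abs_r = abs(r))
}

#' Full component-statistics table
#'
#' Combines group t-tests, reference correlations (each BH-adjusted over
#' the M x K family) and the group-adjusted partial correlation, and flags
#' components whose group difference AND reference correlation both
#' survive FDR — the joint-component selection rule.
#'
#' @param loadings list (per modality) of \[subjects x M\] matrices.
#' @param reference per-subject reference vector.
#' @param group factor control/patient.
#' @param alpha FDR level (default 0.05).
#' @param variant t-test variant, "welch" or "pooled".
#' @return data.frame: component, modality, t, p, q, r_ref, p_ref, q_ref,
#'   r_partial, selected.
#' @export
component_statistics <- function(loadings, reference, group, alpha = 0.05,
                                 variant = "welch") {
  gt <- group_ttest_loadings(loadings, group, variant, alpha)
  rc <- correlate_with_reference(loadings, reference, alpha)
  tab <- merge(gt, rc, by = c("component", "modality"), sort = FALSE)
  tab$r_partial <- mapply(function(m, k) {
    partial_correlation(loadings[[k]][, m], reference, group)$r_partial
  }, tab$component, match(tab$modality, names(loadings)))
  tab$selected <- tab$q < alpha & tab$q_ref < alpha
  tab[order(match(tab$modality, names(loadings)), tab$component), ]
}
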