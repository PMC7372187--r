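#' Locus-wise differential methylation
#'
#' Two-sample t-test (patient vs control) on every CpG locus of a
#' beta-value matrix, with Benjamini-Hochberg FDR across ALL loci, as is
#' standard for array-wide scans. Beta-values may optionally be
#' logit-transformed to M-values for variance stabilization before
#' testing; the test is then on M-values but loci are reported unchanged.
#'
#' @param beta numeric matrix \[subjects x loci\] with entries in \[0, 1\];
#'   column names are locus ids.
#' @param group factor control/patient aligned to rows.
#' @param variant "welch" (default) or "pooled".
#' @param m_values logical; test logit2-transformed values instead of raw
#'   beta (beta clipped to \[1e-6, 1 - 1e-6\] first).
#' @return data.frame (locus, t, p, q) sorted by q then decreasing |t|;
#'   t is patient minus control.
#' @export
differential_loci <- function(beta, group, variant = c("welch", "pooled"),
                              m_values = FALSE) {
  variant <- match.arg(variant)
  beta <- as.matrix(beta)
  if (any(beta < 0 | beta > 1)) stopf("beta values must lie in [0, 1]")
  group <- as_group_factor(group)
  if (min(table(group)) < 2) stopf("need >= 2 subjects per class")
  x <- beta
  if (m_values) {
    x <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
    x <- log2(x / (1 - x))
  }
  pat <- x[group == "patient", , drop = FALSE]
  con <- x[group == "control", , drop = FALSE]
  n1 <- nrow(pat); n2 <- nrow(con)
  m1 <- colMeans(pat); m2 <- colMeans(con)
  v1 <- colSums(sweep(pat, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(con, 2, m2)^2) / (n2 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, ncol(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  q <- bh_fdr(p)$q
  loci <- colnames(beta)
  if (is.null(loci)) loci <- sprintf("locus%06d", seq_len(ncol(beta)))
  out <- data.frame(locus = loci, t = unname(t), p = unname(p),
                    q = unname(q), stringsAsFactors = FALSE)
  out[order(out$q, -abs(out$t)), , drop = FALSE]
}

#' Cross-assay validation correlation
#'
#' Pearson correlation (with two-sided p) between paired methylation
#' measurements from two assays, e.g. array beta-values against
#' pyrosequencing percentages at the same CpG.
#'
#' @param x,y paired numeric measurements, n >= 4.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
assay_crossval <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stopf("need >= 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant vector")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
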