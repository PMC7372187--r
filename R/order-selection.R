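#' Model-order estimation by minimum description length
#'
#' Estimates the number of signal components in a subject-by-feature matrix
#' from the eigenvalues of its sample covariance, using the classical
#' Wax-Kailath MDL criterion:
#' \deqn{MDL(m) = -N (p - m) \log\frac{g_m}{a_m} + \tfrac12 m (2p - m) \log N}
#' where \eqn{g_m} and \eqn{a_m} are the geometric and arithmetic means of
#' the trailing eigenvalues \eqn{\lambda_{m+1} \ge \dots \ge \lambda_p},
#' \eqn{p = \min(N - 1, \mathrm{features})}, and \eqn{N} is the number of
#' (effective) samples. The selected order is the argmin over
#' \eqn{m = 0, \dots, p - 1}.
#'
#' The effective sample size can be overridden through \code{n_eff} to apply
#' a subsampling correction when samples are not independent (smoothed
#' volumetric data); by default all subjects count.
#'
#' @param features a \code{\link{modality_features}} (or numeric matrix).
#' @param n_eff effective sample size; default \code{nrow(data)}.
#' @return object of class \code{order_estimate} with fields
#'   \code{modality}, \code{mdl_curve} (named by m) and
#'   \code{selected_order}.
#' @export
estimate_order_mdl <- function(features, n_eff = NULL) {
  X <- if (inherits(features, "modality_features")) features$data else
    as.matrix(features)
  modality <- if (inherits(features, "modality_features"))
    features$modality else "data"
  N <- nrow(X)
  if (N < 4) stopf("need at least 4 subjects for order estimation")
  if (is.null(n_eff)) n_eff <- N
  p <- min(N - 1L, ncol(X))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  d <- svd(Xc, nu = 0, nv = 0)$d
  lambda <- (d^2) / (N - 1)
  lambda <- lambda[seq_len(p)]
  if (any(!is.finite(lambda))) stopf("non-finite covariance eigenvalues")
  lambda <- pmax(lambda, .Machine$double.eps)
  m_grid <- 0:(p - 1L)
  # suffix means of log-eigenvalues / eigenvalues, vectorized
  rev_cummean <- function(x) rev(cumsum(rev(x))) / (p - m_grid)
  log_geo <- rev_cummean(log(lambda))
  log_ari <- log(rev_cummean(lambda))
  mdl <- -n_eff * (p - m_grid) * (log_geo - log_ari) +
    0.5 * m_grid * (2 * p - m_grid) * log(n_eff)
  names(mdl) <- m_grid
  structure(list(modality = modality, mdl_curve = mdl,
                 selected_order = m_grid[which.min(mdl)]),
            class = "order_estimate")
}

#' @export
print.order_estimate <- function(x, ...) {
  cat(sprintf("<order_estimate> %s: selected order %d (grid 0..%d)\n",
              x$modality, x$selected_order, length(x$mdl_curve) - 1L))
  invisible(x)
}
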