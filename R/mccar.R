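#' Fusion configuration
#'
#' Parameters of the reference-guided multi-set CCA plus joint ICA engine.
#'
#' @param n_components number of joint components M to extract.
#' @param lambda nonnegative weight of the reference-correlation term
#'   (0.5 is the usual cross-validated choice).
#' @param max_iter maximum optimization sweeps.
#' @param tol convergence tolerance on the objective change.
#' @param ica_algorithm "infomax" (natural-gradient, logistic nonlinearity)
#'   or "fastica-logcosh" (symmetric fixed-point).
#' @param seed integer seed for ICA initialization and CV folds.
#' @param cv_folds folds for lambda cross-validation.
#' @param lambda_grid candidate lambda values for cross-validation.
#' @return object of class \code{fusion_config}.
#' @export
fusion_config <- function(n_components = 20L, lambda = 0.5,
                          max_iter = 1000L, tol = 1e-6,
                          ica_algorithm = c("infomax", "fastica-logcosh"),
                          seed = 1L, cv_folds = 5L,
                          lambda_grid = c(0, 0.25, 0.5, 1)) {
  assert_count(n_components, "n_components")
  if (!is.finite(lambda) || lambda < 0) stopf("lambda must be >= 0")
  assert_count(max_iter, "max_iter")
  if (!is.finite(tol) || tol <= 0) stopf("tol must be > 0")
  ica_algorithm <- match.arg(ica_algorithm)
  assert_count(cv_folds, "cv_folds", min = 2L)
  if (!length(lambda_grid) || any(!is.finite(lambda_grid)) ||
      any(lambda_grid < 0))
    stopf("lambda_grid must be nonnegative reals")
  structure(list(n_components = as.integer(n_components), lambda = lambda,
                 max_iter = as.integer(max_iter), tol = tol,
                 ica_algorithm = ica_algorithm, seed = as.integer(seed),
                 cv_folds = as.integer(cv_folds),
                 lambda_grid = sort(lambda_grid)),
            class = "fusion_config")
}

#' PCA whitening
#'
#' Centers the data and projects onto the top \code{M} principal directions,
#' scaled so the output columns have exactly zero mean and identity sample
#' covariance. The dewhitening operator maps whitened coordinates back to
#' the rank-\code{M} PCA approximation of the centered data.
#'
#' @param features a \code{\link{modality_features}} or numeric matrix.
#' @param M retained rank; must not exceed the rank of the centered data.
#' @return list with \code{y} \[subjects x M\], \code{dewhiten} \[M x features\],
#'   \code{proj} \[features x M\] (for projecting new, same-centered data),
#'   \code{center}, \code{rank}.
#' @export
whiten <- function(features, M) {
  X <- if (inherits(features, "modality_features")) features$data else
    as.matrix(features)
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  s <- svd(Xc)
  rank <- sum(s$d > max(dim(X)) * .Machine$double.eps * s$d[1])
  assert_count(M, "M")
  if (M > rank) stopf("M = %d exceeds data rank %d", M, rank)
  sc <- sqrt(n - 1)
  y <- s$u[, seq_len(M), drop = FALSE] * sc
  dimnames(y) <- list(rownames(X), NULL)
  proj <- s$v[, seq_len(M), drop = FALSE] %*%
    diag(sc / s$d[seq_len(M)], M)
  dewhiten <- (diag(s$d[seq_len(M)], M) / sc) %*%
    t(s$v[, seq_len(M), drop = FALSE])
  list(y = y, dewhiten = dewhiten, proj = proj, center = ctr, rank = rank)
}

# objective pieces: cross-covariances of whitened sets and with reference
mcca_objective <- function(W, C, cref, lambda) {
  K <- length(W)
  M <- ncol(W[[1]])
  contrib <- numeric(M)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    cc <- colSums((C[[i]][[j]] %*% W[[j]]) * W[[i]])
    contrib <- contrib + cc^2
  }
  if (lambda > 0) for (k in seq_len(K))
    contrib <- contrib + lambda * drop(crossprod(W[[k]], cref[[k]]))^2
  list(J = sum(contrib), contrib = contrib)
}

#' Multi-set CCA with a reference signal (canonical stage)
#'
#' Finds per-modality weight matrices \eqn{W_k} with orthonormal columns
#' maximizing
#' \deqn{J = \sum_{i<j}\sum_c \mathrm{corr}(D_i[,c], D_j[,c])^2 +
#'   \lambda \sum_k \sum_c \mathrm{corr}(D_k[,c], \mathrm{ref})^2}
#' where \eqn{D_k = Y_k W_k} are the canonical variates of the whitened
#' inputs. Optimization is stage-wise (deflationary): component 1 is found
#' by alternating per-modality eigen-updates of its quadratic form,
#' unconstrained; each later component is found the same way inside the
#' orthogonal complement of the modality's earlier components. Every
#' update increases the running objective, so the recorded trace is
#' non-decreasing. Each stage initializes from the lambda = 0
#' pairwise-CCA solution. Components are sorted by their contribution to
#' J, descending.
#'
#' @param whitened list of K whitened matrices \[subjects x r_k\] sharing
#'   subject order (see \code{\link{whiten}}).
#' @param reference per-subject numeric reference vector; standardized
#'   internally.
#' @param config a \code{\link{fusion_config}}.
#' @return object of class \code{mcca_fit}: \code{W} (list of r_k x M),
#'   \code{variates} (list of subjects x M), \code{objective_trace},
#'   \code{component_objective}, \code{converged}, \code{lambda}.
#' @export
fit_mcca_with_reference <- function(whitened, reference, config) {
  stopifnot(inherits(config, "fusion_config"))
  K <- length(whitened)
  if (K < 2) stopf("need at least 2 modalities")
  whitened <- lapply(whitened, function(w) if (is.list(w)) w$y else
    as.matrix(w))
  n <- nrow(whitened[[1]])
  if (any(vapply(whitened, nrow, 1L) != n))
    stopf("all whitened matrices must share subject order")
  M <- config$n_components
  r <- vapply(whitened, ncol, 1L)
  if (any(r < M)) stopf("n_components = %d exceeds whitened rank %d",
                        M, min(r))
  ref <- standardize(as.numeric(reference), "reference")
  lambda <- config$lambda

  # cross-covariances; whitened columns have unit variance so these are
  # correlations of projections with unit-norm weights
  C <- vector("list", K)
  for (i in seq_len(K)) {
    C[[i]] <- vector("list", K)
    for (j in seq_len(K)) if (i != j)
      C[[i]][[j]] <- crossprod(whitened[[i]], whitened[[j]]) / (n - 1)
  }
  cref <- lapply(whitened, function(y) drop(crossprod(y, ref)) / (n - 1))

  # init from the lambda = 0 pairwise solution: W_1 from the stacked
  # cross-covariances, the rest by polar alignment
  G <- matrix(0, r[1], r[1])
  for (j in 2:K) G <- G + tcrossprod(C[[1]][[j]])
  W <- vector("list", K)
  W[[1]] <- eigen(G, symmetric = TRUE)$vectors[, seq_len(M), drop = FALSE]
  for (k in 2:K) W[[k]] <- polar_orth(C[[k]][[1]] %*% W[[1]])

  # contribution of a single component c to J given current weights
  stage_value <- function(wc, cc_ref = cref, lam = lambda) {
    v <- 0
    for (i in seq_len(K - 1)) for (j in (i + 1):K)
      v <- v + sum(wc[[i]] * (C[[i]][[j]] %*% wc[[j]]))^2
    if (lam > 0) for (k in seq_len(K))
      v <- v + lam * sum(wc[[k]] * cc_ref[[k]])^2
    v
  }

  trace <- 0
  converged <- TRUE
  for (cc in seq_len(M)) {
    wc <- lapply(seq_len(K), function(k) W[[k]][, cc])
    # project the initializer into the feasible complement
    if (cc > 1) for (k in seq_len(K)) {
      Wo <- W[[k]][, seq_len(cc - 1), drop = FALSE]
      w <- wc[[k]] - Wo %*% crossprod(Wo, wc[[k]])
      nw <- sqrt(sum(w^2))
      wc[[k]] <- if (nw > 1e-10) drop(w) / nw else {
        # initializer swallowed by earlier components: restart in complement
        b <- diag(r[k])[, cc]
        b <- b - Wo %*% crossprod(Wo, b)
        drop(b) / sqrt(sum(b^2))
      }
    }
    base <- trace[length(trace)]           # J over completed stages
    v_prev <- stage_value(wc)
    trace <- c(trace, base + v_prev)
    for (it in seq_len(config$max_iter)) {
      for (k in seq_len(K)) {
        A <- matrix(0, r[k], r[k])
        for (j in seq_len(K)) if (j != k) {
          v <- C[[k]][[j]] %*% wc[[j]]
          A <- A + tcrossprod(v)
        }
        if (lambda > 0) A <- A + lambda * tcrossprod(cref[[k]])
        if (cc > 1) {            # restrict to the orthogonal complement
          Wo <- W[[k]][, seq_len(cc - 1), drop = FALSE]
          AW <- A %*% Wo
          A <- A - Wo %*% t(AW) - AW %*% t(Wo) +
            Wo %*% (crossprod(Wo, AW) %*% t(Wo))
        }
        e <- eigen(A, symmetric = TRUE)
        w_new <- e$vectors[, 1]
        if (cc > 1) {
          Wo <- W[[k]][, seq_len(cc - 1), drop = FALSE]
          w_new <- w_new - Wo %*% crossprod(Wo, w_new)
        }
        nw <- sqrt(sum(w_new^2))
        if (nw < 1e-12) next
        w_new <- drop(w_new) / nw
        if (sum(w_new * wc[[k]]) < 0) w_new <- -w_new
        wc[[k]] <- w_new
      }
      v_new <- stage_value(wc)
      trace <- c(trace, base + v_new)
      if (abs(v_new - v_prev) < config$tol) break
      v_prev <- v_new
      if (it == config$max_iter) converged <- FALSE
    }
    for (k in seq_len(K)) W[[k]][, cc] <- wc[[k]]
  }
  obj <- mcca_objective(W, C, cref, lambda)
  if (!converged)
    warning("MCCA stage did not converge in ", config$max_iter, " sweeps")

  ord <- order(obj$contrib, decreasing = TRUE)
  W <- lapply(W, function(w) w[, ord, drop = FALSE])
  contrib <- obj$contrib[ord]
  variates <- lapply(seq_len(K), function(k) whitened[[k]] %*% W[[k]])
  structure(list(W = W, variates = variates, objective_trace = trace,
                 component_objective = contrib, converged = converged,
                 lambda = lambda, reference = ref),
            class = "mcca_fit")
}

# logistic-infomax natural gradient ICA on whitened rows Z [M x F]
infomax_ica <- function(Z, max_iter, tol, seed) {
  M <- nrow(Z); Fn <- ncol(Z)
  U <- with_seed(seed, polar_orth(matrix(stats::rnorm(M * M), M, M)))
  lr <- 0.01 / log(max(M, 3))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- U %*% Z
    g <- 1 / (1 + exp(-Y))
    grad <- (diag(M) + ((1 - 2 * g) %*% t(Y)) / Fn) %*% U
    U_new <- U + lr * grad
    delta <- max(abs(U_new - U))
    if (!is.finite(delta) || delta > 1) {      # blow-up: anneal and retry
      lr <- lr * 0.5
      next
    }
    U <- U_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(U = U, converged = converged)
}

# symmetric FastICA with logcosh contrast on whitened rows Z [M x F]
fastica_logcosh <- function(Z, max_iter, tol, seed) {
  M <- nrow(Z); Fn <- ncol(Z)
  W <- with_seed(seed, polar_orth(matrix(stats::rnorm(M * M), M, M)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- W %*% Z
    gY <- tanh(Y)
    W_new <- (gY %*% t(Z)) / Fn - diag(rowMeans(1 - gY^2), M) %*% W
    W_new <- polar_orth(W_new)
    crit <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (crit < tol) { converged <- TRUE; break }
  }
  list(U = W, converged = converged)
}

#' Joint ICA of concatenated component maps
#'
#' Rotates the rows of the concatenated (across modalities) component-map
#' matrix toward statistical independence, maximizing non-Gaussianity.
#' Rows are centered and whitened in component space first; the returned
#' unmixing matrix acts on the input maps. Gaussian sources are not
#' identifiable by ICA; the run still converges numerically but the
#' rotation is then arbitrary.
#'
#' @param maps numeric matrix \[M x total features\]: canonical maps
#'   concatenated feature-wise over modalities.
#' @param config a \code{\link{fusion_config}} (algorithm, seed, max_iter,
#'   tol).
#' @return list with \code{unmixing} \[M x M\], \code{maps}
#'   \[M x total features\] (unmixed, rows scaled to unit SD),
#'   \code{converged}.
#' @export
joint_ica <- function(maps, config) {
  stopifnot(inherits(config, "fusion_config"))
  maps <- as.matrix(maps)
  M <- nrow(maps)
  if (M < 2) stopf("joint ICA needs at least 2 components")
  Xc <- maps - rowMeans(maps)
  cov_r <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(cov_r, symmetric = TRUE)
  if (any(e$values < 1e-12 * e$values[1]))
    stopf("component maps are rank deficient")
  Kw <- e$vectors %*% diag(1 / sqrt(e$values), M) %*% t(e$vectors)
  Z <- Kw %*% Xc
  fit <- switch(config$ica_algorithm,
    "infomax" = infomax_ica(Z, max_iter = max(config$max_iter, 20000L),
                            tol = config$tol, seed = config$seed),
    "fastica-logcosh" = fastica_logcosh(Z, max_iter = config$max_iter,
                                        tol = config$tol,
                                        seed = config$seed))
  if (!fit$converged)
    warning("joint ICA did not converge within max_iter")
  U <- fit$U %*% Kw
  S <- U %*% Xc
  # unit-SD rows with a deterministic sign (largest |entry| positive)
  sds <- apply(S, 1, stats::sd)
  U <- U / sds
  S <- S / sds
  sgn <- vapply(seq_len(M), function(i) {
    v <- S[i, ]; if (v[which.max(abs(v))] < 0) -1 else 1
  }, 1)
  list(unmixing = sgn * U, maps = sgn * S, converged = fit$converged)
}

#' Subject loadings from data and component maps
#'
#' Least-squares projection of the (prepared) data onto the component maps:
#' \code{loadings = data \%*\% t(maps) \%*\% solve(maps \%*\% t(maps))}.
#'
#' @param features a \code{\link{modality_features}} or numeric matrix.
#' @param maps numeric matrix \[M x features\], full row rank.
#' @return loadings matrix \[subjects x M\].
#' @export
compute_subject_loadings <- function(features, maps) {
  X <- if (inherits(features, "modality_features")) features$data else
    as.matrix(features)
  maps <- as.matrix(maps)
  if (ncol(X) != ncol(maps)) stopf("feature dimensions disagree")
  G <- tcrossprod(maps)
  e <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) < 1e-10 * max(e)) stopf("component maps are rank deficient")
  X %*% t(maps) %*% solve(G)
}

#' Select the reference weight lambda by cross-validation
#'
#' Subject-wise k-fold cross-validation over a lambda grid: for each
#' candidate, the canonical weights are fit on the training folds and the
#' criterion is the mean (over folds and modalities) of the absolute
#' correlation between the held-out top canonical variate and the held-out
#' reference. Ties (within 1e-12) are broken toward the smaller lambda, so
#' a reference that carries no signal defaults to the least-regularized
#' model.
#'
#' @param whitened list of whitened matrices sharing subject order.
#' @param reference per-subject reference vector.
#' @param config a \code{\link{fusion_config}}; uses \code{lambda_grid},
#'   \code{cv_folds} and \code{seed}.
#' @return list with \code{lambda} (selected), \code{criterion} (named by
#'   grid value).
#' @export
select_lambda_cv <- function(whitened, reference, config) {
  stopifnot(inherits(config, "fusion_config"))
  whitened <- lapply(whitened, function(w) if (is.list(w)) w$y else
    as.matrix(w))
  n <- nrow(whitened[[1]])
  ref <- as.numeric(reference)
  folds <- with_seed(config$seed,
                     sample(rep_len(seq_len(config$cv_folds), n)))
  crit <- numeric(length(config$lambda_grid))
  names(crit) <- config$lambda_grid
  for (li in seq_along(config$lambda_grid)) {
    cfg <- config
    cfg$lambda <- config$lambda_grid[li]
    vals <- c()
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      if (stats::sd(ref[!tr]) == 0 || stats::sd(ref[tr]) == 0)
        stopf("degenerate reference variance in fold %d", f)
      fit <- suppressWarnings(fit_mcca_with_reference(
        lapply(whitened, function(y) y[tr, , drop = FALSE]),
        ref[tr], cfg))
      for (k in seq_along(whitened)) {
        d_te <- whitened[[k]][!tr, , drop = FALSE] %*% fit$W[[k]][, 1]
        if (stats::sd(d_te) == 0) next
        vals <- c(vals, abs(stats::cor(d_te, ref[!tr])))
      }
    }
    crit[li] <- mean(vals)
  }
  best <- 1L
  for (li in seq_along(crit))
    if (crit[li] > crit[best] + 1e-12) best <- li
  list(lambda = config$lambda_grid[best], criterion = crit)
}
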