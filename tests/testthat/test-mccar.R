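test_that("whitening yields identity covariance and the rank-M PCA approximation", {
  set.seed(41)
  X <- matrix(rnorm(40 * 15), 40, 15) %*% diag(seq(3, 0.2, length = 15))
  w <- whiten(X, 5)
  expect_lt(max(abs(crossprod(w$y) / (nrow(X) - 1) - diag(5))), 1e-8)
  expect_lt(max(abs(colMeans(w$y))), 1e-12)
  # dewhitening reproduces the best rank-5 approximation (SVD oracle)
  Xc <- scale(X, scale = FALSE)
  s <- svd(Xc)
  best5 <- s$u[, 1:5] %*% diag(s$d[1:5]) %*% t(s$v[, 1:5])
  expect_equal(w$y %*% w$dewhiten, best5, ignore_attr = TRUE,
               tolerance = 1e-8)
  # full rank: exact reconstruction
  wf <- whiten(X, 15)
  expect_lt(max(abs(wf$y %*% wf$dewhiten - Xc)), 1e-8)
  expect_error(whiten(X, 16), "rank")
})

test_that("with lambda = 0, K = 2, M = 1 the fit equals classical CCA", {
  for (s in 1:5) {
    set.seed(400 + s)
    X <- matrix(rnorm(60 * 8), 60, 8)
    Y <- matrix(rnorm(60 * 6), 60, 6)
    fit <- fit_mcca_with_reference(
      list(whiten(X, 8), whiten(Y, 6)), rnorm(60),
      fusion_config(n_components = 1, lambda = 0, tol = 1e-12,
                    max_iter = 5000))
    achieved <- abs(cor(fit$variates[[1]][, 1], fit$variates[[2]][, 1]))
    expect_equal(achieved, cca_first_correlation(X, Y), tolerance = 1e-6)
  }
})

test_that("duplicate datasets give canonical correlations of one", {
  set.seed(42)
  X <- matrix(rnorm(50 * 10), 50, 10)
  w <- whiten(X, 6)
  fit <- fit_mcca_with_reference(list(w, w), rnorm(50),
                                 fusion_config(n_components = 6, lambda = 0))
  for (m in 1:6)
    expect_equal(abs(cor(fit$variates[[1]][, m], fit$variates[[2]][, m])),
                 1, tolerance = 1e-6)
})

test_that("objective trace is monotone and variates are uncorrelated within modality", {
  co <- small_cohort(n_pat = 40, n_con = 40, p = 100, seed = 43)
  wh <- lapply(co$modalities, function(f)
    whiten(normalize_modality(f), 4))
  fit <- fit_mcca_with_reference(wh, co$reference$beta,
                                 fusion_config(n_components = 4,
                                               lambda = 0.5))
  expect_true(all(diff(fit$objective_trace) >= -1e-10))
  expect_true(fit$converged)
  for (k in 1:3) {
    cc <- cor(fit$variates[[k]])
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  }
  # components come out sorted by objective contribution
  expect_true(all(diff(fit$component_objective) <= 1e-10))
})

test_that("the reference term pulls the top component toward the reference", {
  co <- small_cohort(n_pat = 50, n_con = 50, p = 150, rho = 0.5, seed = 44)
  prep <- lapply(co$modalities, normalize_modality)
  wh <- lapply(prep, whiten, M = 5)
  ref <- co$reference$beta
  cors <- sapply(c(0, 0.5), function(l) {
    fit <- fit_mcca_with_reference(wh, ref,
                                   fusion_config(n_components = 5,
                                                 lambda = l))
    sapply(1:3, function(k) abs(cor(fit$variates[[k]][, 1], ref)))
  })
  expect_true(all(cors[, 2] >= cors[, 1] - 1e-8))
})

test_that("joint ICA recovers a planted 2 x 2 mixing of sparse sources", {
  set.seed(45)
  p <- 2000
  S <- matrix(0, 2, p)
  for (i in 1:2) {
    idx <- sample(p, 200)
    S[i, idx] <- rexp(200) - rexp(200)
  }
  A <- matrix(c(1, 0.8, -0.5, 1.2), 2, 2)
  res <- joint_ica(A %*% S, fusion_config(n_components = 2, seed = 45))
  cors <- abs(cor(t(res$maps), t(S)))
  perm <- apply(cors, 1, which.max)
  expect_equal(sort(perm), 1:2)                    # a true permutation
  expect_gt(min(cors[cbind(1:2, perm)]), 0.99)
})

test_that("already-independent sparse rows give a near-signed-permutation unmixing", {
  set.seed(46)
  p <- 3000
  S <- matrix(0, 3, p)
  for (i in 1:3) { idx <- sample(p, 300); S[i, idx] <- rexp(300) - rexp(300) }
  res <- joint_ica(S, fusion_config(n_components = 3, seed = 46))
  U <- res$unmixing
  U <- U / apply(abs(U), 1, max)                   # row-normalized
  perm <- apply(abs(U), 1, which.max)
  expect_equal(sort(perm), 1:3)
  off <- abs(U); off[cbind(1:3, perm)] <- 0
  expect_lt(max(off), 0.1)
})

test_that("Gaussian sources still run to numeric completion", {
  set.seed(47)
  X <- matrix(rnorm(3 * 1000), 3, 1000)
  res <- suppressWarnings(joint_ica(X, fusion_config(n_components = 3,
                                                     seed = 47)))
  expect_true(all(is.finite(res$maps)))
  expect_equal(dim(res$unmixing), c(3, 3))
})

test_that("subject loadings are the least-squares projection", {
  set.seed(48)
  maps <- matrix(rnorm(4 * 80), 4, 80)
  A_true <- matrix(rnorm(200 * 4), 200, 4)
  X <- A_true %*% maps
  expect_equal(compute_subject_loadings(X, maps), A_true,
               tolerance = 1e-8, ignore_attr = TRUE)
  # with noise, per-column recovery stays high
  Xn <- X + matrix(rnorm(200 * 80, sd = 0.1), 200, 80)
  An <- compute_subject_loadings(Xn, maps)
  expect_true(all(diag(cor(An, A_true)) > 0.95))
  # duplicated map row -> rank deficiency error
  expect_error(compute_subject_loadings(X, maps[c(1, 1, 2, 3), ]),
               "rank deficient")
})

test_that("lambda cross-validation: singleton grid, planted signal, null reference", {
  co <- small_cohort(n_pat = 40, n_con = 40, p = 100, rho = 0.6, seed = 49)
  wh <- lapply(co$modalities, function(f) whiten(normalize_modality(f), 3))
  ref <- co$reference$beta
  one <- select_lambda_cv(wh, ref, fusion_config(n_components = 3,
                                                 lambda_grid = 0.7,
                                                 seed = 1))
  expect_equal(one$lambda, 0.7)

  # two latents shared across modalities: a strong one carrying no
  # reference signal and a weaker one correlated with the reference.
  # Unregularized fusion ranks the strong latent first; only lambda > 0
  # makes the top held-out variate track the reference.
  hits <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 100
    z_strong <- rnorm(n)
    z_ref <- rnorm(n)
    ref <- 0.8 * z_ref + 0.6 * rnorm(n)
    wh <- lapply(1:3, function(k) {
      Y <- cbind(z_strong + 0.2 * rnorm(n),
                 z_ref + 0.6 * rnorm(n),
                 rnorm(n), rnorm(n))
      whiten(Y, 4)
    })
    sel <- select_lambda_cv(wh, ref,
                            fusion_config(n_components = 2,
                                          lambda_grid = c(0, 0.5, 1),
                                          cv_folds = 4, seed = s))
    hits <- hits + (sel$lambda > 0)
  }
  expect_gte(hits, 8)

  # pure-noise reference: criterion flat, no systematic pull to large lambda
  picks <- sapply(1:8, function(s) {
    co <- small_cohort(n_pat = 30, n_con = 30, p = 80, rho = 0, d = 0,
                       seed = 600 + s)
    wh <- lapply(co$modalities, function(f)
      whiten(normalize_modality(f), 3))
    sel <- select_lambda_cv(wh, co$reference$beta,
                            fusion_config(n_components = 3,
                                          lambda_grid = c(0, 0.5, 1),
                                          cv_folds = 4, seed = s))
    expect_lt(max(sel$criterion) - min(sel$criterion), 0.25)
    sel$lambda
  })
  expect_lt(sum(picks == 1), 8)

  co2 <- small_cohort(n_pat = 30, n_con = 30, p = 80, seed = 650)
  wh2 <- lapply(co2$modalities, function(f)
    whiten(normalize_modality(f), 3))
  expect_identical(select_lambda_cv(
    wh2, co2$reference$beta,
    fusion_config(n_components = 3, lambda_grid = c(0, 0.5), seed = 3)),
    select_lambda_cv(wh2, co2$reference$beta,
                     fusion_config(n_components = 3,
                                   lambda_grid = c(0, 0.5), seed = 3)))
})
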