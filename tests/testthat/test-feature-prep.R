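test_that("FC features: counts, clipping, and the Pearson value", {
  set.seed(2)
  ts <- lapply(1:4, function(i) matrix(rnorm(50 * 10), 50, 10))
  fc <- compute_fc(ts)
  expect_equal(ncol(fc$data), 45)          # R(R-1)/2 for R = 10
  expect_equal(fc$modality, "FC")

  # duplicated region: r = 1 clips to atanh(1 - 1e-7)
  ts2 <- list(cbind(ts[[1]][, 1], ts[[1]][, 1], ts[[1]][, 2]))
  fc2 <- compute_fc(ts2)
  expect_equal(fc2$data[1, 1], atanh(1 - 1e-7))

  # hand-computed Pearson r for x = 1,2,3 vs y = 1,2,4
  fc3 <- compute_fc(list(cbind(c(1, 2, 3), c(1, 2, 4))), fisher_z = FALSE)
  expect_equal(fc3$data[1, 1], 1.5 / sqrt(7 / 3), tolerance = 1e-5)
  expect_equal(round(fc3$data[1, 1], 5), 0.98198)
})

test_that("constant region series raise a named error", {
  ts <- list(cbind(rnorm(20), rep(1, 20)))
  expect_error(compute_fc(ts, subject_ids = "subj7"),
               "subj7.*constant.*region.*2")
})

test_that("symmetric vectorization follows the row-major convention and round-trips", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1; m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  expect_equal(vectorize_symmetric(m), c(0.1, 0.2, 0.3))

  set.seed(4)
  for (R in c(2, 4, 7)) {
    a <- matrix(rnorm(R * R), R, R); a <- a + t(a); diag(a) <- 0
    expect_equal(devectorize_symmetric(vectorize_symmetric(a)), a)
  }
  # row-major order at R = 4: element 4 is (2,3), not (1,4)
  b <- matrix(0, 4, 4)
  b[1, 4] <- b[4, 1] <- 99; b[2, 3] <- b[3, 2] <- -5
  v <- vectorize_symmetric(b)
  expect_equal(v[3], 99)   # (1,4)
  expect_equal(v[4], -5)   # (2,3)

  expect_error(devectorize_symmetric(numeric(4)), "R\\(R-1\\)/2")
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(vectorize_symmetric(asym), "symmetric")
})

test_that("covariate regression matches the normal-equations oracle", {
  set.seed(8)
  n <- 8
  covs <- data.frame(age = rnorm(n, 30, 5), sex = rbinom(n, 1, 0.5))
  des <- cohort_design(sprintf("S%d", 1:n),
                       rep(c("control", "patient"), each = 4),
                       covariates = covs)
  X <- matrix(rnorm(n * 5), n, 5)
  f <- modality_features("FA", X, subject_ids = sprintf("S%d", 1:n))
  res <- regress_covariates(f, des, c("age", "sex"))
  expect_true(res$residualized)

  D <- cbind(1, as.matrix(covs))
  beta_hat <- solve(t(D) %*% D, t(D) %*% X)      # brute-force least squares
  expect_equal(res$data, X - D %*% beta_hat, ignore_attr = TRUE,
               tolerance = 1e-10)
  # residuals orthogonal to every covariate column
  for (j in 1:2)
    expect_lt(max(abs(crossprod(res$data, as.matrix(covs)[, j]))) /
                (norm(res$data, "F") * sqrt(sum(covs[, j]^2))), 1e-8)
})

test_that("regression edge cases: perfect fit, orthogonal covariate, collinearity", {
  n <- 12
  ids <- sprintf("S%d", 1:n)
  age <- rnorm(n)
  des <- cohort_design(ids, rep(c("control", "patient"), 6),
                       covariates = data.frame(age = age,
                                               age2 = 2 * age))
  # feature equal to a covariate -> residuals ~ 0
  f <- modality_features("GMV", cbind(age), subject_ids = ids)
  r <- regress_covariates(f, des, "age")
  expect_lt(max(abs(r$data)), 1e-10)
  # centered feature orthogonal to the covariate is unchanged
  x <- rnorm(n); x <- x - mean(x)
  x <- x - age * sum(x * (age - mean(age))) / sum((age - mean(age))^2)
  x <- x - mean(x)
  f2 <- modality_features("GMV", cbind(x), subject_ids = ids)
  r2 <- regress_covariates(f2, des, "age")
  expect_equal(as.numeric(r2$data), x, tolerance = 1e-10)
  # collinear design errors and names the column
  expect_error(regress_covariates(f, des, c("age", "age2")), "age2")
})

test_that("normalization yields pooled SD one, idempotence and scale invariance", {
  set.seed(10)
  f <- modality_features("FA", matrix(rnorm(30 * 20, 5, 3), 30, 20))
  nf <- normalize_modality(f)
  expect_true(nf$normalized)
  expect_equal(sd(as.vector(nf$data)), 1, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(nf$data))), 1e-12)
  # idempotent
  expect_equal(normalize_modality(nf)$data, nf$data, tolerance = 1e-12)
  # scale invariant
  f5 <- modality_features("FA", 5 * f$data)
  expect_equal(normalize_modality(f5)$data, nf$data, tolerance = 1e-12)
  expect_error(normalize_modality(
    modality_features("FA", matrix(1, 4, 3))), "zero pooled variance")
})

test_that("residualization then normalization commutes with subject reordering", {
  co <- small_cohort(n_pat = 10, n_con = 10, p = 25, seed = 13)
  f <- co$modalities[[2]]
  des <- co$design
  out1 <- normalize_modality(regress_covariates(f, des, c("age", "sex")))
  perm <- sample(nrow(f$data))
  fp <- modality_features(f$modality, f$data[perm, ], f$feature_ids,
                          f$subject_ids[perm])
  desp <- cohort_design(des$subject_ids[perm], des$group[perm],
                        des$covariates[perm, ], des$clinical[perm, ])
  out2 <- normalize_modality(regress_covariates(fp, desp, c("age", "sex")))
  expect_equal(out2$data, out1$data[perm, ], tolerance = 1e-10)
})
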