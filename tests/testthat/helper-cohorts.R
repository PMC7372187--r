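# Small synthetic cohorts used across test files.

small_cohort <- function(n_pat = 30, n_con = 30, p = 120, M_true = 3,
                         rho = 0.5, d = 0.8, noise = 0.5, seed = 1,
                         K = 3) {
  generate_multimodal(simulation_config(
    n_patients = n_pat, n_controls = n_con, n_modalities = K,
    features_per_modality = rep(p, K), n_sources = M_true,
    rho_ref = rho, group_effect_d = d, noise_sd = noise, seed = seed))
}

# independent classical-CCA oracle: first canonical correlation from the
# generalized-eigenvalue formulation on raw (centered) data
cca_first_correlation <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  n <- nrow(X)
  Sxx <- crossprod(X) / (n - 1); Syy <- crossprod(Y) / (n - 1)
  Sxy <- crossprod(X, Y) / (n - 1)
  Mx <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  sqrt(max(Re(eigen(Mx, only.values = TRUE)$values)))
}

# brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k/m*alpha
bh_stepup_bruteforce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}
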