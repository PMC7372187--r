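test_that("BH step-up matches brute-force enumeration and the worked list", {
  fdr <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(fdr$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(diff(sort(fdr$q)) >= 0))
  expect_equal(bh_fdr(1)$q, 1)
  expect_equal(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))
  one <- bh_fdr(0.04, alpha = 0.05)
  expect_true(one$reject)
  expect_equal(one$q, 0.04)

  set.seed(51)
  for (i in 1:100) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    alpha <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_equal(bh_fdr(p, alpha)$reject, bh_stepup_bruteforce(p, alpha))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("summary t-test reproduces the pyrosequencing statistic and raw-data t", {
  st <- summary_ttest(31.8, 1.5, 10, 21.9, 3.2, 10, variant = "pooled")
  expect_equal(round(st$t, 1), 8.9)
  sw <- summary_ttest(31.8, 1.5, 10, 21.9, 3.2, 10, variant = "welch")
  expect_equal(sw$t, st$t)                # equal n: same statistic
  expect_lt(sw$p, 1e-5)

  expect_equal(summary_ttest(5, 1, 8, 5, 2, 9)$t, 0)

  set.seed(52)
  x <- rnorm(14, 1); y <- rnorm(9, 0.3, 2)
  for (v in c("pooled", "welch")) {
    tt <- t.test(x, y, var.equal = v == "pooled")
    ss <- summary_ttest(mean(x), sd(x), 14, mean(y), sd(y), 9, v)
    expect_equal(ss$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(ss$p, tt$p.value, tolerance = 1e-10)
  }
  expect_error(summary_ttest(1, 0, 5, 2, 1, 5), "SD")
})

test_that("sign alignment enforces control > patient and is an involution", {
  set.seed(53)
  g <- factor(rep(c("control", "patient"), each = 20),
              levels = c("control", "patient"))
  loadings <- list(FA = matrix(rnorm(40 * 3), 40, 3))
  maps <- list(FA = matrix(rnorm(3 * 50), 3, 50))
  al <- align_component_sign(loadings, maps, g)
  for (m in 1:3)
    expect_gte(mean(al$loadings$FA[g == "control", m]),
               mean(al$loadings$FA[g == "patient", m]))
  # idempotent on aligned input, involution on negated input
  al2 <- align_component_sign(al$loadings, al$maps, g)
  expect_equal(al2$loadings, al$loadings)
  expect_equal(al2$maps, al$maps)
  neg <- align_component_sign(lapply(al$loadings, `-`),
                              lapply(al$maps, `-`), g)
  expect_equal(neg$loadings, al$loadings)
  expect_equal(neg$maps, al$maps)
})

test_that("group t-tests on loadings: null, planted power, summary consistency", {
  g <- factor(rep(c("control", "patient"), each = 25),
              levels = c("control", "patient"))
  same <- rep(1:25, 2)
  tab0 <- group_ttest_loadings(list(FC = cbind(same)), g)
  expect_equal(tab0$t, 0)
  expect_equal(tab0$p, 1)

  detected <- 0; false_pos <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    gg <- factor(rep(c("control", "patient"), each = 50),
                 levels = c("control", "patient"))
    A <- matrix(rnorm(100 * 4), 100, 4)
    A[gg == "patient", 2] <- A[gg == "patient", 2] - 1.5
    tab <- group_ttest_loadings(list(mod = A), gg)
    detected <- detected + (tab$q[2] < 0.05)
    false_pos <- false_pos + sum(tab$q[-2] < 0.05)
  }
  expect_equal(detected, 20)            # d = 1.5 at n = 50/50: full power
  expect_lte(false_pos / (20 * 3), 0.1) # null columns rarely dragged in

  set.seed(54)
  a <- rnorm(30); g2 <- factor(rep(c("control", "patient"), 15),
                               levels = c("control", "patient"))
  tab <- group_ttest_loadings(list(m = cbind(a)), g2)
  ss <- summary_ttest(mean(a[g2 == "control"]), sd(a[g2 == "control"]), 15,
                      mean(a[g2 == "patient"]), sd(a[g2 == "patient"]), 15,
                      "welch")
  expect_equal(tab$t, ss$t, tolerance = 1e-10)
  expect_equal(tab$p, ss$p, tolerance = 1e-10)
})

test_that("reference and clinical correlations match the formula oracle", {
  set.seed(55)
  n <- 60
  ref <- rnorm(n)
  A <- cbind(ref, rnorm(n))
  tab <- correlate_with_reference(list(m = A), ref)
  expect_equal(tab$r_ref[1], 1, tolerance = 1e-12)
  r_oracle <- sum((A[, 2] - mean(A[, 2])) * (ref - mean(ref))) /
    ((n - 1) * sd(A[, 2]) * sd(ref))
  expect_equal(tab$r_ref[2], r_oracle, tolerance = 1e-12)
  expect_true(all(tab$q_ref >= tab$p_ref - 1e-15))

  # planted clinical effect recovered at the configured level
  co <- small_cohort(n_pat = 100, n_con = 100, seed = 56, p = 50)
  z <- co$truth$latent
  ct <- correlate_with_clinical(list(FC = z), co$design$clinical)
  r_mmse <- ct$r[ct$score == "MMSE"]
  expect_lt(abs(r_mmse - 0.35), 0.15)
  # onset exists for patients only and is dropped pairwise
  expect_equal(ct$n[ct$score == "onset_age"], 100)
})

test_that("partial correlation removes the group effect", {
  set.seed(57)
  n <- 200
  g <- factor(rep(c("control", "patient"), each = n / 2),
              levels = c("control", "patient"))
  gi <- as.numeric(g == "patient")
  # reference carried almost entirely by the group indicator: the strong
  # marginal correlation collapses to sampling noise once the group is
  # regressed out
  x <- rnorm(n) + 2 * gi
  ref_g <- gi + 0.01 * rnorm(n)
  expect_gt(abs(cor(x, ref_g)), 0.5)
  pc <- partial_correlation(x, ref_g, g)
  expect_lt(abs(pc$r_partial), 3 / sqrt(n))

  # group-independent shared latent: partial r ~ marginal r
  lat <- rnorm(n)
  x2 <- lat + rnorm(n); y2 <- lat + rnorm(n)
  pc2 <- partial_correlation(x2, y2, g)
  expect_lt(abs(pc2$r_partial - cor(x2, y2)), 0.05)

  # equals the correlation of explicit OLS residuals
  y3 <- rnorm(n) + gi
  rx <- residuals(lm(x ~ gi)); ry <- residuals(lm(y3 ~ gi))
  expect_equal(partial_correlation(x, y3, g)$r_partial, cor(rx, ry),
               tolerance = 1e-10)
})

test_that("z-scored maps: moments, Gaussian tail mass, degenerate input", {
  set.seed(58)
  tm <- zscore_threshold_map(rnorm(1e5, 3, 2), 2)
  expect_equal(mean(tm$z_map), 0, tolerance = 1e-12)
  expect_equal(sd(tm$z_map), 1, tolerance = 1e-12)
  expect_lt(abs(mean(tm$mask) - 0.0455), 0.003)
  tm9 <- zscore_threshold_map(rnorm(1000), 50)
  expect_false(any(tm9$mask))
  expect_error(zscore_threshold_map(rep(2, 10), 2), "zero variance")
})

test_that("spatial similarity is Pearson correlation with sign absorbed", {
  set.seed(59)
  a <- rnorm(500); b <- a + rnorm(500)
  expect_equal(spatial_similarity(a, a)$r, 1)
  expect_equal(spatial_similarity(a, -a)$r, -1)
  expect_equal(spatial_similarity(a, -a)$abs_r, 1)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    (499 * sd(a) * sd(b))
  expect_equal(spatial_similarity(a, b)$r, r_oracle, tolerance = 1e-12)
  expect_error(spatial_similarity(a, b[1:10]), "feature spaces")
})

test_that("the combined statistics table applies the joint selection rule", {
  set.seed(60)
  n <- 120
  g <- factor(rep(c("control", "patient"), each = n / 2),
              levels = c("control", "patient"))
  lat <- rnorm(n); lat[g == "patient"] <- lat[g == "patient"] - 1.2
  ref <- 0.6 * scale(lat)[, 1] + 0.8 * rnorm(n)
  loadings <- list(FC = cbind(lat + 0.2 * rnorm(n), rnorm(n)),
                   FA = cbind(lat + 0.2 * rnorm(n), rnorm(n)))
  tab <- component_statistics(loadings, ref, g)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_true(all(tab$selected == (tab$q < 0.05 & tab$q_ref < 0.05)))
  sel <- tab[tab$component == 1, ]
  expect_true(all(sel$selected))
  expect_false(any(tab$selected[tab$component == 2]))
})
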