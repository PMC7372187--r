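#' Simulation configuration for a synthetic multimodal cohort
#'
#' Defines the statistical structure of a simulated imaging-epigenetics
#' cohort: per-modality data are generated as subject loadings times sparse
#' spatial sources plus Gaussian noise, with one joint component shared
#' across modalities whose loadings (i) differ between patients and controls
#' and (ii) correlate with a per-subject reference signal (a methylation
#' beta-value at one CpG site).
#'
#' @param n_patients,n_controls number of subjects per group.
#' @param n_modalities number of modalities K.
#' @param features_per_modality integer vector of length K: features per
#'   modality.
#' @param n_sources true number of spatial sources per modality.
#' @param target_component index (in 1..n_sources) of the joint component
#'   shared across modalities.
#' @param rho_ref target Pearson correlation between the shared latent and
#'   the reference, in (-1, 1). Negative values emulate the hypermethylation
#'   /lower-loading direction.
#' @param group_effect_d standardized shift of the target loading,
#'   controls minus patients (positive: controls higher).
#' @param clinical_effects named numeric vector of target correlations
#'   between clinical scores and the target loading. Recognised names:
#'   \code{onset_age} (patients only), \code{MMSE}, \code{HSCT}.
#' @param noise_sd additive Gaussian noise SD on the data matrices.
#' @param source_sparsity fraction of nonzero entries per source row.
#' @param loading_noise_sd SD of the per-modality perturbation of the shared
#'   target loading.
#' @param seed integer RNG seed; all generator randomness flows through it.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_patients = 100L, n_controls = 100L,
                              n_modalities = 3L,
                              features_per_modality = c(500L, 500L, 500L),
                              n_sources = 5L, target_component = 1L,
                              rho_ref = -0.4, group_effect_d = 0.8,
                              clinical_effects = c(onset_age = 0.6,
                                                   MMSE = 0.35, HSCT = 0.3),
                              noise_sd = 0.5, source_sparsity = 0.1,
                              loading_noise_sd = 0.3, seed = 1L) {
  assert_count(n_patients, "n_patients")
  assert_count(n_controls, "n_controls")
  assert_count(n_modalities, "n_modalities")
  assert_count(n_sources, "n_sources")
  if (length(features_per_modality) != n_modalities)
    stopf("features_per_modality must have length n_modalities (%d)",
          n_modalities)
  for (p in features_per_modality) assert_count(p, "features_per_modality")
  if (any(features_per_modality < n_sources))
    stopf("every modality needs features >= n_sources")
  if (target_component < 1L || target_component > n_sources)
    stopf("target_component out of range 1..%d", n_sources)
  if (!is.finite(rho_ref) || abs(rho_ref) >= 1)
    stopf("rho_ref must be finite with |rho_ref| < 1")
  if (!is.finite(group_effect_d)) stopf("group_effect_d must be finite")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stopf("noise_sd must be a nonnegative real")
  if (!is.finite(source_sparsity) || source_sparsity <= 0 ||
      source_sparsity > 1)
    stopf("source_sparsity must lie in (0, 1]")
  if (length(clinical_effects) &&
      (is.null(names(clinical_effects)) || any(!is.finite(clinical_effects)) ||
       any(abs(clinical_effects) >= 1)))
    stopf("clinical_effects must be a named vector of correlations in (-1,1)")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_modalities = as.integer(n_modalities),
    features_per_modality = as.integer(features_per_modality),
    n_sources = as.integer(n_sources),
    target_component = as.integer(target_component),
    rho_ref = rho_ref, group_effect_d = group_effect_d,
    clinical_effects = clinical_effects, noise_sd = noise_sd,
    source_sparsity = source_sparsity, loading_noise_sd = loading_noise_sd,
    seed = as.integer(seed)), class = "simulation_config")
}

# sparse Laplacian source matrix [m x p]; each row has round(sparsity*p)
# nonzero double-exponential entries and unit root-mean-square over all p.
rlaplace <- function(n, b = 1) {
  u <- stats::runif(n, -0.5, 0.5)
  -b * sign(u) * log(1 - 2 * abs(u))
}

make_sources <- function(m, p, sparsity) {
  s <- matrix(0, m, p)
  k <- max(1L, round(sparsity * p))
  for (i in seq_len(m)) {
    idx <- sample.int(p, k)
    v <- rlaplace(k)
    v <- v / sqrt(sum(v^2) / p)      # row RMS over all p entries = 1
    s[i, idx] <- v
  }
  s
}

#' Generate a synthetic multimodal cohort with planted ground truth
#'
#' Each modality k is built as \code{loadings_k \%*\% sources_k + noise}.
#' The target column of every modality's loading matrix is one shared latent
#' (plus small modality-specific noise); patients' latent values are shifted
#' down by \code{group_effect_d} standard deviations; the reference is that
#' latent mixed with independent noise so its correlation with the latent is
#' \code{rho_ref}, then mapped onto the methylation beta-value scale.
#' Clinical scores are correlated with the latent as configured.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a list with elements \code{modalities} (list of
#'   \code{\link{modality_features}}), \code{reference} (data.frame
#'   subject_id, beta), \code{design} (a \code{\link{cohort_design}}) and
#'   \code{truth} (sources, loadings, latent, target index, config).
#' @export
generate_multimodal <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_patients + config$n_controls
    K <- config$n_modalities
    M <- config$n_sources
    subject_ids <- sprintf("S%03d", seq_len(n))
    group <- as_group_factor(c(rep("patient", config$n_patients),
                               rep("control", config$n_controls)))
    is_pat <- group == "patient"

    # shared latent behind the target component; controls > patients
    z <- stats::rnorm(n)
    z[is_pat] <- z[is_pat] - config$group_effect_d

    # reference: latent + independent noise at the configured correlation,
    # reported on the beta-value scale
    rho <- config$rho_ref
    zs <- standardize(z)
    ref_latent <- rho * zs + sqrt(1 - rho^2) * stats::rnorm(n)
    beta <- pmin(pmax(0.31 + 0.06 * ref_latent, 1e-3), 1 - 1e-3)

    sources <- vector("list", K)
    loadings <- vector("list", K)
    modalities <- vector("list", K)
    modality_names <- if (K == 3L) c("FC", "FA", "GMV") else
      paste0("MOD", seq_len(K))
    for (k in seq_len(K)) {
      p <- config$features_per_modality[k]
      sources[[k]] <- make_sources(M, p, config$source_sparsity)
      A <- matrix(stats::rnorm(n * M), n, M)
      A[, config$target_component] <- z +
        config$loading_noise_sd * stats::rnorm(n)
      loadings[[k]] <- A
      X <- A %*% sources[[k]]
      if (config$noise_sd > 0)
        X <- X + config$noise_sd * matrix(stats::rnorm(n * p), n, p)
      modalities[[k]] <- modality_features(
        modality = modality_names[k], data = X,
        feature_ids = sprintf("%s_f%05d", modality_names[k], seq_len(p)),
        subject_ids = subject_ids)
    }

    # nuisance covariates, independent of the planted structure
    age <- round(stats::rnorm(n, 31, 12), 1)
    sex <- stats::rbinom(n, 1, 0.5)
    meanFD <- round(abs(stats::rnorm(n, 0.15, 0.05)), 4)

    clin <- data.frame(row.names = subject_ids)
    mk_score <- function(r, mu, sdev, lo = -Inf, hi = Inf) {
      y <- r * zs + sqrt(1 - r^2) * stats::rnorm(n)
      pmin(pmax(mu + sdev * y, lo), hi)
    }
    ce <- config$clinical_effects
    clin$onset_age <- if ("onset_age" %in% names(ce))
      round(mk_score(ce[["onset_age"]], 22.9, 13.0, lo = 1), 1) else NA_real_
    clin$onset_age[!is_pat] <- NA_real_     # onset defined for patients only
    clin$MMSE <- if ("MMSE" %in% names(ce))
      round(mk_score(ce[["MMSE"]], 28.5, 3.0, lo = 0, hi = 30), 0) else
        NA_real_
    clin$HSCT <- if ("HSCT" %in% names(ce))
      round(mk_score(ce[["HSCT"]], 12.3, 4.2, lo = 0), 1) else NA_real_

    design <- cohort_design(
      subject_ids = subject_ids, group = group,
      covariates = data.frame(age = age, sex = sex, meanFD = meanFD,
                              row.names = subject_ids),
      clinical = clin)

    list(modalities = modalities,
         reference = data.frame(subject_id = subject_ids, beta = beta,
                                stringsAsFactors = FALSE),
         design = design,
         truth = list(sources = sources, loadings = loadings, latent = z,
                      target_component = config$target_component,
                      config = config))
  })
}

# Beta(a, b) parameters from mean/SD by method of moments
beta_moments <- function(m, s) {
  if (any(m <= 0 | m >= 1)) stopf("Beta mean must lie strictly in (0, 1)")
  v <- s^2
  if (any(v >= m * (1 - m)))
    stopf("SD %.3g incompatible with Beta mean %.3g", max(s), m[which.max(
      v - m * (1 - m))])
  k <- m * (1 - m) / v - 1
  list(a = m * k, b = (1 - m) * k)
}

#' Generate a methylation beta-value matrix with planted differential loci
#'
#' Beta-values are drawn from Beta distributions parameterised by mean/SD
#' via method of moments. At target loci the patient mean exceeds the
#' control mean by \code{delta}; all other loci share one mean per locus in
#' both groups.
#'
#' @param n_patients,n_controls subjects per group.
#' @param n_loci number of CpG loci.
#' @param target_loci integer indices of differentially methylated loci.
#' @param delta patient-minus-control mean difference at target loci
#'   (default 0.06: patient mean 0.34 vs control 0.28).
#' @param control_mean control-group mean beta at target loci.
#' @param sd within-group SD of beta at every locus.
#' @param seed integer RNG seed.
#' @return list with \code{beta} (subjects x loci matrix in \[0,1\], dimnames
#'   set), and \code{group} (factor control/patient).
#' @export
generate_methylation <- function(n_patients, n_controls, n_loci,
                                 target_loci = integer(0), delta = 0.06,
                                 control_mean = 0.28, sd = 0.06, seed = 1L) {
  assert_count(n_patients, "n_patients"); assert_count(n_controls, "n_controls")
  assert_count(n_loci, "n_loci")
  if (length(target_loci) &&
      (any(target_loci < 1) || any(target_loci > n_loci)))
    stopf("target_loci out of range 1..%d", n_loci)
  if (!is.finite(delta)) stopf("delta must be finite")
  if (control_mean + delta <= 0 || control_mean + delta >= 1 ||
      control_mean <= 0 || control_mean >= 1)
    stopf("delta pushes a group mean outside (0, 1)")
  with_seed(seed, {
    n <- n_patients + n_controls
    group <- as_group_factor(c(rep("patient", n_patients),
                               rep("control", n_controls)))
    # per-locus baseline means for null loci; SD-compatible range
    mu <- stats::runif(n_loci, 0.08, 0.92)
    mu[target_loci] <- control_mean
    beta <- matrix(NA_real_, n, n_loci,
                   dimnames = list(sprintf("S%03d", seq_len(n)),
                                   sprintf("cg%06d", seq_len(n_loci))))
    for (j in seq_len(n_loci)) {
      m_pat <- if (j %in% target_loci) mu[j] + delta else mu[j]
      pc <- beta_moments(mu[j], sd)
      pp <- beta_moments(m_pat, sd)
      beta[group == "control", j] <-
        stats::rbeta(n_controls, pc$a, pc$b)
      beta[group == "patient", j] <-
        stats::rbeta(n_patients, pp$a, pp$b)
    }
    list(beta = beta, group = group)
  })
}
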