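#' Run the full reference-guided fusion pipeline on a cohort
#'
#' End-to-end workflow: covariate regression (age and sex for every
#' modality, mean framewise displacement additionally for FC) and modality
#' normalization; model-order selection by MDL (or a fixed order);
#' optional cross-validated selection of the reference weight lambda;
#' multi-set CCA with reference; joint ICA refinement of the concatenated
#' maps; subject loadings recomputed against the final joint maps; sign
#' alignment to control > patient; group t-tests, reference and partial
#' correlations with FDR over the components x modalities family; clinical
#' correlations for the selected joint component; and |Z|-thresholded maps.
#'
#' Subjects lacking a reference value are dropped before fusion (the
#' fusion requires a complete reference).
#'
#' @param cohort list with \code{modalities} (list of
#'   \code{\link{modality_features}}), \code{reference} (data.frame
#'   subject_id, beta) and \code{design} (a \code{\link{cohort_design}}),
#'   as produced by \code{\link{generate_multimodal}} or
#'   \code{\link{read_cohort}}.
#' @param n_components "auto" (MDL per modality, maximum across
#'   modalities) or a fixed integer.
#' @param lambda numeric reference weight, or "cv" for grid
#'   cross-validation.
#' @param lambda_grid,cv_folds cross-validation settings (used when
#'   \code{lambda = "cv"}).
#' @param alpha FDR level for component selection.
#' @param ica_algorithm "infomax" or "fastica-logcosh".
#' @param thresholds named |Z| thresholds: element "FC" for edge maps,
#'   "default" for voxel maps.
#' @param variant t-test variant, "welch" or "pooled".
#' @param covariate_names nuisance covariates to regress (meanFD is added
#'   for FC when present).
#' @param whiten_rank PCA rank retained before fusion; default NULL keeps
#'   exactly \code{n_components} (the usual square-mixing setup). A larger
#'   rank searches canonical weights in a bigger subspace (full rank makes
#'   the two-modality, one-component, lambda = 0 path coincide with
#'   classical CCA).
#' @param max_iter,tol optimizer settings.
#' @param seed master seed (ICA init, CV folds).
#' @return object of class \code{fusion_result}: prepared data, the
#'   decomposition (weights, variates, maps, loadings), the statistics
#'   table, selected joint component(s), thresholded maps, clinical
#'   correlations and a run manifest.
#' @export
fuse_cohort <- function(cohort, n_components = "auto", lambda = 0.5,
                        lambda_grid = c(0, 0.25, 0.5, 1), cv_folds = 5L,
                        alpha = 0.05,
                        ica_algorithm = "infomax",
                        thresholds = c(FC = 3, default = 2),
                        variant = "welch",
                        covariate_names = c("age", "sex"),
                        whiten_rank = NULL,
                        max_iter = 1000L, tol = 1e-6, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  modalities <- cohort$modalities
  design <- cohort$design
  reference <- cohort$reference
  K <- length(modalities)
  if (K < 2) stopf("need at least 2 modalities")

  # subject alignment and complete-reference subset
  ids <- modalities[[1]]$subject_ids
  for (k in seq_len(K))
    if (!identical(modalities[[k]]$subject_ids, ids))
      stopf("subject order differs between modalities '%s' and '%s': %s",
            modalities[[1]]$modality, modalities[[k]]$modality,
            paste(utils::head(setdiff(
              union(ids, modalities[[k]]$subject_ids),
              intersect(ids, modalities[[k]]$subject_ids)), 5),
              collapse = ", "))
  ref_map <- stats::setNames(reference$beta, reference$subject_id)
  keep <- ids %in% names(ref_map)[is.finite(ref_map)]
  if (!all(keep)) {
    message(sum(!keep), " subject(s) without reference dropped")
    modalities <- lapply(modalities, function(f) modality_features(
      f$modality, f$data[keep, , drop = FALSE], f$feature_ids,
      f$subject_ids[keep], f$normalized, f$residualized))
    ids <- ids[keep]
  }
  ref <- unname(ref_map[ids])
  di <- match(ids, design$subject_ids)
  if (any(is.na(di))) stopf("subjects missing from design: %s",
                            paste(utils::head(ids[is.na(di)], 5),
                                  collapse = ", "))
  group <- design$group[di]
  covars <- design$covariates[di, , drop = FALSE]
  clinical <- design$clinical[di, , drop = FALSE]
  sub_design <- cohort_design(ids, group, covars, clinical)

  # preparation: residualize then normalize
  prepared <- lapply(modalities, function(f) {
    cn <- covariate_names
    if (identical(f$modality, "FC") && "meanFD" %in% colnames(covars))
      cn <- union(cn, "meanFD")
    normalize_modality(regress_covariates(f, sub_design, cn))
  })
  names(prepared) <- vapply(prepared, function(f) f$modality, "")

  # model order
  orders <- NULL
  if (identical(n_components, "auto")) {
    orders <- lapply(prepared, estimate_order_mdl)
    M <- max(2L, max(vapply(orders, function(o) o$selected_order, 1L)))
  } else M <- assert_count(n_components, "n_components")
  # cap at the numerical rank left after residualization and centering
  ranks <- vapply(prepared, function(f) {
    d <- svd(sweep(f$data, 2, colMeans(f$data)), nu = 0, nv = 0)$d
    sum(d > max(dim(f$data)) * .Machine$double.eps * d[1])
  }, 1L)
  M <- min(M, min(ranks))
  r <- if (is.null(whiten_rank)) M else
    min(assert_count(whiten_rank, "whiten_rank"), min(ranks))
  r <- max(r, M)
  wh <- lapply(prepared, whiten, M = r)

  # reference weight
  cfg <- fusion_config(n_components = M, lambda = 0.5, max_iter = max_iter,
                       tol = tol, ica_algorithm = ica_algorithm,
                       seed = seed, cv_folds = cv_folds,
                       lambda_grid = lambda_grid)
  cv <- NULL
  if (identical(lambda, "cv")) {
    cv <- select_lambda_cv(wh, ref, cfg)
    cfg$lambda <- cv$lambda
  } else cfg$lambda <- lambda

  mcca <- fit_mcca_with_reference(wh, ref, cfg)

  # canonical maps by regression of prepared data on the variates
  canon_maps <- lapply(seq_len(K), function(k) {
    D <- mcca$variates[[k]]
    solve(crossprod(D), crossprod(D, prepared[[k]]$data))
  })
  p_k <- vapply(prepared, function(f) ncol(f$data), 1L)
  splits <- rep(seq_len(K), p_k)

  ica_converged <- TRUE
  if (M >= 2) {
    ica <- joint_ica(do.call(cbind, canon_maps), cfg)
    ica_converged <- ica$converged
    maps <- lapply(seq_len(K), function(k)
      ica$maps[, splits == k, drop = FALSE])
  } else {
    maps <- lapply(canon_maps, function(m) m / stats::sd(m[1, ]))
  }
  names(maps) <- names(prepared)
  loadings <- lapply(seq_len(K), function(k)
    compute_subject_loadings(prepared[[k]], maps[[k]]))
  names(loadings) <- names(prepared)

  al <- align_component_sign(loadings, maps, group)
  loadings <- al$loadings; maps <- al$maps

  stats_tab <- component_statistics(loadings, ref, group, alpha, variant)
  joint_selected <- which(Reduce(`&`, lapply(names(loadings), function(m)
    stats_tab$selected[stats_tab$modality == m][seq_len(M)])))

  # clinical correlations for the selected joint component(s)
  clinical_tab <- NULL
  if (length(joint_selected) && !is.null(clinical)) {
    clinical_tab <- do.call(rbind, lapply(joint_selected, function(jc) {
      tb <- correlate_with_clinical(
        lapply(loadings, function(A) A[, jc]), clinical)
      tb$component <- jc
      tb
    }))
  }

  thr_maps <- lapply(names(maps), function(mname) {
    th <- if (mname %in% names(thresholds)) thresholds[[mname]] else
      thresholds[["default"]]
    lapply(seq_len(M), function(m)
      zscore_threshold_map(maps[[mname]][m, ], th))
  })
  names(thr_maps) <- names(maps)

  manifest <- list(
    package = "refusion",
    version = as.character(utils::packageVersion("refusion")),
    seed = seed, n_components = M,
    order_selection = if (is.null(orders)) "fixed" else "mdl-auto",
    lambda = cfg$lambda,
    lambda_selection = if (is.null(cv)) "fixed" else "cv",
    alpha = alpha, ica_algorithm = ica_algorithm, variant = variant,
    n_subjects = length(ids), modalities = names(prepared),
    converged = mcca$converged, ica_converged = ica_converged,
    achieved_objective = mcca$objective_trace[length(mcca$objective_trace)],
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))

  structure(list(prepared = prepared, design = sub_design,
                 reference = ref, orders = orders, whitening = wh,
                 mcca = mcca, maps = maps, loadings = loadings,
                 statistics = stats_tab, joint_selected = joint_selected,
                 clinical = clinical_tab, thresholded_maps = thr_maps,
                 cv = cv, config = cfg, manifest = manifest),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<fusion_result> %d subjects, %d modalities, M = %d, lambda = %g\n",
    "  converged: %s | joint component(s) selected: %s\n"),
    x$manifest$n_subjects, length(x$maps), x$config$n_components,
    x$config$lambda, x$manifest$converged,
    if (length(x$joint_selected)) paste(x$joint_selected, collapse = ", ")
    else "none"))
  invisible(x)
}
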