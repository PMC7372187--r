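#' Subset a cohort by subject ids
#'
#' @param cohort cohort list (modalities, reference, design, optional
#'   truth).
#' @param ids subject ids to keep, in cohort order.
#' @return the subset cohort.
#' @export
subset_cohort <- function(cohort, ids) {
  all_ids <- cohort$design$subject_ids
  miss <- setdiff(ids, all_ids)
  if (length(miss)) stopf("unknown subject ids: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  keep <- all_ids %in% ids
  modalities <- lapply(cohort$modalities, function(f) {
    ki <- f$subject_ids %in% ids
    modality_features(f$modality, f$data[ki, , drop = FALSE],
                      f$feature_ids, f$subject_ids[ki],
                      f$normalized, f$residualized)
  })
  design <- cohort_design(
    all_ids[keep], cohort$design$group[keep],
    cohort$design$covariates[keep, , drop = FALSE],
    if (!is.null(cohort$design$clinical))
      cohort$design$clinical[keep, , drop = FALSE] else NULL)
  reference <- cohort$reference[cohort$reference$subject_id %in% ids, ,
                                drop = FALSE]
  out <- cohort
  out$modalities <- modalities
  out$design <- design
  out$reference <- reference
  out
}

# representative component of a fusion run for one modality: selected
# (smallest q_ref) if any, otherwise largest |r_ref|
representative_component <- function(result, modality) {
  tab <- result$statistics
  tab <- tab[tab$modality == modality, , drop = FALSE]
  sel <- tab[tab$selected, , drop = FALSE]
  if (nrow(sel)) sel$component[which.min(sel$q_ref)] else
    tab$component[which.max(abs(tab$r_ref))]
}

#' Subset replication of the fusion analysis
#'
#' Reruns the identical pipeline (preparation, fusion, statistics) on
#' defined subject subsets and quantifies agreement with the full-cohort
#' run through pairwise spatial similarity of the representative
#' (selected) component maps, plus overlap masks of features surviving
#' the |Z| threshold in at least two runs.
#'
#' Schemes: \code{"two_thirds"} draws \code{n_repeats} random subsets of
#' floor(2n/3) subjects without replacement, subsampling patients and
#' controls independently to preserve the class ratio; \code{"by_label"}
#' takes explicit subject-id subsets (e.g. left- and right-lateralized
#' patient subgroups with their matched controls).
#'
#' @param cohort cohort list as for \code{\link{fuse_cohort}}.
#' @param scheme "two_thirds" or "by_label".
#' @param n_repeats number of random subsets for "two_thirds".
#' @param subsets named list of subject-id vectors for "by_label".
#' @param seed seed for subset draws (and passed to each fusion run).
#' @param ... further arguments to \code{\link{fuse_cohort}}
#'   (n_components, lambda, alpha, ...).
#' @return object of class \code{similarity_report}: \code{runs} (labels),
#'   \code{similarity} (per modality, pairwise |r| matrix),
#'   \code{similarity_signed}, \code{overlap} (per modality logical
#'   vector), \code{representative} (per run x modality component index),
#'   \code{subsets} (subject ids per run).
#' @export
run_subset_replication <- function(cohort,
                                   scheme = c("two_thirds", "by_label"),
                                   n_repeats = 2L, subsets = NULL,
                                   seed = 1L, ...) {
  scheme <- match.arg(scheme)
  design <- cohort$design
  group <- design$group
  if (scheme == "two_thirds") {
    subsets <- with_seed(seed, {
      lapply(seq_len(n_repeats), function(r) {
        ids <- c()
        for (g in levels(group)) {
          gi <- design$subject_ids[group == g]
          ids <- c(ids, sample(gi, floor(2 * length(gi) / 3)))
        }
        sort(ids)
      })
    })
    names(subsets) <- sprintf("subset_%d", seq_len(n_repeats))
  } else {
    if (is.null(subsets) || is.null(names(subsets)))
      stopf("by_label scheme needs a named list of subject-id subsets")
  }

  dots <- list(...)
  run_one <- function(co) do.call(fuse_cohort,
                                  c(list(cohort = co, seed = seed), dots))
  full <- run_one(cohort)
  M <- full$config$n_components

  results <- list(all = full)
  for (nm in names(subsets)) {
    ids <- subsets[[nm]]
    sub <- subset_cohort(cohort, ids)
    if (length(unique(sub$design$group)) < 2)
      stopf("subset '%s' lost a class", nm)
    if (length(ids) < M + 2)
      stopf("subset '%s' smaller than n_components + 2", nm)
    results[[nm]] <- run_one(sub)
  }
  runs <- names(results)
  mods <- names(full$maps)

  rep_comp <- matrix(NA_integer_, length(runs), length(mods),
                     dimnames = list(runs, mods))
  sim <- sim_signed <- stats::setNames(vector("list", length(mods)), mods)
  overlap <- stats::setNames(vector("list", length(mods)), mods)
  for (mo in mods) {
    rmaps <- lapply(runs, function(rn) {
      cc <- representative_component(results[[rn]], mo)
      rep_comp[rn, mo] <<- cc
      results[[rn]]$maps[[mo]][cc, ]
    })
    R <- length(runs)
    a <- s <- diag(1, R)
    dimnames(a) <- dimnames(s) <- list(runs, runs)
    for (i in seq_len(R - 1)) for (j in (i + 1):R) {
      ss <- spatial_similarity(rmaps[[i]], rmaps[[j]])
      a[i, j] <- a[j, i] <- ss$abs_r
      s[i, j] <- s[j, i] <- ss$r
    }
    sim[[mo]] <- a
    sim_signed[[mo]] <- s
    masks <- vapply(seq_along(runs), function(i) {
      cc <- rep_comp[runs[i], mo]
      results[[runs[i]]]$thresholded_maps[[mo]][[cc]]$mask
    }, logical(length(rmaps[[1]])))
    overlap[[mo]] <- rowSums(masks) >= 2
  }

  structure(list(runs = runs, similarity = sim,
                 similarity_signed = sim_signed, overlap = overlap,
                 representative = rep_comp,
                 subsets = subsets, results = results),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> runs: %s\n",
              paste(x$runs, collapse = ", ")))
  for (mo in names(x$similarity)) {
    off <- x$similarity[[mo]][upper.tri(x$similarity[[mo]])]
    cat(sprintf("  %s: pairwise |r| %.3f - %.3f\n", mo, min(off), max(off)))
  }
  invisible(x)
}
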