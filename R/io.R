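#' Write a cohort to a directory of delimited files
#'
#' One tab-delimited matrix per modality (first column subject_id, header
#' row of feature ids), a phenotype CSV (subject_id, group, covariates,
#' clinical scores), a reference CSV (subject_id, beta) and, when ground
#' truth is present, a JSON bundle plus per-modality source/loading
#' matrices.
#'
#' @param cohort cohort list (modalities, reference, design, optional
#'   truth).
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in cohort$modalities) {
    df <- data.frame(subject_id = f$subject_ids, f$data, check.names = FALSE)
    colnames(df) <- c("subject_id", f$feature_ids)
    utils::write.table(df, file.path(dir, sprintf("modality_%s.tsv",
                                                  f$modality)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  d <- cohort$design
  pheno <- data.frame(subject_id = d$subject_ids,
                      group = as.character(d$group))
  if (!is.null(d$covariates)) pheno <- cbind(pheno, d$covariates)
  if (!is.null(d$clinical)) pheno <- cbind(pheno, d$clinical)
  utils::write.csv(pheno, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$reference, file.path(dir, "reference.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(target_component = tr$target_component, latent = tr$latent,
           config = unclass(tr$config)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    for (k in seq_along(tr$sources)) {
      mod <- cohort$modalities[[k]]$modality
      utils::write.table(tr$sources[[k]],
                         file.path(dir, sprintf("truth_sources_%s.tsv", mod)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      utils::write.table(tr$loadings[[k]],
                         file.path(dir, sprintf("truth_loadings_%s.tsv", mod)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param dir cohort directory.
#' @return cohort list (modalities, reference, design, truth when present).
#' @export
read_cohort <- function(dir) {
  mod_files <- sort(list.files(dir, "^modality_.*\\.tsv$",
                               full.names = TRUE))
  if (!length(mod_files)) stopf("no modality_*.tsv files in %s", dir)
  pheno <- utils::read.csv(file.path(dir, "phenotype.csv"),
                           stringsAsFactors = FALSE)
  # preserve the phenotype subject order as the cohort order
  modalities <- lapply(mod_files, function(fp) {
    tab <- utils::read.delim(fp, check.names = FALSE,
                             stringsAsFactors = FALSE)
    mod <- sub("^modality_(.*)\\.tsv$", "\\1", basename(fp))
    ids <- as.character(tab$subject_id)
    X <- as.matrix(tab[, -1, drop = FALSE])
    oi <- match(pheno$subject_id, ids)
    if (any(is.na(oi)))
      stopf("modality %s is missing subject(s): %s", mod,
            paste(utils::head(pheno$subject_id[is.na(oi)], 5),
                  collapse = ", "))
    modality_features(mod, X[oi, , drop = FALSE], colnames(X),
                      ids[oi])
  })
  cov_cols <- intersect(c("age", "sex", "meanFD"), colnames(pheno))
  clin_cols <- intersect(c("onset_age", "MMSE", "HSCT"), colnames(pheno))
  design <- cohort_design(
    pheno$subject_id, pheno$group,
    if (length(cov_cols)) pheno[cov_cols] else NULL,
    if (length(clin_cols)) pheno[clin_cols] else NULL)
  reference <- utils::read.csv(file.path(dir, "reference.csv"),
                               stringsAsFactors = FALSE)
  out <- list(modalities = modalities, reference = reference,
              design = design)
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) {
    meta <- jsonlite::read_json(gt, simplifyVector = TRUE)
    mods <- vapply(modalities, function(f) f$modality, "")
    out$truth <- list(
      sources = lapply(mods, function(m) as.matrix(utils::read.delim(
        file.path(dir, sprintf("truth_sources_%s.tsv", m)),
        header = FALSE))),
      loadings = lapply(mods, function(m) as.matrix(utils::read.delim(
        file.path(dir, sprintf("truth_loadings_%s.tsv", m)),
        header = FALSE))),
      latent = meta$latent, target_component = meta$target_component,
      config = meta$config)
  }
  out
}

#' Write a fusion result to a directory
#'
#' Per-modality loadings and joint maps as delimited matrices, the
#' statistics table as CSV, clinical correlations (when computed) as CSV,
#' and a JSON run manifest with configuration and convergence metadata.
#'
#' @param result a \code{fusion_result}.
#' @param dir output directory.
#' @param input_files optional paths whose md5 checksums go into the
#'   manifest.
#' @return \code{dir}, invisibly.
#' @export
write_fusion_result <- function(result, dir, input_files = NULL) {
  stopifnot(inherits(result, "fusion_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mo in names(result$maps)) {
    utils::write.table(result$loadings[[mo]],
                       file.path(dir, sprintf("loadings_%s.tsv", mo)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(result$maps[[mo]],
                       file.path(dir, sprintf("maps_%s.tsv", mo)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.csv(result$statistics, file.path(dir, "statistics.csv"),
                   row.names = FALSE)
  if (!is.null(result$clinical))
    utils::write.csv(result$clinical,
                     file.path(dir, "clinical_correlations.csv"),
                     row.names = FALSE)
  manifest <- result$manifest
  if (!is.null(input_files))
    manifest$input_checksums <- as.list(tools::md5sum(input_files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a cohort from a configuration file (CLI backend)
#'
#' Reads a flat YAML configuration mirroring the
#' \code{\link{simulation_config}} fields, generates the cohort and the
#' methylation matrix is implied by its reference column, and writes the
#' cohort directory plus a manifest.
#'
#' @param config_file YAML file of \code{simulation_config} fields (all
#'   optional), or NULL for defaults.
#' @param out output directory.
#' @param seed overrides the seed in the file when not NULL.
#' @return the cohort, invisibly.
#' @export
cmd_simulate <- function(config_file = NULL, out, seed = NULL) {
  args <- if (!is.null(config_file)) yaml::read_yaml(config_file) else
    list()
  if (!is.null(args$clinical_effects))
    args$clinical_effects <- unlist(args$clinical_effects)
  if (!is.null(seed)) args$seed <- as.integer(seed)
  config <- do.call(simulation_config, args)
  cohort <- generate_multimodal(config)
  write_cohort(cohort, out)
  jsonlite::write_json(
    list(package = "refusion",
         version = as.character(utils::packageVersion("refusion")),
         command = "simulate", seed = config$seed,
         config = unclass(config)),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Fuse a cohort directory (CLI backend)
#'
#' @param cohort_dir directory written by \code{\link{cmd_simulate}} /
#'   \code{\link{write_cohort}}.
#' @param out results directory.
#' @param ... arguments forwarded to \code{\link{fuse_cohort}}.
#' @return the \code{fusion_result}, invisibly.
#' @export
cmd_fuse <- function(cohort_dir, out, ...) {
  cohort <- read_cohort(cohort_dir)
  result <- fuse_cohort(cohort, ...)
  inputs <- list.files(cohort_dir, "\\.(tsv|csv)$", full.names = TRUE)
  write_fusion_result(result, out, input_files = inputs)
  invisible(result)
}

#' Subset replication over a cohort directory (CLI backend)
#'
#' Writes the pairwise similarity matrices (one CSV per modality), the
#' overlap masks, and a JSON report.
#'
#' @param cohort_dir cohort directory.
#' @param out report directory.
#' @param scheme,n_repeats,subsets,seed see
#'   \code{\link{run_subset_replication}}.
#' @param ... forwarded to \code{\link{fuse_cohort}}.
#' @return the \code{similarity_report}, invisibly.
#' @export
cmd_replicate <- function(cohort_dir, out, scheme = "two_thirds",
                          n_repeats = 2L, subsets = NULL, seed = 1L, ...) {
  cohort <- read_cohort(cohort_dir)
  report <- run_subset_replication(cohort, scheme = scheme,
                                   n_repeats = n_repeats,
                                   subsets = subsets, seed = seed, ...)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (mo in names(report$similarity)) {
    utils::write.csv(report$similarity[[mo]],
                     file.path(out, sprintf("similarity_%s.csv", mo)))
    utils::write.table(data.frame(overlap = as.integer(
      report$overlap[[mo]])),
      file.path(out, sprintf("overlap_%s.tsv", mo)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(package = "refusion",
         version = as.character(utils::packageVersion("refusion")),
         command = "replicate", scheme = scheme, seed = seed,
         runs = report$runs,
         representative = as.data.frame(report$representative),
         similarity = lapply(report$similarity, function(m)
           as.data.frame(m)),
         subsets = report$subsets),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}
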