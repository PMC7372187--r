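#' @keywords internal
"_PACKAGE"

# Run expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# z-scored copy of a vector; errors on zero variance
standardize <- function(x, what = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize constant ", what)
  (x - mean(x)) / s
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) stop("matrix is numerically zero")
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# orthonormalize columns via the polar factor (SVD-based)
polar_orth <- function(x) {
  s <- svd(x)
  s$u %*% t(s$v)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# two-level group factor with levels control, patient
as_group_factor <- function(group) {
  if (is.factor(group)) group <- as.character(group)
  if (is.numeric(group) || is.logical(group))
    group <- ifelse(as.numeric(group) > 0, "patient", "control")
  lv <- unique(group)
  if (!all(lv %in% c("control", "patient")))
    stopf("group labels must be 'control'/'patient' (or 0/1); got: %s",
          paste(setdiff(lv, c("control", "patient")), collapse = ", "))
  factor(group, levels = c("control", "patient"))
}
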