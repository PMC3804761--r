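MEASURES <- c("pcc", "pcc2", "mic", "emic")

#' Canonical edge ordering of the upper triangle
#'
#' Row-major upper-triangle ordering: (1,2), (1,3), ..., (1,R), (2,3), ...
#' Every vectorized connectivity matrix and feature table uses this order, so
#' an R-region parcellation yields R(R-1)/2 edge features (116 regions give
#' 6670).
#'
#' @param n_regions number of regions R.
#' @return a data.frame with integer columns `i` and `j` (`i < j`, 1-based).
#' @export
edge_index <- function(n_regions) {
  if (n_regions < 2L) stop("need at least 2 regions")
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(a) (a + 1L):n_regions))
  data.frame(i = as.integer(i), j = as.integer(j))
}

# diagonal self-value per measure (stored, never vectorized)
measure_self_value <- function(measure) {
  switch(measure, pcc = 1, pcc2 = 1, mic = 1, emic = 0)
}

#' Build a connectivity matrix for one subject
#'
#' Computes the chosen association statistic between every pair of regional
#' time series: `pcc` (Pearson correlation), `pcc2` (its square), `mic`
#' (maximal information coefficient), or `emic` (MIC minus squared PCC, the
#' non-linear component). The matrix is symmetric; the diagonal stores the
#' measure's self-value (1, 1, 1, 0 respectively) but is excluded from any
#' feature use. Constant regions are tolerated: their edges are set to 0 with
#' a warning.
#'
#' @param series a [regional_ts()] object (preprocessed).
#' @param measure one of `"pcc"`, `"pcc2"`, `"mic"`, `"emic"`.
#' @param exponent,clumps MIC search parameters, see [mic()].
#' @return an object of class `"fc_matrix"`: list with `values` (R x R
#'   matrix), `measure`, and `regions`.
#' @export
build_connectivity <- function(series, measure = c("emic", "mic", "pcc", "pcc2"),
                               exponent = 0.6, clumps = 15) {
  stopifnot(inherits(series, "regional_ts"))
  measure <- match.arg(measure)
  X <- series$data
  R <- nrow(X)
  if (R < 3L) stop("need at least 3 regions")
  const <- apply(X, 1L, function(v) length(unique(v)) < 2L)
  if (any(const))
    warning("constant region(s) ",
            paste(series$regions[const], collapse = ", "),
            ": their edges are set to 0")
  ok <- !const

  if (measure %in% c("pcc", "pcc2")) {
    V <- matrix(0, R, R)
    if (sum(ok) >= 2L) {
      cc <- stats::cor(t(X[ok, , drop = FALSE]))
      V[ok, ok] <- if (measure == "pcc2") cc^2 else cc
    }
  } else {
    M <- matrix(0, R, R)
    B <- mic_budget(ncol(X), exponent)
    idx <- which(ok)
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        ia <- idx[a]; ib <- idx[b]
        m <- cpp_mic(X[ia, ], X[ib, ], B, clumps)
        M[ia, ib] <- M[ib, ia] <- m
      }
    }
    if (measure == "mic") {
      V <- M
    } else {
      V <- matrix(0, R, R)
      if (sum(ok) >= 2L) {
        cc <- stats::cor(t(X[ok, , drop = FALSE]))
        V[ok, ok] <- cc^2
      }
      V <- M - V
      V[!ok, ] <- 0
      V[, !ok] <- 0
    }
  }
  diag(V) <- measure_self_value(measure)
  dimnames(V) <- list(series$regions, series$regions)
  structure(list(values = V, measure = measure, regions = series$regions),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("Connectivity matrix (", x$measure, "): ", length(x$regions), " x ",
      length(x$regions), " regions\n", sep = "")
  invisible(x)
}

#' Vectorize a connectivity matrix into the canonical edge order
#'
#' Extracts the upper-triangle entries (diagonal excluded) in [edge_index()]
#' order.
#'
#' @param m an `"fc_matrix"` from [build_connectivity()], or a plain
#'   symmetric matrix.
#' @return numeric vector of length R(R-1)/2.
#' @export
vectorize <- function(m) {
  V <- if (inherits(m, "fc_matrix")) m$values else as.matrix(m)
  # t(V)[lower.tri] walks the upper triangle row by row
  t(V)[lower.tri(V)]
}

#' Rebuild the off-diagonal matrix from an edge vector
#'
#' Inverse of [vectorize()] for the off-diagonal part; the diagonal is filled
#' with the measure's self-value.
#'
#' @param v edge vector in canonical order, length R(R-1)/2.
#' @param regions region labels (determines R).
#' @param measure measure name used for the diagonal self-value.
#' @return an `"fc_matrix"`.
#' @export
devectorize <- function(v, regions, measure = "emic") {
  R <- length(regions)
  if (length(v) != R * (R - 1L) / 2L)
    stop("edge vector length ", length(v), " does not match ", R, " regions")
  V <- matrix(0, R, R)
  V[lower.tri(V)] <- v
  V <- t(V)
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  diag(V) <- measure_self_value(measure)
  dimnames(V) <- list(regions, regions)
  structure(list(values = V, measure = measure, regions = regions),
            class = "fc_matrix")
}

#' Edge feature table for a cohort
#'
#' Builds one connectivity matrix per subject and stacks the vectorized
#' upper triangles into a subjects x edges matrix with group labels
#' (+1 control, -1 patient).
#'
#' @param cohort an `"fc_cohort"`: list with `subjects` (ids), `series`
#'   (list of [regional_ts()]), and `labels` (+1/-1) — as produced by
#'   [generate_cohort()] or [read_cohort()].
#' @param measure,exponent,clumps see [build_connectivity()].
#' @return an object of class `"fc_features"`: list with `x` (subjects x
#'   edges matrix), `labels`, `subjects`, `edges` (the [edge_index()] plus
#'   region names), `regions`, and `measure`.
#' @export
cohort_features <- function(cohort, measure = c("emic", "mic", "pcc", "pcc2"),
                            exponent = 0.6, clumps = 15) {
  measure <- match.arg(measure)
  stopifnot(is.list(cohort$series), length(cohort$series) >= 1L)
  regions <- cohort$series[[1L]]$regions
  bad <- vapply(cohort$series, function(s) !identical(s$regions, regions),
                logical(1))
  if (any(bad))
    stop("region labels differ across subjects: ",
         paste(cohort$subjects[bad], collapse = ", "))
  labels <- as.integer(cohort$labels)
  if (!all(labels %in% c(-1L, 1L)))
    stop("labels must be +1 (control) or -1 (patient)")
  E <- length(regions) * (length(regions) - 1L) / 2L
  X <- matrix(0, nrow = length(cohort$series), ncol = E)
  for (s in seq_along(cohort$series)) {
    X[s, ] <- vectorize(build_connectivity(cohort$series[[s]], measure,
                                           exponent = exponent,
                                           clumps = clumps))
  }
  ei <- edge_index(length(regions))
  ei$region_i <- regions[ei$i]
  ei$region_j <- regions[ei$j]
  structure(
    list(x = X, labels = labels, subjects = cohort$subjects, edges = ei,
         regions = regions, measure = measure),
    class = "fc_features"
  )
}

#' @export
print.fc_features <- function(x, ...) {
  cat("Feature table (", x$measure, "): ", nrow(x$x), " subjects x ",
      ncol(x$x), " edges (", sum(x$labels == 1L), " controls, ",
      sum(x$labels == -1L), " patients)\n", sep = "")
  invisible(x)
}

#' Group-mean connectivity profile
#'
#' Per-edge mean over a group's subjects, plus the scalar mean and standard
#' deviation of that per-edge mean vector over all edges — the group-level
#' summary used to compare overall connectivity strength between groups.
#'
#' @param table an `"fc_features"` object.
#' @param group `"control"` / `"patient"`, or +1 / -1.
#' @return list with `edge_mean` (vector over edges), `mean`, and `sd`.
#' @export
group_mean_connectivity <- function(table, group) {
  stopifnot(inherits(table, "fc_features"))
  lab <- if (is.character(group)) {
    switch(match.arg(group, c("control", "patient")), control = 1L,
           patient = -1L)
  } else as.integer(group)
  rows <- which(table$labels == lab)
  if (length(rows) == 0L) stop("group has no subjects")
  em <- colMeans(table$x[rows, , drop = FALSE])
  list(edge_mean = em, mean = mean(em), sd = stats::sd(em))
}
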