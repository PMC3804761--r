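#' @useDynLib emicconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd
NULL

# ---- input checks ------------------------------------------------------

check_pair <- function(x, y, min_n = 4L) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("x and y must be numeric vectors")
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < min_n)
    stop("need at least ", min_n, " paired observations, got ", length(x))
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed")
  invisible(length(x))
}

degenerate_error <- function(what) {
  stop(errorCondition(
    paste0("degenerate input: ", what, " has zero variance"),
    class = c("emicconn_degenerate", "error", "condition")
  ))
}

check_variance <- function(x, y) {
  if (length(unique(x)) < 2L) degenerate_error("x")
  if (length(unique(y)) < 2L) degenerate_error("y")
  invisible(NULL)
}

#' Grid search budget for the MIC
#'
#' The MIC search considers all grid shapes (columns x rows) whose cell count
#' does not exceed a budget that grows with the sample size, `B = floor(n ^
#' exponent)` with a floor of 4 so that the 2 x 2 grid is always admissible.
#'
#' @param n sample size.
#' @param exponent budget exponent; 0.6 is the customary default.
#' @return integer budget B.
#' @export
mic_budget <- function(n, exponent = 0.6) {
  max(4L, as.integer(floor(n^exponent)))
}

# ---- plug-in grid mutual information -----------------------------------

#' Mutual information of a scatterplot under an explicit grid
#'
#' Bins the paired sample by the supplied cut points and returns the plug-in
#' mutual information `MI = H(X) + H(Y) - H(X, Y)` of the resulting discrete
#' cell distribution, in bits.
#'
#' @param x,y numeric vectors of equal length.
#' @param x_edges,y_edges strictly increasing interior cut points; `k` cuts
#'   partition an axis into `k + 1` cells, so each must contain at least one
#'   cut (grids need at least 2 rows and 2 columns to carry information).
#' @return mutual information in bits (non-negative).
#' @examples
#' x <- c(rep(0, 50), rep(1, 50))
#' grid_mutual_information(x, x, x_edges = 0.5, y_edges = 0.5) # 1 bit
#' @export
grid_mutual_information <- function(x, y, x_edges, y_edges) {
  if (length(x) == 0L) stop("empty sample")
  check_pair(x, y, min_n = 1L)
  for (e in list(x_edges, y_edges)) {
    if (length(e) < 1L)
      stop("grid must have at least 2 rows and 2 columns")
    if (is.unsorted(e, strictly = TRUE))
      stop("cut points must be strictly increasing")
  }
  cx <- findInterval(x, x_edges)
  cy <- findInterval(y, y_edges)
  n <- length(x)
  tab <- table(factor(cx, levels = 0:length(x_edges)),
               factor(cy, levels = 0:length(y_edges)))
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  ij <- which(p > 0, arr.ind = TRUE)
  mi <- sum(vapply(seq_len(nrow(ij)), function(k) {
    i <- ij[k, 1L]; j <- ij[k, 2L]
    p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }, numeric(1)))
  max(mi, 0)
}

# ---- internal: exhaustive search helpers -------------------------------

# midpoints between consecutive distinct sorted values; valid cut positions
value_gaps <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(numeric(0))
  (u[-1] + u[-length(u)]) / 2
}

# all cut subsets of size exactly min(k, length(gaps)); list of numeric vecs
cut_subsets <- function(gaps, k) {
  k <- min(k, length(gaps))
  if (k == 0L) return(list(numeric(0)))
  cmb <- utils::combn(length(gaps), k)
  lapply(seq_len(ncol(cmb)), function(j) gaps[cmb[, j]])
}

# exact max MI over grids with <= ncols columns and rows fixed by y_cuts,
# via the C++ dynamic programme with every x-gap as a candidate boundary
exact_colmax_mi <- function(x, y, ncols, y_cuts) {
  rid <- findInterval(y, y_cuts)
  ord <- order(x)
  xs <- x[ord]
  rid <- rid[ord]
  # candidate boundaries after each run of tied x values
  ends <- which(diff(xs) != 0)
  bounds <- as.integer(c(ends, length(xs)))
  I <- cpp_optimize_columns(as.integer(rid), bounds,
                            ny = length(y_cuts) + 1L, lmax = as.integer(ncols))
  max(I)
}

# exhaustive m_{ncols x nrows}: enumerate all row-cut placements, exact DP
# over columns; the true maximum over admissible grids of that shape
exhaustive_grid_mi <- function(x, y, ncols, nrows) {
  best <- 0
  for (yc in cut_subsets(value_gaps(y), nrows - 1L)) {
    if (length(yc) == 0L) next
    best <- max(best, exact_colmax_mi(x, y, ncols, yc))
  }
  best
}

exhaustive_mic <- function(x, y, exponent) {
  n <- length(x)
  if (n > 12L)
    stop("exhaustive search is limited to n <= 12 (combinatorial cost)")
  B <- mic_budget(n, exponent)
  best <- 0
  for (ny in 2:(B %/% 2L)) {
    for (nx in 2:(B %/% ny)) {
      m <- exhaustive_grid_mi(x, y, nx, ny) / log2(min(nx, ny))
      best <- max(best, m)
    }
  }
  min(best, 1)
}

# ---- normalized grid score, MIC, PCC, eMIC -----------------------------

#' Normalized characteristic score of one grid shape
#'
#' Maximizes grid mutual information over partitions with `ncols` columns and
#' `nrows` rows and normalizes by `log2(min(ncols, nrows))`, giving a value in
#' \[0, 1\]. The default search equipartitions one axis on ranks and places
#' cuts on the other by exact dynamic programming over clump boundaries (both
#' orientations are tried); `clumps = Inf` enumerates every admissible row
#' partition as well, which is exact but only feasible for small samples.
#'
#' @param x,y numeric vectors of equal length.
#' @param ncols,nrows grid shape; both at least 2.
#' @param clumps candidate-cut budget factor: the dynamic programme considers
#'   at most `clumps * ncols` candidate boundaries. `Inf` requests the
#'   exhaustive search (n <= 12).
#' @param max_cells guard on `ncols * nrows`.
#' @return the normalized score in \[0, 1\].
#' @export
grid_score <- function(x, y, ncols, nrows, clumps = 15, max_cells = 4096) {
  check_pair(x, y)
  check_variance(x, y)
  if (ncols < 2L || nrows < 2L) stop("grids need at least 2 rows and 2 columns")
  if (ncols * nrows > max_cells)
    stop("grid shape ", ncols, " x ", nrows,
         " exceeds the search budget (max_cells = ", max_cells, ")")
  if (is.infinite(clumps)) {
    if (length(x) > 12L)
      stop("exhaustive search is limited to n <= 12 (combinatorial cost)")
    return(min(exhaustive_grid_mi(x, y, ncols, nrows) / log2(min(ncols, nrows)), 1))
  }
  cpp_grid_score(x, y, as.integer(ncols), as.integer(nrows), clumps)
}

#' Maximal information coefficient
#'
#' Maximum of the normalized grid score over all grid shapes `(ncols, nrows)`
#' with `ncols * nrows <= B`, `B = floor(n ^ exponent)` (floored at 4),
#' `ncols, nrows >= 2`. A value of 1 indicates a noiseless functional
#' relationship; independent pairs give small values that shrink with n.
#'
#' @inheritParams grid_score
#' @param exponent grid-budget exponent, see [mic_budget()].
#' @param clumps candidate-cut budget factor of the partition search; `Inf`
#'   requests the exhaustive search over all partitions (n <= 12 only).
#' @return MIC in \[0, 1\]; symmetric in x and y.
#' @examples
#' x <- seq(-1, 1, length.out = 100)
#' mic(x, x)   # 1: monotone bijection
#' mic(x, x^2) # 1: noiseless parabola
#' @export
mic <- function(x, y, exponent = 0.6, clumps = 15) {
  check_pair(x, y)
  check_variance(x, y)
  if (is.infinite(clumps)) return(exhaustive_mic(x, y, exponent))
  cpp_mic(x, y, mic_budget(length(x), exponent), clumps)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that raises a typed degenerate-input
#' error for constant vectors instead of returning `NA`.
#'
#' @param x,y numeric vectors of equal length with nonzero variance.
#' @return correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  check_pair(x, y, min_n = 3L)
  check_variance(x, y)
  stats::cor(x, y)
}

#' Linear and non-linear association scores of a paired sample
#'
#' Computes the Pearson correlation (PCC), its square, the maximal
#' information coefficient (MIC), and the extended MIC
#' `eMIC = MIC - PCC^2`, the non-linear component of the association.
#' eMIC is reported signed: the partition search is a heuristic maximum, so
#' at finite n MIC can fall below PCC^2 and eMIC below zero; values are never
#' clipped.
#'
#' @inheritParams mic
#' @return an object of class `"association_scores"`: a list with elements
#'   `pcc`, `pcc_squared`, `mic`, `emic`, and `n`.
#' @examples
#' x <- seq(-1, 1, length.out = 200)
#' emic(x, x^2) # pcc 0, mic 1, emic 1
#' @export
emic <- function(x, y, exponent = 0.6, clumps = 15) {
  check_pair(x, y)
  check_variance(x, y)
  r <- pcc(x, y)
  m <- mic(x, y, exponent = exponent, clumps = clumps)
  structure(
    list(pcc = r, pcc_squared = r^2, mic = m, emic = m - r^2, n = length(x)),
    class = "association_scores"
  )
}

#' @export
print.association_scores <- function(x, digits = 4, ...) {
  cat("Association scores (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  pcc   % .*f\n  pcc^2 % .*f\n  mic   % .*f\n  emic  % .*f\n",
              digits, x$pcc, digits, x$pcc_squared,
              digits, x$mic, digits, x$emic))
  invisible(x)
}

#' Brute-force MIC reference for tiny samples
#'
#' Enumerates every placement of row and column cuts between consecutive
#' distinct values, for every grid shape within the budget, and scores each
#' grid by direct plug-in mutual information on the binned counts. This is an
#' independent reference implementation used to validate the partition
#' search; the combinatorial cost restricts it to `n <= 10`.
#'
#' @inheritParams mic
#' @return the exact MIC.
#' @export
mic_oracle <- function(x, y, exponent = 0.6) {
  check_pair(x, y)
  check_variance(x, y)
  n <- length(x)
  if (n > 10L) stop("mic_oracle refuses n > 10 (combinatorial blow-up)")
  B <- mic_budget(n, exponent)
  xg <- value_gaps(x)
  yg <- value_gaps(y)
  best <- 0
  for (ny in 2:(B %/% 2L)) {
    ycuts <- cut_subsets(yg, ny - 1L)
    for (nx in 2:(B %/% ny)) {
      xcuts <- cut_subsets(xg, nx - 1L)
      denom <- log2(min(nx, ny))
      for (yc in ycuts) {
        if (length(yc) == 0L) next
        for (xc in xcuts) {
          if (length(xc) == 0L) next
          mi <- grid_mutual_information(x, y, xc, yc)
          best <- max(best, mi / denom)
        }
      }
    }
  }
  min(best, 1)
}
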