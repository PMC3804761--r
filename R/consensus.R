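#' Edges selected in every cross-validation fold
#'
#' @param fold_selections list of integer edge-index vectors, one per fold.
#' @return integer vector: the exact intersection (possibly empty), sorted.
#' @export
consensus_edges <- function(fold_selections) {
  if (length(fold_selections) < 2L) stop("need at least 2 folds")
  if (any(vapply(fold_selections, length, integer(1)) == 0L))
    stop("every fold must select at least one edge")
  sort(Reduce(intersect, fold_selections))
}

#' Region weights of an edge set
#'
#' Degree of each region in the consensus network: the number of consensus
#' edges incident to it, the region's contribution to the classification.
#'
#' @param edges integer vector of edge indices (canonical order).
#' @param n_regions total number of regions.
#' @return integer vector of length `n_regions` (named R1..Rn unless
#'   `regions` is given).
#' @param regions optional region names.
#' @export
region_weights <- function(edges, n_regions, regions = NULL) {
  ei <- edge_index(n_regions)
  w <- tabulate(c(ei$i[edges], ei$j[edges]), nbins = n_regions)
  names(w) <- if (is.null(regions)) paste0("R", seq_len(n_regions)) else regions
  w
}

# min-max normalized strength: best (smallest) mean rank -> 1, worst ->
# floor eps, so rendered strengths stay positive; display quantity only
normalize_strength <- function(mean_rank, eps = 0.05) {
  if (length(mean_rank) == 1L) return(1)
  rng <- range(mean_rank)
  if (rng[1] == rng[2]) return(rep(1, length(mean_rank)))
  1 - (1 - eps) * (mean_rank - rng[1]) / (rng[2] - rng[1])
}

#' Consensus network of a cross-validated classification
#'
#' Extracts the edges selected in every leave-one-out fold and summarizes
#' them: mean discriminative power (mean |tau| across folds), normalized
#' strength (min-max transform of the mean rank order across folds, best
#' rank mapped to 1 and worst to a small positive floor), direction of the
#' group difference (majority sign of tau across folds; edges whose sign
#' flips between folds are flagged with a warning and tied only on exact
#' balance), and per-region weights.
#'
#' @param fit an `"fc_loocv"` object from [loocv_classify()].
#' @param eps positive floor of the normalized strength (default 0.05).
#' @return an object of class `"fc_consensus"`: list with `edges` (data.frame
#'   edge/i/j/region_i/region_j/mean_power/mean_rank/normalized_strength/
#'   direction), `region_weights`, `n_folds`, `k`, and `measure`.
#' @export
consensus <- function(fit, eps = 0.05) {
  stopifnot(inherits(fit, "fc_loocv"))
  edges <- consensus_edges(fit$selections)
  n_folds <- length(fit$selections)
  ei <- fit$edges
  if (length(edges) == 0L) {
    df <- data.frame(edge = integer(0), i = integer(0), j = integer(0),
                     region_i = character(0), region_j = character(0),
                     mean_power = numeric(0), mean_rank = numeric(0),
                     normalized_strength = numeric(0),
                     direction = tau_direction(numeric(0)))
  } else {
    tau <- fit$fold_tau[edges, , drop = FALSE]
    # per-fold rank orders of the consensus edges
    rank_of <- matrix(0, nrow = length(edges), ncol = n_folds)
    for (f in seq_len(n_folds)) {
      pw <- abs(fit$fold_tau[, f])
      ord <- order(-pw, seq_along(pw))
      rk <- integer(length(pw))
      rk[ord] <- seq_along(pw)
      rank_of[, f] <- rk[edges]
    }
    sgn <- sign(tau)
    flips <- rowSums(sgn > 0) > 0 & rowSums(sgn < 0) > 0
    if (any(flips))
      warning(sum(flips), " consensus edge(s) change tau sign across folds")
    maj <- sign(rowSums(sgn))
    mean_rank <- rowMeans(rank_of)
    df <- data.frame(
      edge = edges, i = ei$i[edges], j = ei$j[edges],
      region_i = ei$region_i[edges], region_j = ei$region_j[edges],
      mean_power = rowMeans(abs(tau)),
      mean_rank = mean_rank,
      normalized_strength = normalize_strength(mean_rank, eps),
      direction = tau_direction(maj)
    )
  }
  n_regions <- max(ei$j)
  rw <- region_weights(edges, n_regions,
                       regions = c(ei$region_i[1],
                                   ei$region_j[ei$i == 1]))
  structure(
    list(edges = df, region_weights = rw, n_folds = n_folds, k = fit$k,
         measure = fit$measure),
    class = "fc_consensus"
  )
}

#' @export
print.fc_consensus <- function(x, n = 10L, ...) {
  cat("Consensus network (", x$measure, ", k = ", x$k, ", ", x$n_folds,
      " folds): ", nrow(x$edges), " consensus edges\n", sep = "")
  if (nrow(x$edges)) {
    dirs <- table(x$edges$direction)
    cat("  direction:", paste(names(dirs), dirs, sep = " = ", collapse = ", "),
        "\n")
    print.data.frame(utils::head(
      x$edges[order(x$edges$mean_rank), ], n), digits = 3)
  }
  invisible(x)
}
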