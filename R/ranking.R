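#' Group-label Kendall tau of one edge
#'
#' Rank correlation between an edge's values and the group labels, counting
#' only cross-group pairs: with m controls (+1) and n patients (-1),
#' `tau = (n_c - n_d) / (m * n)` where `n_c` counts control-patient pairs in
#' which the control has the larger value and `n_d` those in which the
#' patient does. Tied cross-group pairs count toward neither. A positive tau
#' therefore means the edge is weaker in patients (decreased), a negative tau
#' that it is stronger (increased).
#'
#' @param values numeric vector, one connectivity value per subject.
#' @param labels +1 (control) / -1 (patient) per subject.
#' @return tau in \[-1, 1\].
#' @export
kendall_tau_group <- function(values, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L)))
    stop("labels must be +1 (control) or -1 (patient)")
  xc <- values[labels == 1L]
  xp <- values[labels == -1L]
  if (length(xc) == 0L || length(xp) == 0L)
    stop("both groups must be non-empty")
  d <- sign(outer(xc, xp, "-"))
  sum(d) / (length(xc) * length(xp))
}

# vectorized group tau over all columns of a subjects x edges matrix
group_tau <- function(X, labels) {
  labels <- as.integer(labels)
  Xc <- X[labels == 1L, , drop = FALSE]
  Xp <- X[labels == -1L, , drop = FALSE]
  m <- nrow(Xc)
  n <- nrow(Xp)
  if (m == 0L || n == 0L) stop("both groups must be non-empty")
  s <- numeric(ncol(X))
  for (i in seq_len(m)) {
    s <- s + colSums(sign(sweep(Xp, 2L, Xc[i, ], "-")))
  }
  -s / (m * n) # sign(xp - xc) summed, hence negated
}

tau_direction <- function(tau) {
  factor(ifelse(tau > 0, "decreased_in_patients",
                ifelse(tau < 0, "increased_in_patients", "tied")),
         levels = c("decreased_in_patients", "increased_in_patients", "tied"))
}

#' Rank all edges by discriminative power
#'
#' Computes the group-label Kendall tau of every edge, defines discriminative
#' power as |tau|, and ranks edges by power (rank 1 = most discriminative).
#' Ties in power are broken by canonical edge order, making the ranking
#' deterministic.
#'
#' @param table an `"fc_features"` object, or a plain subjects x edges matrix
#'   if `labels` is given.
#' @param labels +1/-1 labels when `table` is a plain matrix.
#' @return an object of class `"fc_ranking"`: a data.frame with one row per
#'   edge (`edge`, `i`, `j`, `region_i`, `region_j`, `tau`, `power`, `rank`,
#'   `direction`), sorted by rank.
#' @export
rank_edges <- function(table, labels = NULL) {
  if (inherits(table, "fc_features")) {
    X <- table$x
    labels <- table$labels
    ei <- table$edges
  } else {
    X <- as.matrix(table)
    if (is.null(labels)) stop("labels required for a plain matrix")
    ei <- NULL
  }
  tau <- group_tau(X, labels)
  ord <- order(-abs(tau), seq_along(tau))
  rk <- integer(length(tau))
  rk[ord] <- seq_along(tau)
  out <- data.frame(edge = seq_along(tau))
  if (!is.null(ei)) {
    out$i <- ei$i
    out$j <- ei$j
    out$region_i <- ei$region_i
    out$region_j <- ei$region_j
  }
  out$tau <- tau
  out$power <- abs(tau)
  out$rank <- rk
  out$direction <- tau_direction(tau)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fc_ranking", "data.frame")
  out
}

#' @export
print.fc_ranking <- function(x, n = 10L, ...) {
  cat("Edge ranking: ", nrow(x), " edges; top ", min(n, nrow(x)), ":\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' Select the k most discriminative edges
#'
#' @param ranked an `"fc_ranking"` from [rank_edges()].
#' @param k number of edges to keep (default 200).
#' @return integer vector of edge indices (canonical order), the k edges
#'   with highest discriminative power.
#' @export
select_top_k <- function(ranked, k = 200L) {
  stopifnot(inherits(ranked, "fc_ranking"))
  k <- as.integer(k)
  if (k < 1L || k > nrow(ranked))
    stop("k must be between 1 and ", nrow(ranked))
  ranked$edge[ranked$rank <= k]
}

#' Select edges above an absolute-tau threshold
#'
#' Alternative selector keeping every edge whose discriminative power |tau|
#' exceeds a fixed threshold.
#'
#' @param ranked an `"fc_ranking"`.
#' @param threshold minimum |tau| (exclusive).
#' @return integer vector of edge indices.
#' @export
select_by_threshold <- function(ranked, threshold) {
  stopifnot(inherits(ranked, "fc_ranking"))
  ranked$edge[ranked$power > threshold]
}
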