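# Linear SVM (C = 1) on selected edges, with the decision score oriented so
# that positive favours the control class (+1); an exact 0 predicts control,
# a fixed rule instead of platform-dependent behaviour.
svm_train_predict <- function(Xtr, ytr, Xte) {
  fit <- e1071::svm(Xtr, factor(ytr, levels = c(-1L, 1L)), kernel = "linear",
                    cost = 1, scale = FALSE)
  pr <- stats::predict(fit, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  score <- if (identical(first, "1")) dv[, 1L] else -dv[, 1L]
  ifelse(score >= 0, 1L, -1L)
}

# per-feature standardization with training-fold statistics
standardize_fold <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[sdv < .Machine$double.eps] <- 1
  list(train = sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(Xte, 2L, mu, check.margin = FALSE), 2L, sdv, "/"))
}

#' Classification metrics
#'
#' Generalization rate (GR, overall accuracy), sensitivity (SS, accuracy on
#' patients, label -1) and specificity (SC, accuracy on controls, label +1).
#'
#' @param predictions,truths vectors of +1/-1 labels, equal length.
#' @return named numeric vector `c(gr, ss, sc)`.
#' @export
classification_metrics <- function(predictions, truths) {
  if (length(predictions) == 0L) stop("empty input")
  if (length(predictions) != length(truths)) stop("length mismatch")
  pat <- truths == -1L
  c(gr = mean(predictions == truths),
    ss = if (any(pat)) mean(predictions[pat] == truths[pat]) else NA_real_,
    sc = if (any(!pat)) mean(predictions[!pat] == truths[!pat]) else NA_real_)
}

#' Leave-one-out cross-validated linear-SVM classification
#'
#' For each fold, one subject is held out; edges are ranked by group-label
#' Kendall tau on the training subjects only, the top-k selected, features
#' standardized with training-fold statistics, a linear SVM (C = 1) trained,
#' and the held-out subject predicted. Feature selection inside the fold
#' prevents the held-out subject from leaking into the ranking.
#'
#' @param table an `"fc_features"` object (see [cohort_features()]).
#' @param k number of top-ranked edges used in each fold (default 200).
#' @param standardize standardize features with training-fold mean/sd
#'   (default TRUE); the measures already live on comparable scales, so this
#'   mainly guards the SVM against scale artefacts.
#' @return an object of class `"fc_loocv"`: list with `gr`, `ss`, `sc`, `k`,
#'   `measure`, `predictions`, `truth`, `folds` (per-fold held-out id,
#'   predicted/true label and selected edges), `selections` (list of per-fold
#'   top-k edge sets), and `fold_tau` (edges x folds matrix of training
#'   taus).
#' @export
loocv_classify <- function(table, k = 200L, standardize = TRUE) {
  stopifnot(inherits(table, "fc_features"))
  X <- table$x
  y <- table$labels
  N <- nrow(X)
  E <- ncol(X)
  if (N < 4L || min(sum(y == 1L), sum(y == -1L)) < 2L)
    stop("need at least 4 subjects with 2 per group")
  k <- as.integer(k)
  if (k < 1L || k > E) stop("k must be between 1 and ", E)

  preds <- integer(N)
  selections <- vector("list", N)
  fold_tau <- matrix(0, nrow = E, ncol = N)
  for (f in seq_len(N)) {
    tr <- setdiff(seq_len(N), f)
    rk <- rank_edges(X[tr, , drop = FALSE], y[tr])
    fold_tau[, f] <- rk$tau[order(rk$edge)]
    sel <- select_top_k(rk, k)
    selections[[f]] <- sel
    Xtr <- X[tr, sel, drop = FALSE]
    Xte <- X[f, sel, drop = FALSE]
    if (isTRUE(standardize)) {
      sdz <- standardize_fold(Xtr, Xte)
      Xtr <- sdz$train
      Xte <- sdz$test
    }
    preds[f] <- svm_train_predict(Xtr, y[tr], Xte)
  }
  met <- classification_metrics(preds, y)
  folds <- lapply(seq_len(N), function(f)
    list(held_out = table$subjects[f], predicted = preds[f], truth = y[f],
         selected_edges = selections[[f]]))
  structure(
    list(gr = unname(met["gr"]), ss = unname(met["ss"]), sc = unname(met["sc"]),
         k = k, measure = table$measure, predictions = preds, truth = y,
         folds = folds, selections = selections, fold_tau = fold_tau,
         edges = table$edges, subjects = table$subjects,
         standardize = isTRUE(standardize)),
    class = "fc_loocv"
  )
}

#' @export
print.fc_loocv <- function(x, ...) {
  cat("Leave-one-out SVM classification (", x$measure, ", k = ", x$k, ")\n",
      "  GR ", sprintf("%.1f%%", 100 * x$gr),
      "  SS ", sprintf("%.1f%%", 100 * x$ss),
      "  SC ", sprintf("%.1f%%", 100 * x$sc),
      "   (", length(x$predictions), " subjects)\n", sep = "")
  invisible(x)
}

#' @export
summary.fc_loocv <- function(object, ...) {
  print(object)
  wrong <- which(object$predictions != object$truth)
  if (length(wrong))
    cat("  misclassified:", paste(object$subjects[wrong], collapse = ", "),
        "\n")
  cons <- Reduce(intersect, object$selections)
  cat("  consensus edges across folds:", length(cons), "\n")
  invisible(object)
}

#' Accuracy as a function of the number of selected edges
#'
#' Repeats the leave-one-out classification over a sweep of selection sizes
#' k; fold rankings are computed once and reused, so only the SVM is refit.
#'
#' @param table an `"fc_features"` object.
#' @param ks selection sizes (default 50, 100, ..., 1000, clipped to the
#'   number of edges).
#' @param standardize see [loocv_classify()].
#' @return data.frame with columns `k`, `gr`, `ss`, `sc`.
#' @export
accuracy_sweep <- function(table, ks = seq(50L, 1000L, by = 50L),
                           standardize = TRUE) {
  stopifnot(inherits(table, "fc_features"))
  X <- table$x
  y <- table$labels
  N <- nrow(X)
  ks <- as.integer(ks[ks <= ncol(X)])
  if (length(ks) == 0L) stop("no k in sweep is <= number of edges")
  rk_folds <- lapply(seq_len(N), function(f)
    rank_edges(X[-f, , drop = FALSE], y[-f]))
  out <- lapply(ks, function(k) {
    preds <- vapply(seq_len(N), function(f) {
      sel <- select_top_k(rk_folds[[f]], k)
      Xtr <- X[-f, sel, drop = FALSE]
      Xte <- X[f, sel, drop = FALSE]
      if (isTRUE(standardize)) {
        sdz <- standardize_fold(Xtr, Xte)
        Xtr <- sdz$train
        Xte <- sdz$test
      }
      svm_train_predict(Xtr, y[-f], Xte)
    }, integer(1))
    met <- classification_metrics(preds, y)
    data.frame(k = k, gr = met["gr"], ss = met["ss"], sc = met["sc"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
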