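# LOOCV linear-SVM classification with fold-internal feature selection.

make_features <- function(X, labels, measure = "pcc") {
  R <- (1 + sqrt(1 + 8 * ncol(X))) / 2 # edges -> implied region count
  ei <- edge_index(as.integer(round(R)))
  ei$region_i <- paste0("R", ei$i)
  ei$region_j <- paste0("R", ei$j)
  structure(list(x = X, labels = as.integer(labels),
                 subjects = paste0("s", seq_len(nrow(X))), edges = ei,
                 regions = paste0("R", seq_len(as.integer(round(R)))),
                 measure = measure),
            class = "fc_features")
}

test_that("metrics follow their definitions", {
  expect_equal(classification_metrics(c(1, -1, 1, -1), c(1, -1, 1, -1)),
               c(gr = 1, ss = 1, sc = 1))
  # all patients wrong, all controls right, balanced
  truth <- c(rep(1, 4), rep(-1, 4))
  pred <- rep(1, 8)
  expect_equal(classification_metrics(pred, truth),
               c(gr = 0.5, ss = 0, sc = 1))
  # 64 subjects, 26/32 correct in each group
  truth64 <- c(rep(1, 32), rep(-1, 32))
  pred64 <- truth64
  pred64[c(1:6, 33:38)] <- -pred64[c(1:6, 33:38)]
  m <- classification_metrics(pred64, truth64)
  expect_equal(unname(m["gr"]), 0.8125)
  expect_equal(unname(m["ss"]), 0.8125)
  expect_equal(unname(m["sc"]), 0.8125)
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
})

test_that("a single separating edge yields perfect LOOCV accuracy", {
  set.seed(41)
  lab <- rep(c(1L, -1L), each = 8)
  X <- matrix(rnorm(16 * 45), 16, 45)
  X[, 7] <- ifelse(lab == 1, 5, -5) + rnorm(16, sd = 0.3)
  fit <- loocv_classify(make_features(X, lab), k = 1)
  expect_equal(fit$gr, 1.0)
  expect_equal(fit$ss, 1.0)
  expect_equal(fit$sc, 1.0)
  expect_true(all(vapply(fit$selections, identical, logical(1), 7L)))
})

test_that("label permutation drives accuracy to chance", {
  set.seed(43)
  X <- matrix(rnorm(16 * 45), 16, 45)
  lab <- rep(c(1L, -1L), each = 8)
  gr <- replicate(60, {
    loocv_classify(make_features(X, sample(lab)), k = 5)$gr
  })
  expect_lt(abs(mean(gr) - 0.5), 0.15)
})

test_that("fold selections are computed from training subjects only", {
  set.seed(45)
  lab <- rep(c(1L, -1L), each = 6)
  X <- matrix(rnorm(12 * 10, sd = 0.1), 12, 10)
  # edges 1 and 2 both separate the groups perfectly on subjects 1..11;
  # subject 12 (a patient) is constructed so that including it in its own
  # fold's ranking would flip the winner from edge 1 to edge 2
  X[, 1] <- c(rep(1, 6), rep(0, 5), 2)
  X[, 2] <- c(rep(1, 6), rep(0, 5), 0)
  ft <- make_features(X, lab)
  fit <- loocv_classify(ft, k = 1)
  for (f in seq_len(12)) {
    rk_tr <- rank_edges(X[-f, , drop = FALSE], lab[-f])
    expect_identical(fit$selections[[f]], select_top_k(rk_tr, 1))
  }
  # fold 12 must pick edge 1 (training tie broken by edge order) ...
  expect_identical(fit$selections[[12]], 1L)
  # ... whereas the leaking, full-data ranking would pick edge 2
  expect_identical(select_top_k(rank_edges(X, lab), 1), 2L)
})

test_that("LOOCV is deterministic and invariant to subject order", {
  set.seed(47)
  lab <- rep(c(1L, -1L), each = 6)
  X <- matrix(rnorm(12 * 45), 12, 45)
  X[, 3] <- X[, 3] + lab
  ft <- make_features(X, lab)
  f1 <- loocv_classify(ft, k = 10)
  f2 <- loocv_classify(ft, k = 10)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$selections, f2$selections)
  expect_identical(f1$gr, f2$gr)

  perm <- sample(12)
  ftp <- make_features(X[perm, ], lab[perm])
  fp <- loocv_classify(ftp, k = 10)
  expect_equal(fp$gr, f1$gr)
})

test_that("accuracy sweep returns one report per k, reproducibly", {
  set.seed(49)
  lab <- rep(c(1L, -1L), each = 6)
  X <- matrix(rnorm(12 * 45), 12, 45)
  X[, c(5, 9)] <- X[, c(5, 9)] + lab
  ft <- make_features(X, lab)
  sw <- accuracy_sweep(ft, ks = c(5, 10, 20))
  expect_equal(nrow(sw), 3)
  expect_equal(sw$k, c(5L, 10L, 20L))
  expect_true(all(sw$gr >= 0 & sw$gr <= 1))
  sw2 <- accuracy_sweep(ft, ks = c(5, 10, 20))
  expect_identical(sw, sw2)
  # ks beyond the edge count are clipped
  expect_equal(nrow(accuracy_sweep(ft, ks = c(10, 1000))), 1)
})

test_that("non-linear group differences favour eMIC over PCC", {
  # quadratic couplings only: the linear measure carries no group signal,
  # so eMIC should classify better in essentially every replicate
  gr <- vapply(1:8, function(r) {
    cps <- lapply(c(1, 3, 5), function(i)
      coupling_spec(i, i + 1L, "quadratic", 0.2, 0.6))
    cfg <- cohort_config(preset = "custom", n_regions = 10,
                         n_timepoints = 175, n_controls = 8, n_patients = 8,
                         couplings = cps, seed = 7000 + r)
    co <- generate_cohort(cfg)
    c(loocv_classify(cohort_features(co, "emic"), k = 5)$gr,
      loocv_classify(cohort_features(co, "pcc"), k = 5)$gr)
  }, numeric(2))
  expect_gte(sum(gr[1, ] > gr[2, ]), 6)
  expect_gt(mean(gr[1, ]), mean(gr[2, ]))
})

test_that("integer consistency of the rates holds", {
  set.seed(51)
  lab <- rep(c(1L, -1L), each = 5)
  X <- matrix(rnorm(10 * 45), 10, 45)
  fit <- loocv_classify(make_features(X, lab), k = 5)
  N <- 10
  expect_equal(fit$gr * N, fit$ss * 5 + fit$sc * 5, tolerance = 1e-12)
})
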