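# Association kernel: grid MI, normalized grid score, MIC, PCC, eMIC.

test_that("grid mutual information matches plug-in entropy computation", {
  # deterministic diagonal on a 2x2 grid: 1 bit
  x <- c(rep(0, 50), rep(1, 50))
  expect_equal(grid_mutual_information(x, x, 0.5, 0.5), 1.0)

  # uniform spread over all 4 cells: independence, 0 bits
  xu <- rep(c(0, 0, 1, 1), 25)
  yu <- rep(c(0, 1, 0, 1), 25)
  expect_equal(grid_mutual_information(xu, yu, 0.5, 0.5), 0.0)

  # fixed 8-point configuration on a 3x2 grid; expected value frozen from a
  # direct plug-in entropy computation on the binned counts
  x8 <- 1:8
  y8 <- c(2, 1, 4, 3, 6, 5, 8, 7)
  expect_equal(
    grid_mutual_information(x8, y8, x_edges = c(2.5, 5.5), y_edges = 4.5),
    0.655639062229566,
    tolerance = 1e-12
  )
})

test_that("grid MI rejects empty samples and degenerate grids", {
  expect_error(grid_mutual_information(numeric(0), numeric(0), 0.5, 0.5),
               "empty")
  expect_error(grid_mutual_information(1:10, 1:10, numeric(0), 0.5),
               "at least 2 rows")
  expect_error(grid_mutual_information(1:10, 1:10, c(2, 2), 0.5),
               "strictly increasing")
})

test_that("normalized grid score behaves on monotone and independent pairs", {
  x <- seq_len(50) / 50
  expect_equal(grid_score(x, x, 2, 2), 1.0)

  # independent pair: heuristic never exceeds the brute-force 2x2 maximum
  # (frozen from enumeration of all cut placements) and stays small
  set.seed(42)
  xi <- rnorm(50)
  yi <- rnorm(50)
  brute <- 0.162151669024668
  s <- grid_score(xi, yi, 2, 2)
  expect_lt(s, 0.2)
  expect_lte(s, brute + 1e-12)

  expect_error(grid_score(x, x, 1, 2), "at least 2 rows")
  expect_error(grid_score(x, x, 100, 100, max_cells = 100), "budget")
})

test_that("normalized grid score equals exhaustive enumeration at small n", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(9)
    y <- rnorm(9)
    for (shape in list(c(2, 2), c(3, 2), c(2, 3))) {
      exact <- grid_score(x, y, shape[1], shape[2], clumps = Inf)
      heur <- grid_score(x, y, shape[1], shape[2])
      expect_lte(heur, exact + 1e-12)
    }
  }
})

test_that("MIC saturates on noiseless functional relationships", {
  x <- seq(-1, 1, length.out = 100)
  expect_equal(mic(x, x), 1.0)

  # noiseless parabola, symmetric sample about 0
  xs <- c(-(100:1), 1:100) / 100
  expect_equal(mic(xs, xs^2), 1.0, tolerance = 1e-9)
})

test_that("MIC is symmetric and confined to [0, 1]", {
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(60)
    y <- rnorm(60)
    m <- mic(x, y)
    expect_identical(m, mic(y, x))
    expect_gte(m, 0)
    expect_lte(m, 1)
  }
})

test_that("MIC is invariant under strictly increasing transforms", {
  set.seed(5)
  for (rep in 1:6) {
    x <- rnorm(80)
    y <- rnorm(80)
    m0 <- mic(x, y)
    expect_equal(mic(exp(x), y), m0, tolerance = 1e-12)
    expect_equal(mic(x, y^3), m0, tolerance = 1e-12)
    expect_equal(mic(2 * x + 5, 0.1 * y - 3), m0, tolerance = 1e-12)
  }
})

test_that("exhaustive search agrees with the brute-force oracle at n <= 10", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(mic(x, y, clumps = Inf), mic_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(mic_oracle(rnorm(11), rnorm(11)), "n > 10")
})

test_that("tied values are handled by the stated tie rule", {
  # tied x values may not be separated by a cut; value frozen from direct
  # enumeration of all admissible 2x2 grids on this configuration
  xt <- c(1, 1, 2, 2, 3, 3)
  yt <- c(1, 2, 3, 4, 5, 6)
  expect_equal(mic_oracle(xt, yt), 0.918295834054490, tolerance = 1e-12)
  expect_equal(mic(xt, yt, clumps = Inf), mic_oracle(xt, yt),
               tolerance = 1e-12)
  # permuting the sample (same ranks) changes nothing: pure function of data
  p <- c(3, 1, 6, 2, 5, 4)
  expect_equal(mic_oracle(xt[p], yt[p]), mic_oracle(xt, yt), tolerance = 1e-12)
})

test_that("PCC wrapper matches closed-form cases and flags degeneracy", {
  x <- seq(-1, 1, length.out = 50)
  expect_equal(pcc(x, 2 * x + 3), 1.0)
  expect_equal(pcc(x, -x), -1.0)
  expect_equal(pcc(x, x^2), 0.0, tolerance = 1e-12)
  expect_error(pcc(rep(1, 10), rnorm(10)), class = "emicconn_degenerate")
  expect_error(mic(rnorm(10), rep(2, 10)), class = "emicconn_degenerate")
})

test_that("eMIC decomposition holds and saturating cases come out right", {
  # identity emic + pcc^2 = mic for arbitrary inputs
  set.seed(19)
  for (rep in 1:10) {
    x <- rnorm(100)
    y <- 0.5 * x + rnorm(100)
    sc <- emic(x, y)
    expect_equal(sc$emic + sc$pcc_squared, sc$mic, tolerance = 1e-12)
    expect_equal(sc$pcc_squared, sc$pcc^2, tolerance = 1e-15)
  }

  # noiseless monotone pair: MIC 1, PCC^2 1, eMIC 0
  x <- seq(-1, 1, length.out = 100)
  sc <- emic(x, x)
  expect_equal(sc$mic, 1.0)
  expect_equal(sc$emic, 0.0, tolerance = 1e-12)

  # noiseless symmetric parabola at n = 200: PCC 0, MIC 1, eMIC 1
  xs <- c(-(100:1), 1:100) / 100
  sc <- emic(xs, xs^2)
  expect_equal(sc$pcc, 0.0, tolerance = 1e-12)
  expect_equal(sc$mic, 1.0, tolerance = 1e-9)
  expect_equal(sc$emic, 1.0, tolerance = 1e-9)
})

test_that("eMIC of an independent pair sits near zero at n = 175", {
  set.seed(23)
  vals <- replicate(40, {
    sc <- emic(rnorm(175), rnorm(175))
    sc$emic
  })
  expect_true(all(abs(vals) < 0.35))
})

test_that("the MIC noise floor shrinks with sample size", {
  set.seed(29)
  med <- vapply(c(50, 175, 500), function(n) {
    stats::median(replicate(80, mic(rnorm(n), rnorm(n))))
  }, numeric(1))
  expect_true(med[1] > med[2] && med[2] > med[3])
})

test_that("association_scores prints all four statistics", {
  x <- seq(-1, 1, length.out = 50)
  out <- capture.output(print(emic(x, x)))
  expect_true(any(grepl("emic", out)))
  expect_true(any(grepl("pcc", out)))
})
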