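# Synthetic two-group cohorts with controlled linear/non-linear couplings.

small_config <- function(...) {
  cohort_config(preset = "custom", n_regions = 4, n_timepoints = 175,
                n_controls = 2, n_patients = 2, seed = 7, ...)
}

test_that("a full-strength linear coupling reproduces the source", {
  cfg <- small_config(
    couplings = list(coupling_spec(1, 2, "linear", 1, 1)), noise_sd = 0)
  s <- generate_subject(cfg, "control", seed = 11)
  expect_gt(pcc(s$data[1, ], s$data[2, ]), 1 - 1e-6)
})

test_that("uncoupled regions are uncorrelated on average", {
  cfg <- small_config(noise_sd = 0)
  r <- vapply(1:50, function(i) {
    s <- generate_subject(cfg, "control", seed = 100 + i)
    pcc(s$data[1, ], s$data[2, ])
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("a full-strength quadratic coupling is non-linear, not linear", {
  cfg <- small_config(
    couplings = list(coupling_spec(1, 2, "quadratic", 1, 1)), noise_sd = 0)
  s <- generate_subject(cfg, "control", seed = 13)
  sc <- emic(s$data[1, ], s$data[2, ])
  expect_gt(sc$emic, 0.5)
  expect_lt(abs(sc$pcc), 0.4)
})

test_that("cohort generation is reproducible and correctly shaped", {
  cfg <- cohort_config(preset = "custom", n_regions = 10, n_timepoints = 175,
                       n_controls = 4, n_patients = 4, seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$series, b$series)
  expect_length(a$series, 8)
  expect_equal(dim(a$series[[1]]$data), c(10, 175))
  expect_equal(a$labels, c(1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L))

  # written twice: byte-identical files
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # collision on existing files is refused
  expect_error(generate_cohort(cfg, dir = d1), "collision")
  unlink(c(d1, d2), recursive = TRUE)

  # growing the cohort leaves existing subjects untouched
  cfg2 <- cohort_config(preset = "custom", n_regions = 10,
                        n_timepoints = 175, n_controls = 5, n_patients = 4,
                        seed = 3)
  big <- generate_cohort(cfg2)
  expect_identical(big$series[1:4], a$series[1:4])
})

test_that("base signals concentrate their power inside the band", {
  cfg <- cohort_config(preset = "null", n_regions = 2, n_timepoints = 2048,
                       n_controls = 1, n_patients = 1, seed = 5)
  s <- generate_subject(cfg, "control", seed = 17)
  v <- s$data[1, ]
  n <- length(v)
  pw <- Mod(stats::fft(v))^2
  freq <- (seq_len(n) - 1) / (n * cfg$tr)
  half <- freq <= 1 / (2 * cfg$tr)
  inband <- freq >= 0.01 & freq <= 0.08
  expect_gt(sum(pw[half & inband]) / sum(pw[half]), 0.9)
})

test_that("generated motion is smooth, reproducible, and regressable", {
  cfg <- small_config()
  m0 <- generate_motion(cfg, seed = 19, amplitude = 0)
  expect_equal(max(abs(m0$data)), 0)
  m1 <- generate_motion(cfg, seed = 19)
  m2 <- generate_motion(cfg, seed = 19)
  expect_identical(m1$data, m2$data)
  expect_equal(dim(m1$data), c(6, 175))

  # injecting a motion regressor into a region: regression removes it
  s <- generate_subject(cfg, "control", seed = 23)
  s$data[1, ] <- s$data[1, ] + 5 * m1$data[3, ]
  r <- regress_motion(s, m1)
  expect_lt(abs(stats::cor(r$data[1, ], m1$data[3, ])), 1e-6)
})

test_that("the paper-like preset shifts group means in opposite directions", {
  cfg <- cohort_config(preset = "paper-like", n_regions = 20,
                       n_timepoints = 175, n_controls = 8, n_patients = 8,
                       seed = 1)
  lin <- vapply(cfg$couplings[1:5], function(cp) c(cp$i, cp$j), numeric(2))
  quad <- vapply(cfg$couplings[6:10], function(cp) c(cp$i, cp$j), numeric(2))
  ok_lin <- 0
  ok_quad <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    cfgr <- cohort_config(preset = "paper-like", n_regions = 20,
                          n_timepoints = 175, n_controls = 8, n_patients = 8,
                          seed = 1000 + r)
    co <- generate_cohort(cfgr)
    mean_score <- function(rows, fun) {
      mean(vapply(rows, function(si) {
        mean(apply(lin_or_quad, 2, function(e)
          fun(co$series[[si]]$data[e[1], ], co$series[[si]]$data[e[2], ])))
      }, numeric(1)))
    }
    ctrl <- which(co$labels == 1L)
    pat <- which(co$labels == -1L)
    lin_or_quad <- lin
    pcc_c <- mean_score(ctrl, pcc)
    pcc_p <- mean_score(pat, pcc)
    lin_or_quad <- quad
    em <- function(a, b) emic(a, b)$emic
    em_c <- mean_score(ctrl, em)
    em_p <- mean_score(pat, em)
    if (pcc_c > pcc_p) ok_lin <- ok_lin + 1
    if (em_p > em_c) ok_quad <- ok_quad + 1
  }
  expect_gte(ok_lin, reps - 1)
  expect_gte(ok_quad, reps - 1)
})

test_that("coupling and config validation catches misuse", {
  expect_error(coupling_spec(2, 2, "linear", 0.5, 0.5), "distinct")
  expect_error(coupling_spec(1, 2, "linear", 1.5, 0.5), "\\[0, 1\\]")
  expect_error(
    cohort_config(preset = "custom", n_regions = 5,
                  couplings = list(coupling_spec(1, 9, "linear", .5, .5))),
    "beyond n_regions")
  expect_error(cohort_config(preset = "paper-like", n_regions = 10),
               ">= 20 regions")
})
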