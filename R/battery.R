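#' Simulation battery of paired samples for stress-testing the MIC
#'
#' Generates paired band-limited signals covering linear, quadratic, and
#' sinusoidal couplings (at full strength) plus independent pairs, each at
#' several observation-noise levels, and computes the MIC of every pair.
#' Useful for verifying the normalization bound (MIC never exceeds 1) across
#' heterogeneous association structures.
#'
#' @param n_pairs number of pairs (spread round-robin over the 4 x 5
#'   form-by-noise conditions).
#' @param n timepoints per pair (default 175).
#' @param seed master seed; pair streams are derived deterministically.
#' @param tr,band sampling interval and passband of the base signals.
#' @return data.frame with columns `form`, `noise_sd`, `mic`.
#' @export
association_battery <- function(n_pairs = 500L, n = 175L, seed = 1L,
                                tr = 2, band = c(0.01, 0.08)) {
  forms <- c("linear", "quadratic", "sinusoidal", "independent")
  noises <- c(0, 0.05, 0.1, 0.2, 0.5)
  grid <- expand.grid(form = forms, noise_sd = noises,
                      stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(grid)), length.out = n_pairs)
  out <- data.frame(form = grid$form[idx], noise_sd = grid$noise_sd[idx],
                    mic = NA_real_)
  for (p in seq_len(n_pairs)) {
    cps <- if (out$form[p] == "independent") list() else
      list(coupling_spec(1, 2, out$form[p], 1, 1))
    cfg <- cohort_config(preset = "custom", n_regions = 2, n_timepoints = n,
                         tr = tr, n_controls = 1, n_patients = 1,
                         couplings = cps, noise_sd = out$noise_sd[p],
                         band = band, seed = seed)
    s <- generate_subject(cfg, "control", seed = subject_seed(seed, p))
    out$mic[p] <- mic(s$data[1, ], s$data[2, ])
  }
  out
}
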