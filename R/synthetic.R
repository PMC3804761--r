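#' Coupling specification between two regions
#'
#' Describes one planted association: the target region's signal receives a
#' strength-weighted transform of the source region's signal. `linear` mixes
#' the source itself, `quadratic` its centered square (which has near-zero
#' linear correlation with the source by symmetry), `sinusoidal` a sine
#' transform (`sin(2 z)` of the standardized source).
#'
#' @param i,j source and target region indices (1-based, distinct).
#' @param form `"linear"`, `"quadratic"`, or `"sinusoidal"`.
#' @param strength_control,strength_patient mixing strengths in \[0, 1\] for
#'   the two groups.
#' @return a list of class `"coupling_spec"`.
#' @export
coupling_spec <- function(i, j, form = c("linear", "quadratic", "sinusoidal"),
                          strength_control, strength_patient) {
  form <- match.arg(form)
  if (i == j) stop("coupling must join two distinct regions")
  for (s in c(strength_control, strength_patient))
    if (s < 0 || s > 1) stop("strengths must lie in [0, 1]")
  structure(list(i = as.integer(i), j = as.integer(j), form = form,
                 strength_control = strength_control,
                 strength_patient = strength_patient),
            class = "coupling_spec")
}

# the paper-like planted structure: linear couplings that weaken in patients
# and quadratic couplings that strengthen, on disjoint region pairs
paper_like_couplings <- function() {
  lin <- lapply(c(1, 3, 5, 7, 9), function(i)
    coupling_spec(i, i + 1L, "linear", 0.6, 0.3))
  quad <- lapply(c(11, 13, 15, 17, 19), function(i)
    coupling_spec(i, i + 1L, "quadratic", 0.2, 0.6))
  c(lin, quad)
}

#' Synthetic cohort configuration
#'
#' Defines a two-group cohort of band-limited regional time series. The
#' defaults mirror a typical resting-state acquisition: 116 regions, 175
#' retained volumes at TR = 2 s, 32 subjects per group, signals confined to
#' 0.01-0.08 Hz. The `"paper-like"` preset plants 5 linear couplings that
#' weaken from control to patient (0.6 to 0.3) and 5 quadratic couplings
#' that strengthen (0.2 to 0.6) on disjoint pairs among the first 20
#' regions; the `"null"` preset plants nothing.
#'
#' @param preset `"null"`, `"paper-like"`, or `"custom"` (couplings supplied
#'   explicitly).
#' @param n_regions,n_timepoints,tr,n_controls,n_patients cohort dimensions.
#' @param couplings list of [coupling_spec()] objects (preset `"custom"`).
#' @param noise_sd observation noise standard deviation added on top of the
#'   unit-variance signals (default 0.1).
#' @param band passband of the base signals in Hz.
#' @param seed master seed; per-subject streams are derived from it
#'   deterministically (`(seed + 7919 * subject_index) mod (2^31 - 1)`), so
#'   existing subjects are unchanged when the cohort grows.
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(preset = c("null", "paper-like", "custom"),
                          n_regions = 116L, n_timepoints = 175L, tr = 2,
                          n_controls = 32L, n_patients = 32L,
                          couplings = list(), noise_sd = 0.1,
                          band = c(0.01, 0.08), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paper-like") {
    if (n_regions < 20L) stop("the paper-like preset needs >= 20 regions")
    couplings <- paper_like_couplings()
  }
  for (cp in couplings) {
    if (!inherits(cp, "coupling_spec")) stop("couplings must be coupling_spec")
    if (cp$i > n_regions || cp$j > n_regions)
      stop("coupling references region beyond n_regions = ", n_regions)
  }
  structure(list(preset = preset, n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients), couplings = couplings,
                 noise_sd = noise_sd, band = band, seed = as.integer(seed)),
            class = "cohort_config")
}

subject_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * index) %% 2147483647)
}

coupling_transform <- function(z, form) {
  f <- switch(form, linear = z, quadratic = z^2 - mean(z^2),
              sinusoidal = sin(2 * z))
  f / stats::sd(f)
}

# band-limited unit-variance Gaussian base signals, padded to kill filter
# edge transients
band_limited_noise <- function(n_signals, n_timepoints, tr, band, pad = 128L) {
  raw <- matrix(stats::rnorm(n_signals * (n_timepoints + 2L * pad)),
                nrow = n_signals)
  flt <- cheby_bandpass_matrix(raw, tr, band[1], band[2])
  flt <- flt[, (pad + 1L):(pad + n_timepoints), drop = FALSE]
  flt <- flt - rowMeans(flt)
  flt / apply(flt, 1L, stats::sd)
}

#' Generate one synthetic subject
#'
#' Base signals are independent band-limited Gaussian processes; each
#' coupling then replaces the target region by
#' `sqrt(1 - s^2) * base + s * f(source)` with the group's strength `s` and
#' the coupling's transform `f` (standardized), so the target keeps unit
#' variance and, for a linear coupling, `cor(source, target) = s` in
#' expectation. Observation noise of sd `noise_sd` is added last.
#'
#' @param config a [cohort_config()].
#' @param group `"control"` or `"patient"` (selects the coupling strengths).
#' @param seed integer seed for this subject's stream.
#' @return a [regional_ts()] object.
#' @export
generate_subject <- function(config, group = c("control", "patient"),
                             seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  set.seed(seed)
  sig <- band_limited_noise(config$n_regions, config$n_timepoints, config$tr,
                            config$band)
  for (cp in config$couplings) {
    s <- if (group == "control") cp$strength_control else cp$strength_patient
    f <- coupling_transform(sig[cp$i, ], cp$form)
    sig[cp$j, ] <- sqrt(1 - s^2) * sig[cp$j, ] + s * f
  }
  if (config$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(length(sig), sd = config$noise_sd),
                        nrow = nrow(sig))
  regional_ts(sig, regions = sprintf("R%03d", seq_len(config$n_regions)),
              tr = config$tr)
}

#' Generate smooth synthetic motion parameters
#'
#' Six low-amplitude random walks (translations and rotations), smoothed
#' with a short moving average, for exercising motion regression.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param amplitude innovation standard deviation (0 gives all-zero
#'   parameters).
#' @return a [motion_params()] object, 6 x n_timepoints.
#' @export
generate_motion <- function(config, seed = config$seed, amplitude = 0.02) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  nt <- config$n_timepoints
  m <- t(vapply(1:6, function(i) {
    w <- cumsum(stats::rnorm(nt + 8L, sd = amplitude))
    as.numeric(stats::filter(w, rep(1 / 9, 9), sides = 2L))[5:(nt + 4L)]
  }, numeric(nt)))
  motion_params(m)
}

#' Generate a two-group synthetic cohort
#'
#' Controls use each coupling's `strength_control`, patients its
#' `strength_patient`; labels are +1 for controls and -1 for patients.
#' Reproducible: the same configuration (including its seed) always yields
#' bit-identical data.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory; when given, per-subject TSVs, a
#'   `manifest.tsv` and a `couplings.tsv` ground-truth table are written and
#'   the manifest paths point at them. Without it the cohort is returned in
#'   memory only.
#' @return an `"fc_cohort"`: list with `subjects`, `series`, `labels`,
#'   `config`, and (when written) `manifest`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_controls + config$n_patients
  groups <- rep(c("control", "patient"),
                c(config$n_controls, config$n_patients))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "ctrl", "pat"),
                 c(seq_len(config$n_controls), seq_len(config$n_patients)))
  series <- lapply(seq_len(n), function(i)
    generate_subject(config, groups[i], seed = subject_seed(config$seed, i)))
  cohort <- list(subjects = ids, series = series,
                 labels = ifelse(groups == "control", 1L, -1L),
                 config = config)
  class(cohort) <- "fc_cohort"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(ids, ".tsv"))
    if (any(file.exists(paths)))
      stop("output path collision: ", paths[file.exists(paths)][1])
    for (i in seq_len(n)) write_timeseries(series[[i]], paths[i])
    manifest <- data.frame(subject_id = ids, path = paste0(ids, ".tsv"),
                           label = cohort$labels)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gt <- do.call(rbind, lapply(config$couplings, function(cp)
      data.frame(i = cp$i, j = cp$j, form = cp$form,
                 strength_control = cp$strength_control,
                 strength_patient = cp$strength_patient)))
    if (is.null(gt))
      gt <- data.frame(i = integer(0), j = integer(0), form = character(0),
                       strength_control = numeric(0),
                       strength_patient = numeric(0))
    utils::write.table(gt, file.path(dir, "couplings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cohort$manifest <- file.path(dir, "manifest.tsv")
  }
  cohort
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", sum(x$labels == 1L), " controls + ",
      sum(x$labels == -1L), " patients, ", nrow(x$series[[1]]$data),
      " regions x ", ncol(x$series[[1]]$data), " timepoints\n", sep = "")
  invisible(x)
}

# canonical edge indices of the planted couplings, split by form
planted_edges <- function(config) {
  ei <- edge_index(config$n_regions)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  lookup <- stats::setNames(seq_len(nrow(ei)), key(ei$i, ei$j))
  out <- list(linear = integer(0), quadratic = integer(0),
              sinusoidal = integer(0))
  for (cp in config$couplings)
    out[[cp$form]] <- c(out[[cp$form]], unname(lookup[key(cp$i, cp$j)]))
  out
}
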