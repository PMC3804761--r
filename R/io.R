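# All tabular output is written at 17 significant digits so that
# write -> read round-trips reproduce doubles exactly.
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Write a regional time series to delimited text
#'
#' Layout: header row `region, t1..tn`, one row per region, first column the
#' region label.
#'
#' @param series a [regional_ts()] object.
#' @param path output file.
#' @param sep field separator (tab default; use "," for CSV).
#' @export
write_timeseries <- function(series, path, sep = "\t") {
  stopifnot(inherits(series, "regional_ts"))
  nt <- ncol(series$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", paste0("t", seq_len(nt))), collapse = sep), con)
  for (r in seq_len(nrow(series$data)))
    writeLines(paste(c(series$regions[r], fmt_num(series$data[r, ])),
                     collapse = sep), con)
  invisible(path)
}

#' Read a regional time series from delimited text
#'
#' Accepts the [write_timeseries()] layout in TSV or CSV dialect; the
#' separator is detected from the header. Parse problems are reported with
#' their row and column.
#'
#' @param path input file.
#' @param tr sampling interval in seconds to attach (default 2).
#' @return a [regional_ts()] object.
#' @export
read_timeseries <- function(path, tr = 2) {
  sep <- detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("no timepoint columns in ", path)
  regions <- raw[[1L]]
  if (anyDuplicated(regions))
    stop("duplicate region label: ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at row ", bad[1L], ", column ", bad[2L] + 1L,
         " of ", path)
  }
  regional_ts(num, regions = regions, tr = tr)
}

#' Write / read motion parameters (timepoints x 6 columns)
#'
#' @param motion a [motion_params()] object.
#' @param path file path.
#' @param sep field separator.
#' @export
write_motion <- function(motion, path, sep = "\t") {
  stopifnot(inherits(motion, "motion_params"))
  m <- t(motion$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("tx", "ty", "tz", "rx", "ry", "rz"), collapse = sep), con)
  for (r in seq_len(nrow(m)))
    writeLines(paste(fmt_num(m[r, ]), collapse = sep), con)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  sep <- detect_sep(path)
  m <- as.matrix(utils::read.table(path, sep = sep, header = TRUE))
  motion_params(t(m))
}

#' Read a cohort manifest and load its subjects
#'
#' The manifest is a TSV with columns `subject_id`, `path`, `label` (+1
#' control / -1 patient) and optional `motion_path`; paths are resolved
#' relative to the manifest's directory.
#'
#' @param manifest_path path to the manifest TSV.
#' @param tr sampling interval to attach to the series.
#' @return an `"fc_cohort"` list: `subjects`, `series`, `labels`, and
#'   `motion` (list, NULL entries where absent).
#' @export
read_cohort <- function(manifest_path, tr = 2) {
  base <- dirname(manifest_path)
  mf <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns subject_id, path, label")
  labels <- as.integer(mf$label)
  if (!all(labels %in% c(-1L, 1L)))
    stop("labels must be +1 (control) or -1 (patient)")
  series <- lapply(file.path(base, mf$path), read_timeseries, tr = tr)
  motion <- vector("list", nrow(mf))
  if ("motion_path" %in% names(mf)) {
    has <- !is.na(mf$motion_path) & nzchar(mf$motion_path)
    motion[has] <- lapply(file.path(base, mf$motion_path[has]), read_motion)
  }
  structure(list(subjects = mf$subject_id, series = series, labels = labels,
                 motion = motion),
            class = "fc_cohort")
}

#' Write a connectivity matrix as square TSV with region labels
#'
#' @param m an `"fc_matrix"`.
#' @param path file path.
#' @export
write_connectivity <- function(m, path) {
  stopifnot(inherits(m, "fc_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", m$regions), collapse = "\t"), con)
  for (r in seq_along(m$regions))
    writeLines(paste(c(m$regions[r], fmt_num(m$values[r, ])),
                     collapse = "\t"), con)
  invisible(path)
}

# 32-bit FNV-1a over a string; used to stamp outputs with their config
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep within integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

resolve_config <- function(config) {
  defaults <- list(
    preset = "paper-like", n_regions = 20L, n_timepoints = 175L, tr = 2,
    n_controls = 16L, n_patients = 16L, noise_sd = 0.1,
    band = c(0.01, 0.08), seed = 1L,
    manifest = NULL, measure = "emic", k = 20L, ks = NULL,
    discard = 0L, detrend = FALSE, motion = FALSE
  )
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}

#' Run the full discriminative pipeline
#'
#' Chains the stages: obtain a cohort (from a manifest or the synthetic
#' generator), optionally preprocess, build the feature table under the
#' chosen measure, rank edges, run the leave-one-out SVM classification (a
#' single k or a sweep), and extract the consensus network. All artifacts
#' are written under `out_dir`, stamped with a hash of the resolved
#' configuration; identical configurations reproduce byte-identical outputs.
#'
#' @param config a named list (or path to a JSON file) with any of: cohort
#'   source (`manifest`, or preset fields `preset`, `n_regions`,
#'   `n_timepoints`, `n_controls`, `n_patients`, `noise_sd`, `seed`),
#'   `measure` (pcc/pcc2/mic/emic), `k`, optional sweep `ks`, and
#'   preprocessing switches `discard`, `detrend`, `band`, `motion`.
#'   Synthetic cohorts default to no further preprocessing (they are already
#'   band-limited and trend-free); file cohorts default to the full temporal
#'   pipeline.
#' @param out_dir output directory.
#' @return (invisibly) a list with the feature table, ranking, fit,
#'   consensus, and the resolved config.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  given <- names(config)
  cfg <- resolve_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(cfg$manifest)) {
    cohort <- read_cohort(cfg$manifest, tr = cfg$tr)
    say("stage load: %d subjects from %s", length(cohort$subjects),
        basename(cfg$manifest))
    if (!"discard" %in% given) cfg$discard <- 5L
    if (!"detrend" %in% given) cfg$detrend <- TRUE
    if (!"motion" %in% given) cfg$motion <- TRUE
    cohort$series <- lapply(seq_along(cohort$series), function(i)
      preprocess_subject(cohort$series[[i]],
                         motion = if (isTRUE(cfg$motion)) cohort$motion[[i]],
                         discard = cfg$discard, detrend = cfg$detrend,
                         band = cfg$band))
    say("stage preprocess: discard=%d detrend=%s band=[%g,%g]", cfg$discard,
        cfg$detrend, cfg$band[1], cfg$band[2])
  } else {
    cc <- cohort_config(preset = cfg$preset, n_regions = cfg$n_regions,
                        n_timepoints = cfg$n_timepoints, tr = cfg$tr,
                        n_controls = cfg$n_controls,
                        n_patients = cfg$n_patients, noise_sd = cfg$noise_sd,
                        band = cfg$band, seed = cfg$seed)
    cohort <- generate_cohort(cc)
    say("stage simulate: preset=%s seed=%d", cfg$preset, cfg$seed)
    if (cfg$discard > 0L || isTRUE(cfg$detrend)) {
      cohort$series <- lapply(cohort$series, preprocess_subject, motion = NULL,
                              discard = cfg$discard, detrend = cfg$detrend,
                              band = cfg$band)
      say("stage preprocess: discard=%d detrend=%s", cfg$discard, cfg$detrend)
    }
  }

  ft <- cohort_features(cohort, cfg$measure)
  say("stage connect: measure=%s, %d x %d features", cfg$measure,
      nrow(ft$x), ncol(ft$x))
  conn_dir <- file.path(out_dir, "connectivity")
  if (!dir.exists(conn_dir)) dir.create(conn_dir)
  for (s in seq_along(cohort$series))
    write_connectivity(
      devectorize(ft$x[s, ], ft$regions, cfg$measure),
      file.path(conn_dir, paste0(cohort$subjects[s], "_", cfg$measure, ".tsv")))

  rk <- rank_edges(ft)
  rk_out <- data.frame(rank = rk$rank, region_i = rk$region_i,
                       region_j = rk$region_j, tau = fmt_num(rk$tau),
                       power = fmt_num(rk$power), direction = rk$direction)
  utils::write.table(rk_out, file.path(out_dir, "ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  say("stage rank: %d edges", nrow(rk))

  fit <- loocv_classify(ft, k = cfg$k)
  say("stage classify: k=%d GR=%.4f SS=%.4f SC=%.4f", cfg$k, fit$gr, fit$ss,
      fit$sc)
  sweep_df <- NULL
  if (!is.null(cfg$ks)) {
    sweep_df <- accuracy_sweep(ft, ks = cfg$ks)
    say("stage sweep: %d settings", nrow(sweep_df))
  }

  cs <- consensus(fit)
  say("stage consensus: %d edges", nrow(cs$edges))
  ce <- cs$edges
  ce_out <- data.frame(region_i = ce$region_i, region_j = ce$region_j,
                       mean_power = fmt_num(ce$mean_power),
                       normalized_strength = fmt_num(ce$normalized_strength),
                       direction = ce$direction)
  utils::write.table(ce_out, file.path(out_dir, "consensus_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(region = names(cs$region_weights),
               weight = as.integer(cs$region_weights)),
    file.path(out_dir, "region_weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  stamp <- fnv1a_hash(as.character(cfg_json))
  report <- list(
    config_hash = stamp,
    measure = cfg$measure, k = cfg$k,
    gr = fit$gr, ss = fit$ss, sc = fit$sc,
    predictions = fit$predictions, truth = fit$truth,
    fold_selections = fit$selections,
    sweep = sweep_df,
    n_consensus = nrow(cs$edges)
  )
  jsonlite::write_json(report, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(as.character(cfg_json), file.path(out_dir, "config.json"))
  writeLines(c(paste0("config_hash: ", stamp), log),
             file.path(out_dir, "run.log"))

  invisible(list(features = ft, ranking = rk, fit = fit, consensus = cs,
                 sweep = sweep_df, config = cfg, config_hash = stamp))
}
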