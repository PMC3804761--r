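#' Regional time-series container
#'
#' Holds one subject's regions x timepoints matrix together with region
#' labels and the sampling interval (repetition time, seconds).
#'
#' @param data numeric matrix, regions in rows, timepoints in columns.
#' @param regions character vector of region names, one per row. Defaults to
#'   `R1..Rn`.
#' @param tr sampling interval in seconds (default 2).
#' @return an object of class `"regional_ts"`.
#' @export
regional_ts <- function(data, regions = NULL, tr = 2) {
  data <- as.matrix(data)
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(data)))
  if (length(regions) != nrow(data))
    stop("need one region label per row: ", length(regions), " labels for ",
         nrow(data), " rows")
  if (anyDuplicated(regions))
    stop("duplicate region label: ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  if (anyNA(data)) stop("missing values are not allowed")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be a positive number")
  structure(list(data = data, regions = as.character(regions), tr = tr),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat("Regional time series: ", nrow(x$data), " regions x ", ncol(x$data),
      " timepoints (TR = ", x$tr, " s)\n", sep = "")
  invisible(x)
}

#' @export
dim.regional_ts <- function(x) dim(x$data)

#' Motion-parameter container
#'
#' Six rigid-body head-motion regressors (3 translations, 3 rotations) as a
#' 6 x timepoints matrix.
#'
#' @param data numeric matrix with 6 rows.
#' @return an object of class `"motion_params"`.
#' @export
motion_params <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) != 6L)
    stop("motion parameters must have 6 rows (3 translations, 3 rotations)")
  if (anyNA(data)) stop("missing values are not allowed")
  structure(list(data = data), class = "motion_params")
}

#' Discard initial volumes
#'
#' Drops the first `k` timepoints of every region, the usual guard against
#' magnetic-saturation effects at the start of an acquisition.
#'
#' @param series a [regional_ts()] object.
#' @param k number of initial timepoints to discard (default 5).
#' @return the shortened series.
#' @export
discard_initial_volumes <- function(series, k = 5L) {
  stopifnot(inherits(series, "regional_ts"))
  k <- as.integer(k)
  if (k < 0L) stop("k must be non-negative")
  if (k >= ncol(series$data))
    stop("cannot discard ", k, " of ", ncol(series$data), " timepoints")
  if (k == 0L) return(series)
  series$data <- series$data[, -(seq_len(k)), drop = FALSE]
  series
}

#' Remove the least-squares linear trend from each region
#'
#' @param series a [regional_ts()] object with at least 3 timepoints.
#' @return the detrended series; regressing any region on the time index
#'   afterwards gives slope and intercept 0.
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "regional_ts"))
  nt <- ncol(series$data)
  if (nt < 3L) stop("need at least 3 timepoints to detrend")
  X <- cbind(1, seq_len(nt))
  # residual maker applied to all regions at once (rows = regions)
  fit <- qr(X)
  series$data <- t(qr.resid(fit, t(series$data)))
  series
}

# design a zero-phase Chebyshev Type I band-pass and apply it to each row
cheby_bandpass_matrix <- function(mat, tr, low, high, order = 4, ripple = 0.5) {
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq))
    stop("band [", low, ", ", high, "] Hz must satisfy 0 < low < high < ",
         "Nyquist (", nyq, " Hz)")
  flt <- signal::cheby1(order, ripple, W = c(low, high) / nyq, type = "pass")
  t(apply(mat, 1L, function(v) signal::filtfilt(flt, v)))
}

#' Chebyshev band-pass filter
#'
#' Temporally filters each region with a Chebyshev Type I band-pass
#' (order 4, 0.5 dB passband ripple) applied forward and backward
#' (zero-phase), so no lag is introduced into the series.
#'
#' @param series a [regional_ts()] object.
#' @param low_hz,high_hz passband edges in Hz; defaults 0.01 and 0.08, the
#'   customary resting-state band.
#' @param order,ripple filter design parameters (order per direction, ripple
#'   in dB).
#' @return the filtered series, same shape.
#' @export
bandpass_chebyshev <- function(series, low_hz = 0.01, high_hz = 0.08,
                               order = 4, ripple = 0.5) {
  stopifnot(inherits(series, "regional_ts"))
  series$data <- cheby_bandpass_matrix(series$data, series$tr, low_hz, high_hz,
                                       order = order, ripple = ripple)
  series
}

#' Regress out head-motion parameters
#'
#' Replaces each region's series by the residual of a least-squares
#' regression on the six motion regressors plus an intercept. Collinear
#' regressor columns are dropped with a warning.
#'
#' @param series a [regional_ts()] object.
#' @param motion a [motion_params()] object with matching timepoints.
#' @return the corrected series (residuals; mean-free by construction).
#' @export
regress_motion <- function(series, motion) {
  stopifnot(inherits(series, "regional_ts"), inherits(motion, "motion_params"))
  nt <- ncol(series$data)
  if (ncol(motion$data) != nt)
    stop("motion parameters have ", ncol(motion$data),
         " timepoints but the series has ", nt)
  X <- cbind(1, t(motion$data))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning("dropping ", ncol(X) - qx$rank,
            " collinear motion regressor(s)")
    qx <- qr(X[, sort(keep), drop = FALSE])
  }
  series$data <- t(qr.resid(qx, t(series$data)))
  series
}

#' Average voxel time series within regions
#'
#' @param voxel_data numeric matrix, voxels x timepoints.
#' @param labels vector mapping each voxel (row) to a region name.
#' @param tr sampling interval in seconds.
#' @return a [regional_ts()] whose rows are unweighted means over each
#'   region's voxels, in order of first appearance of the region labels.
#' @export
regional_average <- function(voxel_data, labels, tr = 2) {
  voxel_data <- as.matrix(voxel_data)
  if (length(labels) != nrow(voxel_data))
    stop("need one region label per voxel row")
  regs <- unique(as.character(labels))
  out <- matrix(0, nrow = length(regs), ncol = ncol(voxel_data))
  for (i in seq_along(regs)) {
    rows <- which(labels == regs[i])
    if (length(rows) == 0L) stop("region '", regs[i], "' has no voxels")
    out[i, ] <- colMeans(voxel_data[rows, , drop = FALSE])
  }
  regional_ts(out, regions = regs, tr = tr)
}

#' Full temporal preprocessing of one subject
#'
#' Applies the temporal pipeline in fixed order: discard initial volumes,
#' linear detrend, Chebyshev band-pass, then head-motion regression (when
#' motion parameters are supplied; they are trimmed to match the discard).
#' The executed stage order is recorded in the `"log"` attribute.
#'
#' @param series a [regional_ts()] object.
#' @param motion optional [motion_params()] with as many timepoints as the
#'   raw series (trimmed alongside it) or as the trimmed series.
#' @param discard number of initial volumes to drop (default 5).
#' @param detrend logical; remove linear trends (default TRUE).
#' @param band passband in Hz, or NULL to skip filtering.
#' @return the preprocessed series with a `"log"` attribute listing stages.
#' @export
preprocess_subject <- function(series, motion = NULL, discard = 5L,
                               detrend = TRUE, band = c(0.01, 0.08)) {
  stopifnot(inherits(series, "regional_ts"))
  log <- character(0)
  if (discard > 0L) {
    series <- discard_initial_volumes(series, discard)
    log <- c(log, sprintf("discard_initial_volumes(k=%d)", discard))
  }
  if (isTRUE(detrend)) {
    series <- detrend_linear(series)
    log <- c(log, "detrend_linear")
  }
  if (!is.null(band)) {
    series <- bandpass_chebyshev(series, band[1], band[2])
    log <- c(log, sprintf("bandpass_chebyshev(%g-%g Hz)", band[1], band[2]))
  }
  if (!is.null(motion)) {
    nt <- ncol(series$data)
    md <- motion$data
    if (ncol(md) == nt + discard) md <- md[, -(seq_len(discard)), drop = FALSE]
    series <- regress_motion(series, motion_params(md))
    log <- c(log, "regress_motion")
  }
  attr(series, "log") <- log
  series
}
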