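#' Sensorimotor ROI label set
#'
#' The 12 bilateral sensorimotor region labels used throughout the pipeline:
#' pre-supplementary and supplementary motor areas, dorsal/ventral premotor,
#' cingulate motor area, primary motor (foot/hand/lip), primary somatosensory
#' (foot/hand), secondary somatosensory, and somatosensory association
#' cortex, each for the left and right hemisphere (24 labels).
#'
#' @return Character vector of 24 ROI labels.
#' @export
roi_labels <- function() {
  base <- c("pSMA", "SMA", "PMd", "PMv", "CMA", "M1F", "M1H", "M1L",
            "S1F", "S1H", "S2", "SAC")
  as.vector(t(outer(base, c("L", "R"), paste, sep = "_")))
}

#' Construct a lead field object
#'
#' @param matrix Numeric sensors x dipoles conduction matrix.
#' @param sensor_labels Character vector, one per row.
#' @param dipole_roi Character vector mapping each dipole (column) to its ROI.
#' @return Object of class `lead_field`.
#' @export
lead_field <- function(matrix, sensor_labels, dipole_roi) {
  stopifnot(is.matrix(matrix))
  if (length(sensor_labels) != nrow(matrix))
    stop_invalid("sensor_labels length != number of rows")
  if (length(dipole_roi) != ncol(matrix))
    stop_invalid("dipole_roi length != number of columns")
  if (any(rowSums(abs(matrix)) == 0) || any(colSums(abs(matrix)) == 0))
    stop_invalid("lead field has an all-zero row or column")
  sv <- svd(matrix, nu = 0, nv = 0)$d
  structure(
    list(matrix = matrix, sensor_labels = as.character(sensor_labels),
         dipole_roi = as.character(dipole_roi),
         condition_number = sv[1] / sv[min(dim(matrix))]),
    class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d sensors x %d dipoles, %d ROI(s), condition %.3g\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$dipole_roi)),
              x$condition_number))
  invisible(x)
}

#' Generate a synthetic lead field with ROI-coherent columns
#'
#' Draws a random sensors x dipoles gain matrix in which dipoles belonging to
#' the same ROI have spatially correlated scalp topographies: each column is
#' `sqrt(1 - s^2) * z_dipole + s * z_roi` with independent standard-normal
#' sensor patterns, so `smoothness` s in [0, 1] is the within-ROI column
#' correlation. This is a statistical stand-in for a head-model forward
#' operator (labelled synthetic; no head geometry is modelled).
#'
#' @param n_sensors Number of sensors (rows).
#' @param n_dipoles Number of dipoles (columns), >= number of ROIs.
#' @param roi_model Either an integer number of ROIs (dipoles are partitioned
#'   evenly, requiring `n_dipoles %% n_rois == 0`), or a character vector of
#'   per-dipole ROI labels of length `n_dipoles`.
#' @param smoothness Within-ROI spatial correlation in [0, 1].
#' @param seed Integer seed.
#' @param sensor_labels Optional sensor names (default "S001", ...).
#' @return A `lead_field`; full row rank is verified and the condition number
#'   stored on the object.
#' @export
generate_lead_field <- function(n_sensors, n_dipoles, roi_model = 24,
                                smoothness = 0.9, seed = 1,
                                sensor_labels = NULL) {
  n_sensors <- check_count(n_sensors, "n_sensors", min = 1)
  n_dipoles <- check_count(n_dipoles, "n_dipoles", min = 1)
  smoothness <- check_fraction(smoothness, "smoothness")
  if (length(roi_model) == 1L && is.numeric(roi_model)) {
    n_rois <- check_count(roi_model, "roi_model", min = 1)
    if (n_dipoles %% n_rois != 0)
      stop_invalid("n_dipoles (%d) not divisible by number of ROIs (%d)",
                   n_dipoles, n_rois)
    labels <- if (n_rois == 24L) roi_labels() else sprintf("ROI%02d", seq_len(n_rois))
    dipole_roi <- rep(labels, each = n_dipoles %/% n_rois)
  } else {
    dipole_roi <- as.character(roi_model)
    if (length(dipole_roi) != n_dipoles)
      stop_invalid("per-dipole roi_model must have length n_dipoles")
  }
  if (n_dipoles < length(unique(dipole_roi)))
    stop_invalid("need at least one dipole per ROI")
  if (n_sensors > n_dipoles)
    stop_invalid("n_sensors (%d) > n_dipoles (%d): full row rank unattainable",
                 n_sensors, n_dipoles)
  L <- with_seed(seed, {
    rois <- unique(dipole_roi)
    roi_pattern <- matrix(stats::rnorm(n_sensors * length(rois)),
                          n_sensors, length(rois), dimnames = list(NULL, rois))
    own <- matrix(stats::rnorm(n_sensors * n_dipoles), n_sensors, n_dipoles)
    sqrt(1 - smoothness^2) * own +
      smoothness * roi_pattern[, dipole_roi, drop = FALSE]
  })
  if (qr(L)$rank < n_sensors)
    stop_invalid("generated lead field is row-rank deficient; change seed or dimensions")
  if (is.null(sensor_labels))
    sensor_labels <- sprintf("S%03d", seq_len(n_sensors))
  lead_field(L, sensor_labels, dipole_roi)
}

#' Project source activity to the scalp through a lead field
#'
#' Implements the linear forward contract m = L d + b. ROI-level sources
#' (one row per ROI) are expanded to all member dipoles with a fixed +/-5%
#' per-dipole gain jitter, emulating coherent cortical patches; dipole-level
#' sources are used as-is. `b` is white Gaussian sensor noise scaled so the
#' ratio of total signal power to total noise power matches `snr_db`
#' (`snr_db = Inf` disables noise).
#'
#' @param sources Array `trials x sources x samples` (or matrix
#'   `sources x samples` for a single trial); rows are ROIs when their count
#'   equals the number of ROIs in `lf`, otherwise dipoles.
#' @param lf A `lead_field`.
#' @param snr_db Signal-to-noise ratio in dB (power ratio over all sensors).
#' @param seed Integer seed for jitter and noise.
#' @param fs Sampling rate recorded on the result (Hz).
#' @return A `sensor_epochs` object (trials x sensors x samples).
#' @export
project_to_scalp <- function(sources, lf, snr_db = Inf, seed = 1, fs = 100) {
  stopifnot(inherits(lf, "lead_field"))
  if (is.matrix(sources)) sources <- array(sources, dim = c(1L, dim(sources)))
  if (!is.array(sources) || length(dim(sources)) != 3L)
    stop_invalid("`sources` must be trials x sources x samples")
  if (!is.null(attr(sources, "fs"))) fs <- attr(sources, "fs")
  n_trials <- dim(sources)[1]; n_src <- dim(sources)[2]; n_samp <- dim(sources)[3]
  rois <- unique(lf$dipole_roi)
  n_dip <- ncol(lf$matrix)
  if (n_src == n_dip) {
    expand <- diag(n_dip)
  } else if (n_src == length(rois)) {
    # ROI series copied to member dipoles with fixed per-dipole gain jitter
    gains <- with_seed(seed, stats::runif(n_dip, 0.95, 1.05))
    expand <- matrix(0, n_dip, n_src)
    expand[cbind(seq_len(n_dip), match(lf$dipole_roi, rois))] <- gains
  } else {
    stop_invalid("source dimension %d matches neither dipoles (%d) nor ROIs (%d)",
                 n_src, n_dip, length(rois))
  }
  proj <- lf$matrix %*% expand                      # sensors x sources
  out <- array(0, dim = c(n_trials, nrow(lf$matrix), n_samp))
  clean <- array(0, dim = dim(out))
  for (tr in seq_len(n_trials))
    clean[tr, , ] <- proj %*% sources[tr, , ]
  if (is.finite(snr_db)) {
    sig_pow <- mean(clean^2)
    noise_sd <- sqrt(sig_pow / 10^(snr_db / 10))
    noise <- with_seed(seed + 1L,
                       array(stats::rnorm(length(clean), sd = noise_sd), dim = dim(clean)))
    out <- clean + noise
  } else {
    out <- clean
  }
  sensor_epochs(out, lf$sensor_labels, fs)
}
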