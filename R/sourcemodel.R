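#' Minimum-norm inverse solution with Tikhonov regularization
#'
#' Estimates dipole currents d minimizing `||m - L d||^2 + lambda ||d||^2`
#' column-wise over time, via the SVD closed form
#' `d = V diag(s / (s^2 + lambda)) U' m`. An optional depth weighting
#' (column-norm) variant is available behind `depth_weight`.
#'
#' @param lf A `lead_field` (M sensors x N dipoles).
#' @param epoch Sensors x samples matrix.
#' @param lambda Regularization parameter, >= 0; `lambda = 0` is refused when
#'   the lead field is rank-deficient.
#' @param depth_weight If TRUE, columns of L are scaled to unit norm before
#'   inversion and the solution rescaled accordingly (weighted minimum norm).
#' @return Object of class `source_estimate` with `dipole_series` (dipoles x
#'   samples), `lambda`, `residual_norm`, `solution_norm`.
#' @export
mne_solve <- function(lf, epoch, lambda, depth_weight = FALSE) {
  stopifnot(inherits(lf, "lead_field"))
  epoch <- as.matrix(epoch)
  L <- lf$matrix
  if (nrow(epoch) != nrow(L))
    stop_invalid("epoch has %d rows but the lead field %d sensors",
                 nrow(epoch), nrow(L))
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop_invalid("`lambda` must be a finite scalar >= 0")
  w <- NULL
  if (depth_weight) {
    w <- sqrt(colSums(L^2))
    L <- sweep(L, 2, w, "/")
  }
  sv <- svd(L)
  tol <- max(sv$d) * max(dim(L)) * .Machine$double.eps
  if (lambda == 0 && min(sv$d) < tol)
    stop_invalid("lead field is rank-deficient: lambda = 0 is not admissible, use lambda > 0")
  filt <- sv$d / (sv$d^2 + lambda)
  d <- sv$v %*% (filt * crossprod(sv$u, epoch))
  if (depth_weight) d <- d / w
  fitted <- lf$matrix %*% d
  structure(
    list(dipole_series = d, lambda = lambda,
         residual_norm = sqrt(sum((epoch - fitted)^2)),
         solution_norm = sqrt(sum(d^2))),
    class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %d dipole(s) x %d sample(s), lambda %.3g, residual %.3g, norm %.3g\n",
              nrow(x$dipole_series), ncol(x$dipole_series), x$lambda,
              x$residual_norm, x$solution_norm))
  invisible(x)
}

#' Default log-spaced regularization grid
#'
#' 40 points log-spaced over `[1e-6, 1e2]` times the mean squared singular
#' value of the lead field, making the grid scale-invariant.
#'
#' @param lf A `lead_field`.
#' @param n Grid size.
#' @return Increasing numeric vector of lambda values.
#' @export
lambda_grid <- function(lf, n = 40) {
  s2 <- mean(svd(lf$matrix, nu = 0, nv = 0)$d^2)
  exp(seq(log(1e-6 * s2), log(1e2 * s2), length.out = n))
}

#' L-curve selection of the regularization parameter
#'
#' Computes the (log residual norm, log solution norm) curve over the grid
#' and returns the interior grid point at the curve's corner, located by the
#' discrete triangle estimator: the point with maximal perpendicular
#' distance from the chord joining the curve's endpoints (the knee of the
#' L). Pointwise Menger curvature is also computed and returned as a
#' diagnostic. A degenerate curve (constant norms) falls back to the median
#' grid value with a warning.
#'
#' @param lf A `lead_field`.
#' @param epoch Sensors x samples matrix.
#' @param grid Increasing vector of >= 10 positive lambda values (default
#'   [lambda_grid()]).
#' @param depth_weight Passed to [mne_solve()].
#' @return Selected lambda, with the diagnostic curve in attribute `curve`
#'   (data frame lambda / residual_norm / solution_norm / curvature).
#' @export
select_lambda_lcurve <- function(lf, epoch, grid = lambda_grid(lf),
                                 depth_weight = FALSE) {
  grid <- sort(as.numeric(grid))
  if (length(grid) < 10 || any(grid <= 0))
    stop_invalid("`grid` needs >= 10 strictly positive values")
  fits <- lapply(grid, function(l) mne_solve(lf, epoch, l, depth_weight))
  rho <- vapply(fits, `[[`, numeric(1), "residual_norm")
  eta <- vapply(fits, `[[`, numeric(1), "solution_norm")
  if (any(rho <= 0)) rho <- pmax(rho, max(rho) * 1e-15 + 1e-300)
  if (stats::sd(log(rho)) < 1e-12 || stats::sd(log(eta + 1e-300)) < 1e-12) {
    warning("degenerate L-curve (constant norms); returning median grid value")
    return(grid[ceiling(length(grid) / 2)])
  }
  if (rho[1] <= 1e-8 * sqrt(sum(epoch^2))) {
    # essentially noiseless data: the L-curve has no corner because there is
    # no noise floor; minimal regularization is appropriate
    out <- grid[2]
    attr(out, "curve") <- data.frame(lambda = grid, residual_norm = rho,
                                     solution_norm = eta,
                                     curvature = NA_real_)
    return(out)
  }
  x <- log(rho); y <- log(eta)
  n <- length(grid)
  # Menger curvature diagnostic at every interior point
  curv <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    a <- c(x[i - 1], y[i - 1]); b <- c(x[i], y[i]); cc <- c(x[i + 1], y[i + 1])
    num <- 2 * abs((b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    den <- sqrt(sum((b - a)^2)) * sqrt(sum((cc - b)^2)) * sqrt(sum((cc - a)^2))
    curv[i] <- if (den > 0) num / den else 0
  }
  # triangle knee: perpendicular distance from the endpoint chord
  vx <- x[n] - x[1]; vy <- y[n] - y[1]
  chord <- sqrt(vx^2 + vy^2)
  dist <- abs((x - x[1]) * vy - (y - y[1]) * vx) / chord
  best <- which.max(dist[2:(n - 1)]) + 1L      # interior points only
  out <- grid[best]
  attr(out, "curve") <- data.frame(lambda = grid, residual_norm = rho,
                                   solution_norm = eta, curvature = curv)
  out
}

#' Average dipole activity into ROI time series
#'
#' Each ROI row is the arithmetic mean of the signed amplitudes of its
#' member dipoles at every sample (consistent dipole orientations are
#' assumed, so signed averaging is meaningful).
#'
#' @param estimate A `source_estimate`.
#' @param lf The `lead_field` whose `dipole_roi` map defines membership.
#' @param fs Sampling rate recorded on the result (Hz).
#' @param interval_tag Interval annotation.
#' @return Object of class `roi_series`: list with `series` (ROIs x
#'   samples), `roi_labels`, `fs`, `interval_tag`.
#' @export
extract_roi_series <- function(estimate, lf, fs = 100, interval_tag = "full") {
  stopifnot(inherits(estimate, "source_estimate"), inherits(lf, "lead_field"))
  d <- estimate$dipole_series
  if (nrow(d) != ncol(lf$matrix))
    stop_invalid("estimate has %d dipoles, lead field %d", nrow(d), ncol(lf$matrix))
  rois <- unique(lf$dipole_roi)
  series <- matrix(0, length(rois), ncol(d), dimnames = list(rois, NULL))
  for (r in seq_along(rois)) {
    members <- which(lf$dipole_roi == rois[r])
    if (!length(members)) stop_invalid("ROI '%s' owns no dipole", rois[r])
    series[r, ] <- colMeans(d[members, , drop = FALSE])
  }
  structure(list(series = series, roi_labels = rois, fs = fs,
                 interval_tag = interval_tag),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> %d ROI(s) x %d sample(s) @ %g Hz (%s)\n",
              nrow(x$series), ncol(x$series), x$fs, x$interval_tag))
  invisible(x)
}
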