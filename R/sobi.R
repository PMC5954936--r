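#' Second-order blind identification (SOBI)
#'
#' Separates linearly mixed sources that are mutually uncorrelated but have
#' distinct temporal autocorrelation: the data are whitened (PCA on the
#' zero-lag covariance, reduced to numerical rank if necessary) and the set
#' of symmetrized time-lagged covariance matrices at lags `1..n_lags` is
#' approximately jointly diagonalized by Givens rotations (Jacobi sweeps
#' with the closed-form pairwise angle). The sweep terminates when every
#' rotation sine falls below `tol`; the off-diagonal criterion is
#' non-increasing across sweeps and is returned for inspection.
#'
#' @param data Channels x samples matrix (continuous, typically the
#'   concatenated recording); channel means are removed internally.
#' @param n_lags Number of covariance lags to diagonalize (default 50).
#' @param tol Convergence threshold on the rotation sines (default 1e-8).
#' @param max_sweeps Sweep cap (default 100).
#' @return List of class `sobi_result` with `mixing` (channels x
#'   components), `unmixing` (components x channels), `components`
#'   (components x samples, ranked by variance), `criterion` (off-diagonal
#'   mass per sweep), and `n_components`.
#' @export
sobi <- function(data, n_lags = 50, tol = 1e-8, max_sweeps = 100) {
  x <- as.matrix(data)
  k <- nrow(x); n <- ncol(x)
  if (n < k * n_lags)
    warning("few samples relative to channels x lags; estimates may be unstable")
  x <- x - rowMeans(x)

  # whitening, reduced to numerical rank
  c0 <- tcrossprod(x) / n
  eg <- eigen(c0, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  if (rank < k)
    warning(sprintf("rank-deficient data: reducing %d channels to %d components", k, rank))
  d <- eg$values[seq_len(rank)]
  E <- eg$vectors[, seq_len(rank), drop = FALSE]
  W <- diag(1 / sqrt(d), rank) %*% t(E)          # whitener
  y <- W %*% x

  # symmetrized lagged covariances of the whitened data
  mats <- lapply(seq_len(n_lags), function(tau) {
    m <- tcrossprod(y[, seq_len(n - tau), drop = FALSE],
                    y[, tau + seq_len(n - tau), drop = FALSE]) / (n - tau)
    (m + t(m)) / 2
  })

  jd <- joint_diagonalize(mats, tol = tol, max_sweeps = max_sweeps)
  V <- jd$rotation                                # orthogonal, rank x rank
  unmixing <- t(V) %*% W
  mixing <- E %*% diag(sqrt(d), rank) %*% V       # pseudo-inverse pair
  comp <- unmixing %*% x

  ord <- order(apply(comp, 1, stats::var), decreasing = TRUE)
  structure(
    list(mixing = mixing[, ord, drop = FALSE],
         unmixing = unmixing[ord, , drop = FALSE],
         components = comp[ord, , drop = FALSE],
         criterion = jd$criterion, n_components = rank),
    class = "sobi_result")
}

#' @export
print.sobi_result <- function(x, ...) {
  cat(sprintf("<sobi_result> %d component(s), %d sweep(s), final off-diagonal mass %.3g\n",
              x$n_components, length(x$criterion), utils::tail(x$criterion, 1)))
  invisible(x)
}

# Jacobi-style approximate joint diagonalization of real symmetric matrices
# (closed-form pairwise rotation angle from the principal eigenvector of the
# 2x2 accumulated quadratic form). Rotations are applied as O(k) row/column
# updates on a k x k x L array.
joint_diagonalize <- function(mats, tol = 1e-8, max_sweeps = 100) {
  k <- nrow(mats[[1]])
  L <- length(mats)
  A <- array(unlist(mats), dim = c(k, k, L))
  V <- diag(k)
  diag_idx <- cbind(rep(seq_len(k), L), rep(seq_len(k), L),
                    rep(seq_len(L), each = k))
  offmass <- function() sum(A^2) - sum(A[diag_idx]^2)
  criterion <- offmass()
  if (k >= 2) {
    for (sweep in seq_len(max_sweeps)) {
      max_s <- 0
      for (p in 1:(k - 1)) for (q in (p + 1):k) {
        h1 <- A[p, p, ] - A[q, q, ]
        h2 <- A[p, q, ] + A[q, p, ]
        g11 <- sum(h1 * h1); g12 <- sum(h1 * h2); g22 <- sum(h2 * h2)
        # principal unit eigenvector (x, y) of [[g11,g12],[g12,g22]], x >= 0
        dg <- g11 - g22
        r <- sqrt(dg * dg + 4 * g12 * g12)
        if (r < .Machine$double.eps) next
        xx <- (dg + r) / 2; yy <- g12
        nv <- sqrt(xx * xx + yy * yy)
        if (nv < .Machine$double.eps) next
        xx <- xx / nv; yy <- yy / nv
        cth <- sqrt((xx + 1) / 2)
        sth <- yy / (2 * cth)
        if (abs(sth) > max_s) max_s <- abs(sth)
        if (abs(sth) < tol) next
        rp <- A[p, , ]; rq <- A[q, , ]             # k x L slabs
        A[p, , ] <- cth * rp + sth * rq
        A[q, , ] <- -sth * rp + cth * rq
        cp <- A[, p, ]; cq <- A[, q, ]
        A[, p, ] <- cth * cp + sth * cq
        A[, q, ] <- -sth * cp + cth * cq
        vp <- V[, p]; vq <- V[, q]
        V[, p] <- cth * vp + sth * vq
        V[, q] <- -sth * vp + cth * vq
      }
      criterion <- c(criterion, offmass())
      if (max_s < tol) break
    }
  }
  list(rotation = V, criterion = criterion)
}

#' Reconstruct epochs with selected components removed
#'
#' Back-projects the retained SOBI components only; rejecting nothing is the
#' identity up to numerical tolerance.
#'
#' @param epochs A `sensor_epochs`.
#' @param result A `sobi_result` fitted on the same channel set.
#' @param rejected Integer indices of components to remove.
#' @return Cleaned `sensor_epochs`.
#' @export
remove_components <- function(epochs, result, rejected) {
  stopifnot(inherits(epochs, "sensor_epochs"), inherits(result, "sobi_result"))
  nc <- result$n_components
  rejected <- as.integer(rejected)
  if (length(rejected) && (any(rejected < 1) || any(rejected > nc)))
    stop_invalid("rejected indices must lie in 1..%d", nc)
  keep <- setdiff(seq_len(nc), rejected)
  if (!length(keep))
    stop_invalid("cannot reject every component")
  P <- result$mixing[, keep, drop = FALSE] %*% result$unmixing[keep, , drop = FALSE]
  out <- epochs$data
  for (tr in seq_len(dim(out)[1]))
    out[tr, , ] <- P %*% epochs$data[tr, , ]
  replace_epoch_data(epochs, out)
}
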