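#' Build a unit-sphere electrode montage
#'
#' @param labels Channel names.
#' @param xyz Numeric n x 3 matrix of sensor positions; rows are normalized
#'   onto the unit sphere.
#' @return Data frame of class `montage` with columns label, x, y, z.
#' @export
montage <- function(labels, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(labels))
  nrm <- sqrt(rowSums(xyz^2))
  if (any(nrm == 0)) stop_invalid("montage position at the origin")
  xyz <- xyz / nrm
  structure(data.frame(label = as.character(labels), x = xyz[, 1],
                       y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE),
            class = c("montage", "data.frame"))
}

#' Quasi-uniform synthetic montage on the upper hemisphere
#'
#' Fibonacci-lattice points restricted to z >= 0, a stand-in for a real
#' electrode layout in simulations.
#'
#' @param n Number of electrodes.
#' @param labels Optional channel names.
#' @return A `montage`.
#' @export
fibonacci_montage <- function(n, labels = sprintf("ch%02d", seq_len(n))) {
  i <- seq_len(2 * n) - 0.5
  z <- 1 - i / n                     # upper hemisphere: z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  keep <- seq_len(n)
  r <- sqrt(pmax(0, 1 - z[keep]^2))
  montage(labels, cbind(r * cos(phi[keep]), r * sin(phi[keep]), z[keep]))
}

# Legendre-series spline kernel g(x) for cosines x (Perrin-style):
# g(x) = (1/4pi) * sum_{l=1}^{N} (2l+1) / (l (l+1))^m * P_l(x)
spline_g <- function(x, m = 4, n_terms = 50) {
  p_prev <- rep(1, length(x))        # P_0
  p_cur <- x                         # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (l in 2:n_terms) {
    p_next <- ((2 * l - 1) * x * p_cur - (l - 1) * p_prev) / l
    acc <- acc + (2 * l + 1) / (l * (l + 1))^m * p_next
    p_prev <- p_cur; p_cur <- p_next
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each bad channel by the spherical-spline estimate from the good
#' channels (Legendre-series kernel with stiffness order `m` and truncation
#' `n_terms`; a small ridge `reg` stabilizes the spline system). The fit
#' includes a constant term, so a spatially uniform field is reproduced
#' exactly, and the estimate is linear in the data. Good channels are left
#' untouched.
#'
#' @param epochs A `sensor_epochs`.
#' @param bad Labels of channels to interpolate (defaults to
#'   `epochs$bad_channels`).
#' @param mont A `montage` covering every channel of `epochs`.
#' @param m Spline stiffness order (default 4).
#' @param n_terms Legendre series truncation (default 50).
#' @param reg Ridge added to the spline system (default 1e-5).
#' @return `sensor_epochs` with interpolated bad channels.
#' @export
interpolate_spherical_spline <- function(epochs, bad = NULL, mont, m = 4,
                                         n_terms = 50, reg = 1e-5) {
  stopifnot(inherits(epochs, "sensor_epochs"), inherits(mont, "montage"))
  if (is.null(bad)) bad <- epochs$bad_channels
  if (!length(bad)) return(epochs)
  labels <- epochs$channel_labels
  if (!all(bad %in% labels))
    stop_invalid("bad channels not in data: %s",
                 paste(setdiff(bad, labels), collapse = ", "))
  if (!all(labels %in% mont$label))
    stop_invalid("montage missing channels: %s",
                 paste(setdiff(labels, mont$label), collapse = ", "))
  pos <- as.matrix(mont[match(labels, mont$label), c("x", "y", "z")])
  good <- which(!labels %in% bad)
  bad_i <- which(labels %in% bad)
  if (length(good) < 4)
    stop_invalid("need at least 4 good channels (have %d)", length(good))

  cosang <- tcrossprod(pos)                        # all-pairs cosines
  cosang[] <- pmin(1, pmax(-1, cosang))
  G <- matrix(spline_g(cosang[good, good], m, n_terms),
              length(good), length(good))
  Gb <- matrix(spline_g(cosang[bad_i, good, drop = FALSE], m, n_terms),
               length(bad_i), length(good))
  ng <- length(good)
  sys <- rbind(cbind(G + diag(reg, ng), rep(1, ng)),
               c(rep(1, ng), 0))
  sys_inv <- solve(sys)

  out <- epochs$data
  for (tr in seq_len(dim(out)[1])) {
    v <- matrix(epochs$data[tr, good, ], ng, dim(out)[3])  # ng x samples
    cc <- sys_inv %*% rbind(v, 0)
    est <- Gb %*% cc[seq_len(ng), , drop = FALSE] +
      matrix(cc[ng + 1, ], length(bad_i), dim(out)[3], byrow = TRUE)
    out[tr, bad_i, ] <- est
  }
  res <- replace_epoch_data(epochs, out)
  res$bad_channels <- character(0)
  res
}
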