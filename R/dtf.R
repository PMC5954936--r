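#' Fit a multivariate autoregressive model by multi-trial least squares
#'
#' Solves the stacked regression X(t) = sum_{j=1..p} A_j X(t-j) + E(t) over
#' all trials jointly: each trial contributes an independent block of
#' equations (no lagged regressor ever straddles a trial boundary). Per-trial
#' channel means are removed before stacking. The residual covariance is
#' estimated from the regression residuals with denominator (n_obs - k*p).
#'
#' @param series Trials x channels x samples array (or channels x samples
#'   matrix for a single trial).
#' @param order Model order p (default 8).
#' @param fs Sampling rate in Hz recorded on the model (default from the
#'   `fs` attribute of `series`, else 100).
#' @return Object of class `mvar_fit`: `order`, `coeffs` (k x k x p;
#'   row = target, column = source), `residual_cov`, `n_obs`, `fs`,
#'   `loglik`, `stable` (companion spectral radius < 1).
#' @export
fit_mvar <- function(series, order = 8, fs = NULL) {
  if (is.matrix(series)) series <- array(series, dim = c(1L, dim(series)))
  stopifnot(is.array(series), length(dim(series)) == 3L)
  if (is.null(fs)) fs <- attr(series, "fs") %||% 100
  order <- check_count(order, "order", min = 1)
  n_trials <- dim(series)[1]; k <- dim(series)[2]; n_samp <- dim(series)[3]
  if (n_samp <= order)
    stop_invalid("trials of %d samples cannot support order %d", n_samp, order)
  n_obs <- n_trials * (n_samp - order)
  if (n_obs < 10 * k * order)
    warning(sprintf("only %d observations for %d parameters per equation; fit may be unstable",
                    n_obs, k * order))
  X <- matrix(0, n_obs, k * order)
  Y <- matrix(0, n_obs, k)
  row0 <- 0L
  for (tr in seq_len(n_trials)) {
    x <- matrix(series[tr, , ], k, n_samp)
    x <- x - rowMeans(x)
    t_idx <- (order + 1L):n_samp
    Y[row0 + seq_along(t_idx), ] <- t(x[, t_idx, drop = FALSE])
    for (j in seq_len(order))
      X[row0 + seq_along(t_idx), (j - 1L) * k + seq_len(k)] <-
        t(x[, t_idx - j, drop = FALSE])
    row0 <- row0 + length(t_idx)
  }
  gram <- crossprod(X)
  cond <- kappa(gram, exact = FALSE)
  if (!is.finite(cond) || cond > 1e12)
    stop_invalid("regressor Gram matrix is ill-conditioned (kappa ~ %.2g); use longer data or a smaller order",
                 cond)
  B <- solve(gram, crossprod(X, Y))            # (k*order) x k
  resid <- Y - X %*% B
  sigma <- crossprod(resid) / max(n_obs - k * order, 1L)
  coeffs <- array(0, dim = c(k, k, order))
  for (j in seq_len(order))
    coeffs[, , j] <- t(B[(j - 1L) * k + seq_len(k), , drop = FALSE])
  sig_det <- determinant(sigma, logarithm = TRUE)
  loglik <- -0.5 * n_obs * (k * log(2 * pi) + as.numeric(sig_det$modulus)) -
    0.5 * (n_obs - k * order) * k
  structure(
    list(order = order, coeffs = coeffs, residual_cov = sigma,
         n_obs = n_obs, fs = fs, loglik = loglik,
         stable = companion_spectral_radius(coeffs) < 1),
    class = "mvar_fit")
}

#' @export
print.mvar_fit <- function(x, ...) {
  cat(sprintf("<mvar_fit> %d channel(s), order %d, %d obs, %sstable\n",
              dim(x$coeffs)[1], x$order, x$n_obs, if (x$stable) "" else "NOT "))
  invisible(x)
}

#' Model-order heuristics report
#'
#' Reports the lag-bound rule (order below tau * fs for an expected
#' inter-process lag tau) alongside AIC/BIC of candidate orders, as a
#' decision aid; it never selects automatically.
#'
#' @param series As in [fit_mvar()].
#' @param orders Candidate orders to profile.
#' @param tau_s Expected inter-areal lag in seconds (default 0.1).
#' @param fs Sampling rate in Hz.
#' @return Data frame with columns order, loglik, aic, bic, within_lag_bound.
#' @export
model_order_report <- function(series, orders = 1:12, tau_s = 0.1, fs = 100) {
  rows <- lapply(orders, function(p) {
    fit <- fit_mvar(series, p, fs = fs)
    k <- dim(fit$coeffs)[1]
    n_par <- k * k * p
    data.frame(order = p, loglik = fit$loglik,
               aic = -2 * fit$loglik + 2 * n_par,
               bic = -2 * fit$loglik + log(fit$n_obs) * n_par,
               within_lag_bound = p < tau_s * fs)
  })
  do.call(rbind, rows)
}

#' Spectral transfer matrix of an MVAR model
#'
#' Evaluates A(f) = I - sum_j A_j exp(-i 2 pi f j / fs) and its inverse
#' H(f) = A(f)^-1 on a frequency grid.
#'
#' @param model An `mvar_fit` or `mvar_system`.
#' @param freqs Frequency grid in Hz, inside (0, fs/2).
#' @return Object of class `spectral_transfer`: `freqs`, `H` (complex
#'   n_freq x k x k array), `fs`.
#' @export
transfer_matrix <- function(model, freqs = NULL) {
  coeffs <- model$coeffs
  fs <- model$fs %||% 100
  if (is.null(freqs)) freqs <- seq(1, floor(fs / 2) - 1)
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop_invalid("`freqs` must lie strictly inside (0, %g)", fs / 2)
  k <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  H <- array(complex(real = 0), dim = c(length(freqs), k, k))
  for (fi in seq_along(freqs)) {
    Af <- diag(k) + 0i
    for (j in seq_len(p))
      Af <- Af - coeffs[, , j] * exp(-2i * pi * freqs[fi] * j / fs)
    Hf <- tryCatch(solve(Af), error = function(e)
      stop_invalid("A(f) is singular at f = %g Hz", freqs[fi]))
    H[fi, , ] <- Hf
  }
  structure(list(freqs = freqs, H = H, fs = fs), class = "spectral_transfer")
}

#' Directed transfer function (normalized, squared)
#'
#' DTF^2 from source channel j to target channel i at frequency f:
#' `|H_ij(f)|^2 / sum_m |H_im(f)|^2`. Each target row therefore sums to one
#' over sources at every frequency.
#'
#' @param transfer A `spectral_transfer`.
#' @return Numeric n_freq x k x k array (element [f, i, j] = DTF^2 of
#'   j -> i).
#' @export
dtf <- function(transfer) {
  stopifnot(inherits(transfer, "spectral_transfer"))
  H2 <- Mod(transfer$H)^2
  out <- H2
  for (fi in seq_len(dim(H2)[1])) {
    rs <- rowSums(H2[fi, , , drop = TRUE])
    if (any(rs == 0))
      stop_invalid("zero transfer row at f = %g Hz", transfer$freqs[fi])
    out[fi, , ] <- H2[fi, , ] / rs
  }
  attr(out, "freqs") <- transfer$freqs
  out
}

#' Frequency bands used throughout the pipeline
#' @return Named list of (low, high) Hz pairs: alpha 8-12, beta 13-30.
#' @export
dtf_bands <- function() list(alpha = c(8, 12), beta = c(13, 30))

#' Construct a connectivity matrix object
#' @keywords internal
connectivity_matrix <- function(weights, band, sig_mask = NULL,
                                n_surrogates = 0L, alpha_level = NA_real_) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (any(weights < -1e-12) || any(weights > 1 + 1e-12))
    stop_invalid("connectivity weights must lie in [0, 1]")
  diag(weights) <- 0
  if (is.null(sig_mask)) sig_mask <- weights > 0
  diag(sig_mask) <- FALSE
  structure(list(weights = weights, band = band, sig_mask = sig_mask,
                 n_surrogates = n_surrogates, alpha_level = alpha_level),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d node(s), band %s, %d significant edge(s)%s\n",
              nrow(x$weights), x$band, sum(x$sig_mask),
              if (x$n_surrogates > 0)
                sprintf(" (%d surrogates, alpha %.3g)", x$n_surrogates, x$alpha_level)
              else " (unthresholded)"))
  invisible(x)
}

#' Aggregate a DTF spectrum over a frequency band
#'
#' Edge weight [i, j] is the mean of DTF^2(j -> i, f) over the grid
#' frequencies falling inside the band (endpoints inclusive). The diagonal
#' is zeroed: self-influence is excluded from the network.
#'
#' @param dtf_spectrum Array from [dtf()] (with `freqs` attribute).
#' @param band Band name from [dtf_bands()] (`"alpha"` or `"beta"`) or a
#'   numeric `(low, high)` pair in Hz.
#' @return An unthresholded `connectivity_matrix`.
#' @export
band_aggregate <- function(dtf_spectrum, band = "alpha") {
  freqs <- attr(dtf_spectrum, "freqs")
  if (is.character(band)) {
    band_name <- band
    lims <- dtf_bands()[[band]]
    if (is.null(lims)) stop_invalid("unknown band '%s'", band)
  } else {
    lims <- as.numeric(band)
    band_name <- sprintf("%g-%gHz", lims[1], lims[2])
  }
  in_band <- which(freqs >= lims[1] & freqs <= lims[2])
  if (!length(in_band))
    stop_invalid("frequency grid has no point inside [%g, %g] Hz", lims[1], lims[2])
  k <- dim(dtf_spectrum)[2]
  w <- matrix(0, k, k)
  for (fi in in_band) w <- w + dtf_spectrum[fi, , ]
  connectivity_matrix(w / length(in_band), band_name)
}

#' Band-aggregated DTF network from multi-trial series
#'
#' Convenience chain: [fit_mvar()] -> [transfer_matrix()] -> [dtf()] ->
#' [band_aggregate()].
#'
#' @inheritParams fit_mvar
#' @inheritParams band_aggregate
#' @param freqs Frequency grid (default 1 Hz spacing over (0, fs/2)).
#' @return An unthresholded `connectivity_matrix`.
#' @export
dtf_network <- function(series, order = 8, band = "alpha", fs = NULL,
                        freqs = NULL) {
  fit <- fit_mvar(series, order, fs = fs)
  band_aggregate(dtf(transfer_matrix(fit, freqs)), band)
}

# conjugate-symmetric phase randomization of one series (FFT magnitudes kept)
phase_randomize <- function(x) {
  n <- length(x)
  sp <- stats::fft(x)
  half <- (n - 1) %/% 2
  if (half >= 1) {
    phases <- stats::runif(half, 0, 2 * pi)
    sp[2:(half + 1)] <- Mod(sp[2:(half + 1)]) * exp(1i * phases)
    sp[n:(n - half + 1)] <- Conj(sp[2:(half + 1)])
  }
  # DC (and Nyquist for even n) stay real
  Re(stats::fft(sp, inverse = TRUE)) / n
}

#' Surrogate-data significance thresholding of DTF networks
#'
#' Builds the empirical null of every band-aggregated edge weight by
#' independently phase-randomizing each channel of each trial (FFT magnitude
#' kept, phases uniform, conjugate-symmetric — preserving univariate spectra
#' while destroying cross-channel causality) and recomputing the full
#' fit -> transfer -> DTF -> band-aggregate chain per surrogate. An edge
#' j -> i is retained iff its observed weight exceeds the empirical
#' (1 - alpha_level) quantile of its surrogate distribution; non-retained
#' weights are zeroed.
#'
#' @inheritParams fit_mvar
#' @inheritParams band_aggregate
#' @param n_surrogates Number of surrogate datasets (1000 in the full
#'   analysis profile); a warning is issued when `(n_surrogates + 1) *
#'   alpha_level < 1`, i.e. when the requested level is finer than the
#'   empirical null can resolve.
#' @param alpha_level Edge-wise significance level (default 0.05).
#' @param seed Integer seed for the surrogate phases.
#' @param freqs Frequency grid (default as in [dtf_network()]).
#' @return A thresholded `connectivity_matrix` with `sig_mask`.
#' @export
surrogate_threshold <- function(series, order = 8, band = "alpha",
                                n_surrogates = 1000, alpha_level = 0.05,
                                seed = 1, fs = NULL, freqs = NULL) {
  if (is.matrix(series)) series <- array(series, dim = c(1L, dim(series)))
  n_surrogates <- check_count(n_surrogates, "n_surrogates", min = 1)
  alpha_level <- check_fraction(alpha_level, "alpha_level")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0))
    stop_invalid("constant (zero-variance) channel(s): %s",
                 paste(which(sds == 0), collapse = ", "))
  if ((n_surrogates + 1) * alpha_level < 1)
    warning(sprintf("%d surrogates cannot resolve alpha = %g (need >= %d)",
                    n_surrogates, alpha_level, ceiling(1 / alpha_level) - 1L))
  if (is.null(fs)) fs <- attr(series, "fs") %||% 100
  observed <- dtf_network(series, order, band, fs = fs, freqs = freqs)
  k <- nrow(observed$weights)
  surr_seeds <- derive_seeds(seed, n_surrogates)
  null_w <- array(0, dim = c(n_surrogates, k, k))
  for (s in seq_len(n_surrogates)) {
    surro <- with_seed(surr_seeds[s], {
      out <- series
      for (tr in seq_len(dim(series)[1]))
        for (ch in seq_len(k))
          out[tr, ch, ] <- phase_randomize(series[tr, ch, ])
      out
    })
    attr(surro, "fs") <- fs
    null_w[s, , ] <- dtf_network(surro, order, band, fs = fs, freqs = freqs)$weights
  }
  thresh <- apply(null_w, c(2, 3), stats::quantile, probs = 1 - alpha_level,
                  names = FALSE)
  mask <- observed$weights > thresh
  diag(mask) <- FALSE
  w <- observed$weights
  w[!mask] <- 0
  connectivity_matrix(w, observed$band, sig_mask = mask,
                      n_surrogates = n_surrogates, alpha_level = alpha_level)
}
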