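#' Generate a stable sparse MVAR system with known causal structure
#'
#' Draws a multivariate autoregressive system X(t) = sum_j A_j X(t-j) + E(t)
#' whose off-diagonal causal graph is sparse and known exactly. Each node
#' carries damped-resonator self-dynamics (an AR(2) pole pair at `osc_freq`
#' with pole radius `osc_damp`) so simulated sources have band-limited,
#' EEG-like spectral content; directed couplings are planted on randomly
#' chosen ordered node pairs, each with a coefficient drawn uniformly on
#' +/-[0.1, 0.5] at a random lag. If the companion spectral radius reaches
#' 0.95 all coefficients are shrunk iteratively until it is below 0.95, so
#' every emitted system is comfortably stable.
#'
#' @param n_nodes Number of channels/ROIs (>= 2).
#' @param order Model order p (>= 1).
#' @param edge_density Fraction of the n_nodes*(n_nodes-1) ordered
#'   off-diagonal pairs that receive a causal coupling.
#' @param seed Integer seed; regenerating with the same seed is bit-identical.
#' @param fs Sampling rate the system is interpreted at (Hz).
#' @param osc_freq Self-dynamics resonance frequency in Hz (alpha-band
#'   default). Ignored when `order == 1`.
#' @param osc_damp Pole radius of the resonator in (0, 1).
#' @param noise_cov Innovation covariance (default identity).
#' @return An object of class `mvar_system` with fields `n_nodes`, `order`,
#'   `coeffs` (k x k x p), `causal_mask` (TRUE where any lag coefficient of
#'   j -> i is nonzero; convention row = target i, column = source j),
#'   `noise_cov`, `fs`, `seed`.
#' @export
generate_mvar_system <- function(n_nodes, order, edge_density, seed,
                                 fs = 100, osc_freq = 10, osc_damp = 0.8,
                                 noise_cov = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2)
  order <- check_count(order, "order", min = 1)
  edge_density <- check_fraction(edge_density, "edge_density")
  if (is.null(noise_cov)) noise_cov <- diag(n_nodes)
  stopifnot(is.matrix(noise_cov), all(dim(noise_cov) == n_nodes))
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop_invalid("`noise_cov` must be positive-semidefinite")

  coeffs <- with_seed(seed, {
    a <- array(0, dim = c(n_nodes, n_nodes, order))
    # self dynamics: damped resonance (order >= 2) or mild AR(1)
    if (order >= 2L) {
      a1 <- 2 * osc_damp * cos(2 * pi * osc_freq / fs)
      for (i in seq_len(n_nodes)) {
        a[i, i, 1] <- a1
        a[i, i, 2] <- -osc_damp^2
      }
    } else {
      for (i in seq_len(n_nodes)) a[i, i, 1] <- 0.5
    }
    # planted directed couplings on distinct ordered off-diagonal pairs
    n_pairs <- n_nodes * (n_nodes - 1L)
    n_edges <- round(edge_density * n_pairs)
    if (n_edges > 0) {
      chosen <- sample.int(n_pairs, n_edges)
      for (idx in chosen) {
        src <- (idx - 1L) %/% (n_nodes - 1L) + 1L
        tgt <- (idx - 1L) %% (n_nodes - 1L) + 1L
        if (tgt >= src) tgt <- tgt + 1L
        lag <- sample.int(order, 1L)
        coef <- sample(c(-1, 1), 1L) * runif(1L, 0.1, 0.5)
        a[tgt, src, lag] <- coef
      }
    }
    a
  })

  # iterative global shrinkage to guarantee stability margin
  n_shrink <- 0L
  while (companion_spectral_radius(coeffs) >= 0.95) {
    coeffs <- coeffs * 0.95
    n_shrink <- n_shrink + 1L
    if (n_shrink > 200L)
      stop_invalid("could not stabilize system at density %g", edge_density)
  }

  mask <- apply(coeffs != 0, c(1, 2), any)
  diag(mask) <- FALSE
  structure(
    list(n_nodes = n_nodes, order = order, coeffs = coeffs,
         causal_mask = mask, noise_cov = noise_cov, fs = fs, seed = seed,
         n_shrink = n_shrink),
    class = "mvar_system")
}

#' @export
print.mvar_system <- function(x, ...) {
  cat(sprintf("<mvar_system> %d nodes, order %d, %d causal edge(s), radius %.3f\n",
              x$n_nodes, x$order, sum(x$causal_mask),
              companion_spectral_radius(x$coeffs)))
  invisible(x)
}

#' Simulate multi-trial source time series from an MVAR system
#'
#' Runs the autoregressive recursion with independent Gaussian innovations of
#' covariance `noise_cov`, discarding a burn-in of `10 * order * n_nodes`
#' samples per trial so initial-condition transients never reach the output.
#'
#' @param system An `mvar_system`.
#' @param n_samples Samples to keep per trial (> 10 * order).
#' @param n_trials Number of independent trials.
#' @param seed Integer seed; trials draw from deterministically derived
#'   per-trial streams.
#' @return Numeric array `n_trials x n_nodes x n_samples` with attribute
#'   `fs`.
#' @export
simulate_sources <- function(system, n_samples, n_trials = 1, seed = 1) {
  stopifnot(inherits(system, "mvar_system"))
  n_samples <- check_count(n_samples, "n_samples", min = 1)
  n_trials <- check_count(n_trials, "n_trials", min = 1)
  if (n_samples <= 10 * system$order)
    stop_invalid("`n_samples` must exceed 10 * order = %d", 10 * system$order)
  radius <- companion_spectral_radius(system$coeffs)
  if (radius >= 1)
    stop_invalid("system is unstable (companion spectral radius %.3f >= 1); refusing to simulate",
                 radius)
  k <- system$n_nodes; p <- system$order
  burn <- 10L * p * k
  chol_cov <- chol(system$noise_cov + diag(1e-12, k))
  total <- burn + n_samples
  trial_seeds <- derive_seeds(seed, n_trials)
  out <- array(0, dim = c(n_trials, k, n_samples))
  for (tr in seq_len(n_trials)) {
    innov <- with_seed(trial_seeds[tr],
                       matrix(stats::rnorm(total * k), k, total))
    innov <- crossprod(chol_cov, innov)      # k x total, cov = noise_cov
    x <- matrix(0, k, total)
    for (t in seq_len(total)) {
      acc <- innov[, t]
      for (j in seq_len(min(p, t - 1L)))
        acc <- acc + system$coeffs[, , j] %*% x[, t - j]
      x[, t] <- acc
    }
    out[tr, , ] <- x[, burn + seq_len(n_samples)]
  }
  attr(out, "fs") <- system$fs
  out
}

#' Deterministic 5-node benchmark system
#'
#' A sparse causal chain 1 -> 2 -> 3 -> 4 -> 5 with one feedback edge
#' 3 -> 2, on top of damped-resonator self-dynamics, globally rescaled to a
#' companion spectral radius below 0.95. Eleven of the twenty ordered node
#' pairs communicate through directed paths; the other nine have no directed
#' path, giving a clean positive/negative split for causal-recovery checks
#' (the DTF measures direct plus cascade flow, so every communicating pair
#' should carry significant weight).
#'
#' @param coupling Coupling coefficient planted on each edge (lag 1).
#' @param order Model order (default 8).
#' @param osc_damp Self-dynamics pole radius.
#' @return An `mvar_system` with the chain-plus-feedback causal mask.
#' @export
benchmark_system <- function(coupling = 0.5, order = 8, osc_damp = 0.7) {
  sys <- generate_mvar_system(5, order, 0, seed = 1, osc_damp = osc_damp)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(3, 2)))
    sys$coeffs[e[2], e[1], 1] <- coupling
  while (companion_spectral_radius(sys$coeffs) >= 0.95)
    sys$coeffs <- sys$coeffs * 0.95
  mask <- apply(sys$coeffs != 0, c(1, 2), any)
  diag(mask) <- FALSE
  sys$causal_mask <- mask
  sys
}

#' Directed reachability closure of a causal mask
#'
#' @param mask Boolean adjacency (element [i, j] TRUE for an edge j -> i).
#' @return Boolean matrix, TRUE where a directed path j -> ... -> i exists
#'   (diagonal FALSE).
#' @export
reachability <- function(mask) {
  r <- (as.matrix(mask) > 0) * 1
  n <- nrow(r)
  for (k in seq_len(n)) {
    rn <- ((r + r %*% r) > 0) * 1
    if (all(rn == r)) break
    r <- rn
  }
  diag(r) <- 0
  r > 0
}

#' Generate a two-group cohort of subject-level MVAR systems
#'
#' Each subject receives an independent copy of the base system whose nonzero
#' coefficients (couplings and self-dynamics) are jittered with Gaussian noise
#' of standard deviation `within_noise_sd`, modelling inter-subject
#' variability while preserving the causal mask. Group B subjects additionally
#' have the lag-1 coefficient of each planted edge shifted by `effect`,
#' creating a known edge-level group difference for power studies. Any subject
#' system pushed to a companion spectral radius >= 0.95 is rescaled back with
#' a warning.
#'
#' @param base_system An `mvar_system` shared by all subjects.
#' @param n_per_group Subjects per group.
#' @param planted_edges Data frame with columns `source`, `target`, `effect`
#'   (node indices and the additive coefficient shift applied in group B), or
#'   NULL for a null cohort.
#' @param within_noise_sd SD of the per-subject coefficient jitter.
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @param n_samples,n_trials If `n_samples` is given, per-subject source data
#'   are simulated and returned alongside the systems.
#' @return List with `systems` (list of lists `A`, `B` of `mvar_system`) and,
#'   when requested, `sources` (same structure of trial arrays), plus
#'   `planted_edges` and `seed`.
#' @export
generate_cohort <- function(base_system, n_per_group, planted_edges = NULL,
                            within_noise_sd = 0.02, seed = 1,
                            n_samples = NULL, n_trials = 1) {
  stopifnot(inherits(base_system, "mvar_system"))
  n_per_group <- check_count(n_per_group, "n_per_group", min = 1)
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("source", "target", "effect") %in% names(planted_edges)))
    if (any(planted_edges$source < 1 | planted_edges$source > base_system$n_nodes |
            planted_edges$target < 1 | planted_edges$target > base_system$n_nodes))
      stop_invalid("planted edges reference node indices outside 1..%d",
                   base_system$n_nodes)
    if (any(planted_edges$source == planted_edges$target))
      stop_invalid("planted edges must be off-diagonal")
    if (any(!is.finite(planted_edges$effect)))
      stop_invalid("planted effect sizes must be finite")
  }
  subject_seeds <- matrix(derive_seeds(seed, 2L * n_per_group), nrow = 2L)
  nz <- base_system$coeffs != 0

  make_subject <- function(group, idx) {
    s <- subject_seeds[group, idx]
    coeffs <- base_system$coeffs
    jitter <- with_seed(s, array(stats::rnorm(length(coeffs), sd = within_noise_sd),
                                 dim = dim(coeffs)))
    coeffs[nz] <- coeffs[nz] + jitter[nz]
    if (group == 2L && !is.null(planted_edges)) {
      for (e in seq_len(nrow(planted_edges)))
        coeffs[planted_edges$target[e], planted_edges$source[e], 1] <-
          coeffs[planted_edges$target[e], planted_edges$source[e], 1] +
          planted_edges$effect[e]
    }
    n_rescale <- 0L
    while (companion_spectral_radius(coeffs) >= 0.95) {
      coeffs <- coeffs * 0.95
      n_rescale <- n_rescale + 1L
      if (n_rescale > 200L) stop_invalid("subject system could not be stabilized")
    }
    if (n_rescale > 0L)
      warning(sprintf("subject (group %s, index %d) rescaled %d time(s) to restore stability",
                      c("A", "B")[group], idx, n_rescale))
    sys <- base_system
    sys$coeffs <- coeffs
    mask <- apply(coeffs != 0, c(1, 2), any)
    diag(mask) <- FALSE
    sys$causal_mask <- mask
    sys$seed <- s
    sys
  }

  systems <- list(A = lapply(seq_len(n_per_group), function(i) make_subject(1L, i)),
                  B = lapply(seq_len(n_per_group), function(i) make_subject(2L, i)))
  out <- list(systems = systems, planted_edges = planted_edges, seed = seed)
  if (!is.null(n_samples)) {
    sim_seeds <- matrix(derive_seeds(seed + 1L, 2L * n_per_group), nrow = 2L)
    out$sources <- list(
      A = lapply(seq_len(n_per_group), function(i)
        simulate_sources(systems$A[[i]], n_samples, n_trials, sim_seeds[1L, i])),
      B = lapply(seq_len(n_per_group), function(i)
        simulate_sources(systems$B[[i]], n_samples, n_trials, sim_seeds[2L, i])))
  }
  class(out) <- "mvar_cohort"
  out
}

#' @export
print.mvar_cohort <- function(x, ...) {
  cat(sprintf("<mvar_cohort> %d vs %d subjects, %d planted edge(s)\n",
              length(x$systems$A), length(x$systems$B),
              if (is.null(x$planted_edges)) 0L else nrow(x$planted_edges)))
  invisible(x)
}
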