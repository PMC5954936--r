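# Independent brute-force oracles used to validate the graph and spectral
# implementations on small instances.

# all-pairs shortest directed distances by exhaustive simple-path enumeration
# (depth-first over all simple paths; exact for n <= ~6)
brute_force_distances <- function(lengths) {
  n <- nrow(lengths)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (start in seq_len(n)) {
    visited <- rep(FALSE, n)
    visited[start] <- TRUE
    walk <- function(node, acc) {
      for (nxt in seq_len(n)) {
        if (visited[nxt] || !is.finite(lengths[nxt, node])) next
        d <- acc + lengths[nxt, node]     # edge node -> nxt (row = target)
        if (d < best[nxt, start]) best[nxt, start] <<- d
        visited[nxt] <<- TRUE
        walk(nxt, d)
        visited[nxt] <<- FALSE
      }
    }
    walk(start, 0)
  }
  best
}

# triangle-count clustering on the OR-symmetrized binarized graph, by
# explicit enumeration over node triples
brute_force_clustering <- function(adj) {
  b <- (adj > 0 | t(adj) > 0) * 1
  diag(b) <- 0
  n <- nrow(b)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(b[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_along(nb)) for (bb in seq_along(nb)) {
      if (a < bb && b[nb[a], nb[bb]] == 1) tri <- tri + 1
    }
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  list(nodal = ci, global = mean(ci))
}

# CPL exactly as defined from a [target, source] distance matrix: the nodal
# mean L_i averages the finite distances FROM node i (column i), then CPL
# averages over nodes with at least one finite outgoing distance
cpl_from_distances <- function(d) {
  n <- nrow(d)
  diag(d) <- Inf
  li <- vapply(seq_len(n), function(i) {
    f <- is.finite(d[, i])
    if (any(f)) mean(d[f, i]) else NA_real_
  }, numeric(1))
  mean(li, na.rm = TRUE)
}

# a small deterministic multichannel test signal
toy_recording <- function(n_chan = 8, n_samp = 3000, fs = 100, seed = 42) {
  set.seed(seed)
  t <- seq_len(n_samp) / fs
  sig <- t(sapply(seq_len(n_chan), function(ch)
    sin(2 * pi * (6 + ch) * t + ch) + 0.3 * rnorm(n_samp)))
  sig
}
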