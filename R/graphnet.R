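as_adjacency <- function(adj) {
  if (inherits(adj, "connectivity_matrix")) adj <- adj$weights
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop_invalid("adjacency must be square")
  diag(adj) <- 0
  adj
}

#' Nodal in- and out-strengths
#'
#' In-strength of node i is the sum of incoming connection weights
#' (column-sums over sources of edges j -> i); out-strength of node j the
#' sum of outgoing weights. The convention throughout is weights[i, j] =
#' weight of the edge j -> i.
#'
#' @param adj `connectivity_matrix` or square weighted adjacency
#'   (row = target, column = source); diagonal ignored.
#' @return List with numeric vectors `in_strength` and `out_strength`.
#' @export
node_strengths <- function(adj) {
  w <- as_adjacency(adj)
  list(in_strength = rowSums(w), out_strength = colSums(w))
}

#' Clustering coefficient
#'
#' Default (`binary_undirected`) applies the classic triangle formula
#' C_i = 2 t_i / (k_i (k_i - 1)) on the binarized, OR-symmetrized graph,
#' with C_i = 0 where the degree k_i < 2; the global CC is the mean of the
#' nodal values. The `directed_weighted` variant implements the standard
#' directed weighted clustering (Fagiolo): with W^(1/3) cube-root weights,
#' t_i = (W^1/3 + W'^1/3)^3_ii / 2 and the denominator uses total degree
#' corrected for reciprocal edges.
#'
#' @param adj `connectivity_matrix` or square weighted adjacency.
#' @param variant `"binary_undirected"` (default) or `"directed_weighted"`.
#' @return List with `nodal` (C_i per node) and `global` (mean CC).
#' @export
clustering_coefficient <- function(adj, variant = c("binary_undirected",
                                                    "directed_weighted")) {
  variant <- match.arg(variant)
  w <- as_adjacency(adj)
  n <- nrow(w)
  if (variant == "binary_undirected") {
    b <- (w > 0 | t(w) > 0) * 1
    diag(b) <- 0
    deg <- rowSums(b)
    tri <- diag(b %*% b %*% b) / 2          # triangles through each node
    ci <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  } else {
    a <- (w > 0) * 1
    w3 <- w^(1 / 3)
    s <- w3 + t(w3)
    tri <- diag(s %*% s %*% s) / 2
    deg_tot <- rowSums(a) + colSums(a)
    recip <- diag(a %*% a)
    denom <- 2 * (deg_tot * (deg_tot - 1) - 2 * recip)
    ci <- ifelse(denom > 0, tri / denom, 0)
  }
  list(nodal = as.numeric(ci), global = mean(ci))
}

#' Characteristic path length of a weighted directed network
#'
#' Edge weights in (0, 1] are converted to lengths by the logarithmic map
#' l = -ln(w) (zero weight = no edge, infinite length); binary graphs
#' (`lengths = "unit"`, the automatic choice when every nonzero weight is 1)
#' use unit hop lengths instead, and a reciprocal map 1/w is available.
#' All-pairs shortest directed distances are computed by Floyd-Warshall;
#' the nodal mean L_i averages the finite distances from i to the other
#' nodes, and CPL is the mean of L_i over nodes with at least one finite
#' distance. The number of unreachable ordered pairs is always reported.
#'
#' @param adj `connectivity_matrix` or square weighted adjacency with
#'   weights in [0, 1] (for the default map).
#' @param lengths `"auto"` (default), `"neglog"`, `"reciprocal"`, or
#'   `"unit"`.
#' @return List with `cpl`, `distances` (d_ij matrix), `nodal` (L_i),
#'   `n_unreachable` (ordered pairs with no directed path).
#' @export
characteristic_path_length <- function(adj, lengths = c("auto", "neglog",
                                                        "reciprocal", "unit")) {
  lengths <- match.arg(lengths)
  w <- as_adjacency(adj)
  n <- nrow(w)
  nz <- w[w != 0]
  if (lengths == "auto")
    lengths <- if (length(nz) && all(nz == 1)) "unit" else "neglog"
  if (lengths == "neglog" && any(w > 1))
    stop_invalid("weights above 1 give negative -log lengths; rescale or use another map")
  if (any(w < 0)) stop_invalid("negative weights are not supported")
  d <- switch(lengths,
              neglog = ifelse(w > 0, -log(w), Inf),
              reciprocal = ifelse(w > 0, 1 / w, Inf),
              unit = ifelse(w > 0, 1, Inf))
  diag(d) <- 0
  for (via in seq_len(n))                       # Floyd-Warshall
    d <- pmin(d, outer(d[, via], d[via, ], "+"))
  off <- d; diag(off) <- Inf
  finite <- is.finite(off)
  # distances are stored [target, source]; L_i averages the distances FROM
  # node i to the others, i.e. the finite entries of column i
  li <- vapply(seq_len(n), function(i) {
    f <- finite[, i]
    if (any(f)) mean(off[f, i]) else NA_real_
  }, numeric(1))
  cpl <- mean(li, na.rm = TRUE)
  if (!any(finite)) cpl <- NA_real_
  list(cpl = cpl, distances = d, nodal = li,
       n_unreachable = sum(!finite) - n)       # off-diagonal pairs only
}

#' Network density
#'
#' Ratio of present directed edges (nonzero off-diagonal weights) to the
#' maximum possible |V| (|V| - 1); weights are ignored.
#'
#' @param adj `connectivity_matrix` or square adjacency.
#' @return Density in [0, 1].
#' @export
network_density <- function(adj) {
  w <- as_adjacency(adj)
  n <- nrow(w)
  sum(w != 0) / (n * (n - 1))
}

#' Uniform random directed graph with fixed edge count
#'
#' Draws `m` distinct ordered off-diagonal pairs uniformly without
#' replacement.
#'
#' @param n Number of nodes.
#' @param m Number of directed edges, 0 <= m <= n (n - 1).
#' @param seed Integer seed.
#' @return Binary n x n adjacency matrix (row = target, column = source).
#' @export
random_directed_graph <- function(n, m, seed = 1) {
  n <- check_count(n, "n", min = 1)
  m <- check_count(m, "m", min = 0)
  n_pairs <- n * (n - 1L)
  if (m > n_pairs)
    stop_invalid("m = %d exceeds the %d possible directed edges", m, n_pairs)
  adj <- matrix(0, n, n)
  if (m > 0) {
    chosen <- with_seed(seed, sample.int(n_pairs, m))
    src <- (chosen - 1L) %/% (n - 1L) + 1L
    tgt <- (chosen - 1L) %% (n - 1L) + 1L
    tgt <- ifelse(tgt >= src, tgt + 1L, tgt)
    adj[cbind(tgt, src)] <- 1
  }
  adj
}

#' Small-worldness against random directed nulls
#'
#' Compares the network's clustering and characteristic path length to
#' `n_random` random directed graphs with the same number of nodes and
#' edges: for each null draw, SW = (CC / CC_rand) / (CPL / CPL_rand) is
#' computed with CC and CPL obtained exactly as for the original (null
#' graphs are binary, hence unit edge lengths), and the draws are averaged
#' into a single value. Null means of CC and CPL are reported. Draws whose
#' null CC or CPL is degenerate (zero / non-finite) are dropped with a
#' diagnostic count; SW is NA if every draw degenerates.
#'
#' @param adj `connectivity_matrix` or square weighted adjacency.
#' @param n_random Number of null draws (10,000 in the full analysis
#'   profile).
#' @param seed Integer seed; each draw uses a derived sub-seed.
#' @param cc_variant Clustering variant applied to original and nulls.
#' @param null_graphs Optional list of reference adjacencies to use instead
#'   of random draws (their path lengths use the automatic length map).
#' @return List with `sw`, `cc`, `cpl`, `cc_rand`, `cpl_rand`,
#'   `n_degenerate`.
#' @export
small_worldness <- function(adj, n_random = 1000, seed = 1,
                            cc_variant = "binary_undirected",
                            null_graphs = NULL) {
  w <- as_adjacency(adj)
  n <- nrow(w)
  m <- sum(w != 0)
  if (m < 1) stop_invalid("graph has no edges")
  if (!is.null(null_graphs)) n_random <- length(null_graphs)
  n_random <- check_count(n_random, "n_random", min = 1)
  cc0 <- clustering_coefficient(w, cc_variant)$global
  cpl0 <- characteristic_path_length(w)$cpl
  seeds <- derive_seeds(seed, n_random)
  sw_vals <- numeric(0)
  cc_r <- numeric(0); cpl_r <- numeric(0)
  n_degenerate <- 0L
  for (i in seq_len(n_random)) {
    r <- if (is.null(null_graphs)) random_directed_graph(n, m, seeds[i])
         else as_adjacency(null_graphs[[i]])
    ccr <- clustering_coefficient(r, cc_variant)$global
    cplr <- characteristic_path_length(
      r, lengths = if (is.null(null_graphs)) "unit" else "auto")$cpl
    if (!is.finite(ccr) || !is.finite(cplr) || ccr <= 0 || cplr <= 0 ||
        !is.finite(cpl0) || cpl0 <= 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    cc_r <- c(cc_r, ccr); cpl_r <- c(cpl_r, cplr)
    sw_vals <- c(sw_vals, (cc0 / ccr) / (cpl0 / cplr))
  }
  if (!length(sw_vals))
    warning("small-worldness undefined: every null draw was degenerate")
  list(sw = if (length(sw_vals)) mean(sw_vals) else NA_real_,
       cc = cc0, cpl = cpl0,
       cc_rand = if (length(cc_r)) mean(cc_r) else NA_real_,
       cpl_rand = if (length(cpl_r)) mean(cpl_r) else NA_real_,
       n_degenerate = n_degenerate)
}

#' Full graph summary of a connectivity network
#'
#' Bundles nodal strengths and clustering with the graph-level descriptors
#' (CPL, CC, density, small-worldness) into one object.
#'
#' @param adj `connectivity_matrix` or square weighted adjacency.
#' @param n_random Null-sample size for small-worldness (0 skips SW).
#' @param seed Seed for the SW nulls.
#' @param cc_variant Clustering variant.
#' @return Object of class `graph_summary`.
#' @export
graph_summary <- function(adj, n_random = 1000, seed = 1,
                          cc_variant = "binary_undirected") {
  w <- as_adjacency(adj)
  st <- node_strengths(w)
  cc <- clustering_coefficient(w, cc_variant)
  cpl <- characteristic_path_length(w)
  dens <- network_density(w)
  sw <- if (n_random > 0 && sum(w != 0) > 0)
    small_worldness(w, n_random, seed, cc_variant)
  else list(sw = NA_real_, cc_rand = NA_real_, cpl_rand = NA_real_,
            n_degenerate = NA_integer_)
  structure(
    list(n = nrow(w), n_edges = sum(w != 0),
         in_strength = st$in_strength, out_strength = st$out_strength,
         nodal_cc = cc$nodal, cc = cc$global,
         cpl = cpl$cpl, nodal_cpl = cpl$nodal,
         n_unreachable = cpl$n_unreachable,
         density = dens, sw = sw$sw, cc_rand = sw$cc_rand,
         cpl_rand = sw$cpl_rand, n_random = n_random),
    class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("<graph_summary> n = %d, edges = %d, D = %.4f, CC = %.4f, CPL = %.4f, SW = %s\n",
              x$n, x$n_edges, x$density, x$cc, x$cpl,
              if (is.na(x$sw)) "NA" else sprintf("%.3f", x$sw)))
  invisible(x)
}
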