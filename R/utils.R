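#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before. All stochastic operations in the
#' package route their draws through this helper so that every generator is
#' bit-reproducible given `(seed, parameters)` and never perturbs the caller's
#' RNG stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a set of child seeds from a master seed
#'
#' Deterministically expands one master seed into `n` independent child seeds
#' (each below 2^31), used to give every subject / trial / surrogate its own
#' attributable stream.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# argument guards ------------------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_invalid("`%s` must be an integer >= %s (got %s)", name, min,
                 paste(format(x), collapse = ","))
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_invalid("`%s` must lie in [0, 1]", name)
  as.numeric(x)
}

#' Spectral radius of the companion matrix of an MVAR coefficient array
#'
#' The k*p x k*p companion form stacks the lag matrices in the first block
#' row; the process is (strictly) stable iff all companion eigenvalues lie
#' inside the unit circle.
#'
#' @param coeffs k x k x p array of lag coefficient matrices.
#' @return Largest eigenvalue modulus.
#' @export
companion_spectral_radius <- function(coeffs) {
  stopifnot(is.array(coeffs), length(dim(coeffs)) == 3L,
            dim(coeffs)[1] == dim(coeffs)[2])
  k <- dim(coeffs)[1]
  p <- dim(coeffs)[3]
  comp <- matrix(0, k * p, k * p)
  for (j in seq_len(p))
    comp[seq_len(k), (j - 1L) * k + seq_len(k)] <- coeffs[, , j]
  if (p > 1L)
    comp[k + seq_len(k * (p - 1L)), seq_len(k * (p - 1L))] <-
      diag(k * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}
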