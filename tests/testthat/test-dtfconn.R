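test_that("multi-trial least squares recovers known MVAR coefficients", {
  sys <- generate_mvar_system(4, 3, 0.3, seed = 13)
  x <- simulate_sources(sys, 500, n_trials = 20, seed = 1)
  fit <- fit_mvar(x, order = 3)
  expect_lt(sqrt(mean((fit$coeffs - sys$coeffs)^2)), 0.05)
  expect_true(fit$stable)
  expect_equal(dim(fit$residual_cov), c(4, 4))
  # deterministic: fitting the same data twice is identical
  expect_identical(fit$coeffs, fit_mvar(x, order = 3)$coeffs)
})

test_that("white-noise fits produce coefficients within sampling error", {
  ok <- vapply(1:10, function(seed) {
    sys <- generate_mvar_system(3, 1, 0, seed = seed)
    sys$coeffs[] <- 0
    x <- simulate_sources(sys, 2000, seed = seed)
    fit <- fit_mvar(x, order = 1)
    # standard error of an AR coefficient on white noise ~ 1/sqrt(n)
    all(abs(fit$coeffs) < 3 / sqrt(fit$n_obs) * 3)
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("ill-conditioned regressions are refused with advice", {
  x <- array(0, c(1, 3, 60))
  x[1, , ] <- matrix(rnorm(9), 3, 3)[, rep(1, 60)] * rep(1, 60)  # collinear
  expect_error(suppressWarnings(fit_mvar(x, order = 4)), "ill-conditioned")
})

test_that("the transfer matrix obeys closed forms and inverse identity", {
  # zero-coefficient model: H(f) = I everywhere
  null_fit <- structure(list(order = 1, coeffs = array(0, c(3, 3, 1)), fs = 100),
                        class = "mvar_fit")
  tm <- transfer_matrix(null_fit, freqs = c(5, 10, 20))
  for (fi in 1:3) expect_equal(tm$H[fi, , ], diag(3) + 0i, tolerance = 1e-12)

  # independent AR(1) channels a = 0.5: |H_ii(f)| = 1 / |1 - 0.5 e^{-iw}|
  diag_fit <- structure(list(order = 1,
                             coeffs = array(diag(0.5, 2), c(2, 2, 1)), fs = 100),
                        class = "mvar_fit")
  freqs <- c(2, 10, 25, 40)
  tmd <- transfer_matrix(diag_fit, freqs)
  for (fi in seq_along(freqs)) {
    w <- 2 * pi * freqs[fi] / 100
    expect_equal(Mod(tmd$H[fi, 1, 1]), 1 / Mod(1 - 0.5 * exp(-1i * w)),
                 tolerance = 1e-12)
    expect_equal(tmd$H[fi, 1, 2], 0 + 0i)
  }

  # H(f) A(f) = I at every grid point
  sys <- generate_mvar_system(5, 3, 0.3, seed = 17)
  fit <- fit_mvar(simulate_sources(sys, 800, seed = 2), order = 3)
  tm2 <- transfer_matrix(fit)
  for (fi in seq_along(tm2$freqs)) {
    Af <- diag(5) + 0i
    for (j in 1:3) Af <- Af - fit$coeffs[, , j] *
        exp(-2i * pi * tm2$freqs[fi] * j / 100)
    expect_lt(max(Mod(tm2$H[fi, , ] %*% Af - diag(5))), 1e-10)
  }
  expect_error(transfer_matrix(fit, freqs = c(0, 10)), "freqs")
  expect_error(transfer_matrix(fit, freqs = 60), "freqs")
})

test_that("DTF rows are normalized and localize a one-way coupling", {
  sys <- generate_mvar_system(2, 1, 0, seed = 1)
  sys$coeffs[] <- 0
  sys$coeffs[1, 1, 1] <- 0.4; sys$coeffs[2, 2, 1] <- 0.4
  sys$coeffs[2, 1, 1] <- 0.6                     # only 1 -> 2
  d <- dtf(transfer_matrix(sys))
  sums <- apply(d, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  expect_true(all(d[, 2, 1] > 0))                # influence 1 -> 2 present
  expect_lt(max(d[, 1, 2]), 1e-20)               # no influence 2 -> 1
  # closed-form check at one frequency: H = A(f)^-1 for the 2x2 system
  f <- 10; w <- 2 * pi * f / 100
  A <- diag(2) - sys$coeffs[, , 1] * exp(-1i * w)
  H <- solve(A)
  expect_equal(d[f, 2, 1], Mod(H[2, 1])^2 / (Mod(H[2, 1])^2 + Mod(H[2, 2])^2),
               tolerance = 1e-12)

  # diagonal model: all inflow is self-directed (identity pattern)
  dd <- dtf(transfer_matrix(structure(
    list(order = 1, coeffs = array(diag(0.5, 3), c(3, 3, 1)), fs = 100),
    class = "mvar_fit")))
  for (fi in seq_len(dim(dd)[1]))
    expect_equal(dd[fi, , ], diag(3), tolerance = 1e-12)
})

test_that("band aggregation averages the in-band grid points", {
  sys <- generate_mvar_system(3, 2, 0.3, seed = 19)
  d <- dtf(transfer_matrix(sys))
  agg <- band_aggregate(d, "alpha")
  manual <- matrix(0, 3, 3)
  for (f in 8:12) manual <- manual + d[f, , ]
  manual <- manual / 5
  diag(manual) <- 0
  expect_equal(agg$weights, manual, tolerance = 1e-12)
  expect_true(all(agg$weights >= 0 & agg$weights <= 1))
  # constant spectrum aggregates to that constant
  dc <- d
  for (f in seq_len(dim(d)[1])) dc[f, , ] <- d[1, , ]
  aggc <- band_aggregate(dc, "beta")
  ref <- d[1, , ]; diag(ref) <- 0
  expect_equal(aggc$weights, ref, tolerance = 1e-12)
  expect_error(band_aggregate(d, c(60, 70)), "no point")
  expect_error(band_aggregate(d, "gamma"), "unknown band")
})

test_that("DTF is invariant to common channel rescaling and monotone in coupling", {
  sys <- generate_mvar_system(2, 1, 0, seed = 1)
  sys$coeffs[] <- 0
  diag(sys$coeffs[, , 1]) <- 0.3
  weights_at <- function(c12) {
    s <- sys
    s$coeffs[2, 1, 1] <- c12
    x <- simulate_sources(s, 3000, seed = 7)
    dtf_network(x, order = 2, band = "alpha")$weights[2, 1]
  }
  w <- vapply(c(0.1, 0.3, 0.5, 0.7), weights_at, numeric(1))
  expect_true(all(diff(w) > 0))
  # common scaling leaves DTF unchanged
  s <- sys; s$coeffs[2, 1, 1] <- 0.5
  x <- simulate_sources(s, 2000, seed = 8)
  n1 <- dtf_network(x, order = 2, band = "alpha")
  xs <- x * 37.5; attr(xs, "fs") <- 100
  n2 <- dtf_network(xs, order = 2, band = "alpha")
  expect_equal(n1$weights, n2$weights, tolerance = 1e-10)
})

test_that("surrogate thresholding is seeded, guarded, and detects strong coupling", {
  sys <- generate_mvar_system(2, 1, 0, seed = 1)
  sys$coeffs[] <- 0
  diag(sys$coeffs[, , 1]) <- 0.3
  sys$coeffs[2, 1, 1] <- 0.9
  while (companion_spectral_radius(sys$coeffs) >= 0.95)
    sys$coeffs <- sys$coeffs * 0.95
  x <- simulate_sources(sys, 2000, n_trials = 5, seed = 5)
  net <- suppressWarnings(
    surrogate_threshold(x, order = 4, band = "alpha", n_surrogates = 100,
                        alpha_level = 0.05, seed = 6))
  expect_true(net$sig_mask[2, 1])
  expect_true(all(net$weights[!net$sig_mask] == 0))
  net2 <- suppressWarnings(
    surrogate_threshold(x, order = 4, band = "alpha", n_surrogates = 100,
                        alpha_level = 0.05, seed = 6))
  expect_identical(net$sig_mask, net2$sig_mask)
  # constant channel is refused by name
  xc <- x; xc[, 2, ] <- 1
  expect_error(surrogate_threshold(xc, order = 4, band = "alpha",
                                   n_surrogates = 50, seed = 1), "zero-variance")
})

test_that("phase randomization preserves the amplitude spectrum", {
  set.seed(23)
  x <- rnorm(512) + sin(2 * pi * 0.1 * seq_len(512))
  y <- dtfnet:::phase_randomize(x)
  expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(x, y)))
})

test_that("model order report profiles candidate orders without choosing", {
  sys <- generate_mvar_system(3, 2, 0.2, seed = 3)
  x <- simulate_sources(sys, 600, seed = 4)
  rep_ <- model_order_report(x, orders = 1:4, tau_s = 0.1, fs = 100)
  expect_equal(nrow(rep_), 4)
  expect_true(all(rep_$within_lag_bound))       # all orders below tau * fs = 10
  expect_true(all(diff(rep_$loglik) > -1e-6))    # loglik non-decreasing in p
})
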