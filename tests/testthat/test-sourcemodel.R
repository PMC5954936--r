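make_lf <- function(m = 8, n = 20, seed = 4) {
  set.seed(seed)
  lead_field(matrix(rnorm(m * n), m, n), sprintf("s%02d", seq_len(m)),
             rep(sprintf("r%d", seq_len(4)), each = n / 4))
}

test_that("minimum-norm inversion matches identity and shrinkage limits", {
  lfI <- lead_field(diag(6), sprintf("s%d", 1:6), sprintf("r%d", 1:6))
  m <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(mne_solve(lfI, m, 0)$dipole_series, m, tolerance = 1e-12)
  # enormous lambda shrinks the solution to (numerically) nothing
  big <- 1e12 * sum(diag(crossprod(lfI$matrix)))
  expect_lt(mne_solve(lfI, m, big)$solution_norm, 1e-6 * sqrt(sum(m^2)))
  # rank-deficient L with lambda = 0 is refused
  lfr <- lead_field(matrix(c(1, 1, 2, 2), 2, 2), c("a", "b"), c("r1", "r2"))
  expect_error(mne_solve(lfr, matrix(1, 2, 1), 0), "rank-deficient")
  expect_error(mne_solve(make_lf(), matrix(1, 8, 1), -1), "lambda")
})

test_that("the Tikhonov solution matches the normal-equations oracle", {
  lf <- make_lf()
  set.seed(9)
  m <- matrix(rnorm(8 * 5), 8, 5)
  for (lambda in c(0.01, 1, 50)) {
    est <- mne_solve(lf, m, lambda)
    # independent route: regularized normal equations on the dual form
    L <- lf$matrix
    oracle <- t(L) %*% solve(L %*% t(L) + lambda * diag(8), m)
    expect_equal(est$dipole_series, oracle, tolerance = 1e-8)
  }
})

test_that("residual and solution norms are monotone in lambda", {
  lf <- make_lf(seed = 10)
  set.seed(2)
  m <- matrix(rnorm(8 * 3), 8, 3)
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 25))
  fits <- lapply(grid, function(l) mne_solve(lf, m, l))
  rho <- sapply(fits, `[[`, "residual_norm")
  eta <- sapply(fits, `[[`, "solution_norm")
  expect_true(all(diff(rho) >= -1e-9))
  expect_true(all(diff(eta) <= 1e-9))
  # optimality: J(d*) never exceeds J(0) = ||m||^2
  for (i in seq_along(grid))
    expect_lte(fits[[i]]$residual_norm^2 + grid[i] * fits[[i]]$solution_norm^2,
               sum(m^2) * (1 + 1e-10))
})

test_that("mne_solve is linear in the measurements for fixed lambda", {
  lf <- make_lf(seed = 12)
  set.seed(3)
  m1 <- matrix(rnorm(8 * 4), 8, 4)
  m2 <- matrix(rnorm(8 * 4), 8, 4)
  d1 <- mne_solve(lf, m1, 0.5)$dipole_series
  d2 <- mne_solve(lf, m2, 0.5)$dipole_series
  d12 <- mne_solve(lf, 3 * m1 - 2 * m2, 0.5)$dipole_series
  expect_equal(d12, 3 * d1 - 2 * d2, tolerance = 1e-9)
})

test_that("L-curve selection lands near the oracle-optimal lambda", {
  lf <- generate_lead_field(32, 96, roi_model = rep(sprintf("r%d", 1:12), each = 8),
                            smoothness = 0.9, seed = 21)
  sys <- generate_mvar_system(12, 4, 0.2, seed = 5)
  src <- simulate_sources(sys, 200, seed = 6)
  scalp <- project_to_scalp(src, lf, snr_db = 10, seed = 7)
  epoch <- matrix(scalp$data[1, , ], 32, 200)
  grid <- lambda_grid(lf, 30)
  lam <- select_lambda_lcurve(lf, epoch, grid)
  # oracle sweep: lambda minimizing the true dipole-domain reconstruction err
  clean <- project_to_scalp(src, lf, snr_db = Inf, seed = 7)
  err <- vapply(grid, function(l) {
    est <- mne_solve(lf, epoch, l)
    sqrt(mean((lf$matrix %*% est$dipole_series - clean$data[1, , ])^2))
  }, numeric(1))
  i_sel <- which.min(abs(grid - as.numeric(lam)))
  i_opt <- which.min(err)
  expect_lte(abs(log(grid[i_sel]) - log(grid[i_opt])),
             3 * diff(log(grid[1:2])))
  # endpoints are never selected
  expect_false(i_sel %in% c(1L, length(grid)))
  # diagnostic curve: residual norm non-decreasing
  curve <- attr(lam, "curve")
  expect_true(all(diff(curve$residual_norm) >= -1e-9))
})

test_that("noiseless data drive the L-curve corner to small lambda", {
  lf <- make_lf(m = 8, n = 20, seed = 30)
  set.seed(31)
  d_true <- matrix(rnorm(20 * 40), 20, 40)
  m <- lf$matrix %*% d_true
  grid <- exp(seq(log(1e-8), log(1e2), length.out = 15))
  lam <- suppressWarnings(select_lambda_lcurve(lf, m, grid))
  expect_lte(which.min(abs(grid - as.numeric(lam))), 4L)
  # degenerate curve falls back to the median grid value with a warning
  expect_warning(l0 <- select_lambda_lcurve(lf, matrix(0, 8, 3), grid),
                 "degenerate")
  expect_equal(as.numeric(l0), grid[8])
  expect_error(select_lambda_lcurve(lf, m, grid[1:5]), ">= 10")
})

test_that("ROI extraction averages member dipoles with sign", {
  lf <- make_lf(m = 8, n = 20, seed = 14)          # 4 ROIs x 5 dipoles
  s <- sin(seq_len(30))
  d <- matrix(0, 20, 30)
  # all dipoles of ROI r1 share s(t): ROI row equals s(t)
  d[1:5, ] <- matrix(s, 5, 30, byrow = TRUE)
  est <- structure(list(dipole_series = d, lambda = 0.1,
                        residual_norm = 0, solution_norm = 0),
                   class = "source_estimate")
  roi <- extract_roi_series(est, lf)
  expect_equal(unname(roi$series["r1", ]), s, tolerance = 1e-12)
  # cancellation: two dipoles with s and -s average to zero
  d2 <- matrix(0, 20, 30)
  d2[6, ] <- s; d2[7, ] <- -s
  est2 <- est; est2$dipole_series <- d2
  roi2 <- extract_roi_series(est2, lf)
  expect_equal(unname(roi2$series["r2", ]), rep(0, 30), tolerance = 1e-12)
  # single-dipole ROI is the identity
  lf1 <- lead_field(matrix(rnorm(4 * 3), 4, 3), sprintf("s%d", 1:4),
                    c("a", "b", "c"))
  est3 <- est; est3$dipole_series <- matrix(seq_len(9), 3, 3)
  roi3 <- extract_roi_series(est3, lf1)
  expect_equal(unname(roi3$series["b", ]), c(2, 5, 8))
})

test_that("end-to-end ROI recovery is accurate at favourable SNR", {
  lf <- generate_lead_field(64, 240, 24, smoothness = 0.9, seed = 5)
  sys <- generate_mvar_system(24, 8, 0.2, seed = 11)
  src <- simulate_sources(sys, 300, seed = 3)
  scalp <- project_to_scalp(src, lf, snr_db = 20, seed = 9)
  epoch <- matrix(scalp$data[1, , ], 64, 300)
  lam <- select_lambda_lcurve(lf, epoch, lambda_grid(lf, 25))
  roi <- extract_roi_series(mne_solve(lf, epoch, as.numeric(lam)), lf)
  cors <- vapply(1:24, function(i) cor(roi$series[i, ], src[1, i, ]), numeric(1))
  expect_gt(median(cors), 0.9)
})
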