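test_that("MVAR system generation honours density, stability, and seeding", {
  # zero density: no off-diagonal causal edges
  s0 <- generate_mvar_system(5, 3, 0, seed = 1)
  expect_false(any(s0$causal_mask))

  # planted density approximately met, system stable with margin
  s <- generate_mvar_system(24, 8, 0.3, seed = 7)
  expect_equal(sum(s$causal_mask), round(0.3 * 24 * 23))
  expect_lt(companion_spectral_radius(s$coeffs), 0.95)

  # bit-identical regeneration under the same seed
  a <- generate_mvar_system(3, 2, 0.5, seed = 3)
  b <- generate_mvar_system(3, 2, 0.5, seed = 3)
  expect_identical(a$coeffs, b$coeffs)
  c2 <- generate_mvar_system(3, 2, 0.5, seed = 4)
  expect_false(identical(a$coeffs, c2$coeffs))

  expect_error(generate_mvar_system(1, 2, 0.5, seed = 1), "n_nodes")
  expect_error(generate_mvar_system(4, 0, 0.5, seed = 1), "order")
  expect_error(generate_mvar_system(4, 2, 1.5, seed = 1), "edge_density")
})

runif_seeded <- function(seed) {
  set.seed(seed + 1000)
  runif(1, 0, 0.6)
}

test_that("every generated system across seeds satisfies the stability margin", {
  for (seed in 1:20) {
    s <- generate_mvar_system(8, 4, runif_seeded(seed), seed = seed)
    expect_lt(companion_spectral_radius(s$coeffs), 0.95)
  }
})

test_that("simulated sources match white-noise and cross-covariance oracles", {
  # zero coefficients + identity innovation covariance: unit variance
  sys <- generate_mvar_system(4, 1, 0, seed = 1)
  sys$coeffs[] <- 0
  x <- simulate_sources(sys, 20000, seed = 3)
  v <- vapply(1:4, function(i) var(x[1, i, ]), numeric(1))
  # SE of the sample variance of N(0,1) at n = 20000 is sqrt(2/n) ~ 0.01
  expect_true(all(abs(v - 1) < 3 * sqrt(2 / 20000) * 3))

  # single coupling 1 -> 2 at lag 1 with coefficient 0.9:
  # cov(x1_t, x2_{t+1}) = 0.9 * var(x1) = 0.9 exactly in the model
  sys2 <- generate_mvar_system(2, 1, 0, seed = 1)
  sys2$coeffs[] <- 0
  sys2$coeffs[2, 1, 1] <- 0.9
  x2 <- simulate_sources(sys2, 10000, seed = 5)
  n <- dim(x2)[3]
  cc <- cor(x2[1, 1, 1:(n - 1)], x2[1, 2, 2:n])
  # analytic correlation = 0.9 / sqrt(1 * (1 + 0.81)) ~ 0.669
  expect_gt(cc, 0.6)
  expect_lt(abs(cc - 0.9 / sqrt(1.81)), 0.05)

  # determinism
  expect_identical(simulate_sources(sys2, 500, 2, seed = 9),
                   simulate_sources(sys2, 500, 2, seed = 9))

  # unstable systems are refused
  bad <- sys2
  bad$coeffs[1, 1, 1] <- 1.05
  expect_error(simulate_sources(bad, 500, seed = 1), "unstable")
})

test_that("a resonant AR(2) channel peaks at the analytic resonance frequency", {
  fs <- 100; f0 <- 10; r <- 0.8
  sys <- generate_mvar_system(2, 2, 0, seed = 2, fs = fs, osc_freq = f0,
                              osc_damp = r)
  x <- simulate_sources(sys, 2^14, seed = 11)
  spec <- stats::spec.pgram(stats::ts(x[1, 1, ], frequency = fs), plot = FALSE,
                            spans = 11)
  peak_f <- spec$freq[which.max(spec$spec)]
  # analytic AR(2) spectral peak: cos w = (1 + r^2) / (2 r) * cos(2 pi f0 / fs)
  w <- acos(min(1, (1 + r^2) / (2 * r) * cos(2 * pi * f0 / fs)))
  f_analytic <- w * fs / (2 * pi)
  expect_lt(abs(peak_f - f_analytic), 1)
})

test_that("lead-field generation yields full-rank ROI-structured matrices", {
  lf0 <- generate_lead_field(8, 8, roi_model = sprintf("r%d", 1:8),
                             smoothness = 0, seed = 2)
  expect_equal(qr(lf0$matrix)$rank, 8)

  lf <- generate_lead_field(64, 240, 24, smoothness = 0.9, seed = 5)
  expect_equal(unname(table(lf$dipole_roi))[1], 10L)
  expect_equal(length(unique(lf$dipole_roi)), 24)
  expect_setequal(unique(lf$dipole_roi), roi_labels())
  # within-ROI columns are correlated, across-ROI columns are not
  same <- cor(lf$matrix[, 1], lf$matrix[, 2])
  expect_gt(same, 0.5)

  expect_identical(generate_lead_field(16, 48, 24, seed = 5)$matrix,
                   generate_lead_field(16, 48, 24, seed = 5)$matrix)
  expect_error(generate_lead_field(50, 20, 4, seed = 1), "full row rank")
  expect_error(generate_lead_field(8, 50, 24, seed = 1), "divisible")
})

test_that("scalp projection respects the forward model and SNR definition", {
  lf <- generate_lead_field(8, 24, roi_model = rep(sprintf("r%d", 1:6), each = 4),
                            smoothness = 0.5, seed = 3)
  set.seed(4)
  d <- array(rnorm(2 * 24 * 100), c(2, 24, 100))      # dipole-level sources

  # noiseless projection is exactly L d
  m <- project_to_scalp(d, lf, snr_db = Inf)
  expect_equal(m$data[1, , ], lf$matrix %*% d[1, , ], tolerance = 1e-12)

  # snr 0 dB: signal and noise power agree within 5%
  m0 <- project_to_scalp(d, lf, snr_db = 0, seed = 8)
  noise <- m0$data - m$data
  expect_lt(abs(mean(noise^2) / mean(m$data^2) - 1), 0.05)

  # single active dipole: sensor pattern proportional to that column
  d1 <- array(0, c(1, 24, 50))
  d1[1, 7, ] <- sin(seq_len(50))
  m1 <- project_to_scalp(d1, lf, snr_db = Inf)
  expect_equal(m1$data[1, , 10], lf$matrix[, 7] * d1[1, 7, 10], tolerance = 1e-12)

  expect_error(project_to_scalp(array(0, c(1, 5, 10)), lf), "matches neither")
})

test_that("ROI-level sources are expanded with bounded gain jitter", {
  lf <- generate_lead_field(8, 12, roi_model = rep(c("a", "b", "c"), each = 4),
                            smoothness = 0.5, seed = 3)
  src <- array(rep(1, 3 * 20), c(1, 3, 20))
  m <- project_to_scalp(src, lf, snr_db = Inf, seed = 1)
  # sensor pattern deviates from the unit-gain projection by at most the
  # 5% jitter amplitude weighted by the absolute lead-field row mass
  target <- m$data[1, , 1]
  centre <- lf$matrix %*% rep(1, 12)
  envelope <- 0.05 * abs(lf$matrix) %*% rep(1, 12)
  expect_true(all(abs(target - centre) <= envelope + 1e-9))
})

test_that("schedules present every task the demanded number of times", {
  sch <- generate_schedule(34, 9, 5, 4, 3, seed = 6)
  expect_equal(nrow(sch), 306)
  expect_true(all(table(sch$task_id) == 9))
  expect_equal(sum(table(sch$task_id)), 34 * 9)
  # consecutive onsets within a part differ by video + rest = 9 s
  for (p in unique(sch$part))
    expect_true(all(diff(sch$onset_s[sch$part == p]) == 9))
  expect_identical(generate_schedule(10, 3, 5, 4, 2, seed = 1),
                   generate_schedule(10, 3, 5, 4, 2, seed = 1))
  expect_false(identical(generate_schedule(10, 3, 5, 4, 2, seed = 1)$task_id,
                         generate_schedule(10, 3, 5, 4, 2, seed = 2)$task_id))
})

test_that("the task taxonomy reproduces the published classification", {
  expect_setequal(categorize_task("Shoulder", "Arm up", "left"),
                  c("Hands", "Left", "Proximal", "Linear"))
  expect_setequal(categorize_task("Wrist", "Internal rotation", "right"),
                  c("Hands", "Right", "Distal", "Rotational"))
  expect_setequal(categorize_task("Forearm", "External rotation", "left"),
                  c("Hands", "Left", "Proximal", "Rotational"))
  expect_identical(categorize_task("Walking"), "Walking")
  expect_error(categorize_task("Knee", "Up", "left"), "unknown task")

  tab <- task_table()
  expect_equal(nrow(tab), 33)                  # 32 arm tasks + walking
  arm <- tab[tab$joint != "Walking", ]
  expect_equal(sum(arm$motion == "Rotational"), 8)
  expect_equal(sum(arm$motion == "Linear"), 24)
  expect_equal(sum(arm$proximity == "Proximal"), 16)
  expect_equal(sum(arm$proximity == "Distal"), 16)
  expect_equal(sum(arm$side == "left"), 16)
})

test_that("cohorts plant group effects while preserving stability and seeding", {
  base <- generate_mvar_system(6, 3, 0.2, seed = 2)
  planted <- data.frame(source = 3, target = 5, effect = 0.4)
  coh <- suppressWarnings(
    generate_cohort(base, 4, planted, within_noise_sd = 0.02, seed = 9))
  # group B subjects carry the shifted coefficient, group A do not
  shift_b <- vapply(coh$systems$B, function(s) s$coeffs[5, 3, 1], numeric(1))
  shift_a <- vapply(coh$systems$A, function(s) s$coeffs[5, 3, 1], numeric(1))
  expect_true(all(shift_b > shift_a + 0.2))
  for (s in c(coh$systems$A, coh$systems$B))
    expect_lt(companion_spectral_radius(s$coeffs), 0.95)
  # bit-identical regeneration
  coh2 <- suppressWarnings(
    generate_cohort(base, 4, planted, within_noise_sd = 0.02, seed = 9))
  expect_identical(lapply(coh$systems$B, `[[`, "coeffs"),
                   lapply(coh2$systems$B, `[[`, "coeffs"))
  # null cohort: groups are exchangeable draws from one distribution
  nullc <- suppressWarnings(
    generate_cohort(base, 3, NULL, within_noise_sd = 0.05, seed = 4))
  all_c <- c(lapply(nullc$systems$A, `[[`, "coeffs"),
             lapply(nullc$systems$B, `[[`, "coeffs"))
  expect_equal(length(unique(lapply(all_c, function(x) round(x, 10)))), 6)

  expect_error(generate_cohort(base, 2, data.frame(source = 9, target = 1,
                                                   effect = 1), seed = 1),
               "outside")
})

test_that("the benchmark system has the documented causal support", {
  sys <- benchmark_system()
  expect_lt(companion_spectral_radius(sys$coeffs), 0.95)
  expect_equal(sum(sys$causal_mask), 5)
  expect_true(all(sys$causal_mask[cbind(c(2, 3, 4, 5, 2), c(1, 2, 3, 4, 3))]))
  r <- reachability(sys$causal_mask)
  expect_equal(sum(r), 11)
  expect_false(r[1, 2])                        # nothing flows back to node 1
})
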