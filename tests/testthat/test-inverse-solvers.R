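test_that("covariance estimation matches brute-force outer-product sums", {
  # two 2-channel trials with hand-sized samples
  tr <- array(0, dim = c(2, 3, 2))
  tr[, , 1] <- rbind(c(1, 2, 3), c(0, -1, 1))
  tr[, , 2] <- rbind(c(2, 0, 1), c(1, 1, -1))
  ds <- beamspike:::new_spike_dataset(tr, 600, 2, "EEG", c("a", "b"))
  Cavg <- estimate_covariance(ds, "average_based")
  Cevt <- estimate_covariance(ds, "event_related")
  D_avg <- (tr[, , 1] + tr[, , 2])/2
  expect_equal(Cavg$C, D_avg %*% t(D_avg)/3, tolerance = 1e-14)
  expect_equal(Cevt$C,
               (tr[, , 1] %*% t(tr[, , 1]) + tr[, , 2] %*% t(tr[, , 2]))/(2*3),
               tolerance = 1e-14)
  # one trial: both modes coincide
  ds1 <- beamspike:::new_spike_dataset(tr[, , 1, drop = FALSE], 600, 2, "EEG",
                                       c("a", "b"))
  expect_equal(estimate_covariance(ds1, "average_based")$C,
               estimate_covariance(ds1, "event_related")$C, tolerance = 1e-14)
  # all-zero data gives the zero matrix
  ds0 <- ds; ds0$trials[] <- 0
  expect_equal(estimate_covariance(ds0, "event_related")$C, matrix(0, 2, 2))
  expect_error(estimate_covariance(ds, window = c(5, 6)), "window")
})

test_that("diagonal loading scales the trace by exactly (1 + alpha)", {
  C1 <- beamspike:::new_covariance(diag(4), "average_based", 10)
  expect_equal(regularize_covariance(C1, 0.05)$C, 1.05*diag(4))
  C2 <- beamspike:::new_covariance(diag(c(3, 1)), "average_based", 10)
  expect_equal(regularize_covariance(C2, 0.1)$C, diag(c(3.2, 1.2)))
  expect_equal(regularize_covariance(C2, 0)$C, C2$C)
  expect_error(regularize_covariance(C2, -0.1), "alpha")
  # exact trace identity across the full 101-point sweep grid
  set.seed(81)
  C <- beamspike:::new_covariance(rand_spd(12), "average_based", 50)
  for (a in seq(0, 0.2, by = 0.002))
    expect_equal(sum(diag(regularize_covariance(C, a)$C)),
                 (1 + a)*sum(diag(C$C)), tolerance = 1e-12)
})

test_that("optimal orientation maximizes output power (grid-search oracle)", {
  set.seed(91)
  for (i in 1:20) {
    S <- 8
    L <- matrix(rnorm(S*3), S)
    C <- beamspike:::new_covariance(rand_spd(S), "average_based", 50, alpha = 0.05)
    phi <- optimal_orientation(L, C)
    ip <- beamspike:::cov_inv_powers(C)
    A <- crossprod(L, ip$C2 %*% L); B <- crossprod(L, ip$C1 %*% L)
    phi_or <- oracle_orientation_grid(A, B)
    expect_lt(angle_deg(phi, phi_or), 1)
  }
  # invariant under leadfield scaling
  set.seed(92)
  L <- matrix(rnorm(24), 8)
  C <- beamspike:::new_covariance(rand_spd(8), "average_based", 50, alpha = 0.05)
  expect_equal(optimal_orientation(L, C), optimal_orientation(10*L, C),
               tolerance = 1e-9)
  # degenerate C = c I: falls back to the dominant right-singular vector
  Ci <- beamspike:::new_covariance(2*diag(8), "average_based", 50, alpha = 0.05)
  expect_equal(optimal_orientation(L, Ci), beamspike:::fix_sign(svd(L)$v[, 1]),
               tolerance = 1e-9)
})

test_that("beamformer filters satisfy their variant-specific identities", {
  set.seed(101)
  S <- 10
  L <- matrix(rnorm(S*3), S)
  C <- beamspike:::new_covariance(rand_spd(S), "average_based", 50, alpha = 0.05)
  fu <- beamformer_filter(L, C, "unit_norm")
  expect_equal(sqrt(sum(fu$W^2)), 1, tolerance = 1e-10)
  expect_gt(sum(fu$W*fu$Lphi), 0)
  # C = I: matched-filter limit, W parallel to L phi
  Ci <- beamspike:::new_covariance(diag(S), "average_based", 50, alpha = 0)
  fi <- beamformer_filter(L, Ci, "unit_norm")
  expect_lt(angle_deg(fi$W, fi$Lphi), 1e-6)
  # as_printed is parallel to unit_norm, shorter by ||C^-1 L_phi||
  fp <- beamformer_filter(L, C, "as_printed", phi = fu$phi)
  expect_lt(angle_deg(fp$W, fu$W), 1e-8)
  ip <- beamspike:::cov_inv_powers(C)
  scale <- sqrt(sum(fu$Lphi*as.vector(ip$C2 %*% fu$Lphi)))
  expect_equal(fp$W*scale, fu$W, tolerance = 1e-10)
})

test_that("beamformer power maps recover noiseless on-grid sources", {
  ev <- fx_noiseless_evoked(fx_eeg_lf)
  ds <- simulate_spike_trials(fx_eeg_lf, fx_true$index, fx_true$ori, 100,
                              make_spike_waveform(srate = 600), n_trials = 1,
                              snr = Inf, seed = 1, amp_jitter_sd = 0,
                              latency_jitter_ms = 0)
  cov0 <- estimate_covariance(ds)
  for (a in c(0.01, 0.05, 0.2)) {
    map <- beamformer_power_map(fx_eeg_lf, regularize_covariance(cov0, a),
                                ev$D_avg, analysis_index = ev$peak_index)
    expect_identical(map$argmax_index, fx_true$index)
    expect_true(all(map$values >= 0))
  }
  # zero data -> all-zero map; quadratic form is sign-invariant
  creg <- regularize_covariance(cov0, 0.05)
  z <- beamformer_power_map(fx_eeg_lf, creg, 0*ev$D_avg,
                            analysis_index = ev$peak_index)
  expect_equal(max(abs(z$values)), 0)
  m1 <- beamformer_power_map(fx_eeg_lf, creg, ev$D_avg, ev$peak_index)
  m2 <- beamformer_power_map(fx_eeg_lf, creg, -ev$D_avg, ev$peak_index)
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
})

test_that("unregularized average covariance of a short window raises the rank error", {
  # T_w < S makes the average-based covariance rank-deficient: alpha = 0 must
  # fail loudly with guidance, not silently pseudo-invert
  w <- make_spike_waveform(srate = 600)
  ds <- simulate_spike_trials(fx_eeg_lf, fx_true$index, fx_true$ori, 100, w,
                              n_trials = 5, snr = 5, seed = 111)
  cov0 <- estimate_covariance(ds, "average_based", window = c(-0.02, 0.02))
  expect_error(
    beamformer_power_map(fx_eeg_lf, regularize_covariance(cov0, 0),
                         average_trials(ds)$D_avg, analysis_index = ds$peak_index),
    "regulariz")
  # with loading the same covariance works
  m <- beamformer_power_map(fx_eeg_lf, regularize_covariance(cov0, 0.05),
                            average_trials(ds)$D_avg,
                            analysis_index = ds$peak_index)
  expect_s3_class(m, "source_map")
})

test_that("dipole scan reports gof in [0, 1] with exact on-grid identities", {
  L_t <- leadfield_at(fx_eeg_lf, fx_true$index)
  d <- as.vector(L_t %*% c(30, -20, 50))
  map <- dipole_scan(fx_eeg_lf, d)
  expect_identical(map$argmax_index, fx_true$index)
  expect_equal(map$values[fx_true$index], 1, tolerance = 1e-12)
  expect_true(all(map$values >= 0 & map$values <= 1))
  # data orthogonal to the local column space scores gof 0 there
  set.seed(121)
  r <- rnorm(nrow(L_t))
  r_perp <- qr.resid(qr(L_t), r)
  map_p <- dipole_scan(fx_eeg_lf, r_perp)
  expect_lt(map_p$values[fx_true$index], 1e-12)
  expect_error(dipole_scan(fx_eeg_lf, 0*d), "zero data")
})

test_that("tSVD-reduced MEG scan equals the full 3-column scan", {
  L_t <- leadfield_at(fx_meg_lf, fx_true$index)
  tang <- tangentialize(c(0.8, -0.1, 0.3), fx_true$point)
  d <- as.vector(L_t %*% (60*tang))
  g3 <- dipole_scan(fx_meg_lf, d, meg_tsvd = FALSE)
  g2 <- dipole_scan(fx_meg_lf, d, meg_tsvd = TRUE)
  expect_lt(max(abs(g3$values - g2$values)), 1e-6)
  expect_identical(g2$argmax_index, fx_true$index)
})
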