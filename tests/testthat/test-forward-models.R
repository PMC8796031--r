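test_that("head model construction validates its geometry and conductivities", {
  h <- build_sphere_head(c(80, 85, 92), c(0.33, 0.01, 0.43), "3C-standard")
  expect_s3_class(h, "head_model")
  expect_identical(h$label, "3C-standard")
  expect_error(build_sphere_head(c(80, 85, 92), c(0.33, -0.01, 0.43)),
               "positive")
  expect_error(build_sphere_head(c(80, 92, 85), c(0.33, 0.01, 0.43)),
               "increasing")
  expect_error(build_sphere_head(c(80, 85), c(0.33, 0.01, 0.43)), "length")
  # degenerate single-shell model is allowed
  expect_s3_class(build_sphere_head(92, 0.33), "head_model")
})

test_that("sensor placement is deterministic, on-surface and modality-aware", {
  a <- place_sensors(fx_head, "EEG", 70)
  b <- place_sensors(fx_head, "EEG", 70)
  expect_identical(a, b)
  expect_equal(a$S, 70)
  # EEG electrodes sit exactly on the scalp shell
  expect_lt(max(abs(sqrt(rowSums(a$positions^2)) - 92)), 1e-6)
  # hemisphere coverage stays in the upper half
  expect_true(all(a$positions[, 3] > 0))
  expect_error(place_sensors(fx_head, "EEG", 70, offset_mm = 10), "scalp")
  expect_error(place_sensors(fx_head, "EEG", 2), "3 sensors")
  m <- place_sensors(fx_head, "MEG", 271, 20)
  expect_equal(sqrt(rowSums(m$positions^2)), rep(112, 271), tolerance = 1e-12)
  # radial unit orientations
  expect_equal(sqrt(rowSums(m$orientations^2)), rep(1, 271), tolerance = 1e-12)
  expect_equal(m$orientations, m$positions/112, tolerance = 1e-12)
})

test_that("source grid matches brute-force lattice enumeration and spacing", {
  g <- build_source_grid(fx_head, spacing = 10, margin = 10)
  # oracle: enumerate lattice points with |x| <= 70 by triple loop
  rmax <- 80 - 10
  cnt <- 0L
  for (x in seq(-70, 70, 10)) for (y in seq(-70, 70, 10)) for (z in seq(-70, 70, 10))
    if (x^2 + y^2 + z^2 <= rmax^2) cnt <- cnt + 1L
  expect_identical(nrow(g$points), cnt)
  expect_true(all(rowSums(g$points^2) <= rmax^2 + 1e-9))
  # median nearest-neighbour distance equals the nominal spacing
  dfull <- as.matrix(dist(g$points)); diag(dfull) <- Inf
  expect_equal(median(apply(dfull, 1L, min)), 10)
  expect_error(build_source_grid(fx_head, spacing = 100), "exceeds")
  tiny <- build_source_grid(fx_head, spacing = 40, margin = 2)
  expect_gt(nrow(tiny$points), 0)
})

test_that("equal-conductivity multilayer EEG solution equals the homogeneous closed form", {
  sig <- 0.33
  h_eq <- build_sphere_head(c(80, 85, 92), c(sig, sig, sig), "equal")
  pts <- beamspike:::as_source_points(rbind(c(20, -15, 45),
                                                      c(-30, 10, 20),
                                                      c(5, 60, 30)))
  lf <- eeg_sphere_leadfield(h_eq, fx_eeg_sens, pts, n_terms = 80)
  for (p in 1:3) for (k in 1:3) {
    m <- c(0, 0, 0); m[k] <- 1
    v_or <- oracle_eeg_homog(fx_eeg_sens$positions, pts$points[p, ], m, 92, sig)
    v_or <- 1000*(v_or - mean(v_or))            # uV scale + average reference
    v_pk <- leadfield_at(lf, p)[, k]
    expect_lt(max(abs(v_pk - v_or))/max(abs(v_or)), 1e-6)
  }
})

test_that("EEG leadfield respects reference, conductivity scaling and convergence", {
  # every column sums to zero under the average reference
  expect_lt(max(abs(colSums(fx_eeg_lf$gain)))/max(abs(fx_eeg_lf$gain)), 1e-12)
  # doubling all conductivities halves all potentials
  h2 <- build_sphere_head(fx_head$radii, 2*fx_head$conductivities)
  pts <- beamspike:::as_source_points(rbind(c(20, -15, 45)))
  a <- eeg_sphere_leadfield(fx_head, fx_eeg_sens, pts)
  b <- eeg_sphere_leadfield(h2, fx_eeg_sens, pts)
  expect_equal(b$gain, a$gain/2, tolerance = 1e-12)
  # series truncation: 60 vs 120 terms
  c120 <- eeg_sphere_leadfield(fx_head, fx_eeg_sens, pts, n_terms = 120)
  expect_lt(max(abs(a$gain - c120$gain))/max(abs(a$gain)), 1e-8)
  out <- beamspike:::as_source_points(rbind(c(0, 0, 85)))
  expect_error(eeg_sphere_leadfield(fx_head, fx_eeg_sens, out), "inside")
})

test_that("spherical MEG annihilates radial moments and ignores conductivity", {
  pt <- c(20, -15, 45)
  src <- beamspike:::as_source_points(rbind(pt))
  lf <- meg_sphere_leadfield(fx_meg_sens, src)
  g_rad <- as.vector(leadfield_at(lf, 1) %*% (pt/sqrt(sum(pt^2))))
  tang <- beamspike::tangentialize(c(1, 0, 0), pt)
  g_tan <- as.vector(leadfield_at(lf, 1) %*% tang)
  expect_lt(max(abs(g_rad)), 1e-12*max(abs(g_tan)))
  # bitwise identical whatever the conductivity profile says
  h_alt <- build_sphere_head(fx_head$radii, c(1, 2, 3))
  expect_identical(meg_sphere_leadfield(fx_meg_sens, src, head = h_alt)$gain,
                   lf$gain)
})

test_that("Sarvas field matches the primary-current radial identity and the reference gains", {
  pt <- c(20, -15, 45)
  src <- beamspike:::as_source_points(rbind(pt))
  lf <- meg_sphere_leadfield(fx_meg_sens, src)
  # radial sensors: full field projection equals the primary-current radial
  # component (volume currents are radially silent in a sphere)
  for (k in 1:3) {
    q <- c(0, 0, 0); q[k] <- 1
    prim <- apply(fx_meg_sens$positions, 1L, oracle_meg_radial_primary,
                  r0 = pt, q = q)*1e5   # mu0/4pi + unit conversion to fT/(nA*m)
    expect_equal(leadfield_at(lf, 1)[, k], prim, tolerance = 1e-10)
  }
  # frozen reference gains (MNE-Python sphere model, T per A*m) for six point
  # magnetometers with mixed non-radial orientations and one dipole
  pos_m <- rbind(c(0.06, -0.04, 0.08), c(0, 0, 0.112), c(0.08, 0.02, 0.06),
                 c(-0.05, 0.05, 0.09), c(0.02, -0.09, 0.05), c(-0.07, -0.03, 0.07))
  ori_m <- rbind(c(0, 0, 1), c(1, 0, 0), c(0.6, 0.8, 0), c(0, 0.6, 0.8),
                 c(1/3, 2/3, 2/3), c(0, 1, 0))
  G_ref <- rbind(
    c(-4.316632928755e-06, -6.894450614245e-06, -3.796466808571e-07),
    c(-1.093224746077e-06,  2.598628892459e-06,  1.352087295743e-06),
    c( 2.236607453632e-06, -5.147523855195e-06, -2.709889042235e-06),
    c( 1.682059077607e-06,  3.045803105783e-06,  2.676858896579e-07),
    c( 1.756749494509e-06, -1.260479485471e-08, -7.849791514002e-07),
    c(-2.487941681884e-06, -1.718614268479e-06,  5.328804357889e-07))
  sens <- structure(list(positions = pos_m*1000, orientations = ori_m,
                         modality = "MEG", channel_names = paste0("M", 1:6),
                         S = 6L, radius = NA), class = "sensor_array")
  src2 <- beamspike:::as_source_points(rbind(c(20, -15, 45)))
  lf2 <- meg_sphere_leadfield(sens, src2)
  # package units fT per nA*m -> T per A*m: x 1e-15 * 1e9 = 1e-6
  expect_equal(leadfield_at(lf2, 1)*1e-6, G_ref, tolerance = 1e-10)
})

test_that("leadfields are linear in the dipole moment", {
  q1 <- c(1, 2, -0.5); q2 <- c(-0.3, 0.4, 1)
  for (lf in list(fx_eeg_lf, fx_meg_lf)) {
    L <- leadfield_at(lf, 2)
    expect_equal(as.vector(L %*% (2*q1 + 3*q2)),
                 as.vector(2*(L %*% q1) + 3*(L %*% q2)), tolerance = 1e-12)
  }
})

test_that("tSVD reduction keeps the two strongest directions and drops the radial one", {
  # rank-2 input is reproduced exactly by the retained basis
  set.seed(4)
  L2 <- matrix(rnorm(20), 10)
  L <- cbind(L2, L2[, 1] + L2[, 2])           # rank 2, 3 columns
  red <- reduce_leadfield_tsvd(L)
  expect_lt(norm(red$gain %*% t(red$basis) - L, "F"), 1e-10)
  # spherical MEG: discarded singular vector within 1 degree of radial
  pt <- fx_true$point
  Lp <- leadfield_at(fx_meg_lf, fx_true$index)
  red2 <- reduce_leadfield_tsvd(Lp)
  expect_lt(angle_deg(red2$dropped, pt/sqrt(sum(pt^2))), 1)
  # deterministic under repetition
  expect_identical(reduce_leadfield_tsvd(Lp), red2)
  expect_error(reduce_leadfield_tsvd(matrix(0, 5, 3)), "zero")
})

test_that("sensor arrays round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sensor_array(fx_meg_sens, path)
  back <- read_sensor_array(path, "MEG")
  expect_equal(back$positions, fx_meg_sens$positions, tolerance = 1e-12)
  expect_equal(back$orientations, fx_meg_sens$orientations, tolerance = 1e-12)
  expect_identical(back$channel_names, fx_meg_sens$channel_names)
})
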