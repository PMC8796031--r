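# Shared fixtures (built once per test session) and independent oracles.

fx_head <- head_profile_3c()                         # 0.33 / 0.01 / 0.43 S/m
fx_eeg_sens <- place_sensors(fx_head, "EEG", 40)
fx_meg_sens <- place_sensors(fx_head, "MEG", 60, offset_mm = 20)
fx_sources <- build_source_grid(fx_head, spacing = 14, margin = 2)
fx_eeg_lf <- eeg_sphere_leadfield(fx_head, fx_eeg_sens, fx_sources)
fx_meg_lf <- suppressWarnings(meg_sphere_leadfield(fx_meg_sens, fx_sources))

# a superficial-ish on-grid source with an oblique (partly radial) moment
fx_true <- local({
  p <- which.min(rowSums(sweep(fx_sources$points, 2L, c(14, -21, 42))^2))
  pt <- fx_sources$points[p, ]
  tang <- beamspike::tangentialize(c(1, 0.4, -0.2), pt)
  ori <- tang + 0.5*pt/sqrt(sum(pt^2))
  list(index = p, ori = ori/sqrt(sum(ori^2)), point = pt)
})

# ---- independent oracles ---------------------------------------------------

# surface potential of a dipole in a homogeneous sphere: closed form obtained
# from the Neumann monopole Green's function of the sphere by analytic
# differentiation with respect to the source position (independent of the
# package's spherical-harmonic series)
oracle_eeg_homog <- function(pos, r0, m, R, sigma) {
  apply(pos, 1L, function(r) {
    d <- r - r0; dn <- sqrt(sum(d^2))
    Fv <- R - sum(r*r0)/R + dn
    (2*sum(m*d)/dn^3 + (sum(m*r)/R + sum(m*d)/dn)/(R*Fv))/(4*pi*sigma)
  })
}

# radial magnetic field of the dipole's primary current alone (Biot-Savart
# of the current element); volume currents in a spherically symmetric
# conductor contribute no radial field, so this equals the full solution's
# radial component
oracle_meg_radial_primary <- function(rs, r0, q) {
  d <- rs - r0
  qxd <- c(q[2]*d[3] - q[3]*d[2], q[3]*d[1] - q[1]*d[3], q[1]*d[2] - q[2]*d[1])
  sum(qxd*rs/sqrt(sum(rs^2)))/sum(d^2)^1.5
}

# brute-force grid search of the beamformer output power over orientations
# (oracle for the generalized-eigenvalue solution): global 1-degree sweep
# followed by a 0.02-degree local refinement around the coarse winner, so the
# oracle's own resolution does not dominate the comparison
oracle_orientation_grid <- function(A, B, step_deg = 1) {
  ratio_argmax <- function(D) {
    num <- colSums(D*(B %*% D))
    den <- colSums(D*(A %*% D))
    D[, which.max(num/den)]
  }
  th <- seq(0, 180, by = step_deg)*pi/180
  ph <- seq(0, 359, by = step_deg)*pi/180
  g <- expand.grid(th = th, ph = ph)
  coarse <- ratio_argmax(rbind(sin(g$th)*cos(g$ph), sin(g$th)*sin(g$ph),
                               cos(g$th)))
  th0 <- acos(coarse[3]); ph0 <- atan2(coarse[2], coarse[1])
  dd <- seq(-3, 3, by = 0.04)*pi/180
  g2 <- expand.grid(th = th0 + dd, ph = ph0 + dd/max(sin(th0), 1e-3))
  ratio_argmax(rbind(sin(g2$th)*cos(g2$ph), sin(g2$th)*sin(g2$ph),
                     cos(g2$th)))
}

angle_deg <- function(a, b) {
  ca <- abs(sum(a*b))/sqrt(sum(a^2)*sum(b^2))
  acos(pmin(1, ca))*180/pi
}

# random SPD matrix
rand_spd <- function(S) {
  X <- matrix(rnorm(S*(S + 4L)), S)
  tcrossprod(X)/(S + 4L) + diag(0.1, S)
}

# quick noiseless spike evoked at the fixture truth source
fx_noiseless_evoked <- function(leadfield, srate = 600) {
  w <- make_spike_waveform(srate = srate)
  ds <- simulate_spike_trials(leadfield, fx_true$index, fx_true$ori, 100, w,
                              n_trials = 1, snr = Inf, seed = 1,
                              amp_jitter_sd = 0, latency_jitter_ms = 0)
  average_trials(ds)
}
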