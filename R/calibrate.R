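# SEP/SEF skull-conductivity calibration. The MEG localization of the
# somatosensory P20 component is conductivity-insensitive in a spherical
# conductor, so it anchors the dipole location; the EEG then determines the
# orientation per candidate skull conductivity, the MEG fixes the amplitude,
# and the skull conductivity minimizing the EEG residual variance wins.

#' Locate the P20 source from the SEF with a dipole scan
#'
#' tSVD-reduced MEG dipole scan at the P20 sample of the averaged SEF.
#'
#' @param sef_evoked MEG `evoked_data` of the somatosensory response.
#' @param meg_leadfield MEG `leadfield`.
#' @param p20_index Sample index of the P20 peak; if `NULL`, the sample of
#'   maximal global field power after the stimulus is used.
#' @return Source index (integer) with the gof map as attribute `map`.
#' @export
scan_location_meg <- function(sef_evoked, meg_leadfield, p20_index = NULL) {
  stopifnot(inherits(sef_evoked, "evoked_data"))
  if (is.null(p20_index)) {
    gfp <- sqrt(colMeans(sef_evoked$D_avg^2))
    post <- seq.int(sef_evoked$peak_index, ncol(sef_evoked$D_avg))
    p20_index <- post[which.max(gfp[post])]
  }
  d <- sef_evoked$D_avg[, p20_index]
  if (all(d == 0)) stop("flat SEF data at the P20 sample")
  map <- dipole_scan(meg_leadfield, d, meg_tsvd = TRUE)
  structure(map$argmax_index, map = map, p20_index = p20_index)
}

#' Fit the dipole orientation from the SEP at a fixed location
#'
#' Full three-component least-squares moment fit `m = L^+ D` with the
#' conductivity-specific EEG gain at the fixed location; the orientation is
#' `m / ||m||` (amplitude positive by construction).
#'
#' @param L_eeg S x 3 EEG gain at the fixed location (computed at the
#'   candidate skull conductivity).
#' @param d_eeg SEP data column at the P20 sample.
#' @return Unit orientation 3-vector; attribute `moment` carries the fitted
#'   moment in nA*m.
#' @export
fit_orientation_eeg <- function(L_eeg, d_eeg) {
  qrL <- qr(L_eeg)
  if (qrL$rank < ncol(L_eeg)) stop("rank-deficient local EEG leadfield")
  m <- qr.coef(qrL, d_eeg)
  if (vnorm(m) == 0) stop("zero fitted moment")
  structure(unitize(m), moment = m)
}

#' Fit the dipole amplitude from the SEF at fixed location and orientation
#'
#' Scalar least squares `a = argmin ||d - a L phi||`. A (quasi-)radial
#' orientation is magnetically silent and is rejected.
#'
#' @param L_meg S x 3 MEG gain at the fixed location.
#' @param phi Unit orientation 3-vector.
#' @param d_meg SEF data column at the P20 sample.
#' @return Amplitude in nA*m.
#' @export
fit_amplitude_meg <- function(L_meg, phi, d_meg) {
  Lphi <- as.vector(L_meg %*% phi)
  n2 <- sum(Lphi^2)
  if (n2 <= 1e-20*sum(L_meg^2))
    stop("orientation is magnetically silent (quasi-radial); ",
         "the MEG cannot determine its amplitude")
  sum(Lphi*d_meg)/n2
}

#' Residual variance of the SEP given a fully fixed dipole
#'
#' `rv = ||d - a L phi||^2 / ||d||^2`, clipped to [0, 1] only from below
#' (a misfit larger than the data norm is reported as is).
#'
#' @param L_eeg S x 3 EEG gain at the location (candidate conductivity).
#' @param phi Unit orientation.
#' @param amplitude Amplitude in nA*m.
#' @param d_eeg SEP data column.
#' @return Relative residual variance (>= 0).
#' @export
sep_rv <- function(L_eeg, phi, amplitude, d_eeg) {
  n2 <- sum(d_eeg^2)
  if (n2 == 0) stop("zero SEP data")
  sum((d_eeg - amplitude*as.vector(L_eeg %*% phi))^2)/n2
}

#' Calibrate the skull conductivity from a paired SEP/SEF dataset
#'
#' Four steps per candidate conductivity: (1) fix the location by a
#' tSVD-reduced MEG dipole scan (done once, since the spherical MEG forward
#' solution does not depend on conductivity), (2) fit the orientation from
#' the EEG with the conductivity-specific gain, (3) fit the amplitude from
#' the MEG, (4) store the EEG residual variance. The conductivity with the
#' lowest residual variance is the calibrated value.
#'
#' @param sep,sef EEG and MEG `spike_dataset`s from [simulate_sep_sef()]
#'   (or their `evoked_data` averages).
#' @param head Template `head_model` whose skull shell is swept.
#' @param eeg_sensors EEG `sensor_array` (for the per-conductivity gain at
#'   the fitted location).
#' @param meg_leadfield MEG `leadfield` over the scan source space.
#' @param sources The scan `source_space`.
#' @param sigma_grid Candidate skull conductivities in S/m. The default is
#'   10 log-spaced values in [0.0021, 0.033], bracketing the literature
#'   spread and containing the standard 0.01 S/m.
#' @param skull_shell Index of the skull shell in `head`.
#' @param p20_index P20 sample index; located from the SEF if `NULL`.
#' @param sc_ss_ratio Compacta:spongiosa conductivity ratio carried as
#'   metadata (a single spherical skull shell cannot separate the layers).
#' @param n_terms EEG series truncation order.
#' @return Object of class `calibration_result`: `sigma_grid`, `rv_curve`,
#'   `best_sigma`, `location_index`, per-sigma `orientations` (3 x n) and
#'   `amplitudes`, `sc_ss_ratio`.
#' @export
calibrate_skull_conductivity <- function(sep, sef, head, eeg_sensors,
                                         meg_leadfield, sources,
                                         sigma_grid = default_sigma_grid(),
                                         skull_shell = 2L, p20_index = NULL,
                                         sc_ss_ratio = 3.6, n_terms = 60L) {
  if (length(sigma_grid) < 1L || any(sigma_grid <= 0))
    stop("sigma_grid must be nonempty and positive")
  sep_ev <- if (inherits(sep, "spike_dataset")) average_trials(sep) else sep
  sef_ev <- if (inherits(sef, "spike_dataset")) average_trials(sef) else sef
  if (is.null(p20_index) && inherits(sep, "spike_dataset"))
    p20_index <- sep$truth$p20_index
  loc <- scan_location_meg(sef_ev, meg_leadfield, p20_index)
  p20_index <- attr(loc, "p20_index")
  d_eeg <- sep_ev$D_avg[, p20_index]
  d_meg <- sef_ev$D_avg[, p20_index]
  L_meg <- leadfield_at(meg_leadfield, as.integer(loc))
  pt <- as_source_points(sources$points[as.integer(loc), , drop = FALSE])
  n <- length(sigma_grid)
  rv <- numeric(n); amps <- numeric(n); oris <- matrix(0, 3L, n)
  for (i in seq_len(n)) {
    head_i <- with_skull_conductivity(head, sigma_grid[i], skull_shell)
    L_eeg <- leadfield_at(
      eeg_sphere_leadfield(head_i, eeg_sensors, pt, n_terms), 1L)
    phi <- fit_orientation_eeg(L_eeg, d_eeg)
    a <- fit_amplitude_meg(L_meg, phi, d_meg)
    rv[i] <- sep_rv(L_eeg, phi, a, d_eeg)
    amps[i] <- a; oris[, i] <- phi
  }
  best <- which.min(rv)
  structure(
    list(sigma_grid = sigma_grid, rv_curve = rv,
         best_sigma = sigma_grid[best], best_index = best,
         location_index = as.integer(loc), p20_index = p20_index,
         orientations = oris, amplitudes = amps, sc_ss_ratio = sc_ss_ratio),
    class = "calibration_result")
}

#' Default skull-conductivity search grid
#'
#' @param n Number of grid values.
#' @param range Bracketing range in S/m.
#' @return Log-spaced conductivity grid.
#' @export
default_sigma_grid <- function(n = 10L, range = c(0.0021, 0.033)) {
  exp(seq(log(range[1L]), log(range[2L]), length.out = n))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> best sigma_skull = %.4g S/m (rv = %.3g) at source %d\n",
              x$best_sigma, x$rv_curve[x$best_index], x$location_index))
  invisible(x)
}

#' Export a calibration curve as delimited text
#'
#' Tab-separated columns: sigma, rv, loc_index, amplitude.
#'
#' @param calib A `calibration_result`.
#' @param path Output file.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_result"))
  df <- data.frame(sigma = calib$sigma_grid, rv = calib$rv_curve,
                   loc_index = calib$location_index,
                   amplitude = calib$amplitudes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
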