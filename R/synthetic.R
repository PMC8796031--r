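# Seeded generators for multi-trial spike and somatosensory-evoked datasets.
# A spike_dataset stores trials as an S x T x n_trials array with the spike
# peak at the epoch center (t = 0), plus ground-truth metadata so every
# downstream stage can be scored against the simulation truth.

new_spike_dataset <- function(trials, srate, peak_index, modality,
                              channel_names, truth = NULL) {
  structure(
    list(trials = trials, srate = srate, peak_index = peak_index,
         modality = modality, channel_names = channel_names,
         n_trials = dim(trials)[3L], truth = truth),
    class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<spike_dataset> %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$modality, d[3L], d[1L], d[2L], x$srate))
  invisible(x)
}

# epoch time axis: t = 0 at the center sample
epoch_times <- function(srate, t_pre = 0.5, t_post = 0.5) {
  n_pre <- round(srate*t_pre); n_post <- round(srate*t_post)
  (-n_pre:n_post)/srate
}

#' Interictal spike-wave template waveform
#'
#' Biphasic spike-and-wave morphology: a sharp component rising monotonically
#' over `rise_ms` to a peak of exactly 1.0 at t = 0, falling over `fall_ms`
#' into a slow wave of opposite polarity and relative amplitude `wave_amp`,
#' which decays back to zero over `wave_ms`. The waveform is identically zero
#' before the rise onset.
#'
#' @param srate Sampling rate in Hz.
#' @param rise_ms Rising-flank duration in ms.
#' @param fall_ms Falling-flank duration in ms.
#' @param wave_ms Slow-wave duration in ms.
#' @param wave_amp Slow-wave amplitude as a fraction of the spike peak.
#' @param shape `"cosine"` (smooth, default) or `"linear"` flanks.
#' @param t_pre,t_post Epoch half-lengths in seconds (default +-0.5 s).
#' @return Numeric vector of length `srate*(t_pre+t_post) + 1` with
#'   attributes `time` (s), `srate`, `peak_index`.
#' @export
make_spike_waveform <- function(srate = 2400, rise_ms = 20, fall_ms = 30,
                                wave_ms = 150, wave_amp = 0.3,
                                shape = c("cosine", "linear"),
                                t_pre = 0.5, t_post = 0.5) {
  shape <- match.arg(shape)
  stopifnot(rise_ms > 0, fall_ms > 0, wave_ms > 0, wave_amp >= 0)
  tt <- epoch_times(srate, t_pre, t_post)
  rise <- rise_ms/1000; fall <- fall_ms/1000; wave <- wave_ms/1000
  ramp <- function(u) if (shape == "linear") u else (1 - cos(pi*u))/2
  y <- numeric(length(tt))
  i <- tt >= -rise & tt <= 0
  y[i] <- ramp((tt[i] + rise)/rise)
  i <- tt > 0 & tt <= fall
  y[i] <- 1 - (1 + wave_amp)*ramp(tt[i]/fall)
  i <- tt > fall & tt <= fall + wave
  y[i] <- -wave_amp*(1 + cos(pi*(tt[i] - fall)/wave))/2
  structure(y, time = tt, srate = srate,
            peak_index = which(tt == 0))
}

# monophasic SEP/SEF component: gaussian bump peaking at `latency_ms`
make_sep_waveform <- function(srate = 1200, latency_ms = 20, width_ms = 4,
                              t_pre = 0.5, t_post = 0.5) {
  tt <- epoch_times(srate, t_pre, t_post)
  y <- exp(-(tt - latency_ms/1000)^2/(2*(width_ms/1000)^2))
  y[tt < 0] <- 0   # stimulus-locked: nothing before the stimulus
  structure(y, time = tt, srate = srate, peak_index = which(tt == 0),
            p20_index = which.min(abs(tt - latency_ms/1000)))
}

# unit-variance AR(1)-plus-white sensor noise, S x T
sim_noise <- function(S, T, ar_coef = 0.95, ar_frac = 0.8) {
  if (ar_frac > 0) {
    innov <- matrix(stats::rnorm(S*T), T, S)*sqrt(1 - ar_coef^2)
    # stationary start so the marginal variance is 1 from the first sample
    init <- stats::rnorm(S)
    ar <- apply(rbind(init, innov), 2L, function(x)
      stats::filter(x[-1L], ar_coef, method = "recursive", init = x[1L]))
    noise <- sqrt(ar_frac)*t(ar)
  } else noise <- matrix(0, S, T)
  if (ar_frac < 1)
    noise <- noise + sqrt(1 - ar_frac)*matrix(stats::rnorm(S*T), S, T)
  noise
}

#' Simulate multi-trial spike recordings from a single grid source
#'
#' Projects `amplitude * orientation * waveform` through the leadfield at
#' `source_index` and adds sensor noise scaled so that the single-trial
#' signal amplitude at the spike peak on the best channel, divided by the
#' per-channel noise standard deviation, equals `snr`. Optional trial-to-trial
#' lognormal amplitude jitter and uniform latency jitter differentiate the
#' average-based from the event-related covariance.
#'
#' @param leadfield A `leadfield`.
#' @param source_index True source index in the leadfield's source space.
#' @param orientation Unit 3-vector dipole orientation.
#' @param amplitude Dipole amplitude in nA*m (default 100).
#' @param waveform Source time course from [make_spike_waveform()] (peak 1 at
#'   t = 0).
#' @param n_trials Number of trials (study presets: 248 "patient-1-like",
#'   54 "patient-2-like").
#' @param noise_model `"ar1"` (AR(1) coefficient 0.95 plus white, default)
#'   or `"iid"`.
#' @param snr Single-trial amplitude SNR at the spike peak, best channel.
#'   `Inf` gives noiseless trials.
#' @param seed Integer seed; all randomness flows through it.
#' @param amp_jitter_sd Lognormal sdlog of per-trial amplitude jitter
#'   (0 disables; default 0.2).
#' @param latency_jitter_ms Half-range of uniform per-trial latency jitter in
#'   ms (0 disables; default 5).
#' @param ar_coef,ar_frac AR(1) coefficient and fraction of noise variance
#'   given to the AR component.
#' @return A `spike_dataset` with `truth` metadata (source index,
#'   orientation, amplitude, waveform, per-trial jitters, noise sd, seed).
#' @export
simulate_spike_trials <- function(leadfield, source_index, orientation,
                                  amplitude = 100,
                                  waveform = make_spike_waveform(),
                                  n_trials = 54, noise_model = c("ar1", "iid"),
                                  snr = 5, seed,
                                  amp_jitter_sd = 0.2, latency_jitter_ms = 5,
                                  ar_coef = 0.95, ar_frac = 0.8) {
  stopifnot(inherits(leadfield, "leadfield"))
  noise_model <- match.arg(noise_model)
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (snr <= 0) stop("snr must be positive")
  if (abs(vnorm(orientation) - 1) > 1e-8) stop("orientation must be unit-norm")
  if (source_index < 1L || source_index > leadfield$n_sources)
    stop("invalid source index")
  set.seed(as.integer(seed))
  srate <- attr(waveform, "srate")
  T <- length(waveform)
  topo <- as.vector(leadfield_at(leadfield, source_index) %*% (amplitude*orientation))
  S <- length(topo)
  noise_sd <- if (is.infinite(snr)) 0 else max(abs(topo))/snr
  if (noise_model == "iid") ar_frac <- 0
  amps <- if (amp_jitter_sd > 0)
    exp(stats::rnorm(n_trials, -amp_jitter_sd^2/2, amp_jitter_sd)) else rep(1, n_trials)
  shifts <- if (latency_jitter_ms > 0)
    round(stats::runif(n_trials, -latency_jitter_ms, latency_jitter_ms)/1000*srate)
  else rep(0L, n_trials)
  trials <- array(0, dim = c(S, T, n_trials))
  for (i in seq_len(n_trials)) {
    w <- shift_zeropad(as.numeric(waveform), shifts[i])
    sig <- outer(topo, amps[i]*w)
    if (noise_sd > 0) sig <- sig + noise_sd*sim_noise(S, T, ar_coef, ar_frac)
    trials[, , i] <- sig
  }
  new_spike_dataset(
    trials, srate, attr(waveform, "peak_index"), leadfield$modality,
    leadfield$channel_names %||% sprintf("ch%03d", seq_len(S)),
    truth = list(source_index = source_index, orientation = orientation,
                 amplitude = amplitude, waveform = waveform,
                 amp_jitter = amps, latency_shift = shifts,
                 noise_sd = noise_sd, snr = snr, seed = seed))
}

shift_zeropad <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(numeric(k), x[1:(n - k)]) else c(x[(1 - k):n], numeric(-k))
}

#' Simulate a paired SEP/SEF (EEG + MEG) calibration dataset
#'
#' A focal, tangentially oriented source with a component peaking exactly
#' 20 ms after the stimulus is projected through an EEG leadfield computed at
#' a known "true" skull conductivity and through the (conductivity-invariant)
#' spherical MEG leadfield. EEG and MEG trials share the source time course
#' but carry independent noise. Trials are stimulus-locked: no amplitude or
#' latency jitter.
#'
#' @param eeg_leadfield EEG `leadfield` computed at the true skull
#'   conductivity.
#' @param meg_leadfield MEG `leadfield` over the same source space.
#' @param source_index Index of the P20 source.
#' @param orientation Unit 3-vector orientation (should be tangential so the
#'   MEG sees the source; use [tangentialize()]).
#' @param amplitude Dipole amplitude in nA*m (default 20, a typical P20
#'   scale).
#' @param n_trials Trials per modality (the study protocol acquires 1200).
#' @param snr Single-trial amplitude SNR as in [simulate_spike_trials()].
#' @param seed Integer seed.
#' @param srate Sampling rate in Hz (acquisition protocol: 1200).
#' @param t_pre,t_post Epoch half-lengths in seconds.
#' @return List with `eeg` and `meg` `spike_dataset`s; `truth` carries the
#'   P20 sample index (`p20_index`).
#' @export
simulate_sep_sef <- function(eeg_leadfield, meg_leadfield, source_index,
                             orientation, amplitude = 20, n_trials = 600,
                             snr = 10, seed, srate = 1200,
                             t_pre = 0.5, t_post = 0.5) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  w <- make_sep_waveform(srate, t_pre = t_pre, t_post = t_post)
  eeg <- simulate_spike_trials(eeg_leadfield, source_index, orientation,
                               amplitude, w, n_trials, "ar1", snr,
                               seed = seed,
                               amp_jitter_sd = 0, latency_jitter_ms = 0)
  meg <- simulate_spike_trials(meg_leadfield, source_index, orientation,
                               amplitude, w, n_trials, "ar1", snr,
                               seed = seed + 1L,
                               amp_jitter_sd = 0, latency_jitter_ms = 0)
  p20 <- attr(w, "p20_index")
  eeg$truth$p20_index <- p20; meg$truth$p20_index <- p20
  list(eeg = eeg, meg = meg)
}

#' Project a vector onto the tangential plane at a source point
#'
#' @param v A 3-vector.
#' @param point Source position (mm, head-centered).
#' @return Unit tangential vector.
#' @export
tangentialize <- function(v, point) {
  rh <- unitize(point)
  unitize(v - sum(v*rh)*rh)
}

#' Define a resection volume as a ball of grid points
#'
#' All source-space points within `radius` mm of the center point. A ball of
#' radius ~6.9 mm matches the ~1.4 cm^3 thermocoagulated volume of the
#' patient-2-like scenario; ~12.4 mm matches the ~8 cm^3 resection of the
#' patient-1-like scenario.
#'
#' @param sources A `source_space`.
#' @param center_index Index of the center point.
#' @param radius Ball radius in mm.
#' @return An object of class `resection_volume` with `member_indices` and
#'   the defining rule.
#' @export
make_resection <- function(sources, center_index, radius) {
  stopifnot(inherits(sources, "source_space"))
  if (radius <= 0) stop("radius must be positive")
  if (center_index < 1L || center_index > nrow(sources$points))
    stop("invalid center index")
  ctr <- sources$points[center_index, ]
  d2 <- rowSums(sweep(sources$points, 2L, ctr)^2)
  members <- which(d2 <= radius^2)
  structure(
    list(member_indices = members,
         definition = list(center_index = center_index, radius = radius)),
    class = "resection_volume")
}

#' @export
print.resection_volume <- function(x, ...) {
  cat(sprintf("<resection_volume> %d points within %.1f mm of point %d\n",
              length(x$member_indices), x$definition$radius,
              x$definition$center_index))
  invisible(x)
}
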