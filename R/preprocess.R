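# Filtering, averaging, analysis-time-point selection, noise normalization
# and combined-MEEG stacking.

new_evoked <- function(D_avg, srate, peak_index, modality, channel_names,
                       n_trials = NA_integer_, analysis_index = NA_integer_,
                       baseline_window = c(-0.5, -0.3)) {
  structure(
    list(D_avg = D_avg, srate = srate, peak_index = peak_index,
         analysis_index = analysis_index, baseline_window = baseline_window,
         modality = modality, channel_names = channel_names,
         n_trials = n_trials),
    class = "evoked_data")
}

#' @export
print.evoked_data <- function(x, ...) {
  cat(sprintf("<evoked_data> %s: %d channels x %d samples @ %g Hz (n = %s trials)\n",
              x$modality, nrow(x$D_avg), ncol(x$D_avg), x$srate,
              format(x$n_trials)))
  invisible(x)
}

# evoked sample index of a time in seconds relative to the peak (t = 0)
time_to_index <- function(evoked, t) evoked$peak_index + round(t*evoked$srate)

# zero-phase Butterworth cascade: high-pass and low-pass are designed as
# cascades of second-order sections (analog prototype poles + bilinear
# transform per conjugate pair), which stays numerically stable at very low
# normalized corner frequencies where a single order-6 polynomial does not.
# Each section is run with signal::filtfilt, doubling the effective order.
butter_sos <- function(order, w, type = c("low", "high")) {
  type <- match.arg(type)
  wa <- tan(pi*w/2)                       # prewarped analog corner
  k <- seq_len(order)
  pk <- exp(1i*pi*(2*k + order - 1)/(2*order))   # prototype poles
  p <- if (type == "low") wa*pk else wa/pk
  zb <- (1 + p)/(1 - p)                   # bilinear-transformed poles
  zref <- if (type == "low") 1 + 0i else -1 + 0i  # unity-gain frequency
  zzero <- if (type == "low") -1 else 1
  secs <- list()
  used <- rep(FALSE, order)
  for (i in seq_len(order)) {
    if (used[i]) next
    j <- which(!used & abs(zb - Conj(zb[i])) < 1e-9 & seq_len(order) != i)[1L]
    if (!is.na(j)) {
      a <- c(1, -2*Re(zb[i]), abs(zb[i])^2)
      b <- c(1, -2*zzero, 1)
      used[c(i, j)] <- TRUE
    } else {                              # real pole (odd order)
      a <- c(1, -Re(zb[i]))
      b <- c(1, -zzero)
      used[i] <- TRUE
    }
    num <- sum(b*zref^-(seq_along(b) - 1))
    den <- sum(a*zref^-(seq_along(a) - 1))
    b <- b*Re(den/num)                    # unity gain at the reference
    secs[[length(secs) + 1L]] <- signal::Arma(b = b, a = a)
  }
  secs
}

# forward-backward filtering with odd-reflection padding to suppress the
# edge transients of plain filtfilt (essential for low high-pass corners)
zero_phase <- function(x, filts, npad = 0L) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  if (npad > 0L) {
    pre <- 2*x[1L] - x[(npad + 1L):2L]
    post <- 2*x[n] - x[(n - 1L):(n - npad)]
    x <- c(pre, x, post)
  }
  for (f in filts) x <- as.numeric(signal::filtfilt(f, x))
  if (npad > 0L) x <- x[(npad + 1L):(npad + n)]
  x
}

#' Zero-phase Butterworth band-pass (and notch) filter
#'
#' Two-pass (forward-backward) application of order-`order` Butterworth
#' high-pass and low-pass filters plus an optional order-2 band-stop notch,
#' matching the standard preprocessing of epileptic spike data (2-80 Hz with
#' a 50 Hz notch).
#'
#' @param data An S x T numeric matrix (channels x samples) or a
#'   `spike_dataset` (filtered trial by trial).
#' @param srate Sampling rate in Hz (taken from the dataset if omitted).
#' @param low High-pass corner frequency in Hz.
#' @param high Low-pass corner frequency in Hz.
#' @param notch Notch center frequency in Hz, or `NULL` for none. The stop
#'   band is `notch` +- 2 Hz.
#' @param order Butterworth order of the high- and low-pass (default 6;
#'   two-pass application doubles the effective order).
#' @return Filtered object of the same shape/class.
#' @export
bandpass_filter <- function(data, srate = NULL, low = 2, high = 80,
                            notch = 50, order = 6) {
  if (inherits(data, "spike_dataset")) {
    out <- data
    for (i in seq_len(data$n_trials))
      out$trials[, , i] <- bandpass_filter(data$trials[, , i], data$srate,
                                           low, high, notch, order)
    return(out)
  }
  if (is.null(srate)) stop("srate required for matrix input")
  nyq <- srate/2
  if (!(low > 0 && low < high && high < nyq))
    stop("need 0 < low < high < srate/2")
  filts <- c(butter_sos(order, low/nyq, type = "high"),
             butter_sos(order, high/nyq, type = "low"))
  if (!is.null(notch)) {
    if (notch >= nyq) stop("notch frequency above Nyquist")
    filts <- c(filts, list(signal::butter(2, c(notch - 2, notch + 2)/nyq,
                                          type = "stop")))
  }
  npad <- round(3*srate/low)
  data <- data - rowMeans(data)   # demean: the high-pass removes DC anyway,
                                  # and it kills the edge step of filtfilt
  out <- t(apply(data, 1L, zero_phase, filts = filts, npad = npad))
  if (any(!is.finite(out)))
    stop("unstable filter design at this sampling rate")
  out
}

#' Average trials into an evoked response
#'
#' @param dataset A `spike_dataset`.
#' @return An `evoked_data` with `D_avg` the arithmetic trial mean and
#'   metadata propagated.
#' @export
average_trials <- function(dataset) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (dataset$n_trials < 1L) stop("dataset has no trials")
  D <- rowMeans(dataset$trials, dims = 2L)
  new_evoked(D, dataset$srate, dataset$peak_index, dataset$modality,
             dataset$channel_names, n_trials = dataset$n_trials)
}

#' Locate the midpoint of the rising flank of an evoked spike
#'
#' The activity is reduced across channels (root-mean-square "global field
#' power" by default, or a single named channel), the flank onset is the last
#' sample before the peak at which the reduced amplitude is at or below
#' `onset_frac` of the peak amplitude, and the midpoint is the first sample
#' after the onset at which it reaches `mid_frac` of the peak amplitude.
#' For a linear ramp this lands exactly halfway up the flank.
#'
#' @param evoked An `evoked_data` with a detectable peak at its
#'   `peak_index`.
#' @param channel_reduction `"gfp"` or a channel name.
#' @param onset_frac,mid_frac Onset and midpoint thresholds as fractions of
#'   the peak amplitude (defaults 0.2 and 0.5).
#' @return The analysis sample index (integer), with attributes
#'   `onset_index` and `time_s` (seconds relative to the peak).
#' @export
find_rising_flank_midpoint <- function(evoked, channel_reduction = "gfp",
                                       onset_frac = 0.2, mid_frac = 0.5) {
  stopifnot(inherits(evoked, "evoked_data"))
  red <- if (identical(channel_reduction, "gfp")) {
    sqrt(colMeans(evoked$D_avg^2))
  } else {
    i <- match(channel_reduction, evoked$channel_names)
    if (is.na(i)) stop("unknown channel: ", channel_reduction)
    abs(evoked$D_avg[i, ])
  }
  pk <- evoked$peak_index
  peak_amp <- red[pk]
  tol <- 1e-9*peak_amp   # guard against float dust at exact threshold hits
  if (peak_amp <= 0 || !any(red[seq_len(pk - 1L)] <= onset_frac*peak_amp + tol))
    stop("no rising flank detectable (flat or non-zero-baseline signal)")
  onset <- max(which(red[seq_len(pk - 1L)] <= onset_frac*peak_amp + tol))
  seg <- seq.int(onset, pk)
  mid <- seg[which(red[seg] >= mid_frac*peak_amp - tol)[1L]]
  structure(as.integer(mid), onset_index = as.integer(onset),
            time_s = (mid - pk)/evoked$srate)
}

#' Estimate per-channel noise standard deviations from a baseline window
#'
#' Computed on the averaged data over a pre-onset window (default -500 to
#' -300 ms relative to the spike peak).
#'
#' @param evoked An `evoked_data`.
#' @param window Window in seconds relative to the peak.
#' @return Named numeric vector of per-channel standard deviations.
#' @export
estimate_noise_std <- function(evoked, window = c(-0.5, -0.3)) {
  stopifnot(inherits(evoked, "evoked_data"))
  i0 <- time_to_index(evoked, window[1L]); i1 <- time_to_index(evoked, window[2L])
  if (i0 < 1L || i1 > ncol(evoked$D_avg) || i1 <= i0)
    stop("baseline window outside the epoch")
  sds <- apply(evoked$D_avg[, i0:i1, drop = FALSE], 1L, stats::sd)
  if (any(sds <= 0))
    stop("zero-variance channel(s) in the baseline window: ",
         paste(evoked$channel_names[sds <= 0], collapse = ", "))
  names(sds) <- evoked$channel_names
  sds
}

# divide rows of evoked data / leadfield / trials by per-channel factors
scale_rows <- function(M, f) M/f

#' Normalize a single modality by its noise standard deviations
#'
#' Divides each channel of the evoked data, the leadfield and (optionally)
#' the single trials by the channel's baseline noise standard deviation,
#' giving unit-free measurements with unit baseline noise.
#'
#' @param evoked An `evoked_data`.
#' @param leadfield The matching `leadfield`.
#' @param norms Per-channel noise sds; estimated from the evoked baseline if
#'   `NULL`.
#' @param dataset Optional `spike_dataset` to normalize alongside.
#' @return List with `evoked`, `leadfield`, `norms` and (if given)
#'   `dataset`.
#' @export
normalize_channels <- function(evoked, leadfield, norms = NULL, dataset = NULL) {
  stopifnot(inherits(evoked, "evoked_data"), inherits(leadfield, "leadfield"))
  if (nrow(evoked$D_avg) != nrow(leadfield$gain))
    stop("channel mismatch between evoked data and leadfield")
  if (is.null(norms)) norms <- estimate_noise_std(evoked)
  ev <- evoked; ev$D_avg <- scale_rows(ev$D_avg, norms)
  lf <- leadfield; lf$gain <- scale_rows(lf$gain, norms); lf$units <- "unit-free"
  out <- list(evoked = ev, leadfield = lf, norms = norms)
  if (!is.null(dataset)) {
    ds <- dataset
    ds$trials <- ds$trials/as.vector(norms)  # recycles over rows (S first dim)
    out$dataset <- ds
  }
  out
}

#' Combine EEG and MEG into one normalized MEEG system
#'
#' Each modality is normalized by its own per-channel noise standard
#' deviations (making both unit-free) and the channel rows are stacked into a
#' single system of `S_eeg + S_meg` channels, used downstream exactly like a
#' single modality.
#'
#' @param eeg,meg Lists with elements `evoked`, `leadfield` and optionally
#'   `dataset` (as accepted by [normalize_channels()]).
#' @param eeg_norms,meg_norms Optional precomputed noise sds.
#' @return List with combined `evoked`, `leadfield`, `norms` and (when both
#'   modalities supplied datasets) `dataset`.
#' @export
normalize_meeg <- function(eeg, meg, eeg_norms = NULL, meg_norms = NULL) {
  e <- normalize_channels(eeg$evoked, eeg$leadfield, eeg_norms, eeg$dataset)
  m <- normalize_channels(meg$evoked, meg$leadfield, meg_norms, meg$dataset)
  if (e$evoked$srate != m$evoked$srate ||
      ncol(e$evoked$D_avg) != ncol(m$evoked$D_avg) ||
      e$evoked$peak_index != m$evoked$peak_index)
    stop("EEG and MEG epochs must share sampling rate, length and peak sample")
  ev <- new_evoked(rbind(e$evoked$D_avg, m$evoked$D_avg), e$evoked$srate,
                   e$evoked$peak_index, "MEEG",
                   c(e$evoked$channel_names, m$evoked$channel_names),
                   n_trials = e$evoked$n_trials,
                   baseline_window = e$evoked$baseline_window)
  lf <- stack_leadfields(e$leadfield, m$leadfield)
  lf$units <- "unit-free"
  out <- list(evoked = ev, leadfield = lf,
              norms = c(e$norms, m$norms))
  if (!is.null(e$dataset) && !is.null(m$dataset)) {
    S_e <- dim(e$dataset$trials)[1L]; S_m <- dim(m$dataset$trials)[1L]
    if (e$dataset$n_trials != m$dataset$n_trials)
      stop("EEG and MEG datasets must have the same number of trials")
    tr <- array(0, dim = c(S_e + S_m, dim(e$dataset$trials)[2L],
                           e$dataset$n_trials))
    tr[seq_len(S_e), , ] <- e$dataset$trials
    tr[S_e + seq_len(S_m), , ] <- m$dataset$trials
    out$dataset <- new_spike_dataset(tr, e$dataset$srate, e$dataset$peak_index,
                                     "MEEG", ev$channel_names,
                                     truth = e$dataset$truth)
  }
  out
}
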