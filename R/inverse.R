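# Covariance estimation and regularization, unit-noise-gain beamforming with
# generalized-eigenvalue optimal orientation, and goodness-of-fit dipole
# scanning.

new_covariance <- function(C, mode, n_samples, alpha = 0) {
  structure(
    list(C = C, mode = mode, n_samples = n_samples, alpha = alpha,
         S = nrow(C)),
    class = "sensor_covariance")
}

#' @export
print.sensor_covariance <- function(x, ...) {
  cat(sprintf("<sensor_covariance> %d x %d, mode = %s, n = %d samples, alpha = %g\n",
              x$S, x$S, x$mode, x$n_samples, x$alpha))
  invisible(x)
}

#' Estimate the sensor covariance from a spike dataset
#'
#' Average-based mode: `C = D_avg D_avg' / T_w` over the window of the
#' averaged trials. Event-related mode: the same second-moment matrix of the
#' concatenated single trials, `C = sum_i D_i D_i' / (n T_w)`. With a single
#' trial the two modes coincide. No regularization is applied here.
#'
#' @param dataset A `spike_dataset`.
#' @param mode `"average_based"` or `"event_related"`.
#' @param window Covariance window in seconds relative to the spike peak;
#'   `NULL` uses the full epoch.
#' @return A `sensor_covariance`.
#' @export
estimate_covariance <- function(dataset,
                                mode = c("average_based", "event_related"),
                                window = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  mode <- match.arg(mode)
  T_all <- dim(dataset$trials)[2L]
  if (is.null(window)) {
    idx <- seq_len(T_all)
  } else {
    i0 <- dataset$peak_index + round(window[1L]*dataset$srate)
    i1 <- dataset$peak_index + round(window[2L]*dataset$srate)
    if (i0 < 1L || i1 > T_all || i1 < i0) stop("window outside the epoch")
    idx <- seq.int(i0, i1)
  }
  if (length(idx) == 0L) stop("empty covariance window")
  Tw <- length(idx)
  if (mode == "average_based") {
    D <- rowMeans(dataset$trials, dims = 2L)[, idx, drop = FALSE]
    C <- tcrossprod(D)/Tw
    n <- Tw
  } else {
    S <- dim(dataset$trials)[1L]
    C <- matrix(0, S, S)
    for (i in seq_len(dataset$n_trials))
      C <- C + tcrossprod(dataset$trials[, idx, i])
    C <- C/(dataset$n_trials*Tw)
    n <- dataset$n_trials*Tw
  }
  C <- (C + t(C))/2
  new_covariance(C, mode, n)
}

#' Regularize a covariance by scaled diagonal loading
#'
#' `C_reg = C + alpha * I * trace(C)/S`. Scaling the identity by the mean
#' sensor variance makes a given `alpha` comparable between EEG and MEG
#' despite different sensor counts and units, so
#' `trace(C_reg) = (1 + alpha) trace(C)`.
#'
#' @param cov A `sensor_covariance`.
#' @param alpha Dimensionless regularization strength (>= 0). The sweep
#'   design of the study uses 0 to 0.2 in steps of 0.002; the common toolbox
#'   default is 0.05.
#' @return A regularized `sensor_covariance`.
#' @export
regularize_covariance <- function(cov, alpha) {
  stopifnot(inherits(cov, "sensor_covariance"))
  if (alpha < 0) stop("alpha must be >= 0")
  out <- cov
  out$C <- cov$C + diag(alpha*sum(diag(cov$C))/cov$S, cov$S)
  out$alpha <- alpha
  out
}

# symmetric-eigendecomposition inverse powers of C_reg with a relative
# eigenvalue floor; rank deficiency is an error directing the user to
# regularize rather than a silent pseudo-inverse
cov_inv_powers <- function(cov, floor_rel = 1e-12) {
  e <- eigen(cov$C, symmetric = TRUE)
  if (min(e$values) <= floor_rel*max(e$values))
    stop("covariance is singular or numerically rank-deficient; ",
         "apply regularization (alpha > 0) before filtering")
  V <- e$vectors
  list(C1 = V %*% (t(V)/e$values),        # C^-1
       C2 = V %*% (t(V)/e$values^2))      # C^-2
}

# smallest-generalized-eigenvalue eigenvector of (A, B), B symmetric PSD.
# Near-null directions of B (e.g. the magnetically silent quasi-radial MEG
# orientation, where the local gain is numerically rank-deficient) are
# projected out before solving; the returned orientation lives in the
# retained subspace.
gev_smallest <- function(A, B, floor_rel = 1e-10) {
  eB <- eigen(B, symmetric = TRUE)
  keep <- eB$values > floor_rel*max(eB$values)
  if (!any(keep)) stop("zero local gain: no resolvable orientation")
  V <- eB$vectors[, keep, drop = FALSE]
  Ri <- V %*% diag(1/sqrt(eB$values[keep]), sum(keep))   # B^-1/2 on subspace
  M <- crossprod(Ri, A %*% Ri)
  M <- (M + t(M))/2
  e <- eigen(M, symmetric = TRUE)
  k <- length(e$values)
  spread <- (e$values[1L] - e$values[k])/max(abs(e$values))
  phi <- Ri %*% e$vectors[, k]
  list(phi = unitize(as.vector(phi)), degenerate = spread < 1e-9)
}

#' Beamformer optimal source orientation
#'
#' The orientation maximizing the (unit-noise-gain) beamformer output power:
#' the eigenvector of the smallest generalized eigenvalue of the pair
#' `(L' C^-2 L, L' C^-1 L)`. If all generalized eigenvalues coincide (e.g.
#' `C_reg` proportional to the identity) the problem is degenerate and the
#' dominant right-singular vector of `L` is returned.
#'
#' @param L S x 3 (or S x 2) gain matrix at one source.
#' @param cov A regularized, invertible `sensor_covariance` (or a
#'   precomputed list from the internal inverse-power factorization).
#' @return Unit orientation vector (length `ncol(L)`), deterministic sign
#'   (largest-magnitude component positive).
#' @export
optimal_orientation <- function(L, cov) {
  ip <- if (inherits(cov, "sensor_covariance")) cov_inv_powers(cov) else cov
  A <- crossprod(L, ip$C2 %*% L)
  B <- crossprod(L, ip$C1 %*% L)
  A <- (A + t(A))/2; B <- (B + t(B))/2
  g <- tryCatch(gev_smallest(A, B), error = function(e)
    stop("rank-deficient local leadfield or singular covariance: ",
         conditionMessage(e)))
  phi <- if (g$degenerate) svd(L)$v[, 1L] else g$phi
  fix_sign(phi)
}

#' Construct a beamformer spatial filter at one source
#'
#' The minimum-variance filter matched to `L phi`. The default
#' `"unit_norm"` variant enforces the unit-noise-gain constraint
#' `||W|| = 1`, `W = C^-1 L_phi / ||C^-1 L_phi||`. The `"as_printed"`
#' variant is the textbook closed form `W = C^-1 L_phi / (L_phi' C^-2
#' L_phi)`; the two are parallel and differ only by a positive scalar, so
#' they share the same normalized output but weight the power map
#' differently.
#'
#' @param L S x k gain at the source.
#' @param cov Regularized `sensor_covariance`.
#' @param variant `"unit_norm"` (default) or `"as_printed"`.
#' @param phi Optional fixed orientation; computed by
#'   [optimal_orientation()] if `NULL`.
#' @return Object of class `beamformer_filter` with fields `W`, `phi`,
#'   `variant`, `Lphi`.
#' @export
beamformer_filter <- function(L, cov, variant = c("unit_norm", "as_printed"),
                              phi = NULL) {
  variant <- match.arg(variant)
  ip <- if (inherits(cov, "sensor_covariance")) cov_inv_powers(cov) else cov
  if (is.null(phi)) phi <- optimal_orientation(L, ip)
  Lphi <- as.vector(L %*% phi)
  v <- as.vector(ip$C1 %*% Lphi)
  W <- switch(variant,
    unit_norm = v/vnorm(v),
    as_printed = v/sum(Lphi*as.vector(ip$C2 %*% Lphi)))
  if (sum(W*Lphi) < 0) { W <- -W; phi <- -phi; Lphi <- -Lphi }
  structure(list(W = W, phi = phi, variant = variant, Lphi = Lphi),
            class = "beamformer_filter")
}

new_source_map <- function(values, kind, method, modality = NA_character_,
                           model = NA_character_, alpha = NA_real_) {
  structure(
    list(values = values, kind = kind,
         argmax_index = which.max(values),   # ties: lowest index
         method = method, modality = modality, model = model, alpha = alpha),
    class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %s (%s): %d sources, argmax = %d (value %.4g)\n",
              x$kind, x$method, length(x$values), x$argmax_index,
              x$values[x$argmax_index]))
  invisible(x)
}

#' Beamformer power map over the source space
#'
#' For every source: optimal orientation, spatial filter, and output power
#' `W' D D' W` of the averaged data at the analysis sample (or a window of
#' samples). The argmax ties break to the lowest source index.
#'
#' @param leadfield A `leadfield`.
#' @param cov Regularized `sensor_covariance`.
#' @param D_avg Averaged data matrix (channels x samples) or an
#'   `evoked_data`.
#' @param analysis_index Sample index (or indices) at which to localize;
#'   defaults to the `analysis_index` of an `evoked_data` input.
#' @param variant Filter variant, see [beamformer_filter()].
#' @return A `source_map` of kind `"beamformer_power"`.
#' @export
beamformer_power_map <- function(leadfield, cov, D_avg, analysis_index = NULL,
                                 variant = c("unit_norm", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(leadfield, "leadfield"))
  if (inherits(D_avg, "evoked_data")) {
    if (is.null(analysis_index)) analysis_index <- D_avg$analysis_index
    D_avg <- D_avg$D_avg
  }
  if (is.null(analysis_index) || any(is.na(analysis_index)))
    stop("analysis_index required (see find_rising_flank_midpoint)")
  D <- D_avg[, analysis_index, drop = FALSE]
  ip <- cov_inv_powers(cov)
  G <- leadfield$gain
  M1 <- ip$C1 %*% G
  M2 <- ip$C1 %*% M1
  k <- leadfield$k; P <- leadfield$n_sources
  vals <- numeric(P)
  for (p in seq_len(P)) {
    cols <- ((p - 1L)*k + 1L):(p*k)
    Lp <- G[, cols, drop = FALSE]
    if (all(Lp == 0)) next            # silent source (e.g. sphere center)
    A <- crossprod(Lp, M2[, cols, drop = FALSE])
    B <- crossprod(Lp, M1[, cols, drop = FALSE])
    A <- (A + t(A))/2; B <- (B + t(B))/2
    g <- gev_smallest(A, B)
    phi <- if (g$degenerate) svd(Lp)$v[, 1L] else g$phi
    v <- M1[, cols, drop = FALSE] %*% phi          # C^-1 L_phi
    W <- switch(variant,
      unit_norm = v/vnorm(v),
      as_printed = v/as.numeric(crossprod(phi, A %*% phi)))
    vals[p] <- sum(as.vector(crossprod(W, D))^2)
  }
  new_source_map(vals, "beamformer_power",
                 method = paste0("bf-", cov$mode), modality = leadfield$modality,
                 alpha = cov$alpha)
}

#' Dipole scan (goodness-of-fit map) over the source space
#'
#' Fits a single dipole at every source point by unregularized least squares
#' through the pseudoinverse of the local gain and scores it by the relative
#' residual variance, reported as goodness of fit
#' `gof = 1 - ||D - L L^+ D||^2 / ||D||^2`. For MEG the quasi-radial
#' direction is numerically silent; `meg_tsvd = TRUE` replaces each S x 3
#' gain by its two strongest singular directions before scanning.
#'
#' @param leadfield A `leadfield`.
#' @param D Data column (channels), matrix of columns, or an `evoked_data`
#'   (its analysis sample is used).
#' @param meg_tsvd Reduce each per-source gain to 2 columns by tSVD.
#' @param analysis_index Sample index when `D` is an `evoked_data`.
#' @return A `source_map` of kind `"gof"`.
#' @export
dipole_scan <- function(leadfield, D, meg_tsvd = FALSE, analysis_index = NULL) {
  stopifnot(inherits(leadfield, "leadfield"))
  if (inherits(D, "evoked_data")) {
    if (is.null(analysis_index)) analysis_index <- D$analysis_index
    D <- D$D_avg[, analysis_index, drop = FALSE]
  }
  D <- as.matrix(D)
  nD2 <- sum(D^2)
  if (nD2 == 0) stop("zero data vector")
  G <- leadfield$gain; k <- leadfield$k; P <- leadfield$n_sources
  gof <- numeric(P)
  for (p in seq_len(P)) {
    Lp <- G[, ((p - 1L)*k + 1L):(p*k), drop = FALSE]
    if (all(Lp == 0)) next            # silent source (e.g. sphere center)
    if (meg_tsvd && k == 3L) Lp <- reduce_leadfield_tsvd(Lp)$gain
    qrL <- qr(Lp)
    res <- qr.resid(qrL, D)
    gof[p] <- 1 - sum(res^2)/nD2
  }
  gof <- pmin(1, pmax(0, gof))
  new_source_map(gof, "gof", method = "dip", modality = leadfield$modality)
}
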