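# Leadfield container: gain is an S x (k*P) matrix, k columns per source
# (k = 3 free orientation, k = 2 after tSVD reduction). Units: microvolt per
# nA*m (EEG) or fT per nA*m (MEG); unit-free after noise normalization.

new_leadfield <- function(gain, k, modality, reference = "none",
                          channel_names = NULL, basis = NULL, units = NULL,
                          flagged = integer(0)) {
  structure(
    list(gain = gain, k = k, n_sources = ncol(gain)/k, modality = modality,
         reference = reference, channel_names = channel_names,
         basis = basis, units = units, flagged = flagged),
    class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %s: %d channels x %d sources (k = %d), ref = %s, units = %s\n",
              x$modality, nrow(x$gain), x$n_sources, x$k, x$reference,
              x$units %||% "?"))
  invisible(x)
}

#' Extract the per-source gain block of a leadfield
#'
#' @param lf A `leadfield`.
#' @param p Source index.
#' @return The S x k gain matrix of source `p`.
#' @export
leadfield_at <- function(lf, p) {
  stopifnot(inherits(lf, "leadfield"))
  if (p < 1L || p > lf$n_sources) stop("invalid source index")
  lf$gain[, ((p - 1L)*lf$k + 1L):(p*lf$k), drop = FALSE]
}

# ---- multilayer concentric-sphere EEG series -------------------------------

# Per-degree shell transfer gain g_n: ratio of the surface potential
# coefficient to the unit primary source coefficient (relative to
# R^-(n+1)). Depends only on radius ratios and conductivities. For a
# homogeneous sphere g_n = (2n+1)/n.
shell_gain <- function(n, radii, cond) {
  N <- length(radii)
  if (N == 1L || length(unique(cond)) == 1L) return((2*n + 1)/n)
  radii <- radii/radii[N]  # dimensionless: conditioning of the solve
  nun <- 2L*N - 1L
  M <- matrix(0, nun, nun); rhs <- numeric(nun)
  iA <- function(j) if (j == 1L) 1L else 2L*(j - 1L)
  iB <- function(j) 2L*(j - 1L) + 1L
  row <- 0L
  for (j in 1:(N - 1L)) {
    r <- radii[j]
    # continuity of the potential at interface j
    row <- row + 1L
    M[row, iA(j)] <- r^n; M[row, iA(j + 1L)] <- -r^n
    M[row, iB(j + 1L)] <- -r^(-(n + 1))
    if (j == 1L) rhs[row] <- -r^(-(n + 1)) else M[row, iB(j)] <- r^(-(n + 1))
    # continuity of the radial current density sigma * dV/dr
    row <- row + 1L
    M[row, iA(j)] <- cond[j]*n*r^(n - 1)
    M[row, iA(j + 1L)] <- -cond[j + 1L]*n*r^(n - 1)
    M[row, iB(j + 1L)] <- cond[j + 1L]*(n + 1)*r^(-(n + 2))
    if (j == 1L) rhs[row] <- cond[j]*(n + 1)*r^(-(n + 2))
    else M[row, iB(j)] <- -cond[j]*(n + 1)*r^(-(n + 2))
  }
  # insulating outer boundary: no radial current at the scalp surface
  R <- radii[N]; row <- row + 1L
  M[row, iA(N)] <- n*R^(n - 1); M[row, iB(N)] <- -(n + 1)*R^(-(n + 2))
  x <- solve(M, rhs)
  (x[iA(N)]*R^n + x[iB(N)]*R^(-(n + 1)))/R^(-(n + 1))
}

#' EEG forward solution for a multilayer concentric-sphere head
#'
#' Series (spherical-harmonic) solution for a current dipole inside the
#' innermost shell of a layered spherical conductor, evaluated at scalp
#' electrodes and average-referenced. Gain units are microvolt per nA*m.
#'
#' @param head A `head_model`.
#' @param sensors An EEG `sensor_array` on the outermost shell.
#' @param sources A `source_space` strictly inside the innermost shell.
#' @param n_terms Series truncation order (default 60; convergence is at the
#'   1e-8 level for sources a few mm below the brain surface).
#' @return A `leadfield` with 3 columns per source and average reference.
#' @export
eeg_sphere_leadfield <- function(head, sensors, sources, n_terms = 60L) {
  stopifnot(inherits(head, "head_model"), inherits(sensors, "sensor_array"),
            inherits(sources, "source_space"))
  if (sensors$modality != "EEG") stop("EEG sensors required")
  R <- max(head$radii)
  pos <- sensors$positions
  if (max(abs(sqrt(rowSums(pos^2)) - R)) > 1e-6)
    stop("EEG electrodes must lie on the outermost shell surface")
  pts <- sources$points
  rin <- head$radii[1L]
  b_all <- sqrt(rowSums(pts^2))
  if (any(b_all >= rin)) stop("all sources must lie strictly inside the innermost shell")
  S <- nrow(pos); P <- nrow(pts)
  sig1 <- head$conductivities[1L]
  g <- vapply(seq_len(n_terms), shell_gain, numeric(1),
              radii = head$radii, cond = head$conductivities)
  rhat <- pos/R
  G <- matrix(0, S, 3L*P)
  for (p in seq_len(P)) {
    r0 <- pts[p, ]; b <- b_all[p]
    if (b < 1e-9) { rh <- c(0, 0, 1) } else rh <- r0/b
    x <- as.vector(rhat %*% rh)          # cos(theta) per sensor
    x <- pmin(1, pmax(-1, x))
    # Legendre recurrences: P_n(x) and P_n'(x)
    Pm1 <- rep(1, S); Pn <- x
    dPm1 <- rep(0, S); dPn <- rep(1, S)
    Sr <- numeric(S); St <- numeric(S)
    for (n in seq_len(n_terms)) {
      radf <- if (n == 1L) 1/R^2 else (b^(n - 1))/R^(n + 1)
      Sr <- Sr + g[n]*radf*n*Pn
      St <- St + g[n]*radf*dPn
      Pnp <- ((2*n + 1)*x*Pn - n*Pm1)/(n + 1)
      dPnp <- dPm1 + (2*n + 1)*Pn
      Pm1 <- Pn; Pn <- Pnp; dPm1 <- dPn; dPn <- dPnp
    }
    for (kk in 1:3) {
      e <- c(0, 0, 0); e[kk] <- 1
      mr <- sum(e*rh)
      tau <- e - mr*rh                   # tangential moment component
      v <- mr*Sr + St*as.vector(rhat %*% tau)
      G[, (p - 1L)*3L + kk] <- v
    }
  }
  G <- G*(1000/(4*pi*sig1))              # mm & nA*m -> microvolt
  G <- sweep(G, 2L, colMeans(G))         # common average reference
  new_leadfield(G, 3L, "EEG", reference = "average",
                channel_names = sensors$channel_names,
                units = "uV/(nA*m)")
}

# ---- spherical-conductor MEG (Sarvas) --------------------------------------

#' MEG forward solution for a spherical conductor
#'
#' Closed-form magnetic field of a current dipole in a homogeneous conducting
#' sphere (Sarvas formula), projected onto the sensor orientations. The
#' solution is exactly independent of the conductivity profile, and a purely
#' radial dipole produces no field. Gain units are fT per nA*m.
#'
#' @param sensors An MEG `sensor_array`.
#' @param sources A `source_space` inside the sphere.
#' @param sphere_center Center of the conductor sphere in mm.
#' @param head Optional `head_model`; accepted (and ignored beyond geometry
#'   checks) to make the conductivity-independence explicit at call sites.
#' @return A `leadfield` with 3 columns per source. Sources at the sphere
#'   center are magnetically silent; their indices are recorded in the
#'   `flagged` field and their gain set to zero.
#' @export
meg_sphere_leadfield <- function(sensors, sources, sphere_center = c(0, 0, 0),
                                 head = NULL) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(sources, "source_space"))
  if (sensors$modality != "MEG") stop("MEG sensors required")
  pos <- sweep(sensors$positions, 2L, sphere_center)
  ori <- sensors$orientations
  if (is.null(ori)) stop("MEG sensor array must carry orientations")
  pts <- sweep(sources$points, 2L, sphere_center)
  S <- nrow(pos); P <- nrow(pts)
  G <- matrix(0, S, 3L*P)
  flagged <- integer(0)
  rn <- sqrt(rowSums(pos^2))
  for (p in seq_len(P)) {
    r0 <- pts[p, ]
    if (vnorm(r0) < 1e-9) { flagged <- c(flagged, p); next }
    A <- sweep(pos, 2L, r0)              # a = r - r0 per sensor
    an <- sqrt(rowSums(A^2))
    adr <- rowSums(A*pos)
    Fv <- an*(rn*an + rn^2 - as.vector(pos %*% r0))
    c1 <- an^2/rn + adr/an + 2*an + 2*rn
    c2 <- an + 2*rn + adr/an
    for (kk in 1:3) {
      q <- c(0, 0, 0); q[kk] <- 1
      qxr0 <- cross3(q, r0)
      dot_qxr0_r <- as.vector(pos %*% qxr0)
      # grad F = c1 * r - c2 * r0
      gF <- pos*c1 - matrix(r0, S, 3L, byrow = TRUE)*c2
      B <- (matrix(qxr0, S, 3L, byrow = TRUE)*Fv - gF*dot_qxr0_r)/Fv^2
      # scale: the Sarvas expression is dimensionally moment/length^2, so
      # mu0/4pi (1e-7) x 1e-9 A*m x 1e6 m^-2/mm^-2 x 1e15 fT/T = 1e5
      G[, (p - 1L)*3L + kk] <- rowSums(B*ori)*1e5
    }
  }
  if (length(flagged))
    warning("sources at the sphere center are magnetically silent; gain set to 0 for indices: ",
            paste(flagged, collapse = ", "))
  new_leadfield(G, 3L, "MEG", reference = "none",
                channel_names = sensors$channel_names,
                units = "fT/(nA*m)", flagged = flagged)
}

#' Reduce a point leadfield to its two strongest orientations (tSVD)
#'
#' Drops the right-singular vector with the smallest singular value. For a
#' spherical-conductor MEG leadfield this discards the quasi-radial (silent)
#' direction. Ties among the smallest singular values are broken by the
#' stable ordering of the SVD (the last column is dropped).
#'
#' @param L_point An S x 3 gain matrix (one source).
#' @return A list with `gain` (S x 2) and `basis` (3 x 2 retained
#'   orientation vectors).
#' @export
reduce_leadfield_tsvd <- function(L_point) {
  if (!all(is.finite(L_point))) stop("leadfield must be finite")
  if (all(L_point == 0)) stop("cannot reduce an all-zero leadfield")
  sv <- svd(L_point)
  keep <- seq_len(ncol(L_point) - 1L)
  list(gain = L_point %*% sv$v[, keep, drop = FALSE],
       basis = sv$v[, keep, drop = FALSE],
       dropped = sv$v[, ncol(L_point)],
       d = sv$d)
}

#' Stack two leadfields row-wise into a combined-modality leadfield
#'
#' @param eeg_lf,meg_lf `leadfield` objects over the same source space.
#' @return A combined `leadfield` with modality `"MEEG"`.
#' @export
stack_leadfields <- function(eeg_lf, meg_lf) {
  stopifnot(inherits(eeg_lf, "leadfield"), inherits(meg_lf, "leadfield"))
  if (eeg_lf$n_sources != meg_lf$n_sources || eeg_lf$k != meg_lf$k)
    stop("leadfields must share source space and orientation count")
  new_leadfield(rbind(eeg_lf$gain, meg_lf$gain), eeg_lf$k, "MEEG",
                reference = eeg_lf$reference,
                channel_names = c(eeg_lf$channel_names, meg_lf$channel_names),
                units = "mixed")
}
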