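#' Build a concentric-sphere head model
#'
#' A volume conductor made of nested spherical shells, innermost (brain) to
#' outermost (scalp). Shell `j` occupies the radial range between shell
#' `j - 1` (or the center) and `radii[j]`.
#'
#' @param radii Outer radius of each shell in mm, strictly increasing,
#'   innermost first.
#' @param conductivities Conductivity of each shell in S/m, all positive.
#' @param label Profile name, e.g. `"3C-standard"` or `"calibrated"`.
#' @return An object of class `head_model`.
#' @examples
#' build_sphere_head(c(80, 85, 92), c(0.33, 0.01, 0.43), "3C-standard")
#' @export
build_sphere_head <- function(radii, conductivities, label = "head") {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  if (length(radii) < 1L) stop("at least one shell is required")
  if (length(radii) != length(conductivities))
    stop("radii and conductivities must have equal length")
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing")
  if (any(radii <= 0)) stop("shell radii must be positive")
  if (any(conductivities <= 0)) stop("shell conductivities must be positive")
  structure(
    list(radii = radii, conductivities = conductivities, label = label),
    class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> ", x$label, "\n", sep = "")
  cat("  shells (inner -> outer):\n")
  for (j in seq_along(x$radii))
    cat(sprintf("    r = %6.1f mm   sigma = %.4g S/m\n",
                x$radii[j], x$conductivities[j]))
  invisible(x)
}

#' Standard three-shell head profile
#'
#' Brain/skull/scalp spheres at the standard conductivities 0.33, 0.01 and
#' 0.43 S/m. The skull value can be overridden, e.g. with an individually
#' calibrated conductivity.
#'
#' @param radii Shell radii in mm (brain, skull, scalp).
#' @param skull_sigma Skull conductivity in S/m.
#' @param label Profile name.
#' @return A `head_model`.
#' @export
head_profile_3c <- function(radii = c(80, 85, 92), skull_sigma = 0.01,
                            label = if (skull_sigma == 0.01) "3C-standard" else "calibrated") {
  build_sphere_head(radii, c(0.33, skull_sigma, 0.43), label)
}

#' Replace the skull conductivity of a head model
#'
#' @param head A `head_model`.
#' @param sigma New skull conductivity in S/m.
#' @param shell Index of the skull shell (default 2, the middle shell of a
#'   three-shell model).
#' @param label Optional new label.
#' @return A `head_model` with the substituted conductivity.
#' @export
with_skull_conductivity <- function(head, sigma, shell = 2L, label = NULL) {
  stopifnot(inherits(head, "head_model"))
  if (shell < 1L || shell > length(head$radii)) stop("invalid shell index")
  cond <- head$conductivities
  cond[shell] <- sigma
  build_sphere_head(head$radii, cond,
                    label %||% sprintf("%s[sigma_skull=%.4g]", head$label, sigma))
}

#' Effective single-shell skull conductivity from a compacta:spongiosa ratio
#'
#' A sphere model has one skull shell, while real skull is layered into
#' compacta (SC) and spongiosa (SS). Radial current crosses the layers in
#' series, so the effective homogeneous conductivity is the thickness-weighted
#' harmonic mean. With the SC:SS conductivity ratio fixed (1:3.6 by default)
#' the effective value is a function of the compacta conductivity alone,
#' which is the single free parameter of the calibration.
#'
#' @param sigma_sc Skull compacta conductivity in S/m.
#' @param sc_ss_ratio Spongiosa-to-compacta conductivity ratio (default 3.6).
#' @param spongiosa_fraction Thickness fraction of spongiosa (default 0.4).
#' @return Effective skull conductivity in S/m.
#' @export
effective_skull_conductivity <- function(sigma_sc, sc_ss_ratio = 3.6,
                                         spongiosa_fraction = 0.4) {
  stopifnot(sigma_sc > 0, sc_ss_ratio > 0,
            spongiosa_fraction >= 0, spongiosa_fraction <= 1)
  f_ss <- spongiosa_fraction
  sigma_sc / ((1 - f_ss) + f_ss/sc_ss_ratio)
}

#' Place sensors quasi-uniformly on a sphere around the head
#'
#' Deterministic Fibonacci-spiral placement on the sphere of radius
#' outermost shell + `offset_mm`. EEG electrodes must sit on the scalp
#' (`offset_mm = 0`); MEG sensors are modelled as radial point magnetometers
#' at a standoff above the scalp.
#'
#' @param head A `head_model`.
#' @param modality `"EEG"` or `"MEG"`.
#' @param n Number of sensors (>= 3).
#' @param offset_mm Radial standoff in mm (must be 0 for EEG).
#' @param coverage `"hemisphere"` (upper, z > 0) or `"full"`.
#' @return An object of class `sensor_array` with fields `positions`
#'   (n x 3, mm), `orientations` (n x 3 unit radial vectors, MEG only),
#'   `modality`, `channel_names`, `S`.
#' @export
place_sensors <- function(head, modality = c("EEG", "MEG"), n,
                          offset_mm = 0, coverage = c("hemisphere", "full")) {
  stopifnot(inherits(head, "head_model"))
  modality <- match.arg(modality)
  coverage <- match.arg(coverage)
  if (n < 3L) stop("at least 3 sensors are required")
  if (offset_mm < 0) stop("offset_mm must be >= 0")
  if (modality == "EEG" && offset_mm != 0)
    stop("EEG electrodes must lie on the scalp: offset_mm must be 0")
  R <- max(head$radii) + offset_mm
  i <- seq_len(n) - 0.5
  golden <- pi*(3 - sqrt(5))
  # z from near-pole down to equator (hemisphere) or to the south pole (full)
  z <- if (coverage == "hemisphere") 1 - i/n*0.95 else 1 - 2*i/n
  theta <- golden*(seq_len(n) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- R*cbind(rho*cos(theta), rho*sin(theta), z)
  dimnames(pos) <- NULL
  ori <- pos/R
  prefix <- if (modality == "EEG") "E" else "M"
  structure(
    list(positions = pos,
         orientations = if (modality == "MEG") ori else NULL,
         modality = modality,
         channel_names = sprintf("%s%03d", prefix, seq_len(n)),
         S = as.integer(n),
         radius = R),
    class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %s, %d channels on radius %.1f mm\n",
              x$modality, x$S, x$radius))
  invisible(x)
}

#' Build a regular source grid inside the brain shell
#'
#' Cartesian lattice at the requested spacing, clipped to the sphere of
#' radius innermost shell radius minus `margin`, in deterministic
#' lexicographic (x, y, z) order.
#'
#' @param head A `head_model`.
#' @param spacing Grid spacing in mm (the study design uses ~2 mm).
#' @param margin Clearance from the brain shell boundary in mm.
#' @return An object of class `source_space` with fields `points` (P x 3,
#'   mm), `spacing`, `indices`.
#' @export
build_source_grid <- function(head, spacing = 2, margin = 2) {
  stopifnot(inherits(head, "head_model"))
  if (spacing <= 0) stop("spacing must be positive")
  if (margin < 0) stop("margin must be >= 0")
  rmax <- head$radii[1L] - margin
  if (spacing > head$radii[1L]) stop("spacing exceeds the brain radius")
  ax <- seq(-floor(rmax/spacing), floor(rmax/spacing))*spacing
  g <- expand.grid(z = ax, y = ax, x = ax, KEEP.OUT.ATTRS = FALSE)
  pts <- as.matrix(g[, c("x", "y", "z")])
  # lexicographic in (x, y, z): expand.grid varies its first factor fastest,
  # so listing z, y, x and reordering columns gives x-major order
  keep <- rowSums(pts^2) <= rmax^2
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no grid points inside the brain shell")
  dimnames(pts) <- NULL
  structure(
    list(points = pts, spacing = spacing, indices = seq_len(nrow(pts)),
         margin = margin, brain_radius = head$radii[1L]),
    class = "source_space")
}

# internal: wrap arbitrary points (k x 3) as a source_space
as_source_points <- function(points, spacing = NA_real_) {
  points <- matrix(as.numeric(points), ncol = 3L)
  structure(list(points = points, spacing = spacing,
                 indices = seq_len(nrow(points))),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d points, spacing %s mm\n",
              nrow(x$points),
              if (is.na(x$spacing)) "?" else format(x$spacing)))
  invisible(x)
}

#' Write / read a sensor array as delimited text
#'
#' Tab-separated columns: name, x, y, z and, for MEG, ox, oy, oz.
#'
#' @param sensors A `sensor_array`.
#' @param path Output file.
#' @return `write_sensor_array` returns `path` invisibly;
#'   `read_sensor_array` returns a `sensor_array`.
#' @export
write_sensor_array <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  df <- data.frame(name = sensors$channel_names,
                   x = sensors$positions[, 1L],
                   y = sensors$positions[, 2L],
                   z = sensors$positions[, 3L])
  if (!is.null(sensors$orientations)) {
    df$ox <- sensors$orientations[, 1L]
    df$oy <- sensors$orientations[, 2L]
    df$oz <- sensors$orientations[, 3L]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_array
#' @param modality Modality of the stored array.
#' @export
read_sensor_array <- function(path, modality = c("EEG", "MEG")) {
  modality <- match.arg(modality)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  ori <- if (all(c("ox", "oy", "oz") %in% names(df))) {
    o <- as.matrix(df[, c("ox", "oy", "oz")]); dimnames(o) <- NULL; o
  } else NULL
  structure(
    list(positions = pos, orientations = ori, modality = modality,
         channel_names = df$name, S = nrow(df),
         radius = stats::median(sqrt(rowSums(pos^2)))),
    class = "sensor_array")
}
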