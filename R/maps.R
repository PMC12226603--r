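#' Imaging grid
#'
#' Regular reconstruction/measurement grid. Matrices indexed `[axial, lateral]`
#' (axial rows point away from the transducer); pixel centers sit at
#' `(i + 0.5) * pitch` with zero-based pixel indices.
#'
#' @param n_ax,n_lat pixel counts (axial, lateral), both >= 2.
#' @param pitch_ax,pitch_lat pixel pitches in mm.
#' @param depth_offset axial offset of the grid top from the transducer face (mm).
#' @return An object of class `sos_grid`.
#' @export
imaging_grid <- function(n_ax, n_lat, pitch_ax = 0.5, pitch_lat = 0.5,
                         depth_offset = 0) {
  stopifnot(n_ax >= 2, n_lat >= 2, pitch_ax > 0, pitch_lat > 0, depth_offset >= 0)
  structure(list(n_ax = as.integer(n_ax), n_lat = as.integer(n_lat),
                 pitch_ax = pitch_ax, pitch_lat = pitch_lat,
                 depth_offset = depth_offset),
            class = "sos_grid")
}

#' @export
print.sos_grid <- function(x, ...) {
  cat(sprintf("<sos_grid> %d x %d px (axial x lateral), pitch %.3g x %.3g mm, depth offset %.3g mm\n",
              x$n_ax, x$n_lat, x$pitch_ax, x$pitch_lat, x$depth_offset))
  invisible(x)
}

grid_npix <- function(grid) grid$n_ax * grid$n_lat

# pixel-center coordinates (mm); axial z measured from the transducer face
grid_axial_centers <- function(grid) grid$depth_offset + (seq_len(grid$n_ax) - 0.5) * grid$pitch_ax
grid_lateral_centers <- function(grid) (seq_len(grid$n_lat) - 0.5) * grid$pitch_lat

grid_extent <- function(grid) {
  c(lat = grid$n_lat * grid$pitch_lat, ax = grid$n_ax * grid$pitch_ax)
}

same_fov <- function(g1, g2, tol = 1e-9) {
  e1 <- grid_extent(g1); e2 <- grid_extent(g2)
  all(abs(e1 - e2) < tol) && abs(g1$depth_offset - g2$depth_offset) < tol
}

same_grid <- function(g1, g2) {
  g1$n_ax == g2$n_ax && g1$n_lat == g2$n_lat && same_fov(g1, g2)
}

#' Convert speed of sound to slowness
#'
#' Slowness is the reciprocal of SoS; the package stores it in s/mm so that
#' path lengths in mm (forward-model entries) yield time delays in seconds.
#'
#' @param c_mps speed of sound in m/s (scalar or array).
#' @return slowness in s/mm.
#' @export
sos_to_slowness <- function(c_mps) {
  stopifnot(all(c_mps > 0))
  1 / (c_mps * 1e3)
}

#' Convert a slowness map to a speed-of-sound map
#'
#' Applies the elementwise reciprocal `c = 1 / (x + x0)` where `x` is the
#' slowness deviation and `x0 = 1/c0` the beamforming slowness.
#'
#' @param x a `slowness_map` (see [slowness_map()]) or a numeric array of
#'   total slowness in s/mm.
#' @return For a `slowness_map` input, an `sos_map` (matrix of m/s values with
#'   the grid attached); otherwise a numeric array in m/s.
#' @export
slowness_to_sos <- function(x) {
  if (inherits(x, "slowness_map")) {
    total <- x$values + x$x0
    n_bad <- sum(total <= 0)
    if (n_bad > 0)
      stop(sprintf("nonpositive total slowness at %d pixel(s); cannot convert to SoS", n_bad))
    sos_map(1 / (total * 1e3), x$grid)
  } else {
    n_bad <- sum(x <= 0)
    if (n_bad > 0)
      stop(sprintf("nonpositive total slowness at %d pixel(s); cannot convert to SoS", n_bad))
    1 / (x * 1e3)
  }
}

#' Slowness-deviation map
#'
#' The reconstructed quantity: deviation `x` of slowness from the beamforming
#' slowness `x0 = 1/c0`, on the reconstruction grid.
#'
#' @param values matrix `n_ax x n_lat` of slowness deviation (s/mm).
#' @param grid the reconstruction [imaging_grid()].
#' @param c0 assumed beamforming SoS in m/s (defines `x0`).
#' @export
slowness_map <- function(values, grid, c0) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == grid$n_ax, ncol(values) == grid$n_lat, c0 > 0)
  structure(list(values = values, grid = grid, c0 = c0, x0 = sos_to_slowness(c0)),
            class = "slowness_map")
}

#' @export
print.slowness_map <- function(x, ...) {
  cat(sprintf("<slowness_map> %d x %d, c0 = %g m/s, deviation range [%.3g, %.3g] s/mm\n",
              x$grid$n_ax, x$grid$n_lat, x$c0, min(x$values), max(x$values)))
  invisible(x)
}

#' Speed-of-sound map
#'
#' @param values matrix `n_ax x n_lat` of SoS (m/s).
#' @param grid the [imaging_grid()] the map lives on.
#' @export
sos_map <- function(values, grid) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == grid$n_ax, ncol(values) == grid$n_lat)
  structure(list(values = values, grid = grid), class = "sos_map")
}

#' @export
print.sos_map <- function(x, ...) {
  cat(sprintf("<sos_map> %d x %d, range [%.1f, %.1f] m/s\n",
              x$grid$n_ax, x$grid$n_lat, min(x$values), max(x$values)))
  invisible(x)
}

# slowness deviation map (matrix, s/mm) of an SoS field w.r.t. beamforming c0
sos_field_to_deviation <- function(sos_values, c0) {
  sos_to_slowness(sos_values) - sos_to_slowness(c0)
}
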