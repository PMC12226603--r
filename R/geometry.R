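#' Acquisition specification
#'
#' Virtual-source (VS) transmit scheme for pulse-echo SoS imaging. Apparent
#' displacements are tracked between pairs of beamformed frames whose transmit
#' indices differ by `pair_offset`, so `n_transmits` transmits yield
#' `n_transmits - pair_offset` displacement maps (17 transmits with offset 2
#' give the default 15 pairs).
#'
#' @param n_transmits number of VS transmit events.
#' @param pair_offset index gap between the two transmits of a pair.
#' @param angles_deg steering angles in degrees, strictly increasing; default
#'   evenly spaced over +/-20 degrees.
#' @param c0 assumed beamforming SoS (m/s).
#' @param aperture_mm receive aperture width (mm); defaults to the lateral
#'   field-of-view width when a forward model is built.
#' @param vs_depth_mm focal offset of the virtual source behind the aperture
#'   (mm); `Inf` (default) is the plane-wavefront limit.
#' @return An object of class `sos_acquisition`.
#' @export
acquisition_spec <- function(n_transmits = 17, pair_offset = 2, angles_deg = NULL,
                             c0 = 1515, aperture_mm = NULL, vs_depth_mm = Inf) {
  n_transmits <- as.integer(n_transmits)
  pair_offset <- as.integer(pair_offset)
  if (pair_offset >= n_transmits)
    stop("configuration error: pair_offset must be smaller than n_transmits")
  stopifnot(n_transmits >= 2, pair_offset >= 1, c0 > 0, vs_depth_mm > 0)
  if (is.null(angles_deg))
    angles_deg <- seq(-20, 20, length.out = n_transmits)
  if (length(angles_deg) != n_transmits)
    stop("angles_deg must have one angle per transmit")
  if (any(diff(angles_deg) <= 0))
    stop("angles_deg must be strictly increasing")
  structure(list(n_transmits = n_transmits, pair_offset = pair_offset,
                 angles_deg = angles_deg, c0 = c0, aperture_mm = aperture_mm,
                 vs_depth_mm = vs_depth_mm),
            class = "sos_acquisition")
}

#' @export
print.sos_acquisition <- function(x, ...) {
  cat(sprintf("<sos_acquisition> %d VS transmits, pair offset %d (%d pairs), angles [%.1f, %.1f] deg, c0 = %g m/s\n",
              x$n_transmits, x$pair_offset, x$n_transmits - x$pair_offset,
              min(x$angles_deg), max(x$angles_deg), x$c0))
  invisible(x)
}

#' Transmit pairs tracked for displacements
#'
#' Deterministic zero-based pairs `(i, i + pair_offset)`.
#'
#' @param spec an [acquisition_spec()].
#' @return A two-column integer matrix of zero-based transmit indices, one row
#'   per pair.
#' @export
build_transmit_pairs <- function(spec) {
  stopifnot(inherits(spec, "sos_acquisition"))
  n_pairs <- spec$n_transmits - spec$pair_offset
  cbind(tx_i = 0:(n_pairs - 1), tx_j = spec$pair_offset:(spec$n_transmits - 1))
}

# Ray endpoints for one transmit: straight round-trip model. The transmit leg
# runs from the virtual-source wavefront to the pixel center; the receive leg
# runs from the pixel center vertically back to the aperture. For a pair the
# receive legs are identical and cancel in the differential row.
transmit_ray_starts <- function(angle_deg, xc, zc, z_top, lat_center, vs_depth) {
  th <- angle_deg * pi / 180
  if (is.infinite(vs_depth)) {
    # plane wavefront: constant direction (sin th, cos th); entry at the grid top
    list(x0 = xc - (zc - z_top) * tan(th), z0 = rep(z_top, length(xc)))
  } else {
    # diverging wave from a virtual source behind the aperture
    vs_x <- lat_center - vs_depth * tan(th)
    vs_z <- z_top - vs_depth
    list(x0 = rep(vs_x, length(xc)), z0 = rep(vs_z, length(xc)))
  }
}

# sparse per-pixel traversal-length matrix (n rays x n recon pixels)
ray_matrix <- function(x0, z0, x1, z1, grid) {
  tr <- trace_rays(x0, z0, x1, z1,
                   grid$n_ax, grid$n_lat, grid$pitch_ax, grid$pitch_lat,
                   0, grid$depth_offset)
  Matrix::sparseMatrix(i = tr$ray, j = tr$pixel, x = tr$length,
                       dims = c(length(x0), grid_npix(grid)))
}

#' Build the sparse forward model
#'
#' Constructs the linear operator `L` mapping a slowness-deviation map (s/mm,
#' on the reconstruction grid) to apparent time-delay measurements (s) for all
#' transmit pairs, by vertically stacking discretized straight-ray path-integral
#' matrices. For each pair and measurement pixel the row holds the per-pixel
#' traversal-length difference (mm) between the two round-trip ray paths; the
#' shared receive leg cancels and rows are assembled pair-major. Rays leaving
#' the field of view are truncated at the boundary.
#'
#' @param spec an [acquisition_spec()].
#' @param recon_grid reconstruction [imaging_grid()].
#' @param meas_grid measurement grid; defaults to `recon_grid`. Must cover the
#'   same physical field of view.
#' @return An object of class `sos_forward_model` with elements `L` (a
#'   `dgCMatrix` of shape `(n_pairs * n_meas_pix, n_recon_pix)`), `Lt` (its
#'   transpose, cached for reconstruction), `pairs`, `spec`, `recon_grid`,
#'   `meas_grid`.
#' @export
build_forward_model <- function(spec, recon_grid, meas_grid = recon_grid) {
  stopifnot(inherits(spec, "sos_acquisition"),
            inherits(recon_grid, "sos_grid"), inherits(meas_grid, "sos_grid"))
  if (!same_fov(recon_grid, meas_grid))
    stop("recon_grid and meas_grid must cover the same physical field of view")

  lat <- grid_lateral_centers(meas_grid)
  ax <- grid_axial_centers(meas_grid)
  xc <- rep(lat, each = meas_grid$n_ax)      # pixel order: axial fastest
  zc <- rep(ax, times = meas_grid$n_lat)
  z_top <- recon_grid$depth_offset
  lat_center <- grid_extent(recon_grid)[["lat"]] / 2

  # per-transmit tx-leg path matrices
  T_list <- lapply(spec$angles_deg, function(a) {
    st <- transmit_ray_starts(a, xc, zc, z_top, lat_center, spec$vs_depth_mm)
    ray_matrix(st$x0, st$z0, xc, zc, recon_grid)
  })

  pairs <- build_transmit_pairs(spec)
  L <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
    T_list[[pairs[p, 1] + 1L]] - T_list[[pairs[p, 2] + 1L]]
  }))
  L <- Matrix::drop0(L)
  structure(list(L = L, Lt = Matrix::t(L), pairs = pairs, spec = spec,
                 recon_grid = recon_grid, meas_grid = meas_grid),
            class = "sos_forward_model")
}

#' @export
print.sos_forward_model <- function(x, ...) {
  cat(sprintf("<sos_forward_model> %d x %d sparse (%.2f%% filled), %d pairs, meas grid %d x %d\n",
              nrow(x$L), ncol(x$L), 100 * Matrix::nnzero(x$L) / prod(dim(x$L)),
              nrow(x$pairs), x$meas_grid$n_ax, x$meas_grid$n_lat))
  invisible(x)
}

#' Displacement measurement set
#'
#' Vectorized time-delay measurements from all transmit pairs.
#'
#' @param values array `(n_ax', n_lat', n_pairs)` of time delays in seconds.
#' @param meas_grid the measurement [imaging_grid()].
#' @export
displacement_set <- function(values, meas_grid) {
  values <- array(values, dim = c(meas_grid$n_ax, meas_grid$n_lat,
                                  length(values) / grid_npix(meas_grid)))
  structure(list(values = values, meas_grid = meas_grid,
                 n_pairs = dim(values)[3]),
            class = "sos_displacements")
}

#' @export
print.sos_displacements <- function(x, ...) {
  cat(sprintf("<sos_displacements> %d pairs on %d x %d grid, rms %.3g s\n",
              x$n_pairs, x$meas_grid$n_ax, x$meas_grid$n_lat,
              sqrt(mean(x$values^2))))
  invisible(x)
}

# flatten to the pair-major vector matching forward-model row order
disp_as_vector <- function(d) as.numeric(d$values)

#' Apply the forward model
#'
#' Noise-free prediction `d = L x` of the displacement measurements for a
#' slowness-deviation map; linear in `x`.
#'
#' @param model an `sos_forward_model`.
#' @param x a [slowness_map()] (or a bare matrix of slowness deviation in s/mm)
#'   on the model's reconstruction grid.
#' @return An [displacement_set()] on the model's measurement grid.
#' @export
apply_forward <- function(model, x) {
  stopifnot(inherits(model, "sos_forward_model"))
  v <- if (inherits(x, "slowness_map")) {
    if (!same_grid(x$grid, model$recon_grid)) stop("slowness map grid does not match model recon_grid")
    as.numeric(x$values)
  } else {
    x <- as.matrix(x)
    if (nrow(x) != model$recon_grid$n_ax || ncol(x) != model$recon_grid$n_lat)
      stop("shape mismatch: expected ", model$recon_grid$n_ax, " x ", model$recon_grid$n_lat)
    as.numeric(x)
  }
  d <- as.numeric(model$L %*% v)
  displacement_set(d, model$meas_grid)
}
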