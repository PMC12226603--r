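#' Simulation configuration
#'
#' Conditions for the synthetic phantom and measurement generator: random
#' ellipse-deformation inclusions with sharp or smooth edges, slightly varying
#' background SoS, a fraction of inclusion-free samples, and anti-inverse-crime
#' measurement simulation on an upsampled grid with additive Gaussian noise.
#'
#' @param n_train,n_test record counts for [make_dataset()]. The scaled-down
#'   default is 500/32; the full-scale reference setting used 10000 ray-based
#'   training samples with the same 32-sample test split.
#' @param p_no_inclusion probability of an inclusion-free sample.
#' @param p_smooth probability that an inclusion boundary is low-pass filtered.
#' @param background_sos_range uniform background SoS range (m/s).
#' @param contrast_range range of the absolute inclusion-background SoS
#'   contrast (m/s); the sign is drawn symmetrically.
#' @param hr_factor integer upsampling factor (>= 2) of the simulation grid
#'   relative to the reconstruction grid, guarding against the inverse crime.
#' @param noise_std standard deviation of the additive Gaussian measurement
#'   noise (seconds). `NULL` (default) calibrates it so the displacement SNR is
#'   about 20 dB on a 40 m/s-contrast reference phantom (see
#'   [calibrate_noise_std()]).
#' @param smooth_sigma_mm Gaussian sigma of the edge low-pass filter (mm).
#' @param deform_sd relative amplitude of the random radial boundary
#'   deformation.
#' @param seed RNG seed.
#' @export
simulation_config <- function(n_train = 500, n_test = 32, p_no_inclusion = 0.05,
                              p_smooth = 0.5,
                              background_sos_range = c(1490, 1540),
                              contrast_range = c(10, 60), hr_factor = 2,
                              noise_std = NULL, smooth_sigma_mm = 1.5,
                              deform_sd = 0.15, seed = 1) {
  stopifnot(p_no_inclusion >= 0, p_no_inclusion <= 1, p_smooth >= 0, p_smooth <= 1,
            hr_factor >= 2, hr_factor == round(hr_factor),
            is.null(noise_std) || noise_std >= 0,
            length(background_sos_range) == 2, length(contrast_range) == 2,
            contrast_range[1] >= 0)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 p_no_inclusion = p_no_inclusion, p_smooth = p_smooth,
                 background_sos_range = background_sos_range,
                 contrast_range = contrast_range,
                 hr_factor = as.integer(hr_factor), noise_std = noise_std,
                 smooth_sigma_mm = smooth_sigma_mm, deform_sd = deform_sd,
                 seed = as.integer(seed)),
            class = "sos_sim_config")
}

# separable Gaussian blur with per-axis sigma in pixels (zero-padded)
gaussian_blur <- function(x, sigma_ax, sigma_lat) {
  g1 <- function(sig) {
    if (sig <= 0) return(matrix(1, 1, 1))
    r <- max(1L, ceiling(3 * sig))
    k <- exp(-((-r:r)^2) / (2 * sig^2))
    k / sum(k)
  }
  ka <- g1(sigma_ax); kl <- g1(sigma_lat)
  k2 <- as.numeric(ka) %o% as.numeric(kl)
  corr2_same(x, k2, floor((nrow(k2) - 1) / 2), floor((ncol(k2) - 1) / 2))
}

#' Sample a random phantom
#'
#' Draws a ground-truth SoS map on `grid`: with probability `p_no_inclusion`
#' the map is a constant background; otherwise one random ellipse (random
#' center, semi-axes, rotation) is warped by a smooth random radial
#' displacement field and, with probability `p_smooth`, its boundary low-pass
#' filtered into a smooth edge. Background SoS is uniform over the configured
#' range and the inclusion SoS is the background plus a signed contrast draw.
#'
#' @param cfg a [simulation_config()].
#' @param grid the (coarse) reconstruction [imaging_grid()].
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @param contrast optional fixed signed contrast (m/s), overriding the draw.
#' @param force_inclusion require an inclusion regardless of `p_no_inclusion`.
#' @return An object of class `sos_phantom` with `sos_map`, logical
#'   `inclusion_mask`, `smooth_edge`, `background_sos`, `contrast`.
#' @export
sample_phantom <- function(cfg, grid, seed = NULL, contrast = NULL,
                           force_inclusion = FALSE) {
  stopifnot(inherits(cfg, "sos_sim_config"), inherits(grid, "sos_grid"))
  if (!is.null(seed)) set.seed(seed)
  bg <- runif(1, cfg$background_sos_range[1], cfg$background_sos_range[2])
  no_inc <- !force_inclusion && (runif(1) < cfg$p_no_inclusion)
  if (no_inc) {
    return(structure(list(sos_map = sos_map(matrix(bg, grid$n_ax, grid$n_lat), grid),
                          inclusion_mask = matrix(FALSE, grid$n_ax, grid$n_lat),
                          smooth_edge = FALSE, background_sos = bg, contrast = 0),
                     class = "sos_phantom"))
  }
  if (is.null(contrast))
    contrast <- sample(c(-1, 1), 1) * runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
  smooth_edge <- runif(1) < cfg$p_smooth

  ext <- grid_extent(grid)
  za <- grid_axial_centers(grid) - grid$depth_offset
  xl <- grid_lateral_centers(grid)
  Z <- matrix(za, grid$n_ax, grid$n_lat)
  X <- matrix(xl, grid$n_ax, grid$n_lat, byrow = TRUE)
  for (try in 1:25) {
    cz <- runif(1, 0.28, 0.72) * ext["ax"]
    cx <- runif(1, 0.28, 0.72) * ext["lat"]
    ax_a <- runif(1, 0.08, 0.2) * min(ext)
    ax_b <- runif(1, 0.08, 0.2) * min(ext)
    rot <- runif(1, 0, pi)
    # smooth periodic radial deformation of the ellipse boundary
    n_ang <- 64
    raw <- rnorm(n_ang)
    kr <- exp(-((-8:8)^2) / (2 * 3^2)); kr <- kr / sum(kr)
    sm <- as.numeric(stats::filter(rep(raw, 3), kr, circular = TRUE))[(n_ang + 1):(2 * n_ang)]
    sm <- sm - mean(sm)
    if (sd(sm) > 0) sm <- sm * (cfg$deform_sd / sd(sm))
    rho <- pmax(1 + sm, 0.3)
    # elliptical coordinates of every pixel
    u <- (X - cx) * cos(rot) + (Z - cz) * sin(rot)
    v <- -(X - cx) * sin(rot) + (Z - cz) * cos(rot)
    re <- sqrt((u / ax_a)^2 + (v / ax_b)^2)
    phi <- atan2(v / ax_b, u / ax_a)            # in (-pi, pi]
    ai <- (phi + pi) / (2 * pi) * n_ang         # fractional angle bin
    i0 <- (floor(ai) %% n_ang) + 1
    i1 <- (i0 %% n_ang) + 1
    fr <- ai - floor(ai)
    rho_px <- (1 - fr) * rho[i0] + fr * rho[i1]
    inside <- matrix(re <= rho_px, grid$n_ax, grid$n_lat)
    if (sum(inside) >= 4) break
  }
  if (sum(inside) < 4) stop("failed to draw a non-degenerate inclusion")

  if (smooth_edge) {
    soft <- gaussian_blur(inside * 1, cfg$smooth_sigma_mm / grid$pitch_ax,
                          cfg$smooth_sigma_mm / grid$pitch_lat)
    sosv <- bg + contrast * soft
    mask <- soft > 0.5
  } else {
    sosv <- bg + contrast * (inside * 1)
    mask <- inside
  }
  structure(list(sos_map = sos_map(sosv, grid), inclusion_mask = mask,
                 smooth_edge = smooth_edge, background_sos = bg, contrast = contrast),
            class = "sos_phantom")
}

#' @export
print.sos_phantom <- function(x, ...) {
  cat(sprintf("<sos_phantom> background %.1f m/s, contrast %+.1f m/s, %d inclusion px (%s edge)\n",
              x$background_sos, x$contrast, sum(x$inclusion_mask),
              if (x$smooth_edge) "smooth" else "sharp"))
  invisible(x)
}

#' High-resolution grid for anti-inverse-crime simulation
#'
#' @param grid coarse [imaging_grid()].
#' @param hr_factor integer upsampling factor.
#' @export
upsample_grid <- function(grid, hr_factor) {
  imaging_grid(grid$n_ax * hr_factor, grid$n_lat * hr_factor,
               grid$pitch_ax / hr_factor, grid$pitch_lat / hr_factor,
               grid$depth_offset)
}

#' Calibrate the measurement noise level
#'
#' Returns the noise standard deviation giving a displacement SNR of
#' `snr_db` on a centered-disk reference phantom of the given contrast.
#'
#' @param model_hr high-resolution `sos_forward_model`.
#' @param contrast reference inclusion contrast (m/s).
#' @param snr_db target signal-to-noise ratio (dB, amplitude).
#' @export
calibrate_noise_std <- function(model_hr, contrast = 40, snr_db = 20) {
  g <- model_hr$recon_grid
  ext <- grid_extent(g)
  za <- grid_axial_centers(g) - g$depth_offset
  xl <- grid_lateral_centers(g)
  Z <- matrix(za, g$n_ax, g$n_lat)
  X <- matrix(xl, g$n_ax, g$n_lat, byrow = TRUE)
  disk <- (X - ext["lat"] / 2)^2 + (Z - ext["ax"] / 2)^2 <= (0.2 * min(ext))^2
  c0 <- model_hr$spec$c0
  x_ref <- sos_field_to_deviation(c0 + contrast * disk, c0)
  d_ref <- as.numeric(model_hr$L %*% as.numeric(x_ref))
  sqrt(mean(d_ref^2)) / 10^(snr_db / 20)
}

resolved_noise_std <- function(cfg, model_hr) {
  if (is.null(cfg$noise_std)) calibrate_noise_std(model_hr) else cfg$noise_std
}

# block-average a matrix by integer factor f per axis
block_average <- function(x, f) {
  n1 <- nrow(x) / f; n2 <- ncol(x) / f
  dim(x) <- c(f, n1, f, n2)
  out <- apply(x, c(2, 4), mean)
  matrix(out, n1, n2)
}

#' Simulate noisy displacement measurements
#'
#' Anti-inverse-crime measurement simulation: the slowness deviation is
#' upsampled to the fine grid, the high-resolution forward model applied,
#' i.i.d. Gaussian noise of `noise_std` added, and the fine measurements
#' block-averaged down to the coarse measurement grid. The coarse operator
#' used for reconstruction is never applied here.
#'
#' @param phantom an `sos_phantom` on the coarse grid.
#' @param model_hr `sos_forward_model` built on the `hr_factor`-upsampled grid.
#' @param cfg a [simulation_config()].
#' @param seed optional seed.
#' @param noise_std override of the configured noise level (seconds).
#' @return An [displacement_set()] on the coarse grid.
#' @export
simulate_measurements <- function(phantom, model_hr, cfg, seed = NULL,
                                  noise_std = NULL) {
  stopifnot(inherits(phantom, "sos_phantom"), inherits(model_hr, "sos_forward_model"))
  if (!is.null(seed)) set.seed(seed)
  f <- cfg$hr_factor
  g <- phantom$sos_map$grid
  ghr <- model_hr$recon_grid
  if (ghr$n_ax != g$n_ax * f || ghr$n_lat != g$n_lat * f || !same_fov(g, ghr))
    stop("model_hr grid is not the hr_factor-upsampled phantom grid")
  if (is.null(noise_std)) noise_std <- resolved_noise_std(cfg, model_hr)

  x <- sos_field_to_deviation(phantom$sos_map$values, model_hr$spec$c0)
  x_hr <- x[rep(seq_len(g$n_ax), each = f), rep(seq_len(g$n_lat), each = f)]
  d_hr <- as.numeric(model_hr$L %*% as.numeric(x_hr))
  d_hr <- d_hr + rnorm(length(d_hr), sd = noise_std)
  M <- nrow(model_hr$pairs)
  d_hr <- array(d_hr, dim = c(ghr$n_ax, ghr$n_lat, M))
  d <- array(0, dim = c(g$n_ax, g$n_lat, M))
  for (m in seq_len(M)) d[, , m] <- block_average(d_hr[, , m], f)
  displacement_set(d, imaging_grid(g$n_ax, g$n_lat, g$pitch_ax, g$pitch_lat, g$depth_offset))
}

#' Generate a training/test dataset
#'
#' Draws phantoms and simulates their noisy displacement measurements, split
#' into `train` and `test` records of (displacements, ground-truth SoS,
#' inclusion mask) triples.
#'
#' @param cfg a [simulation_config()].
#' @param spec an [acquisition_spec()].
#' @param recon_grid coarse reconstruction [imaging_grid()].
#' @param path optional path; when given the dataset container is written
#'   there (see [write_dataset()]).
#' @return An object of class `sos_dataset` with `train`, `test`, `spec`,
#'   `recon_grid`, `meas_grid`, `config`, `noise_std`, `seed`.
#' @export
make_dataset <- function(cfg, spec = acquisition_spec(), recon_grid, path = NULL) {
  stopifnot(inherits(cfg, "sos_sim_config"))
  set.seed(cfg$seed)
  model_hr <- build_forward_model(spec, upsample_grid(recon_grid, cfg$hr_factor))
  noise_std <- resolved_noise_std(cfg, model_hr)
  gen <- function(n) lapply(seq_len(n), function(i) {
    ph <- sample_phantom(cfg, recon_grid)
    d <- simulate_measurements(ph, model_hr, cfg, noise_std = noise_std)
    list(d = d$values, sos_gt = ph$sos_map$values, mask = ph$inclusion_mask,
         smooth_edge = ph$smooth_edge, background_sos = ph$background_sos,
         contrast = ph$contrast)
  })
  ds <- structure(list(train = gen(cfg$n_train), test = gen(cfg$n_test),
                       spec = spec, recon_grid = recon_grid, meas_grid = recon_grid,
                       config = cfg, noise_std = noise_std, seed = cfg$seed),
                  class = "sos_dataset")
  if (!is.null(path)) write_dataset(ds, path)
  ds
}

#' @export
print.sos_dataset <- function(x, ...) {
  cat(sprintf("<sos_dataset> %d train / %d test records, grid %d x %d, %d pairs, noise sd %.3g s\n",
              length(x$train), length(x$test), x$recon_grid$n_ax, x$recon_grid$n_lat,
              x$spec$n_transmits - x$spec$pair_offset, x$noise_std))
  invisible(x)
}

# smooth zero-mean random field on the measurement stack (motion surrogate)
lowfreq_offset_field <- function(meas_grid, n_pairs, rms) {
  if (rms <= 0) return(array(0, dim = c(meas_grid$n_ax, meas_grid$n_lat, n_pairs)))
  out <- array(0, dim = c(meas_grid$n_ax, meas_grid$n_lat, n_pairs))
  for (m in seq_len(n_pairs)) {
    w <- matrix(rnorm(grid_npix(meas_grid)), meas_grid$n_ax, meas_grid$n_lat)
    sm <- gaussian_blur(w, meas_grid$n_ax / 4, meas_grid$n_lat / 4)
    s <- sqrt(mean(sm^2))
    out[, , m] <- if (s > 0) sm * (rms / s) else sm
  }
  out
}

#' Generate a multi-frame lesion acquisition case
#'
#' One phantom imaged `n_frames` times with independent measurement noise.
#' A subset of frames is corrupted: their noise standard deviation is
#' multiplied by `corruption_scale` and a random low-frequency displacement
#' offset field (a surrogate for hand/body motion) of rms
#' `(corruption_scale - 1) * noise_std` is added, so `corruption_scale = 1`
#' leaves corrupted frames statistically identical to clean ones. The case is
#' labelled carcinoma-like (`"CA"`) when the absolute inclusion contrast
#' exceeds `label_threshold`, fibroadenoma-like (`"FA"`) otherwise.
#'
#' @param cfg a [simulation_config()].
#' @param spec an [acquisition_spec()].
#' @param recon_grid coarse [imaging_grid()].
#' @param n_frames number of repeated acquisitions (the clinical protocol
#'   images each lesion 3 to 5 times; default draws from 3:5).
#' @param n_corrupted how many frames to corrupt (0 <= n_corrupted < n_frames).
#' @param corruption_scale noise multiplier for corrupted frames.
#' @param label_threshold CA/FA contrast threshold (m/s).
#' @param contrast optional fixed signed contrast (m/s).
#' @param seed optional seed.
#' @param model_hr optional pre-built high-resolution model (rebuilt when
#'   omitted).
#' @return An object of class `sos_lesion_case`: `frames` (list of
#'   [displacement_set()]), `masks` (per-frame inclusion masks), `label`,
#'   `corrupted_frames` (indices), `phantom`.
#' @export
make_lesion_case <- function(cfg, spec = acquisition_spec(), recon_grid,
                             n_frames = NULL, n_corrupted = 1,
                             corruption_scale = 5, label_threshold = 35,
                             contrast = NULL, seed = NULL, model_hr = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_frames)) n_frames <- sample(3:5, 1)
  stopifnot(n_corrupted >= 0, n_corrupted < n_frames)
  if (is.null(model_hr))
    model_hr <- build_forward_model(spec, upsample_grid(recon_grid, cfg$hr_factor))
  noise_std <- resolved_noise_std(cfg, model_hr)
  ph <- sample_phantom(cfg, recon_grid, contrast = contrast, force_inclusion = TRUE)
  corrupted <- if (n_corrupted > 0) sort(sample.int(n_frames, n_corrupted)) else integer(0)
  frames <- lapply(seq_len(n_frames), function(i) {
    bad <- i %in% corrupted
    sdv <- if (bad) noise_std * corruption_scale else noise_std
    d <- simulate_measurements(ph, model_hr, cfg, noise_std = sdv)
    if (bad) {
      off <- lowfreq_offset_field(d$meas_grid, d$n_pairs,
                                  rms = (corruption_scale - 1) * noise_std)
      d$values <- d$values + off
    }
    d
  })
  structure(list(frames = frames,
                 masks = rep(list(ph$inclusion_mask), n_frames),
                 label = if (abs(ph$contrast) >= label_threshold) "CA" else "FA",
                 corrupted_frames = corrupted, phantom = ph,
                 noise_std = noise_std),
            class = "sos_lesion_case")
}

#' @export
print.sos_lesion_case <- function(x, ...) {
  cat(sprintf("<sos_lesion_case> %s, %d frames (%d corrupted), contrast %+.1f m/s\n",
              x$label, length(x$frames), length(x$corrupted_frames), x$phantom$contrast))
  invisible(x)
}
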