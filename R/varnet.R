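#' Training configuration for the variational network
#'
#' Holds both the unrolled-architecture hyperparameters and the optimization
#' settings. Defaults are the package's scaled-down training conditions; the
#' full-scale architecture of the reference setting (K = 10 layers, 16 priors
#' per layer, 8 x 8 kernels, 31 knots) is available by overriding `K`, `n_k`,
#' `o`, `n_knots`.
#'
#' @param iterations Adam iterations.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param tau exponential decay of the layer-weighted reconstruction loss:
#'   layer `k` of `K` is weighted `exp(-tau * (K - k))`.
#' @param lambda_r weight of the control-point second-difference smoothness
#'   penalty.
#' @param eps smoothing constant inside the second-difference square root.
#' @param alpha prior precision of the Gaussian filter prior (BVI).
#' @param beta weight of the KL term in the BVI loss.
#' @param dropout_p filter dropout probability during training (0 disables;
#'   set to the inference dropout rate when training a Monte Carlo dropout
#'   model).
#' @param K unroll depth.
#' @param n_k priors per layer.
#' @param o kernel size.
#' @param n_knots control points per penalty function.
#' @param seed RNG seed for initialization, batching, and any sampling.
#' @export
training_config <- function(iterations = 1500, batch_size = 8, lr = 2e-3,
                            tau = 0.5, lambda_r = 1e-3, eps = 1e-6,
                            alpha = 0.1, beta = 10, dropout_p = 0,
                            K = 5, n_k = 8, o = 5, n_knots = 21, seed = 1) {
  stopifnot(iterations >= 1, batch_size >= 1, lr > 0, tau >= 0, lambda_r >= 0,
            eps >= 0, alpha >= 0, beta >= 0, dropout_p >= 0, dropout_p < 1,
            K >= 1, n_k >= 1, o >= 1, n_knots >= 2)
  structure(list(iterations = as.integer(iterations), batch_size = as.integer(batch_size),
                 lr = lr, tau = tau, lambda_r = lambda_r, eps = eps,
                 alpha = alpha, beta = beta, dropout_p = dropout_p,
                 K = as.integer(K), n_k = as.integer(n_k), o = as.integer(o),
                 n_knots = as.integer(n_knots), seed = as.integer(seed)),
            class = "sos_training_config")
}

#' Construct one unrolled layer's parameters
#'
#' Mostly useful for tests and for configuring the network in closed form
#' (e.g. as a plain total-variation gradient-descent step).
#'
#' @param r filter kernels, array `o x o x n_k`.
#' @param w spatial prior weights, array `n_ax x n_lat x n_k`.
#' @param phi_y matrix `n_knots x n_k` of penalty-transform ordinates.
#' @param psi_y data penalty-transform ordinates (length `n_knots`).
#' @param s spatial data weights on the measurement grid (vectorized).
#' @param knots shared knot abscissae.
#' @param phi_scale per-prior response normalization.
#' @param psi_scale data response normalization.
#' @export
vn_layer <- function(r, w, phi_y, psi_y, s, knots,
                     phi_scale = rep(1, dim(r)[3]), psi_scale = 1) {
  r <- as.array(r); w <- as.array(w)
  stopifnot(length(dim(r)) == 3, length(dim(w)) == 3,
            dim(r)[3] == dim(w)[3], ncol(as.matrix(phi_y)) == dim(r)[3])
  o <- dim(r)[1]
  structure(list(r = r, w = w, phi_y = as.matrix(phi_y), psi_y = as.numeric(psi_y),
                 s = as.numeric(s), knots = knots, phi_scale = phi_scale,
                 psi_scale = psi_scale,
                 anchor = c(floor((o - 1) / 2), floor((dim(r)[2] - 1) / 2))),
            class = "sos_vn_layer")
}

#' Initialize variational-network parameters
#'
#' Filters start at small zero-mean random values, spatial weights at a small
#' constant, both penalty transforms at the identity, and the data weights at
#' `1/sigma_max(L)` (power-iteration estimate), so the initial network
#' approximates normalized gradient descent on the least-squares data term.
#'
#' @param model an `sos_forward_model`.
#' @param cfg a [training_config()].
#' @return An object of class `sos_vn_params`.
#' @export
vn_init <- function(model, cfg) {
  stopifnot(inherits(model, "sos_forward_model"), inherits(cfg, "sos_training_config"))
  set.seed(cfg$seed)
  n_ax <- model$recon_grid$n_ax; n_lat <- model$recon_grid$n_lat
  m_len <- nrow(model$L)
  knots <- seq(-1, 1, length.out = cfg$n_knots)
  s0 <- 1 / operator_norm(model$L)
  layers <- lapply(seq_len(cfg$K), function(k) {
    r <- array(rnorm(cfg$o^2 * cfg$n_k, sd = 0.01), dim = c(cfg$o, cfg$o, cfg$n_k))
    for (j in seq_len(cfg$n_k)) r[, , j] <- r[, , j] - mean(r[, , j])  # zero-mean at init
    vn_layer(r = r,
             w = array(0.1, dim = c(n_ax, n_lat, cfg$n_k)),
             phi_y = matrix(knots, cfg$n_knots, cfg$n_k),
             psi_y = knots,
             s = rep(s0, m_len),
             knots = knots)
  })
  structure(list(layers = layers, K = cfg$K, n_k = cfg$n_k, o = cfg$o,
                 n_knots = cfg$n_knots, knots = knots, x_scale = 1,
                 recon_grid = model$recon_grid, meas_grid = model$meas_grid,
                 c0 = model$spec$c0),
            class = "sos_vn_params")
}

#' @export
print.sos_vn_params <- function(x, ...) {
  cat(sprintf("<sos_vn_params> K = %d layers, %d priors/layer, %d x %d kernels, %d knots, x_scale = %.3g\n",
              x$K, x$n_k, x$o, x$o, x$n_knots, x$x_scale))
  invisible(x)
}

# largest singular value of sparse L by power iteration (deterministic start)
operator_norm <- function(L, iters = 30) {
  v <- rep(1, ncol(L)); v <- v / sqrt(sum(v^2))
  Lt <- Matrix::t(L)
  for (i in seq_len(iters)) {
    w <- as.numeric(Lt %*% (L %*% v))
    nv <- sqrt(sum(w^2))
    if (nv == 0) return(0)
    v <- w / nv
  }
  sqrt(sqrt(sum((as.numeric(Lt %*% (L %*% v)))^2)))
}

#' Field-of-experts regularizer gradient
#'
#' Computes `sum_j r_j^T * (w_j . phi_j(r_j * x))`: each prior filters the
#' image, passes the response through its learnable penalty transform, weights
#' it spatially, and back-projects with the transposed (flipped) kernel.
#' Boundary handling is zero padding at "same" output size.
#'
#' @param layer an [vn_layer()].
#' @param x image matrix (normalized slowness deviation).
#' @return Gradient map, same shape as `x`.
#' @export
regularizer_gradient <- function(layer, x) {
  stopifnot(inherits(layer, "sos_vn_layer"))
  x <- as.matrix(x)
  a <- layer$anchor
  kn <- layer$knots
  out <- foe_apply(x, layer$r, layer$r, layer$w, layer$phi_y,
                   kn[1], kn[2] - kn[1], layer$phi_scale,
                   dim(layer$r)[1], dim(layer$r)[2], dim(layer$r)[3],
                   a[1], a[2], FALSE)
  out$g_reg
}

# default (point-estimate) per-layer filter sets: analysis (r2) and synthesis
# (r1) sides share the layer filters
default_filters <- function(params) {
  lapply(params$layers, function(ly) list(r1 = ly$r, r2 = ly$r))
}

#' Unrolled variational-network forward pass
#'
#' Runs `K` unrolled gradient-descent updates
#' `x_k = x_{k-1} - [(s_k L)^T psi_k(s_k (L x_{k-1} - d)) + grad R(x_{k-1})]`
#' from `x_0 = 0`, with the regularization weight absorbed into the learnable
#' spatial weights. Internally the slowness deviation and the measurements are
#' expressed in units of `x_scale` (calibrated during training) so that all
#' learnable transforms operate in a normalized range.
#'
#' @param params an `sos_vn_params`.
#' @param d an [displacement_set()] (or measurement vector).
#' @param model the `sos_forward_model` used for reconstruction.
#' @param filters optional per-layer filter override, a list of `K` lists with
#'   elements `r1` (synthesis side) and `r2` (analysis side); used by the
#'   dropout and Bayesian posterior samplers.
#' @return A list with `x` (the reconstructed [slowness_map()]) and
#'   `trajectory` (all intermediates `x_1 .. x_K` in normalized units).
#' @export
vn_forward <- function(params, d, model, filters = NULL) {
  dvec <- if (inherits(d, "sos_displacements")) disp_as_vector(d) else as.numeric(d)
  if (length(dvec) != nrow(model$L)) stop("measurement length does not match the forward model")
  fw <- vn_forward_impl(params, dvec, model, filters = filters, cache = FALSE)
  list(x = slowness_map(fw$x * params$x_scale, params$recon_grid, params$c0),
       trajectory = fw$trajectory)
}

vn_forward_impl <- function(params, dvec, model, filters = NULL, cache = FALSE,
                            record_scales = FALSE) {
  n_ax <- params$recon_grid$n_ax; n_lat <- params$recon_grid$n_lat
  dt <- dvec / params$x_scale
  x <- matrix(0, n_ax, n_lat)
  K <- params$K; n_k <- params$n_k
  traj <- vector("list", K)
  caches <- if (cache) vector("list", K)
  scales <- if (record_scales)
    list(phi = matrix(0, n_k, K), psi = numeric(K), x_max = 0)
  for (k in seq_len(K)) {
    ly <- params$layers[[k]]
    a <- ly$anchor
    r1 <- if (is.null(filters)) ly$r else filters[[k]]$r1
    r2 <- if (is.null(filters)) ly$r else filters[[k]]$r2
    u <- spmv_csc(model$L@p, model$L@i, model$L@x, as.numeric(x), nrow(model$L)) - dt
    v <- ly$s * u
    vn <- v / ly$psi_scale
    psiv <- ly$psi_scale * pwl_eval(ly$knots, ly$psi_y, vn)
    av <- ly$s * psiv
    g_data <- matrix(spmv_csc(model$Lt@p, model$Lt@i, model$Lt@x, av, n_ax * n_lat),
                     n_ax, n_lat)
    kn <- ly$knots
    foe <- foe_apply(x, r1, r2, ly$w, ly$phi_y, kn[1], kn[2] - kn[1],
                     ly$phi_scale, dim(r1)[1], dim(r1)[2], n_k,
                     a[1], a[2], cache)
    g_reg <- foe$g_reg
    if (record_scales) {
      scales$phi[, k] <- pmax(scales$phi[, k], foe$fmax)
      scales$psi[k] <- max(scales$psi[k], max(abs(v)))
      scales$x_max <- max(scales$x_max, max(abs(x)))
    }
    x_new <- x - g_data - g_reg
    if (!all(is.finite(x_new)))
      stop("non-finite intermediate at layer ", k)
    if (cache)
      caches[[k]] <- list(x_in = x, u = u, v = v, vn = vn, psiv = psiv,
                          r1 = r1, r2 = r2, f = foe$f, p = foe$p, t = foe$t)
    x <- x_new
    traj[[k]] <- x
  }
  out <- list(x = x, trajectory = traj)
  if (cache) out$caches <- caches
  if (record_scales) out$scales <- scales
  out
}

#' Variational-network training loss
#'
#' The deterministic part of the training objective: an exponentially
#' layer-weighted L1 reconstruction loss over the unrolled trajectory plus a
#' smoothed second-difference penalty on all penalty-transform control points.
#'
#' @param trajectory list of intermediates from [vn_forward()] (normalized
#'   units).
#' @param x_star ground-truth slowness deviation ([slowness_map()] or matrix in
#'   s/mm).
#' @param params the `sos_vn_params` (for the control points and `x_scale`).
#' @param cfg a [training_config()] (uses `tau`, `lambda_r`, `eps`).
#' @return Scalar loss with attribute `components` (data, smoothness).
#' @export
vn_loss <- function(trajectory, x_star, params, cfg) {
  xs <- if (inherits(x_star, "slowness_map")) x_star$values else as.matrix(x_star)
  xt <- xs / params$x_scale
  K <- length(trajectory)
  data_loss <- 0
  for (k in seq_len(K))
    data_loss <- data_loss + exp(-cfg$tau * (K - k)) * sum(abs(trajectory[[k]] - xt))
  smooth <- 0
  for (ly in params$layers) {
    d2 <- diff(ly$phi_y, differences = 2)   # columnwise second differences
    smooth <- smooth + sum(sqrt(d2^2 + cfg$eps))
  }
  total <- data_loss + cfg$lambda_r * smooth
  attr(total, "components") <- c(data = data_loss, smooth = cfg$lambda_r * smooth)
  total
}

# gradient of the smoothed second-difference penalty w.r.t. one ordinate matrix
phi_smooth_grad <- function(phi_y, lambda_r, eps) {
  d2 <- diff(phi_y, differences = 2)
  wgt <- lambda_r * d2 / sqrt(d2^2 + eps)
  g <- matrix(0, nrow(phi_y), ncol(phi_y))
  n <- nrow(phi_y)
  if (n >= 3) {
    idx <- seq_len(n - 2)
    g[idx, ] <- g[idx, ] + wgt
    g[idx + 1, ] <- g[idx + 1, ] - 2 * wgt
    g[idx + 2, ] <- g[idx + 2, ] + wgt
  }
  g
}

# Reverse-mode gradients of the full training loss for one sample.
# fw: vn_forward_impl(..., cache = TRUE) output; xt: normalized ground truth.
# Returns per-layer grads (r1, r2, w, phi_y, psi_y, s); the smoothness-penalty
# gradient on phi_y is included.
vn_backward <- function(fw, params, xt, cfg, model) {
  K <- params$K; n_k <- params$n_k
  n_ax <- params$recon_grid$n_ax; n_lat <- params$recon_grid$n_lat
  grads <- vector("list", K)
  # cotangent on x_K from the layer-weighted L1 loss
  xhat <- sign(fw$trajectory[[K]] - xt)   # weight exp(0) = 1
  for (k in rev(seq_len(K))) {
    ly <- params$layers[[k]]
    a <- ly$anchor
    cc <- fw$caches[[k]]
    g <- list(r1 = array(0, dim = dim(ly$r)), r2 = array(0, dim = dim(ly$r)),
              w = array(0, dim = dim(ly$w)),
              phi_y = phi_smooth_grad(ly$phi_y, cfg$lambda_r, cfg$eps),
              psi_y = numeric(params$n_knots), s = numeric(length(ly$s)))
    # x_new = x_in - g_data - g_reg ; cotangent on both terms is -xhat
    dx <- xhat
    # data-term path: g_data = L^T (s * psi(s*u/psi_scale_adj)) with u = L x - d
    ahat <- spmv_csc(model$L@p, model$L@i, model$L@x, as.numeric(-xhat),
                     nrow(model$L))                       # cotangent on av
    g$s <- g$s + cc$psiv * ahat
    dpsiv <- ly$s * ahat
    g$psi_y <- g$psi_y + ly$psi_scale * pwl_ygrad(ly$knots, cc$vn, dpsiv)
    dv <- pwl_slope(ly$knots, ly$psi_y, cc$vn) * dpsiv
    g$s <- g$s + cc$u * dv
    du <- ly$s * dv
    dx <- dx + matrix(spmv_csc(model$Lt@p, model$Lt@i, model$Lt@x, du, n_ax * n_lat),
                      n_ax, n_lat)
    # regularizer path (all priors fused; cotangent on each g_j is -xhat)
    kn <- ly$knots
    fb <- foe_backward(-xhat, cc$x_in, cc$r1, cc$r2, ly$w, ly$phi_y,
                       kn[1], kn[2] - kn[1], ly$phi_scale,
                       cc$f, cc$p, cc$t,
                       dim(ly$r)[1], dim(ly$r)[2], n_k, a[1], a[2])
    g$r1 <- g$r1 + array(fb$dr1, dim = dim(ly$r))
    g$r2 <- g$r2 + array(fb$dr2, dim = dim(ly$r))
    g$w <- g$w + array(fb$dw, dim = dim(ly$w))
    g$phi_y <- g$phi_y + fb$dphi
    dx <- dx + fb$dx
    grads[[k]] <- g
    # cotangent on x_{k-1}: the pass-through plus its own loss term
    if (k > 1) {
      xhat <- dx + exp(-cfg$tau * (K - (k - 1))) * sign(fw$trajectory[[k - 1]] - xt)
    }
  }
  grads
}

# ---- parameter flattening utilities (for Adam) ------------------------------

flatten_arrays <- function(lst) {
  unlist(lapply(lst, as.numeric), use.names = FALSE)
}

unflatten_arrays <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  for (i in seq_along(skeleton)) {
    n <- length(skeleton[[i]])
    out[[i]] <- vec[(pos + 1L):(pos + n)]
    if (!is.null(dim(skeleton[[i]]))) dim(out[[i]]) <- dim(skeleton[[i]])
    pos <- pos + n
  }
  out
}

vn_trainable <- function(params) {
  out <- list()
  for (k in seq_len(params$K)) {
    ly <- params$layers[[k]]
    out[[paste0("r.", k)]] <- ly$r
    out[[paste0("w.", k)]] <- ly$w
    out[[paste0("phi.", k)]] <- ly$phi_y
    out[[paste0("psi.", k)]] <- ly$psi_y
    out[[paste0("s.", k)]] <- ly$s
  }
  out
}

vn_set_trainable <- function(params, lst) {
  for (k in seq_len(params$K)) {
    params$layers[[k]]$r <- lst[[paste0("r.", k)]]
    params$layers[[k]]$w <- lst[[paste0("w.", k)]]
    params$layers[[k]]$phi_y <- lst[[paste0("phi.", k)]]
    params$layers[[k]]$psi_y <- lst[[paste0("psi.", k)]]
    params$layers[[k]]$s <- lst[[paste0("s.", k)]]
  }
  params
}

# grads list (per layer r1/r2/w/phi_y/psi_y/s) -> same layout as vn_trainable
vn_grads_to_trainable <- function(grads) {
  out <- list()
  for (k in seq_along(grads)) {
    g <- grads[[k]]
    out[[paste0("r.", k)]] <- g$r1 + g$r2
    out[[paste0("w.", k)]] <- g$w
    out[[paste0("phi.", k)]] <- g$phi_y
    out[[paste0("psi.", k)]] <- g$psi_y
    out[[paste0("s.", k)]] <- g$s
  }
  out
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, g, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

# ---- calibration and training ----------------------------------------------

# Fix the normalization constants from a calibration batch: x_scale from the
# ground-truth slowness deviations, response scales from one recorded forward
# pass per sample. Fixed once before training, never revisited.
vn_calibrate <- function(params, records, model) {
  # internal unit: one m/s of SoS deviation around c0 (so the L1 data loss is
  # commensurate with m/s reconstruction error, the scale the KL weights
  # alpha/beta are balanced against)
  params$x_scale <- 1 / (params$c0^2 * 1e3)
  phi_sc <- matrix(0, params$n_k, params$K)
  psi_sc <- numeric(params$K)
  for (rec in records) {
    fw <- vn_forward_impl(params, as.numeric(rec$d), model, record_scales = TRUE)
    phi_sc <- pmax(phi_sc, fw$scales$phi)
    psi_sc <- pmax(psi_sc, fw$scales$psi)
  }
  for (k in seq_len(params$K)) {
    params$layers[[k]]$phi_scale <- pmax(phi_sc[, k], 1e-12)
    params$layers[[k]]$psi_scale <- max(psi_sc[k], 1e-12)
  }
  params
}

draw_dropout_filters <- function(params, p) {
  lapply(params$layers, function(ly) {
    n_k <- dim(ly$r)[3]
    m1 <- rbinom(n_k, 1, 1 - p)
    m2 <- rbinom(n_k, 1, 1 - p)
    r1 <- ly$r; r2 <- ly$r
    for (j in seq_len(n_k)) { r1[, , j] <- r1[, , j] * m1[j]; r2[, , j] <- r2[, , j] * m2[j] }
    list(r1 = r1, r2 = r2, m1 = m1, m2 = m2)
  })
}

#' Train the variational network
#'
#' Mini-batch Adam on the layer-weighted L1 reconstruction loss plus the
#' control-point smoothness penalty, with gradients from the package's
#' reverse-mode differentiation of the unrolled computation. When
#' `cfg$dropout_p > 0`, independent per-filter Bernoulli masks are drawn per
#' sample and side during training (the Monte Carlo dropout regime).
#'
#' @param dataset a dataset from [make_dataset()] (uses its `train` split and
#'   geometry).
#' @param cfg a [training_config()].
#' @param model optional pre-built coarse `sos_forward_model`; rebuilt from the
#'   dataset geometry when omitted.
#' @return An `sos_vn_params` with attributes `loss_history` (per-iteration
#'   running loss) and `config`.
#' @export
train_vn <- function(dataset, cfg, model = NULL) {
  stopifnot(inherits(cfg, "sos_training_config"))
  if (is.null(model))
    model <- build_forward_model(dataset$spec, dataset$recon_grid, dataset$meas_grid)
  records <- dataset$train
  if (length(records) == 0) stop("dataset has no training records")
  set.seed(cfg$seed)
  params <- vn_init(model, cfg)
  params <- vn_calibrate(params, records[seq_len(min(cfg$batch_size, length(records)))], model)

  sk <- vn_trainable(params)
  theta <- flatten_arrays(sk)
  st <- adam_init(length(theta))
  loss_hist <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    idx <- sample.int(length(records), min(cfg$batch_size, length(records)))
    gacc <- numeric(length(theta))
    lacc <- 0
    for (i in idx) {
      rec <- records[[i]]
      xt <- sos_field_to_deviation(rec$sos_gt, params$c0) / params$x_scale
      filters <- if (cfg$dropout_p > 0) draw_dropout_filters(params, cfg$dropout_p)
      fw <- vn_forward_impl(params, as.numeric(rec$d), model, filters = filters, cache = TRUE)
      loss <- vn_loss(fw$trajectory, xt * params$x_scale, params, cfg)
      grads <- vn_backward(fw, params, xt, cfg, model)
      if (cfg$dropout_p > 0) {
        for (k in seq_len(params$K)) {
          msk <- filters[[k]]
          for (j in seq_len(params$n_k)) {
            grads[[k]]$r1[, , j] <- grads[[k]]$r1[, , j] * msk$m1[j]
            grads[[k]]$r2[, , j] <- grads[[k]]$r2[, , j] * msk$m2[j]
          }
        }
      }
      gacc <- gacc + flatten_arrays(vn_grads_to_trainable(grads))
      lacc <- lacc + as.numeric(loss)
    }
    gacc <- gacc / length(idx)
    lacc <- lacc / length(idx)
    if (!is.finite(lacc)) stop("training diverged (non-finite loss) at iteration ", it)
    st <- adam_step(st, gacc, cfg$lr)
    theta <- theta + st$delta
    params <- vn_set_trainable(params, unflatten_arrays(theta, sk))
    loss_hist[it] <- lacc
  }
  attr(params, "loss_history") <- loss_hist
  attr(params, "config") <- cfg
  params
}
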