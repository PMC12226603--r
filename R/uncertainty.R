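#' Monte Carlo dropout configuration
#'
#' @param p dropout probability in `[0, 1)`; the probability of a prior
#'   component remaining active is `1 - p`.
#' @param granularity `"per-filter"` (a dropped filter zeroes its whole prior
#'   term on that side, the default, matching filter-level removal) or
#'   `"per-element"` (independent Bernoulli mask per kernel coefficient).
#' @param n_samples posterior sample count S.
#' @param seed RNG seed.
#' @export
mcd_config <- function(p = 0.25, granularity = c("per-filter", "per-element"),
                       n_samples = 100, seed = 1) {
  granularity <- match.arg(granularity)
  stopifnot(p >= 0, p < 1, n_samples >= 2)
  structure(list(p = p, granularity = granularity,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "sos_mcd_config")
}

# independent Bernoulli masks on both convolution sides of every layer
draw_mcd_filters <- function(params, cfg) {
  lapply(params$layers, function(ly) {
    n_k <- dim(ly$r)[3]; o1 <- dim(ly$r)[1]; o2 <- dim(ly$r)[2]
    if (cfg$granularity == "per-filter") {
      m1 <- rbinom(n_k, 1, 1 - cfg$p)
      m2 <- rbinom(n_k, 1, 1 - cfg$p)
      r1 <- ly$r; r2 <- ly$r
      for (j in seq_len(n_k)) { r1[, , j] <- r1[, , j] * m1[j]; r2[, , j] <- r2[, , j] * m2[j] }
    } else {
      m1 <- array(rbinom(o1 * o2 * n_k, 1, 1 - cfg$p), dim = dim(ly$r))
      m2 <- array(rbinom(o1 * o2 * n_k, 1, 1 - cfg$p), dim = dim(ly$r))
      r1 <- ly$r * m1; r2 <- ly$r * m2
    }
    list(r1 = r1, r2 = r2, m1 = m1, m2 = m2)
  })
}

#' Draw one Monte Carlo dropout reconstruction
#'
#' Samples independent Bernoulli masks with keep probability `1 - p` for the
#' analysis- and synthesis-side filters of every layer (independently per
#' side) and runs the variational network with the masked filters. No
#' `1/(1-p)` rescaling is applied to surviving filters.
#'
#' @param params trained `sos_vn_params`.
#' @param d an [displacement_set()].
#' @param model the `sos_forward_model`.
#' @param cfg an [mcd_config()].
#' @param seed optional seed (`NULL`: current RNG state).
#' @return One sampled [slowness_map()].
#' @export
mcd_sample <- function(params, d, model, cfg = mcd_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  filters <- draw_mcd_filters(params, cfg)
  vn_forward(params, d, model, filters = filters)$x
}

#' Gaussian filter posterior with block-diagonal Cholesky factor
#'
#' The BVI posterior over all `t = K * n_k * o^2` filter coefficients:
#' a multivariate Gaussian `N(mu, Sigma)` with `Sigma = D D^T`, where `D` is
#' lower-triangular with strictly positive diagonal and block-diagonal with
#' one `o^2 x o^2` block per filter (filters mutually uncorrelated). Block
#' `b = (k-1) * n_k + j` corresponds to filter `j` of layer `k`, its
#' coefficients in column-major kernel order.
#'
#' @param mu mean vector (length t).
#' @param D array `(o^2, o^2, n_blocks)` of lower-triangular blocks.
#' @param o kernel size.
#' @param n_k priors per layer.
#' @param K layers.
#' @param alpha prior precision of the isotropic Gaussian prior.
#' @export
bvi_posterior <- function(mu, D, o, n_k, K, alpha = 0.1) {
  o2 <- o^2; B <- n_k * K
  stopifnot(length(mu) == o2 * B, all(dim(D) == c(o2, o2, B)), alpha >= 0)
  for (b in seq_len(B)) {
    Db <- D[, , b]
    if (any(Db[upper.tri(Db)] != 0)) stop("D blocks must be lower triangular")
  }
  if (any(apply(D, 3, function(m) any(diag(m) <= 0))))
    stop("D must have strictly positive diagonal")
  structure(list(mu = as.numeric(mu), D = D, o = as.integer(o),
                 n_k = as.integer(n_k), K = as.integer(K), alpha = alpha),
            class = "sos_bvi_posterior")
}

#' @export
print.sos_bvi_posterior <- function(x, ...) {
  cat(sprintf("<sos_bvi_posterior> t = %d coefficients, %d blocks of %d x %d, alpha = %g\n",
              length(x$mu), dim(x$D)[3], dim(x$D)[1], dim(x$D)[2], x$alpha))
  invisible(x)
}

bvi_init_posterior <- function(cfg) {
  o2 <- cfg$o^2; B <- cfg$n_k * cfg$K
  mu <- rnorm(o2 * B, sd = 1e-2)
  D <- array(0, dim = c(o2, o2, B))
  for (b in seq_len(B)) diag(D[, , b]) <- runif(o2, 0.9, 1.1)
  bvi_posterior(mu, D, cfg$o, cfg$n_k, cfg$K, cfg$alpha)
}

#' Sample filter coefficients from the BVI posterior
#'
#' Draws `mu + D y` with `y ~ N(0, I)`, exploiting the block structure.
#'
#' @param post an [bvi_posterior()].
#' @param n number of draws.
#' @param seed optional seed.
#' @return A `t x n` matrix of coefficient draws, with the standard-normal
#'   draws attached as attribute `y`.
#' @export
bvi_sample_coefficients <- function(post, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  o2 <- dim(post$D)[1]; B <- dim(post$D)[3]
  y <- matrix(rnorm(o2 * B * n), o2 * B, n)
  out <- matrix(post$mu, o2 * B, n)
  for (b in seq_len(B)) {
    idx <- (b - 1) * o2 + seq_len(o2)
    out[idx, ] <- out[idx, ] + post$D[, , b] %*% y[idx, , drop = FALSE]
  }
  attr(out, "y") <- y
  out
}

# coefficient vector -> per-layer filter arrays (r1 = r2 = sample)
coeffs_to_filters <- function(coeffs, post) {
  o <- post$o; o2 <- o^2; n_k <- post$n_k
  lapply(seq_len(post$K), function(k) {
    r <- array(0, dim = c(o, o, n_k))
    for (j in seq_len(n_k)) {
      b <- (k - 1) * n_k + j
      r[, , j] <- matrix(coeffs[(b - 1) * o2 + seq_len(o2)], o, o)
    }
    list(r1 = r, r2 = r)
  })
}

#' Draw one sampled filter set from the BVI posterior
#'
#' @param post an [bvi_posterior()].
#' @param seed optional seed.
#' @return A per-layer list of filter arrays (`r1`/`r2`, both the same draw),
#'   suitable for the `filters` argument of [vn_forward()]; the underlying
#'   standard-normal draw is attached as attribute `y`.
#' @export
bvi_sample_filters <- function(post, seed = NULL) {
  cf <- bvi_sample_coefficients(post, 1, seed)
  out <- coeffs_to_filters(cf[, 1], post)
  attr(out, "y") <- attr(cf, "y")[, 1]
  out
}

#' KL regularizer of the BVI posterior
#'
#' `alpha * tr(D D^T) - 2 * sum_i log(D_ii)`: the KL divergence of the filter
#' posterior from the isotropic Gaussian prior (constants dropped), with the
#' log-determinant computed from the Cholesky diagonal -- no covariance matrix
#' or determinant is ever formed.
#'
#' @param post an [bvi_posterior()].
#' @return Scalar KL term.
#' @export
kl_term <- function(post) {
  dg <- apply(post$D, 3, diag)
  if (any(dg <= 0)) stop("domain error: D must have strictly positive diagonal")
  post$alpha * sum(post$D^2) - 2 * sum(log(dg))
}

#' Train the Bayesian variational inference model
#'
#' Optimizes the layer-weighted L1 reconstruction loss plus the control-point
#' smoothness penalty plus `beta` times the KL term, drawing one
#' reparameterized filter sample `mu + D y` per forward pass. The posterior
#' mean is initialized from N(0, 1e-4) and the factor diagonal uniformly in
#' (0.9, 1.1); positivity of `diag(D)` is maintained by optimizing its
#' logarithm. Non-filter parameters (w, phi, psi, s) are trained as point
#' estimates.
#'
#' @param dataset an `sos_dataset`.
#' @param init optional `sos_vn_params` providing architecture and non-filter
#'   initialization; created via [vn_init()] when `NULL`.
#' @param cfg a [training_config()] (uses `alpha`, `beta` for the KL).
#' @param model optional pre-built coarse model.
#' @return An object of class `sos_bvi_fit`: `posterior`
#'   ([bvi_posterior()]), `params` (`sos_vn_params` whose layer filters hold
#'   the posterior mean), and attribute `loss_history`.
#' @export
train_bvi <- function(dataset, init = NULL, cfg = training_config(), model = NULL) {
  stopifnot(inherits(cfg, "sos_training_config"))
  if (is.null(model))
    model <- build_forward_model(dataset$spec, dataset$recon_grid, dataset$meas_grid)
  records <- dataset$train
  if (length(records) == 0) stop("dataset has no training records")
  set.seed(cfg$seed)
  params <- if (is.null(init)) vn_init(model, cfg) else init
  post <- bvi_init_posterior(cfg)
  # response scales must be calibrated under the filter-sampling regime the
  # network trains in, not with the (tiny) point-estimate init filters
  cal <- params
  calf <- coeffs_to_filters(bvi_sample_coefficients(post, 1)[, 1], post)
  for (k in seq_len(cal$K)) cal$layers[[k]]$r <- calf[[k]]$r1
  cal <- vn_calibrate(cal, records[seq_len(min(cfg$batch_size, length(records)))], model)
  params$x_scale <- cal$x_scale
  for (k in seq_len(params$K)) {
    params$layers[[k]]$phi_scale <- cal$layers[[k]]$phi_scale
    params$layers[[k]]$psi_scale <- cal$layers[[k]]$psi_scale
  }
  o2 <- cfg$o^2; B <- cfg$n_k * cfg$K
  low_mask <- lower.tri(matrix(0, o2, o2))

  # trainable layout: non-filter VN params, mu, off-diagonal D, log-diagonal D
  sk <- vn_trainable(params)
  sk <- sk[!grepl("^r\\.", names(sk))]
  offdiag <- array(0, dim = c(sum(low_mask), B))
  ell <- log(apply(post$D, 3, diag))                      # o2 x B
  theta <- c(flatten_arrays(sk), post$mu, as.numeric(offdiag), as.numeric(ell))
  n_nf <- length(flatten_arrays(sk)); t_tot <- o2 * B
  st <- adam_init(length(theta))
  loss_hist <- numeric(cfg$iterations)

  unpack <- function(theta) {
    nf <- unflatten_arrays(theta[seq_len(n_nf)], sk)
    mu <- theta[n_nf + seq_len(t_tot)]
    od <- matrix(theta[n_nf + t_tot + seq_len(sum(low_mask) * B)], sum(low_mask), B)
    el <- matrix(theta[n_nf + t_tot + sum(low_mask) * B + seq_len(o2 * B)], o2, B)
    D <- array(0, dim = c(o2, o2, B))
    for (b in seq_len(B)) {
      Db <- matrix(0, o2, o2)
      Db[low_mask] <- od[, b]
      diag(Db) <- exp(el[, b])
      D[, , b] <- Db
    }
    list(nf = nf, mu = mu, D = D, el = el)
  }

  for (it in seq_len(cfg$iterations)) {
    up <- unpack(theta)
    params <- vn_set_nonfilter(params, up$nf)
    post$mu <- up$mu; post$D <- up$D
    idx <- sample.int(length(records), min(cfg$batch_size, length(records)))
    g_nf <- numeric(n_nf); g_mu <- numeric(t_tot)
    g_od <- matrix(0, sum(low_mask), B); g_el <- matrix(0, o2, B)
    lacc <- 0
    for (i in idx) {
      rec <- records[[i]]
      xt <- sos_field_to_deviation(rec$sos_gt, params$c0) / params$x_scale
      cf <- bvi_sample_coefficients(post, 1)
      yv <- attr(cf, "y")[, 1]
      filters <- coeffs_to_filters(cf[, 1], post)
      fw <- vn_forward_impl(params, as.numeric(rec$d), model, filters = filters, cache = TRUE)
      loss <- vn_loss(fw$trajectory, xt * params$x_scale, params, cfg)
      grads <- vn_backward(fw, params, xt, cfg, model)
      gt <- vn_grads_to_trainable(grads)
      g_nf <- g_nf + flatten_arrays(gt[!grepl("^r\\.", names(gt))])
      # filter gradients chain into (mu, D) via r = mu + D y
      dr <- numeric(t_tot)
      for (k in seq_len(cfg$K)) {
        for (j in seq_len(cfg$n_k)) {
          b <- (k - 1) * cfg$n_k + j
          dr[(b - 1) * o2 + seq_len(o2)] <- as.numeric(gt[[paste0("r.", k)]][, , j])
        }
      }
      g_mu <- g_mu + dr
      for (b in seq_len(B)) {
        ib <- (b - 1) * o2 + seq_len(o2)
        dDb <- outer(dr[ib], yv[ib])
        g_od[, b] <- g_od[, b] + dDb[low_mask]
        g_el[, b] <- g_el[, b] + diag(dDb) * exp(up$el[, b])
      }
      lacc <- lacc + as.numeric(loss)
    }
    # the data term is summed over the mini-batch and the KL enters once per
    # batch objective, so the filter-posterior regularization does not grow
    # with the batch size
    # KL gradients (once per objective evaluation)
    kl <- kl_term(post)
    for (b in seq_len(B)) {
      Db <- post$D[, , b]
      gK <- cfg$beta * 2 * post$alpha * Db
      g_od[, b] <- g_od[, b] + gK[low_mask]
      g_el[, b] <- g_el[, b] + (diag(gK) - 2 * cfg$beta / diag(Db)) * diag(Db)
    }
    lacc <- lacc + cfg$beta * kl
    if (!is.finite(lacc)) stop("BVI training diverged (non-finite loss) at iteration ", it)
    g_all <- c(g_nf, g_mu, as.numeric(g_od), as.numeric(g_el))
    st <- adam_step(st, g_all, cfg$lr)
    theta <- theta + st$delta
    loss_hist[it] <- lacc
  }
  up <- unpack(theta)
  params <- vn_set_nonfilter(params, up$nf)
  post$mu <- up$mu; post$D <- up$D
  # store the posterior mean as the point-estimate filters for convenience
  mf <- coeffs_to_filters(post$mu, post)
  for (k in seq_len(params$K)) params$layers[[k]]$r <- mf[[k]]$r1
  out <- structure(list(posterior = post, params = params), class = "sos_bvi_fit")
  attr(out, "loss_history") <- loss_hist
  attr(out, "config") <- cfg
  out
}

vn_set_nonfilter <- function(params, lst) {
  for (k in seq_len(params$K)) {
    params$layers[[k]]$w <- lst[[paste0("w.", k)]]
    params$layers[[k]]$phi_y <- lst[[paste0("phi.", k)]]
    params$layers[[k]]$psi_y <- lst[[paste0("psi.", k)]]
    params$layers[[k]]$s <- lst[[paste0("s.", k)]]
  }
  params
}

#' @export
print.sos_bvi_fit <- function(x, ...) {
  cat("<sos_bvi_fit>\n"); print(x$posterior); print(x$params)
  invisible(x)
}

#' Summarize posterior samples into mean and uncertainty maps
#'
#' Per-pixel sample mean (the SoS reconstruction) and sample standard
#' deviation with `ddof = 1` (the uncertainty estimate).
#'
#' @param samples a list of `sos_map`s (or a 3D array stacked over draws).
#' @return An object of class `sos_posterior_summary`: `mean_sos`
#'   ([sos_map()]), `std_map` (matrix, m/s), `n_samples`.
#' @export
posterior_summarize <- function(samples) {
  if (is.list(samples)) {
    if (length(samples) < 2) stop("at least 2 posterior samples are required")
    grid <- samples[[1]]$grid
    arr <- vapply(samples, function(s) {
      if (!same_grid(s$grid, grid)) stop("posterior samples must share a common grid")
      s$values
    }, matrix(0, grid$n_ax, grid$n_lat))
  } else {
    arr <- samples
    if (length(dim(arr)) != 3 || dim(arr)[3] < 2)
      stop("at least 2 posterior samples are required")
    grid <- imaging_grid(dim(arr)[1], dim(arr)[2])
  }
  S <- dim(arr)[3]
  npix <- dim(arr)[1] * dim(arr)[2]
  flat <- matrix(arr, npix, S)
  m <- rowMeans(flat)
  sdv <- sqrt(rowSums((flat - m)^2) / (S - 1))
  dim(m) <- dim(sdv) <- dim(arr)[1:2]
  structure(list(mean_sos = sos_map(m, grid), std_map = sdv, n_samples = S),
            class = "sos_posterior_summary")
}

#' @export
print.sos_posterior_summary <- function(x, ...) {
  cat(sprintf("<sos_posterior_summary> S = %d, mean SoS [%.1f, %.1f] m/s, std [%.2f, %.2f] m/s\n",
              x$n_samples, min(x$mean_sos$values), max(x$mean_sos$values),
              min(x$std_map), max(x$std_map)))
  invisible(x)
}

#' Sample the reconstruction posterior of a trained model
#'
#' Draws S stochastic reconstructions (Monte Carlo dropout masks or BVI filter
#' samples), converts each to SoS, and summarizes them into mean and
#' uncertainty maps.
#'
#' @param fit a trained `sos_vn_params` (for `method = "mcd"`) or
#'   `sos_bvi_fit` (for `method = "bvi"`).
#' @param d an [displacement_set()].
#' @param model the `sos_forward_model`.
#' @param method `"mcd"` or `"bvi"`.
#' @param n_samples posterior sample count (default 100).
#' @param mcd an [mcd_config()] (dropout rate / granularity for MCD).
#' @param seed RNG seed.
#' @param keep_samples attach the full sample stack as attribute `samples`.
#' @return An `sos_posterior_summary`.
#' @export
sample_posterior <- function(fit, d, model, method = c("mcd", "bvi"),
                             n_samples = 100, mcd = mcd_config(), seed = 1,
                             keep_samples = FALSE) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_samples >= 2)
  draws <- vector("list", n_samples)
  if (method == "mcd") {
    stopifnot(inherits(fit, "sos_vn_params"))
    for (s in seq_len(n_samples))
      draws[[s]] <- slowness_to_sos(mcd_sample(fit, d, model, mcd))
  } else {
    stopifnot(inherits(fit, "sos_bvi_fit"))
    for (s in seq_len(n_samples)) {
      filters <- bvi_sample_filters(fit$posterior)
      draws[[s]] <- slowness_to_sos(vn_forward(fit$params, d, model, filters = filters)$x)
    }
  }
  out <- posterior_summarize(draws)
  if (keep_samples) attr(out, "samples") <- draws
  out
}
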