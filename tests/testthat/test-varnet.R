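corr_anchor <- function(o) floor((o - 1) / 2)

test_that("convolution primitives match a naive dense oracle and satisfy the adjoint identity", {
  set.seed(5)
  for (o in c(2, 3, 5)) {
    x <- matrix(rnorm(6 * 7), 6, 7)
    k <- matrix(rnorm(o * o), o, o)
    a <- corr_anchor(o)
    expect_equal(sosvn:::corr2_same(x, k, a, a), naive_corr2(x, k, a, a),
                 tolerance = 1e-12)
    # adjoint identity <r * a, b> = <a, r^T * b>
    b <- matrix(rnorm(6 * 7), 6, 7)
    lhs <- sum(sosvn:::corr2_same(x, k, a, a) * b)
    rhs <- sum(x * sosvn:::corr2_same_adj(b, k, a, a))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("regularizer gradient: annihilation, additivity, and analytic TV gradient", {
  set.seed(9)
  n_knots <- 9
  knots <- seq(-1, 1, length.out = n_knots)
  x <- matrix(rnorm(36, sd = 0.05), 6, 6)

  # lateral finite-difference kernel, identity transform, unit weights:
  # the result is the analytic gradient of 0.5 * ||r * x||^2
  r <- array(0, c(3, 3, 1)); r[2, 2, 1] <- -1; r[2, 3, 1] <- 1
  ly <- vn_layer(r, array(1, c(6, 6, 1)), matrix(knots, n_knots, 1), knots,
                 s = 1, knots = knots)
  g <- regularizer_gradient(ly, x)
  obj <- function(xv) {
    xm <- matrix(xv, 6, 6)
    0.5 * sum(naive_corr2(xm, r[, , 1], 1, 1)^2)
  }
  expect_equal(as.numeric(g), fd_grad(obj, as.numeric(x)), tolerance = 1e-5)

  # all weights zero annihilate the gradient
  ly0 <- vn_layer(r, array(0, c(6, 6, 1)), matrix(knots, n_knots, 1), knots,
                  s = 1, knots = knots)
  expect_equal(regularizer_gradient(ly0, x), matrix(0, 6, 6))

  # two priors act additively
  r2 <- array(rnorm(18, sd = 0.3), c(3, 3, 2))
  w2 <- array(runif(72), c(6, 6, 2))
  p2 <- matrix(rnorm(n_knots * 2, sd = 0.4), n_knots, 2)
  ly12 <- vn_layer(r2, w2, p2, knots, s = 1, knots = knots)
  lyA <- vn_layer(r2[, , 1, drop = FALSE], w2[, , 1, drop = FALSE],
                  p2[, 1, drop = FALSE], knots, s = 1, knots = knots)
  lyB <- vn_layer(r2[, , 2, drop = FALSE], w2[, , 2, drop = FALSE],
                  p2[, 2, drop = FALSE], knots, s = 1, knots = knots)
  expect_equal(regularizer_gradient(ly12, x),
               regularizer_gradient(lyA, x) + regularizer_gradient(lyB, x),
               tolerance = 1e-12)
})

test_that("null update and single-layer closed forms of the unrolled network", {
  fx <- fixture_tiny()
  model <- fx$model
  cfg <- training_config(K = 2, n_k = 2, o = 3, n_knots = 7, seed = 3)
  params <- vn_init(model, cfg)

  # psi = 0 and w = 0: nothing moves
  for (k in seq_len(params$K)) {
    params$layers[[k]]$psi_y <- rep(0, 7)
    params$layers[[k]]$w[] <- 0
  }
  d <- rnorm(nrow(model$L), sd = 0.1)
  out <- vn_forward(params, d, model)
  expect_equal(out$x$values, matrix(0, 12, 10))

  # K = 1, identity psi, s = 1, no regularizer: x_1 = L^T d
  cfg1 <- training_config(K = 1, n_k = 1, o = 3, n_knots = 7, seed = 3)
  p1 <- vn_init(model, cfg1)
  p1$layers[[1]]$w[] <- 0
  p1$layers[[1]]$s <- rep(1, nrow(model$L))
  d_small <- rnorm(nrow(model$L), sd = 0.01)  # keep responses inside the knot range
  out1 <- vn_forward(p1, d_small, model)
  expect_equal(as.numeric(out1$x$values),
               as.numeric(as.matrix(Matrix::t(model$L)) %*% d_small),
               tolerance = 1e-10)

  expect_error(vn_forward(p1, d_small[-1], model), "does not match")
})

test_that("training loss equals a direct-summation oracle", {
  fx <- fixture_tiny()
  fv <- fixture_vn_params(fx$model)
  params <- fv$params; cfg <- fv$cfg
  set.seed(31)
  traj <- lapply(1:params$K, function(k) matrix(rnorm(120), 12, 10))
  xstar <- matrix(rnorm(120), 12, 10) * params$x_scale
  got <- vn_loss(traj, xstar, params, cfg)

  K <- params$K
  expected <- 0
  for (k in 1:K)
    expected <- expected + exp(-cfg$tau * (K - k)) * sum(abs(traj[[k]] - xstar / params$x_scale))
  for (k in 1:K) for (j in 1:params$n_k) {
    y <- params$layers[[k]]$phi_y[, j]
    for (i in 2:(params$n_knots - 1))
      expected <- expected + cfg$lambda_r * sqrt((y[i - 1] - 2 * y[i] + y[i + 1])^2 + cfg$eps)
  }
  expect_equal(as.numeric(got), expected, tolerance = 1e-10)

  # exact-trajectory, linear-control-point case: only the sqrt(eps) floor remains
  idp <- vn_init(fx$model, cfg)
  idp$x_scale <- 1
  traj0 <- lapply(1:idp$K, function(k) xstar)
  l0 <- vn_loss(traj0, xstar, idp, cfg)
  expect_equal(as.numeric(l0),
               cfg$lambda_r * idp$K * idp$n_k * (idp$n_knots - 2) * sqrt(cfg$eps),
               tolerance = 1e-12)

  # tau = 0 weights all layers equally
  cfg0 <- training_config(K = 2, n_k = 2, o = 3, n_knots = 7, tau = 0, lambda_r = 0)
  l1 <- vn_loss(traj[1:2], xstar, params, cfg0)
  expect_equal(as.numeric(l1),
               sum(abs(traj[[1]] - xstar / params$x_scale)) +
                 sum(abs(traj[[2]] - xstar / params$x_scale)),
               tolerance = 1e-10)
})

test_that("reverse-mode gradients of the unrolled loss match central finite differences for every family", {
  grid <- imaging_grid(6, 6, 1, 1)
  spec <- acquisition_spec(4, 2, angles_deg = c(-15, -5, 5, 15), c0 = 1500)
  model <- build_forward_model(spec, grid)
  fv <- fixture_vn_params(model, K = 2, n_k = 2, o = 3, n_knots = 7, seed = 17)
  params <- fv$params; cfg <- fv$cfg
  set.seed(23)
  xstar <- matrix(rnorm(36, sd = 1.2), 6, 6)
  dvec <- rnorm(nrow(model$L), sd = 2) * params$x_scale

  loss_fn <- function(p) {
    fw <- sosvn:::vn_forward_impl(p, dvec, model)
    as.numeric(vn_loss(fw$trajectory, xstar, p, cfg))
  }
  fw <- sosvn:::vn_forward_impl(params, dvec, model, cache = TRUE)
  gt <- sosvn:::vn_grads_to_trainable(
    sosvn:::vn_backward(fw, params, xstar / params$x_scale, cfg, model))

  fields <- c(r = "r", w = "w", phi = "phi_y", psi = "psi_y", s = "s")
  h <- 1e-6
  for (k in 1:params$K) for (fam in names(fields)) {
    fld <- fields[[fam]]
    vals <- as.numeric(params$layers[[k]][[fld]])
    an <- as.numeric(gt[[paste0(fam, ".", k)]])
    set.seed(100 + k)
    for (i in sample(length(vals), 3)) {
      perturb <- function(delta) {
        p <- params
        v <- vals; v[i] <- v[i] + delta
        dim(v) <- dim(params$layers[[k]][[fld]])
        p$layers[[k]][[fld]] <- v
        p
      }
      fd <- (loss_fn(perturb(h)) - loss_fn(perturb(-h))) / (2 * h)
      expect_equal(an[i], fd, tolerance = 1e-4,
                   label = sprintf("analytic grad %s.%d[%d]", fam, k, i))
    }
  }
})

test_that("a TV-configured network reproduces plain gradient descent on the analytical objective", {
  grid <- imaging_grid(6, 6, 1, 1)
  spec <- acquisition_spec(3, 1, angles_deg = c(-12, 0, 12), c0 = 1500)
  model <- build_forward_model(spec, grid)
  K <- 10; n_knots <- 21
  knots <- seq(-1, 1, length.out = n_knots)
  lambda <- 0.05
  s0 <- 1 / sosvn:::operator_norm(model$L)

  # two TV priors: lateral and axial forward differences
  r <- array(0, c(3, 3, 2))
  r[2, 2, 1] <- -1; r[2, 3, 1] <- 1
  r[2, 2, 2] <- -1; r[3, 2, 2] <- 1
  cfg <- training_config(K = K, n_k = 2, o = 3, n_knots = n_knots, seed = 1)
  params <- vn_init(model, cfg)
  for (k in 1:K) {
    params$layers[[k]]$r <- r
    params$layers[[k]]$w <- array(lambda, c(6, 6, 2))
    params$layers[[k]]$phi_y <- matrix(knots, n_knots, 2)  # identity
    params$layers[[k]]$psi_y <- knots                      # identity
    params$layers[[k]]$s <- rep(s0, nrow(model$L))
  }
  set.seed(41)
  d <- rnorm(nrow(model$L), sd = 0.01)
  out <- vn_forward(params, d, model)

  # independent hand-rolled descent loop (naive R convolutions)
  Ld <- as.matrix(model$L)
  x <- matrix(0, 6, 6)
  trajectory <- vector("list", K)
  for (k in 1:K) {
    gd <- matrix(s0^2 * (t(Ld) %*% (Ld %*% as.numeric(x) - d)), 6, 6)
    gr <- matrix(0, 6, 6)
    for (j in 1:2) {
      f <- naive_corr2(x, r[, , j], 1, 1)
      # transposed convolution = correlation with the flipped kernel, shifted anchor
      rf <- r[3:1, 3:1, j]
      gr <- gr + lambda * naive_corr2(f, rf, 1, 1)
    }
    x <- x - gd - gr
    trajectory[[k]] <- x
  }
  for (k in 1:K)
    expect_equal(out$trajectory[[k]], trajectory[[k]], tolerance = 1e-8,
                 label = paste("trajectory layer", k))
})

test_that("scaled-down training descends and is bit-reproducible", {
  fx <- fixture_tiny()
  cfg <- training_config(iterations = 50, batch_size = 8, K = 2, n_k = 3, o = 3,
                         n_knots = 9, seed = 99)
  fit1 <- train_vn(fx$ds, cfg, fx$model)
  lh <- attr(fit1, "loss_history")
  expect_lt(mean(tail(lh, 10)), lh[1])
  fit2 <- train_vn(fx$ds, cfg, fx$model)
  attr(fit1, "loss_history") <- attr(fit2, "loss_history") <- NULL
  attr(fit1, "config") <- attr(fit2, "config") <- NULL
  expect_identical(fit1, fit2)
})
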