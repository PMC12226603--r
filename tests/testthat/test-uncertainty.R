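test_that("dropout masks follow the configured Bernoulli rate and p = 0 is deterministic", {
  fx <- fixture_tiny()
  fv <- fixture_vn_params(fx$model)
  params <- fv$params
  d <- displacement_set(fx$ds$test[[1]]$d, fx$grid)

  # p = 0 reproduces the deterministic forward pass exactly
  det <- vn_forward(params, d, fx$model)$x
  samp <- mcd_sample(params, d, fx$model, mcd_config(p = 0), seed = 1)
  expect_identical(samp$values, det$values)

  # all priors dropped: regularizer annihilated, equals w = 0 network
  zero_filters <- lapply(params$layers, function(ly)
    list(r1 = ly$r * 0, r2 = ly$r * 0))
  dropped <- vn_forward(params, d, fx$model, filters = zero_filters)$x
  p0 <- params
  for (k in seq_len(p0$K)) p0$layers[[k]]$w[] <- 0
  expect_equal(dropped$values, vn_forward(p0, d, fx$model)$x$values, tolerance = 1e-12)

  # empirical drop fraction at p = 0.25 within the 99% binomial CI
  set.seed(5)
  n_draw <- 10000
  cfgm <- mcd_config(p = 0.25)
  drops <- numeric(n_draw)
  for (i in 1:n_draw) {
    fl <- sosvn:::draw_mcd_filters(params, cfgm)
    m <- unlist(lapply(fl, function(l) c(l$m1, l$m2)))
    drops[i] <- mean(m == 0)
  }
  n_mask <- params$K * params$n_k * 2
  expect_lt(abs(mean(drops) - 0.25),
            2.576 * sqrt(0.25 * 0.75 / (n_draw * n_mask)))
})

test_that("posterior summaries are exact on closed-form sample sets", {
  g <- imaging_grid(4, 3, 1, 1)
  m1 <- sos_map(matrix(1500, 4, 3), g)
  expect_error(posterior_summarize(list(m1)), "at least 2")

  s_same <- posterior_summarize(list(m1, m1, m1))
  expect_equal(s_same$mean_sos$values, matrix(1500, 4, 3))
  expect_equal(s_same$std_map, matrix(0, 4, 3))
  expect_equal(s_same$n_samples, 3)

  m2 <- sos_map(matrix(1502, 4, 3), g)
  s2 <- posterior_summarize(list(m1, m2))
  expect_equal(s2$mean_sos$values, matrix(1501, 4, 3))
  expect_equal(s2$std_map, matrix(sqrt(2), 4, 3), tolerance = 1e-12)
})

test_that("BVI coefficient draws honor the block-diagonal Gaussian posterior", {
  set.seed(3)
  o <- 2; n_k <- 2; K <- 2; o2 <- o^2; B <- n_k * K
  D <- array(0, c(o2, o2, B))
  for (b in 1:B) {
    Db <- matrix(rnorm(o2 * o2, sd = 0.3), o2, o2)
    Db[upper.tri(Db)] <- 0
    diag(Db) <- runif(o2, 0.5, 1.5)
    D[, , b] <- Db
  }
  mu <- rnorm(o2 * B)
  post <- bvi_posterior(mu, D, o, n_k, K, alpha = 0.1)

  draws <- bvi_sample_coefficients(post, 20000, seed = 11)
  # within-block covariance matches D D^T
  for (b in 1:B) {
    idx <- (b - 1) * o2 + 1:o2
    Sg <- D[, , b] %*% t(D[, , b])
    Se <- cov(t(draws[idx, ]))
    expect_lt(norm(Se - Sg, "F") / norm(Sg, "F"), 0.08)
  }
  # cross-block covariance statistically indistinguishable from zero
  cross <- cov(t(draws[1:o2, ])) * 0
  Sfull <- cov(t(draws))
  off <- Sfull[1:o2, o2 + 1:o2]
  expect_lt(max(abs(off)), 4 * max(abs(diag(Sfull))) / sqrt(20000) * 3)

  # degenerate posterior: D -> 0 collapses samples onto the mean
  D0 <- D * 0
  for (b in 1:B) diag(D0[, , b]) <- 1e-12
  post0 <- bvi_posterior(mu, D0, o, n_k, K)
  dr0 <- bvi_sample_coefficients(post0, 100, seed = 2)
  expect_lt(max(abs(dr0 - mu)), 1e-9)

  # structured draw reshapes into per-layer kernels consistently
  fl <- bvi_sample_filters(post, seed = 9)
  cf <- bvi_sample_coefficients(post, 1, seed = 9)
  expect_equal(as.numeric(fl[[2]]$r1[, , 1]), cf[(n_k * o2) + 1:o2, 1])
})

test_that("the KL term equals the dense log-determinant oracle and scales in closed form", {
  set.seed(7)
  o <- 2; o2 <- 4
  for (rep in 1:20) {
    B <- sample(1:4, 1)
    D <- array(0, c(o2, o2, B))
    for (b in 1:B) {
      Db <- matrix(rnorm(16, sd = 0.5), o2, o2); Db[upper.tri(Db)] <- 0
      diag(Db) <- runif(o2, 0.2, 2)
      D[, , b] <- Db
    }
    alpha <- runif(1, 0.05, 1)
    post <- bvi_posterior(rep(0, o2 * B), D, o, n_k = B, K = 1, alpha = alpha)
    # dense oracle: alpha tr(DD^T) - log det(DD^T) on the full block-diagonal
    Dfull <- matrix(0, o2 * B, o2 * B)
    for (b in 1:B) Dfull[(b - 1) * o2 + 1:o2, (b - 1) * o2 + 1:o2] <- D[, , b]
    Sg <- Dfull %*% t(Dfull)
    oracle <- alpha * sum(diag(Sg)) - determinant(Sg, logarithm = TRUE)$modulus
    expect_equal(kl_term(post), as.numeric(oracle), tolerance = 1e-8)

    # scaling: D -> cD multiplies the trace term by c^2, shifts log term by -2t log c
    cc <- 1.7
    post2 <- bvi_posterior(rep(0, o2 * B), D * cc, o, n_k = B, K = 1, alpha = alpha)
    t_tot <- o2 * B
    expect_equal(kl_term(post2),
                 alpha * cc^2 * sum(D^2) - 2 * sum(log(apply(D, 3, diag))) -
                   2 * t_tot * log(cc),
                 tolerance = 1e-10)
  }
  # identity factor: KL = alpha * t
  Di <- array(0, c(4, 4, 2)); for (b in 1:2) diag(Di[, , b]) <- 1
  post_i <- bvi_posterior(rep(0, 8), Di, 2, 2, 1, alpha = 1)
  expect_equal(kl_term(post_i), 8)

  # nonpositive diagonal is a domain error
  Dbad <- Di; Dbad[1, 1, 1] <- 0
  expect_error(bvi_posterior(rep(0, 8), Dbad, 2, 2, 1), "positive diagonal")
})

test_that("BVI training descends and its reparameterized gradients match finite differences", {
  fx <- fixture_tiny()
  cfg <- training_config(iterations = 40, batch_size = 8, K = 2, n_k = 2, o = 3,
                         n_knots = 9, lr = 5e-3, seed = 55)
  fit <- train_bvi(fx$ds, NULL, cfg, fx$model)
  lh <- attr(fit, "loss_history")
  expect_lt(mean(tail(lh, 10)), lh[1])
  expect_s3_class(fit$posterior, "sos_bvi_posterior")

  # finite-difference check of d loss / d mu and d loss / d diag(D) with frozen y
  params <- fit$params; post <- fit$posterior
  rec <- fx$ds$train[[1]]
  xt <- (sos_to_slowness(rec$sos_gt) - sos_to_slowness(params$c0)) / params$x_scale
  o2 <- post$o^2; B <- dim(post$D)[3]
  set.seed(3)
  y <- rnorm(o2 * B)
  loss_of <- function(mu, D) {
    cf <- mu
    for (b in 1:B) {
      idx <- (b - 1) * o2 + 1:o2
      cf[idx] <- cf[idx] + D[, , b] %*% y[idx]
    }
    filters <- sosvn:::coeffs_to_filters(cf, post)
    fw <- sosvn:::vn_forward_impl(params, as.numeric(rec$d), fx$model, filters = filters)
    pl <- bvi_posterior(mu, D, post$o, post$n_k, post$K, post$alpha)
    as.numeric(vn_loss(fw$trajectory, xt * params$x_scale, params, cfg)) +
      cfg$beta * kl_term(pl)
  }
  # analytic gradients via the package's backward pass + KL closed form
  cf <- post$mu
  for (b in 1:B) {
    idx <- (b - 1) * o2 + 1:o2
    cf[idx] <- cf[idx] + post$D[, , b] %*% y[idx]
  }
  filters <- sosvn:::coeffs_to_filters(cf, post)
  fw <- sosvn:::vn_forward_impl(params, as.numeric(rec$d), fx$model,
                                filters = filters, cache = TRUE)
  gt <- sosvn:::vn_grads_to_trainable(
    sosvn:::vn_backward(fw, params, xt, cfg, fx$model))
  dr <- numeric(o2 * B)
  for (k in 1:post$K) for (j in 1:post$n_k) {
    b <- (k - 1) * post$n_k + j
    dr[(b - 1) * o2 + 1:o2] <- as.numeric(gt[[paste0("r.", k)]][, , j])
  }
  h <- 1e-6
  set.seed(9)
  for (i in sample(o2 * B, 4)) {
    mup <- post$mu; mup[i] <- mup[i] + h
    mum <- post$mu; mum[i] <- mum[i] - h
    fd <- (loss_of(mup, post$D) - loss_of(mum, post$D)) / (2 * h)
    expect_equal(dr[i], fd, tolerance = 1e-4, label = paste("d mu", i))
  }
  for (b in sample(B, 2)) for (ii in sample(o2, 2)) {
    Dp <- post$D; Dp[ii, ii, b] <- Dp[ii, ii, b] + h
    Dm <- post$D; Dm[ii, ii, b] <- Dm[ii, ii, b] - h
    fd <- (loss_of(post$mu, Dp) - loss_of(post$mu, Dm)) / (2 * h)
    idx <- (b - 1) * o2 + ii
    an <- dr[idx] * y[idx] +
      cfg$beta * (2 * post$alpha * post$D[ii, ii, b] - 2 / post$D[ii, ii, b])
    expect_equal(an, fd, tolerance = 1e-4, label = paste("d D", b, ii))
  }
})

test_that("posterior uncertainty shrinks monotonically as dropout vanishes", {
  fx <- fixture_tiny()
  cfg <- training_config(iterations = 60, batch_size = 8, K = 2, n_k = 3, o = 3,
                         n_knots = 9, dropout_p = 0.25, seed = 12)
  fit <- train_vn(fx$ds, cfg, fx$model)
  d <- displacement_set(fx$ds$test[[1]]$d, fx$grid)
  mean_std <- vapply(c(0.25, 0.1, 0.01), function(p) {
    ps <- sample_posterior(fit, d, fx$model, method = "mcd", n_samples = 100,
                           mcd = mcd_config(p = p), seed = 4)
    mean(ps$std_map)
  }, 0)
  expect_true(all(diff(mean_std) < 0))
  expect_true(all(mean_std >= 0))
})
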