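test_that("phantom cohort fractions match the generating probabilities", {
  grid <- imaging_grid(12, 10, 2, 2)
  cfg <- simulation_config(seed = 1)
  set.seed(1)
  n <- 4000
  no_inc <- logical(n); smooth <- logical(n); ok_bounds <- logical(n)
  for (i in 1:n) {
    ph <- sample_phantom(cfg, grid)
    no_inc[i] <- !any(ph$inclusion_mask)
    smooth[i] <- ph$smooth_edge
    ok_bounds[i] <- all(ph$sos_map$values >= 1300) && all(ph$sos_map$values <= 1700)
  }
  expect_true(all(ok_bounds))
  # binomial 99% CI around the configured rates
  ci <- function(p) 2.576 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(no_inc) - 0.05), ci(0.05))
  expect_lt(abs(mean(smooth[!no_inc]) - 0.5), ci(0.5) * sqrt(n / sum(!no_inc)))
})

test_that("phantoms are deterministic given a seed and masks track the SoS support", {
  grid <- imaging_grid(12, 10, 2, 2)
  cfg <- simulation_config(seed = 1)
  p1 <- sample_phantom(cfg, grid, seed = 123)
  p2 <- sample_phantom(cfg, grid, seed = 123)
  expect_identical(p1, p2)

  # sharp-edged inclusions: mask support equals the SoS deviation support
  cfg_sharp <- simulation_config(p_smooth = 0, p_no_inclusion = 0, seed = 1)
  for (s in 1:10) {
    ph <- sample_phantom(cfg_sharp, grid, seed = s)
    dev_support <- abs(ph$sos_map$values - ph$background_sos) > 1e-9
    inter <- sum(dev_support & ph$inclusion_mask)
    uni <- sum(dev_support | ph$inclusion_mask)
    expect_gte(inter / uni, 0.95)
  }
})

test_that("measurement simulation matches the dense upsample-multiply-average oracle", {
  grid <- imaging_grid(6, 6, 2, 2)
  spec <- acquisition_spec(3, 1, angles_deg = c(-12, 0, 12), c0 = 1500)
  cfg <- simulation_config(hr_factor = 2, noise_std = 0, p_no_inclusion = 0, seed = 2)
  model_hr <- build_forward_model(spec, upsample_grid(grid, 2))
  ph <- sample_phantom(cfg, grid, seed = 5)
  d <- simulate_measurements(ph, model_hr, cfg)

  x <- sos_to_slowness(ph$sos_map$values) - sos_to_slowness(1500)
  x_hr <- x[rep(1:6, each = 2), rep(1:6, each = 2)]
  d_hr <- as.matrix(model_hr$L) %*% as.numeric(x_hr)
  M <- nrow(model_hr$pairs)
  d_or <- array(0, dim = c(6, 6, M))
  hr_arr <- array(d_hr, dim = c(12, 12, M))
  for (m in 1:M) for (i in 1:6) for (j in 1:6)
    d_or[i, j, m] <- mean(hr_arr[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), m])
  expect_equal(d$values, d_or, tolerance = 1e-12)

  # zero-contrast phantom, zero noise: all-zero measurements
  cfg0 <- simulation_config(p_no_inclusion = 1, noise_std = 0,
                            background_sos_range = c(1500, 1500), seed = 3)
  ph0 <- sample_phantom(cfg0, grid, seed = 7)
  d0 <- simulate_measurements(ph0, model_hr, cfg0)
  expect_equal(max(abs(d0$values)), 0)
})

test_that("measurement noise scales as configured after block averaging", {
  grid <- imaging_grid(6, 6, 2, 2)
  spec <- acquisition_spec(3, 1, angles_deg = c(-12, 0, 12), c0 = 1500)
  noise_std <- 2e-9
  cfg <- simulation_config(hr_factor = 2, noise_std = noise_std,
                           p_no_inclusion = 0, seed = 2)
  model_hr <- build_forward_model(spec, upsample_grid(grid, 2))
  ph <- sample_phantom(cfg, grid, seed = 5)
  set.seed(99)
  draws <- vapply(1:800, function(i)
    as.numeric(simulate_measurements(ph, model_hr, cfg)$values),
    numeric(6 * 6 * 2))
  sds <- apply(draws, 1, sd)
  # block averaging over hr_factor^2 cells divides the std by hr_factor
  expect_lt(abs(mean(sds) - noise_std / 2) / (noise_std / 2), 0.05)
})

test_that("dataset generation is reproducible, sized, and inverse-crime guarded", {
  grid <- imaging_grid(8, 8, 2, 2)
  spec <- acquisition_spec(4, 2, angles_deg = seq(-15, 15, length.out = 4))
  cfg <- simulation_config(n_train = 5, n_test = 3, seed = 77)
  ds1 <- make_dataset(cfg, spec, grid)
  ds2 <- make_dataset(cfg, spec, grid)
  expect_identical(ds1$train, ds2$train)
  expect_length(ds1$train, 5)
  expect_length(ds1$test, 3)
  expect_gte(cfg$hr_factor, 2)   # structural inverse-crime guard

  cfg0 <- simulation_config(n_train = 0, n_test = 0, seed = 1)
  ds0 <- make_dataset(cfg0, spec, grid)
  expect_length(ds0$train, 0)
})

test_that("lesion cases corrupt the designated frames and label by contrast", {
  grid <- imaging_grid(10, 8, 2, 2)
  spec <- acquisition_spec(4, 2, angles_deg = seq(-15, 15, length.out = 4))
  cfg <- simulation_config(seed = 5)
  model_hr <- build_forward_model(spec, upsample_grid(grid, cfg$hr_factor))

  lc <- make_lesion_case(cfg, spec, grid, n_frames = 4, n_corrupted = 2,
                         corruption_scale = 5, contrast = 50, seed = 31,
                         model_hr = model_hr)
  expect_equal(lc$label, "CA")
  expect_length(lc$corrupted_frames, 2)
  lc_fa <- make_lesion_case(cfg, spec, grid, n_frames = 3, n_corrupted = 1,
                            corruption_scale = 5, contrast = 12, seed = 32,
                            model_hr = model_hr)
  expect_equal(lc_fa$label, "FA")

  # corrupted frames carry strictly more measurement energy on average
  set.seed(8)
  var_clean <- var_bad <- 0
  n_rep <- 60
  for (i in 1:n_rep) {
    lc <- make_lesion_case(cfg, spec, grid, n_frames = 4, n_corrupted = 2,
                           corruption_scale = 5, contrast = 40,
                           model_hr = model_hr)
    base <- simulate_measurements(lc$phantom, model_hr, cfg, noise_std = 0)
    for (f in 1:4) {
      resid <- lc$frames[[f]]$values - base$values
      if (f %in% lc$corrupted_frames) var_bad <- var_bad + mean(resid^2)
      else var_clean <- var_clean + mean(resid^2)
    }
  }
  expect_gt(var_bad / (2 * n_rep), 4 * var_clean / (2 * n_rep))

  # corruption_scale = 1 is the null case: no extra noise, no offset field
  lc1 <- make_lesion_case(cfg, spec, grid, n_frames = 3, n_corrupted = 1,
                          corruption_scale = 1, contrast = 40, seed = 77,
                          model_hr = model_hr)
  expect_length(lc1$corrupted_frames, 1)
})
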