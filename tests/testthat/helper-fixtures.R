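# Shared fixtures, built once per test run (all generated in code).

.fixture_env <- new.env(parent = emptyenv())

# small geometry + dataset used across module tests
fixture_tiny <- function() {
  if (is.null(.fixture_env$tiny)) {
    grid <- imaging_grid(12, 10, 2, 2)
    spec <- acquisition_spec(5, 2, angles_deg = seq(-16, 16, length.out = 5), c0 = 1515)
    cfg <- simulation_config(n_train = 16, n_test = 4, seed = 11)
    ds <- make_dataset(cfg, spec, grid)
    model <- build_forward_model(spec, grid)
    .fixture_env$tiny <- list(grid = grid, spec = spec, cfg = cfg, ds = ds,
                              model = model)
  }
  .fixture_env$tiny
}

# small randomized VN parameter set with nontrivial transforms and scales
fixture_vn_params <- function(model, K = 2, n_k = 2, o = 3, n_knots = 7,
                              seed = 7) {
  cfg <- training_config(K = K, n_k = n_k, o = o, n_knots = n_knots, seed = seed)
  params <- vn_init(model, cfg)
  set.seed(seed)
  n_ax <- model$recon_grid$n_ax; n_lat <- model$recon_grid$n_lat
  for (k in seq_len(K)) {
    params$layers[[k]]$r <- array(rnorm(o * o * n_k, sd = 0.1), c(o, o, n_k))
    params$layers[[k]]$w <- array(runif(n_ax * n_lat * n_k, 0, 0.3),
                                  c(n_ax, n_lat, n_k))
    params$layers[[k]]$phi_y <- matrix(rnorm(n_knots * n_k, sd = 0.3), n_knots, n_k)
    params$layers[[k]]$psi_y <- rnorm(n_knots, sd = 0.3)
    params$layers[[k]]$s <- runif(nrow(model$L), 0.05, 0.15)
    params$layers[[k]]$phi_scale <- runif(n_k, 0.7, 1.4)
    params$layers[[k]]$psi_scale <- runif(1, 0.7, 1.4)
  }
  params$x_scale <- 2.3
  list(params = params, cfg = cfg)
}
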