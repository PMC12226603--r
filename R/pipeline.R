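#' Deterministic per-stage seed derivation
#'
#' Every stochastic stage of the pipeline receives its own seed derived from
#' the global seed and a stage tag, so stages are reproducible in isolation
#' and changing one stage's randomness does not perturb the others.
#'
#' @param seed global integer seed.
#' @param tag stage tag string.
#' @return An integer seed in `[1, 2^31)`.
#' @export
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147480009
  as.integer(((seed %% 2147480009) * 48271 + h) %% 2147480009 + 1)
}

default_run_config <- function() {
  list(
    seed = 1,
    grid = list(n_ax = 21, n_lat = 16, pitch_ax = 2, pitch_lat = 2, depth_offset = 0),
    acquisition = list(n_transmits = 17, pair_offset = 2, angles_deg = NULL,
                       c0 = 1515, vs_depth_mm = Inf),
    simulation = list(n_train = 500, n_test = 32, p_no_inclusion = 0.05,
                      p_smooth = 0.5, background_sos_range = c(1490, 1540),
                      contrast_range = c(10, 60), hr_factor = 2,
                      noise_std = NULL, smooth_sigma_mm = 1.5, deform_sd = 0.15),
    training = list(iterations = 1200, batch_size = 8, lr = 2e-3, tau = 0.5,
                    lambda_r = 1e-3, eps = 1e-6, alpha = 0.1, beta = 10,
                    K = 5, n_k = 8, o = 5, n_knots = 21),
    uncertainty = list(method = "mcd", n_samples = 100, dropout_p = 0.25),
    cohort = list(n_cases = 20, n_frames = 4, n_corrupted = 3,
                  corruption_scale = 5, contrast_ca = c(45, 60),
                  contrast_fa = c(10, 20), label_threshold = 35, ring_mm = 5),
    selection = list(policies = c("SI_rel", "SI_inc", "S1", "S3", "SR"))
  )
}

#' Assemble a pipeline run configuration
#'
#' Nested configuration for [run_pipeline()]: blocks `grid`, `acquisition`,
#' `simulation`, `training`, `uncertainty`, `cohort`, `selection` plus the
#' global `seed`. Presets: `"scaled"` (the package's scaled-down study
#' conditions, the default) and `"smoke"` (a minutes-scale end-to-end check
#' on a tiny problem).
#'
#' @param preset `"scaled"` or `"smoke"`.
#' @param ... named overrides merged recursively into the preset (e.g.
#'   `seed = 7`, `training = list(iterations = 100)`).
#' @return A named list of class `sos_run_config`.
#' @export
run_config <- function(preset = c("scaled", "smoke"), ...) {
  preset <- match.arg(preset)
  cfg <- default_run_config()
  if (preset == "smoke") {
    cfg$simulation$n_train <- 24
    cfg$simulation$n_test <- 8
    cfg$training$iterations <- 40
    cfg$training$K <- 3
    cfg$uncertainty$n_samples <- 12
    cfg$cohort$n_cases <- 20
  }
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      modifyList(cfg[[nm]], overrides[[nm]]) else overrides[[nm]]
  }
  structure(cfg, class = "sos_run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param cfg an `sos_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(list(preset = "scaled"), raw))
}

cfg_objects <- function(cfg) {
  g <- cfg$grid
  recon_grid <- imaging_grid(g$n_ax, g$n_lat, g$pitch_ax, g$pitch_lat, g$depth_offset)
  a <- cfg$acquisition
  spec <- acquisition_spec(a$n_transmits, a$pair_offset, a$angles_deg, a$c0,
                           vs_depth_mm = a$vs_depth_mm)
  list(recon_grid = recon_grid, spec = spec)
}

cfg_sim <- function(cfg, seed) {
  s <- cfg$simulation
  simulation_config(n_train = s$n_train, n_test = s$n_test,
                    p_no_inclusion = s$p_no_inclusion, p_smooth = s$p_smooth,
                    background_sos_range = s$background_sos_range,
                    contrast_range = s$contrast_range, hr_factor = s$hr_factor,
                    noise_std = s$noise_std, smooth_sigma_mm = s$smooth_sigma_mm,
                    deform_sd = s$deform_sd, seed = seed)
}

cfg_training <- function(cfg, seed, dropout_p = 0) {
  t <- cfg$training
  training_config(iterations = t$iterations, batch_size = t$batch_size, lr = t$lr,
                  tau = t$tau, lambda_r = t$lambda_r, eps = t$eps,
                  alpha = t$alpha, beta = t$beta, dropout_p = dropout_p,
                  K = t$K, n_k = t$n_k, o = t$o, n_knots = t$n_knots, seed = seed)
}

stage_fresh <- function(path, hash) {
  if (!file.exists(path)) return(FALSE)
  rec <- tryCatch(readRDS(path), error = function(e) NULL)
  identical(rec$config_hash, hash)
}

#' Run the end-to-end pipeline
#'
#' simulate -> train -> per-frame posterior sampling -> frame selection ->
#' contrast-based evaluation. Every stage writes its artifact into `out_dir`
#' stamped with a configuration hash and is resumed from disk when re-run
#' with an unchanged configuration.
#'
#' @param cfg an [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return The evaluation report (named list, also written as
#'   `report.json`): per-policy AUC/F1/operating point, rank-sum p-values,
#'   per-case selections and contrasts, and (when the cohort contains
#'   corrupted frames) the clean-frame hit rate of the informed policies.
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "sos_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- proc.time()[["elapsed"]]
  obj <- cfg_objects(cfg)
  method <- match.arg(cfg$uncertainty$method, c("mcd", "bvi"))

  # --- stage: simulate -------------------------------------------------------
  sim_seed <- derive_seed(cfg$seed, "simulate")
  sim_cfg <- cfg_sim(cfg, sim_seed)
  sim_hash <- config_hash(list(sim_cfg, cfg$grid, cfg$acquisition))
  ds_path <- file.path(out_dir, "dataset.rds")
  if (stage_fresh(ds_path, sim_hash)) {
    say("[simulate] reusing %s", ds_path)
    dataset <- read_dataset(ds_path)
  } else {
    t0 <- proc.time()[["elapsed"]]
    dataset <- make_dataset(sim_cfg, obj$spec, obj$recon_grid)
    write_container(list(dataset = dataset, config_hash = sim_hash, seed = sim_seed),
                    ds_path, "dataset")
    say("[simulate] %d train / %d test records (%.1f s)",
        length(dataset$train), length(dataset$test), proc.time()[["elapsed"]] - t0)
  }
  model <- build_forward_model(obj$spec, obj$recon_grid)

  # --- stage: train ----------------------------------------------------------
  tr_seed <- derive_seed(cfg$seed, paste0("train-", method))
  dropout_p <- if (method == "mcd") cfg$uncertainty$dropout_p else 0
  tr_cfg <- cfg_training(cfg, tr_seed, dropout_p)
  tr_hash <- config_hash(list(tr_cfg, sim_hash, method))
  ck_path <- file.path(out_dir, paste0("checkpoint_", method, ".rds"))
  if (stage_fresh(ck_path, tr_hash)) {
    say("[train] reusing %s", ck_path)
    fit <- read_checkpoint(ck_path)
  } else {
    t0 <- proc.time()[["elapsed"]]
    fit <- if (method == "mcd") train_vn(dataset, tr_cfg, model)
           else train_bvi(dataset, NULL, tr_cfg, model)
    write_container(list(fit = fit, config = tr_cfg, config_hash = tr_hash,
                         seed = tr_seed, loss_history = attr(fit, "loss_history")),
                    ck_path, "checkpoint")
    lh <- attr(fit, "loss_history")
    say("[train] %s: %d iterations, loss %.3g -> %.3g (%.1f s)", method,
        length(lh), lh[1], lh[length(lh)], proc.time()[["elapsed"]] - t0)
  }

  # --- stage: cohort + posteriors + selection --------------------------------
  co <- cfg$cohort
  co_seed <- derive_seed(cfg$seed, "cohort")
  co_hash <- config_hash(list(co, sim_hash, tr_hash, cfg$uncertainty))
  po_path <- file.path(out_dir, "posteriors.rds")
  if (stage_fresh(po_path, co_hash)) {
    say("[posterior] reusing %s", po_path)
    cases <- readRDS(po_path)$cases
  } else {
    t0 <- proc.time()[["elapsed"]]
    model_hr <- build_forward_model(obj$spec,
                                    upsample_grid(obj$recon_grid, sim_cfg$hr_factor))
    n_ca <- ceiling(co$n_cases / 2)
    cases <- lapply(seq_len(co$n_cases), function(i) {
      is_ca <- i <= n_ca
      cr <- if (is_ca) co$contrast_ca else co$contrast_fa
      case_seed <- derive_seed(co_seed, paste0("case-", i))
      set.seed(case_seed)
      contrast <- sample(c(-1, 1), 1) * runif(1, cr[1], cr[2])
      lc <- make_lesion_case(cfg_sim(cfg, case_seed), obj$spec, obj$recon_grid,
                             n_frames = co$n_frames, n_corrupted = co$n_corrupted,
                             corruption_scale = co$corruption_scale,
                             label_threshold = co$label_threshold,
                             contrast = contrast, model_hr = model_hr)
      summaries <- lapply(seq_along(lc$frames), function(f)
        sample_posterior(fit, lc$frames[[f]], model, method = method,
                         n_samples = cfg$uncertainty$n_samples,
                         mcd = mcd_config(p = cfg$uncertainty$dropout_p),
                         seed = derive_seed(case_seed, paste0("post-", f))))
      scores <- lapply(seq_along(summaries), function(f)
        score_frame(summaries[[f]], lc$masks[[f]], ring_mm = co$ring_mm))
      deltas <- vapply(seq_along(summaries), function(f)
        sos_contrast(summaries[[f]]$mean_sos, lc$masks[[f]], ring_mm = co$ring_mm)$delta_c, 0)
      list(label = lc$label, corrupted = lc$corrupted_frames, scores = scores,
           delta_c = deltas, contrast = lc$phantom$contrast)
    })
    saveRDS(list(cases = cases, config_hash = co_hash, kind = "cohort",
                 schema_version = 1L), po_path)
    say("[posterior] %d cases x %d frames scored (%.1f s)", co$n_cases,
        co$n_frames, proc.time()[["elapsed"]] - t0)
  }

  # --- stage: evaluate -------------------------------------------------------
  labels <- vapply(cases, `[[`, "", "label")
  policies <- cfg$selection$policies
  report <- list(method = method, n_cases = length(cases),
                 seed = cfg$seed, policies = list())
  sel_csv <- NULL
  for (pol in policies) {
    sel <- vapply(seq_along(cases), function(i)
      select_frame(cases[[i]]$scores, pol,
                   seed = derive_seed(cfg$seed, paste0("SR-", i))), 0L)
    dc <- vapply(seq_along(cases), function(i) cases[[i]]$delta_c[sel[i]], 0)
    roc <- roc_auc(dc, labels)
    rs <- rank_sum_test(dc[labels == "CA"], dc[labels == "FA"])
    entry <- list(auc = roc$auc, f1 = roc$f1, sensitivity = roc$sensitivity,
                  specificity = roc$specificity, threshold = roc$threshold,
                  rank_sum_p = rs$p_value)
    if (any(vapply(cases, function(cs) length(cs$corrupted) > 0, TRUE))) {
      clean_hit <- mean(vapply(seq_along(cases), function(i)
        !(sel[i] %in% cases[[i]]$corrupted), TRUE))
      entry$clean_frame_hit_rate <- clean_hit
    }
    report$policies[[pol]] <- entry
    sel_csv <- rbind(sel_csv, data.frame(case = seq_along(cases), policy = pol,
                                         selected = sel, label = labels, delta_c = dc))
  }
  report$config_hash <- config_hash(unclass(cfg))
  utils::write.csv(sel_csv, file.path(out_dir, "selections.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[evaluate] report written to %s (total %.1f s)",
      file.path(out_dir, "report.json"), proc.time()[["elapsed"]] - t_start)
  invisible(report)
}
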