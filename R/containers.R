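#' Deterministic configuration hash
#'
#' MD5 of the platform-independent (ASCII) serialization of an R object; used
#' to stamp every output artifact with the configuration that produced it and
#' to decide whether a pipeline stage can be resumed from disk.
#'
#' @param obj any serializable R object.
#' @return 32-character hex string.
#' @export
config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, ascii = TRUE)
  unname(tools::md5sum(f))
}

CONTAINER_SCHEMA <- 1L

write_container <- function(record, path, kind) {
  stopifnot(is.list(record))
  record$schema_version <- CONTAINER_SCHEMA
  record$kind <- kind
  saveRDS(record, path)
  invisible(path)
}

read_container <- function(path, kind, required = character()) {
  if (!file.exists(path)) stop("missing container: ", path)
  rec <- readRDS(path)
  if (!identical(rec$kind, kind))
    stop("container at ", path, " has kind '", rec$kind, "', expected '", kind, "'")
  if (!identical(rec$schema_version, CONTAINER_SCHEMA))
    stop("schema-version mismatch in ", path, " (found ", rec$schema_version,
         ", supported ", CONTAINER_SCHEMA, "); no migration available")
  missing <- setdiff(required, names(rec))
  if (length(missing) > 0)
    stop("container at ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "))
  rec
}

#' Write / read a dataset container
#'
#' Serialized container holding the train/test records, geometry, the
#' generating configuration, its hash, and the seed.
#'
#' @param dataset an `sos_dataset` from [make_dataset()].
#' @param path file path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sos_dataset"))
  write_container(list(dataset = dataset, config_hash = config_hash(dataset$config),
                       seed = dataset$seed), path, "dataset")
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  read_container(path, "dataset", c("dataset", "config_hash", "seed"))$dataset
}

#' Write / read a model checkpoint
#'
#' Stores trained parameters (`sos_vn_params` or `sos_bvi_fit`) together with
#' the training configuration, its hash, seed and loss history.
#'
#' @param fit trained parameters.
#' @param path file path.
#' @export
write_checkpoint <- function(fit, path) {
  cfg <- attr(fit, "config")
  write_container(list(fit = fit, config = cfg,
                       config_hash = config_hash(cfg),
                       seed = if (!is.null(cfg)) cfg$seed,
                       loss_history = attr(fit, "loss_history")),
                  path, "checkpoint")
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  read_container(path, "checkpoint", c("fit", "config_hash"))$fit
}

#' Write / read a posterior container
#'
#' @param summary an `sos_posterior_summary`.
#' @param path file path.
#' @param extra named list merged into the container (e.g. seeds, ids).
#' @export
write_posterior <- function(summary, path, extra = list()) {
  stopifnot(inherits(summary, "sos_posterior_summary"))
  write_container(c(list(mean_sos = summary$mean_sos$values,
                         std_map = summary$std_map,
                         n_samples = summary$n_samples,
                         grid = summary$mean_sos$grid), extra),
                  path, "posterior")
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  rec <- read_container(path, "posterior", c("mean_sos", "std_map", "n_samples", "grid"))
  structure(list(mean_sos = sos_map(rec$mean_sos, rec$grid),
                 std_map = rec$std_map, n_samples = rec$n_samples),
            class = "sos_posterior_summary")
}

#' Read / write an inclusion mask as PNG
#'
#' Masks are stored as grayscale PNG with nonzero pixels marking the
#' inclusion.
#'
#' @param mask logical matrix.
#' @param path file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}
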