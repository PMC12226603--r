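#' Ring background mask around an inclusion
#'
#' Morphological dilation of the inclusion mask by `ceil(ring_mm / pitch)`
#' pixels per axis (anisotropic pitches honored) with an axis-aligned
#' rectangular structuring element, minus the inclusion itself; clipped to the
#' image bounds and disjoint from the inclusion by construction.
#'
#' @param inclusion logical inclusion mask (matrix `n_ax x n_lat`).
#' @param grid the [imaging_grid()] the mask lives on.
#' @param ring_mm ring width in mm (default 5).
#' @return Logical ring mask.
#' @export
ring_background_mask <- function(inclusion, grid, ring_mm = 5) {
  inclusion <- inclusion != 0
  if (!any(inclusion)) stop("empty inclusion mask")
  stopifnot(nrow(inclusion) == grid$n_ax, ncol(inclusion) == grid$n_lat, ring_mm >= 0)
  r_ax <- ceiling(ring_mm / grid$pitch_ax)
  r_lat <- ceiling(ring_mm / grid$pitch_lat)
  if (r_ax == 0 && r_lat == 0) return(matrix(FALSE, grid$n_ax, grid$n_lat))
  se <- matrix(1, 2 * r_ax + 1, 2 * r_lat + 1)
  dil <- corr2_same(inclusion * 1, se, r_ax, r_lat) > 0.5
  dil & !inclusion
}

#' Score one frame by inclusion and relative uncertainty
#'
#' `inc_unc` is the mean of the uncertainty map inside the inclusion,
#' `bkg_unc` the mean over the surrounding ring, and the relative
#' (inclusion-to-background normalized) uncertainty is their absolute
#' difference.
#'
#' @param summary an `sos_posterior_summary`.
#' @param inclusion logical inclusion mask on the summary grid.
#' @param ring_mm ring width in mm.
#' @param stat aggregation over the mask: `"mean"` (default) or `"median"`.
#' @return An object of class `sos_frame_score` with `inc_unc`, `bkg_unc`,
#'   `rel_unc` (m/s).
#' @export
score_frame <- function(summary, inclusion, ring_mm = 5, stat = c("mean", "median")) {
  stopifnot(inherits(summary, "sos_posterior_summary"))
  stat <- match.arg(stat)
  inclusion <- inclusion != 0
  grid <- summary$mean_sos$grid
  if (!any(inclusion)) stop("empty inclusion mask")
  ring <- ring_background_mask(inclusion, grid, ring_mm)
  if (!any(ring)) stop("empty ring background mask")
  agg <- if (stat == "mean") mean else median
  inc_unc <- agg(summary$std_map[inclusion])
  bkg_unc <- agg(summary$std_map[ring])
  structure(list(inc_unc = inc_unc, bkg_unc = bkg_unc,
                 rel_unc = abs(inc_unc - bkg_unc)),
            class = "sos_frame_score")
}

#' @export
print.sos_frame_score <- function(x, ...) {
  cat(sprintf("<sos_frame_score> inclusion %.3f, background %.3f, relative %.3f m/s\n",
              x$inc_unc, x$bkg_unc, x$rel_unc))
  invisible(x)
}

#' Select one acquisition frame
#'
#' Selection policies: `SI_rel` (argmin relative uncertainty), `SI_inc`
#' (argmin inclusion uncertainty), the uninformed baselines `S1` (first
#' frame), `S3` (third frame, requires at least 3), and `SR` (uniform random
#' draw). Ties are broken by the lowest index; all policies except `SR` are
#' deterministic. Indices are 1-based.
#'
#' @param scores list of `sos_frame_score`s, one per frame.
#' @param policy one of `"SI_rel"`, `"SI_inc"`, `"S1"`, `"S3"`, `"SR"`.
#' @param seed optional seed for `SR`.
#' @return Selected frame index (1-based).
#' @export
select_frame <- function(scores, policy = c("SI_rel", "SI_inc", "S1", "S3", "SR"),
                         seed = NULL) {
  policy <- match.arg(policy)
  n <- length(scores)
  if (n < 1) stop("empty score list")
  switch(policy,
    SI_rel = which.min(vapply(scores, `[[`, numeric(1), "rel_unc")),
    SI_inc = which.min(vapply(scores, `[[`, numeric(1), "inc_unc")),
    S1 = 1L,
    S3 = {
      if (n < 3) stop("policy S3 requires at least 3 frames")
      3L
    },
    SR = {
      if (!is.null(seed)) set.seed(seed)
      sample.int(n, 1)
    })
}
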