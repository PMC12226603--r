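#' SoS contrast of an inclusion
#'
#' `delta_c = |median inclusion SoS - median background SoS|`, with the
#' background taken over the same 5 mm ring used for relative uncertainty
#' scoring. The differential-diagnosis statistic: carcinomas present a higher
#' SoS contrast than fibroadenomas.
#'
#' @param c an [sos_map()] (typically the posterior-mean reconstruction).
#' @param inclusion logical inclusion mask.
#' @param ring_mm ring width in mm.
#' @return An object of class `sos_contrast`: `delta_c`, `c_inc_median`,
#'   `c_bkg_median` (m/s).
#' @export
sos_contrast <- function(c, inclusion, ring_mm = 5) {
  stopifnot(inherits(c, "sos_map"))
  inclusion <- inclusion != 0
  if (!any(inclusion)) stop("empty inclusion mask")
  ring <- ring_background_mask(inclusion, c$grid, ring_mm)
  if (!any(ring)) stop("empty ring background mask")
  ci <- median(c$values[inclusion])
  cb <- median(c$values[ring])
  structure(list(delta_c = abs(ci - cb), c_inc_median = ci, c_bkg_median = cb),
            class = "sos_contrast")
}

#' @export
print.sos_contrast <- function(x, ...) {
  cat(sprintf("<sos_contrast> delta_c = %.2f m/s (inclusion %.1f, background %.1f)\n",
              x$delta_c, x$c_inc_median, x$c_bkg_median))
  invisible(x)
}

#' Root-mean-square reconstruction error
#'
#' `sqrt(mean((c - c_hat)^2))` over all pixels, in m/s.
#'
#' @param c_hat reconstructed [sos_map()] (or matrix).
#' @param c_gt ground-truth [sos_map()] (or matrix).
#' @export
rmse <- function(c_hat, c_gt) {
  a <- if (inherits(c_hat, "sos_map")) c_hat$values else as.matrix(c_hat)
  b <- if (inherits(c_gt, "sos_map")) c_gt$values else as.matrix(c_gt)
  if (!all(dim(a) == dim(b))) stop("shape mismatch between reconstruction and ground truth")
  sqrt(mean((a - b)^2))
}

#' ROC analysis of contrast-based lesion classification
#'
#' Carcinoma (CA) is the positive class; scores are oriented so that larger
#' values indicate CA. The ROC is swept over the unique scores (classify
#' positive when `score >= threshold`), AUC computed via the rank statistic
#' (ties credited 0.5, equivalent to trapezoidal integration), and the
#' operating point chosen to maximize sensitivity + specificity, ties going
#' to the lower threshold. F1 = TP / (TP + (FP + FN)/2) at that point.
#'
#' @param scores numeric scores (e.g. per-case `delta_c`).
#' @param labels positive-class indicator: logical, 0/1, or `"CA"`/`"FA"`.
#' @return An object of class `sos_roc`: `auc`, `f1`, `sensitivity`,
#'   `specificity`, `threshold`, and the swept `roc` data frame.
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- as.character(labels) == "CA"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores))
  roc <- data.frame(threshold = th,
                    sensitivity = vapply(th, function(t) sum(scores >= t & labels) / n1, 0),
                    specificity = vapply(th, function(t) sum(scores < t & !labels) / n0, 0))
  best <- which.max(roc$sensitivity + roc$specificity)   # ties -> lower threshold
  t0 <- roc$threshold[best]
  tp <- sum(scores >= t0 & labels); fp <- sum(scores >= t0 & !labels)
  fn <- sum(scores < t0 & labels)
  structure(list(auc = auc,
                 f1 = tp / (tp + 0.5 * (fp + fn)),
                 sensitivity = roc$sensitivity[best],
                 specificity = roc$specificity[best],
                 threshold = t0, roc = roc),
            class = "sos_roc")
}

#' @export
print.sos_roc <- function(x, ...) {
  cat(sprintf("<sos_roc> AUC %.3f, F1 %.3f, sens %.3f / spec %.3f at threshold %.3g\n",
              x$auc, x$f1, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' Wilcoxon rank-sum group comparison
#'
#' Two-sided unpaired rank-sum (Mann-Whitney) test with midranks for ties:
#' exact null distribution for combined n <= 12 without ties, normal
#' approximation with tie correction otherwise.
#'
#' @param group_a,group_b numeric samples (e.g. `delta_c` of CA and FA cases).
#' @return List with `statistic` (Mann-Whitney U of `group_a`), `p_value`,
#'   `method`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b)) <= 12 && !ties
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation with tie correction")
}
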