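#' Dice similarity coefficient
#'
#' `DSC(A, B) = 2|A intersect B| / (|A| + |B|)`.  Both masks empty is defined
#' as 1 (perfect agreement on "nothing"); exactly one empty gives 0.
#'
#' @param A,B [binary_mask()] objects on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(A, B) {
  stopifnot_same_grid(A, B)
  a <- A$voxels != 0; b <- B$voxels != 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Dice coefficient with a border tolerance margin
#'
#' Disagreeing voxels whose Euclidean distance to the other mask's surface is
#' at most `tol_voxels * spacing` are counted as agreeing (they join the
#' intersection and the union), then the Dice formula is applied.  With
#' `tol_voxels = 0` this reduces exactly to [dsc()]; a mask shifted by one
#' voxel against itself scores 1 at the default tolerance.
#'
#' @inheritParams dsc
#' @param tol_voxels tolerance margin in voxels.
#' @return Scalar in \[0, 1\], always `>= dsc(A, B)`.
#' @export
dsc_tolerance <- function(A, B, tol_voxels = 1) {
  stopifnot_same_grid(A, B)
  a <- A$voxels != 0; b <- B$voxels != 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  inter <- sum(a & b)
  thr <- tol_voxels * max(A$spacing) + 1e-9
  count_tolerated <- function(diff_mask, other) {
    w <- which(diff_mask, arr.ind = TRUE)
    if (nrow(w) == 0) return(0)
    surf <- surface_points(other)
    if (nrow(surf) == 0) return(0)
    d <- cpp_nn_dist(index_to_world(A, w), surf)
    sum(d <= thr)
  }
  tA <- count_tolerated(a & !b, B)
  tB <- count_tolerated(b & !a, A)
  2 * (inter + tA + tB) / (na + nb + tA + tB)
}

#' Precision and recall of a predicted mask
#'
#' `precision = |A intersect B| / |B|`, `recall = |A intersect B| / |A|`
#' with `A` the reference (truth) and `B` the prediction.  An empty
#' prediction leaves precision undefined (`NA`) with a warning.
#'
#' @param A truth [binary_mask()].
#' @param B predicted [binary_mask()].
#' @return Named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(A, B) {
  stopifnot_same_grid(A, B)
  a <- A$voxels != 0; b <- B$voxels != 0
  inter <- sum(a & b)
  prec <- if (sum(b) == 0) {
    warning("empty prediction: precision undefined")
    NA_real_
  } else inter / sum(b)
  rec <- if (sum(a) == 0) NA_real_ else inter / sum(a)
  c(precision = prec, recall = rec)
}

# world coordinates of a mask's surface voxels (face-adjacent to background;
# grid border counts as background)
surface_points <- function(mask) {
  d <- dim(mask$voxels)
  surf <- cpp_surface6(mask$voxels != 0, d)
  w <- which(array(surf, d), arr.ind = TRUE)
  index_to_world(mask, w)
}

directed_surface_distances <- function(A, B) {
  pa <- surface_points(A)
  pb <- surface_points(B)
  if (nrow(pa) == 0 || nrow(pb) == 0) stop("empty mask")
  list(ab = cpp_nn_dist(pa, pb), ba = cpp_nn_dist(pb, pa))
}

#' 95th-percentile symmetric Hausdorff surface distance
#'
#' `HD95(A, B) = max(q95(hd(A, B)), q95(hd(B, A)))` over surface-voxel
#' center-to-center Euclidean distances in world mm, with the 95th percentile
#' taken by linear interpolation of the empirical distribution.
#'
#' @inheritParams dsc
#' @return Distance in mm.
#' @export
hd95 <- function(A, B) {
  stopifnot_same_grid(A, B)
  d <- directed_surface_distances(A, B)
  max(stats::quantile(d$ab, 0.95, names = FALSE, type = 7),
      stats::quantile(d$ba, 0.95, names = FALSE, type = 7))
}

#' Average symmetric surface distance
#'
#' `ASD(A, B) = (sum_a d(a, B) + sum_b d(A, b)) / (|A| + |B|)` over surface
#' voxels, world mm.
#'
#' @inheritParams dsc
#' @return Distance in mm.
#' @export
asd <- function(A, B) {
  stopifnot_same_grid(A, B)
  d <- directed_surface_distances(A, B)
  (sum(d$ab) + sum(d$ba)) / (length(d$ab) + length(d$ba))
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-rater ICC (McGraw &
#' Wong ICC(A,1)), computed from the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`.  This variant
#' is used because volumetric and measurement agreement are assessed as
#' absolute agreement between two fixed raters.
#'
#' @param rater1,rater2 equal-length numeric vectors (length >= 3), no
#'   missing values.
#' @return Scalar in (-1, 1\].
#' @export
icc_a1 <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) stop("vectors differ in length")
  if (length(rater1) < 3) stop("need at least 3 paired measurements")
  if (anyNA(rater1) || anyNA(rater2)) stop("missing values not allowed")
  Y <- cbind(rater1, rater2)
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  if (sum((Y - gm)^2) < 1e-24) stop("zero total variance")
  MSR <- k * sum((rowMeans(Y) - gm)^2) / (n - 1)
  MSC <- n * sum((colMeans(Y) - gm)^2) / (k - 1)
  SSE <- sum((Y - gm)^2) - (n - 1) * MSR - (k - 1) * MSC
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

#' Per-case segmentation evaluation report
#'
#' Evaluates DSC, tolerance DSC, precision, recall, HD95 and ASD for paired
#' truth/prediction masks and aggregates them the way segmentation studies
#' report them: mean +/- SD for the spatial metrics, median \[IQR\] for the
#' distance metrics.
#'
#' @param truths,preds lists of [binary_mask()] objects (same length, same
#'   grids pairwise).
#' @param ids optional case identifiers.
#' @return list with `per_case` (data frame) and `aggregate` (data frame of
#'   formatted summaries).
#' @export
metric_report <- function(truths, preds, ids = NULL) {
  stopifnot(length(truths) == length(preds))
  ids <- ids %||% seq_along(truths)
  rows <- lapply(seq_along(truths), function(i) {
    A <- truths[[i]]; B <- preds[[i]]
    pr <- suppressWarnings(precision_recall(A, B))
    data.frame(case = ids[i], dsc = dsc(A, B),
               dsc_tol1 = dsc_tolerance(A, B, 1),
               precision = pr[["precision"]], recall = pr[["recall"]],
               hd95_mm = hd95(A, B), asd_mm = asd(A, B))
  })
  per_case <- do.call(rbind, rows)
  msd <- function(x) sprintf("%.3f +/- %.3f", mean(x), stats::sd(x))
  miqr <- function(x) sprintf("%.3f [%.3f-%.3f]", stats::median(x),
                              stats::quantile(x, 0.25),
                              stats::quantile(x, 0.75))
  aggregate <- data.frame(
    metric = c("dsc", "dsc_tol1", "precision", "recall", "hd95_mm", "asd_mm"),
    summary = c(msd(per_case$dsc), msd(per_case$dsc_tol1),
                msd(per_case$precision), msd(per_case$recall),
                miqr(per_case$hd95_mm), miqr(per_case$asd_mm)))
  list(per_case = per_case, aggregate = aggregate)
}
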