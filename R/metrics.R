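#' Compose the nested evaluation regions from a label volume
#'
#' The three clinically reported regions are nested unions of the raw
#' labels: whole tumor (1, 2, 4), tumor core (1, 4) and enhancing tumor
#' (4).
#'
#' @param label a `label_volume` or integer array with values in
#'   \{0, 1, 2, 4\}.
#' @return list of logical arrays `wt`, `tc`, `et`.
#' @export
compose_regions <- function(label) {
  x <- if (inherits(label, "label_volume")) label$data else label
  check_label_values_(x)
  list(wt = array(x %in% c(1L, 2L, 4L), dim(x)),
       tc = array(x %in% c(1L, 4L), dim(x)),
       et = array(x == 4L, dim(x)))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 TP / (FP + 2 TP + FN)`. By convention two empty masks score 1 and
#' exactly one empty mask scores 0.
#'
#' @param pred,gt logical arrays of identical shape.
#' @return scalar in [0, 1].
#' @export
dice_score <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stopf_("dice_score: shapes differ")
  np <- sum(pred); ng <- sum(gt)
  if (np == 0 && ng == 0) return(1.0)
  if (np == 0 || ng == 0) return(0.0)
  tp <- sum(pred & gt)
  2 * tp / (np + ng)
}

# Surface voxels: mask voxels with at least one 6-connected non-mask
# neighbor (volume boundaries count as outside).
surface_mask_ <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_all <- function(m, axis, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(1, -1)) {
    interior <- interior & shift_all(mask, axis, by)
  }
  mask & !interior
}

#' 95th-percentile symmetric surface distance (HD95)
#'
#' Pools the directed surface-to-surface distances in both directions
#' (prediction to reference and reference to prediction) and reports the
#' 95th percentile, which discards boundary outliers that make the
#' maximum Hausdorff distance unstable. Distances use an exact Euclidean
#' distance transform and respect anisotropic voxel spacing. Two empty
#' masks give 0; exactly one empty mask is undefined and returns `NA`.
#'
#' @param pred,gt logical arrays of identical shape.
#' @param spacing numeric(3) voxel size per axis.
#' @return nonnegative scalar, or `NA_real_` when undefined.
#' @export
hausdorff95 <- function(pred, gt, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(gt))) stopf_("hausdorff95: shapes differ")
  np <- sum(pred); ng <- sum(gt)
  if (np == 0 && ng == 0) return(0.0)
  if (np == 0 || ng == 0) return(NA_real_)
  d <- dim(pred)
  sp <- surface_mask_(pred)
  sg <- surface_mask_(gt)
  dt_g <- edt3d(as.vector(sg), d[1], d[2], d[3], as.numeric(spacing))
  dt_p <- edt3d(as.vector(sp), d[1], d[2], d[3], as.numeric(spacing))
  dists <- c(dt_g[as.vector(sp)], dt_p[as.vector(sg)])
  as.numeric(quantile(dists, 0.95, names = FALSE))
}

#' Evaluate one predicted labeling against the reference
#'
#' @param pred_label,gt_label `label_volume`s (or raw arrays) of
#'   identical shape.
#' @param spacing numeric(3) voxel size.
#' @param case_id identifier for the report row.
#' @return one-row [tibble::tibble()] with columns `case_id`,
#'   `dice_wt/tc/et` and `hd95_wt/tc/et` (`NA` where undefined).
#' @export
evaluate_case <- function(pred_label, gt_label, spacing = c(1, 1, 1),
                          case_id = "case") {
  rp <- compose_regions(pred_label)
  rg <- compose_regions(gt_label)
  tibble::tibble(case_id = case_id,
                 dice_wt = dice_score(rp$wt, rg$wt),
                 dice_tc = dice_score(rp$tc, rg$tc),
                 dice_et = dice_score(rp$et, rg$et),
                 hd95_wt = hausdorff95(rp$wt, rg$wt, spacing),
                 hd95_tc = hausdorff95(rp$tc, rg$tc, spacing),
                 hd95_et = hausdorff95(rp$et, rg$et, spacing))
}

#' Aggregate per-case metrics
#'
#' Means are taken over defined (non-`NA`) values; the number of
#' undefined cases is reported alongside, since cases lacking a region
#' (for instance low-grade gliomas without enhancing tumor) are excluded
#' rather than silently penalized.
#'
#' @param metrics a tibble of [evaluate_case()] rows.
#' @return tibble with one row per metric: `metric`, `mean`, `n_defined`,
#'   `n_undefined`.
#' @export
aggregate_metrics <- function(metrics) {
  if (nrow(metrics) == 0) stopf_("aggregate_metrics: empty metric table")
  cols <- setdiff(names(metrics), "case_id")
  tibble::tibble(metric = cols,
                 mean = vapply(cols, function(cl) mean(metrics[[cl]], na.rm = TRUE),
                               numeric(1), USE.NAMES = FALSE),
                 n_defined = vapply(cols, function(cl) sum(!is.na(metrics[[cl]])),
                                    integer(1), USE.NAMES = FALSE),
                 n_undefined = vapply(cols, function(cl) sum(is.na(metrics[[cl]])),
                                      integer(1), USE.NAMES = FALSE))
}
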