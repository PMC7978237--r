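#' Slice-integral volume of a binary mask stack
#'
#' Integrates the in-plane area of each frame over the sweep:
#' `sum_t area(mask_t) * dy * dx * dz`, assuming the transducer moved at
#' constant uniform velocity so frames are equally spaced slices.
#'
#' @param mask T x H x W binary array.
#' @param spacing c(dz per frame, dy, dx); defaults to voxel units.
#' @export
integral_volume <- function(mask, spacing = c(1, 1, 1)) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (!all(mask %in% c(0, 1))) stop("integral_volume expects a binary mask")
  sum(mask) * prod(spacing)
}

#' Clinical ellipsoid volume approximation
#'
#' `(pi/6) * L * W * H` from the three full caliper extents, the standard
#' bedside estimate of thyroid (and nodule) volume.
#' @param L,W,H full extents along the three axes (> 0).
#' @export
ellipsoid_volume <- function(L, W, H) {
  if (any(c(L, W, H) <= 0)) stop("extents must be positive")
  pi / 6 * L * W * H
}

#' Percent difference between ellipsoid and integral volume
#'
#' `100 * (ellipsoid_v - integral_v) / integral_v`; negative values mean the
#' ellipsoid approximation underestimates the integral volume.
#' @param ellipsoid_v,integral_v volumes (integral_v > 0).
#' @export
percent_difference <- function(ellipsoid_v, integral_v) {
  if (integral_v <= 0) stop("integral volume must be positive")
  100 * (ellipsoid_v - integral_v) / integral_v
}

# full extents (in spacing units) of the nonzero region along t, y, x
mask_extents <- function(mask, spacing = c(1, 1, 1)) {
  if (!any(mask > 0)) return(c(L = 0, W = 0, H = 0))
  along <- function(k) {
    pr <- apply(mask, k, function(s) any(s > 0))
    (max(which(pr)) - min(which(pr)) + 1) * spacing[k]
  }
  c(L = along(1), W = along(3), H = along(2))
}

#' Sum-projections of a mask along the three axes
#'
#' Engineering-plane views: each projection sums the voxels along one axis,
#' so the total of every projection equals the class voxel count.
#' @param mask T x H x W array.
#' @return list of matrices `axial` (sum over t), `coronal` (sum over y),
#'   `sagittal` (sum over x).
#' @export
project_planes <- function(mask) {
  list(axial = apply(mask, c(2, 3), sum),
       coronal = apply(mask, c(1, 3), sum),
       sagittal = apply(mask, c(1, 2), sum))
}

#' Volume report for one segmented clip
#'
#' Per class (thyroid, cyst, nodule): slice-integral volume, caliper extents
#' of the region, the ellipsoid approximation from those extents, and the
#' percent difference between the two.
#'
#' @param masks a [mask_stack()] (ground truth or thresholded predictions).
#' @param spacing c(dz, dy, dx).
#' @return tibble, one row per class present.
#' @export
volume_report <- function(masks, spacing = c(1, 1, 1)) {
  layers <- list(thyroid = masks$thyroid == 1L,
                 cyst = masks$lesion == 1L,
                 nodule = masks$lesion == 2L)
  rows <- lapply(names(layers), function(cl) {
    m <- layers[[cl]] * 1
    iv <- integral_volume(m, spacing)
    ex <- mask_extents(m, spacing)
    ev <- if (all(ex > 0)) ellipsoid_volume(ex["L"], ex["W"], ex["H"]) else 0
    tibble::tibble(class = cl, integral_volume = iv, ellipsoid_volume = ev,
                   percent_difference = if (iv > 0) percent_difference(ev, iv) else NA_real_,
                   extent_L = ex[["L"]], extent_W = ex[["W"]], extent_H = ex[["H"]])
  })
  dplyr::bind_rows(rows)
}

#' Stratified metric report
#'
#' Mean and standard deviation of each metric per class within strata of a
#' manifest variable (echogenicity, malignancy or margins), in the layout of
#' a per-feature results table. Strata with no clips produce dash rows.
#'
#' @param per_clip tibble with columns `clip` (row index into the manifest),
#'   `class`, and metric columns iou, mcc, recall, precision, f2 — e.g. from
#'   [evaluate_cohort()].
#' @param manifest the cohort manifest.
#' @param strata manifest column names to stratify by.
#' @return tibble with stratum, class, and mean/sd columns per metric.
#' @export
stratified_report <- function(per_clip, manifest,
                              strata = c("echogenicity", "malignancy", "margins")) {
  metrics <- c("iou", "mcc", "recall", "precision", "f2")
  out <- list()
  for (sv in strata) {
    levs <- sort(unique(manifest[[sv]]))
    joined <- per_clip
    joined$stratum_value <- manifest[[sv]][per_clip$clip]
    for (lv in levs) {
      for (cl in sort(unique(per_clip$class))) {
        sub <- joined %>% filter(.data$stratum_value == lv, .data$class == cl)
        row <- tibble::tibble(stratum = sv, level = lv, class = cl, n_clips = nrow(sub))
        for (mt in metrics) {
          row[[paste0(mt, "_mean")]] <- if (nrow(sub)) mean(sub[[mt]]) else NA_real_
          row[[paste0(mt, "_sd")]] <- if (nrow(sub) > 1) sd(sub[[mt]]) else if (nrow(sub) == 1) 0 else NA_real_
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Threshold a probabilistic segmentation into a mask stack
#'
#' Thyroid at probability 0.5; the lesion layer takes each pixel's argmax
#' class among background/cyst/nodule.
#' @param seg a `cineseg_segoutput`.
#' @export
seg_to_masks <- function(seg) {
  thy <- (seg$thyroid_prob >= 0.5) * 1L
  am <- apply(seg$lesion_prob, c(1, 2, 3), which.max) - 1L
  mask_stack(thy, array(as.integer(am), dim(thy)))
}

#' Per-clip, per-class segmentation metrics for a cohort
#'
#' Compares thresholded predictions against ground truth per clip and class
#' (thyroid from the sigmoid head; cyst and nodule from the softmax argmax),
#' the aggregation granularity used for reported per-feature means.
#'
#' @param preds list of `cineseg_segoutput` (or mask stacks).
#' @param truths list of [mask_stack()].
#' @return tibble with clip, class and the five metrics.
#' @export
evaluate_cohort <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  rows <- list()
  for (i in seq_along(preds)) {
    pm <- if (inherits(preds[[i]], "cineseg_segoutput")) seg_to_masks(preds[[i]]) else preds[[i]]
    tm <- truths[[i]]
    pairs <- list(thyroid = list(pm$thyroid == 1L, tm$thyroid == 1L),
                  cyst = list(pm$lesion == 1L, tm$lesion == 1L),
                  nodule = list(pm$lesion == 2L, tm$lesion == 2L))
    for (cl in names(pairs)) {
      cc <- confusion_from_masks(pairs[[cl]][[1]], pairs[[cl]][[2]])
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(clip = i, class = cl), compute_metrics(cc))
    }
  }
  dplyr::bind_rows(rows)
}
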