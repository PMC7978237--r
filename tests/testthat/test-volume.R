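test_that("integral_volume sums slice areas exactly", {
  expect_equal(integral_volume(array(0L, c(3, 4, 4))), 0)
  m <- array(0L, c(3, 5, 5)); m[, 1:2, 1:5] <- 1L  # 10 pixels per frame
  expect_equal(integral_volume(m), 30)
  expect_equal(integral_volume(m, spacing = c(2, 1, 0.5)), 30)
  expect_error(integral_volume(m, spacing = c(0, 1, 1)), "positive")
  expect_error(integral_volume(array(0.5, c(1, 2, 2))), "binary")
})

test_that("a digitized ellipsoid integrates to within 2% of the analytic volume", {
  m <- digital_ellipsoid(20, 15, 12)
  expect_lt(abs(integral_volume(m) / (4 / 3 * pi * 20 * 15 * 12) - 1), 0.02)
})

test_that("ellipsoid_volume is the clinical pi/6 L W H formula", {
  expect_equal(ellipsoid_volume(2, 2, 2), pi / 6 * 8)
  d <- 7.3
  expect_equal(ellipsoid_volume(d, d, d), 4 / 3 * pi * (d / 2)^3)
  expect_equal(ellipsoid_volume(3 * 2, 3 * 3, 3 * 5), 27 * ellipsoid_volume(2, 3, 5))
  expect_error(ellipsoid_volume(0, 1, 1), "positive")
})

test_that("percent_difference follows the signed convention", {
  expect_equal(percent_difference(10, 10), 0)
  expect_equal(percent_difference(9, 10), -10)
  expect_error(percent_difference(1, 0), "positive")
  # ellipsoid limit: extents-based approximation agrees with the integral
  m <- digital_ellipsoid(16, 12, 10)
  vr <- volume_report(mask_stack(m, array(0L, dim(m))))
  thy <- vr[vr$class == "thyroid", ]
  expect_lt(abs(thy$percent_difference), 2)
})

test_that("integral volume is additive and monotone under dilation", {
  m <- digital_ellipsoid(8, 8, 6)
  m2 <- m; m2[m2 == 1] <- 0L
  m2[1:2, 1:3, 1:3] <- 1L  # disjoint block
  expect_equal(integral_volume(m) + integral_volume(m2),
               integral_volume(pmax(m, m2)))
  H <- dim(m)[2]
  grown <- m
  grown[, 2:H, ] <- pmax(m[, 2:H, ], m[, 1:(H - 1), ])  # dilate down one row
  expect_gte(integral_volume(grown), integral_volume(m))
})

test_that("the caliper ellipsoid formula underestimates band-shaped glands", {
  # lobulated phantoms: band-profile thyroid with lobulated nodules; the
  # gland fills its bounding box more fully than an ellipsoid, so the
  # clinical pi/6 L W H estimate falls short of the slice integral
  pds <- numeric(6)
  for (i in seq_len(6)) {
    spec <- phantom_spec(canvas = c(64, 64), n_frames = 16,
      thyroid_z_exponent = 4,
      lesions = list(list(kind = "nodule", echogenicity = "hypo",
                          margin = "lobulated",
                          lobe = list(a = 0.25, m = 3 + (i %% 4), phase = i),
                          center = c(30, 32, 8), semi = c(8, 10, 5))), seed = i)
    vr <- volume_report(generate_cineclip(spec)$masks)
    pds[i] <- vr$percent_difference[vr$class == "thyroid"]
  }
  expect_lte(mean(pds), 0)
  expect_true(all(pds < 0))
})

test_that("in-plane sinusoidal lobulation inflates calipers (sign reversal caveat)", {
  # protruding lobes stretch the bounding extents without filling them, so
  # for an isolated lobulated nodule the ellipsoid formula OVERestimates;
  # the gland-level underestimate above is the clinically reported direction
  spec <- phantom_spec(canvas = c(64, 64), n_frames = 16, lesions = list(
    list(kind = "nodule", echogenicity = "hypo", margin = "lobulated",
         lobe = list(a = 0.28, m = 4, phase = 1),
         center = c(30, 32, 8), semi = c(12, 14, 6))), seed = 2)
  vr <- volume_report(generate_cineclip(spec)$masks)
  expect_gt(vr$percent_difference[vr$class == "nodule"], 0)
})

test_that("plane projections conserve voxel counts and localize extents", {
  m <- array(0L, c(5, 6, 7)); m[3, 4, 2] <- 1L
  pr <- project_planes(m)
  for (p in pr) {
    expect_equal(sum(p), 1)
    expect_equal(sum(p > 0), 1)
  }
  me <- digital_ellipsoid(10, 8, 6)
  pr2 <- project_planes(me)
  expect_equal(sum(pr2$axial), sum(me))
  expect_equal(sum(pr2$coronal), sum(me))
  expect_equal(sum(pr2$sagittal), sum(me))
  # axial projection footprint matches the equatorial cross-section extents
  foot <- pr2$axial > 0
  expect_equal(diff(range(which(apply(foot, 1, any)))) + 1, 2 * 10 + 1, tolerance = 2)
  expect_equal(diff(range(which(apply(foot, 2, any)))) + 1, 2 * 8 + 1, tolerance = 2)
})

test_that("stratified reports aggregate per stratum with dashes for empty cells", {
  co <- tiny_cohort(6)
  # synthetic per-clip metrics: clip index i gets iou = i/10
  per_clip <- dplyr::bind_rows(lapply(seq_along(co$clips), function(i)
    tibble::tibble(clip = i, class = "nodule", iou = i / 10, mcc = 0.5,
                   recall = 0.6, precision = 0.7, f2 = 0.6)))
  rep <- stratified_report(per_clip, co$manifest, strata = "echogenicity")
  # singleton stratum: mean equals the clip value, sd 0
  ones <- rep[rep$n_clips == 1, ]
  if (nrow(ones)) {
    i <- per_clip$clip[match(TRUE, co$manifest$echogenicity == ones$level[1])]
    expect_equal(ones$iou_mean[1], per_clip$iou[per_clip$clip == i][1])
    expect_equal(ones$iou_sd[1], 0)
  }
  # empty strata emit NA (rendered as dashes)
  expect_true(all(is.na(rep$iou_mean[rep$n_clips == 0])))
  # pooled mean equals clip-count-weighted stratum means
  filled <- rep[rep$n_clips > 0, ]
  expect_equal(sum(filled$iou_mean * filled$n_clips) / sum(filled$n_clips),
               mean(per_clip$iou))
})
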