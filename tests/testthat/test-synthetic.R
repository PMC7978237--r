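test_that("phantom generation is deterministic and masks are seed-independent", {
  spec <- phantom_spec(n_frames = 8, lesions = list(
    list(kind = "nodule", echogenicity = "hypo", margin = "smooth",
         center = c(28, 32, 4), semi = c(8, 10, 3))), seed = 5)
  a <- generate_cineclip(spec)
  b <- generate_cineclip(spec)
  expect_identical(a$clip$frames, b$clip$frames)
  expect_identical(a$masks, b$masks)
  spec2 <- spec; spec2$seed <- 99L
  c2 <- generate_cineclip(spec2)
  expect_false(identical(a$clip$frames, c2$clip$frames))
  expect_identical(a$masks, c2$masks)   # geometry fixed => masks fixed
})

test_that("a nodule inside the thyroid stays inside it in every frame", {
  spec <- phantom_spec(n_frames = 10,
                       thyroid = list(center = c(30, 32, 5.5), semi = c(16, 24, 6)),
                       lesions = list(list(kind = "nodule", echogenicity = "hypo",
                                           margin = "smooth",
                                           center = c(30, 32, 5.5), semi = c(6, 8, 3))),
                       seed = 2)
  g <- generate_cineclip(spec)
  expect_true(all(g$masks$thyroid[g$masks$lesion == 2L] == 1L))
})

test_that("prevalence targets are met within band over many seeds", {
  # lesion z-span 35% of frames, cross-section sized for ~2% pixels
  fr <- px <- numeric(20)
  for (s in 1:20) {
    Tn <- 16; H <- 64; W <- 64
    rt <- 0.35 * Tn / 2
    ab <- 0.02 * Tn * H * W * 3 / (4 * pi * rt)
    spec <- phantom_spec(canvas = c(H, W), n_frames = Tn, lesions = list(
      list(kind = "nodule", echogenicity = "hypo", margin = "smooth",
           center = c(28, 32, Tn / 2), semi = c(sqrt(ab), sqrt(ab), rt))), seed = s)
    pv <- compute_prevalence(list(generate_cineclip(spec)$masks))
    fr[s] <- pv$frame_fraction[pv$class == "nodule"]
    px[s] <- pv$pixel_fraction[pv$class == "nodule"]
  }
  expect_lt(abs(mean(fr) - 0.35), 0.10)
  expect_lt(abs(mean(px) - 0.02), 0.01)
})

test_that("speckle is multiplicative with mean one", {
  spec0 <- phantom_spec(n_frames = 2, background_level = 0.3, thyroid_level = 0.6,
                        speckle_shape = 4)
  means <- vapply(1:50, function(s) {
    sp <- spec0; sp$seed <- s
    mean(generate_cineclip(sp)$clip$frames)
  }, 0)
  # clipped reflectivity mean: reflectivity field is seed-independent
  sp <- spec0
  refl <- matrix(0.3, 64, 64)
  tm <- cineseg:::ellipsoid_slice(sp$thyroid$center, sp$thyroid$semi, 1, 64, 64)
  refl[tm] <- 0.6
  expect_lt(abs(mean(means) / mean(refl) - 1), 0.02)
})

test_that("flicker perturbs frames only, never masks", {
  les <- list(list(kind = "nodule", echogenicity = "hypo", margin = "smooth",
                   center = c(28, 32, 4), semi = c(8, 10, 3)))
  s0 <- phantom_spec(n_frames = 8, lesions = les, flicker_prob = 0, seed = 3)
  s1 <- phantom_spec(n_frames = 8, lesions = les, flicker_prob = 1, seed = 3)
  g0 <- generate_cineclip(s0); g1 <- generate_cineclip(s1)
  expect_identical(g0$masks, g1$masks)
  nod <- g0$masks$lesion == 2L
  # obscured: contrast against thyroid strongly reduced in the frames
  expect_gt(mean(g1$clip$frames[nod]), mean(g0$clip$frames[nod]))
})

test_that("lesions entirely outside the canvas are skipped with a warning", {
  spec <- phantom_spec(n_frames = 6, lesions = list(
    list(kind = "cyst", echogenicity = "anechoic", margin = "smooth",
         center = c(200, 200, 3), semi = c(5, 5, 2))), seed = 1)
  expect_warning(g <- generate_cineclip(spec), "outside")
  expect_equal(sum(g$masks$lesion), 0)
})

test_that("compute_prevalence counts exactly and respects invariants", {
  m <- mask_stack(array(0L, c(1, 2, 2)),
                  array(c(2L, 0L, 0L, 0L), c(1, 2, 2)))
  pv <- compute_prevalence(list(m))
  expect_equal(pv$pixel_fraction[pv$class == "nodule"], 0.25)
  expect_equal(pv$frame_fraction[pv$class == "nodule"], 1.0)
  # lesion-layer classes partition the pixels
  expect_equal(sum(pv$pixel_fraction[pv$class %in% c("background", "cyst", "nodule")]), 1)
  # permutation invariance over frames
  co <- tiny_cohort(4)
  ms <- lapply(co$clips, `[[`, "masks")
  perm <- lapply(ms, function(m) {
    o <- rev(seq_len(dim(m$thyroid)[1]))
    mask_stack(m$thyroid[o, , , drop = FALSE], m$lesion[o, , , drop = FALSE])
  })
  expect_equal(compute_prevalence(ms), compute_prevalence(perm))
  expect_error(compute_prevalence(list()), "empty")
})

test_that("generated cohorts carry valid stratified manifests and reproduce bytewise", {
  co <- generate_cohort(5, n_frames = 6, seed = 21)
  expect_silent(validate_manifest(co$manifest))
  expect_true(any(co$manifest$n_pathology_cohort < 3))  # rare stratum present
  co2 <- generate_cohort(5, n_frames = 6, seed = 21)
  expect_identical(co$clips[[3]]$clip$frames, co2$clips[[3]]$clip$frames)
  expect_identical(co$manifest, co2$manifest)

  # pooled nodule-frame prevalence within the study band
  big <- tiny_cohort(20, n_frames = 12, seed = 31)
  pv <- compute_prevalence(lapply(big$clips, `[[`, "masks"))
  expect_gt(pv$frame_fraction[pv$class == "nodule"], 0.25)
  expect_lt(pv$frame_fraction[pv$class == "nodule"], 0.45)
})
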