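#' Specification of a synthetic sweep phantom
#'
#' A phantom emulates a transducer sweep across the neck: static 3-D
#' ellipsoids (a thyroid band plus lesions) are sliced by the imaging plane
#' at uniform velocity, so structures grow, shrink and enter/leave the view
#' across frames exactly as in a clinical cineclip. Frames are the
#' reflectivity map corrupted by multiplicative Gamma speckle (mean 1,
#' shape `speckle_shape`); masks are the exact noise-free cross-section
#' geometry and never depend on the seed.
#'
#' @param canvas (H, W) in pixels.
#' @param n_frames sweep length T.
#' @param thyroid list(center = c(y, x, t), semi = c(ry, rx, rt)).
#' @param lesions list of lesions: list(kind = "cyst"|"nodule", echogenicity =
#'   "hypo"|"iso"|"hyper"|"anechoic", margin = "smooth"|"ill-defined"|
#'   "lobulated", center, semi, lobe = list(a, m, phase)).
#' @param background_level,thyroid_level mean reflectivities in `[0, 1]`.
#' @param lesion_contrast reflectivity offset of hypo/hyper lesions from the
#'   thyroid level.
#' @param speckle_shape Gamma shape of the multiplicative speckle (smaller =
#'   noisier; 3-5 mimics B-mode texture).
#' @param flicker_prob per frame-and-lesion probability that the lesion is
#'   rendered at strongly reduced contrast (transient obscuration); affects
#'   frames only, never masks.
#' @param flicker_residual fraction of the contrast kept on flickered frames.
#' @param vessel optional list(center = c(y, x), semi = c(ry, rx)) adding a
#'   dark tube parallel to the sweep (cyst confounder); not in the masks.
#' @param thyroid_z_exponent exponent of the gland's cross-section profile
#'   along the sweep: 2 slices a true ellipsoid; larger values flatten the
#'   profile into a band whose cross-section stays near-constant over most
#'   of the sweep, as a real gland appears in a transverse sweep.
#' @param seed integer.
#' @export
phantom_spec <- function(canvas = c(64L, 64L), n_frames = 16L,
                         thyroid = list(center = c(canvas[1] * 0.45, canvas[2] * 0.5,
                                                   (n_frames + 1) / 2),
                                        semi = c(canvas[1] * 0.22, canvas[2] * 0.42,
                                                 n_frames * 0.55)),
                         lesions = list(),
                         background_level = 0.25, thyroid_level = 0.55,
                         lesion_contrast = 0.20, speckle_shape = 4,
                         flicker_prob = 0, flicker_residual = 0.15,
                         vessel = NULL, thyroid_z_exponent = 2, seed = 1L) {
  stopifnot(all(canvas >= 4), n_frames >= 1,
            all(thyroid$semi > 0),
            background_level >= 0, background_level <= 1,
            thyroid_level >= 0, thyroid_level <= 1,
            speckle_shape > 0, flicker_prob >= 0, flicker_prob <= 1)
  lesions <- lapply(lesions, function(le) {
    le$kind <- match.arg(le$kind, c("cyst", "nodule"))
    le$echogenicity <- match.arg(le$echogenicity, c("hypo", "iso", "hyper", "anechoic"))
    le$margin <- match.arg(le$margin %||% "smooth", c("smooth", "ill-defined", "lobulated"))
    if (any(le$semi <= 0)) stop("lesion semi-axes must be positive")
    if (le$margin == "lobulated" && is.null(le$lobe))
      le$lobe <- list(a = 0.25, m = 4L, phase = 0)
    if (!is.null(le$lobe) && le$lobe$a > 0.3) stop("lobulation amplitude a must be <= 0.3")
    le
  })
  structure(list(canvas = as.integer(canvas), n_frames = as.integer(n_frames),
                 thyroid = thyroid, lesions = lesions,
                 background_level = background_level, thyroid_level = thyroid_level,
                 lesion_contrast = lesion_contrast, speckle_shape = speckle_shape,
                 flicker_prob = flicker_prob, flicker_residual = flicker_residual,
                 vessel = vessel, thyroid_z_exponent = thyroid_z_exponent,
                 seed = as.integer(seed)),
            class = "cineseg_phantom_spec")
}

# in-plane cross-section of a 3D ellipsoid at frame t (logical H x W);
# z_exponent > 2 flattens the profile along the sweep (band-like gland)
ellipsoid_slice <- function(center, semi, t, H, W, lobe = NULL, z_exponent = 2) {
  s2 <- 1 - abs((t - center[3]) / semi[3])^z_exponent
  if (s2 <= 0) return(matrix(FALSE, H, W))
  sc <- sqrt(s2)
  u <- (seq_len(H) - center[1]) / (semi[1] * sc)
  v <- (seq_len(W) - center[2]) / (semi[2] * sc)
  U <- matrix(u, H, W); V <- matrix(v, H, W, byrow = TRUE)
  rho <- sqrt(U^2 + V^2)
  if (is.null(lobe)) rho <= 1
  else rho <= 1 + lobe$a * sin(lobe$m * atan2(V, U) + lobe$phase)
}

# separable Gaussian blur with edge replication
gauss_blur <- function(img, sigma = 2) {
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  xi <- pmin(pmax(outer(seq_len(H), -r:r, `+`), 1), H)
  tmp <- matrix(0, H, W)
  for (j in seq_along(k)) tmp <- tmp + k[j] * img[xi[, j], , drop = FALSE]
  yi <- pmin(pmax(outer(seq_len(W), -r:r, `+`), 1), W)
  out <- matrix(0, H, W)
  for (j in seq_along(k)) out <- out + k[j] * tmp[, yi[, j], drop = FALSE]
  out
}

lesion_level <- function(le, spec) {
  switch(le$echogenicity,
         anechoic = 0.02,
         hypo = max(0, spec$thyroid_level - spec$lesion_contrast),
         iso = spec$thyroid_level,
         hyper = min(1, spec$thyroid_level + spec$lesion_contrast))
}

#' Generate a phantom cineclip with exact ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `clip` ([cineclip()]), `masks` ([mask_stack()]) and the
#'   echoed `spec`.
#' @export
generate_cineclip <- function(spec) {
  stopifnot(inherits(spec, "cineseg_phantom_spec"))
  H <- spec$canvas[1]; W <- spec$canvas[2]; Tn <- spec$n_frames
  # drop lesions that never intersect the canvas/sweep
  keep <- vapply(spec$lesions, function(le) {
    inplane <- le$center[1] + le$semi[1] > 1 && le$center[1] - le$semi[1] < H &&
               le$center[2] + le$semi[2] > 1 && le$center[2] - le$semi[2] < W
    insweep <- le$center[3] + le$semi[3] > 1 && le$center[3] - le$semi[3] < Tn
    inplane && insweep
  }, TRUE)
  if (any(!keep)) warning(sum(!keep), " lesion(s) entirely outside the canvas; skipped")
  lesions <- spec$lesions[keep]
  set.seed(spec$seed)
  frames <- array(0, c(Tn, H, W))
  thy <- les <- array(0L, c(Tn, H, W))
  for (t in seq_len(Tn)) {
    refl <- matrix(spec$background_level, H, W)
    tm <- ellipsoid_slice(spec$thyroid$center, spec$thyroid$semi, t, H, W,
                          z_exponent = spec$thyroid_z_exponent)
    refl[tm] <- spec$thyroid_level
    if (!is.null(spec$vessel))
      refl[ellipsoid_slice(c(spec$vessel$center, (Tn + 1) / 2),
                           c(spec$vessel$semi, Tn), t, H, W)] <- 0.05
    thy[t, , ] <- tm * 1L
    lmask_codes <- matrix(0L, H, W)
    for (le in lesions) {
      cross <- ellipsoid_slice(le$center, le$semi, t, H, W, le$lobe)
      if (!any(cross)) next
      lev <- lesion_level(le, spec)
      if (spec$flicker_prob > 0 && runif(1) < spec$flicker_prob)
        lev <- spec$thyroid_level + spec$flicker_residual * (lev - spec$thyroid_level)
      if (le$margin == "ill-defined") {
        delta <- matrix(0, H, W); delta[cross] <- lev - refl[cross]
        refl <- refl + gauss_blur(delta, sigma = 2)
      } else {
        refl[cross] <- lev
      }
      lmask_codes[cross] <- if (le$kind == "cyst") 1L else 2L
    }
    les[t, , ] <- lmask_codes
    noise <- matrix(rgamma(H * W, shape = spec$speckle_shape,
                           rate = spec$speckle_shape), H, W)
    frames[t, , ] <- pmin(pmax(refl * noise, 0), 1)
  }
  list(clip = cineclip(frames, patient_id = "phantom", source_shape = c(H, W)),
       masks = mask_stack(thy, les), spec = spec)
}

#' Class prevalence of a set of mask stacks
#'
#' Exact frame-level and pixel-level fractions per class. The lesion-layer
#' classes (background, cyst, nodule) partition the pixels, so their pixel
#' fractions sum to 1; thyroid is reported from its own layer.
#'
#' @param masks a list of [mask_stack()] objects.
#' @return tibble with columns class, frame_fraction, pixel_fraction.
#' @export
compute_prevalence <- function(masks) {
  if (!length(masks)) stop("compute_prevalence: empty mask list")
  npx <- nfr <- 0
  pix <- c(background = 0, cyst = 0, nodule = 0, thyroid = 0)
  frm <- c(background = 0, cyst = 0, nodule = 0, thyroid = 0)
  for (m in masks) {
    d <- dim(m$lesion)
    npx <- npx + prod(d); nfr <- nfr + d[1]
    pix <- pix + c(sum(m$lesion == 0L), sum(m$lesion == 1L), sum(m$lesion == 2L),
                   sum(m$thyroid == 1L))
    per_frame <- function(layer, code) sum(apply(layer == code, 1, any))
    frm <- frm + c(per_frame(m$lesion, 0L), per_frame(m$lesion, 1L),
                   per_frame(m$lesion, 2L), per_frame(m$thyroid, 1L))
  }
  tibble::tibble(class = names(pix),
                 frame_fraction = unname(frm / nfr),
                 pixel_fraction = unname(pix / npx))
}

#' Generate a synthetic patient cohort with manifest
#'
#' Draws per-patient phantom geometry so the pooled statistics match the
#' prevalence targets (nodules in ~35% of frames and ~2% of pixels by
#' default), randomizes echogenicity, margins and malignancy labels,
#' synthesizes pathology strata (including one rare cohort when
#' `n_patients >= 5`) and returns clips, masks and a valid manifest ready
#' for [split_by_patient()].
#'
#' @param n_patients number of patients (one clip per patient by default).
#' @param per_patient_clips clips per patient.
#' @param prevalence_targets list(frame, pixel, cyst_rate).
#' @param canvas,n_frames phantom geometry.
#' @param flicker_prob passed to every [phantom_spec()].
#' @param speckle_shape speckle concentration.
#' @param seed master seed; the cohort is byte-identical for a fixed seed.
#' @return list with `clips` (list of list(clip, masks, spec)) and `manifest`.
#' @export
generate_cohort <- function(n_patients, per_patient_clips = 1L,
                            prevalence_targets = list(frame = 0.35, pixel = 0.02,
                                                      cyst_rate = 0.5),
                            canvas = c(64L, 64L), n_frames = 16L,
                            flicker_prob = 0, speckle_shape = 4, seed = 1L) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  H <- canvas[1]; W <- canvas[2]
  pathopool <- c("colloid_nodule", "papillary_carcinoma", "follicular_adenoma")
  clips <- list(); rows <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    pathology <- if (i == 5) "metastatic_rare_synthetic"
                 else pathopool[1 + (i %% length(pathopool))]
    for (j in seq_len(per_patient_clips)) {
      thy_semi <- c(H * runif(1, 0.18, 0.26), W * runif(1, 0.36, 0.45),
                    n_frames * runif(1, 0.5, 0.62))
      thy_c <- c(H * runif(1, 0.4, 0.5), W * runif(1, 0.45, 0.55), (n_frames + 1) / 2)
      # nodule sized from the prevalence targets: z-extent from the frame
      # target, in-plane area from the pixel target
      ft <- min(0.5, max(0.2, rnorm(1, prevalence_targets$frame, 0.04)))
      fp <- max(5e-3, rnorm(1, prevalence_targets$pixel, 0.003))
      rt <- ft * n_frames / 2
      ab <- fp * n_frames * H * W * 3 / (4 * pi * rt)
      q <- runif(1, 0.8, 1.25)
      ry <- min(sqrt(ab * q), thy_semi[1] * 0.85)
      rx <- min(ab / ry, thy_semi[2] * 0.6)
      ecs <- sample(c("hypo", "iso", "hyper"), 1, prob = c(0.6, 0.25, 0.15))
      mgs <- sample(c("smooth", "ill-defined", "lobulated"), 1, prob = c(0.5, 0.2, 0.3))
      mal <- sample(c("benign", "malignant"), 1, prob = c(0.7, 0.3))
      nod <- list(kind = "nodule", echogenicity = ecs, margin = mgs,
                  center = c(thy_c[1] + runif(1, -0.25, 0.25) * thy_semi[1],
                             thy_c[2] + runif(1, -0.45, 0.45) * thy_semi[2],
                             n_frames * runif(1, 0.35, 0.65)),
                  semi = c(ry, rx, rt))
      lesions <- list(nod)
      if (runif(1) < prevalence_targets$cyst_rate) {
        lesions <- c(lesions, list(list(
          kind = "cyst", echogenicity = "anechoic", margin = "smooth",
          center = c(thy_c[1] + runif(1, -0.4, 0.4) * thy_semi[1],
                     thy_c[2] + runif(1, -0.6, 0.6) * thy_semi[2],
                     n_frames * runif(1, 0.3, 0.7)),
          semi = c(ry, rx, rt) * runif(1, 0.45, 0.7))))
      }
      spec <- phantom_spec(canvas = canvas, n_frames = n_frames,
                           thyroid = list(center = thy_c, semi = thy_semi),
                           lesions = lesions, flicker_prob = flicker_prob,
                           speckle_shape = speckle_shape,
                           seed = sample.int(.Machine$integer.max - 1L, 1))
      clips[[length(clips) + 1]] <- suppressWarnings(generate_cineclip(spec))
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = pid, clip_path = sprintf("%s_clip%d.tif", pid, j),
        mask_path = sprintf("%s_clip%d", pid, j), pathology = pathology,
        n_pathology_cohort = NA_integer_, echogenicity = ecs, margins = mgs,
        malignancy = mal, split = "unassigned")
    }
  }
  manifest <- dplyr::bind_rows(rows)
  coh <- manifest %>% dplyr::distinct(.data$patient_id, .data$pathology) %>%
    dplyr::count(.data$pathology, name = "n_pathology_cohort")
  manifest$n_pathology_cohort <- NULL
  manifest <- dplyr::left_join(manifest, coh, by = "pathology")[, manifest_cols]
  validate_manifest(manifest)
  list(clips = clips, manifest = manifest)
}
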