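# shared fixtures, built in code and cached per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# sharp bright disk on dark background
disk_image <- function(H = 128, r = 30, lo = 0.1, hi = 0.9) {
  yy <- matrix(seq_len(H), H, H); xx <- t(yy)
  disk <- ((yy - H / 2)^2 + (xx - H / 2)^2) <= r^2
  img <- matrix(lo, H, H); img[disk] <- hi
  list(img = img, disk = disk)
}

# small phantom cohort with assigned splits
tiny_cohort <- function(n = 6, n_frames = 8, seed = 11, flicker = 0) {
  cached(sprintf("cohort_%d_%d_%d_%g", n, n_frames, seed, flicker), {
    co <- generate_cohort(n, n_frames = n_frames, flicker_prob = flicker, seed = seed)
    co$manifest <- split_by_patient(co$manifest, c(0.6, 0.2, 0.2), seed = seed)
    co
  })
}

tiny_cfg <- function(...) tiny_model_config(...)

# central-difference numerical gradient
num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# manifest row helper
manifest_row <- function(pid, pathology = "a", n_cohort = 5, split = "unassigned") {
  tibble::tibble(patient_id = pid, clip_path = paste0(pid, ".tif"),
                 mask_path = pid, pathology = pathology,
                 n_pathology_cohort = n_cohort, echogenicity = "hypo",
                 margins = "smooth", malignancy = "benign", split = split)
}

# digitized solid ellipsoid mask (T x H x W), semi-axes (c frames, a rows,
# b cols); half-integer centring makes the digitization symmetric, so the
# voxel-set extents match the continuous calipers without a grid-offset bias
digital_ellipsoid <- function(a, b, c, pad = 2) {
  Tn <- 2 * (c + pad); H <- 2 * (a + pad); W <- 2 * (b + pad)
  arr <- array(0L, c(Tn, H, W))
  for (t in seq_len(Tn)) {
    s2 <- 1 - ((t - Tn / 2 - 0.5) / c)^2
    if (s2 <= 0) next
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    arr[t, , ] <- (((yy - H / 2 - 0.5) / (a * sqrt(s2)))^2 +
                   ((xx - W / 2 - 0.5) / (b * sqrt(s2)))^2 <= 1) * 1L
  }
  arr
}
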