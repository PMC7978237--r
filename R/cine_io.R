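#' @importFrom dplyr %>% filter group_by summarise bind_rows arrange
NULL

#' Cineclip container
#'
#' A cineclip is a T x H x W stack of grayscale B-mode frames. Tissue
#' intensities lie in `[0, 1]`; pixels outside the imaged region carry the
#' sentinel value -1, which lets a model distinguish genuinely dark tissue at
#' the frame edge from filler introduced by aspect-preserving resizing.
#'
#' @param frames T x H x W numeric array.
#' @param patient_id opaque identifier.
#' @param side "left", "right" or "unknown".
#' @param source_shape original (H0, W0) before preprocessing.
#' @export
cineclip <- function(frames, patient_id = "unknown", side = "unknown",
                     source_shape = dim(frames)[2:3]) {
  stopifnot(length(dim(frames)) == 3)
  side <- match.arg(side, c("left", "right", "unknown"))
  obj <- structure(list(frames = frames, patient_id = patient_id, side = side,
                        source_shape = as.integer(source_shape)),
                   class = "cineseg_cineclip")
  validate_cineclip(obj)
  obj
}

validate_cineclip <- function(clip) {
  f <- clip$frames
  if (length(dim(f)) != 3 || dim(f)[1] < 1) stop("cineclip frames must be a T x H x W array with T >= 1")
  tissue <- f[f != -1]
  if (length(tissue) && (min(tissue) < 0 || max(tissue) > 1))
    stop("cineclip tissue intensities must lie in [0, 1] (sentinel pixels exactly -1)")
  invisible(clip)
}

#' Two-layer ground-truth mask stack
#'
#' Dual-output ground truth: a binary thyroid layer and an exclusive lesion
#' layer coded 0 = background, 1 = cyst, 2 = nodule. Lesions may extend
#' outside the thyroid layer; no containment is enforced.
#'
#' @param thyroid,lesion T x H x W integer arrays.
#' @export
mask_stack <- function(thyroid, lesion) {
  obj <- structure(list(thyroid = thyroid, lesion = lesion),
                   class = "cineseg_maskstack")
  validate_mask_stack(obj)
  obj
}

validate_mask_stack <- function(m, clip = NULL) {
  if (!identical(dim(m$thyroid), dim(m$lesion)))
    stop("mask layers disagree in shape: thyroid ",
         paste(dim(m$thyroid), collapse = "x"), " vs lesion ",
         paste(dim(m$lesion), collapse = "x"))
  if (!all(m$thyroid %in% c(0L, 1L))) stop("thyroid layer must be binary")
  if (!all(m$lesion %in% c(0L, 1L, 2L)))
    stop("lesion layer codes must be in {0 background, 1 cyst, 2 nodule}; saw ",
         paste(setdiff(unique(as.vector(m$lesion)), 0:2), collapse = ", "))
  if (!is.null(clip) && !identical(dim(m$thyroid), dim(clip$frames)))
    stop("mask shape ", paste(dim(m$thyroid), collapse = "x"),
         " does not match clip shape ", paste(dim(clip$frames), collapse = "x"))
  invisible(m)
}

#' Resize a frame with aspect preservation and sentinel padding
#'
#' The larger dimension is scaled to `target` pixels and the other scaled to
#' preserve the aspect ratio (bilinear for frames); the tissue block is
#' anchored top-left on a `target` x `target` canvas whose remaining pixels
#' are set exactly to -1. Intensities are rescaled to `[0, 1]` when the
#' input range exceeds it (8/16-bit sources divide by the nominal maximum;
#' otherwise min-max).
#'
#' @param image H0 x W0 numeric matrix.
#' @param target canvas side length (>= 2).
#' @param nearest use nearest-neighbor interpolation (for label images).
#' @return list with `frame` (target x target, padded) and `scale`.
#' @export
resize_with_padding <- function(image, target = 256L, nearest = FALSE) {
  if (is.null(dim(image)) || length(dim(image)) != 2 || any(dim(image) == 0))
    stop("resize_with_padding: input must be a non-empty 2-D matrix")
  if (target < 2) stop("target must be >= 2")
  h0 <- nrow(image); w0 <- ncol(image)
  mx <- max(image); mn <- min(image)
  if (mx > 1 || mn < 0) {
    if (mn >= 0 && mx <= 255) image <- image / 255
    else if (mn >= 0 && mx <= 65535) image <- image / 65535
    else image <- if (mx > mn) (image - mn) / (mx - mn) else image * 0
  }
  scale <- target / max(h0, w0)
  h1 <- if (h0 >= w0) target else as.integer(round(h0 * target / w0))
  w1 <- if (w0 > h0) target else as.integer(round(w0 * target / h0))
  tissue <- if (nearest) {
    ri <- pmin(pmax(ceiling((seq_len(h1) - 0.5) * h0 / h1), 1), h0)
    ci <- pmin(pmax(ceiling((seq_len(w1) - 0.5) * w0 / w1), 1), w0)
    image[ri, ci, drop = FALSE]
  } else {
    bilinear_matrix(h0, h1) %*% image %*% t(bilinear_matrix(w0, w1))
  }
  canvas <- matrix(-1, target, target)
  canvas[seq_len(h1), seq_len(w1)] <- pmin(pmax(tissue, 0), 1)
  list(frame = canvas, scale = scale)
}

#' Preprocess a whole clip and its masks to the canonical padded canvas
#' @param frames T x H0 x W0 array; masks optional [mask_stack()].
#' @param target canvas size.
#' @export
preprocess_cineclip <- function(frames, masks = NULL, target = 256L) {
  Tn <- dim(frames)[1]
  out <- array(-1, c(Tn, target, target))
  for (t in seq_len(Tn)) out[t, , ] <- resize_with_padding(frames[t, , ], target)$frame
  res <- list(frames = out)
  if (!is.null(masks)) {
    thy <- les <- array(0L, c(Tn, target, target))
    for (t in seq_len(Tn)) {
      r1 <- resize_with_padding(masks$thyroid[t, , ], target, nearest = TRUE)$frame
      r2 <- resize_with_padding(masks$lesion[t, , ] / 255, target, nearest = TRUE)$frame
      thy[t, , ] <- pmax(r1, 0)
      les[t, , ] <- as.integer(round(pmax(r2, 0) * 255))
    }
    res$masks <- mask_stack(thy, les)
  }
  res
}

# ---------------------------------------------------------------------------
# Manifest
# ---------------------------------------------------------------------------

manifest_cols <- c("patient_id", "clip_path", "mask_path", "pathology",
                   "n_pathology_cohort", "echogenicity", "margins",
                   "malignancy", "split")

#' Validate a dataset manifest
#'
#' A manifest is a tibble with one record per cineclip. Patient-wise split
#' integrity (no patient in more than one of train/validation/test) and
#' rare-pathology routing (cohorts of fewer than 3 patients only in
#' pretrain/train) are enforced.
#' @param manifest a data frame.
#' @export
validate_manifest <- function(manifest) {
  miss <- setdiff(manifest_cols, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  bad_split <- setdiff(unique(manifest$split),
                       c("pretrain", "train", "validation", "test", "unassigned"))
  if (length(bad_split)) stop("unknown split labels: ", paste(bad_split, collapse = ", "))
  core <- manifest %>% filter(.data$split %in% c("train", "validation", "test"))
  multi <- core %>% group_by(.data$patient_id) %>%
    summarise(k = dplyr::n_distinct(.data$split), .groups = "drop") %>% filter(.data$k > 1)
  if (nrow(multi))
    stop("patients assigned to multiple splits: ",
         paste(multi$patient_id, collapse = ", "))
  rare <- manifest %>% filter(.data$n_pathology_cohort < 3,
                              !.data$split %in% c("pretrain", "train", "unassigned"))
  if (nrow(rare))
    stop("rare-pathology patients (cohort < 3) must be routed to train: ",
         paste(unique(rare$patient_id), collapse = ", "))
  invisible(manifest)
}

#' @importFrom rlang .data
NULL

#' Patient-wise stratified split
#'
#' Rare-pathology patients (cohort size < 3) are assigned to the training set
#' first; the rest are stratified by pathology and randomly split per
#' `fractions`, so each pathology's proportions are approximately equal
#' across sets and no patient straddles splits. Deterministic given
#' `(manifest, fractions, seed)`.
#'
#' @param manifest manifest tibble (clip-level; splits assigned per patient).
#' @param fractions named or positional numeric (train, validation, test)
#'   summing to 1.
#' @param seed integer seed.
#' @export
split_by_patient <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (nrow(manifest) == 0) stop("empty manifest")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  fractions <- as.numeric(fractions)
  pts <- manifest %>%
    dplyr::distinct(.data$patient_id, .data$pathology, .data$n_pathology_cohort) %>%
    arrange(.data$patient_id)
  assign <- stats::setNames(rep("train", nrow(pts)), pts$patient_id)
  rare <- pts$n_pathology_cohort < 3
  rest <- pts[!rare, , drop = FALSE]
  set.seed(seed)
  labels <- c("train", "validation", "test")
  nsets <- sum(fractions > 0)
  for (pa in sort(unique(rest$pathology))) {
    ids <- sort(rest$patient_id[rest$pathology == pa])
    if (length(ids) < nsets) {
      warning("pathology stratum '", pa, "' smaller than the number of splits; assigned to train")
      assign[ids] <- "train"
      next
    }
    ids <- sample(ids)
    n <- length(ids)
    ntest <- round(n * fractions[3]); nval <- round(n * fractions[2])
    ntrain <- n - ntest - nval
    assign[ids] <- rep(labels, c(ntrain, nval, ntest))
  }
  pre <- manifest$split == "pretrain"   # pretrain-only resources keep their flag
  manifest$split <- unname(assign[manifest$patient_id])
  manifest$split[pre] <- "pretrain"
  validate_manifest(manifest)
  manifest
}

# ---------------------------------------------------------------------------
# Batch sampler
# ---------------------------------------------------------------------------

#' Frame index of a cohort: which (clip, frame) pairs contain a nodule
#' @param masks list of mask stacks, one per manifest record.
#' @export
frame_index <- function(masks) {
  bind_rows(lapply(seq_along(masks), function(i) {
    nod <- apply(masks[[i]]$lesion == 2L, 1, any)
    tibble::tibble(clip = i, frame = seq_along(nod), has_nodule = nod)
  }))
}

#' Nodule-oversampled batch sampler
#'
#' Returns a closure producing frame batches. With probability
#' `forced_nodule_ratio` a batch is "forced": every frame is drawn from the
#' nodule-bearing frames; otherwise frames are sampled uniformly. The
#' default ratio 2/3 reads "two batches chosen to include a nodule for every
#' three batches" as 2 forced in every 3; it is a configuration knob.
#' Alternative policies: "subsample" draws every batch with a fixed nodule
#' fraction; "duplicate" oversamples by doubling the nodule frames in the
#' uniform pool.
#'
#' @param index a [frame_index()] tibble.
#' @param batch_size frames per batch.
#' @param forced_nodule_ratio fraction of forced batches.
#' @param policy "forced_batches" (default), "subsample", or "duplicate".
#' @param subsample_frac nodule fraction per batch under "subsample".
#' @return function() -> tibble of `batch_size` rows with a `forced` flag.
#' @export
batch_sampler <- function(index, batch_size = 8L, forced_nodule_ratio = 2 / 3,
                          policy = c("forced_batches", "subsample", "duplicate"),
                          subsample_frac = 0.6) {
  policy <- match.arg(policy)
  nod <- which(index$has_nodule)
  if (forced_nodule_ratio > 0 && length(nod) == 0)
    stop("forced_nodule_ratio > 0 but the cohort has no nodule-bearing frames")
  all_rows <- seq_len(nrow(index))
  dup_pool <- c(all_rows, nod)
  function() {
    if (policy == "forced_batches") {
      forced <- runif(1) < forced_nodule_ratio
      rows <- if (forced) sample(nod, batch_size, replace = TRUE)
              else sample(all_rows, batch_size, replace = TRUE)
    } else if (policy == "subsample") {
      k <- round(batch_size * subsample_frac)
      rows <- c(sample(nod, k, replace = TRUE),
                sample(all_rows, batch_size - k, replace = TRUE))
      forced <- FALSE
    } else {
      rows <- sample(dup_pool, batch_size, replace = TRUE)
      forced <- FALSE
    }
    out <- index[rows, ]
    out$forced <- forced
    out
  }
}

# ---------------------------------------------------------------------------
# Persistence: float32 multi-page TIFF for frames, uint8 TIFF for masks,
# JSON for manifests. Frames are mapped [-1, 1] -> [0, 1] on write (the
# sentinel -1 becomes exactly 0.0) and inverted on read.
# ---------------------------------------------------------------------------

#' @rdname cineclip_io
#' @export
write_cineclip <- function(clip, path) {
  f <- clip$frames
  pages <- lapply(seq_len(dim(f)[1]), function(t) (f[t, , ] + 1) / 2)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(patient_id = clip$patient_id, side = clip$side,
               source_shape = clip$source_shape)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read and write cineclips and mask stacks
#'
#' Round-trips are lossless: mask labels bit-exact, frames within float32
#' precision (< 1e-6).
#' @param path TIFF file path (a `.json` sidecar holds clip metadata).
#' @param clip,masks objects to write.
#' @name cineclip_io
#' @export
read_cineclip <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  f <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) f[t, , ] <- pages[[t]] * 2 - 1
  f[abs(f + 1) < 1e-6] <- -1
  f[f != -1] <- pmin(pmax(f[f != -1], 0), 1)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list(patient_id = "unknown", side = "unknown", source_shape = dim(f)[2:3])
  cineclip(f, meta$patient_id, meta$side, meta$source_shape)
}

#' @rdname cineclip_io
#' @export
write_masks <- function(masks, path) {
  validate_mask_stack(masks)
  pg <- function(layer) lapply(seq_len(dim(layer)[1]), function(t) layer[t, , ] / 255)
  tiff::writeTIFF(pg(masks$thyroid), paste0(path, ".thyroid.tif"), bits.per.sample = 8L)
  tiff::writeTIFF(pg(masks$lesion), paste0(path, ".lesion.tif"), bits.per.sample = 8L)
  invisible(path)
}

#' @rdname cineclip_io
#' @export
read_masks <- function(path, clip = NULL) {
  rd <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    out <- array(0L, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (t in seq_along(pages)) out[t, , ] <- as.integer(pages[[t]])
    out
  }
  m <- mask_stack(rd(paste0(path, ".thyroid.tif")), rd(paste0(path, ".lesion.tif")))
  validate_mask_stack(m, clip)
  m
}

#' @rdname cineclip_io
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}

#' @rdname cineclip_io
#' @export
read_manifest <- function(path) {
  m <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_manifest(m)
  m
}
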