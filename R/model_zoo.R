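#' Model configuration
#'
#' Parameterizes the dual-output segmentation models: a residual backbone with
#' a three-convolution input stem, dilated (atrous) stage-3/4 convolutions in
#' place of striding, an atrous spatial pyramid pooling (ASPP) module, four
#' skip-fusion blocks, transposed-convolution upsampling heads, and the
#' bidirectional dilated ConvLSTM recurrent module.
#'
#' @param input_size integer (H, W) of network inputs.
#' @param width_multiplier positive scale applied to every filter count of the
#'   backbone, ASPP, fusion and recurrent module (counts are `ceiling(n * w)`,
#'   floored at 1). Width 1 is the full-size architecture; 1/8 is a desk-size
#'   instantiation whose parameter count scales approximately as the square of
#'   the multiplier.
#' @param block_counts identity-block repeats of the four residual stages
#'   (each stage additionally starts with one projection/convolution block).
#' @param leaky_alpha negative slope of the LeakyReLU activations.
#' @param output_stride total downsampling factor at the ASPP input, 8 or 16.
#' @param aspp_dilations dilation rates of the parallel atrous ASPP branches.
#' @param recurrent_filters base ConvLSTM filter count (scaled by
#'   `width_multiplier`; 32 at width 1).
#' @param recurrent_kernel ConvLSTM gate kernel size.
#' @param recurrent_dilations dilation rate of each of the four ConvLSTM
#'   block stacks.
#' @param window number of frames fed to the recurrent model (even; split into
#'   a forward and a backward backbone group).
#' @param lesion_classes channels of the softmax lesion head (background,
#'   cyst, nodule).
#' @param head_kernel,head_stride transposed-convolution parameters of the
#'   upsampling heads. The default kernel 8 / stride 4 restores the input
#'   resolution exactly from the stride-4 fused feature map with full output
#'   coverage; kernel 4 / stride 8 is accepted for experimentation but leaves
#'   uncovered output pixels and a mismatched output size.
#' @param current_index which frame of the window the recurrent model's
#'   prediction corresponds to; default `window / 2`.
#' @return a validated `cineseg_model_config` list.
#' @export
model_config <- function(input_size = c(256L, 256L),
                         width_multiplier = 1,
                         block_counts = c(2L, 4L, 23L, 2L),
                         leaky_alpha = 0.10,
                         output_stride = 8L,
                         aspp_dilations = c(6L, 12L, 18L),
                         recurrent_filters = 32L,
                         recurrent_kernel = c(3L, 3L),
                         recurrent_dilations = c(1L, 3L, 5L, 7L),
                         window = 6L,
                         lesion_classes = 3L,
                         head_kernel = 8L,
                         head_stride = 4L,
                         current_index = NULL) {
  stopifnot(width_multiplier > 0, length(block_counts) == 4)
  if (width_multiplier * 32 < 1) stop("width_multiplier too small: width_multiplier * 32 must be >= 1")
  if (!(output_stride %in% c(8L, 16L))) stop("output_stride must be 8 or 16")
  if (window < 2 || window %% 2 != 0) stop("window must be even and >= 2")
  if (is.null(current_index)) current_index <- window %/% 2L
  stopifnot(current_index >= 1, current_index <= window)
  cfg <- list(input_size = as.integer(input_size),
              width_multiplier = width_multiplier,
              block_counts = as.integer(block_counts),
              leaky_alpha = leaky_alpha,
              output_stride = as.integer(output_stride),
              aspp_dilations = as.integer(aspp_dilations),
              recurrent_filters = as.integer(recurrent_filters),
              recurrent_kernel = as.integer(recurrent_kernel),
              recurrent_dilations = as.integer(recurrent_dilations),
              window = as.integer(window),
              lesion_classes = as.integer(lesion_classes),
              head_kernel = as.integer(head_kernel),
              head_stride = as.integer(head_stride),
              current_index = as.integer(current_index))
  class(cfg) <- "cineseg_model_config"
  cfg
}

#' A small configuration for desk-size experiments on 64 x 64 phantoms
#'
#' Width 1/8, short ASPP dilations suited to 8 x 8 deep feature maps.
#' @param ... overrides passed on to [model_config()].
#' @export
tiny_model_config <- function(...) {
  args <- list(input_size = c(64L, 64L), width_multiplier = 1 / 8,
               aspp_dilations = c(2L, 4L, 6L), ...)
  do.call(model_config, args[!duplicated(names(args), fromLast = TRUE)])
}

sc_filters <- function(n, w) max(1L, as.integer(ceiling(n * w)))

# ---------------------------------------------------------------------------
# Builders. A model is an environment with $config, $layers (flat registry),
# $arch (structural grouping) and $kind ("static1", "static2", "recurrent").
# Layer environments are shared (not copied) between models derived from one
# another, which is how stage-2 inherits stage-1 weights and the recurrent
# model shares its frozen backbone.
# ---------------------------------------------------------------------------

new_model_env <- function(config, kind) {
  m <- new.env(parent = emptyenv())
  m$config <- config; m$kind <- kind
  m$layers <- list(); m$arch <- list()
  class(m) <- "cineseg_model"
  m
}

model_reg <- function(model, ly) { model$layers[[ly$name]] <- ly; ly }

# reuse a layer env from `base` when present (weight sharing), else create
mk <- function(model, base, name, create) {
  ly <- if (!is.null(base) && !is.null(base$layers[[name]])) base$layers[[name]] else create(name)
  model_reg(model, ly)
}

mk_cbl <- function(model, base, name, kh, cin, f, stride = 1L, dil = 1L) {
  list(conv = mk(model, base, paste0(name, ".conv"), function(n)
         new_conv(n, kh, kh, cin, f, stride, dil)),
       bn = mk(model, base, paste0(name, ".bn"), function(n) new_bn(n, f)))
}

mk_block <- function(model, base, name, kind, cin, xyz, stride = 1L, dil = 1L) {
  x <- xyz[1]; y <- xyz[2]; z <- xyz[3]
  bl <- list(kind = kind,
    c1 = mk(model, base, paste0(name, ".c1"), function(n) new_conv(n, 1L, 1L, cin, x)),
    b1 = mk(model, base, paste0(name, ".b1"), function(n) new_bn(n, x)),
    c2 = mk(model, base, paste0(name, ".c2"), function(n) new_conv(n, 3L, 3L, x, y, stride, dil)),
    b2 = mk(model, base, paste0(name, ".b2"), function(n) new_bn(n, y)),
    c3 = mk(model, base, paste0(name, ".c3"), function(n) new_conv(n, 1L, 1L, y, z)),
    b3 = mk(model, base, paste0(name, ".b3"), function(n) new_bn(n, z)))
  if (kind == "CB") {
    bl$pc <- mk(model, base, paste0(name, ".pc"), function(n) new_conv(n, 1L, 1L, cin, z, stride))
    bl$pb <- mk(model, base, paste0(name, ".pb"), function(n) new_bn(n, z))
  }
  bl
}

#' Build the backbone feature extractor
#'
#' Input stem of three convolutions (ResNet-C style) followed by max pooling;
#' four bottleneck-residual stages, the last two dilated (rates 2 and 4 at
#' output stride 8) instead of strided; ASPP; and four skip-fusion blocks
#' (1 x 1 convolutions on skip and main path, concatenation, batch
#' normalization, LeakyReLU), aligned to the shallowest skip so the fused
#' feature map sits at 1/4 of the input resolution.
#'
#' @param config a [model_config()].
#' @param base optional model whose identically named layers are shared.
#' @return a `cineseg_model` of kind "backbone".
#' @export
build_backbone <- function(config, base = NULL) {
  w <- config$width_multiplier
  m <- new_model_env(config, "backbone")
  s <- function(n) sc_filters(n, w)
  m$arch$stem <- list(
    mk_cbl(m, base, "stem1", 3L, 1L, s(32), stride = 2L),
    mk_cbl(m, base, "stem2", 3L, s(32), s(32)),
    mk_cbl(m, base, "stem3", 3L, s(32), s(64)))
  os16 <- config$output_stride == 16L
  stage_par <- list(
    list(xyz = c(s(64), s(64), s(256)), stride = 1L, dil = 1L),
    list(xyz = c(s(128), s(128), s(512)), stride = 2L, dil = 1L),
    list(xyz = c(s(256), s(256), s(1024)), stride = if (os16) 2L else 1L,
         dil = if (os16) 1L else 2L),
    list(xyz = c(s(512), s(512), s(2048)), stride = 1L, dil = if (os16) 2L else 4L))
  cin <- s(64)
  m$arch$stages <- vector("list", 4)
  for (k in 1:4) {
    sp <- stage_par[[k]]
    blocks <- list(mk_block(m, base, sprintf("s%d.cb", k), "CB", cin, sp$xyz, sp$stride, sp$dil))
    for (j in seq_len(config$block_counts[k]))
      blocks <- c(blocks, list(mk_block(m, base, sprintf("s%d.ib%d", k, j), "IB",
                                        sp$xyz[3], sp$xyz, 1L, sp$dil)))
    m$arch$stages[[k]] <- blocks
    cin <- sp$xyz[3]
  }
  fa <- s(256)
  m$arch$aspp <- list(
    b1 = mk_cbl(m, base, "aspp.b1", 1L, cin, fa),
    atrous = lapply(seq_along(config$aspp_dilations), function(i)
      mk_cbl(m, base, sprintf("aspp.d%d", config$aspp_dilations[i]), 3L, cin, fa,
             dil = config$aspp_dilations[i])),
    img = mk_cbl(m, base, "aspp.img", 1L, cin, fa),
    proj = mk_cbl(m, base, "aspp.proj", 1L, fa * (2L + length(config$aspp_dilations)), fa))
  skip_ch <- c(s(64), s(256), s(512), s(1024))
  ff <- s(128)
  prev <- fa
  m$arch$fusion <- vector("list", 4)
  for (k in 1:4) {
    m$arch$fusion[[k]] <- list(
      main = mk(m, base, sprintf("fuse%d.main", k), function(n) new_conv(n, 1L, 1L, prev, ff)),
      skip = mk(m, base, sprintf("fuse%d.skip", k), function(n) new_conv(n, 1L, 1L, skip_ch[k], ff)),
      bn = mk(m, base, sprintf("fuse%d.bn", k), function(n) new_bn(n, 2L * ff)))
    prev <- 2L * ff
  }
  m$fused_channels <- prev
  m
}

mk_head <- function(model, base, name, cin, cout, config) {
  list(dc = mk(model, base, paste0(name, ".dc"), function(n)
         new_convt(n, config$head_kernel, cout, cin, config$head_stride)),
       c1 = mk(model, base, paste0(name, ".c1"), function(n)
         new_conv(n, 1L, 1L, cout, cout)))
}

#' Build a static (frame-wise) segmentation model
#'
#' Stage 1 carries a single sigmoid thyroid head; stage 2 adds the
#' softmax cyst/nodule/background head on the same backbone. When `base` is
#' given (e.g. the trained stage-1 model), all shared layers are reused by
#' reference so pretrained weights carry over.
#'
#' @param config a [model_config()].
#' @param stage 1 or 2.
#' @param base optional model to inherit layers from.
#' @export
build_static_model <- function(config, stage = 2L, base = NULL) {
  stopifnot(stage %in% c(1L, 2L))
  m <- build_backbone(config, base)
  m$kind <- paste0("static", stage)
  m$arch$heads <- list(thy = mk_head(m, base, "head.thy", m$fused_channels, 1L, config))
  if (stage == 2L)
    m$arch$heads$les <- mk_head(m, base, "head.les", m$fused_channels,
                                config$lesion_classes, config)
  m
}

# ---------------------------------------------------------------------------
# Forward passes
# ---------------------------------------------------------------------------

cbl_fw <- function(tp, u, i, alpha, training) {
  t_lrelu(tp, t_bn(tp, u$bn, t_conv(tp, u$conv, i), training), alpha)
}

block_fw <- function(tp, bl, i, alpha, training) {
  h <- t_lrelu(tp, t_bn(tp, bl$b1, t_conv(tp, bl$c1, i), training), alpha)
  h <- t_lrelu(tp, t_bn(tp, bl$b2, t_conv(tp, bl$c2, h), training), alpha)
  h <- t_bn(tp, bl$b3, t_conv(tp, bl$c3, h), training)
  if (bl$kind == "IB") {
    h <- t_lrelu(tp, h, alpha)          # Table 10: IB activates before the add
    h <- t_add(tp, h, i)
  } else {
    sc <- t_bn(tp, bl$pb, t_conv(tp, bl$pc, i), training)
    h <- t_add(tp, h, sc)
  }
  t_lrelu(tp, h, alpha)
}

backbone_fw <- function(model, tp, x_id, training) {
  a <- model$config$leaky_alpha
  h <- x_id
  for (u in model$arch$stem) h <- cbl_fw(tp, u, h, a, training)
  skip <- integer(4)
  h <- t_maxpool(tp, h)
  skip[1] <- h
  for (k in 1:4) {
    for (bl in model$arch$stages[[k]]) h <- block_fw(tp, bl, h, a, training)
    if (k < 4) skip[k + 1] <- h
  }
  # ASPP
  as <- model$arch$aspp
  d <- dim(tp$vals[[h]])
  ids <- c(cbl_fw(tp, as$b1, h, a, training),
           vapply(as$atrous, function(u) cbl_fw(tp, u, h, a, training), 0L))
  g <- t_gap(tp, h)
  g <- cbl_fw(tp, as$img, g, a, training)
  ids <- c(ids, t_broadcast(tp, g, d[1], d[2]))
  h <- cbl_fw(tp, as$proj, t_concat(tp, ids), a, training)
  aspp_id <- h
  # skip fusion, aligned to the shallower (larger) spatial size
  for (k in 1:4) {
    fu <- model$arch$fusion[[k]]
    mo <- t_conv(tp, fu$main, h)
    so <- t_conv(tp, fu$skip, skip[k])
    dm <- dim(tp$vals[[mo]]); ds <- dim(tp$vals[[so]])
    Ht <- max(dm[1], ds[1]); Wt <- max(dm[2], ds[2])
    mo <- t_resize(tp, mo, Ht, Wt); so <- t_resize(tp, so, Ht, Wt)
    h <- t_lrelu(tp, t_bn(tp, fu$bn, t_concat(tp, c(mo, so)), training), a)
  }
  list(fused = h, skips = skip, aspp = aspp_id)
}

head_fw <- function(tp, hd, i, act) {
  h <- t_conv(tp, hd$c1, t_convt(tp, hd$dc, i))
  if (act == "sigmoid") t_sigmoid(tp, h) else t_softmax(tp, h)
}

# x: (H, W, 1, N). Returns tape plus node ids.
static_fw <- function(model, x, training = FALSE) {
  tp <- new_tape()
  xi <- t_input(tp, x)
  bb <- backbone_fw(model, tp, xi, training)
  out <- list(tp = tp, x = xi, fused = bb$fused, skips = bb$skips, aspp = bb$aspp)
  out$thy <- head_fw(tp, model$arch$heads$thy, bb$fused, "sigmoid")
  if (!is.null(model$arch$heads$les))
    out$les <- head_fw(tp, model$arch$heads$les, bb$fused, "softmax")
  out
}

# ---------------------------------------------------------------------------
# Recurrent model
# ---------------------------------------------------------------------------

#' Build the recurrent (stage-4) model
#'
#' The trained static model's backbone (through skip fusion) is frozen and
#' shared by all `window` frame replicas; each half-window group feeds its
#' fused feature maps through four bidirectional ConvLSTM blocks at dilation
#' rates 1, 3, 5 and 7, a final forward ConvLSTM summarizes the leading group
#' and a final backward ConvLSTM the trailing group, and their concatenation
#' drives fresh dual upsampling heads. At the default configuration the graph
#' contains exactly 18 ConvLSTM layers (2 groups x 4 blocks x 2 + 2).
#'
#' @param config a [model_config()].
#' @param pretrained_static a stage-1/2 model built from the same config.
#' @export
build_recurrent_model <- function(config, pretrained_static) {
  if (config$window %% 2L != 0L) stop("window must be even")
  m <- build_backbone(config, pretrained_static)
  m$kind <- "recurrent"
  for (ly in m$layers) ly$trainable <- FALSE  # freeze shared backbone + fusion
  rf <- sc_filters(config$recurrent_filters, config$width_multiplier)
  kk <- config$recurrent_kernel[1]
  cin0 <- m$fused_channels
  groups <- list()
  for (g in c("f", "b")) {
    blocks <- list(); cin <- cin0
    for (d in config$recurrent_dilations) {
      nm <- sprintf("rmod.%s.d%d", g, d)
      blocks[[length(blocks) + 1]] <- list(
        clf = model_reg(m, new_convlstm(paste0(nm, ".clf"), cin, rf, kk, d)),
        clb = model_reg(m, new_convlstm(paste0(nm, ".clb"), cin, rf, kk, d)),
        bn = model_reg(m, new_bn(paste0(nm, ".bn"), 2L * rf)))
      cin <- 2L * rf
    }
    groups[[g]] <- blocks
  }
  m$arch$rmod <- list(
    groups = groups,
    final_f = model_reg(m, new_convlstm("rmod.final.f", 2L * rf, rf, kk, 1L)),
    final_b = model_reg(m, new_convlstm("rmod.final.b", 2L * rf, rf, kk, 1L)),
    final_bn = model_reg(m, new_bn("rmod.final.bn", 2L * rf)))
  m$arch$heads <- list(
    thy = mk_head(m, NULL, "rhead.thy", 2L * rf, 1L, config),
    les = mk_head(m, NULL, "rhead.les", 2L * rf, config$lesion_classes, config))
  m
}

stack_time <- function(hs) {
  d <- dim(hs[[1]]); Tn <- length(hs)
  y <- array(0, c(d[1], d[2], d[3], d[4] * Tn))
  for (t in seq_len(Tn)) y[, , , (t - 1) * d[4] + seq_len(d[4])] <- hs[[t]]
  y
}
unstack_time <- function(y, Tn) {
  d <- dim(y); N <- d[4] %/% Tn
  lapply(seq_len(Tn), function(t) y[, , , (t - 1) * N + seq_len(N), drop = FALSE])
}

rgroup_fw <- function(blocks, seq, alpha, training) {
  caches <- list()
  for (bi in seq_along(blocks)) {
    bl <- blocks[[bi]]
    rf <- convlstm_fw(bl$clf, seq, reverse = FALSE)
    rb <- convlstm_fw(bl$clb, seq, reverse = TRUE)
    cat_t <- Map(function(a, b) {
      d <- dim(a); y <- array(0, c(d[1], d[2], 2 * d[3], d[4]))
      y[, , seq_len(d[3]), ] <- a; y[, , d[3] + seq_len(d[3]), ] <- b; y
    }, rf$hs, rb$hs)
    big <- stack_time(cat_t)
    bnc <- bn_forward(bl$bn, big, training)
    act <- lrelu(bnc$y, alpha)
    caches[[bi]] <- list(rf = rf, rb = rb, bn = bnc[c("mu", "invstd", "x", "training")],
                         pre = bnc$y)
    seq <- unstack_time(act, length(seq))
  }
  list(seq = seq, caches = caches)
}

rgroup_bw <- function(blocks, caches, dseq, alpha) {
  Tn <- length(dseq)
  for (bi in rev(seq_along(blocks))) {
    bl <- blocks[[bi]]; ca <- caches[[bi]]
    dbig <- stack_time(dseq) * lrelu_dmask(ca$pre, alpha)
    dcat <- bn_backward(bl$bn, ca$bn, dbig)
    dcat_t <- unstack_time(dcat, Tn)
    rfch <- bl$clf$filters
    d_f <- lapply(dcat_t, function(a) a[, , seq_len(rfch), , drop = FALSE])
    d_b <- lapply(dcat_t, function(a) a[, , rfch + seq_len(rfch), , drop = FALSE])
    dxf <- convlstm_bw(bl$clf, ca$rf, d_f)
    dxb <- convlstm_bw(bl$clb, ca$rb, d_b)
    dseq <- Map(`+`, dxf, dxb)
  }
  dseq
}

# feats: list of `window` fused feature maps (H, W, C, N windows).
# Returns probability maps for the current frame plus caches for backward.
rmod_fw <- function(model, feats, training = FALSE) {
  cfg <- model$config; a <- cfg$leaky_alpha
  half <- cfg$window %/% 2L
  rm <- model$arch$rmod
  gf <- rgroup_fw(rm$groups$f, feats[seq_len(half)], a, training)
  gb <- rgroup_fw(rm$groups$b, feats[half + seq_len(half)], a, training)
  ff <- convlstm_fw(rm$final_f, gf$seq, reverse = FALSE)
  fb <- convlstm_fw(rm$final_b, gb$seq, reverse = TRUE)
  hF <- ff$hs[[half]]   # state after the leading group's last frame
  hB <- fb$hs[[1]]      # state after the trailing group, scanned backward
  d <- dim(hF)
  cat2 <- array(0, c(d[1], d[2], 2 * d[3], d[4]))
  cat2[, , seq_len(d[3]), ] <- hF; cat2[, , d[3] + seq_len(d[3]), ] <- hB
  tp <- new_tape()
  ci <- t_input(tp, cat2)
  bi <- t_lrelu(tp, t_bn(tp, rm$final_bn, ci, training), a)
  thy <- head_fw(tp, model$arch$heads$thy, bi, "sigmoid")
  les <- head_fw(tp, model$arch$heads$les, bi, "softmax")
  list(thy_prob = tp$vals[[thy]], les_prob = tp$vals[[les]],
       cache = list(tp = tp, ci = ci, thy = thy, les = les, gf = gf, gb = gb,
                    ff = ff, fb = fb, half = half, rfch = dim(hF)[3]))
}

rmod_bw <- function(model, out, d_thy, d_les) {
  ca <- out$cache
  seeds <- list()
  seeds[[as.character(ca$thy)]] <- d_thy
  seeds[[as.character(ca$les)]] <- d_les
  grads <- t_backward(ca$tp, seeds, need_input_grads = TRUE)
  dcat <- grads[[ca$ci]]
  rfch <- ca$rfch; half <- ca$half
  dhF <- dcat[, , seq_len(rfch), , drop = FALSE]
  dhB <- dcat[, , rfch + seq_len(rfch), , drop = FALSE]
  rm <- model$arch$rmod
  dsF <- vector("list", half); dsF[[half]] <- dhF
  dsB <- vector("list", half); dsB[[1]] <- dhB
  dseq_f <- convlstm_bw(rm$final_f, ca$ff, dsF)
  dseq_b <- convlstm_bw(rm$final_b, ca$fb, dsB)
  rgroup_bw(rm$groups$f, ca$gf$caches, dseq_f, model$config$leaky_alpha)
  rgroup_bw(rm$groups$b, ca$gb$caches, dseq_b, model$config$leaky_alpha)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Inference over whole clips
# ---------------------------------------------------------------------------

pad_input <- function(x, mult = 16L) {
  d <- dim(x)
  Hp <- as.integer(ceiling(d[1] / mult) * mult); Wp <- as.integer(ceiling(d[2] / mult) * mult)
  if (Hp == d[1] && Wp == d[2]) return(list(x = x, H = d[1], W = d[2]))
  y <- array(-1, c(Hp, Wp, d[3], d[4]))
  y[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = y, H = d[1], W = d[2])
}

frames_to_input <- function(frames, idx) {
  # frames: T x H x W -> (H, W, 1, length(idx))
  d <- dim(frames)
  array(aperm(frames[idx, , , drop = FALSE], c(2, 3, 1)), c(d[2], d[3], 1L, length(idx)))
}

# compute fused feature maps of all frames (no gradients, eval-mode BN)
precompute_fused <- function(model, frames, chunk = 16L) {
  Tn <- dim(frames)[1]
  out <- vector("list", Tn)
  for (st in seq(1, Tn, by = chunk)) {
    idx <- st:min(Tn, st + chunk - 1L)
    px <- pad_input(frames_to_input(frames, idx))
    tp <- new_tape()
    bb <- backbone_fw(model, tp, t_input(tp, px$x), training = FALSE)
    fz <- tp$vals[[bb$fused]]
    for (j in seq_along(idx)) out[[idx[j]]] <- fz[, , , j, drop = FALSE]
  }
  out
}

#' Segment a cineclip
#'
#' Runs the model over every frame of a clip. Static models are applied
#' frame-wise; the recurrent model slides its `window` over the sweep (edge
#' frames replicated) and emits the prediction for the window's current
#' frame, so every frame receives exactly one prediction.
#'
#' @param model a `cineseg_model` (static or recurrent).
#' @param clip a [cineclip()] or a T x H x W frame array.
#' @param chunk frames (or windows) evaluated per batch.
#' @return a `cineseg_segoutput`: list with `thyroid_prob` (T x H x W) and
#'   `lesion_prob` (T x H x W x classes, softmax-normalized).
#' @export
segment_cineclip <- function(model, clip, chunk = 16L) {
  frames <- if (is.list(clip) && !is.null(clip$frames)) clip$frames else clip
  stopifnot(length(dim(frames)) == 3)
  d <- dim(frames); Tn <- d[1]
  nles <- model$config$lesion_classes
  thy <- array(0, c(Tn, d[2], d[3]))
  les <- array(0, c(Tn, d[2], d[3], nles))
  if (model$kind %in% c("static1", "static2")) {
    for (st in seq(1, Tn, by = chunk)) {
      idx <- st:min(Tn, st + chunk - 1L)
      px <- pad_input(frames_to_input(frames, idx))
      fw <- static_fw(model, px$x, training = FALSE)
      tpv <- fw$tp$vals
      thp <- tpv[[fw$thy]][seq_len(px$H), seq_len(px$W), 1, , drop = FALSE]
      thy[idx, , ] <- aperm(array(thp, c(px$H, px$W, length(idx))), c(3, 1, 2))
      if (!is.null(fw$les)) {
        lep <- tpv[[fw$les]][seq_len(px$H), seq_len(px$W), , , drop = FALSE]
        les[idx, , , ] <- aperm(lep, c(4, 1, 2, 3))
      } else {
        les[idx, , , 1] <- 1
      }
    }
  } else if (model$kind == "recurrent") {
    wnd <- model$config$window; ci <- model$config$current_index
    feats <- precompute_fused(model, frames, chunk)
    widx <- function(t) pmin(pmax(t - ci + seq_len(wnd), 1L), Tn)
    for (st in seq(1, Tn, by = chunk)) {
      idx <- st:min(Tn, st + chunk - 1L)
      fw_feats <- lapply(seq_len(wnd), function(k) {
        slabs <- lapply(idx, function(t) feats[[widx(t)[k]]])
        dd <- dim(slabs[[1]])
        array(unlist(slabs), c(dd[1], dd[2], dd[3], length(idx)))
      })
      out <- rmod_fw(model, fw_feats, training = FALSE)
      Hp <- dim(out$thy_prob)[1] ; Wp <- dim(out$thy_prob)[2]
      thp <- out$thy_prob[seq_len(min(d[2], Hp)), seq_len(min(d[3], Wp)), 1, , drop = FALSE]
      thy[idx, , ] <- aperm(array(thp, c(d[2], d[3], length(idx))), c(3, 1, 2))
      les[idx, , , ] <- aperm(out$les_prob[seq_len(d[2]), seq_len(d[3]), , , drop = FALSE],
                              c(4, 1, 2, 3))
    }
  } else stop("cannot segment with a model of kind ", model$kind)
  new_seg_output(thy, les)
}

#' @export
new_seg_output <- function(thyroid_prob, lesion_prob) {
  stopifnot(all(dim(thyroid_prob) == dim(lesion_prob)[1:3]))
  structure(list(thyroid_prob = thyroid_prob, lesion_prob = lesion_prob),
            class = "cineseg_segoutput")
}

# ---------------------------------------------------------------------------
# Introspection
# ---------------------------------------------------------------------------

layer_nparams <- function(ly) sum(vapply(ly$par, length, 0))

#' Summarize a model's layers
#'
#' One row per layer: name, type, kernel, filter count, dilation and
#' trainability — the basis of the architecture audits (ConvLSTM census,
#' freeze-scope checks, width-scaling law).
#'
#' @param model a `cineseg_model`.
#' @return a tibble.
#' @export
model_summary <- function(model) {
  rows <- lapply(model$layers, function(ly) tibble::tibble(
    name = ly$name, type = ly$type,
    kernel = if (!is.null(ly$kernel)) paste(ly$kernel, collapse = "x") else NA_character_,
    filters = if (!is.null(ly$filters)) ly$filters else NA_integer_,
    dilation = if (!is.null(ly$dilation)) ly$dilation else NA_integer_,
    trainable = ly$trainable, n_params = layer_nparams(ly)))
  dplyr::bind_rows(rows)
}

#' Total parameter count, optionally restricted to bottleneck-block convolutions
#' @param model a `cineseg_model`.
#' @param core_only count only the residual-stage convolution parameters.
#' @export
count_params <- function(model, core_only = FALSE) {
  s <- model_summary(model)
  if (core_only) s <- s[grepl("^s[1-4]\\.(cb|ib)", s$name) & s$type == "conv", ]
  sum(s$n_params)
}

trainable_layers <- function(model) Filter(function(ly) isTRUE(ly$trainable), model$layers)

#' Set layer trainability by freeze scope
#'
#' `"none"` leaves everything trainable, `"up_to_aspp"` freezes the stem,
#' residual stages and ASPP (skip-fusion and heads stay trainable),
#' `"backbone_all"` freezes everything built by [build_backbone()].
#' @param model a `cineseg_model`.
#' @param scope one of "none", "up_to_aspp", "backbone_all".
#' @export
set_freeze_scope <- function(model, scope = c("none", "up_to_aspp", "backbone_all")) {
  scope <- match.arg(scope)
  pre <- "^(stem|s[1-4]\\.|aspp)"
  bb <- "^(stem|s[1-4]\\.|aspp|fuse)"
  for (ly in model$layers) {
    ly$trainable <- switch(scope,
      none = TRUE,
      up_to_aspp = !grepl(pre, ly$name),
      backbone_all = !grepl(bb, ly$name))
  }
  invisible(model)
}
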