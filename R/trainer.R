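# Four-stage training protocol:
#   1. pre-train the single-output (thyroid) static model on the pretrain set
#   2. add the lesion head; train dual-output with nodule oversampling
#   3. freeze through ASPP; train the remaining output layers on full sequences
#   4. convert to the recurrent model (backbone frozen); train the ConvLSTM
#      module and fresh heads on full sequences

#' Table of augmentation operations per training stage
#'
#' Stage 1: horizontal flip 50%, rotation 25% (+-15 deg), translation 25%
#' (+-10%), color shift 10% (+-5%), crop 100% (300 px); stage 2 drops the
#' rotation, crops at 256 px and adds nodule oversampling (a sampler policy,
#' not a pixel op); stage 3 rotates 50% (+-5 deg); stage 4 uses flip 50% and
#' sequence reversal 50%.
#' @return named list of scheme tibbles (op, frequency, scale).
#' @export
default_schemes <- function() {
  sch <- function(...) {
    m <- rbind(...)
    tibble::tibble(op = m[, 1], frequency = as.numeric(m[, 2]), scale = as.numeric(m[, 3]))
  }
  list(
    stage1 = sch(c("hflip", 0.50, NA), c("rotate", 0.25, 15), c("translate", 0.25, 0.10),
                 c("color_shift", 0.10, 0.05), c("crop", 1.00, 300)),
    stage2 = sch(c("hflip", 0.50, NA), c("translate", 0.25, 0.10),
                 c("color_shift", 0.10, 0.05), c("crop", 1.00, 256)),
    stage3 = sch(c("hflip", 0.50, NA), c("rotate", 0.50, 5), c("translate", 0.25, 0.10),
                 c("color_shift", 0.10, 0.05), c("crop", 1.00, 256)),
    stage4 = sch(c("hflip", 0.50, NA), c("reverse_sequence", 0.50, NA)))
}

# inverse-mapped affine warp; bilinear for images (fill -1, sentinel snapped),
# nearest for labels (fill 0)
warp2d <- function(img, angle = 0, dy = 0, dx = 0, nearest = FALSE, fill = -1) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  a <- angle * pi / 180
  yy <- matrix(seq_len(H), H, W) - cy - dy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - dx
  sy <- cos(a) * yy + sin(a) * xx + cy
  sx <- -sin(a) * yy + cos(a) * xx + cx
  if (nearest) {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(fill, H, W)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sy); c0 <- floor(sx)
  fy <- sy - r0; fx <- sx - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- matrix(fill, H, W)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  out <- get(r0, c0) * (1 - fy) * (1 - fx) + get(r0 + 1, c0) * fy * (1 - fx) +
         get(r0, c0 + 1) * (1 - fy) * fx + get(r0 + 1, c0 + 1) * fy * fx
  out[out < 0] <- -1   # sentinel-contaminated pixels stay sentinel
  out
}

#' Apply an augmentation scheme to frames and masks
#'
#' Each operation fires independently with its frequency. Geometric
#' operations apply identically to frames and both mask layers (nearest
#' neighbor for labels); `color_shift` offsets tissue pixels only, leaving
#' the -1 sentinel untouched; `crop` takes a random square window of
#' `min(scale, canvas)` pixels and resizes back to the canvas;
#' `reverse_sequence` (sequence mode only) flips the temporal order of
#' frames and masks together.
#'
#' @param frames n x H x W array.
#' @param masks a [mask_stack()] aligned with `frames`.
#' @param scheme a scheme tibble from [default_schemes()].
#' @param sequence_mode draw one transform for the whole stack (TRUE) or
#'   independently per frame (FALSE); reverse_sequence requires TRUE.
#' @return list(frames, masks).
#' @export
augment <- function(frames, masks, scheme, sequence_mode = FALSE) {
  if (!sequence_mode && "reverse_sequence" %in% scheme$op &&
      any(scheme$frequency[scheme$op == "reverse_sequence"] > 0))
    stop("reverse_sequence applies to full sequences only")
  n <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  thy <- masks$thyroid; les <- masks$lesion
  draw_ops <- function() {
    fired <- scheme[runif(nrow(scheme)) < scheme$frequency, , drop = FALSE]
    pars <- list()
    for (k in seq_len(nrow(fired))) {
      op <- fired$op[k]; scl <- fired$scale[k]
      pars[[op]] <- switch(op,
        hflip = TRUE,
        rotate = runif(1, -scl, scl),
        translate = c(runif(1, -scl, scl) * H, runif(1, -scl, scl) * W),
        color_shift = runif(1, -scl, scl),
        crop = {
          cs <- min(scl, H, W)
          c(cs, sample.int(H - cs + 1L, 1), sample.int(W - cs + 1L, 1))
        },
        reverse_sequence = TRUE)
    }
    pars
  }
  apply_ops <- function(fr, th, le, pars) {
    if (!is.null(pars$hflip)) {
      fr <- fr[, W:1]; th <- th[, W:1]; le <- le[, W:1]
    }
    if (!is.null(pars$rotate) || !is.null(pars$translate)) {
      ang <- pars$rotate %||% 0
      tr <- pars$translate %||% c(0, 0)
      fr <- warp2d(fr, ang, tr[1], tr[2])
      th <- warp2d(th, ang, tr[1], tr[2], nearest = TRUE, fill = 0)
      le <- warp2d(le, ang, tr[1], tr[2], nearest = TRUE, fill = 0)
    }
    if (!is.null(pars$color_shift)) {
      tt <- fr != -1
      fr[tt] <- pmin(pmax(fr[tt] + pars$color_shift, 0), 1)
    }
    if (!is.null(pars$crop) && pars$crop[1] < min(H, W)) {
      cs <- pars$crop[1]; oy <- pars$crop[2]; ox <- pars$crop[3]
      idx <- function(m) m[oy:(oy + cs - 1), ox:(ox + cs - 1)]
      fr <- bilinear_matrix(cs, H) %*% idx(fr) %*% t(bilinear_matrix(cs, W))
      fr[fr < 0] <- -1; fr[fr > 1] <- 1
      nn <- pmin(pmax(ceiling((seq_len(H) - 0.5) * cs / H), 1), cs)
      nn2 <- pmin(pmax(ceiling((seq_len(W) - 0.5) * cs / W), 1), cs)
      th <- idx(th)[nn, nn2]; le <- idx(le)[nn, nn2]
    }
    list(fr = fr, th = th, le = le)
  }
  if (sequence_mode) {
    pars <- draw_ops()
    for (t in seq_len(n)) {
      r <- apply_ops(frames[t, , ], thy[t, , ], les[t, , ], pars)
      frames[t, , ] <- r$fr; thy[t, , ] <- r$th; les[t, , ] <- r$le
    }
    if (!is.null(pars$reverse_sequence)) {
      frames <- frames[n:1, , , drop = FALSE]
      thy <- thy[n:1, , , drop = FALSE]; les <- les[n:1, , , drop = FALSE]
    }
  } else {
    for (t in seq_len(n)) {
      r <- apply_ops(frames[t, , ], thy[t, , ], les[t, , ], draw_ops())
      frames[t, , ] <- r$fr; thy[t, , ] <- r$th; les[t, , ] <- r$le
    }
  }
  list(frames = frames, masks = mask_stack(array(as.integer(thy), dim(thy)),
                                           array(as.integer(les), dim(les))))
}

#' Plan for one training stage
#'
#' @param stage 1-4.
#' @param epochs passes over the stage's data.
#' @param batch_size frames (stages 1-2) or windows (stage 4) per step.
#' @param learning_rate Adam step size (defaults 1e-3 for stages 1-2, 1e-4
#'   for 3-4).
#' @param scheme augmentation scheme tibble; default per [default_schemes()].
#' @param forced_nodule_ratio stage-2 sampler ratio.
#' @param sampler_policy stage-2 sampler policy.
#' @param steps_per_epoch batches per epoch for sampled stages (default:
#'   cover the training frames once).
#' @param validate_every epochs between validation passes (0 = final only).
#' @param seed stage RNG seed.
#' @export
stage_plan <- function(stage, epochs = 8L, batch_size = 8L,
                       learning_rate = if (stage <= 2) 1e-3 else 1e-4,
                       scheme = default_schemes()[[paste0("stage", stage)]],
                       forced_nodule_ratio = 2 / 3,
                       sampler_policy = "forced_batches",
                       steps_per_epoch = NULL,
                       validate_every = 0L, seed = 1L) {
  stopifnot(stage %in% 1:4)
  structure(list(stage = as.integer(stage), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 scheme = scheme, forced_nodule_ratio = forced_nodule_ratio,
                 sampler_policy = sampler_policy, steps_per_epoch = steps_per_epoch,
                 validate_every = as.integer(validate_every), seed = as.integer(seed)),
            class = "cineseg_stage_plan")
}

# --- internal helpers -------------------------------------------------------

clips_for <- function(cohort, splits) {
  idx <- which(cohort$manifest$split %in% splits)
  cohort$clips[idx]
}

frames_tensor <- function(clip_list, rows) {
  # rows: tibble(clip, frame) indices into clip_list
  n <- nrow(rows)
  d <- dim(clip_list[[1]]$clip$frames)[2:3]
  fr <- array(0, c(n, d[1], d[2]))
  th <- le <- array(0L, c(n, d[1], d[2]))
  for (k in seq_len(n)) {
    cl <- clip_list[[rows$clip[k]]]
    fr[k, , ] <- cl$clip$frames[rows$frame[k], , ]
    th[k, , ] <- cl$masks$thyroid[rows$frame[k], , ]
    le[k, , ] <- cl$masks$lesion[rows$frame[k], , ]
  }
  list(frames = fr, masks = mask_stack(th, le))
}

# convert n x H x W stacks into network tensors
to_net <- function(frames, masks) {
  d <- dim(frames)
  x <- array(aperm(frames, c(2, 3, 1)), c(d[2], d[3], 1L, d[1]))
  thy <- aperm(masks$thyroid, c(2, 3, 1))
  cls <- aperm(pixel_class_codes(masks), c(2, 3, 1))
  list(x = x, thy = thy, cls = cls)
}

static_train_step <- function(model, batch, weights, lr, step_id, thyroid_only,
                              frozen_backbone = FALSE) {
  net <- to_net(batch$frames, batch$masks)
  fw <- static_fw(model, net$x, training = TRUE)
  tpv <- fw$tp$vals
  les_prob <- if (!thyroid_only && !is.null(fw$les)) tpv[[fw$les]] else NULL
  lg <- mcc_loss_grad(tpv[[fw$thy]], les_prob, net$thy, net$cls, weights)
  zero_grads(trainable_layers(model))
  seeds <- list()
  seeds[[as.character(fw$thy)]] <- lg$d_thy
  if (!is.null(les_prob)) seeds[[as.character(fw$les)]] <- lg$d_les
  # with the backbone frozen (stage 3) the gradient need not flow below ASPP
  t_backward(fw$tp, seeds, stop_at = if (frozen_backbone) fw$aspp else 0L)
  adam_step(trainable_layers(model), lr, step_id)
  lg$loss
}

validate_thyroid_iou <- function(model, clips) {
  ious <- vapply(clips, function(cl) {
    seg <- segment_cineclip(model, cl$clip)
    ev <- evaluate_cohort(list(seg), list(cl$masks))
    ev$iou[ev$class == "thyroid"]
  }, 0)
  mean(ious)
}

#' Run one training stage
#'
#' Dispatches on `plan$stage`; see the stage description at the top of the
#' trainer. `state` carries the models between stages (`static1`, `static2`,
#' `recurrent`), the class weights, and accumulated histories. Fully
#' reproducible given the plan seed.
#'
#' @param state list as returned by a previous stage, or `list()` to start.
#' @param cohort list(clips, manifest) with assigned splits.
#' @param plan a [stage_plan()].
#' @param config a [model_config()] (required at stage 1).
#' @return updated state; `state$history` gains per-epoch rows.
#' @export
run_stage <- function(state, cohort, plan, config = NULL) {
  stopifnot(inherits(plan, "cineseg_stage_plan"))
  set.seed(plan$seed)
  stage <- plan$stage
  train_clips <- clips_for(cohort, "train")
  val_clips <- clips_for(cohort, c("validation"))
  if (!length(val_clips)) val_clips <- if (length(train_clips)) train_clips[1] else cohort$clips[1]
  if (is.null(state$weights)) {
    ms <- lapply(train_clips, `[[`, "masks")
    if (!length(ms)) ms <- lapply(cohort$clips, `[[`, "masks")
    state$weights <- compute_class_weights(ms)
  }
  hist <- list()
  record <- function(epoch, loss, val) {
    hist[[length(hist) + 1]] <<- tibble::tibble(
      stage = stage, epoch = epoch, loss = loss, val_thyroid_iou = val)
  }
  if (stage == 1L) {
    if (is.null(config)) stop("stage 1 requires a model config")
    data_clips <- clips_for(cohort, c("pretrain", "train"))
    if (!length(data_clips)) {
      warning("no pretrain/train split found; falling back to all clips")
      data_clips <- cohort$clips
    }
    state$config <- config
    state$static1 <- build_static_model(config, stage = 1L)
    model <- state$static1
  } else if (stage == 2L) {
    if (is.null(state$static1)) stop("stage 2 requires the stage-1 model in state")
    data_clips <- train_clips
    state$static2 <- build_static_model(state$config, stage = 2L, base = state$static1)
    set_freeze_scope(state$static2, "none")
    model <- state$static2
  } else if (stage == 3L) {
    if (is.null(state$static2)) stop("stage 3 requires the stage-2 model in state")
    data_clips <- train_clips
    model <- state$static2
    set_freeze_scope(model, "up_to_aspp")
  } else {
    if (is.null(state$static2)) stop("stage 4 requires the stage-2 model in state")
    data_clips <- train_clips
    state$recurrent <- build_recurrent_model(state$config, state$static2)
    model <- state$recurrent
  }

  step_id <- 0L
  for (epoch in seq_len(plan$epochs)) {
    ep_loss <- c()
    if (stage %in% c(1L, 2L)) {
      idx <- frame_index(lapply(data_clips, `[[`, "masks"))
      sampler <- if (stage == 2L)
        batch_sampler(idx, plan$batch_size, plan$forced_nodule_ratio,
                      policy = plan$sampler_policy)
      else batch_sampler(idx, plan$batch_size, forced_nodule_ratio = 0)
      nsteps <- plan$steps_per_epoch %||% max(1L, nrow(idx) %/% plan$batch_size)
      for (s in seq_len(nsteps)) {
        rows <- sampler()
        bt <- frames_tensor(data_clips, rows)
        ag <- augment(bt$frames, bt$masks, plan$scheme, sequence_mode = FALSE)
        step_id <- step_id + 1L
        ep_loss <- c(ep_loss, static_train_step(model, ag, state$weights,
                                                plan$learning_rate, step_id,
                                                thyroid_only = stage == 1L))
      }
    } else if (stage == 3L) {
      for (ci in sample(seq_along(data_clips))) {
        cl <- data_clips[[ci]]
        ag <- augment(cl$clip$frames, cl$masks, plan$scheme, sequence_mode = TRUE)
        step_id <- step_id + 1L
        ep_loss <- c(ep_loss, static_train_step(model, ag, state$weights,
                                                plan$learning_rate, step_id,
                                                thyroid_only = FALSE,
                                                frozen_backbone = TRUE))
      }
    } else {
      wnd <- state$config$window; ci_out <- state$config$current_index
      for (ci in sample(seq_along(data_clips))) {
        cl <- data_clips[[ci]]
        ag <- augment(cl$clip$frames, cl$masks, plan$scheme, sequence_mode = TRUE)
        Tn <- dim(ag$frames)[1]
        feats <- precompute_fused(model, ag$frames)
        # supervise current frames drawn over the whole sweep, with the same
        # clamped edge-replicated windows that inference uses
        cur <- sample(seq_len(Tn), min(plan$batch_size, Tn))
        fw_feats <- lapply(seq_len(wnd), function(k) {
          slabs <- lapply(cur, function(t)
            feats[[min(max(t - ci_out + k, 1L), Tn)]])
          dd <- dim(slabs[[1]])
          array(unlist(slabs), c(dd[1], dd[2], dd[3], length(cur)))
        })
        out <- rmod_fw(model, fw_feats, training = TRUE)
        net <- to_net(ag$frames[cur, , , drop = FALSE],
                      mask_stack(ag$masks$thyroid[cur, , , drop = FALSE],
                                 ag$masks$lesion[cur, , , drop = FALSE]))
        lg <- mcc_loss_grad(out$thy_prob, out$les_prob, net$thy, net$cls, state$weights)
        zero_grads(trainable_layers(model))
        rmod_bw(model, out, lg$d_thy, lg$d_les)
        step_id <- step_id + 1L
        adam_step(trainable_layers(model), plan$learning_rate, step_id)
        ep_loss <- c(ep_loss, lg$loss)
      }
    }
    do_val <- (plan$validate_every > 0 && epoch %% plan$validate_every == 0) ||
              epoch == plan$epochs
    val <- if (do_val) validate_thyroid_iou(model, val_clips) else NA_real_
    record(epoch, mean(ep_loss), val)
  }
  state$history <- dplyr::bind_rows(state$history, dplyr::bind_rows(hist))
  state
}

#' Run the full four-stage protocol
#'
#' Chains stages 1-4, passing checkpointed models through `state`. Returns
#' the state with `static1`, `static2` (after stage-3 head refinement),
#' `recurrent`, class weights and the full training history.
#'
#' @param config a [model_config()].
#' @param cohort list(clips, manifest) with splits assigned.
#' @param seed master seed (stage seeds derive from it).
#' @param plans optional named list of [stage_plan()]s (`stage1`..`stage4`);
#'   stages absent from the list are skipped.
#' @export
run_full_protocol <- function(config, cohort, seed = 1L, plans = NULL) {
  if (is.null(plans))
    plans <- list(stage1 = stage_plan(1), stage2 = stage_plan(2),
                  stage3 = stage_plan(3), stage4 = stage_plan(4))
  state <- list()
  for (nm in paste0("stage", 1:4)) {
    if (is.null(plans[[nm]])) next
    plan <- plans[[nm]]
    plan$seed <- as.integer((seed * 131L + plan$stage) %% .Machine$integer.max)
    state <- tryCatch(run_stage(state, cohort, plan, config = config),
                      error = function(e) stop("stage ", plan$stage, " failed: ",
                                               conditionMessage(e)))
  }
  state
}

#' Desk-scale training plans for the four-stage protocol
#'
#' Epoch counts and step sizes sized for a width-1/8 model on 64 x 64
#' phantom cohorts: 5 + 5 epochs for the static stages, 2 head-refinement
#' epochs, and 15 recurrent epochs at a larger step (the ConvLSTM module and
#' its heads train from scratch on frozen features).
#' @export
tiny_protocol_plans <- function() {
  list(stage1 = stage_plan(1, epochs = 5L),
       stage2 = stage_plan(2, epochs = 5L),
       stage3 = stage_plan(3, epochs = 2L),
       stage4 = stage_plan(4, epochs = 15L, batch_size = 6L, learning_rate = 3e-3))
}

#' Temporal-benefit experiment on flickered phantoms
#'
#' Trains the full protocol on a clean phantom cohort, then evaluates both
#' the stage-2 static model and the stage-4 recurrent model on a flickered
#' cohort in which lesions are intermittently obscured in the frames while
#' remaining present in the ground truth. A static frame-wise model cannot
#' see an obscured lesion; the recurrent window can carry it across frames,
#' which is the motivation for the time-series model.
#'
#' @param seed master seed for cohort generation and training.
#' @param n_patients training-cohort size.
#' @param n_frames frames per sweep.
#' @param flicker_prob obscuration probability of the evaluation cohort.
#' @param n_eval evaluation-cohort size.
#' @return list: `state` (trained models), `held_out` (metrics of the
#'   recurrent model on held-out clips), `static_flicker`,
#'   `recurrent_flicker` (per-clip metric tibbles on the flickered cohort).
#' @export
temporal_benefit_experiment <- function(seed = 1L, n_patients = 20L,
                                        n_frames = 12L, flicker_prob = 0.35,
                                        n_eval = 6L) {
  co <- generate_cohort(n_patients, n_frames = n_frames, seed = seed + 100L)
  co$manifest <- split_by_patient(co$manifest, c(0.6, 0.2, 0.2), seed = seed)
  cfg <- tiny_model_config()
  st <- run_full_protocol(cfg, co, seed = seed, plans = tiny_protocol_plans())
  held <- co$clips[co$manifest$split %in% c("validation", "test")]
  seg_h <- lapply(held, function(cl) segment_cineclip(st$recurrent, cl$clip))
  held_out <- evaluate_cohort(seg_h, lapply(held, `[[`, "masks"))
  fl <- generate_cohort(n_eval, n_frames = n_frames, flicker_prob = flicker_prob,
                        seed = seed + 700L)
  truths <- lapply(fl$clips, `[[`, "masks")
  seg2 <- lapply(fl$clips, function(cl) segment_cineclip(st$static2, cl$clip))
  seg4 <- lapply(fl$clips, function(cl) segment_cineclip(st$recurrent, cl$clip))
  list(state = st, held_out = held_out,
       static_flicker = evaluate_cohort(seg2, truths),
       recurrent_flicker = evaluate_cohort(seg4, truths))
}

#' Plot a training history
#'
#' Per-epoch loss by stage, with validation thyroid IoU where recorded.
#' @param history the `history` tibble from [run_stage()]/[run_full_protocol()].
#' @return a ggplot object.
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_history requires ggplot2")
  ggplot2::ggplot(history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(y = .data$val_thyroid_iou), na.rm = TRUE,
                        shape = 4) +
    ggplot2::facet_wrap(~stage, nrow = 1, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(y = "training loss (x: validation thyroid IoU)")
}
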