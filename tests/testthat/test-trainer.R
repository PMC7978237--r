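test_that("default augmentation schemes reproduce the published stage settings", {
  sch <- default_schemes()
  s1 <- sch$stage1
  expect_equal(s1$frequency[s1$op == "rotate"], 0.25)
  expect_equal(s1$scale[s1$op == "rotate"], 15)
  expect_equal(s1$scale[s1$op == "crop"], 300)
  expect_equal(s1$frequency[s1$op == "crop"], 1.0)
  s3 <- sch$stage3
  expect_equal(s3$scale[s3$op == "rotate"], 5)
  expect_equal(s3$frequency[s3$op == "rotate"], 0.5)
  s4 <- sch$stage4
  expect_setequal(s4$op, c("hflip", "reverse_sequence"))
  expect_equal(s4$frequency, c(0.5, 0.5))
  for (s in sch) expect_true(all(s$frequency >= 0 & s$frequency <= 1))
})

test_that("horizontal flip is an involution and a null scheme is the identity", {
  co <- tiny_cohort(4)
  cl <- co$clips[[1]]
  fl <- tibble::tibble(op = "hflip", frequency = 1, scale = NA_real_)
  set.seed(1)
  a <- augment(cl$clip$frames, cl$masks, fl)
  b <- augment(a$frames, a$masks, fl)
  expect_equal(b$frames, cl$clip$frames)
  expect_identical(b$masks$lesion, cl$masks$lesion)

  null_s <- tibble::tibble(op = c("hflip", "rotate"), frequency = c(0, 0), scale = c(NA, 15))
  z <- augment(cl$clip$frames, cl$masks, null_s)
  expect_identical(z$frames, cl$clip$frames)
  expect_identical(z$masks, cl$masks)
})

test_that("rotation magnitude honors the per-stage bound", {
  # a point mask at radius r can move at most r * sin(scale deg) + discretization
  H <- 64
  fr <- array(0, c(1, H, H)); fr[1, 32, 52] <- 1
  mk <- mask_stack(array(0L, c(1, H, H)), array(0L, c(1, H, H)))
  max_disp <- function(scale, n = 200) {
    rot <- tibble::tibble(op = "rotate", frequency = 1, scale = scale)
    d <- 0
    for (i in seq_len(n)) {
      a <- augment(fr, mk, rot)
      w <- which(a$frames[1, , ] == max(a$frames[1, , ]), arr.ind = TRUE)[1, ]
      d <- max(d, sqrt((w[1] - 32)^2 + (w[2] - 52)^2))
    }
    d
  }
  set.seed(3)
  r <- 20
  expect_lt(max_disp(5), 2 * r * sin(5 * pi / 360) + 2.5)
  expect_gt(max_disp(15), 2 * r * sin(5 * pi / 360) + 2.5)  # wider bound is used
})

test_that("augmentation preserves the mask vocabulary and the intensity sentinel", {
  co <- tiny_cohort(4)
  cl <- co$clips[[2]]
  full <- default_schemes()$stage1
  set.seed(8)
  for (i in 1:5) {
    a <- augment(cl$clip$frames, cl$masks, full)
    expect_true(all(a$masks$lesion %in% 0:2))
    expect_true(all(a$masks$thyroid %in% 0:1))
    v <- as.numeric(a$frames)
    expect_true(all(v == -1 | (v >= 0 & v <= 1)))
  }
  # color shift leaves sentinel pixels untouched
  fr <- cl$clip$frames; fr[, 1:4, ] <- -1
  cs <- tibble::tibble(op = "color_shift", frequency = 1, scale = 0.05)
  a2 <- augment(fr, cl$masks, cs)
  expect_true(all(a2$frames[, 1:4, ] == -1))
})

test_that("sequence reversal flips frames and masks together and is refused frame-wise", {
  co <- tiny_cohort(4)
  cl <- co$clips[[1]]
  rev_s <- tibble::tibble(op = "reverse_sequence", frequency = 1, scale = NA_real_)
  set.seed(2)
  a <- augment(cl$clip$frames, cl$masks, rev_s, sequence_mode = TRUE)
  Tn <- dim(cl$clip$frames)[1]
  expect_equal(a$frames[Tn, , ], cl$clip$frames[1, , ])
  expect_identical(a$masks$lesion[Tn, , ], cl$masks$lesion[1, , ])
  expect_error(augment(cl$clip$frames, cl$masks, rev_s, sequence_mode = FALSE),
               "full sequences")
})

test_that("stage-1 training decreases the loss and validates above chance", {
  co <- tiny_cohort(5, n_frames = 8, seed = 15)
  set.seed(1)
  st <- run_stage(list(), co, stage_plan(1, epochs = 4, seed = 31), config = tiny_cfg())
  h <- st$history
  expect_equal(nrow(h), 4L)
  expect_true(all(diff(h$loss) < 0))
  expect_gt(tail(h$val_thyroid_iou, 1), 0.2)
})

test_that("training is bit-reproducible under a fixed seed", {
  co <- tiny_cohort(4, n_frames = 6, seed = 16)
  one <- function() {
    st <- run_stage(list(), co, stage_plan(1, epochs = 2, seed = 9,
                                           steps_per_epoch = 3L), config = tiny_cfg())
    tail(st$history$loss, 1)
  }
  expect_equal(one(), one(), tolerance = 1e-6)
})

test_that("stage transitions enforce prerequisites and freeze contracts", {
  co <- tiny_cohort(5, n_frames = 8, seed = 17)
  expect_error(run_stage(list(), co, stage_plan(2, epochs = 1)), "stage-1")
  expect_error(run_stage(list(), co, stage_plan(4, epochs = 1)), "stage-2")

  set.seed(2)
  st <- run_stage(list(), co, stage_plan(1, epochs = 2, seed = 41), config = tiny_cfg())
  st <- run_stage(st, co, stage_plan(2, epochs = 2, seed = 42))
  # stage 3: frozen weights bit-identical before and after
  frozen_before <- lapply(st$static2$layers[c("s2.cb.c2", "aspp.proj.conv", "stem1.conv")],
                          function(ly) ly$par$W)
  st <- run_stage(st, co, stage_plan(3, epochs = 1, seed = 43))
  frozen_after <- lapply(st$static2$layers[c("s2.cb.c2", "aspp.proj.conv", "stem1.conv")],
                        function(ly) ly$par$W)
  expect_identical(frozen_before, frozen_after)
  trn <- model_summary(st$static2)
  expect_true(all(grepl("^(fuse|head)", trn$name[trn$trainable])))

  # stage 4: backbone (incl. fusion) frozen, ConvLSTM module trains
  fuse_before <- st$static2$layers[["fuse1.main"]]$par$W
  st <- run_stage(st, co, stage_plan(4, epochs = 1, batch_size = 2, seed = 44))
  expect_identical(st$recurrent$layers[["fuse1.main"]]$par$W, fuse_before)
  expect_false(identical(st$recurrent$layers[["rmod.f.d1.clf"]]$grad$W * 0,
                         st$recurrent$layers[["rmod.f.d1.clf"]]$par$W))
  expect_equal(nrow(dplyr::filter(st$history, .data$stage == 4)), 1L)
})

test_that("a cohort without held-out splits still trains with a fallback warning", {
  co <- generate_cohort(3, n_frames = 6, seed = 19)  # all splits unassigned
  expect_warning(
    st <- run_stage(list(), co, stage_plan(1, epochs = 1, steps_per_epoch = 2L),
                    config = tiny_cfg()),
    "falling back")
  expect_s3_class(st$history, "tbl_df")
})
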