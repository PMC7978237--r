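test_that("static models honor shape, range and normalization contracts", {
  set.seed(21)
  cfg <- tiny_cfg()
  m1 <- build_static_model(cfg, 1L)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  fw <- cineseg:::static_fw(m1, x)
  thy <- fw$tp$vals[[fw$thy]]
  expect_equal(dim(thy), c(64L, 64L, 1L, 2L))
  expect_true(all(thy >= 0 & thy <= 1))
  expect_null(fw$les)

  m2 <- build_static_model(cfg, 2L, base = m1)
  fw2 <- cineseg:::static_fw(m2, x)
  les <- fw2$tp$vals[[fw2$les]]
  expect_equal(dim(les), c(64L, 64L, 3L, 2L))
  expect_lt(max(abs(apply(les, c(1, 2, 4), sum) - 1)), 1e-5)
  # stage 2 shares the stage-1 backbone by reference
  expect_identical(m1$layers[["s3.ib5.c2"]], m2$layers[["s3.ib5.c2"]])

  # an all-sentinel frame yields finite outputs
  xs <- array(-1, c(64, 64, 1, 1))
  fs <- cineseg:::static_fw(m2, xs)
  expect_true(all(is.finite(fs$tp$vals[[fs$thy]])))
  expect_true(all(is.finite(fs$tp$vals[[fs$les]])))
})

test_that("backbone downsamples to the configured output stride before fusion", {
  set.seed(22)
  m <- build_backbone(tiny_cfg())
  tp <- cineseg:::new_tape()
  bb <- cineseg:::backbone_fw(m, tp, cineseg:::t_input(tp, array(runif(64 * 64), c(64, 64, 1, 1))), FALSE)
  expect_equal(dim(tp$vals[[bb$aspp]])[1:2], c(8L, 8L))   # 64 / output_stride 8
  # skip fusion aligns to the shallowest skip: fused map at 1/4 resolution
  expect_equal(dim(tp$vals[[bb$fused]])[1:2], c(16L, 16L))
})

test_that("width multiplier scales every filter count by ceiling(n * w)", {
  set.seed(23)
  m <- build_backbone(model_config(width_multiplier = 1 / 8))
  s <- model_summary(m)
  pick <- function(nm) s$filters[s$name == nm]
  expect_equal(pick("stem1.conv"), ceiling(32 / 8))
  expect_equal(pick("stem3.conv"), ceiling(64 / 8))
  expect_equal(pick("s1.cb.c3"), ceiling(256 / 8))
  expect_equal(pick("s3.ib17.c2"), ceiling(256 / 8))
  expect_equal(pick("s4.cb.c3"), ceiling(2048 / 8))
  expect_equal(pick("aspp.proj.conv"), ceiling(256 / 8))
  expect_equal(pick("fuse2.main"), ceiling(128 / 8))
  # stage-3/4 dilation replaces striding
  expect_equal(s$dilation[s$name == "s3.ib1.c2"], 2L)
  expect_equal(s$dilation[s$name == "s4.ib1.c2"], 4L)
})

test_that("construction is a pure function of config and seed", {
  mk <- function() {
    set.seed(77)
    model_summary(build_static_model(tiny_cfg(), 2L))
  }
  expect_identical(mk(), mk())
})

test_that("convolutional core parameters scale as the square of the width multiplier", {
  set.seed(24)
  n1 <- count_params(build_backbone(model_config(width_multiplier = 1)), core_only = TRUE)
  for (w in c(1 / 8, 1 / 4)) {
    nw <- count_params(build_backbone(model_config(width_multiplier = w)), core_only = TRUE)
    expect_lt(abs(nw / (w^2 * n1) - 1), 0.05)
  }
})

test_that("the recurrent build contains the specified ConvLSTM census and freeze pattern", {
  set.seed(25)
  cfg <- tiny_cfg()
  m2 <- build_static_model(cfg, 2L)
  rm <- build_recurrent_model(cfg, m2)
  s <- model_summary(rm)
  cl <- s[s$type == "convlstm", ]
  expect_equal(nrow(cl), 18L)
  expect_equal(unique(cl$kernel), "3x3")
  expect_setequal(unique(cl$dilation[grepl("\\.d[0-9]+\\.", cl$name)]), c(1L, 3L, 5L, 7L))
  expect_true(all(cl$trainable))
  # backbone + fusion frozen, recurrent + heads trainable
  frozen <- s$name[!s$trainable]
  expect_true(all(grepl("^(stem|s[1-4]\\.|aspp|fuse)", frozen)))
  expect_true(all(grepl("^(rmod|rhead)", s$name[s$trainable])))
  expect_error(build_recurrent_model(model_config(window = 5), m2), "even")
})

test_that("stage-3 freezing leaves exactly the post-ASPP layers trainable", {
  set.seed(26)
  m2 <- build_static_model(tiny_cfg(), 2L)
  set_freeze_scope(m2, "up_to_aspp")
  s <- model_summary(m2)
  expect_true(all(grepl("^(fuse|head)", s$name[s$trainable])))
  expect_true(all(grepl("^(stem|s[1-4]\\.|aspp)", s$name[!s$trainable])))
  set_freeze_scope(m2, "none")
  expect_true(all(model_summary(m2)$trainable))
})

test_that("segment_cineclip covers every frame for static and recurrent models", {
  set.seed(27)
  cfg <- tiny_cfg()
  m2 <- build_static_model(cfg, 2L)
  rm <- build_recurrent_model(cfg, m2)
  fr <- array(runif(10 * 64 * 64), c(10, 64, 64))
  for (model in list(m2, rm)) {
    seg <- segment_cineclip(model, fr)
    expect_equal(dim(seg$thyroid_prob), c(10L, 64L, 64L))
    expect_equal(dim(seg$lesion_prob), c(10L, 64L, 64L, 3L))
    expect_true(all(seg$thyroid_prob >= 0 & seg$thyroid_prob <= 1))
  }
  # degenerate single-frame clip works via edge replication
  seg1 <- segment_cineclip(rm, fr[1, , , drop = FALSE])
  expect_equal(dim(seg1$thyroid_prob)[1], 1L)
  # constant clips give time-constant recurrent predictions
  frc <- array(rep(fr[1, , ], each = 8), c(8, 64, 64))
  segc <- segment_cineclip(rm, frc)
  spread <- apply(segc$thyroid_prob, c(2, 3), function(v) diff(range(v)))
  expect_lt(max(spread), 1e-5)
})

test_that("a model config survives JSON round-trip and rebuilds an isomorphic graph", {
  cfg <- tiny_cfg(window = 4L, recurrent_dilations = c(1L, 2L))
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  cfg2 <- do.call(model_config, jsonlite::fromJSON(js))
  expect_equal(cfg2, cfg)
  mk <- function(cc) { set.seed(5); model_summary(build_static_model(cc, 2L)) }
  expect_identical(mk(cfg), mk(cfg2))
})
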