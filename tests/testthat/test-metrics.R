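test_that("compute_metrics matches hand-evaluated formulas", {
  m <- compute_metrics(c(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(m), c(iou = 1, mcc = 1, recall = 1, precision = 1, f2 = 1))

  m2 <- compute_metrics(c(tp = 10, tn = 80, fp = 5, fn = 5))
  expect_equal(m2$iou, 0.5)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$f2, 50 / 75)
  expect_equal(m2$mcc, (10 * 80 - 25) / sqrt(15 * 15 * 85 * 85))
})

test_that("zero-denominator metrics use the vacuous-perfection convention", {
  m <- compute_metrics(c(tp = 0, tn = 100, fp = 0, fn = 0))
  expect_equal(unlist(m), c(iou = 1, mcc = 1, recall = 1, precision = 1, f2 = 1))
  m2 <- compute_metrics(c(tp = 0, tn = 90, fp = 10, fn = 0))
  expect_equal(m2$iou, 0)
  expect_equal(m2$recall, 0)   # class absent in truth but predicted
  expect_error(compute_metrics(c(tp = -1, tn = 1, fp = 0, fn = 0)), "non-negative")
})

test_that("confusion_from_masks equals a per-pixel loop and is exhaustive", {
  set.seed(9)
  p <- array(runif(16 * 16) > 0.5, c(16, 16))
  y <- array(runif(16 * 16) > 0.7, c(16, 16))
  cc <- confusion_from_masks(p, y)
  ref <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(p)) {
    ref <- ref + c(tp = p[i] && y[i], tn = !p[i] && !y[i],
                   fp = p[i] && !y[i], fn = !p[i] && y[i])
  }
  expect_equal(unlist(cc), ref)
  expect_equal(sum(unlist(cc)), length(p))
  expect_equal(confusion_from_masks(y, y)$fp + confusion_from_masks(y, y)$fn, 0L)
  expect_equal(confusion_from_masks(!y, y)$tp + confusion_from_masks(!y, y)$tn, 0L)
  expect_error(confusion_from_masks(p, y[1:8, ]), "shape mismatch")
})

test_that("roc_curve is a proper ROC: monotone, Mann-Whitney area, symmetric", {
  y <- c(rep(1, 50), rep(0, 50))
  expect_equal(roc_curve(y, y)$auc, 1)

  set.seed(4)
  s <- rnorm(1e4); yy <- rbinom(1e4, 1, 0.4)
  r <- roc_curve(s, yy)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  expect_lt(abs(r$auc - 0.5), 0.02)
  expect_equal(r$auc + roc_curve(-s, yy)$auc, 1)

  # Mann-Whitney identity with ties counted one half
  s2 <- sample(1:5, 400, replace = TRUE); y2 <- rbinom(400, 1, 0.5)
  pos <- s2[y2 == 1]; neg <- s2[y2 == 0]
  mw <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  expect_equal(roc_curve(s2, y2)$auc, mw)
  expect_error(roc_curve(s, rep(1, 1e4)), "both classes")
})

test_that("roc_curve area agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- rnorm(500) + rbinom(500, 1, 0.5)
  y <- as.integer(s + rnorm(500) > 0.5)
  expect_equal(roc_curve(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

make_seg <- function(thy_p, les_p) new_seg_output(thy_p, les_p)

random_truth <- function(Tn = 2, H = 8, W = 8, seed = 1) {
  set.seed(seed)
  thy <- array(as.integer(runif(Tn * H * W) > 0.5), c(Tn, H, W))
  les <- array(sample(0:2, Tn * H * W, TRUE, prob = c(0.8, 0.1, 0.1)), c(Tn, H, W))
  mask_stack(thy, les)
}

seg_from_truth <- function(truth, t) {
  # p = t*y + (1-t)*(1-y) per class, lesion channels renormalized
  d <- dim(truth$thyroid)
  thy <- t * truth$thyroid + (1 - t) * (1 - truth$thyroid)
  les <- array(0, c(d, 3))
  for (c in 0:2) {
    y <- (truth$lesion == c) * 1
    les[, , , c + 1] <- array(t * y + (1 - t) * (1 - y) / 2, d)
  }
  s <- les[, , , 1, drop = FALSE] + les[, , , 2, drop = FALSE] + les[, , , 3, drop = FALSE]
  for (c in 1:3) les[, , , c] <- array(les[, , , c, drop = FALSE] / s, d)
  new_seg_output(thy, les)
}

test_that("mcc_loss vanishes at perfect saturated predictions", {
  truth <- random_truth(seed = 2)
  loss <- mcc_loss(seg_from_truth(truth, 1), truth)
  expect_lt(as.numeric(loss), 1e-3)
})

test_that("mcc_loss decreases monotonically from inverted to perfect predictions", {
  truth <- random_truth(seed = 3)
  ls <- vapply(c(0, 0.25, 0.5, 0.75, 1),
               function(t) as.numeric(mcc_loss(seg_from_truth(truth, t), truth)), 0)
  expect_true(all(diff(ls) < 0))
})

test_that("on an empty truth a confident false positive costs more than silence, with live gradient", {
  H <- 8; Tn <- 1
  truth <- mask_stack(array(0L, c(Tn, H, H)), array(0L, c(Tn, H, H)))
  w <- c(background = 0.2, thyroid = 1, cyst = 10, nodule = 10)
  # confident nodule + thyroid prediction everywhere
  les_fp <- array(0.02, c(Tn, H, H, 3)); les_fp[, , , 3] <- 0.96
  fp <- new_seg_output(array(0.95, c(Tn, H, H)), les_fp)
  les_ok <- array(0.02, c(Tn, H, H, 3)); les_ok[, , , 1] <- 0.96
  ok <- new_seg_output(array(0.05, c(Tn, H, H)), les_ok)
  l_fp <- as.numeric(mcc_loss(fp, truth, w))
  l_ok <- as.numeric(mcc_loss(ok, truth, w))
  expect_gt(l_fp, l_ok)
  expect_lt(l_ok, 0.5)   # mildly soft probabilities keep the MCC below 1
  expect_gt(l_fp, 1.2)   # aggregated MCC driven negative by the inversion

  # gradients are finite and nonzero despite zero true positives
  thyp <- aperm(fp$thyroid_prob, c(2, 3, 1))
  thyp <- array(thyp, c(H, H, 1, Tn))
  lesp <- aperm(fp$lesion_prob, c(2, 3, 4, 1))
  cls <- array(0L, c(H, H, Tn))
  g <- cineseg:::mcc_loss_grad(thyp, lesp, array(0, c(H, H, Tn)), cls, w)
  expect_true(all(is.finite(g$d_thy)) && all(is.finite(g$d_les)))
  expect_gt(max(abs(g$d_thy)), 0)
  expect_gt(max(abs(g$d_les)), 0)
})

test_that("mcc_loss gradients match finite differences", {
  set.seed(6)
  H <- 4; Tn <- 1
  thyp <- array(runif(H * H), c(H, H, 1, Tn))
  lesp0 <- array(runif(H * H * 3), c(H, H, 3, Tn))
  s <- array(rep(apply(lesp0, c(1, 2, 4), sum), times = 3), dim(lesp0)[c(1, 2, 4, 3)])
  lesp <- lesp0 / aperm(s, c(1, 2, 4, 3))
  thy_true <- array(rbinom(H * H, 1, 0.4), c(H, H, Tn))
  cls <- array(sample(0:3, H * H, TRUE), c(H, H, Tn))
  w <- c(background = 0.3, thyroid = 1, cyst = 5, nodule = 7)
  g <- cineseg:::mcc_loss_grad(thyp, lesp, thy_true, cls, w)
  f_t <- function(v) cineseg:::mcc_loss_grad(array(v, dim(thyp)), lesp, thy_true, cls, w)$loss
  f_l <- function(v) cineseg:::mcc_loss_grad(thyp, array(v, dim(lesp)), thy_true, cls, w)$loss
  expect_lt(max(abs(num_grad(f_t, as.numeric(thyp)) - as.numeric(g$d_thy))), 1e-6)
  expect_lt(max(abs(num_grad(f_l, as.numeric(lesp)) - as.numeric(g$d_les))), 1e-6)
})

test_that("mcc_loss is pixel-permutation and joint-flip invariant, and matches hard MCC when saturated", {
  truth <- random_truth(Tn = 1, seed = 8)
  seg <- seg_from_truth(truth, 0.8)
  w <- c(background = 0.5, thyroid = 1, cyst = 3, nodule = 3)
  l0 <- as.numeric(mcc_loss(seg, truth, w))

  flip <- function(a) {
    if (length(dim(a)) == 3) a[, , dim(a)[3]:1, drop = FALSE]
    else a[, , dim(a)[3]:1, , drop = FALSE]
  }
  seg_f <- new_seg_output(flip(seg$thyroid_prob), flip(seg$lesion_prob))
  truth_f <- mask_stack(flip(truth$thyroid), flip(truth$lesion))
  expect_equal(as.numeric(mcc_loss(seg_f, truth_f, w)), l0)

  # saturated predictions: loss equals 1 - mean of hard aggregated MCCs,
  # recomputed independently from hard counts
  hard <- seg_from_truth(truth, 1)
  pred_ok <- hard; pred_ok$thyroid_prob[1, 1, 1:3] <- 0  # a few hard errors
  l_hard <- as.numeric(mcc_loss(pred_ok, truth, w, eps = 1e-12))
  hard_head_mcc <- function(P, Y, wv) {
    tp <- sum(wv * colSums(matrix(P * Y, ncol = length(wv))))
    fp <- sum(wv * colSums(matrix(P * (1 - Y), ncol = length(wv))))
    fn <- sum(wv * colSums(matrix((1 - P) * Y, ncol = length(wv))))
    tn <- sum(wv * colSums(matrix((1 - P) * (1 - Y), ncol = length(wv))))
    (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  }
  tv <- as.numeric(truth$thyroid); tp <- as.numeric(pred_ok$thyroid_prob)
  P_thy <- cbind(tp, 1 - tp); Y_thy <- cbind(tv, 1 - tv)
  les_y <- cbind(as.numeric(truth$lesion < 1), as.numeric(truth$lesion == 1),
                 as.numeric(truth$lesion == 2))
  les_p <- cbind(as.numeric(pred_ok$lesion_prob[, , , 1]),
                 as.numeric(pred_ok$lesion_prob[, , , 2]),
                 as.numeric(pred_ok$lesion_prob[, , , 3]))
  ref <- 1 - mean(c(hard_head_mcc(P_thy, Y_thy, c(w["thyroid"], w["background"])),
                    hard_head_mcc(les_p, les_y, c(w["background"], w["cyst"], w["nodule"]))))
  expect_equal(l_hard, ref, tolerance = 1e-6)
})

test_that("class weights down-weight the majority classes by inverse frequency", {
  co <- tiny_cohort(6)
  w <- compute_class_weights(lapply(co$clips, `[[`, "masks"))
  expect_true(w["nodule"] > w["thyroid"] && w["thyroid"] > w["background"])
  expect_true(all(w > 0))
})
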