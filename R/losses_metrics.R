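#' Confusion counts from binary masks
#'
#' @param pred,truth equal-shaped binary (0/1 or logical) arrays.
#' @return a one-row tibble with `tp`, `tn`, `fp`, `fn`; their sum equals the
#'   number of pixels exactly.
#' @export
confusion_from_masks <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)))
    stop("confusion_from_masks: shape mismatch between pred (",
         paste(dim(pred) %||% length(pred), collapse = "x"), ") and truth (",
         paste(dim(truth) %||% length(truth), collapse = "x"), ")")
  p <- as.logical(pred); y <- as.logical(truth)
  tibble::tibble(tp = sum(p & y), tn = sum(!p & !y),
                 fp = sum(p & !y), fn = sum(!p & y))
}

#' Segmentation metrics from confusion counts
#'
#' Evaluates IoU = TP/(TP+FN+FP), MCC, Recall = TP/(TP+FN),
#' Precision = TP/(TP+FP) and F2 = 5TP/(5TP+4FN+FP). Soft (real-valued)
#' counts are accepted. When a metric's denominator is zero the convention is
#' uniform: the metric is 1 when the class is absent from both prediction and
#' truth (fp + fn == 0, vacuously perfect) and 0 otherwise.
#'
#' @param counts a data frame with columns `tp`, `tn`, `fp`, `fn`
#'   (non-negative; one row per evaluation unit), or a named vector.
#' @return a tibble with columns iou, mcc, recall, precision, f2.
#' @export
compute_metrics <- function(counts) {
  if (is.numeric(counts) && !is.null(names(counts))) counts <- tibble::as_tibble(as.list(counts))
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be non-negative")
  if (any(tp + tn + fp + fn <= 0)) stop("confusion counts sum to zero")
  sentinel <- ifelse(fp + fn == 0, 1, 0)
  safe <- function(num, den) ifelse(den > 0, num / den, sentinel)
  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble::tibble(
    iou = safe(tp, tp + fn + fp),
    mcc = ifelse(mcc_den2 > 0, (tp * tn - fp * fn) / sqrt(mcc_den2), sentinel),
    recall = safe(tp, tp + fn),
    precision = safe(tp, tp + fp),
    f2 = safe(5 * tp, 5 * tp + 4 * fn + fp))
}

#' Class weights for the MCC loss
#'
#' Inverse pixel-frequency weights over background / thyroid / cyst / nodule,
#' with the two majority classes (background, thyroid) additionally
#' down-weighted, then normalized so the frequency-weighted mean is 1.
#'
#' @param masks a list of mask stacks (see [mask_stack()]).
#' @param majority_factor multiplier applied to background and thyroid.
#' @return named numeric vector (background, thyroid, cyst, nodule).
#' @export
compute_class_weights <- function(masks, majority_factor = 0.1) {
  n <- c(background = 0, thyroid = 0, cyst = 0, nodule = 0)
  tot <- 0
  for (m in masks) {
    cl <- pixel_class_codes(m)
    n <- n + c(sum(cl == 0L), sum(cl == 1L), sum(cl == 2L), sum(cl == 3L))
    tot <- tot + length(cl)
  }
  fr <- n / tot
  w <- 1 / pmax(fr, 1e-6)
  w["background"] <- w["background"] * majority_factor
  w["thyroid"] <- w["thyroid"] * majority_factor
  w / sum(w * fr)
}

# 0 = background, 1 = thyroid (no lesion), 2 = cyst, 3 = nodule
pixel_class_codes <- function(mask) {
  cl <- array(0L, dim(mask$thyroid))
  cl[mask$thyroid == 1L] <- 1L
  cl[mask$lesion == 1L] <- 2L
  cl[mask$lesion == 2L] <- 3L
  cl
}

# Head-level class-weighted soft MCC.
# P, Y: (H, W, C, N) probabilities and one-hot targets; wvec length C.
# Soft counts are summed over pixels and classes, each class's counts scaled
# by its weight, and a single MCC evaluated with eps inside the square root.
mcc_head <- function(P, Y, wvec, eps, grad = TRUE) {
  d <- dim(P); C <- d[3]
  tp <- fp <- fn <- tn <- 0
  for (c in seq_len(C)) {
    p <- P[, , c, , drop = FALSE]; y <- Y[, , c, , drop = FALSE]
    w <- wvec[c]
    sy <- sum(y); spy <- sum(p * y); sp <- sum(p)
    npix <- length(p)
    tp <- tp + w * spy
    fp <- fp + w * (sp - spy)
    fn <- fn + w * (sy - spy)
    tn <- tn + w * (npix - sp - sy + spy)
  }
  num <- tp * tn - fp * fn
  S <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  D <- sqrt(S + eps)
  mcc <- num / D
  out <- list(mcc = mcc, counts = c(tp = tp, tn = tn, fp = fp, fn = fn))
  if (grad) {
    dS <- c(tp = (tp + fn) * (tn + fp) * (tn + fn) + (tp + fp) * (tn + fp) * (tn + fn),
            tn = (tp + fp) * (tp + fn) * (tn + fn) + (tp + fp) * (tp + fn) * (tn + fp),
            fp = (tp + fn) * (tn + fp) * (tn + fn) + (tp + fp) * (tp + fn) * (tn + fn),
            fn = (tp + fp) * (tn + fp) * (tn + fn) + (tp + fp) * (tp + fn) * (tn + fp))
    dD <- dS / (2 * D)
    # d(num)/d counts: tp -> tn, tn -> tp, fp -> -fn, fn -> -fp
    dnum <- c(tp = tn, tn = tp, fp = -fn, fn = -fp)
    dmcc <- (dnum * D - num * dD) / D^2
    dP <- array(0, d)
    for (c in seq_len(C)) {
      y <- Y[, , c, , drop = FALSE]
      w <- wvec[c]
      # dTP/dp = w y ; dFP/dp = w(1-y) ; dFN/dp = -w y ; dTN/dp = -w(1-y)
      dP[, , c, ] <- w * (y * (dmcc[["tp"]] - dmcc[["fn"]]) +
                          (1 - y) * (dmcc[["fp"]] - dmcc[["tn"]]))
    }
    out$dP <- dP
  }
  out
}

# Internal training-shape loss. thy_prob (H,W,1,N) or NULL; les_prob (H,W,C,N)
# or NULL; cls integer codes (H,W,N) in {0 bg, 1 thy, 2 cyst, 3 nodule};
# thy_true binary (H,W,N). Returns loss and gradients w.r.t. the probability
# maps (same shapes).
mcc_loss_grad <- function(thy_prob, les_prob, thy_true, cls, weights, eps = 1e-6) {
  terms <- list(); grads <- list(thy = NULL, les = NULL)
  if (!is.null(thy_prob)) {
    d <- dim(thy_prob)
    P <- array(0, c(d[1], d[2], 2, d[4]))
    P[, , 1, ] <- thy_prob; P[, , 2, ] <- 1 - thy_prob
    Y <- array(0, dim(P))
    Y[, , 1, ] <- thy_true; Y[, , 2, ] <- 1 - thy_true
    h <- mcc_head(P, Y, c(weights[["thyroid"]], weights[["background"]]), eps)
    terms$thy <- h$mcc
    grads$thy <- array(h$dP[, , 1, ] - h$dP[, , 2, ], d)
  }
  if (!is.null(les_prob)) {
    d <- dim(les_prob)
    Y <- array(0, d)
    Y[, , 1, ] <- cls < 2L          # background channel: anything not a lesion
    Y[, , 2, ] <- cls == 2L
    Y[, , 3, ] <- cls == 3L
    h <- mcc_head(les_prob, Y,
                  c(weights[["background"]], weights[["cyst"]], weights[["nodule"]]), eps)
    terms$les <- h$mcc
    grads$les <- h$dP
  }
  k <- length(terms)
  loss <- 1 - mean(unlist(terms))
  if (!is.null(grads$thy)) grads$thy <- -grads$thy / k
  if (!is.null(grads$les)) grads$les <- -grads$les / k
  list(loss = loss, d_thy = grads$thy, d_les = grads$les,
       mcc = unlist(terms))
}

#' Class-balanced soft MCC loss
#'
#' Differentiable segmentation loss adapted from the Matthews correlation
#' coefficient. For each output head, soft confusion counts (TP, FP, FN, TN)
#' are accumulated over all pixels and over the head's classes — the sigmoid
#' thyroid head contributes channels (p, 1-p), the softmax lesion head its
#' background/cyst/nodule channels — with each class's counts multiplied by
#' its weight; a single MCC is evaluated per head with `eps` added inside the
#' square root, and the loss is 1 minus the mean of the head MCCs. Unlike
#' overlap losses (Dice, Tversky), the aggregated MCC remains informative
#' when a frame contains no positive pixels: a confident false positive
#' drives it toward -1 while a correct all-negative prediction scores +1, so
#' the gradient never vanishes on lesion-free frames.
#'
#' @param seg a `cineseg_segoutput` (probabilities for every frame).
#' @param truth a [mask_stack()] with matching shape.
#' @param weights named class weights (background, thyroid, cyst, nodule),
#'   e.g. from [compute_class_weights()]; default equal weights.
#' @param eps stabilizer inside the MCC denominator square root.
#' @return scalar loss (>= 0), with attributes `mcc` (per-head MCCs).
#' @export
mcc_loss <- function(seg, truth, weights = NULL, eps = 1e-6) {
  if (eps <= 0) stop("eps must be > 0")
  if (is.null(weights))
    weights <- c(background = 1, thyroid = 1, cyst = 1, nodule = 1)
  thy <- aperm(seg$thyroid_prob, c(2, 3, 1))        # (H, W, T)
  d <- dim(thy)
  thy <- array(thy, c(d[1], d[2], 1, d[3]))
  les <- aperm(seg$lesion_prob, c(2, 3, 4, 1))      # (H, W, C, T)
  cls <- aperm(pixel_class_codes(truth), c(2, 3, 1))
  thy_true <- aperm(truth$thyroid, c(2, 3, 1))
  r <- mcc_loss_grad(thy, les, thy_true, cls, weights, eps)
  structure(r$loss, mcc = r$mcc)
}

#' ROC curve and area under it
#'
#' Threshold sweep over pixel scores; points are monotone in both
#' coordinates and the area (trapezoidal, equivalently the Mann-Whitney
#' probability with ties counted 1/2) lies in `[0, 1]`.
#'
#' @param scores numeric vector of per-pixel scores.
#' @param labels binary vector (0/1 or logical) of the same length.
#' @return list with `points` (tibble fpr, tpr, threshold) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("roc_curve requires both classes present (", np, " positives, ",
         nn, " negatives)")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(s[-length(s)] != s[-1], TRUE)   # one point per distinct threshold
  ctp <- cumsum(y)[keep]; cfp <- cumsum(1 - y)[keep]
  tpr <- c(0, ctp / np); fpr <- c(0, cfp / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = tibble::tibble(fpr = fpr, tpr = tpr,
                               threshold = c(Inf, s[keep])),
       auc = auc)
}

#' Plot an ROC curve
#'
#' @param roc result of [roc_curve()].
#' @return a ggplot object.
#' @export
plot_roc <- function(roc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_roc requires ggplot2")
  ggplot2::ggplot(roc$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", roc$auc))
}
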