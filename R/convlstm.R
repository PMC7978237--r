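# Convolutional LSTM cell (Shi-style: gates are convolutions over the
# concatenation of input and hidden state; no peepholes). The gate kernel is
# dilated, so the temporal memory also enjoys an enlarged spatial receptive
# field. "Backward" application = run on the time-reversed sequence and
# re-reverse the outputs.

new_convlstm <- function(name, cin, filters, kernel = 3L, dilation = 1L,
                         trainable = TRUE) {
  k <- kernel
  W <- he_uniform(c(k, k, cin + filters, 4L * filters), k * k * cin)
  # orthogonal initialization of the hidden->gate kernels, one column set per gate
  hidx <- cin + seq_len(filters)
  for (gate in 0:3) {
    q <- orthogonal_init(k * k * filters, filters)
    W[, , hidx, gate * filters + seq_len(filters)] <-
      array(q, c(k, k, filters, filters))
  }
  b <- numeric(4L * filters)
  b[filters + seq_len(filters)] <- 1  # forget-gate bias
  ly <- new_layer("convlstm", name, list(W = W, b = b),
                  meta = list(kernel = c(k, k), filters = filters, cin = cin,
                              dilation = as.integer(dilation),
                              pad = as.integer(dilation * (k - 1L) / 2L), stride = 1L),
                  trainable = trainable)
  ly
}

# xs: list of T arrays (H, W, Cin, N). Returns hs (original time order) + caches.
convlstm_fw <- function(cell, xs, reverse = FALSE) {
  xp <- if (reverse) rev(xs) else xs
  Tn <- length(xp)
  d <- dim(xp[[1]])
  Fh <- cell$filters
  h <- array(0, c(d[1], d[2], Fh, d[4]))
  cc <- h
  hs <- vector("list", Tn); caches <- vector("list", Tn)
  idx <- list(seq_len(Fh), Fh + seq_len(Fh), 2L * Fh + seq_len(Fh), 3L * Fh + seq_len(Fh))
  for (t in seq_len(Tn)) {
    xh <- array(0, c(d[1], d[2], d[3] + Fh, d[4]))
    xh[, , seq_len(d[3]), ] <- xp[[t]]
    xh[, , d[3] + seq_len(Fh), ] <- h
    z <- .conv2d_fw(xh, cell$par$W, cell$par$b, 1L, cell$dilation, cell$pad)
    gi <- sigm(z[, , idx[[1]], , drop = FALSE])
    gf <- sigm(z[, , idx[[2]], , drop = FALSE])
    go <- sigm(z[, , idx[[3]], , drop = FALSE])
    gg <- tanh(z[, , idx[[4]], , drop = FALSE])
    cprev <- cc
    cc <- gf * cprev + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    hs[[t]] <- h
    caches[[t]] <- list(xh = xh, i = gi, f = gf, o = go, g = gg,
                        cprev = cprev, tanhc = tc)
  }
  list(hs = if (reverse) rev(hs) else hs, caches = caches, reverse = reverse,
       cin = d[3])
}

# dhs: list of T gradient arrays in ORIGINAL time order (NULL entries allowed).
# Accumulates parameter gradients into the cell; returns dxs in original order.
convlstm_bw <- function(cell, fwd, dhs) {
  caches <- fwd$caches
  Tn <- length(caches)
  dp <- if (fwd$reverse) rev(dhs) else dhs
  Fh <- cell$filters; cin <- fwd$cin
  d <- dim(caches[[1]]$xh)
  dh_next <- array(0, c(d[1], d[2], Fh, d[4]))
  dc_next <- dh_next
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    ca <- caches[[t]]
    dh <- dh_next
    if (!is.null(dp[[t]])) dh <- dh + dp[[t]]
    dcc <- dc_next + dh * ca$o * (1 - ca$tanhc^2)
    do_ <- dh * ca$tanhc
    di <- dcc * ca$g
    dg <- dcc * ca$i
    df <- dcc * ca$cprev
    dc_next <- dcc * ca$f
    dz <- array(0, c(d[1], d[2], 4L * Fh, d[4]))
    dz[, , seq_len(Fh), ] <- di * ca$i * (1 - ca$i)
    dz[, , Fh + seq_len(Fh), ] <- df * ca$f * (1 - ca$f)
    dz[, , 2L * Fh + seq_len(Fh), ] <- do_ * ca$o * (1 - ca$o)
    dz[, , 3L * Fh + seq_len(Fh), ] <- dg * (1 - ca$g^2)
    bw <- .conv2d_bw(ca$xh, cell$par$W, dz, 1L, cell$dilation, cell$pad, TRUE)
    if (cell$trainable) {
      cell$grad$W <- cell$grad$W + bw$dw
      cell$grad$b <- cell$grad$b + bw$db
    }
    dxs[[t]] <- bw$dx[, , seq_len(cin), , drop = FALSE]
    dh_next <- bw$dx[, , cin + seq_len(Fh), , drop = FALSE]
  }
  if (fwd$reverse) rev(dxs) else dxs
}
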