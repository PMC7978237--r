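#' @useDynLib cineseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import tibble
#' @importFrom stats rnorm runif rgamma rbinom median sd dnorm setNames
NULL

# ---------------------------------------------------------------------------
# Layer objects. A layer is an environment carrying parameters, gradient
# accumulators and Adam state. Parameter names are listed in $pnames so the
# optimizer and audits can walk them generically.
# ---------------------------------------------------------------------------

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / max(1, fan_in))
  array(runif(prod(dims), -lim, lim), dims)
}

# orthogonal columns, used for the hidden-to-hidden part of ConvLSTM kernels
orthogonal_init <- function(nrow, ncol) {
  a <- matrix(rnorm(nrow * max(nrow, ncol)), nrow)
  q <- qr.Q(qr(a))[, seq_len(ncol), drop = FALSE]
  q
}

new_layer <- function(type, name, par, meta = list(), trainable = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type; ly$name <- name; ly$trainable <- trainable
  ly$par <- par
  ly$pnames <- names(par)
  ly$grad <- lapply(par, function(p) array(0, dim(p) %||% length(p)))
  ly$m <- lapply(par, function(p) array(0, dim(p) %||% length(p)))
  ly$v <- lapply(par, function(p) array(0, dim(p) %||% length(p)))
  for (nm in names(meta)) assign(nm, meta[[nm]], envir = ly)
  ly
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_conv <- function(name, kh, kw, cin, filters, stride = 1L, dilation = 1L,
                     pad = NULL, trainable = TRUE) {
  if (is.null(pad)) pad <- dilation * (kh - 1L) %/% 2L
  W <- he_uniform(c(kh, kw, cin, filters), kh * kw * cin)
  new_layer("conv", name, list(W = W, b = numeric(filters)),
            meta = list(kernel = c(kh, kw), filters = filters, cin = cin,
                        stride = as.integer(stride), dilation = as.integer(dilation),
                        pad = as.integer(pad)),
            trainable = trainable)
}

new_convt <- function(name, k, cout, cin, stride, trainable = TRUE) {
  pad <- as.integer((k - stride) / 2)  # output = stride * input
  W <- he_uniform(c(k, k, cout, cin), k * k * cin / (stride^2))
  new_layer("convt", name, list(W = W, b = numeric(cout)),
            meta = list(kernel = c(k, k), filters = cout, cin = cin,
                        stride = as.integer(stride), pad = pad),
            trainable = trainable)
}

new_bn <- function(name, channels, trainable = TRUE, eps = 1e-5, momentum = 0.1) {
  ly <- new_layer("bn", name, list(gamma = rep(1, channels), beta = numeric(channels)),
                  meta = list(channels = channels, eps = eps, momentum = momentum),
                  trainable = trainable)
  ly$rmean <- numeric(channels)
  ly$rvar <- rep(1, channels)
  ly
}

# ---------------------------------------------------------------------------
# Elementwise helpers
# ---------------------------------------------------------------------------

lrelu <- function(x, alpha) .lrelu_fw(x, alpha)
lrelu_dmask <- function(x, alpha) alpha + (1 - alpha) * (x > 0)
sigm <- function(x) 1 / (1 + exp(-x))

# channel-axis softmax for (H, W, C, N) arrays
softmax4 <- function(x) {
  d <- dim(x); C <- d[3]
  m <- x[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) m <- pmax(m, x[, , c, , drop = FALSE])
  e <- exp(x - array(m[, , rep(1, C), , drop = FALSE], d))
  s <- e[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) s <- s + e[, , c, , drop = FALSE]
  e / array(s[, , rep(1, C), , drop = FALSE], d)
}

bn_forward <- function(ly, x, training) {
  if (training) {
    st <- .bn_stats(x)
    mu <- st$sum / st$n
    va <- pmax(st$sumsq / st$n - mu^2, 0)
    ly$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * mu
    ly$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * va
  } else {
    mu <- ly$rmean; va <- ly$rvar
  }
  invstd <- 1 / sqrt(va + ly$eps)
  sc <- ly$par$gamma * invstd
  y <- .bn_affine(x, sc, ly$par$beta - mu * sc)
  list(y = y, mu = mu, invstd = invstd, x = x, training = training)
}

bn_backward <- function(ly, cache, dy) {
  r <- .bn_bw(cache$x, dy, cache$mu, cache$invstd, ly$par$gamma, cache$training)
  ly$grad$gamma <- ly$grad$gamma + r$dgamma
  ly$grad$beta <- ly$grad$beta + r$dbeta
  r$dx
}

# bilinear resize matrices (align_corners = FALSE convention)
bilinear_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    lo <- floor(src); whi <- src - lo
    lo0 <- min(max(lo, 0), n_in - 1); hi0 <- min(max(lo + 1, 0), n_in - 1)
    A[i, lo0 + 1] <- A[i, lo0 + 1] + (1 - whi)
    A[i, hi0 + 1] <- A[i, hi0 + 1] + whi
  }
  A
}

# y[h',w',c,n] = sum Ar[h',h] Ac[w',w] x[h,w,c,n]
resize4 <- function(x, Ar, Ac) {
  d <- dim(x)
  y1 <- Ar %*% matrix(x, d[1])                       # (Ho, W*C*N)
  y1 <- array(y1, c(nrow(Ar), d[2], d[3], d[4]))
  y2 <- aperm(y1, c(2, 1, 3, 4))
  y2 <- Ac %*% matrix(y2, d[2])
  aperm(array(y2, c(nrow(Ac), nrow(Ar), d[3], d[4])), c(2, 1, 3, 4))
}

# ---------------------------------------------------------------------------
# Reverse-mode tape over a fixed op vocabulary
# ---------------------------------------------------------------------------

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list(); tp$recs <- list(); tp$n <- 0L
  tp
}

t_push <- function(tp, val, rec = NULL) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- val
  if (!is.null(rec)) { rec$out <- tp$n; tp$recs[[length(tp$recs) + 1L]] <- rec }
  tp$n
}

t_input <- function(tp, x) t_push(tp, x)

t_conv <- function(tp, ly, i) {
  force(i)
  y <- .conv2d_fw(tp$vals[[i]], ly$par$W, ly$par$b, ly$stride, ly$dilation, ly$pad)
  t_push(tp, y, list(op = "conv", ly = ly, ins = i))
}

t_convt <- function(tp, ly, i) {
  force(i)
  y <- .convt2d_fw(tp$vals[[i]], ly$par$W, ly$par$b, ly$stride, ly$pad)
  t_push(tp, y, list(op = "convt", ly = ly, ins = i))
}

t_bn <- function(tp, ly, i, training) {
  force(i)
  cf <- bn_forward(ly, tp$vals[[i]], training)
  t_push(tp, cf$y, list(op = "bn", ly = ly, ins = i,
                        cache = cf[c("mu", "invstd", "x", "training")]))
}

t_lrelu <- function(tp, i, alpha) {
  force(i)
  x <- tp$vals[[i]]
  t_push(tp, lrelu(x, alpha), list(op = "lrelu", ins = i, cache = list(alpha = alpha)))
}

t_maxpool <- function(tp, i, k = 3L, stride = 2L, pad = 1L) {
  force(i)
  r <- .maxpool_fw(tp$vals[[i]], k, stride, pad)
  t_push(tp, r$y, list(op = "maxpool", ins = i,
                       cache = list(arg = r$arg, xdim = dim(tp$vals[[i]]))))
}

t_add <- function(tp, i, j) {
  force(i); force(j)
  t_push(tp, tp$vals[[i]] + tp$vals[[j]], list(op = "add", ins = c(i, j)))
}

t_concat <- function(tp, ids) {
  force(ids)
  xs <- tp$vals[ids]
  chs <- vapply(xs, function(a) dim(a)[3], 0)
  d1 <- dim(xs[[1]])
  y <- array(0, c(d1[1], d1[2], sum(chs), d1[4]))
  at <- 0L
  for (a in xs) { y[, , at + seq_len(dim(a)[3]), ] <- a; at <- at + dim(a)[3] }
  t_push(tp, y, list(op = "concat", ins = ids, cache = list(chs = chs)))
}

t_resize <- function(tp, i, Ho, Wo) {
  force(i)
  d <- dim(tp$vals[[i]])
  if (d[1] == Ho && d[2] == Wo) return(i)
  Ar <- bilinear_matrix(d[1], Ho); Ac <- bilinear_matrix(d[2], Wo)
  t_push(tp, resize4(tp$vals[[i]], Ar, Ac),
         list(op = "resize", ins = i, cache = list(Ar = Ar, Ac = Ac)))
}

t_gap <- function(tp, i) {
  force(i)
  x <- tp$vals[[i]]; d <- dim(x)
  mm <- apply(array(x, c(d[1] * d[2], d[3], d[4])), c(2, 3), mean)
  t_push(tp, array(mm, c(1, 1, d[3], d[4])),
         list(op = "gap", ins = i, cache = list(d = d)))
}

t_broadcast <- function(tp, i, H, W) {
  force(i)
  x <- tp$vals[[i]]; d <- dim(x)
  y <- array(rep(as.numeric(x), each = H * W), c(H, W, d[3], d[4]))
  t_push(tp, y, list(op = "broadcast", ins = i, cache = list(d = d)))
}

t_sigmoid <- function(tp, i) {
  force(i)
  y <- sigm(tp$vals[[i]])
  t_push(tp, y, list(op = "sigmoid", ins = i, cache = list(y = y)))
}

t_softmax <- function(tp, i) {
  force(i)
  y <- softmax4(tp$vals[[i]])
  t_push(tp, y, list(op = "softmax", ins = i, cache = list(y = y)))
}

# Backpropagate from seed gradients (a named list id -> gradient array).
# Parameter gradients accumulate into each layer's $grad; returns the
# gradient list so callers can read gradients at input nodes.
t_backward <- function(tp, seeds, need_input_grads = FALSE, stop_at = 0L) {
  grads <- vector("list", tp$n)
  for (nm in names(seeds)) {
    id <- as.integer(nm)
    grads[[id]] <- if (is.null(grads[[id]])) seeds[[nm]] else grads[[id]] + seeds[[nm]]
  }
  for (r in rev(tp$recs)) {
    dy <- grads[[r$out]]
    if (is.null(dy)) next
    grads[[r$out]] <- NA  # release
    ins <- r$ins
    acc <- function(id, g) {
      if (id <= stop_at) return(invisible(NULL))
      grads[[id]] <<- if (is.null(grads[[id]]) || identical(grads[[id]], NA)) g else grads[[id]] + g
      invisible(NULL)
    }
    switch(r$op,
      conv = {
        ly <- r$ly
        need_dx <- ins[1] > stop_at
        bw <- .conv2d_bw(tp$vals[[ins[1]]], ly$par$W, dy, ly$stride, ly$dilation, ly$pad, need_dx)
        if (ly$trainable) {
          ly$grad$W <- ly$grad$W + bw$dw; ly$grad$b <- ly$grad$b + bw$db
        }
        if (need_dx) acc(ins[1], bw$dx)
      },
      convt = {
        ly <- r$ly
        bw <- .convt2d_bw(tp$vals[[ins[1]]], ly$par$W, dy, ly$stride, ly$pad)
        if (ly$trainable) {
          ly$grad$W <- ly$grad$W + bw$dw; ly$grad$b <- ly$grad$b + bw$db
        }
        acc(ins[1], bw$dx)
      },
      bn = acc(ins[1], bn_backward(r$ly, r$cache, dy)),
      lrelu = acc(ins[1], .lrelu_bw(tp$vals[[ins[1]]], dy, r$cache$alpha)),
      maxpool = acc(ins[1], .maxpool_bw(dy, r$cache$arg, r$cache$xdim)),
      add = { acc(ins[1], dy); acc(ins[2], dy) },
      concat = {
        at <- 0L
        for (k in seq_along(ins)) {
          ch <- r$cache$chs[k]
          acc(ins[k], dy[, , at + seq_len(ch), , drop = FALSE])
          at <- at + ch
        }
      },
      resize = acc(ins[1], resize4(dy, t(r$cache$Ar), t(r$cache$Ac))),
      gap = {
        d <- r$cache$d
        g <- array(rep(as.numeric(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
        acc(ins[1], g)
      },
      broadcast = {
        d <- dim(dy)
        s <- apply(array(dy, c(d[1] * d[2], d[3], d[4])), c(2, 3), sum)
        acc(ins[1], array(s, r$cache$d))
      },
      sigmoid = { y <- r$cache$y; acc(ins[1], dy * y * (1 - y)) },
      softmax = {
        y <- r$cache$y; d <- dim(y)
        dyy <- dy * y
        s <- dyy[, , 1, , drop = FALSE]
        for (c in seq_len(d[3])[-1]) s <- s + dyy[, , c, , drop = FALSE]
        acc(ins[1], y * (dy - array(s[, , rep(1, d[3]), , drop = FALSE], d)))
      },
      stop("unknown tape op: ", r$op)
    )
  }
  if (need_input_grads) grads else invisible(NULL)
}

# ---------------------------------------------------------------------------
# Optimizer
# ---------------------------------------------------------------------------

zero_grads <- function(layers) {
  for (ly in layers)
    for (nm in ly$pnames) ly$grad[[nm]][] <- 0
  invisible(NULL)
}

adam_step <- function(layers, lr, step, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
  for (ly in layers) {
    if (!isTRUE(ly$trainable)) next
    for (nm in ly$pnames) {
      g <- ly$grad[[nm]]
      ly$m[[nm]] <- beta1 * ly$m[[nm]] + (1 - beta1) * g
      ly$v[[nm]] <- beta2 * ly$v[[nm]] + (1 - beta2) * g^2
      ly$par[[nm]] <- ly$par[[nm]] -
        lr * (ly$m[[nm]] / bc1) / (sqrt(ly$v[[nm]] / bc2) + eps)
    }
  }
  invisible(NULL)
}
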