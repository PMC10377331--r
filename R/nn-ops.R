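# Minimal convolutional network engine.
#
# No deep-learning framework is used: feature maps are dense 4-D arrays with
# dim (H, W, C, N), convolutions are lowered to a single BLAS gemm via
# im2col, and every layer has a hand-written backward pass.  Sizes in this
# package are small (<= 256 px, <= 64 channels) so pure R + BLAS is adequate.

nn_init_conv <- function(k, cin, cout, sd = 0.02) {
  list(W = matrix(rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = numeric(cout))
}

nn_init_dense <- function(nin, nout, sd = 0.02) {
  list(W = matrix(rnorm(nout * nin, sd = sd), nout, nin), b = numeric(nout))
}

# infer kernel side from a flattened weight matrix
conv_k <- function(W, cin) as.integer(round(sqrt(nrow(W) / cin)))

conv2d_fwd <- function(x, par, stride = 1L, pad = 0L) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; cin <- d[3L]; N <- d[4L]
  k <- conv_k(par$W, cin)
  if (pad > 0L) {
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, cin, N))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  } else xp <- x
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  M <- matrix(0, Ho * Wo * N, k * k * cin)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    sub <- xp[seq.int(di, by = stride, length.out = Ho),
              seq.int(dj, by = stride, length.out = Wo), , , drop = FALSE]
    sub <- aperm(sub, c(1L, 2L, 4L, 3L))
    dim(sub) <- c(Ho * Wo * N, cin)
    M[, ((dj - 1L) * k + di - 1L) * cin + seq_len(cin)] <- sub
  }
  Y <- M %*% par$W
  Y <- Y + rep(par$b, each = nrow(Y))
  dim(Y) <- c(Ho, Wo, N, ncol(par$W))
  out <- aperm(Y, c(1L, 2L, 4L, 3L))
  list(out = out, cache = list(M = M, xdim = d, pad = pad, stride = stride,
                               Ho = Ho, Wo = Wo, k = k))
}

conv2d_bwd <- function(dout, par, cache, need_dx = TRUE) {
  d <- cache$xdim
  H <- d[1L]; W <- d[2L]; cin <- d[3L]; N <- d[4L]
  k <- cache$k; pad <- cache$pad; stride <- cache$stride
  Ho <- cache$Ho; Wo <- cache$Wo
  dY <- aperm(dout, c(1L, 2L, 4L, 3L))
  dim(dY) <- c(Ho * Wo * N, ncol(par$W))
  gW <- crossprod(cache$M, dY)
  gb <- colSums(dY)
  dx <- NULL
  if (need_dx) {
    dM <- tcrossprod(dY, par$W)
    dxp <- array(0, c(H + 2L * pad, W + 2L * pad, cin, N))
    for (dj in seq_len(k)) for (di in seq_len(k)) {
      dsub <- dM[, ((dj - 1L) * k + di - 1L) * cin + seq_len(cin), drop = FALSE]
      dim(dsub) <- c(Ho, Wo, N, cin)
      dsub <- aperm(dsub, c(1L, 2L, 4L, 3L))
      ri <- seq.int(di, by = stride, length.out = Ho)
      ci <- seq.int(dj, by = stride, length.out = Wo)
      dxp[ri, ci, , ] <- dxp[ri, ci, , , drop = FALSE] + dsub
    }
    dx <- if (pad > 0L) dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
          else dxp
  }
  list(dx = dx, grad = list(W = gW, b = gb))
}

lrelu_fwd <- function(x, alpha = 0.2) {
  mask <- x > 0
  list(out = ifelse(mask, x, alpha * x), mask = mask, alpha = alpha)
}
lrelu_bwd <- function(dout, act) dout * ifelse(act$mask, 1, act$alpha)

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}
relu_bwd <- function(dout, act) dout * act$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# nearest-neighbour 2x upsampling and its adjoint
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , , drop = FALSE]
}
upsample2_bwd <- function(dout) {
  d <- dim(dout)
  H2 <- d[1L]; W2 <- d[2L]
  o <- seq.int(1L, H2, 2L); e <- seq.int(2L, H2, 2L)
  oc <- seq.int(1L, W2, 2L); ec <- seq.int(2L, W2, 2L)
  dout[o, oc, , , drop = FALSE] + dout[e, oc, , , drop = FALSE] +
    dout[o, ec, , , drop = FALSE] + dout[e, ec, , , drop = FALSE]
}

# 2x2 block-mean downsampling (area averaging) and its adjoint
down2_fwd <- function(x) {
  d <- dim(x)
  o <- seq.int(1L, d[1L], 2L); e <- seq.int(2L, d[1L], 2L)
  oc <- seq.int(1L, d[2L], 2L); ec <- seq.int(2L, d[2L], 2L)
  0.25 * (x[o, oc, , , drop = FALSE] + x[e, oc, , , drop = FALSE] +
          x[o, ec, , , drop = FALSE] + x[e, ec, , , drop = FALSE])
}
down2_bwd <- function(dout) 0.25 * upsample2_fwd(dout)

# channel concatenation along dim 3
concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

# ---- reflective-boundary 2-D correlation on plain matrices ------------------
# used by the Sobel operator and the Gaussian blur; p is half the kernel side

reflect_pad <- function(x, p) {
  H <- nrow(x); W <- ncol(x)
  stopifnot(H > p, W > p)
  ridx <- c(rev(seq_len(p) + 1L), seq_len(H), H - seq_len(p))
  cidx <- c(rev(seq_len(p) + 1L), seq_len(W), W - seq_len(p))
  x[ridx, cidx, drop = FALSE]
}

filter2_reflect <- function(x, K) {
  k <- nrow(K); p <- (k - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- reflect_pad(x, p)
  y <- matrix(0, H, W)
  for (j in seq_len(k)) for (i in seq_len(k)) {
    if (K[i, j] != 0)
      y <- y + K[i, j] * xp[i:(i + H - 1L), j:(j + W - 1L)]
  }
  y
}

# adjoint of filter2_reflect (for gradients of filtered losses)
filter2_reflect_adj <- function(dy, K) {
  k <- nrow(K); p <- (k - 1L) %/% 2L
  H <- nrow(dy); W <- ncol(dy)
  dxp <- matrix(0, H + 2L * p, W + 2L * p)
  for (j in seq_len(k)) for (i in seq_len(k)) {
    if (K[i, j] != 0)
      dxp[i:(i + H - 1L), j:(j + W - 1L)] <-
        dxp[i:(i + H - 1L), j:(j + W - 1L)] + K[i, j] * dy
  }
  # adjoint of reflect_pad: fold padded borders back onto their sources
  dx <- dxp[p + seq_len(H), p + seq_len(W), drop = FALSE]
  if (p > 0L) {
    for (q in seq_len(p)) {
      dx[q + 1L, ] <- dx[q + 1L, ] + dxp[p + 1L - q, p + seq_len(W)]
      dx[H - q, ]  <- dx[H - q, ]  + dxp[p + H + q, p + seq_len(W)]
    }
    for (q in seq_len(p)) {
      dx[, q + 1L] <- dx[, q + 1L] + dxp[p + seq_len(H), p + 1L - q]
      dx[, W - q]  <- dx[, W - q]  + dxp[p + seq_len(H), p + W + q]
    }
    # corners: row-fold of the column-folded borders
    for (q in seq_len(p)) for (s in seq_len(p)) {
      dx[q + 1L, s + 1L] <- dx[q + 1L, s + 1L] + dxp[p + 1L - q, p + 1L - s]
      dx[q + 1L, W - s]  <- dx[q + 1L, W - s]  + dxp[p + 1L - q, p + W + s]
      dx[H - q, s + 1L]  <- dx[H - q, s + 1L]  + dxp[p + H + q, p + 1L - s]
      dx[H - q, W - s]   <- dx[H - q, W - s]   + dxp[p + H + q, p + W + s]
    }
  }
  dx
}

# ---- parameter trees and Adam ----------------------------------------------
# parameters are nested lists whose leaves are numeric arrays

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x)); names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}

tree_map3 <- function(f, x, y, z) {
  if (is.list(x)) {
    out <- vector("list", length(x)); names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map3(f, x[[i]], y[[i]], z[[i]])
    out
  } else f(x, y, z)
}

tree_zeros <- function(x) tree_map(function(e) e * 0, x)

tree_finite <- function(x) {
  ok <- TRUE
  walk_ <- function(e) {
    if (is.list(e)) lapply(e, walk_) else if (!all(is.finite(e))) ok <<- FALSE
    invisible(NULL)
  }
  walk_(x)
  ok
}

adam_new <- function(params) list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)

adam_update <- function(params, grads, st, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, st$v, grads)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  params <- tree_map3(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                      params, st$m, st$v)
  list(params = params, state = st)
}
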