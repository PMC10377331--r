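# Generator: per-modality encoders, soft-thresholded sparse channel-attention
# fusion at every level, U-Net-style decoder with skips from the fused maps,
# tanh output on [-1,1].

#' Soft thresholding of attention weights
#'
#' The sparsity operator \eqn{S_\lambda(c) = \max(c - \lambda, 0)} applied
#' elementwise, zeroing weakly-informative fused channels. Non-expansive and
#' monotone in \eqn{\lambda}.
#'
#' @param c Nonnegative numeric vector of attention weights.
#' @param lambda Sparsity threshold, \eqn{\lambda \ge 0}.
#' @return Thresholded vector of the same length.
#' @export
soft_threshold <- function(c, lambda) {
  if (lambda < 0) abort("`lambda` must be >= 0.")
  pmax(c - lambda, 0)
}

#' Attention state at one fusion site
#'
#' Bundles the raw per-channel attention weights \code{c}, the sparsity level
#' \code{lambda}, and the soft-thresholded weights
#' \code{c_star = max(c - lambda, 0)}.
#'
#' @param c Nonnegative numeric vector (one weight per fused channel).
#' @param lambda Sparsity threshold.
#' @return A list of class \code{attention_state}.
#' @export
attention_state <- function(c, lambda = 0) {
  if (any(!is.finite(c))) abort("attention weights must be finite.")
  if (any(c < 0)) abort("attention weights must be nonnegative.")
  structure(list(c = c, lambda = lambda, c_star = soft_threshold(c, lambda)),
            class = "attention_state")
}

#' Fuse two feature maps under sparse channel attention
#'
#' Concatenates the two maps along channels and reweights every channel by
#' the thresholded attention weight \code{state$c_star}; channels with
#' \code{c_star = 0} contribute exactly zero. This is the deterministic core
#' of the learned fusion module (which produces \code{c} from the features
#' and projects the result back down).
#'
#' @param feat_a,feat_b Feature arrays of dim (H, W, C, N) with identical
#'   spatial shape.
#' @param state An [attention_state()] with \code{length(c)} equal to the
#'   total concatenated channel count.
#' @return The reweighted concatenated array (H, W, 2C, N).
#' @export
fuse_features <- function(feat_a, feat_b, state) {
  stopifnot(inherits(state, "attention_state"))
  da <- dim(feat_a); db <- dim(feat_b)
  if (!identical(da[c(1, 2, 4)], db[c(1, 2, 4)]))
    abort("feat_a and feat_b must share spatial shape and batch size.")
  z <- concat_c(feat_a, feat_b)
  dz <- dim(z)
  if (length(state$c_star) != dz[3])
    abort("attention state length must equal the concatenated channel count.")
  sc <- array(rep(rep(state$c_star, each = dz[1] * dz[2]), dz[4]), dz)
  z * sc
}

#' Generator configuration
#'
#' @param n_levels Encoder depth (stride-2 stages per modality); >= 2.
#' @param base_channels Channels after the first stage (doubled per level);
#'   >= 8.
#' @param lambda_sparsity Soft-threshold level applied to the sigmoid
#'   attention weights on every forward pass; default 0.05 on the
#'   \code{[0,1]} attention scale.
#' @param fusion_sites Integer vector of encoder levels at which sparse
#'   attention fusion is applied (default: all levels; non-fusion levels use
#'   a plain learned projection of the concatenated features).
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(n_levels = 4L, base_channels = 32L,
                             lambda_sparsity = 0.05,
                             fusion_sites = seq_len(n_levels)) {
  if (n_levels < 2L) abort("`n_levels` must be >= 2.")
  if (base_channels < 8L) abort("`base_channels` must be >= 8.")
  if (lambda_sparsity < 0) abort("`lambda_sparsity` must be >= 0.")
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 lambda_sparsity = lambda_sparsity,
                 fusion_sites = as.integer(fusion_sites)),
            class = "generator_config")
}

gen_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$n_levels) - 1L)

#' Initialize generator parameters
#'
#' Weights are drawn N(0, 0.02) from the current RNG stream, so results are
#' deterministic under a fixed seed.
#'
#' @param cfg A [generator_config()].
#' @return A nested parameter list (class \code{generator_params}).
#' @export
init_generator <- function(cfg) {
  ch <- gen_channels(cfg)
  n <- cfg$n_levels
  encA <- encB <- att <- vector("list", n)
  for (l in seq_len(n)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    encA[[l]] <- nn_init_conv(4L, cin, ch[l])
    encB[[l]] <- nn_init_conv(4L, cin, ch[l])
    c2 <- 2L * ch[l]
    hid <- max(4L, c2 %/% 4L)
    att[[l]] <- list(fc1 = nn_init_dense(c2, hid),
                     fc2 = nn_init_dense(hid, c2),
                     proj = nn_init_conv(1L, c2, ch[l]))
  }
  dec <- vector("list", max(n - 1L, 0L))
  for (l in seq_len(n - 1L)) # step from level l+1 down to level l
    dec[[l]] <- nn_init_conv(3L, ch[l + 1L] + ch[l], ch[l])
  head1 <- nn_init_conv(3L, ch[1L], ch[1L])
  head2 <- nn_init_conv(3L, ch[1L], 1L)
  structure(list(encA = encA, encB = encB, att = att, dec = dec,
                 head1 = head1, head2 = head2),
            class = "generator_params")
}

# one fusion site: channel attention over concatenated features, soft
# threshold, reweight, 1x1 projection, leaky ReLU
fusion_fwd <- function(a, b, ap, lambda, use_attention = TRUE) {
  z <- concat_c(a, b)
  dz <- dim(z)
  HW <- dz[1] * dz[2]; C2 <- dz[3]; N <- dz[4]
  if (use_attention) {
    zm <- z; dim(zm) <- c(HW, C2 * N)
    g <- matrix(colMeans(zm), C2, N)
    h <- ap$fc1$W %*% g + ap$fc1$b
    hmask <- h > 0
    a1 <- h * hmask
    craw <- ap$fc2$W %*% a1 + ap$fc2$b
    cc <- sigmoid(craw)
    cs <- pmax(cc - lambda, 0)
    collapsed <- colSums(cs) == 0
    if (any(collapsed))
      warn("sparse attention collapsed at a fusion site; using mean-skip path.")
  } else {
    cs <- matrix(1, C2, N)
    g <- a1 <- cc <- hmask <- NULL
    collapsed <- rep(FALSE, N)
  }
  sc <- array(rep(as.vector(cs), each = HW), dz)
  zw <- z * sc
  # 1x1 projection as a dense map over channels
  zmat <- aperm(zw, c(1, 2, 4, 3))
  dim(zmat) <- c(HW * N, C2)
  fm <- zmat %*% ap$proj$W + rep(ap$proj$b, each = HW * N)
  dim(fm) <- c(dz[1], dz[2], N, ncol(ap$proj$W))
  fused <- aperm(fm, c(1, 2, 4, 3))
  act <- lrelu_fwd(fused)
  out <- act$out
  if (any(collapsed)) {
    for (nidx in which(collapsed))
      out[, , , nidx] <- (a[, , , nidx, drop = FALSE] + b[, , , nidx, drop = FALSE]) / 2
  }
  list(out = out,
       cache = list(z = z, zmat = zmat, g = g, a1 = a1, cc = cc, cs = cs,
                    hmask = hmask, act = act, collapsed = collapsed,
                    dims = dz, use_attention = use_attention))
}

fusion_bwd <- function(dout, ap, cache, lambda) {
  dz4 <- cache$dims
  HW <- dz4[1] * dz4[2]; C2 <- dz4[3]; N <- dz4[4]
  C <- C2 %/% 2L
  grads <- list(fc1 = list(W = ap$fc1$W * 0, b = ap$fc1$b * 0),
                fc2 = list(W = ap$fc2$W * 0, b = ap$fc2$b * 0),
                proj = list(W = ap$proj$W * 0, b = ap$proj$b * 0))
  dskip_a <- dskip_b <- NULL
  if (any(cache$collapsed)) {
    dskip <- dout
    dskip[, , , !cache$collapsed] <- 0
    dskip_a <- dskip / 2
    dskip_b <- dskip / 2
    dout[, , , cache$collapsed] <- 0
  }
  dfused <- lrelu_bwd(dout, cache$act)
  dfm <- aperm(dfused, c(1, 2, 4, 3))
  dim(dfm) <- c(HW * N, ncol(ap$proj$W))
  grads$proj$W <- crossprod(cache$zmat, dfm)
  grads$proj$b <- colSums(dfm)
  dzmat <- tcrossprod(dfm, ap$proj$W)
  dim(dzmat) <- c(dz4[1], dz4[2], N, C2)
  dzw <- aperm(dzmat, c(1, 2, 4, 3))
  sc <- array(rep(as.vector(cache$cs), each = HW), dz4)
  dz <- dzw * sc
  if (cache$use_attention) {
    # d wrt per-(channel, sample) attention weight
    prod <- dzw * cache$z
    dim(prod) <- c(HW, C2 * N)
    dcs <- matrix(colSums(prod), C2, N)
    dcc <- dcs * (cache$cc > lambda)
    dcraw <- dcc * cache$cc * (1 - cache$cc)
    grads$fc2$W <- dcraw %*% t(cache$a1)
    grads$fc2$b <- rowSums(dcraw)
    da1 <- (t(ap$fc2$W) %*% dcraw) * cache$hmask
    grads$fc1$W <- da1 %*% t(cache$g)
    grads$fc1$b <- rowSums(da1)
    dg <- t(ap$fc1$W) %*% da1
    dz <- dz + array(rep(as.vector(dg), each = HW), dz4) / HW
  }
  da <- dz[, , seq_len(C), , drop = FALSE]
  db <- dz[, , C + seq_len(C), , drop = FALSE]
  if (!is.null(dskip_a)) {
    da <- da + dskip_a
    db <- db + dskip_b
  }
  list(da = da, db = db, grads = grads)
}

gen_forward <- function(params, x1, x2, cfg, keep_cache = TRUE) {
  n <- cfg$n_levels
  caches <- list(encA = vector("list", n), encB = vector("list", n),
                 fus = vector("list", n), dec = vector("list", n))
  a <- x1; b <- x2
  featA <- featB <- fused <- vector("list", n)
  for (l in seq_len(n)) {
    ca <- conv2d_fwd(a, params$encA[[l]], stride = 2L, pad = 1L)
    aa <- lrelu_fwd(ca$out)
    cb <- conv2d_fwd(b, params$encB[[l]], stride = 2L, pad = 1L)
    ab <- lrelu_fwd(cb$out)
    caches$encA[[l]] <- list(conv = ca$cache, act = aa)
    caches$encB[[l]] <- list(conv = cb$cache, act = ab)
    a <- aa$out; b <- ab$out
    featA[[l]] <- a; featB[[l]] <- b
    fw <- fusion_fwd(a, b, params$att[[l]], cfg$lambda_sparsity,
                     use_attention = l %in% cfg$fusion_sites)
    caches$fus[[l]] <- fw$cache
    fused[[l]] <- fw$out
  }
  cur <- fused[[n]]
  for (l in rev(seq_len(n - 1L))) {
    up <- upsample2_fwd(cur)
    cat_ <- concat_c(up, fused[[l]])
    cv <- conv2d_fwd(cat_, params$dec[[l]], stride = 1L, pad = 1L)
    act <- relu_fwd(cv$out)
    caches$dec[[l]] <- list(conv = cv$cache, act = act,
                            ch_up = dim(up)[3])
    cur <- act$out
  }
  up <- upsample2_fwd(cur)
  h1 <- conv2d_fwd(up, params$head1, stride = 1L, pad = 1L)
  a1 <- relu_fwd(h1$out)
  h2 <- conv2d_fwd(a1$out, params$head2, stride = 1L, pad = 1L)
  out <- tanh(h2$out)
  caches$head <- list(h1 = h1$cache, a1 = a1, h2 = h2$cache, out = out)
  list(out = out, cache = if (keep_cache) caches else NULL)
}

gen_backward <- function(params, cfg, cache, dout) {
  n <- cfg$n_levels
  grads <- tree_zeros(unclass(params))
  dh2 <- dout * (1 - cache$head$out^2)
  bw2 <- conv2d_bwd(dh2, params$head2, cache$head$h2)
  grads$head2 <- bw2$grad
  da1 <- relu_bwd(bw2$dx, cache$head$a1)
  bw1 <- conv2d_bwd(da1, params$head1, cache$head$h1)
  grads$head1 <- bw1$grad
  dcur <- upsample2_bwd(bw1$dx)
  dfused <- vector("list", n)
  for (l in seq_len(n - 1L)) {
    cc <- cache$dec[[l]]
    dact <- relu_bwd(dcur, cc$act)
    bw <- conv2d_bwd(dact, params$dec[[l]], cc$conv)
    grads$dec[[l]] <- bw$grad
    ch_up <- cc$ch_up
    dup <- bw$dx[, , seq_len(ch_up), , drop = FALSE]
    dfused[[l]] <- bw$dx[, , ch_up + seq_len(dim(bw$dx)[3] - ch_up), , drop = FALSE]
    dcur <- upsample2_bwd(dup)
  }
  dfused[[n]] <- dcur
  dA <- dB <- vector("list", n)
  for (l in seq_len(n)) {
    fb <- fusion_bwd(dfused[[l]], params$att[[l]], cache$fus[[l]],
                     cfg$lambda_sparsity)
    grads$att[[l]] <- fb$grads
    dA[[l]] <- fb$da
    dB[[l]] <- fb$db
  }
  for (l in rev(seq_len(n))) {
    dact <- lrelu_bwd(dA[[l]], cache$encA[[l]]$act)
    bw <- conv2d_bwd(dact, params$encA[[l]], cache$encA[[l]]$conv,
                     need_dx = l > 1L)
    grads$encA[[l]] <- bw$grad
    if (l > 1L) dA[[l - 1L]] <- dA[[l - 1L]] + bw$dx
    dact <- lrelu_bwd(dB[[l]], cache$encB[[l]]$act)
    bw <- conv2d_bwd(dact, params$encB[[l]], cache$encB[[l]]$conv,
                     need_dx = l > 1L)
    grads$encB[[l]] <- bw$grad
    if (l > 1L) dB[[l - 1L]] <- dB[[l - 1L]] + bw$dx
  }
  grads
}

#' Synthesize a contrast-enhanced slice
#'
#' Runs the generator on normalized (\code{[-1,1]}) T1pre and T2 inputs and
#' returns the synthetic T1ce on \code{[-1,1]}. Inputs whose side length is
#' not divisible by \code{2^n_levels} are reflect-padded and the output is
#' cropped back.
#'
#' @param t1pre,t2 Numeric matrices on \code{[-1,1]} with identical shape.
#' @param params Generator parameters from [init_generator()] or a trained
#'   fit's \code{generator}.
#' @param cfg The matching [generator_config()].
#' @return A numeric matrix of the same spatial shape, values in
#'   \code{[-1,1]}. Deterministic given fixed parameters.
#' @export
synthesize <- function(t1pre, t2, params, cfg) {
  stopifnot(identical(dim(t1pre), dim(t2)))
  H <- nrow(t1pre); W <- ncol(t1pre)
  div <- 2L^cfg$n_levels
  Hp <- ceiling(H / div) * div
  Wp <- ceiling(W / div) * div
  padded <- Hp != H || Wp != W
  if (padded) {
    inform(sprintf("synthesize: padding %dx%d to %dx%d for the encoder pyramid.",
                   H, W, Hp, Wp))
    padm <- function(m) {
      out <- matrix(0, Hp, Wp)
      out[seq_len(H), seq_len(W)] <- m
      if (Hp > H) out[(H + 1):Hp, seq_len(W)] <- m[H - seq_len(Hp - H) + 1, , drop = FALSE]
      if (Wp > W) out[, (W + 1):Wp] <- out[, W - seq_len(Wp - W) + 1, drop = FALSE]
      out
    }
    t1pre <- padm(t1pre); t2 <- padm(t2)
  }
  x1 <- array(t1pre, c(Hp, Wp, 1L, 1L))
  x2 <- array(t2, c(Hp, Wp, 1L, 1L))
  out <- gen_forward(params, x1, x2, cfg, keep_cache = FALSE)$out
  res <- matrix(out[, , 1L, 1L], Hp, Wp)
  if (padded) res <- res[seq_len(H), seq_len(W), drop = FALSE]
  res
}
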