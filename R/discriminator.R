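# Multi-scale multi-smoothness discriminator bank: three patch-based
# conditional discriminators at halved resolutions; synthetic candidates are
# additionally presented Gaussian-blurred as negatives so over-smoothed
# output is penalised.

#' Discriminator bank configuration
#'
#' @param n_scales Number of discrimination scales; fixed at 3.
#' @param blur_sigma Gaussian blur sigma in pixels for the over-smoothed
#'   negative; > 0.
#' @param blur_kernel Gaussian kernel side in pixels; odd.
#' @param base_channels Channels of the first discriminator stage.
#' @return A list of class \code{disc_bank_config}.
#' @export
disc_bank_config <- function(n_scales = 3L, blur_sigma = 1.0, blur_kernel = 5L,
                             base_channels = 64L) {
  if (n_scales != 3L) abort("the discriminator bank uses exactly 3 scales.")
  if (blur_sigma <= 0) abort("`blur_sigma` must be > 0.")
  if (blur_kernel %% 2L == 0L) abort("`blur_kernel` must be odd.")
  structure(list(n_scales = 3L, blur_sigma = blur_sigma,
                 blur_kernel = as.integer(blur_kernel),
                 base_channels = as.integer(base_channels)),
            class = "disc_bank_config")
}

#' Build a three-scale image pyramid
#'
#' Downsamples twice by 2 x 2 area averaging, yielding the three
#' discrimination scales (e.g. 256, 128, 64 for a 256-pixel input).
#'
#' @param image Numeric matrix with side lengths divisible by 4.
#' @param n_scales Number of scales (3).
#' @return A list of class \code{scale_pyramid}: one matrix per scale,
#'   largest first.
#' @export
build_pyramid <- function(image, n_scales = 3L) {
  stopifnot(is.matrix(image))
  if (nrow(image) %% 4L != 0L || ncol(image) %% 4L != 0L)
    abort("pyramid input side lengths must be divisible by 4.")
  out <- vector("list", n_scales)
  x <- array(image, c(dim(image), 1L, 1L))
  for (k in seq_len(n_scales)) {
    out[[k]] <- matrix(x[, , 1L, 1L], dim(x)[1L], dim(x)[2L])
    if (k < n_scales) x <- down2_fwd(x)
  }
  structure(out, class = "scale_pyramid")
}

# batched pyramid on (H, W, 1, N) arrays, used by the trainer
build_pyramid4 <- function(x, n_scales = 3L) {
  out <- vector("list", n_scales)
  for (k in seq_len(n_scales)) {
    out[[k]] <- x
    if (k < n_scales) x <- down2_fwd(x)
  }
  out
}

gaussian_kernel <- function(sigma, kernel) {
  half <- (kernel - 1L) %/% 2L
  g <- exp(-(seq.int(-half, half))^2 / (2 * sigma^2))
  K <- outer(g, g)
  K / sum(K)
}

#' Gaussian blur with reflective boundary
#'
#' Convolution with a normalized Gaussian kernel; constants are preserved
#' exactly (the kernel sums to 1 and the boundary is reflective).
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian sigma in pixels; > 0.
#' @param kernel Kernel side in pixels; odd.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(image, sigma = 1.0, kernel = 5L) {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (kernel %% 2L == 0L) abort("`kernel` must be odd.")
  filter2_reflect(image, gaussian_kernel(sigma, kernel))
}

gaussian_blur4 <- function(x, sigma, kernel) {
  K <- gaussian_kernel(sigma, kernel)
  d <- dim(x)
  out <- x
  for (n in seq_len(d[4L])) for (ch in seq_len(d[3L]))
    out[, , ch, n] <- filter2_reflect(matrix(x[, , ch, n], d[1L], d[2L]), K)
  out
}

#' Initialize one patch discriminator
#'
#' Three-stage convolutional patch classifier: two stride-2 leaky-ReLU
#' stages followed by a 3 x 3 score head with sigmoid output; the score map
#' is smaller than the input (patch-based receptive field). Input has three
#' channels: the two conditioning modalities and the candidate.
#'
#' @param base_channels Channels of the first stage.
#' @return A nested parameter list.
#' @export
init_discriminator <- function(base_channels = 64L) {
  list(c1 = nn_init_conv(4L, 3L, base_channels),
       c2 = nn_init_conv(4L, base_channels, 2L * base_channels),
       c3 = nn_init_conv(3L, 2L * base_channels, 1L))
}

disc_forward <- function(par, x) {
  f1 <- conv2d_fwd(x, par$c1, stride = 2L, pad = 1L)
  a1 <- lrelu_fwd(f1$out)
  f2 <- conv2d_fwd(a1$out, par$c2, stride = 2L, pad = 1L)
  a2 <- lrelu_fwd(f2$out)
  f3 <- conv2d_fwd(a2$out, par$c3, stride = 1L, pad = 1L)
  s <- sigmoid(f3$out)
  list(score = s, cache = list(f1 = f1$cache, a1 = a1, f2 = f2$cache,
                               a2 = a2, f3 = f3$cache, s = s))
}

# dscore: gradient wrt the sigmoid score map
disc_backward <- function(par, cache, dscore, need_dx = FALSE) {
  dlogit <- dscore * cache$s * (1 - cache$s)
  bw3 <- conv2d_bwd(dlogit, par$c3, cache$f3)
  da2 <- lrelu_bwd(bw3$dx, cache$a2)
  bw2 <- conv2d_bwd(da2, par$c2, cache$f2)
  da1 <- lrelu_bwd(bw2$dx, cache$a1)
  bw1 <- conv2d_bwd(da1, par$c1, cache$f1, need_dx = need_dx)
  list(dx = bw1$dx, grads = list(c1 = bw1$grad, c2 = bw2$grad, c3 = bw3$grad))
}

#' Score real, synthetic and blurred-synthetic candidates at all scales
#'
#' For each scale k, discriminator k scores three candidates — the real
#' image, the synthetic image, and the Gaussian-blurred synthetic image —
#' each conditioned on the (T1pre, T2) inputs downsampled to that scale.
#'
#' @param bank List of 3 discriminator parameter sets
#'   (from [init_discriminator()]).
#' @param cond1,cond2 Conditioning matrices (T1pre, T2) at full resolution,
#'   model scale.
#' @param real,synth Real and synthetic candidates at full resolution.
#' @param config A [disc_bank_config()].
#' @return A list with per-scale score maps \code{real}, \code{synth},
#'   \code{blurred} (each a list of 3 matrices, largest scale first).
#' @export
discriminate_all <- function(bank, cond1, cond2, real, synth, config = disc_bank_config()) {
  stopifnot(length(bank) == 3L)
  if (!identical(dim(real), dim(synth)))
    abort("real and synthetic pyramids must match in shape.")
  p1 <- build_pyramid(cond1); p2 <- build_pyramid(cond2)
  pr <- build_pyramid(real); ps <- build_pyramid(synth)
  out <- list(real = vector("list", 3L), synth = vector("list", 3L),
              blurred = vector("list", 3L))
  for (k in 1:3) {
    as4 <- function(m) array(m, c(dim(m), 1L, 1L))
    cond <- concat_c(as4(p1[[k]]), as4(p2[[k]]))
    blur <- gaussian_blur(ps[[k]], config$blur_sigma, config$blur_kernel)
    for (cand in c("real", "synth", "blurred")) {
      m <- switch(cand, real = pr[[k]], synth = ps[[k]], blurred = blur)
      x <- concat_c(cond, as4(m))
      sc <- disc_forward(bank[[k]], x)$score
      out[[cand]][[k]] <- matrix(sc[, , 1L, 1L], dim(sc)[1L], dim(sc)[2L])
    }
  }
  out
}
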