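# Objective terms: conditional-GAN loss, L1 fidelity, Sobel gradient
# regularization, the combined weighted objective, and the lambda1 /
# learning-rate schedules. All expectations are per-pixel means so the
# weights are resolution-independent.

#' Sobel kernels
#'
#' The horizontal-gradient kernel \code{[[-1,0,1],[-2,0,2],[-1,0,1]]} and its
#' transpose. Both sum to zero, so constant images (and constant offsets)
#' are annihilated.
#'
#' @return A list with 3 x 3 matrices \code{kx} and \code{ky}.
#' @export
sobel_kernels <- function() {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  list(kx = kx, ky = t(kx))
}

#' Sobel gradient response
#'
#' Correlates the image with the two Sobel kernels under a reflective
#' boundary, returning a two-channel response of the same spatial size
#' (channel 1: horizontal/x gradient, channel 2: vertical/y gradient).
#'
#' @param image Numeric matrix, at least 3 x 3.
#' @return Array of dim (H, W, 2).
#' @export
sobel_response <- function(image) {
  if (nrow(image) < 3L || ncol(image) < 3L)
    abort("sobel_response requires an image of at least 3 x 3.")
  counter_bump("sobel")
  K <- sobel_kernels()
  out <- array(0, c(dim(image), 2L))
  out[, , 1L] <- filter2_reflect(image, K$kx)
  out[, , 2L] <- filter2_reflect(image, K$ky)
  out
}

#' Gradient-regularization loss
#'
#' Mean over pixels and both gradient channels of the squared Sobel response
#' of \code{synth - real}; zero iff the two images differ by a constant
#' (the zero-sum kernels annihilate constant offsets).
#'
#' @param synth,real Numeric matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
gr_loss <- function(synth, real) {
  if (!identical(dim(synth), dim(real))) abort("gr_loss: shape mismatch.")
  r <- sobel_response(synth - real)
  mean(r^2)
}

# gradient of gr_loss wrt synth (adjoint Sobel correlation)
gr_grad <- function(synth, real) {
  counter_bump("sobel")
  K <- sobel_kernels()
  d <- synth - real
  rx <- filter2_reflect(d, K$kx)
  ry <- filter2_reflect(d, K$ky)
  n <- 2 * length(d)
  (2 / n) * (filter2_reflect_adj(rx, K$kx) + filter2_reflect_adj(ry, K$ky))
}

#' L1 fidelity loss
#'
#' Mean absolute pixel difference; promotes structural consistency between
#' the synthetic and real images.
#'
#' @param synth,real Numeric arrays of identical shape.
#' @return Nonnegative scalar.
#' @export
l1_loss <- function(synth, real) {
  if (!identical(dim(synth), dim(real))) abort("l1_loss: shape mismatch.")
  mean(abs(synth - real))
}

#' Conditional-GAN loss from score maps
#'
#' Discriminator loss \code{-mean(log s_real + log(1 - s_fake))} and the
#' generator's non-saturating loss \code{-mean(log s_fake)} (pass
#' \code{saturating = TRUE} for the literal minimax form
#' \code{mean(log(1 - s_fake))}). Scores are probabilities; values outside
#' \code{(0,1)} are clamped at 1e-7.
#'
#' @param score_real,score_fake Numeric score maps in (0,1).
#' @param saturating Use the saturating generator form.
#' @return A list with \code{d_loss} and \code{g_loss}.
#' @export
cgan_loss <- function(score_real, score_fake, saturating = FALSE) {
  eps <- 1e-7
  clamp <- function(s) {
    if (any(s <= 0 | s >= 1)) {
      inform("cgan_loss: scores clamped into (0,1).")
      s <- pmin(pmax(s, eps), 1 - eps)
    }
    s
  }
  sr <- clamp(score_real)
  sf <- clamp(score_fake)
  d_loss <- -(mean(log(sr)) + mean(log(1 - sf)))
  g_loss <- if (saturating) mean(log(1 - sf)) else -mean(log(sf))
  list(d_loss = d_loss, g_loss = g_loss)
}

#' Loss weights
#'
#' @param lambda1 Weight of the gradient-regularization term (scheduled
#'   during training, reaching 50).
#' @param lambda2 Weight of the L1 term (100).
#' @return A list of class \code{loss_weights}.
#' @export
loss_weights <- function(lambda1 = 50, lambda2 = 100) {
  if (lambda1 < 0 || lambda2 < 0) abort("loss weights must be >= 0.")
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "loss_weights")
}

#' Combine loss terms into the training objective
#'
#' Generator total = sum of the per-scale adversarial generator terms +
#' \code{lambda1 * l_gr} + \code{lambda2 * l_l1}; discriminator total = sum
#' of the per-scale discriminator terms. Ablation \code{"no_mmd"} keeps only
#' scale 1; \code{"no_gr_no_mmd"} additionally drops the gradient term.
#'
#' @param g_per_scale,d_per_scale Numeric vectors of per-scale adversarial
#'   terms (3 entries for the full model).
#' @param l_l1,l_gr The fidelity and gradient terms.
#' @param weights A [loss_weights()].
#' @param ablation \code{"full"}, \code{"no_mmd"} or \code{"no_gr_no_mmd"}.
#' @return A one-row tibble (LossReport): per-scale adversarial terms,
#'   \code{l_l1}, \code{l_gr}, the weights, \code{total_g}, \code{total_d}.
#' @export
total_objective <- function(g_per_scale, d_per_scale, l_l1, l_gr,
                            weights = loss_weights(),
                            ablation = c("full", "no_mmd", "no_gr_no_mmd")) {
  ablation <- match.arg(ablation)
  keep <- if (ablation == "full") seq_along(g_per_scale) else 1L
  lam1 <- if (ablation == "no_gr_no_mmd") 0 else weights$lambda1
  g3 <- d3 <- numeric(3)
  g3[seq_along(g_per_scale)] <- g_per_scale
  d3[seq_along(d_per_scale)] <- d_per_scale
  total_g <- sum(g_per_scale[keep]) + lam1 * l_gr + weights$lambda2 * l_l1
  total_d <- sum(d_per_scale[keep])
  tibble(l_cgan_1 = g3[1], l_cgan_2 = g3[2], l_cgan_3 = g3[3],
         l_l1 = l_l1, l_gr = l_gr,
         lambda1 = lam1, lambda2 = weights$lambda2,
         total_g = total_g, total_d = total_d)
}

#' Gradient-regularization weight schedule
#'
#' Linear increase from 0 to 50 over the first 50 epochs, then frozen at 50.
#'
#' @param epoch 1-based epoch in 1..150.
#' @return The lambda1 value at that epoch.
#' @export
lambda1_at <- function(epoch) {
  if (any(epoch < 1 | epoch > 150)) abort("`epoch` must be in 1..150.")
  50 * pmin(epoch, 50) / 50
}

#' Learning-rate schedule
#'
#' Fixed at 2e-4 for the first 50 epochs, then linearly decayed to 0 over
#' the following 100.
#'
#' @param epoch 1-based epoch in 1..150.
#' @return The learning rate at that epoch.
#' @export
lr_at <- function(epoch) {
  if (any(epoch < 1 | epoch > 150)) abort("`epoch` must be in 1..150.")
  ifelse(epoch <= 50, 2e-4, 2e-4 * (150 - epoch) / 100)
}
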