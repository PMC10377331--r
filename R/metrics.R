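# Quantitative evaluation: MSE, PSNR, global SSIM, tumor CNR, Dice,
# Hausdorff distance, center-of-mass shift, and Turing-test scoring.
# All intensity metrics assume the metric_255 scale (8-bit dynamic range,
# L = 255).

#' SSIM stabilization constants
#'
#' @param L Dynamic range (255).
#' @param k1,k2 Stabilization factors (0.01, 0.03); give
#'   \code{c1 = (k1 L)^2 = 6.5025} and \code{c2 = (k2 L)^2 = 58.5225}.
#' @return A list of class \code{metric_params}.
#' @export
metric_params <- function(L = 255, k1 = 0.01, k2 = 0.03) {
  structure(list(L = L, k1 = k1, k2 = k2, c1 = (k1 * L)^2, c2 = (k2 * L)^2),
            class = "metric_params")
}

#' Mean squared error
#' @param y,g Numeric matrices (ground truth, synthesis) of identical shape.
#' @return Nonnegative scalar.
#' @export
mse <- function(y, g) {
  if (!identical(dim(y), dim(g))) abort("mse: shape mismatch.")
  mean((y - g)^2)
}

#' Peak signal-to-noise ratio
#'
#' \code{10 log10(L^2 / MSE)} with L = 255; identical images return
#' \code{Inf}.
#'
#' @param y,g Numeric matrices on the metric_255 scale.
#' @param L Dynamic range.
#' @return PSNR in dB (possibly \code{Inf}).
#' @export
psnr <- function(y, g, L = 255) {
  m <- mse(y, g)
  if (m == 0) return(Inf)
  10 * log10(L^2 / m)
}

#' Global (single-window) structural similarity
#'
#' Whole-image means, variances and covariance in the standard SSIM ratio
#' with stabilizers c1, c2. Population (1/n) moments are used.
#'
#' @param y,g Numeric matrices on the metric_255 scale.
#' @param params A [metric_params()].
#' @return SSIM in \code{[-1, 1]}.
#' @export
ssim_global <- function(y, g, params = metric_params()) {
  if (!identical(dim(y), dim(g))) abort("ssim_global: shape mismatch.")
  n <- length(y)
  muy <- mean(y); mug <- mean(g)
  vy <- mean((y - muy)^2); vg <- mean((g - mug)^2)
  cov <- mean((y - muy) * (g - mug))
  ((2 * muy * mug + params$c1) * (2 * cov + params$c2)) /
    ((muy^2 + mug^2 + params$c1) * (vy + vg + params$c2))
}

#' Windowed SSIM (mean over sliding windows)
#'
#' Alternative to the global form: uniform square windows with stride 1,
#' population moments per window, averaged. Provided because published SSIM
#' values are sometimes windowed.
#'
#' @param y,g Numeric matrices on the metric_255 scale.
#' @param window Window side in pixels.
#' @param params A [metric_params()].
#' @return Mean local SSIM.
#' @export
ssim_windowed <- function(y, g, window = 8L, params = metric_params()) {
  if (!identical(dim(y), dim(g))) abort("ssim_windowed: shape mismatch.")
  H <- nrow(y); W <- ncol(y)
  stopifnot(window <= H, window <= W)
  box <- matrix(1 / window^2, window, window)
  run <- function(m) { # 'valid' box filter via cumulative sums
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative sum
    cs <- t(cs)
    pad <- matrix(0, H + 1, W + 1)
    pad[-1, -1] <- cs
    (pad[(window + 1):(H + 1), (window + 1):(W + 1)] -
       pad[1:(H - window + 1), (window + 1):(W + 1)] -
       pad[(window + 1):(H + 1), 1:(W - window + 1)] +
       pad[1:(H - window + 1), 1:(W - window + 1)]) / window^2
  }
  muy <- run(y); mug <- run(g)
  vy <- run(y^2) - muy^2; vg <- run(g^2) - mug^2
  cov <- run(y * g) - muy * mug
  s <- ((2 * muy * mug + params$c1) * (2 * cov + params$c2)) /
    ((muy^2 + mug^2 + params$c1) * (vy + vg + params$c2))
  mean(s)
}

#' Region boxes for CNR
#'
#' Axis-aligned, non-overlapping pixel rectangles (rows r1..r2, cols c1..c2,
#' 1-based inclusive) for the tumor, normal-liver and background-noise
#' regions on one slice.
#'
#' @param tumor_box,normal_box,background_box Length-4 integer vectors
#'   \code{c(r1, r2, c1, c2)}.
#' @return A list of class \code{region_boxes}.
#' @export
region_boxes <- function(tumor_box, normal_box, background_box) {
  chk <- function(b) stopifnot(length(b) == 4, b[1] <= b[2], b[3] <= b[4])
  chk(tumor_box); chk(normal_box); chk(background_box)
  overlaps <- function(a, b)
    a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
  if (overlaps(tumor_box, normal_box) || overlaps(tumor_box, background_box) ||
      overlaps(normal_box, background_box))
    abort("region boxes must be pairwise non-overlapping.")
  structure(list(tumor = tumor_box, normal = normal_box,
                 background = background_box), class = "region_boxes")
}

box_pixels <- function(slice, b) slice[b[1]:b[2], b[3]:b[4]]

#' Tumor contrast-to-noise ratio
#'
#' \code{|mean(tumor) - mean(normal)| / sd(background)} with the population
#' (1/n) standard deviation of the background-noise region. Invariant under
#' whole-slice affine intensity changes with positive scale.
#'
#' @param slice Numeric matrix.
#' @param boxes A [region_boxes()].
#' @return Nonnegative scalar (\code{Inf} with a warning if the background
#'   is constant).
#' @export
cnr <- function(slice, boxes) {
  stopifnot(inherits(boxes, "region_boxes"))
  bt <- box_pixels(slice, boxes$tumor)
  bn <- box_pixels(slice, boxes$normal)
  bb <- box_pixels(slice, boxes$background)
  sb <- sqrt(mean((bb - mean(bb))^2))
  if (sb == 0) {
    warn("cnr: constant background region; returning Inf.")
    return(Inf)
  }
  abs(mean(bt) - mean(bn)) / sb
}

#' Dice overlap coefficient
#'
#' \code{2|A \eqn{\cap} B| / (|A| + |B|)} — intersection over the average of
#' the two volumes.
#'
#' @param mask_a,mask_b Logical (or 0/1) matrices of identical shape.
#' @return Dice in \code{[0,1]}; both-empty masks are an error.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) abort("dice: shape mismatch.")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) abort("dice undefined: both masks are empty.")
  2 * sum(a & b) / (sa + sb)
}

mask_coords_mm <- function(mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask has no foreground pixels.")
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
}

#' Hausdorff distance between two masks
#'
#' Classical max form: the larger of the two directed Hausdorff distances
#' between the foreground point sets, in mm (anisotropic spacing honoured).
#'
#' @param mask_a,mask_b Logical matrices of identical shape, each non-empty.
#' @param spacing mm per pixel (row, col).
#' @return Distance in mm.
#' @export
hausdorff <- function(mask_a, mask_b, spacing = c(1, 1)) {
  if (!identical(dim(mask_a), dim(mask_b))) abort("hausdorff: shape mismatch.")
  A <- mask_coords_mm(mask_a, spacing)
  B <- mask_coords_mm(mask_b, spacing)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  dirAB <- max(apply(d2, 1, min))
  dirBA <- max(apply(d2, 2, min))
  sqrt(max(dirAB, dirBA))
}

#' Tumor center-of-mass shift
#'
#' Componentwise difference of the two mask centroids, scaled by spacing and
#' mapped to anatomical axes under the package coordinate convention
#' (row = anterior-posterior, column = right-left; single axial slices have
#' superior-inferior shift 0).
#'
#' @param mask_a,mask_b Logical matrices (e.g. real and synthetic tumor
#'   masks), each non-empty.
#' @param spacing mm per pixel (row, col).
#' @return Named numeric \code{c(SI, RL, AP)} in mm
#'   (centroid of \code{mask_b} minus centroid of \code{mask_a}).
#' @export
com_shift <- function(mask_a, mask_b, spacing = c(1, 1)) {
  if (!identical(dim(mask_a), dim(mask_b))) abort("com_shift: shape mismatch.")
  ca <- colMeans(mask_coords_mm(mask_a, spacing))
  cb <- colMeans(mask_coords_mm(mask_b, spacing))
  d <- cb - ca
  c(SI = 0, RL = unname(d[2]), AP = unname(d[1]))
}

#' Score a Turing test
#'
#' Per-rater percent correct plus the mean and sample (n-1) standard
#' deviation across raters. A single rater yields sd 0 with a warning.
#'
#' @param record A data frame with columns \code{n_correct} and
#'   \code{n_total} (one row per rater; an optional \code{rater} column is
#'   carried through).
#' @return A list of class \code{turing_score}: \code{per_rater} tibble with
#'   \code{pct_correct}, \code{mean_pct}, \code{sd_pct}.
#' @export
turing_score <- function(record) {
  if (nrow(record) == 0) abort("turing_score: empty record.")
  stopifnot(all(c("n_correct", "n_total") %in% names(record)))
  if (any(record$n_total <= 0)) abort("turing_score: n_total must be > 0.")
  if (any(record$n_correct > record$n_total))
    abort("turing_score: n_correct exceeds n_total.")
  per <- as_tibble(record)
  per$pct_correct <- 100 * per$n_correct / per$n_total
  sd_pct <- if (nrow(per) < 2) {
    warn("turing_score: single rater; sd reported as 0.")
    0
  } else sd(per$pct_correct)
  structure(list(per_rater = per, mean_pct = mean(per$pct_correct),
                 sd_pct = sd_pct), class = "turing_score")
}

#' @export
print.turing_score <- function(x, ...) {
  cat(sprintf("Turing test: %.2f%% +/- %.2f correct across %d raters\n",
              x$mean_pct, x$sd_pct, nrow(x$per_rater)))
  invisible(x)
}

#' @rdname turing_score
#' @param x A \code{turing_score} object.
#' @param ... Unused.
#' @export
glance.turing_score <- function(x, ...) {
  tibble(mean_pct = x$mean_pct, sd_pct = x$sd_pct, n_raters = nrow(x$per_rater))
}

#' Build a blinded Turing-test presentation manifest
#'
#' Samples n/2 real and n/2 synthetic slice paths, shuffles their
#' presentation order (seeded), and returns the blinded manifest together
#' with a separate answer key.
#'
#' @param real_paths,synth_paths Character vectors of candidate slice paths.
#' @param n Total presentations (even); 1:1 real:synthetic.
#' @param seed Integer seed for sampling and shuffling.
#' @return A list with \code{manifest} (tibble: \code{position},
#'   \code{path}) and \code{key} (tibble: \code{position}, \code{truth}).
#' @export
make_turing_manifest <- function(real_paths, synth_paths, n = 100L, seed = 1L) {
  if (n %% 2L != 0L) abort("`n` must be even for a 1:1 ratio.")
  half <- n %/% 2L
  if (length(real_paths) < half || length(synth_paths) < half)
    abort("not enough images in one of the pools for a 1:1 manifest.")
  with_seed(seed, {
    r <- sample(real_paths, half)
    s <- sample(synth_paths, half)
    ord <- sample(n)
    paths <- c(r, s)[ord]
    truth <- c(rep("real", half), rep("synthetic", half))[ord]
    list(manifest = tibble(position = seq_len(n), path = paths),
         key = tibble(position = seq_len(n), truth = truth))
  })
}

#' Score rater responses against a Turing answer key
#'
#' @param responses Tibble with \code{position} and \code{truth} columns
#'   (the rater's calls, "real"/"synthetic").
#' @param key The answer key from [make_turing_manifest()].
#' @return Number of correct calls.
#' @export
score_turing_responses <- function(responses, key) {
  j <- merge(as.data.frame(responses), as.data.frame(key),
             by = "position", suffixes = c("_resp", "_key"))
  sum(j$truth_resp == j$truth_key)
}
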