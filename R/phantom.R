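# Synthetic abdominal phantom: stylized anatomy (ellipse body/liver, tube
# vessels, disc tumors with enhancing rims) rendered in three MR modalities
# with a known deterministic contrast-enhancement rule.

PHANTOM_CLASSES <- c(background = 0L, body = 1L, liver = 2L, vessel = 3L,
                     tumor_core = 4L, tumor_rim = 5L)

# class intensity tables on [0,255]: columns follow PHANTOM_CLASSES order.
# Chosen so every class has a distinct (T1pre, T2) pair (min pairwise
# distance ~36 intensity units), which makes the enhancement rule exactly
# invertible from the two inputs in noise-free mode.
default_class_means <- function() {
  rbind(
    t1pre = c(20, 80, 120, 100, 70, 90),
    t2    = c(15, 70, 60, 180, 160, 120)
  )
}

#' Phantom generation parameters
#'
#' Parameters of the seeded synthetic abdominal-phantom generator. The phantom
#' emulates the statistical structure a multi-modal contrast-synthesis model
#' exploits — complementary class contrast between T1pre and T2, enhancing
#' vessel/tumor-rim structures, sharp edges, inter-study heterogeneity —
#' not MR physics.
#'
#' @param image_size Side length in pixels; must be divisible by 4.
#' @param class_intensity_means 2 x 6 matrix of per-modality class means on
#'   \code{[0,255]} (rows \code{t1pre}, \code{t2}; columns background, body,
#'   liver, vessel, tumor_core, tumor_rim). The noise-free T1ce equals T1pre
#'   plus \code{enhancement_gain} on vessel and tumor-rim pixels.
#' @param enhancement_gain Additive T1ce intensity boost on vessel and
#'   tumor-rim pixels; must be positive.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity units).
#' @param misreg_magnitude Maximum smooth-displacement magnitude in pixels
#'   applied to the T2 input (emulating breathing-motion mis-registration);
#'   0 disables it.
#' @param n_tumors Number of tumor discs per study.
#' @param jitter_sd Per-study perturbation of the class means (clamped to
#'   \eqn{\pm 8} so classes stay separable), emulating inter-patient
#'   heterogeneity.
#' @param fov_mm Physical field of view in mm; sets the recorded pixel spacing.
#' @param seed Integer seed; all phantom outputs are pure functions of
#'   (parameters, seed).
#' @return A list of class \code{phantom_params}.
#' @export
phantom_params <- function(image_size = 64L,
                           class_intensity_means = default_class_means(),
                           enhancement_gain = 80,
                           noise_sd = 0,
                           misreg_magnitude = 0,
                           n_tumors = 2L,
                           jitter_sd = 3,
                           fov_mm = 320,
                           seed = 1L) {
  if (image_size %% 4L != 0L)
    abort("`image_size` must be divisible by 4 (scale-pyramid requirement).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (enhancement_gain < 0) abort("`enhancement_gain` must be >= 0.")
  if (misreg_magnitude < 0) abort("`misreg_magnitude` must be >= 0.")
  stopifnot(is.matrix(class_intensity_means),
            nrow(class_intensity_means) == 2L,
            ncol(class_intensity_means) == 6L)
  structure(list(image_size = as.integer(image_size),
                 class_intensity_means = class_intensity_means,
                 enhancement_gain = enhancement_gain,
                 noise_sd = noise_sd,
                 misreg_magnitude = misreg_magnitude,
                 n_tumors = as.integer(n_tumors),
                 jitter_sd = jitter_sd,
                 fov_mm = fov_mm,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

disc_mask <- function(n, cy, cx, ry, rx = ry) {
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1
}

#' Generate a tissue label map
#'
#' Draws the stylized anatomy for one study: an elliptical body, a liver
#' ellipse inside it, tube-like vessels inside the liver, and \code{n_tumors}
#' non-touching tumor discs each surrounded by a one-to-two-pixel enhancing
#' rim. Deterministic given \code{params$seed}.
#'
#' @param params A [phantom_params()] object.
#' @return A list of class \code{tissue_map} with integer matrix
#'   \code{labels} (values 0..5: background, body, liver, vessel,
#'   tumor_core, tumor_rim) and \code{spacing} in mm per pixel.
#' @export
make_tissue_map <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  n <- params$image_size
  with_seed(params$seed, {
    labels <- matrix(PHANTOM_CLASSES[["background"]], n, n)

    body <- disc_mask(n, n / 2 + runif(1, -1, 1) * n / 32,
                      n / 2 + runif(1, -1, 1) * n / 32,
                      ry = n * runif(1, 0.42, 0.46), rx = n * runif(1, 0.44, 0.47))
    labels[body] <- PHANTOM_CLASSES[["body"]]

    lcy <- n * runif(1, 0.42, 0.48)
    lcx <- n * runif(1, 0.36, 0.42)
    lry <- n * runif(1, 0.24, 0.28)
    lrx <- n * runif(1, 0.26, 0.30)
    liver <- disc_mask(n, lcy, lcx, lry, lrx) & body
    labels[liver] <- PHANTOM_CLASSES[["liver"]]

    # vessels: two smooth tubes through the liver
    vw <- max(1L, round(n / 48))
    rgrid <- matrix(seq_len(n), n, n); cgrid <- t(rgrid)
    for (v in 1:2) {
      t0 <- runif(1, 0, pi)
      amp <- n * runif(1, 0.02, 0.05)
      off <- runif(1, -0.4, 0.4) * lry
      # curve row = f(col): a gentle sinusoid through the liver center
      crow <- lcy + off + amp * sin(2 * pi * (cgrid - lcx) / n + t0)
      tube <- abs(rgrid - crow) <= vw
      labels[tube & liver] <- PHANTOM_CLASSES[["vessel"]]
    }

    # tumors: non-touching discs fully inside the liver
    if (params$n_tumors > 0L) {
      rimw <- max(1L, round(n / 64))
      centers <- matrix(numeric(0), 0, 2)
      radii <- numeric(0)
      tries <- 0L
      while (nrow(centers) < params$n_tumors && tries < 2000L) {
        tries <- tries + 1L
        # radii shrink slowly under repeated failure so placement terminates
        rad <- runif(1, n / 28, n / 16) * 0.97^(tries %/% 50L)
        th <- runif(1, 0, 2 * pi)
        u <- sqrt(runif(1))
        cy <- lcy + u * (lry - rad - rimw - 2) * sin(th)
        cx <- lcx + u * (lrx - rad - rimw - 2) * cos(th)
        # inside-liver check at the disc's bounding extremes
        ok <- ((cy - lcy) / (lry - rad - rimw - 1))^2 +
              ((cx - lcx) / (lrx - rad - rimw - 1))^2 <= 1
        if (ok && nrow(centers) > 0) {
          dmin <- min(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) -
                        (radii + rad))
          ok <- dmin > 2 * rimw + 2
        }
        if (ok) {
          centers <- rbind(centers, c(cy, cx))
          radii <- c(radii, rad)
        }
      }
      if (nrow(centers) < params$n_tumors)
        warn("phantom: could not place all tumors without contact; placed fewer.")
      for (i in seq_len(nrow(centers))) {
        core <- disc_mask(n, centers[i, 1], centers[i, 2], radii[i])
        rim <- disc_mask(n, centers[i, 1], centers[i, 2], radii[i] + rimw) & !core
        labels[rim] <- PHANTOM_CLASSES[["tumor_rim"]]
        labels[core] <- PHANTOM_CLASSES[["tumor_core"]]
      }
    }
    structure(list(labels = labels, spacing = rep(params$fov_mm / n, 2)),
              class = "tissue_map")
  })
}

#' Render a study triplet from a tissue map
#'
#' Produces the three modality images on \code{[0,255]}. In noise-free mode
#' the contrast-enhanced image satisfies exactly
#' \code{T1ce = T1pre + enhancement_gain} on vessel and tumor-rim pixels and
#' \code{T1ce = T1pre} elsewhere, so the synthesis target is a deterministic
#' function of the inputs. Gaussian noise (sd \code{noise_sd}) is added
#' independently per modality; intensities are clamped to \code{[0,255]}.
#'
#' @param map A [make_tissue_map()] result.
#' @param params A [phantom_params()] object (its \code{seed} drives the noise).
#' @param class_means Optional 2 x 6 override of the class-mean table (used
#'   for per-study jitter); defaults to \code{params$class_intensity_means}.
#' @param study_id Identifier stored in the returned triplet.
#' @return A list of class \code{study_triplet} with \code{mr_slice} fields
#'   \code{t1pre}, \code{t2}, \code{t1ce} and the \code{study_id}.
#' @export
render_study <- function(map, params, class_means = NULL, study_id = "study001") {
  stopifnot(inherits(map, "tissue_map"), inherits(params, "phantom_params"))
  cm <- class_means %||% params$class_intensity_means
  lab1 <- map$labels + 1L
  n <- nrow(map$labels)
  if (n != params$image_size)
    abort("tissue map and params disagree on image size.")
  t1pre <- matrix(cm["t1pre", lab1], n, n)
  t2 <- matrix(cm["t2", lab1], n, n)
  enh <- map$labels == PHANTOM_CLASSES[["vessel"]] |
         map$labels == PHANTOM_CLASSES[["tumor_rim"]]
  t1ce <- t1pre + params$enhancement_gain * enh
  if (params$noise_sd > 0) {
    with_seed(params$seed + 1L, {
      t1pre <- t1pre + rnorm(n * n, sd = params$noise_sd)
      t2 <- t2 + rnorm(n * n, sd = params$noise_sd)
      t1ce <- t1ce + rnorm(n * n, sd = params$noise_sd)
    })
    t1pre <- pmin(pmax(t1pre, 0), 255)
    t2 <- pmin(pmax(t2, 0), 255)
    t1ce <- pmin(pmax(t1ce, 0), 255)
  }
  sp <- map$spacing
  structure(list(
    t1pre = mr_slice(t1pre, "T1pre", sp),
    t2 = mr_slice(t2, "T2", sp),
    t1ce = mr_slice(t1ce, "T1ce", sp),
    study_id = study_id
  ), class = "study_triplet")
}

bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(as.vector(r), 1), H)
  c <- pmin(pmax(as.vector(c), 1), W)
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

#' Apply a smooth random mis-registration to one image
#'
#' Emulates breathing-motion mismatch between sequences: a smooth random
#' displacement field (bilinear upsampling of a coarse 4 x 4 field) with
#' maximum displacement magnitude at most \code{magnitude} pixels is applied
#' by backward warping with bilinear interpolation. Intended for an input
#' modality only, never for the target used as metric ground truth.
#'
#' @param image Numeric matrix.
#' @param magnitude Maximum displacement in pixels (>= 0); 0 returns the
#'   image unchanged.
#' @param seed Integer seed making the field deterministic.
#' @return A numeric matrix of the same size.
#' @export
misregister <- function(image, magnitude, seed = 1L) {
  if (magnitude < 0) abort("`magnitude` must be >= 0.")
  if (magnitude == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  with_seed(seed, {
    ur <- matrix(runif(16, -1, 1), 4, 4)
    uc <- matrix(runif(16, -1, 1), 4, 4)
    gr <- matrix(seq(1, 4, length.out = H), H, W)
    gc <- t(matrix(seq(1, 4, length.out = W), W, H))
    fr <- matrix(bilinear_sample(ur, gr, gc), H, W)
    fc <- matrix(bilinear_sample(uc, gr, gc), H, W)
    mag <- sqrt(fr^2 + fc^2)
    scl <- magnitude / max(mag, 1e-12)
    fr <- fr * scl; fc <- fc * scl
    rg <- matrix(seq_len(H), H, W); cg <- t(matrix(seq_len(W), W, H))
    matrix(bilinear_sample(image, rg + fr, cg + fc), H, W)
  })
}

#' Write a synthetic multi-study phantom dataset to disk
#'
#' Generates \code{n_train + n_val + n_test} studies, each with its own
#' anatomy and a per-study jitter of the class-mean table (clamped to
#' \eqn{\pm 8} intensity units so the classes stay separable), writes one
#' 8-bit PNG per modality, and returns the manifest. Splits are disjoint by
#' study. If \code{params$misreg_magnitude > 0} the stored T2 image is warped
#' by [misregister()]; the T1pre/T1ce pairing used as ground truth is never
#' warped.
#'
#' @param n_train,n_val,n_test Split sizes (counts of studies).
#' @param params A [phantom_params()] object.
#' @param dir Output directory (created if missing).
#' @return A tibble manifest with columns \code{study_id}, \code{split},
#'   \code{t1pre_path}, \code{t2_path}, \code{t1ce_path}, \code{spacing_mm};
#'   also written to \code{file.path(dir, "manifest.csv")}.
#' @export
make_dataset <- function(n_train, n_val, n_test, params, dir) {
  stopifnot(n_train >= 0, n_val >= 0, n_test >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  splits <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  total <- length(splits)
  rows <- vector("list", total)
  for (i in seq_len(total)) {
    sid <- sprintf("study%03d", i)
    pi_ <- params
    pi_$seed <- params$seed + 1000L * i
    cm <- with_seed(pi_$seed + 7L, {
      j <- matrix(rnorm(12, sd = params$jitter_sd), 2, 6)
      params$class_intensity_means + pmin(pmax(j, -8), 8)
    })
    map <- make_tissue_map(pi_)
    st <- render_study(map, pi_, class_means = cm, study_id = sid)
    t2img <- st$t2$intensities
    if (params$misreg_magnitude > 0)
      t2img <- misregister(t2img, params$misreg_magnitude, seed = pi_$seed + 13L)
    paths <- file.path(dir, paste0(sid, "_", c("t1pre", "t2", "t1ce"), ".png"))
    write_png_255(st$t1pre$intensities, paths[1])
    write_png_255(t2img, paths[2])
    write_png_255(st$t1ce$intensities, paths[3])
    rows[[i]] <- tibble(study_id = sid, split = splits[i],
                        t1pre_path = basename(paths[1]),
                        t2_path = basename(paths[2]),
                        t1ce_path = basename(paths[3]),
                        spacing_mm = map$spacing[1])
  }
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Latent-class lookup oracle for the phantom enhancement rule
#'
#' Classifies each pixel to the nearest canonical class centroid in
#' (T1pre, T2) intensity space and predicts
#' \code{T1ce = T1pre + enhancement_gain} on enhancing classes (vessel,
#' tumor rim), \code{T1ce = T1pre} otherwise. On noise-free phantoms this
#' achieves MSE 0, certifying that the synthesis task is a well-posed
#' deterministic regression with a known floor.
#'
#' @param t1pre,t2 Numeric matrices on the stored \code{[0,255]} scale.
#' @param params The [phantom_params()] the data were generated with.
#' @return Predicted T1ce matrix.
#' @export
enhancement_oracle <- function(t1pre, t2, params) {
  cm <- params$class_intensity_means
  pix <- cbind(as.vector(t1pre), as.vector(t2))
  d2 <- outer(pix[, 1], cm["t1pre", ], "-")^2 + outer(pix[, 2], cm["t2", ], "-")^2
  cls <- max.col(-d2)
  enh <- cls %in% c(4L, 6L)  # vessel, tumor_rim columns
  matrix(as.vector(t1pre) + params$enhancement_gain * enh,
         nrow(t1pre), ncol(t1pre))
}
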