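# Adversarial training orchestration: alternating D/G Adam updates, the
# lambda1 and learning-rate schedules, ablation modes, validation tracking,
# and inference over a manifest split.

#' Training configuration
#'
#' Defaults follow the full-scale recipe (150 epochs, Adam with batch 16,
#' lambda2 = 100, lambda1 and learning rate on their schedules, 256-pixel
#' slices). [smoke_config()] provides the reduced configuration used in
#' tests and examples.
#'
#' @param epochs Number of epochs (1..150; the schedules are defined on
#'   that range).
#' @param batch_size Minibatch size.
#' @param beta1,beta2 Adam moment decay rates ((0.5, 0.999), the standard
#'   image-to-image translation setting).
#' @param lambda2 L1 weight (100).
#' @param lambda_sparsity Attention soft-threshold level.
#' @param n_levels,base_channels Generator architecture (see
#'   [generator_config()]).
#' @param d_channels First-stage channels of each discriminator.
#' @param ablation \code{"full"} (all three discriminators, blur negatives,
#'   gradient regularization), \code{"no_mmd"} (single-scale discriminator +
#'   GR + L1) or \code{"no_gr_no_mmd"} (single-scale + L1 only).
#' @param image_size Slice side length; must be divisible by
#'   \code{2^n_levels}.
#' @param blur_sigma,blur_kernel Gaussian blur of the over-smoothed
#'   negatives.
#' @param saturating Use the saturating generator adversarial form.
#' @param seed Integer seed; initialization and shuffling derive from it.
#' @return A list of class \code{train_config}.
#' @export
train_config <- function(epochs = 150L, batch_size = 16L,
                         beta1 = 0.5, beta2 = 0.999,
                         lambda2 = 100, lambda_sparsity = 0.05,
                         n_levels = 4L, base_channels = 32L,
                         d_channels = 64L,
                         ablation = c("full", "no_mmd", "no_gr_no_mmd"),
                         image_size = 256L,
                         blur_sigma = 1.0, blur_kernel = 5L,
                         saturating = FALSE, seed = 1L) {
  ablation <- match.arg(ablation)
  if (epochs < 1L || epochs > 150L) abort("`epochs` must be in 1..150.")
  if (batch_size < 1L) abort("`batch_size` must be >= 1.")
  if (image_size %% 2L^n_levels != 0L)
    abort("`image_size` must be divisible by 2^n_levels.")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, lambda2 = lambda2,
                 lambda_sparsity = lambda_sparsity,
                 n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 d_channels = as.integer(d_channels),
                 ablation = ablation, image_size = as.integer(image_size),
                 blur_sigma = blur_sigma, blur_kernel = as.integer(blur_kernel),
                 saturating = saturating, seed = as.integer(seed)),
            class = "train_config")
}

#' Reduced training configuration for smoke-scale runs
#'
#' 64-pixel slices, 3 encoder levels, 8 base channels, 5 epochs, batch size
#' 1 (the classic conditional-GAN setting, maximizing the update count when
#' only a handful of training studies are available): small enough for
#' minutes-scale CPU training while exercising every component.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A \code{train_config}.
#' @export
smoke_config <- function(...) {
  args <- list(epochs = 5L, batch_size = 1L, n_levels = 3L,
               base_channels = 8L, d_channels = 8L, image_size = 64L)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

clamp01 <- function(s, eps = 1e-7) pmin(pmax(s, eps), 1 - eps)

# read one split of a manifest into batched model-scale arrays
split_arrays <- function(manifest, split, image_size) {
  rows <- manifest[manifest$split == split, ]
  n <- nrow(rows)
  if (n == 0) return(NULL)
  x1 <- x2 <- y <- array(0, c(image_size, image_size, 1L, n))
  for (i in seq_len(n)) {
    st <- load_study(manifest, rows$study_id[[i]])
    get <- function(sl) {
      if (nrow(sl$intensities) != image_size)
        sl <- resample_to(sl, image_size)
      sl$intensities / 127.5 - 1
    }
    x1[, , 1L, i] <- get(st$t1pre)
    x2[, , 1L, i] <- get(st$t2)
    y[, , 1L, i] <- get(st$t1ce)
  }
  list(x1 = x1, x2 = x2, y = y, ids = rows$study_id)
}

val_metrics <- function(gpar, gcfg, val) {
  out <- gen_forward(gpar, val$x1, val$x2, gcfg, keep_cache = FALSE)$out
  n <- dim(out)[4L]
  ms <- ps <- ss <- numeric(n)
  for (i in seq_len(n)) {
    yh <- to_metric_scale(matrix(out[, , 1L, i], dim(out)[1L], dim(out)[2L]))
    yt <- to_metric_scale(matrix(val$y[, , 1L, i], dim(out)[1L], dim(out)[2L]))
    ms[i] <- mse(yt, yh)
    ps[i] <- psnr(yt, yh)
    ss[i] <- ssim_global(yt, yh)
  }
  c(val_mse = mean(ms), val_psnr = mean(ps), val_ssim = mean(ss))
}

#' Train the synthesis GAN
#'
#' Alternating discriminator/generator Adam updates with the scheduled
#' lambda1 and learning rate. All three discriminators are initialized in
#' every ablation mode (so RNG streams — and hence generator initialization
#' and batch order — are identical across ablation arms), but only the
#' active ones are evaluated and updated. Validation MSE/PSNR/SSIM are
#' computed after every epoch; the parameters with the best validation MSE
#' are kept alongside the final ones.
#'
#' @param manifest A [load_manifest()] tibble (or the return of
#'   [make_dataset()] re-loaded) with nonempty train and val splits.
#' @param config A [train_config()].
#' @return A \code{cesynth_fit}: generator parameters (best and final),
#'   discriminators, configs, and a per-epoch \code{history} tibble
#'   (epoch 0 is the untrained network).
#' @export
train <- function(manifest, config = smoke_config()) {
  stopifnot(inherits(config, "train_config"))
  trn <- split_arrays(manifest, "train", config$image_size)
  val <- split_arrays(manifest, "val", config$image_size)
  if (is.null(trn) || is.null(val))
    abort("manifest must contain nonempty train and val splits.")
  n_train <- dim(trn$x1)[4L]

  gcfg <- generator_config(config$n_levels, config$base_channels,
                           config$lambda_sparsity)
  dcfg <- disc_bank_config(blur_sigma = config$blur_sigma,
                           blur_kernel = config$blur_kernel,
                           base_channels = config$d_channels)
  set.seed(config$seed)
  gpar <- init_generator(gcfg)
  bank <- lapply(1:3, function(k) init_discriminator(config$d_channels))

  opt_g <- adam_new(unclass(gpar))
  opt_d <- lapply(bank, adam_new)

  active <- if (config$ablation == "full") 1:3 else 1L
  use_blur <- config$ablation == "full"
  use_gr <- config$ablation != "no_gr_no_mmd"
  wneg <- if (use_blur) 0.5 else 1.0

  history <- list()
  history[[1]] <- tibble(epoch = 0L, lambda1 = 0, lr = 0,
                         l_cgan_1 = NA_real_, l_cgan_2 = NA_real_,
                         l_cgan_3 = NA_real_, l_l1 = NA_real_, l_gr = NA_real_,
                         total_g = NA_real_, total_d = NA_real_,
                         !!!as.list(val_metrics(gpar, gcfg, val)))
  best <- list(params = gpar, val_mse = history[[1]]$val_mse, epoch = 0L)
  last_finite <- gpar
  diverged <- FALSE

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(epoch)
    lam1 <- if (use_gr) lambda1_at(epoch) else 0
    ord <- sample(n_train)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep <- c(g1 = 0, g2 = 0, g3 = 0, d = 0, l1 = 0, gr = 0, tg = 0, nb = 0)
    for (idx in batches) {
      x1 <- trn$x1[, , , idx, drop = FALSE]
      x2 <- trn$x2[, , , idx, drop = FALSE]
      y <- trn$y[, , , idx, drop = FALSE]
      nb <- length(idx)

      gfw <- gen_forward(gpar, x1, x2, gcfg)
      yh <- gfw$out

      p1 <- build_pyramid4(x1); p2 <- build_pyramid4(x2)
      py <- build_pyramid4(y); ph <- build_pyramid4(yh)

      # ---- discriminator updates -------------------------------------
      d_losses <- numeric(3)
      for (k in active) {
        cond <- concat_c(p1[[k]], p2[[k]])
        fr <- disc_forward(bank[[k]], concat_c(cond, py[[k]]))
        ff <- disc_forward(bank[[k]], concat_c(cond, ph[[k]]))
        sr <- clamp01(fr$score); sf <- clamp01(ff$score)
        dsr <- -1 / (length(sr) * sr)
        dsf <- wneg / (length(sf) * (1 - sf))
        gr_r <- disc_backward(bank[[k]], fr$cache, dsr)$grads
        gr_f <- disc_backward(bank[[k]], ff$cache, dsf)$grads
        grads <- tree_map2(`+`, gr_r, gr_f)
        dl <- -(mean(log(sr)) + wneg * mean(log(1 - sf)))
        if (use_blur) {
          bh <- gaussian_blur4(ph[[k]], config$blur_sigma, config$blur_kernel)
          fb <- disc_forward(bank[[k]], concat_c(cond, bh))
          sb <- clamp01(fb$score)
          dsb <- wneg / (length(sb) * (1 - sb))
          grads <- tree_map2(`+`, grads, disc_backward(bank[[k]], fb$cache, dsb)$grads)
          dl <- dl - wneg * mean(log(1 - sb))
        }
        up <- adam_update(bank[[k]], grads, opt_d[[k]], lr,
                          config$beta1, config$beta2)
        bank[[k]] <- up$params
        opt_d[[k]] <- up$state
        counter_bump("d_updates")
        d_losses[k] <- dl
      }

      # ---- generator update ------------------------------------------
      dyh <- array(0, dim(yh))
      g_losses <- numeric(3)
      for (k in active) {
        cond <- concat_c(p1[[k]], p2[[k]])
        ff <- disc_forward(bank[[k]], concat_c(cond, ph[[k]]))
        sf <- clamp01(ff$score)
        if (config$saturating) {
          g_losses[k] <- mean(log(1 - sf))
          dsf <- -1 / (length(sf) * (1 - sf))
        } else {
          g_losses[k] <- -mean(log(sf))
          dsf <- -1 / (length(sf) * sf)
        }
        dxk <- disc_backward(bank[[k]], ff$cache, dsf, need_dx = TRUE)$dx
        dyk <- dxk[, , 3L, , drop = FALSE]
        for (j in seq_len(k - 1L)) dyk <- down2_bwd(dyk)
        dyh <- dyh + dyk
      }
      l1v <- l1_loss(yh, y)
      dyh <- dyh + config$lambda2 * sign(yh - y) / length(yh)
      grv <- 0
      if (use_gr && lam1 > 0) {
        for (i in seq_len(nb)) {
          d <- dim(yh)
          sm <- matrix(yh[, , 1L, i], d[1L], d[2L])
          rm <- matrix(y[, , 1L, i], d[1L], d[2L])
          grv <- grv + gr_loss(sm, rm) / nb
          dyh[, , 1L, i] <- dyh[, , 1L, i] + lam1 * gr_grad(sm, rm) / nb
        }
      }
      ggrads <- gen_backward(gpar, gcfg, gfw$cache, dyh)
      up <- adam_update(unclass(gpar), ggrads, opt_g, lr,
                        config$beta1, config$beta2)
      gpar <- structure(up$params, class = "generator_params")
      opt_g <- up$state

      rep_ <- total_objective(g_losses[active], d_losses[active], l1v, grv,
                              loss_weights(lam1, config$lambda2),
                              ablation = config$ablation)
      if (!all(is.finite(c(rep_$total_g, rep_$total_d))) || !tree_finite(gpar)) {
        warn(sprintf("training diverged at epoch %d; returning last finite parameters.",
                     epoch))
        gpar <- last_finite
        diverged <- TRUE
        break
      }
      last_finite <- gpar
      ep <- ep + c(g_losses, rep_$total_d, l1v, grv, rep_$total_g, 1)
    }
    if (diverged) break
    nb_ <- ep[["nb"]]
    vm <- val_metrics(gpar, gcfg, val)
    history[[epoch + 1L]] <- tibble(
      epoch = epoch, lambda1 = lam1, lr = lr,
      l_cgan_1 = ep[["g1"]] / nb_, l_cgan_2 = ep[["g2"]] / nb_,
      l_cgan_3 = ep[["g3"]] / nb_, l_l1 = ep[["l1"]] / nb_,
      l_gr = ep[["gr"]] / nb_, total_g = ep[["tg"]] / nb_,
      total_d = ep[["d"]] / nb_, !!!as.list(vm))
    if (vm[["val_mse"]] < best$val_mse) {
      best <- list(params = gpar, val_mse = vm[["val_mse"]], epoch = epoch)
    }
  }

  structure(list(generator = best$params, generator_final = gpar,
                 discriminators = bank, config = config, gen_config = gcfg,
                 disc_config = dcfg, history = bind_rows(history),
                 best_epoch = best$epoch, diverged = diverged),
            class = "cesynth_fit")
}

#' @export
print.cesynth_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<cesynth_fit  %s  %d epochs  best val MSE %.2f (epoch %d)>\n",
              x$config$ablation, max(h$epoch), min(h$val_mse), x$best_epoch))
  invisible(x)
}

#' @rdname train
#' @param x A \code{cesynth_fit}.
#' @param ... Unused.
#' @export
tidy.cesynth_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -epoch, names_to = "term", values_to = "value")
}

#' @rdname train
#' @export
glance.cesynth_fit <- function(x, ...) {
  h <- x$history
  fin <- h[h$epoch == max(h$epoch), ]
  tibble(epochs = max(h$epoch), best_epoch = x$best_epoch,
         best_val_mse = min(h$val_mse), final_val_mse = fin$val_mse,
         final_val_psnr = fin$val_psnr, final_val_ssim = fin$val_ssim,
         ablation = x$config$ablation, diverged = x$diverged)
}

#' Predict a synthetic T1ce slice from a fit
#'
#' @param object A \code{cesynth_fit}.
#' @param t1pre,t2 Matrices on the stored \code{[0,255]} scale.
#' @param which \code{"best"} (best-validation checkpoint) or \code{"final"}.
#' @param ... Unused.
#' @return Synthetic T1ce matrix on the metric \code{[0,255]} scale.
#' @export
predict.cesynth_fit <- function(object, t1pre, t2, which = c("best", "final"), ...) {
  which <- match.arg(which)
  par <- if (which == "best") object$generator else object$generator_final
  out <- synthesize(t1pre / 127.5 - 1, t2 / 127.5 - 1, par, object$gen_config)
  to_metric_scale(out)
}

#' Synthesize and evaluate a manifest split
#'
#' Runs the generator over every study in a split and computes MSE, PSNR and
#' global SSIM against the ground-truth T1ce on the metric_255 scale.
#'
#' @param fit A \code{cesynth_fit}.
#' @param manifest A [load_manifest()] tibble.
#' @param split Which split to evaluate.
#' @param out_dir Optional directory for the synthetic PNG outputs.
#' @param bypass_truth Sanity path: score the ground truth against itself
#'   (yields MSE 0, SSIM 1).
#' @return A tibble with one row per study: \code{study_id}, \code{mse},
#'   \code{psnr}, \code{ssim}.
#' @export
synthesize_split <- function(fit, manifest, split = "test", out_dir = NULL,
                             bypass_truth = FALSE) {
  rows <- manifest[manifest$split == split, ]
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    sid <- rows$study_id[[i]]
    st <- tryCatch(load_study(manifest, sid), error = function(e) {
      warn(sprintf("skipping study %s: %s", sid, conditionMessage(e)))
      NULL
    })
    if (is.null(st)) next
    fix <- function(sl) if (nrow(sl$intensities) != fit$config$image_size)
      resample_to(sl, fit$config$image_size) else sl
    st$t1pre <- fix(st$t1pre); st$t2 <- fix(st$t2); st$t1ce <- fix(st$t1ce)
    yt <- st$t1ce$intensities
    yh <- if (bypass_truth) yt else predict(fit, st$t1pre$intensities, st$t2$intensities)
    if (!is.null(out_dir))
      write_png_255(yh, file.path(out_dir, paste0(sid, "_synth.png")))
    res[[i]] <- tibble(study_id = sid, mse = mse(yt, yh), psnr = psnr(yt, yh),
                       ssim = ssim_global(yt, yh))
  }
  bind_rows(res)
}

#' Mean and sd summary of a per-study metric report
#'
#' @param report The tibble returned by [synthesize_split()].
#' @return A tibble with one row per metric: mean and sd across studies.
#' @export
summarise_metrics <- function(report) {
  long <- tidyr::pivot_longer(report, -study_id,
                              names_to = "metric", values_to = "value")
  dplyr::summarise(dplyr::group_by(long, .data$metric),
                   mean = mean(.data$value), sd = sd(.data$value),
                   .groups = "drop")
}

#' Save / load a training checkpoint
#'
#' Checkpoints carry parameters, configs, seed and history.
#'
#' @param fit A \code{cesynth_fit}.
#' @param path Destination file.
#' @return \code{path} (save) or the restored fit (load).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
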