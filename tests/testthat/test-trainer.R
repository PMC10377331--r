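# fast trainer checks run on a very small phantom set; the fuller
# 20-study smoke comparison lives in test-acceptance.R

tiny_cfg <- function(...) {
  smoke_config(image_size = 32, epochs = 1, batch_size = 2, ...)
}

tiny_fixture <- function() phantom_fixture(n_train = 4, n_val = 2, n_test = 2,
                                           image_size = 32, seed = 2)

test_that("training is bitwise reproducible under a fixed seed", {
  fix <- tiny_fixture()
  f1 <- train(fix$manifest, tiny_cfg(seed = 5))
  f2 <- train(fix$manifest, tiny_cfg(seed = 5))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generator, f2$generator)
})

test_that("the schedules wired into training equal lambda1_at and lr_at", {
  fix <- tiny_fixture()
  f <- train(fix$manifest, tiny_cfg(seed = 3, epochs = 2))
  h <- f$history[f$history$epoch > 0, ]
  expect_equal(h$lambda1, lambda1_at(h$epoch))
  expect_equal(h$lr, lr_at(h$epoch))
  # epoch 0 row records the untrained network's validation metrics
  expect_equal(f$history$epoch[1], 0L)
  expect_true(is.finite(f$history$val_mse[1]))
})

test_that("ablations update one discriminator and skip the Sobel operator as specified", {
  fix <- tiny_fixture()
  steps <- 2  # 4 train studies / batch 2

  cesynth:::counters_reset()
  fa <- train(fix$manifest, tiny_cfg(seed = 1, ablation = "no_gr_no_mmd"))
  cnt <- cesynth:::counters_get()
  expect_equal(cnt$d_updates, steps)     # one discriminator's worth per step
  expect_equal(cnt$sobel, 0L)            # Sobel never evaluated

  cesynth:::counters_reset()
  fm <- train(fix$manifest, tiny_cfg(seed = 1, ablation = "no_mmd"))
  cnt <- cesynth:::counters_get()
  expect_equal(cnt$d_updates, steps)
  expect_gt(cnt$sobel, 0)                # GR active

  cesynth:::counters_reset()
  ff <- train(fix$manifest, tiny_cfg(seed = 1, ablation = "full"))
  cnt <- cesynth:::counters_get()
  expect_equal(cnt$d_updates, 3L * steps)

  # identical seeds give identical initialization across ablation arms
  expect_equal(fa$history$val_mse[1], ff$history$val_mse[1])
})

test_that("synthesize_split reports per-study metrics and the bypass sanity path", {
  fix <- tiny_fixture()
  f <- train(fix$manifest, tiny_cfg(seed = 4))
  rep1 <- synthesize_split(f, fix$manifest, "val")
  expect_equal(nrow(rep1), 2)
  expect_true(all(c("study_id", "mse", "psnr", "ssim") %in% names(rep1)))
  rep2 <- synthesize_split(f, fix$manifest, "val")
  expect_identical(rep1, rep2)  # inference determinism

  one <- fix$manifest[fix$manifest$split == "test", ][1, ]
  rep_one <- synthesize_split(f, one, "test")
  expect_equal(nrow(rep_one), 1)

  byp <- synthesize_split(f, fix$manifest, "test", bypass_truth = TRUE)
  expect_true(all(byp$mse == 0))
  expect_true(all(byp$ssim == 1))
  expect_true(all(byp$psnr == Inf))

  sm <- summarise_metrics(rep1)
  expect_equal(sort(sm$metric), c("mse", "psnr", "ssim"))
})

test_that("fits expose tidy, glance, prediction and checkpoint round-trips", {
  fix <- tiny_fixture()
  f <- train(fix$manifest, tiny_cfg(seed = 6))
  td <- tidy(f)
  expect_true(all(c("epoch", "term", "value") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$epochs, 1)
  expect_false(gl$diverged)

  st <- load_study(fix$manifest, fix$manifest$study_id[1])
  pr <- predict(f, st$t1pre$intensities, st$t2$intensities)
  expect_identical(dim(pr), dim(st$t1pre$intensities))
  expect_true(all(pr >= 0 & pr <= 255))

  cp <- tempfile(fileext = ".rds")
  save_checkpoint(f, cp)
  f2 <- load_checkpoint(cp)
  expect_identical(f2$generator, f$generator)
  pr2 <- predict(f2, st$t1pre$intensities, st$t2$intensities)
  expect_identical(pr, pr2)
})

test_that("training configuration contracts are enforced", {
  expect_error(train_config(epochs = 0), "1..150")
  expect_error(train_config(image_size = 100, n_levels = 3), "divisible")
  expect_error(train_config(ablation = "bogus"))
  cfg <- smoke_config(epochs = 2)
  expect_equal(cfg$epochs, 2L)
  expect_equal(cfg$image_size, 64L)
})
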