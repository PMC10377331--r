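test_that("tissue maps are deterministic under a fixed seed and honour class structure", {
  p <- phantom_params(image_size = 64, n_tumors = 2, seed = 7)
  m1 <- make_tissue_map(p)
  m2 <- make_tissue_map(p)
  expect_identical(m1, m2)
  expect_true(all(m1$labels %in% 0:5))
  expect_gt(sum(m1$labels == 2), 0)  # liver present
  expect_gt(sum(m1$labels == 3), 0)  # vessels present
  # vessel pixels never touch background (they live inside the liver)
  ves <- which(m1$labels == 3, arr.ind = TRUE)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- cbind(pmin(pmax(ves[, 1] + d[1], 1), 64),
                pmin(pmax(ves[, 2] + d[2], 1), 64))
    expect_false(any(m1$labels[nb] == 0))
  }
})

test_that("tumor count and rim geometry are as requested", {
  p0 <- phantom_params(image_size = 64, n_tumors = 0, seed = 3)
  m0 <- make_tissue_map(p0)
  expect_equal(sum(m0$labels %in% 4:5), 0)

  p3 <- phantom_params(image_size = 256, n_tumors = 3, seed = 5)
  m3 <- make_tissue_map(p3)
  expect_equal(count_components(m3$labels == 4), 3)
  # each core is wrapped by rim: dilating the core by one pixel stays in core+rim
  core <- m3$labels == 4
  rim <- m3$labels == 5
  idx <- which(core, arr.ind = TRUE)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- cbind(idx[, 1] + d[1], idx[, 2] + d[2])
    expect_true(all(core[nb] | rim[nb]))
  }
  # and the rim touches the core somewhere
  expect_gt(sum(rim), 0)
})

test_that("noise-free rendering follows the exact enhancement rule", {
  p <- phantom_params(image_size = 64, seed = 11, enhancement_gain = 80)
  m <- make_tissue_map(p)
  st <- render_study(m, p)
  enh <- m$labels == 3 | m$labels == 5
  diff <- st$t1ce$intensities - st$t1pre$intensities
  expect_equal(diff, 80 * (enh + 0), ignore_attr = TRUE)
  expect_true(all(diff >= 0))  # enhancement positivity
  # T2 carries a different class-contrast table
  expect_false(isTRUE(all.equal(st$t2$intensities, st$t1pre$intensities)))

  p0 <- phantom_params(image_size = 64, seed = 11, enhancement_gain = 0)
  st0 <- render_study(make_tissue_map(p0), p0)
  expect_identical(st0$t1ce$intensities, st0$t1pre$intensities)
})

test_that("additive noise matches the stated model per tissue class", {
  p <- phantom_params(image_size = 128, seed = 21, noise_sd = 5)
  m <- make_tissue_map(p)
  st <- render_study(m, p)
  cm <- p$class_intensity_means
  for (cls in 1:2) {  # body, liver: large interior classes far from clamping
    px <- st$t1pre$intensities[m$labels == cls]
    tol <- 3 * 5 / sqrt(length(px))
    expect_lt(abs(mean(px) - cm["t1pre", cls + 1]), tol)
  }
})

test_that("misregistration is seeded, bounded and vanishes at magnitude zero", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  expect_identical(misregister(img, 0, seed = 4), img)
  expect_error(misregister(img, -1), "magnitude")
  w1 <- misregister(img, 2, seed = 4)
  w2 <- misregister(img, 2, seed = 4)
  expect_identical(w1, w2)
  # impulse: the bright mass center moves at most `magnitude` pixels
  imp <- matrix(0, 64, 64); imp[33, 30] <- 1
  w <- misregister(imp, 2, seed = 9)
  idx <- which(w > 1e-9, arr.ind = TRUE)
  com <- colSums(idx * w[idx]) / sum(w[idx])
  expect_lte(sqrt(sum((com - c(33, 30))^2)), 2 + 1e-6)
})

test_that("make_dataset writes disjoint seeded splits", {
  dir <- file.path(tempdir(), "ph_book")
  p <- phantom_params(image_size = 32, seed = 2)
  m1 <- make_dataset(4, 2, 2, p, dir)
  expect_equal(nrow(m1), 8)
  expect_equal(unname(table(m1$split)[c("train", "val", "test")]),
               c(4L, 2L, 2L), ignore_attr = TRUE)
  expect_false(anyDuplicated(m1$study_id) > 0)
  m2 <- make_dataset(4, 2, 2, p, file.path(tempdir(), "ph_book2"))
  expect_identical(m1[c("study_id", "split", "spacing_mm")],
                   m2[c("study_id", "split", "spacing_mm")])
  # same seed -> identical image bytes
  f1 <- file.path(dir, m1$t1ce_path[1])
  f2 <- file.path(tempdir(), "ph_book2", m2$t1ce_path[1])
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the latent-class lookup oracle attains zero error on noise-free phantoms", {
  fix <- phantom_fixture(n_train = 3, n_val = 1, n_test = 1, image_size = 64)
  for (sid in fix$manifest$study_id) {
    st <- load_study(fix$manifest, sid)
    pred <- enhancement_oracle(st$t1pre$intensities, st$t2$intensities, fix$params)
    expect_equal(mse(st$t1ce$intensities, pred), 0)
  }
})

test_that("parameter validation catches configuration errors", {
  expect_error(phantom_params(image_size = 63), "divisible by 4")
  expect_error(phantom_params(noise_sd = -1), "noise_sd")
  expect_error(phantom_params(enhancement_gain = -5), "enhancement_gain")
})
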