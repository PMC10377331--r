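test_that("MSE and PSNR follow their closed forms", {
  expect_equal(mse(matrix(0, 2, 2), matrix(c(1, 0, 3, 0), 2, 2)), 2.5)
  set.seed(1)
  y <- matrix(runif(64, 0, 255), 8, 8)
  g <- matrix(runif(64, 0, 255), 8, 8)
  # brute-force pixel loop oracle
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (y[i, j] - g[i, j])^2
  expect_equal(mse(y, g), acc / 64, tolerance = 1e-9)

  d <- matrix(sqrt(65.025), 8, 8)
  expect_equal(psnr(matrix(0, 8, 8), d), 30, tolerance = 1e-9)
  expect_identical(psnr(y, y), Inf)
  # halving the MSE raises PSNR by 10 log10 2
  expect_equal(psnr(matrix(0, 8, 8), d / sqrt(2)) - psnr(matrix(0, 8, 8), d),
               10 * log10(2), tolerance = 1e-9)
  expect_error(mse(y, matrix(0, 4, 4)), "shape")
})

test_that("global SSIM matches a direct moment-sum evaluation", {
  mp <- metric_params()
  expect_equal(mp$c1, 6.5025)
  expect_equal(mp$c2, 58.5225)

  y <- matrix(runif(256, 0, 255), 16, 16)
  expect_equal(ssim_global(y, y), 1, tolerance = 1e-12)

  z0 <- matrix(0, 8, 8); z255 <- matrix(255, 8, 8)
  expect_equal(ssim_global(z0, z255), 6.5025 / (255^2 + 6.5025), tolerance = 1e-12)

  set.seed(2)
  for (i in 1:10) {
    a <- matrix(runif(144, 0, 255), 12, 12)
    b <- a + matrix(rnorm(144, sd = 20), 12, 12)
    # independent evaluation from raw moment sums
    n <- length(a)
    sa <- sum(a); sb <- sum(b)
    saa <- sum(a^2); sbb <- sum(b^2); sab <- sum(a * b)
    mua <- sa / n; mub <- sb / n
    va <- saa / n - mua^2; vb <- sbb / n - mub^2
    cab <- sab / n - mua * mub
    want <- ((2 * mua * mub + mp$c1) * (2 * cab + mp$c2)) /
      ((mua^2 + mub^2 + mp$c1) * (va + vb + mp$c2))
    expect_equal(ssim_global(a, b), want, tolerance = 1e-9)
    expect_equal(ssim_global(a, b), ssim_global(b, a), tolerance = 1e-12)
  }
  # the windowed variant agrees with the global form on constant-structure images
  expect_equal(ssim_windowed(y, y), 1, tolerance = 1e-9)
  # ... and with a naive sliding-window oracle on a random pair
  yw <- matrix(runif(400, 0, 255), 20, 20)
  gw <- yw + matrix(rnorm(400, sd = 15), 20, 20)
  w <- 8
  vals <- c()
  for (r in 1:(20 - w + 1)) for (cc in 1:(20 - w + 1)) {
    aa <- yw[r:(r + w - 1), cc:(cc + w - 1)]
    bb <- gw[r:(r + w - 1), cc:(cc + w - 1)]
    mua <- mean(aa); mub <- mean(bb)
    va <- mean((aa - mua)^2); vb <- mean((bb - mub)^2)
    cab <- mean((aa - mua) * (bb - mub))
    vals <- c(vals, ((2 * mua * mub + mp$c1) * (2 * cab + mp$c2)) /
                ((mua^2 + mub^2 + mp$c1) * (va + vb + mp$c2)))
  }
  expect_equal(ssim_windowed(yw, gw, w), mean(vals), tolerance = 1e-9)
})

test_that("CNR is the box contrast over background noise and is affine invariant", {
  sl <- matrix(0, 20, 20)
  sl[1:4, 1:4] <- 10                     # tumor box, mean 10
  sl[1:4, 6:9] <- 4                      # normal box, mean 4
  sl[10:13, 1:4] <- rep(c(-2, 2), 8)     # background box, population sd 2
  boxes <- region_boxes(c(1, 4, 1, 4), c(1, 4, 6, 9), c(10, 13, 1, 4))
  expect_equal(cnr(sl, boxes), 3.0)
  swapped <- region_boxes(c(1, 4, 6, 9), c(1, 4, 1, 4), c(10, 13, 1, 4))
  expect_equal(cnr(sl, swapped), 3.0)            # absolute value symmetry
  expect_equal(cnr(5 * sl + 11, boxes), 3.0)     # affine invariance, a > 0
  sl2 <- sl; sl2[1:4, 6:9] <- 10
  expect_equal(cnr(sl2, boxes), 0)
  expect_warning(v <- cnr(matrix(1, 20, 20), boxes), "constant")
  expect_identical(v, Inf)
  expect_error(region_boxes(c(1, 4, 1, 4), c(2, 5, 2, 5), c(10, 13, 1, 4)),
               "non-overlapping")
})

test_that("Dice and Hausdorff agree with brute-force set oracles", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:3] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_equal(dice(a, b), 0)
  nest_in <- matrix(FALSE, 6, 6); nest_in[2:3, 2:5] <- TRUE   # 8 px
  nest_out <- matrix(FALSE, 6, 6); nest_out[2:5, 2:5] <- TRUE # 16 px
  expect_equal(dice(nest_in, nest_out), 2 / 3)
  expect_error(dice(a & FALSE, b & FALSE), "empty")

  expect_equal(hausdorff(a, a), 0)
  p1 <- matrix(FALSE, 8, 8); p1[4, 2] <- TRUE
  p2 <- matrix(FALSE, 8, 8); p2[4, 5] <- TRUE
  expect_equal(hausdorff(p1, p2), 3.0)
  expect_equal(hausdorff(p1, p2, spacing = c(2, 2)), 6.0)

  set.seed(3)
  for (i in 1:25) {
    ma <- random_mask(32); mb <- random_mask(32)
    expect_equal(dice(ma, mb), dice_oracle(ma, mb), tolerance = 1e-12)
    expect_equal(hausdorff(ma, mb), hausdorff_oracle(ma, mb), tolerance = 1e-9)
    expect_equal(hausdorff(ma, mb), hausdorff(mb, ma), tolerance = 1e-12)
  }
})

test_that("center-of-mass shifts map pixels to anatomical axes", {
  m <- matrix(FALSE, 10, 10); m[3:5, 2:4] <- TRUE
  expect_equal(com_shift(m, m), c(SI = 0, RL = 0, AP = 0))
  shifted <- matrix(FALSE, 10, 10); shifted[3:5, 5:7] <- TRUE  # +3 columns
  expect_equal(com_shift(m, shifted), c(SI = 0, RL = 3, AP = 0))
  expect_equal(com_shift(shifted, m), -com_shift(m, shifted))
  expect_equal(com_shift(m, shifted, spacing = c(1, 0.5)),
               c(SI = 0, RL = 1.5, AP = 0))
})

test_that("Turing scoring aggregates per-rater accuracies with a sample sd", {
  rec <- tibble::tibble(n_correct = c(55, 56, 42, 59, 53, 49), n_total = 100)
  ts <- turing_score(rec)
  expect_equal(ts$mean_pct, 52.33, tolerance = 0.005)
  expect_equal(ts$sd_pct, 6.06, tolerance = 0.005)
  g <- glance(ts)
  expect_equal(g$n_raters, 6)

  all100 <- turing_score(tibble::tibble(n_correct = rep(100, 4), n_total = 100))
  expect_equal(all100$mean_pct, 100)
  expect_equal(all100$sd_pct, 0)

  expect_warning(one <- turing_score(tibble::tibble(n_correct = 50, n_total = 100)),
                 "single rater")
  expect_equal(one$sd_pct, 0)
  expect_error(turing_score(tibble::tibble(n_correct = 5, n_total = 0)), "n_total")
  expect_error(turing_score(tibble::tibble(n_correct = 101, n_total = 100)),
               "exceeds")
})

test_that("Turing manifests are balanced, seeded and self-consistent", {
  real <- sprintf("real_%03d.png", 1:60)
  synth <- sprintf("synth_%03d.png", 1:60)
  tm1 <- make_turing_manifest(real, synth, n = 100, seed = 4)
  expect_equal(nrow(tm1$manifest), 100)
  expect_equal(sum(tm1$key$truth == "real"), 50)
  expect_equal(sum(tm1$key$truth == "synthetic"), 50)
  tm2 <- make_turing_manifest(real, synth, n = 100, seed = 4)
  expect_identical(tm1, tm2)
  # the answer key scores itself at 100%
  expect_equal(score_turing_responses(tm1$key, tm1$key), 100)
  expect_error(make_turing_manifest(real[1:10], synth, n = 100, seed = 1),
               "not enough")
  expect_error(make_turing_manifest(real, synth, n = 99), "even")
})
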