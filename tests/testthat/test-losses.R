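test_that("sobel responses match a brute-force convolution oracle", {
  K <- sobel_kernels()
  expect_equal(sum(K$kx), 0)
  expect_equal(sum(K$ky), 0)
  expect_equal(K$ky, t(K$kx))

  expect_true(all(sobel_response(matrix(3, 8, 8)) == 0))

  # horizontal unit ramp: interior x-response 8, y-response 0
  ramp <- matrix(rep(1:5, each = 5), 5, 5)  # I(r,c) = c
  r <- sobel_response(ramp)
  expect_true(all(r[2:4, 2:4, 1] == 8))
  expect_true(all(r[2:4, 2:4, 2] == 0))

  set.seed(8)
  img <- matrix(rnorm(49), 7, 7)
  r <- sobel_response(img)
  expect_equal(r[, , 1], filter2_oracle(img, K$kx), tolerance = 1e-12)
  expect_equal(r[, , 2], filter2_oracle(img, K$ky), tolerance = 1e-12)

  # transposing the image swaps the channels
  rt <- sobel_response(t(img))
  expect_equal(rt[, , 1], t(r[, , 2]), tolerance = 1e-12)
  expect_equal(rt[, , 2], t(r[, , 1]), tolerance = 1e-12)

  expect_error(sobel_response(matrix(0, 2, 5)), "3 x 3")
})

test_that("the gradient-regularization loss is a shift-invariant edge penalty", {
  set.seed(9)
  a <- matrix(rnorm(64), 8, 8)
  b <- matrix(rnorm(64), 8, 8)
  expect_equal(gr_loss(a, a), 0)
  expect_equal(gr_loss(a, a + 5), 0)               # constants are annihilated
  expect_equal(gr_loss(a + 2.5, b + 2.5), gr_loss(a, b), tolerance = 1e-12)
  expect_equal(gr_loss(a, b), gr_loss(b, a), tolerance = 1e-12)

  # center impulse: value from the brute-force oracle
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  K <- sobel_kernels()
  want <- mean(c(filter2_oracle(imp, K$kx)^2, filter2_oracle(imp, K$ky)^2))
  expect_equal(gr_loss(imp, matrix(0, 5, 5)), want, tolerance = 1e-12)
  expect_error(gr_loss(a, matrix(0, 4, 4)), "shape")
})

test_that("the L1 loss is the mean absolute difference", {
  expect_equal(l1_loss(matrix(0, 2, 2), matrix(c(1, 0, 3, 0), 2, 2)), 1.0)
  a <- matrix(rnorm(36), 6, 6); b <- matrix(rnorm(36), 6, 6)
  expect_equal(l1_loss(a, a), 0)
  expect_equal(l1_loss(3 * a, 3 * b), 3 * l1_loss(a, b))
  expect_equal(l1_loss(a, b), l1_loss(b, a))
})

test_that("the adversarial loss takes its closed-form values", {
  half <- matrix(0.5, 4, 4)
  l <- cgan_loss(half, half)
  expect_equal(l$d_loss, 2 * log(2), tolerance = 1e-12)
  expect_equal(l$g_loss, log(2), tolerance = 1e-12)

  near <- cgan_loss(matrix(1 - 1e-9, 2, 2), matrix(1e-9, 2, 2))
  expect_lt(near$d_loss, 1e-6)  # perfect-discriminator limit

  sat <- cgan_loss(half, half, saturating = TRUE)
  expect_equal(sat$g_loss, -log(2), tolerance = 1e-12)

  expect_message(cl <- cgan_loss(matrix(1.2, 2, 2), half), "clamped")
  expect_true(is.finite(cl$d_loss))
})

test_that("the combined objective recomposes exactly and honours ablation flags", {
  g <- c(0.3, 0.4, 0.5); d <- c(1.1, 1.2, 1.3)
  r0 <- total_objective(g, d, l_l1 = 0.2, l_gr = 0.1, loss_weights(0, 0))
  expect_equal(r0$total_g, sum(g))

  r1 <- total_objective(0, 0, l_l1 = 0.01, l_gr = 0, loss_weights(0, 100))
  expect_equal(r1$total_g, 1.0)

  rab <- total_objective(g[1], d[1], l_l1 = 0.2, l_gr = 0.7,
                         loss_weights(50, 100), ablation = "no_gr_no_mmd")
  expect_equal(rab$total_g, g[1] + 100 * 0.2)  # GR and extra scales dropped
  expect_equal(rab$lambda1, 0)

  rfull <- total_objective(g, d, l_l1 = 0.2, l_gr = 0.1, loss_weights(50, 100))
  # machine-precision recomposition from the report's own fields
  expect_identical(rfull$total_g,
                   rfull$l_cgan_1 + rfull$l_cgan_2 + rfull$l_cgan_3 +
                     rfull$lambda1 * rfull$l_gr + rfull$lambda2 * rfull$l_l1)
  expect_equal(rfull$total_d, sum(d))
})

test_that("the lambda1 and learning-rate schedules match the published recipe", {
  expect_equal(lambda1_at(50), 50)
  expect_equal(lambda1_at(150), 50)
  expect_equal(lambda1_at(25), 25)
  expect_true(all(lr_at(1:50) == 2e-4))
  expect_equal(lr_at(150), 0)
  expect_equal(lr_at(100), 1e-4)
  # continuity across the epoch-50 boundary
  expect_lte(abs(lambda1_at(51) - lambda1_at(50)), 1 + 1e-12)
  expect_lte(abs(lr_at(51) - lr_at(50)), 2e-4 / 100 + 1e-12)
  expect_error(lambda1_at(0), "1..150")
  expect_error(lr_at(151), "1..150")
})
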