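test_that("net intensity is plain background subtraction, sign preserved", {
  expect_equal(net_intensity(150, 50, 1), 100)
  expect_equal(net_intensity(123.4, 0, 7), 123.4)
  expect_equal(net_intensity(100, 30, 4), -20)
})

test_that("membrane band membership and means equal pixel enumeration", {
  set.seed(5)
  img <- matrix(runif(150 * 150, 0, 200), 150, 150)
  circle <- list(cx = 74.2, cy = 71.9, r = 28.6)
  res <- membrane_intensity(img, circle, inward_px = 4,
                            background_per_px = 12)

  xs <- matrix(0:149, 150, 150, byrow = TRUE)
  ys <- matrix(0:149, 150, 150)
  d <- sqrt((xs - circle$cx)^2 + (ys - circle$cy)^2)
  band <- d > circle$r - 4 & d <= circle$r
  expect_identical(res$pixel_count, sum(band))
  expect_equal(res$total_net, sum(img[band]) - 12 * sum(band))
  expect_equal(res$per_px_net, res$total_net / res$pixel_count)
})

test_that("uniform band yields exactly v - b per pixel", {
  img <- make_ring(120, 60, 60, 25, level = 700, background = 55,
                   interior = 55)
  # band of width 1 centered on the drawn ring
  res <- membrane_intensity(img, list(cx = 60, cy = 60, r = 25.49),
                            inward_px = 1, background_per_px = 55)
  expect_equal(res$per_px_net, 700 - 55)

  zero <- membrane_intensity(matrix(0, 100, 100),
                             list(cx = 50, cy = 50, r = 20),
                             inward_px = 3, background_per_px = 0)
  expect_equal(zero$total_net, 0)
})

test_that("with zero background, total scales linearly with the image", {
  set.seed(9)
  img <- matrix(runif(100 * 100, 0, 50), 100, 100)
  circle <- list(cx = 50, cy = 50, r = 20)
  r1 <- membrane_intensity(img, circle, 3, 0)
  r2 <- membrane_intensity(2 * img, circle, 3, 0)
  expect_equal(r2$total_net, 2 * r1$total_net)
})

test_that("droplet interior mean covers the full disc", {
  img <- make_disc(100, 50, 50, 10, level = 300, background = 40)
  res <- droplet_interior_intensity(img, list(cx = 50, cy = 50, r = 10), 40)
  expect_equal(res$per_px_net, 260)

  xs <- matrix(0:99, 100, 100, byrow = TRUE)
  ys <- matrix(0:99, 100, 100)
  expect_identical(res$pixel_count,
                   sum(sqrt((xs - 50)^2 + (ys - 50)^2) <= 10))

  same <- droplet_interior_intensity(img, list(cx = 50, cy = 50, r = 10), 300)
  expect_equal(same$per_px_net, 0)
})

test_that("condition summary reports between-stack SD with n-1", {
  res <- tibble::tibble(
    condition = "a",
    stack_id = rep(1:3, each = 2),
    vesicle_mean_per_px = c(9, 11, 11, 13, 13, 15)) # stack means 10, 12, 14
  s <- condition_summary(res)
  expect_equal(s$mean_per_px, 12)
  expect_equal(s$sd_between_stacks, 2)
  expect_identical(s$n_stacks, 3L)

  one <- condition_summary(tibble::tibble(condition = "a", stack_id = 1,
                                          vesicle_mean_per_px = 5))
  expect_true(is.na(one$sd_between_stacks))

  set.seed(13)
  big <- tibble::tibble(condition = "c",
                        stack_id = rep(1:50, each = 3),
                        vesicle_mean_per_px = rnorm(150, 100, 10))
  s2 <- condition_summary(big)
  stack_means <- tapply(big$vesicle_mean_per_px, big$stack_id, mean)
  expect_equal(s2$mean_per_px, mean(stack_means))
  expect_equal(s2$sd_between_stacks, sd(stack_means))
})

test_that("binding analysis weights vesicle means by pixel count", {
  imgB <- make_ring(160, 80, 80, 30, level = 500, background = 0)
  imgB2 <- make_ring(160, 80, 80, 20, level = 900, background = 0)
  stkB <- guv_stack(list(imgB, imgB2), pixel_size = 1, z_spacing = 1,
                    channel_name = "B")
  grouped <- tibble::tibble(vesicle_id = 1L, z_index = 0:1,
                            cx = 80, cy = 80, r = c(30.49, 20.49),
                            score = 1)
  out <- binding_analysis(stkB, grouped, inward_px = 1, background = 0)
  ps <- out$per_section
  expect_equal(ps$per_px_net, c(500, 900), tolerance = 1e-10)
  manual <- sum(ps$per_px_net * ps$pixel_count) / sum(ps$pixel_count)
  expect_equal(out$per_vesicle$vesicle_mean_per_px, manual)
})
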