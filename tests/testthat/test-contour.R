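test_that("a uniform ring gives near-equal segment means", {
  # uniform band of width 3 sampled by an exactly matching annulus
  img <- make_half_ring(140, 70, 70, 30, right = 800, left = 800, width = 3)
  prof <- contour_profile(img, list(cx = 70, cy = 70, r = 30), N = 36,
                          delta_r = 3, background_per_px = 0)
  m <- prof$segment_means
  expect_equal(m, rep(800, 36), tolerance = 0.02) # rotational symmetry
})

test_that("segment means equal brute-force wedge enumeration", {
  img <- make_half_ring(160, 80, 80, 30, right = 100, left = 10, width = 4)
  circle <- list(cx = 80, cy = 80, r = 30)
  N <- 36; dr <- 4; bg <- 2
  prof <- contour_profile(img, circle, N = N, delta_r = dr,
                          background_per_px = bg)

  xs <- matrix(0:159, 160, 160, byrow = TRUE)
  ys <- matrix(0:159, 160, 160)
  d <- sqrt((xs - 80)^2 + (ys - 80)^2)
  ang <- (atan2(ys - 80, xs - 80) * 180 / pi) %% 360
  manual <- vapply(0:(N - 1), function(k) {
    sel <- d > 30 - dr & d <= 30 & ang >= k * 10 & ang < (k + 1) * 10
    mean(img[sel]) - bg
  }, numeric(1))
  expect_equal(prof$segment_means, manual)
})

test_that("an empty wedge is reported as an error", {
  img <- make_ring(60, 30, 30, 8, level = 100)
  expect_error(contour_profile(img, list(cx = 30, cy = 30, r = 8),
                               N = 360, delta_r = 1), "smaller N")
})

test_that("rotating the image cyclically shifts the profile by N/4", {
  img <- make_half_ring(160, 80, 80, 30, right = 100, left = 10, width = 5)
  circle <- list(cx = 79.5, cy = 79.5, r = 30) # rotation center of the grid
  N <- 36
  p0 <- contour_profile(img, circle, N = N, delta_r = 5)$segment_means
  rot <- t(img)[, rev(seq_len(160))] # 90 deg rotation on the pixel grid
  p1 <- contour_profile(rot, circle, N = N, delta_r = 5)$segment_means
  shifted <- c(p0[(N - N / 4 + 1):N], p0[1:(N - N / 4)])
  expect_equal(p1, shifted, tolerance = 0.02 * mean(abs(p0)) * N)
})

test_that("domain levels follow the 20% rank rule", {
  const <- domain_levels(rep(7, 20), percentile = 20)
  expect_equal(unlist(const), c(high = 7, low = 7, mid = 7))

  lev <- domain_levels(c(rep(10, 5), rep(100, 5)), percentile = 20)
  expect_equal(lev$high, 100)
  expect_equal(lev$low, 10)
  expect_equal(lev$mid, 55)

  set.seed(17)
  for (k in 1:20) {
    N <- sample(10:60, 1)
    m <- runif(N, 0, 1000)
    pct <- runif(1, 5, 45)
    lev <- domain_levels(m, percentile = pct)
    srt <- sort(m, decreasing = TRUE)
    rank <- ceiling(pct / 100 * N)
    expect_equal(lev$high, srt[rank])
    expect_equal(lev$low, srt[N - rank + 1])
    expect_equal(lev$mid, (srt[rank] + srt[N - rank + 1]) / 2)
  }
})

test_that("discontinuity counting: constant 0, half/half 2, 2k arcs 2k", {
  expect_identical(detect_discontinuities(rep(50, 36), mid = 50, p = 20), 0L)

  half <- c(rep(100, 18), rep(10, 18))
  expect_identical(detect_discontinuities(half, mid = 55, p = 20), 2L)

  quad <- rep(c(rep(100, 9), rep(10, 9)), 2)
  expect_identical(detect_discontinuities(quad, mid = 55, p = 20), 4L)

  for (k in 1:6) {
    arcs <- rep(c(rep(100, 3), rep(10, 3)), k)
    expect_identical(detect_discontinuities(arcs, mid = 55, p = 20), 2L * k)
  }
  expect_error(detect_discontinuities(half, mid = 0, p = 20), "mid")
})

test_that("discontinuity count matches an exhaustive crossing oracle", {
  set.seed(37)
  for (rep_i in 1:30) {
    N <- 36
    m <- runif(N, 0, 100)
    mid <- 50; p <- 20
    got <- detect_discontinuities(m, mid, p)
    # oracle: classify each segment as +1/-1/0 against the band, drop the
    # dead-band segments, and count sign changes around the cycle
    s <- ifelse(m >= mid * (1 + p / 100), 1L,
                ifelse(m <= mid * (1 - p / 100), -1L, 0L))
    s <- s[s != 0L]
    expected <- if (length(s) < 2) 0L else sum(s != c(s[-1], s[1]))
    expect_identical(got, expected)
  }
})

test_that("discontinuity count is invariant under cyclic shifts", {
  set.seed(41)
  m <- runif(36, 0, 100)
  ref <- detect_discontinuities(m, 50, 20)
  for (sh in c(1, 5, 17, 35)) {
    shifted <- c(m[(sh + 1):36], m[1:sh])
    expect_identical(detect_discontinuities(shifted, 50, 20), ref)
  }
})

test_that("section state: uniform vs separated, robust to mild noise", {
  expect_identical(section_state(rep(80, 36))$state, "uniform")
  half <- c(rep(100, 18), rep(10, 18))
  expect_identical(section_state(half)$state, "separated")

  set.seed(43)
  wrong <- 0
  for (i in 1:100) {
    noisy <- 100 * (1 + rnorm(36, 0, 0.02))
    if (section_state(noisy, percentile = 20, p = 20)$state != "uniform")
      wrong <- wrong + 1
  }
  expect_lte(wrong, 1)
})

test_that("state decision is invariant to intensity scaling", {
  set.seed(47)
  for (i in 1:20) {
    m <- runif(36, 1, 100)
    s1 <- section_state(m)
    s2 <- section_state(m * 37.5)
    expect_identical(s1$state, s2$state)
    expect_equal(s2$mid, s1$mid * 37.5)
  }
})

test_that("vesicle state follows the inclusive 40% fraction rule", {
  d <- vesicle_state(c("separated", "separated", "uniform", "uniform",
                       "uniform"), decision_fraction = 0.4)
  expect_identical(d$vesicle_state, "separated") # 2/5 = 40% >= 40%
  expect_equal(d$fraction_separated, 0.4)

  u <- vesicle_state(rep("uniform", 6))
  expect_identical(u$vesicle_state, "uniform")
  expect_equal(u$fraction_separated, 0)

  set.seed(53)
  for (i in 1:30) {
    n <- sample(1:12, 1)
    states <- sample(c("uniform", "separated"), n, TRUE)
    frac <- runif(1)
    d <- vesicle_state(states, frac)
    expect_equal(d$fraction_separated, mean(states == "separated"))
    expect_identical(d$vesicle_state,
                     ifelse(mean(states == "separated") >= frac,
                            "separated", "uniform"))
  }
})
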