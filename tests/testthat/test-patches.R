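test_that("patch sets enforce their contracts", {
  expect_error(generate_training_set("state-2class", 0), "n_per_class")

  set.seed(61)
  ps <- generate_training_set("state-2class", 10, seed = 2)
  expect_identical(length(ps), 20L)
  expect_identical(as.integer(table(ps$labels)), c(10L, 10L))
  expect_identical(ps$class_names, c("uniform", "separated"))
  expect_identical(dim(ps$patches)[1:2], c(50L, 50L))

  sel <- generate_training_set("selection-4class", 5, seed = 3)
  expect_identical(length(sel), 20L)
  expect_identical(sel$class_names, c("C1", "C2", "C3", "C4"))

  expect_identical(generate_training_set("state-2class", 5, seed = 7),
                   generate_training_set("state-2class", 5, seed = 7))
})

test_that("state patches are background-thresholded to zero", {
  ps <- generate_training_set("state-2class", 25, seed = 11)
  mins <- apply(ps$patches, 3, min)
  expect_true(all(mins == 0))
  # thresholding zeroes, it does not binarize: rims keep graded intensity
  n_levels <- apply(ps$patches, 3, function(m) length(unique(as.numeric(m))))
  expect_true(all(n_levels > 2))
})

test_that("uniform patches have lower contour variation than separated", {
  ps <- generate_training_set("state-2class", 250, seed = 13)
  cv <- numeric(length(ps))
  ok <- logical(length(ps))
  for (i in seq_len(length(ps))) {
    meta <- ps$meta[i, ]
    r <- meta$r_px
    if (r < 8 || meta$cx - r < 3 || meta$cx + r > 46 ||
        meta$cy - r < 3 || meta$cy + r > 46) next
    prof <- try(contour_profile(ps$patches[, , i],
                                list(cx = meta$cx, cy = meta$cy, r = r + 1),
                                N = 18, delta_r = 4), silent = TRUE)
    if (inherits(prof, "try-error")) next
    m <- prof$segment_means
    if (mean(m) <= 0) next
    cv[i] <- sd(m) / mean(m)
    ok[i] <- TRUE
  }
  cv_uniform <- mean(cv[ok & ps$labels == 1])
  cv_separated <- mean(cv[ok & ps$labels == 2])
  expect_lt(cv_uniform, cv_separated)
})

test_that("prepare_patch crops, clamps and resamples to 50x50", {
  img <- make_ring(300, 150, 150, 40, level = 1200, background = 10)
  patch <- prepare_patch(img, list(cx = 150, cy = 150, r = 40), margin = 1.2)
  expect_identical(dim(patch), c(50L, 50L))
  expect_error(prepare_patch(img, list(cx = 10, cy = 10, r = 0.5)),
               "degenerate")

  # constant image stays constant
  flat <- prepare_patch(matrix(7, 200, 200), list(cx = 100, cy = 100, r = 40))
  expect_true(all(flat == 7))

  # crop side 2 * 1.2 * 40 = 96 px; compare to an independent pure-R
  # bilinear resampler with the same pixel-center convention
  crop <- img[(150 - 48 + 1):(150 + 48 + 1), (150 - 48 + 1):(150 + 48 + 1)]
  out <- matrix(0, 50, 50)
  n <- nrow(crop)
  for (oy in 0:49) for (ox in 0:49) {
    fy <- min(max((oy + 0.5) * n / 50 - 0.5, 0), n - 1)
    fx <- min(max((ox + 0.5) * n / 50 - 0.5, 0), n - 1)
    y0 <- floor(fy); x0 <- floor(fx)
    y1 <- min(y0 + 1, n - 1); x1 <- min(x0 + 1, n - 1)
    wy <- fy - y0; wx <- fx - x0
    out[oy + 1, ox + 1] <-
      (1 - wy) * ((1 - wx) * crop[y0 + 1, x0 + 1] + wx * crop[y0 + 1, x1 + 1]) +
      wy * ((1 - wx) * crop[y1 + 1, x0 + 1] + wx * crop[y1 + 1, x1 + 1])
  }
  expect_equal(patch, out, tolerance = 1 / 1200)
})

test_that("zero-background patch preparation floors the background", {
  img <- make_ring(200, 100, 100, 30, level = 1000, background = 50)
  patch <- prepare_patch(img, list(cx = 100, cy = 100, r = 30),
                         zero_background = TRUE)
  expect_equal(min(patch), 0)
  expect_gt(max(patch), 500)
})

test_that("augmentation: identity, counting and inverse-shift checks", {
  ps <- generate_training_set("state-2class", 6, seed = 17)

  ident <- augment(ps, scale_range = c(1, 1), shift_range = c(0, 0),
                   multiplier = 1, seed = 1)
  expect_equal(ident$patches, ps$patches)
  expect_identical(ident$labels, ps$labels)

  tripled <- augment(ps, multiplier = 3, seed = 2)
  expect_identical(length(tripled), 36L)
  expect_identical(tripled$labels, rep(ps$labels, 3))

  expect_error(augment(ps, scale_range = c(1.05, 1.2)), "identity")
  expect_error(augment(ps, shift_range = c(2, 5)), "identity")

  # shifting by (dx, dy) then un-shifting recovers the overlap region
  patch <- ps$patches[, , 1]
  shifted <- guvstack:::.cpp_scale_shift(patch, 1, 4, -3, 0)
  back <- guvstack:::.cpp_scale_shift(shifted, 1, -4, 3, 0)
  inner <- 8:42
  expect_equal(back[inner, inner], patch[inner, inner], tolerance = 1e-10)
})

test_that("patch sets round-trip through a TIFF directory + manifest", {
  ps <- generate_training_set("state-2class", 3, seed = 19)
  dir <- file.path(tempdir(), "patchset-test")
  manifest <- write_patch_set(ps, dir)
  labs <- read.csv(manifest)
  expect_identical(nrow(labs), 6L)
  expect_setequal(unique(labs$label), c("uniform", "separated"))
  expect_true(all(file.exists(file.path(dir, labs$file))))
  unlink(dir, recursive = TRUE)
})
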