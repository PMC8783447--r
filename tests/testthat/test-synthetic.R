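test_that("scene sampling respects ranges, counts and determinism", {
  p <- scene_params(n_vesicles = c(5, 5), domain_prob = 0,
                    field_of_view = 400, pixel_size = 1,
                    radius_um = c(20, 40))
  sc <- sample_scene(p, seed = 1)
  expect_identical(nrow(sc$vesicles), 5L)
  expect_identical(nrow(sc$domains), 0L)

  expect_identical(sample_scene(p, seed = 99), sample_scene(p, seed = 99))

  expect_error(scene_params(radius_um = c(15, 8)), "min must be <=")

  # empirical radius range stays inside the declared range
  p2 <- scene_params(n_vesicles = c(1, 3), radius_um = c(8, 15),
                     domain_prob = 0.5)
  radii <- unlist(lapply(1:200, function(s)
    sample_scene(p2, seed = s)$vesicles$radius_um))
  expect_gte(min(radii), 8)
  expect_lte(max(radii), 15)
})

test_that("domain caps intersect their parent shells", {
  p <- scene_params(n_vesicles = c(4, 4), domain_prob = 1)
  for (s in 1:20) {
    sc <- sample_scene(p, seed = s)
    R <- sc$vesicles$radius_um[sc$domains$parent]
    dc <- sqrt((sc$domains$center_x_um - sc$vesicles$x_um[sc$domains$parent])^2 +
                 (sc$domains$center_y_um - sc$vesicles$y_um[sc$domains$parent])^2 +
                 (sc$domains$center_z_um - sc$vesicles$z_um[sc$domains$parent])^2)
    expect_equal(dc, R) # cap sphere sits on the shell
    expect_true(all(sc$domains$radius_um > 0))
    expect_true(all(sc$domains$radius_um <= 2 * R))
  }
})

test_that("a section beyond every vesicle is pure background", {
  sc <- pixel_scene(128, 64, 64, R = 20, z0 = 0)
  img <- render_section(sc, z = 25, noiseless = TRUE)
  expect_equal(img, matrix(sc$background_level, nrow(img), ncol(img)),
               tolerance = 1e-12)
})

test_that("rendered ring radius follows the spherical cross-section", {
  # R = 10 px scaled: use R = 30 px sphere, section at z = z0 + 18 ->
  # rho = sqrt(30^2 - 18^2) = 24 (same sqrt geometry as the 10/6/8 case)
  sc <- pixel_scene(160, 80, 80, R = 30, z0 = 0, psf = 2)
  img <- render_section(sc, z = 18, noiseless = TRUE)
  expect_equal(radial_peak_radius(img, 80, 80, 50), 24, tolerance = 1)
  # and the exact 10-6-8 triangle, at 1 um/px calibration
  sc2 <- pixel_scene(64, 32, 32, R = 10, z0 = 0, psf = 1)
  img2 <- render_section(sc2, z = 6, noiseless = TRUE)
  expect_equal(radial_peak_radius(img2, 32, 32, 20), 8, tolerance = 1)
})

test_that("default field of view matches the acquisition geometry", {
  p <- scene_params()
  expect_equal(p$field_of_view, 127.3)
  expect_equal(p$pixel_size, 127.3 / 1024)
  expect_equal(p$z_spacing, 1)
})

test_that("disabling PSF and noise reproduces ground-truth levels", {
  dom <- cap_domain(c(60, 60, 0), R = 25, theta_deg = 90, phi_deg = 0,
                    half_angle_deg = 60, level = 2500)
  sc <- pixel_scene(120, 60, 60, R = 25, z0 = 0, membrane = 10000,
                    interior = 500, background = 100, psf = 0, domains = dom)
  img <- render_section(sc, z = 0, noiseless = TRUE)
  xs <- matrix(0:119, 120, 120, byrow = TRUE)
  ys <- matrix(0:119, 120, 120)
  d <- sqrt((xs - 60)^2 + (ys - 60)^2)
  # fluorescence is additive over the background offset: background alone
  # away from the vesicle, background + interior inside the lumen
  expect_true(all(img[d > 26.5] == 100))
  expect_true(all(img[d < 23.5] == 100 + 500))
  # rim crest reaches background + membrane level (up to sub-pixel
  # sampling) and never exceeds it; the domain arc reaches its own level
  expect_gt(max(img), 100 + 0.98 * 10000)
  expect_lte(max(img), 100 + 10000)
  arc <- img[d >= 23.5 & d <= 26.5 & abs(ys - 60) < 10 & xs > 60]
  expect_gt(max(arc), 0.9 * 2500)
  expect_lt(max(arc), 10000 * 0.5) # the domain arc is dim, not membrane
})

test_that("rim brightness per wedge is angle-independent", {
  sc <- pixel_scene(120, 60, 60, R = 30, z0 = 0, membrane = 10000,
                    interior = 0, background = 100, psf = 2)
  img <- render_section(sc, z = 0, noiseless = TRUE)
  prof <- contour_profile(img, list(cx = 60, cy = 60, r = 30), N = 36,
                          delta_r = 3, background_per_px = 100)
  m <- prof$segment_means
  # well inside the +/-20% discontinuity band of the phase statistic
  expect_lt(max(abs(m / mean(m) - 1)), 0.10)
})

test_that("z-stacks cover the vesicle extent with annotations", {
  p <- scene_params(n_vesicles = c(1, 1), radius_um = c(5, 5),
                    z_center_um = c(0, 0), field_of_view = 40,
                    pixel_size = 0.5, domain_prob = 0)
  sc <- sample_scene(p, seed = 3)
  out <- render_zstack(sc, noiseless = TRUE)
  ann <- out$annotations
  expect_gte(nrow(ann), 11) # 2R / z_spacing + 1 sections carry the vesicle
  expect_identical(length(out$stack), length(stack_z(out$stack)))

  # annotation centers agree with a centroid-of-ring oracle on the renders
  for (i in seq_len(nrow(ann))) {
    if (ann$r_px[i] < 3) next
    img <- out$stack$sections[[ann$z_index[i] + 1]]
    w <- img - min(img)
    xs <- matrix(0:(ncol(img) - 1), nrow(img), ncol(img), byrow = TRUE)
    ys <- matrix(0:(nrow(img) - 1), nrow(img), ncol(img))
    expect_lt(abs(sum(w * xs) / sum(w) - ann$cx_px[i]), 1)
    expect_lt(abs(sum(w * ys) / sum(w) - ann$cy_px[i]), 1)
  }
})

test_that("an empty scene renders background-only sections", {
  p <- scene_params(n_vesicles = c(0, 0), domain_prob = 0,
                    field_of_view = 30, pixel_size = 1)
  sc <- sample_scene(p, seed = 5)
  out <- render_zstack(sc, noiseless = TRUE)
  expect_identical(nrow(out$annotations), 0L)
  for (s in out$stack$sections)
    expect_equal(max(abs(s - sc$background_level)), 0, tolerance = 1e-9)
})

test_that("section labels are separated exactly when the ring meets a cap", {
  # cap on the equator: sections near the equator cross it, sections close
  # to the opposite pole do not
  dom <- cap_domain(c(40, 40, 0), R = 20, theta_deg = 90, phi_deg = 0,
                    half_angle_deg = 40, level = 2500)
  sc <- pixel_scene(80, 40, 40, R = 20, z0 = 0, psf = 0, domains = dom)
  zs <- c(-18, -10, 0, 10, 18)
  ann <- scene_annotations(sc, zs)
  lab <- setNames(ann$phase_label, ann$z_um)
  expect_identical(unname(lab["0"]), "separated")
  # cap half-angle 40 deg spans polar angles 50..130 deg; a section at
  # z = 18 (polar 26 deg) lies outside it
  expect_identical(unname(lab["18"]), "uniform")
  expect_identical(unname(lab["-18"]), "uniform")

  # oracle on the rendered ground truth: a section is separated iff the
  # rim crest drops to the (dim) domain level over some arc
  for (z in zs) {
    rho <- sqrt(400 - z^2)
    if (rho < 12) next # crest sampling is unreliable on tiny pole rings
    img <- render_section(sc, z, ground_truth = TRUE)
    theta <- seq(0, 2 * pi, length.out = 721)[-721]
    crest <- vapply(theta, function(a) {
      pts <- cbind(round(40 + (rho + c(-1, 0, 1)) * sin(a)) + 1,
                   round(40 + (rho + c(-1, 0, 1)) * cos(a)) + 1)
      max(img[pts])
    }, numeric(1))
    has_domain <- any(crest < 0.6 * 10000 & crest > 0.5 * 2500)
    expect_identical(ann$phase_label[ann$z_um == z] == "separated",
                     has_domain)
  }
})

test_that("stack round-trips through 16-bit TIFF", {
  p <- scene_params(n_vesicles = c(1, 1), radius_um = c(6, 6),
                    z_center_um = c(0, 0), field_of_view = 40,
                    pixel_size = 1, domain_prob = 0)
  sc <- sample_scene(p, seed = 8)
  out <- render_zstack(sc, noiseless = TRUE)
  tf <- tempfile(fileext = ".tif")
  write_stack(out$stack, tf)
  back <- read_stack(tf, pixel_size = 1, z_spacing = 1)
  expect_identical(length(back), length(out$stack))
  orig <- out$stack$sections[[3]]
  expect_equal(back$sections[[3]], orig, tolerance = 1) # 16-bit rounding
})
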