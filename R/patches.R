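#' Labeled 50x50 patch set
#'
#' Container for CNN training/validation data: a `50 x 50 x n` array of
#' intensity patches, an integer label per patch indexing `class_names`,
#' and per-patch ground-truth metadata.
#'
#' @param patches numeric array `50 x 50 x n`.
#' @param labels integer vector of length `n` (1-based class indices).
#' @param class_names ordered character vector of class names.
#' @param meta optional tibble of per-patch metadata.
#' @return A `patch_set` object.
#' @export
patch_set <- function(patches, labels, class_names, meta = NULL) {
  stopifnot(length(dim(patches)) == 3, dim(patches)[1] == 50,
            dim(patches)[2] == 50)
  n <- dim(patches)[3]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("patches and labels must have equal length")
  if (any(labels < 1 | labels > length(class_names)))
    stop("every label must index class_names")
  structure(list(patches = patches, labels = labels,
                 class_names = class_names,
                 meta = meta %||% tibble::tibble(.rows = n)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  cat("<patch_set>", dim(x$patches)[3], "patches of 50 x 50:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.patch_set <- function(x) dim(x$patches)[3]

subset_patch_set <- function(set, idx) {
  patch_set(set$patches[, , idx, drop = FALSE], set$labels[idx],
            set$class_names, set$meta[idx, , drop = FALSE])
}

combine_patch_sets <- function(a, b) {
  stopifnot(identical(a$class_names, b$class_names))
  patch_set(array(c(a$patches, b$patches),
                  c(50, 50, length(a) + length(b))),
            c(a$labels, b$labels), a$class_names,
            dplyr::bind_rows(a$meta, b$meta))
}

#' Patch-rendering parameter ranges
#'
#' Ranges used by [generate_training_set()] when rendering single-vesicle
#' section patches. Radii and offsets are in patch pixels (patch geometry
#' is independent of the full-scene calibration); intensities are 16-bit
#' scale.
#'
#' @param sphere_radius_px vesicle sphere radius range (px).
#' @param z_offset_frac section height as a fraction of the sphere radius.
#' @param membrane_level,background_level,interior_frac,domain_level_frac
#'   intensity ranges, as in [scene_params()].
#' @param domain_half_angle_deg cap half-angle range (deg).
#' @param center_jitter_px patch-center offset range (px).
#' @param psf_sigma_px PSF sigma range (px).
#' @param noise_sigma_frac Gaussian noise sigma / membrane level range.
#' @return list of class `patch_params`.
#' @export
patch_params <- function(sphere_radius_px = c(13, 20),
                         z_offset_frac = c(-0.6, 0.6),
                         membrane_level = c(8000, 20000),
                         background_level = c(100, 400),
                         interior_frac = c(0, 0.06),
                         domain_level_frac = c(0.25, 0.25),
                         domain_half_angle_deg = c(30, 150),
                         center_jitter_px = c(-2, 2),
                         psf_sigma_px = c(1, 2),
                         noise_sigma_frac = c(0.02, 0.06)) {
  p <- as.list(environment())
  for (nm in names(p)) {
    rng <- p[[nm]]
    if (length(rng) == 1) rng <- c(rng, rng)
    if (length(rng) != 2 || rng[1] > rng[2])
      stop("invalid range for ", nm, ": min must be <= max")
    p[[nm]] <- rng
  }
  class(p) <- "patch_params"
  p
}

# Render one 50x50 single-vesicle section patch via the 3-D scene renderer
# (pixel units: pixel_size = 1). Extra vesicles model multilamellar
# interiors (concentric) or overlapping neighbors.
render_patch <- function(p, domain = FALSE, extra_interior = 0,
                         overlap = FALSE, hazy = FALSE) {
  R <- runif_range(1, p$sphere_radius_px)
  f <- runif_range(1, p$z_offset_frac)
  if (hazy) f <- sample(c(-1, 1), 1) * runif(1, 0.9, 0.995)
  cx <- 24.5 + runif_range(1, p$center_jitter_px)
  cy <- 24.5 + runif_range(1, p$center_jitter_px)
  mem <- runif_range(1, p$membrane_level)
  bg <- runif_range(1, p$background_level)
  z0 <- 0; z <- f * R
  ves <- tibble::tibble(
    x_um = cx, y_um = cy, z_um = z0, radius_um = R,
    membrane_level = mem,
    interior_level = mem * runif_range(1, p$interior_frac))
  if (extra_interior > 0) {
    for (k in seq_len(extra_interior)) {
      Ri <- R * runif(1, 0.35, 0.75)
      ves <- dplyr::bind_rows(ves, tibble::tibble(
        x_um = cx + runif(1, -2, 2), y_um = cy + runif(1, -2, 2),
        z_um = z0, radius_um = Ri,
        membrane_level = mem * runif(1, 0.6, 1),
        interior_level = mem * runif(1, 0.05, 0.2)))
    }
  }
  if (overlap) {
    rho <- sqrt(max(R^2 - z^2, 0))
    ang <- runif(1, 0, 2 * pi)
    dist <- rho * runif(1, 0.8, 1.4)
    ves <- dplyr::bind_rows(ves, tibble::tibble(
      x_um = cx + dist * cos(ang), y_um = cy + dist * sin(ang),
      z_um = z0 + runif(1, -0.2, 0.2) * R, radius_um = R * runif(1, 0.7, 1.1),
      membrane_level = mem * runif(1, 0.7, 1.2),
      interior_level = 0))
  }
  if (domain) {
    alpha <- runif_range(1, p$domain_half_angle_deg)
    # aim the cap so its boundary crosses the rendered section's ring: the
    # section must show both domain and non-domain membrane (a ring lying
    # entirely inside the cap would be indistinguishable from a uniform
    # one). Ring points sit at angular distance [|t_u - t_r|, min(t_u +
    # t_r, 360 - t_u - t_r)] from the cap axis; both a domain arc and a
    # non-domain arc are visible when alpha lies strictly inside that
    # interval (5 deg guard bands).
    theta_ring <- acos(f) * 180 / pi
    theta <- theta_ring
    for (try in 1:50) {
      cand <- theta_ring + runif(1, -0.8, 0.8) * alpha
      cand <- min(max(cand, 0), 180)
      gmin <- abs(cand - theta_ring)
      gmax <- min(cand + theta_ring, 360 - cand - theta_ring)
      if (gmin <= alpha - 5 && alpha <= gmax - 5) { theta <- cand; break }
    }
    phi <- runif(1, 0, 360)
    ux <- sin(theta * pi / 180) * cos(phi * pi / 180)
    uy <- sin(theta * pi / 180) * sin(phi * pi / 180)
    uz <- cos(theta * pi / 180)
    domains <- tibble::tibble(
      parent = 1L, cap_theta_deg = theta, cap_phi_deg = phi,
      cap_half_angle_deg = alpha,
      center_x_um = cx + R * ux, center_y_um = cy + R * uy,
      center_z_um = z0 + R * uz,
      radius_um = 2 * R * sin(alpha / 2 * pi / 180),
      level = mem * runif_range(1, p$domain_level_frac))
  } else {
    domains <- tibble::tibble(parent = integer(), cap_theta_deg = numeric(),
                              cap_phi_deg = numeric(),
                              cap_half_angle_deg = numeric(),
                              center_x_um = numeric(), center_y_um = numeric(),
                              center_z_um = numeric(), radius_um = numeric(),
                              level = numeric())
  }
  psf <- runif_range(1, p$psf_sigma_px)
  if (hazy) psf <- psf * runif(1, 2.5, 4)
  noise <- mem * runif_range(1, p$noise_sigma_frac)
  if (hazy) { mem_scale <- runif(1, 0.3, 0.5); noise <- noise * 2 } else mem_scale <- 1
  # Render into a wider field than the final 50x50 crop. Background
  # thresholding downstream mimics the pipeline, where the triangle
  # threshold comes from the whole section (dominated by background) and
  # so sits just above the background mode; on a bare 50x50 crop the rim
  # occupies so much of the histogram that the threshold would cut into
  # the membrane signal itself.
  field <- 120
  off <- (field - 50) / 2
  # detector offset stays above the rendered noise floor (see the scene
  # sampler: a zero-clipped noise floor defeats histogram thresholding)
  bg <- max(bg, 2.5 * noise * psf_peak_attenuation(psf))
  scene <- structure(list(
    vesicles = dplyr::mutate(ves,
      x_um = .data$x_um + off, y_um = .data$y_um + off,
      membrane_level = .data$membrane_level * mem_scale,
      interior_level = .data$interior_level * mem_scale),
    domains = dplyr::mutate(domains,
      center_x_um = .data$center_x_um + off,
      center_y_um = .data$center_y_um + off,
      level = .data$level * mem_scale),
    field_of_view = field, pixel_size = 1, z_spacing = 1,
    psf_sigma_px = psf, background_level = bg,
    noise_model = "gaussian", noise_sigma = noise), class = "guv_scene")
  img <- render_section(scene, z)
  # true ring geometry of the primary vesicle at this section, in field
  # coordinates
  rho <- sqrt(max(R^2 - z^2, 0))
  list(img = img, cx_field = cx + off, cy_field = cy + off,
       rho = rho, sphere_r = R,
       meta = tibble::tibble(
         z_offset_frac = f, membrane_level = mem * mem_scale,
         background_level = bg, domain = domain))
}

#' Generate a labeled virtual training set
#'
#' Renders `n_per_class` virtual confocal 50x50 vesicle-section patches per
#' class, automatically annotated from the generating geometry.
#'
#' * `kind = "selection-4class"`: the program-2 vesicle-selection classes --
#'   C1 typical unilamellar vesicles (clean ring), C2 vesicles with internal
#'   membrane structure (concentric shells / bright interior), C3 vesicles
#'   overlapped with other vesicles, C4 hazy or out-of-focus images (near-
#'   pole sections with strong extra blur and low signal-to-noise ratio).
#' * `kind = "state-2class"`: the program-3 phase-state classes -- uniform
#'   shell sections vs. sections whose ring crosses a phase-domain cap.
#'   Background elimination markedly improves this classifier, so each
#'   patch is thresholded (triangle method) with sub-threshold pixels set
#'   to zero; the same preprocessing must be applied at inference (see
#'   [prepare_patch()] with `zero_background = TRUE`).
#'
#' Every patch goes through the same 50x50 conversion the analysis
#' applies to detected circles -- a crop of side `2 * 1.2 * r` around the
#' vesicle, bilinearly resampled -- so training and inference patches
#' share one geometry (ring radius about 21 px in patch coordinates).
#'
#' @param kind `"selection-4class"` or `"state-2class"`.
#' @param n_per_class patches per class (> 0).
#' @param params a [patch_params()] object.
#' @param seed integer seed, or `NULL`.
#' @return A [patch_set()]; `meta` carries the generating geometry.
#' @export
generate_training_set <- function(kind = c("state-2class", "selection-4class"),
                                  n_per_class, params = patch_params(),
                                  seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "patch_params"))
  if (n_per_class <= 0) stop("n_per_class must be > 0")
  with_seed(seed, {
    if (kind == "state-2class") {
      class_names <- c("uniform", "separated")
      gens <- list(function() render_patch(params, domain = FALSE),
                   function() render_patch(params, domain = TRUE))
    } else {
      class_names <- c("C1", "C2", "C3", "C4")
      gens <- list(
        function() render_patch(params),
        function() render_patch(params,
                                extra_interior = sample(1:2, 1)),
        function() render_patch(params, overlap = TRUE),
        function() render_patch(params, hazy = TRUE))
    }
    n_total <- n_per_class * length(class_names)
    patches <- array(0, c(50, 50, n_total))
    labels <- integer(n_total)
    meta <- vector("list", n_total)
    i <- 0
    for (cl in seq_along(class_names)) {
      for (k in seq_len(n_per_class)) {
        i <- i + 1
        rp <- gens[[cl]]()
        img <- rp$img
        # threshold on the full rendered field (the pipeline thresholds
        # whole sections, not patches), then put the patch through the
        # same 50x50 conversion the analysis applies to detections:
        # crop at margin * r around the circle and resample
        if (kind == "state-2class") img <- zero_background(img)
        crop_r <- max(rp$rho, 0.5 * rp$sphere_r, 8)
        patch <- prepare_patch(img, list(cx = rp$cx_field, cy = rp$cy_field,
                                         r = crop_r), margin = 1.2)
        patches[, , i] <- patch
        labels[i] <- cl
        # geometry in resampled patch coordinates
        x0 <- max(0L, as.integer(round(rp$cx_field - 1.2 * crop_r)))
        x1 <- min(119L, as.integer(round(rp$cx_field + 1.2 * crop_r)))
        y0 <- max(0L, as.integer(round(rp$cy_field - 1.2 * crop_r)))
        y1 <- min(119L, as.integer(round(rp$cy_field + 1.2 * crop_r)))
        sx <- 50 / (x1 - x0 + 1); sy <- 50 / (y1 - y0 + 1)
        meta[[i]] <- dplyr::bind_cols(tibble::tibble(
          cx = (rp$cx_field - x0 + 0.5) * sx - 0.5,
          cy = (rp$cy_field - y0 + 0.5) * sy - 0.5,
          r_px = rp$rho * (sx + sy) / 2,
          sphere_r_px = rp$sphere_r), rp$meta)
      }
    }
    patch_set(patches, labels, class_names, dplyr::bind_rows(meta))
  })
}

# triangle-threshold background elimination: sub-threshold pixels to zero
# (intensities above threshold keep their values; this is not binarization)
zero_background <- function(img) {
  if (max(img) <= min(img)) return(img * 0)
  thr <- triangular_threshold(img)
  img[img <= thr] <- 0
  img
}

#' Extract a 50x50 classification patch around a detected circle
#'
#' Crops the square of side `2 * margin * r` centered on the detection
#' (clamped to the image bounds) and resamples it to 50x50 by bilinear
#' interpolation. With `zero_background = TRUE` (used by the phase-state
#' classifier), pixels at or below the triangle threshold of the full
#' section are zeroed before cropping.
#'
#' @param image numeric matrix (section).
#' @param circle list or one-row data frame with `cx`, `cy`, `r` (r >= 1).
#' @param margin crop half-side as a multiple of `r`.
#' @param zero_background eliminate sub-threshold background first.
#' @return 50x50 numeric matrix.
#' @export
prepare_patch <- function(image, circle, margin = 1.2,
                          zero_background = FALSE) {
  if (circle$r < 1) stop("degenerate circle: r must be >= 1 px")
  if (zero_background) image <- zero_background(image)
  H <- nrow(image); W <- ncol(image)
  half <- margin * circle$r
  x0 <- max(0L, as.integer(round(circle$cx - half)))
  x1 <- min(W - 1L, as.integer(round(circle$cx + half)))
  y0 <- max(0L, as.integer(round(circle$cy - half)))
  y1 <- min(H - 1L, as.integer(round(circle$cy + half)))
  crop <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  .cpp_resize_bilinear(crop, 50L, 50L)
}

#' Augment a patch set by scaling and position shifting
#'
#' Each output patch is a randomly scaled (about the patch center) and
#' shifted copy of an input patch, with labels preserved; the output holds
#' `multiplier` copies per input. Both ranges must contain the identity
#' (scale 1, shift 0) so the unaugmented data stays representable; with
#' degenerate identity ranges the inputs are reproduced exactly.
#'
#' @param set a [patch_set()].
#' @param scale_range `c(min, max)` scale factors containing 1.
#' @param shift_range `c(min, max)` shift in px containing 0 (applied
#'   independently in x and y).
#' @param multiplier output copies per input patch.
#' @param fill fill value for out-of-view samples.
#' @param seed integer seed, or `NULL`.
#' @return A [patch_set()] with `multiplier * length(set)` patches.
#' @export
augment <- function(set, scale_range = c(0.9, 1.1), shift_range = c(-3, 3),
                    multiplier = 2, fill = 0, seed = NULL) {
  stopifnot(inherits(set, "patch_set"), multiplier >= 1)
  if (scale_range[1] > 1 || scale_range[2] < 1)
    stop("scale_range must contain the identity scale 1")
  if (shift_range[1] > 0 || shift_range[2] < 0)
    stop("shift_range must contain the identity shift 0")
  n <- length(set)
  with_seed(seed, {
    out <- array(0, c(50, 50, n * multiplier))
    labels <- integer(n * multiplier)
    for (m in seq_len(multiplier)) {
      for (i in seq_len(n)) {
        j <- (m - 1) * n + i
        s <- runif_range(1, scale_range)
        dx <- runif_range(1, shift_range)
        dy <- runif_range(1, shift_range)
        out[, , j] <- if (s == 1 && dx == 0 && dy == 0) {
          set$patches[, , i]
        } else {
          .cpp_scale_shift(set$patches[, , i], s, dx, dy, fill)
        }
        labels[j] <- set$labels[i]
      }
    }
    meta <- dplyr::bind_rows(replicate(multiplier, set$meta,
                                       simplify = FALSE))
    patch_set(out, labels, set$class_names, meta)
  })
}

#' Write a patch set as TIFF files plus a CSV label manifest
#'
#' @param set a [patch_set()].
#' @param dir output directory (created if missing).
#' @param scale intensity mapped to the 16-bit maximum.
#' @return The manifest path, invisibly.
#' @export
write_patch_set <- function(set, dir, scale = 65535) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(set)
  files <- sprintf("patch_%05d.tif", seq_len(n))
  for (i in seq_len(n)) {
    tiff::writeTIFF(pmin(pmax(set$patches[, , i] / scale, 0), 1),
                    file.path(dir, files[i]), bits.per.sample = 16,
                    compression = "none")
  }
  manifest <- file.path(dir, "labels.csv")
  write.csv(tibble::tibble(file = files,
                           label = set$class_names[set$labels]),
            manifest, row.names = FALSE)
  invisible(manifest)
}
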