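# Programmatic fixtures shared across the suite. All geometry uses the
# package's pixel convention: 0-based, x = column, y = row, pixel centers at
# integer coordinates; matrix[y + 1, x + 1].

# 1-px-wide ring of a given level on a constant background
make_ring <- function(size, cx, cy, r, level = 1000, background = 0,
                      interior = background) {
  img <- matrix(background, size, size)
  xs <- matrix(0:(size - 1), size, size, byrow = TRUE)
  ys <- matrix(0:(size - 1), size, size)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  img[d < r - 0.5] <- interior
  img[abs(d - r) <= 0.5] <- level
  img
}

# filled disc
make_disc <- function(size, cx, cy, r, level = 500, background = 0) {
  img <- matrix(background, size, size)
  xs <- matrix(0:(size - 1), size, size, byrow = TRUE)
  ys <- matrix(0:(size - 1), size, size)
  img[sqrt((xs - cx)^2 + (ys - cy)^2) <= r] <- level
  img
}

# ring whose right half (|angle| < 90 deg from +x) has a different level
make_half_ring <- function(size, cx, cy, r, right = 100, left = 10,
                           width = 3, background = 0) {
  img <- matrix(background, size, size)
  xs <- matrix(0:(size - 1), size, size, byrow = TRUE)
  ys <- matrix(0:(size - 1), size, size)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  band <- d > r - width & d <= r
  img[band & (xs - cx) >= 0] <- right
  img[band & (xs - cx) < 0] <- left
  img
}

# single-vesicle scene in pixel units (pixel_size = 1) for renderer tests
pixel_scene <- function(fov, cx, cy, R, z0 = 0, membrane = 10000,
                        interior = 0, background = 100, psf = 2,
                        noise_sigma = 0, domains = NULL) {
  empty_domains <- tibble::tibble(
    parent = integer(), cap_theta_deg = numeric(), cap_phi_deg = numeric(),
    cap_half_angle_deg = numeric(), center_x_um = numeric(),
    center_y_um = numeric(), center_z_um = numeric(), radius_um = numeric(),
    level = numeric())
  structure(list(
    vesicles = tibble::tibble(x_um = cx, y_um = cy, z_um = z0,
                              radius_um = R, membrane_level = membrane,
                              interior_level = interior),
    domains = domains %||% empty_domains,
    field_of_view = fov, pixel_size = 1, z_spacing = 1,
    psf_sigma_px = psf, background_level = background,
    noise_model = if (noise_sigma > 0) "gaussian" else "none",
    noise_sigma = noise_sigma), class = "guv_scene")
}

# spherical-cap domain row for pixel_scene (direction polar/azimuth in deg)
cap_domain <- function(scene_center, R, theta_deg, phi_deg, half_angle_deg,
                       level) {
  u <- c(sin(theta_deg * pi / 180) * cos(phi_deg * pi / 180),
         sin(theta_deg * pi / 180) * sin(phi_deg * pi / 180),
         cos(theta_deg * pi / 180))
  tibble::tibble(
    parent = 1L, cap_theta_deg = theta_deg, cap_phi_deg = phi_deg,
    cap_half_angle_deg = half_angle_deg,
    center_x_um = scene_center[1] + R * u[1],
    center_y_um = scene_center[2] + R * u[2],
    center_z_um = scene_center[3] + R * u[3],
    radius_um = 2 * R * sin(half_angle_deg / 2 * pi / 180),
    level = level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: radius of the brightest ring by radial profile peak
radial_peak_radius <- function(img, cx, cy, rmax) {
  xs <- matrix(0:(ncol(img) - 1), nrow(img), ncol(img), byrow = TRUE)
  ys <- matrix(0:(nrow(img) - 1), nrow(img), ncol(img))
  d <- round(sqrt((xs - cx)^2 + (ys - cy)^2))
  prof <- vapply(0:rmax, function(b) {
    px <- img[d == b]
    if (length(px)) mean(px) else -Inf
  }, numeric(1))
  which.max(prof) - 1
}

# independent oracle: brute-force Hough over a center window and all radii;
# counts edge pixels within 0.5 px of each circle
brute_force_hough <- function(edge_xy, cx_range, cy_range, r_range) {
  best <- c(score = -1, cx = NA, cy = NA, r = NA)
  for (cx in cx_range) for (cy in cy_range) {
    d <- sqrt((edge_xy[, 1] - cx)^2 + (edge_xy[, 2] - cy)^2)
    counts <- tabulate(round(d) + 1L, nbins = max(r_range) + 1L)
    for (r in r_range) {
      sc <- counts[r + 1L]
      if (sc > best["score"]) best <- c(score = sc, cx = cx, cy = cy, r = r)
    }
  }
  best
}

# edge pixels of a binary image (8-neighborhood boundary)
mask_edges <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  inner <- mask[2:(H - 1), 2:(W - 1)]
  nb <- mask[1:(H - 2), 2:(W - 1)] & mask[3:H, 2:(W - 1)] &
    mask[2:(H - 1), 1:(W - 2)] & mask[2:(H - 1), 3:W]
  edge <- inner & !nb
  idx <- which(edge, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1]) # already offset by 1 -> 0-based
}
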