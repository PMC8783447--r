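#' Scene-distribution parameters for the virtual GUV simulator
#'
#' Ranges from which [sample_scene()] draws one ground-truth scene. All
#' ranges are `c(min, max)` (a degenerate range fixes the value). The
#' geometric defaults mirror the typical confocal acquisition the pipeline
#' targets: 1,024 x 1,024 px spanning 127.3 um x 127.3 um with 1 um
#' z-spacing. Intensity levels are on a 16-bit scale; domain membranes
#' render at `domain_level_frac` of the vesicle's membrane level (a dim
#' domain, as for a reporter partitioning away from it), and the Gaussian
#' read+shot noise sigma defaults to 5% of the membrane level.
#'
#' Phase domains are modeled as spherical caps: a cap direction on the
#' vesicle plus a half-angle, internally converted to the equivalent
#' intersecting sphere centered on the shell (radius `2 R sin(alpha/2)`).
#'
#' @param n_vesicles range of vesicle counts.
#' @param radius_um range of vesicle radii (um).
#' @param membrane_level range of membrane intensity levels.
#' @param interior_frac range of interior intensity as a fraction of the
#'   membrane level.
#' @param domain_prob probability that a vesicle carries a phase domain.
#' @param domain_half_angle_deg range of cap half-angles (deg); a cap of
#'   half-angle alpha subtends an arc of 2*alpha on an equatorial section.
#' @param domain_level_frac range of domain membrane intensity as a
#'   fraction of the membrane level.
#' @param z_center_um range of vesicle center z positions (um).
#' @param field_of_view x/y extent (um).
#' @param pixel_size um per px.
#' @param z_spacing um between sections.
#' @param psf_sigma_px in-plane Gaussian PSF sigma (px).
#' @param background_level background intensity.
#' @param noise_sigma_frac Gaussian noise sigma as a fraction of the mean
#'   membrane level.
#' @param noise_model `"gaussian"`, `"poisson"` or `"none"`.
#' @param allow_overlap permit overlapping vesicles (default FALSE:
#'   placement is rejection-sampled to keep vesicles disjoint in x/y).
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_vesicles = c(3, 8),
                         radius_um = c(8, 15),
                         membrane_level = c(8000, 20000),
                         interior_frac = c(0, 0.08),
                         domain_prob = 0.5,
                         domain_half_angle_deg = c(30, 150),
                         domain_level_frac = c(0.25, 0.25),
                         z_center_um = c(-5, 5),
                         field_of_view = 127.3,
                         pixel_size = 127.3 / 1024,
                         z_spacing = 1,
                         psf_sigma_px = 2,
                         background_level = 200,
                         noise_sigma_frac = 0.05,
                         noise_model = "gaussian",
                         allow_overlap = FALSE) {
  p <- list(n_vesicles = n_vesicles, radius_um = radius_um,
            membrane_level = membrane_level, interior_frac = interior_frac,
            domain_prob = domain_prob,
            domain_half_angle_deg = domain_half_angle_deg,
            domain_level_frac = domain_level_frac,
            z_center_um = z_center_um, field_of_view = field_of_view,
            pixel_size = pixel_size, z_spacing = z_spacing,
            psf_sigma_px = psf_sigma_px,
            background_level = background_level,
            noise_sigma_frac = noise_sigma_frac, noise_model = noise_model,
            allow_overlap = allow_overlap)
  for (nm in c("n_vesicles", "radius_um", "membrane_level", "interior_frac",
               "domain_half_angle_deg", "domain_level_frac", "z_center_um")) {
    rng <- p[[nm]]
    if (length(rng) == 1) rng <- c(rng, rng)
    if (length(rng) != 2 || rng[1] > rng[2])
      stop("invalid range for ", nm, ": min must be <= max")
    p[[nm]] <- rng
  }
  if (p$domain_prob < 0 || p$domain_prob > 1)
    stop("domain_prob must be in [0, 1]")
  if (p$pixel_size <= 0 || p$z_spacing <= 0)
    stop("pixel_size and z_spacing must be > 0")
  class(p) <- "scene_params"
  p
}

runif_range <- function(n, rng) {
  if (rng[1] == rng[2]) rep(rng[1], n) else runif(n, rng[1], rng[2])
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample one ground-truth virtual GUV scene
#'
#' Draws vesicle count, positions, radii, intensity levels and (with
#' probability `domain_prob` per vesicle) a phase-domain cap from the
#' parameter ranges. Ground-truth labels (which vesicle is phase separated,
#' and where) are fully determined by the returned scene; rendering is a
#' separate step. The same `params` and `seed` always reproduce the same
#' scene bit for bit.
#'
#' @param params a [scene_params()] object.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A `guv_scene`: list with `vesicles` tibble (`x_um`, `y_um`,
#'   `z_um`, `radius_um`, `membrane_level`, `interior_level`), `domains`
#'   tibble (`parent`, cap geometry, equivalent sphere `center_*_um` /
#'   `radius_um`, `level`), and the render parameters.
#' @export
sample_scene <- function(params = scene_params(), seed = NULL) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(seed, {
    n <- if (params$n_vesicles[1] == params$n_vesicles[2]) {
      as.integer(params$n_vesicles[1])
    } else {
      sample(seq(params$n_vesicles[1], params$n_vesicles[2]), 1)
    }
    fov <- params$field_of_view
    radius <- runif_range(n, params$radius_um)
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      margin <- radius[i] + 1
      ok <- FALSE
      for (try in 1:200) {
        x <- runif(1, margin, fov - margin)
        y <- runif(1, margin, fov - margin)
        if (params$allow_overlap || i == 1 ||
            all(sqrt((x - xs[seq_len(i - 1)])^2 +
                     (y - ys[seq_len(i - 1)])^2) >
                  radius[i] + radius[seq_len(i - 1)] + 2)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place ", n, " non-overlapping vesicles; ",
                    "reduce n_vesicles or radius_um, or allow_overlap")
      xs[i] <- x; ys[i] <- y
    }
    mem <- runif_range(n, params$membrane_level)
    vesicles <- tibble::tibble(
      x_um = xs, y_um = ys,
      z_um = runif_range(n, params$z_center_um),
      radius_um = radius,
      membrane_level = mem,
      interior_level = mem * runif_range(n, params$interior_frac))
    has_domain <- runif(n) < params$domain_prob
    dom_idx <- which(has_domain)
    if (length(dom_idx) > 0) {
      alpha <- runif_range(length(dom_idx), params$domain_half_angle_deg)
      theta <- acos(runif(length(dom_idx), -1, 1)) * 180 / pi # polar, deg
      phi <- runif(length(dom_idx), 0, 360)
      R <- vesicles$radius_um[dom_idx]
      ux <- sin(theta * pi / 180) * cos(phi * pi / 180)
      uy <- sin(theta * pi / 180) * sin(phi * pi / 180)
      uz <- cos(theta * pi / 180)
      domains <- tibble::tibble(
        parent = dom_idx,
        cap_theta_deg = theta, cap_phi_deg = phi, cap_half_angle_deg = alpha,
        center_x_um = vesicles$x_um[dom_idx] + R * ux,
        center_y_um = vesicles$y_um[dom_idx] + R * uy,
        center_z_um = vesicles$z_um[dom_idx] + R * uz,
        radius_um = 2 * R * sin(alpha / 2 * pi / 180),
        level = vesicles$membrane_level[dom_idx] *
          runif_range(length(dom_idx), params$domain_level_frac))
    } else {
      domains <- tibble::tibble(
        parent = integer(), cap_theta_deg = numeric(),
        cap_phi_deg = numeric(), cap_half_angle_deg = numeric(),
        center_x_um = numeric(), center_y_um = numeric(),
        center_z_um = numeric(), radius_um = numeric(), level = numeric())
    }
    noise_sigma <- params$noise_sigma_frac *
      mean(c(params$membrane_level[1], params$membrane_level[2]))
    # keep the detector offset above the rendered noise floor, as an
    # operator does: a zero-clipped noise floor puts a delta spike into the
    # intensity histogram that defeats histogram-based thresholding
    bg <- max(params$background_level,
              2.5 * noise_sigma * psf_peak_attenuation(params$psf_sigma_px))
    structure(list(
      vesicles = vesicles, domains = domains,
      field_of_view = fov, pixel_size = params$pixel_size,
      z_spacing = params$z_spacing, psf_sigma_px = params$psf_sigma_px,
      background_level = bg,
      noise_model = params$noise_model,
      noise_sigma = noise_sigma),
      class = "guv_scene")
  })
}

#' @export
print.guv_scene <- function(x, ...) {
  cat(sprintf("<guv_scene> %d vesicles (%d with domains), %.4g um/px, fov %.4g um\n",
              nrow(x$vesicles), length(unique(x$domains$parent)),
              x$pixel_size, x$field_of_view))
  invisible(x)
}

# Ground-truth raster of one z-section (no PSF, no noise). Fluorescence is
# additive over the detector offset (background_level): every level in the
# scene is the fluorescence contribution above background, so a dim
# membrane remains measurable after background subtraction no matter how
# it compares to the offset. The membrane is a 1-px-wide shell
# cross-section ring of radius sqrt(R^2 - (z - z0)^2), deposited with
# linear anti-aliasing (tent weight 1 - |d - rho|, unit integral across
# the rim) so the brightness per unit arc length is independent of angle:
# a binary |d - rho| <= 0.5 ring aliases with 90-deg periodicity (diagonal
# arcs collect more pixels), which after blur shows up as a spurious
# contour modulation. Ring pixels whose 3-D position falls inside a domain
# sphere contribute the domain level; the interior disc contributes the
# interior level; overlapping vesicles add.
render_ground_truth <- function(scene, z, nx = NULL, ny = NULL) {
  px <- scene$pixel_size
  nx <- nx %||% round(scene$field_of_view / px)
  ny <- ny %||% nx
  out <- matrix(scene$background_level, ny, nx)
  if (nrow(scene$vesicles) == 0) return(out)
  for (i in seq_len(nrow(scene$vesicles))) {
    v <- scene$vesicles[i, ]
    dz <- z - v$z_um
    if (abs(dz) > v$radius_um) next
    rho <- sqrt(max(v$radius_um^2 - dz^2, 0)) # um
    # paint only inside the vesicle's pixel bounding box
    x0 <- max(0L, floor((v$x_um - rho) / px - 1))
    x1 <- min(nx - 1L, ceiling((v$x_um + rho) / px + 1))
    y0 <- max(0L, floor((v$y_um - rho) / px - 1))
    y1 <- min(ny - 1L, ceiling((v$y_um + rho) / px + 1))
    if (x1 < x0 || y1 < y0) next
    bw <- x1 - x0 + 1L; bh <- y1 - y0 + 1L
    xs <- matrix((x0:x1) * px, bh, bw, byrow = TRUE)
    ys <- matrix((y0:y1) * px, bh, bw)
    d <- sqrt((xs - v$x_um)^2 + (ys - v$y_um)^2)
    w <- pmax(0, 1 - abs(d - rho) / px) # anti-aliased rim weight
    ring_level <- matrix(v$membrane_level, bh, bw)
    doms <- scene$domains[scene$domains$parent == i, , drop = FALSE]
    if (nrow(doms) > 0 && any(w > 0)) {
      for (j in seq_len(nrow(doms))) {
        dm <- doms[j, ]
        d3 <- (xs - dm$center_x_um)^2 + (ys - dm$center_y_um)^2 +
          (z - dm$center_z_um)^2
        ring_level[w > 0 & d3 < dm$radius_um^2] <- dm$level
      }
    }
    base <- matrix(0, bh, bw)
    base[d < rho] <- v$interior_level
    contrib <- w * ring_level + (1 - w) * base
    out[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <-
      out[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] + contrib
  }
  out
}

#' Render one z-section of a scene as a virtual confocal image
#'
#' The ground-truth section raster is convolved with an in-plane Gaussian
#' PSF and, unless `noiseless`, noise is added (Gaussian of the scene's
#' sigma, or Poisson shot noise). The Gaussian sigma is interpreted
#' relative to the membrane's observed brightness: convolving the 1-px
#' ground-truth shell with a PSF of sigma `s` attenuates its peak by about
#' `1/(sqrt(2*pi)*s)`, so the nominal noise fraction is scaled by the same
#' factor. A scene declaring noise at 5% of the membrane level therefore
#' renders with a rim signal-to-noise ratio of 20 regardless of the PSF
#' width. With `psf_sigma_px = 0` and `noiseless = TRUE` the ground-truth
#' levels are returned exactly.
#'
#' @param scene a `guv_scene`.
#' @param z section height (um).
#' @param noiseless skip the noise step.
#' @param ground_truth skip both PSF and noise (raw level raster).
#' @return Numeric matrix (rows = y, cols = x).
#' @export
render_section <- function(scene, z, noiseless = FALSE, ground_truth = FALSE) {
  img <- render_ground_truth(scene, z)
  if (ground_truth) return(img)
  if (scene$psf_sigma_px > 0) img <- .cpp_gauss_blur(img, scene$psf_sigma_px)
  if (!noiseless && scene$noise_model != "none") {
    atten <- psf_peak_attenuation(scene$psf_sigma_px)
    if (scene$noise_model == "gaussian") {
      img <- img + matrix(rnorm(length(img), 0, scene$noise_sigma * atten),
                          nrow(img), ncol(img))
    } else if (scene$noise_model == "poisson") {
      img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
    }
    img[img < 0] <- 0
  }
  img
}

# peak attenuation of a 1-px-wide line source under Gaussian blur
psf_peak_attenuation <- function(psf_sigma_px) {
  if (psf_sigma_px <= 0) return(1)
  min(1, 1 / (sqrt(2 * pi) * psf_sigma_px))
}

#' Render a whole z-stack with ground-truth annotations
#'
#' Sections run from one `z_spacing` below the lowest vesicle extent to one
#' above the highest. The annotation table records, per vesicle and
#' section, the true center and ring radius in px and the true phase label:
#' a section is `"separated"` exactly when its ground-truth ring intersects
#' a domain sphere over a nonzero arc.
#'
#' @param scene a `guv_scene`.
#' @param noiseless render without noise.
#' @param seed RNG seed for the noise, or `NULL`.
#' @return list with `stack` (a [guv_stack()]) and `annotations` tibble
#'   (`vesicle_id`, `z_index`, `z_um`, `cx_px`, `cy_px`, `r_px`,
#'   `phase_label`).
#' @export
render_zstack <- function(scene, noiseless = FALSE, seed = NULL) {
  dz <- scene$z_spacing
  if (nrow(scene$vesicles) == 0) {
    zs <- c(-dz, 0, dz)
  } else {
    zlo <- min(scene$vesicles$z_um - scene$vesicles$radius_um) - dz
    zhi <- max(scene$vesicles$z_um + scene$vesicles$radius_um) + dz
    zs <- seq(zlo, zhi + dz / 2, by = dz)
  }
  sections <- with_seed(seed,
    lapply(zs, function(z) render_section(scene, z, noiseless = noiseless)))
  stack <- guv_stack(sections, scene$pixel_size, dz, channel_name = "A",
                     z0 = zs[1])
  ann <- scene_annotations(scene, zs)
  list(stack = stack, annotations = ann)
}

#' Ground-truth annotations of a scene at given section heights
#'
#' @param scene a `guv_scene`.
#' @param zs numeric vector of section z positions (um).
#' @return Annotation tibble as in [render_zstack()].
#' @export
scene_annotations <- function(scene, zs) {
  px <- scene$pixel_size
  rows <- list()
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  for (i in seq_len(nrow(scene$vesicles))) {
    v <- scene$vesicles[i, ]
    doms <- scene$domains[scene$domains$parent == i, , drop = FALSE]
    for (k in seq_along(zs)) {
      dzv <- zs[k] - v$z_um
      if (abs(dzv) > v$radius_um) next
      rho <- sqrt(max(v$radius_um^2 - dzv^2, 0))
      sep <- FALSE
      if (nrow(doms) > 0 && rho > 0) {
        rx <- v$x_um + rho * cos(theta)
        ry <- v$y_um + rho * sin(theta)
        for (j in seq_len(nrow(doms))) {
          dm <- doms[j, ]
          if (any((rx - dm$center_x_um)^2 + (ry - dm$center_y_um)^2 +
                    (zs[k] - dm$center_z_um)^2 < dm$radius_um^2)) {
            sep <- TRUE; break
          }
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        vesicle_id = i, z_index = k - 1L, z_um = zs[k],
        cx_px = v$x_um / px, cy_px = v$y_um / px, r_px = rho / px,
        phase_label = ifelse(sep, "separated", "uniform"))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(vesicle_id = integer(), z_index = integer(),
                          z_um = numeric(), cx_px = numeric(),
                          cy_px = numeric(), r_px = numeric(),
                          phase_label = character()))
  }
  dplyr::bind_rows(rows)
}

#' Write annotations to CSV
#' @param annotations annotation tibble from [render_zstack()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}
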