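#' Contour intensity profile around a detected circle
#'
#' Divides the membrane contour into `N` angular segments and returns the
#' net mean intensity per pixel of each. Segment `k` (0-based) collects the
#' pixels in the annular wedge `r - delta_r < d <= r` (center distance) and
#' angle in `[theta0 + k*360/N, theta0 + (k+1)*360/N)`, angles measured
#' counterclockwise from the +x axis at the circle center. The per-pixel
#' background is subtracted from each segment mean.
#'
#' @param image numeric matrix (section).
#' @param circle list or one-row data frame with `cx`, `cy`, `r`.
#' @param N number of segments (>= 8).
#' @param delta_r annulus depth in px (>= 1).
#' @param background_per_px per-pixel background to subtract.
#' @param theta0 start angle of segment 0, degrees.
#' @return A `contour_profile` object: list with `segment_means`, `N`,
#'   `delta_r`, `theta0`.
#' @export
contour_profile <- function(image, circle, N = 36, delta_r = 3,
                            background_per_px = 0, theta0 = 0) {
  stopifnot(N >= 8, delta_r >= 1)
  cx <- circle$cx; cy <- circle$cy; r <- circle$r
  H <- nrow(image); W <- ncol(image)
  if (cx - r < 0 || cy - r < 0 || cx + r > W - 1 || cy + r > H - 1)
    stop("circle extends outside the image")
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ys <- matrix(0:(H - 1), H, W)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  in_band <- d > r - delta_r & d <= r
  ang <- (atan2(ys - cy, xs - cx) * 180 / pi - theta0) %% 360
  seg <- pmin(floor(ang / (360 / N)), N - 1)
  means <- numeric(N)
  for (k in 0:(N - 1)) {
    px <- image[in_band & seg == k]
    if (length(px) == 0)
      stop("empty contour segment; use smaller N or larger delta_r")
    means[k + 1] <- mean(px) - background_per_px
  }
  structure(list(segment_means = means, N = N, delta_r = delta_r,
                 theta0 = theta0),
            class = "contour_profile")
}

#' @export
print.contour_profile <- function(x, ...) {
  cat(sprintf("<contour_profile> N = %d segments, delta_r = %g px\n",
              x$N, x$delta_r))
  print(summary(x$segment_means))
  invisible(x)
}

segment_means_of <- function(profile) {
  if (inherits(profile, "contour_profile")) profile$segment_means
  else as.numeric(profile)
}

#' High, low and mid contour intensities
#'
#' Segment means are sorted in descending order; the high intensity is the
#' value at rank `ceiling(percentile/100 * N)` from the top, the low
#' intensity the value at the same rank from the bottom, and the mid
#' intensity their average. High and low estimate the fluorescence levels
#' of the two coexisting lipid domains (usable downstream for a partition
#' coefficient); the percentile guards against single-segment outliers.
#'
#' @param profile a [contour_profile()] or numeric vector of segment means.
#' @param percentile rank percentile in (0, 50); default 20.
#' @return A named list: `high`, `low`, `mid`.
#' @export
domain_levels <- function(profile, percentile = 20) {
  stopifnot(percentile > 0, percentile < 50)
  m <- segment_means_of(profile)
  N <- length(m)
  k <- ceiling(percentile / 100 * N)
  s <- sort(m, decreasing = TRUE)
  high <- s[k]
  low <- s[N - k + 1]
  list(high = high, low = low, mid = (high + low) / 2)
}

#' Count contour discontinuities
#'
#' Traverses the segments cyclically in increasing angle with a two-state
#' hysteresis machine: the state becomes HIGH when the trace exceeds
#' `mid * (1 + p/100)` and LOW when it drops below `mid * (1 - p/100)`;
#' each HIGH-to-LOW or LOW-to-HIGH transition counts as one discontinuity.
#' A transition therefore only registers once the trace has swung across
#' the full +/- p% band around the mid intensity, so noise inside the dead
#' band is not double-counted. Traversal starts at the first unambiguous
#' segment; a profile that never leaves the dead band has 0
#' discontinuities. For a closed contour the count is even, and for a
#' vesicle with k domain pairs it equals the number of domain boundaries
#' (2 for a binary two-domain vesicle, 2k for 2k alternating arcs).
#'
#' @param profile a [contour_profile()] or numeric vector.
#' @param mid mid intensity (from [domain_levels()]; must be > 0).
#' @param p band half-width as a percentage of `mid`; match it to the
#'   partition coefficient of the reporter (high-contrast reporters allow a
#'   larger `p`).
#' @return Integer discontinuity count.
#' @export
detect_discontinuities <- function(profile, mid, p = 20) {
  stopifnot(p > 0)
  if (mid <= 0) stop("mid intensity must be > 0 (no dynamic range)")
  m <- segment_means_of(profile)
  hi_thr <- mid * (1 + p / 100)
  lo_thr <- mid * (1 - p / 100)
  state0 <- ifelse(m >= hi_thr, 1L, ifelse(m <= lo_thr, -1L, 0L))
  start <- which(state0 != 0L)[1]
  if (is.na(start)) return(0L)
  n <- length(m)
  idx <- c(seq(start, n), seq_len(start - 1))
  state <- state0[start]
  count <- 0L
  for (i in idx[-1]) {
    if (state0[i] != 0L && state0[i] != state) {
      count <- count + 1L
      state <- state0[i]
    }
  }
  # close the cycle back to the starting segment
  if (state != state0[start]) count <- count + 1L
  count
}

#' Phase state of one section
#'
#' A section is called `"separated"` when its contour shows at least two
#' discontinuities (a single domain has two boundaries); otherwise
#' `"uniform"`.
#'
#' @inheritParams domain_levels
#' @inheritParams detect_discontinuities
#' @return A one-row tibble: `state`, `n_discontinuities`, `high`, `low`,
#'   `mid`.
#' @export
section_state <- function(profile, percentile = 20, p = 20) {
  lev <- domain_levels(profile, percentile)
  nd <- if (lev$mid > 0) detect_discontinuities(profile, lev$mid, p) else 0L
  tibble::tibble(
    state = ifelse(nd >= 2, "separated", "uniform"),
    n_discontinuities = nd,
    high = lev$high, low = lev$low, mid = lev$mid)
}

#' Vesicle-level phase decision from per-section states
#'
#' A vesicle is called phase-separated when at least `decision_fraction`
#' (default 40%, boundary inclusive) of its section images show phase
#' separation.
#'
#' @param states character vector of per-section states (`"uniform"` /
#'   `"separated"`).
#' @param decision_fraction fraction threshold in `[0, 1]`.
#' @return A one-row tibble: `n_sections`, `n_separated`,
#'   `fraction_separated`, `vesicle_state`.
#' @export
vesicle_state <- function(states, decision_fraction = 0.4) {
  stopifnot(length(states) >= 1)
  n <- length(states)
  ns <- sum(states == "separated")
  frac <- ns / n
  tibble::tibble(
    n_sections = n, n_separated = ns, fraction_separated = frac,
    vesicle_state = ifelse(frac >= decision_fraction, "separated", "uniform"))
}

#' Refine a detected circle against the rim ridge
#'
#' The contour statistic samples a narrow annulus on a thin, bright rim, so
#' a sub-pixel center or radius error converts the steep radial profile
#' into a smooth spurious modulation along the contour. This refinement
#' decouples geometry from brightness: along `n_angles` rays from the
#' current center, the radial position of the intensity maximum within
#' `search` px of `r` is located (bilinear sampling at 0.25-px steps), and
#' a least-squares (Kasa) circle is fitted to those ridge points, dropping
#' the 20% worst residuals and refitting once. Because only peak positions
#' enter the fit, a dim phase-domain arc pulls neither the center nor the
#' radius.
#'
#' @param image numeric matrix (section).
#' @param circle list or one-row data frame with `cx`, `cy`, `r`.
#' @param n_angles number of rays.
#' @param search radial search half-width (px).
#' @return list with refined `cx`, `cy`, `r`.
#' @export
refine_circle <- function(image, circle, n_angles = 72, search = 4) {
  H <- nrow(image); W <- ncol(image)
  cx <- circle$cx; cy <- circle$cy; r <- circle$r
  theta <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  rad <- seq(max(1, r - search), r + search, by = 0.25)
  bilinear <- function(x, y) {
    x <- pmin(pmax(x, 0), W - 1); y <- pmin(pmax(y, 0), H - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
    wx <- x - x0; wy <- y - y0
    (1 - wy) * ((1 - wx) * image[cbind(y0 + 1, x0 + 1)] +
                  wx * image[cbind(y0 + 1, x1 + 1)]) +
      wy * ((1 - wx) * image[cbind(y1 + 1, x0 + 1)] +
              wx * image[cbind(y1 + 1, x1 + 1)])
  }
  kasa <- function(px, py) {
    # least-squares circle: minimize |(x-a)^2 + (y-b)^2 - R^2|
    A <- cbind(2 * px, 2 * py, 1)
    b <- px^2 + py^2
    sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    list(cx = sol[1], cy = sol[2],
         r = sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, 0)))
  }
  for (pass in 1:2) {
    px <- numeric(n_angles); py <- numeric(n_angles)
    for (i in seq_along(theta)) {
      xs <- cx + rad * cos(theta[i])
      ys <- cy + rad * sin(theta[i])
      v <- bilinear(xs, ys)
      k <- which.max(v)
      px[i] <- xs[k]; py[i] <- ys[k]
    }
    fit <- kasa(px, py)
    if (is.null(fit)) return(list(cx = cx, cy = cy, r = r))
    resid <- abs(sqrt((px - fit$cx)^2 + (py - fit$cy)^2) - fit$r)
    keep <- resid <= quantile(resid, 0.8)
    fit2 <- kasa(px[keep], py[keep])
    if (!is.null(fit2)) fit <- fit2
    cx <- fit$cx; cy <- fit$cy; r <- fit$r
  }
  list(cx = cx, cy = cy, r = r)
}

#' Contour phase analysis of grouped detections over a stack
#'
#' Runs [contour_profile()] + [section_state()] on every section circle and
#' [vesicle_state()] per entity.
#'
#' @param stack detection-channel [guv_stack()].
#' @param grouped accepted detections tibble with `vesicle_id`.
#' @param N,delta_r,percentile,p,decision_fraction see the per-operation
#'   docs.
#' @param background `"auto"` or numeric per-pixel background.
#' @param refine refine each circle against the rim ridge with
#'   [refine_circle()] before sampling the contour (recommended: the
#'   statistic is sensitive to sub-pixel geometry errors).
#' @return list with `per_section` and `per_vesicle` tibbles.
#' @export
phase_analysis <- function(stack, grouped, N = 36, delta_r = 3,
                           percentile = 20, p = 20, decision_fraction = 0.4,
                           background = "auto", refine = TRUE) {
  bg <- section_backgrounds(stack, background)
  rows <- purrr::pmap(grouped[c("vesicle_id", "z_index", "cx", "cy", "r")],
    function(vesicle_id, z_index, cx, cy, r) {
      img <- stack$sections[[z_index + 1L]]
      circ <- list(cx = cx, cy = cy, r = r)
      if (refine) {
        ref <- refine_circle(img, circ)
        H <- nrow(img); W <- ncol(img)
        if (ref$r >= delta_r + 1 && ref$cx - ref$r >= 0 &&
            ref$cy - ref$r >= 0 && ref$cx + ref$r <= W - 1 &&
            ref$cy + ref$r <= H - 1) {
          circ <- ref
        }
      }
      prof <- contour_profile(img, circ,
                              N = N, delta_r = delta_r,
                              background_per_px = bg[z_index + 1L])
      dplyr::bind_cols(
        tibble::tibble(vesicle_id = vesicle_id, z_index = z_index),
        section_state(prof, percentile, p))
    })
  per_section <- dplyr::bind_rows(rows)
  per_vesicle <- dplyr::reframe(
    dplyr::group_by(per_section, .data$vesicle_id),
    vesicle_state(.data$state, decision_fraction))
  per_vesicle <- dplyr::left_join(
    per_vesicle,
    dplyr::summarise(dplyr::group_by(per_section, .data$vesicle_id),
                     high = mean(.data$high), low = mean(.data$low),
                     .groups = "drop"),
    by = "vesicle_id")
  list(per_section = per_section, per_vesicle = per_vesicle)
}
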