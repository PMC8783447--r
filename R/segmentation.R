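#' Detect candidate vesicle circles with a circular Hough transform
#'
#' Classic two-stage circular Hough transform (CHT). The image (by default
#' the binary mask produced by [triangular_threshold()] +
#' [make_binary_mask()], which greatly improves robustness at low
#' signal-to-noise ratio) is converted to an edge map by Sobel gradient
#' magnitude; each edge pixel votes along both directions of its gradient at
#' every radius in `radius_range`, peaks of the center accumulator become
#' candidate centers, and for each candidate the radius is read off the
#' radial histogram of edge pixels. Each circle is scored by the fraction of
#' its circumference angularly supported by edge pixels (the radius itself
#' is read off the peak of the radial mean-intensity profile, the unbiased
#' rim estimate for a fluorescent shell); circles with score below
#' `1 - sensitivity` are dropped, so raising the sensitivity admits
#' lower-score circles and never removes one. Overlapping candidates are
#' resolved by non-maximum suppression on center distance (within
#' `0.75 * min(radius_range)` the higher score wins), which also suppresses
#' near-duplicates (center distance < 2 px and radius difference < 2 px).
#'
#' @param image numeric matrix (raw intensities) or logical/0-1 matrix
#'   (mask). When `mask = TRUE` (default) and a numeric image is given, the
#'   triangle threshold is applied first.
#' @param radius_range integer vector `c(min, max)` in px; the field default
#'   20--120 px covers typical GUV radii at 100x confocal magnification.
#' @param sensitivity detection sensitivity in (0, 1); a circle is kept
#'   when the edge-supported fraction of its circumference is at least
#'   `1 - sensitivity` (the default 0.5 demands half the rim).
#' @param mask threshold the image to a binary mask before edge extraction.
#' @param edge_frac gradient-magnitude fraction (of the image maximum)
#'   defining edge pixels.
#' @param smooth_sigma Gaussian pre-smoothing (px) applied to numeric
#'   images before thresholding and radial profiling; suppresses noise
#'   speckle in the mask. Set 0 to disable.
#' @param min_component masked connected components smaller than this (px)
#'   are treated as noise speckle and removed before edge extraction; must
#'   stay well below the pixel count of the smallest real rim band.
#' @param min_hole background holes in the mask smaller than this (px) are
#'   filled before edge extraction (patchy bright interiors otherwise
#'   scatter spurious edges); must stay well below the lumen area of the
#'   smallest real vesicle.
#' @param z_index section index recorded in the result (0-based).
#' @param max_peaks maximum number of candidate centers examined.
#'
#' @return A tibble with one row per detection, columns `z_index`, `cx`,
#'   `cy`, `r` (px, sub-pixel, 0-based coordinates) and `score`, sorted by
#'   descending score.
#' @export
detect_circles <- function(image, radius_range = c(20, 120),
                           sensitivity = 0.5, mask = TRUE,
                           edge_frac = 0.1, smooth_sigma = 1.5,
                           min_component = 50L, min_hole = 200L,
                           z_index = 0L, max_peaks = 200L) {
  if (!is.numeric(radius_range) || length(radius_range) != 2 ||
      radius_range[1] < 1 || radius_range[1] > radius_range[2])
    stop("radius_range must be c(min, max) with 1 <= min <= max")
  stopifnot(sensitivity > 0, sensitivity < 1)
  is_mask <- FALSE
  if (is.logical(image)) {
    img <- image * 1.0
    intensity <- img
    is_mask <- TRUE
  } else {
    im <- image
    storage.mode(im) <- "double"
    if (smooth_sigma > 0) im <- .cpp_gauss_blur(im, smooth_sigma)
    intensity <- im
    img <- im
    if (mask) {
      rng <- range(im)
      if (rng[2] > rng[1]) {
        thr <- triangular_threshold(im)
        img <- (im > thr) * 1.0
        is_mask <- TRUE
      }
    }
  }
  det <- .cpp_cht_detect(img, intensity, as.integer(radius_range[1]),
                         as.integer(radius_range[2]), sensitivity,
                         edge_frac, as.integer(max_peaks), is_mask,
                         as.integer(min_component), as.integer(min_hole))
  tibble::tibble(
    z_index = rep(as.integer(z_index), nrow(det)),
    cx = det$cx, cy = det$cy, r = det$r, score = det$score
  )
}

#' Detect circles in every section of a stack
#'
#' Runs [detect_circles()] section by section and binds the results.
#'
#' @param stack a [guv_stack()].
#' @inheritParams detect_circles
#' @param ... further arguments passed to [detect_circles()].
#' @return A tibble of detections with `z_index` set per section.
#' @export
detect_circles_stack <- function(stack, radius_range = c(20, 120),
                                 sensitivity = 0.5, ...) {
  res <- purrr::imap(stack$sections, function(s, i) {
    if (max(s) <= min(s)) {
      return(tibble::tibble(z_index = integer(), cx = numeric(),
                            cy = numeric(), r = numeric(), score = numeric()))
    }
    detect_circles(s, radius_range = radius_range,
                   sensitivity = sensitivity, z_index = i - 1L, ...)
  })
  dplyr::bind_rows(res)
}
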