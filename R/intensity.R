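#' Background-corrected net intensity
#'
#' Net intensity of a region: the raw summed intensity minus the estimated
#' per-pixel background times the number of pixels
#' (`I_net = I_raw - I_background`). Negative results are reported as-is so
#' that condition means stay unbiased.
#'
#' @param raw raw summed intensity over the region.
#' @param background_per_px background intensity per pixel.
#' @param n_px number of pixels in the region (>= 1).
#' @return Net intensity.
#' @export
net_intensity <- function(raw, background_per_px, n_px = 1) {
  stopifnot(all(n_px >= 1))
  raw - background_per_px * n_px
}

#' Membrane-band intensity of one circle in the analysis channel
#'
#' Sums the analysis-channel (channel B) intensity over the membrane band:
#' pixels whose center distance `d` from the circle center satisfies
#' `r - inward_px < d <= r`, i.e. a user-defined number of pixels inward
#' from the detected rim. The background is subtracted per pixel.
#'
#' @param image channel-B section (numeric matrix).
#' @param circle list or one-row data frame with `cx`, `cy`, `r`.
#' @param inward_px band depth in px (>= 1).
#' @param background_per_px per-pixel background (e.g. from
#'   [estimate_background()] on this section).
#' @return A one-row tibble: `total_net`, `per_px_net`, `pixel_count`.
#' @export
membrane_intensity <- function(image, circle, inward_px = 3,
                               background_per_px = 0) {
  stopifnot(inward_px >= 1)
  cx <- circle$cx; cy <- circle$cy; r <- circle$r
  H <- nrow(image); W <- ncol(image)
  if (cx - r < 0 || cy - r < 0 || cx + r > W - 1 || cy + r > H - 1)
    stop("circle extends outside the image")
  d <- pixel_distances(image, cx, cy)
  in_band <- d > r - inward_px & d <= r
  n <- sum(in_band)
  if (n == 0) stop("no pixels in the membrane band; increase inward_px")
  total_net <- net_intensity(sum(image[in_band]), background_per_px, n)
  tibble::tibble(total_net = total_net, per_px_net = total_net / n,
                 pixel_count = n)
}

#' Interior (droplet) intensity of one circle
#'
#' For globular protein droplets the relevant quantity is the net average
#' intensity per pixel over the entire disc inside the detected circle
#' (`d <= r`), not just the periphery.
#'
#' @inheritParams membrane_intensity
#' @return A one-row tibble: `per_px_net`, `pixel_count`.
#' @export
droplet_interior_intensity <- function(image, circle, background_per_px = 0) {
  cx <- circle$cx; cy <- circle$cy; r <- circle$r
  H <- nrow(image); W <- ncol(image)
  if (cx - r < 0 || cy - r < 0 || cx + r > W - 1 || cy + r > H - 1)
    stop("circle extends outside the image")
  d <- pixel_distances(image, cx, cy)
  inside <- d <= r
  n <- sum(inside)
  tibble::tibble(per_px_net = mean(image[inside]) - background_per_px,
                 pixel_count = n)
}

#' Per-vesicle binding analysis over a stack
#'
#' Measures the channel-B membrane intensity for every accepted section
#' circle, with the background estimated per section image, and aggregates
#' to a per-vesicle mean per pixel weighted by each section's pixel count
#' (so the vesicle mean represents the whole spherical shell).
#'
#' @param stackB analysis-channel [guv_stack()].
#' @param grouped accepted detections tibble with `vesicle_id`, `z_index`,
#'   `cx`, `cy`, `r`.
#' @param inward_px membrane band depth (px).
#' @param background `"auto"` (per-section [estimate_background()]) or a
#'   fixed numeric per-pixel value.
#' @return list with `per_section` (tibble: vesicle_id, z_index, total_net,
#'   per_px_net, pixel_count, background_per_px) and `per_vesicle` (tibble:
#'   vesicle_id, vesicle_mean_per_px, n_sections).
#' @export
binding_analysis <- function(stackB, grouped, inward_px = 3,
                             background = "auto") {
  bg <- section_backgrounds(stackB, background)
  rows <- purrr::pmap(grouped[c("vesicle_id", "z_index", "cx", "cy", "r")],
    function(vesicle_id, z_index, cx, cy, r) {
      m <- membrane_intensity(stackB$sections[[z_index + 1L]],
                              list(cx = cx, cy = cy, r = r),
                              inward_px = inward_px,
                              background_per_px = bg[z_index + 1L])
      dplyr::bind_cols(tibble::tibble(vesicle_id = vesicle_id,
                                      z_index = z_index,
                                      background_per_px = bg[z_index + 1L]), m)
    })
  per_section <- dplyr::bind_rows(rows)
  per_vesicle <- dplyr::summarise(
    dplyr::group_by(per_section, .data$vesicle_id),
    vesicle_mean_per_px = sum(.data$per_px_net * .data$pixel_count) /
      sum(.data$pixel_count),
    n_sections = dplyr::n(), .groups = "drop")
  list(per_section = per_section, per_vesicle = per_vesicle)
}

#' Per-droplet interior intensity over a stack
#'
#' @param stack reporter-channel [guv_stack()].
#' @inheritParams binding_analysis
#' @return list with `per_section` and `per_vesicle` tibbles
#'   (pixel-count-weighted droplet means).
#' @export
droplet_analysis <- function(stack, grouped, background = "auto") {
  bg <- section_backgrounds(stack, background)
  rows <- purrr::pmap(grouped[c("vesicle_id", "z_index", "cx", "cy", "r")],
    function(vesicle_id, z_index, cx, cy, r) {
      m <- droplet_interior_intensity(stack$sections[[z_index + 1L]],
                                      list(cx = cx, cy = cy, r = r),
                                      background_per_px = bg[z_index + 1L])
      dplyr::bind_cols(tibble::tibble(vesicle_id = vesicle_id,
                                      z_index = z_index,
                                      background_per_px = bg[z_index + 1L]), m)
    })
  per_section <- dplyr::bind_rows(rows)
  per_vesicle <- dplyr::summarise(
    dplyr::group_by(per_section, .data$vesicle_id),
    vesicle_mean_per_px = sum(.data$per_px_net * .data$pixel_count) /
      sum(.data$pixel_count),
    n_sections = dplyr::n(), .groups = "drop")
  list(per_section = per_section, per_vesicle = per_vesicle)
}

section_backgrounds <- function(stack, background) {
  if (identical(background, "auto")) {
    vapply(stack$sections, estimate_background, numeric(1))
  } else {
    rep(as.numeric(background), length(stack$sections))
  }
}

#' Summarize per-vesicle intensities across stacks and conditions
#'
#' Per-stack means are computed first (equal weight per vesicle within a
#' stack), then conditions are summarized by the mean of per-stack means
#' with the standard deviation between stacks (n - 1 denominator) as the
#' error estimate. With a single stack in a condition the SD is reported as
#' `NA`.
#'
#' @param results tibble with columns `condition`, `stack_id` and
#'   `vesicle_mean_per_px` (one row per vesicle).
#' @return A tibble: `condition`, `mean_per_px`, `sd_between_stacks`,
#'   `n_stacks`, `n_vesicles`.
#' @export
condition_summary <- function(results) {
  stopifnot(nrow(results) >= 1)
  per_stack <- dplyr::summarise(
    dplyr::group_by(results, .data$condition, .data$stack_id),
    stack_mean = mean(.data$vesicle_mean_per_px),
    n_vesicles = dplyr::n(), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_stack, .data$condition),
    mean_per_px = mean(.data$stack_mean),
    sd_between_stacks = if (dplyr::n() > 1) sd(.data$stack_mean) else NA_real_,
    n_stacks = dplyr::n(),
    n_vesicles = sum(.data$n_vesicles), .groups = "drop")
}
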