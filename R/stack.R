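#' Image stack container
#'
#' A `guv_stack` holds one fluorescence channel's z-stack: an ordered list of
#' 2-D intensity matrices (ascending z) plus the physical calibration needed
#' to convert between pixels and micrometers.
#'
#' @param sections list of numeric matrices, all of one shape, ascending z.
#' @param pixel_size pixel size in um/px (> 0).
#' @param z_spacing spacing between consecutive sections in um (> 0).
#' @param channel_name channel label, e.g. `"A"` (detection) or `"B"`
#'   (analysis).
#' @param z0 z position (um) of the first section.
#'
#' @return An object of class `guv_stack`.
#' @export
guv_stack <- function(sections, pixel_size, z_spacing, channel_name = "A",
                      z0 = 0) {
  stopifnot(is.list(sections), length(sections) >= 1)
  dims <- vapply(sections, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop("all sections must share one shape")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(z_spacing) || z_spacing <= 0) stop("z_spacing must be > 0")
  structure(
    list(sections = sections, pixel_size = pixel_size, z_spacing = z_spacing,
         channel_name = channel_name, z0 = z0),
    class = "guv_stack"
  )
}

#' @export
print.guv_stack <- function(x, ...) {
  d <- dim(x$sections[[1]])
  cat(sprintf(
    "<guv_stack> channel %s: %d sections of %d x %d px, %.4g um/px, dz %.3g um\n",
    x$channel_name, length(x$sections), d[1], d[2], x$pixel_size, x$z_spacing))
  invisible(x)
}

#' @export
length.guv_stack <- function(x) length(x$sections)

#' z position (um) of each section of a stack
#' @param stack a [guv_stack()].
#' @return numeric vector of z positions.
#' @export
stack_z <- function(stack) {
  stack$z0 + (seq_along(stack$sections) - 1) * stack$z_spacing
}

#' Read a z-stack from a multi-page TIFF file
#'
#' Multi-channel files are de-interleaved according to `n_channels` and
#' `interleave`: `"z-major"` means all sections of channel 1 come first
#' (page order z1c1, z2c1, ..., z1c2, ...), `"channel-major"` means channels
#' cycle fastest (z1c1, z1c2, z2c1, ...). The dialect must be declared
#' explicitly; there is no safe way to guess it from the file.
#'
#' @param path TIFF file path.
#' @param pixel_size,z_spacing physical calibration (um/px, um).
#' @param n_channels number of interleaved channels in the file.
#' @param channel which channel to extract (1-based).
#' @param interleave `"channel-major"` or `"z-major"`.
#' @param channel_name label for the returned stack.
#' @param scale multiply the [0, 1] values returned by the TIFF reader by
#'   this factor (default 65535 recovers 16-bit counts).
#'
#' @return A [guv_stack()].
#' @export
read_stack <- function(path, pixel_size, z_spacing, n_channels = 1,
                       channel = 1, interleave = c("channel-major", "z-major"),
                       channel_name = NULL, scale = 65535) {
  interleave <- match.arg(interleave)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * scale
  })
  n <- length(pages)
  if (n %% n_channels != 0)
    stop("page count ", n, " is not a multiple of n_channels = ", n_channels)
  nz <- n %/% n_channels
  idx <- if (interleave == "channel-major") {
    seq(channel, n, by = n_channels)
  } else {
    seq((channel - 1) * nz + 1, length.out = nz)
  }
  guv_stack(pages[idx], pixel_size, z_spacing,
            channel_name = channel_name %||% as.character(channel))
}

#' Write a z-stack to a 16-bit multi-page TIFF file
#'
#' Intensities are clipped to `[0, scale]` and stored as 16-bit samples.
#'
#' @param stack a [guv_stack()].
#' @param path output file path.
#' @param scale intensity that maps to the maximum 16-bit value.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale = 65535) {
  pages <- lapply(stack$sections, function(s) {
    pmin(pmax(s / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
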