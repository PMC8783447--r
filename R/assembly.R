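#' Edge-contrast selection filter for one detected circle
#'
#' Computational vesicle-selection filter (program 1). Compares the mean
#' intensity per pixel in the membrane band -- the annulus of pixels at
#' center distance `d` with `r - band_px < d <= r` -- against the mean over
#' the interior disc (`d <= r - band_px`). A well-formed unilamellar vesicle
#' shows a bright rim and a dark lumen; a circle passes when
#' `edge / interior >= min_ratio`. Circles with too much interior
#' fluorescence (e.g. multilamellar vesicles) or too little rim signal fail.
#' An interior mean of exactly 0 with a positive edge mean passes (infinite
#' contrast). Circles whose bounding box leaves the image fail with reason
#' `"edge-touching"`.
#'
#' @param image numeric matrix (the detection-channel section).
#' @param circle list or one-row data frame with `cx`, `cy`, `r` (px,
#'   0-based).
#' @param band_px width of the membrane band in px (>= 1).
#' @param min_ratio minimum edge/interior intensity ratio.
#' @return A one-row tibble: `pass`, `reason`, `edge_mean`, `interior_mean`.
#' @export
edge_contrast_filter <- function(image, circle, band_px = 3, min_ratio = 1.5) {
  stopifnot(band_px >= 1)
  cx <- circle$cx; cy <- circle$cy; r <- circle$r
  H <- nrow(image); W <- ncol(image)
  if (cx - r < 0 || cy - r < 0 || cx + r > W - 1 || cy + r > H - 1) {
    return(tibble::tibble(pass = FALSE, reason = "edge-touching",
                          edge_mean = NA_real_, interior_mean = NA_real_))
  }
  d <- pixel_distances(image, cx, cy)
  edge_px <- image[d > r - band_px & d <= r]
  int_px <- image[d <= r - band_px]
  edge_mean <- if (length(edge_px)) mean(edge_px) else NA_real_
  interior_mean <- if (length(int_px)) mean(int_px) else 0
  pass <- !is.na(edge_mean) &&
    (interior_mean == 0 && edge_mean > 0 ||
       interior_mean > 0 && edge_mean / interior_mean >= min_ratio)
  tibble::tibble(pass = pass,
                 reason = if (pass) NA_character_ else "low-edge-contrast",
                 edge_mean = edge_mean, interior_mean = interior_mean)
}

# matrix of distances from pixel centers to (cx, cy); 0-based convention
pixel_distances <- function(image, cx, cy) {
  H <- nrow(image); W <- ncol(image)
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ys <- matrix(0:(H - 1), H, W)
  sqrt((xs - cx)^2 + (ys - cy)^2)
}

#' Apply the edge-contrast filter to a whole detection table
#'
#' @param stack a [guv_stack()] (detection channel).
#' @param detections tibble from [detect_circles_stack()].
#' @inheritParams edge_contrast_filter
#' @return `detections` with `pass`, `reason`, `edge_mean`, `interior_mean`
#'   columns appended.
#' @export
edge_contrast_filter_stack <- function(stack, detections, band_px = 3,
                                       min_ratio = 1.5) {
  res <- purrr::pmap(detections[c("z_index", "cx", "cy", "r")],
    function(z_index, cx, cy, r) {
      edge_contrast_filter(stack$sections[[z_index + 1L]],
                           list(cx = cx, cy = cy, r = r),
                           band_px = band_px, min_ratio = min_ratio)
    })
  dplyr::bind_cols(detections, dplyr::bind_rows(res))
}

#' Group per-section circle detections into 3-D vesicle entities
#'
#' Circles are linked across sections by center proximity: walking the
#' sections in ascending z, each circle joins the entity whose most recent
#' section center is nearest and within `center_tolerance`; otherwise it
#' seeds a new entity. Within one section the circle--entity assignment is
#' made greedily by ascending center distance (each entity takes at most one
#' circle per section), which makes the grouping independent of the order of
#' detections within a section. Every detection ends up in exactly one
#' entity.
#'
#' @param detections tibble with `z_index`, `cx`, `cy`, `r` (and any other
#'   columns, which are preserved).
#' @param center_tolerance maximum center distance (px) to join an entity;
#'   the default 10 px is well below the minimum vesicle radius so adjacent
#'   vesicles do not merge.
#' @return `detections` with an integer `vesicle_id` column, sorted by
#'   `vesicle_id` then `z_index`.
#' @export
group_circles <- function(detections, center_tolerance = 10) {
  n <- nrow(detections)
  if (n == 0)
    return(dplyr::mutate(detections, vesicle_id = integer()))
  det <- detections
  det$.row <- seq_len(n)
  ids <- integer(n)
  last_cx <- numeric(0); last_cy <- numeric(0) # per entity
  for (z in sort(unique(det$z_index))) {
    rows <- det[det$z_index == z, , drop = FALSE]
    # deterministic candidate order: all (circle, entity) pairs by distance
    taken_circle <- rep(FALSE, nrow(rows))
    taken_entity <- rep(FALSE, length(last_cx))
    if (length(last_cx) > 0) {
      dmat <- outer(rows$cx, last_cx, "-")^2 + outer(rows$cy, last_cy, "-")^2
      dmat <- sqrt(dmat)
      cand <- which(dmat <= center_tolerance, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(dmat[cand], cand[, 1], cand[, 2])
        for (k in ord) {
          ci <- cand[k, 1]; ei <- cand[k, 2]
          if (taken_circle[ci] || taken_entity[ei]) next
          taken_circle[ci] <- TRUE; taken_entity[ei] <- TRUE
          ids[rows$.row[ci]] <- ei
          last_cx[ei] <- rows$cx[ci]; last_cy[ei] <- rows$cy[ci]
        }
      }
    }
    # unmatched circles seed new entities, in deterministic spatial order
    left <- which(!taken_circle)
    left <- left[order(rows$cy[left], rows$cx[left])]
    for (ci in left) {
      last_cx <- c(last_cx, rows$cx[ci]); last_cy <- c(last_cy, rows$cy[ci])
      ids[rows$.row[ci]] <- length(last_cx)
    }
  }
  det$vesicle_id <- ids
  det$.row <- NULL
  dplyr::arrange(det, .data$vesicle_id, .data$z_index)
}

#' Entity summary table
#'
#' @param grouped detections tibble with a `vesicle_id` column (from
#'   [group_circles()]).
#' @return One row per entity: `vesicle_id`, `n_sections`, `z_min`, `z_max`,
#'   `mean_r_px`, mean center.
#' @export
entity_table <- function(grouped) {
  dplyr::summarise(
    dplyr::group_by(grouped, .data$vesicle_id),
    n_sections = dplyr::n(),
    z_min = min(.data$z_index), z_max = max(.data$z_index),
    mean_r_px = mean(.data$r),
    mean_cx = mean(.data$cx), mean_cy = mean(.data$cy),
    .groups = "drop"
  )
}

#' Reject entities with too few sections
#'
#' A 3-D vesicle reconstructed from only one or two sections does not carry
#' enough information to be treated as an intact GUV, so entities with fewer
#' than `min_sections` sections are rejected.
#'
#' @param grouped detections tibble with `vesicle_id`.
#' @param min_sections minimum number of sections for acceptance (default 3,
#'   i.e. one- and two-section entities are rejected).
#' @return Entity table ([entity_table()]) with `status` (`"accepted"` /
#'   `"rejected"`) and `reason` columns.
#' @export
filter_min_sections <- function(grouped, min_sections = 3) {
  stopifnot(min_sections >= 1)
  ent <- entity_table(grouped)
  dplyr::mutate(ent,
    status = ifelse(.data$n_sections >= min_sections, "accepted", "rejected"),
    reason = ifelse(.data$n_sections >= min_sections, NA_character_,
                    "too-few-sections"))
}

#' Reject entities touching the image edge
#'
#' An entity is rejected if any of its section circles' bounding square
#' exits the image (`cx - r < 0`, `cy - r < 0`, `cx + r > W - 1` or
#' `cy + r > H - 1` with 0-based pixel centers).
#'
#' @param grouped detections tibble with `vesicle_id`.
#' @param image_shape `c(height, width)` in px.
#' @return One row per entity: `vesicle_id`, `edge_touching`.
#' @export
exclude_edge_entities <- function(grouped, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  dplyr::summarise(
    dplyr::group_by(grouped, .data$vesicle_id),
    edge_touching = any(.data$cx - .data$r < 0 | .data$cy - .data$r < 0 |
                          .data$cx + .data$r > W - 1 |
                          .data$cy + .data$r > H - 1),
    .groups = "drop"
  )
}

#' Assemble and select vesicle entities from a detection table
#'
#' Convenience wrapper chaining [group_circles()], [filter_min_sections()]
#' and [exclude_edge_entities()]; the two-stage selection applied after
#' per-circle filtering.
#'
#' @param detections tibble of per-section detections (already
#'   circle-filtered).
#' @param image_shape `c(height, width)` px.
#' @param center_tolerance grouping tolerance (px).
#' @param min_sections minimum sections per accepted entity.
#' @return list with `sections` (grouped detections) and `entities` (entity
#'   table with `status`, `reason`, `edge_touching`).
#' @export
assemble_entities <- function(detections, image_shape, center_tolerance = 10,
                              min_sections = 3) {
  grouped <- group_circles(detections, center_tolerance)
  ent <- filter_min_sections(grouped, min_sections)
  edge <- exclude_edge_entities(grouped, image_shape)
  ent <- dplyr::left_join(ent, edge, by = "vesicle_id")
  ent <- dplyr::mutate(ent,
    reason = ifelse(.data$edge_touching & .data$status == "accepted",
                    "edge-touching", .data$reason),
    status = ifelse(.data$edge_touching, "rejected", .data$status))
  list(sections = grouped, entities = ent)
}
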