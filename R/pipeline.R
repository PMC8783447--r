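#' Analysis configuration
#'
#' One versioned record of every user parameter of the three analysis
#' programs. Any run report embeds the fully resolved configuration, so
#' results are reproducible from the report alone.
#'
#' @param radius_range_px circle radius search range (px); 20--120 px
#'   covers typical GUV radii at the target magnification.
#' @param cht_sensitivity Hough sensitivity in (0, 1) (see
#'   [detect_circles()]).
#' @param mask apply triangle-threshold masking before the Hough transform
#'   (recommended at low signal-to-noise ratio).
#' @param edge_frac Sobel edge threshold as a fraction of the maximum
#'   gradient.
#' @param center_tolerance_px grouping tolerance across sections (px).
#' @param min_sections minimum sections per accepted entity.
#' @param band_px edge-contrast band width (px).
#' @param min_edge_ratio edge/interior ratio to pass the contrast filter.
#' @param inward_px membrane intensity band depth (px).
#' @param contour_N contour segments per circle.
#' @param contour_delta_r contour annulus depth (px).
#' @param percentile high/low rank percentile of the contour histogram.
#' @param p discontinuity band half-width (% of mid intensity).
#' @param decision_fraction separated-section fraction for a separated
#'   vesicle.
#' @param cnn_margin patch crop margin (multiple of r).
#' @param background `"auto"` or a numeric per-pixel value.
#' @param selection_model,state_model optional paths to saved classifiers.
#' @param seed integer seed recorded with the run.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(radius_range_px = c(20, 120),
                            cht_sensitivity = 0.5,
                            mask = TRUE,
                            edge_frac = 0.1,
                            center_tolerance_px = 10,
                            min_sections = 3,
                            band_px = 3,
                            min_edge_ratio = 1.5,
                            inward_px = 3,
                            contour_N = 36,
                            contour_delta_r = 3,
                            percentile = 20,
                            p = 20,
                            decision_fraction = 0.4,
                            cnn_margin = 1.2,
                            background = "auto",
                            selection_model = NULL,
                            state_model = NULL,
                            seed = NULL) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file path.
#' @param config an [analysis_config()].
#' @return For `read_config`, an `analysis_config` (unknown fields are
#'   rejected); for `write_config`, `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# shared front end: detect circles in every section of channel A and apply
# the per-circle selection filter (computational or CNN)
segment_and_select <- function(stackA, config, classifier = NULL) {
  det <- detect_circles_stack(stackA,
                              radius_range = config$radius_range_px,
                              sensitivity = config$cht_sensitivity,
                              mask = config$mask,
                              edge_frac = config$edge_frac)
  if (nrow(det) == 0) return(det)
  if (is.null(classifier)) {
    det <- edge_contrast_filter_stack(stackA, det,
                                      band_px = config$band_px,
                                      min_ratio = config$min_edge_ratio)
  } else {
    det <- cnn_selection_filter(stackA, det, classifier,
                                margin = config$cnn_margin)
  }
  det
}

finish_report <- function(program, mode, config, det, assembled, result,
                          out_dir = NULL) {
  report <- structure(list(
    program = program, mode = mode,
    config = config,
    package_version = as.character(utils::packageVersion("guvstack")),
    detections = det,
    sections = assembled$sections,
    entities = assembled$entities,
    per_section = result$per_section,
    per_vesicle = result$per_vesicle), class = "guv_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

empty_report <- function(program, mode, config, out_dir = NULL) {
  warning("no circles detected; returning an empty report")
  finish_report(program, mode, config,
                det = tibble::tibble(z_index = integer(), cx = numeric(),
                                     cy = numeric(), r = numeric(),
                                     score = numeric()),
                assembled = list(sections = tibble::tibble(),
                                 entities = tibble::tibble()),
                result = list(per_section = tibble::tibble(),
                              per_vesicle = tibble::tibble()),
                out_dir = out_dir)
}

run_mode_analysis <- function(mode, stacks, accepted_sections, config) {
  if (mode == "binding") {
    if (is.null(stacks$B)) stop("binding analysis needs an analysis channel B")
    binding_analysis(stacks$B, accepted_sections,
                     inward_px = config$inward_px,
                     background = config$background)
  } else if (mode == "droplet") {
    ch <- stacks$B %||% stacks$A
    droplet_analysis(ch, accepted_sections, background = config$background)
  } else {
    phase_analysis(stacks$A, accepted_sections,
                   N = config$contour_N, delta_r = config$contour_delta_r,
                   percentile = config$percentile, p = config$p,
                   decision_fraction = config$decision_fraction,
                   background = config$background)
  }
}

#' Program 1: fully computational z-stack analysis
#'
#' Per section of the detection channel: triangle-threshold masking,
#' circular Hough segmentation and the edge-contrast selection filter;
#' passing circles are grouped into 3-D entities, entities with too few
#' sections or touching the image edge are rejected, and the accepted
#' sections feed the chosen analysis: membrane `binding` intensity in
#' channel B, `droplet` interior intensity, or contour `phase`-state
#' determination.
#'
#' @param stacks list with detection channel `A` (a [guv_stack()]) and
#'   optionally analysis channel `B`.
#' @param config an [analysis_config()].
#' @param mode `"binding"`, `"droplet"` or `"phase"`.
#' @param out_dir optional directory; when given, CSV reports, overlays and
#'   a YAML run manifest are written there.
#' @return A `guv_report`: list with `detections`, `sections` (grouped,
#'   with selection columns), `entities` (with status), `per_section`,
#'   `per_vesicle`, and the resolved `config`.
#' @export
run_program1 <- function(stacks, config = analysis_config(),
                         mode = c("phase", "binding", "droplet"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(stacks$A, "guv_stack"))
  det <- segment_and_select(stacks$A, config)
  if (nrow(det) == 0) return(empty_report(1L, mode, config, out_dir))
  shape <- dim(stacks$A$sections[[1]])
  assembled <- assemble_entities(det[det$pass, , drop = FALSE], shape,
                                 center_tolerance = config$center_tolerance_px,
                                 min_sections = config$min_sections)
  acc_ids <- assembled$entities$vesicle_id[assembled$entities$status == "accepted"]
  acc <- assembled$sections[assembled$sections$vesicle_id %in% acc_ids, ,
                            drop = FALSE]
  result <- if (nrow(acc) > 0) {
    run_mode_analysis(mode, stacks, acc, config)
  } else {
    list(per_section = tibble::tibble(), per_vesicle = tibble::tibble())
  }
  finish_report(1L, mode, config, det, assembled, result, out_dir)
}

#' Program 2: CNN vesicle selection, computational analysis
#'
#' As [run_program1()], with the edge-contrast filter replaced by the
#' 4-class CNN selection filter: only sections classified C1 (typical
#' unilamellar vesicle) proceed to grouping; phase decisions are still made
#' by contour computation.
#'
#' @inheritParams run_program1
#' @param selection_model a 4-class `guv_cnn`, or a path to one saved with
#'   [save_cnn()] (falls back to `config$selection_model`).
#' @return A `guv_report`; `sections` carries the per-section class and
#'   class probability.
#' @export
run_program2 <- function(stacks, config = analysis_config(),
                         selection_model = NULL,
                         mode = c("phase", "binding", "droplet"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(stacks$A, "guv_stack"))
  sel <- resolve_model(selection_model %||% config$selection_model,
                       "selection")
  det <- segment_and_select(stacks$A, config, classifier = sel)
  if (nrow(det) == 0) return(empty_report(2L, mode, config, out_dir))
  shape <- dim(stacks$A$sections[[1]])
  assembled <- assemble_entities(det[det$pass, , drop = FALSE], shape,
                                 center_tolerance = config$center_tolerance_px,
                                 min_sections = config$min_sections)
  acc_ids <- assembled$entities$vesicle_id[assembled$entities$status == "accepted"]
  acc <- assembled$sections[assembled$sections$vesicle_id %in% acc_ids, ,
                            drop = FALSE]
  result <- if (nrow(acc) > 0) {
    run_mode_analysis(mode, stacks, acc, config)
  } else {
    list(per_section = tibble::tibble(), per_vesicle = tibble::tibble())
  }
  finish_report(2L, mode, config, det, assembled, result, out_dir)
}

#' Program 3: CNN vesicle selection and CNN phase-state decision
#'
#' CNN selection as in [run_program2()]; the per-section phase state is
#' then decided by the 2-class state CNN on background-thresholded 50x50
#' patches, and the vesicle decision follows the same fraction rule as the
#' contour method. The report schema matches program 1's phase mode, plus
#' per-section class probabilities.
#'
#' @inheritParams run_program2
#' @param state_model a 2-class `guv_cnn` or a checkpoint path (falls back
#'   to `config$state_model`).
#' @return A `guv_report`.
#' @export
run_program3 <- function(stacks, config = analysis_config(),
                         selection_model = NULL, state_model = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(stacks$A, "guv_stack"))
  sel <- resolve_model(selection_model %||% config$selection_model,
                       "selection")
  sta <- resolve_model(state_model %||% config$state_model, "state")
  det <- segment_and_select(stacks$A, config, classifier = sel)
  if (nrow(det) == 0) return(empty_report(3L, "phase", config, out_dir))
  shape <- dim(stacks$A$sections[[1]])
  assembled <- assemble_entities(det[det$pass, , drop = FALSE], shape,
                                 center_tolerance = config$center_tolerance_px,
                                 min_sections = config$min_sections)
  acc_ids <- assembled$entities$vesicle_id[assembled$entities$status == "accepted"]
  acc <- assembled$sections[assembled$sections$vesicle_id %in% acc_ids, ,
                            drop = FALSE]
  result <- if (nrow(acc) > 0) {
    cnn_phase_analysis(stacks$A, acc, sta, margin = config$cnn_margin,
                       decision_fraction = config$decision_fraction)
  } else {
    list(per_section = tibble::tibble(), per_vesicle = tibble::tibble())
  }
  finish_report(3L, "phase", config, det, assembled, result, out_dir)
}

resolve_model <- function(model, kind) {
  if (is.null(model))
    stop("no ", kind, " model given; train one with train_cnn() or set the ",
         "path in the config")
  if (is.character(model)) {
    if (!file.exists(model))
      stop("model checkpoint not found: ", model)
    model <- load_cnn(model)
  }
  stopifnot(inherits(model, "guv_cnn"))
  model
}

#' CNN phase-state analysis of grouped detections
#'
#' Per-section 2-class classification on background-thresholded patches,
#' then the fraction rule per vesicle.
#'
#' @param stack detection-channel [guv_stack()].
#' @param grouped accepted detections tibble with `vesicle_id`.
#' @param classifier a 2-class `guv_cnn` trained on background-thresholded
#'   patches (label order: uniform, separated).
#' @param margin patch margin.
#' @param decision_fraction fraction rule threshold.
#' @return list with `per_section` and `per_vesicle` tibbles.
#' @export
cnn_phase_analysis <- function(stack, grouped, classifier, margin = 1.2,
                               decision_fraction = 0.4) {
  if (length(classifier$class_names) != 2)
    stop("state classifier must have 2 classes")
  X <- array(0, c(50, 50, nrow(grouped)))
  for (i in seq_len(nrow(grouped))) {
    X[, , i] <- prepare_patch(stack$sections[[grouped$z_index[i] + 1L]],
                              grouped[i, ], margin = margin,
                              zero_background = TRUE)
  }
  res <- classify(classifier, X)
  sep_name <- classifier$class_names[2]
  per_section <- dplyr::bind_cols(
    grouped[c("vesicle_id", "z_index")],
    tibble::tibble(state = ifelse(res$class == sep_name, "separated",
                                  "uniform")),
    res[setdiff(names(res), "class")])
  per_vesicle <- dplyr::reframe(
    dplyr::group_by(per_section, .data$vesicle_id),
    vesicle_state(.data$state, decision_fraction))
  list(per_section = per_section, per_vesicle = per_vesicle)
}

#' @export
print.guv_report <- function(x, ...) {
  cat(sprintf("<guv_report> program %d, mode %s: %d detections, %d entities (%d accepted)\n",
              x$program, x$mode, nrow(x$detections), nrow(x$entities),
              if (nrow(x$entities)) sum(x$entities$status == "accepted") else 0L))
  invisible(x)
}

#' Tidy a run report
#' @param x a `guv_report`.
#' @param ... unused.
#' @return The per-vesicle result tibble joined with entity status.
#' @method tidy guv_report
#' @export
tidy.guv_report <- function(x, ...) {
  if (nrow(x$per_vesicle) == 0) return(x$per_vesicle)
  dplyr::left_join(x$per_vesicle,
                   x$entities[c("vesicle_id", "n_sections", "mean_r_px",
                                "status")],
                   by = "vesicle_id",
                   suffix = c("", ".entity"))
}

#' One-row summary of a run report
#' @param x a `guv_report`.
#' @param ... unused.
#' @return tibble with detection/entity counts and, in phase mode, the
#'   separated fraction.
#' @method glance guv_report
#' @export
glance.guv_report <- function(x, ...) {
  tibble::tibble(
    program = x$program, mode = x$mode,
    n_detections = nrow(x$detections),
    n_entities = nrow(x$entities),
    n_accepted = if (nrow(x$entities)) sum(x$entities$status == "accepted") else 0L,
    n_separated = if (x$mode == "phase" && nrow(x$per_vesicle))
      sum(x$per_vesicle$vesicle_state == "separated") else NA_integer_)
}

#' Write a run report to a directory
#'
#' CSV tables (`entities.csv`, `sections.csv`, `per_section.csv`,
#' `per_vesicle.csv`), color-coded PNG overlays per section, and a YAML
#' manifest embedding the resolved configuration and package version.
#'
#' @param report a `guv_report`.
#' @param dir output directory (created if needed).
#' @param stack optional detection-channel [guv_stack()] for the overlays
#'   (skipped when absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, stack = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("entities", "sections", "per_section", "per_vesicle")) {
    write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  cfg <- unclass(report$config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(list(program = report$program, mode = report$mode,
                        package_version = report$package_version,
                        config = cfg),
                   file.path(dir, "manifest.yaml"))
  if (!is.null(stack)) write_overlays(stack, report, dir)
  invisible(dir)
}

# Fig.-style color conventions
overlay_palette <- list(
  uniform = c(0, 0.4, 1),       # blue
  separated = c(1, 0.9, 0),     # yellow
  C1 = c(0, 1, 1),              # cyan
  C2 = c(0, 1, 0),              # green
  C3 = c(0, 0.3, 1),            # blue
  C4 = c(1, 0, 1),              # magenta
  edge = c(1, 0, 0),            # red
  rejected = c(1, 0, 0))

#' Write color-coded overlay PNGs
#'
#' Draws every detection on its grayscale section. Coloring: in phase mode
#' accepted vesicles are circled blue (uniform) or yellow (separated); with
#' CNN selection, classes C1--C4 are cyan/green/blue/magenta; entities at
#' the image edge are red.
#'
#' @param stack detection-channel [guv_stack()].
#' @param report a `guv_report`.
#' @param dir output directory.
#' @return file paths, invisibly.
#' @export
write_overlays <- function(stack, report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  secs <- report$sections
  if (nrow(secs) == 0) return(invisible(character()))
  ent <- report$entities
  edge_ids <- ent$vesicle_id[!is.na(ent$reason) & ent$reason == "edge-touching"]
  states <- if (nrow(report$per_vesicle) > 0 && "vesicle_state" %in%
                names(report$per_vesicle)) {
    setNames(report$per_vesicle$vesicle_state, report$per_vesicle$vesicle_id)
  } else NULL
  paths <- character(0)
  for (zi in sort(unique(secs$z_index))) {
    img <- stack$sections[[zi + 1L]]
    g <- img - min(img)
    if (max(g) > 0) g <- g / max(g)
    rgb <- array(rep(g, 3), c(dim(g), 3))
    rows <- secs[secs$z_index == zi, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      row <- rows[i, ]
      col <- if (row$vesicle_id %in% edge_ids) {
        overlay_palette$edge
      } else if ("class" %in% names(rows)) {
        overlay_palette[[row$class]] %||% overlay_palette$rejected
      } else if (!is.null(states) && !is.na(states[as.character(row$vesicle_id)])) {
        overlay_palette[[unname(states[as.character(row$vesicle_id)])]]
      } else {
        overlay_palette$uniform
      }
      rgb <- draw_circle_rgb(rgb, row$cx, row$cy, row$r, col)
    }
    path <- file.path(dir, sprintf("overlay_z%03d.png", zi))
    png::writePNG(rgb, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

draw_circle_rgb <- function(rgb, cx, cy, r, col) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  theta <- seq(0, 2 * pi, length.out = max(32, ceiling(2 * pi * r)))
  xs <- round(cx + r * cos(theta)); ys <- round(cy + r * sin(theta))
  keep <- xs >= 0 & xs < W & ys >= 0 & ys < H
  for (k in 1:3) {
    rgb[cbind(ys[keep] + 1, xs[keep] + 1, k)] <- col[k]
  }
  rgb
}
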