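test_that("edge-contrast filter: annulus and disc means equal enumeration", {
  img <- matrix(runif(120 * 120, 0, 100), 120, 120)
  circle <- list(cx = 60.4, cy = 58.7, r = 22.3)
  res <- edge_contrast_filter(img, circle, band_px = 4, min_ratio = 1.5)

  xs <- matrix(0:119, 120, 120, byrow = TRUE)
  ys <- matrix(0:119, 120, 120)
  d <- sqrt((xs - circle$cx)^2 + (ys - circle$cy)^2)
  expect_equal(res$edge_mean, mean(img[d > circle$r - 4 & d <= circle$r]))
  expect_equal(res$interior_mean, mean(img[d <= circle$r - 4]))
})

test_that("edge-contrast filter separates rings from filled discs", {
  ring <- make_ring(100, 50, 50, 30, level = 1000, background = 1e-6)
  expect_true(edge_contrast_filter(ring, list(cx = 50, cy = 50, r = 30),
                                   band_px = 3, min_ratio = 2)$pass)
  disc <- make_disc(100, 50, 50, 30, level = 500)
  res <- edge_contrast_filter(disc, list(cx = 50, cy = 50, r = 30),
                              band_px = 3, min_ratio = 2)
  expect_false(res$pass) # multilamellar-like: edge/interior ratio 1 < 2
  off <- edge_contrast_filter(ring, list(cx = 5, cy = 5, r = 30))
  expect_false(off$pass)
  expect_identical(off$reason, "edge-touching")
})

test_that("well-separated circle tracks group into distinct entities", {
  det <- dplyr::bind_rows(
    tibble::tibble(z_index = 0:5, cx = 100, cy = 100, r = 30, score = 1),
    tibble::tibble(z_index = 0:4, cx = 300, cy = 300, r = 25, score = 1))
  g <- group_circles(det, center_tolerance = 10)
  expect_identical(length(unique(g$vesicle_id)), 2L)
  counts <- sort(table(g$vesicle_id))
  expect_identical(as.integer(counts), c(5L, 6L))

  one <- group_circles(tibble::tibble(z_index = 3L, cx = 10, cy = 10,
                                      r = 5, score = 1), 10)
  expect_identical(one$vesicle_id, 1L)
})

test_that("grouping of jittered tracks matches a transitive-closure oracle", {
  set.seed(19)
  centers <- cbind(x = runif(7, 50, 950), y = runif(7, 50, 950))
  rows <- list()
  for (v in 1:7) {
    nz <- sample(5:9, 1)
    for (z in seq_len(nz) - 1) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        z_index = z,
        cx = centers[v, "x"] + runif(1, -3, 3),
        cy = centers[v, "y"] + runif(1, -3, 3),
        r = 30, score = 1)
    }
  }
  det <- dplyr::bind_rows(rows)
  det <- det[sample(nrow(det)), ] # order must not matter
  g <- group_circles(det, center_tolerance = 10)
  expect_identical(length(unique(g$vesicle_id)), 7L)

  # oracle: connected components of the adjacency graph where two
  # detections connect when their centers lie within tolerance
  n <- nrow(det)
  adj <- as.matrix(dist(det[, c("cx", "cy")])) <= 10
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) new[i] <- min(comp[adj[i, ]])
    if (identical(new, comp)) break
    comp <- new
  }
  expect_identical(length(unique(comp)), 7L)
  # grouping refines the oracle's partition identically here
  key_impl <- split(seq_len(n), g$vesicle_id[match(
    paste(det$cx, det$cy), paste(g$cx, g$cy))])
  expect_identical(length(key_impl), 7L)
})

test_that("every detection lands in exactly one entity", {
  set.seed(23)
  det <- tibble::tibble(z_index = sample(0:8, 60, TRUE),
                        cx = runif(60, 0, 500), cy = runif(60, 0, 500),
                        r = 25, score = 1)
  g <- group_circles(det, center_tolerance = 15)
  expect_identical(nrow(g), nrow(det))
  expect_identical(sort(paste(g$z_index, g$cx, g$cy)),
                   sort(paste(det$z_index, det$cx, det$cy)))
  expect_false(any(is.na(g$vesicle_id)))
})

test_that("permuting detections within a section leaves entities unchanged", {
  set.seed(29)
  det <- dplyr::bind_rows(lapply(1:4, function(v) {
    tibble::tibble(z_index = 0:6,
                   cx = 100 * v + runif(7, -2, 2),
                   cy = 100 * v + runif(7, -2, 2), r = 20, score = 1)
  }))
  g1 <- group_circles(det, 10)
  det2 <- det[order(det$z_index, -det$cx), ]
  g2 <- group_circles(det2, 10)
  sig <- function(g) sort(vapply(split(paste(g$z_index, round(g$cx, 6)),
                                       g$vesicle_id),
                                 function(s) paste(sort(s), collapse = ";"),
                                 character(1)))
  expect_identical(sig(g1), sig(g2))
})

test_that("entities with one or two sections are rejected, three accepted", {
  det <- dplyr::bind_rows(lapply(1:10, function(v) {
    tibble::tibble(z_index = seq_len(v) - 1, cx = 100 * v, cy = 50,
                   r = 20, score = 1)
  }))
  g <- group_circles(det, 10)
  ent <- filter_min_sections(g, min_sections = 3)
  expect_identical(sum(ent$status == "accepted"), 8L)
  expect_identical(ent$status[ent$n_sections == 2], "rejected")
  expect_identical(ent$status[ent$n_sections == 3], "accepted")
  expect_identical(unique(ent$reason[ent$status == "rejected"]),
                   "too-few-sections")
})

test_that("edge exclusion equals the explicit bounding-box inequalities", {
  g <- tibble::tibble(z_index = 0L, vesicle_id = 1:2,
                      cx = c(5, 512), cy = c(5, 512), r = c(30, 120),
                      score = 1)
  res <- exclude_edge_entities(g, c(1024, 1024))
  expect_true(res$edge_touching[res$vesicle_id == 1])
  expect_false(res$edge_touching[res$vesicle_id == 2])

  set.seed(31)
  rand <- tibble::tibble(z_index = 0L, vesicle_id = 1:50,
                         cx = runif(50, 0, 300), cy = runif(50, 0, 300),
                         r = runif(50, 5, 80), score = 1)
  res <- exclude_edge_entities(rand, c(300, 300))
  oracle <- rand$cx - rand$r < 0 | rand$cy - rand$r < 0 |
    rand$cx + rand$r > 299 | rand$cy + rand$r > 299
  expect_identical(res$edge_touching[order(res$vesicle_id)], oracle)
})

test_that("assemble_entities applies both stack-level filters", {
  det <- dplyr::bind_rows(
    tibble::tibble(z_index = 0:5, cx = 200, cy = 200, r = 30, score = 1),
    tibble::tibble(z_index = 0:5, cx = 15, cy = 200, r = 30, score = 1),
    tibble::tibble(z_index = 0:1, cx = 380, cy = 380, r = 25, score = 1))
  out <- assemble_entities(det, c(450, 450))
  expect_identical(nrow(out$entities), 3L)
  expect_identical(sum(out$entities$status == "accepted"), 1L)
  expect_setequal(out$entities$reason[out$entities$status == "rejected"],
                  c("edge-touching", "too-few-sections"))
})
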