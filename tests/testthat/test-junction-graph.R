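test_that("label validation accepts uniform rasters and names broken labels", {
  expect_s3_class(validate_labels(matrix(1L, 8, 8)), "label_image")
  split5 <- matrix(1L, 8, 8)
  split5[2, 2] <- 5L
  split5[7, 7] <- 5L
  expect_error(validate_labels(split5), "label 5")
  expect_error(validate_labels(matrix(0L, 8, 8)), "background")
})

test_that("a vertical two-cell split gives one junction and no vertices", {
  g <- extract_junction_graph(two_cell_vertical())
  expect_identical(nrow(g$junctions), 1L)
  expect_identical(nrow(g$vertices), 0L)
  expect_identical(g$adjacency$cell_a, 1L)
  expect_identical(g$adjacency$cell_b, 2L)
  expect_equal(g$junctions$theta_deg, 90)
})

test_that("four quadrants give four junctions and one four-cell vertex", {
  g <- extract_junction_graph(quadrant_image())
  expect_identical(nrow(g$junctions), 4L)
  expect_identical(nrow(g$vertices), 1L)
  expect_identical(g$vertices$n_cells, 4L)
  expect_identical(g$vertex_cells[[1]], 1:4)
  # arm orientations: the two vertical arms at 90, the two horizontal at 0
  th <- sort(round(g$junctions$theta_deg))
  expect_identical(th, c(0, 0, 90, 90))
})

test_that("a single-cell image yields an empty graph", {
  g <- extract_junction_graph(matrix(1L, 10, 10))
  expect_identical(nrow(g$junctions), 0L)
  expect_identical(nrow(g$vertices), 0L)
})

test_that("orientation follows the total-least-squares axis", {
  expect_equal(junction_orientation(cbind(5, 1:10)), 0)
  expect_equal(junction_orientation(cbind(1:10, 5)), 90)
  expect_equal(junction_orientation(cbind(1:10, 1:10)), 45)
  # ML = rows convention swaps the reference axis
  expect_equal(junction_orientation(cbind(5, 1:10), ml_axis = "row"), 90)
  # degenerate sets are flagged with NA, not an arbitrary angle
  expect_true(is.na(junction_orientation(cbind(3, 3))))
  expect_true(is.na(junction_orientation(rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)))))
})

test_that("every boundary pixel belongs to exactly one junction or vertex", {
  ts <- small_tessellation(rng_seed = 13L, rosette_count = 1L)
  g <- extract_junction_graph(ts$label)
  jpx <- unlist(g$junction_pixels)
  vpx <- unlist(g$vertex_pixels)
  expect_identical(anyDuplicated(c(jpx, vpx)), 0L)
  # recompute the boundary set independently: pixels with a differing
  # 8-neighbour
  m <- ts$label$raster
  H <- nrow(m); W <- ncol(m)
  boundary <- matrix(FALSE, H, W)
  for (r in 1:H) {
    for (cc in 1:W) {
      nb <- m[max(1, r - 1):min(H, r + 1), max(1, cc - 1):min(W, cc + 1)]
      if (length(unique(as.integer(nb))) >= 2L) boundary[r, cc] <- TRUE
    }
  }
  expect_setequal(c(jpx, vpx), which(boundary))
})

test_that("the graph is invariant under label permutation", {
  ts <- small_tessellation(rng_seed = 17L)
  g1 <- extract_junction_graph(ts$label)
  labs <- sort(unique(as.integer(ts$label$raster)))
  set.seed(1)
  perm <- sample(labs)
  relabelled <- matrix(perm[ts$label$raster], nrow(ts$label$raster))
  g2 <- extract_junction_graph(relabelled)
  expect_identical(nrow(g1$junctions), nrow(g2$junctions))
  expect_identical(nrow(g1$vertices), nrow(g2$vertices))
  # junction pixel sets and orientations must match junction-for-junction
  # once identities are mapped through the permutation
  key1 <- vapply(g1$junction_pixels, function(px) paste(sort(px), collapse = ","), "")
  key2 <- vapply(g2$junction_pixels, function(px) paste(sort(px), collapse = ","), "")
  m <- match(key1, key2)
  expect_false(anyNA(m))
  expect_equal(g1$junctions$theta_deg, g2$junctions$theta_deg[m])
  expect_identical(
    cbind(pmin(perm[g1$junctions$cell_a], perm[g1$junctions$cell_b]),
          pmax(perm[g1$junctions$cell_a], perm[g1$junctions$cell_b])),
    cbind(g2$junctions$cell_a[m], g2$junctions$cell_b[m])
  )
})

test_that("rotating the raster by 90 degrees shifts orientations by 90", {
  ts <- small_tessellation(rng_seed = 19L)
  g1 <- extract_junction_graph(ts$label)
  rot <- t(ts$label$raster[nrow(ts$label$raster):1, ]) # 90 deg clockwise
  g2 <- extract_junction_graph(rot)
  key <- function(g) paste(g$junctions$cell_a, g$junctions$cell_b, g$junctions$length_px)
  m <- match(key(g1), key(g2))
  ok <- !is.na(m) & !g1$junctions$degenerate & !duplicated(key(g1))
  expect_gt(sum(ok), 50L)
  d <- abs((g1$junctions$theta_deg[ok] + 90) %% 180 - g2$junctions$theta_deg[m[ok]])
  expect_lt(max(pmin(d, 180 - d)), 1e-8)
})

test_that("extracted orientations agree with seed-geometry ground truth", {
  for (s in c(701L, 702L, 703L)) {
    ts <- generate_tessellation(tessellation_params(
      image_height = 160L, image_width = 160L, n_rows = 9L, n_cols = 9L,
      rng_seed = s
    ))
    g <- extract_junction_graph(ts$label, validate = FALSE)
    key <- paste(ts$truth$junctions$cell_a, ts$truth$junctions$cell_b)
    m <- match(paste(g$junctions$cell_a, g$junctions$cell_b), key)
    ok <- !is.na(m) & !g$junctions$degenerate & g$junctions$length_px >= 8L
    d <- abs(g$junctions$theta_deg[ok] - ts$truth$junctions$theta_deg[m[ok]])
    expect_lt(max(pmin(d, 180 - d)), 10)
  }
})
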