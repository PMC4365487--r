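test_that("four quadrants form one cluster of coordination 4", {
  q <- quadrant_image()
  for (f in list(coordination_numbers, coordination_oracle)) {
    cm <- f(q, 2)
    expect_identical(nrow(cm$clusters), 1L)
    expect_identical(cm$clusters$coordination, 4L)
    expect_identical(cm$cluster_cells[[1]], 1:4)
    expect_identical(cm$cells$coordination, rep(4L, 4))
  }
})

test_that("a bicellular image has no clusters and coordination 2", {
  for (k in c(2, 3)) {
    cm <- coordination_numbers(two_cell_vertical(), k)
    expect_identical(nrow(cm$clusters), 0L)
    expect_identical(cm$cells$coordination, c(2L, 2L))
  }
  cm1 <- coordination_oracle(matrix(1L, 20, 20), 2)
  expect_identical(nrow(cm1$clusters), 0L)
})

test_that("expansion and oracle agree on random tessellations", {
  for (s in 1:6) {
    ts <- generate_tessellation(tessellation_params(
      image_height = 64L, image_width = 64L, n_rows = 5L, n_cols = 5L,
      rosette_count = s %% 2L, rosette_cellularity = 5L, rng_seed = 60L + s
    ))
    for (k in c(2, 3)) {
      a <- coordination_numbers(ts$label, k, validate = FALSE)
      b <- coordination_oracle(ts$label, k)
      expect_identical(a$cells, b$cells)
      expect_identical(a$clusters, b$clusters)
    }
  }
})

test_that("chebyshev expansion also matches its oracle", {
  ts <- generate_tessellation(tessellation_params(
    image_height = 64L, image_width = 64L, n_rows = 5L, n_cols = 5L,
    rng_seed = 77L
  ))
  a <- coordination_numbers(ts$label, 2, metric = "chebyshev", validate = FALSE)
  b <- coordination_oracle(ts$label, 2, metric = "chebyshev")
  expect_identical(a$cells, b$cells)
  expect_identical(a$clusters, b$clusters)
})

test_that("coordination grows monotonically from k = 2 to k = 3", {
  for (s in c(81L, 82L)) {
    ts <- generate_tessellation(tessellation_params(
      image_height = 100L, image_width = 100L, n_rows = 6L, n_cols = 6L,
      rosette_count = 1L, rosette_cellularity = 6L, rng_seed = s
    ))
    c2 <- coordination_numbers(ts$label, 2, validate = FALSE)
    c3 <- coordination_numbers(ts$label, 3, validate = FALSE)
    expect_true(all(c3$cells$coordination >= c2$cells$coordination))
    # every k=2 cluster is swallowed by a k=3 cluster of >= its cellularity
    for (i in seq_len(nrow(c2$clusters))) {
      grown <- vapply(
        c3$cluster_cells,
        function(cc) all(c2$cluster_cells[[i]] %in% cc),
        logical(1)
      )
      expect_true(any(grown))
    }
  }
})

test_that("coordination maps are invariant to relabeling, rotation and reflection", {
  ts <- generate_tessellation(tessellation_params(
    image_height = 80L, image_width = 80L, n_rows = 5L, n_cols = 5L,
    rng_seed = 91L
  ))
  m <- ts$label$raster
  base <- coordination_numbers(m, 2, validate = FALSE)
  # label permutation
  labs <- sort(unique(as.integer(m)))
  set.seed(2)
  perm <- sample(labs)
  cp <- coordination_numbers(matrix(perm[m], nrow(m)), 2, validate = FALSE)
  expect_identical(
    cp$cells$coordination[match(perm[base$cells$cell], cp$cells$cell)],
    base$cells$coordination
  )
  # 90 degree rotation and row reflection leave per-cell coordination unchanged
  for (tr in list(t(m[nrow(m):1, ]), m[nrow(m):1, ])) {
    ct <- coordination_numbers(tr, 2, validate = FALSE)
    expect_identical(ct$cells$coordination, base$cells$coordination)
  }
})

test_that("every junction-graph vertex seeds a cluster of at least its degree", {
  ts <- small_tessellation(rng_seed = 97L, rosette_count = 1L)
  g <- extract_junction_graph(ts$label)
  cm <- coordination_numbers(ts$label, 2, validate = FALSE)
  for (i in seq_len(nrow(g$vertices))) {
    inc <- g$vertex_cells[[i]]
    holds <- vapply(cm$cluster_cells, function(cc) all(inc %in% cc), logical(1))
    expect_true(any(holds))
  }
})

test_that("histogram percentages are exact and sum to 100", {
  map <- structure(
    list(cells = data.frame(cell = 1:4, coordination = c(3L, 3L, 4L, 4L))),
    class = "coordination_map"
  )
  h <- coordination_histogram(map)
  expect_equal(sum(h$percent), 100)
  expect_equal(h$percent[h$coordination == "3"], 50)
  expect_equal(h$percent[h$coordination == "4"], 50)
  all3 <- structure(
    list(cells = data.frame(cell = 1:5, coordination = rep(3L, 5))),
    class = "coordination_map"
  )
  h3 <- coordination_histogram(all3)
  expect_equal(h3$percent[h3$coordination == "3"], 100)
  # open top bin absorbs high coordination numbers
  hi <- structure(
    list(cells = data.frame(cell = 1:2, coordination = c(11L, 12L))),
    class = "coordination_map"
  )
  expect_equal(coordination_histogram(hi)$percent[9], 100)
})

test_that("apical areas average interior cells and flag border crop", {
  lab <- matrix(5L, 20, 20)
  lab[5:14, 3:12] <- 1L
  lab[5:14, 13:19] <- 2L
  # cells 1 (10x10) and 2 (10x7, touches no frame? col 19 < 20 so interior)
  st <- apical_area_stats(lab)
  expect_identical(st$border_excluded, 1L) # the surrounding cell 5
  expect_identical(sort(st$cells$area_px[!st$cells$border_cell]), c(70L, 100L))
  expect_equal(st$mean, 85)
  expect_error(apical_area_stats(matrix(1L, 8, 8)), "border")
  # pixel size scales areas quadratically
  st2 <- apical_area_stats(label_image(lab, pixel_size = 2))
  expect_equal(st2$mean, 4 * st$mean)
})

test_that("colour coding paints each cell with its coordination number", {
  q <- quadrant_image()
  cm <- coordination_numbers(q, 2)
  expect_identical(color_code_clusters(q, cm), matrix(4L, 16, 16))
  tc <- two_cell_vertical()
  expect_identical(
    color_code_clusters(tc, coordination_numbers(tc, 2)),
    matrix(2L, 12, 12)
  )
})
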