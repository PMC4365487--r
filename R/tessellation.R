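#' Parameters of the synthetic epithelium tessellation
#'
#' The synthetic tissue stands in for a segmented apical surface of the
#' neural plate: a confluent, watertight mosaic of cells obtained as the
#' rasterised nearest-seed (Voronoi) partition of a jittered rectangular
#' seed lattice. Rosettes — groups of >= 4 cells meeting at one point — are
#' injected by replacing a lattice seed with `rosette_cellularity` seeds on a
#' tight circle, which guarantees those cells share a common vertex region.
#'
#' `area_scale` multiplies the mean cell area (the seed count is kept fixed
#' and the canvas is scaled by `sqrt(area_scale)`), emulating the enlarged
#' apical surfaces of apical-constriction mutants.
#'
#' @param image_height,image_width canvas size in pixels (>= 32).
#' @param n_rows,n_cols seed-lattice dimensions (product >= 4).
#' @param jitter_sd Gaussian displacement (pixels) applied to each lattice
#'   seed. 0 gives a perfectly rectangular grid, whose four-fold corner
#'   vertices are degenerate; use a positive jitter for generic tissue.
#' @param area_scale dimensionless multiplier on mean cell area.
#' @param rosette_count number of injected rosettes.
#' @param rosette_cellularity cells per injected rosette, in [4, 12].
#' @param rosette_radius radius (pixels) of the seed circle of an injected
#'   rosette (default 3).
#' @param rng_seed integer seed; identical params + seed give bit-identical
#'   output.
#' @return a `tessellation_params` list.
#' @export
tessellation_params <- function(image_height = 200L, image_width = 200L,
                                n_rows = 10L, n_cols = 10L,
                                jitter_sd = 0.75, area_scale = 1,
                                rosette_count = 0L, rosette_cellularity = 6L,
                                rosette_radius = 3, rng_seed = 1L) {
  stopifnot_scalar(image_height, "image_height", 32)
  stopifnot_scalar(image_width, "image_width", 32)
  stopifnot_scalar(n_rows, "n_rows", 1)
  stopifnot_scalar(n_cols, "n_cols", 1)
  if (n_rows * n_cols < 4) stop("n_rows * n_cols must be >= 4")
  stopifnot_scalar(jitter_sd, "jitter_sd", 0)
  stopifnot_scalar(area_scale, "area_scale", lower = 1e-6)
  stopifnot_scalar(rosette_count, "rosette_count", 0)
  if (rosette_count > 0) {
    stopifnot_scalar(rosette_cellularity, "rosette_cellularity", 4, 12)
  }
  structure(
    list(
      image_height = as.integer(image_height), image_width = as.integer(image_width),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      jitter_sd = jitter_sd, area_scale = area_scale,
      rosette_count = as.integer(rosette_count),
      rosette_cellularity = as.integer(rosette_cellularity),
      rosette_radius = rosette_radius, rng_seed = as.integer(rng_seed)
    ),
    class = "tessellation_params"
  )
}

# Rasterising a Voronoi partition can pinch a thin wedge (rosette cells)
# into disconnected islands. Repair deterministically: each label keeps its
# largest 4-connected component; every minor island is handed to the
# neighbouring label with the longest shared border, iterating until all
# labels are 4-connected. The raster stays watertight throughout.
repair_connectivity <- function(raster) {
  dim_ <- dim(raster)
  H <- dim_[1L]
  for (pass in seq_len(10L)) {
    clean <- TRUE
    for (lab in sort(unique(as.integer(raster)))) {
      if (lab <= 0L) next
      idx <- which(raster == lab)
      comp <- uf_components(idx, dim_, connectivity = 4L)
      if (max(comp) == 1L) next
      clean <- FALSE
      sizes <- tabulate(comp)
      keep <- which.max(sizes)
      for (k in seq_len(max(comp))) {
        if (k == keep) next
        px <- idx[comp == k]
        nb <- integer(0)
        for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          r <- ((px - 1L) %% H) + 1L + off[1L]
          cc <- ((px - 1L) %/% H) + 1L + off[2L]
          ok <- r >= 1L & r <= dim_[1L] & cc >= 1L & cc <= dim_[2L]
          nb <- c(nb, raster[r[ok] + (cc[ok] - 1L) * H])
        }
        nb <- nb[nb > 0L & nb != lab]
        if (length(nb) == 0L) next
        raster[px] <- as.integer(names(which.max(table(nb))))
      }
    }
    if (clean) break
  }
  raster
}

#' Generate a synthetic watertight tessellation with ground truth
#'
#' Rasterises the nearest-seed partition of the jittered seed set described
#' by `params`. Every pixel receives a positive cell identity (watertight, no
#' background band); the number of cells equals the number of seeds. The
#' returned ground truth records per-cell areas, per-junction orientations
#' derived from seed geometry (a Voronoi edge is perpendicular to its seed
#' displacement), and the membership of every injected rosette.
#'
#' Rosette centres are drawn on interior lattice positions at least two
#' lattice spacings apart; placement is retried up to 10 times and failure is
#' an explicit error, never a silent omission.
#'
#' @param params a [tessellation_params()] object.
#' @return list with elements `label` (a [label_image()]), `truth` (list of
#'   data frames `cells`, `junctions`, `rosettes`) and `params`.
#' @export
generate_tessellation <- function(params) {
  stopifnot(inherits(params, "tessellation_params"))
  with_seed(params$rng_seed, {
    H <- max(32L, as.integer(round(params$image_height * sqrt(params$area_scale))))
    W <- max(32L, as.integer(round(params$image_width * sqrt(params$area_scale))))
    sy <- H / params$n_rows
    sx <- W / params$n_cols
    grid_r <- (rep(seq_len(params$n_rows), times = params$n_cols) - 0.5) * sy
    grid_c <- (rep(seq_len(params$n_cols), each = params$n_rows) - 0.5) * sx

    rosette_of <- integer(0)
    if (params$rosette_count > 0L) {
      interior <- which(
        grid_r > sy & grid_r < H - sy & grid_c > sx & grid_c < W - sx
      )
      if (length(interior) < params$rosette_count) {
        stop(sprintf(
          "failed to place %d rosettes: only %d interior lattice sites",
          params$rosette_count, length(interior)
        ))
      }
      min_sep <- 2 * max(sy, sx)
      centres <- integer(0)
      ok <- FALSE
      for (attempt in seq_len(10L)) {
        cand <- interior[sample.int(length(interior), params$rosette_count)]
        if (params$rosette_count == 1L ||
          min(stats::dist(cbind(grid_r[cand], grid_c[cand]))) >= min_sep) {
          centres <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "failed to place %d rosettes at separation >= %.1f px after 10 attempts",
          params$rosette_count, min_sep
        ))
      }
      keep <- setdiff(seq_along(grid_r), centres)
      seeds_r <- grid_r[keep] + stats::rnorm(length(keep), 0, params$jitter_sd)
      seeds_c <- grid_c[keep] + stats::rnorm(length(keep), 0, params$jitter_sd)
      rosette_of <- rep(0L, length(keep))
      for (ri in seq_along(centres)) {
        mcell <- params$rosette_cellularity
        ang <- 2 * pi * (seq_len(mcell) - 1L) / mcell + stats::runif(1, 0, 2 * pi)
        seeds_r <- c(seeds_r, grid_r[centres[ri]] + params$rosette_radius * sin(ang))
        seeds_c <- c(seeds_c, grid_c[centres[ri]] + params$rosette_radius * cos(ang))
        rosette_of <- c(rosette_of, rep(ri, mcell))
      }
    } else {
      seeds_r <- grid_r + stats::rnorm(length(grid_r), 0, params$jitter_sd)
      seeds_c <- grid_c + stats::rnorm(length(grid_c), 0, params$jitter_sd)
      rosette_of <- rep(0L, length(grid_r))
    }
    seeds_r <- pmin(pmax(seeds_r, 1), H)
    seeds_c <- pmin(pmax(seeds_c, 1), W)

    # nearest-seed rasterisation; ties broken by lowest seed index
    pr <- rep(seq_len(H), times = W)
    pc <- rep(seq_len(W), each = H)
    best <- rep(Inf, H * W)
    lab <- integer(H * W)
    for (s in seq_along(seeds_r)) {
      d <- (pr - seeds_r[s])^2 + (pc - seeds_c[s])^2
      upd <- d < best
      best[upd] <- d[upd]
      lab[upd] <- s
    }
    raster <- repair_connectivity(matrix(lab, H, W))

    n_seeds <- length(seeds_r)
    areas <- tabulate(raster, nbins = n_seeds)
    if (any(areas == 0L)) {
      stop(sprintf("seed %d produced an empty cell; increase image size",
                   which(areas == 0L)[1L]))
    }

    # ground-truth junctions: 4-adjacent label pairs; orientation is the
    # perpendicular of the seed displacement, from the ML (column) axis
    right <- cbind(as.vector(raster[, -W]), as.vector(raster[, -1L]))
    down <- cbind(as.vector(raster[-H, ]), as.vector(raster[-1L, ]))
    pr2 <- rbind(right[right[, 1L] != right[, 2L], , drop = FALSE],
                 down[down[, 1L] != down[, 2L], , drop = FALSE])
    pairs <- unique(cbind(pmin(pr2[, 1L], pr2[, 2L]), pmax(pr2[, 1L], pr2[, 2L])))
    dr <- seeds_r[pairs[, 2L]] - seeds_r[pairs[, 1L]]
    dc <- seeds_c[pairs[, 2L]] - seeds_c[pairs[, 1L]]
    theta <- (atan2(dr, dc) * 180 / pi + 90) %% 180

    truth <- list(
      cells = data.frame(cell_id = seq_len(n_seeds), area = areas,
                         seed_row = seeds_r, seed_col = seeds_c),
      junctions = data.frame(cell_a = pairs[, 1L], cell_b = pairs[, 2L],
                             theta_deg = theta),
      rosettes = data.frame(
        rosette_id = rosette_of[rosette_of > 0L],
        cell_id = which(rosette_of > 0L)
      )
    )
    list(label = label_image(raster), truth = truth, params = params)
  })
}
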