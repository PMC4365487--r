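#' Coordination numbers by ROI expansion
#'
#' The rosette statistic: each cell's mask is expanded (dilated) by
#' `radius_k` pixels; wherever three or more expanded masks overlap, the
#' cells meeting there form a cluster. Formally, candidate-vertex pixels are
#' pixels covered by >= 3 dilated masks; clusters are the 8-connected
#' components of candidate pixels; a cluster's members are all cells whose
#' dilated mask intersects it; a cell's coordination number is the size of
#' the largest cluster it belongs to (cells in multiple clusters take the
#' highest), and 2 for cells in no cluster (purely bicellular contacts).
#' Increasing `radius_k` can merge nearby vertices into one cluster —
#' coordination numbers and cluster cellularity are non-decreasing in k.
#'
#' @param label a `label_image` or integer matrix.
#' @param radius_k expansion radius in pixels (>= 1; 2 and 3 are the
#'   conventional choices).
#' @param metric `"euclidean"` (disk, default) or `"chebyshev"` (square).
#' @param validate run [validate_labels()] first (default TRUE).
#' @return object of class `coordination_map`: list with `cells`
#'   (data frame: cell, coordination), `clusters` (data frame: cluster_id,
#'   coordination, cell_ids semicolon-joined), `cluster_cells` (list),
#'   `cluster_pixels` (list of linear indices), `radius_k`, `metric`, `dim`.
#' @export
coordination_numbers <- function(label, radius_k = 2,
                                 metric = c("euclidean", "chebyshev"),
                                 validate = TRUE) {
  metric <- match.arg(metric)
  if (radius_k < 1) stop("`radius_k` must be >= 1")
  label <- as_label_image(label)
  if (validate) label <- validate_labels(label)
  m <- label$raster
  H <- nrow(m); W <- ncol(m)
  labs <- cell_labels(label)
  offs <- ball_offsets(radius_k, metric)
  k <- as.integer(ceiling(radius_k))

  overlap <- matrix(0L, H, W)
  dil_idx <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    idx <- which(m == labs[i])
    r <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    r0 <- max(1L, min(r) - k); r1 <- min(H, max(r) + k)
    c0 <- max(1L, min(cc) - k); c1 <- min(W, max(cc) + k)
    crop <- m[r0:r1, c0:c1, drop = FALSE] == labs[i]
    dil <- dilate_offsets(crop, offs)
    w <- which(dil)
    hh <- r1 - r0 + 1L
    gr <- ((w - 1L) %% hh) + r0
    gc <- ((w - 1L) %/% hh) + c0
    gi <- gr + (gc - 1L) * H
    dil_idx[[i]] <- gi
    overlap[gi] <- overlap[gi] + 1L
  }

  finish_coordination_map(dil_idx, labs, overlap, c(H, W), radius_k, metric,
                          component_fun = function(idx) uf_components(idx, c(H, W), 8L))
}

# Shared tail of the main implementation and the brute-force oracle: given
# per-cell reach (pixel index sets), build clusters and coordination numbers.
finish_coordination_map <- function(dil_idx, labs, overlap, dim_, radius_k,
                                    metric, component_fun) {
  cand <- which(overlap >= 3L)
  comp <- if (length(cand)) component_fun(cand) else integer(0)
  n_cl <- if (length(comp)) max(comp) else 0L

  members <- vector("list", n_cl)
  if (n_cl > 0L) {
    comp_of <- integer(prod(dim_))
    comp_of[cand] <- comp
    for (i in seq_along(labs)) {
      touched <- unique(comp_of[dil_idx[[i]]])
      touched <- touched[touched > 0L]
      for (cl in touched) members[[cl]] <- c(members[[cl]], labs[i])
    }
    members <- lapply(members, sort)
  }

  coord <- rep(2L, length(labs))
  names(coord) <- labs
  for (cl in seq_len(n_cl)) {
    sz <- length(members[[cl]])
    for (cell in members[[cl]]) {
      i <- match(cell, labs)
      if (sz > coord[i]) coord[i] <- sz
    }
  }

  clusters <- data.frame(
    cluster_id = seq_len(n_cl),
    coordination = vapply(members, length, integer(1)),
    cell_ids = vapply(members, paste, character(1), collapse = ";")
  )
  cluster_pixels <- if (n_cl > 0L) split(cand, comp) else list()

  structure(
    list(
      cells = data.frame(cell = labs, coordination = as.integer(coord)),
      clusters = clusters, cluster_cells = members,
      cluster_pixels = cluster_pixels,
      radius_k = radius_k, metric = metric, dim = dim_
    ),
    class = "coordination_map"
  )
}

#' @export
print.coordination_map <- function(x, ...) {
  cat(sprintf(
    "coordination_map: k = %g (%s), %d cells, %d clusters, max coordination %d\n",
    x$radius_k, x$metric, nrow(x$cells), nrow(x$clusters),
    max(x$cells$coordination)
  ))
  invisible(x)
}

#' Brute-force coordination oracle
#'
#' Independent reference implementation of [coordination_numbers()] for
#' testing: for every pixel it evaluates, directly and without morphological
#' operations, which cells have a pixel within `radius_k` (by scanning the
#' exact metric ball around the pixel), then builds clusters from pixels
#' reaching >= 3 cells with a queue-based flood fill. Guarded to images of
#' at most 128 x 128 pixels.
#'
#' @inheritParams coordination_numbers
#' @return a `coordination_map` with the identical contract.
#' @export
coordination_oracle <- function(label, radius_k = 2,
                                metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  label <- as_label_image(label)
  m <- label$raster
  H <- nrow(m); W <- ncol(m)
  if (H > 128L || W > 128L) stop("coordination_oracle is limited to 128 x 128 images")
  labs <- cell_labels(label)
  offs <- ball_offsets(radius_k, metric)
  n_off <- nrow(offs)

  # labels reachable from each pixel: label value at every in-ball offset
  vals <- vector("list", n_off)
  for (j in seq_len(n_off)) {
    vals[[j]] <- shift_mat(m, offs[j, 1L], offs[j, 2L], fill = 0L)
  }
  count <- matrix(0L, H, W)
  for (j in seq_len(n_off)) {
    vj <- vals[[j]]
    new <- vj > 0L
    if (j > 1L) for (i in seq_len(j - 1L)) new <- new & (vals[[i]] != vj)
    count <- count + new
  }

  # per-cell reach sets (pixel p is in cell c's reach iff some offset sees c)
  dil_idx <- vector("list", length(labs))
  lab_sets <- lapply(seq_len(n_off), function(j) as.integer(vals[[j]]))
  for (i in seq_along(labs)) {
    hit <- rep(FALSE, H * W)
    for (j in seq_len(n_off)) hit <- hit | (lab_sets[[j]] == labs[i])
    dil_idx[[i]] <- which(hit)
  }
  overlap <- count

  flood8 <- function(idx) {
    # queue-based 8-connected flood fill over the pixel set `idx`
    inset <- logical(H * W)
    inset[idx] <- TRUE
    compid <- integer(H * W)
    cur <- 0L
    for (start in idx) {
      if (compid[start] > 0L) next
      cur <- cur + 1L
      queue <- start
      compid[start] <- cur
      while (length(queue)) {
        p <- queue[[1L]]
        queue <- queue[-1L]
        r <- ((p - 1L) %% H) + 1L
        cc <- ((p - 1L) %/% H) + 1L
        for (dr in -1L:1L) {
          for (dc in -1L:1L) {
            if (dr == 0L && dc == 0L) next
            rr <- r + dr; ccc <- cc + dc
            if (rr < 1L || rr > H || ccc < 1L || ccc > W) next
            q <- rr + (ccc - 1L) * H
            if (inset[q] && compid[q] == 0L) {
              compid[q] <- cur
              queue <- c(queue, q)
            }
          }
        }
      }
    }
    compid[idx]
  }

  finish_coordination_map(dil_idx, labs, overlap, c(H, W), radius_k, metric,
                          component_fun = flood8)
}

#' Coordination-number histogram
#'
#' Percent of cells at each coordination number, with an open top bin
#' (`>= max_bin`). Percentages sum to 100.
#'
#' @param map a `coordination_map`.
#' @param max_bin top (open) bin, default 10.
#' @return data frame with columns `coordination` (as label, e.g. `">=10"`),
#'   `n_cells`, `percent`.
#' @export
coordination_histogram <- function(map, max_bin = 10L) {
  stopifnot(inherits(map, "coordination_map"))
  co <- map$cells$coordination
  if (length(co) == 0L) stop("empty coordination map")
  capped <- pmin(co, max_bin)
  lv <- 2:max_bin
  n <- vapply(lv, function(v) sum(capped == v), integer(1))
  data.frame(
    coordination = c(as.character(lv[-length(lv)]), paste0(">=", max_bin)),
    n_cells = n,
    percent = 100 * n / length(co)
  )
}

#' Apical-area statistics of a label image
#'
#' Per-cell pixel counts, scaled by `pixel_size^2` into physical units, with
#' cells touching the image frame excluded by default (their apical surface
#' is cropped and their area meaningless).
#'
#' @param label a `label_image` or matrix.
#' @param exclude_border drop cells touching the image frame (default TRUE).
#' @return object of class `area_stats`: list with `cells` (data frame:
#'   cell, area_px, area_units, border_cell), `mean`, `sem`, `n_cells`,
#'   `border_excluded`.
#' @export
apical_area_stats <- function(label, exclude_border = TRUE) {
  label <- as_label_image(label)
  m <- label$raster
  labs <- cell_labels(label)
  areas <- tabulate(m, nbins = max(labs))[labs]
  border <- labs %in% unique(c(m[1L, ], m[nrow(m), ], m[, 1L], m[, ncol(m)]))
  cells <- data.frame(
    cell = labs, area_px = areas,
    area_units = areas * label$pixel_size^2,
    border_cell = border
  )
  keep <- if (exclude_border) !border else rep(TRUE, length(labs))
  if (!any(keep)) stop("all cells touch the image border; no areas to average")
  x <- cells$area_units[keep]
  structure(
    list(
      cells = cells, mean = mean(x),
      sem = if (length(x) > 1) sem(x) else NA_real_,
      n_cells = length(x),
      border_excluded = sum(!keep)
    ),
    class = "area_stats"
  )
}

#' @export
print.area_stats <- function(x, ...) {
  cat(sprintf(
    "area_stats: mean apical area %.1f +/- %.1f (s.e.m.), n = %d cells (%d border cells excluded)\n",
    x$mean, x$sem, x$n_cells, x$border_excluded
  ))
  invisible(x)
}

#' Colour-code cells by coordination number
#'
#' @param label a `label_image` or matrix.
#' @param map the matching `coordination_map`.
#' @return integer matrix in which every pixel carries its cell's
#'   coordination number (for rendering with a lookup table); masked pixels
#'   stay 0.
#' @export
color_code_clusters <- function(label, map) {
  stopifnot(inherits(map, "coordination_map"))
  label <- as_label_image(label)
  m <- label$raster
  lut <- integer(max(map$cells$cell))
  lut[map$cells$cell] <- map$cells$coordination
  out <- matrix(0L, nrow(m), ncol(m))
  pos <- m > 0L
  out[pos] <- lut[m[pos]]
  out
}
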