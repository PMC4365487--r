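#' Orientation of a pixel set relative to the mediolateral axis
#'
#' The orientation is the principal (total-least-squares) axis of the pixel
#' coordinates, i.e. the eigenvector of the coordinate scatter matrix with
#' the larger eigenvalue, expressed in degrees in the half-open interval
#' [0, 180) measured from the mediolateral image axis. Under the default
#' convention (ML = image columns) a row-aligned junction has orientation 0
#' and a column-aligned junction 90.
#'
#' Sets with fewer than 2 pixels, or whose scatter is perfectly isotropic
#' (no defined principal axis), return `NA` — such junctions are flagged and
#' excluded from orientation binning rather than given an arbitrary angle.
#'
#' @param coords two-column matrix of (row, col) pixel coordinates.
#' @param ml_axis `"col"` (default) or `"row"`.
#' @return orientation in degrees in [0, 180), or `NA_real_`.
#' @export
junction_orientation <- function(coords, ml_axis = c("col", "row")) {
  ml_axis <- match.arg(ml_axis)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) return(NA_real_)
  r <- coords[, 1L]; cc <- coords[, 2L]
  mu20 <- mean(cc^2) - mean(cc)^2     # variance along columns (ML default)
  mu02 <- mean(r^2) - mean(r)^2
  mu11 <- mean(r * cc) - mean(r) * mean(cc)
  if (abs(mu11) < 1e-12 && abs(mu20 - mu02) < 1e-12) return(NA_real_)
  phi <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  theta <- phi %% 180
  if (ml_axis == "row") theta <- (90 - theta) %% 180
  theta
}

#' Extract the cell/junction/vertex graph of a label image
#'
#' Classifies every boundary pixel of a watertight label image: a pixel whose
#' 8-neighbourhood (own label included) contains exactly 2 distinct labels
#' belongs to the junction of that cell pair; a pixel whose neighbourhood
#' contains 3 or more labels is a vertex pixel. Junction segments are the
#' 8-connected components of same-pair boundary pixels (so two junctions of
#' the same cell pair separated by a vertex stay distinct); vertices are
#' 8-connected components of vertex pixels, with incident cells the union of
#' labels seen in their neighbourhoods. Every boundary pixel is assigned to
#' exactly one junction or one vertex.
#'
#' Per-junction orientation is computed with [junction_orientation()].
#'
#' @param label a `label_image` (or integer label matrix).
#' @param validate run [validate_labels()] first (default TRUE).
#' @return an object of class `junction_graph`: list with data frames
#'   `cells` (cell, area_px), `junctions` (junction_id, cell_a, cell_b,
#'   length_px, theta_deg, degenerate), `vertices` (vertex_id, row, col,
#'   n_cells), `adjacency` (cell_a, cell_b), plus pixel index lists
#'   `junction_pixels`, `vertex_pixels`, `vertex_cells`, the image `dim` and
#'   the `ml_axis` convention.
#' @export
extract_junction_graph <- function(label, validate = TRUE) {
  label <- as_label_image(label)
  if (validate) label <- validate_labels(label)
  m <- label$raster
  dim_ <- dim(m)
  H <- dim_[1L]
  labs <- cell_labels(label)
  cells <- data.frame(cell = labs, area_px = tabulate(m, nbins = max(labs))[labs])

  st <- neighbor_label_stats(m)
  own_pos <- m > 0L
  pair_idx <- which(st$count == 2L & own_pos)
  vert_idx <- which(st$count >= 3L & own_pos)

  # --- junction segments: components of same-pair boundary pixels ---
  jlist <- list()
  if (length(pair_idx) > 0L) {
    a <- pmin(m[pair_idx], st$other[pair_idx])
    b <- pmax(m[pair_idx], st$other[pair_idx])
    key <- paste(a, b)
    groups <- split(seq_along(pair_idx), key)
    for (g in groups) {
      gi <- pair_idx[g]
      comp <- uf_components(gi, dim_, connectivity = 8L)
      for (k in seq_len(max(comp))) {
        jlist[[length(jlist) + 1L]] <- list(
          cell_a = a[g[1L]], cell_b = b[g[1L]], pixels = gi[comp == k]
        )
      }
    }
  }
  n_j <- length(jlist)
  theta <- rep(NA_real_, n_j)
  len <- integer(n_j)
  ja <- integer(n_j); jb <- integer(n_j)
  jpix <- vector("list", n_j)
  for (i in seq_len(n_j)) {
    px <- jlist[[i]]$pixels
    coords <- cbind(((px - 1L) %% H) + 1L, ((px - 1L) %/% H) + 1L)
    theta[i] <- junction_orientation(coords, ml_axis = label$ml_axis)
    len[i] <- length(px)
    ja[i] <- jlist[[i]]$cell_a
    jb[i] <- jlist[[i]]$cell_b
    jpix[[i]] <- px
  }
  junctions <- data.frame(
    junction_id = seq_len(n_j), cell_a = ja, cell_b = jb,
    length_px = len, theta_deg = theta, degenerate = is.na(theta)
  )

  # --- vertices: components of >=3-label pixels ---
  vdf <- data.frame(
    vertex_id = integer(0), row = numeric(0), col = numeric(0), n_cells = integer(0)
  )
  vpix <- list(); vcells <- list()
  if (length(vert_idx) > 0L) {
    comp <- uf_components(vert_idx, dim_, connectivity = 8L)
    nv <- max(comp)
    vr <- numeric(nv); vc <- numeric(nv); vn <- integer(nv)
    for (k in seq_len(nv)) {
      px <- vert_idx[comp == k]
      cs <- integer(0)
      for (j in seq_len(nrow(NBHD9))) {
        cs <- c(cs, st$shifted[[j]][px])
      }
      cs <- sort(unique(cs[cs > 0L]))
      vr[k] <- mean(((px - 1L) %% H) + 1L)
      vc[k] <- mean(((px - 1L) %/% H) + 1L)
      vn[k] <- length(cs)
      vpix[[k]] <- px
      vcells[[k]] <- cs
    }
    vdf <- data.frame(vertex_id = seq_len(nv), row = vr, col = vc, n_cells = vn)
  }

  adj <- unique(junctions[, c("cell_a", "cell_b")])
  rownames(adj) <- NULL

  structure(
    list(
      cells = cells, junctions = junctions, vertices = vdf,
      adjacency = adj, junction_pixels = jpix,
      vertex_pixels = vpix, vertex_cells = vcells,
      dim = dim_, ml_axis = label$ml_axis
    ),
    class = "junction_graph"
  )
}

#' @export
print.junction_graph <- function(x, ...) {
  cat(sprintf(
    "junction_graph: %d cells, %d junctions, %d vertices (%d x %d px)\n",
    nrow(x$cells), nrow(x$junctions), nrow(x$vertices), x$dim[1L], x$dim[2L]
  ))
  invisible(x)
}

#' Write junction and vertex tables
#'
#' @param graph a `junction_graph`.
#' @param junctions_csv,vertices_csv output paths (NULL to skip one).
#' @return invisibly, the written paths.
#' @export
write_junction_graph <- function(graph, junctions_csv = NULL, vertices_csv = NULL) {
  if (!is.null(junctions_csv)) {
    utils::write.csv(
      graph$junctions[, c("junction_id", "cell_a", "cell_b", "length_px", "theta_deg")],
      junctions_csv,
      row.names = FALSE
    )
  }
  if (!is.null(vertices_csv)) {
    v <- graph$vertices
    v$cell_ids <- vapply(
      seq_len(nrow(v)),
      function(i) paste(graph$vertex_cells[[i]], collapse = ";"), character(1)
    )
    utils::write.csv(v, vertices_csv, row.names = FALSE)
  }
  invisible(c(junctions_csv, vertices_csv))
}
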