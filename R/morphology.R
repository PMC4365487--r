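# Internal raster morphology: integer shifts, neighbourhood gathering,
# union-find connected components, and exact metric-ball offsets.
# Connectivity conventions follow the analysis contracts: cells must be
# 4-connected, boundary/vertex/cluster pixel components are 8-connected.

# Value of m at (r + dr, c + dc); out-of-image reads as `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  src_r <- max(1L, 1L + dr):min(H, H + dr)
  src_c <- max(1L, 1L + dc):min(W, W + dc)
  if (length(src_r) < 1L || length(src_c) < 1L) return(out)
  out[src_r - dr, src_c - dc] <- m[src_r, src_c]
  out
}

# The 9 offsets of a 3x3 neighbourhood, centre first (so a pixel's own label
# is always the first occurrence in distinct-label counting).
NBHD9 <- rbind(
  c(0L, 0L),
  c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
  c(0L, -1L), c(0L, 1L),
  c(1L, -1L), c(1L, 0L), c(1L, 1L)
)

# For every pixel: number of distinct positive labels in its 8-neighbourhood
# (own pixel included) and, where that count is exactly 2, the other label.
# Returns list(count, other, shifted) where `shifted` is the list of the 9
# shifted label matrices (reused by callers that need full label sets).
neighbor_label_stats <- function(label) {
  n <- nrow(NBHD9)
  shifted <- vector("list", n)
  for (j in seq_len(n)) {
    shifted[[j]] <- shift_mat(label, NBHD9[j, 1L], NBHD9[j, 2L], fill = 0L)
  }
  count <- matrix(0L, nrow(label), ncol(label))
  for (j in seq_len(n)) {
    vj <- shifted[[j]]
    new <- vj > 0L
    if (j > 1L) {
      for (i in seq_len(j - 1L)) new <- new & (shifted[[i]] != vj)
    }
    count <- count + new
  }
  own <- shifted[[1L]]
  other <- matrix(0L, nrow(label), ncol(label))
  for (j in 2L:n) {
    vj <- shifted[[j]]
    cand <- vj > 0L & vj != own
    other[cand] <- vj[cand]
  }
  list(count = count, other = other, shifted = shifted)
}

# Connected components of a pixel set given by linear indices into an
# H x W raster. Union-find with path halving; connectivity 4 or 8.
# Returns an integer component id (1..k) per input index.
uf_components <- function(idx, dim, connectivity = 8L) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  H <- dim[1L]; W <- dim[2L]
  ord <- order(idx)
  idx_s <- idx[ord]
  r <- ((idx_s - 1L) %% H) + 1L
  c <- ((idx_s - 1L) %/% H) + 1L
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- if (connectivity == 8L) {
    rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L))
  } else {
    rbind(c(0L, -1L), c(-1L, 0L))
  }
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]
    valid <- r + dr >= 1L & r + dr <= H & c + dc >= 1L & c + dc <= W
    nb <- idx_s[valid] + dr + dc * H
    j <- match(nb, idx_s)
    ii <- which(valid)[!is.na(j)]
    jj <- j[!is.na(j)]
    for (q in seq_along(ii)) {
      a <- find(ii[q]); b <- find(jj[q])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp_s <- match(root, unique(root))
  comp <- integer(n)
  comp[ord] <- comp_s
  comp
}

# Offsets (dr, dc) of the closed metric ball of radius k.
ball_offsets <- function(radius_k, metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  k <- as.integer(radius_k)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  keep <- if (metric == "euclidean") g$dr^2 + g$dc^2 <= k^2 else rep(TRUE, nrow(g))
  as.matrix(g[keep, , drop = FALSE])
}

# Binary dilation of a logical matrix by an explicit offset set.
dilate_offsets <- function(mask, offsets) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (j in seq_len(nrow(offsets))) {
    out <- out | shift_mat(mask, offsets[j, 1L], offsets[j, 2L], fill = FALSE)
  }
  out
}

# Chebyshev erosion of a per-cell mask: a pixel survives if no pixel of a
# *different* positive label (or a masked 0 pixel) lies within Chebyshev
# distance `margin`. The image frame itself does not erode (cropping an
# embryo does not create a cell boundary).
erode_cell_chebyshev <- function(label, margin) {
  H <- nrow(label); W <- ncol(label)
  near_other <- matrix(FALSE, H, W)
  for (dr in -margin:margin) {
    for (dc in -margin:margin) {
      if (dr == 0L && dc == 0L) next
      v <- shift_mat(label, dr, dc, fill = NA_integer_)
      diff <- !is.na(v) & v != label
      near_other <- near_other | diff
    }
  }
  label > 0L & !near_other
}
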