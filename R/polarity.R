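#' Assign a junction orientation to its angular bin and axis class
#'
#' Orientations in [0, 180) degrees (from the mediolateral axis) are
#' partitioned into four half-open bins: Bin 1 = [0, 45), Bin 2 = [45, 90),
#' Bin 3 = [90, 135), Bin 4 = [135, 180). Bins 1 and 4 are classed as
#' mediolateral (ML), bins 2 and 3 as anteroposterior (AP). The half-open
#' convention makes the partition exact: 45, 90 and 135 fall in bins 2, 3
#' and 4 respectively.
#'
#' @param theta_deg orientation(s) in degrees, each in [0, 180).
#' @return data frame with columns `bin` (1..4) and `axis_class`
#'   ("ML"/"AP"), one row per input angle.
#' @export
assign_bin <- function(theta_deg) {
  if (any(is.na(theta_deg))) stop("NA orientation cannot be binned")
  if (any(theta_deg < 0 | theta_deg >= 180)) {
    stop("orientations must lie in [0, 180)")
  }
  bin <- findInterval(theta_deg, c(0, 45, 90, 135))
  data.frame(bin = bin, axis_class = ifelse(bin %in% c(1L, 4L), "ML", "AP"))
}

#' Mean junction fluorescence
#'
#' Arithmetic mean of channel grey values over a junction's 1-pixel pixel
#' set — the digital analogue of reading a 1-pixel line profile across a
#' junction.
#'
#' @param pixels linear pixel indices of the junction (into the channel).
#' @param channel numeric intensity matrix, same shape as the label image.
#' @param dim expected image dimension (validated against `channel`).
#' @return mean grey value.
#' @export
measure_junction_intensity <- function(pixels, channel, dim = NULL) {
  if (!is.null(dim) && !all(dim(channel) == dim)) {
    stop("channel shape does not match the label image")
  }
  if (length(pixels) == 0L) stop("empty junction pixel set")
  mean(channel[pixels])
}

#' Per-junction intensity table of a junction graph
#'
#' Measures every junction of the graph on `channel` and marks which
#' junctions enter polarity analysis: non-degenerate orientation and length
#' of at least `min_length` pixels (shorter segments are raster-noise
#' dominated).
#'
#' @param graph a [extract_junction_graph()] result.
#' @param channel intensity matrix of the same shape.
#' @param min_length minimum junction length in pixels (default 4).
#' @param embryo optional embryo identifier attached to all rows.
#' @return the graph's junction table with `mean_intensity`, `analyzable`
#'   and `embryo` columns appended.
#' @export
measure_junction_intensities <- function(graph, channel, min_length = 4,
                                         embryo = NA_character_) {
  stopifnot(inherits(graph, "junction_graph"))
  if (!all(dim(channel) == graph$dim)) {
    stop("channel shape does not match the label image")
  }
  j <- graph$junctions
  j$mean_intensity <- vapply(
    graph$junction_pixels, function(px) mean(channel[px]), numeric(1)
  )
  j$analyzable <- !j$degenerate & j$length_px >= min_length
  j$embryo <- embryo
  j
}

#' Planar-polarity summary statistic
#'
#' Pools per-junction mean intensities (the junction is the statistical
#' unit) across embryos, averages them within the four orientation bins and
#' the two axis classes, and compares ML against AP junctions with a
#' two-tailed pooled-variance Student's t-test. Error bars are standard
#' errors of the mean over the pooled junction set.
#'
#' @param junctions data frame with columns `theta_deg`, `mean_intensity`
#'   and optionally `analyzable` (rows with `FALSE` are dropped) and
#'   `embryo`.
#' @return object of class `polarity_result`: list with `bins` (bin, n,
#'   mean, sem), `axes` (axis_class, n, mean, sem), `ml_ap_ratio`,
#'   `t_statistic`, `df`, `p_value`, `n_ml`, `n_ap`, `n_embryos`.
#' @export
polarity_summary <- function(junctions) {
  j <- junctions
  if (!is.null(j$analyzable)) j <- j[j$analyzable, , drop = FALSE]
  if (nrow(j) == 0L) stop("no analyzable junctions")
  ba <- assign_bin(j$theta_deg)
  j$bin <- ba$bin
  j$axis_class <- ba$axis_class
  n_ml <- sum(j$axis_class == "ML")
  n_ap <- sum(j$axis_class == "AP")
  if (n_ml < 2L || n_ap < 2L) {
    stop(sprintf("need >= 2 junctions per axis class (ML: %d, AP: %d)", n_ml, n_ap))
  }
  agg <- function(split_var, levels_) {
    do.call(rbind, lapply(levels_, function(lv) {
      x <- j$mean_intensity[split_var == lv]
      data.frame(
        level = lv, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sem = if (length(x) > 1) sem(x) else NA_real_
      )
    }))
  }
  bins <- agg(j$bin, 1:4); names(bins)[1] <- "bin"
  axes <- agg(j$axis_class, c("ML", "AP")); names(axes)[1] <- "axis_class"
  tt <- students_t(
    j$mean_intensity[j$axis_class == "ML"],
    j$mean_intensity[j$axis_class == "AP"]
  )
  n_embryos <- if (!is.null(j$embryo)) length(unique(j$embryo[!is.na(j$embryo)])) else 0L
  structure(
    list(
      bins = bins, axes = axes,
      ml_ap_ratio = axes$mean[axes$axis_class == "ML"] /
        axes$mean[axes$axis_class == "AP"],
      t_statistic = tt$t, df = tt$df, p_value = tt$p,
      n_ml = n_ml, n_ap = n_ap, n_embryos = max(n_embryos, 0L)
    ),
    class = "polarity_result"
  )
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf(
    "polarity_result: ML/AP ratio %.3f (ML n=%d, AP n=%d, %d embryos)\n  t = %.3f, df = %d, p = %.3g\n",
    x$ml_ap_ratio, x$n_ml, x$n_ap, x$n_embryos, x$t_statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' Junctional vs medial fluorescence partition
#'
#' Splits the image into a junctional zone (all pixels within Chebyshev
#' distance 1 of a label boundary pixel — the rendering/measurement band)
#' and a medial zone (each cell's mask shrunk so that no pixel of another
#' cell lies within Chebyshev distance `margin`). Pixels in neither zone
#' (the guard ring between them) are excluded and counted. Cells whose
#' medial zone erodes away entirely are excluded with a warning count.
#'
#' @param label a `label_image` or matrix.
#' @param channel intensity matrix of the same shape.
#' @param margin medial inset in pixels (>= 1, default 2).
#' @return object of class `fluorescence_partition`: list with
#'   `junctional_mean`, `medial_mean`, `junctional_fraction`
#'   (junctional sum / (junctional + medial sum)), `margin`,
#'   `excluded_pixels`, `n_cells_excluded`.
#' @export
partition_fluorescence <- function(label, channel, margin = 2) {
  label <- as_label_image(label)
  m <- label$raster
  if (!all(dim(channel) == dim(m))) {
    stop("channel shape does not match the label image")
  }
  if (margin < 1) stop("`margin` must be >= 1")
  st <- neighbor_label_stats(m)
  boundary <- st$count >= 2L & m > 0L
  junctional <- dilate_offsets(boundary, NBHD9) & m > 0L
  medial <- erode_cell_chebyshev(m, as.integer(margin)) & !junctional

  labs <- cell_labels(label)
  kept <- unique(m[medial])
  n_excluded_cells <- length(setdiff(labs, kept))
  if (n_excluded_cells > 0L) {
    warning(sprintf("%d cell(s) have no medial zone at margin %d and are excluded",
                    n_excluded_cells, margin))
  }
  js <- sum(channel[junctional])
  ms <- sum(channel[medial])
  structure(
    list(
      junctional_mean = mean(channel[junctional]),
      medial_mean = if (any(medial)) mean(channel[medial]) else NA_real_,
      junctional_fraction = js / (js + ms),
      margin = margin,
      excluded_pixels = sum(m > 0L) - sum(junctional) - sum(medial),
      n_cells_excluded = n_excluded_cells
    ),
    class = "fluorescence_partition"
  )
}

#' @export
print.fluorescence_partition <- function(x, ...) {
  cat(sprintf(
    "fluorescence_partition: junctional %.1f, medial %.1f, junctional fraction %.3f (margin %d px)\n",
    x$junctional_mean, x$medial_mean, x$junctional_fraction, x$margin
  ))
  invisible(x)
}
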