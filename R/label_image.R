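#' Construct a label image
#'
#' A label image is a watertight 2-D raster of integer cell identities as
#' produced by a watershed-style segmenter: every pixel carries the identity
#' of the cell it belongs to. Label 0 is reserved for optionally masked
#' (non-analysed) regions. Row/column indexing follows R matrices, with row 1
#' at the top of the image.
#'
#' @param raster integer matrix of labels (>= 0).
#' @param pixel_size physical units per pixel edge (default 1).
#' @param ml_axis which image axis is the embryo's mediolateral axis:
#'   `"col"` (default, image columns run mediolaterally) or `"row"`.
#' @return an object of class `label_image`.
#' @seealso [validate_labels()], [extract_junction_graph()]
#' @export
label_image <- function(raster, pixel_size = 1, ml_axis = c("col", "row")) {
  ml_axis <- match.arg(ml_axis)
  if (!is.matrix(raster)) stop("`raster` must be a matrix")
  storage.mode(raster) <- "integer"
  structure(
    list(raster = raster, pixel_size = pixel_size, ml_axis = ml_axis),
    class = "label_image"
  )
}

#' @export
print.label_image <- function(x, ...) {
  labs <- sort(unique(as.integer(x$raster)))
  labs <- labs[labs > 0L]
  cat(sprintf(
    "label_image: %d x %d px, %d cells, pixel_size = %g, ML axis = %s\n",
    nrow(x$raster), ncol(x$raster), length(labs), x$pixel_size,
    if (x$ml_axis == "col") "columns" else "rows"
  ))
  invisible(x)
}

as_label_image <- function(x) {
  if (inherits(x, "label_image")) x else label_image(x)
}

cell_labels <- function(label) {
  labs <- sort(unique(as.integer(label$raster)))
  labs[labs > 0L]
}

#' Validate a segmented label image
#'
#' Checks the contract every downstream stage relies on: the raster is an
#' integer matrix with non-negative entries, at least one positive label is
#' present, and every label's pixel set is 4-connected (a label split into
#' islands indicates a broken segmentation and is reported by name).
#'
#' @param raster integer matrix or `label_image`.
#' @inheritParams label_image
#' @return a validated `label_image` (invisibly usable downstream).
#' @export
validate_labels <- function(raster, pixel_size = 1, ml_axis = c("col", "row")) {
  if (inherits(raster, "label_image")) {
    img <- raster
  } else {
    ml_axis <- match.arg(ml_axis)
    img <- label_image(raster, pixel_size = pixel_size, ml_axis = ml_axis)
  }
  m <- img$raster
  if (length(m) == 0L) stop("empty raster")
  if (anyNA(m)) stop("raster contains NA labels")
  if (any(m < 0L)) stop("raster contains negative labels")
  labs <- cell_labels(img)
  if (length(labs) == 0L) stop("raster contains no positive labels (all background)")
  dim_ <- dim(m)
  for (lab in labs) {
    idx <- which(m == lab)
    comp <- uf_components(idx, dim_, connectivity = 4L)
    if (max(comp) > 1L) {
      stop(sprintf("label %d is not 4-connected (%d islands)", lab, max(comp)))
    }
  }
  img
}

#' Read / write label images as 16-bit TIFF
#'
#' Labels are stored as grey values 1..N in a single-channel 16-bit TIFF, the
#' native output format of segmentation tools.
#'
#' @param path file path.
#' @inheritParams label_image
#' @return `read_label_tiff()` returns a `label_image`.
#' @export
read_label_tiff <- function(path, pixel_size = 1, ml_axis = c("col", "row")) {
  ml_axis <- match.arg(ml_axis)
  if (!file.exists(path)) stop(sprintf("label image not found: %s", path))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  label_image(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)),
    pixel_size = pixel_size, ml_axis = ml_axis
  )
}

#' @rdname read_label_tiff
#' @param label a `label_image` or integer matrix.
#' @export
write_label_tiff <- function(label, path) {
  label <- as_label_image(label)
  m <- label$raster
  if (max(m) > 65535L) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read / write fluorescence channels as 16-bit TIFF
#'
#' Grey values are clipped to the unsigned 16-bit range on write. On read the
#' matrix is returned on the original grey-value scale (0..65535). Channels
#' whose maximum sits at the dtype ceiling are flagged (attribute
#' `saturated`), since saturated projections bias junction intensity means.
#'
#' @param path file path.
#' @return `read_intensity_tiff()` returns a numeric matrix with attribute
#'   `saturated` (logical).
#' @export
read_intensity_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("intensity image not found: %s", path))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  out <- m * 65535
  attr(out, "saturated") <- max(out) >= 65535
  out
}

#' @rdname read_intensity_tiff
#' @param channel numeric matrix of grey values.
#' @export
write_intensity_tiff <- function(channel, path) {
  m <- pmin(pmax(channel, 0), 65535)
  tiff::writeTIFF(round(m) / 65535, path, bits.per.sample = 16)
  invisible(path)
}
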