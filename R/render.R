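#' Optical parameters of the synthetic fluorescence channel
#'
#' The rendered channel emulates a non-saturated confocal projection of a
#' junctional protein (ZO1, F-actin, Shroom3, ...). Junction pixels of a
#' junction with orientation `theta` (degrees from the mediolateral axis)
#' receive the noise-free mean
#' \deqn{I(\theta) = \mathrm{base\_intensity}\,(1 + (\rho - 1)\cos^2\theta),}
#' so mediolateral junctions (`theta` near 0) are `rho`-fold brighter than
#' anteroposterior ones (`theta` near 90); `rho = 1` renders an unpolarised
#' tissue. A fraction `1 - junctional_fraction` of each cell's total signal
#' is spread uniformly over the cell interior, emulating the junctional vs
#' medial pool split; Gaussian noise and an optional Gaussian blur are
#' applied last.
#'
#' @param base_intensity grey value of an anteroposterior (theta = 90)
#'   junction; > 0.
#' @param anisotropy_rho ML:AP mean-intensity ratio; > 0, 1 = no polarity.
#' @param junctional_fraction fraction in [0, 1] of per-cell total signal in
#'   the junctional band.
#' @param noise_sd additive Gaussian noise, grey values.
#' @param blur_sigma optional Gaussian PSF sigma in pixels (0 = none).
#' @param rng_seed integer seed.
#' @return a `render_params` list.
#' @export
render_params <- function(base_intensity = 100, anisotropy_rho = 1,
                          junctional_fraction = 1, noise_sd = 0,
                          blur_sigma = 0, rng_seed = 1L) {
  stopifnot_scalar(base_intensity, "base_intensity", lower = 1e-9)
  stopifnot_scalar(anisotropy_rho, "anisotropy_rho", lower = 1e-9)
  stopifnot_scalar(junctional_fraction, "junctional_fraction", 0, 1)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  stopifnot_scalar(blur_sigma, "blur_sigma", 0)
  structure(
    list(
      base_intensity = base_intensity, anisotropy_rho = anisotropy_rho,
      junctional_fraction = junctional_fraction, noise_sd = noise_sd,
      blur_sigma = blur_sigma, rng_seed = as.integer(rng_seed)
    ),
    class = "render_params"
  )
}

#' Angular intensity law of the renderer
#'
#' @param theta_deg orientation(s) in degrees from the ML axis.
#' @param optics a [render_params()] object.
#' @return noise-free mean grey value(s).
#' @export
intensity_law <- function(theta_deg, optics) {
  optics$base_intensity *
    (1 + (optics$anisotropy_rho - 1) * cos(theta_deg * pi / 180)^2)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) {
    # separable 1-D convolution along rows with edge renormalisation
    out <- matrix(0, nrow(x), ncol(x))
    wsum <- matrix(0, nrow(x), ncol(x))
    for (i in -r:r) {
      out <- out + k[i + r + 1L] * shift_mat(x, i, 0L, fill = 0)
      wsum <- wsum + k[i + r + 1L] * shift_mat(matrix(1, nrow(x), ncol(x)), i, 0L, fill = 0)
    }
    out / wsum
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Render a synthetic fluorescence channel
#'
#' Applies the angular intensity law to the 1-pixel junction skeleton (the
#' boundary pixels of [extract_junction_graph()]), widens it to the rendering
#' band (all pixels within Chebyshev distance 1 of a boundary pixel; band
#' pixels that are not themselves boundary pixels inherit the brightest
#' adjacent boundary value), distributes the medial pool uniformly over cell
#' interiors, then blurs and adds noise. Vertex pixels, whose orientation is
#' undefined, receive the angular mean of the law
#' (`base * (1 + (rho-1)/2)`).
#'
#' With `noise_sd = 0` and `blur_sigma = 0` the mean grey value over a
#' junction's pixel set equals `intensity_law(theta)` exactly.
#'
#' @param label a `label_image` (or matrix) matching `truth`.
#' @param truth ground truth from [generate_tessellation()] (uses the
#'   per-pair junction orientations).
#' @param optics a [render_params()] object.
#' @return numeric matrix of grey values (clipped to [0, 65535]).
#' @export
render_channel <- function(label, truth, optics) {
  stopifnot(inherits(optics, "render_params"))
  label <- as_label_image(label)
  m <- label$raster
  H <- nrow(m); W <- ncol(m)
  st <- neighbor_label_stats(m)
  own_pos <- m > 0L
  pair_mask <- st$count == 2L & own_pos
  vert_mask <- st$count >= 3L & own_pos
  boundary <- pair_mask | vert_mask

  # per-pair orientation lookup from ground truth
  tj <- truth$junctions
  key_truth <- paste(pmin(tj$cell_a, tj$cell_b), pmax(tj$cell_a, tj$cell_b))
  pidx <- which(pair_mask)
  a <- pmin(m[pidx], st$other[pidx])
  b <- pmax(m[pidx], st$other[pidx])
  theta <- tj$theta_deg[match(paste(a, b), key_truth)]

  base <- matrix(0, H, W)
  iso <- optics$base_intensity * (1 + (optics$anisotropy_rho - 1) / 2)
  vals <- ifelse(is.na(theta), iso, intensity_law(theta, optics))
  base[pidx] <- vals
  base[vert_mask] <- iso

  # widen to the Chebyshev-1 band; boundary pixels keep their own value
  band_max <- matrix(0, H, W)
  for (j in seq_len(nrow(NBHD9))) {
    band_max <- pmax(band_max, shift_mat(base, NBHD9[j, 1L], NBHD9[j, 2L], fill = 0))
  }
  img <- base
  fill_px <- !boundary & band_max > 0
  img[fill_px] <- band_max[fill_px]
  band <- boundary | fill_px

  # medial pool: fraction (1 - f) of each cell's total signal, uniform over
  # the interior; the junctional band fixes the remaining fraction f
  f <- optics$junctional_fraction
  labs <- cell_labels(label)
  if (f == 0) {
    img[] <- 0
    interior <- own_pos & !band
    img[interior] <- optics$base_intensity
  } else if (f < 1) {
    lab_vec <- as.integer(m)
    band_sum <- rowsum(as.numeric(img[band]), lab_vec[band])
    interior <- own_pos & !band
    int_count <- rowsum(rep(1, sum(interior)), lab_vec[interior])
    dens <- rep(0, max(labs))
    common <- intersect(rownames(band_sum), rownames(int_count))
    dens[as.integer(common)] <-
      band_sum[common, 1L] * (1 - f) / f / int_count[common, 1L]
    img[interior] <- dens[lab_vec[interior]]
  }

  img <- gaussian_blur(img, optics$blur_sigma)
  if (optics$noise_sd > 0) {
    img <- with_seed(optics$rng_seed,
      img + stats::rnorm(length(img), 0, optics$noise_sd)
    )
  }
  pmin(pmax(img, 0), 65535)
}
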