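# Fixtures are built in code; nothing is read from disk.

# Four equal 8x8 quadrants meeting at one four-fold vertex.
quadrant_image <- function(n = 16L) {
  h <- n %/% 2L
  m <- matrix(1L, n, n)
  m[seq_len(h), (h + 1L):n] <- 2L
  m[(h + 1L):n, seq_len(h)] <- 3L
  m[(h + 1L):n, (h + 1L):n] <- 4L
  m
}

# Two cells split by a vertical boundary (junction parallel to columns,
# orientation 90 degrees under the default ML = columns convention).
two_cell_vertical <- function(n = 12L) {
  m <- matrix(1L, n, n)
  m[, (n %/% 2L + 1L):n] <- 2L
  m
}

# Two cells split by a horizontal boundary (orientation 0 degrees).
two_cell_horizontal <- function(n = 12L) {
  m <- matrix(1L, n, n)
  m[(n %/% 2L + 1L):n, ] <- 2L
  m
}

# Ground-truth junction table for the manual two-cell images.
two_cell_truth <- function(theta) {
  list(junctions = data.frame(cell_a = 1L, cell_b = 2L, theta_deg = theta))
}

# Small default tessellation shared by several tests.
small_tessellation <- function(rng_seed = 11L, ...) {
  generate_tessellation(tessellation_params(
    image_height = 120L, image_width = 120L, n_rows = 6L, n_cols = 6L,
    rng_seed = rng_seed, ...
  ))
}

# A polarised synthetic tissue with extracted junction intensities:
# the standard round-trip input for polarity tests.
polarized_tissue <- function(rho, rng_seed, noise_sd = 10, n_rows = 11L,
                             junctional_fraction = 0.9) {
  tess <- generate_tessellation(tessellation_params(
    image_height = 200L, image_width = 200L, n_rows = n_rows, n_cols = n_rows,
    rng_seed = rng_seed
  ))
  optics <- render_params(
    base_intensity = 100, anisotropy_rho = rho,
    junctional_fraction = junctional_fraction, noise_sd = noise_sd,
    rng_seed = rng_seed + 1L
  )
  channel <- render_channel(tess$label, tess$truth, optics)
  graph <- extract_junction_graph(tess$label, validate = FALSE)
  list(
    tess = tess, graph = graph, channel = channel, optics = optics,
    junctions = measure_junction_intensities(graph, channel)
  )
}
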