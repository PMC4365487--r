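#' Pipeline run configuration
#'
#' Collects the file paths and per-stage parameters of a full analysis run.
#' Paths are checked at [run_pipeline()] time; parameter values are checked
#' against each stage's preconditions here.
#'
#' @param label path to the label TIFF.
#' @param channel path to the fluorescence channel TIFF (optional; polarity
#'   and partition stages are skipped without it).
#' @param embryos path to an embryo table CSV (optional; morphometrics is
#'   skipped without it).
#' @param out_dir output directory (created if missing).
#' @param min_junction_length minimum junction length for polarity (px).
#' @param medial_margin medial erosion margin (px).
#' @param radius_k expansion radii for coordination analysis.
#' @param metric dilation metric, `"euclidean"` or `"chebyshev"`.
#' @param exclude_border drop border cells from area statistics.
#' @param ml_axis mediolateral image axis, `"col"` or `"row"`.
#' @param wildtype_genotype wildtype label in the embryo table.
#' @param seed integer seed recorded in the report (the analysis itself is
#'   deterministic; the seed documents the provenance of synthetic inputs).
#' @param verbose log stage progress to stderr.
#' @return a `run_config` list.
#' @export
run_config <- function(label, channel = NULL, embryos = NULL, out_dir,
                       min_junction_length = 4, medial_margin = 2,
                       radius_k = c(2, 3), metric = "euclidean",
                       exclude_border = TRUE, ml_axis = "col",
                       wildtype_genotype = "+/+", seed = 1L,
                       verbose = TRUE) {
  if (min_junction_length < 1) stop("min_junction_length must be >= 1")
  if (medial_margin < 1) stop("medial_margin must be >= 1")
  if (any(radius_k < 1)) stop("radius_k must be >= 1")
  metric <- match.arg(metric, c("euclidean", "chebyshev"))
  ml_axis <- match.arg(ml_axis, c("col", "row"))
  structure(
    list(
      label = label, channel = channel, embryos = embryos, out_dir = out_dir,
      min_junction_length = min_junction_length, medial_margin = medial_margin,
      radius_k = radius_k, metric = metric, exclude_border = exclude_border,
      ml_axis = ml_axis, wildtype_genotype = wildtype_genotype,
      seed = as.integer(seed), verbose = verbose
    ),
    class = "run_config"
  )
}

log_stage <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full quantification pipeline
#'
#' Stages, in order: label validation and junction-graph extraction;
#' junction-intensity measurement, orientation binning and the planar
#' polarity statistic; junctional/medial fluorescence partition;
#' coordination-number analysis at every requested radius with histograms
#' and a colour-coded raster; apical-area statistics; and, when an embryo
#' table is supplied, morphometric summaries with pairwise Student's
#' t-tests. All tabular outputs are written under `config$out_dir`, and a
#' `report.json` records configuration, package version, and per-stage
#' counts. Given identical inputs and configuration the outputs are
#' byte-identical.
#'
#' @param config a [run_config()] object.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$label, config$channel, config$embryos)) {
    if (!is.null(p) && !file.exists(p)) stop(sprintf("input file not found: %s", p))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  report <- list(
    package_version = as.character(utils::packageVersion("neuralplate")),
    config = config[setdiff(names(config), "verbose")],
    stages = list()
  )

  log_stage(config, "[junction_graph] reading %s", config$label)
  label <- read_label_tiff(config$label, ml_axis = config$ml_axis)
  graph <- extract_junction_graph(label)
  write_junction_graph(graph, out("junctions.csv"), out("vertices.csv"))
  report$stages$junction_graph <- list(
    n_cells = nrow(graph$cells), n_junctions = nrow(graph$junctions),
    n_vertices = nrow(graph$vertices)
  )
  log_stage(config, "[junction_graph] %d cells, %d junctions, %d vertices",
            nrow(graph$cells), nrow(graph$junctions), nrow(graph$vertices))

  if (!is.null(config$channel)) {
    channel <- read_intensity_tiff(config$channel)
    if (isTRUE(attr(channel, "saturated"))) {
      warning("channel maximum sits at the 16-bit ceiling; projection may be saturated")
    }
    ji <- measure_junction_intensities(graph, channel,
                                       min_length = config$min_junction_length)
    pol <- polarity_summary(ji)
    utils::write.csv(
      data.frame(bin = pol$bins$bin, n = pol$bins$n,
                 mean = pol$bins$mean, sem = pol$bins$sem),
      out("polarity.csv"), row.names = FALSE
    )
    write_json_file(
      list(
        ml_mean = pol$axes$mean[pol$axes$axis_class == "ML"],
        ap_mean = pol$axes$mean[pol$axes$axis_class == "AP"],
        ratio = pol$ml_ap_ratio, t = pol$t_statistic, df = pol$df,
        p = pol$p_value, n_ml = pol$n_ml, n_ap = pol$n_ap,
        n_embryos = pol$n_embryos
      ),
      out("polarity_summary.json")
    )
    part <- partition_fluorescence(label, channel, margin = config$medial_margin)
    write_json_file(
      list(
        junctional_mean = part$junctional_mean, medial_mean = part$medial_mean,
        junctional_fraction = part$junctional_fraction,
        margin = part$margin, excluded_pixels = part$excluded_pixels,
        n_cells_excluded = part$n_cells_excluded
      ),
      out("partition.json")
    )
    report$stages$polarity <- list(
      ml_ap_ratio = pol$ml_ap_ratio, p_value = pol$p_value,
      n_ml = pol$n_ml, n_ap = pol$n_ap,
      junctional_fraction = part$junctional_fraction
    )
    log_stage(config, "[polarity] ML/AP ratio %.3f (p = %.3g); junctional fraction %.3f",
              pol$ml_ap_ratio, pol$p_value, part$junctional_fraction)
  }

  maps <- list()
  hist_rows <- list()
  cluster_rows <- list()
  for (k in config$radius_k) {
    maps[[as.character(k)]] <- coordination_numbers(
      label, radius_k = k, metric = config$metric, validate = FALSE
    )
    h <- coordination_histogram(maps[[as.character(k)]])
    hist_rows[[as.character(k)]] <- cbind(k = k, h)
    cl <- maps[[as.character(k)]]$clusters
    if (nrow(cl)) cluster_rows[[as.character(k)]] <- cbind(k = k, cl)
  }
  first_map <- maps[[1L]]
  areas <- apical_area_stats(label, exclude_border = config$exclude_border)
  coord_tab <- data.frame(
    cell = areas$cells$cell, area_px = areas$cells$area_px,
    border_cell = areas$cells$border_cell
  )
  for (k in config$radius_k) {
    coord_tab[[paste0("coordination_k", k)]] <- maps[[as.character(k)]]$cells$coordination
  }
  utils::write.csv(coord_tab, out("coordination.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, hist_rows), out("histogram.csv"), row.names = FALSE)
  if (length(cluster_rows)) {
    utils::write.csv(do.call(rbind, cluster_rows), out("clusters.csv"), row.names = FALSE)
  }
  write_intensity_tiff(color_code_clusters(label, first_map), out("coordination_coded.tif"))
  report$stages$rosettes <- list(
    n_clusters = vapply(maps, function(mp) nrow(mp$clusters), integer(1)),
    max_coordination = vapply(maps, function(mp) max(mp$cells$coordination), integer(1)),
    mean_area = areas$mean, sem_area = areas$sem, n_cells = areas$n_cells,
    border_excluded = areas$border_excluded
  )
  log_stage(config, "[rosettes] mean apical area %.1f px (n = %d); max coordination %s",
            areas$mean, areas$n_cells,
            paste(report$stages$rosettes$max_coordination, collapse = "/"))

  if (!is.null(config$embryos)) {
    emb <- utils::read.csv(config$embryos, stringsAsFactors = FALSE)
    ms <- morpho_summary(emb, wildtype_genotype = config$wildtype_genotype)
    utils::write.csv(ms, out("morpho_summary.csv"), row.names = FALSE)
    mw <- litter_axis_ratios(emb, wildtype_genotype = config$wildtype_genotype)
    gts <- unique(mw$genotype)
    tests <- list()
    if (length(gts) >= 2L) {
      for (i in seq_len(length(gts) - 1L)) {
        for (j in (i + 1L):length(gts)) {
          a <- mw$mw_ratio[mw$genotype == gts[i]]
          b <- mw$mw_ratio[mw$genotype == gts[j]]
          if (length(a) >= 2L && length(b) >= 2L) {
            tt <- students_t(a, b)
            tests[[paste(gts[i], "vs", gts[j])]] <-
              tt[c("t", "df", "p", "mean_a", "mean_b", "n_a", "n_b")]
          }
        }
      }
    }
    write_json_file(tests, out("tests.json"))
    report$stages$morphometrics <- list(
      n_embryos = nrow(emb), genotypes = nrow(ms)
    )
    log_stage(config, "[morphometrics] %d embryos, %d genotypes", nrow(emb), nrow(ms))
  }

  write_json_file(report, out("report.json"))
  invisible(report)
}

#' Preset synthetic fixtures
#'
#' Emits, under `out_dir`, a complete synthetic data set (label TIFF,
#' fluorescence channel TIFF, ground-truth CSVs, embryo cohort CSV) plus a
#' ready [run_config()] for one of three presets:
#'
#' * `wildtype` — polarised tissue (ML:AP ratio 2), 90% junctional signal,
#'   baseline apical areas, high-cellularity rosettes;
#' * `shroom3_mutant` — apical-constriction mutant: 48% larger apical areas,
#'   ~40% dimmer junctions with half of the signal medial, lower-cellularity
#'   rosettes, ML enrichment of the remaining junctional signal retained;
#' * `unpolarized` — planar-polarity mutant: ML:AP ratio 1, otherwise
#'   wildtype-like.
#'
#' @param out_dir writable directory (created if missing).
#' @param preset one of `"wildtype"`, `"shroom3_mutant"`, `"unpolarized"`.
#' @param rng_seed integer seed.
#' @return list with the written `paths`, the generator parameter objects,
#'   and the `config`.
#' @export
make_fixture <- function(out_dir, preset = c("wildtype", "shroom3_mutant", "unpolarized"),
                         rng_seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pp <- fixture_presets(rng_seed)[[preset]]
  tess <- generate_tessellation(pp$tess)
  channel <- render_channel(tess$label, tess$truth, pp$render)
  cohort <- simulate_cohort(fixture_cohort_params(rng_seed))

  paths <- list(
    label = file.path(out_dir, "label.tif"),
    channel = file.path(out_dir, "channel.tif"),
    cells = file.path(out_dir, "cells.csv"),
    junctions = file.path(out_dir, "junctions_truth.csv"),
    rosettes = file.path(out_dir, "rosettes_truth.csv"),
    embryos = file.path(out_dir, "embryos.csv")
  )
  write_label_tiff(tess$label, paths$label)
  write_intensity_tiff(channel, paths$channel)
  utils::write.csv(tess$truth$cells[, c("cell_id", "area")], paths$cells, row.names = FALSE)
  tj <- tess$truth$junctions
  tj$true_intensity <- intensity_law(tj$theta_deg, pp$render)
  utils::write.csv(tj, paths$junctions, row.names = FALSE)
  utils::write.csv(tess$truth$rosettes, paths$rosettes, row.names = FALSE)
  utils::write.csv(cohort, paths$embryos, row.names = FALSE)

  config <- run_config(
    label = paths$label, channel = paths$channel, embryos = paths$embryos,
    out_dir = file.path(out_dir, "results"), seed = rng_seed, verbose = FALSE
  )
  list(paths = paths, tess_params = pp$tess, render_params = pp$render,
       truth = tess$truth, config = config)
}

# Preset parameter tables. The mutant echoes an apical-constriction
# phenotype: 1.48x apical area, junctional signal reduced to 0.6x with only
# half of the total signal junctional; ML enrichment of what remains is
# retained. The unpolarized preset models loss of planar polarity (rho = 1).
fixture_presets <- function(rng_seed = 1L) {
  base_tess <- function(...) {
    tessellation_params(
      image_height = 220L, image_width = 220L, n_rows = 12L, n_cols = 12L,
      jitter_sd = 0.75, rosette_count = 2L, rng_seed = rng_seed, ...
    )
  }
  list(
    wildtype = list(
      tess = base_tess(rosette_cellularity = 7L),
      render = render_params(
        base_intensity = 100, anisotropy_rho = 2, junctional_fraction = 0.9,
        noise_sd = 5, rng_seed = rng_seed + 101L
      )
    ),
    shroom3_mutant = list(
      tess = base_tess(rosette_cellularity = 5L, area_scale = 1.48),
      render = render_params(
        base_intensity = 60, anisotropy_rho = 2, junctional_fraction = 0.5,
        noise_sd = 5, rng_seed = rng_seed + 102L
      )
    ),
    unpolarized = list(
      tess = base_tess(rosette_cellularity = 7L),
      render = render_params(
        base_intensity = 100, anisotropy_rho = 1, junctional_fraction = 0.9,
        noise_sd = 5, rng_seed = rng_seed + 103L
      )
    )
  )
}

# Cohort emulating the genetic-interaction crosses: penetrances of 37.5%
# and 75% for the single- and double-insult genotypes and a shortened axis
# in the double mutant.
fixture_cohort_params <- function(rng_seed = 1L) {
  cohort_params(
    genotypes = data.frame(
      genotype = c("+/+", "Shroom3+/gt;Vangl2+/Lp", "Shroom3gt/gt;Vangl2+/Lp"),
      n_embryos = c(24L, 24L, 12L),
      ntd_probability = c(0, 0.375, 0.75),
      axis_mean = c(5.0, 4.6, 3.9),
      axis_sd = c(0.25, 0.25, 0.25),
      sb_fraction_mean = c(0, 0.15, 0.35)
    ),
    rng_seed = rng_seed + 201L
  )
}
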