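#' Parameters of a synthetic embryo cohort
#'
#' One row of `genotypes` per genotype: number of embryos, probability of a
#' neural tube defect, mean and SD of the anteroposterior axis length
#' (2nd cervical vertebra to pelvic girdle, arbitrary length units), the mean
#' spina bifida fraction (open-spinal-cord length / axis length) for affected
#' embryos, and the NTD class assigned to affected embryos.
#'
#' Embryos are grouped into litters such that every litter contains at least
#' one wildtype embryo — required for mutant:wildtype axis normalisation.
#'
#' @param genotypes data frame with columns `genotype`, `n_embryos`,
#'   `ntd_probability`, `axis_mean`, `axis_sd`, `sb_fraction_mean`, and
#'   optionally `ntd_type` (default "spina_bifida").
#' @param wildtype_genotype the genotype string treated as wildtype
#'   (default `"+/+"`); must appear in `genotypes`.
#' @param litter_size target embryos per litter (default 8).
#' @param rng_seed integer seed.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(genotypes, wildtype_genotype = "+/+",
                          litter_size = 8L, rng_seed = 1L) {
  req <- c("genotype", "n_embryos", "ntd_probability", "axis_mean",
           "axis_sd", "sb_fraction_mean")
  if (!all(req %in% names(genotypes))) {
    stop("`genotypes` must have columns: ", paste(req, collapse = ", "))
  }
  if (!wildtype_genotype %in% genotypes$genotype) {
    stop(sprintf("wildtype genotype %s missing from `genotypes`", wildtype_genotype))
  }
  if (any(genotypes$ntd_probability < 0 | genotypes$ntd_probability > 1)) {
    stop("ntd_probability must be in [0, 1]")
  }
  if (any(genotypes$sb_fraction_mean < 0 | genotypes$sb_fraction_mean > 1)) {
    stop("sb_fraction_mean must be in [0, 1]")
  }
  if (any(genotypes$axis_sd < 0)) stop("axis_sd must be >= 0")
  if (any(genotypes$axis_mean <= 0)) stop("axis_mean must be > 0")
  if (is.null(genotypes$ntd_type)) genotypes$ntd_type <- "spina_bifida"
  structure(
    list(
      genotypes = genotypes, wildtype_genotype = wildtype_genotype,
      litter_size = as.integer(litter_size), rng_seed = as.integer(rng_seed)
    ),
    class = "cohort_params"
  )
}

#' Simulate an embryo cohort
#'
#' Draws, per embryo: NTD status Bernoulli(`ntd_probability`); axis length
#' Normal(`axis_mean`, `axis_sd`) truncated at zero; spina bifida length
#' `sb_fraction_mean * axis_length` for affected spina-bifida embryos
#' (`NA` otherwise — craniorachischisis and exencephaly carry no measurable
#' spina bifida length). Embryos are dealt into litters round-robin with the
#' wildtype embryos spread first, so every litter holds >= 1 wildtype.
#'
#' @param params a [cohort_params()] object.
#' @return data frame (the embryo table) with columns `embryo_id`, `litter`,
#'   `genotype`, `ntd` (one of none/spina_bifida/exencephaly/
#'   craniorachischisis), `axis_len`, `sb_len`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  g <- params$genotypes
  with_seed(params$rng_seed, {
    n_wt <- g$n_embryos[g$genotype == params$wildtype_genotype]
    n_total <- sum(g$n_embryos)
    n_litters <- max(1L, min(n_wt, ceiling(n_total / params$litter_size)))

    rows <- lapply(seq_len(nrow(g)), function(i) {
      n <- g$n_embryos[i]
      if (n < 1L) return(NULL)
      affected <- stats::runif(n) < g$ntd_probability[i]
      axis <- stats::rnorm(n, g$axis_mean[i], g$axis_sd[i])
      while (any(axis <= 0)) {
        bad <- axis <= 0
        axis[bad] <- stats::rnorm(sum(bad), g$axis_mean[i], g$axis_sd[i])
      }
      ntd <- ifelse(affected, g$ntd_type[i], "none")
      sb <- ifelse(affected & ntd == "spina_bifida",
                   g$sb_fraction_mean[i] * axis, NA_real_)
      data.frame(genotype = g$genotype[i], ntd = ntd,
                 axis_len = axis, sb_len = sb)
    })
    tab <- do.call(rbind, rows)

    is_wt <- tab$genotype == params$wildtype_genotype
    litter <- integer(nrow(tab))
    litter[is_wt] <- rep_len(seq_len(n_litters), sum(is_wt))
    litter[!is_wt] <- rep_len(seq_len(n_litters), sum(!is_wt))
    tab <- data.frame(
      embryo_id = sprintf("E%03d", seq_len(nrow(tab))),
      litter = sprintf("L%02d", litter),
      tab,
      row.names = NULL
    )
    tab
  })
}
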