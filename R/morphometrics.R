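#' Neural tube defect penetrance
#'
#' Percent of embryos of a genotype exhibiting the phenotype,
#' `100 * affected / total`. Printing convention: round half away from zero
#' to `decimals` places with trailing zeros dropped (so 9/24 prints 37.5 and
#' 9/12 prints 75); `style = "integer"` rounds to a whole percent (3/9
#' prints 33). A warning is issued for `total < 4`, the conventional minimum
#' group size for penetrance reporting.
#'
#' @param affected,total non-negative counts, `affected <= total`, `total >= 1`.
#' @param decimals decimal places for `style = "decimal"` (default 1).
#' @param style `"decimal"` (default) or `"integer"`.
#' @return penetrance in percent, as a number.
#' @examples
#' penetrance(9, 24) # 37.5
#' penetrance(9, 12) # 75
#' penetrance(3, 9, style = "integer") # 33
#' @export
penetrance <- function(affected, total, decimals = 1, style = c("decimal", "integer")) {
  style <- match.arg(style)
  stopifnot_scalar(affected, "affected", 0)
  stopifnot_scalar(total, "total")
  if (total < 1) stop("`total` must be >= 1")
  if (affected > total) stop("`affected` cannot exceed `total`")
  if (total < 4) warning(sprintf("penetrance from only %d embryos (minimum n = 4 convention)", total))
  pct <- 100 * affected / total
  d <- if (style == "integer") 0 else decimals
  # round half away from zero (printing convention; R's round() is half-even)
  sign(pct) * floor(abs(pct) * 10^d + 0.5) / 10^d
}

#' Mutant:wildtype axis-length ratio
#'
#' @param mutant_length,wildtype_littermate_length axis lengths (> 0) of a
#'   mutant embryo and its wildtype littermate.
#' @return dimensionless m/w ratio.
#' @export
axis_ratio <- function(mutant_length, wildtype_littermate_length) {
  stopifnot_scalar(mutant_length, "mutant_length", lower = 1e-12)
  stopifnot_scalar(wildtype_littermate_length, "wildtype_littermate_length", lower = 1e-12)
  mutant_length / wildtype_littermate_length
}

#' Per-embryo m/w ratios across an embryo table
#'
#' Normalises every non-wildtype embryo's axis length to its wildtype
#' littermate. When a litter contains several wildtypes the normaliser is
#' their mean axis length (`normalizer = "mean"`, the default) or the first
#' listed wildtype (`"first"`). A litter without any wildtype embryo is an
#' error naming the litter.
#'
#' @param embryos embryo table as produced by [simulate_cohort()] (columns
#'   `litter`, `genotype`, `axis_len` required).
#' @param wildtype_genotype genotype string treated as wildtype.
#' @param normalizer `"mean"` or `"first"`.
#' @return the embryo table restricted to non-wildtype embryos, with an
#'   `mw_ratio` column appended.
#' @export
litter_axis_ratios <- function(embryos, wildtype_genotype = "+/+",
                               normalizer = c("mean", "first")) {
  normalizer <- match.arg(normalizer)
  req <- c("litter", "genotype", "axis_len")
  if (!all(req %in% names(embryos))) {
    stop("embryo table must have columns: ", paste(req, collapse = ", "))
  }
  mut <- embryos[embryos$genotype != wildtype_genotype, , drop = FALSE]
  wt <- embryos[embryos$genotype == wildtype_genotype, , drop = FALSE]
  norm <- vapply(mut$litter, function(l) {
    w <- wt$axis_len[wt$litter == l]
    if (length(w) == 0L) {
      stop(sprintf("litter %s has no wildtype littermate for normalisation", l))
    }
    if (normalizer == "mean") mean(w) else w[1L]
  }, numeric(1))
  mut$mw_ratio <- mut$axis_len / norm
  rownames(mut) <- NULL
  mut
}

#' Spina bifida severity
#'
#' Length of the open spinal cord as a fraction of the body axis length.
#'
#' @param sb_length spina bifida length, `0 <= sb_length <= axis_length`.
#' @param axis_length body axis length, > 0.
#' @return severity ratio in [0, 1].
#' @export
spina_bifida_severity <- function(sb_length, axis_length) {
  stopifnot_scalar(sb_length, "sb_length", 0)
  stopifnot_scalar(axis_length, "axis_length", lower = 1e-12)
  if (sb_length > axis_length) stop("sb_length cannot exceed axis_length")
  sb_length / axis_length
}

#' Two-tailed unpaired Student's t-test (pooled variance)
#'
#' The significance test used throughout the analyses: pooled-variance
#' two-sample t with `df = n_a + n_b - 2` and a two-tailed p-value. Group
#' means with standard errors of the mean are returned alongside. Two groups
#' with zero pooled variance and equal means give `t = 0, p = 1`; zero
#' pooled variance with unequal means is an error (infinite t).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `sem_a`, `sem_b`,
#'   `n_a`, `n_b`.
#' @export
students_t <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled_var <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      res <- list(t = 0, df = length(a) + length(b) - 2L, p = 1)
    } else {
      stop("zero pooled variance with unequal means: t undefined")
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  c(res, list(
    mean_a = mean(a), mean_b = mean(b),
    sem_a = sem(a), sem_b = sem(b),
    n_a = length(a), n_b = length(b)
  ))
}

#' Genotype-level morphometric summary of an embryo table
#'
#' Per genotype: group size, NTD penetrance (percent), mean and s.e.m. of
#' the m/w axis ratio (non-wildtype genotypes), and mean and s.e.m. of spina
#' bifida severity over affected embryos with a measurable spina bifida.
#' Craniorachischisis embryos (fully open axis, no defined spina bifida
#' length) count towards penetrance but are excluded from severity.
#'
#' @inheritParams litter_axis_ratios
#' @return data frame with one row per genotype.
#' @export
morpho_summary <- function(embryos, wildtype_genotype = "+/+",
                           normalizer = c("mean", "first")) {
  normalizer <- match.arg(normalizer)
  mw <- litter_axis_ratios(embryos, wildtype_genotype, normalizer)
  gts <- unique(embryos$genotype)
  out <- lapply(gts, function(gt) {
    sub <- embryos[embryos$genotype == gt, , drop = FALSE]
    aff <- sum(sub$ntd != "none")
    pen <- suppressWarnings(penetrance(aff, nrow(sub)))
    r <- mw$mw_ratio[mw$genotype == gt]
    sev <- sub$sb_len[!is.na(sub$sb_len)] /
      sub$axis_len[!is.na(sub$sb_len)]
    data.frame(
      genotype = gt, n = nrow(sub), affected = aff, penetrance_pct = pen,
      mean_mw = if (length(r)) mean(r) else NA_real_,
      sem_mw = if (length(r) > 1) sem(r) else NA_real_,
      mean_severity = if (length(sev)) mean(sev) else NA_real_,
      sem_severity = if (length(sev) > 1) sem(sev) else NA_real_
    )
  })
  do.call(rbind, out)
}
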