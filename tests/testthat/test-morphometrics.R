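test_that("penetrance reproduces the standard printing conventions", {
  expect_identical(penetrance(9, 24), 37.5)
  expect_identical(penetrance(9, 12), 75)
  expect_identical(penetrance(3, 9, style = "integer"), 33)
  expect_identical(penetrance(0, 10), 0)
  expect_identical(penetrance(1, 3000), 0) # rounds below 0.05
  expect_warning(penetrance(1, 3), "minimum n")
  expect_error(penetrance(5, 0), "total")
  expect_error(penetrance(5, 4), "exceed")
})

test_that("axis ratio and severity obey their bounds and errors", {
  expect_identical(axis_ratio(4, 5), 0.8)
  expect_identical(axis_ratio(5, 5), 1)
  expect_error(axis_ratio(0, 5))
  expect_identical(spina_bifida_severity(0, 7), 0)
  expect_identical(spina_bifida_severity(7, 7), 1)
  expect_error(spina_bifida_severity(8, 7), "exceed")
})

test_that("litter normalisation uses wildtype littermates and names gaps", {
  emb <- data.frame(
    litter = c("L1", "L1", "L1", "L2", "L2"),
    genotype = c("+/+", "+/+", "mut", "+/+", "mut"),
    axis_len = c(4, 6, 4, 5, 4.5)
  )
  mw <- litter_axis_ratios(emb)
  expect_equal(mw$mw_ratio, c(4 / 5, 4.5 / 5)) # L1 wildtype mean = 5
  mw_first <- litter_axis_ratios(emb, normalizer = "first")
  expect_equal(mw_first$mw_ratio[1], 1)
  orphan <- data.frame(litter = "L9", genotype = "mut", axis_len = 3)
  expect_error(litter_axis_ratios(rbind(emb, orphan)), "L9")
})

test_that("students_t matches the textbook pooled-variance formula", {
  textbook_t <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    df <- length(a) + length(b) - 2
    list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
  }
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(4 + i, 10, 2)
    b <- rnorm(9 - i, 12, 3)
    got <- students_t(a, b)
    want <- textbook_t(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_identical(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_equal(students_t(c(1, 2, 3, 4), c(2, 3, 4, 5))$t,
               textbook_t(c(1, 2, 3, 4), c(2, 3, 4, 5))$t, tolerance = 1e-10)
})

test_that("students_t is antisymmetric, shift-invariant and handles zero variance", {
  set.seed(6)
  a <- rnorm(8); b <- rnorm(10, 1)
  f <- students_t(a, b); r <- students_t(b, a)
  expect_equal(f$t, -r$t)
  expect_equal(f$p, r$p)
  sh <- students_t(a + 100, b + 100)
  expect_equal(sh$t, f$t)
  same <- students_t(c(2, 2, 2), c(2, 2, 2))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_identical(students_t(1:3, 1:3)$t, 0)
  expect_error(students_t(c(1, 1), c(2, 2)), "zero pooled variance")
})

test_that("simulated cohorts reproduce their generating parameters", {
  g0 <- data.frame(
    genotype = c("+/+", "mut"), n_embryos = c(60L, 60L),
    ntd_probability = c(0, 0), axis_mean = c(5, 5), axis_sd = c(0.2, 0.2),
    sb_fraction_mean = c(0, 0)
  )
  tab0 <- simulate_cohort(cohort_params(g0, rng_seed = 2L))
  expect_identical(sum(tab0$ntd != "none"), 0L)
  expect_true(all(table(tab0$litter, tab0$genotype)[, "+/+"] >= 1))

  g1 <- g0
  g1$ntd_probability <- c(0, 0.75)
  g1$n_embryos <- c(100L, 400L)
  g1$axis_mean <- c(5, 4)
  g1$sb_fraction_mean <- c(0, 0.3)
  tab1 <- simulate_cohort(cohort_params(g1, rng_seed = 3L))
  pen <- 100 * mean(tab1$ntd[tab1$genotype == "mut"] != "none")
  expect_lt(abs(pen - 75), 5)
  mw <- litter_axis_ratios(tab1)
  expect_equal(mean(mw$mw_ratio), 0.8, tolerance = 0.02)
  sm <- morpho_summary(tab1)
  expect_equal(sm$mean_severity[sm$genotype == "mut"], 0.3, tolerance = 0.03)
  # determinism
  expect_identical(tab1, simulate_cohort(cohort_params(g1, rng_seed = 3L)))
})

test_that("significance calls track simulated effects at calibrated rates", {
  g <- function(delta) data.frame(
    genotype = c("+/+", "a", "b"), n_embryos = c(12L, 10L, 10L),
    ntd_probability = 0, axis_mean = c(5, 4.99, 4.99 - delta),
    axis_sd = 0.25, sb_fraction_mean = 0
  )
  pvals <- function(delta, seeds) {
    vapply(seeds, function(s) {
      tab <- simulate_cohort(cohort_params(g(delta), rng_seed = s))
      mw <- litter_axis_ratios(tab)
      students_t(mw$mw_ratio[mw$genotype == "a"], mw$mw_ratio[mw$genotype == "b"])$p
    }, numeric(1))
  }
  # large effect (an axis shortened by 20%): detected at p < 0.001
  expect_gte(mean(pvals(1.0, 1:50) < 0.001), 0.9)
  # null effect: false-positive rate at 0.001 stays below 1%
  expect_lte(mean(pvals(0, 1:200) < 0.001), 0.01)
})
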