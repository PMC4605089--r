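test_that("yield_pct matches an independent ratio on randomized masses", {
  expect_equal(yield_pct(0, 40), 0)
  expect_equal(yield_pct(19.644, 40), 49.11)
  expect_error(yield_pct(1, 0), "feed")
  expect_error(yield_pct(-1, 40), "product")
  set.seed(11)
  for (i in 1:1000) {
    m <- runif(1, 0, 50); f <- runif(1, 1, 100)
    expect_equal(yield_pct(m, f), 100 * m / f, tolerance = 1e-12)
  }
})

test_that("mass closure sums component yields and complements to 100", {
  # non-catalytic 300 C column: 49.11 + 20.06 + 1.09 + 16.28
  sl <- product_slate(40, 19.644 * 0.7, 19.644 * 0.3, 8.024, 0.436, 6.512)
  cl <- mass_closure(sl)
  expect_equal(cl$total_recovery_pct, 86.54)
  expect_equal(cl$mass_lost_pct, 13.46)
  expect_equal(cl$total_recovery_pct + cl$mass_lost_pct, 100)

  # vented-gas run: gas NA contributes zero, reported as NA
  sl2 <- product_slate(40, 22.552 * 0.7, 22.552 * 0.3, 12.26, NA, 0.584)
  cl2 <- mass_closure(sl2)
  expect_true(is.na(cl2$gas_yield_pct))
  expect_equal(cl2$total_recovery_pct, 88.49)
  expect_equal(cl2$mass_lost_pct, 11.51)

  # all-zero products
  cl3 <- mass_closure(product_slate(40, 0, 0, 0, 0, 0))
  expect_equal(cl3$total_recovery_pct, 0)
  expect_equal(cl3$mass_lost_pct, 100)

  # closure is exact on random slates
  set.seed(12)
  for (i in 1:200) {
    f <- runif(1, 1, 100); y <- runif(4, 0, 0.25)
    cl <- mass_closure(product_slate(f, y[1] * f, 0, y[2] * f, y[3] * f,
                                     y[4] * f))
    comp <- c(cl$biocrude_yield_pct, cl$solids_yield_pct, cl$gas_yield_pct,
              cl$nvr_yield_pct)
    expect_equal(cl$total_recovery_pct, sum(comp), tolerance = 1e-15)
    expect_identical(cl$mass_lost_pct, 100 - cl$total_recovery_pct)
  }
})

test_that("energy recovery reproduces the reported treatment values", {
  expect_equal(energy_recovery(0.5638, 36.65, 24.88), 83.05, tolerance = 1e-4)
  expect_equal(energy_recovery(0.4911, 36.55, 24.88), 72.14, tolerance = 2e-3)
  expect_equal(energy_recovery(0.5261, 37.00, 24.88), 78.25, tolerance = 2e-3)
  expect_equal(energy_recovery(0.5794, 37.01, 24.88), 86.20, tolerance = 2e-3)
  expect_equal(energy_recovery(1, 24.88, 24.88), 100)
  expect_error(energy_recovery(0.5, 36, 0), "hhv_feed")
  expect_error(energy_recovery(1.2, 36, 24), "1.05")
})

test_that("carbon-hydrogen recovery matches direct arithmetic", {
  feed <- yeast_feedstock()
  crude_cos <- fraction_properties(74.67, 12.56, 0.51, 12.58, 0.05, 36.65)
  expect_equal(ch_recovery(0.5638, crude_cos, feed), 77.3, tolerance = 1e-3)
  crude_non <- fraction_properties(77.54, 11.51, 1.96, 12.73, 0.06, 36.55)
  # recomputes to 68.7, a known 0.5-point gap from the reported lower
  # bound of 68.2; the arithmetic value is asserted, not forced
  expect_equal(ch_recovery(0.4911, crude_non, feed), 68.7, tolerance = 1e-2)
  expect_equal(ch_recovery(0, crude_non, feed), 0)
  set.seed(13)
  for (i in 1:1000) {
    y <- runif(1, 0, 1)
    cc <- runif(1, 50, 85); hh <- runif(1, 5, 14)
    cr <- fraction_properties(cc, hh, 1, 10, 0.05, 36)
    expect_equal(ch_recovery(y, cr, feed),
                 100 * y * (cc + hh) / (54.92 + 8.73), tolerance = 1e-12)
  }
})

test_that("atomic ratios agree with mole arithmetic and reported rounding", {
  expect_equal(round(atomic_ratio(12.73, 77.54, 16, 12), 2), 0.12)
  expect_equal(round(atomic_ratio(1.96, 77.54, 14, 12), 2), 0.02)
  expect_equal(atomic_ratio(0, 77.54, 16, 12), 0)
  expect_error(atomic_ratio(10, 0, 16, 12), "element_pct_c")
  set.seed(14)
  for (i in 1:1000) {
    x <- runif(1, 0, 40); cc <- runif(1, 30, 90)
    mx <- runif(1, 1, 40); mc <- runif(1, 1, 40)
    expect_equal(atomic_ratio(x, cc, mx, mc), (x / mx) / (cc / mc),
                 tolerance = 1e-12)
  }
})

test_that("oxygen by difference flags inconsistencies instead of hiding them", {
  # feedstock: 100 - 54.92 - 8.73 - 2.40 = 33.95 (printed value is 33.85)
  expect_equal(oxygen_by_difference(54.92, 8.73, 2.40), 33.95)
  expect_equal(oxygen_by_difference(60, 30, 10), 0)
  # biocrude with ash: 8.93, far from the printed 12.73 -> surfaced as a gap
  o <- oxygen_by_difference(77.54, 11.51, 1.96, include_ash = TRUE,
                            ash_pct = 0.06)
  expect_equal(o, 8.93)
  acc <- account_experiments(htl_reference_runs())
  expect_equal(acc$o_by_difference_gap_pct[1], 12.73 - 8.93)
  expect_error(oxygen_by_difference(80, 20, 5), "102")
})

test_that("relative yield change reproduces the catalyst effect", {
  expect_equal(relative_yield_change(49.11, 52.61), 7.1, tolerance = 1e-1)
  expect_equal(round(relative_yield_change(49.11, 52.61), 1), 7.1)
  expect_equal(relative_yield_change(5, 5), 0)
  expect_equal(relative_yield_change(56.38, 57.94), 100 * 1.56 / 56.38)
  expect_error(relative_yield_change(0, 10), "baseline")
})

test_that("one-way ANOVA equals a from-scratch sum-of-squares oracle", {
  anova_oracle <- function(groups) {
    y <- unlist(groups); n <- lengths(groups)
    gm <- mean(y)
    means <- vapply(groups, mean, numeric(1))
    ssb <- sum(n * (means - gm)^2)
    ssw <- sum(unlist(mapply(function(g, m) (g - m)^2, groups, means,
                             SIMPLIFY = FALSE)))
    df1 <- length(groups) - 1; df2 <- length(y) - length(groups)
    f <- (ssb / df1) / (ssw / df2)
    list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  res <- anova_one_way(list(c(10, 12), c(20, 22)))
  orc <- anova_oracle(list(c(10, 12), c(20, 22)))
  expect_equal(res$f_statistic, orc$f, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)

  ident <- anova_one_way(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$f_statistic, 0)
  expect_equal(ident$p_value, 1)

  expect_error(anova_one_way(list(c(1, 2))), "two groups")
  expect_error(anova_one_way(list(c(1, 2), 3)), "replicates")

  set.seed(15)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(2:6, 1), mean = runif(1, 0, 10), sd = runif(1, 0.1, 2)))
    res <- anova_one_way(groups)
    orc <- anova_oracle(groups)
    expect_equal(res$f_statistic, orc$f, tolerance = 1e-9)
    expect_equal(res$p_value, orc$p, tolerance = 1e-9)
  }
})

test_that("gas normalization scales to unit sum and is idempotent", {
  g <- normalize_gas(gas_profile(c(CO2 = 93, CO = 5, CH4 = 1, C2H6 = 1)))
  expect_equal(sum(g$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(g$fractions[["CO2"]]), 0.93)
  g2 <- normalize_gas(g)
  expect_equal(g2$fractions, g$fractions, tolerance = 1e-12)
  expect_error(normalize_gas(gas_profile(c(CO2 = 0, CO = 0))), "positive")
  set.seed(16)
  for (i in 1:200) {
    v <- runif(4, 0.001, 10); names(v) <- c("CO2", "CO", "CH4", "C2H6")
    gn <- normalize_gas(gas_profile(v))
    expect_equal(unname(gn$fractions), unname(v / sum(v)), tolerance = 1e-12)
  }
})
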