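test_that("pearson_r matches the definition and validates input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_error(pearson_r(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(pearson_r(1:3, 1:4), "length")
  expect_error(pearson_r(1:2, 2:3), "3 paired")
  # invariant under positive affine transforms of either argument
  set.seed(8)
  x <- rnorm(20); y <- x + rnorm(20)
  expect_equal(pearson_r(2.5 * x + 7, y), pearson_r(x, y))
  expect_equal(pearson_r(x, 0.3 * y - 2), pearson_r(x, y))
})

test_that("per-age correlation series respects sample-size bookkeeping", {
  ds <- generate_population(synthetic_config(n_cells = 120), seed = 21)
  co <- fit_cohort(ds)
  ser <- per_age_lifespan_correlation(co, "fold_increase", min_n = 10)
  expect_true(all(abs(ser$r) <= 1))
  expect_true(all(diff(ser$n) <= 0))          # cells only drop out with age
  expect_true(all(ser$n >= 10))
  # pre-SEP restriction never increases the per-age sample
  pre <- per_age_lifespan_correlation(co, "fold_increase", min_n = 10,
                                      exclude_post_sep = TRUE)
  joined <- merge(ser, pre, by = "age", suffixes = c("_all", "_pre"))
  expect_true(all(joined$n_pre <= joined$n_all))
  expect_error(per_age_lifespan_correlation(co, "no_such_feature"), "unknown")
})

test_that("permuted lifespans give null per-age correlations", {
  ds <- generate_population(synthetic_config(n_cells = 150), seed = 31)
  co <- fit_cohort(ds)
  pts <- co$points
  rls <- setNames(co$cells$rls, co$cells$cell_id)
  set.seed(77)
  rs <- c(); ns <- c()
  for (a in c(2, 4, 6, 8, 10)) {
    sel <- pts$age == a
    if (sum(sel) < 20) next
    alive <- rls[pts$cell_id[sel]]
    for (perm in 1:60) {
      rs <- c(rs, cor(pts$fold[sel], sample(alive)))
      ns <- c(ns, sum(sel))
    }
  }
  expect_lt(abs(mean(rs)), 0.02)                      # centred at zero
  expect_gte(mean(abs(rs) < 2 / sqrt(ns)), 0.9)       # ~95% inside null band
})

test_that("median split uses a strict below-threshold rule", {
  cells <- list(
    cell_life_history("a", c(10, 11), c(0, 1)),
    cell_life_history("b", c(10, 12), c(0, 1)),
    cell_life_history("c", c(10, 13), c(0, 1)),
    cell_life_history("d", c(10, 14), c(0, 1)))
  co <- fit_cohort(life_history_dataset(cells))
  sp <- median_split_at_age(co, age = 2, feature = "raw_size")
  expect_equal(sp$threshold, 12.5)
  expect_setequal(sp$less_ids, c("a", "b"))
  expect_setequal(sp$more_ids, c("c", "d"))
  expect_false(sp$degenerate)
  expect_error(median_split_at_age(co, age = 9), "age 9")

  tied <- list(cell_life_history("x", c(10, 12), c(0, 1)),
               cell_life_history("y", c(10, 12), c(0, 1)),
               cell_life_history("z", c(10, 12), c(0, 1)))
  sp2 <- median_split_at_age(fit_cohort(life_history_dataset(tied)),
                             age = 2, feature = "raw_size")
  expect_true(sp2$degenerate)
  expect_equal(sp2$n_less, 0)  # everything lands at-or-above the threshold

  # only cells alive at the split age enter the partition
  mixed <- life_history_dataset(list(
    cell_life_history("long", 10 + 1:8, seq(0, 14, by = 2)),
    cell_life_history("mid", 10 + 1:6, seq(0, 10, by = 2)),
    cell_life_history("short", 10 + 1:3, c(0, 2, 4))))
  sp3 <- median_split_at_age(fit_cohort(mixed), age = 5, feature = "raw_size")
  expect_setequal(c(sp3$less_ids, sp3$more_ids), c("long", "mid"))
})

test_that("Kaplan-Meier estimate matches hand computation and the ECDF", {
  km <- km_estimate(c(1, 2, 3))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median_rls, 2)
  # without censoring the curve is the empirical survival function and the
  # median equals the sample median
  set.seed(12)
  for (i in 1:20) {
    ls <- sample(3:30, sample(5:40, 1), replace = TRUE)
    km <- km_estimate(ls)
    for (j in seq_len(nrow(km$curve)))
      expect_equal(km$curve$surv[j], mean(ls > km$curve$age[j]))
    expect_equal(km$median_rls, min(ls[2 * rank(ls, ties.method = "max") >=
                                         length(ls)]))
  }
  expect_error(km_estimate(numeric(0)), "no observations")
})

test_that("censoring pushes the KM median above the naive median", {
  obs <- c(10, 12, 14, 16, 18, 9, 9, 9, 9)
  ev <- c(rep(TRUE, 5), rep(FALSE, 4))
  km <- km_estimate(obs, ev)
  expect_equal(km$median_rls, 14)
  expect_gt(km$median_rls, median(obs))
})

test_that("log-rank test is symmetric, null on identical groups, and matches
           the hand-computed life table", {
  a <- c(5, 8, 12, 15)
  lr0 <- logrank_test(a, a)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  b <- c(4, 6, 9, 11, 20, 22)
  lr1 <- logrank_test(a, b)
  lr2 <- logrank_test(b, a)
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-10)
  expect_equal(lr1$statistic, oracle_logrank_chisq(a, b), tolerance = 1e-8)
  expect_equal(lr1$p_value,
               pchisq(oracle_logrank_chisq(a, b), 1, lower.tail = FALSE),
               tolerance = 1e-8)

  set.seed(4)
  for (i in 1:10) {
    ga <- sample(5:25, 8, replace = TRUE)
    gb <- sample(8:30, 10, replace = TRUE)
    expect_equal(logrank_test(ga, gb)$statistic,
                 oracle_logrank_chisq(ga, gb), tolerance = 1e-8)
  }
  expect_error(logrank_test(a, numeric(0)), "non-empty")
  expect_error(logrank_test(a, b, events_a = FALSE, events_b = FALSE),
               "no events")
})

test_that("rank-sum test: exact enumeration for small samples, approximation
           beyond", {
  x <- c(1.2, 3.4, 2.2)
  expect_equal(ranksum_test(x, x)$p_value, 1, tolerance = 1e-12)

  set.seed(9)
  for (i in 1:15) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    if (i <= 10) {               # continuous, no ties
      x <- rnorm(n); y <- rnorm(m, 0.8)
    } else {                     # heavy ties
      x <- sample(1:3, n, replace = TRUE)
      y <- sample(2:4, m, replace = TRUE)
    }
    got <- ranksum_test(x, y)
    expect_match(got$method, "exact")
    expect_equal(got$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12)
  }

  # no-ties exact path agrees with the classical exact distribution
  x <- c(0.3, 1.7, 2.9, 4.1); y <- c(0.9, 2.2, 5.5)
  expect_equal(ranksum_test(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)

  # large samples: tie-corrected normal approximation
  set.seed(10)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  got <- ranksum_test(x, y)
  expect_match(got$method, "approximation")
  expect_equal(got$p_value,
               wilcox.test(x, y, exact = FALSE)$p.value, tolerance = 1e-12)
  expect_error(ranksum_test(numeric(0), 1:3), "empty")
})

test_that("percent median difference reports integer percents", {
  expect_equal(percent_median_difference(17, 15), 13)
  expect_equal(percent_median_difference(10, 10), 0)
  expect_equal(percent_median_difference(30, 15), 100)
  expect_error(percent_median_difference(5, 0), "positive")
})

test_that("total fluorescence is the intensity-area product", {
  expect_equal(total_fluorescence(2, 20), 40)
  expect_equal(total_fluorescence(0, 123), 0)
  expect_equal(total_fluorescence(c(1, 2), c(10, 10)), c(10, 20))
  expect_error(total_fluorescence(-1, 5), "non-negative")
})

test_that("dilution coupling drives the concentration-size relation", {
  with_dil <- generate_population(synthetic_config(n_cells = 500,
                                                   fluor_dilution = 0.5),
                                  seed = 41)
  co1 <- fit_cohort(with_dil)
  rel <- concentration_size_relation(co1, age = 7)
  expect_lt(rel$r, -0.2)
  expect_lt(rel$slope, 0)

  no_dil <- generate_population(synthetic_config(n_cells = 500,
                                                 fluor_dilution = 0),
                                seed = 41)
  co0 <- fit_cohort(no_dil)
  rel0 <- concentration_size_relation(co0, age = 7)
  expect_lt(abs(rel0$r), 0.1)

  nofl <- life_history_dataset(make_test_cells())
  expect_error(concentration_size_relation(fit_cohort(nofl), 2),
               "fluorescence")
})

test_that("conditional screen with min_rls = 0 is the unconditional screen", {
  ds <- generate_population(synthetic_config(n_cells = 150), seed = 51)
  co <- fit_cohort(ds)
  un <- per_age_lifespan_correlation(co, "concentration", min_n = 10)
  cond <- conditional_age_correlation(co, "concentration", min_rls = 0,
                                      min_n = 10)
  expect_equal(cond, un)
  expect_error(conditional_age_correlation(co, "concentration",
                                           min_rls = 1000), "fewer than 3")
})

test_that("total reporter amount rises with age while concentration does not", {
  ds <- generate_population(synthetic_config(n_cells = 300), seed = 61)
  co <- fit_cohort(ds)
  fs <- fluorescence_fold_summary(co, min_n = 20)
  late <- fs[fs$age >= 10, ]
  expect_true(all(late$total_fold_median > 1.1))
  expect_true(all(late$avg_fold_median < 1.05))
  early <- fs$total_fold_median[fs$age <= 4]
  expect_lt(mean(early), mean(late$total_fold_median))
})
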