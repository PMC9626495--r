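test_that("the reference cutoff uses exclusive rank interpolation", {
  t3 <- load_fixture_cohort("table3")
  cm <- percentile_cutoff(t3$ln_a_over_n, 0.95)
  expect_equal(cm$interpolation_rank, 0.95 * 28)
  expect_equal(cm$cutoff, 6.75 + 0.6 * (7.13 - 6.75))
  expect_equal(cm$cutoff_2dp, 6.98)

  # integer rank: no interpolation
  expect_equal(percentile_cutoff(1:19, 0.95)$cutoff, 19)

  # random reference sets match the type-6 quantile estimator
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(27, 6, 0.8)
    expect_equal(percentile_cutoff(x, 0.95)$cutoff,
                 unname(quantile(x, 0.95, type = 6)))
  }
})

test_that("the cutoff is permutation invariant and monotone in p", {
  set.seed(6)
  x <- rnorm(27, 6, 0.8)
  expect_equal(percentile_cutoff(sample(x), 0.95)$cutoff,
               percentile_cutoff(x, 0.95)$cutoff)
  ps <- seq(0.1, 0.95, by = 0.05)
  cuts <- vapply(ps, function(p) percentile_cutoff(x, p)$cutoff, numeric(1))
  expect_true(all(diff(cuts) >= 0))

  expect_error(percentile_cutoff(rnorm(5), 0.95), "insufficient reference")
})

test_that("classification is AD above the cutoff, non-AD at or below", {
  expect_identical(classify_score(8.39, 6.98), "AD")
  expect_identical(classify_score(4.6, 6.98), "nonAD")
  expect_identical(classify_score(6.98, 6.98), "nonAD")  # boundary tie

  cm <- percentile_cutoff(load_fixture_cohort("table3")$ln_a_over_n)
  expect_identical(classify_score(c(7.1, 6.77), cm), c("AD", "nonAD"))
})

test_that("fixture cohorts separate perfectly at the control-derived cutoff", {
  t1 <- load_fixture_cohort("table1")
  t2 <- load_fixture_cohort("table2")
  t3 <- load_fixture_cohort("table3")
  cm <- percentile_cutoff(t3$ln_a_over_n)

  expect_true(all(t1$ln_a_over_n > cm$cutoff_2dp))
  expect_true(all(t2$ln_a_over_n < cm$cutoff_2dp))
  above <- t3$ln_a_over_n[t3$ln_a_over_n > cm$cutoff_2dp]
  expect_equal(above, 7.13)  # exactly one control above its own cutoff
})

test_that("the confusion report tallies calls against gold labels", {
  co <- rbind(load_fixture_cohort("table1"), load_fixture_cohort("table2"))
  rep <- confusion_report(co, 6.98)
  expect_identical(c(rep$tp, rep$fn, rep$fp, rep$tn), c(25L, 0L, 0L, 21L))
  s <- rep$statistics
  expect_equal(s$value[s$statistic %in% c("sensitivity", "specificity",
                                          "accuracy")],
               c(100, 100, 100))
  expect_true(all(rep$calls$correct))

  # controls may not enter the accuracy tables
  expect_error(confusion_report(rbind(co, load_fixture_cohort("table3")),
                                6.98),
               "AHC")

  empty <- confusion_report(co[0, ], 6.98)
  expect_identical(c(empty$tp, empty$fn, empty$fp, empty$tn),
                   c(0L, 0L, 0L, 0L))
  expect_true(all(is.na(empty$statistics$value)))
})

test_that("confusion counts match a brute-force tally on shifted cohorts", {
  spec <- cohort_spec(n_per_group = c(AD = 40L, nonADD = 40L),
                      group_means = c(AD = 7.4, nonADD = 6.6),
                      group_sds = c(AD = 0.5, nonADD = 0.5), seed = 77)
  co <- generate_cohort(spec)
  rep <- confusion_report(co, 6.98)
  tally_tp <- sum(co$group == "AD" & co$ln_a_over_n > 6.98)
  tally_fn <- sum(co$group == "AD" & co$ln_a_over_n <= 6.98)
  tally_fp <- sum(co$group == "nonADD" & co$ln_a_over_n > 6.98)
  tally_tn <- sum(co$group == "nonADD" & co$ln_a_over_n <= 6.98)
  expect_identical(c(rep$tp, rep$fn, rep$fp, rep$tn),
                   c(tally_tp, tally_fn, tally_fp, tally_tn))
  expect_gt(rep$fn + rep$fp, 0L)  # overlap by construction
})

test_that("exact binomial intervals match tail inversion and closed forms", {
  expect_equal(round(100 * clopper_pearson(25, 25)[["ci_low"]], 2), 86.28)
  expect_equal(round(100 * clopper_pearson(21, 21)[["ci_low"]], 2), 83.89)
  expect_equal(round(100 * clopper_pearson(46, 46)[["ci_low"]], 2), 92.29)
  expect_equal(clopper_pearson(25, 25)[["ci_low"]], 0.025^(1 / 25))

  # symmetry: (0, n) mirrors (n, n) about 1/2
  expect_equal(unname(clopper_pearson(0, 10)),
               unname(rev(1 - clopper_pearson(10, 10))))

  for (n in c(1, 7, 21, 25, 46, 50)) {
    for (x in unique(c(0, 1, floor(n / 2), n))) {
      got <- unname(clopper_pearson(x, n))
      ref <- oracle_clopper(x, n)
      expect_equal(got, ref, tolerance = 1e-6)
    }
  }
  expect_error(clopper_pearson(1, 0), ">= 1")
})

test_that("group distributions are Gaussian fits with 4-sd buffer boundaries", {
  co <- rbind(load_fixture_cohort("table1"), load_fixture_cohort("table2"))
  fits <- fit_group_distributions(co)
  t2 <- load_fixture_cohort("table2")
  expect_equal(fits[["nonADD"]]$mean, mean(t2$ln_a_over_n))
  expect_equal(fits[["nonADD"]]$sd, sd(t2$ln_a_over_n))
  expect_equal(fits[["AD"]]$buffer_low,
               fits[["AD"]]$mean - 4 * fits[["AD"]]$sd)
  expect_false(fits[["AD"]]$degenerate)

  # degenerate group: all values equal
  cst <- data.frame(sample_id = as.character(1:4), group = "AD",
                    ln_a_over_n = rep(7, 4))
  f <- fit_group_distributions(cst)
  expect_true(f[["AD"]]$degenerate)
  expect_equal(f[["AD"]]$sd, 0)

  # buffers clear each other iff the gap exceeds 4 (sd1 + sd2)
  mk <- function(gap, s) {
    rbind(data.frame(sample_id = paste0("a", 1:50), group = "nonADD",
                     ln_a_over_n = rnorm(50, 6, s)),
          data.frame(sample_id = paste0("b", 1:50), group = "AD",
                     ln_a_over_n = rnorm(50, 6 + gap, s)))
  }
  set.seed(10)
  wide <- fit_group_distributions(mk(10, 0.5))
  expect_gt(wide[["AD"]]$buffer_low, wide[["nonADD"]]$buffer_high)
  narrow <- fit_group_distributions(mk(1, 0.5))
  expect_lt(narrow[["AD"]]$buffer_low, narrow[["nonADD"]]$buffer_high)

  expect_error(fit_group_distributions(cst[1:2, ]), "at least 3")
})
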