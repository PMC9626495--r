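test_that("field generation is deterministic and carries consistent ground truth", {
  spec <- field_spec("attachment", n_objects = 15, image_shape = c(300, 300),
                     seed = 9)
  f1 <- generate_field(spec)
  f2 <- generate_field(spec)
  expect_identical(f1$image$pixels, f2$image$pixels)
  expect_identical(f1$truth, f2$truth)

  expect_identical(f1$truth$object_count, 15L)
  expect_length(f1$truth$object_areas, f1$truth$object_count)
  expect_equal(f1$truth$mean_area, mean(f1$truth$object_areas))
})

test_that("an empty field is pure background plus noise", {
  f <- generate_field(field_spec("attachment", n_objects = 0,
                                 image_shape = c(200, 200), seed = 1))
  expect_identical(f$truth$object_count, 0L)
  expect_length(f$truth$object_areas, 0L)
  # intensities hover around the background level, far below foreground
  expect_lt(max(f$image$pixels), 100)
})

test_that("different seeds give different fields", {
  s1 <- field_spec("attachment", n_objects = 10, image_shape = c(200, 200),
                   seed = 1)
  s2 <- field_spec("attachment", n_objects = 10, image_shape = c(200, 200),
                   seed = 2)
  expect_false(identical(generate_field(s1)$image$pixels,
                         generate_field(s2)$image$pixels))
})

test_that("aggregated regimes order ln(mean area / count) as intended", {
  ad <- generate_field(field_spec("aggregated_AD_like", n_objects = 5,
                                  radius_mean = 40, radius_sd = 3, seed = 3))
  nad <- generate_field(field_spec("aggregated_nonAD_like", n_objects = 60,
                                   radius_mean = 8, radius_sd = 1, seed = 3))
  score <- function(t) log(t$mean_area / t$object_count)
  expect_gt(score(ad$truth), score(nad$truth))
})

test_that("ground truth reflects post-merge components, not seeds placed", {
  # many large objects crammed into a small frame must merge
  f <- generate_field(field_spec("aggregated_AD_like", n_objects = 30,
                                 radius_mean = 30, radius_sd = 2,
                                 image_shape = c(300, 300), seed = 8))
  expect_lt(f$truth$object_count, 30L)
  expect_gt(f$truth$object_count, 0L)
})

test_that("impossible non-overlapping placement fails naming the limiting parameter", {
  expect_error(
    generate_field(field_spec("attachment", n_objects = 400,
                              image_shape = c(120, 120), seed = 1)),
    "n_objects|radius|image_shape")
})

test_that("pipeline counting matches generator ground truth (plug-in validation)", {
  f <- generate_field(field_spec("attachment", n_objects = 417, seed = 7))
  expect_identical(f$truth$object_count, 417L)
  cnt <- count_cells(f$image)
  expect_lt(abs(cnt - 417) / 417, 0.07)
})

test_that("cohort generation is deterministic with the documented schema", {
  spec <- cohort_spec(n_per_group = c(AD = 6L, nonADD = 4L), seed = 12)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_identical(nrow(c1), 10L)
  expect_identical(as.integer(table(c1$group)[c("AD", "nonADD")]),
                   c(6L, 4L))
  expect_named(c1, c("sample_id", "source", "age", "gender", "group",
                     "validation", "comorbidity", "ln_a_over_n"))
})

test_that("an all-zero cohort spec yields an empty cohort", {
  empty <- generate_cohort(cohort_spec(n_per_group = c(AD = 0L, nonADD = 0L,
                                                       AHC = 0L), seed = 1))
  expect_identical(nrow(empty), 0L)
})

test_that("packaged cohort tables reproduce the study groups exactly", {
  t1 <- load_fixture_cohort("table1")
  t2 <- load_fixture_cohort("table2")
  t3 <- load_fixture_cohort("table3")
  expect_identical(c(nrow(t1), nrow(t2), nrow(t3)), c(25L, 21L, 27L))
  expect_identical(unique(t1$group), "AD")
  expect_identical(unique(t2$group), "nonADD")
  expect_identical(unique(t3$group), "AHC")

  expect_equal(t1$ln_a_over_n[t1$sample_id == "538"], 8.39)
  expect_equal(t2$ln_a_over_n[t2$sample_id == "ND27760"], 4.6)
  expect_equal(max(t3$ln_a_over_n), 7.13)
})
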