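test_that("despeckle is a 3x3 median with edge replication", {
  m <- matrix(42, 12, 12)
  expect_identical(despeckle(m), m)

  m[6, 6] <- 255
  expect_equal(despeckle(m)[6, 6], 42)

  for (seed in 1:3) {
    set.seed(seed)
    r <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    expect_equal(despeckle(r), oracle_median3x3(r))
  }
})

test_that("minimum filter at radius 0.5 is erosion over the 5-pixel cross", {
  m <- matrix(7, 10, 10)
  expect_identical(min_filter(m), m)

  m[5, 5] <- 200
  expect_true(all(min_filter(m) == 7))

  cross <- cbind(c(0, -1, 1, 0, 0), c(0, 0, 0, -1, 1))
  for (seed in 4:6) {
    set.seed(seed)
    r <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    expect_equal(min_filter(r, radius = 0.5), oracle_min_filter(r, cross))
  }
})

test_that("rolling-ball subtraction removes flat and smoothly varying background", {
  expect_true(all(subtract_background(matrix(50, 40, 40)) == 0))

  # compact bright feature much narrower than the ball survives intact
  px <- matrix(0, 128, 128)
  rr <- row(px); cc <- col(px)
  px[(rr - 64)^2 + (cc - 64)^2 <= 25] <- 100
  out <- subtract_background(px, 20)
  expect_gt(max(out), 90)  # peak amplitude preserved within 10%

  # smooth illumination plane at field-realistic slope leaves almost nothing
  amp <- 20
  g <- matrix(rep(seq(0, amp, length.out = 256), each = 256), 256, 256)
  expect_lt(max(subtract_background(g, 20)), 0.05 * amp)
})

test_that("binarisation separates bimodal images and rejects constant ones", {
  m <- matrix(10, 16, 16)
  m[5:8, 5:8] <- 200
  mask <- binarize(m)
  expect_identical(mask, m == 200)

  expect_identical(binarize(matrix(3, 8, 8)), matrix(FALSE, 8, 8))
})

test_that("binarisation of a synthetic field recovers the object area", {
  f <- generate_field(field_spec("attachment", n_objects = 40,
                                 image_shape = c(500, 500), seed = 21))
  mask <- binarize(f$image)
  truth_area <- sum(f$truth$object_areas)
  expect_lt(abs(sum(mask) - truth_area) / truth_area, 0.2)
})

test_that("particle analysis filters by inclusive area and matches a flood-fill oracle", {
  empty <- matrix(FALSE, 20, 20)
  expect_identical(analyze_particles(empty)$particle_count, 0L)

  # components of 200, 179, 181 px^2: the 180 floor is inclusive
  m <- matrix(FALSE, 40, 80)
  m[1:10, 1:20] <- TRUE            # 200
  m[15:25, 30:45] <- TRUE          # 11 x 16 = 176
  m[15, 46] <- TRUE; m[16, 46] <- TRUE; m[17, 46] <- TRUE  # -> 179
  m[30:40, 50:65] <- TRUE          # 176
  m[30, 66] <- TRUE; m[31, 66] <- TRUE; m[32, 66] <- TRUE
  m[33, 66] <- TRUE; m[34, 66] <- TRUE                      # -> 181
  ps <- analyze_particles(m, min_size = 180)
  expect_identical(ps$particle_count, 2L)
  expect_setequal(ps$particle_areas, c(200L, 181L))

  for (seed in 7:9) {
    mask <- random_blob_mask(48, 48, seed)
    ps <- analyze_particles(mask, min_size = 1)
    lab <- oracle_label(mask, 8L)
    expect_identical(ps$particle_count, max(lab))
    expect_identical(sort(ps$particle_areas), sort(tabulate(lab)))
  }
})

test_that("raising the particle size floor never increases the count", {
  mask <- random_blob_mask(64, 64, 11)
  sizes <- c(1, 5, 20, 50, 100, 180)
  counts <- vapply(sizes, function(s) analyze_particles(mask, s)$particle_count,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cell counting recovers ground truth across seeding densities", {
  expect_identical(
    count_cells(generate_field(field_spec("attachment", n_objects = 0,
                                          image_shape = c(400, 400),
                                          seed = 5))$image),
    0L)

  densities <- round(seq(330, 500, length.out = 9))
  errs <- vapply(seq_along(densities), function(i) {
    f <- generate_field(field_spec("attachment", n_objects = densities[i],
                                   seed = 100 + i))
    abs(count_cells(f$image) - densities[i]) / densities[i]
  }, numeric(1))
  expect_lt(mean(errs), 0.07)
})

test_that("aggregate measurement is the mean-area/count of retained particles", {
  # mask-level arithmetic through the particle/score path
  m <- matrix(FALSE, 100, 100)
  m[10:24, 10:29] <- TRUE   # 15 x 20 = 300
  m[50:74, 50:69] <- TRUE   # 25 x 20 = 500
  ps <- analyze_particles(m, min_size = 180)
  A <- mean(ps$particle_areas); N <- ps$particle_count
  expect_equal(c(A, N), c(400, 2))
  expect_equal(image_score(A, N), log(200))

  m2 <- matrix(FALSE, 500, 60)
  m2[1:453, 1:6] <- TRUE    # single particle of 2718 px^2
  ps2 <- analyze_particles(m2, min_size = 180)
  expect_equal(image_score(mean(ps2$particle_areas), ps2$particle_count),
               log(2718))

  # regime ordering through the full chain at matched seed
  a <- measure_aggregates(generate_field(field_spec("aggregated_AD_like",
                                                    seed = 3))$image)
  b <- measure_aggregates(generate_field(field_spec("aggregated_nonAD_like",
                                                    seed = 3))$image)
  expect_true(a$usable && b$usable)
  expect_gt(a$ln_a_over_n, b$ln_a_over_n)
})

test_that("the counting chain is translation equivariant", {
  spec <- field_spec("attachment", n_objects = 24, image_shape = c(420, 420),
                     gradient_amp = 0, seed = 31)
  f <- generate_field(spec)
  px <- f$image$pixels
  roll <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
  }
  expect_identical(count_cells(px), count_cells(roll(px, 7, 11)))
})
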