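test_that("sinogram matches the analytic chord length of a uniform disk", {
  ph <- make_concentric_phantom(4, "adipose", 1, "adipose", 240)
  geom <- small_geom(n_proj = 50)
  sino <- line_integral_sinogram(ph, 26, geom, bct_lib)
  mu <- get_mu(bct_lib, "adipose", 26)
  n <- nrow(ph$labels)
  R <- 2e4 / 240  # disk radius in px
  s <- (seq_len(n) - 1) - (n - 1) / 2
  chord <- 2 * sqrt(pmax(0, R^2 - s^2)) * 240 / 1e4 * mu
  # central ray within 0.5%; rasterization keeps rim rays within ~1 px
  inner <- abs(s) < 0.8 * R
  expect_equal(sino[(n + 1) / 2, 1], mu * 4, tolerance = 0.005)
  expect_lt(sqrt(mean((sino[inner, 1] - chord[inner])^2)), 0.005 * mu * 4)
  expect_lt(max(abs(sino[inner, 1] - chord[inner])), 1.2 * mu * 240 / 1e4)
  # rays missing the disk integrate to zero
  expect_true(all(sino[abs(s) > R + 2, ] == 0))
})

test_that("concentric phantoms give rotationally invariant sinograms", {
  ph <- small_phantom(240)
  geom <- small_geom(n_proj = 36)
  sino <- line_integral_sinogram(ph, 22, geom, bct_lib)
  n <- nrow(sino)
  R <- 2e4 / 240
  inner <- abs((seq_len(n) - 1) - (n - 1) / 2) < 0.8 * R
  spread <- apply(sino[inner, ], 1, function(r) diff(range(r)))
  # rays tangent to a rasterized boundary shift by up to one pixel of path
  expect_lt(max(spread), 0.02 * max(sino))
})

test_that("expected counts follow Beer-Lambert on the flat level", {
  geom <- small_geom()
  sino <- matrix(c(0, log(2), 1), 3, 1)
  ec <- expected_counts(sino, 1e6, geom)
  expect_equal(ec$flat, 1e6 * 0.24^2)
  expect_equal(ec$expected[1, 1], ec$flat)
  expect_equal(ec$expected[2, 1], ec$flat / 2)
  # doubling the fluence doubles every expectation
  ec2 <- expected_counts(sino, 2e6, geom)
  expect_equal(ec2$expected, 2 * ec$expected)
})

test_that("count sampling is Poisson, seeded, and row-independent", {
  geom <- small_geom(n_proj = 10, n_rows = 4)
  ec <- list(expected = matrix(3, 50, 10), flat = 100)
  s1 <- sample_counts(ec, geom, seed = 11)
  s2 <- sample_counts(ec, geom, seed = 11)
  expect_identical(s1$counts, s2$counts)
  s3 <- sample_counts(ec, geom, seed = 12)
  expect_false(identical(s1$counts, s3$counts))
  # sample mean within 3 standard errors of lambda = 3
  nn <- length(s1$counts)
  expect_lt(abs(mean(s1$counts) - 3), 3 * sqrt(3 / nn))
  # rows are distinct realizations
  expect_false(identical(s1$counts[, , 1], s1$counts[, , 2]))
  # zero expectation gives zero counts
  s0 <- sample_counts(list(expected = matrix(0, 5, 10), flat = 1), geom, 1)
  expect_true(all(s0$counts == 0))
})

test_that("noiseless pipeline inverts to the sinogram", {
  ph <- small_phantom(240)
  geom <- small_geom(n_proj = 40)
  sino <- line_integral_sinogram(ph, 26, geom, bct_lib)
  ec <- expected_counts(sino, 1e6, geom)
  back <- -log(ec$expected / ec$flat)
  expect_equal(back, sino, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("zero-count policies touch only zero pixels", {
  geom <- small_geom(n_proj = 1, n_rows = 5)
  counts <- array(4L, dim = c(6, 1, 5))
  stack <- structure(list(counts = counts, expected = matrix(4, 6, 1),
                          flat = 8, seed = 1, geom = geom),
                     class = "count_stack")
  # no zeros: exact division by flat
  expect_equal(preprocess_counts(stack, "median3"), counts / 8,
               ignore_attr = TRUE)

  # single zero amid value-4 neighbours takes their median
  counts2 <- counts
  counts2[3, 1, 3] <- 0L
  stack$counts <- counts2
  tr <- preprocess_counts(stack, "median3")
  expect_equal(tr[3, 1, 3], 4 / 8)
  expect_equal(tr[-3 * 1, , ], counts2[-3 * 1, , ] / 8, ignore_attr = TRUE)

  # all-zero stack: floor at half a count
  stack$counts <- array(0L, dim = c(6, 1, 5))
  expect_true(all(preprocess_counts(stack, "floor_half") == 0.5 / 8))
  # median3 falls back to half a count when all neighbours are zero too
  expect_true(all(preprocess_counts(stack, "median3") == 0.5 / 8))
  expect_error(preprocess_counts(stack, "nope"))
})

test_that("starvation metrics report the most-attenuated projection", {
  geom <- small_geom(n_proj = 6, n_rows = 4)
  expected <- matrix(50, 40, 6)
  expected[15:25, ] <- 5  # phantom shadow
  stack <- sample_counts(list(expected = expected, flat = 50), geom, 3)
  stack$counts[, 4, ] <- 0L  # starved projection
  sm <- starvation_metrics(stack, central_fraction = 0.5)
  expect_equal(sm$projection_min, 4)
  expect_equal(sm$n_min, 0)
  expect_equal(sm$zero_fraction, 1)
  expect_true(all(sm$window_columns >= 15 & sm$window_columns <= 25))

  # constant counts: n_min = c and no zeros
  stack$counts[] <- 7L
  sm2 <- starvation_metrics(stack, 0.5)
  expect_equal(sm2$n_min, 7)
  expect_equal(sm2$zero_fraction, 0)
})

test_that("zero-count fraction follows Poisson statistics", {
  geom <- small_geom(n_proj = 4, n_rows = 50)
  expected <- matrix(10, 101, 4)
  expected[26:76, ] <- 1  # shadow with lambda = 1
  stack <- sample_counts(list(expected = expected, flat = 10), geom, 21)
  sm <- starvation_metrics(stack, central_fraction = 0.9)
  n_win <- length(sm$window_columns) * 50
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n_win)
  expect_lt(abs(sm$zero_fraction - p), 3 * se)

  expected[26:76, ] <- 10
  stack10 <- sample_counts(list(expected = expected, flat = 10), geom, 22)
  expect_lt(starvation_metrics(stack10, 0.9)$zero_fraction, 0.01)
})

test_that("doubling fluence doubles expected counts (linearity)", {
  ph <- small_phantom(480)
  geom <- small_geom(n_proj = 20, pixel_um = 480)
  sino <- line_integral_sinogram(ph, 22, geom, bct_lib)
  e1 <- expected_counts(sino, 5e5, geom)
  e2 <- expected_counts(sino, 1e6, geom)
  expect_equal(e2$expected, 2 * e1$expected)
})
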