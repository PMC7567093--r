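test_that("air kerma is linear in fluence and matches a hand computation", {
  expect_equal(kerma_from_fluence(0, 30, bct_lib), 0)
  expect_equal(kerma_from_fluence(2e9, 30, bct_lib),
               2 * kerma_from_fluence(1e9, 30, bct_lib))
  # hand computation at the 30 keV knot: K = Phi[1/m^2] E[J] (mu_en/rho)[m^2/kg]
  oracle_mGy <- 1e9 * 1e6 * (30 * 1.602176634e-16) * (0.1537 * 0.1) * 1e3
  expect_equal(kerma_from_fluence(1e9, 30, bct_lib), oracle_mGy,
               tolerance = 0.01)
})

test_that("DgN surrogate approaches the coefficient ratio for a vanishing phantom", {
  tiny <- make_concentric_phantom(0.2, "glandular", 0.1, "glandular", 60)
  lim <- get_mu_en_rho(bct_lib, "glandular", 26) /
    get_mu_en_rho(bct_lib, "air", 26)
  got <- dgn_surrogate(tiny, 26, bct_lib)
  expect_lt(got, lim)
  expect_gt(got, 0.95 * lim)
})

test_that("DgN surrogate matches a brute-force quadrature on a uniform disk", {
  # homogeneous glandular cylinder: entrance path length from a point at
  # radius r with polar angle offset phi is sqrt(R^2 - (r sin phi)^2) +
  # r cos phi, so the oracle is a direct average of exp(-mu * t) over
  # pixels and 1-degree-spaced angles
  ph <- make_concentric_phantom(2, "glandular", 1, "glandular", 120)
  E <- 26
  mu <- get_mu(bct_lib, "glandular", E)
  R <- 1  # cm
  n <- nrow(ph$labels)
  idx <- which(ph$labels > 0L, arr.ind = TRUE)
  c0 <- (n + 1) / 2
  x <- (idx[, 2] - c0) * 120 / 1e4
  y <- (idx[, 1] - c0) * 120 / 1e4
  angles <- (0:179) * pi / 180
  tmean <- 0
  for (a in angles) {
    bx <- sin(a); by <- -cos(a)  # marching against the beam
    proj <- x * bx + y * by
    perp2 <- (x^2 + y^2) - proj^2
    t_len <- sqrt(pmax(R^2 - perp2, 0)) - proj
    tmean <- tmean + mean(exp(-mu * t_len))
  }
  oracle <- tmean / length(angles) *
    get_mu_en_rho(bct_lib, "glandular", E) / get_mu_en_rho(bct_lib, "air", E)
  expect_equal(dgn_surrogate(ph, E, bct_lib), oracle, tolerance = 0.02)
})

test_that("DgN surrogate grows with energy and shrinks with diameter", {
  p12 <- make_concentric_phantom(12, "polyethylene", 1, "glandular", 480)
  d_vals <- vapply(seq(18, 38, 4), function(E) dgn_surrogate(p12, E, bct_lib), 0)
  expect_true(all(diff(d_vals) > 0))
  p6 <- make_concentric_phantom(6, "polyethylene", 1, "glandular", 480)
  expect_lt(dgn_surrogate(p12, 26, bct_lib), dgn_surrogate(p6, 26, bct_lib))
})

test_that("fluence inverts the MGD = K * DgN dose model", {
  ph <- small_phantom(480)
  c0 <- dose_config(0, n_projections = 600)
  expect_equal(fluence_for_mgd(c0, ph, 26, bct_lib)$phi_total_mm2, 0)

  c20 <- dose_config(20, n_projections = 600)
  c5 <- dose_config(5, n_projections = 600)
  f20 <- fluence_for_mgd(c20, ph, 26, bct_lib)
  f5 <- fluence_for_mgd(c5, ph, 26, bct_lib)
  expect_equal(f20$phi_proj_mm2 / f5$phi_proj_mm2, 4, tolerance = 1e-12)

  # round trip: K(Phi_total) * DgN recovers the MGD to machine precision
  mgd_back <- kerma_from_fluence(f20$phi_total_mm2, 26, bct_lib) * f20$dgn
  expect_equal(mgd_back, 20, tolerance = 1e-12)
})

test_that("a user DgN table bypasses the surrogate entirely", {
  ph <- small_phantom(480)
  tab <- data.frame(energy_keV = c(18, 28, 38), dgn = c(0.2, 0.4, 0.5))
  cfg <- dose_config(10, dgn = tab, n_projections = 100)
  f <- fluence_for_mgd(cfg, ph, 23, bct_lib)
  expect_equal(f$dgn, 0.3)  # linear interpolation of the table only
  expect_equal(f$phi_total_mm2,
               10 / (0.3 * kerma_per_unit_fluence(23, bct_lib)))
  expect_error(fluence_for_mgd(cfg, ph, 40, bct_lib), "cover")
  expect_error(dose_config(5, dgn = data.frame(energy_keV = 20, dgn = -1)),
               "positive")
})

test_that("fixed-MGD fluence is finite and positive across the band", {
  ph <- make_concentric_phantom(12, "polyethylene", 1, "glandular", 480)
  cfg <- dose_config(20, n_projections = 600)
  phi <- vapply(seq(18, 38, 4),
                function(E) fluence_for_mgd(cfg, ph, E, bct_lib)$phi_proj_mm2, 0)
  expect_true(all(is.finite(phi) & phi > 0))
})
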