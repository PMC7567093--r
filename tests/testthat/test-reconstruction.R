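test_that("log transform inverts Beer-Lambert", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(-2)), 2)
  expect_error(log_transform(c(1, 0)), "positive")
})

test_that("Shepp-Logan filtering has (near-)zero DC response", {
  resp <- bctsim:::.shepp_logan_response(128, 0.006, 256)
  # the finite spatial kernel leaves a DC residue of order 1/n only
  expect_lt(abs(resp[1]) / max(resp), 1 / 128)
  # response peaks at the Nyquist end of the band
  expect_gt(resp[129], 0.9 * max(resp))
})

test_that("FBP recovers a uniform disk within 1%", {
  ph <- make_concentric_phantom(7, "adipose", 1, "adipose", 240)
  geom <- scan_geometry(n_projections = 400, detector_pixel_um = 240,
                        n_rows = 1)
  mu <- get_mu(bct_lib, "adipose", 26)
  sino <- line_integral_sinogram(ph, 26, geom, bct_lib)
  sl <- fbp(sino, geom, 240, 26)
  R <- 3.5e4 / 240
  inner <- interior_mask(nrow(sl$image), R, 0.8)
  expect_equal(mean(sl$image[inner]), mu, tolerance = 0.01)

  # linearity
  expect_true(all(fbp(matrix(0, 64, 400), geom)$image == 0))
  sl2 <- fbp(2 * sino, geom, 240, 26)
  expect_equal(sl2$image, 2 * sl$image, tolerance = 1e-10)
})

test_that("reconstruction of a symmetric phantom is rotationally symmetric", {
  ph <- make_concentric_phantom(4, "adipose", 2, "glandular", 240)
  geom <- scan_geometry(n_projections = 300, detector_pixel_um = 240,
                        n_rows = 1)
  sino <- line_integral_sinogram(ph, 26, geom, bct_lib)
  img <- fbp(sino, geom, 240, 26)$image
  n <- nrow(img)
  c0 <- (n + 1) / 2
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  for (r_px in c(10, 25)) {
    ring <- vapply(theta, function(a) {
      img[round(c0 + r_px * sin(a)), round(c0 + r_px * cos(a))]
    }, 0)
    expect_lt(sd(ring) / abs(mean(ring)), 0.02)
  }
})

test_that("centered subgrid reconstruction equals the full-grid crop", {
  ph <- small_phantom(240)
  geom <- small_geom(n_proj = 120)
  sino <- line_integral_sinogram(ph, 24, geom, bct_lib)
  full <- fbp(sino, geom, 240, 24)$image
  sub <- fbp(sino, geom, 240, 24, n_out = 61)$image
  sh <- (nrow(full) - 61) %/% 2
  expect_equal(sub, full[sh + 1:61, sh + 1:61], tolerance = 1e-12)
})

test_that("noiseless pipeline recovers the glandular attenuation", {
  ph <- make_concentric_phantom(7, "adipose", 1, "glandular", 120)
  geom <- scan_geometry(n_projections = 600, detector_pixel_um = 120,
                        n_rows = 3)
  E <- 26
  sino <- line_integral_sinogram(ph, E, geom, bct_lib)
  ec <- expected_counts(sino, 1e6, geom)
  trans <- noiseless_transmittance(ec, 3)
  rois <- auto_roi(ph, margin_px = 10)

  slices_abs <- reconstruct_stack(NULL, geom, transmittance = trans,
                                  rows = 2)
  mu_gl <- get_mu(bct_lib, "glandular", E)
  got <- mean(slices_abs[[1]]$image[rois$glandular])
  expect_equal(got, mu_gl, tolerance = 0.01)

  # phase retrieval preserves the low-frequency plateau (same contrast)
  db <- get_delta_beta(bct_lib, "breast_icru44", E)$delta_beta
  phr <- phr_params(E, db, 120, 1.6)
  slices_phr <- reconstruct_stack(NULL, geom, phr = phr,
                                  transmittance = trans, rows = 2)
  m_abs <- mean(slices_abs[[1]]$image[rois$glandular])
  m_phr <- mean(slices_phr[[1]]$image[rois$glandular])
  expect_equal(m_phr / m_abs, 1, tolerance = 0.002)
  b_abs <- mean(slices_abs[[1]]$image[rois$background])
  b_phr <- mean(slices_phr[[1]]$image[rois$background])
  expect_equal(b_phr / b_abs, 1, tolerance = 0.002)
})

test_that("phase retrieval shrinks noise in reconstructed ROIs", {
  ph <- small_phantom(240)
  geom <- scan_geometry(n_projections = 200, detector_pixel_um = 240,
                        n_rows = 12)
  sino <- line_integral_sinogram(ph, 24, geom, bct_lib)
  ec <- expected_counts(sino, 2e5, geom)
  stack <- sample_counts(ec, geom, 7)
  rois <- auto_roi(ph, margin_px = 4)
  db <- get_delta_beta(bct_lib, "breast_icru44", 24)$delta_beta
  phr <- phr_params(24, db, 240, 1.6)
  s_abs <- reconstruct_stack(stack, geom, rows = 6)
  s_phr <- reconstruct_stack(stack, geom, phr = phr, rows = 6)
  sd_abs <- sd(s_abs[[1]]$image[rois$background])
  sd_phr <- sd(s_phr[[1]]$image[rois$background])
  expect_lt(sd_phr, sd_abs)
})

test_that("reconstructed slices round-trip through 32-bit TIFF", {
  img <- matrix(rnorm(32 * 32, 0.3, 0.05), 32, 32)
  sl <- recon_slice(img, 120, 26)
  path <- tempfile(fileext = ".tif")
  write_recon_slice(sl, path)
  back <- read_recon_slice(path)
  expect_equal(back$image, img, tolerance = 1e-6)
  expect_equal(back$energy_keV, 26)
  expect_equal(back$pixel_size_um, 120)
})
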