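coarse_scan_geom <- function(n_rows = 6) {
  scan_geometry(n_projections = 150, detector_pixel_um = 480,
                n_rows = n_rows)
}

test_that("a single-energy grid trivially maximizes at that energy", {
  ph <- make_concentric_phantom(4, "adipose", 1, "glandular", 480)
  sc <- energy_scan(ph, 26, 20, "absorption", coarse_scan_geom(),
                    lib = bct_lib, n_slices = 4, seed = 1, margin_px = 2)
  expect_equal(sc$argmax_energy, 26)
  expect_equal(sc$ties, 26)
})

test_that("energy scans are deterministic under a fixed seed", {
  ph <- make_concentric_phantom(4, "adipose", 1, "glandular", 480)
  g <- coarse_scan_geom()
  s1 <- energy_scan(ph, c(20, 30), 20, "absorption", g, bct_lib,
                    n_slices = 4, seed = 9, margin_px = 2)
  s2 <- energy_scan(ph, c(20, 30), 20, "absorption", g, bct_lib,
                    n_slices = 4, seed = 9, margin_px = 2)
  expect_identical(s1$table, s2$table)
  s3 <- energy_scan(ph, c(20, 30), 20, "absorption", g, bct_lib,
                    n_slices = 4, seed = 10, margin_px = 2)
  expect_false(identical(s1$table$cnr, s3$table$cnr))
})

test_that("the CNR argmax does not move with the dose level", {
  ph <- make_concentric_phantom(7, "adipose", 1, "glandular", 480)
  g <- scan_geometry(n_projections = 200, detector_pixel_um = 480,
                     n_rows = 6)
  E <- c(18, 24, 30, 36)
  s20 <- energy_scan(ph, E, 20, "absorption", g, bct_lib, n_slices = 6,
                     seed = 3, margin_px = 2)
  s05 <- energy_scan(ph, E, 5, "absorption", g, bct_lib, n_slices = 6,
                     seed = 4, margin_px = 2)
  expect_equal(s20$argmax_energy, s05$argmax_energy)
  # CNR rescales roughly as sqrt(dose)
  expect_equal(mean(s20$table$cnr / s05$table$cnr), 2, tolerance = 0.15)
})

test_that("phase retrieval gain is 1 for delta/beta = 0 and grows with distance", {
  ph <- make_concentric_phantom(4, "adipose", 1, "glandular", 480)
  g <- coarse_scan_geom(n_rows = 8)
  base <- phr_gain(ph, 22, 20, g, bct_lib, n_slices = 6, seed = 2,
                   margin_px = 2, delta_beta = 0)
  expect_equal(base$ratio, 1, tolerance = 1e-12)

  g08 <- scan_geometry(n_projections = 150, detector_pixel_um = 480,
                       n_rows = 8, propagation_distance_m = 0.8)
  r08 <- phr_gain(ph, 22, 20, g08, bct_lib, n_slices = 6, seed = 2,
                  margin_px = 2)
  r16 <- phr_gain(ph, 22, 20, g, bct_lib, n_slices = 6, seed = 2,
                  margin_px = 2)
  expect_gt(r08$ratio, 1)
  expect_gte(r16$ratio, r08$ratio)
})

test_that("starvation scans order with dose and follow sqrt statistics", {
  ph <- make_concentric_phantom(3.2, "adipose", 1, "glandular", 240)
  g <- scan_geometry(n_projections = 240, detector_pixel_um = 240,
                     n_rows = 12)
  sv <- starvation_scan(ph, 22, c(20, 10, 5, 2.5, 1), g, bct_lib,
                        n_slices = 10, seed = 1, margin_px = 4)
  tab <- sv$table
  expect_true(all(diff(tab$phi_proj_mm2) < 0))
  expect_true(all(diff(tab$n_min) < 0))
  # at generous doses no pixel starves
  expect_equal(tab$zero_fraction[1], 0)
  ex <- cnr_dose_exponent(sv)
  expect_gt(ex$exponent, 0.45)
  expect_lt(ex$exponent, 0.55)
})

test_that("config-driven runs are reproducible and validated", {
  preset <- system.file("extdata", "presets", "p1_energy_scan_demo.yaml",
                        package = "bctsim")
  out1 <- tempfile("run1")
  out2 <- tempfile("run2")
  res <- run_config(preset, out1)
  expect_s3_class(res, "energy_scan_result")
  expect_true(file.exists(file.path(out1, "results.csv")))
  expect_true(file.exists(file.path(out1, "config-resolved.json")))
  run_config(preset, out2)
  expect_identical(readLines(file.path(out1, "results.csv")),
                   readLines(file.path(out2, "results.csv")))

  bad <- list(task = "energy_scan",
              phantom = list(type = "concentric", pixel_size_um = 480))
  expect_error(run_config(bad, tempfile()), "diameter_cm")
  expect_error(run_config(list(task = "fly"), tempfile()), "unknown task")
})
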