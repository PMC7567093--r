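# shared fixtures; material_library() is cached inside the package
bct_lib <- material_library()

# small concentric phantom for fast pipeline tests (4 cm disk, 1 cm detail)
small_phantom <- function(pixel_um = 240) {
  make_concentric_phantom(4, "adipose", 1, "glandular", pixel_um)
}

small_geom <- function(n_proj = 200, pixel_um = 240, n_rows = 2) {
  scan_geometry(n_projections = n_proj, detector_pixel_um = pixel_um,
                n_rows = n_rows)
}

# noiseless transmittance array from an expected-counts object
noiseless_transmittance <- function(ec, n_rows) {
  tr <- ec$expected / ec$flat
  array(rep(tr, n_rows), dim = c(nrow(tr), ncol(tr), n_rows))
}

# interior disk mask of a reconstructed image (radius fraction of r_px)
interior_mask <- function(n, r_px, frac = 0.8) {
  xy <- seq_len(n) - (n + 1) / 2
  outer(xy^2, xy^2, "+") < (frac * r_px)^2
}
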