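#' Scan geometry
#'
#' Parallel monochromatic beam, no scatter, ideal photon-counting detector
#' with 100% efficiency. Angles are sampled as `theta_k = k * arc/n`,
#' `k = 0..n-1` (endpoint excluded, continuous-rotation convention).
#' Detector rows are independent noise realizations of the same (vertically
#' uniform) phantom slice.
#'
#' @param n_projections number of projections over the arc.
#' @param arc_deg angular arc, degrees (180 for parallel-beam CT).
#' @param detector_pixel_um square detector pixel side, micrometers; must
#'   match the phantom pixel size when projecting a phantom.
#' @param propagation_distance_m object-to-detector distance, m (used by the
#'   phase-retrieval filter).
#' @param n_rows number of detector rows simulated.
#' @param n_det number of detector columns; defaults to the phantom grid
#'   side at projection time.
#' @return `scan_geometry` object.
#' @export
scan_geometry <- function(n_projections = 1200L, arc_deg = 180,
                          detector_pixel_um = 60, propagation_distance_m = 1.6,
                          n_rows = 10L, n_det = NULL) {
  stopifnot(n_projections >= 1, arc_deg > 0, arc_deg <= 360,
            detector_pixel_um > 0, propagation_distance_m >= 0, n_rows >= 1)
  structure(list(n_projections = as.integer(n_projections),
                 arc_deg = arc_deg,
                 detector_pixel_um = detector_pixel_um,
                 propagation_distance_m = propagation_distance_m,
                 n_rows = as.integer(n_rows),
                 n_det = if (is.null(n_det)) NULL else as.integer(n_det)),
            class = "scan_geometry")
}

.geom_angles <- function(geom) {
  (seq_len(geom$n_projections) - 1) * geom$arc_deg * pi / 180 /
    geom$n_projections
}

# cached per-label thickness sinograms [n_det, n_proj, n_label]
.label_sinograms <- function(phantom, geom, n_det) {
  key <- .phantom_key(phantom, paste("sino", geom$n_projections,
                                     geom$arc_deg, n_det))
  hit <- .bct_cache$sino[[key]]
  if (!is.null(hit)) return(hit)
  basis <- cpp_label_sinogram(phantom$labels, length(phantom$label_map),
                              .geom_angles(geom), n_det, (n_det - 1) / 2,
                              phantom$pixel_size_um / 1e4, 0.5,
                              .phantom_rmax(phantom))
  if (is.null(.bct_cache$sino)) .bct_cache$sino <- list()
  # keep the cache from growing without bound
  if (length(.bct_cache$sino) >= 6) {
    .bct_cache$sino <- .bct_cache$sino[-1]
  }
  .bct_cache$sino[[key]] <- basis
  basis
}

#' Line-integral sinogram of a phantom
#'
#' Path integrals of the linear attenuation coefficient through the label
#' map (ray marching at half-pixel steps with bilinear label weights); air
#' contributes zero. Per-label thickness sinograms are cached per phantom
#' and geometry, so scanning many energies re-uses the ray tracing.
#'
#' @param phantom a [phantom_grid()].
#' @param E energy, keV.
#' @param geom a [scan_geometry()]; `detector_pixel_um` must equal the
#'   phantom pixel size.
#' @param lib a [material_library()].
#' @return matrix `[n_det, n_projections]` of dimensionless line integrals,
#'   with attributes `energy_keV` and `pixel_size_um`.
#' @export
line_integral_sinogram <- function(phantom, E, geom,
                                   lib = material_library()) {
  stopifnot(inherits(phantom, "phantom_grid"),
            inherits(geom, "scan_geometry"))
  if (!isTRUE(all.equal(geom$detector_pixel_um, phantom$pixel_size_um))) {
    stop("detector pixel size must match the phantom pixel size")
  }
  n <- nrow(phantom$labels)
  n_det <- if (is.null(geom$n_det)) n else geom$n_det
  if (n_det < 2 * .phantom_rmax(phantom) - 2) {
    stop("phantom wider than the detector: truncated projections")
  }
  basis <- .label_sinograms(phantom, geom, n_det)
  mu <- vapply(phantom$label_map, function(m) get_mu(lib, m, E), 0)
  sino <- matrix(0, n_det, geom$n_projections)
  for (l in seq_along(mu)) sino <- sino + mu[l] * basis[, , l]
  attr(sino, "energy_keV") <- E
  attr(sino, "pixel_size_um") <- phantom$pixel_size_um
  sino
}

#' Expected detector counts from a sinogram
#'
#' `N = Phi_proj * A_px * exp(-int mu dl)` for an ideal 100%-efficiency
#' photon-counting pixel of area `A_px`; the flat (unattenuated) expectation
#' is `Phi_proj * A_px`.
#'
#' @param sinogram line-integral sinogram `[n_det, n_projections]`.
#' @param phi_proj_mm2 fluence per projection, photons/mm^2 (>= 0).
#' @param geom a [scan_geometry()].
#' @return list with `expected` (matrix like `sinogram`) and scalar `flat`.
#' @export
expected_counts <- function(sinogram, phi_proj_mm2, geom) {
  stopifnot(phi_proj_mm2 >= 0)
  area_mm2 <- (geom$detector_pixel_um / 1e3)^2
  flat <- phi_proj_mm2 * area_mm2
  list(expected = flat * exp(-sinogram), flat = flat)
}

#' Sample a Poisson count stack
#'
#' Independent Poisson draws of the expected counts, replicated over
#' `geom$n_rows` detector rows (independent realizations of the same
#' vertically uniform slice). Reproducible under `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param exp_counts result of [expected_counts()].
#' @param geom a [scan_geometry()].
#' @param seed integer seed.
#' @return `count_stack` object: integer `counts[n_det, n_proj, n_rows]`,
#'   the `expected` matrix, scalar `flat` (treated as noiseless - the
#'   flat-field reference is an average of many frames), and metadata.
#' @export
sample_counts <- function(exp_counts, geom, seed) {
  expected <- exp_counts$expected
  stopifnot(all(expected >= 0))
  n_det <- nrow(expected)
  n_proj <- ncol(expected)
  counts <- .with_seed(seed, {
    x <- rpois(length(expected) * geom$n_rows, rep(as.vector(expected),
                                                   geom$n_rows))
    array(x, dim = c(n_det, n_proj, geom$n_rows))
  })
  structure(list(counts = counts, expected = expected,
                 flat = exp_counts$flat, seed = seed, geom = geom),
            class = "count_stack")
}

#' @export
print.count_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<count_stack> %d det x %d proj x %d rows, flat = %.1f counts/px, seed = %d\n",
              d[1], d[2], d[3], x$flat, x$seed))
  invisible(x)
}

#' Flat-field normalization with zero-count handling
#'
#' Divides counts by the (noiseless) flat reference after replacing
#' zero-count pixels, so the downstream log transform is defined
#' everywhere:
#' * `median3`: a zero pixel takes the median of its non-zero 3x3
#'   neighbours in the projection image (rows x columns); pixels with no
#'   non-zero neighbour fall back to 0.5 counts;
#' * `floor_half`: every zero pixel is set to 0.5 counts.
#'
#' Non-zero pixels are never altered.
#'
#' @param stack a [sample_counts()] stack.
#' @param policy `"median3"` (default) or `"floor_half"`.
#' @return transmittance array `[n_det, n_proj, n_rows]`, strictly positive.
#' @export
preprocess_counts <- function(stack, policy = c("median3", "floor_half")) {
  policy <- match.arg(policy)
  counts <- stack$counts
  d <- dim(counts)
  out <- array(as.double(counts), dim = d)
  if (policy == "floor_half") {
    out[out == 0] <- 0.5
  } else {
    for (k in seq_len(d[2])) {
      img <- out[, k, , drop = TRUE]
      if (is.null(dim(img))) img <- matrix(img, d[1], d[3])
      if (any(img == 0)) {
        out[, k, ] <- cpp_fill_zeros_median3(img, 0.5)
      }
    }
  }
  out / stack$flat
}

#' Photon-starvation metrics
#'
#' Mean counts `N` in a central window of the phantom shadow for each
#' projection, the minimum `N_min` over projections (the most attenuated
#' view), and the fraction of zero-counting pixels in that window.
#'
#' @param stack a [sample_counts()] stack.
#' @param central_fraction fraction of the phantom-shadow columns forming
#'   the central window, in (0, 1].
#' @return list: `n_per_projection`, `n_min`, `projection_min` (1-based
#'   index of the starved projection), `zero_fraction_per_projection`, and
#'   `zero_fraction` (evaluated on the `n_min` projection's window).
#' @export
starvation_metrics <- function(stack, central_fraction = 0.1) {
  stopifnot(central_fraction > 0, central_fraction <= 1)
  shadow <- which(stack$expected[, 1] < stack$flat * (1 - 1e-9))
  if (length(shadow) == 0L) shadow <- seq_len(nrow(stack$expected))
  ctr <- (min(shadow) + max(shadow)) / 2
  half <- max(0.5, length(shadow) * central_fraction / 2)
  win <- max(1L, ceiling(ctr - half)):min(nrow(stack$expected),
                                          floor(ctr + half))
  sub <- stack$counts[win, , , drop = FALSE]
  n_per <- apply(sub, 2, mean)
  zf_per <- apply(sub, 2, function(v) mean(v == 0))
  k <- which.min(n_per)
  list(n_per_projection = n_per, n_min = n_per[k], projection_min = k,
       zero_fraction_per_projection = zf_per, zero_fraction = zf_per[k],
       window_columns = win)
}
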