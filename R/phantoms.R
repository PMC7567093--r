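#' Pixelized phantom grids
#'
#' A `phantom_grid` is a single transverse slice of a vertically uniform
#' (extruded) phantom: an integer label map on a square pixel grid plus a
#' binding of each non-zero label to a material name. Label 0 is air.
#' The rotation axis used by the projector and reconstructor is the grid
#' center, pixel `(n-1)/2` in 0-based coordinates.
#'
#' @param labels square integer matrix of region labels (0 = air).
#' @param pixel_size_um pixel side, micrometers.
#' @param label_map character vector; `label_map[k]` is the material bound to
#'   label `k`.
#' @param height_mm extrusion height of the physical phantom, mm.
#' @return `phantom_grid` object.
#' @export
phantom_grid <- function(labels, pixel_size_um, label_map, height_mm = 5) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  stopifnot(nrow(labels) == ncol(labels), pixel_size_um > 0, height_mm > 0)
  labs <- sort(unique(as.vector(labels)))
  labs <- labs[labs > 0]
  if (length(labs) && max(labs) > length(label_map)) {
    stop("every non-zero label needs an entry in label_map")
  }
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 label_map = as.character(label_map),
                 height_mm = height_mm),
            class = "phantom_grid")
}

#' @export
print.phantom_grid <- function(x, ...) {
  n <- nrow(x$labels)
  cat(sprintf("<phantom_grid> %d x %d px @ %g um (%.2f cm field), height %g mm\n",
              n, n, x$pixel_size_um, n * x$pixel_size_um / 1e4, x$height_mm))
  cnt <- tabulate(x$labels + 1L, nbins = length(x$label_map) + 1L)
  for (k in seq_along(x$label_map)) {
    cat(sprintf("  label %d -> %-14s %d px\n", k, x$label_map[k], cnt[k + 1L]))
  }
  invisible(x)
}

# pixel-center coordinates relative to the grid/rotation center
.center_coords <- function(n) {
  seq_len(n) - 1 - (n - 1) / 2
}

.disk_mask <- function(n, radius_px, cx = 0, cy = 0) {
  xy <- .center_coords(n)
  outer((xy - cy)^2, (xy - cx)^2, "+") < radius_px^2
}

.grid_side <- function(diameter_cm, pixel_size_um, margin_px = 4L) {
  r_px <- diameter_cm * 1e4 / 2 / pixel_size_um
  2L * as.integer(ceiling(r_px + margin_px)) + 1L
}

#' Concentric two-material cylinder phantom
#'
#' A centered disk of a background material containing a centered detail disk
#' of a second material - the geometry of the 7 cm adipose-equivalent
#' phantom with a 1 cm glandular-equivalent insert, and of its 12 cm
#' polyethylene counterpart.
#'
#' @param outer_diameter_cm outer cylinder diameter, cm.
#' @param outer_material,detail_material material names (see
#'   [material_library()]).
#' @param detail_diameter_cm detail cylinder diameter, cm (must be smaller).
#' @param pixel_size_um pixel side, micrometers.
#' @param height_mm extrusion height, mm.
#' @return [phantom_grid()] with labels 1 (outer) and 2 (detail).
#' @examples
#' p1 <- make_concentric_phantom(7, "adipose", 1, "glandular", 120)
#' @export
make_concentric_phantom <- function(outer_diameter_cm, outer_material,
                                    detail_diameter_cm, detail_material,
                                    pixel_size_um, height_mm = 5) {
  if (detail_diameter_cm >= outer_diameter_cm) {
    stop("detail diameter must be smaller than the outer diameter")
  }
  stopifnot(pixel_size_um > 0)
  n <- .grid_side(outer_diameter_cm, pixel_size_um)
  r_out <- outer_diameter_cm * 1e4 / 2 / pixel_size_um
  r_det <- detail_diameter_cm * 1e4 / 2 / pixel_size_um
  labels <- matrix(0L, n, n)
  labels[.disk_mask(n, r_out)] <- 1L
  labels[.disk_mask(n, r_det)] <- 2L
  phantom_grid(labels, pixel_size_um,
               c(outer_material, detail_material), height_mm)
}

#' Composite two-tissue cylinder in a polyethylene holder
#'
#' A 3.2 cm cylinder split into two half-disks (adipose and glandular),
#' centered in a 12 cm polyethylene cylinder - a stand-in for a small
#' surgical sample sealed in a holder. The half-disk split leaves each
#' tissue a region that admits a disk ROI at least 10 px from every
#' interface at 60 um pixels.
#'
#' @param pixel_size_um pixel side, micrometers.
#' @param height_mm extrusion height, mm.
#' @return [phantom_grid()] with labels 1 = polyethylene, 2 = adipose,
#'   3 = glandular.
#' @export
make_t1_phantom <- function(pixel_size_um, height_mm = 5) {
  stopifnot(pixel_size_um > 0)
  n <- .grid_side(12, pixel_size_um)
  r_out <- 12e4 / 2 / pixel_size_um
  r_in <- 3.2e4 / 2 / pixel_size_um
  labels <- matrix(0L, n, n)
  labels[.disk_mask(n, r_out)] <- 1L
  inner <- .disk_mask(n, r_in)
  xcol <- matrix(rep(.center_coords(n), each = n), n, n)
  labels[inner & xcol < 0] <- 2L
  labels[inner & xcol > 0] <- 3L
  # the dividing plane bisects the central pixel column: split it evenly
  # between the two tissues (alternating rows) so the half areas match
  mid <- inner & xcol == 0
  odd <- matrix(rep(c(TRUE, FALSE), length.out = n), n, n)
  labels[mid & odd] <- 2L
  labels[mid & !odd] <- 3L
  phantom_grid(labels, pixel_size_um,
               c("polyethylene", "adipose", "glandular"), height_mm)
}

# FFT Gaussian blur with circular wrap; the padding margin of the disk
# phantoms keeps wrap-around away from the tissue.
.gaussian_blur_fft <- function(img, sigma_px) {
  n <- nrow(img)
  idx <- 0:(n - 1)
  d <- ifelse(idx > n / 2, idx - n, idx)
  g <- exp(-d^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k <- k / sum(k)
  Re(fft(fft(img) * fft(k), inverse = TRUE)) / length(img)
}

#' Breast-like phantom with blobby glandular texture
#'
#' An adipose disk containing smooth glandular regions obtained by
#' thresholding a Gaussian-smoothed white-noise field at the quantile that
#' yields the requested glandular area fraction. This emulates, at the ROI
#' scale relevant for CNR, the mixed fibroglandular/adipose content of a
#' mastectomy sample; it makes no claim of anatomical realism.
#'
#' @param diameter_cm disk diameter, cm.
#' @param glandular_fraction target glandular area fraction in (0, 1).
#' @param pixel_size_um pixel side, micrometers.
#' @param seed integer seed; the label map is a pure function of the
#'   arguments and the seed.
#' @param smooth_mm Gaussian smoothing length (sigma), mm.
#' @param height_mm extrusion height, mm.
#' @return [phantom_grid()] with labels 1 = adipose, 2 = glandular.
#' @export
make_breast_phantom <- function(diameter_cm, glandular_fraction,
                                pixel_size_um, seed, smooth_mm = 5,
                                height_mm = 5) {
  stopifnot(glandular_fraction > 0, glandular_fraction < 1,
            pixel_size_um > 0)
  n <- .grid_side(diameter_cm, pixel_size_um)
  r_px <- diameter_cm * 1e4 / 2 / pixel_size_um
  disk <- .disk_mask(n, r_px)
  noise <- .with_seed(seed, matrix(rnorm(n * n), n, n))
  field <- .gaussian_blur_fft(noise, smooth_mm * 1e3 / pixel_size_um)
  thr <- quantile(field[disk], 1 - glandular_fraction, names = FALSE)
  labels <- matrix(0L, n, n)
  labels[disk] <- 1L
  labels[disk & field > thr] <- 2L
  got <- sum(labels == 2L) / sum(disk)
  if (abs(got - glandular_fraction) > 0.02) {
    stop(sprintf("achieved glandular fraction %.3f is off target %.3f; %s",
                 got, glandular_fraction,
                 "grid too coarse for the requested fraction"))
  }
  phantom_grid(labels, pixel_size_um, c("adipose", "glandular"), height_mm)
}

# run expr with a local RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Step-wedge transmittance fixture
#'
#' Simulates a planar transmittance image of a step wedge: one band per
#' thickness step plus an unattenuated flat band, with expected per-band
#' transmittance exp(-mu t) and optional Poisson counting noise at a stated
#' per-pixel fluence.
#'
#' @param material material name, or `"vacuum"` for mu = 0.
#' @param thicknesses_mm strictly increasing step thicknesses, mm.
#' @param E beam energy, keV.
#' @param fluence_per_px expected flat-field counts per pixel.
#' @param lib a [material_library()].
#' @param seed integer seed for the Poisson draw (ignored if `noiseless`).
#' @param noiseless if `TRUE`, counts equal their expectation.
#' @param band_px `c(width, height)` of each band in pixels.
#' @param mu_per_cm optional attenuation coefficient override (1/cm),
#'   bypassing the library lookup.
#' @return `step_wedge` object: the transmittance image, raw counts, band
#'   index map, per-step mean transmittance and generation parameters.
#' @export
make_stepwedge <- function(material, thicknesses_mm, E, fluence_per_px,
                           lib = material_library(), seed = 1L,
                           noiseless = FALSE, band_px = c(32L, 64L),
                           mu_per_cm = NULL) {
  stopifnot(all(thicknesses_mm > 0),
            !is.unsorted(thicknesses_mm, strictly = TRUE),
            fluence_per_px > 0)
  if (is.null(mu_per_cm)) {
    mu_per_cm <- if (identical(material, "vacuum")) 0 else get_mu(lib, material, E)
  }
  t_steps <- c(0, thicknesses_mm)  # leading flat band
  t_exp <- exp(-mu_per_cm * t_steps / 10)
  w <- band_px[1L]
  h <- band_px[2L]
  nbands <- length(t_steps)
  band <- matrix(rep(seq_len(nbands), each = w), nrow = h,
                 ncol = nbands * w, byrow = TRUE)
  expected <- fluence_per_px * t_exp[band]
  dim(expected) <- dim(band)
  counts <- if (noiseless) expected else {
    .with_seed(seed, matrix(rpois(length(expected), expected), nrow = h))
  }
  transmittance <- counts / fluence_per_px
  mean_t <- vapply(seq_len(nbands),
                   function(b) mean(transmittance[band == b]), 0)
  structure(list(material = material, thicknesses_mm = thicknesses_mm,
                 E_keV = E, fluence_per_px = fluence_per_px,
                 mu_per_cm = mu_per_cm, noiseless = noiseless,
                 band = band, counts = counts,
                 transmittance = transmittance,
                 expected_transmittance = t_exp,
                 mean_transmittance = mean_t),
            class = "step_wedge")
}

#' Write / read a phantom as 16-bit TIFF plus JSON sidecar
#'
#' The label map round-trips losslessly (labels < 65536). The sidecar
#' `<path>.json` stores `pixel_size_um`, `label_map` and `height_mm`.
#'
#' @param phantom a [phantom_grid()].
#' @param path TIFF file path.
#' @return `write_phantom`: the path, invisibly. `read_phantom`: the
#'   reconstructed [phantom_grid()].
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_grid"))
  tiff::writeTIFF(phantom$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_um = phantom$pixel_size_um,
                            label_map = phantom$label_map,
                            height_mm = phantom$height_mm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  phantom_grid(labels, meta$pixel_size_um, meta$label_map, meta$height_mm)
}
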