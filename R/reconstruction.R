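#' Beer-Lambert log transform
#'
#' @param transmittance strictly positive transmittance values (sinogram,
#'   image or array).
#' @return `-log(transmittance)`, elementwise.
#' @export
log_transform <- function(transmittance) {
  if (any(transmittance <= 0)) {
    stop("transmittance must be strictly positive; apply a zero-count policy first")
  }
  -log(transmittance)
}

# Shepp-Logan filter responses for projections of length n_det sampled at
# tau (cm): the ramp |w| apodized by sinc(w / (2 w_N)), built by sampling
# the exact spatial-domain kernel h(k tau) = -2 / (pi^2 tau^2 (4 k^2 - 1))
# and transforming (this avoids the DC bias of direct frequency sampling).
.shepp_logan_response <- function(n_det, tau, n_fft) {
  k <- c(0:(n_fft %/% 2 - 1), -(n_fft - n_fft %/% 2):-1)
  h <- -2 / (pi^2 * tau^2 * (4 * k^2 - 1))
  Re(fft(h))
}

#' Filtered back-projection with Shepp-Logan filtering
#'
#' Parallel-beam FBP: each projection is convolved (via FFT, zero-padded to
#' at least twice the detector length) with the Shepp-Logan kernel, then
#' back-projected with linear interpolation onto a square grid whose center
#' is the rotation axis. Scaling is such that a uniform disk of attenuation
#' mu reconstructs to mu (1/cm).
#'
#' @param sinogram matrix `[n_det, n_projections]` of line integrals
#'   (dimensionless, path lengths in cm).
#' @param geom a [scan_geometry()] with uniform angles over the arc.
#' @param pixel_size_um reconstruction pixel size = detector pixel, um.
#' @param energy_keV optional energy tag carried into the slice.
#' @param n_out output image side; defaults to `n_det`.
#' @return `recon_slice` object: `image` (n x n matrix, 1/cm),
#'   `pixel_size_um`, `energy_keV`.
#' @export
fbp <- function(sinogram, geom, pixel_size_um = geom$detector_pixel_um,
                energy_keV = NA_real_, n_out = NULL) {
  stopifnot(inherits(geom, "scan_geometry"),
            ncol(sinogram) == geom$n_projections)
  n_det <- nrow(sinogram)
  if (is.null(n_out)) n_out <- n_det
  tau <- pixel_size_um / 1e4  # cm
  n_fft <- .next_fast(2L * n_det)
  resp <- .shepp_logan_response(n_det, tau, n_fft)
  padded <- matrix(0, n_fft, ncol(sinogram))
  padded[seq_len(n_det), ] <- sinogram
  q <- Re(mvfft(mvfft(padded) * resp, inverse = TRUE)) / n_fft
  q <- q[seq_len(n_det), , drop = FALSE] * tau
  dtheta <- geom$arc_deg * pi / 180 / geom$n_projections
  img <- cpp_backproject(q, .geom_angles(geom), n_out, (n_det - 1) / 2,
                         dtheta, n_det / 2)
  recon_slice(img, pixel_size_um, energy_keV)
}

#' Reconstructed slice container
#'
#' @param image square matrix of reconstructed attenuation, 1/cm.
#' @param pixel_size_um pixel size, um.
#' @param energy_keV beam energy tag, keV.
#' @return `recon_slice` object.
#' @export
recon_slice <- function(image, pixel_size_um, energy_keV = NA_real_) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  structure(list(image = image, pixel_size_um = pixel_size_um,
                 energy_keV = energy_keV),
            class = "recon_slice")
}

#' @export
print.recon_slice <- function(x, ...) {
  cat(sprintf("<recon_slice> %d x %d px @ %g um, E = %s keV, range [%.4g, %.4g] 1/cm\n",
              nrow(x$image), ncol(x$image), x$pixel_size_um,
              format(x$energy_keV), min(x$image), max(x$image)))
  invisible(x)
}

#' Write / read a reconstructed slice as 32-bit float TIFF + JSON sidecar
#'
#' @param slice a [recon_slice()].
#' @param path TIFF file path.
#' @return `write_recon_slice`: the path, invisibly; `read_recon_slice`:
#'   the [recon_slice()].
#' @export
write_recon_slice <- function(slice, path) {
  stopifnot(inherits(slice, "recon_slice"))
  tiff::writeTIFF(slice$image, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  jsonlite::write_json(list(pixel_size_um = slice$pixel_size_um,
                            energy_keV = slice$energy_keV),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recon_slice
#' @export
read_recon_slice <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  recon_slice(img, meta$pixel_size_um,
              if (is.null(meta$energy_keV)) NA_real_ else meta$energy_keV)
}

#' Full reconstruction pipeline for a count stack
#'
#' preprocess (zero-count policy + flat normalization) -> optional TIE-Hom
#' phase retrieval on each 2D projection -> log transform -> per-row
#' Shepp-Logan FBP. With phase retrieval enabled the 2D filter runs on the
#' full (rows x columns) projections before rows are sliced, so vertical
#' noise smoothing is captured.
#'
#' @param stack a [sample_counts()] stack.
#' @param geom the [scan_geometry()] of the stack.
#' @param phr `NULL` for absorption reconstruction, or a [phr_params()].
#' @param policy zero-count policy for [preprocess_counts()].
#' @param rows detector rows to reconstruct (default: the central
#'   `min(10, n_rows)` rows).
#' @param transmittance optional precomputed transmittance array (to share
#'   one preprocessing pass between modalities).
#' @param n_out output image side (centered on the rotation axis); defaults
#'   to the full detector width. Because FBP is per-pixel independent, a
#'   centered subregion reconstructs to exactly the same values as the
#'   corresponding pixels of the full image.
#' @return list of [recon_slice()] objects, one per requested row.
#' @export
reconstruct_stack <- function(stack, geom, phr = NULL, policy = "median3",
                              rows = NULL, transmittance = NULL,
                              n_out = NULL) {
  if (is.null(transmittance)) {
    transmittance <- preprocess_counts(stack, policy)
  }
  d <- dim(transmittance)
  n_rows <- d[3]
  if (is.null(rows)) {
    take <- min(10L, n_rows)
    first <- (n_rows - take) %/% 2
    rows <- first + seq_len(take)
  }
  if (!is.null(phr)) {
    stopifnot(inherits(phr, "phr_params"))
    if (phr$delta_beta > 0) {
      for (k in seq_len(d[2])) {
        transmittance[, k, ] <- apply_phr(
          matrix(transmittance[, k, ], d[1], d[3]), phr)
      }
    }
  }
  energy <- if (is.null(phr)) NA_real_ else phr$E_keV
  lapply(rows, function(r) {
    sino <- log_transform(matrix(transmittance[, , r], d[1], d[2]))
    fbp(sino, geom, pixel_size_um = geom$detector_pixel_um,
        energy_keV = energy, n_out = n_out)
  })
}
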