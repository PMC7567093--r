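#' Phase-retrieval (TIE-Hom) parameters
#'
#' The single-material TIE-Hom filter acts in 2D Fourier space as
#' `H(u, v) = 1 / (1 + pi * d * lambda * (delta/beta) * |w|^2)` with
#' `w = sqrt(u^2 + v^2)`. Frequencies are in cycles per meter, so the
#' filter coefficient is exactly `pi * d * lambda * (delta/beta)` (radian
#' conventions would differ by (2*pi)^2).
#'
#' @param E_keV beam energy, keV (sets lambda).
#' @param delta_beta delta/beta ratio of the retrieval material (breast
#'   ICRU-44 by convention for breast imaging; see [get_delta_beta()]).
#' @param pixel_um detector pixel side, micrometers.
#' @param distance_m propagation (object-to-detector) distance, m.
#' @param pad_factor padding factor (>= 1) for the Fourier transform;
#'   images are edge-replicated to `pad_factor` times each dimension
#'   (rounded up to a fast FFT size) to suppress wrap-around of the
#'   long-tailed kernel.
#' @return `phr_params` object with the precomputed coefficient
#'   `a_m2 = pi * d * lambda * delta/beta` (m^2).
#' @export
phr_params <- function(E_keV, delta_beta, pixel_um, distance_m = 1.6,
                       pad_factor = 2) {
  stopifnot(E_keV > 0, delta_beta >= 0, pixel_um > 0, distance_m >= 0,
            pad_factor >= 1)
  structure(list(E_keV = E_keV, delta_beta = delta_beta,
                 pixel_um = pixel_um, distance_m = distance_m,
                 pad_factor = pad_factor,
                 a_m2 = pi * distance_m * wavelength(E_keV) * delta_beta),
            class = "phr_params")
}

#' TIE-Hom transfer function
#'
#' @param u,v spatial frequencies, cycles/m (vectorized, recycled).
#' @param params a [phr_params()].
#' @return `H(u, v)` in (0, 1]; `H(0, 0) = 1`, radially symmetric and
#'   strictly decreasing in `|w|` for `delta_beta > 0`.
#' @export
tie_hom_transfer <- function(u, v, params) {
  stopifnot(inherits(params, "phr_params"))
  1 / (1 + params$a_m2 * (u^2 + v^2))
}

.fft_freqs <- function(n, dx_m) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (n %% 2 == 0) k <- c(0:(n %/% 2 - 1), -(n %/% 2):-1)
  k / (n * dx_m)
}

.next_fast <- function(n) {
  # smallest 2^a * 3^b * 5^c >= n
  best <- 2^ceiling(log2(n))
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      m <- p35 * 2^max(0, ceiling(log2(n / p35)))
      if (m >= n && m < best) best <- m
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  best
}

.pad_idx <- function(n, npad) {
  lo <- (npad - n) %/% 2
  c(rep(1L, lo), seq_len(n), rep(n, npad - n - lo))
}

#' Apply the TIE-Hom filter to a projection image
#'
#' Edge-replicated padding to `pad_factor` times each dimension (next fast
#' FFT size), multiplication by the transfer function in Fourier space,
#' inverse transform and crop. Constant images are invariant (only the DC
#' term survives and `H(0,0) = 1`) and the operation commutes with scalar
#' scaling.
#'
#' @param projection 2D image (rows x columns of one projection), strictly
#'   positive transmittance after the zero-count policy.
#' @param params a [phr_params()].
#' @return filtered image, same dimensions, real-valued.
#' @export
apply_phr <- function(projection, params) {
  stopifnot(inherits(params, "phr_params"), is.matrix(projection))
  if (any(projection <= 0)) {
    stop("projection must be strictly positive (run the zero-count policy first)")
  }
  nr <- nrow(projection)
  nc <- ncol(projection)
  NR <- .next_fast(max(2L, ceiling(params$pad_factor * nr)))
  NC <- .next_fast(max(2L, ceiling(params$pad_factor * nc)))
  rlo <- (NR - nr) %/% 2
  clo <- (NC - nc) %/% 2
  padded <- projection[.pad_idx(nr, NR), .pad_idx(nc, NC), drop = FALSE]
  dx <- params$pixel_um * 1e-6
  hkey <- paste(NR, NC, params$a_m2, dx, sep = "/")
  H <- .bct_cache$H[[hkey]]
  if (is.null(H)) {
    H <- outer(.fft_freqs(NR, dx)^2, .fft_freqs(NC, dx)^2, "+")
    H <- 1 / (1 + params$a_m2 * H)
    if (is.null(.bct_cache$H) || length(.bct_cache$H) > 8) {
      .bct_cache$H <- list()
    }
    .bct_cache$H[[hkey]] <- H
  }
  out <- Re(fft(fft(padded) * H, inverse = TRUE)) / (NR * NC)
  out[rlo + seq_len(nr), clo + seq_len(nc), drop = FALSE]
}

#' Real-space width of the TIE-Hom kernel
#'
#' Full width at half maximum of the real-space filter kernel as it acts on
#' pixel-sampled images (the transfer function times the pixel-aperture
#' transform), measured on a finely sampled central profile. In the
#' identity limit (`delta_beta -> 0`) the kernel collapses to the 1-pixel
#' detector aperture; the width grows with `d` and with `delta/beta`.
#'
#' @param params a [phr_params()].
#' @param oversample sub-pixel sampling factor of the profile.
#' @param support_px half-support of the evaluation window, pixels.
#' @return FWHM in detector pixels.
#' @export
kernel_width <- function(params, oversample = 16L, support_px = 64L) {
  stopifnot(inherits(params, "phr_params"))
  dx <- params$pixel_um * 1e-6 / oversample
  n <- .next_fast(2L * oversample * support_px)
  fu <- .fft_freqs(n, dx)
  # radial kernel: 2D filter evaluated on the (u, 0) axis times the pixel
  # aperture transform in that direction
  px <- params$pixel_um * 1e-6
  apert <- ifelse(fu == 0, 1, sin(pi * fu * px) / (pi * fu * px))
  H1 <- (1 / (1 + params$a_m2 * fu^2)) * apert
  prof <- Re(fft(H1, inverse = TRUE))
  prof <- prof / prof[1]
  # profile at radii 0, dx, 2 dx, ...
  r <- seq(0, by = dx, length.out = n %/% 2)
  p <- prof[seq_len(n %/% 2)]
  below <- which(p < 0.5)
  if (length(below) == 0L) return(Inf)
  i <- below[1]
  # linear interpolation of the half-max crossing
  r_half <- r[i - 1] + (0.5 - p[i - 1]) * (r[i] - r[i - 1]) / (p[i] - p[i - 1])
  2 * r_half / px
}
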