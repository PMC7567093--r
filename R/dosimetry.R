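#' Dose configuration
#'
#' Describes how a prescribed mean glandular dose (MGD) is turned into photon
#' fluence: MGD = K * DgN, with K the entrance air kerma of the unattenuated
#' (free-in-air) beam and DgN the normalized glandular dose. DgN comes either
#' from the built-in primary-beam surrogate ([dgn_surrogate()]) or from a
#' user-supplied table, making the dose model pluggable.
#'
#' @param mgd_mGy mean glandular dose, mGy (>= 0).
#' @param dgn `"surrogate"`, a data frame with columns `energy_keV` and
#'   `dgn`, or the path of a CSV file with those columns. Table values are
#'   interpolated linearly in energy.
#' @param n_projections number of projections the total fluence is divided
#'   into (continuous-rotation uniform exposure).
#' @return `dose_config` object.
#' @export
dose_config <- function(mgd_mGy, dgn = "surrogate", n_projections = 1200L) {
  stopifnot(mgd_mGy >= 0, n_projections >= 1)
  if (is.character(dgn) && !identical(dgn, "surrogate")) {
    dgn <- read.csv(dgn)
  }
  if (is.data.frame(dgn)) {
    if (!all(c("energy_keV", "dgn") %in% names(dgn))) {
      stop("DgN table needs columns energy_keV and dgn")
    }
    if (any(dgn$dgn <= 0)) stop("DgN values must be positive")
  } else if (!identical(dgn, "surrogate")) {
    stop("dgn must be \"surrogate\", a data frame, or a CSV path")
  }
  structure(list(mgd_mGy = mgd_mGy, dgn = dgn,
                 n_projections = as.integer(n_projections)),
            class = "dose_config")
}

.KEV_TO_J <- 1.602176634e-16

#' Entrance air kerma per unit fluence
#'
#' K/Phi = E * (mu_en/rho)_air, converted so that fluence in photons/mm^2
#' gives kerma in mGy.
#'
#' @param E energy, keV.
#' @param lib a [material_library()].
#' @return kerma per unit fluence, mGy / (photons/mm^2).
#' @export
kerma_per_unit_fluence <- function(E, lib = material_library()) {
  muen_m2_kg <- get_mu_en_rho(lib, "air", E) * 0.1
  # photons/mm^2 -> photons/m^2 (1e6), Gy -> mGy (1e3)
  1e6 * E * .KEV_TO_J * muen_m2_kg * 1e3
}

#' Air kerma of a photon fluence
#'
#' @param phi_mm2 fluence, photons/mm^2 (>= 0).
#' @inheritParams kerma_per_unit_fluence
#' @return air kerma, mGy (linear in `phi_mm2`).
#' @export
kerma_from_fluence <- function(phi_mm2, E, lib = material_library()) {
  stopifnot(all(phi_mm2 >= 0))
  phi_mm2 * kerma_per_unit_fluence(E, lib)
}

.phantom_key <- function(phantom, extra = "") {
  l <- phantom$labels
  paste(nrow(l), phantom$pixel_size_um,
        paste(phantom$label_map, collapse = "|"),
        sum(l), sum(as.double(l) * seq_along(l) %% 1e9), extra, sep = "/")
}

.phantom_rmax <- function(phantom) {
  n <- nrow(phantom$labels)
  nz <- which(phantom$labels > 0L, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(1)
  c0 <- (n - 1) / 2 + 1
  sqrt(max((nz[, 1] - c0)^2 + (nz[, 2] - c0)^2)) + 1.5
}

# cached per-label entrance path lengths [pixel, angle, label] for the
# dose-target pixels (all pixels bound to target_mat) of a phantom
.entry_lengths <- function(phantom, target_mat, n_angles, max_pixels) {
  key <- .phantom_key(phantom, paste("entry", target_mat, n_angles,
                                     max_pixels))
  hit <- .bct_cache$entry[[key]]
  if (!is.null(hit)) return(hit)
  target_labels <- which(phantom$label_map == target_mat)
  idx <- which(matrix(phantom$labels %in% target_labels,
                      nrow(phantom$labels)), arr.ind = TRUE)
  if (nrow(idx) > max_pixels) {
    keep <- unique(round(seq(1, nrow(idx), length.out = max_pixels)))
    idx <- idx[keep, , drop = FALSE]
  }
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  lens <- cpp_entry_integrals(phantom$labels, length(phantom$label_map),
                              idx[, 1] - 1L, idx[, 2] - 1L, angles,
                              phantom$pixel_size_um / 1e4, 0.5,
                              .phantom_rmax(phantom))
  if (is.null(.bct_cache$entry)) .bct_cache$entry <- list()
  .bct_cache$entry[[key]] <- lens
  lens
}

#' Primary-beam surrogate for the normalized glandular dose
#'
#' DgN is approximated as the entrance-beam transmittance to the glandular
#' pixels, averaged over those pixels and over the 180-degree view set,
#' times the ratio of mass energy-absorption coefficients of glandular
#' tissue and air:
#' `DgN = < exp(-int mu dl) > * (mu_en/rho)_gland / (mu_en/rho)_air`.
#' It is primary-beam only (no scatter, no secondary transport), the same
#' physics tier as the projector; Monte-Carlo DgN tables can be supplied
#' through [dose_config()] instead.
#'
#' @param phantom a [phantom_grid()]. If it contains no glandular-bound
#'   label, a homogeneous (single-material) phantom is accepted and that
#'   material becomes the dose target.
#' @param E energy, keV.
#' @param lib a [material_library()].
#' @param n_angles number of view angles for the angular average.
#' @param max_pixels cap on target pixels (deterministic thinning).
#' @return DgN, mGy/mGy, in (0, (mu_en/rho)_target / (mu_en/rho)_air].
#' @export
dgn_surrogate <- function(phantom, E, lib = material_library(),
                          n_angles = 180L, max_pixels = 2000L) {
  present <- unique(phantom$label_map[phantom$labels[phantom$labels > 0L]])
  target_mat <- if ("glandular" %in% present) {
    "glandular"
  } else if (length(present) == 1L) {
    present
  } else {
    stop("phantom has no glandular label and is not homogeneous; ",
         "no dose target")
  }
  lens <- .entry_lengths(phantom, target_mat, n_angles, max_pixels)
  mu <- vapply(phantom$label_map, function(m) get_mu(lib, m, E), 0)
  nl <- length(phantom$label_map)
  np <- dim(lens)[1]
  na <- dim(lens)[2]
  path <- matrix(0, np, na)
  for (l in seq_len(nl)) path <- path + mu[l] * lens[, , l]
  mean_t <- mean(exp(-path))
  mean_t * get_mu_en_rho(lib, target_mat, E) / get_mu_en_rho(lib, "air", E)
}

.dgn_at <- function(config, phantom, E, lib) {
  if (is.data.frame(config$dgn)) {
    tab <- config$dgn
    if (E < min(tab$energy_keV) || E > max(tab$energy_keV)) {
      stop(sprintf("DgN table does not cover %g keV", E))
    }
    approx(tab$energy_keV, tab$dgn, xout = E)$y
  } else {
    dgn_surrogate(phantom, E, lib)
  }
}

#' Per-projection fluence realizing a prescribed mean glandular dose
#'
#' Inverts MGD = K * DgN: total entrance fluence
#' `Phi_total = MGD / (DgN(E) * K_per_fluence(E))`, divided equally among
#' the projections.
#'
#' @param config a [dose_config()].
#' @param phantom a [phantom_grid()] (used by the DgN surrogate; ignored
#'   when `config` carries a DgN table).
#' @param E energy, keV.
#' @param lib a [material_library()].
#' @return list with `phi_total_mm2`, `phi_proj_mm2` (photons/mm^2),
#'   `dgn`, and `kerma_mGy`.
#' @export
fluence_for_mgd <- function(config, phantom, E, lib = material_library()) {
  stopifnot(inherits(config, "dose_config"))
  dgn <- .dgn_at(config, phantom, E, lib)
  kpf <- kerma_per_unit_fluence(E, lib)
  phi_total <- config$mgd_mGy / (dgn * kpf)
  list(phi_total_mm2 = phi_total,
       phi_proj_mm2 = phi_total / config$n_projections,
       dgn = dgn, kerma_mGy = phi_total * kpf)
}
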