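# derived sub-seed, kept below 2^31
.sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 77003 * i) %% 2147483647)
}

.breast_delta_beta <- function(E, lib) {
  get_delta_beta(lib, "breast_icru44", E)$delta_beta
}

#' CNR-versus-energy scan at fixed mean glandular dose
#'
#' For each energy: convert the prescribed MGD to a per-projection fluence,
#' simulate a Poisson count stack, reconstruct (absorption, or TIE-Hom
#' phase-retrieved with the breast ICRU-44 delta/beta) and compute the
#' glandular-vs-background CNR averaged over `n_slices` independent row
#' realizations. The maximizing energy is reported; exact ties break toward
#' the lower energy.
#'
#' @param phantom a [phantom_grid()].
#' @param energies energy grid, keV (ascending).
#' @param mgd_mGy mean glandular dose, mGy (constant across the scan).
#' @param modality `"absorption"` or `"phase"`.
#' @param geom a [scan_geometry()]; its `n_rows` must be >= `n_slices`
#'   (use extra rows as vertical margin for the 2D phase-retrieval filter).
#' @param lib a [material_library()].
#' @param n_slices slices (rows) averaged into each CNR value.
#' @param seed base seed; each energy uses a derived sub-seed.
#' @param dgn DgN source for [dose_config()].
#' @param policy zero-count policy.
#' @param margin_px ROI margin from interfaces, pixels.
#' @return `energy_scan_result`: `table` (energy, cnr, sem, ROI stats,
#'   fluence), `argmax_energy`, `ties`, `modality`, `rois`.
#' @export
energy_scan <- function(phantom, energies, mgd_mGy = 20,
                        modality = c("absorption", "phase"), geom,
                        lib = material_library(), n_slices = 10L, seed = 1L,
                        dgn = "surrogate", policy = "median3",
                        margin_px = 10) {
  modality <- match.arg(modality)
  stopifnot(!is.unsorted(energies, strictly = TRUE),
            geom$n_rows >= n_slices)
  rois <- auto_roi(phantom, margin_px)
  crop <- .roi_crop(rois, nrow(phantom$labels))
  config <- dose_config(mgd_mGy, dgn, geom$n_projections)
  rows <- lapply(seq_along(energies), function(i) {
    E <- energies[i]
    fl <- fluence_for_mgd(config, phantom, E, lib)
    sino <- line_integral_sinogram(phantom, E, geom, lib)
    ec <- expected_counts(sino, fl$phi_proj_mm2, geom)
    stack <- sample_counts(ec, geom, .sub_seed(seed, i))
    phr <- if (modality == "phase") {
      phr_params(E, .breast_delta_beta(E, lib), geom$detector_pixel_um,
                 geom$propagation_distance_m)
    }
    first <- (geom$n_rows - n_slices) %/% 2
    slices <- reconstruct_stack(stack, geom, phr = phr, policy = policy,
                                rows = first + seq_len(n_slices),
                                n_out = crop$n_out)
    res <- cnr_stack(slices, crop$rois)
    data.frame(energy_keV = E, cnr = res$cnr, sem = res$sem,
               S_g = res$S_g, S_f = res$S_f, sigma_f = res$sigma_f,
               dgn = fl$dgn, phi_proj_mm2 = fl$phi_proj_mm2)
  })
  tab <- do.call(rbind, rows)
  best <- which(tab$cnr == max(tab$cnr))  # ascending grid: first = lowest E
  structure(list(table = tab, argmax_energy = energies[best[1L]],
                 ties = energies[best], modality = modality,
                 mgd_mGy = mgd_mGy, n_slices = n_slices, seed = seed,
                 rois = rois),
            class = "energy_scan_result")
}

#' @export
print.energy_scan_result <- function(x, ...) {
  cat(sprintf("<energy_scan_result> %s, MGD %g mGy, %d energies\n",
              x$modality, x$mgd_mGy, nrow(x$table)))
  print(x$table[, c("energy_keV", "cnr", "sem")], row.names = FALSE,
        digits = 4)
  cat(sprintf("argmax CNR at %g keV%s\n", x$argmax_energy,
              if (length(x$ties) > 1) {
                paste0(" (tied: ", paste(x$ties, collapse = ", "), " keV)")
              } else ""))
  invisible(x)
}

#' Phase-retrieval CNR gain on identical noise realizations
#'
#' Simulates one noisy scan and reconstructs the same count data twice,
#' with and without the TIE-Hom filter, on identical ROIs; returns the CNR
#' ratio. With `delta_beta = 0` the filter is the identity and the ratio is
#' exactly 1.
#'
#' @inheritParams energy_scan
#' @param E beam energy, keV.
#' @param delta_beta filter strength; default: breast ICRU-44 at `E`.
#' @return list: `ratio`, `cnr_phase`, `cnr_absorption`, `rois`.
#' @export
phr_gain <- function(phantom, E, mgd_mGy = 20, geom,
                     lib = material_library(), n_slices = 10L, seed = 1L,
                     dgn = "surrogate", policy = "median3", margin_px = 10,
                     delta_beta = NULL) {
  stopifnot(geom$n_rows >= n_slices)
  if (is.null(delta_beta)) delta_beta <- .breast_delta_beta(E, lib)
  rois <- auto_roi(phantom, margin_px)
  crop <- .roi_crop(rois, nrow(phantom$labels))
  config <- dose_config(mgd_mGy, dgn, geom$n_projections)
  fl <- fluence_for_mgd(config, phantom, E, lib)
  sino <- line_integral_sinogram(phantom, E, geom, lib)
  ec <- expected_counts(sino, fl$phi_proj_mm2, geom)
  stack <- sample_counts(ec, geom, seed)
  trans <- preprocess_counts(stack, policy)
  first <- (geom$n_rows - n_slices) %/% 2
  rows <- first + seq_len(n_slices)
  phr <- phr_params(E, delta_beta, geom$detector_pixel_um,
                    geom$propagation_distance_m)
  s_abs <- reconstruct_stack(stack, geom, phr = NULL, rows = rows,
                             transmittance = trans, n_out = crop$n_out)
  s_phr <- reconstruct_stack(stack, geom, phr = phr, rows = rows,
                             transmittance = trans, n_out = crop$n_out)
  c_abs <- cnr_stack(s_abs, crop$rois)
  c_phr <- cnr_stack(s_phr, crop$rois)
  list(ratio = c_phr$cnr / c_abs$cnr, cnr_phase = c_phr,
       cnr_absorption = c_abs, rois = rois, E_keV = E, seed = seed)
}

#' CNR and photon-starvation metrics versus dose
#'
#' At fixed energy, scans a list of doses: per dose the fluence, a noisy
#' stack, starvation metrics (minimum mean counts `N_min` in the central
#' shadow window and zero-count fraction), and the CNR of the
#' phase-retrieved reconstruction on fixed ROIs.
#'
#' @inheritParams energy_scan
#' @param E beam energy, keV.
#' @param doses_mGy dose list, mGy (any order; tabulated as given).
#' @param central_fraction window for [starvation_metrics()].
#' @param phase if `TRUE` (default) reconstruct with phase retrieval.
#' @return `starvation_scan_result` with a per-dose `table`.
#' @export
starvation_scan <- function(phantom, E, doses_mGy, geom,
                            lib = material_library(), n_slices = 10L,
                            seed = 1L, dgn = "surrogate", policy = "median3",
                            margin_px = 10, central_fraction = 0.1,
                            phase = TRUE) {
  stopifnot(all(doses_mGy > 0), geom$n_rows >= n_slices)
  rois <- auto_roi(phantom, margin_px)
  crop <- .roi_crop(rois, nrow(phantom$labels))
  sino <- line_integral_sinogram(phantom, E, geom, lib)
  phr <- if (phase) {
    phr_params(E, .breast_delta_beta(E, lib), geom$detector_pixel_um,
               geom$propagation_distance_m)
  }
  first <- (geom$n_rows - n_slices) %/% 2
  rows_sel <- first + seq_len(n_slices)
  rows <- lapply(seq_along(doses_mGy), function(i) {
    config <- dose_config(doses_mGy[i], dgn, geom$n_projections)
    fl <- fluence_for_mgd(config, phantom, E, lib)
    ec <- expected_counts(sino, fl$phi_proj_mm2, geom)
    stack <- sample_counts(ec, geom, .sub_seed(seed, i))
    sm <- starvation_metrics(stack, central_fraction)
    slices <- reconstruct_stack(stack, geom, phr = phr, policy = policy,
                                rows = rows_sel, n_out = crop$n_out)
    res <- cnr_stack(slices, crop$rois)
    data.frame(mgd_mGy = doses_mGy[i], phi_proj_mm2 = fl$phi_proj_mm2,
               n_min = sm$n_min, zero_fraction = sm$zero_fraction,
               cnr = res$cnr, sem = res$sem)
  })
  structure(list(table = do.call(rbind, rows), E_keV = E, seed = seed,
                 rois = rois, phase = phase),
            class = "starvation_scan_result")
}

#' @export
print.starvation_scan_result <- function(x, ...) {
  cat(sprintf("<starvation_scan_result> E = %g keV, %d doses%s\n", x$E_keV,
              nrow(x$table), if (x$phase) ", phase-retrieved" else ""))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Power-law exponent of CNR versus dose
#'
#' Log-log linear fit of `cnr ~ dose`, typically restricted to the
#' well-sampled regime (zero-count fraction below 25%), where counting
#' statistics predict an exponent of 1/2.
#'
#' @param scan a [starvation_scan()] result (or a data frame with columns
#'   `mgd_mGy`, `cnr`, `zero_fraction`).
#' @param max_zero_fraction regime cut on the zero-count fraction.
#' @return list: `exponent`, `stderr`, `n_points`.
#' @export
cnr_dose_exponent <- function(scan, max_zero_fraction = 0.25) {
  tab <- if (inherits(scan, "starvation_scan_result")) scan$table else scan
  keep <- tab$zero_fraction < max_zero_fraction & tab$cnr > 0
  if (sum(keep) < 2L) stop("fewer than 2 doses in the well-sampled regime")
  fit <- lm(log(cnr) ~ log(mgd_mGy), data = tab[keep, ])
  list(exponent = coef(fit)[["log(mgd_mGy)"]],
       stderr = sqrt(vcov(fit)["log(mgd_mGy)", "log(mgd_mGy)"]),
       n_points = sum(keep))
}
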