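#' Energy-dependent material coefficients
#'
#' A material record holds, on a common ascending energy grid (keV), the
#' linear attenuation coefficient mu (1/cm), the mass energy-absorption
#' coefficient mu_en/rho (cm^2/g) and the X-ray refractive index parts
#' delta and beta (n = 1 - delta + i beta). The built-in library embeds
#' tables at 1 keV spacing over 10-50 keV for:
#'
#' * `adipose`, `glandular` - Hammerstein breast-tissue compositions,
#'   standing in for the CIRS tissue-equivalent materials;
#' * `polyethylene` - (C2H4)n at 0.93 g/cm^3;
#' * `breast_icru44` - ICRU Report 44 breast tissue (the delta/beta source
#'   for phase retrieval);
#' * `air` - dry air near sea level (for entrance air kerma).
#'
#' Interpolation between grid points is linear in log-log coordinates, which
#' is accurate for smooth photoelectric-plus-Compton curves without
#' absorption edges, and exact at the grid points.
#'
#' @param custom optional named list of extra [material_record()] objects
#'   (or a single record); same-name entries override built-ins.
#' @return An object of class `material_library`: a named list of
#'   `material_record` objects with a `provenance` attribute.
#' @examples
#' lib <- material_library()
#' get_mu(lib, "glandular", 26)
#' @export
material_library <- function(custom = NULL) {
  if (is.null(.bct_cache$material_library)) {
    dir <- system.file("extdata", "materials", package = "bctsim")
    idx <- jsonlite::read_json(file.path(dir, "index.json"))
    recs <- lapply(names(idx), function(nm) {
      read_material_csv(file.path(dir, paste0(nm, ".csv")), name = nm,
                        density = idx[[nm]]$density_g_cm3)
    })
    names(recs) <- names(idx)
    attr(recs, "provenance") <- vapply(idx, function(x) x$provenance, "")
    class(recs) <- "material_library"
    .bct_cache$material_library <- recs
  }
  lib <- .bct_cache$material_library
  if (!is.null(custom)) {
    if (inherits(custom, "material_record")) custom <- list(custom)
    for (rec in custom) {
      stopifnot(inherits(rec, "material_record"))
      lib[[rec$name]] <- rec
    }
  }
  lib
}

#' Build a material record
#'
#' @param name material identifier.
#' @param density mass density, g/cm^3.
#' @param energies ascending energy grid, keV.
#' @param mu_over_rho mass attenuation coefficient, cm^2/g, per grid point.
#' @param mu_en_over_rho mass energy-absorption coefficient, cm^2/g.
#' @param delta,beta refractive-index decrement and imaginary part.
#' @return `material_record` object; `$mu` holds the linear attenuation
#'   coefficient (1/cm) = `mu_over_rho * density`.
#' @export
material_record <- function(name, density, energies, mu_over_rho,
                            mu_en_over_rho, delta, beta) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(density), density > 0,
            !is.unsorted(energies, strictly = TRUE))
  n <- length(energies)
  for (v in list(mu_over_rho, mu_en_over_rho, delta, beta)) {
    stopifnot(length(v) == n, all(v > 0))
  }
  structure(list(name = name, density = density,
                 energies = as.numeric(energies),
                 mu = as.numeric(mu_over_rho) * density,
                 mu_over_rho = as.numeric(mu_over_rho),
                 mu_en_rho = as.numeric(mu_en_over_rho),
                 delta = as.numeric(delta), beta = as.numeric(beta)),
            class = "material_record")
}

#' Read a material coefficient table from CSV
#'
#' Expected columns (header required): `energy_keV`, `mu_over_rho_cm2_g`,
#' `mu_en_over_rho_cm2_g`, `delta`, `beta`.
#'
#' @param path CSV file path.
#' @param name material name to register.
#' @param density mass density, g/cm^3 (not stored in the CSV).
#' @return A [material_record()].
#' @export
read_material_csv <- function(path, name, density) {
  tab <- read.csv(path)
  need <- c("energy_keV", "mu_over_rho_cm2_g", "mu_en_over_rho_cm2_g",
            "delta", "beta")
  if (!all(need %in% names(tab))) {
    stop("material CSV must have columns: ", paste(need, collapse = ", "))
  }
  material_record(name, density, tab$energy_keV, tab$mu_over_rho_cm2_g,
                  tab$mu_en_over_rho_cm2_g, tab$delta, tab$beta)
}

#' @export
print.material_library <- function(x, ...) {
  cat("<material_library> ", length(x), " materials: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.material_record <- function(x, ...) {
  cat(sprintf("<material_record> %s (rho = %g g/cm^3), %g-%g keV (%d points)\n",
              x$name, x$density, min(x$energies), max(x$energies),
              length(x$energies)))
  invisible(x)
}

.get_record <- function(lib, material) {
  rec <- lib[[material]]
  if (is.null(rec)) {
    stop("unknown material '", material, "'; available: ",
         paste(names(lib), collapse = ", "))
  }
  rec
}

.interp_loglog <- function(xgrid, ygrid, x) {
  if (any(x < xgrid[1L] | x > xgrid[length(xgrid)])) {
    stop(sprintf("energy out of table range [%g, %g] keV",
                 xgrid[1L], xgrid[length(xgrid)]))
  }
  exp(approx(log(xgrid), log(ygrid), xout = log(x))$y)
}

#' Linear attenuation coefficient at given energies
#'
#' @param lib a [material_library()].
#' @param material material name.
#' @param E energies, keV (vectorized); must lie within the table range.
#' @return mu in 1/cm (log-log interpolated, exact at grid points).
#' @export
get_mu <- function(lib, material, E) {
  rec <- .get_record(lib, material)
  .interp_loglog(rec$energies, rec$mu, E)
}

#' Mass energy-absorption coefficient at given energies
#'
#' @inheritParams get_mu
#' @return mu_en/rho in cm^2/g.
#' @export
get_mu_en_rho <- function(lib, material, E) {
  rec <- .get_record(lib, material)
  .interp_loglog(rec$energies, rec$mu_en_rho, E)
}

#' Refractive-index decrement, absorption index and their ratio
#'
#' @inheritParams get_mu
#' @return list with elements `delta`, `beta`, `delta_beta` (each vectorized
#'   over `E`).
#' @export
get_delta_beta <- function(lib, material, E) {
  rec <- .get_record(lib, material)
  d <- .interp_loglog(rec$energies, rec$delta, E)
  b <- .interp_loglog(rec$energies, rec$beta, E)
  list(delta = d, beta = b, delta_beta = d / b)
}

#' Photon wavelength
#'
#' lambda = hc/E with hc = 1.2398420 keV nm.
#'
#' @param E photon energy, keV (vectorized, positive).
#' @return wavelength in meters.
#' @export
wavelength <- function(E) {
  if (any(E <= 0)) stop("E must be positive")
  1.2398420 / E * 1e-9
}
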