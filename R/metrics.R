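#' Automatic ROI pair placement
#'
#' Places the largest concentric disk ROI that fits inside the detail
#' (glandular) region at `margin_px` from every material interface, and a
#' background ROI of exactly the same pixel footprint (the same offsets,
#' translated) inside the background material, also `margin_px` from every
#' interface. Among admissible background centers, the one whose distance
#' from the rotation axis is closest to the detail ROI's is chosen, so both
#' ROIs sit in the same radial band and share any residual radial
#' reconstruction bias.
#'
#' @param phantom a [phantom_grid()].
#' @param margin_px minimum distance from any interface, pixels (default 10
#'   at native resolution).
#' @param detail_material material name of the detail region (default
#'   `"glandular"`).
#' @param background_material material name of the background region;
#'   default: `"adipose"` when an adipose-bound label is present (the CNR
#'   reference tissue), otherwise the first other non-air label.
#' @return `roi_pair` object: integer index vectors `glandular` and
#'   `background` (same length), plus centers and radius.
#' @export
auto_roi <- function(phantom, margin_px = 10,
                     detail_material = "glandular",
                     background_material = NULL) {
  labels <- phantom$labels
  n <- nrow(labels)
  det_label <- match(detail_material, phantom$label_map)
  if (is.na(det_label)) stop("no label bound to ", detail_material)
  if (is.null(background_material)) {
    cand <- setdiff(seq_along(phantom$label_map), det_label)
    cand <- cand[cand %in% labels]
    if (length(cand) == 0L) stop("no background material present")
    adip <- cand[phantom$label_map[cand] == "adipose"]
    background_material <- phantom$label_map[if (length(adip)) adip[1L] else cand[1L]]
  }
  bg_label <- match(background_material, phantom$label_map)
  if (is.na(bg_label)) stop("no label bound to ", background_material)

  dd <- cpp_distance_transform(labels == det_label)
  db <- cpp_distance_transform(labels == bg_label)
  i_det <- which.max(dd)
  # the shared ROI radius must fit in both regions with the margin
  r_roi <- floor(min(dd[i_det], max(db)) - margin_px)
  if (r_roi < 2) {
    stop(sprintf("regions admit no common ROI with a %g px margin",
                 margin_px))
  }
  det_rc <- c((i_det - 1) %% n + 1, (i_det - 1) %/% n + 1)

  ok <- which(db >= r_roi + margin_px)
  c0 <- (n + 1) / 2
  ok_rc <- cbind((ok - 1) %% n + 1, (ok - 1) %/% n + 1)
  r_axis <- sqrt((ok_rc[, 1] - c0)^2 + (ok_rc[, 2] - c0)^2)
  det_axis <- sqrt(sum((det_rc - c0)^2))
  bg_rc <- ok_rc[which.min(abs(r_axis - det_axis)), ]

  # identical pixel footprint, translated
  w <- ceiling(r_roi)
  off <- expand.grid(dr = -w:w, dc = -w:w)
  off <- off[off$dr^2 + off$dc^2 < r_roi^2, ]
  gl_idx <- (det_rc[1] + off$dr) + n * (det_rc[2] + off$dc - 1)
  bg_idx <- (bg_rc[1] + off$dr) + n * (bg_rc[2] + off$dc - 1)
  stopifnot(all(labels[gl_idx] == det_label), all(labels[bg_idx] == bg_label))
  structure(list(glandular = as.integer(gl_idx),
                 background = as.integer(bg_idx),
                 radius_px = r_roi, margin_px = margin_px,
                 detail_center = det_rc, background_center = bg_rc,
                 detail_material = detail_material,
                 background_material = background_material),
            class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("<roi_pair> %d px each; detail (%s) at (%d, %d), background (%s) at (%d, %d), r = %g px, margin %g px\n",
              length(x$glandular), x$detail_material, x$detail_center[1],
              x$detail_center[2], x$background_material,
              x$background_center[1], x$background_center[2], x$radius_px,
              x$margin_px))
  invisible(x)
}

#' Contrast-to-noise ratio of one slice
#'
#' `CNR = (S_g - S_f) / sigma_f`, with `S_g` the mean gray level in the
#' glandular ROI and `S_f`, `sigma_f` the mean and standard deviation in
#' the background (adipose-role) ROI.
#'
#' @param slice a [recon_slice()] or a plain matrix.
#' @param rois an [auto_roi()] pair (index vectors into the image).
#' @return `cnr_result` object with `S_g`, `S_f`, `sigma_f`, `cnr`.
#' @export
cnr <- function(slice, rois) {
  img <- if (inherits(slice, "recon_slice")) slice$image else slice
  stopifnot(inherits(rois, "roi_pair"),
            max(rois$glandular, rois$background) <= length(img))
  s_g <- mean(img[rois$glandular])
  s_f <- mean(img[rois$background])
  sig <- sd(img[rois$background])
  if (sig == 0) stop("background ROI has zero variance; CNR undefined")
  structure(list(S_g = s_g, S_f = s_f, sigma_f = sig,
                 cnr = (s_g - s_f) / sig, per_slice = (s_g - s_f) / sig,
                 sem = NA_real_, n_slices = 1L),
            class = "cnr_result")
}

#' Aggregated CNR over a stack of slices
#'
#' The per-slice CNRs are averaged and the standard deviation of the mean
#' is reported as the statistical error.
#'
#' @param slices list of [recon_slice()] objects (or matrices).
#' @param rois an [auto_roi()] pair.
#' @return `cnr_result` with `cnr` (mean over slices), `sem`
#'   (sd/sqrt(n)), `per_slice`, and the per-slice means/SDs averaged into
#'   `S_g`, `S_f`, `sigma_f`.
#' @export
cnr_stack <- function(slices, rois) {
  stopifnot(length(slices) >= 1L)
  per <- lapply(slices, cnr, rois = rois)
  vals <- vapply(per, function(x) x$cnr, 0)
  structure(list(S_g = mean(vapply(per, function(x) x$S_g, 0)),
                 S_f = mean(vapply(per, function(x) x$S_f, 0)),
                 sigma_f = mean(vapply(per, function(x) x$sigma_f, 0)),
                 cnr = mean(vals),
                 per_slice = vals,
                 sem = if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else NA_real_,
                 n_slices = length(vals)),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("<cnr_result> CNR = %.3f%s (S_g = %.4g, S_f = %.4g, sigma_f = %.4g, n = %d)\n",
              x$cnr,
              if (is.na(x$sem)) "" else sprintf(" +/- %.3f", x$sem),
              x$S_g, x$S_f, x$sigma_f, x$n_slices))
  invisible(x)
}

# Translate an ROI pair onto a centered n_out x n_out reconstruction
# subgrid. FBP values on the subgrid are identical to the corresponding
# pixels of the full-grid reconstruction, so CNR is unchanged.
.roi_crop <- function(rois, n_full, pad = 4L) {
  c0 <- (n_full + 1) / 2
  idx <- c(rois$glandular, rois$background)
  r <- (idx - 1) %% n_full + 1
  cc <- (idx - 1) %/% n_full + 1
  ext <- max(abs(c(r, cc) - c0))
  n_out <- 2L * (as.integer(ceiling(ext)) + pad) + 1L
  if (n_out >= n_full) {
    return(list(n_out = NULL, rois = rois))
  }
  shift <- (n_full - n_out) %/% 2
  remap <- function(i) {
    rr <- (i - 1) %% n_full + 1 - shift
    ci <- (i - 1) %/% n_full + 1 - shift
    stopifnot(all(rr >= 1), all(rr <= n_out), all(ci >= 1), all(ci <= n_out))
    as.integer(rr + n_out * (ci - 1))
  }
  out <- rois
  out$glandular <- remap(rois$glandular)
  out$background <- remap(rois$background)
  out$detail_center <- rois$detail_center - shift
  out$background_center <- rois$background_center - shift
  list(n_out = n_out, rois = out)
}
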