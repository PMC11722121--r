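#' Segment the foveal avascular zone
#'
#' Morphologically closes the vessel mask (bridging capillary gaps), then
#' extracts the avascular connected component containing the fovea seed
#' point and traces its closed boundary contour.
#'
#' @param mask a `vessel_mask` of the averaged image (or an
#'   [enface_image], which is binarized first with default parameters).
#' @param fovea_point (x, y) px seed; default image centre.
#' @param closing_radius_px radius of the closing disc (default 5).
#' @return object of class `faz_region`: `pixels` logical matrix,
#'   `boundary` n x 2 (x, y) contour, `centroid`, `pixel_size_mm`.
#' @export
segment_faz <- function(mask, fovea_point = NULL, closing_radius_px = 5) {
  if (inherits(mask, "enface_image")) mask <- binarize_vessels(mask)
  m <- mask$pixels
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(fovea_point)) fovea_point <- c((nc + 1) / 2, (nr + 1) / 2)
  fx <- round(fovea_point[1]); fy <- round(fovea_point[2])
  if (fx < 1 || fx > nc || fy < 1 || fy > nr)
    stop("fovea_point outside the image grid")
  brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
  closed <- as.matrix(EBImage::closing(matrix(as.numeric(m), nr, nc),
                                       brush)) > 0.5
  avas <- !closed
  if (!avas[fy, fx])
    stop("no avascular region at seed: fovea point lies on a vessel after closing")
  lab <- EBImage::bwlabel(avas)
  region <- matrix(lab == lab[fy, fx], nr, nc)
  # drop any border-touching spill-through
  ct <- EBImage::ocontour(EBImage::bwlabel(region))[[1]]
  boundary <- cbind(x = ct[, 1] + 1, y = ct[, 2] + 1)  # 0-based to 1-based
  px <- which(region, arr.ind = TRUE)
  structure(list(pixels = region, boundary = boundary,
                 centroid = c(x = mean(px[, 2]), y = mean(px[, 1])),
                 pixel_size_mm = mask$pixel_size_mm),
            class = "faz_region")
}

# contour perimeter with the Vossepoel-Smeulders step weights: straight
# steps 0.980, diagonal steps 1.406, minus 0.091 per corner (direction
# change); largely removes digitization bias
contour_perimeter <- function(boundary) {
  d <- diff(rbind(boundary, boundary[1, ]))
  straight <- rowSums(abs(d)) == 1
  diag <- rowSums(abs(d)) == 2
  codes <- atan2(d[, 2], d[, 1])
  corners <- sum(abs(diff(c(codes, codes[1]))) > 1e-9)
  # + pi: offset from tracing pixel centres rather than outer pixel edges
  0.980 * sum(straight) + 1.406 * sum(diag) - 0.091 * corners + pi
}

#' Shape metrics of a FAZ region
#'
#' Computes area, perimeter, moment-based eccentricity, bounding-box axis
#' ratio, acircularity index (perimeter of the region divided by the
#' perimeter of the equal-area circle), and min/max Feret (caliper)
#' diameters.
#'
#' @param region a `faz_region`.
#' @param pixel_size_mm overrides the region's pixel size if given.
#' @return object of class `faz_metrics`: fields `area_mm2`,
#'   `perimeter_mm`, `eccentricity`, `axis_ratio`, `acircularity_index`,
#'   `min_feret_mm`, `max_feret_mm`, `corrected`.
#' @export
faz_metrics <- function(region, pixel_size_mm = NULL) {
  ps <- pixel_size_mm %||% region$pixel_size_mm
  px <- which(region$pixels, arr.ind = TRUE)
  if (nrow(px) == 0) stop("empty region")
  area <- nrow(px) * ps^2
  perim <- contour_perimeter(region$boundary) * ps
  # second central moments of the pixel set
  x <- px[, 2]; y <- px[, 1]
  mxx <- stats::var(x) * (length(x) - 1) / length(x) + 1 / 12
  myy <- stats::var(y) * (length(y) - 1) / length(y) + 1 / 12
  mxy <- stats::cov(x, y) * (length(x) - 1) / length(x)
  tr <- (mxx + myy) / 2
  dlt <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr + dlt; l2 <- max(tr - dlt, 1e-12)
  ecc <- sqrt(max(0, 1 - l2 / l1))
  bw <- diff(range(x)) + 1; bh <- diff(range(y)) + 1
  axis_ratio <- max(bw, bh) / min(bw, bh)
  acirc <- perim / (2 * sqrt(pi * area))
  # Feret diameters over the convex hull of the boundary
  b <- region$boundary
  hull <- b[grDevices::chull(b), , drop = FALSE]
  n <- nrow(hull)
  dmat <- as.matrix(stats::dist(hull))
  max_feret <- (max(dmat) + 1) * ps
  # min Feret by rotating calipers: min over hull edges of the max
  # projection width onto the edge normal
  minf <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    el <- sqrt(sum(e^2)); if (el < 1e-9) next
    nrm <- c(-e[2], e[1]) / el
    proj <- (hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2]
    minf <- min(minf, max(proj) - min(proj))
  }
  min_feret <- (minf + 1) * ps
  structure(list(area_mm2 = area, perimeter_mm = perim, eccentricity = ecc,
                 axis_ratio = axis_ratio, acircularity_index = acirc,
                 min_feret_mm = min_feret, max_feret_mm = max_feret,
                 corrected = FALSE), class = "faz_metrics")
}

#' @export
print.faz_metrics <- function(x, ...) {
  cat(sprintf(paste0("<faz_metrics%s> area %.4f mm^2, perimeter %.3f mm, ",
                     "ecc %.3f, axis ratio %.2f, acirc %.3f, ",
                     "Feret %.3f-%.3f mm\n"),
              if (x$corrected) " corrected" else "", x$area_mm2,
              x$perimeter_mm, x$eccentricity, x$axis_ratio,
              x$acircularity_index, x$min_feret_mm, x$max_feret_mm))
  invisible(x)
}

#' Littmann-Bennett ocular magnification scale factor
#'
#' The modified Bennett formula gives the retinal scaling
#' `q = 0.01306 * (AL - 1.82)` for an eye of axial length AL (mm). The
#' returned factor `s = q_eye / q_device` rescales linear measurements made
#' under the device's assumed axial length to the individual eye; areas
#' scale by `s^2`.
#'
#' @param axial_length_mm the eye's measured axial length (mm).
#' @param device_assumed_al_mm axial length assumed by the device
#'   (default 23.95 mm).
#' @param bennett_slope,bennett_offset constants of the modified Bennett
#'   formula (defaults 0.01306 per mm and 1.82 mm).
#' @return linear scale factor s.
#' @export
magnification_scale <- function(axial_length_mm, device_assumed_al_mm = 23.95,
                                bennett_slope = 0.01306,
                                bennett_offset = 1.82) {
  if (axial_length_mm <= bennett_offset)
    stop("axial length must exceed the Bennett offset")
  q_eye <- bennett_slope * (axial_length_mm - bennett_offset)
  q_dev <- bennett_slope * (device_assumed_al_mm - bennett_offset)
  q_eye / q_dev
}

#' Apply a magnification scale to FAZ metrics
#'
#' Linear fields are multiplied by `s`, the area by `s^2`; dimensionless
#' shape descriptors (eccentricity, axis ratio, acircularity) are
#' unchanged. Re-correcting an already corrected object is an error.
#'
#' @param metrics a `faz_metrics` object with `corrected = FALSE`.
#' @param s linear scale factor from [magnification_scale].
#' @return corrected `faz_metrics`.
#' @export
apply_magnification <- function(metrics, s) {
  if (isTRUE(metrics$corrected)) stop("metrics are already corrected")
  metrics$area_mm2 <- metrics$area_mm2 * s^2
  metrics$perimeter_mm <- metrics$perimeter_mm * s
  metrics$min_feret_mm <- metrics$min_feret_mm * s
  metrics$max_feret_mm <- metrics$max_feret_mm * s
  metrics$corrected <- TRUE
  metrics
}
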