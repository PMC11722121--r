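#' Perfusion density of the capillary bed
#'
#' Fraction of the image occupied by vessel pixels, with the pixels of the
#' delineated arterioles/venules removed. By default AV pixels are excluded
#' from both numerator and denominator (capillary density of the non-AV
#' area); `exclusion = "numerator"` removes them from the numerator only.
#'
#' @param mask a `vessel_mask` (binarized microvasculature).
#' @param av_mask logical matrix of arteriole/venule pixels (or a
#'   `vessel_mask`); may be NULL for none.
#' @param exclusion `"both"` (default) or `"numerator"`.
#' @return perfusion density in `[0, 1]`.
#' @export
perfusion_density <- function(mask, av_mask = NULL,
                              exclusion = c("both", "numerator")) {
  exclusion <- match.arg(exclusion)
  m <- if (inherits(mask, "vessel_mask")) mask$pixels else mask > 0
  av <- if (is.null(av_mask)) matrix(FALSE, nrow(m), ncol(m)) else
    if (inherits(av_mask, "vessel_mask")) av_mask$pixels else av_mask > 0
  if (!identical(dim(m), dim(av))) stop("mask shapes differ")
  if (all(av)) stop("AV mask covers the entire image")
  num <- sum(m & !av)
  den <- if (exclusion == "both") sum(!av) else length(m)
  num / den
}

#' Vessel density from the skeletonized vasculature
#'
#' Same ratio as [perfusion_density] but with the 1-px skeleton as the
#' numerator source, which ignores vessel width.
#'
#' @param skeleton a `skeleton_mask` (or logical matrix).
#' @param av_mask as in [perfusion_density].
#' @param exclusion as in [perfusion_density].
#' @return vessel density in `[0, 1]`.
#' @export
vessel_density <- function(skeleton, av_mask = NULL,
                           exclusion = c("both", "numerator")) {
  sk <- if (inherits(skeleton, "skeleton_mask")) skeleton$pixels else
    skeleton > 0
  perfusion_density(vessel_mask(sk), av_mask, exclusion)
}

#' Mean vessel diameter from the distance transform
#'
#' Mean over skeleton pixels of twice the Euclidean distance-transform
#' value of the vessel mask, scaled to mm.
#'
#' @param mask a `vessel_mask`.
#' @param skeleton the matching `skeleton_mask`.
#' @return mean diameter in mm.
#' @export
mean_vessel_diameter <- function(mask, skeleton) {
  sk <- skeleton$pixels
  if (!any(sk)) stop("empty skeleton")
  dt <- as.matrix(EBImage::distmap(matrix(as.numeric(mask$pixels),
                                          nrow(mask$pixels), ncol(mask$pixels))))
  # 2*dt counts one extra half-pixel on each side of the ribbon
  mean(pmax(2 * dt[sk] - 1, 1)) * mask$pixel_size_mm
}

#' Box-counting fractal dimension of a skeleton
#'
#' Least-squares slope of log(count) against log(1/size) over dyadic box
#' sizes.
#'
#' @param skeleton a `skeleton_mask` (or logical matrix).
#' @param box_sizes box edge lengths in px.
#' @return estimated fractal dimension.
#' @export
fractal_dimension <- function(skeleton, box_sizes = c(2, 4, 8, 16, 32, 64)) {
  sk <- if (inherits(skeleton, "skeleton_mask")) skeleton$pixels else
    skeleton > 0
  if (!any(sk)) stop("empty skeleton")
  nr <- nrow(sk); nc <- ncol(sk)
  box_sizes <- box_sizes[box_sizes <= min(nr, nc) / 2]
  if (length(box_sizes) < 3) stop("need at least 3 usable box scales")
  px <- which(sk, arr.ind = TRUE)
  counts <- vapply(box_sizes, function(s) {
    length(unique((px[, 1] - 1) %/% s * 1e6 + (px[, 2] - 1) %/% s))
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(1 / box_sizes)))[[2]]
}

#' Tortuosity method 1: arc/chord ratio
#'
#' Centerline path length divided by the Euclidean distance between its
#' endpoints; 1 for a straight segment. Closed loops (coincident
#' endpoints) are rejected and excluded from aggregation.
#'
#' @param polyline n x 2 matrix of (x, y) coordinates, n >= 2.
#' @return tortuosity >= 1.
#' @export
tortuosity_m1 <- function(polyline) {
  if (nrow(polyline) < 2) stop("polyline needs at least 2 points")
  chord <- sqrt(sum((polyline[nrow(polyline), ] - polyline[1, ])^2))
  if (chord < 1e-9) stop("coincident endpoints (closed loop)")
  arc <- sum(sqrt(rowSums(diff(polyline)^2)))
  arc / chord
}

#' Tortuosity method 2: composite local/global centerline index
#'
#' Vessel tortuosity index in the style of Khansari et al. (2017):
#' \deqn{VTI = 0.1 \cdot SD_\theta \cdot N \cdot \bar M \cdot (L_A / L_C) / L_A}
#' where \eqn{SD_\theta} is the SD of the tangent-angle sequence (degrees),
#' N the number of critical (inflection) points of the curvature sign,
#' \eqn{\bar M} the mean centerline amplitude between critical points,
#' \eqn{L_A} the arc length and \eqn{L_C} the chord length. Zero for
#' straight lines; grows with oscillation amplitude and frequency.
#'
#' @param polyline n x 2 matrix of (x, y) coordinates, n >= 5.
#' @param smooth_sd optional Gaussian smoothing (in samples) applied to the
#'   coordinates before differentiation; 0 disables.
#' @return non-negative tortuosity index.
#' @export
tortuosity_m2 <- function(polyline, smooth_sd = 1) {
  if (nrow(polyline) < 5) stop("polyline needs at least 5 points")
  p <- polyline
  if (smooth_sd > 0 && nrow(p) >= 7) {
    k <- ceiling(3 * smooth_sd)
    w <- stats::dnorm(-k:k, sd = smooth_sd); w <- w / sum(w)
    pad <- function(v) c(rep(v[1], k), v, rep(v[length(v)], k))
    p <- cbind(stats::filter(pad(p[, 1]), w, sides = 2)[(k + 1):(k + nrow(p))],
               stats::filter(pad(p[, 2]), w, sides = 2)[(k + 1):(k + nrow(p))])
  }
  d <- diff(p)
  keep <- rowSums(d^2) > 1e-12
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 2) stop("degenerate polyline")
  theta <- atan2(d[, 2], d[, 1])
  # unwrap angle sequence
  dth <- diff(theta)
  dth <- ((dth + pi) %% (2 * pi)) - pi
  theta <- cumsum(c(theta[1], dth))
  sd_theta <- stats::sd(theta) * 180 / pi
  la <- sum(sqrt(rowSums(d^2)))
  chord <- p[nrow(p), ] - p[1, ]
  lc <- sqrt(sum(chord^2))
  if (lc < 1e-9) stop("coincident endpoints")
  # signed deviation from the chord; critical points = sign changes of the
  # turning (curvature) sequence
  turn <- dth
  sgn <- sign(turn)
  sgn <- sgn[sgn != 0]
  n_crit <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0L
  if (n_crit == 0L) return(0)
  # amplitude: max |normal deviation from chord| within spans between
  # critical points (approximated on the deviation profile)
  u <- chord / lc
  nvec <- c(-u[2], u[1])
  dev <- (p[, 1] - p[1, 1]) * nvec[1] + (p[, 2] - p[1, 2]) * nvec[2]
  crit_idx <- which(diff(sign(turn)[sign(turn) != 0]) != 0)
  bounds <- unique(c(1, crit_idx + 1, length(dev)))
  amps <- vapply(seq_len(length(bounds) - 1), function(i) {
    seg <- dev[bounds[i]:bounds[i + 1]]
    max(abs(seg - mean(seg)))
  }, numeric(1))
  m_bar <- mean(amps)
  0.1 * sd_theta * n_crit * m_bar * (la / lc) / la
}

#' Mean tortuosity per vessel class
#'
#' Unweighted mean of the requested tortuosity measure over the edges of
#' each vessel class, restricted to edges passing a minimum length filter.
#' Closed-loop edges are excluded. Classes with no qualifying edge are
#' reported as `NA`.
#'
#' @param graph a classified `vessel_graph`.
#' @param method `"m1"` or `"m2"`.
#' @param min_len_px minimum edge length included (default 10 px).
#' @return named numeric vector of class means (`AV`, `capillary`).
#' @export
aggregate_tortuosity <- function(graph, method = c("m1", "m2"),
                                 min_len_px = 10) {
  method <- match.arg(method)
  fn <- if (method == "m1") tortuosity_m1 else tortuosity_m2
  classes <- c("AV", "capillary")
  out <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    sel <- which(graph$edges$vessel_class == cl &
                   graph$edges$length_px >= min_len_px)
    vals <- c()
    for (e in sel) {
      v <- tryCatch(fn(graph$polylines[[e]]), error = function(err) NA_real_)
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (length(vals)) out[cl] <- mean(vals)
  }
  out
}

#' All quantitative vascular metrics for one eye
#'
#' Convenience wrapper computing perfusion density, vessel density, mean
#' diameter, fractal dimension and per-class tortuosity from a mask,
#' skeleton and classified graph.
#'
#' @param mask `vessel_mask`; @param skeleton `skeleton_mask`;
#' @param graph classified `vessel_graph`; @param av_mask logical AV pixel
#'   mask (default: stamped from the graph's AV edges).
#' @param exclusion PD/VD exclusion convention (see [perfusion_density]).
#' @return named list of metrics.
#' @export
vascular_metrics <- function(mask, skeleton, graph, av_mask = NULL,
                             exclusion = "both") {
  if (is.null(av_mask)) av_mask <- av_mask_from_graph(graph)
  list(
    perfusion_density = perfusion_density(mask, av_mask, exclusion),
    vessel_density = vessel_density(skeleton, av_mask, exclusion),
    mean_diameter_mm = mean_vessel_diameter(mask, skeleton),
    fractal_dimension = fractal_dimension(skeleton),
    tortuosity_m1 = aggregate_tortuosity(graph, "m1"),
    tortuosity_m2 = aggregate_tortuosity(graph, "m2"))
}
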