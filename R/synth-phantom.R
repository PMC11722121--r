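#' Specification of a synthetic en face vascular phantom
#'
#' Describes a 3 x 3 mm style en face angiogram phantom: a set of branching
#' arteriole/venule trees, a space-filling capillary mesh, and an avascular
#' elliptical FAZ at the fovea. Tortuosity is injected as a sinusoidal
#' displacement normal to each segment so the generating arc/chord ratio is
#' known for every centerline.
#'
#' @param grid_size integer vector (rows, cols); default 304 x 304.
#' @param field_mm physical field width in mm (default 3.0).
#' @param n_trees number of arteriole/venule trees entering from the border.
#' @param branch_depth bifurcation levels per tree; the root attains
#'   Horton-Strahler order up to `branch_depth`.
#' @param capillary_density_target approximate fraction of pixels covered by
#'   vessels (trees + mesh).
#' @param faz_axes_mm semi-axes (a, b) of the FAZ ellipse in mm.
#' @param faz_center_px ellipse centre (x, y) in px; default image centre.
#' @param tortuosity_amp sine-perturbation amplitude as a fraction of segment
#'   chord length. Either a scalar or a named vector
#'   `c(av = ..., capillary = ...)` for class-specific amplitudes.
#' @param seed integer seed driving all randomness of the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(304L, 304L), field_mm = 3.0,
                         n_trees = 4L, branch_depth = 4L,
                         capillary_density_target = 0.42,
                         faz_axes_mm = c(0.33, 0.27), faz_center_px = NULL,
                         tortuosity_amp = c(av = 0.10, capillary = 0.20),
                         seed = 1L) {
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 2L)
  grid_size <- as.integer(grid_size)
  if (field_mm <= 0) stop("field_mm must be > 0")
  if (any(tortuosity_amp < 0)) stop("tortuosity_amp must be >= 0")
  if (length(faz_axes_mm) != 2L || any(faz_axes_mm <= 0))
    stop("faz_axes_mm must be two positive semi-axes")
  pixel_size <- field_mm / grid_size[2]
  if (is.null(faz_center_px)) faz_center_px <- (grid_size[c(2, 1)] + 1) / 2
  ax_px <- faz_axes_mm / pixel_size
  if (faz_center_px[1] - ax_px[1] < 1 || faz_center_px[1] + ax_px[1] > grid_size[2] ||
      faz_center_px[2] - ax_px[2] < 1 || faz_center_px[2] + ax_px[2] > grid_size[1])
    stop("FAZ ellipse exceeds the image grid")
  amp <- tortuosity_amp
  if (length(amp) == 1L) amp <- c(av = unname(amp), capillary = unname(amp))
  if (!all(c("av", "capillary") %in% names(amp)))
    stop("tortuosity_amp must be scalar or named c(av=, capillary=)")
  structure(list(grid_size = grid_size, field_mm = field_mm,
                 pixel_size_mm = pixel_size, n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 capillary_density_target = capillary_density_target,
                 faz_axes_mm = faz_axes_mm, faz_axes_px = ax_px,
                 faz_center_px = faz_center_px, tortuosity_amp = amp,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Sample a sine-perturbed segment between p0 and p1 (x, y in px).
# amp is relative to chord length; nwaves = number of half-waves.
# Returns list(points, tortuosity) with the generating arc/chord ratio
# computed by dense quadrature.
sine_segment <- function(p0, p1, amp, nwaves) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("degenerate segment")
  u <- d / len
  nrm <- c(-u[2], u[1])
  a <- amp * len
  mk <- function(m) {
    t <- seq(0, 1, length.out = m)
    s <- a * sin(pi * nwaves * t)
    cbind(p0[1] + t * len * u[1] + s * nrm[1],
          p0[2] + t * len * u[2] + s * nrm[2])
  }
  # sample densely enough that the discrete arc length tracks the smooth
  # curve even for short, high-frequency segments
  pts <- mk(max(16L, ceiling(8 * len), 30L * nwaves))
  dense <- mk(2001L)
  arc <- sum(sqrt(rowSums(diff(dense)^2)))
  list(points = pts, dense = dense, tortuosity = arc / len)
}

# generating arc/chord ratio of the leading fraction of a segment (used
# when a polyline is truncated at the FAZ or border)
partial_tortuosity <- function(seg, n_kept, n_total) {
  t_max <- (n_kept - 1) / (n_total - 1)
  k <- max(2L, floor(t_max * (nrow(seg$dense) - 1)) + 1L)
  dd <- seg$dense[seq_len(k), , drop = FALSE]
  arc <- sum(sqrt(rowSums(diff(dd)^2)))
  chord <- sqrt(sum((dd[k, ] - dd[1, ])^2))
  arc / chord
}

# TRUE where (x, y) lies inside the FAZ ellipse grown by `margin` px.
in_faz <- function(x, y, spec, margin = 0) {
  a <- spec$faz_axes_px[1] + margin
  b <- spec$faz_axes_px[2] + margin
  ((x - spec$faz_center_px[1]) / a)^2 + ((y - spec$faz_center_px[2]) / b)^2 < 1
}

# Truncate a polyline where it first enters the forbidden FAZ zone or leaves
# the in-grid margin. Returns NULL if fewer than 4 points survive.
clip_polyline <- function(pts, spec, margin) {
  nr <- spec$grid_size[1]; nc <- spec$grid_size[2]
  bad <- in_faz(pts[, 1], pts[, 2], spec, margin) |
    pts[, 1] < 2 | pts[, 1] > nc - 1 | pts[, 2] < 2 | pts[, 2] > nr - 1
  if (!any(bad)) return(list(points = pts, clipped = FALSE))
  k <- which(bad)[1] - 1L
  if (k < 4L) return(NULL)
  list(points = pts[seq_len(k), , drop = FALSE], clipped = TRUE)
}

# Recursive bifurcating tree. Returns a data-structure of edges with parent
# pointers; Strahler orders are assigned by the generator's merge
# bookkeeping (two children of order k meet in an order k+1 parent).
grow_tree <- function(spec, root_pt, root_dir, tree_id) {
  edges <- list()
  amp <- spec$tortuosity_amp[["av"]]
  base_len <- 0.17 * min(spec$grid_size)
  recurse <- function(p0, dir, depth, parent_id) {
    len <- base_len * 0.72^(spec$branch_depth - depth)
    p1 <- p0 + len * c(cos(dir), sin(dir))
    seg <- sine_segment(p0, p1, amp, sample(1:3, 1))
    margin <- 3
    cl <- clip_polyline(seg$points, spec, margin)
    if (is.null(cl)) return(invisible(NULL))
    id <- length(edges) + 1L
    tort <- if (cl$clipped)
      partial_tortuosity(seg, nrow(cl$points), nrow(seg$points)) else
        seg$tortuosity
    edges[[id]] <<- list(id = id, parent = parent_id, tree = tree_id,
                         points = cl$points, tortuosity = tort,
                         children = integer(0))
    if (!is.na(parent_id))
      edges[[parent_id]]$children <<- c(edges[[parent_id]]$children, id)
    tip <- cl$points[nrow(cl$points), ]
    terminate <- cl$clipped || depth <= 1L || stats::runif(1) < 0.08
    if (!terminate) {
      spread <- (26 + stats::runif(2, 0, 20)) * pi / 180
      recurse(tip, dir - spread[1], depth - 1L, id)
      recurse(tip, dir + spread[2], depth - 1L, id)
    }
    invisible(NULL)
  }
  recurse(root_pt, root_dir, spec$branch_depth, NA_integer_)
  edges
}

# Generator-side Strahler bookkeeping on the recorded topology.
tree_strahler <- function(edges) {
  ord <- rep(NA_integer_, length(edges))
  assign_ord <- function(i) {
    ch <- edges[[i]]$children
    if (length(ch) == 0L) { ord[i] <<- 1L; return(1L) }
    ks <- vapply(ch, assign_ord, integer(1))
    k <- max(ks)
    ord[i] <<- if (sum(ks == k) >= 2L) k + 1L else k
    ord[i]
  }
  roots <- which(vapply(edges, function(e) is.na(e$parent), logical(1)))
  for (r in roots) assign_ord(r)
  ord
}

#' Rasterize centerline polylines with widths into a vessel mask
#'
#' Stamps each polyline as a tube of the given width (disc of radius
#' `width / 2` around every densified centerline point).
#'
#' @param centerlines list of n x 2 matrices of (x, y) px coordinates.
#' @param widths vessel widths (px), one per polyline.
#' @param dims image dims (rows, cols).
#' @return logical matrix vessel mask.
#' @export
rasterize_centerlines <- function(centerlines, widths, dims) {
  mask <- matrix(FALSE, dims[1], dims[2])
  disc_cache <- list()
  for (i in seq_along(centerlines)) {
    pts <- centerlines[[i]]
    # densify so consecutive samples are <= ~0.35 px apart
    steps <- sqrt(rowSums(diff(pts)^2))
    if (any(steps > 0.35)) {
      cum <- c(0, cumsum(steps))
      tt <- seq(0, cum[length(cum)], by = 0.3)
      pts <- cbind(stats::approx(cum, pts[, 1], xout = tt)$y,
                   stats::approx(cum, pts[, 2], xout = tt)$y)
    }
    rad <- widths[i] / 2 + 0.25
    key <- sprintf("%.3f", rad)
    if (is.null(disc_cache[[key]])) {
      r <- ceiling(rad)
      disc_cache[[key]] <- as.matrix(expand.grid(dx = -r:r, dy = -r:r))
    }
    off <- disc_cache[[key]]
    m <- nrow(off)
    px <- rep(pts[, 1], each = m); py <- rep(pts[, 2], each = m)
    cx <- round(px) + off[, 1]; cy <- round(py) + off[, 2]
    # a pixel is vessel iff its centre lies within rad of a centerline point
    ok <- (cx - px)^2 + (cy - py)^2 <= rad^2 &
      cx >= 1 & cx <= dims[2] & cy >= 1 & cy <= dims[1]
    mask[cbind(cy[ok], cx[ok])] <- TRUE
  }
  mask
}

#' Generate a vascular phantom with full ground truth
#'
#' Builds a noise-free reference en face image containing `n_trees`
#' recursively bifurcating arteriole/venule trees, a relaxed-lattice
#' capillary mesh connected to the tree tips, and an avascular FAZ ellipse.
#' Every centerline's width, Strahler order, vessel class and generating
#' arc/chord tortuosity are recorded, together with the FAZ generating
#' values.
#'
#' @param spec a [phantom_spec].
#' @return list with components `image` (an [enface_image]) and `truth`
#'   (class `phantom_truth`: centerlines, widths, class, strahler order,
#'   per-polyline generating tortuosity, vessel mask, FAZ generating
#'   metrics, and the raw tree topology).
#' @export
generate_vessel_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_size[1]; nc <- spec$grid_size[2]
  ctr <- c((nc + 1) / 2, (nr + 1) / 2)

  ## arteriole/venule trees entering from the border
  all_edges <- list(); tree_topologies <- list()
  for (k in seq_len(spec$n_trees)) {
    phi <- 2 * pi * (k - 1) / spec$n_trees + stats::runif(1, -0.25, 0.25)
    entry <- ctr + 0.47 * min(nr, nc) * c(cos(phi), sin(phi))
    entry <- pmin(pmax(entry, 3), c(nc - 2, nr - 2))
    aim <- atan2(ctr[2] - entry[2], ctr[1] - entry[1]) +
      stats::runif(1, -0.3, 0.3)
    ed <- grow_tree(spec, entry, aim, k)
    if (length(ed) == 0L) next
    ords <- tree_strahler(ed)
    for (j in seq_along(ed)) ed[[j]]$order <- ords[j]
    tree_topologies[[length(tree_topologies) + 1L]] <- ed
    all_edges <- c(all_edges, ed)
  }

  centerlines <- lapply(all_edges, `[[`, "points")
  orders <- vapply(all_edges, `[[`, integer(1), "order")
  torts <- vapply(all_edges, `[[`, numeric(1), "tortuosity")
  widths <- 1.0 + 0.9 * orders
  classes <- ifelse(orders >= 2 & orders <= 4, "AV", "capillary")
  tree_ids <- vapply(all_edges, `[[`, integer(1), "tree")

  ## capillary mesh: jittered lattice, edges to right/down neighbours
  sp <- 9
  gx <- seq(5, nc - 4, by = sp); gy <- seq(5, nr - 4, by = sp)
  nodes <- expand.grid(x = gx, y = gy)
  nodes$x <- nodes$x + stats::rnorm(nrow(nodes), 0, 1.4)
  nodes$y <- nodes$y + stats::rnorm(nrow(nodes), 0, 1.4)
  nodes$x <- pmin(pmax(nodes$x, 3), nc - 2)
  nodes$y <- pmin(pmax(nodes$y, 3), nr - 2)
  ix <- function(i, j) (j - 1L) * length(gx) + i   # i over gx, j over gy
  mesh_pairs <- list()
  for (j in seq_along(gy)) for (i in seq_along(gx)) {
    if (i < length(gx)) mesh_pairs[[length(mesh_pairs) + 1L]] <- c(ix(i, j), ix(i + 1L, j))
    if (j < length(gy)) mesh_pairs[[length(mesh_pairs) + 1L]] <- c(ix(i, j), ix(i, j + 1L))
  }
  cap_w <- 1.5
  # thin the mesh toward the density target, accounting for tree coverage;
  # +0.8 px approximates the widening of the discrete disc stamp
  tree_px <- sum(vapply(seq_along(centerlines), function(i) {
    sum(sqrt(rowSums(diff(centerlines[[i]])^2))) * (widths[i] + 0.2)
  }, numeric(1)))
  arc_factor <- 1 + (spec$tortuosity_amp[["capillary"]] * 1.5 * pi)^2 / 4
  mesh_px <- length(mesh_pairs) * sp * (cap_w + 0.2) * arc_factor
  want <- spec$capillary_density_target * nr * nc - tree_px
  p_keep <- if (want <= 0) 0 else min(1, max(0.05, want / mesh_px))
  keep <- stats::runif(length(mesh_pairs)) < p_keep
  amp_cap <- spec$tortuosity_amp[["capillary"]]
  cap_margin <- cap_w / 2 + 1.2
  add_cap <- function(p0, p1) {
    if (sqrt(sum((p1 - p0)^2)) < 3) return(NULL)
    seg <- sine_segment(p0, p1, amp_cap, sample(1:2, 1))
    if (any(in_faz(seg$points[, 1], seg$points[, 2], spec, cap_margin)))
      return(NULL)
    seg
  }
  for (m in mesh_pairs[keep]) {
    p0 <- c(nodes$x[m[1]], nodes$y[m[1]]); p1 <- c(nodes$x[m[2]], nodes$y[m[2]])
    seg <- add_cap(p0, p1)
    if (is.null(seg)) next
    centerlines[[length(centerlines) + 1L]] <- seg$points
    orders <- c(orders, 1L); torts <- c(torts, seg$tortuosity)
    widths <- c(widths, cap_w); classes <- c(classes, "capillary")
    tree_ids <- c(tree_ids, NA_integer_)
  }
  ## connect tree tips into the mesh
  tips <- if (p_keep > 0)
    which(vapply(all_edges, function(e) length(e$children) == 0L, logical(1)))
  else integer(0)
  for (t in tips) {
    tip <- all_edges[[t]]$points[nrow(all_edges[[t]]$points), ]
    d2 <- (nodes$x - tip[1])^2 + (nodes$y - tip[2])^2
    nn <- which.min(d2)
    if (d2[nn] > (2.5 * sp)^2) next
    seg <- add_cap(tip, c(nodes$x[nn], nodes$y[nn]))
    if (is.null(seg)) next
    centerlines[[length(centerlines) + 1L]] <- seg$points
    orders <- c(orders, 1L); torts <- c(torts, seg$tortuosity)
    widths <- c(widths, cap_w); classes <- c(classes, "capillary")
    tree_ids <- c(tree_ids, NA_integer_)
  }

  ## terminal capillary ring hugging the FAZ boundary: keeps the avascular
  ## region a clean ellipse matching the generating values
  ring_off <- 1.0
  tt <- seq(0, 2 * pi, length.out = 720)
  ring <- cbind(spec$faz_center_px[1] + (spec$faz_axes_px[1] + ring_off) * cos(tt),
                spec$faz_center_px[2] + (spec$faz_axes_px[2] + ring_off) * sin(tt))
  centerlines[[length(centerlines) + 1L]] <- ring
  orders <- c(orders, 1L); torts <- c(torts, NA_real_)
  widths <- c(widths, cap_w); classes <- c(classes, "capillary")
  tree_ids <- c(tree_ids, NA_integer_)

  mask <- rasterize_centerlines(centerlines, widths, c(nr, nc))
  img <- 0.12 + 0.78 * as.matrix(EBImage::gblur(mask * 1.0, sigma = 0.7))
  image <- enface_image(img, spec$pixel_size_mm,
                        device_meta = list(ssi = 99, quality = 10),
                        provenance = "raw")

  a_mm <- spec$faz_axes_mm[1]; b_mm <- spec$faz_axes_mm[2]
  amax <- max(a_mm, b_mm); bmin <- min(a_mm, b_mm)
  h <- ((amax - bmin) / (amax + bmin))^2
  perim <- pi * (amax + bmin) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  truth <- structure(list(
    centerlines = centerlines, widths = widths, strahler_order = orders,
    vessel_class = classes, tortuosity_m1 = torts, tree_id = tree_ids,
    mask = mask, tree_topologies = tree_topologies,
    faz_area_mm2 = pi * a_mm * b_mm,
    faz_eccentricity = sqrt(1 - (bmin / amax)^2),
    faz_perimeter_mm = perim,
    faz_center_px = spec$faz_center_px, faz_axes_px = spec$faz_axes_px,
    frame_transforms = NULL, spec = spec), class = "phantom_truth")
  list(image = image, truth = truth)
}

#' Generate a stack of noisy, motion-corrupted frames from a reference
#'
#' Each frame is the reference translated by a draw from
#' `Normal(0, motion_sd)` in x and y (plus an optional small rotation),
#' multiplied by speckle noise and perturbed by additive Gaussian noise.
#' The true per-frame transforms are recorded.
#'
#' @param reference an [enface_image] (noise-free phantom reference).
#' @param n_frames number of frames (>= 1).
#' @param motion_sd SD of the per-frame translation in px.
#' @param noise_sd relative intensity noise level; `noise_sd` scales the
#'   multiplicative speckle and `0.5 * noise_sd` the additive component.
#' @param rotation_sd_deg SD of an optional per-frame rotation (degrees).
#' @param seed integer seed.
#' @return A [frame_stack] with attribute `true_transforms`: a data frame of
#'   per-frame `tx`, `ty` (px) and `rot_deg`.
#' @export
generate_frame_stack <- function(reference, n_frames, motion_sd = 1.5,
                                 noise_sd = 0.15, rotation_sd_deg = 0,
                                 seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  set.seed(seed)
  px <- reference$pixels
  nr <- nrow(px); nc <- ncol(px)
  id <- identity_map(nr, nc)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  frames <- vector("list", n_frames)
  tr <- data.frame(tx = stats::rnorm(n_frames, 0, motion_sd),
                   ty = stats::rnorm(n_frames, 0, motion_sd),
                   rot_deg = stats::rnorm(n_frames, 0, rotation_sd_deg))
  if (motion_sd == 0) tr$tx <- tr$ty <- rep(0, n_frames)
  if (rotation_sd_deg == 0) tr$rot_deg <- rep(0, n_frames)
  for (i in seq_len(n_frames)) {
    th <- tr$rot_deg[i] * pi / 180
    # map output coords back into the reference: inverse of rotate-then-shift
    rr <- id$r - ctr[1] - tr$ty[i]
    cc <- id$c - ctr[2] - tr$tx[i]
    map_r <- cos(th) * rr + sin(th) * cc + ctr[1]
    map_c <- -sin(th) * rr + cos(th) * cc + ctr[2]
    f <- warp_by_map(px, map_r, map_c, fill = mean(px))
    if (noise_sd > 0) {
      f <- f * (1 + noise_sd * matrix(stats::rnorm(nr * nc), nr, nc)) +
        0.5 * noise_sd * mean(px) * matrix(stats::rnorm(nr * nc), nr, nc)
      f <- pmax(f, 0)
    }
    frames[[i]] <- enface_image(f, reference$pixel_size_mm,
                                device_meta = reference$device_meta,
                                provenance = "raw")
  }
  st <- frame_stack(frames, 1L)
  attr(st, "true_transforms") <- tr
  st
}
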