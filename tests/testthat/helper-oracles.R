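# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Recursive Horton-Strahler order on an adjacency topology: edges is a data
# frame (from, to); returns the order of every edge, rooted at `root`.
oracle_strahler <- function(edges, root) {
  nb <- function(v) which(edges$from == v | edges$to == v)
  other <- function(e, v) if (edges$from[e] == v) edges$to[e] else edges$from[e]
  ord <- rep(NA_integer_, nrow(edges))
  # order of the edge entering v from parent edge pe
  rec <- function(v, pe) {
    ch <- setdiff(nb(v), pe)
    if (length(ch) == 0L) return(1L)
    ks <- vapply(ch, function(e) {
      k <- rec(other(e, v), e)
      ord[e] <<- k
      k
    }, integer(1))
    m <- max(ks)
    if (sum(ks == m) >= 2L) m + 1L else m
  }
  for (e in nb(root)) ord[e] <- rec(other(e, root), e)
  ord
}

# Random labelled tree on n nodes (random attachment), as an edge list.
random_tree_edges <- function(n_edges, seed) {
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  for (v in 2:(n_edges + 1)) {
    from <- c(from, sample.int(v - 1L, 1L))
    to <- c(to, v)
  }
  data.frame(from = from, to = to)
}

# Wrap an abstract tree topology as a vessel_graph with unit widths and
# straight 2-point polylines, so strahler_order() can run on it.
tree_as_vessel_graph <- function(edges, n_nodes) {
  set.seed(99)
  coords <- cbind(x = runif(n_nodes, 10, 90), y = runif(n_nodes, 10, 90))
  polylines <- lapply(seq_len(nrow(edges)), function(i)
    rbind(coords[edges$from[i], ], coords[edges$to[i], ]))
  structure(list(
    nodes = data.frame(id = seq_len(n_nodes), x = coords[, 1],
                       y = coords[, 2], kind = "junction"),
    edges = data.frame(id = seq_len(nrow(edges)), from = edges$from,
                       to = edges$to,
                       length_px = rep(10, nrow(edges)),
                       mean_width_px = rep(2, nrow(edges)),
                       strahler_order = NA_integer_,
                       vessel_class = NA_character_, chord = FALSE),
    polylines = polylines, dims = c(100L, 100L), pixel_size_mm = 0.01),
    class = "vessel_graph")
}

# Brute-force per-pixel polyline stamping: a pixel is vessel iff its centre
# lies within width/2 + 0.25 of any densified centerline point.
oracle_rasterize <- function(centerlines, widths, dims) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_along(centerlines)) {
    pts <- centerlines[[i]]
    steps <- sqrt(rowSums(diff(pts)^2))
    if (any(steps > 0.35)) {
      cum <- c(0, cumsum(steps))
      tt <- seq(0, cum[length(cum)], by = 0.3)
      pts <- cbind(approx(cum, pts[, 1], xout = tt)$y,
                   approx(cum, pts[, 2], xout = tt)$y)
    }
    rad <- widths[i] / 2 + 0.25
    r <- ceiling(rad)
    for (k in seq_len(nrow(pts))) {
      cx <- round(pts[k, 1]); cy <- round(pts[k, 2])
      for (dy in -r:r) for (dx in -r:r) {
        yy <- cy + dy; xx <- cx + dx
        if (yy >= 1 && yy <= dims[1] && xx >= 1 && xx <= dims[2] &&
            (round(pts[k, 1]) + dx - pts[k, 1])^2 +
            (round(pts[k, 2]) + dy - pts[k, 2])^2 <= rad^2)
          mask[yy, xx] <- TRUE
      }
    }
  }
  mask
}

# O(n^2) concordance-count AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Build a faz_region directly from a logical matrix (test fixture helper).
region_from_matrix <- function(m, ps = 1) {
  lab <- EBImage::bwlabel(m)
  ct <- EBImage::ocontour(lab)[[1]]
  px <- which(m, arr.ind = TRUE)
  structure(list(pixels = m, boundary = cbind(x = ct[, 1] + 1, y = ct[, 2] + 1),
                 centroid = c(x = mean(px[, 2]), y = mean(px[, 1])),
                 pixel_size_mm = ps), class = "faz_region")
}

# Small phantom spec used throughout the suite.
small_phantom_spec <- function(seed, ...)
  phantom_spec(seed = seed, grid_size = c(160L, 160L), field_mm = 1.6,
               n_trees = 3L, ...)
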