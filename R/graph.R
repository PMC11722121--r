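#' Segment the microvasculature of an averaged en face image
#'
#' Deterministic classical segmenter: multiscale Hessian ridge (vesselness)
#' enhancement, hysteresis thresholding, and small-object removal.
#'
#' @param image an [enface_image] (averaged).
#' @param scales Gaussian scales (px) for the ridge filter.
#' @param beta blobness sensitivity of the vesselness response.
#' @param low_frac low hysteresis threshold as a fraction of the high
#'   (Otsu) threshold.
#' @param min_size_px minimum connected-component size kept.
#' @return list with `pixels` (logical matrix mask) and `pixel_size_mm`;
#'   class `vessel_mask`.
#' @export
binarize_vessels <- function(image, scales = c(0.7, 1.1, 1.8), beta = 1.5,
                             low_frac = 0.25, min_size_px = 10L) {
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  V <- matrix(0, nr, nc)
  for (sg in scales) {
    sm <- as.matrix(EBImage::gblur(px, sigma = sg))
    sh <- function(m, dr, dc) {
      out <- matrix(0, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs] <- m[rs - dr, cs - dc]
      out
    }
    Ixx <- sh(sm, 0, 1) - 2 * sm + sh(sm, 0, -1)
    Iyy <- sh(sm, 1, 0) - 2 * sm + sh(sm, -1, 0)
    Ixy <- (sh(sm, 1, 1) + sh(sm, -1, -1) - sh(sm, 1, -1) - sh(sm, -1, 1)) / 4
    s2 <- sg^2
    Ixx <- Ixx * s2; Iyy <- Iyy * s2; Ixy <- Ixy * s2
    tmp <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
    m1 <- (Ixx + Iyy) / 2 + tmp
    m2 <- (Ixx + Iyy) / 2 - tmp
    # order |l1| <= |l2|
    swap <- abs(m1) > abs(m2)
    l1 <- ifelse(swap, m2, m1); l2 <- ifelse(swap, m1, m2)
    S2 <- l1^2 + l2^2
    # robust structure scale: an outlier pixel must not squash the response
    c2 <- stats::quantile(S2[S2 > 0], 0.99) / 4
    if (!is.finite(c2) || c2 <= 0) c2 <- max(S2) / 4
    v <- exp(-(l1 / pmin(l2, -1e-12))^2 / (2 * beta^2)) *
      (1 - exp(-S2 / (2 * c2)))
    v[l2 >= 0] <- 0
    V <- pmax(V, v)
  }
  if (max(V) <= 0) stop("no vessel response in image")
  vhi <- stats::quantile(V[V > 0], 0.999)
  V <- pmin(V / vhi, 1)
  hi <- EBImage::otsu(EBImage::Image(V))
  lo <- low_frac * hi
  lo_mask <- V >= lo
  lab <- EBImage::bwlabel(lo_mask)
  keep <- unique(lab[V >= hi & lo_mask])
  keep <- keep[keep > 0]
  mask <- matrix(lab %in% keep, nr, nc)
  # small object removal
  lab2 <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab2[lab2 > 0])
  small <- which(sizes < min_size_px)
  if (length(small)) mask[lab2 %in% small] <- FALSE
  if (!any(mask)) stop("segmentation produced an empty vessel mask")
  structure(list(pixels = mask, pixel_size_mm = image$pixel_size_mm),
            class = "vessel_mask")
}

#' Construct a vessel mask from a logical matrix
#' @param pixels logical matrix.
#' @param pixel_size_mm physical pixel size (mm).
#' @return a `vessel_mask`.
#' @export
vessel_mask <- function(pixels, pixel_size_mm = 1) {
  structure(list(pixels = pixels > 0, pixel_size_mm = pixel_size_mm),
            class = "vessel_mask")
}

# 3x3 neighbour extraction with zero padding, in Zhang-Suen ordering
# P2..P9 = N, NE, E, SE, S, SW, W, NW (row 1 = top).
zs_neighbours <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  list(p2 = sh(1, 0), p3 = sh(1, -1), p4 = sh(0, -1), p5 = sh(-1, -1),
       p6 = sh(-1, 0), p7 = sh(-1, 1), p8 = sh(0, 1), p9 = sh(1, 1))
}

#' Thin a vessel mask to single-pixel centerlines
#'
#' Topology-preserving Zhang-Suen thinning.
#'
#' @param mask a `vessel_mask`.
#' @return list with `pixels` (logical skeleton) and `pixel_size_mm`;
#'   class `skeleton_mask`.
#' @export
skeletonize_mask <- function(mask) {
  m <- matrix(as.integer(mask$pixels), nrow(mask$pixels), ncol(mask$pixels))
  if (!any(m > 0)) stop("empty mask cannot be skeletonized")
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- zs_neighbours(m)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (step == 1) {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1L &
          (nb$p2 * nb$p4 * nb$p6) == 0L & (nb$p4 * nb$p6 * nb$p8) == 0L
      } else {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1L &
          (nb$p2 * nb$p4 * nb$p8) == 0L & (nb$p2 * nb$p6 * nb$p8) == 0L
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  structure(list(pixels = m == 1L, pixel_size_mm = mask$pixel_size_mm),
            class = "skeleton_mask")
}

# 8-neighbour offsets
NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# connected components of a set of pixels (n x 2 matrix row, col) under
# 8-connectivity; returns integer component labels
pixel_components <- function(px, nr, nc) {
  if (nrow(px) == 0L) return(integer(0))
  key <- (px[, 2] - 1L) * nr + px[, 1]
  idx <- seq_len(nrow(px))
  lookup <- new.env(hash = TRUE, size = nrow(px))
  for (i in idx) assign(as.character(key[i]), i, envir = lookup)
  edges <- list()
  for (k in seq_len(nrow(NB8))) {
    nk <- (px[, 2] + NB8[k, 2] - 1L) * nr + px[, 1] + NB8[k, 1]
    ok <- px[, 1] + NB8[k, 1] >= 1 & px[, 1] + NB8[k, 1] <= nr &
      px[, 2] + NB8[k, 2] >= 1 & px[, 2] + NB8[k, 2] <= nc
    for (i in idx[ok]) {
      j <- mget(as.character(nk[i]), envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > i) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(px) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nrow(px))]
}

#' Build a vessel graph from a skeleton and its source mask
#'
#' Junction pixels (three or more skeleton neighbours) are clustered into
#' junction nodes; free ends become endpoint nodes; maximal junction-free
#' centerline runs become edges. Mean edge width is sampled from twice the
#' Euclidean distance transform of the mask along the run.
#'
#' @param skeleton a `skeleton_mask`.
#' @param mask the `vessel_mask` the skeleton was derived from.
#' @return object of class `vessel_graph`: `nodes` data frame
#'   (id, x, y, kind), `edges` data frame (id, from, to, length_px,
#'   mean_width_px, strahler_order, vessel_class, chord), `polylines` list
#'   of n x 2 (x, y) matrices, `dims`, `pixel_size_mm`.
#' @export
build_graph <- function(skeleton, mask) {
  sk <- skeleton$pixels
  nr <- nrow(sk); nc <- ncol(sk)
  dt <- as.matrix(EBImage::distmap(matrix(as.numeric(mask$pixels), nr, nc)))
  # crossing number: 0->1 transitions in the 8-neighbour ring; robust to
  # staircase pixels on diagonal runs
  nb <- zs_neighbours(matrix(as.integer(sk), nr, nc))
  seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  A <- matrix(0L, nr, nc)
  for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
  junction <- sk & A >= 3L
  path <- sk & !junction

  jpx <- which(junction, arr.ind = TRUE)
  jlab <- if (nrow(jpx)) pixel_components(jpx, nr, nc) else integer(0)
  njn <- if (length(jlab)) max(jlab) else 0L
  jmap <- matrix(0L, nr, nc)
  if (nrow(jpx)) jmap[jpx] <- jlab

  nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      kind = character(0))
  for (j in seq_len(njn)) {
    sel <- jlab == j
    nodes <- rbind(nodes, data.frame(
      id = j, x = mean(jpx[sel, 2]), y = mean(jpx[sel, 1]),
      kind = "junction"))
  }

  ppx <- which(path, arr.ind = TRUE)
  edges <- list(); polylines <- list()
  add_node <- function(r, c, kind) {
    onb <- min(r, c, nr - r + 1, nc - c + 1) <= 2
    nodes <<- rbind(nodes, data.frame(
      id = nrow(nodes) + 1L, x = c, y = r,
      kind = if (onb) "border" else kind))
    nrow(nodes)
  }
  junction_at <- function(r, c) {
    for (k in seq_len(nrow(NB8))) {
      rr <- r + NB8[k, 1]; cc <- c + NB8[k, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && jmap[rr, cc] > 0)
        return(jmap[rr, cc])
    }
    0L
  }
  visited <- matrix(FALSE, nr, nc)
  adj_to_cluster <- function(r, c, cl) {
    for (k in seq_len(nrow(NB8))) {
      rr <- r + NB8[k, 1]; cc <- c + NB8[k, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && jmap[rr, cc] == cl)
        return(TRUE)
    }
    FALSE
  }
  emit_edge <- function(run, na, nb_, closed = FALSE) {
    pl <- cbind(x = run[, 2], y = run[, 1])
    ja <- if (na <= njn) na else 0L
    jb <- if (nb_ <= njn) nb_ else 0L
    if (ja > 0) pl <- rbind(c(nodes$x[ja], nodes$y[ja]), pl)
    if (jb > 0 && !closed) pl <- rbind(pl, c(nodes$x[jb], nodes$y[jb]))
    if (closed) pl <- rbind(pl, pl[1, ])
    len <- if (nrow(pl) > 1) sum(sqrt(rowSums(diff(pl)^2))) else 0
    edges[[length(edges) + 1L]] <<- data.frame(
      id = length(edges) + 1L, from = na, to = nb_, length_px = len,
      mean_width_px = mean(2 * dt[run]), strahler_order = NA_integer_,
      vessel_class = NA_character_, chord = FALSE)
    polylines[[length(polylines) + 1L]] <<- pl
  }
  # walk along unvisited path pixels starting at (r0, c0), having left
  # junction cluster j0 (0 = free run); stops at a junction cluster or a
  # free end
  walk_run <- function(r0, c0, j0) {
    run <- matrix(c(r0, c0), 1, 2)
    visited[r0, c0] <<- TRUE
    cur <- c(r0, c0); steps <- 1L
    term_cluster <- 0L
    repeat {
      jn_cand <- integer(0); pa_cand <- NULL
      for (k in seq_len(nrow(NB8))) {
        rr <- cur[1] + NB8[k, 1]; cc <- cur[2] + NB8[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || !sk[rr, cc]) next
        if (jmap[rr, cc] > 0L) {
          jn_cand <- c(jn_cand, jmap[rr, cc])
        } else if (path[rr, cc] && !visited[rr, cc]) {
          pa_cand <- rbind(pa_cand, c(rr, cc))
        }
      }
      jn_cand <- unique(jn_cand)
      jn_ok <- jn_cand[jn_cand != j0 | steps > 2L]
      if (length(jn_ok)) { term_cluster <- jn_ok[1]; break }
      if (!is.null(pa_cand) && steps <= 2L && j0 > 0L) {
        away <- !apply(pa_cand, 1, function(p) adj_to_cluster(p[1], p[2], j0))
        if (any(away)) pa_cand <- pa_cand[away, , drop = FALSE]
      }
      if (is.null(pa_cand) || nrow(pa_cand) == 0L) break
      d4 <- abs(pa_cand[, 1] - cur[1]) + abs(pa_cand[, 2] - cur[2])
      cur <- pa_cand[order(d4)[1], ]
      visited[cur[1], cur[2]] <<- TRUE
      run <- rbind(run, cur); steps <- steps + 1L
    }
    list(run = run, term = term_cluster)
  }
  if (nrow(ppx)) {
    # edges incident to junction clusters
    for (i in seq_len(nrow(jpx))) {
      j <- jlab[i]
      r <- jpx[i, 1]; c <- jpx[i, 2]
      for (k in seq_len(nrow(NB8))) {
        rr <- r + NB8[k, 1]; cc <- c + NB8[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (!path[rr, cc] || visited[rr, cc]) next
        w <- walk_run(rr, cc, j)
        endpx <- w$run[nrow(w$run), ]
        # junction-fringe stub: a dead-ended 1-2 px run whose tip is not a
        # genuine free end (crossing number != 1) is junction spill-over
        if (w$term == 0L && nrow(w$run) <= 2L &&
            A[endpx[1], endpx[2]] != 1L) next
        nb_ <- if (w$term > 0L) w$term else
          add_node(endpx[1], endpx[2], "endpoint")
        emit_edge(w$run, j, nb_)
      }
    }
    # leftover runs: open arcs between free ends, or isolated cycles
    left <- ppx[!visited[ppx], , drop = FALSE]
    if (nrow(left)) {
      comp <- pixel_components(left, nr, nc)
      for (cmp in seq_len(max(comp))) {
        sub <- left[comp == cmp, , drop = FALSE]
        if (nrow(sub) == 1L) { visited[sub] <- TRUE; next }
        inset <- matrix(FALSE, nr, nc); inset[sub] <- TRUE
        deg <- vapply(seq_len(nrow(sub)), function(i) {
          d <- 0L
          for (k in seq_len(nrow(NB8))) {
            rr <- sub[i, 1] + NB8[k, 1]; cc <- sub[i, 2] + NB8[k, 2]
            if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && inset[rr, cc])
              d <- d + 1L
          }
          d
        }, integer(1))
        open_run <- any(deg <= 1L)
        st <- if (open_run) which(deg <= 1L)[1] else 1L
        w <- walk_run(sub[st, 1], sub[st, 2], 0L)
        run <- w$run
        na <- add_node(run[1, 1], run[1, 2], "endpoint")
        nb_ <- if (!open_run) na else
          add_node(run[nrow(run), 1], run[nrow(run), 2], "endpoint")
        emit_edge(run, na, nb_, closed = !open_run)
      }
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(id = integer(0), from = integer(0), to = integer(0),
               length_px = numeric(0), mean_width_px = numeric(0),
               strahler_order = integer(0), vessel_class = character(0),
               chord = logical(0))
  structure(list(nodes = nodes, edges = ed, polylines = polylines,
                 dims = c(nr, nc), pixel_size_mm = skeleton$pixel_size_mm),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

node_degrees <- function(graph) {
  tabulate(c(graph$edges$from, graph$edges$to), nbins = nrow(graph$nodes))
}

# merge chains through degree-2 junction nodes into single edges
merge_degree2 <- function(graph) {
  repeat {
    deg <- node_degrees(graph)
    cand <- which(deg == 2 & graph$nodes$kind != "endpoint")
    done <- TRUE
    for (v in cand) {
      inc <- which(graph$edges$from == v | graph$edges$to == v)
      if (length(inc) != 2L) next             # self-loop at v
      e1 <- inc[1]; e2 <- inc[2]
      p1 <- graph$polylines[[e1]]; p2 <- graph$polylines[[e2]]
      if (graph$edges$to[e1] != v) { p1 <- p1[nrow(p1):1, , drop = FALSE]
        tmp <- graph$edges$from[e1]; graph$edges$from[e1] <- graph$edges$to[e1]
        graph$edges$to[e1] <- tmp }
      if (graph$edges$from[e2] != v) { p2 <- p2[nrow(p2):1, , drop = FALSE]
        tmp <- graph$edges$from[e2]; graph$edges$from[e2] <- graph$edges$to[e2]
        graph$edges$to[e2] <- tmp }
      l1 <- graph$edges$length_px[e1]; l2 <- graph$edges$length_px[e2]
      graph$edges$to[e1] <- graph$edges$to[e2]
      graph$edges$length_px[e1] <- l1 + l2
      graph$edges$mean_width_px[e1] <-
        if (l1 + l2 > 0) (graph$edges$mean_width_px[e1] * l1 +
                            graph$edges$mean_width_px[e2] * l2) / (l1 + l2) else
          mean(c(graph$edges$mean_width_px[e1], graph$edges$mean_width_px[e2]))
      graph$polylines[[e1]] <- rbind(p1, p2[-1, , drop = FALSE])
      graph$edges <- graph$edges[-e2, , drop = FALSE]
      graph$polylines <- graph$polylines[-e2]
      done <- FALSE
      break
    }
    if (done) break
  }
  graph$edges$id <- seq_len(nrow(graph$edges))
  graph
}

#' Remove short endpoint-terminated spurs
#'
#' Iteratively deletes edges shorter than `min_len_px` that terminate in an
#' endpoint (degree-1) node, then re-merges pass-through nodes; idempotent
#' at the fixed point.
#'
#' @param graph a `vessel_graph`.
#' @param min_len_px spur length threshold (px); 0 leaves the graph
#'   untouched.
#' @return pruned `vessel_graph`.
#' @export
prune_spurs <- function(graph, min_len_px) {
  if (min_len_px < 0) stop("min_len_px must be >= 0")
  if (min_len_px == 0) return(graph)
  repeat {
    deg <- node_degrees(graph)
    spur <- which((deg[graph$edges$from] == 1L | deg[graph$edges$to] == 1L) &
                    graph$edges$length_px < min_len_px &
                    !(deg[graph$edges$from] == 1L & deg[graph$edges$to] == 1L))
    if (length(spur) == 0L) break
    graph$edges <- graph$edges[-spur, , drop = FALSE]
    graph$polylines <- graph$polylines[-spur]
    graph$edges$id <- seq_len(nrow(graph$edges))
    graph <- merge_degree2(graph)
  }
  graph
}

#' Assign Horton-Strahler orders to a vessel graph
#'
#' Each connected component is reduced to a breadth-first spanning tree
#' rooted at its root node; cycle chords are dropped for ordering and
#' assigned order 1 with `chord = TRUE`. Leaf edges get order 1; a parent
#' edge whose child edges attain maximum order k gets k + 1 when at least
#' two children attain k, otherwise k. Edges inherit the order of their
#' distal (child-side) subtree.
#'
#' @param graph a `vessel_graph`.
#' @param roots `"auto"` (the border-most node of each component's widest
#'   edge) or an integer vector of node ids, one per component.
#' @return `vessel_graph` with `strahler_order` filled in.
#' @export
strahler_order <- function(graph, roots = "auto") {
  ne <- nrow(graph$edges)
  if (ne == 0L) return(graph)
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to,
               eid = graph$edges$id),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$nodes))))
  comp <- igraph::components(g)$membership
  ord <- rep(NA_integer_, ne)
  chord <- rep(FALSE, ne)
  nr <- graph$dims[1]; nc <- graph$dims[2]
  border_dist <- pmin(graph$nodes$x - 1, graph$nodes$y - 1,
                      nc - graph$nodes$x, nr - graph$nodes$y)
  for (ci in sort(unique(comp[comp > 0]))) {
    vids <- which(comp == ci)
    eids <- which(graph$edges$from %in% vids | graph$edges$to %in% vids)
    if (is.character(roots) && identical(roots, "auto")) {
      we <- eids[which.max(graph$edges$mean_width_px[eids])]
      cand <- c(graph$edges$from[we], graph$edges$to[we])
      root <- cand[which.min(border_dist[cand])]
    } else {
      root <- intersect(as.integer(roots), vids)
      if (length(root) == 0L)
        stop(sprintf("no root supplied for component %d", ci))
      root <- root[1]
    }
    bf <- igraph::bfs(g, root = as.character(root), father = TRUE,
                      unreachable = FALSE)
    father <- as.integer(bf$father)
    visit_order <- as.integer(igraph::as_ids(bf$order))
    visit_order <- visit_order[!is.na(visit_order)]
    # tree edge for node v: the component edge joining v and father[v]
    tree_edge_of <- rep(NA_integer_, nrow(graph$nodes))
    used <- rep(FALSE, ne)
    for (v in visit_order) {
      f <- father[v]
      if (is.na(f)) next
      ecand <- which(((graph$edges$from == v & graph$edges$to == f) |
                        (graph$edges$from == f & graph$edges$to == v)) & !used)
      if (length(ecand)) {
        tree_edge_of[v] <- ecand[1]
        used[ecand[1]] <- TRUE
      }
    }
    children_of <- split(visit_order[!is.na(father[visit_order])],
                         father[visit_order[!is.na(father[visit_order])]])
    # bottom-up over reverse BFS order
    node_edge_order <- rep(NA_integer_, nrow(graph$nodes))
    for (v in rev(visit_order)) {
      ch <- children_of[[as.character(v)]]
      ch <- ch[!is.na(tree_edge_of[ch])]
      ks <- node_edge_order[ch]
      ks <- ks[!is.na(ks)]
      k <- if (length(ks) == 0L) 1L else {
        m <- max(ks)
        if (sum(ks == m) >= 2L) m + 1L else m
      }
      node_edge_order[v] <- k
      if (!is.na(tree_edge_of[v])) ord[tree_edge_of[v]] <- k
    }
    # chords: component edges not in the spanning tree
    rest <- eids[is.na(ord[eids])]
    ord[rest] <- 1L
    chord[rest] <- TRUE
  }
  graph$edges$strahler_order <- ord
  graph$edges$chord <- chord
  graph
}

#' Classify edges as arteriole/venule (AV) or capillary
#'
#' AV = Horton-Strahler order 2 to 4 (strict band); everything else,
#' including chords and order >= 5, is capillary.
#'
#' @param graph a `vessel_graph` with orders assigned.
#' @return `vessel_graph` with `vessel_class` filled in.
#' @export
classify_vessels <- function(graph) {
  if (nrow(graph$edges) && all(is.na(graph$edges$strahler_order)))
    stop("assign Strahler orders before classification")
  o <- graph$edges$strahler_order
  graph$edges$vessel_class <-
    ifelse(!is.na(o) & o >= 2L & o <= 4L & !graph$edges$chord,
           "AV", "capillary")
  graph
}

#' Stamp the AV edges of a classified graph into a pixel mask
#'
#' @param graph classified `vessel_graph`.
#' @return logical matrix; AV pixels TRUE.
#' @export
av_mask_from_graph <- function(graph) {
  sel <- which(graph$edges$vessel_class == "AV")
  if (length(sel) == 0L)
    return(matrix(FALSE, graph$dims[1], graph$dims[2]))
  rasterize_centerlines(graph$polylines[sel],
                        graph$edges$mean_width_px[sel], graph$dims)
}
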