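test_that("segmentation overlaps the phantom ground truth and is deterministic", {
  ph <- generate_vessel_phantom(phantom_spec(seed = 1))
  bm <- binarize_vessels(ph$image)
  dice <- 2 * sum(bm$pixels & ph$truth$mask) /
    (sum(bm$pixels) + sum(ph$truth$mask))
  expect_gte(dice, 0.85)
  bm2 <- binarize_vessels(ph$image)
  expect_identical(bm$pixels, bm2$pixels)
  expect_error(binarize_vessels(enface_image(matrix(0, 64, 64), 0.01)),
               "no vessel")
})

test_that("thinning produces 1-px centerlines and preserves topology", {
  bar <- matrix(FALSE, 20, 40); bar[8:12, 5:35] <- TRUE
  sk <- skeletonize_mask(vessel_mask(bar))
  rows_used <- unique(which(sk$pixels, arr.ind = TRUE)[, 1])
  expect_equal(length(rows_used), 1L)
  expect_true(abs(sum(sk$pixels) - 31) <= 6)   # bar length 31, eroded ends
  # ring stays a single closed loop
  rg <- matrix(FALSE, 40, 40)
  for (a in seq(0, 2 * pi, 0.01)) for (r in 10:13)
    rg[round(20 + r * sin(a)), round(20 + r * cos(a))] <- TRUE
  skr <- skeletonize_mask(vessel_mask(rg))
  g <- build_graph(skr, vessel_mask(rg))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$from, g$edges$to)
  # skeleton is a subset of the mask
  ph <- generate_vessel_phantom(small_phantom_spec(2))
  m <- vessel_mask(ph$truth$mask, ph$image$pixel_size_mm)
  skp <- skeletonize_mask(m)
  expect_true(all(m$pixels[skp$pixels]))
  expect_lte(sum(skp$pixels), sum(m$pixels))
})

test_that("skeleton centerlines stay close to the generating centerlines", {
  ph <- generate_vessel_phantom(small_phantom_spec(4))
  m <- vessel_mask(ph$truth$mask, ph$image$pixel_size_mm)
  sk <- skeletonize_mask(m)
  truecl <- do.call(rbind, ph$truth$centerlines)
  skp <- which(sk$pixels, arr.ind = TRUE)
  set.seed(1)
  idx <- sample(nrow(skp), min(1500, nrow(skp)))
  d <- vapply(idx, function(i)
    sqrt(min((truecl[, 1] - skp[i, 2])^2 + (truecl[, 2] - skp[i, 1])^2)),
    numeric(1))
  expect_gte(mean(d <= 2), 0.90)
})

test_that("graph construction recovers elementary topologies", {
  # single open curve: 2 endpoints, 1 edge
  cv <- rasterize_centerlines(list(cbind(c(5, 25), c(5, 25))), 1, c(30, 30))
  g <- build_graph(skeletonize_mask(vessel_mask(cv)), vessel_mask(cv))
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  # Y: 3 endpoints + 1 junction, 3 edges
  cl <- list(cbind(c(20, 20), c(35, 20)), cbind(c(20, 10), c(20, 8)),
             cbind(c(20, 30), c(20, 8)))
  ym <- rasterize_centerlines(cl, rep(3, 3), c(40, 40))
  gy <- build_graph(skeletonize_mask(vessel_mask(ym)), vessel_mask(ym))
  expect_equal(nrow(gy$nodes), 4L)
  expect_equal(nrow(gy$edges), 3L)
  expect_equal(sort(table(gy$nodes$kind), decreasing = TRUE),
               sort(c(junction = 1L, endpoint = 3L), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("node/edge counts match an independent pixel-neighbourhood scan", {
  ph <- generate_vessel_phantom(phantom_spec(
    seed = 6, grid_size = c(120L, 120L), field_mm = 1.2, n_trees = 2L,
    capillary_density_target = 0, faz_axes_mm = c(0.1, 0.09)))
  m <- vessel_mask(ph$truth$mask, ph$image$pixel_size_mm)
  sk <- skeletonize_mask(m)
  g <- build_graph(sk, m)
  # oracle: crossing-number classification + cluster counting
  s <- sk$pixels
  nr <- nrow(s); nc <- ncol(s)
  crossing <- function(r, c) {
    ring <- c(s[r - 1, c], s[r - 1, c + 1], s[r, c + 1], s[r + 1, c + 1],
              s[r + 1, c], s[r + 1, c - 1], s[r, c - 1], s[r - 1, c - 1])
    sum(!ring & c(ring[-1], ring[1]))
  }
  jn <- 0L; ep <- 0L
  jmask <- matrix(FALSE, nr, nc)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    if (!s[r, c]) next
    a <- crossing(r, c)
    if (a >= 3) jmask[r, c] <- TRUE
    if (a == 1) ep <- ep + 1L
  }
  ncl <- max(EBImage::bwlabel(jmask))
  expect_equal(sum(g$nodes$kind %in% c("junction")), ncl)
  expect_equal(sum(g$nodes$kind %in% c("endpoint", "border")), ep)
})

test_that("spur pruning removes short endpoint spurs and is idempotent", {
  cl <- list(cbind(c(10, 50), c(30, 30)),      # long horizontal
             cbind(c(30, 30), c(30, 10)),      # long vertical branch
             cbind(c(40, 43), c(30, 26)))      # 5 px spur
  ym <- rasterize_centerlines(cl, rep(3, 3), c(60, 60))
  m <- vessel_mask(ym)
  g0 <- build_graph(skeletonize_mask(m), m)
  expect_identical(prune_spurs(g0, 0)$edges, g0$edges)
  g1 <- prune_spurs(g0, 8)
  # the spur is gone; the two long runs remain
  expect_lt(nrow(g1$edges), nrow(g0$edges))
  expect_gte(min(g1$edges$length_px), 8)
  g2 <- prune_spurs(g1, 8)
  expect_equal(nrow(g2$edges), nrow(g1$edges))
})

test_that("Strahler ordering matches the recursive oracle on random trees", {
  for (s in 1:30) {
    ne <- sample(3:15, 1)
    ed <- random_tree_edges(ne, seed = s)
    g <- tree_as_vessel_graph(ed, ne + 1L)
    g <- strahler_order(g, roots = 1L)
    oracle <- oracle_strahler(ed, root = 1L)
    expect_identical(g$edges$strahler_order, oracle)
  }
})

test_that("Strahler ordering is invariant to edge enumeration order", {
  ed <- random_tree_edges(12, seed = 4)
  g <- tree_as_vessel_graph(ed, 13L)
  o1 <- strahler_order(g, roots = 1L)$edges$strahler_order
  perm <- sample(nrow(ed))
  g2 <- tree_as_vessel_graph(ed[perm, ], 13L)
  o2 <- strahler_order(g2, roots = 1L)$edges$strahler_order
  expect_identical(o1, o2[order(perm)][order(seq_along(perm))] ,
                   label = "orders after permutation")
  expect_identical(o1[perm], o2)
})

test_that("simple-path and confluence orders follow the definition", {
  # chain of 3 edges: all order 1
  ed <- data.frame(from = c(1, 2, 3), to = c(2, 3, 4))
  g <- strahler_order(tree_as_vessel_graph(ed, 4L), roots = 1L)
  expect_true(all(g$edges$strahler_order == 1L))
  # two order-1 branches merging
  ed2 <- data.frame(from = c(1, 2, 2), to = c(2, 3, 4))
  g2 <- strahler_order(tree_as_vessel_graph(ed2, 4L), roots = 1L)
  expect_equal(sort(g2$edges$strahler_order), c(1L, 1L, 2L))
})

test_that("vessel classification applies the strict order band 2-4", {
  ed <- data.frame(from = c(1, 2, 3), to = c(2, 3, 4))
  g <- classify_vessels(strahler_order(tree_as_vessel_graph(ed, 4L),
                                       roots = 1L))
  expect_true(all(g$edges$vessel_class == "capillary"))
  g2 <- tree_as_vessel_graph(ed, 4L)
  g2$edges$strahler_order <- c(2L, 4L, 5L)
  g2$edges$chord <- FALSE
  g2 <- classify_vessels(g2)
  expect_equal(g2$edges$vessel_class, c("AV", "AV", "capillary"))
})

test_that("AV labels on tree-only phantoms match the generator classes", {
  agree <- 0; total <- 0
  for (s in 1:6) {
    ph <- generate_vessel_phantom(phantom_spec(
      seed = s, grid_size = c(220L, 220L), field_mm = 2.2, n_trees = 1L,
      capillary_density_target = 0, branch_depth = 4L,
      faz_axes_mm = c(0.08, 0.07)))
    m <- vessel_mask(ph$truth$mask, ph$image$pixel_size_mm)
    g <- classify_vessels(strahler_order(prune_spurs(
      build_graph(skeletonize_mask(m), m), 6)))
    av_est <- av_mask_from_graph(g)
    av_true <- rasterize_centerlines(
      ph$truth$centerlines[ph$truth$vessel_class == "AV"],
      ph$truth$widths[ph$truth$vessel_class == "AV"], dim(ph$truth$mask))
    # per-pixel agreement on vessel pixels
    vp <- ph$truth$mask
    agree <- agree + sum((av_est & av_true & vp) | (!av_est & !av_true & vp))
    total <- total + sum(vp)
  }
  expect_gte(agree / total, 0.90)
})
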