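test_that("straight and diagonal lines measure exactly", {
  # 11-px horizontal line: one endpoint-to-endpoint segment, c = d = 10 um
  m <- matrix(FALSE, 9, 15); m[5, 3:13] <- TRUE
  G <- build_graph(as_skeleton(m, 1))
  expect_equal(nrow(G$segments), 1L)
  expect_equal(G$segments$category, "endpoint_to_endpoint")
  expect_equal(G$segments$c_um, 10)
  expect_equal(G$segments$d_um, 10)
  # 10-px perfect diagonal: c = 9 * sqrt(2), exact
  md <- matrix(FALSE, 14, 14); md[cbind(3:12, 3:12)] <- TRUE
  Gd <- build_graph(as_skeleton(md, 1))
  expect_equal(Gd$segments$c_um, 9 * sqrt(2), tolerance = 1e-12)
  expect_equal(Gd$segments$d_um, 9 * sqrt(2), tolerance = 1e-12)
  # calibration scales both
  Gc <- build_graph(as_skeleton(m, 2.5))
  expect_equal(Gc$segments$c_um, 25)
})

test_that("junction and cycle topologies are categorized correctly", {
  # T: one junction node, three junction-to-endpoint arms
  mT <- matrix(FALSE, 15, 15)
  mT[4, 3:13] <- TRUE; mT[5:12, 8] <- TRUE
  GT <- build_graph(as_skeleton(mT, 1))
  expect_equal(sum(GT$nodes$type == "junction"), 1L)
  expect_equal(unname(table(GT$segments$category)["junction_to_endpoint"]), 3L)
  expect_equal(nrow(GT$segments), 3L)
  # X from two crossing diagonals: one junction cluster, four arms
  n <- 15
  mX <- matrix(FALSE, n, n)
  mX[cbind(1:n, 1:n)] <- TRUE
  mX[cbind(1:n, n:1)] <- TRUE
  GX <- build_graph(as_skeleton(mX, 1))
  expect_equal(sum(GX$nodes$type == "junction"), 1L)
  expect_equal(nrow(GX$segments), 4L)
  expect_true(all(GX$segments$category == "junction_to_endpoint"))
  # O: a rasterized circle is one isolated cycle with d = 0
  t <- seq(0, 2 * pi, length.out = 200)
  pts <- cbind(16 + 9 * sin(t), 16 + 9 * cos(t))
  mO <- rasterize_polyline(rbind(pts, pts[1, ]), 31, 31)
  mO <- skeletonize(structure(list(mask = mO, pixel_size_um = 1),
                              class = "binary_mask"))$mask
  GO <- build_graph(as_skeleton(mO, 1))
  expect_equal(nrow(GO$segments), 1L)
  expect_equal(GO$segments$category, "isolated_cycle")
  expect_equal(GO$segments$d_um, 0)
  expect_gt(GO$segments$c_um, 2 * pi * 7)  # near the circumference
})

test_that("degenerate pieces follow the documented conventions", {
  # two-pixel segment is valid and measured
  m2 <- matrix(FALSE, 6, 6); m2[3, 3:4] <- TRUE
  G2 <- build_graph(as_skeleton(m2, 1))
  expect_equal(G2$segments$c_um, 1)
  expect_equal(G2$segments$category, "endpoint_to_endpoint")
  # isolated single pixel is discarded as noise
  m1 <- matrix(FALSE, 6, 6); m1[3, 3] <- TRUE
  expect_equal(nrow(build_graph(as_skeleton(m1, 1))$segments), 0L)
  # empty skeleton gives an empty graph with positive area
  G0 <- build_graph(as_skeleton(matrix(FALSE, 8, 8), 2))
  expect_equal(nrow(G0$segments), 0L)
  expect_equal(G0$area_mm2, 64 * 4 / 1e6)
  # non-thin input is rejected
  mb <- matrix(FALSE, 6, 6); mb[2:3, 2:3] <- TRUE
  expect_error(build_graph(as_skeleton(mb, 1)), "non-thin")
})

test_that("the micron filters exclude on either criterion", {
  segs <- data.frame(category = rep("endpoint_to_endpoint", 4),
                     c_um = c(150, 90, 120, 200),
                     d_um = c(60, 80, 40, 55))
  G <- skeleton_graph(segs, area_mm2 = 1)
  kept <- filter_segments(G, 100, 50)$segments
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$c_um, c(150, 200))
  # (90, 80) fails the length cut, (120, 40) fails the chord cut
  expect_false(90 %in% kept$c_um)
  expect_false(120 %in% kept$c_um)
  expect_error(filter_segments(G, -1, 50), "non-negative")
})

test_that("filtering is monotone in both thresholds", {
  set.seed(5)
  segs <- data.frame(category = "endpoint_to_endpoint",
                     c_um = runif(200, 0, 300))
  segs$d_um <- segs$c_um * runif(200, 0.3, 1)
  G <- skeleton_graph(segs, area_mm2 = 1)
  prev <- Inf
  for (thr in seq(0, 300, by = 25)) {
    n_now <- nrow(filter_segments(G, thr, 50)$segments)
    expect_lte(n_now, prev)
    prev <- n_now
  }
  prev <- Inf
  for (thr in seq(0, 300, by = 25)) {
    n_now <- nrow(filter_segments(G, 100, thr)$segments)
    expect_lte(n_now, prev)
    prev <- n_now
  }
})

test_that("tracing agrees with brute-force degree analysis on random polylines", {
  set.seed(31)
  for (i in 1:100) {
    nr <- 60; nc <- 60
    k <- sample(1:3, 1)
    m <- matrix(FALSE, nr, nc)
    for (j in seq_len(k)) {
      m <- m | rasterize_polyline(random_polyline(nr, nc), nr, nc)
    }
    sk <- skeletonize(structure(list(mask = m, pixel_size_um = 1),
                                class = "binary_mask"))$mask
    G <- build_graph(as_skeleton(sk, 1))
    deg <- oracle_degrees(sk)
    if (all(deg[sk] <= 2, na.rm = TRUE) && all(deg[sk] >= 1, na.rm = TRUE) &&
        !any(G$segments$category == "isolated_cycle")) {
      # pure open curves: segments must equal 8-connected components
      expect_equal(nrow(G$segments), oracle_component_count(sk))
      expect_true(all(G$segments$category == "endpoint_to_endpoint"))
    }
    # pixel conservation: every skeleton pixel is on a path or in a node
    covered <- matrix(FALSE, nr, nc)
    for (p in G$paths) covered[p] <- TRUE
    if (!is.null(G$nodes) && nrow(G$nodes)) {
      # node pixels: within 1.5 px of a recorded node centroid
      for (q in which(sk & !covered)) {
        rc <- arrayInd(q, c(nr, nc))
        dmin <- min(sqrt((G$nodes$r - rc[1])^2 + (G$nodes$c - rc[2])^2))
        expect_lt(dmin, 2.5)
      }
    }
    # invariant: c >= d >= 0 and d = sqrt(h^2 + w^2)
    s <- G$segments
    expect_true(all(s$c_um >= s$d_um - 1e-9))
    expect_equal(s$d_um, sqrt(s$h_um^2 + s$w_um^2), tolerance = 1e-12)
  }
})
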