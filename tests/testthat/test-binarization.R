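thin_map <- function(values, pixel_size_um = 1) {
  structure(list(prob = values, pixel_size_um = pixel_size_um),
            class = c("thin_edge_map", "edge_prob_map"))
}

test_that("double thresholding applies the three inequalities, boundaries intermediate", {
  E <- thin_map(matrix(c(0.05, 0.2, 0.9, 0.3, 0.1, 0), 1, 6))
  L <- double_threshold(E, tl = 0.1, th = 0.3)
  # weak, intermediate, strong; th exactly -> intermediate; tl exactly ->
  # intermediate; 0 below tl -> weak
  expect_equal(as.vector(L$labels), c(0L, 1L, 2L, 1L, 1L, 0L))
  expect_error(double_threshold(E, 0.3, 0.3), "tl < th")
  expect_error(double_threshold(E, 0.5, 0.2), "tl < th")
})

test_that("hysteresis modes differ exactly as transitive vs one-hop reach", {
  labels <- matrix(0L, 3, 5)
  labels[2, 1] <- 2L; labels[2, 2] <- 1L; labels[2, 3] <- 1L
  L <- structure(list(labels = labels, tl = 0.1, th = 0.3, pixel_size_um = 1),
                 class = "labeled_mask")
  trans <- hysteresis_track(L, "transitive")$mask
  hop <- hysteresis_track(L, "one_hop")$mask
  expect_equal(which(trans), which(labels > 0))          # whole chain kept
  expect_true(hop[2, 1] && hop[2, 2] && !hop[2, 3])      # one hop only
  # isolated intermediate pixel with no strong anywhere
  iso <- structure(list(labels = matrix(c(0L, 1L, 0L, 0L), 2, 2),
                        tl = 0.1, th = 0.3, pixel_size_um = 1),
                   class = "labeled_mask")
  expect_false(any(hysteresis_track(iso, "transitive")$mask))
  expect_false(any(hysteresis_track(iso, "one_hop")$mask))
  # all-strong labelling is the identity
  allS <- structure(list(labels = matrix(2L, 4, 4), tl = 0.1, th = 0.3,
                         pixel_size_um = 1), class = "labeled_mask")
  expect_true(all(hysteresis_track(allS)$mask))
})

test_that("hysteresis is monotone in th and one_hop is nested in transitive", {
  set.seed(11)
  E <- thin_map(matrix(runif(40 * 40), 40, 40))
  for (i in 1:10) {
    th1 <- runif(1, 0.3, 0.6); th2 <- th1 + runif(1, 0.05, 0.3)
    m_lo <- hysteresis_track(double_threshold(E, 0.1, th1))$mask
    m_hi <- hysteresis_track(double_threshold(E, 0.1, th2))$mask
    expect_true(all(m_lo[m_hi]))  # raising th never adds edge pixels
    L <- double_threshold(E, 0.1, th1)
    hop <- hysteresis_track(L, "one_hop")$mask
    trans <- hysteresis_track(L, "transitive")$mask
    expect_true(all(trans[hop]))  # one_hop subset of transitive
  }
})

test_that("skeletonization preserves thin lines and thins blobs to 1 px", {
  # 1-px horizontal line is unchanged
  m <- matrix(FALSE, 9, 9); m[5, 2:8] <- TRUE
  S <- skeletonize(structure(list(mask = m, pixel_size_um = 1),
                             class = "binary_mask"))
  expect_equal(S$mask, m)
  # empty mask stays empty
  S0 <- skeletonize(structure(list(mask = matrix(FALSE, 5, 5), pixel_size_um = 1),
                              class = "binary_mask"))
  expect_false(any(S0$mask))
  # 5x3 filled rectangle reduces to a connected path of < 15 px
  m2 <- matrix(FALSE, 11, 9); m2[4:8, 4:6] <- TRUE
  S2 <- skeletonize(structure(list(mask = m2, pixel_size_um = 1),
                              class = "binary_mask"))
  expect_lt(sum(S2$mask), 15)
  expect_gt(sum(S2$mask), 0)
  expect_equal(oracle_component_count(S2$mask), 1L)
  expect_true(all(m2[S2$mask]))  # support subset of input
})

test_that("skeletons have no 2x2 block and preserve component counts", {
  set.seed(23)
  for (i in 1:15) {
    m <- matrix(runif(50 * 50) > 0.8, 50, 50)
    # dilate a little to create blobs
    m <- fibertrace:::dilate8(m)
    S <- skeletonize(structure(list(mask = m, pixel_size_um = 1),
                               class = "binary_mask"))
    sk <- S$mask
    expect_equal(nrow(fibertrace:::.find_blocks(sk)), 0L)
    expect_equal(oracle_component_count(sk), oracle_component_count(m))
    expect_true(all(m[sk]))  # skeleton support inside mask support
  }
})

test_that("border clearing removes exactly the margin band", {
  m <- matrix(FALSE, 50, 50)
  diag_idx <- cbind(1:50, 1:50)
  m[diag_idx] <- TRUE
  S <- as_skeleton(m)
  expect_equal(clear_border(S, 0)$mask, m)  # margin 0 is the identity
  out <- clear_border(S, 5)$mask
  kept <- which(out, arr.ind = TRUE)
  expect_true(all(kept >= 6 & kept <= 45))  # coordinate-filter oracle
  expect_equal(sum(out), 40)
  # full-width line at the top row disappears for any positive margin
  m2 <- matrix(FALSE, 20, 20); m2[1, ] <- TRUE
  expect_false(any(clear_border(as_skeleton(m2), 5)$mask))
  expect_error(clear_border(as_skeleton(m2), 10), "margin")
  expect_error(clear_border(as_skeleton(m2), -1), "non-negative")
})
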