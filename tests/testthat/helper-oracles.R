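# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own helpers (igraph labelling, vectorized shifts) so
# that agreement is informative.

# Flood-fill hysteresis oracle: label strong+intermediate components with a
# hand-rolled BFS; keep components containing at least one strong pixel.
oracle_hysteresis_transitive <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  cand <- labels >= 1L
  seen <- matrix(FALSE, nr, nc)
  out <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!cand[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    comp <- list()
    has_strong <- FALSE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      comp[[length(comp) + 1L]] <- p
      if (labels[p[1], p[2]] == 2L) has_strong <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (cand[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    if (has_strong) for (p in comp) out[p[1], p[2]] <- TRUE
  }
  out
}

# one-hop oracle: strong pixels, plus intermediates with a strong 8-neighbour
oracle_hysteresis_one_hop <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- labels == 2L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (labels[r, c] != 1L) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && labels[r2, c2] == 2L) {
        out[r, c] <- TRUE
      }
    }
  }
  out
}

random_labeled_mask <- function(nr = 64, nc = 64,
                                p = c(0.85, 0.10, 0.05), tl = 0.1, th = 0.3) {
  labels <- matrix(sample(0:2, nr * nc, replace = TRUE, prob = p), nr, nc)
  structure(list(labels = labels, tl = tl, th = th, pixel_size_um = 1),
            class = "labeled_mask")
}

# brute-force pixel degrees in 8-connectivity (double loop, no shifts)
oracle_degrees <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  deg <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    d <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && mask[r2, c2]) d <- d + 1L
    }
    deg[r, c] <- d
  }
  deg
}

# count 8-connected components by BFS (independent of igraph)
oracle_component_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    ncomp <- ncomp + 1L
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  ncomp
}

# logical mask from a list of (row, col) pixel matrices
mask_from_pixels <- function(coords, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[coords] <- TRUE
  m
}

as_skeleton <- function(mask, pixel_size_um = 1) {
  structure(list(mask = mask, pixel_size_um = pixel_size_um), class = "skeleton")
}

as_prob_map <- function(prob, pixel_size_um = 1) {
  structure(list(prob = prob, pixel_size_um = pixel_size_um),
            class = "edge_prob_map")
}

# Gaussian-profile straight ridge through the image centre at `angle`
# (tangent direction, radians), peak 1, cross-section sigma.
gaussian_ridge <- function(nr = 80, nc = 80, angle = 0, sigma = 2) {
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # signed distance to the line through (r0, c0) with tangent angle
  d <- -(rr - r0) * cos(angle) + (cc - c0) * sin(angle)
  exp(-d^2 / (2 * sigma^2))
}

# rasterize a polyline (n x 2 real row/col) into a pixel mask
rasterize_polyline <- function(pts, nr, nc, step = 0.25) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    L <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(L / step)))
    r <- round(a[1] + t * (b[1] - a[1]))
    c <- round(a[2] + t * (b[2] - a[2]))
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    m[cbind(r[ok], c[ok])] <- TRUE
  }
  m
}

# a smooth random open polyline that stays inside the frame
random_polyline <- function(nr, nc, n_steps = 6, seg_len = 8) {
  start <- c(runif(1, nr * 0.25, nr * 0.75), runif(1, nc * 0.25, nc * 0.75))
  ang <- runif(1, 0, 2 * pi)
  pts <- matrix(start, 1, 2)
  for (i in seq_len(n_steps)) {
    ang <- ang + runif(1, -0.4, 0.4)
    nxt <- pts[nrow(pts), ] + seg_len * c(sin(ang), cos(ang))
    nxt[1] <- min(max(nxt[1], 2), nr - 1)
    nxt[2] <- min(max(nxt[2], 2), nc - 1)
    pts <- rbind(pts, nxt)
  }
  pts
}
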