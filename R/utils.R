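# Internal raster helpers shared across pipeline stages.

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# 8-neighbourhood offsets, clockwise from north (used by thinning and tracing).
.OFF8 <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
               dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# Count of true 8-neighbours for every cell of a logical matrix.
neighbor_count8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- matrix(0, nrow(mask), ncol(mask))
  for (k in seq_len(8L)) out <- out + shift_mat(m, .OFF8[k, 1L], .OFF8[k, 2L])
  out
}

# Binary dilation with the 3x3 (8-connected) structuring element.
dilate8 <- function(mask) {
  out <- mask
  for (k in seq_len(8L)) {
    out <- out | (shift_mat(matrix(as.numeric(mask), nrow(mask)),
                            .OFF8[k, 1L], .OFF8[k, 2L]) > 0)
  }
  out
}

# Label 8-connected components of a logical matrix. Returns an integer matrix
# with 0 on background; labels are 1..n_components.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_len(n)
  # Undirected adjacency needs only half the 8 offsets.
  offs <- cbind(c(0L, 1L, 1L, 1L), c(1L, 0L, 1L, -1L))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(4L)) {
    sh <- shift_mat(id, offs[k, 1L], offs[k, 2L], fill = 0L)
    both <- which(mask & sh > 0L)
    if (length(both)) {
      from <- c(from, id[both])
      to <- c(to, sh[both])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Separable Gaussian blur with replicated borders. sigma in pixels.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  # vertical pass
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nr, r), , drop = FALSE])
  out <- matrix(0, nr, nc)
  for (i in seq.int(-r, r)) {
    out <- out + k[i + r + 1L] * mp[(1L + r + i):(nr + r + i), , drop = FALSE]
  }
  # horizontal pass
  mp <- cbind(out[, rep(1L, r), drop = FALSE], out, out[, rep(nc, r), drop = FALSE])
  out2 <- matrix(0, nr, nc)
  for (i in seq.int(-r, r)) {
    out2 <- out2 + k[i + r + 1L] * mp[, (1L + r + i):(nc + r + i), drop = FALSE]
  }
  out2
}

# Bilinear sampling of matrix m at real-valued (rr, cc) (1-based, row/col).
# Points outside [1, nrow] x [1, ncol] yield NA.
bilinear_sample <- function(m, rr, cc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(rr))
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc & is.finite(rr) & is.finite(cc)
  if (!any(ok)) return(out)
  r <- rr[ok]; c <- cc[ok]
  r0 <- pmin(floor(r), nr - 1); r0 <- pmax(r0, 1)
  c0 <- pmin(floor(c), nc - 1); c0 <- pmax(c0, 1)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + nr] +
    fr * fc * m[i00 + nr + 1]
  out[ok] <- v
  out
}

# Fold an angle (radians) into [0, pi). Segment chords are undirected.
fold_angle <- function(theta) {
  out <- theta %% pi
  out[out >= pi] <- 0  # guard against floating wrap at exactly pi
  out
}

# Restore the caller's RNG state on exit; used by seeded generators.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
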