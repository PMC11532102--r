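# Double thresholding, hysteresis tracking, skeletonization, border clearing.

#' Double thresholding of a thinned edge map
#'
#' Pixels are labelled strong if `I(p) > th`, weak if `I(p) < tl`, and
#' intermediate if `tl <= I(p) <= th` (both boundary values are intermediate).
#'
#' @param E a `thin_edge_map` (or any `edge_prob_map`).
#' @param tl low threshold in `[0, 1)`.
#' @param th high threshold in `(tl, 1]`.
#' @return An object of class `labeled_mask`: integer matrix `labels`
#'   (0 = weak, 1 = intermediate, 2 = strong) plus the thresholds.
#' @export
double_threshold <- function(E, tl = 0.1, th = 0.3) {
  if (!(tl >= 0 && th <= 1 && tl < th)) stop("need 0 <= tl < th <= 1")
  I <- E$prob
  labels <- matrix(1L, nrow(I), ncol(I))
  labels[I > th] <- 2L
  labels[I < tl] <- 0L
  structure(list(labels = labels, tl = tl, th = th,
                 pixel_size_um = E$pixel_size_um),
            class = "labeled_mask")
}

#' Hysteresis tracking of intermediate pixels
#'
#' Strong pixels are always edges; weak pixels never are. An intermediate
#' pixel becomes an edge pixel if it has a strong 8-neighbour (`one_hop`), or —
#' the classical transitive rule, default — if it is 8-connected to a strong
#' pixel through a chain of intermediate/strong pixels.
#'
#' @param L a [double_threshold()] labelling.
#' @param mode `"transitive"` (default) or `"one_hop"`.
#' @return An object of class `binary_mask` (logical matrix `mask`).
#' @export
hysteresis_track <- function(L, mode = c("transitive", "one_hop")) {
  mode <- match.arg(mode)
  strong <- L$labels == 2L
  inter <- L$labels == 1L
  if (mode == "one_hop") {
    mask <- strong | (inter & dilate8(strong))
  } else {
    cand <- strong | inter
    lab <- label_components8(cand)
    keep_labs <- unique(lab[strong])
    mask <- cand & matrix(lab %in% keep_labs, nrow(lab), ncol(lab))
  }
  structure(list(mask = mask, pixel_size_um = L$pixel_size_um),
            class = "binary_mask")
}

# One Zhang-Suen subiteration; returns the updated logical matrix.
.zs_subiter <- function(m, step) {
  num <- matrix(as.numeric(m), nrow(m), ncol(m))
  p <- lapply(seq_len(8L), function(k) shift_mat(num, .OFF8[k, 1L], .OFF8[k, 2L]) > 0)
  # p[[1]]..p[[8]] = P2..P9 (N, NE, E, SE, S, SW, W, NW)
  B <- Reduce(`+`, lapply(p, as.numeric))
  seqp <- c(p, p[1L])
  A <- Reduce(`+`, lapply(seq_len(8L), function(k) as.numeric(!seqp[[k]] & seqp[[k + 1L]])))
  if (step == 1L) {
    c1 <- !(p[[1]] & p[[3]] & p[[5]])  # P2*P4*P6 == 0
    c2 <- !(p[[3]] & p[[5]] & p[[7]])  # P4*P6*P8 == 0
  } else {
    c1 <- !(p[[1]] & p[[3]] & p[[7]])  # P2*P4*P8 == 0
    c2 <- !(p[[1]] & p[[5]] & p[[7]])  # P2*P6*P8 == 0
  }
  del <- m & B >= 2 & B <= 6 & A == 1 & c1 & c2
  m & !del
}

# Simple-point test for 8-connected foreground / 4-connected background:
# removal of (r, c) preserves topology iff its foreground ring forms one
# 8-connected component and at least one axial neighbour is background.
.is_simple8 <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  vals <- matrix(FALSE, 3L, 3L)
  rs <- (r - 1L):(r + 1L); cs <- (c - 1L):(c + 1L)
  okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
  vals[okr, okc] <- m[rs[okr], cs[okc], drop = FALSE]
  vals[2L, 2L] <- FALSE
  if (vals[1L, 2L] && vals[2L, 1L] && vals[2L, 3L] && vals[3L, 2L]) return(FALSE)
  fg <- which(vals, arr.ind = TRUE)
  n <- nrow(fg)
  if (n == 0L) return(FALSE)
  if (n == 1L) return(TRUE)
  comp <- seq_len(n)
  for (i in 1L:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (max(abs(fg[i, ] - fg[j, ])) == 1L && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  length(unique(comp)) == 1L
}

.find_blocks <- function(m) {
  num <- matrix(as.numeric(m), nrow(m), ncol(m))
  which(m & shift_mat(num, -1, 0) > 0 & shift_mat(num, 0, -1) > 0 &
          shift_mat(num, -1, -1) > 0, arr.ind = TRUE)
}

.zs_converge <- function(m) {
  repeat {
    m1 <- .zs_subiter(m, 1L)
    m2 <- .zs_subiter(m1, 2L)
    if (identical(m2, m)) return(m)
    m <- m2
  }
}

# Sequentially remove redundant pixels: simple points with >= 3 neighbours
# (Zhang-Suen staircase leftovers that masquerade as junctions) and simple
# pixels sitting in 2x2 blocks. Endpoints (1 neighbour) are never touched,
# and clean 2-neighbour corners survive unless they are part of a 2x2 block,
# so minimal digital lines and cycles are preserved.
.remove_redundant_pixels <- function(m) {
  repeat {
    B <- neighbor_count8(m)
    num <- matrix(as.numeric(m), nrow(m), ncol(m))
    in_block <- m & ((shift_mat(num, -1, 0) > 0 & shift_mat(num, 0, -1) > 0 & shift_mat(num, -1, -1) > 0) |
                       (shift_mat(num, -1, 0) > 0 & shift_mat(num, 0, 1) > 0 & shift_mat(num, -1, 1) > 0) |
                       (shift_mat(num, 1, 0) > 0 & shift_mat(num, 0, -1) > 0 & shift_mat(num, 1, -1) > 0) |
                       (shift_mat(num, 1, 0) > 0 & shift_mat(num, 0, 1) > 0 & shift_mat(num, 1, 1) > 0))
    cand <- which((m & B >= 3) | (in_block & B >= 2), arr.ind = TRUE)
    removed_any <- FALSE
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      if (!m[r, c]) next
      if (.is_simple8(m, r, c)) {
        m[r, c] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(m)
  }
}

#' Skeletonize a binary mask to one-pixel width
#'
#' Iterative Zhang-Suen thinning to an 8-connected skeleton, followed by
#' sequential removal of redundant simple points (staircase leftovers and
#' braid pixels around one-pixel holes). Simple-point removal preserves
#' foreground connectivity, so the component count is unchanged; the output
#' support is a subset of the input mask and contains no 2x2 all-true block.
#'
#' @param B a [hysteresis_track()] mask (or any `binary_mask`).
#' @return An object of class `skeleton` (logical matrix `mask`).
#' @export
skeletonize <- function(B) {
  m <- B$mask
  for (round in 1:25) {
    m <- .zs_converge(m)
    m <- .remove_redundant_pixels(m)
    pos <- .find_blocks(m)
    if (nrow(pos) == 0L) break
    # locked braid: drop the most redundant pixel of each block and re-thin
    nc8 <- neighbor_count8(m)
    for (i in seq_len(nrow(pos))) {
      r <- pos[i, 1L]; c <- pos[i, 2L]
      quad <- rbind(c(r, c), c(r, c + 1L), c(r + 1L, c), c(r + 1L, c + 1L))
      on <- quad[m[quad], , drop = FALSE]
      if (nrow(on) == 0L) next
      kill <- on[which.max(nc8[on]), ]
      m[kill[1L], kill[2L]] <- FALSE
    }
  }
  structure(list(mask = m, pixel_size_um = B$pixel_size_um), class = "skeleton")
}

#' Discard skeleton pixels near the image border
#'
#' Edge-detection artifacts concentrate at the frame; all skeleton pixels
#' within `margin_px` of any image edge are cleared.
#'
#' @param S a [skeletonize()] output.
#' @param margin_px non-negative integer, less than half the smaller dimension.
#' @return A `skeleton`.
#' @export
clear_border <- function(S, margin_px = 10) {
  m <- S$mask
  margin_px <- as.integer(margin_px)
  if (margin_px < 0) stop("margin_px must be non-negative")
  if (margin_px >= min(dim(m)) / 2) stop("margin too large for image")
  if (margin_px > 0) {
    m[seq_len(margin_px), ] <- FALSE
    m[(nrow(m) - margin_px + 1L):nrow(m), ] <- FALSE
    m[, seq_len(margin_px)] <- FALSE
    m[, (ncol(m) - margin_px + 1L):ncol(m)] <- FALSE
  }
  structure(list(mask = m, pixel_size_um = S$pixel_size_um), class = "skeleton")
}
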