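# Trace a 1-px skeleton into categorized edge segments with micron lengths.

# Moving-average smoothing of a path (n x 2 matrix of row/col coordinates).
# Endpoints stay fixed for open paths; closed paths are smoothed circularly.
# Collinear equally spaced points are invariant, so straight chain-code
# fixtures keep their exact lengths.
smooth_path <- function(coords, window = 5L, closed = FALSE) {
  n <- nrow(coords)
  if (window <= 1L || n <= 2L) return(coords)
  half <- (as.integer(window) - 1L) %/% 2L
  out <- coords
  if (closed) {
    # drop the duplicated last point, smooth on the circle, re-append
    pts <- coords[-n, , drop = FALSE]
    m <- nrow(pts)
    if (m > 2L) {
      h <- min(half, (m - 1L) %/% 2L)
      idx <- seq_len(m)
      acc_r <- numeric(m); acc_c <- numeric(m)
      for (k in seq.int(-h, h)) {
        j <- ((idx - 1L + k) %% m) + 1L
        acc_r <- acc_r + pts[j, 1L]
        acc_c <- acc_c + pts[j, 2L]
      }
      pts <- cbind(acc_r, acc_c) / (2L * h + 1L)
    }
    out <- rbind(pts, pts[1L, , drop = FALSE])
  } else {
    for (i in 2:(n - 1L)) {
      h <- min(half, i - 1L, n - i)
      out[i, ] <- colMeans(coords[(i - h):(i + h), , drop = FALSE])
    }
  }
  out
}

path_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

.new_skeleton_graph <- function(segments, paths, nodes, area_mm2, pixel_size_um, dim) {
  structure(list(segments = segments, paths = paths, nodes = nodes,
                 area_mm2 = area_mm2, pixel_size_um = pixel_size_um, dim = dim),
            class = "skeleton_graph")
}

.empty_segments_df <- function() {
  data.frame(segment_id = integer(0), category = character(0),
             c_um = numeric(0), d_um = numeric(0),
             h_um = numeric(0), w_um = numeric(0),
             n_px = integer(0), stringsAsFactors = FALSE)
}

#' Construct a skeleton graph from per-segment measurements
#'
#' Programmatic constructor used when segment geometry is already known (e.g.
#' when re-filtering exported tables). `build_graph()` is the usual entry
#' point from a pixel skeleton.
#'
#' @param segments data frame with columns `category`, `c_um`, `d_um`, and
#'   optionally `h_um`, `w_um`.
#' @param area_mm2 image area in square millimetres.
#' @param pixel_size_um calibration (used only for reporting).
#' @param paths optional list of pixel paths (n x 2 matrices), one per segment.
#' @return A `skeleton_graph`.
#' @export
skeleton_graph <- function(segments, area_mm2, pixel_size_um = 1, paths = NULL) {
  stopifnot(is.data.frame(segments), area_mm2 > 0)
  if (is.null(segments$h_um)) segments$h_um <- rep(0, nrow(segments)) + segments$d_um
  if (is.null(segments$w_um)) segments$w_um <- rep(0, nrow(segments))
  if (is.null(segments$segment_id)) segments$segment_id <- seq_len(nrow(segments))
  if (is.null(segments$n_px)) segments$n_px <- rep(NA_integer_, nrow(segments))
  if (is.null(paths)) paths <- vector("list", nrow(segments))
  .new_skeleton_graph(segments, paths, nodes = NULL, area_mm2 = area_mm2,
                      pixel_size_um = pixel_size_um, dim = NULL)
}

#' Trace a skeleton into categorized edge segments
#'
#' Pixel degree is computed in 8-connectivity. Degree-1 pixels are endpoints;
#' pixels of degree >= 3 are junction pixels, with 8-adjacent junction pixels
#' merged into one junction node at their centroid. Segments are maximal
#' degree-2 chains between nodes (the traced path excludes junction pixels but
#' includes endpoints); closed degree-2 loops become `isolated_cycle` segments.
#' Path length `c_um` is the arc length of the traced path after light
#' moving-average smoothing (see `smooth_window`); chord `d_um` and its signed
#' vertical/horizontal components `h_um`/`w_um` come from the path ends.
#' Isolated single pixels are discarded as noise, as are zero-length artifacts.
#'
#' @param S a [skeletonize()] / [clear_border()] skeleton.
#' @param smooth_window odd moving-average window (in pixels) applied to each
#'   traced path before measuring arc length; 1 gives the raw 1 / sqrt(2)
#'   chain-code length. Default 5 suppresses raster staircase bias.
#' @return A `skeleton_graph`: `segments` (data frame), `paths` (list of pixel
#'   coordinate matrices), `nodes` (data frame), `area_mm2`.
#' @export
build_graph <- function(S, smooth_window = 5L) {
  mask <- S$mask
  ps <- S$pixel_size_um
  nr <- nrow(mask); nc <- ncol(mask)
  num <- matrix(as.numeric(mask), nr, nc)
  if (any(mask & shift_mat(num, -1, 0) > 0 & shift_mat(num, 0, -1) > 0 &
          shift_mat(num, -1, -1) > 0)) {
    stop("non-thin input: skeleton contains a 2x2 block")
  }
  area_mm2 <- nr * nc * ps^2 / 1e6
  idx <- which(mask)
  n <- length(idx)
  segs <- .empty_segments_df()
  paths <- list()
  nodes <- data.frame(node_id = integer(0), type = character(0),
                      r = numeric(0), c = numeric(0), n_px = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(.new_skeleton_graph(segs, paths, nodes, area_mm2, ps, c(nr, nc)))

  id <- matrix(0L, nr, nc)
  id[idx] <- seq_len(n)
  rc <- arrayInd(idx, c(nr, nc))
  # neighbour table: n x 8 of pixel ids (0 = none)
  nbr <- matrix(0L, n, 8L)
  for (k in seq_len(8L)) {
    sh <- shift_mat(id, -.OFF8[k, 1L], -.OFF8[k, 2L], fill = 0L)
    nbr[, k] <- sh[idx]
  }
  deg <- rowSums(nbr > 0L)

  is_node <- deg == 1L | deg >= 3L
  node_of <- integer(n)  # 0 for chain pixels
  node_type <- character(0)
  next_node <- 0L
  # endpoints: one node each
  for (i in which(deg == 1L)) {
    next_node <- next_node + 1L
    node_of[i] <- next_node
    node_type[next_node] <- "endpoint"
  }
  # junction clusters: 8-adjacent junction pixels merge
  junc <- which(deg >= 3L)
  if (length(junc)) {
    in_junc <- logical(n); in_junc[junc] <- TRUE
    jid <- match(seq_len(n), junc)  # pixel -> position in junc (NA otherwise)
    from <- integer(0); to <- integer(0)
    for (k in seq_len(8L)) {
      a <- junc
      b <- nbr[junc, k]
      okp <- b > 0L & in_junc[pmax(b, 1L)]
      if (any(okp)) {
        from <- c(from, jid[a[okp]])
        to <- c(to, jid[b[okp]])
      }
    }
    g <- igraph::make_empty_graph(n = length(junc), directed = FALSE)
    if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
    memb <- igraph::components(g)$membership
    for (cl in seq_len(max(memb))) {
      next_node <- next_node + 1L
      node_of[junc[memb == cl]] <- next_node
      node_type[next_node] <- "junction"
    }
  }

  visited <- logical(n)     # chain (degree-2) pixels consumed by a trace
  seg_list <- list()
  add_segment <- function(path_ids, type_a, type_b, closed = FALSE) {
    coords <- rc[path_ids, , drop = FALSE]
    if (closed) coords <- rbind(coords, coords[1L, , drop = FALSE])
    if (nrow(coords) < 2L) return(invisible(NULL))  # zero-length artifact
    sm <- smooth_path(coords, window = smooth_window, closed = closed)
    c_um <- path_length(sm) * ps
    if (c_um <= 0) return(invisible(NULL))
    h <- (coords[nrow(coords), 1L] - coords[1L, 1L]) * ps
    w <- (coords[nrow(coords), 2L] - coords[1L, 2L]) * ps
    d_um <- if (closed) 0 else sqrt(h^2 + w^2)
    category <- if (closed) "isolated_cycle"
    else if (type_a == "endpoint" && type_b == "endpoint") "endpoint_to_endpoint"
    else if (type_a == "junction" && type_b == "junction") "junction_to_junction"
    else "junction_to_endpoint"
    seg_list[[length(seg_list) + 1L]] <<- list(
      category = category, c_um = c_um, d_um = d_um, h_um = h, w_um = w,
      n_px = nrow(coords) - as.integer(closed), path = coords)
    invisible(NULL)
  }

  other_neighbor <- function(i, not) {
    nb <- nbr[i, ]
    nb <- nb[nb > 0L]
    nb[nb != not][1L]
  }

  node_px <- which(is_node)
  done_pairs <- character(0)
  for (u in node_px) {
    for (v in nbr[u, ]) {
      if (v == 0L) next
      if (is_node[v]) {
        if (node_of[v] == node_of[u]) next  # same junction cluster
        key <- paste(min(u, v), max(u, v))
        if (key %in% done_pairs) next
        done_pairs <- c(done_pairs, key)
        # direct node-node adjacency: keep only the endpoint pixels
        keep <- c(if (node_type[node_of[u]] == "endpoint") u,
                  if (node_type[node_of[v]] == "endpoint") v)
        if (length(keep) == 2L) {
          add_segment(keep, "endpoint", "endpoint")
        }
        # endpoint-junction or junction-junction direct contacts are
        # zero-length artifacts and are dropped
        next
      }
      if (visited[v]) next
      # walk the degree-2 chain starting at v
      chain <- integer(0)
      prev <- u; cur <- v
      repeat {
        visited[cur] <- TRUE
        chain <- c(chain, cur)
        nxt <- other_neighbor(cur, prev)
        if (is.na(nxt)) { nxt <- 0L; break }       # dangling (shouldn't happen)
        if (is_node[nxt]) break
        prev <- cur; cur <- nxt
      }
      ta <- node_type[node_of[u]]
      if (nxt == 0L) {
        tb <- "endpoint"
        term <- integer(0)
      } else {
        tb <- node_type[node_of[nxt]]
        term <- if (tb == "endpoint") nxt else integer(0)
      }
      path_ids <- c(if (ta == "endpoint") u, chain, term)
      add_segment(path_ids, ta, tb)
    }
  }

  # remaining unvisited degree-2 pixels form pure cycles
  for (s in which(deg == 2L & !visited)) {
    if (visited[s]) next
    chain <- s
    visited[s] <- TRUE
    prev <- s
    cur <- nbr[s, ][nbr[s, ] > 0L][1L]
    while (cur != s) {
      visited[cur] <- TRUE
      chain <- c(chain, cur)
      nxt <- other_neighbor(cur, prev)
      prev <- cur; cur <- nxt
    }
    add_segment(chain, NA, NA, closed = TRUE)
  }

  if (length(seg_list)) {
    segs <- data.frame(
      segment_id = seq_along(seg_list),
      category = vapply(seg_list, `[[`, "", "category"),
      c_um = vapply(seg_list, `[[`, 0, "c_um"),
      d_um = vapply(seg_list, `[[`, 0, "d_um"),
      h_um = vapply(seg_list, `[[`, 0, "h_um"),
      w_um = vapply(seg_list, `[[`, 0, "w_um"),
      n_px = vapply(seg_list, `[[`, 0L, "n_px"),
      stringsAsFactors = FALSE)
    paths <- lapply(seg_list, `[[`, "path")
  }
  if (next_node > 0L) {
    nodes <- do.call(rbind, lapply(seq_len(next_node), function(nd) {
      pix <- which(node_of == nd)
      data.frame(node_id = nd, type = node_type[nd],
                 r = mean(rc[pix, 1L]), c = mean(rc[pix, 2L]),
                 n_px = length(pix), stringsAsFactors = FALSE)
    }))
  }
  .new_skeleton_graph(segs, paths, nodes, area_mm2, ps, c(nr, nc))
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d segment(s) over %.4g mm^2\n",
              nrow(x$segments), x$area_mm2))
  if (nrow(x$segments)) print(table(x$segments$category))
  invisible(x)
}

#' @export
as.data.frame.skeleton_graph <- function(x, ...) {
  out <- x$segments
  out$tortuosity <- tortuosity(out$c_um, out$d_um)
  out$orientation_rad <- ifelse(out$d_um > 0,
                                fold_angle(atan2(out$h_um, out$w_um)), NA_real_)
  out
}

#' Exclude short edge segments
#'
#' A segment is removed iff its path length is below `min_length_um` *or* its
#' end-to-end chord is below `min_chord_um`. Isolated cycles (chord 0) are
#' therefore always removed under the defaults.
#'
#' @param G a [build_graph()] result.
#' @param min_length_um minimum traced path length in micrometres.
#' @param min_chord_um minimum end-to-end Euclidean distance in micrometres.
#' @return A filtered `skeleton_graph`.
#' @export
filter_segments <- function(G, min_length_um = 100, min_chord_um = 50) {
  if (min_length_um < 0 || min_chord_um < 0) stop("thresholds must be non-negative")
  keep <- G$segments$c_um >= min_length_um & G$segments$d_um >= min_chord_um
  G$segments <- G$segments[keep, , drop = FALSE]
  if (nrow(G$segments)) G$segments$segment_id <- seq_len(nrow(G$segments))
  G$paths <- G$paths[keep]
  G
}
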