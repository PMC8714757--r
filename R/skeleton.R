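# Topology-preserving thinning and centerline graph extraction.

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighborhood offsets in Zhang-Suen order P2..P9
# (clockwise starting north; row axis points down the image).
.zs_offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

zhang_suen <- function(m) {
  m <- as_binary(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(.zs_offsets, function(o) shift_mat(m, -o[1], -o[2]))
      B <- Reduce(`+`, P)
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (!P[[i]]) & P[[if (i == 8) 1 else i + 1]]
      }))
      if (step == 1) {
        c3 <- !(P[[1]] & P[[3]] & P[[5]])  # P2*P4*P6 == 0
        c4 <- !(P[[3]] & P[[5]] & P[[7]])  # P4*P6*P8 == 0
      } else {
        c3 <- !(P[[1]] & P[[3]] & P[[7]])  # P2*P4*P8 == 0
        c4 <- !(P[[1]] & P[[5]] & P[[7]])  # P2*P6*P8 == 0
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Neighbor count within the skeleton for each skeleton pixel.
skeleton_degree <- function(skel) {
  B <- Reduce(`+`, lapply(.zs_offsets, function(o) shift_mat(skel, -o[1], -o[2])))
  B[!skel] <- 0L
  B
}

# Crossing number: 0->1 transitions around the 8-neighborhood. Unlike the raw
# neighbor count it does not over-count the redundant diagonal links next to
# a junction: 1 = endpoint, 2 = regular path pixel, >= 3 = branch point.
crossing_number <- function(skel) {
  P <- lapply(.zs_offsets, function(o) shift_mat(skel, -o[1], -o[2]))
  A <- Reduce(`+`, lapply(1:8, function(i) {
    (!P[[i]]) & P[[if (i == 8) 1 else i + 1]]
  }))
  A[!skel] <- 0L
  A
}

# Trace node-to-node paths through an 8-connected skeleton.
# Returns a list of integer matrices (n x 2, row/col), each path spanning two
# nodes (branch point or endpoint); isolated cycles are returned closed.
trace_segments <- function(skel) {
  nr <- nrow(skel)
  pix <- which(skel)
  if (length(pix) == 0) return(list())
  deg <- crossing_number(skel)
  id <- matrix(0L, nr, ncol(skel))
  id[pix] <- seq_along(pix)
  pr <- ((pix - 1) %% nr) + 1
  pc <- ((pix - 1) %/% nr) + 1

  neigh <- function(r, c) {
    out <- matrix(0L, 0, 2)
    for (o in .zs_offsets) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(skel) && skel[rr, cc])
        out <- rbind(out, c(rr, cc))
    }
    out
  }
  # visited[i, k]: edge from pixel i along direction k consumed
  visited <- matrix(FALSE, length(pix), 8)
  dir_of <- function(from, to) {
    d <- c(to[1] - from[1], to[2] - from[2])
    for (k in 1:8) if (all(.zs_offsets[[k]] == d)) return(k)
    stop("not adjacent")
  }
  mark <- function(from, to) {
    visited[id[from[1], from[2]], dir_of(from, to)] <<- TRUE
    visited[id[to[1], to[2]], dir_of(to, from)] <<- TRUE
  }

  walk <- function(start, nxt) {
    path <- list(start, nxt)
    mark(start, nxt)
    prev <- start; cur <- nxt
    while (deg[cur[1], cur[2]] == 2 && !all(cur == start)) {
      nb <- neigh(cur[1], cur[2])
      keep <- !(nb[, 1] == prev[1] & nb[, 2] == prev[2])
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0) break
      if (nrow(nb) > 1) {
        # redundant diagonal links next to a junction: prefer the orthogonal
        # continuation
        orth <- abs(nb[, 1] - cur[1]) + abs(nb[, 2] - cur[2]) == 1
        if (any(orth)) nb <- nb[orth, , drop = FALSE]
      }
      nxt <- nb[1, ]
      if (visited[id[cur[1], cur[2]], dir_of(cur, nxt)]) break
      mark(cur, nxt)
      path[[length(path) + 1]] <- nxt
      prev <- cur; cur <- nxt
    }
    do.call(rbind, path)
  }

  segments <- list()
  node_idx <- which(deg[pix] != 2L)
  for (i in node_idx) {
    r <- pr[i]; c <- pc[i]
    nb <- neigh(r, c)
    if (nrow(nb) == 0) next  # isolated pixel: no segment
    for (j in seq_len(nrow(nb))) {
      if (!visited[i, dir_of(c(r, c), nb[j, ])])
        segments[[length(segments) + 1]] <- walk(c(r, c), nb[j, ])
    }
  }
  # pure cycles: every pixel has degree 2, never touched above
  for (i in seq_along(pix)) {
    if (deg[pix[i]] == 2L && !any(visited[i, ])) {
      r <- pr[i]; c <- pc[i]
      nb <- neigh(r, c)
      segments[[length(segments) + 1]] <- walk(c(r, c), nb[1, ])
    }
  }
  segments
}

path_arclength <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

#' Skeletonize a vessel map into a centerline segment graph
#'
#' Thins the binary vessel mask to one-pixel-wide centerlines (Zhang-Suen
#' topology-preserving thinning), measures a per-centerline-pixel vessel
#' half-width from the Euclidean distance transform of the mask, prunes
#' short terminal spurs, and decomposes the skeleton into node-to-node
#' segments (nodes are branch points and endpoints).
#'
#' The radius at a skeleton pixel is the distance to the nearest background
#' pixel minus half a pixel, so a bar of width `w` pixels has centerline
#' radius `w / 2`.
#'
#' @param map a [vessel_map()], or a binary matrix (1 = vessel).
#' @param prune_px terminal spurs strictly shorter than this many pixels of
#'   arclength are removed (default 5).
#' @return An object of class `vessel_graph`: `skeleton` (logical matrix),
#'   `segments` (list of n x 2 path matrices), `radius` (matrix of
#'   half-widths in px, `NA` off the skeleton), `empty` flag, and the input
#'   mask dimensions. An empty mask yields a flagged-empty graph, not an
#'   error.
#' @examples
#' m <- matrix(0, 20, 40); m[9:13, 5:35] <- 1
#' g <- skeletonize(m)
#' length(g$segments)
#' @export
skeletonize <- function(map, prune_px = 5) {
  m <- if (inherits(map, "vessel_map")) map$pixels else map
  if (!is_binary_matrix(m)) stop_validation("vessel map must be a binary matrix")
  m <- as_binary(m)
  if (!any(m)) {
    return(structure(list(skeleton = m, segments = list(),
                          radius = matrix(NA_real_, nrow(m), ncol(m)),
                          empty = TRUE, dim = dim(m)),
                     class = "vessel_graph"))
  }
  skel <- zhang_suen(m)
  segs <- trace_segments(skel)
  # prune terminal spurs shorter than prune_px
  deg <- crossing_number(skel)
  is_spur <- vapply(segs, function(p) {
    ends_deg <- c(deg[p[1, 1], p[1, 2]], deg[p[nrow(p), 1], p[nrow(p), 2]])
    any(ends_deg == 1L) && path_arclength(p) < prune_px
  }, logical(1))
  if (any(is_spur)) {
    for (p in segs[is_spur]) {
      # keep the junction end so remaining segments stay connected
      drop <- p
      if (deg[p[1, 1], p[1, 2]] > 1L) drop <- drop[-1, , drop = FALSE]
      n <- nrow(drop)
      if (n > 0 && deg[p[nrow(p), 1], p[nrow(p), 2]] > 1L)
        drop <- drop[-n, , drop = FALSE]
      skel[drop] <- FALSE
    }
    segs <- trace_segments(skel)
  }
  d <- as.matrix(EBImage::distmap(m * 1))
  # Half-width at a skeleton pixel: distance to the nearest background pixel
  # center minus half a pixel. When the true centerline falls between two
  # pixel rows (even vessel widths) the thinning keeps one of two equal-EDT
  # pixels; an off-skeleton neighbor with EDT >= our own marks that case and
  # the ridge lies half a pixel away, so half a pixel is added back.
  plateau <- Reduce(`|`, lapply(.zs_offsets, function(o) {
    shift_mat(!skel & m, -o[1], -o[2]) & (d <= shift_mat(d, -o[1], -o[2]))
  }))
  rad <- matrix(NA_real_, nrow(m), ncol(m))
  rad[skel] <- pmax(d[skel] - 0.5 + 0.5 * plateau[skel], 0.5)
  structure(list(skeleton = skel, segments = segs, radius = rad,
                 empty = !any(skel), dim = dim(m)),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat("vessel graph:", sum(x$skeleton), "skeleton px,",
      length(x$segments), "segments",
      if (x$empty) "(empty)" else "", "\n")
  invisible(x)
}
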