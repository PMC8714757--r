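#' Binary macular vessel map
#'
#' Couples a binary vessel raster with its ETDRS grid specification and eye
#' metadata. Any nonzero pixel counts as vessel.
#'
#' @param pixels binary matrix (1/TRUE = vessel).
#' @param spec a [grid_spec()] whose `image_shape` matches `dim(pixels)`.
#' @param subject_id,eye optional metadata carried into metric records.
#' @return An object of class `vessel_map`.
#' @export
vessel_map <- function(pixels, spec, subject_id = NA_character_, eye = NULL) {
  if (!is_binary_matrix(pixels)) stop_validation("pixels must be a binary matrix")
  if (!inherits(spec, "grid_spec")) stop_validation("spec must be a grid_spec")
  if (!all(dim(pixels) == spec$image_shape))
    stop_validation("pixel raster shape does not match spec$image_shape")
  eye <- if (is.null(eye)) spec$laterality else match.arg(eye, c("OD", "OS"))
  structure(list(pixels = as_binary(pixels), spec = spec,
                 subject_id = subject_id, eye = eye),
            class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat("vessel map:", nrow(x$pixels), "x", ncol(x$pixels), "px,",
      sum(x$pixels), "vessel px,", x$eye,
      if (!is.na(x$subject_id)) paste0("(", x$subject_id, ")"), "\n")
  invisible(x)
}

#' Box-counting fractal dimension of a point set
#'
#' Counts the number `N(eps)` of `eps x eps` boxes containing at least one
#' point, for box sides `eps = 2, 4, 8, ...` up to a quarter of the longer
#' side of the region bounding box, with the box grid anchored at the
#' bounding-box origin. The dimension is the least-squares slope of
#' `log N(eps)` against `log(1/eps)`: it measures the space-filling
#' complexity of the vessel skeleton.
#'
#' @param points n x 2 matrix of (row, col) pixel coordinates.
#' @param region_mask logical matrix delimiting the region; its bounding box
#'   anchors the box grid and bounds the scales.
#' @return A list with `value` (the dimension, `NA` if undefined), `defined`,
#'   and the per-scale counts (`eps`, `counts`). Undefined when the point set
#'   is empty or fewer than 4 scales have nonzero counts.
#' @examples
#' mask <- matrix(TRUE, 64, 64)
#' pts <- cbind(32, 1:64)                  # a line has dimension 1
#' box_counting_dimension(pts, mask)$value
#' @export
box_counting_dimension <- function(points, region_mask) {
  if (is.null(points) || NROW(points) == 0)
    return(list(value = NA_real_, defined = FALSE, eps = numeric(0),
                counts = integer(0)))
  points <- matrix(as.numeric(points), ncol = 2)
  idx <- which(region_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_validation("region mask is empty")
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  side <- max(max(idx[, 1]) - r0, max(idx[, 2]) - c0) + 1
  eps <- 2^(1:30)
  eps <- eps[eps <= side / 4]
  counts <- vapply(eps, function(e) {
    bx <- floor((points[, 1] - r0) / e)
    by <- floor((points[, 2] - c0) / e)
    length(unique(bx * 2^16 + by))
  }, numeric(1))
  keep <- counts > 0
  if (sum(keep) < 4)
    return(list(value = NA_real_, defined = FALSE, eps = eps, counts = counts))
  fit <- stats::lm.fit(cbind(1, log(1 / eps[keep])), log(counts[keep]))
  list(value = unname(fit$coefficients[2]), defined = TRUE,
       eps = eps, counts = counts)
}

#' Vessel area rate of a region
#'
#' The fraction of the region's pixels occupied by vessel: an exact
#' integer-count ratio.
#'
#' @param map a [vessel_map()] or binary matrix.
#' @param region_mask nonempty logical matrix of the same shape.
#' @return A single number in `[0, 1]`.
#' @export
vessel_area_rate <- function(map, region_mask) {
  m <- if (inherits(map, "vessel_map")) map$pixels else as_binary(map)
  n <- sum(region_mask)
  if (n == 0) stop_validation("region mask is empty")
  sum(m & region_mask) / n
}

#' Mean vessel diameter of a region
#'
#' Averages twice the centerline half-width over all skeleton pixels inside
#' the region, converted to mm. Averaging per skeleton pixel makes the
#' estimate length-weighted automatically.
#'
#' @param graph a [skeletonize()] result.
#' @param region_mask logical matrix.
#' @param scale_mm_per_px physical scale.
#' @return List with `value` (mm) and `defined`; undefined when the region
#'   holds no skeleton pixels.
#' @export
mean_diameter <- function(graph, region_mask, scale_mm_per_px) {
  sel <- graph$skeleton & region_mask
  if (!any(sel)) return(list(value = NA_real_, defined = FALSE))
  list(value = mean(2 * graph$radius[sel]) * scale_mm_per_px, defined = TRUE)
}

# Resample a polyline (n x 2) at m+1 equally spaced arclength stations.
resample_path <- function(path, m) {
  d <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(d))
  L <- s[length(s)]
  st <- seq(0, L, length.out = m + 1)
  cbind(stats::approx(s, path[, 1], xout = st, ties = "ordered")$y,
        stats::approx(s, path[, 2], xout = st, ties = "ordered")$y)
}

wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Subdivision tortuosity of one vessel segment
#'
#' Scores a centerline path by chord-angle accumulation over dyadic
#' subdivisions: at level `k` the path is split into `2^k` equal-arclength
#' chords and the absolute turning angles between consecutive chords are
#' summed; the base score `T` is the maximum over levels
#' `k = 1..K`, `K = min(6, floor(log2(L / 4)))` (at least one level is always
#' evaluated). `T` is then scaled by a sigmoid of the inflection count `m`
#' (sign changes of the discrete curvature along the finest-level chords):
#' `tau = T * 2 / (1 + exp(-m / 2))`, so an inflection-free arc is
#' unpenalized (`g(0) = 1`) and the factor saturates at 2. Straight paths
#' score exactly 0.
#'
#' @param path n x 2 matrix of ordered (row, col) coordinates (pixel units,
#'   possibly fractional), arclength >= 4 px and at least 4 points.
#' @return List with `tau`, base score `T`, inflection count `m`, and the
#'   arclength `length_px`.
#' @export
segment_tortuosity <- function(path) {
  path <- matrix(as.numeric(path), ncol = 2)
  L <- path_arclength(path)
  if (nrow(path) < 4 || L < 4)
    stop_validation("path must have >= 4 points and >= 4 px of arclength")
  K <- max(1, min(6, floor(log2(L / 4))))
  Tk <- numeric(K)
  finest <- NULL
  for (k in seq_len(K)) {
    pts <- resample_path(path, 2^k)
    v <- diff(pts)
    th <- atan2(v[, 1], v[, 2])
    Tk[k] <- if (nrow(v) < 2) 0 else sum(abs(wrap_angle(diff(th))))
    if (k == K) finest <- v
  }
  Tbase <- max(Tk)
  m <- 0L
  if (nrow(finest) >= 3) {
    cr <- finest[-nrow(finest), 2] * finest[-1, 1] -
          finest[-nrow(finest), 1] * finest[-1, 2]
    sg <- sign(cr)
    sg <- sg[sg != 0]
    if (length(sg) >= 2) m <- sum(diff(sg) != 0)
  }
  list(tau = Tbase * 2 / (1 + exp(-m / 2)), T = Tbase, m = m, length_px = L)
}

# Maximal in-mask sub-paths of a (possibly fractional-coordinate) path.
clip_path_to_mask <- function(path, mask) {
  ri <- round(path[, 1]); ci <- round(path[, 2])
  ok <- ri >= 1 & ri <= nrow(mask) & ci >= 1 & ci <= ncol(mask)
  inside <- ok
  inside[ok] <- mask[cbind(ri[ok], ci[ok])]
  if (!any(inside)) return(list())
  rl <- rle(inside)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  out <- list()
  for (i in seq_along(rl$values)) {
    if (rl$values[i])
      out[[length(out) + 1]] <- path[starts[i]:ends[i], , drop = FALSE]
  }
  out
}

#' Region tortuosity
#'
#' Clips every skeleton segment to its maximal sub-paths inside the region
#' mask, scores each eligible sub-path (arclength >= 4 px) with
#' [segment_tortuosity()], and returns the arclength-weighted mean.
#'
#' @param graph a [skeletonize()] result.
#' @param region_mask logical matrix.
#' @return List with `value`, `defined` and the number of eligible sub-paths
#'   `n_segments`; undefined when no eligible segment intersects the mask.
#' @export
region_tortuosity <- function(graph, region_mask) {
  taus <- numeric(0); lens <- numeric(0)
  for (seg in graph$segments) {
    for (sub in clip_path_to_mask(seg, region_mask)) {
      if (nrow(sub) >= 4 && path_arclength(sub) >= 4) {
        st <- segment_tortuosity(sub)
        taus <- c(taus, st$tau); lens <- c(lens, st$length_px)
      }
    }
  }
  if (length(taus) == 0)
    return(list(value = NA_real_, defined = FALSE, n_segments = 0L))
  list(value = sum(taus * lens) / sum(lens), defined = TRUE,
       n_segments = length(taus))
}

#' Quantify macular vascular geometry per ETDRS region
#'
#' Computes fractal dimension (`Df`), vessel area rate (`VAR`), mean vessel
#' diameter (`Dm`, mm) and tortuosity (`tau`) for the 8 ETDRS quadrant
#' sectors and the composites `inner_ring`, `outer_ring` and `whole`.
#' Fractal dimension and tortuosity are computed from the skeleton points
#' and segments masked to each region; metrics that are undefined in a
#' region (no vessel / no skeleton there) are flagged, never reported as 0.
#'
#' @param map a [vessel_map()].
#' @param grid an [build_grid()] result sharing the map's shape; built from
#'   `map$spec` when omitted.
#' @param graph optionally a precomputed [skeletonize()] result.
#' @param regions regions to quantify (default: all 8 quadrant sectors plus
#'   the 3 composites).
#' @return An object of class `sector_metrics`: a data frame with one row per
#'   region x metric (`subject_id, eye, region, metric, value, defined`).
#' @export
quantify <- function(map, grid = NULL, graph = NULL, regions = NULL) {
  if (is.null(regions)) regions <- .all_regions
  if (!all(regions %in% .all_regions))
    stop_validation("unknown region name(s): ",
                    paste(setdiff(regions, .all_regions), collapse = ", "))
  if (!inherits(map, "vessel_map")) stop_validation("map must be a vessel_map")
  if (is.null(grid)) grid <- build_grid(map$spec)
  if (!all(dim(map$pixels) == dim(grid$labels)))
    stop_validation("map and grid shapes differ")
  if (is.null(graph)) graph <- skeletonize(map)
  scale <- map$spec$scale_mm_per_px
  skel_pts <- which(graph$skeleton, arr.ind = TRUE)

  rows <- list()
  for (region in regions) {
    mask <- grid$masks[[region]]
    pts <- skel_pts[mask[skel_pts], , drop = FALSE]
    df <- box_counting_dimension(pts, mask)
    var <- vessel_area_rate(map, mask)
    dm <- mean_diameter(graph, mask, scale)
    tau <- region_tortuosity(graph, mask)
    rows[[region]] <- data.frame(
      subject_id = map$subject_id, eye = map$eye, region = region,
      metric = c("Df", "VAR", "Dm", "tau"),
      value = c(df$value, var, dm$value, tau$value),
      defined = c(df$defined, TRUE, dm$defined, tau$defined),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sector_metrics", "data.frame")
  out
}

#' @export
print.sector_metrics <- function(x, ...) {
  cat("sector metrics for", x$subject_id[1], x$eye[1], "\n")
  wide <- stats::reshape(as.data.frame(x)[c("region", "metric", "value")],
                         idvar = "region", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}
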