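# Brute-force oracles and fixture builders, independent of the package's
# own implementation paths.

# Exact box counts: unique occupied boxes by direct string keying.
brute_box_counts <- function(points, origin, eps) {
  vapply(eps, function(e) {
    keys <- paste(floor((points[, 1] - origin[1]) / e),
                  floor((points[, 2] - origin[2]) / e))
    length(unique(keys))
  }, numeric(1))
}

# Exact distance from each foreground pixel to the nearest background pixel
# center, by full scan. Small images only.
brute_nearest_bg <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# Horizontal bar of the given pixel width centered at row `row`.
make_bar <- function(nr, nc, row, width, c0 = 4, c1 = nc - 3) {
  m <- matrix(0, nr, nc)
  half <- (width - 1) / 2
  m[(row - floor(half)):(row + ceiling(half)), c0:c1] <- 1
  m
}

# Sierpinski triangle point set on a 2^k x 2^k lattice (1-based coords).
sierpinski_points <- function(k = 8) {
  pts <- as.matrix(expand.grid(0:(2^k - 1), 0:(2^k - 1)))
  pts[bitwAnd(pts[, 1], pts[, 2]) == 0, ] + 1
}

# Sampled sinusoid path: `periods` full periods, amplitude `a` px,
# along a straight run of length `len` px.
sine_path <- function(a, periods, len = 60, n = 400) {
  t <- seq(0, 1, length.out = n)
  cbind(a * sin(2 * pi * periods * t), len * t)
}

rotate_path <- function(path, theta) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  path %*% t(R)
}

# A grid spec centered in a square raster: 201 px at 0.03 mm/px spans the
# full 6 mm circle with a margin.
small_spec <- function(laterality = "OD", scale = 0.03, n = 201) {
  grid_spec(c((n + 1) / 2, (n + 1) / 2), scale, laterality, c(n, n))
}

# Minimal stand-in vessel graph for region aggregation tests.
fake_graph <- function(segments, dim = c(100, 100)) {
  structure(list(skeleton = NULL, segments = segments, radius = NULL,
                 empty = length(segments) == 0, dim = dim),
            class = "vessel_graph")
}
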