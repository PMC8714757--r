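test_that("box-counting dimension recovers line, square and Sierpinski", {
  mask256 <- matrix(TRUE, 256, 256)

  line <- cbind(128, 1:256)
  bc <- box_counting_dimension(line, mask256)
  expect_true(bc$defined)
  expect_lt(abs(bc$value - 1), 0.05)
  # oracle: exact counts N(eps) = 256/eps for an axis-aligned line
  expect_equal(bc$counts, 256 / bc$eps)

  sq <- as.matrix(expand.grid(1:128, 1:128))
  bc2 <- box_counting_dimension(sq, matrix(TRUE, 128, 128))
  expect_lt(abs(bc2$value - 2), 0.10)
  expect_equal(bc2$counts, (128 / bc2$eps)^2)

  sier <- sierpinski_points(8)
  bc3 <- box_counting_dimension(sier, mask256)
  expect_lt(abs(bc3$value - log2(3)), 0.1)
  # dual route: counts match the brute-force box occupancy oracle
  expect_equal(bc3$counts, brute_box_counts(sier, c(1, 1), bc3$eps))
})

test_that("box-counting flags degenerate inputs instead of guessing", {
  expect_false(box_counting_dimension(matrix(0, 0, 2), matrix(TRUE, 64, 64))$defined)
  # region too small for 4 dyadic scales
  small <- box_counting_dimension(cbind(1:10, 1:10), matrix(TRUE, 10, 10))
  expect_false(small$defined)
  expect_error(box_counting_dimension(cbind(1, 1), matrix(FALSE, 8, 8)),
               class = "macvasc_validation_error")
})

test_that("vessel area rate is exact integer-count arithmetic", {
  mask <- matrix(FALSE, 10, 10); mask[3:8, 3:8] <- TRUE
  full <- matrix(1, 10, 10)
  expect_identical(vessel_area_rate(full, mask), 1)
  expect_identical(vessel_area_rate(matrix(0, 10, 10), mask), 0)
  half <- matrix(0, 10, 10); half[3:5, 3:8] <- 1     # 18 of 36 mask pixels
  expect_identical(vessel_area_rate(half, mask), 0.5)
  set.seed(11)
  rnd <- matrix(rbinom(100, 1, 0.4), 10, 10)
  expect_identical(vessel_area_rate(rnd, mask), sum(rnd[mask]) / 36)
  expect_error(vessel_area_rate(full, matrix(FALSE, 10, 10)),
               class = "macvasc_validation_error")
})

test_that("mean diameter tracks analytic bar widths within 1 px * scale", {
  scale <- 0.01
  for (w in c(3, 5, 7, 9, 11, 15)) {
    m <- make_bar(2 * w + 11, 60, w + 6, w)
    g <- skeletonize(m)
    dm <- mean_diameter(g, matrix(TRUE, nrow(m), 60), scale)
    expect_true(dm$defined)
    expect_lt(abs(dm$value - w * scale), 1 * scale)
  }
  # two bars, widths 4 and 8, equal skeleton lengths -> mean 0.06 mm
  m <- matrix(0, 40, 60)
  m[5:8, 6:55] <- 1
  m[20:27, 6:55] <- 1
  g <- skeletonize(m)
  dm <- mean_diameter(g, matrix(TRUE, 40, 60), scale)
  expect_lt(abs(dm$value - 0.06), 0.01)
  # empty region flag
  expect_false(mean_diameter(g, matrix(FALSE, 40, 60), scale)$defined)
})

test_that("straight segments score zero tortuosity; arcs score positive", {
  expect_identical(segment_tortuosity(cbind(5, seq(1, 40, 0.5)))$tau, 0)
  diag_path <- cbind(seq(0, 30, 0.25), seq(0, 60, 0.5))
  expect_lt(segment_tortuosity(diag_path)$tau, 1e-10)
  # half-sine arc: no curvature sign change, so g(m) = 1 and tau = T > 0
  t <- seq(0, pi, length.out = 300)
  arc <- cbind(8 * sin(t), 40 * t / pi)
  st <- segment_tortuosity(arc)
  expect_identical(st$m, 0L)
  expect_identical(st$tau, st$T)
  expect_gt(st$tau, 0)
  expect_error(segment_tortuosity(cbind(1, 1:3)),
               class = "macvasc_validation_error")
})

test_that("tortuosity is monotone in amplitude and in inflection count", {
  taus_amp <- vapply(c(2, 5, 10, 15), function(a)
    segment_tortuosity(sine_path(a, 2))$tau, numeric(1))
  expect_true(all(diff(taus_amp) > 0))
  taus_per <- vapply(c(1, 2, 3), function(p)
    segment_tortuosity(sine_path(6, p, len = 90, n = 600))$tau, numeric(1))
  expect_true(all(diff(taus_per) > 0))
  # more inflections are penalized through the sigmoid factor
  m1 <- segment_tortuosity(sine_path(6, 1, len = 90, n = 600))$m
  m3 <- segment_tortuosity(sine_path(6, 3, len = 90, n = 600))$m
  expect_gt(m3, m1)
})

test_that("tortuosity is invariant under reversal and rigid rotation", {
  p <- sine_path(7, 2)
  st <- segment_tortuosity(p)
  expect_equal(segment_tortuosity(p[nrow(p):1, ])$tau, st$tau, tolerance = 1e-8)
  for (theta in c(0.3, 1.1, 2.5)) {
    rot <- segment_tortuosity(rotate_path(p, theta))$tau
    expect_lt(abs(rot / st$tau - 1), 0.05)
  }
})

test_that("region tortuosity is the arclength-weighted segment mean", {
  mask <- matrix(TRUE, 200, 200)
  straight <- list(cbind(10, 5:60), cbind(30:80, 20))
  expect_identical(region_tortuosity(fake_graph(straight), mask)$value, 0)
  # one curved segment fully inside: region value equals its own tau
  curve <- sine_path(6, 2) + 40
  rt <- region_tortuosity(fake_graph(list(curve)), mask)
  expect_equal(rt$value, segment_tortuosity(curve)$tau, tolerance = 1e-12)
  # equal lengths, tau x and approx 3x -> weighted mean approx 2x
  a <- sine_path(4, 2, len = 80, n = 500) + 10
  b <- sine_path(12.55, 2, len = 80, n = 500) + 50
  ta <- segment_tortuosity(a)$tau; tb <- segment_tortuosity(b)$tau
  la <- sum(sqrt(rowSums(diff(a)^2)));  lb <- sum(sqrt(rowSums(diff(b)^2)))
  rt2 <- region_tortuosity(fake_graph(list(a, b)), mask)
  expect_equal(rt2$value, (ta * la + tb * lb) / (la + lb), tolerance = 1e-12)
  # no eligible segment -> undefined
  expect_false(region_tortuosity(fake_graph(list()), mask)$defined)
})

test_that("quantify is deterministic, additive in VAR, and flags empty regions", {
  sp <- small_spec()
  grid <- build_grid(sp)
  vm <- generate_tree_image(tree_params(seed = 5), sp)
  q1 <- quantify(vm, grid)
  q2 <- quantify(vm, grid)
  expect_identical(q1, q2)

  v <- function(q, reg, met) q$value[q$region == reg & q$metric == met]
  n_in <- sum(grid$masks$inner_ring); n_out <- sum(grid$masks$outer_ring)
  expect_equal(v(q1, "whole", "VAR"),
               (n_in * v(q1, "inner_ring", "VAR") + n_out * v(q1, "outer_ring", "VAR")) /
                 (n_in + n_out), tolerance = 1e-12)
  # composite VAR is the mask-area-weighted mean of its quadrant VARs
  inner_q <- paste0("inner_", c("superior", "inferior", "nasal", "temporal"))
  w <- vapply(grid$masks[inner_q], sum, numeric(1))
  vars <- vapply(inner_q, function(r) v(q1, r, "VAR"), numeric(1))
  expect_equal(v(q1, "inner_ring", "VAR"), sum(w * vars) / sum(w),
               tolerance = 1e-12)

  # vessels confined to the outer ring: inner metrics undefined, VAR_inner = 0
  m <- matrix(0, 201, 201)
  m[9:13, 30:170] <- 1                               # bar through the outer ring only
  m[grid$masks$inner_ring | grid$labels == 2L] <- 0
  vm2 <- vessel_map(m, sp)
  q3 <- quantify(vm2, grid, regions = c("inner_ring", "outer_ring"))
  expect_identical(v(q3, "inner_ring", "VAR"), 0)
  expect_false(q3$defined[q3$region == "inner_ring" & q3$metric == "Dm"])
  expect_false(q3$defined[q3$region == "inner_ring" & q3$metric == "tau"])
  expect_false(q3$defined[q3$region == "inner_ring" & q3$metric == "Df"])
})
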