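test_that("sector masks tile the 0.5-3 mm annulus and respect ring areas", {
  g <- build_grid(small_spec())
  sectors <- g$masks[1:8]

  # pairwise disjoint quadrant sectors
  overlap <- Reduce(`+`, sectors)
  expect_true(all(overlap <= 1))

  # partition: sectors + center + outside = all pixels
  n_center <- sum(g$labels == 2L)
  n_outside <- sum(g$labels == 1L)
  expect_identical(sum(overlap) + n_center + n_outside, length(g$labels))

  # composites are exact unions
  expect_identical(g$masks$inner_ring,
                   Reduce(`|`, sectors[paste0("inner_", c("superior", "inferior", "nasal", "temporal"))]))
  expect_identical(g$masks$outer_ring,
                   Reduce(`|`, sectors[paste0("outer_", c("superior", "inferior", "nasal", "temporal"))]))
  expect_identical(g$masks$whole, g$masks$inner_ring | g$masks$outer_ring)

  # the central 1 mm circle touches no analysis region
  for (m in g$masks) expect_false(any(m & g$labels == 2L))

  # annulus pixel areas: |inner|/|outer| = (1.5^2-0.5^2)/(3^2-1.5^2) = 8/27
  ratio <- sum(g$masks$inner_ring) / sum(g$masks$outer_ring)
  expect_lt(abs(ratio / (8 / 27) - 1), 0.02)
})

test_that("laterality mirrors nasal/temporal and nasal_side can override", {
  g_od <- build_grid(small_spec("OD"))
  g_os <- build_grid(small_spec("OS"))
  # same geometry: OD nasal occupies the pixels OS calls temporal
  expect_identical(g_od$masks$inner_nasal, g_os$masks$inner_temporal)
  expect_identical(g_od$masks$outer_temporal, g_os$masks$outer_nasal)
  # and the two nasal masks are mirror images about the vertical axis
  mirror <- function(m) m[, ncol(m):1]
  expect_identical(g_od$masks$inner_nasal, mirror(g_os$masks$inner_nasal))
  # override flag
  sp <- grid_spec(c(101, 101), 0.03, "OD", c(201, 201), nasal_side = "left")
  g_ov <- build_grid(sp)
  expect_identical(g_ov$masks$inner_nasal, g_os$masks$inner_nasal)
})

test_that("sector_of resolves center, rings, quadrants and diagonal ties", {
  g <- build_grid(small_spec("OD"))
  px_per_mm <- 1 / 0.03
  expect_identical(sector_of(c(101, 101), g), "center")
  expect_identical(sector_of(c(101 - 2 * px_per_mm, 101), g), "outer_superior")
  expect_identical(sector_of(c(101, 101 + 1 * px_per_mm), g), "inner_nasal")   # OD: nasal right
  expect_identical(sector_of(c(101, 101 - 1 * px_per_mm), g), "inner_temporal")
  expect_identical(sector_of(c(101 + 2 * px_per_mm, 101), g), "outer_inferior")
  # pixels exactly on the 45-degree diagonals belong to the vertical quadrants
  d <- round(2 * px_per_mm / sqrt(2))
  expect_identical(sector_of(c(101 - d, 101 + d), g), "outer_superior")
  expect_identical(sector_of(c(101 + d, 101 - d), g), "outer_inferior")
  expect_error(sector_of(c(0, 5), g), "outside")
})

test_that("halving the scale quadruples every mask area within 2%", {
  g1 <- build_grid(small_spec(scale = 0.03, n = 201))
  g2 <- build_grid(small_spec(scale = 0.015, n = 401))
  for (nm in names(g1$masks)) {
    expect_lt(abs(sum(g2$masks[[nm]]) / (4 * sum(g1$masks[[nm]])) - 1), 0.02)
  }
})

test_that("invalid specs are rejected with the right error classes", {
  expect_error(grid_spec(c(50, 50), -0.01, "OD", c(101, 101)),
               class = "macvasc_validation_error")
  expect_error(grid_spec(c(500, 50), 0.01, "OD", c(101, 101)),
               class = "macvasc_validation_error")  # fovea outside
  # 6 mm circle does not fit: needs 300 px radius
  expect_error(grid_spec(c(50, 50), 0.01, "OD", c(101, 101)),
               class = "macvasc_config_error")
})
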