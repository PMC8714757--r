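#' Parameters for the synthetic macular vessel-tree generator
#'
#' Controls the stochastic branching trees that emulate a macular vascular
#' network in a binarized fundus vessel map: arcade entry points on the 6 mm
#' circle, recursive branching toward the fovea with Murray-law caliber
#' tapering, sinusoidal centerline wiggle and a capillary-free foveal
#' avascular zone.
#'
#' @param seed RNG seed; the generated image is a pure function of
#'   `(params, spec)`.
#' @param n_roots number of arcade entry points on the 6 mm boundary.
#' @param branch_prob probability of a bifurcation per mm of grown vessel,
#'   in `[0, 1]`.
#' @param branch_angle_spread full angular spread (degrees) between the two
#'   children at a bifurcation.
#' @param root_diameter trunk diameter at the entry points, mm.
#' @param taper_exponent Murray-law exponent: each child caliber is
#'   `parent * 2^(-1/taper_exponent)` (default 3).
#' @param tortuosity_amplitude,tortuosity_wavelength sinusoidal lateral
#'   displacement of the centerlines, mm.
#' @param faz_radius foveal avascular zone radius, mm (< 0.5).
#' @param target_density overall density dial; scales the number of trees.
#' @param min_diameter terminal caliber, mm; branches thinner than this stop.
#' @return An object of class `tree_params`.
#' @export
tree_params <- function(seed = 1L, n_roots = 5, branch_prob = 0.5,
                        branch_angle_spread = 40, root_diameter = 0.07,
                        taper_exponent = 3, tortuosity_amplitude = 0.02,
                        tortuosity_wavelength = 0.8, faz_radius = 0.3,
                        target_density = 1, min_diameter = 0.02) {
  p <- list(seed = as.integer(seed), n_roots = n_roots,
            branch_prob = branch_prob,
            branch_angle_spread = branch_angle_spread,
            root_diameter = root_diameter, taper_exponent = taper_exponent,
            tortuosity_amplitude = tortuosity_amplitude,
            tortuosity_wavelength = tortuosity_wavelength,
            faz_radius = faz_radius, target_density = target_density,
            min_diameter = min_diameter)
  lens <- c("root_diameter", "tortuosity_wavelength", "min_diameter")
  if (any(unlist(p[lens]) <= 0))
    stop_validation("lengths must be positive")
  if (p$tortuosity_amplitude < 0 || p$target_density <= 0 || p$n_roots < 1)
    stop_validation("tortuosity_amplitude >= 0, target_density > 0, n_roots >= 1 required")
  if (p$branch_prob < 0 || p$branch_prob > 1)
    stop_validation("branch_prob must be in [0, 1]")
  if (p$faz_radius < 0 || p$faz_radius >= 0.5)
    stop_validation("faz_radius must be in [0, 0.5) mm")
  structure(p, class = "tree_params")
}

# Grow one branch as a polyline in mm coordinates (x right, y up, origin at
# the fovea). Returns centerline points, per-point diameter, and spawned
# children.
grow_branch <- function(start, dir, diameter, phase, p, step = 0.03) {
  pts <- list(); dia <- numeric(0)
  children <- list()
  u <- dir / sqrt(sum(dir^2))
  v <- c(-u[2], u[1])  # lateral unit
  s <- 0
  base <- start
  next_branch <- if (p$branch_prob > 0)
    stats::rexp(1, rate = max(p$branch_prob, 1e-9)) else Inf
  repeat {
    pos <- base + u * s +
      v * p$tortuosity_amplitude * sin(2 * pi * s / p$tortuosity_wavelength + phase)
    r <- sqrt(sum(pos^2))
    if (r <= p$faz_radius + 0.03 || r > 3.05 && s > 0) break
    pts[[length(pts) + 1]] <- pos
    dia <- c(dia, diameter)
    if (s >= next_branch) {
      if (diameter * 2^(-1 / p$taper_exponent) >= p$min_diameter) {
        half <- p$branch_angle_spread / 2 * pi / 180
        a <- atan2(u[2], u[1])
        for (sgn in c(-1, 1)) {
          na <- a + sgn * (half + stats::runif(1, -0.2, 0.2))
          children[[length(children) + 1]] <-
            list(start = pos, dir = c(cos(na), sin(na)),
                 diameter = diameter * 2^(-1 / p$taper_exponent),
                 phase = stats::runif(1, 0, 2 * pi))
        }
        break  # parent terminates at the bifurcation
      }
      next_branch <- next_branch + stats::rexp(1, rate = max(p$branch_prob, 1e-9))
    }
    if (s > 6) break
    s <- s + step
  }
  list(points = if (length(pts)) do.call(rbind, pts) else matrix(0, 0, 2),
       diameter = dia, children = children)
}

#' Generate a synthetic binary macular vessel map
#'
#' Grows `round(n_roots * target_density)` stochastic vessel trees from entry
#' points on the 6 mm circle toward the fovea, perturbs the centerlines
#' sinusoidally, tapers child calibers by a Murray-law rule, rasterizes the
#' centerlines by stamping discs of the local radius, and clears every pixel
#' within `faz_radius` of the fovea. Bit-identical for identical
#' `(params, spec)`.
#'
#' @param params a [tree_params()].
#' @param spec a [grid_spec()]; the raster geometry of the output.
#' @param subject_id optional subject id carried into the map's metadata.
#' @return A [vessel_map()] with the given spec.
#' @examples
#' sp <- grid_spec(c(101, 101), 0.03, "OD", c(201, 201))
#' vm <- generate_tree_image(tree_params(seed = 7), sp)
#' sum(vm$pixels) > 0
#' @export
generate_tree_image <- function(params, spec, subject_id = NA_character_) {
  if (!inherits(params, "tree_params")) stop_validation("params must be tree_params")
  if (!inherits(spec, "grid_spec")) stop_validation("spec must be a grid_spec")
  with_seed(params$seed, {
    n_trees <- max(1, round(params$n_roots * params$target_density))
    queue <- list()
    for (i in seq_len(n_trees)) {
      ang <- stats::runif(1, 0, 2 * pi)
      start <- 3.0 * c(cos(ang), sin(ang))
      # aim inward with some jitter
      na <- ang + pi + stats::runif(1, -0.5, 0.5)
      queue[[length(queue) + 1]] <-
        list(start = start, dir = c(cos(na), sin(na)),
             diameter = params$root_diameter,
             phase = stats::runif(1, 0, 2 * pi))
    }
    centers <- list(); dias <- list()
    guard <- 0
    while (length(queue) > 0 && guard < 5000) {
      guard <- guard + 1
      b <- queue[[1]]; queue[[1]] <- NULL
      g <- grow_branch(b$start, b$dir, b$diameter, b$phase, params)
      if (nrow(g$points) > 0) {
        centers[[length(centers) + 1]] <- g$points
        dias[[length(dias) + 1]] <- g$diameter
      }
      queue <- c(queue, g$children)
    }
    pts <- do.call(rbind, centers)
    dia <- unlist(dias)
    if (is.null(pts) || nrow(pts) == 0)
      stop_config("tree parameters produced no vessels inside the 6 mm circle")
    # mm -> pixel (row = fovea_row - y/scale, col = fovea_col + x/scale)
    sc <- spec$scale_mm_per_px
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    img <- matrix(FALSE, nr, nc)
    rr <- spec$fovea_center[1] - pts[, 2] / sc
    cc <- spec$fovea_center[2] + pts[, 1] / sc
    rad_px <- pmax(dia / 2 / sc, 0.5)
    for (i in seq_len(nrow(pts))) {
      r0 <- max(1L, floor(rr[i] - rad_px[i])); r1 <- min(nr, ceiling(rr[i] + rad_px[i]))
      c0 <- max(1L, floor(cc[i] - rad_px[i])); c1 <- min(nc, ceiling(cc[i] + rad_px[i]))
      if (r0 > r1 || c0 > c1) next
      dr <- (r0:r1) - rr[i]; dc <- (c0:c1) - cc[i]
      disc <- outer(dr^2, dc^2, `+`) <= rad_px[i]^2
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] | disc
    }
    # clear the foveal avascular zone
    dyv <- (spec$fovea_center[1] - seq_len(nr)) * sc
    dxv <- (seq_len(nc) - spec$fovea_center[2]) * sc
    faz <- outer(dyv^2, dxv^2, `+`) <= params$faz_radius^2
    img[faz] <- FALSE
    if (!any(img))
      stop_config("tree parameters produced no vessels inside the 6 mm circle")
    vessel_map(img, spec, subject_id = subject_id)
  })
}

#' Dial-to-metric calibration curve
#'
#' Sweeps one generator parameter over a grid of values, generates `n_seeds`
#' trees per value, quantifies the whole-macula metrics and returns their
#' means. Used to verify that the generator dials move the metrics they are
#' meant to move (tortuosity amplitude -> tau, branching -> Df, root
#' diameter -> Dm, density -> VAR).
#'
#' @param param_name one of the [tree_params()] field names.
#' @param values numeric vector of dial values.
#' @param n_seeds number of seeds per value (>= 2).
#' @param spec raster geometry; a 201 x 201 px, 0.03 mm/px grid by default.
#' @param base_params baseline [tree_params()] to perturb.
#' @param region region whose metrics are averaged (default `"whole"`).
#' @return Data frame: one row per value with mean `Df`, `VAR`, `Dm`, `tau`.
#' @export
calibration_curve <- function(param_name, values, n_seeds,
                              spec = NULL, base_params = tree_params(),
                              region = "whole") {
  if (!param_name %in% names(base_params))
    stop_validation("unknown generator parameter: ", param_name)
  if (n_seeds < 2) stop_validation("n_seeds must be >= 2")
  if (is.null(spec)) spec <- grid_spec(c(101, 101), 0.03, "OD", c(201, 201))
  grid <- build_grid(spec)
  rows <- lapply(values, function(v) {
    p <- unclass(base_params); p[[param_name]] <- v
    mets <- vapply(seq_len(n_seeds), function(s) {
      p$seed <- 1000L + s
      vm <- generate_tree_image(do.call(tree_params, p), spec)
      q <- quantify(vm, grid, regions = region)
      stats::setNames(q$value, q$metric)
    }, numeric(4))
    data.frame(value = v, t(rowMeans(mets, na.rm = TRUE)))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- param_name
  out
}
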