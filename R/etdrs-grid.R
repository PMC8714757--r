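#' ETDRS grid specification
#'
#' Describes the geometry needed to place a fovea-centered ETDRS grid on a
#' pixel raster: the fovea position, the physical scale, the eye side (which
#' decides where "nasal" is) and the raster size.
#'
#' @param fovea_center numeric length-2, fovea position as (row, col) in
#'   pixels (1-based, may be fractional). Row 1 is the top of the image;
#'   "superior" is up.
#' @param scale_mm_per_px physical scale in mm per pixel, > 0.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye). For OD the
#'   nasal retina is on the image's right, for OS on the left.
#' @param image_shape integer length-2, (rows, cols) of the raster.
#' @param nasal_side `"auto"` (derive from laterality, the default) or
#'   `"left"`/`"right"` to override, since fundus-camera mirroring
#'   conventions vary.
#'
#' @return An object of class `grid_spec`.
#' @seealso [build_grid()]
#' @export
grid_spec <- function(fovea_center, scale_mm_per_px, laterality,
                      image_shape, nasal_side = "auto") {
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1 ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop_validation("scale_mm_per_px must be a single positive number")
  laterality <- match.arg(laterality, c("OD", "OS"))
  nasal_side <- match.arg(nasal_side, c("auto", "left", "right"))
  fovea_center <- as.numeric(fovea_center)
  image_shape <- as.integer(image_shape)
  if (length(fovea_center) != 2 || any(!is.finite(fovea_center)))
    stop_validation("fovea_center must be a finite (row, col) pair")
  if (length(image_shape) != 2 || any(image_shape < 1))
    stop_validation("image_shape must be positive (rows, cols)")
  if (fovea_center[1] < 1 || fovea_center[1] > image_shape[1] ||
      fovea_center[2] < 1 || fovea_center[2] > image_shape[2])
    stop_validation("fovea_center lies outside the image bounds")
  r_px <- 3 / scale_mm_per_px  # outer ETDRS radius (3 mm) in pixels
  if (fovea_center[1] - r_px < 1 || fovea_center[1] + r_px > image_shape[1] ||
      fovea_center[2] - r_px < 1 || fovea_center[2] + r_px > image_shape[2])
    stop_config("the 6 mm ETDRS circle does not fit inside the image")
  structure(list(fovea_center = fovea_center,
                 scale_mm_per_px = scale_mm_per_px,
                 laterality = laterality,
                 nasal_side = nasal_side,
                 image_shape = image_shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("ETDRS grid spec:", x$image_shape[1], "x", x$image_shape[2],
      "px, fovea (", x$fovea_center[1], ",", x$fovea_center[2], "),",
      x$scale_mm_per_px, "mm/px,", x$laterality, "\n")
  invisible(x)
}

# Region names: 8 quadrant sectors + composites.
.sector_levels <- c("outside", "center",
                    "inner_superior", "inner_inferior",
                    "inner_nasal", "inner_temporal",
                    "outer_superior", "outer_inferior",
                    "outer_nasal", "outer_temporal")

.quadrant_regions <- .sector_levels[3:10]
.composite_regions <- c("inner_ring", "outer_ring", "whole")
.all_regions <- c(.quadrant_regions, .composite_regions)

#' Build the fovea-centered ETDRS partition
#'
#' Labels every pixel of the raster by its ETDRS sector. The grid consists of
#' three concentric circles of diameter 1, 3 and 6 mm centered at the fovea;
#' the two rings between them (inner: 0.5--1.5 mm radius, outer: 1.5--3 mm)
#' are each split into superior / inferior / nasal / temporal quadrants by the
#' two diagonals through the fovea at +-45 degrees. The central 1 mm circle
#' (foveal avascular zone territory) is labeled `center` and excluded from all
#' analysis regions.
#'
#' A pixel belongs to a ring when its center's radial distance falls in the
#' half-open interval `[inner, outer)`. Pixels exactly on a +-45 degree
#' diagonal go to the superior/inferior quadrants (vertical quadrants win
#' ties).
#'
#' @param spec a [grid_spec()].
#' @return An object of class `etdrs_grid` with elements
#'   * `labels`: integer matrix of sector codes (see `sector_names`),
#'   * `sector_names`: the code-to-name mapping,
#'   * `masks`: named list of logical matrices for the 8 quadrant sectors
#'     plus the composites `inner_ring`, `outer_ring` and `whole`
#'     (= inner ring union outer ring; the central circle is excluded),
#'   * `spec`: the input spec.
#' @examples
#' sp <- grid_spec(c(101, 101), 0.03, "OD", c(201, 201))
#' g <- build_grid(sp)
#' table(g$sector_names[g$labels])["center"]
#' @export
build_grid <- function(spec) {
  if (!inherits(spec, "grid_spec")) stop_validation("spec must be a grid_spec")
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  # dx right-positive, dy up-positive (row 1 = top of image)
  dy <- spec$fovea_center[1] - seq_len(nr)
  dx <- seq_len(nc) - spec$fovea_center[2]
  DX <- matrix(dx, nr, nc, byrow = TRUE)
  DY <- matrix(dy, nr, nc)
  r_mm <- spec$scale_mm_per_px * sqrt(DX^2 + DY^2)
  ang <- atan2(DY, DX) * 180 / pi  # degrees, 0 = image right, 90 = up

  ring <- matrix(0L, nr, nc)                 # 0 outside, 1 center, 2 inner, 3 outer
  ring[r_mm < 3.0] <- 3L
  ring[r_mm < 1.5] <- 2L
  ring[r_mm < 0.5] <- 1L

  # Quadrants; ties on the diagonals go to superior/inferior.
  quad <- matrix("", nr, nc)
  quad[ang >= 45 & ang <= 135] <- "superior"
  quad[ang <= -45 & ang >= -135] <- "inferior"
  right <- ang > -45 & ang < 45
  left <- ang > 135 | ang < -135
  nasal_right <- switch(spec$nasal_side,
                        auto = spec$laterality == "OD",
                        right = TRUE, left = FALSE)
  if (nasal_right) {
    quad[right] <- "nasal"; quad[left] <- "temporal"
  } else {
    quad[right] <- "temporal"; quad[left] <- "nasal"
  }

  lab <- matrix(1L, nr, nc)  # code 1 = outside
  lab[ring == 1L] <- 2L
  for (ringname in c("inner", "outer")) {
    rcode <- if (ringname == "inner") 2L else 3L
    for (q in c("superior", "inferior", "nasal", "temporal")) {
      code <- match(paste(ringname, q, sep = "_"), .sector_levels)
      lab[ring == rcode & quad == q] <- code
    }
  }

  masks <- lapply(3:10, function(code) lab == code)
  names(masks) <- .sector_levels[3:10]
  masks$inner_ring <- lab >= 3L & lab <= 6L
  masks$outer_ring <- lab >= 7L & lab <= 10L
  masks$whole <- masks$inner_ring | masks$outer_ring

  structure(list(labels = lab, sector_names = .sector_levels,
                 masks = masks, spec = spec),
            class = "etdrs_grid")
}

#' Look up the ETDRS sector of a pixel
#'
#' @param point numeric length-2 (row, col), inside the image.
#' @param grid an [build_grid()] result.
#' @return The sector name (one of the ten labels).
#' @export
sector_of <- function(point, grid) {
  if (!inherits(grid, "etdrs_grid")) stop_validation("grid must be an etdrs_grid")
  point <- as.numeric(point)
  sh <- dim(grid$labels)
  if (length(point) != 2 || point[1] < 1 || point[1] > sh[1] ||
      point[2] < 1 || point[2] > sh[2])
    stop_validation("point is outside the image")
  grid$sector_names[grid$labels[round(point[1]), round(point[2])]]
}

#' @export
print.etdrs_grid <- function(x, ...) {
  px <- table(factor(x$sector_names[x$labels], levels = x$sector_names))
  cat("ETDRS grid,", nrow(x$labels), "x", ncol(x$labels), "px (",
      x$spec$scale_mm_per_px, "mm/px,", x$spec$laterality, ")\n")
  print(px)
  invisible(x)
}

#' Display an ETDRS grid as a label image
#'
#' @param x an `etdrs_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.etdrs_grid <- function(x, ...) {
  lab <- x$labels
  graphics::image(t(lab[nrow(lab):1, ]), col = grDevices::hcl.colors(10, "Spectral"),
                  axes = FALSE, asp = nrow(lab) / ncol(lab), ...)
  invisible(x)
}

#' Write ETDRS region masks as 8-bit PNG files
#'
#' Each mask is written as a 0/255 grayscale PNG named `<region>.png`.
#'
#' @param grid an `etdrs_grid`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_grid_masks <- function(grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(grid$masks), function(nm) {
    p <- file.path(dir, paste0(nm, ".png"))
    png::writePNG(grid$masks[[nm]] * 1, p)
    p
  }, character(1))
  invisible(paths)
}
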