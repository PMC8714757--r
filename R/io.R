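# Readers/writers and the end-to-end pipeline driver.

read_image_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop_validation("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB(A)
  img != 0
}

#' Read a binary vessel map with its sidecar metadata
#'
#' The image (PNG or TIFF) is binarized: any nonzero pixel is vessel. The
#' sidecar JSON must provide `fovea_row`, `fovea_col`, `scale_mm_per_px` and
#' `laterality` (optionally `subject_id`, `nasal_side`).
#'
#' @param image_path path to the PNG/TIFF mask.
#' @param sidecar_path path to the JSON sidecar; defaults to the image path
#'   with a `.json` extension.
#' @return A [vessel_map()].
#' @export
read_vessel_map <- function(image_path,
                            sidecar_path = paste0(tools::file_path_sans_ext(image_path), ".json")) {
  if (!file.exists(sidecar_path)) stop_validation("sidecar not found: ", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("fovea_row", "fovea_col", "scale_mm_per_px", "laterality")
  missing <- setdiff(need, names(side))
  if (length(missing))
    stop_validation("sidecar is missing fields: ", paste(missing, collapse = ", "))
  m <- read_image_matrix(image_path)
  spec <- grid_spec(c(side$fovea_row, side$fovea_col), side$scale_mm_per_px,
                    side$laterality, dim(m),
                    nasal_side = if (is.null(side$nasal_side)) "auto" else side$nasal_side)
  vessel_map(m, spec,
             subject_id = if (is.null(side$subject_id)) NA_character_ else side$subject_id)
}

#' Write a vessel map as PNG plus JSON sidecar
#'
#' @param map a [vessel_map()].
#' @param image_path output PNG path; the sidecar is written next to it.
#' @return Invisibly, the two paths.
#' @export
write_vessel_map <- function(map, image_path) {
  png::writePNG(map$pixels * 1, image_path)
  sidecar <- paste0(tools::file_path_sans_ext(image_path), ".json")
  jsonlite::write_json(list(fovea_row = map$spec$fovea_center[1],
                            fovea_col = map$spec$fovea_center[2],
                            scale_mm_per_px = map$spec$scale_mm_per_px,
                            laterality = map$spec$laterality,
                            nasal_side = map$spec$nasal_side,
                            subject_id = map$subject_id),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(image = image_path, sidecar = sidecar))
}

#' Emit a small standard fixture set of synthetic eyes
#'
#' Writes `n_subjects` synthetic subjects x 2 eyes (PNG + sidecar) into
#' `dir`, with a `cohort.csv` of subject covariates.
#'
#' @param dir output directory.
#' @param n_subjects number of subjects (default 5, i.e. 10 eyes).
#' @param seed RNG seed.
#' @param scale_mm_per_px raster scale (default 0.03 mm/px, 201 x 201 px).
#' @return Invisibly, the cohort CSV path.
#' @export
write_fixture_set <- function(dir, n_subjects = 5, seed = 1,
                              scale_mm_per_px = 0.03) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  half <- ceiling(3 / scale_mm_per_px) + 1
  n_px <- 2 * half + 1
  rows <- list()
  with_seed(seed, {
    sexes <- sample(c("M", "F"), n_subjects, replace = TRUE)
    ages <- round(stats::runif(n_subjects, 18, 70), 1)
    seeds <- sample.int(1e6, 2 * n_subjects)
  })
  k <- 0
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    for (eye in c("OD", "OS")) {
      k <- k + 1
      spec <- grid_spec(c(half + 1, half + 1), scale_mm_per_px, eye,
                        c(n_px, n_px))
      vm <- generate_tree_image(tree_params(seed = seeds[k]), spec,
                                subject_id = sid)
      write_vessel_map(vm, file.path(dir, paste0(sid, "_", eye, ".png")))
      rows[[k]] <- data.frame(subject_id = sid, eye = eye, sex = sexes[i],
                              age_years = ages[i],
                              image = paste0(sid, "_", eye, ".png"))
    }
  }
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}

#' Run the full macular vascular geometry pipeline
#'
#' For every eye image listed in the cohort CSV: build the ETDRS grid,
#' skeletonize, quantify all metrics per region; assemble the eye-level
#' metric table; then (when both sexes / varying ages are present) run the
#' sex-difference, age-association, age-group and baseline analyses. All
#' outputs are written under `out_dir` together with a manifest carrying the
#' seed and a config hash. Per-eye failures are logged and skipped; the run
#' fails only if every eye fails.
#'
#' @param config a list (or path to a JSON file) with fields `input_dir`
#'   (images + sidecars + `cohort.csv`), `out_dir`, and optional `seed`,
#'   `adjust` (p adjustment), `verbose`.
#' @return Invisibly, a list with the metrics table, the analysis reports
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (f in c("input_dir", "out_dir"))
    if (is.null(config[[f]])) stop_validation("config is missing '", f, "'")
  verbose <- isTRUE(config$verbose)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  cohort <- utils::read.csv(file.path(config$input_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  metrics <- list(); failures <- character(0)
  for (i in seq_len(nrow(cohort))) {
    img <- file.path(config$input_dir, cohort$image[i])
    res <- tryCatch({
      vm <- read_vessel_map(img)
      vm$subject_id <- cohort$subject_id[i]
      vm$eye <- cohort$eye[i]
      quantify(vm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, cohort$image[i])
      message("skipping ", cohort$image[i], ": ", conditionMessage(res))
    } else {
      metrics[[length(metrics) + 1]] <- res
      if (verbose) message("quantified ", cohort$image[i])
    }
  }
  if (length(metrics) == 0) stop_config("all eyes failed")
  long <- do.call(rbind, lapply(metrics, as.data.frame))
  utils::write.csv(long, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  # wide eye-level table for the statistics layer
  long$column <- paste(long$metric, long$region, sep = "_")
  wide <- stats::reshape(long[c("subject_id", "eye", "column", "value")],
                         idvar = c("subject_id", "eye"), timevar = "column",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- merge(wide, cohort[c("subject_id", "eye", "sex", "age_years")],
                by = c("subject_id", "eye"))
  utils::write.csv(wide, file.path(config$out_dir, "cohort_metrics.csv"),
                   row.names = FALSE)

  reports <- list()
  regions <- c("whole", "inner_ring", "outer_ring")
  have <- function(cols) all(paste0("Df_", regions) %in% names(wide))
  if (length(unique(wide$sex)) >= 2 && have()) {
    reports$sex <- sex_difference_analysis(wide, regions = regions)
    utils::write.csv(reports$sex, file.path(config$out_dir, "sex_differences.csv"),
                     row.names = FALSE)
  }
  if (length(unique(wide$age_years)) >= 2 && have()) {
    reports$age <- age_association_analysis(wide, regions = regions)
    utils::write.csv(reports$age, file.path(config$out_dir, "age_association.csv"),
                     row.names = FALSE)
    reports$baseline <- baseline_table(wide, regions = regions)
    utils::write.csv(reports$baseline, file.path(config$out_dir, "baseline.csv"),
                     row.names = FALSE)
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(seed = if (is.null(config$seed)) NA else config$seed,
                   config = config,
                   config_md5 = unname(tools::md5sum(tmp)),
                   n_eyes = length(metrics), n_failed = length(failures),
                   failed = failures,
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(metrics = long, reports = reports, manifest = manifest))
}
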