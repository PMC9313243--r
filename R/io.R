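# File formats: grayscale TIFF for images and probability maps (with JSON
# sidecars for provenance), CSV for spot tables, JSON for results.
# All coordinates written to disk are 1-based (row, col) = (y, x) with pixel
# centers at integer coordinates.

#' Write / read a grayscale image as TIFF
#'
#' Integer count images are stored as 8- or 16-bit grayscale TIFF;
#' [read_image_tiff()] restores the original counts.
#'
#' @param image Numeric matrix of counts in `[0, 2^bit_depth - 1]`.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly; the image matrix for the reader.
#' @export
write_image_tiff <- function(image, path, bit_depth = 16) {
  stopifnot(is.matrix(image), bit_depth %in% c(8, 16))
  maxv <- 2^bit_depth - 1
  tiff::writeTIFF(pmin(pmax(image, 0), maxv) / maxv, path,
                  bits.per.sample = bit_depth)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, bit_depth = 16) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * (2^bit_depth - 1))
}

#' Write a simulated scene to a directory
#'
#' Writes `qd_channel.tif` and `boundary_channel.tif` (16-bit),
#' `boundary_mask.tif` (8-bit 0/255), `spots_truth.csv` (`spot_id`, `y_px`,
#' `x_px`, `label`) and `scene.json` (all specs and seeds).
#'
#' @param scene A [simulate_scene()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "qd_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_tiff(scene$qd_channel, file.path(dir, "qd_channel.tif"),
                   bit_depth = scene$specs$imaging$bit_depth)
  write_image_tiff(scene$boundary_channel,
                   file.path(dir, "boundary_channel.tif"), bit_depth = 16)
  write_image_tiff(scene$boundary_mask * 255,
                   file.path(dir, "boundary_mask.tif"), bit_depth = 8)
  write.csv(scene$spots_truth, file.path(dir, "spots_truth.csv"),
            row.names = FALSE)
  specs <- lapply(scene$specs, function(s) {
    if (is.null(s)) NULL else unclass(s)
  })
  jsonlite::write_json(specs, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write / read a probability map as 32-bit float TIFF with JSON sidecar
#'
#' @param map A [probability_map()].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path` invisibly; the map for the reader.
#' @export
write_probability_map <- function(map, path) {
  stopifnot(inherits(map, "probability_map"))
  tiff::writeTIFF(map$values, path, bits.per.sample = 32)
  jsonlite::write_json(list(source_id = map$source_id, method = map$method),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  vals <- tiff::readTIFF(path)
  if (length(dim(vals)) == 3) vals <- vals[, , 1]
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"))
  } else list(source_id = basename(path), method = "ridge_filter")
  probability_map(pmin(pmax(vals, 0), 1), source_id = meta$source_id,
                  method = meta$method)
}

#' Write / read a spot set as CSV with JSON parameter sidecar
#'
#' @param spots A [spot_set()].
#' @param path CSV path; parameters go to `<path>.json`.
#' @return `path` invisibly; the spot set for the reader.
#' @export
write_spots_csv <- function(spots, path) {
  stopifnot(inherits(spots, "spot_set"))
  write.csv(spots$spots, path, row.names = FALSE)
  jsonlite::write_json(list(source_id = spots$source_id,
                            detection_params = spots$detection_params,
                            image_dim = spots$image_dim),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$flag <- as.character(df$flag)
  df$flag[is.na(df$flag)] <- ""
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else list(source_id = basename(path), detection_params = list(),
              image_dim = NULL)
  spot_set(df, source_id = meta$source_id,
           detection_params = as.list(meta$detection_params),
           image_dim = meta$image_dim)
}

#' Write a colocalization result as JSON (+ histogram CSV)
#'
#' @param result A [colocalize()] result.
#' @param path JSON output path; the histogram is also written as
#'   `<dir>/coloc_histogram.csv`.
#' @return `path`, invisibly.
#' @export
write_coloc_json <- function(result, path) {
  stopifnot(inherits(result, "coloc_result"))
  jsonlite::write_json(
    list(source_id = result$source_id,
         n_spots = result$n_spots,
         boundary_fraction = result$boundary_fraction,
         config = unclass(result$config),
         per_spot_probability = result$per_spot_probability,
         histogram = result$histogram),
    path, auto_unbox = TRUE, digits = NA)
  hist_path <- file.path(dirname(path), "coloc_histogram.csv")
  h <- result$histogram
  write.csv(data.frame(bin_left = h$breaks[-length(h$breaks)],
                       bin_right = h$breaks[-1], count = h$counts),
            hist_path, row.names = FALSE)
  invisible(path)
}
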