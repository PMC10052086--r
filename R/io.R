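# File formats: depth rasters are 16-bit (TIFF, or PNG on read) holding
# millimetres after the intrinsics' depth_scale; RGB is 8-bit PNG; masks are
# single-channel 8-bit PNG, 0 = background / 255 = lettuce. CSVs carry a
# one-line version header so readers can reject incompatible schemas.

csv_version <- 1L

write_versioned_csv <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lettucecv %s v%d", kind, csv_version), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_versioned_csv <- function(path, kind) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^# lettucecv ([a-z_-]+) v(\\d+)", header))[[1]]
  if (length(m) == 3) {
    if (m[2] != kind)
      stop(sprintf("%s: expected a '%s' table, found '%s'", path, kind, m[2]))
    if (as.integer(m[3]) > csv_version)
      stop(sprintf("%s: schema v%s is newer than this package understands", path, m[3]))
    return(read.csv(path, skip = 1L))
  }
  read.csv(path)  # unversioned: accept as-is
}

parse_frame_timestamp <- function(path) {
  m <- regmatches(basename(path), regexec("(\\d{8}T\\d{4})", basename(path)))[[1]]
  if (length(m) < 2)
    stop("cannot parse an ISO timestamp (YYYYMMDDTHHMM) from: ", path)
  m[2]
}

timestamp_to_time <- function(stamp) {
  as.POSIXct(stamp, format = "%Y%m%dT%H%M", tz = "UTC")
}

#' Read one RGB-D frame from disk
#'
#' Depth must be a single-channel 16-bit raster (TIFF or PNG); anything
#' else -- notably 8-bit depth, which cannot hold millimetre ranges -- is
#' rejected with the offending path named. RGB must be an 8-bit 3-channel
#' PNG of the same size. Stored depth units are scaled to mm by the
#' intrinsics' `depth_scale`; the timestamp is parsed from the depth
#' filename.
#'
#' @param depth_path path to the depth raster.
#' @param rgb_path path to the RGB image.
#' @param cam a [camera_intrinsics()].
#' @return A `frame_rgbd` (list with `depth` in mm, `rgb` 0..255, `cam`,
#'   `timestamp`).
#' @export
read_frame <- function(depth_path, rgb_path, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  ext <- tolower(tools::file_ext(depth_path))
  if (ext %in% c("tif", "tiff")) {
    units <- suppressWarnings(tiff::readTIFF(depth_path, as.is = TRUE, info = TRUE))
    bits <- attr(units, "bits.per.sample")
    if (!is.null(bits) && bits != 16L)
      stop(sprintf("%s: depth must be 16-bit, found %d-bit", depth_path, bits))
    attributes(units) <- list(dim = dim(units))
  } else if (ext == "png") {
    raw <- png::readPNG(depth_path, info = TRUE)
    info <- attr(raw, "info")
    if (info$bit.depth != 16L)
      stop(sprintf("%s: depth must be 16-bit, found %d-bit", depth_path, info$bit.depth))
    units <- round(raw * 65535)
  } else {
    stop(depth_path, ": unsupported depth format (use 16-bit TIFF or PNG)")
  }
  if (length(dim(units)) != 2)
    stop(depth_path, ": depth must be single-channel")
  rgb <- png::readPNG(rgb_path)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop(rgb_path, ": RGB image must have 3 channels")
  rgb <- rgb[, , 1:3, drop = FALSE] * 255
  if (!all(dim(units) == dim(rgb)[1:2]))
    stop(sprintf("%s / %s: depth and RGB sizes differ", depth_path, rgb_path))
  structure(list(depth = units * cam$depth_scale, rgb = rgb, cam = cam,
                 timestamp = parse_frame_timestamp(depth_path)),
            class = "frame_rgbd")
}

#' Write one RGB-D frame
#'
#' Depth goes to 16-bit TIFF (mm divided by `depth_scale`, rounded and
#' clamped to 0..65535), RGB to 8-bit PNG.
#'
#' @param frame a `frame_rgbd`.
#' @param depth_path,rgb_path output paths.
#' @export
write_frame <- function(frame, depth_path, rgb_path) {
  units <- pmin(pmax(round(frame$depth / frame$cam$depth_scale), 0), 65535)
  tiff::writeTIFF(units / 65535, depth_path, bits.per.sample = 16L,
                  compression = "none")
  png::writePNG(frame$rgb / 255, rgb_path)
  invisible(c(depth_path, rgb_path))
}

#' Read / write a binary mask PNG
#'
#' Masks are single-channel 8-bit PNGs, 0 = background, 255 = lettuce.
#'
#' @param path file path.
#' @param provenance tag attached to the mask on read.
#' @return `read_mask`: a `seg_mask`.
#' @export
read_mask <- function(path, provenance = "external") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  as_seg_mask(m > 0.5, provenance = provenance)
}

#' @rdname read_mask
#' @param mask a `seg_mask` (or logical matrix).
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(as_seg_mask(mask)), nrow(mask), ncol(mask)),
                path)
  invisible(path)
}

#' Read / write camera intrinsics as JSON
#'
#' @param path file path.
#' @return `read_intrinsics`: a [camera_intrinsics()].
#' @export
read_intrinsics <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(j$fx, j$fy, j$cx, j$cy, j$width, j$height,
                    depth_scale = j$depth_scale %||% 1)
}

#' @rdname read_intrinsics
#' @param cam a [camera_intrinsics()].
#' @export
write_intrinsics <- function(cam, path) {
  jsonlite::write_json(unclass(cam), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a density schedule as CSV
#'
#' @param path file path.
#' @param ladder passed to [density_schedule()] on read; `NULL` accepts any
#'   decreasing schedule.
#' @return `read_schedule`: a [density_schedule()].
#' @export
read_schedule <- function(path, ladder = NULL) {
  df <- read_versioned_csv(path, "schedule")
  density_schedule(df$day, df$density, ladder = ladder)
}

#' @rdname read_schedule
#' @param schedule a [density_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  write_versioned_csv(as.data.frame(schedule), path, "schedule")
}

#' Write a synthetic batch to a frames directory
#'
#' Lays a [simulate_batch()] result out as the on-disk structure
#' [run_pipeline()] consumes: per frame `<stamp>_depth.tif`,
#' `<stamp>_rgb.png` and `<stamp>_gtmask.png`, plus `intrinsics.json`,
#' `schedule.csv`, `ground_truth.csv` (per-frame per-plant traits) and
#' `sim_config.json`.
#'
#' @param batch a `synthetic_batch`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_batch <- function(batch, dir) {
  stopifnot(inherits(batch, "synthetic_batch"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_intrinsics(batch$intrinsics, file.path(dir, "intrinsics.json"))
  write_schedule(batch$schedule, file.path(dir, "schedule.csv"))
  gt <- list()
  for (fr in batch$frames) {
    stem <- file.path(dir, fr$timestamp)
    write_frame(fr$frame, paste0(stem, "_depth.tif"), paste0(stem, "_rgb.png"))
    write_mask(fr$mask, paste0(stem, "_gtmask.png"))
    p <- fr$plants
    gt[[length(gt) + 1]] <-
      data.frame(timestamp = fr$timestamp, time_days = fr$time_days,
                 density = fr$density, plant_id = p$id,
                 x_mm = p$x, y_mm = p$y, radius_mm = p$radius,
                 height_mm = p$height, area_cm2 = p$area_cm2,
                 weight_g = p$weight_g, class = p$class)
  }
  write_versioned_csv(do.call(rbind, gt), file.path(dir, "ground_truth.csv"),
                      "ground-truth")
  cfg <- batch$cfg
  cfg$schedule <- NULL
  jsonlite::write_json(c(unclass(cfg),
                         list(schedule_file = "schedule.csv")),
                       file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
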