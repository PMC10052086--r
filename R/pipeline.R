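#' Pipeline run configuration
#'
#' Bundles everything [run_pipeline()] needs: where the frames and sidecar
#' files live, segmentation and RANSAC settings, decision thresholds and
#' the seed. Referenced files must exist when the run starts.
#'
#' @param frames_dir directory of `<stamp>_depth.tif` / `<stamp>_rgb.png`
#'   frames with `intrinsics.json` and `schedule.csv` sidecars (see
#'   [write_batch()]).
#' @param out_dir output directory for the report files.
#' @param masks_dir optional directory of external `<stamp>_mask.png`
#'   masks; when absent the built-in excess-green segmenter is used.
#' @param intrinsics_file,schedule_file sidecar overrides.
#' @param ledger_file optional JSON of [economic_ledger()] fields.
#' @param calibration_file optional CSV of calibration pairs
#'   (`indicator_cm3`, `weight_g`); when given, the harvest threshold is
#'   recomputed from the fitted weight model instead of the default.
#' @param exg_threshold excess-green threshold (number or `"otsu"`).
#' @param coverage_threshold spacing-recommendation threshold, percent.
#' @param harvest_threshold harvest-indicator threshold, cm^3.
#' @param target_weight_g target head weight for calibration, g.
#' @param height_method,height_prob passed to [height_map()] /
#'   [max_height()].
#' @param ransac list of [fit_ground_plane()] settings.
#' @param seed integer seed (drives RANSAC; recorded in every output).
#' @return A `run_config`.
#' @export
run_config <- function(frames_dir, out_dir,
                       masks_dir = NULL,
                       intrinsics_file = file.path(frames_dir, "intrinsics.json"),
                       schedule_file = file.path(frames_dir, "schedule.csv"),
                       ledger_file = NULL,
                       calibration_file = NULL,
                       exg_threshold = 20,
                       coverage_threshold = 98,
                       harvest_threshold = 7840,
                       target_weight_g = 250,
                       height_method = "point_to_plane",
                       height_prob = 1,
                       ransac = list(iterations = 1000, threshold = 5),
                       seed = 1L) {
  for (f in c(intrinsics_file, schedule_file, ledger_file, calibration_file))
    if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
  if (!dir.exists(frames_dir)) stop("missing frames directory: ", frames_dir)
  structure(list(frames_dir = frames_dir, out_dir = out_dir,
                 masks_dir = masks_dir, intrinsics_file = intrinsics_file,
                 schedule_file = schedule_file, ledger_file = ledger_file,
                 calibration_file = calibration_file,
                 exg_threshold = exg_threshold,
                 coverage_threshold = coverage_threshold,
                 harvest_threshold = harvest_threshold,
                 target_weight_g = target_weight_g,
                 height_method = height_method, height_prob = height_prob,
                 ransac = ransac, seed = as.integer(seed)),
            class = "run_config")
}

# Shared trait extraction: frames is a list of entries with `time_days`,
# `timestamp`, `density`, `frame` (frame_rgbd) and optionally `mask`.
# The ground plane is fitted on the non-lettuce pixels of the first
# (planting-day) frame and reused for every height measurement; the
# effective ground sampling distance follows from the fitted plane
# distance and the focal length.
analyze_frames <- function(frames, opts) {
  first <- frames[[1]]
  mask0 <- first$mask %||% exg_segment(first$frame$rgb, opts$exg_threshold)
  pts0 <- backproject(first$frame$depth, first$frame$cam)
  bg <- !mask0[cbind(pts0$row, pts0$col)]
  if (sum(bg) < 3) stop("planting-day frame has too few background pixels for a plane fit")
  plane <- fit_ground_plane(pts0$xyz[bg, , drop = FALSE],
                            iterations = opts$ransac$iterations %||% 1000,
                            threshold = opts$ransac$threshold %||% 5,
                            seed = opts$seed)
  cam <- first$frame$cam
  gsd <- -plane$d / cam$fx  # mm per pixel at the fitted ground distance

  traits <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    mask <- fr$mask %||% exg_segment(fr$frame$rgb, opts$exg_threshold)
    cov <- coverage(mask)
    if (cov > 0) {
      pts <- backproject(fr$frame$depth, fr$frame$cam)
      hm <- height_map(pts, plane, mask, method = opts$height_method)
      mh <- max_height(hm, opts$height_prob)
      vol <- volume_per_plant(hm, gsd, fr$density)
    } else {
      mh <- 0; vol <- 0
    }
    traits[[k]] <- trait_record(fr$time_days, cov, mh, fr$density,
                                volume_cm3 = vol, timestamp = fr$timestamp)
  }
  list(plane = plane, gsd = gsd, traits = do.call(rbind, traits))
}

#' Analyze a synthetic batch in memory
#'
#' Runs the measurement pipeline (segmentation, plane fit, heights,
#' traits, spacing evaluation, harvest date) directly on a
#' [simulate_batch()] result, without touching disk.
#'
#' @param batch a `synthetic_batch`.
#' @param segmenter `"exg"` (measure masks from the rendered RGB) or
#'   `"ground-truth"` (use the generator's masks).
#' @param exg_threshold threshold for the excess-green segmenter.
#' @param height_method,height_prob see [height_map()] / [max_height()].
#' @param ransac list of [fit_ground_plane()] settings.
#' @param seed seed for the plane fit (defaults to the batch's own).
#' @param weight_model optional [fit_weight_model()]; its threshold drives
#'   the harvest date.
#' @param harvest_threshold fallback harvest threshold, cm^3.
#' @return List with `plane`, `gsd`, `traits`, `spacing` and `harvest`.
#' @export
analyze_batch <- function(batch, segmenter = c("exg", "ground-truth"),
                          exg_threshold = 20,
                          height_method = "point_to_plane", height_prob = 1,
                          ransac = list(iterations = 1000, threshold = 5),
                          seed = NULL, weight_model = NULL,
                          harvest_threshold = 7840) {
  stopifnot(inherits(batch, "synthetic_batch"))
  segmenter <- match.arg(segmenter)
  frames <- lapply(batch$frames, function(fr) {
    list(time_days = fr$time_days, timestamp = fr$timestamp,
         density = fr$density, frame = fr$frame,
         mask = if (segmenter == "ground-truth") fr$mask else NULL)
  })
  opts <- list(exg_threshold = exg_threshold, ransac = ransac,
               seed = seed %||% batch$cfg$seed,
               height_method = height_method, height_prob = height_prob)
  res <- analyze_frames(frames, opts)
  res$spacing <- evaluate_schedule(res$traits)
  res$harvest <- harvest_date(res$traits, model = weight_model,
                              threshold = harvest_threshold)
  res
}

#' Run the full pipeline on a frames directory
#'
#' Reads the frames and sidecars named by the configuration, fits the
#' planting-day ground plane, computes the per-frame trait series, the
#' light loss of every spacing event, the recommended harvest date (after
#' recalibrating the weight model when calibration pairs are supplied) and
#' the economics ledger when one is provided, then writes `traits.csv`,
#' `spacing.csv` and `report.json` to the output directory. Outputs are a
#' pure function of the inputs and the seed: re-running an identical
#' configuration reproduces them byte for byte.
#'
#' @param config a [run_config()].
#' @return A `batch_report` list (also written to `out_dir`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cam <- read_intrinsics(config$intrinsics_file)
  schedule <- read_schedule(config$schedule_file)
  depth_files <- sort(list.files(config$frames_dir, "_depth\\.(tif|tiff|png)$",
                                 full.names = TRUE))
  if (length(depth_files) == 0)
    stop("no depth frames found in ", config$frames_dir)
  stamps <- vapply(depth_files, parse_frame_timestamp, character(1))
  ord <- order(timestamp_to_time(stamps))
  depth_files <- depth_files[ord]; stamps <- stamps[ord]
  t0 <- timestamp_to_time(stamps[1])

  frames <- vector("list", length(depth_files))
  for (k in seq_along(depth_files)) {
    stem <- sub("_depth\\.(tif|tiff|png)$", "", depth_files[k])
    frame <- read_frame(depth_files[k], paste0(stem, "_rgb.png"), cam)
    mask <- NULL
    if (!is.null(config$masks_dir)) {
      mp <- file.path(config$masks_dir, paste0(stamps[k], "_mask.png"))
      if (!file.exists(mp)) stop("external mask missing for frame: ", stamps[k])
      mask <- read_mask(mp)
    }
    td <- as.numeric(difftime(timestamp_to_time(stamps[k]), t0, units = "days"))
    frames[[k]] <- list(time_days = td, timestamp = stamps[k],
                        density = density_at(schedule, td),
                        frame = frame, mask = mask)
  }

  res <- analyze_frames(frames, config)
  spacing <- evaluate_schedule(res$traits)

  wm <- NULL
  threshold <- config$harvest_threshold
  if (!is.null(config$calibration_file)) {
    cal <- read_versioned_csv(config$calibration_file, "calibration")
    wm <- fit_weight_model(cal$indicator_cm3, cal$weight_g,
                           target = config$target_weight_g)
    threshold <- wm$threshold_cm3
  }
  harvest <- harvest_date(res$traits, threshold = threshold)

  economics <- NULL
  if (!is.null(config$ledger_file)) {
    lj <- jsonlite::read_json(config$ledger_file, simplifyVector = TRUE)
    ledger <- economic_ledger(income = lj$income, fixed = lj$fixed %||% 0,
                              heating = lj$heating %||% 0,
                              electricity = lj$electricity %||% 0,
                              co2 = lj$co2 %||% 0,
                              interventions = lj$interventions %||% 0,
                              total_operational = lj$total_operational)
    economics <- c(unclass(ledger), net_profit = net_profit(ledger))
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # the hash covers every analysis-relevant setting; the output location
  # (where this record itself lives) is not one of them
  cfg_json <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(unclass(config)[setdiff(names(config), "out_dir")],
                       cfg_json, auto_unbox = TRUE, digits = NA, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_json))

  traits_out <- res$traits
  traits_out$config_hash <- cfg_hash
  spacing_out <- spacing
  if (nrow(spacing_out) > 0) spacing_out$config_hash <- cfg_hash
  write_versioned_csv(traits_out, file.path(config$out_dir, "traits.csv"),
                      "traits")
  write_versioned_csv(spacing_out, file.path(config$out_dir, "spacing.csv"),
                      "spacing")

  report <- list(config_hash = cfg_hash, seed = config$seed,
                 package_version = as.character(utils::packageVersion("lettucecv")),
                 n_frames = length(frames),
                 gsd_mm = res$gsd,
                 plane = list(normal = res$plane$normal, d = res$plane$d,
                              inliers = res$plane$inliers,
                              residual_mm = res$plane$residual_mm),
                 harvest = harvest,
                 weight_model = if (!is.null(wm)) unclass(wm),
                 spacing_verdicts = if (nrow(spacing) > 0) spacing$verdict,
                 economics = economics)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(structure(c(report, list(traits = res$traits, spacing = spacing)),
                      class = "batch_report"))
}
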