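#' Configuration of the synthetic greenhouse scene generator
#'
#' Describes one simulated batch of lettuce imaged top-down by a fixed
#' RGB-D camera about 1 m above the crop. Plants are spherical caps (dome
#' at most a hemisphere, cap height <= base radius) growing logistically on
#' a slightly tilted ground plane; the batch is re-spaced down the density
#' ladder according to `schedule`. All randomness (per-plant variability,
#' depth noise) is driven by `seed`: identical configurations give
#' byte-identical batches.
#'
#' @param seed integer RNG seed.
#' @param days cultivation length in days; frames cover day 0 (planting)
#'   up to, not including, day `days`.
#' @param frames_per_day frames captured per day, evenly spaced.
#' @param gsd ground sampling distance at the nominal camera-to-ground
#'   distance, mm per pixel (> 0).
#' @param image_size `(rows, cols)` of the rasters.
#' @param camera_height camera-to-ground distance along the optical axis, mm.
#' @param plane_tilt ground-plane tilt in degrees, `[0, 10)`; the tilt is on
#'   the plane (about the image y-axis), the camera stays nadir.
#' @param depth_noise_sd Gaussian depth noise, mm (0 disables).
#' @param growth list: `radius0`, `height0` initial cap radius/height (mm);
#'   `radius_max`, `height_max` logistic asymptotes (mm, height_max <=
#'   radius_max); `rate_radius`, `rate_height` logistic rates (1/day);
#'   `cv` coefficient of variation of per-plant asymptotes (0 = uniform
#'   plants).
#' @param allometry list: `c0`, `c1`, `c2` quadratic coefficients mapping
#'   the true per-plant indicator (projected area cm^2 times cap height cm)
#'   to fresh weight in g, and `noise_sd`, the per-plant weight scatter in g.
#' @param schedule a [density_schedule()], or `NULL` to construct a
#'   near-optimally timed one with [plan_balanced_schedule()] at simulation
#'   time.
#' @param start_date calendar date of planting (frames get ISO timestamps).
#' @return A `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       days = 50,
                       frames_per_day = 1L,
                       gsd = 2,
                       image_size = c(256L, 256L),
                       camera_height = 1000,
                       plane_tilt = 1,
                       depth_noise_sd = 2,
                       growth = list(),
                       allometry = list(),
                       schedule = NULL,
                       start_date = "2022-05-03") {
  stopifnot(gsd > 0, camera_height > 0, days >= 1, frames_per_day >= 1,
            length(image_size) == 2, all(image_size >= 16),
            depth_noise_sd >= 0)
  if (plane_tilt < 0 || plane_tilt >= 10)
    stop("plane tilt must be in [0, 10) degrees")
  growth <- modifyList(list(radius0 = 15, height0 = 12,
                            radius_max = 160, height_max = 128,
                            rate_radius = 0.13, rate_height = 0.13,
                            cv = 0.05), growth)
  if (growth$height0 > growth$radius0 || growth$height_max > growth$radius_max)
    stop("cap height must not exceed base radius (dome model)")
  allometry <- modifyList(list(c0 = 10, c1 = 0.0212, c2 = 1.2e-6,
                               noise_sd = 20), allometry)
  if (!is.null(schedule)) stopifnot(inherits(schedule, "density_schedule"))
  structure(list(seed = as.integer(seed), days = days,
                 frames_per_day = as.integer(frames_per_day), gsd = gsd,
                 image_size = as.integer(image_size),
                 camera_height = camera_height, plane_tilt = plane_tilt,
                 depth_noise_sd = depth_noise_sd, growth = growth,
                 allometry = allometry, schedule = schedule,
                 start_date = start_date),
            class = "sim_config")
}

#' Intrinsics of the simulated camera
#'
#' Focal length is chosen so one pixel spans `gsd` mm on the ground at the
#' nominal camera height; the principal point is the image centre.
#'
#' @param cfg a [sim_config()].
#' @return A [camera_intrinsics()].
#' @export
sim_intrinsics <- function(cfg) {
  f <- cfg$camera_height / cfg$gsd
  camera_intrinsics(fx = f, fy = f,
                    cx = (cfg$image_size[2] - 1) / 2,
                    cy = (cfg$image_size[1] - 1) / 2,
                    width = cfg$image_size[2], height = cfg$image_size[1])
}

# True scene ground plane (n . p = d, unit normal toward the camera).
# Tilt is about the y-axis: n = (sin t, 0, -cos t), passing through
# (0, 0, camera_height).
sim_plane_truth <- function(cfg) {
  t <- cfg$plane_tilt * pi / 180
  n <- c(sin(t), 0, -cos(t))
  list(normal = n, d = -cfg$camera_height * cos(t))
}

#' Ground-intersection geometry of every pixel ray
#'
#' For each pixel, the camera ray is intersected with the true ground
#' plane, giving the ground depth `zg` and the ground-plane world
#' coordinates `(x, y)` (mm) at which plant height fields are sampled.
#'
#' @param cfg a [sim_config()].
#' @return List of matrices `x`, `y`, `zg` (rows x cols) plus the
#'   intrinsics `cam` and the true plane.
#' @export
frame_geometry <- function(cfg) {
  cam <- sim_intrinsics(cfg)
  rows <- cfg$image_size[1]; cols <- cfg$image_size[2]
  u <- (seq_len(cols) - 1) - cam$cx
  v <- (seq_len(rows) - 1) - cam$cy
  tant <- tan(cfg$plane_tilt * pi / 180)
  zg_col <- cfg$camera_height / (1 - tant * u / cam$fx)  # per column
  zg <- matrix(zg_col, rows, cols, byrow = TRUE)
  x <- matrix(u / cam$fx * zg_col, rows, cols, byrow = TRUE)
  y <- (v / cam$fy) %o% zg_col
  list(x = x, y = y, zg = zg, cam = cam, plane = sim_plane_truth(cfg))
}

#' Elevation field of one spherical-cap plant
#'
#' A plant is modelled as a spherical cap of base radius `a` and apex
#' height `h` (mm, `0 < h <= a`) standing on the ground: elevation at
#' in-plane distance `r` from the centre is
#' `sqrt(R^2 - r^2) - (R - h)` with sphere radius `R = (a^2 + h^2) / (2 h)`,
#' and 0 outside `r >= a`. The apex equals `h`, the boundary is 0, and the
#' enclosed volume has the closed form `pi h (3 a^2 + h^2) / 6`.
#'
#' @param plant list or one-row data.frame with `x`, `y` (centre, mm),
#'   `radius`, `height` (mm).
#' @param grid list with matrices `x` and `y` of ground coordinates (mm),
#'   e.g. from [frame_geometry()].
#' @return Elevation matrix (mm), 0 outside the cap.
#' @export
cap_height_field <- function(plant, grid) {
  a <- plant$radius; h <- plant$height
  if (is.na(a) || a <= 0) stop("cap base radius must be positive")
  if (is.na(h) || h <= 0) stop("cap height must be positive")
  if (h > a) stop("cap height must not exceed base radius (dome model)")
  r2 <- (grid$x - plant$x)^2 + (grid$y - plant$y)^2
  R <- (a^2 + h^2) / (2 * h)
  e <- sqrt(pmax(R^2 - r2, 0)) - (R - h)
  e[r2 >= a^2] <- 0
  pmax(e, 0)
}

#' Closed-form volume of a spherical-cap plant
#'
#' @param a base radius (mm or any length unit).
#' @param h cap height (same unit).
#' @return Volume in the unit cubed.
#' @export
cap_volume <- function(a, h) pi * h * (3 * a^2 + h^2) / 6

# Grid positions for a density: a square grid at the density's pitch with
# one plant anchored on the optical axis (so successive layouts stay in
# phase), extended `margin` mm beyond the imaged window so border pixels
# see the plants whose centres fall just outside. Ordered by distance from
# the centre (ties broken by x then y) so re-spacing maps plants
# deterministically.
layout_positions <- function(density, cfg, margin = cfg$growth$radius_max) {
  s <- 1000 / sqrt(density)  # grid pitch, mm
  mx <- ceiling((cfg$image_size[2] * cfg$gsd / 2 + margin) / s)
  my <- ceiling((cfg$image_size[1] * cfg$gsd / 2 + margin) / s)
  pos <- expand.grid(x = (-mx:mx) * s, y = (-my:my) * s,
                     KEEP.OUT.ATTRS = FALSE)
  pos[order(pos$x^2 + pos$y^2, pos$x, pos$y), , drop = FALSE]
}

# Draw the pool of per-plant attributes (asymptote jitter, weight scatter,
# hue jitter). Consumes the session RNG.
draw_plant_pool <- function(n, cfg) {
  g <- cfg$growth
  mult <- if (g$cv > 0) pmax(0.5, rnorm(n, 1, g$cv)) else rep(1, n)
  data.frame(id = seq_len(n),
             radius_max = g$radius_max * mult,
             height_max = g$height_max * mult,
             weight_err = rnorm(n, 0, cfg$allometry$noise_sd),
             hue = runif(n, -25, 25))
}

init_plants <- function(cfg, density) {
  pos <- layout_positions(density, cfg)
  pool <- draw_plant_pool(nrow(pos), cfg)
  data.frame(id = pool$id, x = pos$x, y = pos$y,
             radius = cfg$growth$radius0, height = cfg$growth$height0,
             radius_max = pool$radius_max, height_max = pool$height_max,
             weight_err = pool$weight_err, hue = pool$hue)
}

#' Grow plants by a time step
#'
#' Discrete logistic growth of cap radius and height toward the per-plant
#' asymptotes: `a <- a + rate * a * (1 - a / a_max) * dt`. Traits are
#' non-decreasing and approach the asymptote; a zero rate freezes growth.
#'
#' @param plants plant state data.frame (see [simulate_batch()]).
#' @param growth growth parameter list from [sim_config()].
#' @param dt time step in days.
#' @return Updated plant data.frame.
#' @export
grow_plants <- function(plants, growth, dt = 1) {
  plants$radius <- plants$radius +
    growth$rate_radius * plants$radius * (1 - plants$radius / plants$radius_max) * dt
  plants$height <- plants$height +
    growth$rate_height * plants$height * (1 - plants$height / plants$height_max) * dt
  plants
}

#' Re-lay plants on the grid of a new (lower) density
#'
#' Spacing moves plants apart without touching their growth state: the new
#' grid at `density` is populated from the centre outward with the plants
#' previously nearest the centre, radii and heights unchanged. The imaged
#' window then holds fewer, wider-spaced heads.
#'
#' @param plants plant state data.frame.
#' @param density new density (heads/m^2); must be lower than the pitch of
#'   the current layout implies.
#' @param cfg the [sim_config()].
#' @return Plant data.frame at the new layout.
#' @export
space_plants <- function(plants, density, cfg) {
  pos <- layout_positions(density, cfg)
  n_new <- nrow(pos)
  ord <- order(plants$x^2 + plants$y^2, plants$x, plants$y)
  keep <- plants[ord, , drop = FALSE]
  if (n_new > nrow(keep)) {
    # wider margin can ask for more border plants than exist: clone the
    # outermost state (identical under zero cv; negligible otherwise)
    extra <- keep[rep(nrow(keep), n_new - nrow(keep)), , drop = FALSE]
    extra$id <- max(plants$id) + seq_len(nrow(extra))
    keep <- rbind(keep, extra)
  }
  keep <- keep[seq_len(n_new), , drop = FALSE]
  keep$x <- pos$x
  keep$y <- pos$y
  rownames(keep) <- NULL
  keep
}

#' Advance the batch state by one frame interval
#'
#' Grows all plants by `to - from` days and applies any schedule events
#' with day in `(from, to]`. Schedules that would increase density are
#' rejected by [density_schedule()] itself.
#'
#' @param state list with elements `plants` and `density`.
#' @param cfg the [sim_config()].
#' @param schedule a [density_schedule()].
#' @param from,to previous and current frame times (days).
#' @return Updated state.
#' @export
grow_and_space <- function(state, cfg, schedule, from, to) {
  state$plants <- grow_plants(state$plants, cfg$growth, to - from)
  ev <- schedule$day > from & schedule$day <= to
  if (any(ev)) {
    new_density <- schedule$density[max(which(ev))]
    state$plants <- space_plants(state$plants, new_density, cfg)
    state$density <- new_density
  }
  state
}

#' Allometric fresh weight from the true per-plant indicator
#'
#' Ground-truth relation of the generator: fresh weight is a quadratic in
#' the indicator `x = projected area (cm^2) * cap height (cm)`,
#' `w = c0 + c1 x + c2 x^2 + noise`, clamped at 0. The default coefficients
#' put the 250 g target crossing near an indicator of 7.8e3 cm^3.
#'
#' @param area_cm2 projected area(s), cm^2 (>= 0).
#' @param hmax_cm cap height(s), cm (>= 0).
#' @param params allometry list (`c0`, `c1`, `c2`, `noise_sd`).
#' @param noise optional explicit noise vector in g; by default drawn from
#'   `N(0, noise_sd)` using the session RNG.
#' @return Fresh weight(s) in g.
#' @export
allometric_weight <- function(area_cm2, hmax_cm, params = sim_config()$allometry,
                              noise = NULL) {
  stopifnot(all(area_cm2 >= 0), all(hmax_cm >= 0))
  x <- area_cm2 * hmax_cm
  w <- params$c0 + params$c1 * x + params$c2 * x^2
  if (is.null(noise))
    noise <- if (params$noise_sd > 0) rnorm(length(w), 0, params$noise_sd) else 0
  pmax(w + noise, 0)
}

#' True indicator crossing of the generator's allometry
#'
#' The smallest indicator value at which the noise-free allometric weight
#' reaches `target` grams -- the ground truth that a fitted
#' [fit_weight_model()] threshold is compared against.
#'
#' @param params allometry list.
#' @param target target weight in g (default 250).
#' @return Indicator in cm^3.
#' @export
true_weight_crossing <- function(params = sim_config()$allometry, target = 250) {
  quad_crossing(params$c0, params$c1, params$c2, target)
}

class_of_weight <- function(w) {
  ifelse(w >= 250, "A", ifelse(w >= 220, "B", "C"))
}

# Attach ground-truth trait columns to a plant state.
plant_ground_truth <- function(plants, cfg) {
  plants$area_cm2 <- pi * plants$radius^2 / 100
  plants$height_cm <- plants$height / 10
  plants$indicator_cm3 <- plants$area_cm2 * plants$height_cm
  plants$weight_g <- allometric_weight(plants$area_cm2, plants$height_cm,
                                       cfg$allometry, noise = plants$weight_err)
  plants$class <- class_of_weight(plants$weight_g)
  plants
}

#' Render one synthetic RGB-D frame
#'
#' The canopy elevation at each pixel is the maximum over all plant cap
#' fields (overlapping leaves occlude; hidden leaf area contributes
#' nothing). Depth is the pixel ray's ground depth minus the elevation,
#' plus Gaussian noise of `cfg$depth_noise_sd` mm drawn from the session
#' RNG. RGB is a grey background with per-plant-jittered green canopy; the
#' ground-truth mask marks pixels with positive elevation.
#'
#' @param plants plant state data.frame (positions/sizes in mm).
#' @param cfg the [sim_config()].
#' @param geom optional precomputed [frame_geometry()] (saves rework in
#'   loops).
#' @param noise set `FALSE` to suppress depth noise regardless of the
#'   configuration.
#' @return List with `frame` (a `frame_rgbd`: `depth` mm matrix, `rgb`
#'   0..255 array, `cam`), `mask` (ground-truth `seg_mask`) and `plants`
#'   (state with ground-truth trait columns).
#' @export
render_frame <- function(plants, cfg, geom = NULL, noise = TRUE) {
  if (is.null(geom)) geom <- frame_geometry(cfg)
  rows <- cfg$image_size[1]; cols <- cfg$image_size[2]
  elev <- matrix(0, rows, cols)
  owner <- matrix(0L, rows, cols)
  for (i in seq_len(nrow(plants))) {
    e <- cap_height_field(plants[i, ], geom)
    upd <- e > elev
    if (any(upd)) {
      elev[upd] <- e[upd]
      owner[upd] <- i
    }
  }
  depth <- geom$zg - elev
  if (noise && cfg$depth_noise_sd > 0)
    depth <- depth + rnorm(length(depth), 0, cfg$depth_noise_sd)

  rgb <- array(120, dim = c(rows, cols, 3))
  canopy <- owner > 0L
  if (any(canopy)) {
    hue <- plants$hue[owner[canopy]]
    r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
    r[canopy] <- 50
    g[canopy] <- pmin(pmax(170 + hue, 0), 255)
    b[canopy] <- 70
    rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  }
  frame <- structure(list(depth = depth, rgb = rgb, cam = geom$cam),
                     class = "frame_rgbd")
  list(frame = frame,
       mask = as_seg_mask(elev > 0, provenance = "ground-truth"),
       plants = plant_ground_truth(plants, cfg))
}

#' Simulate a full synthetic batch
#'
#' Runs the generator over the whole cultivation: plants are initialised on
#' the planting-density grid, grown each frame interval, re-spaced at the
#' schedule's events, and rendered to RGB-D frames with ground-truth masks
#' and per-plant traits. All draws derive from `cfg$seed`, so the batch is
#' reproducible bit for bit.
#'
#' @param cfg a [sim_config()]. When `cfg$schedule` is `NULL` a
#'   near-optimally timed schedule is constructed first with
#'   [plan_balanced_schedule()].
#' @return A `synthetic_batch`: list with `cfg`, `schedule`, `intrinsics`,
#'   `plane_truth` and `frames` -- one element per frame holding
#'   `time_days`, `timestamp`, `density`, `frame`, `mask` and `plants`.
#' @export
simulate_batch <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  schedule <- cfg$schedule %||% plan_balanced_schedule(cfg)
  set.seed(cfg$seed)
  geom <- frame_geometry(cfg)
  dt <- 1 / cfg$frames_per_day
  times <- seq(0, cfg$days - dt, by = dt)
  state <- list(plants = init_plants(cfg, schedule$density[1]),
                density = schedule$density[1])
  frames <- vector("list", length(times))
  for (k in seq_along(times)) {
    if (k > 1)
      state <- grow_and_space(state, cfg, schedule, times[k - 1], times[k])
    rf <- render_frame(state$plants, cfg, geom = geom)
    frames[[k]] <- list(time_days = times[k],
                        timestamp = frame_timestamp(cfg, times[k]),
                        density = state$density,
                        frame = rf$frame, mask = rf$mask, plants = rf$plants)
  }
  structure(list(cfg = cfg, schedule = schedule, intrinsics = geom$cam,
                 plane_truth = geom$plane, frames = frames),
            class = "synthetic_batch")
}

# ISO-8601 compact timestamp for a frame time; frames within a day are
# spread over 08:00-20:00 (a single daily frame sits at noon).
frame_timestamp <- function(cfg, time_days) {
  day <- floor(time_days + 1e-9)
  frac <- time_days - day
  hour <- if (cfg$frames_per_day == 1) 12 else 8 + frac * 12
  tt <- as.POSIXct(cfg$start_date, tz = "UTC") + day * 86400 +
    round(hour * 3600)
  format(tt, "%Y%m%dT%H%M", tz = "UTC")
}

# Union-disc coverage (percent) of a uniform layout with radius a at a
# density, on the actual pixel grid -- the planner's forward model; it is
# exactly what a rendered ground-truth mask would measure.
layout_coverage <- function(density, a, cfg, geom) {
  pos <- layout_positions(density, cfg)
  covered <- matrix(FALSE, cfg$image_size[1], cfg$image_size[2])
  a2 <- a^2
  for (i in seq_len(nrow(pos))) {
    covered <- covered |
      ((geom$x - pos$x[i])^2 + (geom$y - pos$y[i])^2 < a2)
  }
  100 * sum(covered) / length(covered)
}

#' Construct a near-optimally timed spacing schedule
#'
#' Builds the density schedule a grower with perfect foresight would apply:
#' for every ladder transition, the spacing is placed at the frame interval
#' where the light-loss indicator of the event crosses zero. With
#' disc-shaped plants that balance point sits just past the moment the
#' heads start touching at the incoming density -- spacing exactly at
#' tangency still leaves the floor-light term ahead of the overlap term.
#' The planner scans the generator's own noise-free ground-truth masks
#' (nominal, jitter-free trajectory), so its timing is exact for uniform
#' plants and approximate within the per-plant scatter otherwise.
#'
#' @param cfg a [sim_config()] (its `schedule` is ignored).
#' @param ladder densities to pass through, highest first.
#' @return A [density_schedule()] whose events sit mid-way between the two
#'   frames they separate, with the planner's predicted light loss attached
#'   as attribute `planned_light_loss`.
#' @export
plan_balanced_schedule <- function(cfg, ladder = density_ladder()) {
  stopifnot(inherits(cfg, "sim_config"), length(ladder) >= 1)
  geom <- frame_geometry(cfg)
  dt <- 1 / cfg$frames_per_day
  times <- seq(0, cfg$days - dt, by = dt)
  nf <- length(times)
  # nominal trajectory, no per-plant jitter
  a <- numeric(nf); h <- numeric(nf)
  a[1] <- cfg$growth$radius0; h[1] <- cfg$growth$height0
  for (k in seq_len(nf - 1)) {
    a[k + 1] <- a[k] + cfg$growth$rate_radius * a[k] * (1 - a[k] / cfg$growth$radius_max) * dt
    h[k + 1] <- h[k] + cfg$growth$rate_height * h[k] * (1 - h[k] / cfg$growth$height_max) * dt
  }
  ev_day <- 0; ev_density <- ladder[1]; planned_ll <- NA_real_
  k <- 1L
  for (i in seq_len(length(ladder) - 1)) {
    d_prev <- ladder[i]; d_next <- ladder[i + 1]
    r <- d_next / d_prev
    ll_last <- NA_real_
    found <- FALSE
    while (k < nf) {
      c_prev <- layout_coverage(d_prev, a[k], cfg, geom)
      c_next <- layout_coverage(d_next, a[k + 1], cfg, geom)
      ll <- (100 - c_next) - (c_next - c_prev * r)
      if (ll <= 0) {
        if (!is.na(ll_last) && abs(ll_last) < abs(ll)) k <- k - 1L
        found <- TRUE
        break
      }
      ll_last <- ll
      k <- k + 1L
    }
    if (!found) {
      warning(sprintf("cultivation too short to reach the %g -> %g transition; schedule truncated",
                      d_prev, d_next))
      break
    }
    ev_day <- c(ev_day, times[k] + dt / 2)
    ev_density <- c(ev_density, d_next)
    planned_ll <- c(planned_ll,
                    (100 - layout_coverage(d_next, a[k + 1], cfg, geom)) -
                      (layout_coverage(d_next, a[k + 1], cfg, geom) -
                         layout_coverage(d_prev, a[k], cfg, geom) * r))
    k <- k + 1L
  }
  sched <- density_schedule(ev_day, ev_density, ladder = NULL)
  attr(sched, "planned_light_loss") <- planned_ll
  sched
}

#' Destructive fresh-weight calibration records
#'
#' Emulates the weekly destructive sampling used to calibrate the harvest
#' indicator: at regular intervals a few heads are picked at random and
#' their true indicator (projected area times cap height, the quantity the
#' allometry is defined on) is paired with their fresh weight, which
#' carries the generator's per-plant scatter. Sampling uses the session
#' RNG; seed it for reproducibility.
#'
#' @param batch a [simulate_batch()] result.
#' @param every_days sampling interval (default 7).
#' @param heads heads sampled per visit (default 5).
#' @return data.frame with `time_days`, `plant_id`, `indicator_cm3`,
#'   `weight_g`.
#' @export
calibration_records <- function(batch, every_days = 7, heads = 5) {
  stopifnot(inherits(batch, "synthetic_batch"))
  times <- vapply(batch$frames, `[[`, numeric(1), "time_days")
  pick_days <- seq(0, max(times), by = every_days)
  idx <- vapply(pick_days, function(d) which.min(abs(times - d)), integer(1))
  recs <- lapply(unique(idx), function(k) {
    p <- batch$frames[[k]]$plants
    j <- sample.int(nrow(p), min(heads, nrow(p)))
    data.frame(time_days = batch$frames[[k]]$time_days,
               plant_id = p$id[j],
               indicator_cm3 = p$indicator_cm3[j],
               weight_g = p$weight_g[j])
  })
  do.call(rbind, recs)
}
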