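test_that("spherical-cap field has the right peak, boundary and volume", {
  g <- list(x = matrix(seq(-60, 60, by = 0.5), 1), y = matrix(0, 1, 241))
  p <- plant_row(radius = 50, height = 50)
  e <- cap_height_field(p, g)
  expect_equal(e[g$x == 0], 50)                 # apex equals cap height
  expect_equal(e[abs(g$x) >= 50], rep(0, sum(abs(g$x) >= 50)))  # boundary

  # fine-grid integral vs analytic hemisphere volume (within 1%)
  xs <- seq(-52, 52, by = 0.5)
  gg <- list(x = outer(rep(1, length(xs)), xs), y = outer(xs, rep(1, length(xs))))
  v <- sum(cap_height_field(p, gg)) * 0.5^2
  expect_equal(v, 2 / 3 * pi * 50^3, tolerance = 0.01)

  # a flatter cap too
  p2 <- plant_row(radius = 50, height = 30)
  v2 <- sum(cap_height_field(p2, gg)) * 0.5^2
  expect_equal(v2, cap_volume(50, 30), tolerance = 0.01)

  expect_error(cap_height_field(plant_row(radius = 0), g), "radius")
  expect_error(cap_height_field(plant_row(radius = 10, height = 20), g),
               "height must not exceed")
})

test_that("rendered frames honour the scene: background, mask area, overlap", {
  cfg <- quiet_cfg(image_size = c(96L, 96L), gsd = 3)
  geom <- frame_geometry(cfg)

  # zero plants: all background, depth is exactly the plane depth
  rf0 <- render_frame(plant_row()[0, ], cfg, noise = FALSE)
  expect_equal(sum(rf0$mask), 0)
  expect_equal(rf0$frame$depth, geom$zg)
  expect_identical(attr(rf0$mask, "provenance"), "ground-truth")

  # one plant: mask pixel count matches the analytic disc within a
  # one-pixel boundary band
  a <- 40
  rf1 <- render_frame(plant_row(radius = a, height = 30), cfg, noise = FALSE)
  expect_equal(sum(rf1$mask) * cfg$gsd^2, pi * a^2,
               tolerance = 2 * pi * a * cfg$gsd / (pi * a^2))

  # two plants closer than the sum of radii: union strictly below the sum
  close <- rbind(plant_row(x = -20, radius = 40, height = 30),
                 plant_row(x = 20, radius = 40, height = 30, id = 2L))
  rf2 <- render_frame(close, cfg, noise = FALSE)
  expect_lt(sum(rf2$mask), 2 * sum(rf1$mask))

  # depth noise is applied when configured
  cfgn <- quiet_cfg(image_size = c(96L, 96L), gsd = 3, depth_noise_sd = 2)
  set.seed(1)
  rfn <- render_frame(plant_row()[0, ], cfgn)
  expect_equal(sd(rfn$frame$depth - geom$zg), 2, tolerance = 0.1)
})

test_that("ground-truth projected area agrees with the rendered mask for isolated plants", {
  cfg <- quiet_cfg(image_size = c(128L, 128L), gsd = 2)
  for (a in c(25, 40, 60)) {
    rf <- render_frame(plant_row(radius = a, height = 0.7 * a), cfg, noise = FALSE)
    mask_cm2 <- sum(rf$mask) * cfg$gsd^2 / 100
    expect_equal(mask_cm2, rf$plants$area_cm2[1],
                 tolerance = (2 * pi * a * cfg$gsd / 100) / rf$plants$area_cm2[1])
  }
})

test_that("logistic growth approaches asymptotes, freezes at rate zero", {
  growth <- quiet_cfg()$growth
  p <- plant_row(radius = 15, height = 12)
  p$radius_max <- 150; p$height_max <- 120
  for (i in 1:400) p <- grow_plants(p, growth)
  expect_equal(p$radius, 150, tolerance = 1e-3)
  expect_equal(p$height, 120, tolerance = 1e-3)

  frozen <- list(rate_radius = 0, rate_height = 0)
  q <- plant_row(radius = 33, height = 21)
  expect_identical(grow_plants(q, c(growth[setdiff(names(growth), names(frozen))], frozen)),
                   q)

  # growth is monotone non-decreasing
  p2 <- plant_row(radius = 15, height = 12)
  traj <- replicate(50, { p2 <<- grow_plants(p2, growth); p2$radius })
  expect_true(all(diff(traj) >= 0))
})

test_that("spacing preserves plant state and drops the in-window head count", {
  cfg <- quiet_cfg(image_size = c(128L, 128L), gsd = 4)
  plants <- lettucecv:::init_plants(cfg, 92)
  plants$radius <- 48
  spaced <- space_plants(plants, 60, cfg)
  # heads inside the imaged window thin out to the new density
  half <- 128 * 4 / 2
  in_window <- function(p) sum(abs(p$x) < half & abs(p$y) < half)
  expect_lt(in_window(spaced), in_window(plants))
  expect_true(all(spaced$radius == 48))          # radii unchanged
  expect_true(all(spaced$id %in% plants$id))
  # pitch of the new layout matches the new density
  pitch <- min(diff(sort(unique(spaced$x))))
  expect_equal(pitch, 1000 / sqrt(60), tolerance = 1e-9)
  # rejected upward schedules never reach spacing: the schedule refuses
  expect_error(density_schedule(c(0, 5), c(60, 92)), "decrease")
})

test_that("allometric weight is the quadratic with clamping, classes follow weight", {
  params <- list(c0 = 10, c1 = 0.0212, c2 = 1.2e-6, noise_sd = 0)
  expect_equal(allometric_weight(0, 0, params), 10)            # area 0 -> c0
  x <- 600 * 13
  expect_equal(allometric_weight(600, 13, params),
               10 + 0.0212 * x + 1.2e-6 * x^2)
  expect_equal(allometric_weight(10, 1, list(c0 = -50, c1 = 0, c2 = 0, noise_sd = 0)),
               0)                                              # clamped
  expect_identical(lettucecv:::class_of_weight(c(260, 250, 240, 220, 210)),
                   c("A", "A", "B", "B", "C"))
})

test_that("noiseless samples recover the allometric polynomial to 1e-6", {
  params <- list(c0 = 10, c1 = 0.0212, c2 = 1.2e-6, noise_sd = 0)
  x <- seq(200, 9000, length.out = 25)
  w <- allometric_weight(x / 10, 10, params)    # area = x/10 cm2, h = 10 cm
  wm <- fit_weight_model(x, w)
  expect_equal(unname(wm$coefficients), c(10, 0.0212, 1.2e-6), tolerance = 1e-6)
  expect_lt(wm$mae_g, 1e-8)
})

test_that("identical configurations give byte-identical batches", {
  cfg <- quiet_cfg(days = 6, depth_noise_sd = 2,
                   growth = list(cv = 0.05),
                   schedule = density_schedule(0, 92))
  b1 <- simulate_batch(cfg)
  b2 <- simulate_batch(cfg)
  expect_identical(b1, b2)
  b3 <- simulate_batch(quiet_cfg(days = 6, seed = 2L, depth_noise_sd = 2,
                                 growth = list(cv = 0.05),
                                 schedule = density_schedule(0, 92)))
  expect_false(identical(b1$frames[[1]]$frame$depth, b3$frames[[1]]$frame$depth))
})

test_that("ground-truth coverage rises between spacings and drops at them", {
  sched <- density_schedule(c(0, 8, 16), c(92, 60, 45))
  cfg <- quiet_cfg(days = 22, schedule = sched, image_size = c(128L, 128L))
  b <- simulate_batch(cfg)
  cov <- vapply(b$frames, function(f) coverage(f$mask), numeric(1))
  days <- vapply(b$frames, `[[`, numeric(1), "time_days")
  ev <- c(8, 16)
  for (k in seq_len(length(cov) - 1)) {
    crosses <- any(ev > days[k] & ev <= days[k + 1])
    if (crosses) expect_lt(cov[k + 1], cov[k]) else expect_gte(cov[k + 1], cov[k])
  }
})
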