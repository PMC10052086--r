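test_that("back-projection follows the pinhole model and skips invalid pixels", {
  cam <- camera_intrinsics(600, 600, 32, 32, 700, 65)
  depth <- matrix(1000, 65, 700)
  depth[1, 1] <- 0                      # invalid
  pts <- backproject(depth, cam)
  expect_equal(nrow(pts$xyz), 65 * 700 - 1)
  # principal ray: pixel (cx, cy) -> (0, 0, z)
  at <- which(pts$row == 33 & pts$col == 33)
  expect_equal(unname(pts$xyz[at, ]), c(0, 0, 1000))
  # similar triangles: 600 px right of cx at fx=600, z=1000 -> x = 1000 mm
  at <- which(pts$row == 33 & pts$col == 633)
  expect_equal(unname(pts$xyz[at, 1]), 1000)
  expect_false(any(pts$row == 1 & pts$col == 1))
  expect_error(backproject(matrix(0, 65, 700), cam), "no valid depth")
  expect_error(backproject(matrix(1, 2, 2), cam), "does not match")
})

test_that("projecting back-projected points reproduces pixel coordinates", {
  cam <- camera_intrinsics(500.3, 481.7, 31.2, 30.8, 64, 64)
  set.seed(3)
  depth <- matrix(runif(64 * 64, 500, 1500), 64, 64)
  pts <- backproject(depth, cam)
  uv <- project_points(pts$xyz, cam)
  expect_lt(max(abs(uv[, 1] - (pts$col - 1))), 1e-9)
  expect_lt(max(abs(uv[, 2] - (pts$row - 1))), 1e-9)
})

test_that("RANSAC recovers an exact plane and is deterministic given a seed", {
  set.seed(11)
  xy <- matrix(runif(600, -300, 300), ncol = 2)
  pts <- cbind(xy, 1000)
  pl <- fit_ground_plane(pts, seed = 5)
  expect_equal(pl$normal, c(0, 0, -1), tolerance = 1e-9)
  expect_equal(pl$d, -1000, tolerance = 1e-6)
  expect_identical(pl$normal, fit_ground_plane(pts, seed = 5)$normal)

  expect_error(fit_ground_plane(pts[1:2, ]), "at least 3")
  line <- cbind(seq_len(50), seq_len(50), 1000)  # collinear support
  expect_error(fit_ground_plane(line, seed = 1), "degenerate|collinear")
})

test_that("RANSAC resists gross outliers as well as a least-squares fit on the true inliers", {
  set.seed(21)
  n <- 1000
  tilt <- 3 * pi / 180
  nrm <- c(sin(tilt), 0, -cos(tilt))
  xy <- matrix(runif(2 * n, -400, 400), ncol = 2)
  z <- (-(1000) * cos(tilt) - nrm[1] * xy[, 1] - nrm[2] * xy[, 2]) / nrm[3]
  pts <- cbind(xy, z) + rnorm(3 * n, 0, 1)
  out <- seq_len(n) <= n * 0.2                 # 20% gross outliers
  pts[out, 3] <- pts[out, 3] - runif(sum(out), 50, 400)

  pl <- fit_ground_plane(pts, threshold = 5, seed = 9)
  expect_lt(plane_normal_error(pl, nrm), 0.5)

  # independent oracle: total-least-squares plane on the known inlier subset
  oracle <- lettucecv:::plane_lsq(pts[!out, ])
  ang <- acos(min(1, abs(sum(pl$normal * oracle$normal)))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("heights are point-to-plane distances in cm over lettuce pixels only", {
  cam <- camera_intrinsics(500, 500, 15.5, 15.5, 32, 32)
  depth <- matrix(1000, 32, 32)
  depth[10, 10] <- 950
  depth[20, 20] <- 1030                       # below the plane: clipped
  pts <- backproject(depth, cam)
  pl <- structure(list(normal = c(0, 0, -1), d = -1000, inliers = 0,
                       residual_mm = 0), class = "ground_plane")
  mask <- matrix(FALSE, 32, 32); mask[10, 10] <- TRUE; mask[20, 20] <- TRUE
  hm <- height_map(pts, pl, mask)
  expect_equal(hm[10, 10], 5)                 # 50 mm -> 5 cm
  expect_equal(hm[20, 20], 0)                 # clipped, not negative
  expect_true(all(is.na(hm[mask == FALSE])))
  expect_equal(sum(!is.na(hm)), 2)
  # a pixel exactly on the plane measures 0
  mask2 <- matrix(FALSE, 32, 32); mask2[5, 5] <- TRUE
  expect_equal(height_map(pts, pl, mask2)[5, 5], 0)
  # vertical and point-to-plane agree for a horizontal plane
  expect_equal(height_map(pts, pl, mask, method = "vertical")[10, 10], 5)
  expect_error(height_map(pts, pl, matrix(FALSE, 3, 3)), "mask size")
})

test_that("volume per plant matches the closed-form spherical-cap volume", {
  cfg <- quiet_cfg(image_size = c(128L, 128L), gsd = 2)
  rf <- render_frame(plant_row(radius = 50, height = 50), cfg, noise = FALSE)
  pts <- backproject(rf$frame$depth, rf$frame$cam)
  bg <- !rf$mask[cbind(pts$row, pts$col)]
  pl <- fit_ground_plane(pts$xyz[bg, ], seed = 2)
  hm <- height_map(pts, pl, rf$mask)
  area_m2 <- prod(dim(hm)) * (2 / 1000)^2
  v <- volume_per_plant(hm, 2, density = 1 / area_m2)
  expect_equal(v, cap_volume(5, 5), tolerance = 0.01)       # cm^3
  expect_equal(max_height(hm), 5, tolerance = 0.005)

  # doubling density with plant count doubled leaves per-plant volume alone
  two <- rbind(plant_row(x = -60, radius = 50, height = 50),
               plant_row(x = 60, radius = 50, height = 50, id = 2L))
  rf2 <- render_frame(two, cfg, noise = FALSE)
  hm2 <- height_map(backproject(rf2$frame$depth, rf2$frame$cam), pl, rf2$mask)
  expect_equal(volume_per_plant(hm2, 2, density = 2 / area_m2),
               volume_per_plant(hm, 2, density = 1 / area_m2),
               tolerance = 0.01)
  expect_equal(volume_per_plant(hm[0, 0, drop = FALSE], 2, 1), 0)
  expect_error(volume_per_plant(hm, 2, density = 0), "positive")
})

test_that("overlap never increases measured volume and isolated plants sum exactly", {
  cfg <- quiet_cfg(image_size = c(128L, 128L), gsd = 3)
  pl <- structure(list(normal = c(0, 0, -1), d = -1000, inliers = 0,
                       residual_mm = 0), class = "ground_plane")
  vol_of <- function(plants) {
    rf <- render_frame(plants, cfg, noise = FALSE)
    hm <- height_map(backproject(rf$frame$depth, rf$frame$cam), pl, rf$mask)
    area_m2 <- prod(dim(hm)) * (3 / 1000)^2
    volume_per_plant(hm, 3, density = 1 / area_m2)  # total volume, one "head"
  }
  apart <- rbind(plant_row(x = -100, radius = 45, height = 36),
                 plant_row(x = 100, radius = 55, height = 44, id = 2L))
  overlapping <- rbind(plant_row(x = -30, radius = 45, height = 36),
                       plant_row(x = 30, radius = 55, height = 44, id = 2L))
  v_apart <- vol_of(apart)
  expect_equal(v_apart, cap_volume(4.5, 3.6) + cap_volume(5.5, 4.4),
               tolerance = 0.02)
  expect_lt(vol_of(overlapping), v_apart)
})

test_that("upper-quantile height ignores single-pixel spikes", {
  hm <- structure(matrix(10, 100, 100), class = c("height_map", "matrix"))
  hm[50, 50] <- 100
  expect_equal(max_height(hm), 100)
  expect_equal(max_height(hm, prob = 0.99), 10)  # order statistic on 1e4 px
  empty <- structure(matrix(NA_real_, 4, 4), class = c("height_map", "matrix"))
  expect_warning(res <- max_height(empty), "undefined")
  expect_true(is.na(res))
})
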