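test_that("trait records follow the coverage/density arithmetic", {
  # worked example: 87.2% coverage at 15 heads/m2, 15.7 cm max height
  tr <- trait_record(0, 87.2, 15.7, 15)
  expect_equal(tr$area_per_plant_cm2, 0.872 / 15 * 1e4, tolerance = 1e-12)
  expect_equal(tr$indicator_cm3, 0.872 / 15 * 1e4 * 15.7, tolerance = 1e-12)
  expect_equal(round(tr$area_per_plant_cm2, 1), 581.3)
  expect_equal(round(tr$indicator_cm3), 9127)

  expect_equal(trait_record(0, 100, 10, 20)$indicator_cm3, 5000)
  expect_equal(trait_record(0, 0, 10, 20)$indicator_cm3, 0)
  expect_error(trait_record(0, 120, 10, 20))
})

test_that("light loss evaluates its two terms exactly", {
  # direct evaluation: 98% at 60 -> 80% at 45
  ev <- light_loss(98, 80, 60, 45)
  expect_equal(ev$theoretical_coverage, 73.5)
  expect_equal(ev$light_loss_before, 6.5)
  expect_equal(ev$light_loss_current, 20)
  expect_equal(ev$light_loss, 13.5)
  expect_identical(ev$verdict, "early")

  # 99% at 92 -> 95% at 60: strongly negative, spaced too late
  ev2 <- light_loss(99, 95, 92, 60)
  expect_equal(ev2$theoretical_coverage, 99 * 60 / 92)
  expect_equal(ev2$light_loss, 5 - (95 - 99 * 60 / 92))
  expect_equal(round(ev2$light_loss, 2), -25.43)
  expect_identical(ev2$verdict, "late")

  # the indicator is exactly the difference of its two loss terms, and
  # vanishes when floor loss balances overlap loss
  set.seed(5)
  for (rep in 1:20) {
    dp <- sample(c(92, 60, 45, 30), 1); dc <- dp * runif(1, 0.4, 0.9)
    cp <- runif(1, 40, 100); cc <- runif(1, 40, 100)
    e <- light_loss(cp, cc, dp, dc)
    expect_equal(e$light_loss, e$light_loss_current - e$light_loss_before)
  }
  balanced <- light_loss(90, (100 + 90 * 45 / 60) / 2, 60, 45)
  expect_equal(balanced$light_loss, 0)
  expect_identical(balanced$verdict, "near-optimal")

  expect_error(light_loss(90, 80, 45, 60), "decrease")
})

test_that("light loss grows more negative as pre-spacing overlap grows", {
  # all else fixed, higher hidden overlap (higher observed coverage after
  # spacing relative to the projection) pushes the indicator down
  lls <- vapply(seq(70, 95, by = 5),
                function(cc) light_loss(95, cc, 60, 45)$light_loss, numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("evaluate_schedule picks flanking frames and skips broken events", {
  tr <- rbind(trait_record(0, 50, 5, 92), trait_record(1, 60, 6, 92),
              trait_record(2, 45, 6, 60), trait_record(3, 50, 7, 60))
  ev <- evaluate_schedule(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$coverage_prev, 60)   # last frame before
  expect_equal(ev$coverage_curr, 45)   # first frame after
  expect_equal(ev$light_loss, light_loss(60, 45, 92, 60)$light_loss)

  # no transitions: empty evaluation with the right schema
  ev0 <- evaluate_schedule(tr[tr$density == 92, ])
  expect_equal(nrow(ev0), 0)
  expect_true(all(c("light_loss", "verdict") %in% names(ev0)))

  # an event before the first frame lacks a flank and is skipped
  sched <- density_schedule(c(0, 5), c(92, 60), ladder = NULL)
  expect_warning(ev2 <- evaluate_schedule(tr[3:4, ], schedule = sched),
                 "skipped")
  expect_equal(nrow(ev2), 0)
})

test_that("spacing recommendation applies the coverage threshold on the ladder", {
  expect_identical(recommend_spacing(97.9, 60)$action, "hold")
  r <- recommend_spacing(98.3, 60)
  expect_identical(r$action, "space")
  expect_equal(r$next_density, 45)
  expect_identical(recommend_spacing(99, 15)$action, "hold")  # ladder exhausted
  r2 <- recommend_spacing(95, 92, threshold = 90)
  expect_equal(r2$next_density, 60)
  expect_error(recommend_spacing(99, 60, threshold = 0))
})

test_that("weight calibration recovers exact quadratics and handles degenerate fits", {
  x <- c(500, 1500, 3000, 5200, 8000)
  w <- 12 + 0.03 * x + 5e-7 * x^2
  wm <- fit_weight_model(x, w)
  expect_equal(unname(wm$coefficients), c(12, 0.03, 5e-7), tolerance = 1e-6)
  expect_lt(wm$mae_g, 1e-9)
  expect_lt(wm$rmse_g, 1e-9)

  # threshold: smallest crossing of the target, checked against uniroot
  thr <- wm$threshold_cm3
  f <- function(z) 12 + 0.03 * z + 5e-7 * z^2 - 250
  oracle <- uniroot(f, c(0, 2e4), tol = 1e-10)$root
  expect_equal(thr, oracle, tolerance = 1e-6)
  expect_equal(predict(wm, thr), 250, tolerance = 1e-6)

  # constant weights: flat polynomial at the mean, threshold undefined
  wc <- fit_weight_model(c(1, 2, 3, 4), rep(100, 4))
  expect_equal(unname(wc$coefficients), c(100, 0, 0), tolerance = 1e-8)
  expect_true(is.na(wc$threshold_cm3))

  # already above target at indicator 0
  wa <- fit_weight_model(x, w + 300)
  expect_equal(wa$threshold_cm3, 0)

  expect_error(fit_weight_model(c(1, 1, 1, 2), c(5, 5, 5, 6)), "3 distinct")
})

test_that("harvest date is the first threshold crossing or reported absent", {
  tr <- do.call(rbind, lapply(0:9, function(d)
    trait_record(d, 50 + d, 10 + d / 2, 18)))
  # indicator rises monotonically; find its crossing by direct scan
  thr <- tr$indicator_cm3[7]
  h <- harvest_date(tr, threshold = thr)
  expect_equal(h$time_days, 6)
  h2 <- harvest_date(tr, threshold = max(tr$indicator_cm3) + 1)
  expect_true(is.na(h2$time_days))
  expect_error(harvest_date(tr[0, ]), "empty")

  # a weight model's threshold takes precedence
  wm <- fit_weight_model(c(1000, 2000, 4000), c(50, 120, 260), target = 250)
  h3 <- harvest_date(tr, model = wm)
  expect_equal(h3$threshold_cm3, wm$threshold_cm3)
})

test_that("the harvest indicator rises monotonically between spacings under growth", {
  sched <- density_schedule(c(0, 8), c(92, 60))
  cfg <- quiet_cfg(days = 16, schedule = sched, image_size = c(96L, 96L))
  b <- simulate_batch(cfg)
  res <- analyze_batch(b, segmenter = "ground-truth")
  tr <- res$traits
  same_density <- diff(tr$density) == 0
  expect_true(all(diff(tr$indicator_cm3)[same_density] >= -1e-9))
})
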