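#' Assemble the per-frame trait record
#'
#' Bundles the canopy traits of one frame into the row format all
#' downstream indicators consume. Area per plant follows from coverage and
#' the density in force, `(coverage/100) / density * 1e4` cm^2, and the
#' harvest indicator is area per plant times maximum height (cm^3).
#'
#' @param time_days frame time, days since planting.
#' @param coverage canopy coverage percent (0--100).
#' @param max_height_cm maximum (or upper-quantile) canopy height, cm.
#' @param density plant density in force, heads/m^2.
#' @param volume_cm3 per-plant canopy volume, cm^3 (optional, `NA` if not
#'   computed).
#' @param timestamp optional timestamp string carried through to reports.
#' @return One-row data.frame with columns `time_days`, `timestamp`,
#'   `coverage`, `density`, `max_height_cm`, `area_per_plant_cm2`,
#'   `volume_per_plant_cm3`, `indicator_cm3`.
#' @export
trait_record <- function(time_days, coverage, max_height_cm, density,
                         volume_cm3 = NA_real_, timestamp = NA_character_) {
  stopifnot(coverage >= 0, coverage <= 100, density > 0)
  area <- (coverage / 100) / density * 1e4
  data.frame(time_days = time_days, timestamp = timestamp,
             coverage = coverage, density = density,
             max_height_cm = max_height_cm,
             area_per_plant_cm2 = area,
             volume_per_plant_cm3 = volume_cm3,
             indicator_cm3 = area * max_height_cm)
}

#' Light loss of one spacing event
#'
#' Judges the timing of a spacing action from the coverage just before and
#' just after it. The floor-light loss after spacing is `100 - coverage_t`;
#' the overlap-light loss before spacing is the excess of the observed
#' post-spacing coverage over the theoretical one (previous coverage scaled
#' by the density ratio `density_t / density_t-1`) -- overlapping leaves
#' hidden before the move become visible after it. The indicator is their
#' difference:
#' `LightLoss = (100 - coverage_t) - (coverage_t - coverage_t-1 * density_t / density_t-1)`.
#' Values near zero mark well-timed spacing (heads just touching); negative
#' values mean the spacing came too late (overlap loss dominated), large
#' positive values that it came too early (floor loss dominates).
#'
#' @param coverage_prev,coverage_curr coverage percent just before / after
#'   the event.
#' @param density_prev,density_curr densities before / after; must
#'   decrease.
#' @param time event time (days), carried through.
#' @param band half-width (percentage points) of the "near-optimal" label
#'   around zero (default 5).
#' @return A `spacing_evaluation`: one-row data.frame with the event
#'   coverages, densities, the two loss terms, `light_loss` and a `verdict`
#'   in `{"near-optimal", "late", "early"}`.
#' @export
light_loss <- function(coverage_prev, coverage_curr, density_prev, density_curr,
                       time = NA_real_, band = 5) {
  stopifnot(coverage_prev >= 0, coverage_prev <= 100,
            coverage_curr >= 0, coverage_curr <= 100)
  if (density_curr >= density_prev)
    stop("spacing must decrease the density")
  theoretical <- coverage_prev * density_curr / density_prev
  ll_current <- 100 - coverage_curr
  ll_before <- coverage_curr - theoretical
  ll <- ll_current - ll_before
  verdict <- if (abs(ll) < band) "near-optimal" else if (ll < 0) "late" else "early"
  structure(data.frame(time_days = time,
                       coverage_prev = coverage_prev,
                       coverage_curr = coverage_curr,
                       density_prev = density_prev,
                       density_curr = density_curr,
                       theoretical_coverage = theoretical,
                       light_loss_current = ll_current,
                       light_loss_before = ll_before,
                       light_loss = ll,
                       verdict = verdict),
            class = c("spacing_evaluation", "data.frame"))
}

#' Evaluate every spacing event of a trait series
#'
#' Applies [light_loss()] to each density transition found in the series,
#' using the last frame before and the first frame after the event (the
#' indicator can only be computed once the spacing has happened). Events
#' without a flanking frame on both sides are skipped with a warning.
#'
#' @param traits data.frame of [trait_record()] rows, time-ordered.
#' @param schedule optional [density_schedule()]; by default transitions
#'   are read off the series' own `density` column.
#' @param band passed to [light_loss()].
#' @return A `spacing_evaluation` data.frame, one row per evaluated event
#'   (zero rows when the series has no transition).
#' @export
evaluate_schedule <- function(traits, schedule = NULL, band = 5) {
  stopifnot(is.data.frame(traits), nrow(traits) >= 1)
  traits <- traits[order(traits$time_days), , drop = FALSE]
  if (is.null(schedule)) {
    chg <- which(diff(traits$density) != 0)
    ev_days <- (traits$time_days[chg] + traits$time_days[chg + 1]) / 2
  } else {
    ev_days <- schedule$day[-1]
  }
  out <- list()
  for (ed in ev_days) {
    before <- traits[traits$time_days < ed, , drop = FALSE]
    after <- traits[traits$time_days >= ed, , drop = FALSE]
    if (nrow(before) == 0 || nrow(after) == 0 ||
        before$density[nrow(before)] <= after$density[1]) {
      warning(sprintf("spacing event at day %.2f lacks flanking frames; skipped", ed))
      next
    }
    b <- before[nrow(before), ]
    a <- after[1, ]
    out[[length(out) + 1]] <-
      light_loss(b$coverage, a$coverage, b$density, a$density,
                 time = ed, band = band)
  }
  if (length(out) == 0) {
    ev <- light_loss(50, 40, 92, 60)[0, ]  # empty frame with the schema
    rownames(ev) <- NULL
    return(ev)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spacing recommendation from current coverage
#'
#' The simple autonomous spacing rule: space to the next ladder density as
#' soon as coverage reaches the threshold (98% by default), hold otherwise
#' or when the ladder is exhausted.
#'
#' @param coverage current coverage percent.
#' @param density density currently in force.
#' @param threshold coverage threshold in percent, `(0, 100]`.
#' @param ladder admissible densities.
#' @return List with `action` (`"hold"` or `"space"`) and `next_density`
#'   (`NA` when holding).
#' @export
recommend_spacing <- function(coverage, density, threshold = 98,
                              ladder = density_ladder()) {
  stopifnot(threshold > 0, threshold <= 100,
            coverage >= 0, coverage <= 100)
  lower <- ladder[ladder < density]
  if (coverage >= threshold && length(lower) > 0)
    list(action = "space", next_density = max(lower))
  else
    list(action = "hold", next_density = NA_real_)
}

# Smallest x >= 0 at which c0 + c1 x + c2 x^2 reaches `target`; NA when the
# polynomial never reaches it.
quad_crossing <- function(c0, c1, c2, target) {
  f <- function(x) c0 + c1 * x + c2 * x^2 - target
  if (f(0) >= 0) return(0)
  if (abs(c2) < 1e-12) {
    if (c1 <= 0) return(NA_real_)
    return((target - c0) / c1)
  }
  disc <- c1^2 - 4 * c2 * (c0 - target)
  if (disc < 0) return(NA_real_)
  roots <- sort((-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2))
  cand <- roots[roots >= 0 & abs(vapply(roots, f, numeric(1))) < 1e-6]
  # keep upward crossings only: f must be negative just below the root
  cand <- cand[vapply(cand, function(r) f(r - max(1e-6, abs(r)) * 1e-6) < 0, logical(1))]
  if (length(cand) == 0) NA_real_ else cand[1]
}

#' Calibrate the quadratic fresh-weight model
#'
#' Least-squares fit of a second-order polynomial mapping the harvest
#' indicator (area per plant times maximum height, cm^3) to measured fresh
#' weight (g), as used to turn the image-derived indicator into a
#' non-destructive weight proxy. The harvest threshold is the smallest
#' indicator whose predicted weight reaches the target.
#'
#' @param indicator_cm3 indicator values of the calibration pairs; at
#'   least 3 distinct values are required.
#' @param weight_g measured fresh weights, g.
#' @param target target head weight in g (default 250, the sellable class-A
#'   minimum).
#' @return A `weight_model`: list with `coefficients` (`c0`, `c1`, `c2`),
#'   `threshold_cm3`, `target_g`, fit diagnostics `mae_g` and `rmse_g`, and
#'   the number of pairs `n`.
#' @export
fit_weight_model <- function(indicator_cm3, weight_g, target = 250) {
  stopifnot(length(indicator_cm3) == length(weight_g))
  if (length(unique(indicator_cm3)) < 3)
    stop("weight calibration needs at least 3 distinct indicator values")
  fit <- lm(weight_g ~ indicator_cm3 + I(indicator_cm3^2))
  cc <- unname(coef(fit))
  cc[is.na(cc)] <- 0
  resid <- weight_g - (cc[1] + cc[2] * indicator_cm3 + cc[3] * indicator_cm3^2)
  structure(list(coefficients = c(c0 = cc[1], c1 = cc[2], c2 = cc[3]),
                 threshold_cm3 = quad_crossing(cc[1], cc[2], cc[3], target),
                 target_g = target,
                 mae_g = mean(abs(resid)),
                 rmse_g = sqrt(mean(resid^2)),
                 n = length(weight_g)),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cc <- x$coefficients
  cat(sprintf("weight_model  w = %.4g + %.4g x + %.4g x^2  (n = %d)\n",
              cc[1], cc[2], cc[3], x$n))
  cat(sprintf("  MAE %.2f g  RMSE %.2f g  threshold %.0f cm^3 at target %g g\n",
              x$mae_g, x$rmse_g, x$threshold_cm3, x$target_g))
  invisible(x)
}

#' Predicted fresh weight from indicator values
#'
#' @param object a `weight_model`.
#' @param indicator_cm3 indicator values, cm^3.
#' @param ... unused.
#' @return Predicted weights in g.
#' @export
predict.weight_model <- function(object, indicator_cm3, ...) {
  cc <- object$coefficients
  cc[["c0"]] + cc[["c1"]] * indicator_cm3 + cc[["c2"]] * indicator_cm3^2
}

#' First time the harvest indicator reaches its threshold
#'
#' Scans a time-ordered trait series for the first frame whose harvest
#' indicator is at or above the threshold -- the recommended harvest date.
#' A batch that never crosses returns `NA` (reported as absence, not an
#' error).
#'
#' @param traits data.frame of [trait_record()] rows.
#' @param model optional `weight_model`; its `threshold_cm3` overrides
#'   `threshold`.
#' @param threshold indicator threshold in cm^3 (default 7840, the
#'   published crossing for the 250 g target).
#' @return List with `time_days`, `timestamp` and `indicator_cm3` of the
#'   crossing frame, or all-`NA` when never crossed.
#' @export
harvest_date <- function(traits, model = NULL, threshold = 7840) {
  stopifnot(is.data.frame(traits))
  if (nrow(traits) == 0) stop("empty trait series")
  if (!is.null(model)) {
    stopifnot(inherits(model, "weight_model"))
    threshold <- model$threshold_cm3
  }
  traits <- traits[order(traits$time_days), , drop = FALSE]
  hit <- which(traits$indicator_cm3 >= threshold)
  if (length(hit) == 0)
    return(list(time_days = NA_real_, timestamp = NA_character_,
                indicator_cm3 = NA_real_, threshold_cm3 = threshold))
  k <- hit[1]
  list(time_days = traits$time_days[k], timestamp = traits$timestamp[k],
       indicator_cm3 = traits$indicator_cm3[k], threshold_cm3 = threshold)
}
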