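#' The standard plant-density ladder
#'
#' Spacing systems for greenhouse lettuce admit a fixed set of plant
#' densities; a batch starts at the highest density and can only move down
#' the ladder. Values are heads per square metre of growing area.
#'
#' @export
density_ladder <- function() c(92, 60, 45, 30, 23, 18, 15)

#' Create a plant-density schedule
#'
#' A schedule is the ordered list of density transitions applied to one
#' batch: the density in force at time `t` is the last event at or before
#' `t`. Densities must decrease strictly over events (plants are never packed
#' closer) and, unless a custom `ladder` is supplied, must be drawn from the
#' standard ladder [density_ladder()].
#'
#' @param day numeric vector of event times in days since planting; the first
#'   event must be day 0 (the planting density).
#' @param density densities (heads/m^2) in force from each event onward.
#' @param ladder admissible densities, or `NULL` to allow any positive value.
#' @return A `density_schedule`: a data.frame with columns `day` and
#'   `density`, one row per event.
#' @examples
#' sched <- density_schedule(c(0, 10, 18, 25), c(92, 60, 45, 30))
#' density_at(sched, 12)   # 60
#' @export
density_schedule <- function(day, density, ladder = density_ladder()) {
  if (length(day) != length(density) || length(day) == 0L)
    stop("`day` and `density` must be non-empty and of equal length")
  if (is.unsorted(day, strictly = TRUE))
    stop("event days must be strictly increasing")
  if (day[1L] != 0)
    stop("the first event must be at day 0 (planting density)")
  if (any(density <= 0))
    stop("densities must be positive")
  if (any(diff(density) >= 0))
    stop("densities must decrease strictly over events (no re-packing)")
  if (!is.null(ladder) && !all(density %in% ladder))
    stop("densities must be drawn from the ladder: ",
         paste(ladder, collapse = ", "))
  structure(data.frame(day = as.numeric(day), density = as.numeric(density)),
            class = c("density_schedule", "data.frame"))
}

#' Density in force at given times
#'
#' @param schedule a [density_schedule()].
#' @param t numeric vector of times (days since planting).
#' @return Numeric vector of densities (heads/m^2).
#' @export
density_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "density_schedule"))
  idx <- findInterval(t, schedule$day)
  if (any(idx < 1L)) stop("times before planting (day 0) have no density")
  schedule$density[idx]
}

#' Expand a schedule to one density per whole day
#'
#' Day `d` (1-based, covering days `1..n_days` since transplanting) is
#' assigned the density in force at its start, i.e. at time `d - 1`.
#'
#' @param schedule a [density_schedule()].
#' @param n_days total number of cultivation days.
#' @return Numeric vector of length `n_days`.
#' @export
daily_densities <- function(schedule, n_days) {
  stopifnot(n_days >= 1)
  density_at(schedule, seq_len(n_days) - 1)
}

#' Delay one spacing event of a schedule
#'
#' Utility for constructing deliberately mistimed spacing scenarios: event
#' `which` (2 = the first actual transition) is moved `by` days later, with
#' an error if the shift would re-order events.
#'
#' @param schedule a [density_schedule()].
#' @param which index of the event to delay (>= 2).
#' @param by days to delay by (> 0).
#' @return A new `density_schedule`.
#' @export
delay_event <- function(schedule, which, by) {
  stopifnot(inherits(schedule, "density_schedule"),
            which >= 2, which <= nrow(schedule), by > 0)
  day <- schedule$day
  day[which] <- day[which] + by
  if (which < length(day) && day[which] >= day[which + 1L])
    stop("delay would re-order events")
  density_schedule(day, schedule$density, ladder = NULL)
}
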