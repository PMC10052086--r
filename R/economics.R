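#' Resource tariffs and head prices
#'
#' The price set of the production economics: heating energy 0.0375 €/kWh,
#' electricity 0.125 €/kWh on-peak (07:00--23:00, half-open) and
#' 0.075 €/kWh off-peak, CO2 0.12 €/kg, 1 € per manual intervention, and
#' head prices of 0.50 € (class A, >= 250 g), 0.40 € (class B, 220--250 g)
#' and 0.00 € (class C, non-sellable).
#'
#' @param heating_eur_kwh,electricity_on_peak_eur_kwh,electricity_off_peak_eur_kwh,co2_eur_kg,intervention_eur
#'   tariff overrides.
#' @param head_prices named vector of €/head for classes A, B, C.
#' @param target_weight_g sellable target weight, g.
#' @param on_peak_hours half-open clock-hour interval `[from, to)` of the
#'   on-peak electricity tariff.
#' @return A `tariffs` list.
#' @export
tariffs <- function(heating_eur_kwh = 0.0375,
                    electricity_on_peak_eur_kwh = 0.125,
                    electricity_off_peak_eur_kwh = 0.075,
                    co2_eur_kg = 0.12,
                    intervention_eur = 1,
                    head_prices = c(A = 0.50, B = 0.40, C = 0.00),
                    target_weight_g = 250,
                    on_peak_hours = c(7, 23)) {
  vals <- c(heating_eur_kwh, electricity_on_peak_eur_kwh,
            electricity_off_peak_eur_kwh, co2_eur_kg, intervention_eur,
            head_prices, target_weight_g)
  if (any(vals < 0)) stop("tariffs must be non-negative")
  stopifnot(all(c("A", "B", "C") %in% names(head_prices)))
  structure(list(heating_eur_kwh = heating_eur_kwh,
                 electricity_on_peak_eur_kwh = electricity_on_peak_eur_kwh,
                 electricity_off_peak_eur_kwh = electricity_off_peak_eur_kwh,
                 co2_eur_kg = co2_eur_kg,
                 intervention_eur = intervention_eur,
                 head_prices = head_prices,
                 target_weight_g = target_weight_g,
                 on_peak_hours = on_peak_hours),
            class = "tariffs")
}

#' Average crop density over a cultivation
#'
#' The per-square-metre basis of income and resource use: the harmonic mean
#' of the daily plant densities, `D / sum_d (1 / density_d)` over the `D`
#' cultivation days. It is bounded by the minimum and maximum daily density
#' and equals them only for a constant schedule.
#'
#' @param schedule a [density_schedule()], or a numeric vector of daily
#'   densities.
#' @param n_days total number of cultivation days (required with a
#'   schedule; ignored when daily densities are given).
#' @return Average density in heads/m^2.
#' @export
average_crop_density <- function(schedule, n_days = NULL) {
  dens <- if (inherits(schedule, "density_schedule")) {
    if (is.null(n_days)) stop("`n_days` is required with a schedule")
    daily_densities(schedule, n_days)
  } else {
    as.numeric(schedule)
  }
  if (any(dens <= 0)) stop("densities must be positive")
  length(dens) / sum(1 / dens)
}

#' Crop income per square metre
#'
#' Income is the class price averaged over the harvested quality-class
#' fractions, multiplied by the average number of heads per m^2 of growing
#' area.
#'
#' @param class_fractions named fractions of heads in classes A, B, C;
#'   must sum to 1 (tolerance 1e-9).
#' @param avg_density average crop density, heads/m^2.
#' @param prices a [tariffs()] object.
#' @return Income in €/m^2.
#' @export
crop_income <- function(class_fractions, avg_density, prices = tariffs()) {
  stopifnot(all(c("A", "B", "C") %in% names(class_fractions)),
            avg_density > 0)
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1")
  avg_density * sum(class_fractions[c("A", "B", "C")] *
                      prices$head_prices[c("A", "B", "C")])
}

#' Resource costs per square metre
#'
#' Heating energy is metered in MJ/m^2 but priced per kWh (1 kWh = 3.6 MJ
#' exactly); electricity is split by clock hour into the on-peak interval
#' `[07:00, 23:00)` and off-peak; CO2 is priced per kg.
#'
#' @param heating_mj heating energy use, MJ/m^2.
#' @param electricity_kwh electricity use: either a single on-peak total
#'   (with `electricity_off_peak_kwh` for the rest), or an hourly series
#'   paired with `hours`.
#' @param electricity_off_peak_kwh off-peak electricity, kWh/m^2.
#' @param hours optional clock hours (0--23, or POSIXct) of the entries of
#'   `electricity_kwh`; when given, the split is computed here.
#' @param co2_kg CO2 use, kg/m^2.
#' @param prices a [tariffs()] object.
#' @return List of cost components in €/m^2: `heating`, `electricity`,
#'   `co2`, and `total`.
#' @export
resource_costs <- function(heating_mj = 0, electricity_kwh = 0,
                           electricity_off_peak_kwh = 0, hours = NULL,
                           co2_kg = 0, prices = tariffs()) {
  if (any(c(heating_mj, electricity_kwh, electricity_off_peak_kwh, co2_kg) < 0))
    stop("resource use must be non-negative")
  if (!is.null(hours)) {
    if (inherits(hours, "POSIXt"))
      hours <- as.integer(format(hours, "%H"))
    stopifnot(length(hours) == length(electricity_kwh))
    on <- hours >= prices$on_peak_hours[1] & hours < prices$on_peak_hours[2]
    on_kwh <- sum(electricity_kwh[on])
    off_kwh <- sum(electricity_kwh[!on])
  } else {
    on_kwh <- sum(electricity_kwh)
    off_kwh <- sum(electricity_off_peak_kwh)
  }
  heating <- heating_mj / 3.6 * prices$heating_eur_kwh
  electricity <- on_kwh * prices$electricity_on_peak_eur_kwh +
    off_kwh * prices$electricity_off_peak_eur_kwh
  co2 <- co2_kg * prices$co2_eur_kg
  list(heating = heating, electricity = electricity, co2 = co2,
       total = heating + electricity + co2)
}

#' Assemble an economics ledger
#'
#' Collects the income and cost components of one cultivation in €/m^2.
#' Fixed costs (plant material, maintenance, depreciation) are an input,
#' not modelled. `total_operational` defaults to the sum of fixed plus the
#' three resource components, but a pre-totalled figure can be supplied
#' instead (as when reproducing a published breakdown whose components
#' were rounded independently of the total). A missing intervention entry
#' counts as zero interventions.
#'
#' @param income total income, €/m^2.
#' @param fixed fixed costs, €/m^2.
#' @param heating,electricity,co2 resource cost components, €/m^2.
#' @param interventions number of manual interventions (priced via the
#'   tariff), or `NA`/missing for none.
#' @param total_operational optional override of the operational-cost
#'   total, €/m^2.
#' @param prices a [tariffs()] object.
#' @return An `economic_ledger` list.
#' @export
economic_ledger <- function(income, fixed = 0, heating = 0, electricity = 0,
                            co2 = 0, interventions = 0,
                            total_operational = NULL, prices = tariffs()) {
  if (is.na(interventions) || is.null(interventions)) interventions <- 0
  comp_total <- fixed + heating + electricity + co2
  structure(list(income = income, fixed = fixed, heating = heating,
                 electricity = electricity, co2 = co2,
                 total_operational = total_operational %||% comp_total,
                 interventions = interventions,
                 intervention_cost = interventions * prices$intervention_eur),
            class = "economic_ledger")
}

#' Net profit of a cultivation
#'
#' Net profit is income minus the total operational costs (fixed plus
#' resource use) minus the intervention penalty.
#'
#' @param ledger an [economic_ledger()].
#' @return Net profit in €/m^2.
#' @export
net_profit <- function(ledger) {
  stopifnot(inherits(ledger, "economic_ledger"))
  ledger$income - ledger$total_operational - ledger$intervention_cost
}

#' @export
print.economic_ledger <- function(x, ...) {
  cat(sprintf("economic_ledger [EUR/m^2]\n"))
  cat(sprintf("  income               %8.2f\n", x$income))
  cat(sprintf("  fixed costs          %8.2f\n", x$fixed))
  cat(sprintf("  heating costs        %8.2f\n", x$heating))
  cat(sprintf("  electricity costs    %8.2f\n", x$electricity))
  cat(sprintf("  CO2 costs            %8.2f\n", x$co2))
  cat(sprintf("  total operational    %8.2f\n", x$total_operational))
  cat(sprintf("  interventions        %8.2f  (%g x)\n",
              x$intervention_cost, x$interventions))
  cat(sprintf("  net profit           %8.2f\n", net_profit(x)))
  invisible(x)
}
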