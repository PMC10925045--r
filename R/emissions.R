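#' Apportion national activity: turnover shares per airport and month
#'
#' Computes, for every (year, month) present in the activity table, the share
#' of national transport turnover (or of LTO movement counts) accounted for by
#' each airport. Shares within a month are non-negative and sum to one.
#'
#' @param activity A data frame with columns `year`, `month`, `airport`, and
#'   `turnover_tonkm` (ton-km; non-negative). When `basis = "lto_count"` a
#'   column `lto_count` is required instead.
#' @param basis Quantity shares are computed from: `"turnover"` (ton-km,
#'   default) or `"lto_count"` (number of landing-take-off movements).
#'
#' @return A tibble with columns `year`, `month`, `airport`, `share`.
#' @examples
#' act <- tibble::tibble(
#'   year = 2020, month = 6, airport = c("AAA", "BBB"),
#'   turnover_tonkm = c(100, 300)
#' )
#' compute_turnover_shares(act)
#' @export
compute_turnover_shares <- function(activity, basis = c("turnover", "lto_count")) {
  basis <- match.arg(basis)
  value_col <- if (basis == "turnover") "turnover_tonkm" else "lto_count"
  check_activity(activity, value_col)

  shares <- activity |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::mutate(.month_total = sum(.data[[value_col]])) |>
    dplyr::ungroup()
  if (any(shares$.month_total <= 0)) {
    bad <- shares[shares$.month_total <= 0, c("year", "month")]
    bad <- unique(bad)
    stop(
      "no activity to apportion: ", basis, " is zero for every airport in ",
      paste(sprintf("%d-%02d", bad$year, bad$month), collapse = ", "),
      call. = FALSE
    )
  }
  shares$share <- shares[[value_col]] / shares$.month_total
  tibble::as_tibble(shares[c("year", "month", "airport", "share")])
}

#' Fuel burn from turnover and unit ton-kilometre consumption
#'
#' @param turnover_tonkm Transport turnover in ton-km (non-negative).
#' @param unit_consumption_kg_per_tonkm Fuel burned per ton-km (kg/ton-km, > 0).
#' @return Fuel consumption in kg, `turnover * unit_consumption`.
#' @examples
#' compute_fuel(1000, 0.3)
#' @export
compute_fuel <- function(turnover_tonkm, unit_consumption_kg_per_tonkm) {
  stopifnot(is.numeric(turnover_tonkm), is.numeric(unit_consumption_kg_per_tonkm))
  if (any(turnover_tonkm < 0)) stop("turnover must be non-negative", call. = FALSE)
  if (any(unit_consumption_kg_per_tonkm < 0)) {
    stop("unit consumption must be non-negative", call. = FALSE)
  }
  turnover_tonkm * unit_consumption_kg_per_tonkm
}

#' PM2.5 emission mass from fuel burn and emission intensity
#'
#' The intensity abstracts the per-engine emission-index calculation into a
#' single grams-of-PM2.5-per-kilogram-of-fuel factor; the packaged default
#' elsewhere is 0.2772 g/kg, a fleet-average value for a modern
#' narrow-body-dominated fleet.
#'
#' @param fuel_kg Fuel burned, kg (non-negative).
#' @param intensity_g_per_kg Emission intensity, g PM2.5 per kg fuel (> 0).
#' @return PM2.5 mass in grams.
#' @examples
#' compute_emission_mass(300, 0.2772)
#' @export
compute_emission_mass <- function(fuel_kg, intensity_g_per_kg) {
  stopifnot(is.numeric(fuel_kg), is.numeric(intensity_g_per_kg))
  if (any(fuel_kg < 0)) stop("fuel must be non-negative", call. = FALSE)
  if (any(intensity_g_per_kg <= 0)) {
    stop("emission intensity must be positive", call. = FALSE)
  }
  fuel_kg * intensity_g_per_kg
}

#' Gregorian day count of a month
#'
#' @param year 4-digit year (vectorised).
#' @param month Month number 1-12 (vectorised).
#' @return Integer number of days, leap-year aware.
#' @examples
#' days_in_month(2020, 2) # 29
#' @export
days_in_month <- function(year, month) {
  if (any(month < 1 | month > 12 | month != floor(month))) {
    stop("month must be an integer in 1..12", call. = FALSE)
  }
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- as.Date(sprintf(
    "%04d-%02d-01",
    year + (month == 12), ifelse(month == 12, 1, month + 1)
  ))
  as.integer(nxt - first)
}

#' Average a monthly emission mass to an emission flow in g/s
#'
#' Divides the month's emitted mass by the number of seconds in that month
#' (days x 24 x 3600), giving the steady emission rate E used as the plume
#' source strength.
#'
#' @param mass_g Emitted PM2.5 mass in grams (non-negative).
#' @param year,month Calendar month the mass was emitted in.
#' @return Emission flow E in g/s.
#' @examples
#' mass_to_flow(2592000, 2021, 6) # 30 days -> 1 g/s
#' @export
mass_to_flow <- function(mass_g, year, month) {
  stopifnot(is.numeric(mass_g))
  if (any(mass_g < 0)) stop("mass must be non-negative", call. = FALSE)
  mass_g / (days_in_month(year, month) * 86400)
}

#' Per-airport monthly fuel, PM2.5 mass and emission flow
#'
#' Runs the full emission stage: each airport-month's turnover is multiplied
#' by that month's unit ton-kilometre consumption to get fuel burn, by the
#' emission intensity to get PM2.5 mass, and averaged over the month's seconds
#' to get the emission flow E (g/s). Airports with zero turnover get zero
#' emissions (rows are kept, so downstream tables stay rectangular).
#'
#' @param activity Data frame `year`, `month`, `airport`, `turnover_tonkm`.
#' @param fuel_params Either a single unit consumption (kg fuel per ton-km)
#'   applied everywhere, or a data frame `year`, `month`,
#'   `unit_consumption_kg_per_tonkm` joined by calendar month.
#' @param intensity Either a single emission intensity (g PM2.5 per kg fuel)
#'   or a data frame `year`, `intensity_g_per_kg` (a national annual average).
#'   Default 0.2772 g/kg.
#' @return A tibble `year`, `month`, `airport`, `fuel_kg`, `pm25_g`,
#'   `flow_g_per_s`.
#' @examples
#' act <- tibble::tibble(
#'   year = 2020, month = 6, airport = c("AAA", "BBB"),
#'   turnover_tonkm = c(1e6, 3e6)
#' )
#' compute_emissions(act, fuel_params = 0.29)
#' @export
compute_emissions <- function(activity, fuel_params, intensity = 0.2772) {
  check_activity(activity, "turnover_tonkm")

  out <- tibble::as_tibble(activity[c("year", "month", "airport", "turnover_tonkm")])
  if (is.data.frame(fuel_params)) {
    need <- c("year", "month", "unit_consumption_kg_per_tonkm")
    if (!all(need %in% names(fuel_params))) {
      stop("fuel_params must have columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    out <- dplyr::left_join(out, fuel_params[need], by = c("year", "month"))
    if (anyNA(out$unit_consumption_kg_per_tonkm)) {
      stop("fuel_params missing for some activity months", call. = FALSE)
    }
  } else {
    stopifnot(is.numeric(fuel_params), length(fuel_params) == 1)
    out$unit_consumption_kg_per_tonkm <- fuel_params
  }

  if (is.data.frame(intensity)) {
    need <- c("year", "intensity_g_per_kg")
    if (!all(need %in% names(intensity))) {
      stop("intensity must have columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    out <- dplyr::left_join(out, intensity[need], by = "year")
    if (anyNA(out$intensity_g_per_kg)) {
      stop("intensity missing for some activity years", call. = FALSE)
    }
  } else {
    stopifnot(is.numeric(intensity), length(intensity) == 1)
    out$intensity_g_per_kg <- intensity
  }

  out$fuel_kg <- compute_fuel(out$turnover_tonkm, out$unit_consumption_kg_per_tonkm)
  out$pm25_g <- compute_emission_mass(out$fuel_kg, out$intensity_g_per_kg)
  out$flow_g_per_s <- mass_to_flow(out$pm25_g, out$year, out$month)
  out[c("year", "month", "airport", "fuel_kg", "pm25_g", "flow_g_per_s")]
}

# shared input validation for activity tables
check_activity <- function(activity, value_col) {
  stopifnot(is.data.frame(activity))
  need <- c("year", "month", "airport", value_col)
  missing_cols <- setdiff(need, names(activity))
  if (length(missing_cols)) {
    stop("activity table lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(activity[[value_col]] < 0)) {
    stop(value_col, " must be non-negative", call. = FALSE)
  }
  key <- paste(activity$year, activity$month, activity$airport)
  if (anyDuplicated(key)) {
    stop("duplicate (year, month, airport) rows in activity table", call. = FALSE)
  }
  invisible(activity)
}
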