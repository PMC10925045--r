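#' Inverse-distance weights for monitoring stations
#'
#' Weight of station i is \eqn{d_i^{-p} / \sum_j d_j^{-p}}: the farther the
#' station, the smaller the weight. Weights form a probability vector.
#'
#' @param distance_km Station-to-airport distances in km (all > 0).
#' @param power IDW exponent p (> 0). Default 1, the plainest reading of
#'   "inverse distance".
#' @return Numeric weights summing to 1.
#' @examples
#' idw_weights(c(10, 20)) # 2/3, 1/3
#' idw_weights(c(10, 20), power = 2) # 0.8, 0.2
#' @export
idw_weights <- function(distance_km, power = 1) {
  stopifnot(is.numeric(distance_km), is.numeric(power), power > 0)
  if (length(distance_km) == 0) stop("no stations supplied", call. = FALSE)
  if (any(distance_km <= 0)) {
    stop("station distances must be positive", call. = FALSE)
  }
  w <- distance_km^(-power)
  w / sum(w)
}

#' Inverse-distance-weighted station average
#'
#' Averages observed concentrations over the stations within `radius_km` of
#' the airport, weighting each by inverse distance. The result lies between
#' the minimum and maximum retained observation.
#'
#' @param stations Data frame with columns `distance_km` and `observed_ugm3`.
#' @param power IDW exponent p. Default 1.
#' @param radius_km Stations farther than this are dropped before weighting.
#'   Default 50 km. `Inf` keeps all.
#' @return The weighted average concentration (same units as the input).
#' @examples
#' st <- tibble::tibble(distance_km = c(10, 20), observed_ugm3 = c(3, 0))
#' idw_average(st) # 2
#' @export
idw_average <- function(stations, power = 1, radius_km = 50) {
  stopifnot(is.data.frame(stations))
  need <- c("distance_km", "observed_ugm3")
  if (!all(need %in% names(stations))) {
    stop("stations table lacks columns: ",
      paste(setdiff(need, names(stations)), collapse = ", "),
      call. = FALSE
    )
  }
  keep <- stations$distance_km <= radius_km
  if (!any(keep)) {
    stop("no stations within ", radius_km, " km", call. = FALSE)
  }
  st <- stations[keep, ]
  sum(idw_weights(st$distance_km, power) * st$observed_ugm3)
}

#' Relative error of the modeled concentration against observations
#'
#' \eqn{|obs - mod| / obs}: the error rate of the modeled value taken
#' against the station-derived observed average.
#'
#' @param observed_avg Observed (station-average) concentration (> 0).
#' @param modeled Modeled concentration.
#' @return Relative error as a fraction (multiply by 100 for percent).
#' @examples
#' relative_error(2.767, 2.603) # ~0.059
#' @export
relative_error <- function(observed_avg, modeled) {
  stopifnot(is.numeric(observed_avg), is.numeric(modeled))
  if (any(observed_avg <= 0)) {
    stop("observed average must be positive", call. = FALSE)
  }
  abs(observed_avg - modeled) / observed_avg
}

#' Accuracy report: IDW station average versus modeled concentration
#'
#' @param stations Data frame `station_id`, `distance_km`, `observed_ugm3`.
#' @param modeled Modeled airport concentration (same units as observations).
#' @param power IDW exponent. Default 1.
#' @param radius_km Inclusion radius in km. Default 50.
#' @return A one-row tibble: `n_stations` (retained), `idw_average`,
#'   `modeled`, `relative_error`.
#' @export
validate_concentration <- function(stations, modeled, power = 1, radius_km = 50) {
  obs <- idw_average(stations, power = power, radius_km = radius_km)
  tibble::tibble(
    n_stations = sum(stations$distance_km <= radius_km),
    idw_average = obs,
    modeled = modeled,
    relative_error = relative_error(obs, modeled)
  )
}

#' Monitoring stations around Guangzhou Baiyun airport (CAN)
#'
#' Identifiers and straight-line distances (km) of the 16 national
#' monitoring stations within 50 km of CAN, usable as a validation fixture.
#' Distances only; observed concentrations must be supplied (e.g. via
#' [generate_station_observations()]).
#'
#' @return A tibble `station_id`, `distance_km` with 16 rows.
#' @examples
#' can_station_distances()
#' @export
can_station_distances <- function() {
  path <- system.file("extdata", "can_station_distances.csv",
    package = "aeroplume", mustWork = TRUE
  )
  readr::read_csv(path, col_types = "cd", progress = FALSE)
}
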