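#' Default seasonal multipliers for monthly aviation activity
#'
#' A mean-one profile over the calendar year with the summer-travel peak in
#' August and the post-holiday trough in February that characterise Chinese
#' aviation turnover (August ~9.2% of annual activity, February ~7.2%). The
#' profile is chosen so the ordering survives division by month length:
#' both monthly mass and the per-second emission flow (hence concentration)
#' are maximal in August and minimal in February.
#'
#' @return A numeric vector of 12 multipliers with mean 1, maximum in
#'   August and minimum in February.
#' @examples
#' seasonal_multipliers()
#' @export
seasonal_multipliers <- function() {
  c(0.98, 0.86, 0.97, 0.96, 0.99, 0.99, 1.06, 1.10, 1.05, 1.07, 1.00, 0.97)
}

#' Synthetic scenario configuration
#'
#' Describes a download-free national aviation activity scenario with the
#' statistical structure the pipeline assumes: multiplicative seasonality
#' peaking in August and troughing in February, multiplicative year-on-year
#' growth, an optional abrupt annual shock with gradual recovery toward the
#' pre-shock trend, heavy-tailed airport shares (a few hubs dominate), and
#' multiplicative log-normal noise on turnover.
#'
#' @param n_airports Number of airports. Default 20 (a compact test scale;
#'   use [full_scale_config()] for a 175-airport, 18-year demonstration).
#' @param years Integer vector of consecutive years. Default `2019:2021`.
#' @param base_national_turnover National monthly turnover (ton-km) in the
#'   first year before seasonality. Default 2.55e9.
#' @param annual_growth Year-on-year multiplicative growth of national
#'   turnover. Default 0.11.
#' @param seasonal Length-12 positive multipliers with mean 1, August the
#'   maximum and February the minimum. Default [seasonal_multipliers()].
#' @param shock_year Year hit by an abrupt activity shock (`NA` for none).
#'   Default the second configured year.
#' @param shock_depth Fractional drop of that year's activity relative to
#'   the no-shock counterfactual, in `[0, 1)`. Default 0.3165.
#' @param recovery_rate Year-on-year growth from the shock level in later
#'   years, until the pre-shock trend is rejoined. Default 0.0477.
#' @param coastal_fraction Probability an airport is coastal. Default 0.3.
#' @param share_concentration Gamma shape of the Dirichlet-type airport
#'   share draw; values < 1 make a few airports dominate. Default 0.5.
#' @param noise_sd Relative standard deviation of multiplicative log-normal
#'   turnover noise; 0 disables noise. Default 0.05.
#' @param unit_consumption Fuel burn per ton-km, kg. Default 0.29.
#' @param intensity Emission intensity, g PM2.5 per kg fuel. Default 0.2772.
#' @param seed Integer seed making every generated object reproducible.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_airports = 20, years = 2019:2021,
                            base_national_turnover = 2.55e9,
                            annual_growth = 0.11,
                            seasonal = seasonal_multipliers(),
                            shock_year = years[min(2, length(years))],
                            shock_depth = 0.3165, recovery_rate = 0.0477,
                            coastal_fraction = 0.3,
                            share_concentration = 0.5,
                            noise_sd = 0.05,
                            unit_consumption = 0.29, intensity = 0.2772,
                            seed = 20060101) {
  stopifnot(
    n_airports >= 1, length(years) >= 1, all(diff(years) == 1),
    base_national_turnover > 0, annual_growth > -1,
    length(seasonal) == 12, all(seasonal > 0),
    abs(mean(seasonal) - 1) < 1e-8,
    is.na(shock_year) || shock_year %in% years,
    shock_depth >= 0, shock_depth < 1, recovery_rate >= 0,
    coastal_fraction >= 0, coastal_fraction <= 1,
    share_concentration > 0, noise_sd >= 0,
    unit_consumption > 0, intensity > 0,
    seed == floor(seed), abs(seed) < 2^31 - 16
  )
  if (which.max(seasonal) != 8 || which.min(seasonal) != 2) {
    stop("seasonal multipliers must peak in August and trough in February",
      call. = FALSE
    )
  }
  structure(
    list(
      n_airports = as.integer(n_airports), years = as.integer(years),
      base_national_turnover = base_national_turnover,
      annual_growth = annual_growth, seasonal = seasonal,
      shock_year = shock_year, shock_depth = shock_depth,
      recovery_rate = recovery_rate, coastal_fraction = coastal_fraction,
      share_concentration = share_concentration, noise_sd = noise_sd,
      unit_consumption = unit_consumption, intensity = intensity,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Full-scale scenario preset
#'
#' The demonstration scale: 175 airports over 2006-2023 with a 2020 shock.
#'
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
full_scale_config <- function(...) {
  scenario_config(n_airports = 175, years = 2006:2023, shock_year = 2020, ...)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic aviation scenario: %d airports, %d-%d\n",
    x$n_airports, min(x$years), max(x$years)
  ))
  cat(sprintf(
    "  base turnover %.3g ton-km/month, growth %+.1f%%/yr, noise sd %.3g\n",
    x$base_national_turnover, 100 * x$annual_growth, x$noise_sd
  ))
  if (!is.na(x$shock_year)) {
    cat(sprintf(
      "  shock: %d, depth %.2f%%, recovery %+.2f%%/yr\n",
      x$shock_year, 100 * x$shock_depth, 100 * x$recovery_rate
    ))
  }
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Generate a synthetic airport registry
#'
#' Draws unique three-letter codes, coastal flags (probability
#' `coastal_fraction`), and normalised national turnover shares from a
#' Dirichlet-type allocation (independent Gamma draws with shape
#' `share_concentration`, normalised), so that a handful of hub airports
#' dominate as real networks do.
#'
#' @param config A [scenario_config()].
#' @return A tibble `airport`, `coastal`, `share` (shares sum to 1).
#' @export
generate_airports <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_airports
  with_local_seed(config$seed, {
    codes <- character(0)
    while (length(codes) < n) {
      more <- apply(
        matrix(sample(LETTERS, 3 * (n - length(codes)), replace = TRUE), ncol = 3),
        1, paste, collapse = ""
      )
      codes <- unique(c(codes, more))
    }
    coastal <- stats::runif(n) < config$coastal_fraction
    raw <- stats::rgamma(n, shape = config$share_concentration, rate = 1)
    if (sum(raw) == 0) raw <- rep(1, n)
    tibble::tibble(
      airport = codes[seq_len(n)],
      coastal = coastal,
      share = raw / sum(raw)
    )
  })
}

# national turnover for one (year, month) before airport apportionment
national_turnover <- function(config, year, month) {
  y0 <- config$years[1]
  trend <- config$base_national_turnover * (1 + config$annual_growth)^(year - y0)
  shock <- rep(1, length(year))
  if (!is.na(config$shock_year)) {
    ys <- config$shock_year
    after <- year >= ys
    # drop to (1 - depth) in the shock year, then grow at recovery_rate from
    # that level, capped at the no-shock trend
    rel <- (1 - config$shock_depth) *
      (1 + config$recovery_rate)^(pmax(year - ys, 0)) /
      (1 + config$annual_growth)^(pmax(year - ys, 0))
    shock[after] <- pmin(rel[after], 1)
  }
  trend * shock * config$seasonal[month]
}

#' Generate a synthetic activity series
#'
#' Turnover of airport a in (year, month) is
#' `national(year, month) * share(a) * noise`, where the national series is
#' `base * (1 + growth)^(year - y0) * seasonal(month) * shock(year)` and the
#' noise is multiplicative log-normal with relative sd `noise_sd` (mean 1),
#' keeping turnover positive. With noise off, August is every year's maximum
#' and February its minimum by construction.
#'
#' @param config A [scenario_config()].
#' @param airports Registry from [generate_airports()] (regenerated from the
#'   config when omitted).
#' @return A tibble `year`, `month`, `airport`, `turnover_tonkm`.
#' @export
generate_activity <- function(config, airports = generate_airports(config)) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- tidyr::expand_grid(
    year = config$years, month = 1:12,
    airport = airports$airport
  )
  grid <- dplyr::left_join(grid, airports[c("airport", "share")], by = "airport")
  national <- national_turnover(config, grid$year, grid$month)
  noise <- if (config$noise_sd > 0) {
    sdlog <- sqrt(log(1 + config$noise_sd^2))
    with_local_seed(
      config$seed + 1L,
      stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    )
  } else {
    1
  }
  tibble::tibble(
    year = grid$year, month = grid$month, airport = grid$airport,
    turnover_tonkm = national * grid$share * noise
  )
}

#' Generate synthetic monitoring-station observations
#'
#' Each station observes the true airport-attributable concentration plus a
#' constant background (other nearby sources) plus additive Gaussian noise,
#' truncated at zero.
#'
#' @param true_concentration The modeled concentration at the airport.
#' @param distances Station distances in km (> 0); default the 16 station
#'   distances around CAN from [can_station_distances()].
#' @param background Constant background concentration added to every
#'   station. Default 0.
#' @param noise_sd Standard deviation of additive station noise. Default 0.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param station_ids Optional identifiers; defaults to S01, S02, ...
#' @return A tibble `station_id`, `distance_km`, `observed_ugm3`.
#' @export
generate_station_observations <- function(true_concentration,
                                          distances = can_station_distances()$distance_km,
                                          background = 0, noise_sd = 0,
                                          seed = 1L, station_ids = NULL) {
  stopifnot(
    is.numeric(true_concentration), length(true_concentration) == 1,
    true_concentration >= 0, all(distances > 0),
    background >= 0, noise_sd >= 0
  )
  n <- length(distances)
  if (is.null(station_ids)) station_ids <- sprintf("S%02d", seq_len(n))
  eps <- if (noise_sd > 0) {
    with_local_seed(as.integer(seed), stats::rnorm(n, 0, noise_sd))
  } else {
    0
  }
  tibble::tibble(
    station_id = station_ids,
    distance_km = as.numeric(distances),
    observed_ugm3 = pmax(true_concentration + background + eps, 0)
  )
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
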