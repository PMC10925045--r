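month_cols <- month.abb

#' Reshape a long airport-month table to the wide records layout
#'
#' The wide layout is the distribution format of the results: one row per
#' (year, airport) keyed by 4-digit year and 3-letter code, followed by the
#' twelve monthly value columns Jan..Dec (14 columns in total). Months absent
#' from the input become empty cells (`NA`), never zero — zero is a
#' meaningful emission value.
#'
#' @param records Data frame `year`, `month`, `airport` plus the value column.
#' @param value_col Name of the value column to spread (e.g. `flow_g_per_s`).
#' @return A tibble `year`, `airport`, `Jan`..`Dec`.
#' @export
long_to_wide <- function(records, value_col) {
  stopifnot(is.data.frame(records), value_col %in% names(records))
  key <- paste(records$year, records$month, records$airport)
  if (anyDuplicated(key)) {
    stop("duplicate (year, month, airport) records", call. = FALSE)
  }
  wide <- records |>
    dplyr::mutate(.month = factor(month_cols[.data$month], levels = month_cols)) |>
    tidyr::pivot_wider(
      id_cols = c("year", "airport"),
      names_from = ".month", values_from = dplyr::all_of(value_col),
      names_expand = TRUE
    ) |>
    dplyr::arrange(.data$year, .data$airport)
  wide[c("year", "airport", month_cols)]
}

#' Reshape a wide records table back to long format
#'
#' @param wide A tibble as produced by [long_to_wide()] or [read_wide()].
#' @param value_col Name for the value column in the long output.
#' @return A tibble `year`, `month`, `airport`, `<value_col>`; empty cells
#'   are dropped.
#' @export
wide_to_long <- function(wide, value_col) {
  stopifnot(is.data.frame(wide), all(c("year", "airport", month_cols) %in% names(wide)))
  long <- tidyr::pivot_longer(wide, dplyr::all_of(month_cols),
    names_to = ".month", values_to = value_col
  )
  long$month <- match(long$.month, month_cols)
  long <- long[!is.na(long[[value_col]]), c("year", "month", "airport", value_col)]
  dplyr::arrange(long, .data$year, .data$month, .data$airport)
}

#' Write a wide records table to CSV
#'
#' Columns are Year, Airport, Jan..Dec; values are written in shortest
#' round-trip decimal representation so that [read_wide()] recovers them
#' bit-exactly. Missing months are written as empty cells.
#'
#' @param records Long data frame (`year`, `month`, `airport`, value) or an
#'   already-wide table from [long_to_wide()].
#' @param kind Which quantity the table holds: `"flow"` (g/s) or
#'   `"concentration"` (ug/m3). Used to pick the value column of a long
#'   input and recorded in a comment-free header-only sense (the layout is
#'   identical for both kinds).
#' @param path Output CSV path.
#' @return The wide tibble that was written, invisibly.
#' @export
write_wide <- function(records, kind = c("flow", "concentration"), path) {
  kind <- match.arg(kind)
  value_col <- if (kind == "flow") "flow_g_per_s" else "conc_ugm3"
  wide <- if (all(month_cols %in% names(records))) {
    if (anyDuplicated(paste(records$year, records$airport))) {
      stop("duplicate (year, airport) rows", call. = FALSE)
    }
    tibble::as_tibble(records[c("year", "airport", month_cols)])
  } else {
    long_to_wide(records, value_col)
  }
  bad <- !grepl("^[A-Z]{3}$", wide$airport)
  if (any(bad)) {
    stop("invalid airport code(s): ", paste(unique(wide$airport[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  # 17 significant digits guarantee exact binary round-trip through text
  printable <- wide
  for (m in month_cols) {
    printable[[m]] <- ifelse(is.na(wide[[m]]), NA_character_,
      sprintf("%.17g", wide[[m]])
    )
  }
  readr::write_csv(printable, path, na = "", progress = FALSE)
  invisible(wide)
}

#' Read a wide records table from CSV
#'
#' Validates the layout strictly: 14 columns (Year, Airport, Jan..Dec),
#' 4-digit years, 3-letter airport codes, numeric or empty month cells.
#' Malformed rows are reported with their line numbers. Empty cells become
#' `NA` (missing), never zero.
#'
#' @param path CSV file written by [write_wide()].
#' @return A tibble `year`, `airport`, `Jan`..`Dec`.
#' @export
read_wide <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  ))
  if (!identical(names(raw), c("year", "airport", month_cols))) {
    stop(
      "unexpected column layout in ", path, ": expected year, airport, ",
      paste(month_cols, collapse = ", "),
      call. = FALSE
    )
  }
  # numeric conversion via base R, which parses decimal text exactly
  # (bit-for-bit round trip of what write_wide printed); empty cells are
  # missing values, never zero
  wide <- raw
  wide$year <- suppressWarnings(as.integer(raw$year))
  bad_rows <- integer(0)
  for (m in month_cols) {
    cell <- raw[[m]]
    empty <- is.na(cell) | cell == ""
    val <- suppressWarnings(as.numeric(cell))
    bad_rows <- union(bad_rows, which(is.na(val) & !empty))
    val[empty] <- NA_real_
    wide[[m]] <- val
  }
  if (length(bad_rows)) {
    stop(
      "malformed cells in ", path, " at data row(s) ",
      paste(sort(bad_rows), collapse = ", "),
      call. = FALSE
    )
  }
  bad_code <- which(!grepl("^[A-Z]{3}$", wide$airport))
  if (length(bad_code)) {
    stop(
      "invalid airport code at data row(s) ",
      paste(bad_code, collapse = ", "), " of ", path,
      call. = FALSE
    )
  }
  bad_year <- which(is.na(wide$year) | wide$year < 1000 | wide$year > 9999)
  if (length(bad_year)) {
    stop(
      "invalid year at data row(s) ", paste(bad_year, collapse = ", "),
      " of ", path,
      call. = FALSE
    )
  }
  wide
}

#' Run the full synthetic pipeline: activity to flows, concentrations and
#' an accuracy report
#'
#' Generates a scenario from `config`, runs the emission stage
#' (apportionment, fuel, mass, flow), applies the Gaussian plume model per
#' airport-month, and produces an inverse-distance-weighted accuracy report
#' for the airport-month with the highest modeled concentration using
#' synthetic stations at the packaged CAN distances. Deterministic for a
#' fixed config seed.
#'
#' @param config A [scenario_config()].
#' @param params A [plume_params()] object (its `l` is resolved per airport).
#' @param station_background Constant background added to synthetic station
#'   observations in the accuracy report. Default 0.
#' @param station_noise_sd Additive station noise sd. Default 0.
#' @param out_dir Optional directory; when given, writes
#'   `monthly_pm25_flow.csv` and `monthly_pm25_concentration.csv` (wide
#'   layout), the long `emissions.csv`, and `validation.csv` there.
#' @return A list with `airports`, `activity`, `emissions`, `concentrations`
#'   (long tibbles), `flow_wide`, `concentration_wide`, `validation`
#'   (one-row accuracy report), and `log` (the parameters used).
#' @export
run_pipeline <- function(config = scenario_config(), params = plume_params(),
                         station_background = 0, station_noise_sd = 0,
                         out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"), inherits(params, "plume_params"))
  airports <- generate_airports(config)
  activity <- generate_activity(config, airports)
  emissions <- compute_emissions(
    activity,
    fuel_params = config$unit_consumption,
    intensity = config$intensity
  )
  concentrations <- run_concentration_table(emissions, airports, params)

  top <- concentrations[which.max(concentrations$conc_ugm3), ]
  stations <- generate_station_observations(
    top$conc_ugm3,
    background = station_background,
    noise_sd = station_noise_sd,
    seed = config$seed + 2L
  )
  validation <- validate_concentration(stations, modeled = top$conc_ugm3)
  validation <- tibble::add_column(validation,
    year = top$year, month = top$month, airport = top$airport,
    .before = 1
  )

  result <- list(
    airports = airports,
    activity = activity,
    emissions = emissions,
    concentrations = concentrations,
    flow_wide = long_to_wide(emissions, "flow_g_per_s"),
    concentration_wide = long_to_wide(concentrations, "conc_ugm3"),
    validation = validation,
    log = list(config = config, plume = params)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_wide(result$flow_wide, "flow",
      file.path(out_dir, "monthly_pm25_flow.csv")
    )
    write_wide(result$concentration_wide, "concentration",
      file.path(out_dir, "monthly_pm25_concentration.csv")
    )
    readr::write_csv(emissions, file.path(out_dir, "emissions.csv"), progress = FALSE)
    readr::write_csv(validation, file.path(out_dir, "validation.csv"), progress = FALSE)
  }
  result
}
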