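#' Gaussian plume parameters
#'
#' Bundles every constant of the steady-state Gaussian diffusion model with
#' image-source reflection terms. Defaults are the study configuration: a
#' single fixed wind speed of 3.7 m/s for all airports and months, constant
#' diffusion coefficients (no downwind-distance dependence, no stability
#' classes), effective source height 2 m, reflections summed to n = 2, and
#' the near-ground receptor offsets {1, 2, 3} m whose concentrations are
#' averaged into the reported value.
#'
#' @param mu Wind speed, m/s (> 0). Default 3.7.
#' @param delta_y Horizontal diffusion coefficient (> 0). Default 1.33.
#' @param delta_z Vertical diffusion coefficient (> 0). Default 1.
#' @param h Effective source height, m. Default 2.
#' @param n_reflections Upper bound of the image-source reflection sums
#'   (integer >= 0). Default 2. At the default geometry the reflection
#'   exponents are of order -(900 - 2)^2 / 2 and underflow to zero, so any
#'   bound >= 1 gives identical results.
#' @param l Mixing-layer height, m (> 0): the boundary-layer lid that traps
#'   the plume. 900 m for coastal airports, 1100 m inland; see
#'   [select_mixing_layer()]. Default 1100.
#' @param receptor_offsets Offsets y (m) at which the plume is evaluated;
#'   their mean is the reported concentration. Default `c(1, 2, 3)`.
#' @param unit_scale Multiplicative scale applied to the formula's literal
#'   output. Default 1 (report the literal value); set 1e6 to reinterpret a
#'   g/m^3-scaled literal value as micrograms.
#' @param literal_exp_of_sum If `TRUE`, evaluate the reflection factor as the
#'   exponential of the summed exponents rather than the standard
#'   sum-of-exponentials image-source form. For comparison only.
#' @return A list of class `"plume_params"`.
#' @examples
#' plume_params()
#' plume_params(l = 900)
#' @export
plume_params <- function(mu = 3.7, delta_y = 1.33, delta_z = 1, h = 2,
                         n_reflections = 2, l = 1100,
                         receptor_offsets = c(1, 2, 3), unit_scale = 1,
                         literal_exp_of_sum = FALSE) {
  stopifnot(
    mu > 0, delta_y > 0, delta_z > 0, l > 0,
    n_reflections >= 0, n_reflections == floor(n_reflections),
    length(receptor_offsets) >= 1, is.numeric(receptor_offsets),
    unit_scale > 0, is.logical(literal_exp_of_sum)
  )
  structure(
    list(
      mu = mu, delta_y = delta_y, delta_z = delta_z, h = h,
      n_reflections = as.integer(n_reflections), l = l,
      receptor_offsets = as.numeric(receptor_offsets),
      unit_scale = unit_scale, literal_exp_of_sum = literal_exp_of_sum
    ),
    class = "plume_params"
  )
}

#' @export
print.plume_params <- function(x, ...) {
  cat("Gaussian plume parameters\n")
  cat(sprintf("  wind speed mu       : %g m/s\n", x$mu))
  cat(sprintf("  diffusion delta_y/z : %g / %g\n", x$delta_y, x$delta_z))
  cat(sprintf("  effective height h  : %g m\n", x$h))
  cat(sprintf("  mixing layer l      : %g m\n", x$l))
  cat(sprintf("  reflections n       : 1..%d%s\n", x$n_reflections,
    if (x$literal_exp_of_sum) " (literal exp-of-sum)" else ""
  ))
  cat(sprintf(
    "  receptor offsets y  : %s m\n",
    paste(x$receptor_offsets, collapse = ", ")
  ))
  if (x$unit_scale != 1) cat(sprintf("  unit scale          : %g\n", x$unit_scale))
  invisible(x)
}

#' Vertical reflection factor P
#'
#' Dimensionless factor collecting the direct ground-level term and the
#' image-source reflections at the ground and at the mixing-layer lid:
#' \deqn{P = 2 e^{-h^2/2\delta_z^2}
#'   + \sum_{n=1}^{N} e^{-(nl-h)^2/2\delta_z^2}
#'   + \sum_{n=1}^{N} e^{-(nl+h)^2/2\delta_z^2}.}
#' With a mixing layer hundreds of metres deep and \eqn{\delta_z = 1}, every
#' reflection exponent underflows and P reduces to the direct term.
#'
#' @param params A [plume_params()] object.
#' @return P, a scalar in (0, 2 + 2N].
#' @examples
#' vertical_term(plume_params(l = 900)) # ~0.27067
#' @export
vertical_term <- function(params) {
  stopifnot(inherits(params, "plume_params"))
  direct <- 2 * exp(-params$h^2 / (2 * params$delta_z^2))
  n <- seq_len(params$n_reflections)
  expo_minus <- -(n * params$l - params$h)^2 / (2 * params$delta_z^2)
  expo_plus <- -(n * params$l + params$h)^2 / (2 * params$delta_z^2)
  if (params$literal_exp_of_sum) {
    refl <- if (length(n)) exp(sum(expo_minus)) + exp(sum(expo_plus)) else 0
  } else {
    refl <- sum(exp(expo_minus)) + sum(exp(expo_plus))
  }
  direct + refl
}

#' Plume concentration at a single receptor offset
#'
#' \deqn{C = \frac{E}{2\pi\mu\delta_y\delta_z}
#'   \exp\!\left(\frac{-y^2}{2\delta_y^2}\right) P}
#' The result is linear in the emission flow E and maximal at y = 0.
#'
#' @param E Emission flow, g/s (non-negative; vectorised).
#' @param y Receptor offset, m.
#' @param params A [plume_params()] object.
#' @return Concentration in the model's reporting units.
#' @examples
#' concentration_at(1, 0, plume_params(l = 900))
#' @export
concentration_at <- function(E, y, params) {
  stopifnot(inherits(params, "plume_params"), is.numeric(E), is.numeric(y))
  if (any(E < 0)) stop("emission flow E must be non-negative", call. = FALSE)
  prefactor <- 1 / (2 * pi * params$mu * params$delta_y * params$delta_z)
  lateral <- exp(-y^2 / (2 * params$delta_y^2))
  params$unit_scale * E * prefactor * lateral * vertical_term(params)
}

#' 24-hour average concentration: mean over the receptor offsets
#'
#' Evaluates the plume at each configured receptor offset and returns the
#' mean, the quantity reported per airport-month.
#'
#' @inheritParams concentration_at
#' @return Mean concentration over `params$receptor_offsets` (vectorised
#'   over `E`).
#' @examples
#' average_concentration(1, plume_params(l = 900)) # ~3.3708e-3
#' @export
average_concentration <- function(E, params) {
  stopifnot(inherits(params, "plume_params"))
  if (length(params$receptor_offsets) == 0) {
    stop("receptor_offsets must be non-empty", call. = FALSE)
  }
  per_offset <- vapply(
    params$receptor_offsets,
    function(y) concentration_at(E, y, params),
    numeric(length(E))
  )
  if (length(E) == 1L) mean(per_offset) else rowMeans(per_offset)
}

#' Mixing-layer height for an airport
#'
#' Coastal airports sit under a shallower marine boundary layer (900 m);
#' inland airports get 1100 m. An explicit per-airport override wins.
#'
#' @param coastal Logical (vectorised): is the airport coastal?
#' @param override Optional per-airport mixing-layer height in m; `NA` means
#'   use the coastal/inland default.
#' @return Mixing-layer height(s) in m.
#' @examples
#' select_mixing_layer(c(TRUE, FALSE))
#' @export
select_mixing_layer <- function(coastal, override = NA_real_) {
  stopifnot(is.logical(coastal) || all(coastal %in% c(0, 1)))
  coastal <- as.logical(coastal)
  override <- rep_len(as.numeric(override), length(coastal))
  if (any(!is.na(override) & override <= 0)) {
    stop("mixing-layer override must be positive", call. = FALSE)
  }
  ifelse(!is.na(override), override, ifelse(coastal, 900, 1100))
}

#' Concentrations for a table of emission flows
#'
#' Applies the plume model to every airport-month emission record, resolving
#' each airport's mixing-layer height from the registry (coastal flag or
#' explicit override).
#'
#' @param emissions Data frame `year`, `month`, `airport`, `flow_g_per_s`
#'   (as produced by [compute_emissions()]).
#' @param airports Registry data frame with columns `airport`, `coastal`
#'   and optionally `mixing_layer_override`.
#' @param params A [plume_params()] object; its `l` is replaced per airport.
#' @return A tibble `year`, `month`, `airport`, `conc_ugm3`.
#' @export
run_concentration_table <- function(emissions, airports, params = plume_params()) {
  stopifnot(is.data.frame(emissions), is.data.frame(airports))
  need <- c("year", "month", "airport", "flow_g_per_s")
  if (!all(need %in% names(emissions))) {
    stop("emissions table lacks columns: ",
      paste(setdiff(need, names(emissions)), collapse = ", "),
      call. = FALSE
    )
  }
  check_airports(airports)
  unknown <- setdiff(unique(emissions$airport), airports$airport)
  if (length(unknown)) {
    stop("airport(s) not in registry: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  override <- if ("mixing_layer_override" %in% names(airports)) {
    airports$mixing_layer_override
  } else {
    NA_real_
  }
  l_by_airport <- stats::setNames(
    select_mixing_layer(airports$coastal, override),
    airports$airport
  )
  # the per-offset factor only depends on l through P; precompute per distinct l
  k_for_l <- vapply(
    unique(l_by_airport),
    function(l) {
      p <- params
      p$l <- l
      average_concentration(1, p)
    },
    numeric(1)
  )
  names(k_for_l) <- as.character(unique(l_by_airport))
  k <- k_for_l[as.character(l_by_airport[emissions$airport])]
  tibble::tibble(
    year = emissions$year,
    month = emissions$month,
    airport = emissions$airport,
    conc_ugm3 = unname(k) * emissions$flow_g_per_s
  )
}

check_airports <- function(airports) {
  need <- c("airport", "coastal")
  if (!all(need %in% names(airports))) {
    stop("airport registry lacks columns: ",
      paste(setdiff(need, names(airports)), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- !grepl("^[A-Z]{3}$", airports$airport)
  if (any(bad)) {
    stop("invalid airport code(s): ",
      paste(airports$airport[bad], collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(airports$airport)) {
    stop("duplicate airport codes in registry", call. = FALSE)
  }
  invisible(airports)
}
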