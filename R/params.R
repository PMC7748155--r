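# Simulator parameters and their randomized-initialization windows.

param_names <- c(
  "water_source_distance", "min_death_age", "death_age_span",
  "min_fertility", "fertility_span", "min_fertility_ends_age",
  "fertility_ends_age_span", "base_nutrition_need", "harvest_adjustment",
  "harvest_variance", "maize_gift_to_child"
)

#' Default parameter-initialization windows
#'
#' The +/-5 percent windows around the best published calibration of the
#' household model: each simulator evaluation draws its parameters uniformly
#' and independently from these intervals, so evolved rules are selected for
#' robustness to parameter initialization rather than for one parameter
#' vector. Units: distances in cells, ages/spans in years, fertility in
#' probability per year, nutrition need in kg maize per year, harvest
#' adjustment/variance unitless, maize gift as a fraction of the parent's
#' stock.
#'
#' @return Named list of `c(low, high)` ranges.
#' @export
default_param_ranges <- function() {
  list(
    water_source_distance   = c(10.925, 12.075),
    min_death_age           = c(38.0, 42.0),
    death_age_span          = c(9.5, 10.5),
    min_fertility           = c(0.1615, 0.1785),
    fertility_span          = c(0.0285, 0.0315),
    min_fertility_ends_age  = c(27.55, 30.45),
    fertility_ends_age_span = c(4.75, 5.25),
    base_nutrition_need     = c(175.75, 194.25),
    harvest_adjustment      = c(0.608, 0.672),
    harvest_variance        = c(0.418, 0.462),
    maize_gift_to_child     = c(0.4465, 0.4935)
  )
}

#' Draw one simulator parameter set
#'
#' Each parameter is drawn independently from `Uniform(low, high)` over its
#' window. A degenerate window `c(v, v)` pins the parameter at `v` exactly.
#'
#' @param ranges Named list of `c(low, high)` windows; names must be a subset
#'   of the known parameter names (unknown names are an error). Missing
#'   parameters fall back to the midpoint of [default_param_ranges()].
#' @param seed Optional integer seed (sets the global RNG).
#' @return Named list of parameter values, class `emd_params`.
#' @export
draw_params <- function(ranges = default_param_ranges(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(names(ranges), param_names)
  if (length(unknown) > 0) stop("unknown parameter name: ", unknown[1])
  defaults <- default_param_ranges()
  p <- lapply(param_names, function(nm) {
    r <- if (nm %in% names(ranges)) ranges[[nm]] else defaults[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("invalid range for ", nm)
    if (nm %in% names(ranges)) runif(1, r[1], r[2]) else mean(r)
  })
  names(p) <- param_names
  structure(p, class = "emd_params")
}

#' Zero-width windows reproducing a given parameter set
#'
#' @param params An `emd_params` object.
#' @return Named list of degenerate `c(v, v)` ranges, usable wherever
#'   parameter windows are expected; useful to re-run a recorded simulation
#'   exactly.
#' @export
degenerate_ranges <- function(params) {
  lapply(params, function(v) c(v, v))
}
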