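# Scenario engine: the eight standard projection scenarios (two population
# variants x two mortality rate ratios, with and without a 2% annual
# incidence trend), run separately per sex.

#' Specify one projection scenario
#'
#' @param id scenario identifier (integer).
#' @param variant population projection variant, 1 or 2.
#' @param R mortality rate ratio m1/m0.
#' @param trend annual multiplicative increase of the incidence rate
#'   (0 for constant incidence, 0.02 for a 2% annual rise).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, variant, R, trend = 0) {
  if (!variant %in% c(1, 2)) stop("variant must be 1 or 2")
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (!is.finite(trend) || trend < 0) stop("trend must be non-negative")
  structure(list(id = as.integer(id), variant = as.integer(variant),
                 R = R, trend = trend),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %d: variant %d, R = %g, incidence trend %g%%/yr\n",
              x$id, x$variant, x$R, 100 * x$trend))
  invisible(x)
}

#' The eight standard scenarios
#'
#' Scenarios 1-4 keep incidence constant, 5-8 add a 2% annual incidence
#' increase; within each block the mortality rate ratio is 3.2 for the
#' first pair and 1.17 for the second, and the population variant
#' alternates 1, 2.
#'
#' @return A list of eight [scenario_spec()] objects named `"1"` to `"8"`.
#' @examples
#' default_scenarios()[["7"]]  # variant 1, R = 1.17, 2% trend
#' @export
default_scenarios <- function() {
  Rs <- c(3.2, 3.2, 1.17, 1.17)
  specs <- lapply(1:8, function(k) {
    scenario_spec(id = k,
                  variant = ifelse(k %% 2 == 1, 1, 2),
                  R = Rs[(k - 1) %% 4 + 1],
                  trend = ifelse(k <= 4, 0, 0.02))
  })
  names(specs) <- as.character(1:8)
  specs
}

#' Incidence rate under an annual multiplicative trend
#'
#' Scales a baseline incidence by `(1 + trend)^(t - t0)`; the age profile's
#' shape is unchanged. The first affected year is t0 + 1 (exponent 1), so a
#' 2050 value under a 2021 baseline uses exponent 29.
#'
#' @param i0 baseline incidence rate(s) at year `t0`.
#' @param trend annual multiplicative increase (>= 0).
#' @param t calendar year at which to evaluate (t >= t0).
#' @param t0 baseline calendar year.
#' @return `i0 * (1 + trend)^(t - t0)`, vectorized.
#' @examples
#' apply_incidence_trend(0.1, 0.02, 2050, 2021)  # 0.1 * 1.02^29
#' @export
apply_incidence_trend <- function(i0, trend, t, t0) {
  if (any(!is.finite(trend)) || any(trend < 0))
    stop("trend must be non-negative")
  if (any(t < t0)) stop("t must not precede the baseline year t0")
  i0 * (1 + trend)^(t - t0)
}

#' Build an incidence surface from an age profile and a trend
#'
#' Expands a baseline age profile of incidence rates into a full
#' [rate_surface()], constant in calendar time when `trend = 0` and scaled
#' by `(1 + trend)^(t - t0)` otherwise.
#'
#' @param profile data frame with columns `age` and `rate` covering all
#'   grid ages.
#' @param grid an [age_time_grid()].
#' @param trend annual multiplicative incidence increase.
#' @param t0 baseline year of the profile (default `grid$t_min`).
#' @return A [rate_surface()].
#' @export
build_incidence_surface <- function(profile, grid = age_time_grid(),
                                    trend = 0, t0 = grid$t_min) {
  stopifnot(is.data.frame(profile), all(c("age", "rate") %in% names(profile)))
  idx <- match(grid$ages, profile$age)
  if (anyNA(idx))
    stop(sprintf("incidence profile missing age(s) %s",
                 paste(grid$ages[is.na(idx)], collapse = ", ")))
  i0 <- profile$rate[idx]
  vals <- outer(apply_incidence_trend(1, trend, grid$years, t0), i0)
  rate_surface(grid, vals)
}

#' Run one projection scenario
#'
#' Solves the illness-death transport equation separately for each sex with
#' the scenario's mortality rate ratio, population variant (which selects
#' the mortality surface and the population counts) and incidence trend,
#' then converts the projected prevalence to head counts.
#'
#' @param spec a [scenario_spec()].
#' @param inputs an input bundle as produced by [gen_full_fixture()] (or
#'   assembled from files): elements `grid`, `baseline`, `incidence`,
#'   `mortality[[variant]][[sex]]`, `population[[variant]]`.
#' @param substeps RK4 steps per node interval.
#' @param entry_prevalence passed to [project_prevalence_surface()].
#' @return A list of class `scenario_result` with the spec, per-sex
#'   prevalence surfaces, per-sex count tables (year x age) and a `totals`
#'   data frame (year, male, female, total persons).
#' @export
run_scenario <- function(spec, inputs, substeps = 10, entry_prevalence = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  v <- as.character(spec$variant)
  if (is.null(inputs$mortality[[v]]) || is.null(inputs$population[[v]]))
    stop(sprintf("inputs do not cover population variant %s", v))
  grid <- inputs$grid
  surfaces <- list(); counts <- list()
  for (sx in c("male", "female")) {
    if (is.null(inputs$baseline[[sx]]) || is.null(inputs$incidence[[sx]]) ||
        is.null(inputs$mortality[[v]][[sx]]))
      stop(sprintf("inputs do not cover sex '%s'", sx))
    i_surf <- build_incidence_surface(inputs$incidence[[sx]], grid,
                                      trend = spec$trend, t0 = grid$t_min)
    surfaces[[sx]] <- project_prevalence_surface(
      inputs$baseline[[sx]], i_surf, inputs$mortality[[v]][[sx]],
      spec$R, grid, substeps, entry_prevalence)
    counts[[sx]] <- counts_from_prevalence(surfaces[[sx]],
                                           inputs$population[[v]], sx)
  }
  totals <- data.frame(year = grid$years,
                       male = rowSums(counts$male),
                       female = rowSums(counts$female))
  totals$total <- totals$male + totals$female
  structure(list(spec = spec, surfaces = surfaces, counts = counts,
                 totals = totals),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  n <- nrow(x$totals)
  cat(sprintf("<scenario_result> scenario %d (variant %d, R = %g, trend %g%%): total %.2fM (%d) -> %.2fM (%d)\n",
              x$spec$id, x$spec$variant, x$spec$R, 100 * x$spec$trend,
              x$totals$total[1] / 1e6, x$totals$year[1],
              x$totals$total[n] / 1e6, x$totals$year[n]))
  invisible(x)
}

#' Run a set of scenarios
#'
#' @param inputs an input bundle (see [run_scenario()]).
#' @param specs list of [scenario_spec()]s; default the eight standard
#'   scenarios.
#' @param substeps RK4 steps per node interval.
#' @param entry_prevalence passed through to the projection.
#' @return A named list of class `scenario_results`, one
#'   [run_scenario()] result per spec.
#' @export
run_scenarios <- function(inputs, specs = default_scenarios(), substeps = 10,
                          entry_prevalence = NULL) {
  out <- lapply(specs, run_scenario, inputs = inputs, substeps = substeps,
                entry_prevalence = entry_prevalence)
  names(out) <- vapply(specs, function(s) as.character(s$id), character(1))
  structure(out, class = "scenario_results")
}

#' @export
print.scenario_results <- function(x, ...) {
  cat(sprintf("<scenario_results> %d scenario(s)\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}
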