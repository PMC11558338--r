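#' Age-calendar-time grid
#'
#' Defines the rectangular (calendar year, age) lattice on which rate and
#' prevalence surfaces live. The default grid is ages 60 to 100 and years
#' 2021 to 2050 with one-year node spacing.
#'
#' @param t_min,t_max first and last calendar year covered by the grid.
#' @param a_min,a_max youngest and oldest age (years) covered by the grid.
#' @param step node spacing in years (the same in both directions).
#'
#' @return An object of class `age_time_grid` with elements `t_min`, `t_max`,
#'   `a_min`, `a_max`, `step`, `years` and `ages`.
#' @examples
#' g <- age_time_grid()
#' length(g$years)  # 30 projection years + baseline
#' @export
age_time_grid <- function(t_min = 2021, t_max = 2050,
                          a_min = 60, a_max = 100, step = 1) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), is.numeric(a_min),
            is.numeric(a_max), is.numeric(step), length(step) == 1L)
  if (!(t_min < t_max)) stop("t_min must be smaller than t_max")
  if (!(a_min < a_max)) stop("a_min must be smaller than a_max")
  if (!(step > 0)) stop("step must be positive")
  nt <- (t_max - t_min) / step
  na <- (a_max - a_min) / step
  if (max(abs(nt - round(nt)), abs(na - round(na))) > 1e-9)
    stop("grid extents must be integer multiples of the step")
  structure(
    list(t_min = t_min, t_max = t_max, a_min = a_min, a_max = a_max,
         step = step,
         years = seq(t_min, t_max, by = step),
         ages = seq(a_min, a_max, by = step)),
    class = "age_time_grid")
}

#' @export
print.age_time_grid <- function(x, ...) {
  cat(sprintf("<age_time_grid> years %s-%s, ages %s-%s, step %s (%d x %d nodes)\n",
              x$t_min, x$t_max, x$a_min, x$a_max, x$step,
              length(x$years), length(x$ages)))
  invisible(x)
}

same_grid <- function(g1, g2, tol = 1e-9) {
  all(abs(c(g1$t_min - g2$t_min, g1$t_max - g2$t_max,
            g1$a_min - g2$a_min, g1$a_max - g2$a_max,
            g1$step - g2$step)) < tol)
}

new_surface <- function(grid, values, class, what, unit_interval = FALSE) {
  if (!inherits(grid, "age_time_grid")) stop("grid must be an age_time_grid")
  values <- as.matrix(values)
  if (nrow(values) != length(grid$years) || ncol(values) != length(grid$ages))
    stop(sprintf("%s values must be a %d x %d (year x age) matrix",
                 what, length(grid$years), length(grid$ages)))
  if (any(!is.finite(values))) stop(sprintf("%s values must be finite", what))
  if (any(values < 0)) stop(sprintf("%s values must be non-negative", what))
  if (unit_interval && any(values > 1))
    stop(sprintf("%s values must not exceed 1", what))
  dimnames(values) <- list(year = grid$years, age = grid$ages)
  structure(list(grid = grid, values = values), class = class)
}

#' Rate surface on an age-time grid
#'
#' A non-negative rate (per person-year) tabulated at every (year, age) node,
#' with bilinear interpolation for off-node evaluation. Used for the
#' incidence rate of need for long-term care and for all-cause mortality.
#'
#' @param grid an [age_time_grid()].
#' @param values numeric matrix, years in rows and ages in columns, or a
#'   single number recycled over the grid.
#' @return An object of class `rate_surface`.
#' @examples
#' g <- age_time_grid(2021, 2023, 60, 62)
#' rate_surface(g, 0.05)
#' @export
rate_surface <- function(grid, values) {
  if (length(values) == 1L)
    values <- matrix(values, length(grid$years), length(grid$ages))
  new_surface(grid, values, c("rate_surface", "ltc_surface"), "rate")
}

#' Prevalence surface on an age-time grid
#'
#' The fraction of the population in the "need for long-term care" state at
#' every (year, age) node; all values must lie in \[0, 1\].
#'
#' @inheritParams rate_surface
#' @return An object of class `prevalence_surface`.
#' @export
prevalence_surface <- function(grid, values) {
  if (length(values) == 1L)
    values <- matrix(values, length(grid$years), length(grid$ages))
  new_surface(grid, values, c("prevalence_surface", "ltc_surface"),
              "prevalence", unit_interval = TRUE)
}

#' @export
print.ltc_surface <- function(x, ...) {
  cat(sprintf("<%s> %d years x %d ages, range [%.4g, %.4g]\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Evaluate a surface at arbitrary (year, age) points
#'
#' Bilinear interpolation between the four surrounding grid nodes. Points
#' must lie inside the grid hull (a tiny tolerance absorbs floating-point
#' drift at the boundary).
#'
#' @param surface a `rate_surface` or `prevalence_surface`.
#' @param t,a numeric vectors (recycled to common length) of calendar years
#'   and ages.
#' @return Numeric vector of interpolated values.
#' @examples
#' g <- age_time_grid(2021, 2022, 60, 61)
#' s <- rate_surface(g, matrix(c(0, 1, 2, 3), 2, 2))
#' eval_surface(s, 2021.5, 60.5)  # mean of the four corners
#' @export
eval_surface <- function(surface, t, a) {
  g <- surface$grid
  n <- max(length(t), length(a))
  t <- rep_len(t, n); a <- rep_len(a, n)
  eps <- 1e-9 * max(1, abs(g$t_max))
  if (any(t < g$t_min - eps | t > g$t_max + eps |
          a < g$a_min - eps | a > g$a_max + eps))
    stop("evaluation point outside the grid hull")
  # fractional node coordinates, clamped so the upper boundary stays in-cell
  ft <- pmin(pmax((t - g$t_min) / g$step, 0), length(g$years) - 1L)
  fa <- pmin(pmax((a - g$a_min) / g$step, 0), length(g$ages) - 1L)
  i0 <- pmin(floor(ft), length(g$years) - 2L) + 1L
  j0 <- pmin(floor(fa), length(g$ages) - 2L) + 1L
  if (length(g$years) == 1L) i0 <- rep(1L, n)
  if (length(g$ages) == 1L) j0 <- rep(1L, n)
  wt <- ft - (i0 - 1L); wa <- fa - (j0 - 1L)
  v <- surface$values
  i1 <- pmin(i0 + 1L, nrow(v)); j1 <- pmin(j0 + 1L, ncol(v))
  (1 - wt) * (1 - wa) * v[cbind(i0, j0)] +
    wt * (1 - wa) * v[cbind(i1, j0)] +
    (1 - wt) * wa * v[cbind(i0, j1)] +
    wt * wa * v[cbind(i1, j1)]
}

#' Baseline age profile of prevalence
#'
#' Age-specific prevalence fractions at the baseline year for one sex, e.g.
#' the official care rates ("Pflegequote") for 2021. Profiles read from
#' published tables typically end in an open age group ("90+"); use
#' [extend_open_group()] to cover the full model age range.
#'
#' @param age integer vector of ages.
#' @param value prevalence fractions in \[0, 1\], same length as `age`.
#' @param sex `"male"` or `"female"`.
#' @param source free-text note on provenance.
#' @return An object of class `baseline_profile`.
#' @export
baseline_profile <- function(age, value, sex = c("male", "female"),
                             source = "unspecified") {
  sex <- match.arg(sex)
  age <- as.numeric(age); value <- as.numeric(value)
  if (length(age) != length(value)) stop("age and value lengths differ")
  if (anyDuplicated(age)) stop("duplicate ages in baseline profile")
  if (any(!is.finite(value)) || any(value < 0 | value > 1))
    stop("baseline prevalences must lie in [0, 1]")
  o <- order(age)
  structure(list(age = age[o], value = value[o], sex = sex, source = source),
            class = "baseline_profile")
}

#' @export
print.baseline_profile <- function(x, ...) {
  cat(sprintf("<baseline_profile> %s, ages %g-%g (%d values), source: %s\n",
              x$sex, min(x$age), max(x$age), length(x$age), x$source))
  invisible(x)
}

#' Extend a baseline profile over an open age group
#'
#' Published prevalence tables end at an open group such as "90+" while the
#' model runs to age 100. By default the open-group value is replicated for
#' all older ages; alternatively it is extrapolated linearly from the slope
#' of the last two closed groups (capped at 1).
#'
#' @param profile a [baseline_profile()].
#' @param a_max oldest age the extended profile must reach.
#' @param rule `"replicate"` (default) or `"linear"`.
#' @return A `baseline_profile` covering all ages up to `a_max`.
#' @examples
#' bp <- baseline_profile(60:90, seq(0.02, 0.5, length.out = 31), "female")
#' range(extend_open_group(bp, 100)$age)
#' @export
extend_open_group <- function(profile, a_max = 100,
                              rule = c("replicate", "linear")) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "baseline_profile"))
  top <- max(profile$age)
  if (top >= a_max) return(profile)
  new_age <- seq(top + 1, a_max)
  last <- profile$value[length(profile$value)]
  if (rule == "replicate") {
    new_val <- rep(last, length(new_age))
  } else {
    n <- length(profile$value)
    slope <- if (n >= 2) last - profile$value[n - 1] else 0
    new_val <- pmin(pmax(last + slope * (new_age - top), 0), 1)
  }
  baseline_profile(c(profile$age, new_age), c(profile$value, new_val),
                   profile$sex, profile$source)
}

#' Look up baseline prevalence at given ages
#'
#' @param profile a [baseline_profile()].
#' @param age ages to look up (must be present in the profile).
#' @return Numeric vector of prevalences.
#' @export
profile_at <- function(profile, age) {
  idx <- match(age, profile$age)
  if (anyNA(idx))
    stop(sprintf("baseline profile does not cover age(s) %s",
                 paste(age[is.na(idx)], collapse = ", ")))
  profile$value[idx]
}
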