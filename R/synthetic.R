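# Mechanistic generator of demography-shaped test inputs: logistic baseline
# prevalence, Gompertz all-cause mortality with secular improvement, an
# exponential-in-age incidence profile and a cohort-consistent population
# pyramid. Shapes and magnitudes emulate the German 60+ population; the
# generator is deterministic given (config, seed).

#' Configuration of the synthetic input generator
#'
#' Parameters of the mechanistic fixture: a logistic age profile for
#' baseline prevalence, Gompertz mortality `exp(b0 + b1 * a - g * (t - t0))`
#' with a variant-specific annual improvement g, an exponential-in-age
#' incidence profile `exp(c0 + c1 * a)`, and a population pyramid obtained
#' by cohort survival under the same mortality surface. All rate parameters
#' are per person-year; ages in years.
#'
#' @param seed integer seed driving the (small, multiplicative) random
#'   jitter on population counts.
#' @param grid an [age_time_grid()].
#' @param prev_max,prev_mid,prev_slope per-sex logistic parameters of the
#'   baseline prevalence: plateau, midpoint age and slope.
#' @param mort_b0,mort_b1 per-sex Gompertz intercept and age slope of
#'   log-mortality at the baseline year.
#' @param mort_improvement per-variant annual decline of log-mortality;
#'   variant 2 (higher life expectancy) must be at least variant 1.
#' @param inc_c0,inc_c1 per-sex intercept and age slope of log-incidence.
#' @param entry_size per-sex long-run size of the cohort reaching the
#'   youngest age in a given year (before the bulge factor).
#' @param entry_growth annual multiplicative drift of entry-cohort size.
#' @param boom_center,boom_width,boom_height Gaussian bulge of cohort sizes
#'   (in the year a cohort reaches the youngest age) emulating the
#'   baby-boom generations moving into old age; height is the fractional
#'   excess at the bulge's centre year.
#' @param jitter_sd standard deviation of the lognormal jitter applied to
#'   baseline-year and entry-cohort counts (0 disables it).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L,
                             grid = age_time_grid(),
                             prev_max = c(male = 0.75, female = 0.85),
                             prev_mid = c(male = 86, female = 84),
                             prev_slope = c(male = 0.16, female = 0.16),
                             mort_b0 = c(male = -10.7, female = -11.3),
                             mort_b1 = c(male = 0.10, female = 0.10),
                             mort_improvement = c(`1` = 0.005, `2` = 0.010),
                             inc_c0 = c(male = -11.8, female = -12.0),
                             inc_c1 = c(male = 0.105, female = 0.110),
                             entry_size = c(male = 0.62e6, female = 0.60e6),
                             entry_growth = -0.005,
                             boom_center = 2026, boom_width = 9,
                             boom_height = 0.30,
                             jitter_sd = 0.01) {
  two <- function(x, nm) {
    x <- rep_len(x, 2L)
    if (is.null(names(x)) || !all(nm %in% names(x))) names(x) <- nm
    x[nm]
  }
  sexes <- c("male", "female")
  cfg <- list(seed = as.integer(seed), grid = grid,
              prev_max = two(prev_max, sexes), prev_mid = two(prev_mid, sexes),
              prev_slope = two(prev_slope, sexes),
              mort_b0 = two(mort_b0, sexes), mort_b1 = two(mort_b1, sexes),
              mort_improvement = two(mort_improvement, c("1", "2")),
              inc_c0 = two(inc_c0, sexes), inc_c1 = two(inc_c1, sexes),
              entry_size = two(entry_size, sexes),
              entry_growth = entry_growth, boom_center = boom_center,
              boom_width = boom_width, boom_height = boom_height,
              jitter_sd = jitter_sd)
  if (any(cfg$prev_max < 0 | cfg$prev_max > 1))
    stop("prev_max must lie in [0, 1]")
  if (cfg$mort_improvement[["2"]] < cfg$mort_improvement[["1"]])
    stop("variant 2 must have at least the mortality improvement of variant 1")
  if (cfg$jitter_sd < 0) stop("jitter_sd must be non-negative")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> seed %d, grid %s-%s x %s-%s\n",
              x$seed, x$grid$t_min, x$grid$t_max, x$grid$a_min, x$grid$a_max))
  invisible(x)
}

#' Baseline prevalence profiles (synthetic)
#'
#' Logistic-in-age prevalence fractions at the baseline year, one profile
#' per sex. With the default parameters prevalence rises from about 1% at
#' age 60 to a plateau near the open age group, women above men at high
#' ages, mimicking published care-rate tables.
#'
#' @param cfg a [synthetic_config()].
#' @return Named list with `male` and `female` [baseline_profile()]s
#'   covering all grid ages.
#' @export
gen_baseline_prevalence <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ages <- cfg$grid$ages
  out <- lapply(c(male = "male", female = "female"), function(sx) {
    v <- cfg$prev_max[[sx]] *
      stats::plogis(cfg$prev_slope[[sx]] * (ages - cfg$prev_mid[[sx]]))
    baseline_profile(ages, v, sx, source = "synthetic logistic profile")
  })
  out
}

#' Incidence-rate profiles (synthetic)
#'
#' Exponential-in-age incidence of need for long-term care at the baseline
#' year, per sex: `i0(a) = exp(c0 + c1 * a)`.
#'
#' @param cfg a [synthetic_config()].
#' @return Named list (`male`, `female`) of data frames with columns `age`
#'   and `rate`.
#' @export
gen_incidence_profile <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ages <- cfg$grid$ages
  lapply(c(male = "male", female = "female"), function(sx) {
    data.frame(age = ages,
               rate = exp(cfg$inc_c0[[sx]] + cfg$inc_c1[[sx]] * ages))
  })
}

#' All-cause mortality surface (synthetic)
#'
#' Gompertz mortality with secular improvement:
#' `m(t, a) = exp(b0 + b1 * a - g * (t - t_min))`, increasing in age and
#' decreasing in calendar time; the improvement g is larger for population
#' variant 2 (higher life expectancy).
#'
#' @param cfg a [synthetic_config()].
#' @param variant population projection variant, 1 or 2.
#' @param sex `"male"` or `"female"`.
#' @return A [rate_surface()] on the configuration's grid.
#' @export
gen_mortality_surface <- function(cfg = synthetic_config(), variant = 1,
                                  sex = c("male", "female")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sex <- match.arg(sex)
  variant <- as.character(variant)
  if (!variant %in% c("1", "2")) stop("variant must be 1 or 2")
  g <- cfg$grid
  m <- exp(outer(-cfg$mort_improvement[[variant]] * (g$years - g$t_min),
                 cfg$mort_b0[[sex]] + cfg$mort_b1[[sex]] * g$ages, "+"))
  rate_surface(g, m)
}

# size of the cohort reaching the youngest grid age in year y
entry_cohort_size <- function(cfg, sex, y) {
  cfg$entry_size[[sex]] *
    (1 + cfg$entry_growth)^(y - cfg$grid$t_min) *
    (1 + cfg$boom_height * exp(-((y - cfg$boom_center) / cfg$boom_width)^2))
}

#' Population projection (synthetic)
#'
#' Cohort-consistent population counts N(t, a, sex): the baseline-year
#' column is built by surviving each cohort through the baseline mortality
#' schedule from a cohort-size curve with a baby-boom bulge, later years
#' follow the survival recursion N(t+1, a+1) = N(t, a) * exp(-m(t, a)) with
#' fresh entry cohorts at the youngest age. Both variants share entry
#' cohorts and the baseline column; variant 2's lower mortality makes its
#' later counts at least variant 1's. A small seeded lognormal jitter
#' perturbs baseline and entry counts so the pyramid is not perfectly
#' smooth.
#'
#' @param cfg a [synthetic_config()].
#' @param variant population projection variant, 1 or 2.
#' @return An object of class `population_projection`: list with `variant`
#'   and `counts`, a year x age x sex array.
#' @export
gen_population_projection <- function(cfg = synthetic_config(), variant = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  variant <- as.character(variant)
  if (!variant %in% c("1", "2")) stop("variant must be 1 or 2")
  g <- cfg$grid
  nt <- length(g$years); na <- length(g$ages)
  counts <- array(NA_real_, dim = c(nt, na, 2L),
                  dimnames = list(year = g$years, age = g$ages,
                                  sex = c("male", "female")))
  # jitter is a function of (seed) only, shared by both variants
  set.seed(cfg$seed)
  jit <- function(n) exp(stats::rnorm(n, 0, cfg$jitter_sd))
  base_jit <- list(male = jit(na), female = jit(na))
  entry_jit <- list(male = jit(nt - 1L), female = jit(nt - 1L))
  for (sx in c("male", "female")) {
    m <- gen_mortality_surface(cfg, variant, sx)$values
    m_base <- m[1L, ]  # identical across variants at t = t_min
    # baseline column: survive each cohort through the baseline schedule;
    # the cohort now aged a reached a_min in year t_min - (a - a_min)
    surv <- exp(-cumsum(c(0, m_base[-na] * g$step)))
    sizes <- entry_cohort_size(cfg, sx, g$t_min - (g$ages - g$a_min))
    counts[1L, , sx] <- sizes * surv * base_jit[[sx]]
    entry <- entry_cohort_size(cfg, sx, g$years[-1L]) * entry_jit[[sx]]
    for (r in seq_len(nt - 1L)) {
      counts[r + 1L, 1L, sx] <- entry[r]
      counts[r + 1L, -1L, sx] <-
        counts[r, -na, sx] * exp(-m[r, -na] * g$step)
    }
  }
  structure(list(variant = as.integer(variant), counts = counts,
                 grid = g),
            class = "population_projection")
}

#' @export
print.population_projection <- function(x, ...) {
  cat(sprintf("<population_projection> variant %d, %d years x %d ages x 2 sexes, total %0.3g persons at baseline\n",
              x$variant, dim(x$counts)[1], dim(x$counts)[2],
              sum(x$counts[1, , ])))
  invisible(x)
}

#' Complete synthetic input bundle
#'
#' Generates every input the scenario engine needs: per-sex baseline
#' prevalence profiles and incidence profiles, per-variant and per-sex
#' mortality surfaces, and per-variant population projections, all on one
#' grid and internally consistent (the population obeys cohort survival
#' under the same mortality surfaces the model uses).
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `ltc_inputs` with elements `grid`, `baseline`,
#'   `incidence`, `mortality` (nested `[[variant]][[sex]]`), `population`
#'   (`[[variant]]`) and `config`.
#' @export
gen_full_fixture <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mort <- lapply(c(`1` = "1", `2` = "2"), function(v)
    lapply(c(male = "male", female = "female"), function(sx)
      gen_mortality_surface(cfg, v, sx)))
  structure(list(grid = cfg$grid,
                 baseline = gen_baseline_prevalence(cfg),
                 incidence = gen_incidence_profile(cfg),
                 mortality = mort,
                 population = list(`1` = gen_population_projection(cfg, 1),
                                   `2` = gen_population_projection(cfg, 2)),
                 config = cfg),
            class = "ltc_inputs")
}

#' @export
print.ltc_inputs <- function(x, ...) {
  cat(sprintf("<ltc_inputs> synthetic bundle, seed %d, grid %s-%s x ages %s-%s\n",
              x$config$seed, x$grid$t_min, x$grid$t_max,
              x$grid$a_min, x$grid$a_max))
  invisible(x)
}
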