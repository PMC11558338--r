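# Long-format CSV readers and writers. Values are serialized with 17
# significant digits so that write -> read round-trips doubles exactly.

fmt_dbl <- function(x) sprintf("%.17g", x)

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  df
}

grid_from_long <- function(years, ages) {
  ys <- sort(unique(years)); as <- sort(unique(ages))
  step_candidates <- unique(c(diff(ys), diff(as)))
  if (length(ys) < 2 || length(as) < 2)
    stop("table must cover at least two years and two ages")
  step <- step_candidates[1]
  if (any(abs(step_candidates - step) > 1e-9))
    stop("years/ages are not evenly spaced")
  age_time_grid(min(ys), max(ys), min(as), max(as), step)
}

check_long_complete <- function(df, keys, path) {
  key <- do.call(paste, c(df[keys], sep = "|"))
  dup <- duplicated(key)
  if (any(dup))
    stop(sprintf("%s: duplicate key(s), e.g. %s", path, key[dup][1]))
  full <- do.call(paste,
                  c(expand.grid(lapply(df[keys], function(x) sort(unique(x)))),
                    sep = "|"))
  gaps <- setdiff(full, key)
  if (length(gaps))
    stop(sprintf("%s: missing cell(s): %s%s", path,
                 paste(utils::head(gaps, 5), collapse = "; "),
                 if (length(gaps) > 5) sprintf(" (and %d more)",
                                               length(gaps) - 5) else ""))
  invisible(NULL)
}

#' Read baseline prevalence profiles
#'
#' Expects a CSV with header `age_group,sex,prevalence` (or `percent`
#' instead of `prevalence`, in which case values are divided by 100).
#' `age_group` is an integer age or an open group written like `"90+"`,
#' which is expanded over the remaining ages with [extend_open_group()].
#'
#' @param path CSV file path.
#' @param a_max oldest age after open-group expansion (default 100).
#' @param rule open-group expansion rule, see [extend_open_group()].
#' @return Named list of [baseline_profile()]s, one per sex in the file.
#' @export
read_prevalence_table <- function(path, a_max = 100,
                                  rule = c("replicate", "linear")) {
  rule <- match.arg(rule)
  df <- read_csv_checked(path, c("age_group", "sex"))
  if ("prevalence" %in% names(df)) {
    val <- df$prevalence
  } else if ("percent" %in% names(df)) {
    val <- df$percent / 100
  } else stop(sprintf("%s: need a 'prevalence' or 'percent' column", path))
  bad <- which(!is.finite(val) | val < 0 | val > 1)
  if (length(bad))
    stop(sprintf("%s: prevalence out of [0, 1] at row %d (value %s)",
                 path, bad[1], val[bad[1]]))
  open <- grepl("\\+$", df$age_group)
  age <- suppressWarnings(as.numeric(sub("\\+$", "", df$age_group)))
  bad <- which(!is.finite(age))
  if (length(bad))
    stop(sprintf("%s: malformed age_group at row %d ('%s')",
                 path, bad[1], df$age_group[bad[1]]))
  out <- list()
  for (sx in unique(df$sex)) {
    rows <- df$sex == sx
    if (any(open[rows]) && any(age[rows][open[rows]] != max(age[rows])))
      stop(sprintf("%s: open age group must be the oldest group (sex %s)",
                   path, sx))
    bp <- baseline_profile(age[rows], val[rows], sx, source = path)
    out[[sx]] <- extend_open_group(bp, a_max = a_max, rule = rule)
  }
  out
}

#' Write baseline prevalence profiles
#'
#' @param profiles named list of [baseline_profile()]s (or a single one).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_prevalence_table <- function(profiles, path) {
  if (inherits(profiles, "baseline_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(bp)
    data.frame(age_group = bp$age, sex = bp$sex,
               prevalence = fmt_dbl(bp$value))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_surface_table <- function(path, kind, sex = NULL) {
  df <- read_csv_checked(path, c("year", "age", "sex", "value"))
  if (is.null(sex)) {
    sexes <- unique(df$sex)
    if (length(sexes) > 1)
      return(stats::setNames(lapply(sexes, function(sx)
        read_surface_table(path, kind, sx)), sexes))
    sex <- sexes
  }
  df <- df[df$sex == sex, , drop = FALSE]
  if (!nrow(df)) stop(sprintf("%s: no rows for sex '%s'", path, sex))
  if (any(!is.finite(df$value) | df$value < 0))
    stop(sprintf("%s: negative or non-finite values", path))
  check_long_complete(df, c("year", "age"), path)
  g <- grid_from_long(df$year, df$age)
  vals <- matrix(NA_real_, length(g$years), length(g$ages))
  vals[cbind(match(df$year, g$years), match(df$age, g$ages))] <- df$value
  if (kind == "rate") rate_surface(g, vals) else prevalence_surface(g, vals)
}

#' Read a rate surface from long-format CSV
#'
#' Expects columns `year,age,sex,value`; the (year, age) cells must form a
#' complete, evenly spaced grid per sex. Duplicate keys, gaps and negative
#' values are rejected.
#'
#' @param path CSV file path.
#' @param sex optional sex to select; with `NULL` and a multi-sex file a
#'   named list of surfaces is returned.
#' @return A [rate_surface()] (or named list of them).
#' @export
read_rate_table <- function(path, sex = NULL)
  read_surface_table(path, "rate", sex)

#' Read a prevalence surface from long-format CSV
#'
#' Same layout as [read_rate_table()], values additionally checked to lie
#' in \[0, 1\].
#'
#' @inheritParams read_rate_table
#' @return A [prevalence_surface()] (or named list of them).
#' @export
read_prevalence_surface <- function(path, sex = NULL)
  read_surface_table(path, "prevalence", sex)

#' Write one or more surfaces to long-format CSV
#'
#' @param surfaces a surface or a named list of surfaces keyed by sex.
#' @param path output CSV path.
#' @param sex sex label used when a single unnamed surface is given.
#' @return The path, invisibly.
#' @export
write_surface_table <- function(surfaces, path, sex = "all") {
  if (inherits(surfaces, "ltc_surface"))
    surfaces <- stats::setNames(list(surfaces), sex)
  df <- do.call(rbind, lapply(names(surfaces), function(sx) {
    s <- surfaces[[sx]]
    g <- s$grid
    data.frame(year = rep(g$years, times = length(g$ages)),
               age = rep(g$ages, each = length(g$years)),
               sex = sx, value = fmt_dbl(as.vector(s$values)))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read population projections from long-format CSV
#'
#' Expects columns `year,age,sex,count,variant`; per variant and sex the
#' (year, age) cells must form a complete grid.
#'
#' @param path CSV file path.
#' @return Named list of `population_projection` objects keyed by variant.
#' @export
read_population_table <- function(path) {
  df <- read_csv_checked(path, c("year", "age", "sex", "count", "variant"))
  if (any(!is.finite(df$count) | df$count < 0))
    stop(sprintf("%s: negative or non-finite counts", path))
  out <- list()
  for (v in sort(unique(df$variant))) {
    dv <- df[df$variant == v, , drop = FALSE]
    check_long_complete(dv, c("year", "age", "sex"), path)
    g <- grid_from_long(dv$year, dv$age)
    sexes <- sort(unique(dv$sex), decreasing = TRUE)  # male, female order
    counts <- array(NA_real_,
                    dim = c(length(g$years), length(g$ages), length(sexes)),
                    dimnames = list(year = g$years, age = g$ages, sex = sexes))
    counts[cbind(match(dv$year, g$years), match(dv$age, g$ages),
                 match(dv$sex, sexes))] <- dv$count
    out[[as.character(v)]] <-
      structure(list(variant = as.integer(v), counts = counts, grid = g),
                class = "population_projection")
  }
  out
}

#' Write population projections to long-format CSV
#'
#' @param pops a `population_projection` or named list of them.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_population_table <- function(pops, path) {
  if (inherits(pops, "population_projection")) pops <- list(pops)
  df <- do.call(rbind, lapply(pops, function(pp) {
    g <- pp$grid
    sexes <- dimnames(pp$counts)$sex
    do.call(rbind, lapply(sexes, function(sx)
      data.frame(year = rep(g$years, times = length(g$ages)),
                 age = rep(g$ages, each = length(g$years)),
                 sex = sx, count = fmt_dbl(as.vector(pp$counts[, , sx])),
                 variant = pp$variant)))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read incidence profiles from CSV
#'
#' Expects columns `age,sex,rate`.
#'
#' @param path CSV file path.
#' @return Named list of data frames (`age`, `rate`) keyed by sex.
#' @export
read_incidence_profile <- function(path) {
  df <- read_csv_checked(path, c("age", "sex", "rate"))
  if (any(!is.finite(df$rate) | df$rate < 0))
    stop(sprintf("%s: negative or non-finite rates", path))
  out <- list()
  for (sx in unique(df$sex)) {
    d <- df[df$sex == sx, c("age", "rate")]
    if (anyDuplicated(d$age))
      stop(sprintf("%s: duplicate ages for sex '%s'", path, sx))
    out[[sx]] <- d[order(d$age), ]
    rownames(out[[sx]]) <- NULL
  }
  out
}

#' Write incidence profiles to CSV
#'
#' @param profiles named list of data frames (`age`, `rate`) keyed by sex.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_incidence_profile <- function(profiles, path) {
  df <- do.call(rbind, lapply(names(profiles), function(sx)
    data.frame(age = profiles[[sx]]$age, sex = sx,
               rate = fmt_dbl(profiles[[sx]]$rate))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an input bundle as a directory of CSV files
#'
#' Writes `baseline_prevalence.csv`, `incidence_profile.csv`,
#' `mortality_variant<k>.csv` and `population.csv` in the layouts the
#' corresponding readers consume.
#'
#' @param inputs an input bundle (see [gen_full_fixture()]).
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_prevalence_table(inputs$baseline,
                         file.path(dir, "baseline_prevalence.csv"))
  write_incidence_profile(inputs$incidence,
                          file.path(dir, "incidence_profile.csv"))
  for (v in names(inputs$mortality))
    write_surface_table(inputs$mortality[[v]],
                        file.path(dir, sprintf("mortality_variant%s.csv", v)))
  write_population_table(inputs$population, file.path(dir, "population.csv"))
  invisible(dir)
}

#' Read an input bundle from a directory of CSV files
#'
#' Inverse of [write_inputs()].
#'
#' @param dir directory containing the input CSV files.
#' @param a_max oldest model age (open prevalence groups are expanded up
#'   to it).
#' @return A list of class `ltc_inputs`.
#' @export
read_inputs <- function(dir, a_max = 100) {
  baseline <- read_prevalence_table(file.path(dir, "baseline_prevalence.csv"),
                                    a_max = a_max)
  incidence <- read_incidence_profile(file.path(dir, "incidence_profile.csv"))
  mort_files <- list.files(dir, pattern = "^mortality_variant[0-9]+\\.csv$")
  if (!length(mort_files)) stop(sprintf("no mortality tables found in %s", dir))
  mortality <- list()
  for (f in mort_files) {
    v <- sub("^mortality_variant([0-9]+)\\.csv$", "\\1", f)
    mortality[[v]] <- read_rate_table(file.path(dir, f))
  }
  population <- read_population_table(file.path(dir, "population.csv"))
  grid <- mortality[[1]][[1]]$grid
  structure(list(grid = grid, baseline = baseline, incidence = incidence,
                 mortality = mortality, population = population,
                 config = NULL),
            class = "ltc_inputs")
}

#' Read a run configuration file
#'
#' YAML configuration for a projection run. Recognized keys: `scenarios`
#' (a list of mappings with `id`, `variant`, `R`, `trend`; omit for the
#' eight standard scenarios), `substeps`, `seed`, `a_max`,
#' `entry_prevalence`. Omitted keys fall back to the package defaults, so
#' an empty file reproduces the standard eight-scenario run.
#'
#' @param path YAML file path.
#' @return A list with elements `specs` (list of [scenario_spec()]s),
#'   `substeps`, `seed`, `a_max` and `entry_prevalence`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  specs <- if (is.null(cfg$scenarios)) default_scenarios()
  else {
    sp <- lapply(cfg$scenarios, function(s) {
      for (f in c("id", "variant", "R"))
        if (is.null(s[[f]])) stop(sprintf("scenario entry lacks '%s'", f))
      scenario_spec(s$id, s$variant, s$R,
                    if (is.null(s$trend)) 0 else s$trend)
    })
    stats::setNames(sp, vapply(sp, function(s) as.character(s$id),
                               character(1)))
  }
  list(specs = specs,
       substeps = if (is.null(cfg$substeps)) 10L else as.integer(cfg$substeps),
       seed = if (is.null(cfg$seed)) 42L else as.integer(cfg$seed),
       a_max = if (is.null(cfg$a_max)) 100 else as.numeric(cfg$a_max),
       entry_prevalence = cfg$entry_prevalence)
}

#' Write scenario totals to long-format CSV
#'
#' One row per scenario and year with the per-sex and total head counts
#' plus the scenario's defining parameters.
#'
#' @param results a `scenario_results` object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_totals_table <- function(results, path) {
  stopifnot(inherits(results, "scenario_results"))
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(scenario = r$spec$id, variant = r$spec$variant,
               R = r$spec$R, trend = r$spec$trend,
               year = r$totals$year, male = fmt_dbl(r$totals$male),
               female = fmt_dbl(r$totals$female),
               total = fmt_dbl(r$totals$total))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the scenario summary table from a totals CSV
#'
#' Recreates the [make_report()] table from the long totals file written by
#' [write_totals_table()], without re-running the projection.
#'
#' @param path CSV written by [write_totals_table()].
#' @param with_care_ratio see [make_report()].
#' @return A data frame, one row per scenario.
#' @export
report_from_totals <- function(path, with_care_ratio = FALSE) {
  df <- read_csv_checked(path, c("scenario", "variant", "R", "trend",
                                 "year", "male", "female", "total"))
  results <- lapply(split(df, df$scenario), function(d) {
    d <- d[order(d$year), ]
    structure(list(spec = scenario_spec(d$scenario[1], d$variant[1],
                                        d$R[1], d$trend[1]),
                   totals = data.frame(year = d$year, male = d$male,
                                       female = d$female, total = d$total)),
              class = "scenario_result")
  })
  results <- results[order(as.integer(names(results)))]
  make_report(structure(results, class = "scenario_results"),
              with_care_ratio = with_care_ratio)
}
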