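# Head-count conversion and reporting: prevalence x population products,
# percent changes, care ratios and the eight-scenario summary table.

#' Head counts from prevalence and population
#'
#' Multiplies the projected age- and sex-specific prevalence with the
#' projected population counts: count(t, a) = p(t, a) * N(t, a, sex).
#'
#' @param p a [prevalence_surface()].
#' @param pop a `population_projection` (see [gen_population_projection()]
#'   or [read_population_table()]).
#' @param sex `"male"` or `"female"`.
#' @return A year x age matrix of persons in need of long-term care.
#' @export
counts_from_prevalence <- function(p, pop, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(inherits(p, "prevalence_surface"),
            inherits(pop, "population_projection"))
  if (!same_grid(p$grid, pop$grid))
    stop("prevalence and population grids do not match")
  p$values * pop$counts[, , sex]
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the reported percent
#' changes and the count tables in millions; base R's `round()` rounds
#' half to even instead.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Percent change between two counts
#'
#' `100 * (projected / baseline - 1)`, rounded half-up to an integer
#' percent, matching the formatting of published projection tables.
#'
#' @param baseline_count count at the baseline year (> 0).
#' @param projected_count count at the projection year.
#' @return Integer percent change (vectorized).
#' @examples
#' percent_change(5.0e6, 6.6e6)  # +32
#' percent_change(1.8e6, 2.6e6)  # +44
#' @export
percent_change <- function(baseline_count, projected_count) {
  if (any(!is.finite(baseline_count)) || any(baseline_count <= 0))
    stop("baseline count must be positive")
  round_half_up(100 * (projected_count / baseline_count - 1))
}

#' Care ratio: recipients in formal care per professional caregiver
#'
#' Multiplies the total number of care recipients by the share cared for in
#' stationary facilities or by outpatient services and divides by the
#' number of professional caregivers. The defaults (36% formal-care share,
#' 1.6 million caregivers) reflect the German situation around the
#' baseline year and can be overridden.
#'
#' @param total_recipients total persons in need of long-term care.
#' @param formal_share fraction cared for by formal services, in \[0, 1\].
#' @param caregivers number of professional caregivers (> 0).
#' @return Recipients in formal care per caregiver (vectorized).
#' @examples
#' care_ratio(5.0e6)             # about 1 caregiver per 1.1 recipients
#' care_ratio(14.0e6)            # about 1 per 3.2 if demand nearly triples
#' @export
care_ratio <- function(total_recipients, formal_share = 0.36,
                       caregivers = 1.6e6) {
  if (any(!is.finite(caregivers)) || any(caregivers <= 0))
    stop("caregivers must be positive")
  if (any(!is.finite(formal_share)) || any(formal_share < 0 | formal_share > 1))
    stop("formal_share must lie in [0, 1]")
  total_recipients * formal_share / caregivers
}

#' Scenario summary table
#'
#' Condenses a set of scenario runs into one row per scenario: head counts
#' in millions (rounded to one decimal) by sex and in total at the baseline
#' and final projection year, with percent changes (computed on the
#' unrounded counts, half-up to integer percent). Optionally appends the
#' care ratio implied by the final-year total.
#'
#' @param results a `scenario_results` object from [run_scenarios()].
#' @param with_care_ratio append a `care_ratio_<final year>` column
#'   computed with [care_ratio()] defaults.
#' @return A data frame, one row per scenario.
#' @export
make_report <- function(results, with_care_ratio = FALSE) {
  stopifnot(inherits(results, "scenario_results"), length(results) > 0)
  rows <- lapply(results, function(r) {
    tt <- r$totals
    n <- nrow(tt)
    y0 <- tt$year[1]; y1 <- tt$year[n]
    row <- data.frame(
      scenario = r$spec$id, variant = r$spec$variant, R = r$spec$R,
      trend = r$spec$trend,
      men_base = round_half_up(tt$male[1] / 1e6, 1),
      women_base = round_half_up(tt$female[1] / 1e6, 1),
      total_base = round_half_up(tt$total[1] / 1e6, 1),
      men_proj = round_half_up(tt$male[n] / 1e6, 1),
      men_pct = percent_change(tt$male[1], tt$male[n]),
      women_proj = round_half_up(tt$female[n] / 1e6, 1),
      women_pct = percent_change(tt$female[1], tt$female[n]),
      total_proj = round_half_up(tt$total[n] / 1e6, 1),
      total_pct = percent_change(tt$total[1], tt$total[n]))
    names(row) <- sub("base", y0, names(row))
    names(row) <- sub("proj", y1, names(row))
    if (with_care_ratio)
      row[[paste0("care_ratio_", y1)]] <-
        round_half_up(care_ratio(tt$total[n]), 2)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot projected head counts by year
#'
#' Simple base-graphics line plot of total projected persons in need of
#' long-term care per scenario, by sex or in total.
#'
#' @param results a `scenario_results` object.
#' @param what `"total"`, `"male"` or `"female"`.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return Invisibly, the year x scenario matrix that was plotted.
#' @export
plot_projection <- function(results, what = c("total", "male", "female"),
                            ...) {
  what <- match.arg(what)
  stopifnot(inherits(results, "scenario_results"))
  years <- results[[1]]$totals$year
  mat <- vapply(results, function(r) r$totals[[what]] / 1e6,
                numeric(length(years)))
  graphics::matplot(years, mat, type = "l", lty = 1, lwd = 2,
                    xlab = "calendar year",
                    ylab = sprintf("persons in need of LTC (%s, millions)",
                                   what), ...)
  graphics::legend("topleft", legend = paste("scenario", colnames(mat)),
                   col = seq_len(ncol(mat)), lty = 1, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(mat)
}
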