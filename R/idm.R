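# Illness-death model core: the transport PDE along age-period
# characteristics, its RK4 integration, and the inverse (incidence) problem.

check_idm_args <- function(p, i, m, R) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("prevalence p must lie in [0, 1]")
  if (any(!is.finite(i)) || any(i < 0)) stop("incidence rate must be >= 0")
  if (any(!is.finite(m)) || any(m < 0)) stop("mortality rate must be >= 0")
  if (any(!is.finite(R)) || any(R <= 0))
    stop("mortality rate ratio R must be positive")
  invisible(NULL)
}

#' Rate of prevalence change along a characteristic
#'
#' The illness-death model links prevalence p, incidence i, all-cause
#' mortality m and the mortality rate ratio R = m1/m0 through a transport
#' equation in age and calendar time. Along a birth cohort's characteristic
#' (age and time advancing together) it reduces to the ordinary differential
#' equation
#'
#'   dp/dtau = (1 - p) * ( i - m * p * (R - 1) / (1 + p * (R - 1)) )
#'
#' whose right-hand side this function evaluates. With R = 1 (no excess
#' mortality of care-dependent people) it collapses to (1 - p) * i.
#'
#' @param p prevalence fraction in \[0, 1\].
#' @param i incidence rate (per person-year), non-negative.
#' @param m all-cause mortality rate (per person-year), non-negative.
#' @param R mortality rate ratio m1/m0, positive.
#' @return The rate of change of prevalence (per year). Vectorized.
#' @examples
#' pde_rhs(p = 0, i = 0.10, m = 0.02, R = 3.2)   # just the incidence
#' pde_rhs(p = 1, i = 0.10, m = 0.02, R = 3.2)   # saturated: 0
#' @export
pde_rhs <- function(p, i, m, R) {
  check_idm_args(p, i, m, R)
  (1 - p) * (i - m * p * (R - 1) / (1 + p * (R - 1)))
}

#' Partition all-cause mortality into state-specific rates
#'
#' All-cause mortality is the prevalence-weighted mixture of the mortality
#' of people without (m0) and with (m1) need for long-term care:
#' m = (1 - p) m0 + p m1 with m1 = R m0. Solving gives
#' m0 = m / (1 + p (R - 1)) and m1 = R m0.
#'
#' @inheritParams pde_rhs
#' @return A list with components `m0` and `m1` (vectorized).
#' @examples
#' split_mortality(m = 0.05, p = 0.5, R = 3.2)
#' @export
split_mortality <- function(m, p, R) {
  check_idm_args(p, 0, m, R)
  m0 <- m / (1 + p * (R - 1))
  list(m0 = m0, m1 = R * m0)
}

# Clamp prevalence to [0, 1]; excursions beyond tol indicate a genuinely
# invalid state and raise an error instead of being hidden.
clamp_unit <- function(p, tol = 1e-6) {
  if (any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol))
    stop(sprintf("prevalence left [0, 1] by more than %g (min %g, max %g)",
                 tol, min(p), max(p)))
  pmin(pmax(p, 0), 1)
}

as_rate_fun <- function(x, what) {
  if (inherits(x, "rate_surface")) return(function(t, a) eval_surface(x, t, a))
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0)
    return(function(t, a) rep_len(x, length(t)))
  stop(sprintf("%s must be a rate_surface, a function(t, a) or a single rate",
               what))
}

#' Integrate one cohort's prevalence along its characteristic
#'
#' Classical fourth-order Runge-Kutta integration of the illness-death ODE
#' (see [pde_rhs()]) along the diagonal a = a0 + (t - t0), with `substeps`
#' RK4 steps per grid interval. Rates are evaluated at the characteristic's
#' (t, a) points, by bilinear interpolation when given as surfaces.
#'
#' @param p0 prevalence at (t0, a0), in \[0, 1\].
#' @param i,m incidence and all-cause mortality: a [rate_surface()], a
#'   `function(t, a)`, or a single constant rate.
#' @param R mortality rate ratio m1/m0.
#' @param t0,a0 calendar year and age at which the cohort enters.
#' @param t1 calendar year at which integration stops (t1 >= t0).
#' @param substeps number of RK4 steps per node interval (default 10,
#'   i.e. step 0.1 years on a one-year grid).
#' @param step node spacing of the returned path; defaults to the grid step
#'   of `i` or `m` when one is a surface, else 1.
#' @return Named numeric vector of prevalence at the nodes t0, t0 + step,
#'   ..., t1, clamped to \[0, 1\].
#' @examples
#' # with R = 1 and constant incidence the closed form is
#' # p(tau) = 1 - (1 - p0) * exp(-i * tau)
#' p <- solve_cohort(0, i = 0.05, m = 0.02, R = 1, t0 = 0, a0 = 60, t1 = 10)
#' abs(p[["10"]] - (1 - exp(-0.5)))
#' @export
solve_cohort <- function(p0, i, m, R, t0, a0, t1, substeps = 10, step = NULL) {
  if (!is.finite(p0) || p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (!is.finite(R) || R <= 0) stop("mortality rate ratio R must be positive")
  if (t1 < t0) stop("t1 must not precede t0")
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("substeps must be at least 1")
  if (is.null(step)) {
    step <- if (inherits(i, "rate_surface")) i$grid$step
            else if (inherits(m, "rate_surface")) m$grid$step else 1
  }
  fi <- as_rate_fun(i, "i"); fm <- as_rate_fun(m, "m")
  n_nodes <- round((t1 - t0) / step)
  if (abs(n_nodes - (t1 - t0) / step) > 1e-9)
    stop("t1 - t0 must be an integer multiple of the step")
  h <- step / substeps
  rhs <- function(tau, p) {
    p <- pmin(pmax(p, 0), 1)  # guard RK stage excursions
    t <- t0 + tau; a <- a0 + tau
    ii <- fi(t, a); mm <- fm(t, a)
    if (!is.finite(ii) || !is.finite(mm) || ii < 0 || mm < 0)
      stop(sprintf("non-finite or negative rate at (t = %g, a = %g)", t, a))
    (1 - p) * (ii - mm * p * (R - 1) / (1 + p * (R - 1)))
  }
  out <- numeric(n_nodes + 1L)
  out[1L] <- p0
  p <- p0
  for (node in seq_len(n_nodes)) {
    tau <- (node - 1L) * step
    for (s in seq_len(substeps)) {
      tt <- tau + (s - 1L) * h
      k1 <- rhs(tt, p)
      k2 <- rhs(tt + h / 2, p + h / 2 * k1)
      k3 <- rhs(tt + h / 2, p + h / 2 * k2)
      k4 <- rhs(tt + h, p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    p <- clamp_unit(p)
    out[node + 1L] <- p
  }
  names(out) <- format(seq(t0, t1, by = step), trim = TRUE)
  out
}

#' Project a full prevalence surface from a baseline profile
#'
#' Fills the (year, age) grid by integrating every cohort once along its
#' characteristic. Cohorts already present at the baseline year start from
#' the baseline profile; cohorts entering at the lower age boundary in later
#' years start from an entry prevalence (by default the baseline value at
#' the youngest age, i.e. constant entry conditions).
#'
#' @param baseline a [baseline_profile()] covering all grid ages (extend an
#'   open age group first with [extend_open_group()]).
#' @param i,m incidence and all-cause mortality as [rate_surface()] objects
#'   covering the grid (constants and functions are also accepted).
#' @param R mortality rate ratio m1/m0.
#' @param grid an [age_time_grid()].
#' @param substeps RK4 steps per node interval (default 10).
#' @param entry_prevalence prevalence assigned to cohorts entering at
#'   `grid$a_min` after the baseline year; default `NULL` uses the baseline
#'   profile's value at `a_min`.
#' @return A [prevalence_surface()] whose first-year column equals the
#'   baseline profile.
#' @export
project_prevalence_surface <- function(baseline, i, m, R, grid = age_time_grid(),
                                       substeps = 10, entry_prevalence = NULL) {
  stopifnot(inherits(baseline, "baseline_profile"),
            inherits(grid, "age_time_grid"))
  missing_ages <- setdiff(grid$ages, baseline$age)
  if (length(missing_ages))
    stop(sprintf("baseline profile is missing age(s) %s",
                 paste(missing_ages, collapse = ", ")))
  for (s in list(i, m)) {
    if (inherits(s, "rate_surface") && !same_grid(s$grid, grid))
      stop("rate surface grid does not match the projection grid")
  }
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("substeps must be at least 1")
  years <- grid$years; ages <- grid$ages
  step <- grid$step; h <- step / substeps
  P <- matrix(NA_real_, length(years), length(ages))
  p_entry <- if (is.null(entry_prevalence))
    profile_at(baseline, grid$a_min) else entry_prevalence
  if (!is.finite(p_entry) || p_entry < 0 || p_entry > 1)
    stop("entry prevalence must lie in [0, 1]")
  fi <- as_rate_fun(i, "i"); fm <- as_rate_fun(m, "m")
  rhs_vec <- function(t, a, p) {
    p <- pmin(pmax(p, 0), 1)
    ii <- fi(t, a); mm <- fm(t, a)
    if (any(!is.finite(ii) | !is.finite(mm) | ii < 0 | mm < 0))
      stop("non-finite or negative rate evaluation")
    (1 - p) * (ii - mm * p * (R - 1) / (1 + p * (R - 1)))
  }
  # advance a vector of cohorts over one node interval starting at (t, a)
  advance <- function(t, a, p) {
    for (s in seq_len(substeps)) {
      tt <- t + (s - 1L) * h; aa <- a + (s - 1L) * h
      k1 <- rhs_vec(tt, aa, p)
      k2 <- rhs_vec(tt + h / 2, aa + h / 2, p + h / 2 * k1)
      k3 <- rhs_vec(tt + h / 2, aa + h / 2, p + h / 2 * k2)
      k4 <- rhs_vec(tt + h, aa + h, p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    clamp_unit(p)
  }
  eps <- 1e-9
  # cohorts present at baseline, swept in lockstep along their diagonals
  p <- profile_at(baseline, ages)
  P[1L, ] <- p
  for (node in seq_len(length(years) - 1L)) {
    act <- ages + node * step <= grid$a_max + eps
    if (!any(act)) break
    p[act] <- advance(rep(years[node], sum(act)),
                      ages[act] + (node - 1L) * step, p[act])
    P[cbind(node + 1L, match(ages[act] + node * step, ages))] <- p[act]
  }
  # cohorts entering at a_min after baseline
  t0s <- years[-1L]
  if (length(t0s)) {
    p <- rep(p_entry, length(t0s))
    P[cbind(match(t0s, years), 1L)] <- p
    for (k in seq_len(length(ages) - 1L)) {
      act <- t0s + k * step <= grid$t_max + eps
      if (!any(act)) break
      p[act] <- advance(t0s[act] + (k - 1L) * step,
                        rep(grid$a_min + (k - 1L) * step, sum(act)), p[act])
      P[cbind(match(t0s[act] + k * step, years), k + 1L)] <- p[act]
    }
  }
  prevalence_surface(grid, P)
}

#' Derive the incidence rate from prevalence, mortality and R
#'
#' Algebraic rearrangement of the illness-death transport equation:
#'
#'   i = d p / (1 - p) + m * p * (R - 1) / (1 + p * (R - 1))
#'
#' where d p is the directional derivative of prevalence along the
#' characteristic, estimated by the centred diagonal difference
#' (p(t+1, a+1) - p(t-1, a-1)) / 2 at interior nodes and by one-sided
#' differences along the grid edges. At the two corner nodes with no
#' diagonal neighbour inside the grid the derivative is set to 0.
#'
#' Negative derived rates (possible from differencing noise; the derived
#' incidence is a lower limit in the presence of unmodelled remission) are
#' floored at 0 with a warning unless `floor_negative = FALSE`.
#'
#' @param p a [prevalence_surface()] with p < 1 everywhere.
#' @param m all-cause mortality as a [rate_surface()] on the same grid.
#' @param R mortality rate ratio m1/m0.
#' @param floor_negative replace negative derived rates by 0 (default TRUE).
#' @return A [rate_surface()] of incidence with attribute `n_floored`, the
#'   number of nodes floored at 0.
#' @export
derive_incidence <- function(p, m, R, floor_negative = TRUE) {
  stopifnot(inherits(p, "prevalence_surface"), inherits(m, "rate_surface"))
  if (!same_grid(p$grid, m$grid))
    stop("prevalence and mortality grids do not match")
  if (!is.finite(R) || R <= 0) stop("mortality rate ratio R must be positive")
  P <- p$values
  if (any(P >= 1)) stop("saturated prevalence (p = 1): incidence undefined")
  g <- p$grid
  nt <- nrow(P); na <- ncol(P)
  # directional derivative along the diagonal, centred where possible
  D <- matrix(0, nt, na)
  it <- seq_len(nt); ia <- seq_len(na)
  for (r in it) {
    for (c in ia) {
      has_b <- r > 1L && c > 1L
      has_f <- r < nt && c < na
      D[r, c] <- if (has_b && has_f)
        (P[r + 1L, c + 1L] - P[r - 1L, c - 1L]) / (2 * g$step)
      else if (has_f) (P[r + 1L, c + 1L] - P[r, c]) / g$step
      else if (has_b) (P[r, c] - P[r - 1L, c - 1L]) / g$step
      else 0
    }
  }
  Pc <- pmin(P, 1 - 1e-9)
  I <- D / (1 - Pc) + m$values * Pc * (R - 1) / (1 + Pc * (R - 1))
  n_neg <- sum(I < 0)
  if (n_neg > 0) {
    if (!floor_negative)
      stop(sprintf("%d derived incidence value(s) are negative", n_neg))
    warning(sprintf("floored %d negative derived incidence value(s) at 0",
                    n_neg))
    I[I < 0] <- 0
  }
  out <- rate_surface(g, I)
  attr(out, "n_floored") <- n_neg
  out
}
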