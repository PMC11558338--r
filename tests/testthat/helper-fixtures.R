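# Shared helpers: small grids and fixtures keep unit tests fast; the
# full default grid is exercised in the acceptance tests.

tiny_grid <- function(t0 = 2021, t1 = 2026, a0 = 60, a1 = 66) {
  age_time_grid(t0, t1, a0, a1)
}

small_cfg <- function(seed = 42L) {
  synthetic_config(seed = seed, grid = age_time_grid(2021, 2035, 60, 80))
}

const_surface <- function(grid, value) rate_surface(grid, value)

flat_baseline <- function(grid, value = 0.1, sex = "male") {
  baseline_profile(grid$ages, rep(value, length(grid$ages)), sex)
}

# independent forward-Euler integration along the characteristics,
# vectorized over cohorts; used as an oracle for the RK4 surface solver
euler_surface <- function(baseline, i, m, R, grid, nsub = 512) {
  years <- grid$years; ages <- grid$ages
  h <- grid$step / nsub
  P <- matrix(NA_real_, length(years), length(ages))
  adv <- function(t, a, p) {
    for (s in seq_len(nsub)) {
      tt <- t + (s - 1) * h; aa <- a + (s - 1) * h
      ii <- eval_surface(i, tt, aa); mm <- eval_surface(m, tt, aa)
      p <- p + h * (1 - p) * (ii - mm * p * (R - 1) / (1 + p * (R - 1)))
    }
    pmin(pmax(p, 0), 1)
  }
  p <- profile_at(baseline, ages); P[1, ] <- p
  for (node in seq_len(length(years) - 1)) {
    act <- ages + node * grid$step <= grid$a_max + 1e-9
    if (!any(act)) break
    p[act] <- adv(rep(years[node], sum(act)),
                  ages[act] + (node - 1) * grid$step, p[act])
    P[cbind(node + 1, match(ages[act] + node * grid$step, ages))] <- p[act]
  }
  t0s <- years[-1]
  p <- rep(profile_at(baseline, grid$a_min), length(t0s))
  P[cbind(match(t0s, years), 1)] <- p
  for (k in seq_len(length(ages) - 1)) {
    act <- t0s + k * grid$step <= grid$t_max + 1e-9
    if (!any(act)) break
    p[act] <- adv(t0s[act] + (k - 1) * grid$step,
                  rep(grid$a_min + (k - 1) * grid$step, sum(act)), p[act])
    P[cbind(match(t0s[act] + k * grid$step, years), k + 1)] <- p[act]
  }
  P
}

interior <- function(M) M[2:(nrow(M) - 1), 2:(ncol(M) - 1)]
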