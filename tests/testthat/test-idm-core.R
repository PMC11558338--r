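test_that("the PDE right-hand side matches direct arithmetic", {
  # at p = 0 the mortality term vanishes
  expect_equal(pde_rhs(0, 0.10, 0.02, 3.2), 0.10)
  # saturated prevalence cannot grow
  expect_equal(pde_rhs(1, 0.10, 0.02, 3.2), 0)
  # R = 1: no excess mortality, rhs = (1 - p) * i
  expect_equal(pde_rhs(0.3, 0.20, 0.05, 1), 0.7 * 0.2)
  # general case, evaluated independently
  expect_equal(pde_rhs(0.5, 0.10, 0.05, 3.2),
               0.5 * (0.1 - 0.05 * (0.5 * 2.2) / (1 + 0.5 * 2.2)))
})

test_that("the right-hand side rejects out-of-domain states", {
  expect_error(pde_rhs(-0.1, 0.1, 0.05, 2), "\\[0, 1\\]")
  expect_error(pde_rhs(1.1, 0.1, 0.05, 2), "\\[0, 1\\]")
  expect_error(pde_rhs(0.5, -0.1, 0.05, 2), "incidence")
  expect_error(pde_rhs(0.5, 0.1, -0.05, 2), "mortality")
  expect_error(pde_rhs(0.5, 0.1, 0.05, 0), "positive")
})

test_that("with R = 1 the rhs reduces to (1 - p) * i for any state", {
  set.seed(11)
  for (k in 1:50) {
    p <- runif(1); i <- rexp(1, 10); m <- rexp(1, 10)
    expect_equal(pde_rhs(p, i, m, 1), (1 - p) * i)
  }
})

test_that("mortality partition conserves the mixture and the ratio", {
  sm <- split_mortality(0.05, 0, 3.2)
  expect_equal(c(sm$m0, sm$m1), c(0.05, 0.16))
  sm <- split_mortality(0.05, 0.5, 1)
  expect_equal(c(sm$m0, sm$m1), c(0.05, 0.05))
  sm <- split_mortality(0.05, 0.5, 3.2)
  expect_equal(sm$m0, 0.05 / 2.1)
  expect_equal(sm$m1, 3.2 * 0.05 / 2.1)
  set.seed(22)
  for (k in 1:100) {
    m <- rexp(1, 5); p <- runif(1); R <- runif(1, 0.2, 5)
    sm <- split_mortality(m, p, R)
    expect_equal((1 - p) * sm$m0 + p * sm$m1, m, tolerance = 1e-12)
    expect_equal(sm$m1 / sm$m0, R, tolerance = 1e-12)
  }
})

test_that("RK4 cohort solution matches the R = 1 closed form to 1e-8 over 40 years", {
  i0 <- 0.05
  p <- solve_cohort(0, i = i0, m = 0.03, R = 1, t0 = 0, a0 = 0, t1 = 40,
                    substeps = 10)
  tau <- 0:40
  expect_lt(max(abs(p - (1 - exp(-i0 * tau)))), 1e-8)
  # nonzero starting prevalence
  p <- solve_cohort(0.25, i = i0, m = 0.1, R = 1, t0 = 0, a0 = 0, t1 = 40,
                    substeps = 10)
  expect_lt(max(abs(p - (1 - 0.75 * exp(-i0 * tau)))), 1e-8)
})

test_that("zero incidence with R = 1 leaves prevalence unchanged", {
  p <- solve_cohort(0.4, i = 0, m = 0.08, R = 1, t0 = 2021, a0 = 60,
                    t1 = 2050, substeps = 5)
  expect_equal(unname(p), rep(0.4, 30), tolerance = 1e-14)
})

test_that("a constructed equilibrium is preserved to 1e-10 over 20 years", {
  p_star <- 0.3; m <- 0.06; R <- 3.2
  i_star <- m * p_star * (R - 1) / (1 + p_star * (R - 1))
  p <- solve_cohort(p_star, i = i_star, m = m, R = R, t0 = 0, a0 = 60,
                    t1 = 20, substeps = 10)
  expect_lt(max(abs(p - p_star)), 1e-10)
})

test_that("halving the RK4 step shrinks the closed-form error about 16-fold", {
  closed <- function(tau) 1 - exp(-0.05 * tau)
  err <- function(substeps) {
    p <- solve_cohort(0, i = 0.05, m = 0.03, R = 1, t0 = 0, a0 = 0,
                      t1 = 40, substeps = substeps)
    max(abs(p - closed(0:40)))
  }
  ratio <- err(5) / err(10)
  expect_gt(ratio, 12)
  expect_lt(ratio, 20)
})

test_that("projected prevalence stays in [0, 1] for random non-negative rates", {
  g <- tiny_grid()
  set.seed(7)
  for (k in 1:10) {
    i <- rate_surface(g, matrix(rexp(length(g$years) * length(g$ages), 2),
                                length(g$years)))
    m <- rate_surface(g, matrix(rexp(length(g$years) * length(g$ages), 2),
                                length(g$years)))
    bl <- baseline_profile(g$ages, runif(length(g$ages)), "male")
    p <- project_prevalence_surface(bl, i, m, R = runif(1, 0.5, 4), g,
                                    substeps = 4)
    expect_true(all(p$values >= 0 & p$values <= 1))
  }
})

test_that("the cohort solver matches deSolve's classical RK4 on the same ODE", {
  skip_if_not_installed("deSolve")
  g <- age_time_grid(2021, 2031, 60, 70)
  i <- rate_surface(g, outer(rep(1, 11), exp(-6 + 0.08 * (g$ages - 60))))
  m <- rate_surface(g, outer(rep(1, 11), exp(-5 + 0.09 * (g$ages - 60))))
  R <- 3.2
  ours <- solve_cohort(0.05, i, m, R, 2021, 60, 2031, substeps = 10)
  ref <- deSolve::rk4(
    y = c(p = 0.05), times = seq(0, 10, by = 0.1),
    func = function(tau, y, parms) {
      ii <- eval_surface(i, 2021 + tau, 60 + tau)
      mm <- eval_surface(m, 2021 + tau, 60 + tau)
      list(pde_rhs(min(max(y, 0), 1), ii, mm, R))
    }, parms = NULL)
  expect_equal(unname(ours), unname(ref[ref[, "time"] %% 1 == 0, "p"]),
               tolerance = 1e-10)
})

test_that("surface projection starts at the baseline and respects characteristics", {
  g <- tiny_grid()
  bl <- baseline_profile(g$ages, seq(0.05, 0.35, by = 0.05), "male")
  p <- project_prevalence_surface(bl, i = const_surface(g, 0),
                                  m = const_surface(g, 0.1), R = 1, grid = g)
  # baseline column returned exactly
  expect_identical(unname(p$values[1, ]), profile_at(bl, g$ages))
  # i = 0, R = 1: rhs is 0, so the surface is constant along every diagonal
  for (d in -5:5) {
    idx <- which(row(p$values) - col(p$values) == d)
    expect_equal(diff(p$values[idx]), rep(0, length(idx) - 1),
                 tolerance = 1e-14)
  }
  # missing baseline ages are reported
  short <- baseline_profile(60:63, rep(0.1, 4), "male")
  expect_error(project_prevalence_surface(short, 0, 0.1, 1, g), "missing age")
})

test_that("the surface sweep agrees with per-cohort integration", {
  cfg <- small_cfg()
  fx <- gen_full_fixture(cfg)
  g <- fx$grid
  i <- build_incidence_surface(fx$incidence$female, g)
  m <- fx$mortality[["1"]]$female
  p <- project_prevalence_surface(fx$baseline$female, i, m, 3.2, g)
  for (a0 in c(60, 68, 75)) {
    t1 <- min(g$t_max, g$t_min + (g$a_max - a0))
    path <- solve_cohort(profile_at(fx$baseline$female, a0), i, m, 3.2,
                         g$t_min, a0, t1)
    k <- seq_along(path) - 1
    expect_equal(unname(path),
                 unname(p$values[cbind(1 + k, match(a0 + k, g$ages))]),
                 tolerance = 1e-12)
  }
})

test_that("projected prevalence is non-increasing in the mortality rate ratio", {
  cfg <- small_cfg()
  fx <- gen_full_fixture(cfg)
  g <- fx$grid
  i <- build_incidence_surface(fx$incidence$male, g)
  m <- fx$mortality[["1"]]$male
  ps <- lapply(c(1, 1.17, 3.2), function(R)
    project_prevalence_surface(fx$baseline$male, i, m, R, g)$values)
  expect_true(all(ps[[1]] - ps[[2]] >= -1e-12))
  expect_true(all(ps[[2]] - ps[[3]] >= -1e-12))
  # and strictly decreasing somewhere
  expect_gt(max(ps[[2]] - ps[[3]]), 1e-4)
})
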