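test_that("the generator is deterministic for a fixed seed and config", {
  expect_identical(gen_full_fixture(synthetic_config(seed = 42)),
                   gen_full_fixture(synthetic_config(seed = 42)))
  # a different seed changes the population jitter
  a <- gen_population_projection(synthetic_config(seed = 1))
  b <- gen_population_projection(synthetic_config(seed = 2))
  expect_false(identical(a$counts, b$counts))
})

test_that("baseline prevalence is a monotone logistic with female excess at high ages", {
  cfg <- synthetic_config()
  bl <- gen_baseline_prevalence(cfg)
  for (sx in c("male", "female")) {
    v <- bl[[sx]]$value
    expect_length(v, 41)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= 0))
  }
  old <- cfg$grid$ages >= 85
  expect_true(all(profile_at(bl$female, cfg$grid$ages[old]) >=
                    profile_at(bl$male, cfg$grid$ages[old])))
  # the logistic midpoint sits at half the plateau
  cfg2 <- synthetic_config(prev_mid = c(male = 85, female = 85),
                           prev_max = c(male = 0.8, female = 0.8))
  bl2 <- gen_baseline_prevalence(cfg2)
  expect_equal(profile_at(bl2$male, 85), 0.4)
})

test_that("mortality is Gompertz in age, improving in time, variant 2 faster", {
  cfg <- synthetic_config(mort_b0 = c(male = -11, female = -11),
                          mort_b1 = c(male = 0.1, female = 0.1))
  m <- gen_mortality_surface(cfg, 1, "male")
  expect_equal(m$values["2021", "60"], exp(-5))
  # increasing in age at every node
  expect_true(all(apply(m$values, 1, diff) > 0))
  # decreasing in calendar time
  expect_true(all(apply(m$values, 2, diff) < 0))
  m1 <- gen_mortality_surface(synthetic_config(), 1, "female")$values
  m2 <- gen_mortality_surface(synthetic_config(), 2, "female")$values
  expect_true(all(m2[-1, ] <= m1[-1, ]))
  # zero improvement freezes the surface in time
  m0 <- gen_mortality_surface(synthetic_config(mort_improvement = c(0, 0)),
                              1, "male")$values
  expect_equal(max(apply(m0, 2, function(x) diff(range(x)))), 0)
})

test_that("the population pyramid obeys its own survival recursion exactly", {
  cfg <- small_cfg()
  for (v in 1:2) {
    pop <- gen_population_projection(cfg, v)
    nt <- dim(pop$counts)[1]; na <- dim(pop$counts)[2]
    for (sx in c("male", "female")) {
      m <- gen_mortality_surface(cfg, v, sx)$values
      lhs <- pop$counts[-1, -1, sx]
      rhs <- pop$counts[-nt, -na, sx] * exp(-m[-nt, -na])
      expect_lt(max(abs(lhs - rhs) / rhs), 1e-12)
    }
    expect_true(all(is.finite(pop$counts)) && all(pop$counts >= 0))
  }
})

test_that("variant 2 counts are at least variant 1 counts node by node", {
  cfg <- synthetic_config()
  p1 <- gen_population_projection(cfg, 1)$counts
  p2 <- gen_population_projection(cfg, 2)$counts
  expect_true(all(p2 - p1 >= -1e-9))
  expect_gt(sum(p2) / sum(p1), 1)  # strictly more survivors overall
})

test_that("the baseline-year prevalence share over 60+ lies in a plausible band", {
  fx <- gen_full_fixture(synthetic_config())
  pop <- fx$population[["1"]]$counts[1, , ]
  ages <- fx$grid$ages
  ltc <- sum(profile_at(fx$baseline$male, ages) * pop[, "male"] +
               profile_at(fx$baseline$female, ages) * pop[, "female"])
  share <- ltc / sum(pop)
  expect_gt(share, 0.05)
  expect_lt(share, 0.30)
})

test_that("the bundle feeds all eight scenarios and embeds a recoverable incidence", {
  fx <- gen_full_fixture(small_cfg())
  res <- run_scenarios(fx)  # smoke: all eight run without error
  expect_length(res, 8)
  g <- fx$grid
  i0 <- build_incidence_surface(fx$incidence$female, g)
  i_rec <- derive_incidence(res[["1"]]$surfaces$female,
                            fx$mortality[["1"]]$female, 3.2)
  expect_lt(max(abs(interior(i_rec$values) - interior(i0$values))), 1e-4)
})
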