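test_that("head counts are prevalence times population", {
  cfg <- small_cfg()
  fx <- gen_full_fixture(cfg)
  g <- fx$grid
  pop <- fx$population[["1"]]
  p <- prevalence_surface(g, 0.1)
  cnt <- counts_from_prevalence(p, pop, "male")
  expect_equal(cnt, 0.1 * pop$counts[, , "male"])
  # zero population gives zero counts regardless of prevalence
  pop0 <- pop; pop0$counts[, , "male"] <- 0
  expect_true(all(counts_from_prevalence(prevalence_surface(g, 0.9),
                                         pop0, "male") == 0))
  # counts never exceed the population
  p2 <- fx$baseline$male
  surf <- prevalence_surface(g, matrix(rep(profile_at(p2, g$ages),
                                           each = length(g$years)),
                                       length(g$years)))
  cnt2 <- counts_from_prevalence(surf, pop, "male")
  expect_true(all(cnt2 >= 0 & cnt2 <= pop$counts[, , "male"]))
  # independent elementwise oracle for the total
  expect_equal(sum(cnt2),
               sum(surf$values * pop$counts[, , "male"]))
  g2 <- tiny_grid(t1 = 2030)
  expect_error(counts_from_prevalence(prevalence_surface(g2, 0.1), pop,
                                      "male"), "do not match")
})

test_that("percent changes reproduce the published worked examples", {
  expect_equal(percent_change(5.0e6, 6.6e6), 32)
  expect_equal(percent_change(1.8e6, 2.6e6), 44)
  expect_equal(percent_change(5.0e6, 5.6e6), 12)
  expect_equal(percent_change(5.0e6, 14.0e6), 180)
  expect_equal(percent_change(3.2e6, 3.5e6), 9)
  expect_equal(percent_change(3.2e6, 7.6e6), 138)  # 137.5 rounds half-up
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 10), "positive")
})

test_that("percent change is scale invariant and rounding is half-up", {
  set.seed(5)
  for (k in 1:20) {
    b <- runif(1, 1, 10); p <- runif(1, 1, 10); s <- runif(1, 0.1, 1000)
    expect_identical(percent_change(b, p), percent_change(s * b, s * p))
  }
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(1.24, 1), 1.2)
})

test_that("care ratios follow the stated arithmetic", {
  expect_equal(care_ratio(5.0e6, 0.36, 1.6e6), 1.125)
  expect_equal(care_ratio(14.0e6, 0.36, 1.6e6), 3.15)
  expect_equal(care_ratio(2.2e6, 1.0, 2.2e6), 1.0)
  expect_error(care_ratio(5e6, 0.36, 0), "positive")
  expect_error(care_ratio(5e6, 1.36, 1e6), "\\[0, 1\\]")
})

make_fake_results <- function(totals_list) {
  res <- lapply(seq_along(totals_list), function(k)
    structure(list(spec = scenario_spec(k, 1, 3.2, 0),
                   totals = totals_list[[k]]),
              class = "scenario_result"))
  names(res) <- as.character(seq_along(totals_list))
  structure(res, class = "scenario_results")
}

test_that("the summary table applies the reporting rules", {
  tt <- data.frame(year = c(2021, 2050), male = c(1.0e6, 2.0e6),
                   female = c(2.0e6, 4.0e6))
  tt$total <- tt$male + tt$female
  rep <- make_report(make_fake_results(list(tt)))
  # a doubled final year reports +100%
  expect_equal(rep$total_pct, 100)
  expect_equal(rep$men_2050, 2.0)
  expect_equal(rep$total_2050, 6.0)
  expect_equal(rep$total_2021, 3.0)
})

test_that("summary rows are additive and share the baseline across scenarios", {
  fx <- gen_full_fixture(small_cfg())
  res <- run_scenarios(fx, default_scenarios()[c("1", "2", "5")])
  rep <- make_report(res, with_care_ratio = TRUE)
  base_year <- paste0("total_", fx$grid$t_min)
  expect_equal(length(unique(rep[[base_year]])), 1)
  # total = men + women before rounding, so rounded discrepancy <= 0.1
  final <- paste0("_", fx$grid$t_max)
  expect_true(all(abs(rep[[paste0("total", final)]] -
                        rep[[paste0("men", final)]] -
                        rep[[paste0("women", final)]]) <= 0.1 + 1e-9))
  # care ratio column recomputes from the final-year total
  r1 <- res[["1"]]$totals
  expect_equal(rep[[paste0("care_ratio", final)]][1],
               round_half_up(care_ratio(r1$total[nrow(r1)]), 2))
})
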