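# Scaling, rate arithmetic, cross-country rollups and sensitivity scenarios.

test_that("scaling to the national population is linear and consistent", {
  expect_equal(scale_to_national(10, 100, 1000), 100)
  expect_equal(scale_to_national(0, 50, 123456), 0)
  expect_error(scale_to_national(10, 0, 1000), "virtual_size")
  # scaling then per-100k equals per-100k on the virtual cohort directly
  count <- 137; vsize <- 20000; pop <- 5.4e6
  expect_equal(per_100k(scale_to_national(count, vsize, pop), pop),
               per_100k(count, vsize))
})

test_that("per-100k and percent-change arithmetic match their definitions", {
  expect_equal(per_100k(2963, 1e5), 2963)
  expect_equal(per_100k(1, 2e5), 0.5)
  expect_equal(per_100k(0, 7), 0)
  expect_error(per_100k(1, 0), "denominator")
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 50), -50)
  expect_equal(round(percent_change(2963, 3193), 1), 7.8)
  expect_error(percent_change(0, 10), "baseline")
})

test_that("cumulative incidence sums the six annual values", {
  expect_equal(cumulative_incidence(rep(1, 6)), 6)
  expect_equal(cumulative_incidence(rep(0, 6)), 0)
  x <- c(3, 1, 4, 1, 5, 9)
  expect_equal(cumulative_incidence(x), cumulative_incidence(rev(x)))
  expect_error(cumulative_incidence(1:5), "annual values")
  expect_error(cumulative_incidence(c(1, 1, 1, 1, 1, -1)), ">= 0")
})

test_that("weighted means interpolate their inputs", {
  expect_equal(weighted_mean_rate(c(10, 20), c(1, 1)), 15)
  expect_equal(weighted_mean_rate(c(10, 20), c(1, 3)), 17.5)
  expect_error(weighted_mean_rate(c(1, 2), c(0, 0)), "weights")
  expect_error(weighted_mean_rate(1:3, 1:2), "equal length")
  set.seed(5)
  for (k in 1:10) {
    v <- runif(8, 0, 100); w <- runif(8)
    wm <- weighted_mean_rate(v, w)
    expect_gte(wm, min(v)); expect_lte(wm, max(v))
  }
})

test_that("the rollup is additive and homogeneous in population", {
  tabs <- load_reference_tables()
  total <- rollup_total_cases(tabs, 2027)
  percountry <- sapply(tabs$demographics$country, function(ct) {
    prev <- tabs$prevalence
    sub <- prev[prev$country == ct & prev$year == 2027, ]
    pop <- tabs$demographics$population_2027[tabs$demographics$country == ct]
    sum(sub$total) / 1e5 * pop
  })
  expect_equal(sum(percountry), total)
  tabs2 <- tabs
  tabs2$demographics$population_2027 <- 2 * tabs2$demographics$population_2027
  expect_equal(rollup_total_cases(tabs2, 2027), 2 * total)
  # a missing country is an error
  tabs3 <- tabs
  tabs3$prevalence <- tabs3$prevalence[tabs3$prevalence$country != "Japan", ]
  expect_error(rollup_total_cases(tabs3, 2027), "Japan")
})

test_that("undiagnosed share handles a fully diagnosed dataset", {
  tabs <- load_reference_tables()
  tabs$prevalence$total[tabs$prevalence$status == "undiagnosed"] <- 0
  us <- undiagnosed_share(tabs, 2027)
  expect_equal(us$weighted_share, 0)
  expect_equal(us$min, 0)
  expect_equal(us$max, 0)
})

test_that("projection prevalences per 100k are non-negative and coherent", {
  proj <- run_projection(generate_bundle("small_aged"), 5000, seed = 55)
  tab <- projection_prevalence_per_100k(proj)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$total_per_100k >= 0))
  expect_equal(tab$diagnosed_per_100k + tab$undiagnosed_per_100k,
               tab$total_per_100k)
})

test_that("zero diagnosis rates make sensitivity scenarios identical", {
  b <- generate_bundle("degenerate")
  out <- run_diagnosis_sensitivity(b, 500, seed = 21)
  expect_identical(out$base$annual, out$increased$annual)
  expect_identical(out$base$annual, out$decreased$annual)
  expect_length(out$capped_stages, 0)
})

test_that("diagnosed prevalence is monotone in the rate multiplier (CRN)", {
  b <- generate_bundle("small_aged")
  out <- run_diagnosis_sensitivity(b, 1e4, seed = 33)
  base <- out$base$annual$n_diagnosed
  up <- out$increased$annual$n_diagnosed
  down <- out$decreased$annual$n_diagnosed
  expect_true(all(up >= base))
  expect_true(all(base >= down))
  # everything except diagnosis is unaffected by the scenario
  expect_equal(out$base$annual$alive_end, out$increased$annual$alive_end)
  expect_equal(out$base$annual$n_ckd, out$decreased$annual$n_ckd)
})

test_that("rates pushed past 1 by the +10% scenario are capped and logged", {
  b <- fixture_bundle(diagnosis = c(G1 = 0.1, G2 = 0.1, G3a = 0.3,
                                    G3b = 0.5, G4 = 0.7, G5 = 0.95))
  out <- run_diagnosis_sensitivity(b, 2000, seed = 41)
  expect_true("G5" %in% out$capped_stages)
  expect_false("G4" %in% out$capped_stages)
})
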