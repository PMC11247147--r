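# Annual-cycle engine: null dynamics, event sampling, absorbing states,
# conservation and determinism.

test_that("null dynamics change nothing but age", {
  b <- generate_bundle("degenerate")
  co <- synthesize_cohort(b, 500, seed = 2)
  step <- advance_year(co, b, 2022, seed = 77)
  expect_equal(step$cohort$age, co$age + 1L)
  same_cols <- setdiff(names(co), "age")
  expect_identical(step$cohort[same_cols], co[same_cols])
  expect_equal(step$outputs$deaths, 0)
  expect_equal(step$outputs$inc_onset, 0)

  proj <- run_projection(b, 500, seed = 2)
  expect_equal(nrow(proj$annual), 6)
  expect_true(all(proj$annual$n_ckd == 0))
  expect_true(all(proj$annual$alive_end == 500))
})

test_that("certain death empties the cohort in one year, tallied once", {
  sc <- generate_ground_truth_scenario("constant_hazard")
  b <- sc$bundle
  b$mortality_base$p <- 1
  co <- synthesize_cohort(b, 50, seed = 8)
  step <- advance_year(co, b, 2022, seed = 9)
  expect_equal(step$outputs$deaths, 50)
  expect_true(all(!step$cohort$alive))
  expect_true(all(step$cohort$death_year == 2022))
  # a dead cohort cannot be advanced further
  expect_error(advance_year(step$cohort, b, 2023, seed = 10), "no living")
})

test_that("projections are deterministic given the master seed", {
  b <- generate_bundle("small_aged")
  p1 <- run_projection(b, 5000, seed = 123)
  p2 <- run_projection(b, 5000, seed = 123)
  expect_identical(p1$annual, p2$annual)
  expect_identical(p1$cohort, p2$cohort)
  p3 <- run_projection(b, 5000, seed = 124)
  expect_false(identical(p1$annual, p3$annual))
})

test_that("advance_year rejects years outside the horizon", {
  b <- generate_bundle("degenerate")
  co <- synthesize_cohort(b, 10, seed = 1)
  expect_error(advance_year(co, b, 2030, seed = 1), "horizon")
  expect_error(run_projection(b, 10, seed = 1, years = 2021:2023), "horizon")
})

test_that("sample_event respects probabilities, caps, and relative risks", {
  expect_true(all(!sample_event(rep(0, 1000), 1)))
  expect_true(all(sample_event(rep(0.4, 1000), 5)))     # capped at 1
  expect_error(sample_event(1.2, 1), "p_base")
  expect_error(sample_event(0.5, -1), "rr")

  # empirical ratio of event rates at rr = 2 vs rr = 1 (binomial oracle)
  n <- 1e5
  set.seed(42)
  e2 <- sample_event(rep(0.01, n), 2)
  set.seed(42)
  e1 <- sample_event(rep(0.01, n), 1)
  ratio <- mean(e2) / mean(e1)
  se_log <- sqrt(1 / sum(e1) + 1 / sum(e2))
  expect_lt(abs(log(ratio / 2)), 3 * se_log)
})

test_that("diagnosis is stage-driven and absorbing", {
  rates <- c(G1 = 0, G2 = 0, G3a = 1, G3b = 1, G4 = 0, G5 = 0)
  u <- rep(0.5, 4)
  d <- update_diagnosis(c(FALSE, FALSE, TRUE, FALSE),
                        c("G3a", "G1", "G4", "G2"), rates, u)
  expect_equal(d, c(TRUE, FALSE, TRUE, FALSE)) # rate 1 diagnoses; rate 0
  expect_error(update_diagnosis(FALSE, "none", rates, 0.5), "non-CKD")
  # multiplier caps at 1
  d2 <- update_diagnosis(FALSE, "G3a", c(G3a = 0.95), u = 0.99,
                         multiplier = 1.1)
  expect_true(d2)
})

test_that("KRT initiates below the threshold and never reverts", {
  params <- default_krt_parameters()
  params$modality_shares <- c(HD = 1, PD = 0, Tx = 0)
  k <- krt_update("none", 8, params, u_init = 0.99, u_modal = 0.5,
                  u_trans = 0.5)
  expect_equal(k, "HD")
  expect_equal(krt_update("none", 20, params, 0.01, 0.5, 0.5), "none")
  params$access_probability <- 0
  expect_equal(krt_update("none", 8, params, 0.001, 0.5, 0.5), "none")

  # access fraction recovered (binomial oracle)
  params$access_probability <- 0.5
  n <- 1e4
  set.seed(7)
  k <- krt_update(rep("none", n), rep(5, n), params, runif(n), runif(n),
                  runif(n))
  frac <- mean(k != "none")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))

  # modality transitions move dialysis patients to transplant
  params$modality_transition <- matrix(
    c(0, 0, 1, 0, 0, 1, 0, 0, 1), nrow = 3, byrow = TRUE,
    dimnames = list(c("HD", "PD", "Tx"), c("HD", "PD", "Tx"))
  )
  expect_equal(krt_update("HD", 50, params, 0.99, 0.5, 0.5), "Tx")
  expect_error(
    krt_update("none", 8,
               utils::modifyList(params,
                                 list(modality_shares = c(HD = 0.5, PD = 0.1,
                                                          Tx = 0.1))),
               0.5, 0.5, 0.5),
    "malformed"
  )
})

test_that("persons are conserved and states are absorbing across a run", {
  b <- generate_bundle("small_aged")
  proj <- run_projection(b, 2e4, seed = 31)
  a <- proj$annual
  # closed cohort: alive at start = alive at end + deaths, chained over years
  expect_equal(a$alive_end + a$deaths, a$alive_start)
  expect_equal(a$alive_start[-1], a$alive_end[-6])
  expect_equal(a$alive_start[1], 2e4)
  # death is absorbing and consistent
  co <- proj$cohort
  expect_true(all(is.na(co$death_year) == co$alive))
  expect_true(all(co$death_year[!co$alive] %in% 2022:2027))
  # diagnosed individuals all have CKD; KRT only within CKD
  expect_true(all(co$is_ckd[co$diagnosed]))
  expect_true(all(co$is_ckd[co$krt != "none"]))
  # stage counts sum to the CKD count each year
  stage_cols <- grep("^ckd_G", names(a), value = TRUE)
  expect_equal(rowSums(a[stage_cols]), a$n_ckd, ignore_attr = TRUE)
  expect_equal(a$n_diagnosed + a$n_undiagnosed, a$n_ckd)
})

test_that("diagnosis counts never decrease when nobody dies", {
  b <- fixture_bundle(mortality_base = data.frame(
    age_band = rep(c("0-17", "18-34", "35-64", "65+"), each = 2),
    sex = rep(c("F", "M"), 4), p = 0, stringsAsFactors = FALSE
  ))
  proj <- run_projection(b, 5000, seed = 13)
  expect_true(all(diff(proj$annual$n_diagnosed) >= 0))
})

test_that("a cohort on zero slopes keeps its stage counts fixed", {
  b <- fixture_bundle()
  zero <- stats::setNames(rep(0, 8), names(default_slopes()))
  b$slopes <- zero
  b$ckd_incidence$p <- 0
  b$mortality_base$p <- 0
  proj <- run_projection(b, 5000, seed = 17)
  stage_cols <- grep("^ckd_G", names(proj$annual), value = TRUE)
  totals <- rowSums(proj$annual[stage_cols])
  expect_true(all(totals == totals[1]))
})
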