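# Bundle construction, validation, YAML round trips, proxy resolution and
# the transcribed reference tables.

test_that("a valid bundle constructs and save/load is the identity", {
  b <- fixture_bundle()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_country_bundle(b, path)
  b2 <- load_country_bundle(path)
  expect_equal(length(b2$population_by_year), 6)
  for (field in setdiff(names(b), "meta")) {
    expect_equal(b2[[field]], b[[field]], info = field,
                 tolerance = 1e-12, ignore_attr = FALSE)
  }
  # and a second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".yaml")
  save_country_bundle(b2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("validation errors name the offending field", {
  b <- fixture_bundle()
  b$stage_distribution$prob[1] <- b$stage_distribution$prob[1] - 0.02
  expect_error(validate_country_bundle(b), "stage_distribution")

  b <- fixture_bundle()
  b$population_by_year <- b$population_by_year[-6]
  expect_error(validate_country_bundle(b), "population_by_year.*2027")

  b <- fixture_bundle()
  b$population_by_year[2] <- -5
  expect_error(validate_country_bundle(b), "strictly positive")

  b <- fixture_bundle()
  b$diagnosis_rate_by_stage["G4"] <- 1.7
  expect_error(validate_country_bundle(b), "diagnosis_rate_by_stage")

  b <- fixture_bundle()
  b$krt$modality_shares <- c(HD = 0.9, PD = 0.2, Tx = 0.1)
  expect_error(validate_country_bundle(b), "modality_shares")

  expect_error(
    fixture_bundle(stage_distribution = data.frame(
      age_band = "18-34", sex = "F", G = "G1", A = "A1", prob = 1
    )),
    "not a CKD cell"
  )
})

test_that("a no-CKD cell must be ('none', 'none') jointly", {
  b <- fixture_bundle()
  b$stage_distribution$A[b$stage_distribution$G == "none"][1] <- "A1"
  expect_error(validate_country_bundle(b), "both 'none'")
})

test_that("proxy resolution follows priority order and records provenance", {
  target <- fixture_bundle()
  target$diagnosis_rate_by_stage <- NULL
  donor_x <- fixture_bundle(country_code = "XXX",
                            diagnosis = c(G1 = 0.2, G2 = 0.2, G3a = 0.2,
                                          G3b = 0.2, G4 = 0.2, G5 = 0.2))
  donor_y <- fixture_bundle(country_code = "YYY",
                            diagnosis = c(G1 = 0.4, G2 = 0.4, G3a = 0.4,
                                          G3b = 0.4, G4 = 0.4, G5 = 0.4))
  res <- resolve_proxy(target, "diagnosis_rate_by_stage",
                       list(donor_x, donor_y), c("XXX", "YYY"))
  expect_equal(unname(res$diagnosis_rate_by_stage["G1"]), 0.2)
  expect_equal(res$meta$proxy$diagnosis_rate_by_stage, "XXX")

  # fallback to the second donor when the first lacks the field
  donor_x2 <- donor_x
  donor_x2$diagnosis_rate_by_stage <- NULL
  res2 <- resolve_proxy(target, "diagnosis_rate_by_stage",
                        list(donor_x2, donor_y), c("XXX", "YYY"))
  expect_equal(unname(res2$diagnosis_rate_by_stage["G1"]), 0.4)
  expect_equal(res2$meta$proxy$diagnosis_rate_by_stage, "YYY")

  # no donor has it -> error listing tried donors
  donor_y2 <- donor_y
  donor_y2$diagnosis_rate_by_stage <- NULL
  expect_error(
    resolve_proxy(target, "diagnosis_rate_by_stage",
                  list(donor_x2, donor_y2), c("XXX", "YYY")),
    "XXX, YYY"
  )

  # present fields are never overwritten
  expect_error(
    resolve_proxy(fixture_bundle(), "diagnosis_rate_by_stage",
                  list(donor_x), "XXX"),
    "refusing to overwrite"
  )
})

test_that("reference tables load with 31 countries and printed cell values", {
  tabs <- load_reference_tables()
  expect_equal(nrow(tabs$demographics), 31)
  expect_equal(nrow(tabs$cv), 31)
  expect_equal(nrow(tabs$prevalence), 31 * 2 * 2)
  expect_true(all(!is.na(tabs$demographics$population_2027)))

  demo <- tabs$demographics
  expect_equal(demo$population_2027[demo$country == "USA"], 344100699)
  expect_equal(demo$population_2022[demo$country == "Brazil"], 215353588)
  expect_equal(demo$pct_age_65_plus[demo$country == "Japan"], 28.9)
  expect_equal(demo$pct_male[demo$country == "UAE Emirati"], 76.7)
  expect_equal(demo$pct_female[demo$country == "Sweden"], 49.9)

  prev <- tabs$prevalence
  cell <- function(ctry, status, yr) {
    prev$total[prev$country == ctry & prev$status == status &
                 prev$year == yr]
  }
  expect_equal(cell("USA", "diagnosed", 2027), 3394)
  expect_equal(cell("Brazil", "diagnosed", 2022), 2963)
  expect_equal(cell("Brazil", "diagnosed", 2027), 3193)
  expect_equal(cell("China", "undiagnosed", 2027), 7516)
  expect_equal(cell("Japan", "undiagnosed", 2022), 12860)
  expect_equal(prev$g3a[prev$country == "Japan" & prev$status == "diagnosed" &
                          prev$year == 2027], 3179)

  cv <- tabs$cv
  expect_equal(cv$heart_failure[cv$country == "Brazil"], 7595)
  expect_equal(cv$myocardial_infarction[cv$country == "USA"], 6505)
  expect_equal(cv$stroke[cv$country == "Poland"], 44838)
  expect_equal(cv$total[cv$country == "Israel"], 8559)
  expect_equal(cv$heart_failure[cv$country == "Hungary"], 25826)

  base <- tabs$ckd_baseline
  expect_equal(base$pct_ckd_all_stages[base$country == "Brazil"], 9.73)
  expect_equal(base$pct_t2d_in_ckd[base$country == "Mexico"], 43.1)
  expect_equal(base$pct_ckd_all_stages[base$country == "Japan"], 18.79)
  expect_equal(base$pct_stage_g1[base$country == "Germany"], 8.33)
  expect_equal(base$pct_htn_in_ckd[base$country == "Mexico"], 79.8)
})

test_that("reference-table loading rejects row-count mismatches", {
  tmp <- withr::local_tempdir()
  src <- system.file("extdata/reference_tables", package = "ckdsim")
  for (f in list.files(src)) file.copy(file.path(src, f), tmp)
  demo <- utils::read.csv(file.path(tmp, "demographics.csv"),
                          comment.char = "#")
  utils::write.csv(demo[-1, ], file.path(tmp, "demographics.csv"),
                   row.names = FALSE)
  expect_error(load_reference_tables(tmp), "expected 31 rows")
})
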