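# Scale cohort outputs to national populations and compute reported
# statistics: per-100k prevalence, cumulative incidence, percent change,
# population-weighted means, cross-country rollups and diagnosis-rate
# sensitivity scenarios.

#' Scale a virtual-cohort count to the national population
#'
#' @param count_virtual Count observed in the virtual cohort.
#' @param virtual_size Size of the virtual cohort (> 0).
#' @param national_pop National population the cohort represents.
#' @return `count_virtual * national_pop / virtual_size`.
#' @export
scale_to_national <- function(count_virtual, virtual_size, national_pop) {
  if (any(virtual_size <= 0)) stop("virtual_size must be > 0")
  count_virtual * national_pop / virtual_size
}

#' Rate per 100,000
#'
#' @param count Numerator count.
#' @param denominator Population denominator (> 0).
#' @return `count / denominator * 1e5`.
#' @export
per_100k <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  count / denominator * 1e5
}

#' Percent change between the 2022 and 2027 values
#'
#' @param v2022 Baseline value (> 0).
#' @param v2027 End-of-horizon value.
#' @return `(v2027 - v2022) / v2022 * 100` (unrounded; display convention is
#'   one decimal).
#' @export
percent_change <- function(v2022, v2027) {
  if (any(v2022 <= 0)) stop("baseline value must be > 0")
  (v2027 - v2022) / v2022 * 100
}

#' Cumulative incidence over the projection horizon
#'
#' The sum of annual incident counts from baseline (2022) up to and including
#' 2027.
#'
#' @param annual_incident_counts Six non-negative yearly values.
#' @return Their sum.
#' @export
cumulative_incidence <- function(annual_incident_counts) {
  if (length(annual_incident_counts) != length(BUNDLE_YEARS)) {
    stop("expected ", length(BUNDLE_YEARS), " annual values (2022-2027)")
  }
  if (any(annual_incident_counts < 0)) stop("incident counts must be >= 0")
  sum(annual_incident_counts)
}

#' Population-weighted mean
#'
#' @param values Per-country rates.
#' @param weights Per-country population (e.g. CKD population) weights,
#'   non-negative and not all zero.
#' @return `sum(values * weights) / sum(weights)`.
#' @export
weighted_mean_rate <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights must have equal length")
  }
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  sum(values * weights) / sum(weights)
}

# national CKD cases (diagnosed + undiagnosed) per country for one year,
# from the reference tables
national_ckd_cases <- function(tables, year, status = c("diagnosed",
                                                        "undiagnosed")) {
  prev <- tables$prevalence
  demo <- tables$demographics
  sub <- prev[prev$year == year & prev$status %in% status, ]
  tot <- tapply(sub$total, sub$country, sum)
  pop <- stats::setNames(demo[[paste0("population_", year)]], demo$country)
  if (length(setdiff(demo$country, names(tot)))) {
    stop("prevalence table missing countries: ",
         paste(setdiff(demo$country, names(tot)), collapse = ", "))
  }
  tot <- tot[demo$country]
  pop <- pop[demo$country]
  tot / 1e5 * pop
}

#' Total national CKD cases across all countries
#'
#' Sums, over the 31 countries/regions of the reference tables, the
#' (diagnosed + undiagnosed) prevalence per 100,000 scaled by each national
#' population for the given year.
#'
#' @param tables Reference tables from [load_reference_tables()].
#' @param year 2022 or 2027.
#' @return Total persons with CKD.
#' @export
rollup_total_cases <- function(tables, year) {
  sum(national_ckd_cases(tables, year))
}

#' Population-weighted undiagnosed share and per-country range
#'
#' @param tables Reference tables from [load_reference_tables()].
#' @param year 2022 or 2027.
#' @return list(weighted_share, per_country = data.frame(country, share),
#'   min, min_country, max, max_country); shares are fractions in \[0, 1\].
#' @export
undiagnosed_share <- function(tables, year) {
  undiag <- national_ckd_cases(tables, year, "undiagnosed")
  all_cases <- national_ckd_cases(tables, year)
  prev <- tables$prevalence
  sub <- prev[prev$year == year, ]
  tot <- tapply(sub$total, list(sub$country, sub$status), sum)
  share <- tot[, "undiagnosed"] / (tot[, "diagnosed"] + tot[, "undiagnosed"])
  list(
    weighted_share = sum(undiag) / sum(all_cases),
    per_country = data.frame(country = rownames(tot), share = unname(share),
                             stringsAsFactors = FALSE),
    min = unname(min(share)), min_country = names(which.min(share)),
    max = unname(max(share)), max_country = names(which.max(share))
  )
}

#' CKD-population-weighted means of cardiovascular complication prevalence
#'
#' Weights each country's 2027 prevalence of heart failure, myocardial
#' infarction and stroke (per 100,000 CKD patients) by its 2027 national CKD
#' population (diagnosed + undiagnosed).
#'
#' @param tables Reference tables from [load_reference_tables()].
#' @return Named numeric: heart_failure, myocardial_infarction, stroke.
#' @export
cv_weighted_means <- function(tables) {
  w <- national_ckd_cases(tables, 2027)
  cv <- tables$cv
  w <- w[cv$country]
  vapply(c("heart_failure", "myocardial_infarction", "stroke"),
         function(col) weighted_mean_rate(cv[[col]], w), numeric(1))
}

#' Per-100,000 prevalence table of a projection
#'
#' Converts the engine's end-of-year counts into prevalence per 100,000 of
#' the (virtual) national population, by diagnosis status; identical, by
#' construction, to scaling counts to the national population first.
#'
#' @param projection A `ckd_projection`.
#' @return data.frame(year, diagnosed_per_100k, undiagnosed_per_100k,
#'   total_per_100k, krt_per_100k).
#' @export
projection_prevalence_per_100k <- function(projection) {
  a <- projection$annual
  n <- projection$n
  data.frame(
    year = a$year,
    diagnosed_per_100k = per_100k(a$n_diagnosed, n),
    undiagnosed_per_100k = per_100k(a$n_undiagnosed, n),
    total_per_100k = per_100k(a$n_ckd, n),
    krt_per_100k = per_100k(a$krt_HD + a$krt_PD + a$krt_Tx, n),
    stringsAsFactors = FALSE
  )
}

#' Diagnosis-rate sensitivity scenarios under common random numbers
#'
#' Runs the projection three times with identical seeds: at the bundle's
#' diagnosis rates, and with every stage's rate scaled by (1 + delta) and
#' (1 - delta), capped at 1 (caps are recorded). With common random numbers
#' the diagnosed prevalence is non-decreasing in the rate multiplier at every
#' year.
#'
#' @param bundle A validated `country_bundle`.
#' @param n Virtual cohort size.
#' @param seed Master seed shared by the three scenarios.
#' @param delta Relative perturbation (default 0.10).
#' @return list(base, increased, decreased) of `ckd_projection`s, plus
#'   `capped_stages` listing stages whose increased rate hit the cap.
#' @export
run_diagnosis_sensitivity <- function(bundle, n, seed, delta = 0.10) {
  scenarios <- list(base = 1, increased = 1 + delta, decreased = 1 - delta)
  out <- lapply(scenarios, function(m) {
    run_projection(bundle, n, seed, multipliers = list(diagnosis = m))
  })
  out$capped_stages <- out$increased$diagnosis_rate_capped
  out
}
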