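# Shared fixture builders: small, fully explicit bundles built in code.

# a minimal valid bundle with uniform adult CKD prevalence `prev` and
# adjustable pieces; adults only unless kids = TRUE
fixture_bundle <- function(prev = 0.1,
                           diagnosis = c(G1 = 0.1, G2 = 0.1, G3a = 0.3,
                                         G3b = 0.5, G4 = 0.7, G5 = 0.9),
                           comorb_ckd = c(t2d_only = 0.1, htn_only = 0.4,
                                          both = 0.15),
                           kids = FALSE,
                           ...) {
  props <- if (kids) c(0.2, 0.3, 0.3, 0.2) else c(0, 0.4, 0.4, 0.2)
  pyramid <- data.frame(
    sex = rep(c("F", "M"), each = 4),
    age_band = rep(c("0-17", "18-34", "35-64", "65+"), 2),
    prop = rep(props * 0.5, 2),
    stringsAsFactors = FALSE
  )
  prev_by_band <- list("0-17" = 0, "18-34" = prev, "35-64" = prev,
                       "65+" = prev)
  cells <- data.frame(
    G = c("G1", "G2", "G3a", "G3b", "G4", "G5"),
    A = c("A2", "A2", "A1", "A1", "A2", "A3"),
    w = c(0.3, 0.25, 0.25, 0.12, 0.06, 0.02),
    stringsAsFactors = FALSE
  )
  sd <- do.call(rbind, lapply(c("0-17", "18-34", "35-64", "65+"), function(b) {
    do.call(rbind, lapply(c("F", "M"), function(s) {
      p <- prev_by_band[[b]]
      data.frame(age_band = b, sex = s,
                 G = c("none", cells$G), A = c("none", cells$A),
                 prob = c(1 - p, p * cells$w),
                 stringsAsFactors = FALSE)
    }))
  }))
  flat <- function(vals) {
    df <- data.frame(age_band = rep(c("0-17", "18-34", "35-64", "65+"),
                                    each = 2),
                     sex = rep(c("F", "M"), 4), stringsAsFactors = FALSE)
    for (nm in names(vals)) df[[nm]] <- vals[[nm]]
    df
  }
  args <- utils::modifyList(list(
    country_code = "FIX",
    population_by_year = stats::setNames(seq(1e6, 1.05e6, by = 1e4),
                                         2022:2027),
    pyramid = pyramid,
    stage_distribution = sd,
    diagnosis_rate_by_stage = diagnosis,
    ckd_incidence = flat(list(p = 0.003)),
    comorbidity_prevalence = list(
      ckd = comorb_ckd,
      non_ckd = c(t2d_only = 0.05, htn_only = 0.2, both = 0.03)
    ),
    cv_base_rates = flat(list(heart_failure = 0.002, mi = 0.002,
                              stroke = 0.0015)),
    mortality_base = flat(list(p = 0.005))
  ), list(...))
  do.call(new_country_bundle, args)
}

# hand-built two-person cohort for summary edge cases
tiny_cohort <- function() {
  structure(data.frame(
    id = 1:2, age = c(40L, 70L), sex = c("F", "M"), alive = TRUE,
    egfr = c(100, 50), acr = c(10, 40), G = c("none", "G3a"),
    A = c("none", "A2"), is_ckd = c(FALSE, TRUE),
    diagnosed = c(FALSE, TRUE), t2d = c(FALSE, TRUE),
    htn = c(FALSE, TRUE), cv_hf = FALSE, cv_mi = FALSE, cv_stroke = FALSE,
    krt = "none", krt_start = NA_integer_, death_year = NA_integer_,
    stringsAsFactors = FALSE
  ), virtual_size = 2L, country_code = "FIX", base_year = 2022L,
  class = c("ckd_cohort", "data.frame"))
}
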