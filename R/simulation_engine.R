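# Annual Monte Carlo engine: advance the cohort through one-year cycles,
# generating eGFR progression, incident CKD, diagnosis, cardiovascular
# events, KRT transitions and deaths.
#
# Sub-step order within a year (fixed and documented):
#   age+1 -> eGFR slope & albuminuria update -> incident CKD onset ->
#   comorbidity incidence -> diagnosis update -> CV events -> KRT update ->
#   mortality.
# Each sub-step consumes one fixed-length uniform vector (one draw per
# individual, in id order) from a per-year seeded stream, so results are
# deterministic, independent of row order, and aligned across scenarios for
# common-random-numbers comparisons.

A_MIDPOINTS <- c(A1 = 15, A2 = 165, A3 = 1650)

year_seed <- function(seed, year) {
  as.integer((as.numeric(seed) * 131 + (year - 2000) * 1000003) %% 2147483629)
}

lookup_by_band_sex <- function(df, value_col, band, sex) {
  key <- stats::setNames(df[[value_col]], paste(df$age_band, df$sex))
  unname(key[paste(band, sex)])
}

#' Draw a Bernoulli event from a base probability and a relative risk
#'
#' The event probability is `min(1, p_base * rr)`.
#'
#' @param p_base Annual base probability in \[0, 1\].
#' @param rr Relative-risk multiplier (>= 0).
#' @param u Optional uniform draws (for common random numbers); drawn from
#'   the current RNG stream if omitted.
#' @return Logical vector of events.
#' @export
sample_event <- function(p_base, rr, u = NULL) {
  if (any(p_base < 0) || any(p_base > 1) || any(!is.finite(p_base))) {
    stop("p_base must lie in [0, 1]")
  }
  if (any(rr < 0)) stop("rr must be >= 0")
  n <- max(length(p_base), length(rr))
  if (is.null(u)) u <- stats::runif(n)
  u < pmin(1, p_base * rr)
}

#' Annual diagnosis update for undiagnosed CKD cases
#'
#' An undiagnosed prevalent case becomes diagnosed with the stage-specific
#' annual probability (times an optional multiplier, capped at 1); diagnosis
#' is absorbing. Calling this on a non-CKD individual is an error.
#'
#' @param diagnosed Logical vector of current diagnosis status.
#' @param G G stages of the individuals (must be CKD stages, not "none").
#' @param rates Named annual diagnosis probabilities per G stage.
#' @param u Uniform draws, one per individual.
#' @param multiplier Scalar multiplier on every stage's rate (sensitivity
#'   scenarios); resulting rates are capped at 1.
#' @return Updated logical vector.
#' @export
update_diagnosis <- function(diagnosed, G, rates, u, multiplier = 1) {
  if (any(G == "none")) stop("update_diagnosis called on non-CKD individual")
  p <- pmin(1, unname(rates[G]) * multiplier)
  diagnosed | (u < p)
}

#' Annual KRT update
#'
#' Individuals with eGFR below the initiation threshold and no current KRT
#' initiate with the access probability, drawing a modality from the modality
#' shares; individuals already on KRT move between modalities per the annual
#' transition matrix. KRT is never abandoned ("none" never recurs).
#'
#' @param krt Character vector over "none", "HD", "PD", "Tx".
#' @param egfr Current eGFR values.
#' @param params KRT parameter block (see [default_krt_parameters()]).
#' @param u_init,u_modal,u_trans Uniform draws, one per individual each.
#' @param access_multiplier Scalar multiplier on the access probability
#'   (calibration knob), capped at 1.
#' @return Updated modality vector.
#' @export
krt_update <- function(krt, egfr, params, u_init, u_modal, u_trans,
                       access_multiplier = 1) {
  shares <- params$modality_shares[KRT_MODALITIES]
  if (anyNA(shares) || abs(sum(shares) - 1) > 1e-9) {
    stop("malformed modality shares")
  }
  eligible <- krt == "none" & egfr < params$egfr_initiation_threshold
  p_access <- min(1, params$access_probability * access_multiplier)
  initiate <- eligible & u_init < p_access
  if (any(initiate)) {
    idx <- findInterval(u_modal[initiate], c(0, cumsum(shares)[-3]))
    krt[initiate] <- KRT_MODALITIES[idx]
  }
  on_krt <- krt != "none" & !initiate
  if (any(on_krt)) {
    tm <- params$modality_transition[KRT_MODALITIES, KRT_MODALITIES]
    cum <- t(apply(tm, 1, cumsum))
    row <- match(krt[on_krt], KRT_MODALITIES)
    idx <- 1 + (u_trans[on_krt] >= cum[cbind(row, 1)]) +
      (u_trans[on_krt] >= cum[cbind(row, 2)])
    krt[on_krt] <- KRT_MODALITIES[idx]
  }
  krt
}

default_multipliers <- function() {
  list(diagnosis = 1, krt_access = 1, ckd_incidence = 1)
}

#' Advance the cohort through one simulated year
#'
#' Applies the fixed sub-step sequence to every living individual and tallies
#' the year's transitions. Dead individuals are never updated again.
#'
#' @param cohort A `ckd_cohort`.
#' @param bundle The country's `country_bundle`.
#' @param year Calendar year, within 2022-2027.
#' @param seed Integer seed for this year's draws (derive from a master seed
#'   via the projection driver for reproducible multi-year runs).
#' @param multipliers list(diagnosis=, krt_access=, ckd_incidence=) scenario
#'   and calibration multipliers.
#' @return list(cohort = updated cohort, outputs = one-row data.frame of
#'   annual tallies). The outputs carry an attribute `diagnosis_rate_capped`
#'   flagging stages whose multiplied rate was capped at 1.
#' @export
advance_year <- function(cohort, bundle, year, seed,
                         multipliers = default_multipliers()) {
  if (!year %in% BUNDLE_YEARS) {
    stop("year ", year, " outside the 2022-2027 horizon")
  }
  year <- as.integer(year)
  if (!any(cohort$alive)) stop("no living individuals in cohort")
  mult <- utils::modifyList(default_multipliers(), multipliers)
  n <- nrow(cohort)
  set.seed(seed)
  # fixed draw order, one vector per sub-step, one uniform per individual
  u_atrans <- stats::runif(n)
  u_onset <- stats::runif(n)
  u_onset_stage <- stats::runif(n)
  u_onset_egfr <- stats::runif(n)
  u_onset_acr <- stats::runif(n)
  u_t2d <- stats::runif(n)
  u_htn <- stats::runif(n)
  u_diag <- stats::runif(n)
  u_cv <- list(heart_failure = stats::runif(n), mi = stats::runif(n),
               stroke = stats::runif(n))
  u_krt_init <- stats::runif(n)
  u_krt_modal <- stats::runif(n)
  u_krt_trans <- stats::runif(n)
  u_death <- stats::runif(n)

  alive <- cohort$alive
  alive_start <- sum(alive)

  # 1. ageing
  cohort$age[alive] <- cohort$age[alive] + 1L
  band <- age_band(cohort$age)
  adult <- cohort$age >= 18

  # 2. eGFR slope progression (CKD, not on KRT) and albuminuria transition
  prog <- alive & cohort$is_ckd & cohort$krt == "none"
  if (any(prog)) {
    cv_hist <- cohort$cv_hf | cohort$cv_mi | cohort$cv_stroke
    st <- subtype_key(cohort$t2d[prog], cohort$htn[prog], cv_hist[prog])
    cohort$egfr[prog] <- apply_slope(cohort$egfr[prog], st, bundle$slopes, 1)
    cohort$G[prog] <- stage_from_measures(cohort$egfr[prog],
                                          cohort$acr[prog])$G
    at <- bundle$a_transition[A_STAGES, A_STAGES]
    cum <- t(apply(at, 1, cumsum))
    row <- match(cohort$A[prog], A_STAGES)
    newA <- A_STAGES[1 + (u_atrans[prog] >= cum[cbind(row, 1)]) +
                       (u_atrans[prog] >= cum[cbind(row, 2)])]
    changed <- which(prog)[newA != cohort$A[prog]]
    cohort$A[prog] <- newA
    # a stage move re-anchors the concrete ACR at the new cell midpoint
    cohort$acr[changed] <- unname(A_MIDPOINTS[cohort$A[changed]])
  }

  # 3. incident CKD onset among CKD-free adults
  can_onset <- alive & !cohort$is_ckd & adult
  inc_onset <- 0L
  if (any(can_onset)) {
    p <- pmin(1, lookup_by_band_sex(bundle$ckd_incidence, "p",
                                    band[can_onset], cohort$sex[can_onset]) *
                mult$ckd_incidence)
    onset <- can_onset
    onset[can_onset] <- u_onset[can_onset] < p
    inc_onset <- sum(onset)
    if (inc_onset) {
      osd <- bundle$onset_stage_distribution
      cum <- cumsum(osd$prob)
      idx <- findInterval(u_onset_stage[onset], c(0, cum[-length(cum)]))
      cohort$G[onset] <- osd$G[idx]
      cohort$A[onset] <- osd$A[idx]
      cohort$egfr[onset] <- draw_in_cell(G_BOUNDS, cohort$G[onset],
                                         u_onset_egfr[onset])
      cohort$acr[onset] <- draw_in_cell(A_BOUNDS, cohort$A[onset],
                                        u_onset_acr[onset])
      cohort$is_ckd[onset] <- TRUE
    }
  }

  # 4. comorbidity incidence (optional; default rates are 0)
  ci <- bundle$comorbidity_incidence
  if (ci[["t2d"]] > 0) {
    cohort$t2d <- cohort$t2d | (alive & adult & u_t2d < ci[["t2d"]])
  }
  if (ci[["htn"]] > 0) {
    cohort$htn <- cohort$htn | (alive & adult & u_htn < ci[["htn"]])
  }

  # 5. diagnosis update (absorbing)
  undiag <- alive & cohort$is_ckd & !cohort$diagnosed
  capped <- names(which(bundle$diagnosis_rate_by_stage * mult$diagnosis > 1))
  new_diag <- 0L
  if (any(undiag)) {
    upd <- update_diagnosis(cohort$diagnosed[undiag], cohort$G[undiag],
                            bundle$diagnosis_rate_by_stage, u_diag[undiag],
                            mult$diagnosis)
    new_diag <- sum(upd) - sum(cohort$diagnosed[undiag])
    cohort$diagnosed[undiag] <- upd
  }

  # 6. cardiovascular events; KDIGO category drives the relative risk
  category <- rep("low", n)
  ckd_alive <- alive & cohort$is_ckd
  if (any(ckd_alive)) {
    category[ckd_alive] <- kdigo_category(cohort$G[ckd_alive],
                                          cohort$A[ckd_alive],
                                          bundle$kdigo_grid)
  }
  inc_events <- list()
  flag_col <- c(heart_failure = "cv_hf", mi = "cv_mi", stroke = "cv_stroke")
  for (oc in CV_OUTCOMES) {
    rr <- risk_rr_lookup(bundle$kdigo_grid, oc)[category]
    p_base <- lookup_by_band_sex(bundle$cv_base_rates, oc, band, cohort$sex)
    ev <- alive & sample_event(p_base, rr, u_cv[[oc]])
    inc_events[[oc]] <- c(
      diagnosed = sum(ev & ckd_alive & cohort$diagnosed),
      undiagnosed = sum(ev & ckd_alive & !cohort$diagnosed),
      non_ckd = sum(ev & !cohort$is_ckd)
    )
    cohort[[flag_col[[oc]]]] <- cohort[[flag_col[[oc]]]] | ev
  }

  # 7. KRT initiation and modality transitions (CKD only)
  krt_before <- cohort$krt
  if (any(ckd_alive)) {
    cohort$krt[ckd_alive] <- krt_update(
      cohort$krt[ckd_alive], cohort$egfr[ckd_alive], bundle$krt,
      u_krt_init[ckd_alive], u_krt_modal[ckd_alive], u_krt_trans[ckd_alive],
      mult$krt_access
    )
    started <- cohort$krt != krt_before & krt_before == "none"
    cohort$krt_start[started] <- year
  }

  # 8. all-cause mortality
  rr_death <- risk_rr_lookup(bundle$kdigo_grid, "death")[category]
  rr_death[cohort$krt == "Tx"] <- rr_death[cohort$krt == "Tx"] *
    bundle$krt$tx_mortality_multiplier
  p_death <- lookup_by_band_sex(bundle$mortality_base, "p", band, cohort$sex)
  died <- alive & sample_event(p_death, rr_death, u_death)
  deaths_by <- c(
    diagnosed = sum(died & cohort$is_ckd & cohort$diagnosed),
    undiagnosed = sum(died & cohort$is_ckd & !cohort$diagnosed),
    non_ckd = sum(died & !cohort$is_ckd)
  )
  cohort$alive[died] <- FALSE
  cohort$death_year[died] <- year

  outputs <- annual_outputs_row(cohort, year, alive_start, inc_onset,
                                new_diag, inc_events, deaths_by)
  attr(outputs, "diagnosis_rate_capped") <- capped
  list(cohort = cohort, outputs = outputs)
}

annual_outputs_row <- function(cohort, year, alive_start, inc_onset,
                               new_diag, inc_events, deaths_by) {
  alive <- cohort$alive
  ckd <- alive & cohort$is_ckd
  row <- data.frame(year = year, alive_start = alive_start,
                    alive_end = sum(alive), deaths = sum(deaths_by),
                    stringsAsFactors = FALSE)
  row$deaths_ckd_diagnosed <- deaths_by[["diagnosed"]]
  row$deaths_ckd_undiagnosed <- deaths_by[["undiagnosed"]]
  row$deaths_non_ckd <- deaths_by[["non_ckd"]]
  row$n_ckd <- sum(ckd)
  row$n_diagnosed <- sum(ckd & cohort$diagnosed)
  row$n_undiagnosed <- sum(ckd & !cohort$diagnosed)
  for (g in G_STAGES) {
    row[[paste0("ckd_", g, "_diagnosed")]] <-
      sum(ckd & cohort$G == g & cohort$diagnosed)
    row[[paste0("ckd_", g, "_undiagnosed")]] <-
      sum(ckd & cohort$G == g & !cohort$diagnosed)
  }
  for (m in KRT_MODALITIES) {
    row[[paste0("krt_", m)]] <- sum(alive & cohort$krt == m)
  }
  for (oc in CV_OUTCOMES) {
    row[[paste0("inc_", oc, "_diagnosed")]] <- inc_events[[oc]][["diagnosed"]]
    row[[paste0("inc_", oc, "_undiagnosed")]] <-
      inc_events[[oc]][["undiagnosed"]]
    row[[paste0("inc_", oc, "_non_ckd")]] <- inc_events[[oc]][["non_ckd"]]
  }
  row$inc_onset <- inc_onset
  row$inc_diagnosis <- new_diag
  row
}

#' Run a full 2022-2027 projection for one country
#'
#' Synthesizes the baseline cohort and advances it through the annual cycles,
#' collecting end-of-year outputs. A closed cohort is used throughout and
#' later rescaled to the national population for reporting.
#'
#' @param bundle A validated `country_bundle`.
#' @param n Virtual cohort size.
#' @param seed Master seed; per-year streams are derived from it.
#' @param years Projection years (default 2022:2027).
#' @param multipliers Scenario/calibration multipliers, see [advance_year()].
#' @return A `ckd_projection`: list(annual = data.frame with one row per
#'   year, cohort = final cohort, n, seed, country_code).
#' @export
run_projection <- function(bundle, n, seed, years = BUNDLE_YEARS,
                           multipliers = default_multipliers()) {
  validate_country_bundle(bundle)
  if (!all(years %in% BUNDLE_YEARS)) stop("years outside the 2022-2027 horizon")
  cohort <- synthesize_cohort(bundle, n, seed)
  rows <- vector("list", length(years))
  capped <- character(0)
  for (i in seq_along(years)) {
    step <- advance_year(cohort, bundle, years[i],
                         seed = year_seed(seed, years[i]),
                         multipliers = multipliers)
    cohort <- step$cohort
    capped <- union(capped, attr(step$outputs, "diagnosis_rate_capped"))
    rows[[i]] <- step$outputs
  }
  annual <- do.call(rbind, rows)
  structure(list(annual = annual, cohort = cohort, n = n, seed = seed,
                 country_code = bundle$country_code,
                 diagnosis_rate_capped = capped),
            class = "ckd_projection")
}

#' @export
print.ckd_projection <- function(x, ...) {
  cat("CKD microsimulation projection:", x$country_code,
      "| n =", format(x$n, big.mark = ","), "| seed =", x$seed, "\n")
  print(x$annual[, c("year", "alive_end", "n_ckd", "n_diagnosed",
                     "krt_HD", "krt_PD", "krt_Tx", "deaths")],
        row.names = FALSE)
  invisible(x)
}
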