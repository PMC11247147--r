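# Baseline virtual cohort synthesis: draw individuals so that the cohort's
# marginal distributions match the country input bundle.

# stage-cell bounds for drawing a concrete eGFR / ACR uniformly within a cell
G_BOUNDS <- list(G1 = c(90, 120), G2 = c(60, 90), G3a = c(45, 60),
                 G3b = c(30, 45), G4 = c(15, 30), G5 = c(1, 15))
A_BOUNDS <- list(A1 = c(0, 30), A2 = c(30, 300), A3 = c(300, 3000))
# no-CKD individuals: normal-to-mild eGFR with A1 albuminuria
HEALTHY_EGFR <- c(75, 115)

AGE_RANGES <- list("0-17" = c(0, 17), "18-34" = c(18, 34),
                   "35-64" = c(35, 64), "65+" = c(65, 89))

draw_in_cell <- function(bounds_list, key, u) {
  lo <- vapply(bounds_list[key], `[`, numeric(1), 1)
  hi <- vapply(bounds_list[key], `[`, numeric(1), 2)
  unname(lo + u * (hi - lo))
}

#' Synthesize a baseline virtual cohort
#'
#' Draws `n` virtual individuals for the bundle's country: sex and age band
#' from the pyramid (age uniform within the band), a (G, A) stage cell from
#' the stage distribution conditional on age band and sex, a concrete eGFR
#' and ACR uniform within the stage cell, a diagnosed flag from the
#' stage-specific diagnosis rate, and comorbidities from the CKD-conditional
#' prevalence. Individuals under 18 carry no CKD state; they age into
#' eligibility during the projection. Reproducible given `seed`.
#'
#' @param bundle A validated `country_bundle`.
#' @param n Number of virtual individuals (>= 1).
#' @param seed Integer seed.
#' @return A `ckd_cohort` data.frame with one row per individual and
#'   attributes `virtual_size`, `country_code`, `base_year`.
#' @export
synthesize_cohort <- function(bundle, n, seed) {
  validate_country_bundle(bundle)
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))

  # sex and age band
  pyr <- bundle$pyramid
  cell <- sample.int(nrow(pyr), n, replace = TRUE, prob = pyr$prop)
  sex <- pyr$sex[cell]
  band <- pyr$age_band[cell]
  lo <- vapply(AGE_RANGES[band], `[`, numeric(1), 1)
  hi <- vapply(AGE_RANGES[band], `[`, numeric(1), 2)
  age <- as.integer(floor(lo + stats::runif(n) * (hi - lo + 1)))

  # (G, A) stage cell conditional on (age band, sex); under-18s stay CKD-free
  sd <- bundle$stage_distribution
  sd_key <- paste(sd$age_band, sd$sex)
  G <- rep("none", n)
  A <- rep("none", n)
  u_stage <- stats::runif(n)
  adult <- age >= 18
  for (key in unique(sd_key)) {
    rows <- which(sd_key == key)
    members <- which(paste(band, sex) == key & adult)
    if (!length(members)) next
    cum <- cumsum(sd$prob[rows])
    idx <- findInterval(u_stage[members], c(0, cum[-length(cum)]))
    G[members] <- sd$G[rows][idx]
    A[members] <- sd$A[rows][idx]
  }
  is_ckd <- G != "none"

  # concrete eGFR / ACR within the stage cell
  u_egfr <- stats::runif(n)
  u_acr <- stats::runif(n)
  egfr <- HEALTHY_EGFR[1] + u_egfr * diff(HEALTHY_EGFR)
  acr <- u_acr * A_BOUNDS$A1[2]
  if (any(is_ckd)) {
    egfr[is_ckd] <- draw_in_cell(G_BOUNDS, G[is_ckd], u_egfr[is_ckd])
    acr[is_ckd] <- draw_in_cell(A_BOUNDS, A[is_ckd], u_acr[is_ckd])
  }

  # diagnosis: stage-specific diagnosed fraction at baseline
  diagnosed <- rep(FALSE, n)
  if (any(is_ckd)) {
    rate <- bundle$diagnosis_rate_by_stage[G[is_ckd]]
    diagnosed[is_ckd] <- stats::runif(sum(is_ckd)) < rate
  }

  # comorbidities conditional on CKD status
  u_com <- stats::runif(n)
  t2d <- rep(FALSE, n)
  htn <- rep(FALSE, n)
  for (grp in c("ckd", "non_ckd")) {
    cp <- bundle$comorbidity_prevalence[[grp]]
    members <- if (grp == "ckd") is_ckd & adult else !is_ckd & adult
    if (!any(members)) next
    cuts <- cumsum(c(cp[["t2d_only"]], cp[["htn_only"]], cp[["both"]]))
    cat_idx <- findInterval(u_com[members], c(0, cuts)) # 4 = neither
    t2d[members] <- cat_idx %in% c(1, 3)
    htn[members] <- cat_idx %in% c(2, 3)
  }

  cohort <- data.frame(
    id = seq_len(n),
    age = age,
    sex = sex,
    alive = TRUE,
    egfr = egfr,
    acr = acr,
    G = G,
    A = A,
    is_ckd = is_ckd,
    diagnosed = diagnosed,
    t2d = t2d,
    htn = htn,
    cv_hf = FALSE,
    cv_mi = FALSE,
    cv_stroke = FALSE,
    krt = "none",
    krt_start = NA_integer_,
    death_year = NA_integer_,
    stringsAsFactors = FALSE
  )
  structure(cohort,
            virtual_size = n,
            country_code = bundle$country_code,
            base_year = BUNDLE_YEARS[1],
            class = c("ckd_cohort", "data.frame"))
}

#' Baseline summary of a cohort
#'
#' Proportions of the cohort by sex, age band, KDIGO G stage (among the whole
#' cohort, diagnosed and undiagnosed combined), all-stage CKD, diagnosed CKD,
#' and comorbidity prevalence within the CKD population.
#'
#' @param cohort A `ckd_cohort`.
#' @return data.frame(metric, value) with proportions in \[0, 1\].
#' @export
baseline_summary <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort")
  n <- nrow(cohort)
  n_ckd <- sum(cohort$is_ckd)
  stage_prop <- vapply(G_STAGES,
                       function(g) sum(cohort$G == g) / n, numeric(1))
  band <- age_band(cohort$age)
  metrics <- c(
    prop_female = mean(cohort$sex == "F"),
    stats::setNames(vapply(AGE_BANDS, function(b) mean(band == b), numeric(1)),
                    paste0("prop_age_", AGE_BANDS)),
    stats::setNames(stage_prop, paste0("prop_stage_", G_STAGES)),
    prop_ckd_all_stages = n_ckd / n,
    prop_ckd_diagnosed = sum(cohort$diagnosed) / n,
    prop_t2d_in_ckd = if (n_ckd) sum(cohort$t2d & cohort$is_ckd) / n_ckd else NA_real_,
    prop_htn_in_ckd = if (n_ckd) sum(cohort$htn & cohort$is_ckd) / n_ckd else NA_real_
  )
  data.frame(metric = names(metrics), value = unname(metrics),
             stringsAsFactors = FALSE)
}
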