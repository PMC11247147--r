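# Country input bundle: the full per-country parameter set consumed by the
# engine, with validation, YAML serialisation and proxy resolution.

AGE_BANDS <- c("0-17", "18-34", "35-64", "65+")
BUNDLE_YEARS <- 2022:2027
KRT_MODALITIES <- c("HD", "PD", "Tx")
SCHEMA_VERSION <- 1L

#' Map an age in years to the reporting age band
#'
#' @param age Integer ages.
#' @return Character vector over `"0-17"`, `"18-34"`, `"35-64"`, `"65+"`.
#' @export
age_band <- function(age) {
  AGE_BANDS[findInterval(age, c(0, 18, 35, 65))]
}

#' Construct a country input bundle
#'
#' Assembles and validates the complete parameter set the microsimulation
#' consumes for one country: national population by calendar year, the
#' sex-by-age-band pyramid, the KDIGO (G x A) stage distribution conditional
#' on age band and sex (including a "none" cell for no CKD), stage-specific
#' diagnosis rates, incidence, comorbidity prevalence, cardiovascular base
#' rates, all-cause mortality, the KDIGO risk grid, eGFR slopes, albuminuria
#' transitions and kidney replacement therapy (KRT) parameters.
#'
#' @param country_code Identifier, e.g. "BRA".
#' @param population_by_year Named numeric, names "2022".."2027", persons.
#' @param pyramid data.frame(sex, age_band, prop); props sum to 1.
#' @param stage_distribution data.frame(age_band, sex, G, A, prob). `G`/`A`
#'   are KDIGO stages, or `"none"`/`"none"` for the no-CKD cell; probabilities
#'   sum to 1 within each (age_band, sex) row.
#' @param diagnosis_rate_by_stage Named numeric over G1..G5 (G3 split a/b):
#'   annual probability that a prevalent undiagnosed case is diagnosed; also
#'   the diagnosed fraction at baseline synthesis.
#' @param ckd_incidence data.frame(age_band, sex, p): annual onset probability
#'   among CKD-free adults.
#' @param comorbidity_prevalence list(ckd=, non_ckd=) each a named numeric
#'   (t2d_only, htn_only, both); remainder is neither.
#' @param cv_base_rates data.frame(age_band, sex, heart_failure, mi, stroke):
#'   annual base event probabilities.
#' @param mortality_base data.frame(age_band, sex, p): annual all-cause death
#'   probability at low KDIGO risk.
#' @param kdigo_grid A [default_kdigo_grid()]-style object.
#' @param slopes Named numeric of annual eGFR change per subtype key.
#' @param krt list(egfr_initiation_threshold, access_probability,
#'   modality_shares, modality_transition, historical_prevalence,
#'   tx_mortality_multiplier).
#' @param onset_stage_distribution data.frame(G, A, prob) for incident CKD
#'   entry stage; default 50/50 (G2, A2) / (G3a, A1).
#' @param a_transition 3x3 annual A-stage transition matrix (rows = from);
#'   default identity (albuminuria stage retained).
#' @param comorbidity_incidence Named numeric c(t2d=, htn=): annual onset
#'   probabilities; default 0 (comorbidities fixed at baseline).
#' @param egfr_equation_version 2009 or 2021 (default).
#' @param meta Free-form provenance list.
#' @return Validated object of class `country_bundle`.
#' @export
new_country_bundle <- function(country_code,
                               population_by_year,
                               pyramid,
                               stage_distribution,
                               diagnosis_rate_by_stage,
                               ckd_incidence,
                               comorbidity_prevalence,
                               cv_base_rates,
                               mortality_base,
                               kdigo_grid = default_kdigo_grid(),
                               slopes = default_slopes(),
                               krt = default_krt_parameters(),
                               onset_stage_distribution = NULL,
                               a_transition = NULL,
                               comorbidity_incidence = c(t2d = 0, htn = 0),
                               egfr_equation_version = 2021,
                               meta = list()) {
  if (is.null(onset_stage_distribution)) {
    onset_stage_distribution <- data.frame(
      G = c("G2", "G3a"), A = c("A2", "A1"), prob = c(0.5, 0.5),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(a_transition)) {
    a_transition <- diag(3)
    dimnames(a_transition) <- list(A_STAGES, A_STAGES)
  }
  bundle <- structure(list(
    schema_version = SCHEMA_VERSION,
    country_code = country_code,
    population_by_year = population_by_year,
    pyramid = pyramid,
    stage_distribution = stage_distribution,
    diagnosis_rate_by_stage = diagnosis_rate_by_stage,
    ckd_incidence = ckd_incidence,
    comorbidity_prevalence = comorbidity_prevalence,
    cv_base_rates = cv_base_rates,
    mortality_base = mortality_base,
    kdigo_grid = kdigo_grid,
    slopes = slopes,
    krt = krt,
    onset_stage_distribution = onset_stage_distribution,
    a_transition = a_transition,
    comorbidity_incidence = comorbidity_incidence,
    egfr_equation_version = egfr_equation_version,
    meta = meta
  ), class = "country_bundle")
  validate_country_bundle(bundle)
}

#' Default KRT parameter block
#'
#' eGFR initiation threshold of 10 mL/min/1.73 m2, universal access, a
#' haemodialysis-dominant modality mix and no inter-modality transitions.
#'
#' @return A list suitable for the `krt` field of a bundle.
#' @export
default_krt_parameters <- function() {
  trans <- diag(3)
  dimnames(trans) <- list(KRT_MODALITIES, KRT_MODALITIES)
  list(
    egfr_initiation_threshold = 10,
    access_probability = 1,
    modality_shares = c(HD = 0.7, PD = 0.2, Tx = 0.1),
    modality_transition = trans,
    historical_prevalence = NULL,
    tx_mortality_multiplier = 1
  )
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("bundle field '", field, "': probabilities must lie in [0, 1]",
         call. = FALSE)
  }
}

check_rate_table <- function(df, field, value_cols) {
  need <- c("age_band", "sex", value_cols)
  if (!all(need %in% names(df))) {
    stop("bundle field '", field, "': missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  keys <- paste(df$age_band, df$sex)
  need_keys <- paste(rep(AGE_BANDS, each = 2), rep(c("F", "M"), 4))
  if (length(setdiff(need_keys, keys))) {
    stop("bundle field '", field, "': missing (age_band, sex) rows: ",
         paste(setdiff(need_keys, keys), collapse = "; "), call. = FALSE)
  }
  for (col in value_cols) check_prob(df[[col]], paste0(field, "$", col))
}

#' Validate a country input bundle
#'
#' Checks every bundle invariant: probabilities in \[0, 1\], stage
#' distribution rows summing to 1 (±1e-9), strictly positive populations for
#' all six years 2022-2027, complete rate tables, a complete KDIGO grid,
#' finite slopes for all eight subtypes, and coherent KRT parameters.
#' Errors name the offending field.
#'
#' @param bundle A `country_bundle`.
#' @return The bundle, invisibly-validated (returned unchanged).
#' @export
validate_country_bundle <- function(bundle) {
  if (!inherits(bundle, "country_bundle")) stop("not a country_bundle")
  pop <- bundle$population_by_year
  missing_years <- setdiff(as.character(BUNDLE_YEARS), names(pop))
  if (length(missing_years)) {
    stop("bundle field 'population_by_year': missing years ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(pop)) || any(pop <= 0)) {
    stop("bundle field 'population_by_year': must be strictly positive",
         call. = FALSE)
  }

  pyr <- bundle$pyramid
  if (!all(c("sex", "age_band", "prop") %in% names(pyr))) {
    stop("bundle field 'pyramid': needs columns sex, age_band, prop",
         call. = FALSE)
  }
  check_prob(pyr$prop, "pyramid$prop")
  if (abs(sum(pyr$prop) - 1) > 1e-9) {
    stop("bundle field 'pyramid': proportions must sum to 1", call. = FALSE)
  }

  sd <- bundle$stage_distribution
  if (!all(c("age_band", "sex", "G", "A", "prob") %in% names(sd))) {
    stop("bundle field 'stage_distribution': needs columns age_band, sex, G, A, prob",
         call. = FALSE)
  }
  check_prob(sd$prob, "stage_distribution$prob")
  ok_g <- sd$G %in% c("none", G_STAGES)
  ok_a <- sd$A %in% c("none", A_STAGES)
  if (!all(ok_g) || !all(ok_a)) {
    stop("bundle field 'stage_distribution': unknown G or A stage",
         call. = FALSE)
  }
  if (any(xor(sd$G == "none", sd$A == "none"))) {
    stop("bundle field 'stage_distribution': the no-CKD cell must have G and A both 'none'",
         call. = FALSE)
  }
  bad <- sd$G %in% c("G1", "G2") & sd$A == "A1"
  if (any(bad)) {
    stop("bundle field 'stage_distribution': (G1/G2, A1) is not a CKD cell; use G = 'none'",
         call. = FALSE)
  }
  sums <- tapply(sd$prob, paste(sd$age_band, sd$sex), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("bundle field 'stage_distribution': rows must sum to 1 (off for ",
         paste(names(sums)[abs(sums - 1) > 1e-9], collapse = "; "), ")",
         call. = FALSE)
  }

  dr <- bundle$diagnosis_rate_by_stage
  if (length(setdiff(G_STAGES, names(dr)))) {
    stop("bundle field 'diagnosis_rate_by_stage': needs all G stages",
         call. = FALSE)
  }
  check_prob(dr, "diagnosis_rate_by_stage")

  check_rate_table(bundle$ckd_incidence, "ckd_incidence", "p")
  check_rate_table(bundle$mortality_base, "mortality_base", "p")
  check_rate_table(bundle$cv_base_rates, "cv_base_rates", CV_OUTCOMES)

  for (grp in c("ckd", "non_ckd")) {
    cp <- bundle$comorbidity_prevalence[[grp]]
    if (is.null(cp) ||
        length(setdiff(c("t2d_only", "htn_only", "both"), names(cp)))) {
      stop("bundle field 'comorbidity_prevalence$", grp,
           "': needs t2d_only, htn_only, both", call. = FALSE)
    }
    check_prob(cp, paste0("comorbidity_prevalence$", grp))
    if (sum(cp) > 1 + 1e-9) {
      stop("bundle field 'comorbidity_prevalence$", grp,
           "': categories must sum to at most 1", call. = FALSE)
    }
  }

  validate_kdigo_grid(bundle$kdigo_grid)

  if (length(setdiff(ALL_SUBTYPES, names(bundle$slopes))) ||
      any(!is.finite(bundle$slopes))) {
    stop("bundle field 'slopes': needs finite values for all eight subtypes",
         call. = FALSE)
  }

  osd <- bundle$onset_stage_distribution
  if (abs(sum(osd$prob) - 1) > 1e-9) {
    stop("bundle field 'onset_stage_distribution': probabilities must sum to 1",
         call. = FALSE)
  }

  at <- bundle$a_transition
  if (!is.matrix(at) || !identical(dim(at), c(3L, 3L)) ||
      any(abs(rowSums(at) - 1) > 1e-9) || any(at < 0)) {
    stop("bundle field 'a_transition': must be a 3x3 row-stochastic matrix",
         call. = FALSE)
  }

  krt <- bundle$krt
  if (!is.numeric(krt$egfr_initiation_threshold) ||
      krt$egfr_initiation_threshold <= 0) {
    stop("bundle field 'krt$egfr_initiation_threshold': must be > 0",
         call. = FALSE)
  }
  check_prob(krt$access_probability, "krt$access_probability")
  ms <- krt$modality_shares
  if (length(setdiff(KRT_MODALITIES, names(ms)))) {
    stop("bundle field 'krt$modality_shares': needs HD, PD, Tx", call. = FALSE)
  }
  if (abs(sum(ms) - 1) > 1e-9) {
    stop("bundle field 'krt$modality_shares': must sum to 1", call. = FALSE)
  }
  mt <- krt$modality_transition
  if (!is.matrix(mt) || !identical(dim(mt), c(3L, 3L)) ||
      any(abs(rowSums(mt) - 1) > 1e-9) || any(mt < 0)) {
    stop("bundle field 'krt$modality_transition': must be a 3x3 row-stochastic matrix",
         call. = FALSE)
  }
  hp <- krt$historical_prevalence
  if (!is.null(hp) && !all(c("year", "count") %in% names(hp))) {
    stop("bundle field 'krt$historical_prevalence': needs columns year, count",
         call. = FALSE)
  }

  ci <- bundle$comorbidity_incidence
  check_prob(ci, "comorbidity_incidence")

  if (!as.character(bundle$egfr_equation_version) %in% names(CKD_EPI_PARAMS)) {
    stop("bundle field 'egfr_equation_version': must be 2009 or 2021",
         call. = FALSE)
  }
  bundle
}

# --- YAML serialisation ------------------------------------------------------

df_to_list <- function(df) lapply(df, function(col) unname(col))

list_to_df <- function(lst) {
  as.data.frame(lapply(lst, unlist), stringsAsFactors = FALSE)
}

mat_to_list <- function(m) {
  list(dimnames = dimnames(m), values = as.vector(t(m)))
}

list_to_mat <- function(lst) {
  dn <- lapply(lst$dimnames, unlist)
  matrix(unlist(lst$values), nrow = length(dn[[1]]), byrow = TRUE,
         dimnames = dn)
}

#' Write a country bundle to a YAML document
#'
#' @param bundle A validated `country_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_country_bundle()]
#' @export
save_country_bundle <- function(bundle, path) {
  validate_country_bundle(bundle)
  doc <- list(
    schema_version = bundle$schema_version,
    country_code = bundle$country_code,
    population_by_year = as.list(bundle$population_by_year),
    pyramid = df_to_list(bundle$pyramid),
    stage_distribution = df_to_list(bundle$stage_distribution),
    diagnosis_rate_by_stage = as.list(bundle$diagnosis_rate_by_stage),
    ckd_incidence = df_to_list(bundle$ckd_incidence),
    comorbidity_prevalence = lapply(bundle$comorbidity_prevalence, as.list),
    cv_base_rates = df_to_list(bundle$cv_base_rates),
    mortality_base = df_to_list(bundle$mortality_base),
    kdigo_grid = list(category = df_to_list(bundle$kdigo_grid$category),
                      rr = df_to_list(bundle$kdigo_grid$rr)),
    slopes = as.list(bundle$slopes),
    krt = list(
      egfr_initiation_threshold = bundle$krt$egfr_initiation_threshold,
      access_probability = bundle$krt$access_probability,
      modality_shares = as.list(bundle$krt$modality_shares),
      modality_transition = mat_to_list(bundle$krt$modality_transition),
      historical_prevalence = if (is.null(bundle$krt$historical_prevalence))
        NULL else df_to_list(bundle$krt$historical_prevalence),
      tx_mortality_multiplier = bundle$krt$tx_mortality_multiplier
    ),
    onset_stage_distribution = df_to_list(bundle$onset_stage_distribution),
    a_transition = mat_to_list(bundle$a_transition),
    comorbidity_incidence = as.list(bundle$comorbidity_incidence),
    egfr_equation_version = bundle$egfr_equation_version,
    meta = bundle$meta
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load and validate a country bundle from YAML
#'
#' Reads a bundle document written by [save_country_bundle()] (or authored by
#' hand against the same schema), reconstructs all typed fields and runs the
#' full validation; schema violations raise errors naming the field.
#'
#' @param path Path to a YAML bundle document.
#' @return A validated `country_bundle`.
#' @export
load_country_bundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path)
  doc <- yaml::read_yaml(path)
  need <- c("country_code", "population_by_year", "pyramid",
            "stage_distribution", "diagnosis_rate_by_stage", "ckd_incidence",
            "comorbidity_prevalence", "cv_base_rates", "mortality_base")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop("bundle document missing required fields: ",
         paste(missing, collapse = ", "))
  }
  grid <- if (is.null(doc$kdigo_grid)) default_kdigo_grid() else {
    g <- list(category = list_to_df(doc$kdigo_grid$category),
              rr = list_to_df(doc$kdigo_grid$rr))
    class(g) <- "kdigo_grid"
    g
  }
  krt <- if (is.null(doc$krt)) default_krt_parameters() else list(
    egfr_initiation_threshold = doc$krt$egfr_initiation_threshold,
    access_probability = doc$krt$access_probability,
    modality_shares = unlist(doc$krt$modality_shares),
    modality_transition = list_to_mat(doc$krt$modality_transition),
    historical_prevalence = if (is.null(doc$krt$historical_prevalence))
      NULL else list_to_df(doc$krt$historical_prevalence),
    tx_mortality_multiplier = doc$krt$tx_mortality_multiplier
  )
  new_country_bundle(
    country_code = doc$country_code,
    population_by_year = unlist(doc$population_by_year),
    pyramid = list_to_df(doc$pyramid),
    stage_distribution = list_to_df(doc$stage_distribution),
    diagnosis_rate_by_stage = unlist(doc$diagnosis_rate_by_stage),
    ckd_incidence = list_to_df(doc$ckd_incidence),
    comorbidity_prevalence = lapply(doc$comorbidity_prevalence, unlist),
    cv_base_rates = list_to_df(doc$cv_base_rates),
    mortality_base = list_to_df(doc$mortality_base),
    kdigo_grid = grid,
    slopes = if (is.null(doc$slopes)) default_slopes() else unlist(doc$slopes),
    krt = krt,
    onset_stage_distribution = if (is.null(doc$onset_stage_distribution))
      NULL else list_to_df(doc$onset_stage_distribution),
    a_transition = if (is.null(doc$a_transition)) NULL
      else list_to_mat(doc$a_transition),
    comorbidity_incidence = if (is.null(doc$comorbidity_incidence))
      c(t2d = 0, htn = 0) else unlist(doc$comorbidity_incidence),
    egfr_equation_version = if (is.null(doc$egfr_equation_version)) 2021
      else doc$egfr_equation_version,
    meta = if (is.null(doc$meta)) list() else doc$meta
  )
}

# --- proxy resolution --------------------------------------------------------

#' Fill a missing bundle field from donor countries
#'
#' When a country lacks an input, the value is copied from the first donor in
#' an explicit, user-supplied priority list that has the field, and the
#' substitution is recorded in the bundle's provenance metadata. A field that
#' is already present is never overwritten.
#'
#' @param bundle Target `country_bundle` with `field` absent (NULL).
#' @param field Name of the bundle field to resolve.
#' @param donor_bundles List of `country_bundle`s to draw from.
#' @param priority Character vector of donor country codes, tried in order.
#' @return The bundle with the field filled and provenance recorded under
#'   `meta$proxy`.
#' @export
resolve_proxy <- function(bundle, field, donor_bundles, priority) {
  if (!length(priority)) stop("priority list must be non-empty")
  if (!is.null(bundle[[field]])) {
    stop("field '", field, "' is already present in bundle '",
         bundle$country_code, "'; refusing to overwrite")
  }
  codes <- vapply(donor_bundles, function(b) b$country_code, character(1))
  tried <- character(0)
  for (code in priority) {
    tried <- c(tried, code)
    idx <- match(code, codes)
    if (is.na(idx)) next
    value <- donor_bundles[[idx]][[field]]
    if (is.null(value)) next
    bundle[[field]] <- value
    bundle$meta$proxy <- c(bundle$meta$proxy,
                           stats::setNames(list(code), field))
    return(validate_country_bundle(bundle))
  }
  stop("no donor provides field '", field, "'; tried: ",
       paste(tried, collapse = ", "))
}

# --- cross-country reference tables ------------------------------------------

#' Load the transcribed cross-country reference tables
#'
#' Reads the CSV transcriptions of the published 31-country summary tables
#' shipped with the package: national demographics and populations for
#' 2022/2027, baseline (2022) CKD stage percentages, diagnosed/undiagnosed
#' CKD prevalence per 100,000 by stage and year, and cardiovascular
#' complication prevalence per 100,000 CKD patients in 2027. The UAE is
#' represented by its Emirati population only. Values are exactly as printed.
#'
#' @param dir Directory holding the CSVs; defaults to the copies installed
#'   with the package.
#' @return List of data.frames: `demographics`, `ckd_baseline`, `prevalence`,
#'   `cv`.
#' @export
load_reference_tables <- function(dir = system.file("extdata/reference_tables",
                                                    package = "ckdsim")) {
  read1 <- function(name, nrows_expected) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("reference table not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
    if (nrow(df) != nrows_expected) {
      stop("reference table ", name, ": expected ", nrows_expected,
           " rows, found ", nrow(df))
    }
    df
  }
  list(
    demographics = read1("demographics.csv", 31),
    ckd_baseline = read1("ckd_baseline.csv", 31),
    prevalence = read1("prevalence_per_100k.csv", 124),
    cv = read1("cv_prevalence_2027.csv", 31)
  )
}
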