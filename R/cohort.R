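# Open-cohort follow-up construction and analysis covariates.
#
# Each child enters at birth and exits at the earliest of outcome
# incidence, death, emigration, the outcome-specific age cap (3rd birthday
# for wheeze, 12th for the asthma variants) or the administrative end of
# study. Ties on the same day resolve event > death > emigration > age_cap
# > admin_end, so incidence on a censoring boundary still counts as an
# event. The administrative-end exit counts the final study day as lived
# (admin_end - birth + 1 days); all other exits are plain date differences.

#' The three register-based outcomes
#' @export
OUTCOMES <- c("wheeze", "asthma", "asthma3plus")

outcome_cap_years <- function(outcome) {
  switch(outcome, wheeze = 3L, asthma = 12L, asthma3plus = 12L,
         stop_config("unknown outcome '%s'", outcome))
}

#' Build one child's follow-up record
#'
#' @param birth_date the child's birth date
#' @param ascertainment list with `is_case` and `incident_age_days`, as
#'   returned by the `ascertain_*` functions
#' @param vitals data.frame of the child's vital events (`event_date`,
#'   `kind` in death/emigration), or `NULL`
#' @param admin_end administrative end-of-study date
#' @param outcome one of `"wheeze"`, `"asthma"`, `"asthma3plus"`
#' @return list with `entry_age_days` (0), `exit_age_days`, `event` (0/1)
#'   and `censor_reason`
#' @export
build_followup <- function(birth_date, ascertainment, vitals = NULL,
                           admin_end = as.Date("2022-12-31"),
                           outcome = "asthma") {
  birth_date <- as.Date(birth_date)
  cap <- age_days(birth_date, add_years(birth_date,
                                        outcome_cap_years(outcome)))
  death <- emigration <- Inf
  if (!is.null(vitals) && nrow(vitals)) {
    aged <- as.numeric(as.Date(vitals$event_date) - birth_date)
    if (any(vitals$kind == "death"))
      death <- min(aged[vitals$kind == "death"])
    if (any(vitals$kind == "emigration"))
      emigration <- min(aged[vitals$kind == "emigration"])
  }
  incident <- if (isTRUE(ascertainment$is_case))
    ascertainment$incident_age_days else Inf
  admin <- as.numeric(as.Date(admin_end) - birth_date) + 1
  cand <- c(event = incident, death = death, emigration = emigration,
            age_cap = cap, admin_end = admin)
  exit <- min(cand)
  if (!is.finite(exit) || exit <= 0)
    stop("follow-up exit is not positive", call. = FALSE)
  reason <- names(cand)[which(cand == exit)][1]  # precedence by order
  list(entry_age_days = 0, exit_age_days = exit,
       event = as.integer(reason == "event"), censor_reason = reason)
}

#' Derive the analysis covariate panel
#'
#' Quartile cutpoints for family income and maternal age are the empirical
#' quartiles of the cohort passed in; parental asthma comes from
#' [ascertain_parental_asthma()] output.
#'
#' @param persons child table (bundle `persons`)
#' @param parental data.frame with `person_id` and `parental_asthma`
#' @return data.frame keyed by `person_id` with analysis covariates
#'   (missing inputs propagate as `NA`)
#' @export
derive_covariates <- function(persons, parental) {
  quartile <- function(x, label) {
    br <- unique(stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1),
                                 na.rm = TRUE))
    if (length(br) < 3) {
      warning(sprintf("degenerate distribution for %s: %d level(s)",
                      label, length(br) - 1), call. = FALSE)
      return(factor(ifelse(is.na(x), NA, "Q1"), levels = "Q1"))
    }
    cut(x, breaks = br, include.lowest = TRUE,
        labels = paste0("Q", seq_len(length(br) - 1)))
  }
  data.frame(
    person_id = persons$person_id,
    sex = factor(persons$sex, levels = c("female", "male")),
    parity = factor(persons$parity,
                    levels = c("primiparous", "multiparous")),
    smoking = persons$maternal_smoking,
    education = factor(persons$maternal_education, levels = EDU_LEVELS),
    foreign_born = persons$foreign_born_parent,
    parental_asthma = parental$parental_asthma[
      match(persons$person_id, parental$person_id)],
    family_income = persons$family_income,
    maternal_age = persons$maternal_age_at_delivery,
    income_quartile = quartile(persons$family_income, "family_income"),
    maternal_age_quartile = quartile(persons$maternal_age_at_delivery,
                                     "maternal_age"),
    stringsAsFactors = FALSE)
}

#' Analysis covariate columns (adjustment and matching set)
#' @export
COVARIATE_COLS <- c("sex", "parity", "smoking", "education", "foreign_born",
                    "parental_asthma", "income_quartile",
                    "maternal_age_quartile")

#' Build the outcome-specific analysis cohort
#'
#' Runs exposure classification, phenotyping, the parental-asthma
#' indicator, covariate derivation and follow-up construction for one
#' outcome over a register bundle.
#'
#' @param bundle a `register_bundle`
#' @param outcome `"wheeze"`, `"asthma"` or `"asthma3plus"`
#' @param codes a [code_set_config()]
#' @return data.frame with one row per child: identifiers, `exposure`,
#'   follow-up (`exit_age_days`, `event`, `censor_reason`) and covariates
#' @export
build_analysis_cohort <- function(bundle, outcome = "asthma",
                                  codes = code_set_config()) {
  p <- bundle$persons
  expo <- classify_exposure(bundle)
  pheno <- ascertain_outcomes(p, bundle$diagnoses, bundle$dispensations,
                              codes)
  parental <- ascertain_parental_asthma(p, bundle$parent_diagnoses,
                                        bundle$parent_dispensations, codes,
                                        study_window = c(
                                          as.Date(sprintf("%d-01-01",
                                            bundle$config$birth_year_range[1])),
                                          bundle$config$admin_end))
  cov <- derive_covariates(p, parental)
  fu <- followup_table(p, pheno, bundle$vitals, bundle$config$admin_end,
                       outcome)
  out <- data.frame(person_id = p$person_id,
                    cluster_id = p$mother_id,
                    outcome = outcome,
                    exposure = expo$exposure,
                    entry_age_days = 0,
                    exit_age_days = fu$exit_age_days,
                    event = fu$event,
                    censor_reason = fu$censor_reason,
                    stringsAsFactors = FALSE)
  cbind(out, cov[match(p$person_id, cov$person_id),
                 setdiff(names(cov), "person_id"), drop = FALSE],
        row.names = NULL)
}

# vectorized follow-up over a cohort
followup_table <- function(persons, pheno, vitals, admin_end, outcome) {
  n <- nrow(persons)
  cap <- age_days(persons$birth_date,
                  add_years(persons$birth_date, outcome_cap_years(outcome)))
  death <- emigration <- rep(Inf, n)
  if (!is.null(vitals) && nrow(vitals)) {
    i <- match(vitals$person_id, persons$person_id)
    ok <- !is.na(i)
    aged <- as.numeric(as.Date(vitals$event_date[ok]) -
                       persons$birth_date[i[ok]])
    kd <- vitals$kind[ok] == "death"
    death[i[ok][kd]] <- aged[kd]
    ke <- vitals$kind[ok] == "emigration"
    emigration[i[ok][ke]] <- aged[ke]
  }
  case <- pheno[[paste0(outcome, "_case")]]
  incident <- ifelse(case, pheno[[paste0(outcome, "_age")]], Inf)
  admin <- as.numeric(as.Date(admin_end) - persons$birth_date) + 1
  m <- cbind(event = incident, death = death, emigration = emigration,
             age_cap = cap, admin_end = admin)
  exit <- do.call(pmin, as.data.frame(m))
  if (any(exit <= 0)) stop("follow-up exit is not positive", call. = FALSE)
  reason <- colnames(m)[apply(m == exit, 1, which.max)]
  data.frame(exit_age_days = exit, event = as.integer(reason == "event"),
             censor_reason = reason, stringsAsFactors = FALSE)
}

#' Complete-case split with missingness report
#'
#' @param cohort an analysis cohort from [build_analysis_cohort()]
#' @param covariate_cols covariate columns required complete
#' @return list with `complete` (the retained sub-cohort), `report`
#'   (per-covariate missingness tallies) and `comparison` (means of key
#'   characteristics among included vs excluded children)
#' @export
complete_case_split <- function(cohort, covariate_cols = COVARIATE_COLS) {
  miss <- sapply(covariate_cols, function(cl) sum(is.na(cohort[[cl]])))
  any_missing <- Reduce(`|`, lapply(covariate_cols,
                                    function(cl) is.na(cohort[[cl]])))
  complete <- cohort[!any_missing, , drop = FALSE]
  if (nrow(complete) == 0L)
    stop("no children with complete covariate information", call. = FALSE)
  report <- data.frame(covariate = covariate_cols,
                       n_missing = as.integer(miss),
                       pct_missing = 100 * miss / nrow(cohort),
                       row.names = NULL)
  num_or_na <- function(x) if (is.numeric(x)) x else as.numeric(x == levels(factor(x))[length(levels(factor(x)))])
  cmp_cols <- intersect(c("family_income", "maternal_age", "foreign_born",
                          "parental_asthma", "event"), names(cohort))
  comparison <- data.frame(
    characteristic = cmp_cols,
    included_mean = sapply(cmp_cols, function(cl)
      mean(cohort[[cl]][!any_missing], na.rm = TRUE)),
    excluded_mean = sapply(cmp_cols, function(cl)
      if (any(any_missing)) mean(cohort[[cl]][any_missing], na.rm = TRUE)
      else NA_real_),
    row.names = NULL)
  list(complete = complete, report = report, comparison = comparison,
       n_total = nrow(cohort), n_complete = nrow(complete),
       retained_fraction = nrow(complete) / nrow(cohort))
}
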