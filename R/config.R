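#' Ordered prenatal exposure levels
#'
#' The four-level address-based prenatal exposure proxy, ordered from
#' background to very high.
#' @export
EXPOSURE_LEVELS <- c("background", "intermediate", "high", "very_high")

#' Exposure factor helper
#'
#' Coerce a character vector of exposure labels to the ordered factor used
#' throughout the package (background < intermediate < high < very_high).
#'
#' @param x character vector of exposure labels
#' @return ordered factor
#' @export
exposure_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), c(EXPOSURE_LEVELS, NA))
  if (length(bad)) stop_config("unknown exposure level(s): %s",
                               paste(bad, collapse = ", "))
  factor(as.character(x), levels = EXPOSURE_LEVELS, ordered = TRUE)
}

#' Simulation configuration for the synthetic register generator
#'
#' Builds and validates the configuration driving [generate_registers()] and
#' its component stages. Defaults emulate the study conditions of an 8-year
#' birth cohort in a county with a localized drinking-water PFAS point
#' source: four exposure groups in proportions 194/479/1591/9224 of 11,488,
#' sibling clustering of 24%, covariate margins shifted by exposure group,
#' and outcome hazards with configurable true hazard ratios.
#'
#' @param n_children number of children to simulate (default 11488)
#' @param birth_year_range inclusive calendar-year range of births
#'   (default `c(2006, 2013)`)
#' @param group_proportions probabilities over the four exposure categories,
#'   ordered background/intermediate/high/very_high; must sum to 1
#' @param group_counts optional exact per-group child counts (same order);
#'   overrides `group_proportions` and `n_children` when supplied
#' @param true_hr named list of per-group multiplicative hazards on latent
#'   outcome onset, one numeric vector of length 4 per outcome
#'   (`wheeze`, `asthma`); the default encodes adjusted effects of
#'   0.95/0.96/1.44 (intermediate/high/very high vs background) for asthma
#'   and no effect for wheeze
#' @param baseline_cuminc target background-group cumulative incidence by the
#'   outcome age cap, absent censoring (default wheeze 0.18, asthma 0.17)
#' @param persist_prob probability that an asthma case with onset before 36
#'   months also generates a qualifying event after 36 months (default 0.76,
#'   so roughly 13% of children meet the stricter persistent-asthma
#'   definition when 17% meet the asthma definition)
#' @param covariate_effects named numeric vector of log-hazard shifts applied
#'   to latent onset (names among `smoking`, `parental_asthma`, `sex_male`,
#'   `foreign_born`)
#' @param sibling_rate fraction of children sharing a mother with another
#'   cohort child (default 0.24)
#' @param frailty_sd standard deviation of an optional lognormal shared
#'   (maternal) frailty on the latent hazard; default 0 (off)
#' @param missing_rate named per-covariate missingness probabilities
#'   (default smoking 6%, education 2%, income 1.5%, jointly leaving about
#'   91% of children with complete covariates)
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"`; under MAR the
#'   missingness odds are tilted by low family income
#' @param death_rate probability of death during follow-up (default 0.002)
#' @param emigration_rate probability of emigration during follow-up
#'   (default 0.03)
#' @param noise_rate rate of non-qualifying noise events (isolated single
#'   dispensations, post-36-month respiratory infections) per child
#'   (default 0.3; set 0 to disable noise)
#' @param admin_end administrative end of study (default `"2022-12-31"`)
#' @param biomarker per-analyte, per-group lognormal medians and log-scale
#'   spreads for the serum PFAS validation cohort; see
#'   [generate_biomarker_cohort()]
#' @param seed integer RNG seed
#' @return an object of class `sim_config` (a validated list)
#' @export
sim_config <- function(n_children = 11488L,
                       birth_year_range = c(2006L, 2013L),
                       group_proportions = c(9224, 1591, 479, 194) / 11488,
                       group_counts = NULL,
                       true_hr = list(
                         wheeze = c(background = 1, intermediate = 1,
                                    high = 1, very_high = 1),
                         asthma = c(background = 1, intermediate = 0.95,
                                    high = 0.96, very_high = 1.44)),
                       baseline_cuminc = c(wheeze = 0.18, asthma = 0.17),
                       persist_prob = 0.76,
                       covariate_effects = c(smoking = 0.26,
                                             parental_asthma = 0.69,
                                             sex_male = 0.30,
                                             foreign_born = 0.10),
                       sibling_rate = 0.24,
                       frailty_sd = 0,
                       missing_rate = c(smoking = 0.06, education = 0.02,
                                        income = 0.015),
                       missing_mechanism = c("MCAR", "MAR"),
                       death_rate = 0.002,
                       emigration_rate = 0.03,
                       noise_rate = 0.3,
                       admin_end = "2022-12-31",
                       biomarker = NULL,
                       seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (!is.null(group_counts)) {
    if (length(group_counts) != 4L || any(group_counts < 0))
      stop_config("group_counts must be 4 nonnegative counts")
    n_children <- sum(group_counts)
    group_proportions <- if (n_children > 0) group_counts / n_children
                         else rep(0.25, 4)
  }
  if (length(n_children) != 1L || is.na(n_children) || n_children < 0)
    stop_config("n_children must be a single nonnegative count")
  if (length(group_proportions) != 4L ||
      abs(sum(group_proportions) - 1) > 1e-8 || any(group_proportions < 0))
    stop_config("group_proportions must be 4 nonnegative values summing to 1")
  for (o in names(true_hr))
    if (any(!is.finite(true_hr[[o]])) || any(true_hr[[o]] <= 0))
      stop_config("true_hr must be positive")
  rates <- c(baseline_cuminc, persist_prob, sibling_rate,
             missing_rate, death_rate, emigration_rate)
  if (any(rates < 0 | rates > 1))
    stop_config("rates and probabilities must lie in [0, 1]")
  if (frailty_sd < 0) stop_config("frailty_sd must be nonnegative")
  if (noise_rate < 0) stop_config("noise_rate must be nonnegative")
  if (diff(birth_year_range) < 0)
    stop_config("birth_year_range must be increasing")
  cfg <- list(
    n_children = as.integer(n_children),
    birth_year_range = as.integer(birth_year_range),
    group_proportions = group_proportions,
    group_counts = group_counts,
    true_hr = true_hr,
    baseline_cuminc = baseline_cuminc,
    persist_prob = persist_prob,
    covariate_effects = covariate_effects,
    sibling_rate = sibling_rate,
    frailty_sd = frailty_sd,
    missing_rate = missing_rate,
    missing_mechanism = missing_mechanism,
    death_rate = death_rate,
    emigration_rate = emigration_rate,
    noise_rate = noise_rate,
    admin_end = as.Date(admin_end),
    biomarker = biomarker %||% default_biomarker_params(),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n_children: %d, births %d-%d, seed %s\n",
              x$n_children, x$birth_year_range[1], x$birth_year_range[2],
              x$seed %||% "NULL"))
  cat(sprintf("  group proportions (bg/int/high/vhigh): %s\n",
              paste(signif(x$group_proportions, 3), collapse = "/")))
  invisible(x)
}

#' Outcome phenotyping code-set configuration
#'
#' Code sets and windows used by the wheeze/asthma/persistent-asthma
#' phenotyping algorithms. Defaults use ICD-10 J45 for asthma, J45 plus the
#' acute lower-respiratory-infection codes J20-J22 for wheeze, and the ATC
#' chapter R03 (drugs for obstructive airway disease) for dispensations.
#' Codes are matched as prefixes, so `"J45"` covers `"J45.0"` etc.
#'
#' @param asthma_icd ICD-10 prefixes counting as asthma diagnoses
#' @param wheeze_icd ICD-10 prefixes counting as wheeze diagnoses
#' @param asthma_atc ATC prefixes counting as asthma dispensations
#' @param wheeze_atc ATC prefixes counting as wheeze dispensations
#' @param repeat_window_days maximum days between first and repeat
#'   dispensation for the asthma algorithm; `Inf` (default) accepts any
#'   second dispensation
#' @return an object of class `code_set_config`
#' @export
code_set_config <- function(asthma_icd = "J45",
                            wheeze_icd = c("J45", "J20", "J21", "J22"),
                            asthma_atc = "R03",
                            wheeze_atc = "R03",
                            repeat_window_days = Inf) {
  for (s in list(asthma_icd, wheeze_icd, asthma_atc, wheeze_atc))
    if (!length(s)) stop_config("code sets must be nonempty")
  if (repeat_window_days <= 0) stop_config("repeat_window_days must be > 0")
  structure(list(asthma_icd = asthma_icd, wheeze_icd = wheeze_icd,
                 asthma_atc = asthma_atc, wheeze_atc = wheeze_atc,
                 repeat_window_days = repeat_window_days),
            class = "code_set_config")
}

# prefix matcher for ICD/ATC codes
matches_prefix <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}
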