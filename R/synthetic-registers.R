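# Synthetic linked-register generation.
#
# The generator emulates the statistical structure of a linked Swedish
# register extract for an 8-year birth cohort exposed through a localized
# drinking-water PFAS point source: one birth record per child with
# maternal covariates whose margins differ by exposure group, annual
# maternal address snapshots carrying waterworks flags, diagnosis and
# drug-dispensation event streams consistent with the phenotyping
# algorithms, vital (death/emigration) events, parental event streams for
# the parental-asthma indicator, and a serum-biomarker validation cohort.
# Everything is reproducible bit-for-bit from (config, seed).

# Table-margin defaults per exposure group, ordered
# background / intermediate / high / very_high.
GROUP_MARGINS <- list(
  smoking   = c(0.072, 0.083, 0.171, 0.098),
  multiparous = c(0.581, 0.571, 0.541, 0.753),
  female    = c(0.479, 0.502, 0.497, 0.448),
  edu_probs = list(c(0.194, 0.311, 0.495),
                   c(0.193, 0.319, 0.488),
                   c(0.282, 0.365, 0.353),
                   c(0.320, 0.407, 0.273)),
  age_median = c(30.1, 30.1, 27.7, 30.9),
  age_sd     = c(5.34, 5.19, 5.63, 6.00),
  income_median = c(3.8, 3.8, 3.5, 3.7),   # SEK x 1e5
  income_sdlog  = c(0.317, 0.335, 0.310, 0.284),
  foreign   = c(0.201, 0.172, 0.157, 0.093),
  parental_asthma = c(0.170, 0.157, 0.221, 0.191)
)

EDU_LEVELS <- c("primary", "secondary", "post_secondary")

# Lognormal serum-PFAS parameters per analyte and exposure group.
# Medians in ng/mL; sdlog derived from interquartile ratios,
# sdlog = log(q3/q1) / (2 * qnorm(0.75)).
default_biomarker_params <- function() {
  iqr_sdlog <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))
  list(
    n = c(background = 36, intermediate = 39, high = 54, very_high = 80),
    sampling_years = 2014:2016,
    median = list(
      pfos  = c(background = 3.6, intermediate = 47.7,
                high = 137.4, very_high = 218.7),
      pfhxs = c(background = 0.8, intermediate = 30.5,
                high = 100.0, very_high = 164.8),
      pfoa  = c(background = 1.6, intermediate = 3.8,
                high = 7.3, very_high = 11.8)),
    sdlog = list(
      pfos  = c(background = iqr_sdlog(2.6, 4.8),
                intermediate = iqr_sdlog(30.8, 121.1),
                high = iqr_sdlog(80.7, 194.8),
                very_high = iqr_sdlog(140.4, 344.1)),
      pfhxs = c(background = iqr_sdlog(0.7, 1.1),
                intermediate = iqr_sdlog(21.3, 102.4),
                high = iqr_sdlog(64.8, 180.3),
                very_high = iqr_sdlog(106.1, 283.0)),
      pfoa  = c(background = iqr_sdlog(0.8, 1.9),
                intermediate = iqr_sdlog(2.0, 5.6),
                high = iqr_sdlog(3.7, 14.2),
                very_high = iqr_sdlog(7.2, 18.9)))
  )
}

empty_bundle <- function(config) {
  chr <- character(0); num <- numeric(0); lgl <- logical(0)
  dt <- as.Date(chr)
  b <- list(
    persons = data.frame(person_id = chr, mother_id = chr, father_id = chr,
                         birth_date = dt, sex = chr, parity = chr,
                         maternal_smoking = num, maternal_education = chr,
                         maternal_age_at_delivery = num,
                         foreign_born_parent = num, family_income = num,
                         stringsAsFactors = FALSE),
    addresses = data.frame(person_id = chr, calendar_year = integer(0),
                           in_ronneby = lgl, contaminated_water = lgl),
    diagnoses = data.frame(person_id = chr, event_date = dt,
                           icd10_code = chr, source = chr),
    dispensations = data.frame(person_id = chr, dispense_date = dt,
                               atc_code = chr),
    vitals = data.frame(person_id = chr, event_date = dt, kind = chr),
    parent_diagnoses = data.frame(person_id = chr, event_date = dt,
                                  icd10_code = chr, source = chr),
    parent_dispensations = data.frame(person_id = chr, dispense_date = dt,
                                      atc_code = chr),
    latent = data.frame(person_id = chr, exposure = chr,
                        smoking_true = num, education_true = chr,
                        income_true = num, parental_asthma = num,
                        frailty = num),
    config = config
  )
  class(b) <- "register_bundle"
  b
}

#' @export
print.register_bundle <- function(x, ...) {
  cat("<register_bundle>\n")
  cat(sprintf("  %d children, %d address-years, %d diagnoses, %d dispensations, %d vital events\n",
              nrow(x$persons), nrow(x$addresses), nrow(x$diagnoses),
              nrow(x$dispensations), nrow(x$vitals)))
  invisible(x)
}

#' Generate the synthetic study population
#'
#' Draws children, mothers (with sibling clustering), per-group covariates,
#' latent parental-asthma status and five-year maternal address histories
#' consistent with each mother's assigned exposure category: very-high
#' mothers hold a contaminated-waterworks address for all five years before
#' every delivery, high mothers for at least one but not all five,
#' intermediate mothers live in Ronneby on the uncontaminated waterworks,
#' and background mothers never live in Ronneby. Covariate missingness is
#' injected at the configured rates (MCAR by default, optionally tilted by
#' low family income).
#'
#' @param config a [sim_config()]
#' @return a `register_bundle` with `persons`, `addresses` and `latent`
#'   tables populated (event tables empty until
#'   [generate_health_events()] runs)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_children == 0L) return(empty_bundle(config))
  with_seed(child_seed(config$seed, "population"), {
    n <- config$n_children
    yr <- config$birth_year_range

    # child counts per group (exact if group_counts given)
    if (!is.null(config$group_counts)) {
      counts <- as.integer(config$group_counts)
    } else {
      counts <- as.integer(stats::rmultinom(1, n, config$group_proportions))
    }

    # mothers per group: sibling pairs realized within group
    span <- yr[2] - yr[1]
    mother_group <- integer(0); mother_size <- integer(0)
    for (g in seq_len(4)) {
      cg <- counts[g]
      if (cg == 0L) next
      pairs <- if (span >= 1) min(round(config$sibling_rate * cg / 2), cg %/% 2)
               else 0L
      singles <- cg - 2L * pairs
      mother_group <- c(mother_group, rep(g, pairs + singles))
      mother_size <- c(mother_size, rep(2L, pairs), rep(1L, singles))
    }
    n_mother <- length(mother_group)
    mid <- sprintf("M%05d", seq_len(n_mother))
    fid <- sprintf("F%05d", seq_len(n_mother))

    # birth years: pairs get a 1-3 year gap inside the range
    first_year <- integer(n_mother); gap <- integer(n_mother)
    is_pair <- mother_size == 2L
    gap[is_pair] <- sample(1:3, sum(is_pair), replace = TRUE,
                           prob = c(0.5, 0.3, 0.2))
    gap[is_pair] <- pmin(gap[is_pair], span)
    first_year[is_pair] <- yr[1] +
      floor(stats::runif(sum(is_pair)) * (span - gap[is_pair] + 1))
    first_year[!is_pair] <- yr[1] +
      floor(stats::runif(sum(!is_pair)) * (span + 1))

    # expand to children
    child_mother <- rep(seq_len(n_mother), mother_size)
    birth_order <- unlist(lapply(mother_size, seq_len), use.names = FALSE)
    group <- mother_group[child_mother]
    birth_year <- ifelse(birth_order == 1L, first_year[child_mother],
                         first_year[child_mother] + gap[child_mother])
    nk <- length(child_mother)
    ydays <- as.integer(as.Date(sprintf("%d-12-31", birth_year)) -
                        as.Date(sprintf("%d-01-01", birth_year)))
    birth_date <- as.Date(sprintf("%d-01-01", birth_year)) +
      floor(stats::runif(nk) * (ydays + 1))

    m <- GROUP_MARGINS
    smoking <- as.numeric(stats::runif(nk) < m$smoking[group])
    parity <- ifelse(birth_order > 1L, "multiparous",
                     ifelse(stats::runif(nk) < m$multiparous[group],
                            "multiparous", "primiparous"))
    sex <- ifelse(stats::runif(nk) < m$female[group], "female", "male")
    edu <- character(nk)
    for (g in seq_len(4)) {
      sel <- group == g
      if (any(sel))
        edu[sel] <- sample(EDU_LEVELS, sum(sel), replace = TRUE,
                           prob = m$edu_probs[[g]])
    }
    mat_age <- pmin(pmax(stats::rnorm(nk, m$age_median[group],
                                      m$age_sd[group]), 18), 45)
    income <- stats::rlnorm(nk, log(m$income_median[group]),
                            m$income_sdlog[group])
    foreign <- as.numeric(stats::runif(nk) < m$foreign[group])
    # parental asthma is a family-level trait
    pa_mother_family <- stats::runif(n_mother) < m$parental_asthma[mother_group]
    pa <- as.numeric(pa_mother_family[child_mother])
    frailty <- if (config$frailty_sd > 0)
      stats::rnorm(n_mother, 0, config$frailty_sd) else rep(0, n_mother)

    pid <- sprintf("C%06d", seq_len(nk))
    persons <- data.frame(
      person_id = pid,
      mother_id = mid[child_mother],
      father_id = fid[child_mother],
      birth_date = birth_date,
      sex = sex,
      parity = parity,
      maternal_smoking = smoking,
      maternal_education = edu,
      maternal_age_at_delivery = mat_age,
      foreign_born_parent = foreign,
      family_income = income,
      stringsAsFactors = FALSE)

    latent <- data.frame(
      person_id = pid,
      exposure = EXPOSURE_LEVELS[group],
      smoking_true = smoking,
      education_true = edu,
      income_true = income,
      parental_asthma = pa,
      frailty = frailty[child_mother],
      stringsAsFactors = FALSE)

    # covariate missingness
    persons <- inject_missingness(persons, config)

    # maternal address histories covering every child's five-year window
    addresses <- build_addresses(mid, mother_group, first_year, gap,
                                 mother_size)

    b <- empty_bundle(config)
    b$persons <- persons
    b$addresses <- addresses
    b$latent <- latent
    b
  })
}

inject_missingness <- function(persons, config) {
  nk <- nrow(persons)
  rates <- config$missing_rate
  weight <- rep(1, nk)
  if (identical(config$missing_mechanism, "MAR")) {
    # low-income families roughly twice as likely to have gaps
    low <- persons$family_income < stats::median(persons$family_income)
    weight <- ifelse(low, 2, 1)
    weight <- weight / mean(weight)
  }
  miss <- function(rate) stats::runif(nk) < pmin(rate * weight, 1)
  if (!is.na(rates["smoking"]) && rates["smoking"] > 0)
    persons$maternal_smoking[miss(rates["smoking"])] <- NA
  if (!is.na(rates["education"]) && rates["education"] > 0)
    persons$maternal_education[miss(rates["education"])] <- NA
  if (!is.na(rates["income"]) && rates["income"] > 0)
    persons$family_income[miss(rates["income"])] <- NA
  persons
}

# One AddressYear row per mother-year spanning [first_birth-5, last_birth-1].
# Group semantics: background never in Ronneby; intermediate in Ronneby on
# the clean waterworks; very_high contaminated every year; high contaminated
# exactly in the year before the first delivery (inside every child's
# window because sibling gaps are <= 4 years) and in Ronneby otherwise.
build_addresses <- function(mid, mother_group, first_year, gap, mother_size) {
  last_year <- first_year + ifelse(mother_size == 2L, gap, 0L)
  nyears <- (last_year - 1L) - (first_year - 5L) + 1L
  idx <- rep(seq_along(mid), nyears)
  year <- unlist(lapply(seq_along(mid), function(i)
    seq.int(first_year[i] - 5L, last_year[i] - 1L)), use.names = FALSE)
  g <- mother_group[idx]
  in_ronneby <- g != 1L
  contaminated <- (g == 4L) | (g == 3L & year == (first_year[idx] - 1L))
  data.frame(person_id = mid[idx], calendar_year = as.integer(year),
             in_ronneby = in_ronneby, contaminated_water = contaminated,
             stringsAsFactors = FALSE)
}
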