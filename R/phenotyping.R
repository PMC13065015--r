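# Register-based outcome phenotyping.
#
# Three algorithms over diagnosis (ICD-10) and dispensation (ATC) streams:
#   wheeze      — any wheeze-coded diagnosis (J45, J20-J22) or any single
#                 wheeze-medication dispensation strictly before the 3rd
#                 birthday; incident age = earliest qualifying event.
#   asthma      — an asthma diagnosis (J45) before the 12th birthday, OR a
#                 first asthma-medication dispensation confirmed by at least
#                 one repeat (both before the 12th birthday, repeat within
#                 repeat_window_days); incident age = earliest of the first
#                 qualifying diagnosis and the *first* dispensation (the
#                 repeat only confirms).
#   asthma_3plus — asthma criteria met AND at least one qualifying
#                 diagnosis/dispensation on or after the 3rd birthday
#                 (lookahead confirmation); incident age equals the asthma
#                 incident age.
# Ages are integer days; "36 months" and "age 12" are the 3rd and 12th
# birthdays, and an event on the birthday counts as after it.

# first and second smallest age per person index (1..n); returns list of
# length-n vectors (Inf where absent)
first_two_ages <- function(person, age, n) {
  first <- rep(Inf, n); second <- rep(Inf, n)
  if (length(person)) {
    o <- order(person, age)
    ps <- person[o]; as <- age[o]
    new <- !duplicated(ps)
    first[ps[new]] <- as[new]
    pos <- seq_along(ps)
    start <- pos[new][match(ps, ps[new])]
    rk <- pos - start + 1L
    sec <- rk == 2L
    second[ps[sec]] <- as[sec]
  }
  list(first = first, second = second)
}

# Vectorized phenotyping over a cohort. `persons` needs person_id and
# birth_date; dx needs person_id, event_date (or age_days), icd10_code;
# rx needs person_id, dispense_date (or age_days), atc_code.
#' Ascertain all three outcomes for a cohort
#'
#' Applies the wheeze, asthma and asthma (3+) phenotyping algorithms to
#' every child in `persons` at once.
#'
#' @param persons data.frame with `person_id` and `birth_date`
#' @param dx diagnosis events (`person_id`, `event_date` or `age_days`,
#'   `icd10_code`); events for ids absent from `persons` are ignored
#' @param rx dispensation events (`person_id`, `dispense_date` or
#'   `age_days`, `atc_code`)
#' @param codes a [code_set_config()]
#' @return data.frame with one row per child and columns
#'   `wheeze_case`/`wheeze_age`, `asthma_case`/`asthma_age`,
#'   `asthma3plus_case`/`asthma3plus_age` (ages `NA` for non-cases)
#' @export
ascertain_outcomes <- function(persons, dx, rx, codes = code_set_config()) {
  n <- nrow(persons)
  cap3 <- age_days(persons$birth_date, add_years(persons$birth_date, 3L))
  cap12 <- age_days(persons$birth_date, add_years(persons$birth_date, 12L))

  get_age <- function(ev, datecol) {
    i <- match(ev$person_id, persons$person_id)
    keep <- !is.na(i)
    ev <- ev[keep, , drop = FALSE]; i <- i[keep]
    age <- if ("age_days" %in% names(ev)) as.numeric(ev$age_days)
           else as.numeric(as.Date(ev[[datecol]]) -
                           persons$birth_date[i])
    if (any(age < 0)) stop("event dated before birth", call. = FALSE)
    list(i = i, age = age, ev = ev)
  }
  D <- get_age(dx, "event_date")
  R <- get_age(rx, "dispense_date")
  dx_asthma <- matches_prefix(D$ev$icd10_code, codes$asthma_icd)
  dx_wheeze <- matches_prefix(D$ev$icd10_code, codes$wheeze_icd)
  rx_asthma <- matches_prefix(R$ev$atc_code, codes$asthma_atc)
  rx_wheeze <- matches_prefix(R$ev$atc_code, codes$wheeze_atc)

  # asthma
  qd <- dx_asthma & D$age < cap12[D$i]
  dxf <- first_two_ages(D$i[qd], D$age[qd], n)$first
  qr <- rx_asthma & R$age < cap12[R$i]
  rxp <- first_two_ages(R$i[qr], R$age[qr], n)
  rx_ok <- is.finite(rxp$second) &
    (rxp$second - rxp$first) <= codes$repeat_window_days
  asthma_age <- pmin(dxf, ifelse(rx_ok, rxp$first, Inf))
  asthma_case <- is.finite(asthma_age)

  # asthma (3+): any qualifying event on/after the 3rd birthday
  late <- rep(FALSE, n)
  ld <- dx_asthma & D$age >= cap3[D$i] & D$age < cap12[D$i]
  late[unique(D$i[ld])] <- TRUE
  lr <- rx_asthma & R$age >= cap3[R$i] & R$age < cap12[R$i]
  late[unique(R$i[lr])] <- TRUE
  a3_case <- asthma_case & late

  # wheeze: single qualifying event before the 3rd birthday
  wd <- dx_wheeze & D$age < cap3[D$i]
  wr <- rx_wheeze & R$age < cap3[R$i]
  w_age <- pmin(first_two_ages(D$i[wd], D$age[wd], n)$first,
                first_two_ages(R$i[wr], R$age[wr], n)$first)
  w_case <- is.finite(w_age)

  data.frame(
    person_id = persons$person_id,
    wheeze_case = w_case,
    wheeze_age = ifelse(w_case, w_age, NA_real_),
    asthma_case = asthma_case,
    asthma_age = ifelse(asthma_case, asthma_age, NA_real_),
    asthma3plus_case = a3_case,
    asthma3plus_age = ifelse(a3_case, asthma_age, NA_real_),
    stringsAsFactors = FALSE)
}

one_child <- function(dx, rx, birth_date) {
  empty_dx <- data.frame(person_id = character(0), age_days = numeric(0),
                         icd10_code = character(0))
  empty_rx <- data.frame(person_id = character(0), age_days = numeric(0),
                         atc_code = character(0))
  norm <- function(ev, empty) {
    if (is.null(ev) || !nrow(as.data.frame(ev))) return(empty)
    ev <- as.data.frame(ev)
    ev$person_id <- "self"
    ev
  }
  list(persons = data.frame(person_id = "self",
                            birth_date = as.Date(birth_date)),
       dx = norm(dx, empty_dx), rx = norm(rx, empty_rx))
}

ascertain_one <- function(outcome, dx, rx, birth_date, codes) {
  x <- one_child(dx, rx, birth_date)
  res <- ascertain_outcomes(x$persons, x$dx, x$rx, codes)
  case <- res[[paste0(outcome, "_case")]]
  list(outcome = sub("3plus", "_3plus", outcome),
       is_case = case,
       incident_age_days = if (case) res[[paste0(outcome, "_age")]]
                           else NA_real_)
}

#' Single-child asthma ascertainment
#'
#' @param dx data.frame of diagnoses with `icd10_code` and either
#'   `event_date` or `age_days`; may be `NULL`
#' @param rx data.frame of dispensations with `atc_code` and either
#'   `dispense_date` or `age_days`; may be `NULL`
#' @param birth_date the child's birth date
#' @param codes a [code_set_config()]
#' @return list with `outcome`, `is_case`, `incident_age_days`
#' @export
ascertain_asthma <- function(dx, rx, birth_date,
                             codes = code_set_config()) {
  ascertain_one("asthma", dx, rx, birth_date, codes)
}

#' Single-child asthma (3+) ascertainment
#' @inheritParams ascertain_asthma
#' @return list with `outcome`, `is_case`, `incident_age_days`
#' @export
ascertain_asthma_3plus <- function(dx, rx, birth_date,
                                   codes = code_set_config()) {
  ascertain_one("asthma3plus", dx, rx, birth_date, codes)
}

#' Single-child wheeze ascertainment
#' @inheritParams ascertain_asthma
#' @return list with `outcome`, `is_case`, `incident_age_days`
#' @export
ascertain_wheeze <- function(dx, rx, birth_date,
                             codes = code_set_config()) {
  ascertain_one("wheeze", dx, rx, birth_date, codes)
}

#' Parental asthma indicator
#'
#' Applies the asthma algorithm's diagnosis-or-repeat-dispensation rule
#' with no age cap to each parent's event stream restricted to the study
#' window, then ORs over the two parents of each child.
#'
#' @param persons child table with `person_id`, `mother_id`, `father_id`
#' @param parent_dx,parent_rx parental diagnosis/dispensation streams keyed
#'   by parent `person_id`
#' @param codes a [code_set_config()]
#' @param study_window length-2 Date vector; events outside it are ignored
#'   (default 2006-01-01 to 2022-12-31)
#' @return data.frame with `person_id` and binary `parental_asthma`
#' @export
ascertain_parental_asthma <- function(persons, parent_dx, parent_rx,
                                      codes = code_set_config(),
                                      study_window = as.Date(c("2006-01-01",
                                                               "2022-12-31"))) {
  ids <- unique(c(persons$mother_id, persons$father_id))
  ptab <- data.frame(person_id = ids,
                     birth_date = as.Date("1900-01-01"),
                     stringsAsFactors = FALSE)
  clip <- function(ev, datecol) {
    d <- as.Date(ev[[datecol]])
    ev[d >= study_window[1] & d <= study_window[2], , drop = FALSE]
  }
  dxw <- clip(parent_dx, "event_date")
  rxw <- clip(parent_rx, "dispense_date")
  n <- nrow(ptab)
  i_d <- match(dxw$person_id, ptab$person_id)
  keep <- !is.na(i_d); dxw <- dxw[keep, , drop = FALSE]; i_d <- i_d[keep]
  i_r <- match(rxw$person_id, ptab$person_id)
  keep <- !is.na(i_r); rxw <- rxw[keep, , drop = FALSE]; i_r <- i_r[keep]
  has_dx <- rep(FALSE, n)
  has_dx[unique(i_d[matches_prefix(dxw$icd10_code, codes$asthma_icd)])] <- TRUE
  qr <- matches_prefix(rxw$atc_code, codes$asthma_atc)
  ages <- as.numeric(as.Date(rxw$dispense_date) - study_window[1])
  rxp <- first_two_ages(i_r[qr], ages[qr], n)
  rx_ok <- is.finite(rxp$second) &
    (rxp$second - rxp$first) <= codes$repeat_window_days
  parent_case <- has_dx | rx_ok
  pm <- parent_case[match(persons$mother_id, ptab$person_id)]
  pf <- parent_case[match(persons$father_id, ptab$person_id)]
  pm[is.na(pm)] <- FALSE; pf[is.na(pf)] <- FALSE
  data.frame(person_id = persons$person_id,
             parental_asthma = as.numeric(pm | pf),
             stringsAsFactors = FALSE)
}
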