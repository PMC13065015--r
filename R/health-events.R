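# Latent outcome model and event-stream emission.
#
# Latent onset ages follow a piecewise-constant hazard on age with knots at
# 36 months and 6 years, multiplied by the child's exposure-group hazard
# ratio, covariate log-hazard shifts and (optionally) a shared maternal
# frailty. An onset observable before censoring emits diagnosis and/or
# dispensation streams constructed to satisfy the corresponding phenotyping
# algorithm with incident age exactly at onset; noise streams are
# constructed never to satisfy any algorithm, so the generator's latent
# labels are recoverable exactly.

# nominal knots (days) and relative per-day hazard weights of the three
# age segments [0,3y), [3,6y), [6,12y)
ONSET_KNOTS <- c(0, 1096, 2192, 4383)
ONSET_WEIGHTS <- c(1, 0.45, 0.18)

# unit-scale cumulative baseline hazard at day t (vectorized)
unit_cumhaz <- function(t) {
  L <- diff(ONSET_KNOTS)
  cums <- c(0, cumsum(ONSET_WEIGHTS * L))
  seg <- findInterval(t, ONSET_KNOTS, rightmost.closed = FALSE)
  seg <- pmin(pmax(seg, 1L), 3L)
  cums[seg] + ONSET_WEIGHTS[seg] * (pmin(t, ONSET_KNOTS[4]) - ONSET_KNOTS[seg])
}

# inverse of unit_cumhaz; returns Inf beyond the last knot
unit_cumhaz_inv <- function(h) {
  L <- diff(ONSET_KNOTS)
  cums <- c(0, cumsum(ONSET_WEIGHTS * L))
  seg <- findInterval(h, cums, rightmost.closed = FALSE)
  seg <- pmin(pmax(seg, 1L), 3L)
  t <- ONSET_KNOTS[seg] + (h - cums[seg]) / ONSET_WEIGHTS[seg]
  ifelse(h >= cums[4], Inf, t)
}

# scale c such that mean over lp of 1 - exp(-exp(lp) * c * Hcap) = target
calibrate_scale <- function(lp, Hcap, target) {
  if (target <= 0 || target >= 1)
    stop_config("baseline_cuminc targets must lie in (0, 1)")
  f <- function(cc) mean(1 - exp(-exp(lp) * cc * Hcap)) - target
  upper <- 1e-6
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 10
  stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

#' Generate health-event streams for a synthetic population
#'
#' Draws latent wheeze and asthma onset ages from the piecewise-constant
#' hazard model, draws deaths and emigrations, and emits ICD-10/ATC event
#' streams (plus parental streams encoding the latent parental-asthma
#' indicator). The background-group cumulative incidence by the outcome age
#' cap is calibrated to `config$baseline_cuminc` absent censoring. Latent
#' case labels and onset ages are stored in `bundle$latent` so that the
#' generator/phenotyper contract can be verified.
#'
#' @param bundle a `register_bundle` from [generate_population()]
#' @param config the same [sim_config()]
#' @return the bundle with `diagnoses`, `dispensations`, `vitals`,
#'   `parent_diagnoses`, `parent_dispensations` populated and latent labels
#'   (`wheeze_case`, `wheeze_age`, `asthma_case`, `asthma_age`,
#'   `asthma3plus_case`, `death_age`, `emigration_age`) added to
#'   `bundle$latent`
#' @export
generate_health_events <- function(bundle, config) {
  stopifnot(inherits(bundle, "register_bundle"))
  nk <- nrow(bundle$persons)
  if (nk == 0L) return(bundle)
  with_seed(child_seed(config$seed, "events"), {
    p <- bundle$persons
    lat <- bundle$latent
    group <- match(lat$exposure, EXPOSURE_LEVELS)

    ce <- config$covariate_effects
    eff <- function(nm) if (nm %in% names(ce)) ce[[nm]] else 0
    lp_cov <- eff("smoking") * lat$smoking_true +
      eff("parental_asthma") * lat$parental_asthma +
      eff("sex_male") * (p$sex == "male") +
      eff("foreign_born") * p$foreign_born_parent
    lp_cov[is.na(lp_cov)] <- 0
    lp_cov <- as.numeric(lp_cov) + lat$frailty

    hr_a <- config$true_hr$asthma
    hr_w <- config$true_hr$wheeze
    lp_a <- lp_cov + log(hr_a[group])
    lp_w <- lp_cov + log(hr_w[group])

    cap3 <- age_days(p$birth_date, add_years(p$birth_date, 3L))
    cap12 <- age_days(p$birth_date, add_years(p$birth_date, 12L))
    admin_days <- as.integer(config$admin_end - p$birth_date) + 1L

    bg <- group == 1L
    lp_ref_a <- if (any(bg)) lp_a[bg] else lp_cov
    lp_ref_w <- if (any(bg)) lp_w[bg] else lp_cov

    # asthma latent onset
    Hcap12 <- unit_cumhaz(ONSET_KNOTS[4])
    c_a <- calibrate_scale(lp_ref_a, Hcap12, config$baseline_cuminc["asthma"])
    onset_a <- pmax(1, floor(unit_cumhaz_inv(stats::rexp(nk) / (exp(lp_a) * c_a))))

    # wheeze latent onset, net of asthma-induced early events: total
    # background wheeze incidence by 36 months targets baseline_cuminc
    pa3 <- mean(1 - exp(-exp(lp_ref_a) * c_a * unit_cumhaz(ONSET_KNOTS[2])))
    tw <- config$baseline_cuminc["wheeze"]
    pw <- if (tw > pa3) 1 - (1 - tw) / (1 - pa3) else 0
    onset_w <- rep(Inf, nk)
    if (pw > 0) {
      Hcap3 <- unit_cumhaz(ONSET_KNOTS[2])
      c_w <- calibrate_scale(lp_ref_w, Hcap3, pw)
      onset_w <- pmax(1, floor(unit_cumhaz_inv(stats::rexp(nk) / (exp(lp_w) * c_w))))
      onset_w[onset_w >= ONSET_KNOTS[2]] <- Inf
    }

    # vital events
    death_age <- rep(Inf, nk)
    dies <- stats::runif(nk) < config$death_rate
    death_age[dies] <- 1L + floor(stats::runif(sum(dies)) *
                                  pmax(admin_days[dies] - 1L, 1L))
    emig_age <- rep(Inf, nk)
    emig <- stats::runif(nk) < config$emigration_rate
    emig_age[emig] <- 1L + floor(stats::runif(sum(emig)) *
                                 pmax(admin_days[emig] - 1L, 1L))
    emig_age[emig_age >= death_age] <- Inf
    censor <- pmin(death_age, emig_age, admin_days)

    # observable cases
    a_case <- is.finite(onset_a) & onset_a < pmin(censor, cap12)
    w_own <- is.finite(onset_w) & onset_w < pmin(censor, cap3)
    w_from_a <- a_case & onset_a < cap3
    w_case <- w_own | w_from_a
    w_age <- ifelse(w_case,
                    pmin(ifelse(w_own, onset_w, Inf),
                         ifelse(w_from_a, onset_a, Inf)), NA_real_)

    # asthma emission route and persistence
    bound12 <- pmin(censor, cap12)   # events must be < bound12
    room12 <- bound12 - onset_a      # > 1 needed for an rx repeat
    persist <- a_case & (onset_a >= cap3 |
      (stats::runif(nk) < config$persist_prob & bound12 - 1L > cap3))
    # for non-persistent early cases the repeat must stay before 36 months
    bound_rep <- ifelse(a_case & onset_a < cap3 & !persist,
                        pmin(censor, cap3), bound12)
    room_rep <- bound_rep - onset_a
    want_dx <- stats::runif(nk) < 0.4
    route_dx <- a_case & (want_dx | room_rep < 2L)

    pid <- p$person_id
    dx_pid <- character(0); dx_age <- numeric(0); dx_code <- character(0)
    rx_pid <- character(0); rx_age <- numeric(0)

    # asthma: diagnosis route
    i <- which(route_dx)
    dx_pid <- c(dx_pid, pid[i]); dx_age <- c(dx_age, onset_a[i])
    dx_code <- c(dx_code, rep("J45.9", length(i)))
    # asthma: dispensation route, first + repeat
    j <- which(a_case & !route_dx)
    delta <- 1L + floor(stats::runif(length(j)) *
                        pmin(365, room_rep[j] - 1L))
    rx_pid <- c(rx_pid, pid[j], pid[j])
    rx_age <- c(rx_age, onset_a[j], onset_a[j] + delta)
    # persistence event after 36 months for early-onset persistent cases
    k <- which(persist & onset_a < cap3)
    if (length(k)) {
      page <- cap3[k] + floor(stats::runif(length(k)) *
                              pmax(bound12[k] - cap3[k], 1L))
      page <- pmin(page, bound12[k] - 1L)
      rx_pid <- c(rx_pid, pid[k]); rx_age <- c(rx_age, page)
    }
    # occasional extra confirmatory diagnosis for persistent cases
    e <- which(persist & stats::runif(nk) < 0.3 & room12 > 1L)
    if (length(e)) {
      eage <- onset_a[e] + floor(stats::runif(length(e)) * (room12[e] - 1L))
      dx_pid <- c(dx_pid, pid[e]); dx_age <- c(dx_age, eage)
      dx_code <- c(dx_code, rep("J45.9", length(e)))
    }

    # wheeze-only onsets: acute lower-respiratory-infection diagnoses
    w <- which(w_own)
    if (length(w)) {
      code <- sample(c("J20.9", "J21.0", "J21.9", "J22"),
                     length(w), replace = TRUE)
      dx_pid <- c(dx_pid, pid[w]); dx_age <- c(dx_age, onset_w[w])
      dx_code <- c(dx_code, code)
    }

    # noise events (never satisfy an algorithm)
    if (config$noise_rate > 0) {
      lam <- config$noise_rate / 3
      # (1) isolated unrepeated dispensation after 36 months, non-cases only
      n1 <- which(!a_case & censor - 1L > cap3 &
                  stats::runif(nk) < (1 - exp(-lam)))
      if (length(n1)) {
        age1 <- cap3[n1] + floor(stats::runif(length(n1)) *
                                 pmax(censor[n1] - 1L - cap3[n1], 1L))
        rx_pid <- c(rx_pid, pid[n1]); rx_age <- c(rx_age, age1)
      }
      # (2) respiratory-infection diagnoses after 36 months, anyone
      k2 <- stats::rpois(nk, lam)
      k2[censor - 1L <= cap3] <- 0L
      n2 <- rep(seq_len(nk), k2)
      if (length(n2)) {
        age2 <- cap3[n2] + floor(stats::runif(length(n2)) *
                                 pmax(censor[n2] - 1L - cap3[n2], 1L))
        dx_pid <- c(dx_pid, pid[n2]); dx_age <- c(dx_age, age2)
        dx_code <- c(dx_code, sample(c("J20.9", "J22"), length(n2),
                                     replace = TRUE))
      }
      # (3) extra infant infections for existing wheeze cases
      k3 <- stats::rpois(nk, lam)
      k3[!w_case] <- 0L
      room3 <- pmin(cap3, censor) - ifelse(w_case, w_age, Inf) - 1L
      k3[!is.finite(room3) | room3 < 1L] <- 0L
      n3 <- rep(seq_len(nk), k3)
      if (length(n3)) {
        age3 <- w_age[n3] + 1L + floor(stats::runif(length(n3)) * room3[n3])
        dx_pid <- c(dx_pid, pid[n3]); dx_age <- c(dx_age, age3)
        dx_code <- c(dx_code, sample(c("J20.9", "J21.9"), length(n3),
                                     replace = TRUE))
      }
    }

    birth_for <- p$birth_date[match(dx_pid, pid)]
    diagnoses <- data.frame(
      person_id = dx_pid,
      event_date = birth_for + as.integer(dx_age),
      icd10_code = dx_code,
      source = sample(c("inpatient", "outpatient"), length(dx_pid),
                      replace = TRUE, prob = c(0.15, 0.85)),
      stringsAsFactors = FALSE)
    dispensations <- data.frame(
      person_id = rx_pid,
      dispense_date = p$birth_date[match(rx_pid, pid)] + as.integer(rx_age),
      atc_code = sample(c("R03AC02", "R03BA02", "R03AK06", "R03DC03"),
                        length(rx_pid), replace = TRUE),
      stringsAsFactors = FALSE)

    vit_i <- which(is.finite(death_age))
    vit_j <- which(is.finite(emig_age))
    vitals <- data.frame(
      person_id = c(pid[vit_i], pid[vit_j]),
      event_date = c(p$birth_date[vit_i] + as.integer(death_age[vit_i]),
                     p$birth_date[vit_j] + as.integer(emig_age[vit_j])),
      kind = c(rep("death", length(vit_i)), rep("emigration", length(vit_j))),
      stringsAsFactors = FALSE)

    # parental event streams encoding the family parental-asthma flag
    par <- build_parent_events(p, lat, config)

    ord <- order(diagnoses$person_id, diagnoses$event_date,
                 diagnoses$icd10_code)
    bundle$diagnoses <- diagnoses[ord, , drop = FALSE]
    ord <- order(dispensations$person_id, dispensations$dispense_date,
                 dispensations$atc_code)
    bundle$dispensations <- dispensations[ord, , drop = FALSE]
    bundle$vitals <- vitals[order(vitals$person_id, vitals$event_date), ,
                            drop = FALSE]
    rownames(bundle$diagnoses) <- rownames(bundle$dispensations) <-
      rownames(bundle$vitals) <- NULL
    bundle$parent_diagnoses <- par$diagnoses
    bundle$parent_dispensations <- par$dispensations

    lat$wheeze_case <- w_case
    lat$wheeze_age <- ifelse(w_case, w_age, NA_real_)
    lat$asthma_case <- a_case
    lat$asthma_age <- ifelse(a_case, onset_a, NA_real_)
    lat$asthma3plus_case <- persist
    lat$death_age <- ifelse(is.finite(death_age), death_age, NA_real_)
    lat$emigration_age <- ifelse(is.finite(emig_age), emig_age, NA_real_)
    bundle$latent <- lat
    bundle
  })
}

build_parent_events <- function(p, lat, config) {
  fam <- !duplicated(p$mother_id)
  mid <- p$mother_id[fam]; fid <- p$father_id[fam]
  has <- lat$parental_asthma[fam] == 1
  start <- as.Date("2006-01-01")
  span <- as.integer(config$admin_end - start) - 40L
  carrier <- sample(c("mother", "father", "both"), length(mid),
                    replace = TRUE, prob = c(0.4, 0.4, 0.2))
  aff <- c(mid[has & carrier != "father"], fid[has & carrier != "mother"])
  d0 <- start + floor(stats::runif(length(aff)) * span)
  pdx <- data.frame(person_id = aff, event_date = d0,
                    icd10_code = rep("J45.9", length(aff)),
                    source = rep("outpatient", length(aff)),
                    stringsAsFactors = FALSE)
  prx <- data.frame(person_id = rep(aff, 2),
                    dispense_date = c(d0, d0 + 30L),
                    atc_code = rep("R03AC02", 2 * length(aff)),
                    stringsAsFactors = FALSE)
  # unaffected parents occasionally receive a single unrepeated dispensation
  un <- c(mid[!has], fid[!has], mid[has & carrier == "father"],
          fid[has & carrier == "mother"])
  un <- un[stats::runif(length(un)) < 0.08]
  if (length(un)) {
    prx <- rbind(prx, data.frame(
      person_id = un,
      dispense_date = start + floor(stats::runif(length(un)) * span),
      atc_code = rep("R03AC02", length(un)), stringsAsFactors = FALSE))
  }
  list(diagnoses = pdx[order(pdx$person_id, pdx$event_date), , drop = FALSE],
       dispensations = prx[order(prx$person_id, prx$dispense_date), ,
                           drop = FALSE])
}

#' Generate the serum PFAS biomarker validation cohort
#'
#' Draws per-participant serum PFOS/PFHxS/PFOA concentrations from
#' per-exposure-group lognormal distributions whose medians are calibrated
#' to the validation-cohort summary (e.g., median PFHxS 164.8 ng/mL in the
#' very-high group versus 0.8 ng/mL at background).
#'
#' @param config a [sim_config()]; `config$biomarker` holds per-group
#'   sample sizes, sampling years, lognormal medians and log-scale spreads
#' @param n_per_group optional single count overriding the per-group sample
#'   sizes (useful for calibration checks at large n)
#' @return data.frame with columns `person_id`, `sampling_year`,
#'   `exposure`, `pfos_ngml`, `pfhxs_ngml`, `pfoa_ngml`
#' @export
generate_biomarker_cohort <- function(config, n_per_group = NULL) {
  bm <- config$biomarker
  for (a in names(bm$median))
    if (any(bm$median[[a]] <= 0)) stop_config("biomarker medians must be > 0")
  if (any(unlist(bm$sdlog) < 0)) stop_config("sdlog must be nonnegative")
  n <- if (is.null(n_per_group)) bm$n[EXPOSURE_LEVELS]
       else stats::setNames(rep(n_per_group, 4), EXPOSURE_LEVELS)
  with_seed(child_seed(config$seed, "biomarker"), {
    grp <- rep(EXPOSURE_LEVELS, n)
    nt <- length(grp)
    draw <- function(analyte) {
      stats::rlnorm(nt, log(bm$median[[analyte]][grp]),
                    bm$sdlog[[analyte]][grp])
    }
    data.frame(
      person_id = sprintf("B%06d", seq_len(nt)),
      sampling_year = sample(bm$sampling_years, nt, replace = TRUE),
      exposure = grp,
      pfos_ngml = draw("pfos"),
      pfhxs_ngml = draw("pfhxs"),
      pfoa_ngml = draw("pfoa"),
      stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic register bundle
#'
#' Convenience wrapper running [generate_population()],
#' [generate_health_events()] and [generate_biomarker_cohort()].
#'
#' @param config a [sim_config()]
#' @return a `register_bundle` with a `biomarkers` element attached
#' @export
generate_registers <- function(config = sim_config()) {
  b <- generate_population(config)
  b <- generate_health_events(b, config)
  b$biomarkers <- generate_biomarker_cohort(config)
  b
}
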