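# Kaplan-Meier curves and Cox proportional-hazards models.
#
# Model contract: age (days) is the time axis; the baseline hazard is
# stratified by sex and parity (adjusted model) or sex alone (simple
# model); variance is a sandwich aggregated over maternal sibling clusters;
# ties use the Efron approximation; exposure enters as three indicator
# contrasts against background.

ADJUSTMENT_COVARIATES <- c("smoking", "education", "foreign_born",
                           "parental_asthma", "income_quartile",
                           "maternal_age_quartile")

#' Kaplan-Meier cumulative incidence curves
#'
#' Product-limit estimator of survival (and cumulative incidence
#' 1 - survival) per group.
#'
#' @param followups data.frame with `exit_age_days`, `event` and, unless
#'   `group` is `NULL`, the grouping column
#' @param group name of the grouping column (e.g. `"exposure"`), or `NULL`
#'   for a single overall curve
#' @return tidy data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, `cuminc`
#' @export
km_curve <- function(followups, group = "exposure") {
  if (any(followups$exit_age_days < 0))
    stop("negative follow-up times", call. = FALSE)
  if (is.null(group)) {
    followups$.g <- "all"
    group <- ".g"
  }
  g <- factor(followups[[group]])
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    sub <- followups[g == lv, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sf <- survival::survfit(
      survival::Surv(sub$exit_age_days, sub$event) ~ 1, conf.type = "none")
    data.frame(group = lv, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, survival = sf$surv,
               cuminc = 1 - sf$surv, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# KM cumulative incidence at the last observed time <= horizon
km_cuminc_at <- function(time, event, horizon) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "none")
  keep <- sf$time <= horizon
  if (!any(keep)) return(0)
  1 - min(sf$surv[keep])
}

exposure_term <- function(x) factor(as.character(x),
                                    levels = EXPOSURE_LEVELS)

#' Fit the cohort Cox proportional-hazards model
#'
#' @param cohort analysis cohort (complete cases) from
#'   [build_analysis_cohort()]
#' @param covariates adjustment covariate columns; `character(0)` gives the
#'   unadjusted (exposure-only) model
#' @param strata baseline-hazard strata columns (default sex and parity)
#' @param cluster cluster column for the robust sandwich variance (default
#'   maternal sibling clusters)
#' @param extra_terms optional extra model terms (character), e.g.
#'   interaction terms
#' @return object of class `cox_result`: the `survival::coxph` fit plus an
#'   HR table (`hr_table`), event/person-year tallies and convergence flags
#' @export
cox_fit <- function(cohort, covariates = ADJUSTMENT_COVARIATES,
                    strata = c("sex", "parity"), cluster = "cluster_id",
                    extra_terms = character(0)) {
  dat <- cohort
  dat$.exposure <- droplevels(exposure_term(dat$exposure))
  if (nlevels(droplevels(dat$.exposure)) < 2 && !length(covariates))
    stop("exposure is constant: inestimable", call. = FALSE)
  for (cl in covariates)
    if (length(unique(dat[[cl]][!is.na(dat[[cl]])])) < 2)
      stop(sprintf("covariate '%s' is constant: inestimable", cl),
           call. = FALSE)
  rhs <- c(".exposure", covariates, extra_terms,
           if (length(strata))
             sprintf("strata(%s)", paste(strata, collapse = ", ")))
  f <- stats::as.formula(paste(
    "Surv(exit_age_days, event) ~", paste(rhs, collapse = " + ")))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f, data = dat, ties = "efron",
                    cluster = dat[[cluster]], x = TRUE, y = TRUE),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))  # robust when cluster is used
  hr <- data.frame(term = names(co), coef = as.numeric(co),
                   robust_se = as.numeric(se),
                   hr = exp(as.numeric(co)),
                   lo95 = exp(as.numeric(co) - 1.96 * as.numeric(se)),
                   hi95 = exp(as.numeric(co) + 1.96 * as.numeric(se)),
                   row.names = NULL)
  structure(list(fit = fit, coefficients = co, vcov = stats::vcov(fit),
                 hr_table = hr, n = nrow(dat), n_event = sum(dat$event),
                 person_years = sum(dat$exit_age_days) / 365.25,
                 strata = strata, cluster = cluster,
                 converged = is.null(fit$info) ||
                   !isTRUE(grepl("did not converge",
                                 paste(flags, collapse = " "))),
                 flags = flags),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n=%d, events=%d, person-years=%.0f\n",
              x$n, x$n_event, x$person_years))
  print(x$hr_table, digits = 3)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Robust Wald test of a coefficient subset
#'
#' Quadratic form b' V^-1 b on the (cluster-robust) covariance of the
#' selected coefficients; chi-squared reference with df = number of terms.
#'
#' @param coefs named coefficient vector (or a `cox_result`)
#' @param vcov matching covariance matrix (ignored when `coefs` is a
#'   `cox_result`)
#' @param terms character vector of coefficient names, or a regular
#'   expression when `regex = TRUE`
#' @param regex interpret `terms` as a regular expression
#' @return list with `statistic`, `df`, `p_value`
#' @export
robust_wald <- function(coefs, vcov = NULL, terms, regex = FALSE) {
  if (inherits(coefs, "cox_result")) {
    vcov <- coefs$vcov
    coefs <- coefs$coefficients
  }
  sel <- if (regex) grep(terms, names(coefs), value = TRUE) else terms
  if (!length(sel)) stop("no coefficients selected", call. = FALSE)
  # drop aliased coefficients (risk-set-constant columns have no
  # information and a degenerate variance row)
  sel <- sel[!is.na(coefs[sel]) & diag(vcov)[sel] > 1e-12]
  if (!length(sel)) stop("no estimable coefficients selected",
                         call. = FALSE)
  b <- coefs[sel]
  V <- vcov[sel, sel, drop = FALSE]
  qf <- tryCatch(as.numeric(t(b) %*% solve(V, b)), error = function(e) {
    as.numeric(t(b) %*% MASS::ginv(V) %*% b)
  })
  df <- qr(V)$rank
  list(statistic = qf, df = df,
       p_value = stats::pchisq(qf, df, lower.tail = FALSE))
}

#' Proportional-hazards diagnostics
#'
#' Per-covariate scaled-Schoenfeld tests against Kaplan-Meier-transformed
#' time, plus a joint cluster-robust Wald test of exposure-by-time
#' interaction coefficients from a time-split refit.
#'
#' @param coxres a `cox_result`
#' @param cohort the cohort the model was fitted on
#' @param cut_quantiles follow-up-time quantiles at which the time-split
#'   refit cuts episodes (default deciles of event times)
#' @return list with `schoenfeld` (the `survival::cox.zph` table) and
#'   `exposure_wald` (joint test; `NULL` with an `undefined` flag when too
#'   few events)
#' @export
ph_diagnostics <- function(coxres, cohort,
                           cut_quantiles = seq(0.1, 0.9, by = 0.1)) {
  if (coxres$n_event < 10)
    return(list(schoenfeld = NULL, exposure_wald = NULL,
                undefined = TRUE))
  zph <- survival::cox.zph(coxres$fit, transform = "km")
  dat <- cohort
  dat$.exposure <- exposure_term(dat$exposure)
  cuts <- unique(stats::quantile(dat$exit_age_days[dat$event == 1],
                                 probs = cut_quantiles))
  split <- survival::survSplit(
    Surv(exit_age_days, event) ~ ., data = dat, cut = cuts,
    episode = ".episode")
  # KM transform evaluated at the episode start: a step-function
  # time-varying coefficient, constant within each risk set (the
  # background-level interaction column is then risk-set-constant and
  # drops out as NA, leaving the three exposure-specific time trends)
  sf <- survival::survfit(survival::Surv(exit_age_days, event) ~ 1,
                          data = dat, conf.type = "none")
  kmfun <- stats::stepfun(sf$time, c(1, sf$surv))
  split$.gt <- 1 - kmfun(split$tstart)
  rhs <- attr(stats::terms(coxres$fit$formula), "term.labels")
  rhs <- setdiff(rhs, ".exposure")
  f <- stats::as.formula(paste(
    "Surv(tstart, exit_age_days, event) ~ .exposure + .exposure:.gt",
    if (length(rhs)) paste("+", paste(rhs, collapse = " + ")) else ""))
  flags <- character(0)
  fit2 <- withCallingHandlers(
    survival::coxph(f, data = split, ties = "efron",
                    cluster = split[[coxres$cluster]]),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit2)
  keep <- grepl("^\\.exposure.*:\\.gt$", names(co)) & !is.na(co)
  wald <- robust_wald(co[!is.na(co)], stats::vcov(fit2)[!is.na(co),
                                                        !is.na(co)],
                      names(co)[keep])
  list(schoenfeld = zph, exposure_wald = wald, undefined = FALSE,
       flags = flags)
}

#' Sex-by-exposure interaction test and sex-stratified fits
#'
#' Joint cluster-robust Wald test of the three exposure-by-sex interaction
#' coefficients (sex main effect absorbed by the stratified baseline), and
#' per-sex refits of the adjusted model.
#'
#' @param cohort analysis cohort (complete cases)
#' @param covariates adjustment covariates
#' @return list with `wald` and `by_sex` (list of `cox_result` per sex,
#'   parity-stratified)
#' @export
interaction_wald <- function(cohort, covariates = ADJUSTMENT_COVARIATES) {
  fit <- cox_fit(cohort, covariates = covariates,
                 strata = c("sex", "parity"),
                 extra_terms = ".exposure:sex")
  co <- fit$coefficients
  terms <- grep("^\\.exposure.*:sex", names(co), value = TRUE)
  ok <- terms[!is.na(co[terms])]
  wald <- robust_wald(fit, terms = ok)
  by_sex <- lapply(stats::setNames(nm = levels(factor(cohort$sex))),
                   function(s)
    cox_fit(cohort[cohort$sex == s, , drop = FALSE],
            covariates = covariates, strata = "parity"))
  list(wald = wald, by_sex = by_sex, fit = fit)
}
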