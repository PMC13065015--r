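# One-call pipeline orchestration and publication-shaped report tables.

#' Rounded percentage as printed in report tables
#'
#' @param n numerator count
#' @param d denominator count
#' @param digits decimal places (default 0, matching "50/194 -> 26")
#' @return numeric percentage rounded to `digits`
#' @export
pct_round <- function(n, d, digits = 0) round(100 * n / d, digits)

#' Cumulative-incidence difference in percentage points
#'
#' @param treated_pct,control_pct cumulative incidences in percent
#' @param digits decimal places (default 1)
#' @return rounded difference in percentage points
#' @export
cuminc_difference_pp <- function(treated_pct, control_pct, digits = 1)
  round(treated_pct - control_pct, digits)

#' Baseline-characteristics table
#'
#' N with percentages (or median \[IQR\] for continuous variables) overall
#' and per exposure group.
#'
#' @param cohort complete-case analysis cohort
#' @return data.frame, one row per characteristic
#' @export
baseline_table <- function(cohort) {
  grp <- exposure_term(cohort$exposure)
  cols <- c(list(Overall = rep(TRUE, nrow(cohort))),
            stats::setNames(lapply(EXPOSURE_LEVELS, function(g) grp == g),
                            EXPOSURE_LEVELS))
  npct <- function(flag) vapply(cols, function(sel) {
    n <- sum(flag[sel], na.rm = TRUE)
    sprintf("%d (%.1f)", n, 100 * n / sum(sel))
  }, character(1))
  medi <- function(x) vapply(cols, function(sel) {
    q <- stats::quantile(x[sel], c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
  }, character(1))
  rows <- list(
    N = vapply(cols, function(sel) sprintf("%d", sum(sel)), character(1)),
    `Maternal smoking (yes)` = npct(cohort$smoking == 1),
    `Parity (multiparous)` = npct(cohort$parity == "multiparous"),
    `Sex (female)` = npct(cohort$sex == "female"),
    `Education: primary` = npct(cohort$education == "primary"),
    `Education: secondary` = npct(cohort$education == "secondary"),
    `Education: post-secondary` = npct(cohort$education == "post_secondary"),
    `Maternal age at delivery` = medi(cohort$maternal_age),
    `Foreign-born parent (yes)` = npct(cohort$foreign_born == 1),
    `Family income (SEK 1e5)` = medi(cohort$family_income),
    `Parental asthma (yes)` = npct(cohort$parental_asthma == 1))
  out <- data.frame(variable = names(rows),
                    do.call(rbind, rows), row.names = NULL,
                    check.names = FALSE)
  names(out)[-1] <- c("Overall", EXPOSURE_LEVELS)
  out
}

#' Hazard-ratio table for one outcome
#'
#' Events, person-years, and simple (sex-stratified, exposure-only) plus
#' adjusted (sex-by-parity-stratified, covariate-adjusted) hazard ratios
#' with 95% confidence intervals per exposure level versus background.
#'
#' @param cohort complete-case cohort for one outcome
#' @return list with the formatted `table` and the two `cox_result`s
#' @export
hr_table <- function(cohort) {
  simple <- cox_fit(cohort, covariates = character(0), strata = "sex")
  adjusted <- cox_fit(cohort)
  grp <- exposure_term(cohort$exposure)
  fmt <- function(fit, lev) {
    term <- paste0(".exposure", lev)
    r <- fit$hr_table[fit$hr_table$term == term, ]
    if (!nrow(r)) return("-")
    sprintf("%.2f (%.2f, %.2f)", r$hr, r$lo95, r$hi95)
  }
  rows <- lapply(EXPOSURE_LEVELS, function(lev) {
    sel <- grp == lev
    data.frame(
      exposure = lev,
      events = sum(cohort$event[sel]),
      events_pct = pct_round(sum(cohort$event[sel]), sum(sel)),
      person_years = round(sum(cohort$exit_age_days[sel]) / 365.25),
      hr_simple = if (lev == "background") "-" else fmt(simple, lev),
      hr_adjusted = if (lev == "background") "-" else fmt(adjusted, lev),
      stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), simple = simple, adjusted = adjusted)
}

#' Outcome-combination counts
#'
#' Tallies the combinations of the three outcomes among children with at
#' least one outcome (UpSet-style underlying table).
#'
#' @param pheno output of [ascertain_outcomes()]
#' @return data.frame with `combination` and `n`
#' @export
outcome_overlap <- function(pheno) {
  flags <- cbind(wheeze = pheno$wheeze_case, asthma = pheno$asthma_case,
                 asthma3plus = pheno$asthma3plus_case)
  any1 <- rowSums(flags) > 0
  combo <- apply(flags[any1, , drop = FALSE], 1, function(r)
    paste(colnames(flags)[r], collapse = "+"))
  tab <- sort(table(combo), decreasing = TRUE)
  data.frame(combination = names(tab), n = as.integer(tab),
             row.names = NULL)
}

#' Run the full analysis pipeline
#'
#' simulate -> classify -> phenotype -> build -> fit -> impute/pool ->
#' match/test -> validate, with one root seed governing every stage.
#'
#' @param config a [sim_config()], or a path to a JSON file whose fields
#'   are passed to [sim_config()]
#' @param outcomes outcomes to analyse
#' @param n_perm randomization-test permutations
#' @param m imputed datasets (and `iterations` chained sweeps each)
#' @param iterations chained-equation sweeps per dataset
#' @param skip_imputation,skip_matching stage switches
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV/JSON
#' @param verbose log stage progress to stderr
#' @return a `report_bundle` list: `baseline`, per-outcome `hr`, `km`,
#'   `pooled`, `matched`, `balance`, `overlap`, `trend_tests`,
#'   `missingness`, `ph_tests`, `meta`
#' @export
run_pipeline <- function(config = sim_config(),
                         outcomes = OUTCOMES,
                         n_perm = 10000L, m = 20L, iterations = 20L,
                         skip_imputation = FALSE, skip_matching = FALSE,
                         out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) {
    config <- do.call(sim_config, jsonlite::fromJSON(config))
  }
  stopifnot(inherits(config, "sim_config"))
  log <- function(...) if (verbose) message(sprintf(...))

  log("simulate: n=%d children", config$n_children)
  bundle <- generate_registers(config)
  pheno <- ascertain_outcomes(bundle$persons, bundle$diagnoses,
                              bundle$dispensations)

  report <- list(meta = list(seed = config$seed,
                             n_children = config$n_children,
                             admin_end = as.character(config$admin_end),
                             timestamp = format(Sys.time())),
                 hr = list(), km = list(), pooled = list(),
                 matched = list(), balance = list(), ph_tests = list())

  for (oc in outcomes) {
    log("build/fit: %s", oc)
    cohort <- build_analysis_cohort(bundle, outcome = oc)
    split <- complete_case_split(cohort)
    cc <- split$complete
    if (oc == outcomes[1]) {
      report$baseline <- baseline_table(cc)
      report$missingness <- split$report
      report$retained_fraction <- split$retained_fraction
    }
    hr <- hr_table(cc)
    report$hr[[oc]] <- hr$table
    report$km[[oc]] <- km_curve(cc)
    report$ph_tests[[oc]] <- tryCatch(
      ph_diagnostics(hr$adjusted, cc)$exposure_wald,
      error = function(e) NULL)
    if (!skip_imputation) {
      log("impute/pool: %s", oc)
      stack <- run_chained_imputation(cohort, m = m,
                                      iterations = iterations,
                                      seed = child_seed(config$seed,
                                                        paste0("mice-", oc)))
      report$pooled[[oc]] <- pool_cox(stack)$pooled
    }
    if (!skip_matching) {
      log("match/test: %s", oc)
      ma <- matched_analysis(cc, n_perm = n_perm,
                             seed = child_seed(config$seed,
                                               paste0("match-", oc)))
      report$matched[[oc]] <- data.frame(
        outcome = oc, t_obs_pp = ma$result$t_obs,
        p_one_sided = ma$result$p_value, n_perm = ma$result$n_perm,
        n_treated = sum(ma$matched$treated == 1),
        n_controls = sum(ma$matched$treated == 0))
      report$balance[[oc]] <- ma$balance
    }
  }
  report$overlap <- outcome_overlap(pheno)
  report$trend_tests <- biomarker_trend_tests(bundle$biomarkers)
  class(report) <- "report_bundle"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  wr(report$baseline, "baseline")
  wr(report$missingness, "missingness")
  wr(report$overlap, "outcome_overlap")
  wr(report$trend_tests, "trend_tests")
  for (oc in names(report$hr)) wr(report$hr[[oc]], paste0("hr_", oc))
  for (oc in names(report$km)) wr(report$km[[oc]], paste0("km_", oc))
  for (oc in names(report$pooled))
    wr(report$pooled[[oc]], paste0("pooled_", oc))
  for (oc in names(report$balance))
    wr(report$balance[[oc]], paste0("balance_", oc))
  if (length(report$matched))
    wr(do.call(rbind, report$matched), "matched_results")
  jsonlite::write_json(report$meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(sprintf("  outcomes: %s\n", paste(names(x$hr), collapse = ", ")))
  if (length(x$matched))
    print(do.call(rbind, x$matched), digits = 3)
  invisible(x)
}
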