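# Validation statistics: ordered trend test for the exposure proxy and
# sensitivity/specificity of the outcome algorithms against a gold
# standard.

jt_statistic <- function(groups) {
  J <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      xi <- groups[[i]]; xj <- groups[[j]]
      # between-group Mann-Whitney count with half credit for ties
      J <- J + sum(outer(xi, xj, `<`)) + 0.5 * sum(outer(xi, xj, `==`))
    }
  }
  J
}

# enumerate all distinct assignments of `values` into groups of sizes `ns`
jt_enumerate <- function(values, ns) {
  out <- numeric(0)
  recurse <- function(idx, sizes, acc) {
    if (!length(sizes)) {
      out[length(out) + 1L] <<- jt_statistic(acc)
      return(invisible())
    }
    picks <- if (length(idx) == 1L) list(idx)
             else utils::combn(idx, sizes[1], simplify = FALSE)
    for (p in picks)
      recurse(setdiff(idx, p), sizes[-1], c(acc, list(values[p])))
  }
  recurse(seq_along(values), ns, list())
  out
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' Tests for a monotone trend in a continuous response across ordered
#' categories (here, serum PFAS concentration across exposure levels).
#' J sums between-group Mann-Whitney counts over all ordered group pairs,
#' with half credit for ties. The null distribution is enumerated exactly
#' when the total sample size is at most `exact_max` (and the arrangement
#' count is tractable); otherwise a tie-corrected normal approximation is
#' used.
#'
#' @param values numeric response vector
#' @param groups ordered group labels aligned with `values` (coerced to an
#'   ordered factor in the order of first appearance unless already a
#'   factor)
#' @param alternative `"increasing"` (default) or `"decreasing"`
#' @param exact_max total-n threshold for exact enumeration (default 10)
#' @return list with `J`, `z` (tie-corrected; `NA` under exact
#'   enumeration), `p_value` (one-sided), `exact`
#' @export
jonckheere_terpstra <- function(values, groups,
                                alternative = c("increasing", "decreasing"),
                                exact_max = 10L) {
  alternative <- match.arg(alternative)
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop_config("need at least 2 non-empty groups")
  if (alternative == "decreasing")
    groups <- factor(groups, levels = rev(levels(groups)), ordered = TRUE)
  gl <- split(values, groups)
  ns <- lengths(gl)
  N <- sum(ns)
  J <- jt_statistic(gl)

  n_arrangements <- exp(lgamma(N + 1) - sum(lgamma(ns + 1)))
  if (N <= exact_max && n_arrangements <= 2e5) {
    null <- jt_enumerate(unlist(gl, use.names = FALSE), as.integer(ns))
    return(list(J = J, z = NA_real_,
                p_value = mean(null >= J - 1e-9), exact = TRUE))
  }
  # tie-corrected normal approximation
  mu <- (N^2 - sum(ns^2)) / 4
  tj <- table(values)
  t1 <- sum(ns * (ns - 1) * (2 * ns + 5))
  u1 <- sum(tj * (tj - 1) * (2 * tj + 5))
  t2 <- sum(ns * (ns - 1) * (ns - 2))
  u2 <- sum(tj * (tj - 1) * (tj - 2))
  t3 <- sum(ns * (ns - 1))
  u3 <- sum(tj * (tj - 1))
  v <- (N * (N - 1) * (2 * N + 5) - t1 - u1) / 72 +
    t2 * u2 / (36 * N * (N - 1) * (N - 2)) +
    t3 * u3 / (8 * N * (N - 1))
  if (v <= 0) return(list(J = J, z = 0, p_value = 1, exact = FALSE))
  z <- (J - mu) / sqrt(v)
  list(J = J, z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
       exact = FALSE)
}

#' Trend tests for the biomarker validation cohort
#'
#' Runs [jonckheere_terpstra()] for each serum analyte across the ordered
#' exposure categories.
#'
#' @param biomarkers data.frame from [generate_biomarker_cohort()] (needs
#'   `exposure` plus the `*_ngml` columns)
#' @return data.frame with one row per analyte: `analyte`, `J`, `z`,
#'   `p_value`, `exact`
#' @export
biomarker_trend_tests <- function(biomarkers) {
  analytes <- grep("_ngml$", names(biomarkers), value = TRUE)
  grp <- exposure_factor(biomarkers$exposure)
  do.call(rbind, lapply(analytes, function(a) {
    r <- jonckheere_terpstra(biomarkers[[a]], grp)
    data.frame(analyte = sub("_ngml$", "", a), J = r$J, z = r$z,
               p_value = r$p_value, exact = r$exact)
  }))
}

#' Sensitivity and specificity against a gold standard
#'
#' @param test logical/0-1 vector of algorithm case flags
#' @param gold matching vector of gold-standard case flags
#' @return list with the confusion table (`TP`, `FP`, `TN`, `FN`),
#'   `sensitivity`, `specificity` and `undefined` flags for empty classes
#' @export
confusion_metrics <- function(test, gold) {
  if (length(test) != length(gold))
    stop_config("test and gold standard must cover the same children")
  test <- as.logical(test); gold <- as.logical(gold)
  TP <- sum(test & gold); FN <- sum(!test & gold)
  TN <- sum(!test & !gold); FP <- sum(test & !gold)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = sens, specificity = spec,
       undefined = c(sensitivity = TP + FN == 0,
                     specificity = TN + FP == 0))
}
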