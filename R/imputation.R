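# Chained-equation multiple imputation with survival-appropriate
# predictors, and Rubin's-rules pooling.
#
# The chained-equation core follows the conventional fully-conditional
# specification: binary smoking by Bayesian logistic draws, 3-level
# education by multinomial draws, continuous income by type-1 predictive
# mean matching (5 donors). Every conditional model includes the
# outcome-specific event indicator and the Nelson-Aalen cumulative-hazard
# value at the subject's exit, as survival-compatible imputation requires.

#' Nelson-Aalen cumulative hazard at each subject's exit
#'
#' Marginal (whole-cohort) Nelson-Aalen increments d/n summed through each
#' subject's own exit time (inclusive).
#'
#' @param followups data.frame with `exit_age_days` and `event`
#' @return numeric vector, one value per row of `followups`
#' @export
nelson_aalen_at_exit <- function(followups) {
  t <- followups$exit_age_days
  if (any(t < 0)) stop("negative follow-up times", call. = FALSE)
  if (!nrow(followups)) return(numeric(0))
  sf <- survival::survfit(survival::Surv(t, followups$event) ~ 1,
                          conf.type = "none")
  if (!length(sf$time)) return(rep(0, length(t)))
  stats::stepfun(sf$time, c(0, sf$cumhaz))(t)
}

IMPUTED_VARS <- c("smoking", "education", "family_income")

imp_predictor_frame <- function(dat) {
  data.frame(
    exposure = exposure_term(dat$exposure),
    sex = dat$sex, parity = dat$parity,
    foreign_born = dat$foreign_born,
    parental_asthma = dat$parental_asthma,
    maternal_age = dat$maternal_age,
    event = dat$event,
    na_hazard = dat$.na_hazard,
    smoking = dat$smoking,
    education = dat$education,
    family_income = dat$family_income)
}

draw_logistic <- function(df, target, miss) {
  f <- stats::as.formula(paste(target, "~ ."))
  fit <- tryCatch(
    suppressWarnings(stats::glm(f, data = df, family = stats::binomial(),
                                subset = !miss)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(sample(df[[target]][!miss], sum(miss), replace = TRUE))
  beta <- MASS::mvrnorm(1, stats::coef(fit), stats::vcov(fit))
  X <- stats::model.matrix(f, data = df[miss, , drop = FALSE])
  p <- stats::plogis(drop(X %*% beta))
  as.numeric(stats::runif(sum(miss)) < p)
}

draw_multinomial <- function(df, target, miss) {
  f <- stats::as.formula(paste(target, "~ ."))
  fit <- tryCatch(
    suppressWarnings(nnet::multinom(f, data = df[!miss, , drop = FALSE],
                                    trace = FALSE)),
    error = function(e) NULL)
  lev <- levels(df[[target]])
  if (is.null(fit))
    return(sample(df[[target]][!miss], sum(miss), replace = TRUE))
  co <- stats::coef(fit)                       # (K-1) x p
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(V)) {
    drawn <- tryCatch(MASS::mvrnorm(1, as.vector(t(co)), V),
                      error = function(e) as.vector(t(co)))
    co <- matrix(drawn, nrow = nrow(co), byrow = TRUE,
                 dimnames = dimnames(co))
  }
  X <- stats::model.matrix(stats::as.formula(paste("~", paste(
    setdiff(names(df), target), collapse = "+"))),
    data = df[miss, , drop = FALSE])
  eta <- cbind(0, X %*% t(co[, colnames(X), drop = FALSE]))
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  idx <- apply(pr, 1, function(p) sample.int(length(lev), 1, prob = p))
  factor(lev[idx], levels = lev)
}

draw_pmm <- function(df, target, miss, donors = 5L) {
  f <- stats::as.formula(paste(target, "~ ."))
  fit <- tryCatch(stats::lm(f, data = df, subset = !miss),
                  error = function(e) NULL)
  yobs <- df[[target]][!miss]
  if (is.null(fit)) return(sample(yobs, sum(miss), replace = TRUE))
  n <- sum(!miss); pcoef <- length(stats::coef(fit))
  s2 <- sum(stats::residuals(fit)^2) /
    stats::rchisq(1, max(n - pcoef, 1))
  Vb <- stats::vcov(fit) * s2 / stats::sigma(fit)^2
  beta <- MASS::mvrnorm(1, stats::coef(fit), Vb)
  Xo <- stats::model.matrix(f, df[!miss, , drop = FALSE])
  Xm <- stats::model.matrix(f, df[miss, , drop = FALSE])
  pred_obs <- drop(Xo %*% stats::coef(fit))
  pred_mis <- drop(Xm %*% beta)
  vapply(pred_mis, function(ph) {
    d <- abs(pred_obs - ph)
    k <- min(donors, length(d))
    pick <- order(d)[seq_len(k)]
    yobs[sample(pick, 1)]
  }, numeric(1))
}

#' Chained-equation multiple imputation of missing covariates
#'
#' @param cohort analysis cohort (possibly with missing `smoking`,
#'   `education`, `family_income`) from [build_analysis_cohort()]
#' @param m number of imputed datasets (default 20)
#' @param iterations chained-equation sweeps per dataset (default 20)
#' @param seed RNG seed
#' @return object of class `imputed_stack`: list with `datasets` (m
#'   completed cohorts with income/age quartiles recomputed) and `m`
#' @export
run_chained_imputation <- function(cohort, m = 20L, iterations = 20L,
                                   seed = NULL) {
  for (v in IMPUTED_VARS)
    if (all(is.na(cohort[[v]])))
      stop_config("covariate '%s' is entirely missing", v)
  miss <- lapply(IMPUTED_VARS, function(v) is.na(cohort[[v]]))
  names(miss) <- IMPUTED_VARS
  any_missing <- Reduce(`|`, miss)
  cohort$.na_hazard <- nelson_aalen_at_exit(cohort)

  complete_one <- function() {
    df <- imp_predictor_frame(cohort)
    # initial fill: random draws from the observed margins
    for (v in IMPUTED_VARS)
      if (any(miss[[v]]))
        df[[v]][miss[[v]]] <- sample(df[[v]][!miss[[v]]],
                                     sum(miss[[v]]), replace = TRUE)
    if (any(any_missing)) {
      for (it in seq_len(iterations)) {
        if (any(miss$smoking))
          df$smoking[miss$smoking] <-
            draw_logistic(df, "smoking", miss$smoking)
        if (any(miss$education))
          df$education[miss$education] <-
            draw_multinomial(df, "education", miss$education)
        if (any(miss$family_income))
          df$family_income[miss$family_income] <-
            draw_pmm(df, "family_income", miss$family_income)
      }
    }
    out <- cohort
    out$.na_hazard <- NULL
    out$smoking <- df$smoking
    out$education <- df$education
    out$family_income <- df$family_income
    qt <- function(x) cut(x, breaks = unique(stats::quantile(
      x, probs = c(0, 0.25, 0.5, 0.75, 1))), include.lowest = TRUE,
      labels = FALSE)
    out$income_quartile <- factor(paste0("Q", qt(out$family_income)))
    out$maternal_age_quartile <- factor(paste0("Q", qt(out$maternal_age)))
    out
  }
  datasets <- with_seed(seed, lapply(seq_len(m), function(i) complete_one()))
  structure(list(datasets = datasets, m = m, iterations = iterations),
            class = "imputed_stack")
}

#' Rubin's-rules pooling
#'
#' Pools per-dataset estimates: pooled mean, within-imputation variance W,
#' between-imputation variance B, total variance T = W + (1 + 1/m) B, and
#' the standard small-sample degrees of freedom.
#'
#' @param estimates numeric matrix (m x k) or vector of per-dataset
#'   estimates (log-HR scale for Cox models)
#' @param variances matching matrix/vector of squared standard errors
#' @return data.frame with `term`, `pooled`, `W`, `B`, `T`, `df`,
#'   `pooled_hr`, `lo95`, `hi95` (HR columns exponentiate the pooled
#'   estimate and its normal-theory interval)
#' @export
rubin_pool <- function(estimates, variances) {
  est <- if (is.matrix(estimates)) estimates else cbind(pooled = estimates)
  var <- if (is.matrix(variances)) variances else cbind(pooled = variances)
  if (!all(dim(est) == dim(var)))
    stop_config("estimates and variances must have matching shapes")
  m <- nrow(est)
  terms <- colnames(est) %||% paste0("term", seq_len(ncol(est)))
  pooled <- colMeans(est)
  W <- colMeans(var)
  B <- if (m > 1) apply(est, 2, stats::var) else rep(0, ncol(est))
  Tt <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  crit <- ifelse(is.finite(df), stats::qt(0.975, df), stats::qnorm(0.975))
  data.frame(term = terms, pooled = pooled, W = W, B = B, T = Tt, df = df,
             pooled_hr = exp(pooled),
             lo95 = exp(pooled - crit * sqrt(Tt)),
             hi95 = exp(pooled + crit * sqrt(Tt)),
             row.names = NULL)
}

#' Fit the Cox model on each imputed dataset and pool
#'
#' @param stack an `imputed_stack`
#' @param ... passed to [cox_fit()]
#' @return list with `pooled` (Rubin's-rules table) and `fits`
#' @export
pool_cox <- function(stack, ...) {
  fits <- lapply(stack$datasets, cox_fit, ...)
  est <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  var <- do.call(rbind, lapply(fits, function(f) diag(f$vcov)))
  list(pooled = rubin_pool(est, var), fits = fits)
}
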