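# Matched-design secondary analysis in the potential-outcomes framework:
# robust rank-based Mahalanobis 3:1 nearest-neighbour matching without
# replacement, covariate balance, and a Fisher-sharp-null randomization
# test of the Kaplan-Meier cumulative-incidence difference.

#' Expand covariates to a numeric matrix
#'
#' Factors become one indicator column per non-reference level; numeric
#' columns pass through. Used for distance computation and balance tables.
#'
#' @param data data.frame
#' @param cols covariate columns
#' @return numeric matrix, one row per row of `data`
#' @export
covariate_matrix <- function(data, cols) {
  parts <- lapply(cols, function(cl) {
    x <- data[[cl]]
    if (is.numeric(x)) {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, cl))
    } else {
      x <- factor(x)
      if (nlevels(x) < 2) {
        m <- matrix(0, nrow = length(x), ncol = 1,
                    dimnames = list(NULL, cl))
      } else {
        m <- stats::model.matrix(~ x)[, -1, drop = FALSE]
        colnames(m) <- paste0(cl, "_", levels(x)[-1])
      }
    }
    m
  })
  do.call(cbind, parts)
}

#' Robust rank-based Mahalanobis distance matrix
#'
#' Covariates are replaced by midranks over the pooled (treated + control)
#' sample; the rank covariance matrix has its diagonal rescaled so every
#' variable carries the variance of untied ranks (the robust variant, which
#' prevents heavily tied or outlier-prone variables from dominating), and
#' squared Mahalanobis distances are computed under that matrix.
#'
#' @param treated numeric covariate matrix (or data.frame rows) of treated
#'   units
#' @param control matching matrix of control units
#' @param ridge ridge factor applied (with a warning) when the rank
#'   covariance is singular
#' @return `nrow(treated)` x `nrow(control)` matrix of squared distances
#' @export
rank_mahalanobis_distance <- function(treated, control, ridge = 1e-6) {
  X <- rbind(as.matrix(treated), as.matrix(control))
  if (anyNA(X)) stop("missing covariate values", call. = FALSE)
  nt <- nrow(as.matrix(treated))
  N <- nrow(X)
  R <- apply(X, 2, rank)           # midranks over the pooled sample
  S <- stats::cov(R)
  vuntied <- (N^2 - 1) / 12        # variance of midranks 1..N without ties
  d <- diag(as.matrix(S))
  sc <- ifelse(d > 1e-12, sqrt(vuntied / d), 1)
  S <- diag(sc, ncol(S)) %*% S %*% diag(sc, ncol(S))
  const <- d <= 1e-12
  if (any(const)) {                # constant columns contribute nothing
    S[const, ] <- 0; S[, const] <- 0; diag(S)[const] <- vuntied
  }
  A <- tryCatch(solve(S), error = function(e) {
    warning("singular rank covariance: ridge-regularized", call. = FALSE)
    solve(S + diag(ridge * vuntied, ncol(S)))
  })
  # d2(i,j) = (ri - rj)' A (ri - rj) expanded as quadratic forms
  RA <- R %*% A
  q <- rowSums(RA * R)
  rt <- R[seq_len(nt), , drop = FALSE]
  rc <- R[-seq_len(nt), , drop = FALSE]
  cross <- rt %*% A %*% t(rc)
  d2 <- outer(q[seq_len(nt)], q[-seq_len(nt)], `+`) - 2 * cross
  pmax(d2, 0)
}

#' Greedy 3:1 nearest-neighbour matching without replacement
#'
#' Treated units are processed in input order; each takes its `ratio`
#' nearest unused controls, ties broken by control input index. The
#' procedure is deterministic.
#'
#' @param distances treated x control (squared) distance matrix
#' @param ratio controls per treated unit (default 3)
#' @param treated_ids,control_ids optional identifier vectors (defaults to
#'   the matrix dimnames, else indices)
#' @return data.frame of matched sets in long format: `set`, `person_id`,
#'   `treated` (1 for the treated member, 0 for its controls)
#' @export
greedy_nn_match <- function(distances, ratio = 3L,
                            treated_ids = NULL, control_ids = NULL) {
  nt <- nrow(distances); nc <- ncol(distances)
  if (nc < ratio * nt)
    stop(sprintf(
      "insufficient controls: need %d (%d treated x %d), have %d",
      ratio * nt, nt, ratio, nc), call. = FALSE)
  treated_ids <- treated_ids %||% rownames(distances) %||%
    as.character(seq_len(nt))
  control_ids <- control_ids %||% colnames(distances) %||%
    as.character(seq_len(nc))
  used <- logical(nc)
  sets <- vector("list", nt)
  for (i in seq_len(nt)) {
    avail <- which(!used)
    o <- avail[order(distances[i, avail], avail)][seq_len(ratio)]
    used[o] <- TRUE
    sets[[i]] <- data.frame(set = i,
                            person_id = c(treated_ids[i], control_ids[o]),
                            treated = c(1L, rep(0L, ratio)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  out
}

#' Standardized mean differences before and after matching
#'
#' SMD = (treated mean - control mean) / pooled pre-matching standard
#' deviation; binary covariates use their 0/1 means. The pre-matching SD is
#' kept as the denominator after matching so the two columns are on the
#' same scale.
#'
#' @param data data.frame containing covariates for all units
#' @param treated logical/0-1 vector over rows of `data`
#' @param matched_ids person ids retained after matching (treated and
#'   controls); `data` must have a `person_id` column
#' @param cols covariate columns
#' @return data.frame with `covariate`, `smd_before`, `smd_after`
#' @export
covariate_balance <- function(data, treated, matched_ids,
                              cols = COVARIATE_COLS) {
  X <- covariate_matrix(data, cols)
  tr <- as.logical(treated)
  sd_pool <- sqrt((apply(X[tr, , drop = FALSE], 2, stats::var) +
                   apply(X[!tr, , drop = FALSE], 2, stats::var)) / 2)
  smd <- function(rows) {
    dm <- colMeans(X[rows & tr, , drop = FALSE]) -
      colMeans(X[rows & !tr, , drop = FALSE])
    ifelse(sd_pool > 0, dm / sd_pool, NA_real_)
  }
  inmatch <- data$person_id %in% matched_ids
  data.frame(covariate = colnames(X),
             smd_before = smd(rep(TRUE, nrow(X))),
             smd_after = smd(inmatch),
             row.names = NULL)
}

# --- fast Kaplan-Meier difference kernel -------------------------------

# Precompute the tie-group structure of a matched cohort's exit times.
km_kernel_prep <- function(time, event, horizon) {
  ord <- order(time)
  ts <- time[ord]
  grp <- cumsum(!duplicated(ts))
  G <- max(grp)
  endpos <- cumsum(tabulate(grp, G))
  list(ord = ord, ev_sorted = as.numeric(event[ord]), grp = grp, G = G,
       endpos = endpos, keep = ts[endpos] <= horizon, n = length(time))
}

# KM cumulative incidence (at the last observed time <= horizon) for the
# members flagged in `member` (logical over original indices).
km_kernel_cuminc <- function(prep, member) {
  ms <- member[prep$ord]
  total <- sum(ms)
  if (total == 0L) return(0)
  cs <- cumsum(ms)
  cs_end <- cs[prep$endpos]
  atrisk <- total - c(0, cs_end[-prep$G])
  d <- rowsum(ms * prep$ev_sorted, prep$grp)[, 1]
  use <- prep$keep & d > 0 & atrisk > 0
  1 - prod(1 - d[use] / atrisk[use])
}

#' Kaplan-Meier cumulative-incidence difference statistic
#'
#' T = KM cumulative incidence among treated minus among controls, both
#' evaluated at the last observed time at or before the horizon, in
#' percentage points.
#'
#' @param followups data.frame with `exit_age_days`, `event` and a 0/1
#'   `treated` column
#' @param horizon evaluation horizon in days (the outcome age cap)
#' @return numeric scalar (percentage points)
#' @export
km_difference_statistic <- function(followups, horizon = 4383) {
  tr <- as.logical(followups$treated)
  if (!any(tr) || all(tr)) stop("both arms must be non-empty",
                                call. = FALSE)
  prep <- km_kernel_prep(followups$exit_age_days, followups$event, horizon)
  100 * (km_kernel_cuminc(prep, tr) - km_kernel_cuminc(prep, !tr))
}

#' Fisherian randomization test in the matched design
#'
#' Under the sharp null that each child's outcome is identical at both
#' exposure levels, the exposure label is hypothetically re-randomized
#' within each matched set of four children (one treated per set,
#' preserving the 1:3 design); follow-up records travel with the child.
#' The one-sided p-value counts permuted statistics at least as large as
#' the observed one, with the add-one correction
#' p = (1 + #\{T* >= T_obs\}) / (1 + n_perm). With at most `exact_max_sets`
#' sets the full 4^S assignment distribution is enumerated instead.
#'
#' @param matched matched sets in long format from [greedy_nn_match()]
#' @param followups data.frame keyed by `person_id` with `exit_age_days`
#'   and `event` for every matched child
#' @param horizon KM evaluation horizon in days
#' @param n_perm number of Monte-Carlo permutations (default 100000)
#' @param seed RNG seed
#' @param exact_max_sets enumerate exhaustively when the number of sets is
#'   at most this (default 8)
#' @return object of class `randomization_result`: `t_obs`, `p_value`,
#'   `n_perm`, `exact`, and a `null_summary` of the permutation
#'   distribution (the permuted statistics in `null_stats`)
#' @export
fisher_randomization_test <- function(matched, followups, horizon = 4383,
                                      n_perm = 100000L, seed = NULL,
                                      exact_max_sets = 8L) {
  if (n_perm < 1) stop_config("n_perm must be at least 1")
  idx <- match(matched$person_id, followups$person_id)
  if (anyNA(idx)) stop("matched children missing from follow-up table",
                       call. = FALSE)
  time <- followups$exit_age_days[idx]
  event <- followups$event[idx]
  sets <- matched$set
  S <- length(unique(sets))
  # member index matrix: rows 1..4 within set, columns sets
  bys <- split(seq_along(idx), sets)
  if (any(lengths(bys) != 4L))
    stop("each matched set must have exactly 4 members", call. = FALSE)
  members <- matrix(unlist(bys), nrow = 4L)
  obs_treated <- matched$treated == 1L
  n <- length(idx)
  prep <- km_kernel_prep(time, event, horizon)
  stat <- function(treated_logical) {
    100 * (km_kernel_cuminc(prep, treated_logical) -
           km_kernel_cuminc(prep, !treated_logical))
  }
  t_obs <- stat(obs_treated)

  if (S <= exact_max_sets) {
    choices <- as.matrix(expand.grid(rep(list(1:4), S)))
    null_stats <- apply(choices, 1, function(ch) {
      tr <- logical(n)
      tr[members[cbind(ch, seq_len(S))]] <- TRUE
      stat(tr)
    })
    p <- mean(null_stats >= t_obs - 1e-12)
    exact <- TRUE
    n_used <- nrow(choices)
  } else {
    null_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        ch <- sample.int(4L, S, replace = TRUE)
        tr <- logical(n)
        tr[members[cbind(ch, seq_len(S))]] <- TRUE
        stat(tr)
      }, numeric(1))
    })
    p <- (1 + sum(null_stats >= t_obs - 1e-12)) / (1 + n_perm)
    exact <- FALSE
    n_used <- n_perm
  }
  structure(list(
    t_obs = t_obs, p_value = p, n_perm = n_used, exact = exact,
    null_stats = null_stats,
    null_summary = c(mean = mean(null_stats), sd = stats::sd(null_stats),
                     stats::quantile(null_stats,
                                     c(0.025, 0.5, 0.975)))),
    class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "<randomization_result> T_obs = %.2f pp, one-sided p = %.4g (%s, %d assignments)\n",
    x$t_obs, x$p_value, if (x$exact) "exact" else "Monte Carlo", x$n_perm))
  invisible(x)
}

#' Run the full matched secondary analysis for one outcome
#'
#' Matches very-high-exposed children 3:1 to background controls on the
#' analysis covariates, assesses balance, computes the KM
#' cumulative-incidence difference at the outcome age cap and its
#' Fisherian one-sided p-value.
#'
#' @param cohort complete-case analysis cohort for one outcome
#' @param n_perm randomization draws
#' @param seed RNG seed
#' @param cols matching covariates
#' @return list with `matched`, `balance`, `result`
#' @export
matched_analysis <- function(cohort, n_perm = 100000L, seed = NULL,
                             cols = COVARIATE_COLS) {
  vh <- cohort[cohort$exposure == "very_high", , drop = FALSE]
  bg <- cohort[cohort$exposure == "background", , drop = FALSE]
  if (!nrow(vh) || !nrow(bg))
    stop("need both very-high and background children", call. = FALSE)
  D <- rank_mahalanobis_distance(covariate_matrix(vh, cols),
                                 covariate_matrix(bg, cols))
  matched <- greedy_nn_match(D, ratio = 3L, treated_ids = vh$person_id,
                             control_ids = bg$person_id)
  both <- rbind(vh, bg)
  balance <- covariate_balance(both,
                               treated = both$exposure == "very_high",
                               matched_ids = matched$person_id, cols = cols)
  horizon <- if (unique(cohort$outcome)[1] == "wheeze") 1096 else 4383
  res <- fisher_randomization_test(
    matched, both[, c("person_id", "exit_age_days", "event")],
    horizon = horizon, n_perm = n_perm, seed = seed)
  list(matched = matched, balance = balance, result = res)
}
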