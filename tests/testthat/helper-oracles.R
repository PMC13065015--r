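# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force, enumeration, hand formula) kept separate
# from the package's computation paths.

# Negative log partial likelihood for untied right-censored data
# (Breslow = Efron when there are no tied event times).
oracle_neg_logpl <- function(beta, time, status, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  -ll
}

# Direct maximization of the partial likelihood.
oracle_cox_coef <- function(time, status, X) {
  X <- as.matrix(X)
  opt <- stats::optim(rep(0, ncol(X)), oracle_neg_logpl, time = time,
                      status = status, X = X, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  opt$par
}

# Hand product-limit estimator: survival at each distinct event time.
oracle_km <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    n_at <- sum(time >= ut[k])
    d <- sum(time == ut[k] & status == 1)
    s <- s * (1 - d / n_at)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Hand Nelson-Aalen increments d/n summed through each subject's exit.
oracle_nelson_aalen <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  inc <- vapply(ut, function(t)
    sum(time == t & status == 1) / sum(time >= t), numeric(1))
  H <- cumsum(inc)
  vapply(time, function(t) {
    k <- which(ut <= t)
    if (length(k)) H[max(k)] else 0
  }, numeric(1))
}

# Brute-force double-loop Jonckheere-Terpstra J.
oracle_jt_doubleloop <- function(values, groups) {
  groups <- as.integer(factor(groups, levels = unique(groups)))
  J <- 0
  n <- length(values)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (groups[i] < groups[j]) {
        if (values[i] < values[j]) J <- J + 1
        else if (values[i] == values[j]) J <- J + 0.5
      }
    }
  }
  J
}

# small survival fixture without ties
fixture_surv6 <- function() {
  data.frame(
    person_id = paste0("P", 1:6),
    cluster_id = paste0("P", 1:6),
    exposure = c("very_high", "background", "very_high", "background",
                 "very_high", "background"),
    exit_age_days = c(3, 5, 7, 11, 13, 17),
    event = c(1, 1, 0, 1, 1, 0),
    stringsAsFactors = FALSE)
}

# a tiny well-formed register bundle via the generator
small_bundle <- function(n = 500, seed = 11, ...) {
  generate_registers(sim_config(n_children = n, seed = seed, ...))
}
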