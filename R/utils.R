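# Internal helpers: calendar arithmetic at day resolution, local RNG scope.

#' Add whole years to a calendar date
#'
#' Birthday arithmetic used for outcome age caps. A Feb-29 anniversary in a
#' non-leap year rolls forward to Mar 1, so that "on the birthday" always
#' means "on or after the anniversary date".
#'
#' @param date a `Date` vector
#' @param n integer number of years
#' @return a `Date` vector
#' @keywords internal
add_years <- function(date, n) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L + n
  m <- lt$mon + 1L
  d <- lt$mday
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
  feb29 <- which(is.na(out))
  if (length(feb29)) {
    out[feb29] <- as.Date(sprintf("%04d-03-01", y[feb29]))
  }
  out
}

#' Age in integer days between two dates
#' @keywords internal
age_days <- function(birth_date, date) {
  as.integer(as.Date(date) - as.Date(birth_date))
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `seed` may be NULL (leave the stream alone).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a root seed and a stage label; keeps per-stage
# reproducibility when stages are skipped. Result always < 2^31.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
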