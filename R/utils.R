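#' @importFrom stats rbeta rbinom rpois rnorm runif rgamma quantile var cor kmeans
#' @importFrom utils write.table read.table
NULL

# All randomness flows through this helper: it seeds the session RNG locally
# and restores the previous RNG state when the calling frame exits.
local_seed <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, why) {
  stop(sprintf("invalid config field '%s': %s", field, why), call. = FALSE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_fraction <- function(x, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x))) return(FALSE)
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  ok_lo && ok_hi
}

# Six-number summary used by all stratified accuracy tables.
# Quartiles use the linear-interpolation convention (stats::quantile type 7).
six_num <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) {
    return(data.frame(n = 0L, min = NA_real_, q1 = NA_real_, median = NA_real_,
                      mean = NA_real_, q3 = NA_real_, max = NA_real_))
  }
  q <- unname(quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  data.frame(n = length(x), min = q[1], q1 = q[2], median = q[3],
             mean = mean(x), q3 = q[4], max = q[5])
}

# Population variance (divide by n); the Rsq statistic uses this convention.
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}
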