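#' @import data.table
#' @importFrom stats dnorm rnorm runif rlnorm rgamma density sd var aggregate
#'   setNames plogis qlogis uniroot
#' @importFrom utils write.csv read.csv head
NULL

# data.table NSE columns
utils::globalVariables(c(
  "participant", "condition", "laterality", "congruency", "trial_kind",
  "correct", "rt_ms", "cce_ms", "d_ms", "response", "group", ".N", ".",
  "n_ok", "n_tot", "component", "time", "score", "cell", "y", "accuracy",
  "mean_rt_congruent", "mean_rt_incongruent", "n_congruent", "n_incongruent",
  "ipsilateral", "contralateral", "visits", "hypothesis", "se", "block"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg(name, " must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_bad_arg(name, " must be in ", if (strict_lower) "(" else "[",
                 lower, ", ", upper, "]")
  x
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stop_bad_arg(name, " must be an integer")
  as.integer(x)
}

# Deterministic child seed from a user seed and a small stream offset;
# kept below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + stream * 9973) %% 2147483647
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Split-\eqn{\hat{R}} convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, following the standard split-chain recipe. Values near 1 indicate
#' that the chains mix over the same distribution.
#'
#' @param chains list of numeric vectors (one per chain), equal lengths.
#' @return a single numeric value; `NA` if the draws are constant.
#' @export
split_rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1L)
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1L]])
  if (n < 2L) return(NA_real_)
  m <- length(halves)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(if (b == 0) NA_real_ else Inf)
  sqrt(((n - 1) / n * w + b / n) / w)
}
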