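# Within-model machinery: hypothesis specifications, hierarchical linear
# models for CCE data, cumulative-logit models for Likert data, their exact
# log-likelihoods, Gibbs/MH posterior samplers, and analytic oracles.
#
# A hypothesis assigns a prior label (e.g. "null"/"active" on the CCE scale,
# "low"/"high" on the log-odds scale) to each effect parameter.  Defaults:
# null ~ N(0 ms, 5 ms) and active ~ N(40 ms, 20 ms) for the
# ipsilateral-minus-contralateral CCE difference, low ~ N(-3, 1) and
# high ~ N(+3, 1) for logit coefficients.  All are configurable and echoed
# in reports.

#' Default effect priors
#'
#' @return named list of `c(mean, sd)` pairs per prior label.
#' @export
default_effect_priors <- function() list(null = c(mean = 0, sd = 5),
                                         active = c(mean = 40, sd = 20),
                                         baseline = c(mean = 30, sd = 40))

#' @rdname default_effect_priors
#' @export
default_logit_priors <- function() list(low = c(mean = -3, sd = 1),
                                        high = c(mean = 3, sd = 1))

#' Hypothesis specification
#'
#' @param id hypothesis label.
#' @param effects named character vector mapping each effect parameter to a
#'   prior label.
#' @param priors named list of `c(mean, sd)` per label (defaults to
#'   [default_effect_priors()]).
#' @param X optional design matrix mapping effect parameters (columns) to
#'   observation cells (rows); identity over `names(effects)` when omitted.
#' @return a `hypothesis_spec` object.
#' @export
hypothesis_spec <- function(id, effects, priors = default_effect_priors(),
                            X = NULL) {
  stopifnot(is.character(effects), length(effects) >= 1L,
            !is.null(names(effects)))
  miss <- setdiff(unique(effects), names(priors))
  if (length(miss))
    stop_bad_arg("no prior for label(s): ", paste(miss, collapse = ", "))
  for (p in priors[unique(effects)])
    if (length(p) != 2L || p[2L] <= 0)
      stop_bad_arg("each prior must be c(mean, sd) with sd > 0")
  if (!is.null(X)) {
    stopifnot(is.matrix(X), ncol(X) == length(effects))
    colnames(X) <- names(effects)
  }
  structure(list(id = id, effects = effects, priors = priors, X = X),
            class = "hypothesis_spec")
}

#' @export
print.hypothesis_spec <- function(x, ...) {
  cat("Hypothesis", x$id, ":",
      paste(names(x$effects), x$effects, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# prior mean/sd vectors aligned with the effect parameters
prior_moments <- function(hypothesis) {
  lab <- hypothesis$effects
  list(mean = vapply(lab, function(l) hypothesis$priors[[l]][1L], 0),
       sd = vapply(lab, function(l) hypothesis$priors[[l]][2L], 0))
}

#' MCMC configuration
#'
#' Defaults follow the analysis budget of 3 chains of 10,000 kept samples
#' after 1,000 burn-in each (30,000 kept draws in total).
#'
#' @param n_chains number of chains.
#' @param burn_in discarded draws per chain.
#' @param n_samples kept draws per chain.
#' @return an `mcmc_config` object.
#' @export
mcmc_config <- function(n_chains = 3L, burn_in = 1000L, n_samples = 10000L) {
  structure(list(n_chains = check_count(n_chains, "n_chains"),
                 burn_in = check_count(burn_in, "burn_in", lower = 0L),
                 n_samples = check_count(n_samples, "n_samples")),
            class = "mcmc_config")
}

## ----------------------------------------------------- model families ------
# A family bundles the full-conditional machinery one hypothesis-model needs:
#   suffstats(data)                    precomputed indexing
#   init_theta(ss, prior)              starting effect vector
#   update_theta(theta, common, ss, prior)   one full-conditional sweep
#   log_lik(theta, common, ss)         exact log p(y | theta, common)
#   init_common(ss) / update_common(common, theta, ss)  shared nuisance block
# theta is the (possibly model-specific) effect vector; `common` holds
# parameters shared across hypotheses (participant intercepts, variances).

# Inverse-gamma hyperprior on variances, the vague precision-Gamma(a, b)
# convention of general-purpose Gibbs samplers.
IG_A0 <- 0.001
IG_B0 <- 0.001

draw_inv_gamma <- function(a, b) b / rgamma(1L, shape = a)

# --- i.i.d. normal with known sigma (conjugate fixture / oracle family) ----
family_normal <- function(sigma) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  list(
    name = "normal_known_sigma",
    suffstats = function(data) {
      y <- as.numeric(data)
      list(n = length(y), ybar = if (length(y)) mean(y) else 0,
           ss = sum(y^2), sigma = sigma)
    },
    param_names = function(ss, hypothesis) names(hypothesis$effects),
    init_theta = function(ss, prior) prior$mean,
    update_theta = function(theta, common, ss, prior, ...) {
      prec <- ss$n / ss$sigma^2 + 1 / prior$sd^2
      m <- (ss$n * ss$ybar / ss$sigma^2 + prior$mean / prior$sd^2) / prec
      rnorm(length(theta), m, sqrt(1 / prec))
    },
    log_lik = function(theta, common, ss, ...) {
      mu <- theta[[1L]]
      -ss$n / 2 * log(2 * pi * ss$sigma^2) -
        (ss$ss - 2 * mu * ss$n * ss$ybar + ss$n * mu^2) / (2 * ss$sigma^2)
    },
    init_common = function(ss) NULL,
    update_common = function(common, theta, ss, ...) NULL
  )
}

# Effect-to-cell design matrix: the hypothesis's own X when given, otherwise
# an identity aligned by name with the (sorted) data cells.
resolved_X <- function(hypothesis, cells) {
  if (!is.null(hypothesis$X) || is.null(cells)) return(hypothesis$X)
  nm <- names(hypothesis$effects)
  X <- matrix(0, length(cells), length(nm), dimnames = list(cells, nm))
  for (i in seq_along(cells)) X[i, nm == cells[i]] <- 1
  X
}

# --- hierarchical linear model for per-participant CCE quantities ----------
# y_{pc} = (X theta)_c + b_p + eps,  b_p ~ N(0, tau^2), eps ~ N(0, sigma^2);
# cells are conditions (or groups, or group x laterality), theta the effect
# coefficients a hypothesis puts priors on.
family_hier_linear <- function() {
  list(
    name = "hier_linear",
    suffstats = function(data) {
      d <- as.data.frame(data)
      stopifnot(all(c("participant", "cell", "y") %in% names(d)))
      cells <- sort(unique(as.character(d$cell)))
      parts <- sort(unique(as.character(d$participant)))
      list(y = as.numeric(d$y),
           cell = match(as.character(d$cell), cells),
           part = match(as.character(d$participant), parts),
           cells = cells, parts = parts,
           n = nrow(d), n_part = length(parts),
           scale = max(sd(d$y), 1))
    },
    param_names = function(ss, hypothesis) names(hypothesis$effects),
    init_theta = function(ss, prior) prior$mean,
    update_theta = function(theta, common, ss, prior, X = NULL) {
      X <- X %||% diag(length(theta))
      r0 <- ss$y - common$b[ss$part]
      for (j in seq_along(theta)) {
        xj <- X[ss$cell, j]
        r <- r0 - (X[, -j, drop = FALSE] %*% theta[-j])[ss$cell]
        prec <- sum(xj^2) / common$sigma2 + 1 / prior$sd[j]^2
        m <- (sum(xj * r) / common$sigma2 + prior$mean[j] / prior$sd[j]^2) /
          prec
        theta[j] <- rnorm(1L, m, sqrt(1 / prec))
      }
      theta
    },
    log_lik = function(theta, common, ss, X = NULL) {
      X <- X %||% diag(length(theta))
      mu <- (X %*% theta)[ss$cell] + common$b[ss$part]
      -ss$n / 2 * log(2 * pi * common$sigma2) -
        sum((ss$y - mu)^2) / (2 * common$sigma2)
    },
    init_common = function(ss) list(b = numeric(ss$n_part),
                                    sigma2 = ss$scale^2, tau2 = ss$scale^2 / 4),
    update_common = function(common, theta, ss, X = NULL) {
      X <- X %||% diag(length(theta))
      cellmean <- (X %*% theta)[ss$cell]
      res <- ss$y - cellmean
      # participant intercepts (conjugate)
      sum_r <- tapply(res, ss$part, sum)
      n_p <- tabulate(ss$part, ss$n_part)
      prec <- n_p / common$sigma2 + 1 / common$tau2
      common$b <- rnorm(ss$n_part, (sum_r / common$sigma2) / prec,
                        sqrt(1 / prec))
      # variances (conjugate inverse-gamma)
      sse <- sum((res - common$b[ss$part])^2)
      common$sigma2 <- draw_inv_gamma(IG_A0 + ss$n / 2, IG_B0 + sse / 2)
      common$tau2 <- draw_inv_gamma(IG_A0 + ss$n_part / 2,
                                    IG_B0 + sum(common$b^2) / 2)
      common
    }
  )
}

# --- hierarchical cumulative-logit model for Likert scores -----------------
# P(Y_{ipc} <= k) = logistic(c_k - eta),  eta = (X theta)_c + b_p, with fixed
# equidistant cut-points c and participant intercepts b_p ~ N(0, tau^2).
family_ordinal <- function(cutpoints = likert_cutpoints(),
                           proposal_sd = 0.4) {
  n_cat <- length(cutpoints) + 1L
  loglik_rows <- function(eta, score) {
    upper <- c(cutpoints, Inf)[score]
    lower <- c(-Inf, cutpoints)[score]
    log(plogis(upper - eta) - plogis(lower - eta))
  }
  list(
    name = "ordinal_logit",
    cutpoints = cutpoints,
    suffstats = function(data) {
      d <- as.data.frame(data)
      stopifnot(all(c("participant", "cell", "score") %in% names(d)))
      if (any(d$score < 1L | d$score > n_cat | d$score != round(d$score)))
        stop_bad_arg("scores must be integers in 1..", n_cat)
      cells <- sort(unique(as.character(d$cell)))
      parts <- sort(unique(as.character(d$participant)))
      list(score = as.integer(d$score),
           cell = match(as.character(d$cell), cells),
           part = match(as.character(d$participant), parts),
           cells = cells, parts = parts, n = nrow(d), n_part = length(parts))
    },
    param_names = function(ss, hypothesis) names(hypothesis$effects),
    init_theta = function(ss, prior) prior$mean,
    update_theta = function(theta, common, ss, prior, X = NULL) {
      X <- X %||% diag(length(theta))
      for (j in seq_along(theta)) {
        rows <- which(X[ss$cell, j] != 0)
        if (!length(rows)) {  # parameter untouched by the data: prior draw
          theta[j] <- rnorm(1L, prior$mean[j], prior$sd[j])
          next
        }
        prop <- theta
        prop[j] <- theta[j] + rnorm(1L, 0, proposal_sd)
        eta_cur <- (X %*% theta)[ss$cell[rows]] + common$b[ss$part[rows]]
        eta_new <- (X %*% prop)[ss$cell[rows]] + common$b[ss$part[rows]]
        la <- sum(loglik_rows(eta_new, ss$score[rows])) -
          sum(loglik_rows(eta_cur, ss$score[rows])) +
          dnorm(prop[j], prior$mean[j], prior$sd[j], log = TRUE) -
          dnorm(theta[j], prior$mean[j], prior$sd[j], log = TRUE)
        if (log(runif(1L)) < la) theta <- prop
      }
      theta
    },
    log_lik = function(theta, common, ss, X = NULL) {
      X <- X %||% diag(length(theta))
      eta <- (X %*% theta)[ss$cell] + common$b[ss$part]
      sum(loglik_rows(eta, ss$score))
    },
    init_common = function(ss) list(b = numeric(ss$n_part), tau2 = 1),
    update_common = function(common, theta, ss, X = NULL) {
      X <- X %||% diag(length(theta))
      cellpart <- (X %*% theta)[ss$cell]
      for (p in seq_len(ss$n_part)) {
        rows <- which(ss$part == p)
        bp <- common$b[p]
        prop <- bp + rnorm(1L, 0, proposal_sd)
        la <- sum(loglik_rows(cellpart[rows] + prop, ss$score[rows])) -
          sum(loglik_rows(cellpart[rows] + bp, ss$score[rows])) +
          dnorm(prop, 0, sqrt(common$tau2), log = TRUE) -
          dnorm(bp, 0, sqrt(common$tau2), log = TRUE)
        if (log(runif(1L)) < la) common$b[p] <- prop
      }
      common$tau2 <- draw_inv_gamma(IG_A0 + ss$n_part / 2,
                                    IG_B0 + sum(common$b^2) / 2)
      common
    }
  )
}

## ------------------------------------------------- exported likelihoods ----

#' Exact log-likelihood of the hierarchical linear model
#'
#' Participant random intercepts are integrated out in closed form: each
#' participant's residual vector is multivariate normal with
#' compound-symmetric covariance `sigma^2 I + tau_p^2 J`, so the marginal
#' log-density is exact and deterministic.
#'
#' @param data data.frame with columns `participant`, `cell` (condition or
#'   group label) and `y` (e.g. the ipsi-minus-contra CCE difference in ms).
#' @param params list with `mu` (named numeric, one mean per cell), `tau_p`
#'   (participant SD, >= 0) and `sigma` (residual SD, > 0).
#' @return the log joint density of the observations given `params`.
#' @export
loglik_linear <- function(data, params) {
  d <- as.data.frame(data)
  stopifnot(all(c("participant", "cell", "y") %in% names(d)))
  check_number(params$sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(params$tau_p, "tau_p", lower = 0)
  mu <- params$mu
  cells <- unique(as.character(d$cell))
  if (is.null(names(mu))) {
    if (length(mu) == 1L) mu <- setNames(rep(mu, length(cells)), cells)
    else stop_bad_arg("params$mu must be named by cell")
  }
  if (!all(cells %in% names(mu)))
    stop_bad_arg("params$mu missing cell(s): ",
                 paste(setdiff(cells, names(mu)), collapse = ", "))
  s2 <- params$sigma^2; t2 <- params$tau_p^2
  r <- d$y - mu[as.character(d$cell)]
  total <- 0
  for (p in split(r, d$participant)) {
    k <- length(p)
    denom <- s2 + k * t2
    logdet <- (k - 1) * log(s2) + log(denom)
    quad <- sum(p^2) / s2 - (t2 / (s2 * denom)) * sum(p)^2
    total <- total - k / 2 * log(2 * pi) - logdet / 2 - quad / 2
  }
  total
}

#' Cumulative-logit log-likelihood for Likert data
#'
#' Fixed equidistant cut-points; the linear predictor of a record is the
#' coefficient of its cell plus (optionally) its participant intercept.
#'
#' @param data data.frame with columns `participant`, `cell`, `score`
#'   (integers 1..10).
#' @param params list with `coef` (named numeric per cell) and optionally
#'   `b` (named numeric per participant, default all 0).
#' @param cutpoints cut-point vector, see [likert_cutpoints()].
#' @return log-density (deterministic).
#' @export
loglik_ordinal_logit <- function(data, params,
                                 cutpoints = likert_cutpoints()) {
  d <- as.data.frame(data)
  stopifnot(all(c("participant", "cell", "score") %in% names(d)))
  n_cat <- length(cutpoints) + 1L
  if (any(d$score < 1 | d$score > n_cat | d$score != round(d$score)))
    stop_bad_arg("scores must be integers in 1..", n_cat)
  coef <- params$coef
  if (!all(unique(as.character(d$cell)) %in% names(coef)))
    stop_bad_arg("params$coef must be named by cell")
  b <- params$b %||% setNames(numeric(0L), character(0L))
  bp <- ifelse(as.character(d$participant) %in% names(b),
               b[as.character(d$participant)], 0)
  eta <- coef[as.character(d$cell)] + bp
  upper <- c(cutpoints, Inf)[d$score]
  lower <- c(-Inf, cutpoints)[d$score]
  sum(log(plogis(upper - eta) - plogis(lower - eta)))
}

#' Ordinal category probabilities at a linear predictor
#'
#' @param eta linear predictor (log-odds scale), vectorised.
#' @param cutpoints cut-point vector.
#' @return matrix (`length(eta)` x categories) of probabilities; each row
#'   sums to 1.
#' @export
ordinal_probs <- function(eta, cutpoints = likert_cutpoints()) {
  cdf <- cbind(0, plogis(outer(-eta, cutpoints, `+`)), 1)
  t(apply(cdf, 1L, diff))
}

## ------------------------------------------------------------ samplers ----

# Generic single-model Gibbs runner over a family; returns per-chain draw
# matrices (theta columns first, then any scalar common parameters).
run_single_model <- function(family, ss, hypothesis, config, seed) {
  pm <- prior_moments(hypothesis)
  X <- hypothesis$X
  nm <- names(hypothesis$effects)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(child_seed(seed, 100L + ch))
    theta <- setNames(family$init_theta(ss, pm), nm)
    common <- family$init_common(ss)
    extra <- if (!is.null(common))
      names(Filter(function(v) is.numeric(v) && length(v) == 1L, common))
    draws <- matrix(NA_real_, config$n_samples, length(nm) + length(extra),
                    dimnames = list(NULL, c(nm, extra)))
    for (it in seq_len(config$burn_in + config$n_samples)) {
      if (!is.null(common))
        common <- family$update_common(common, theta, ss, X = X)
      theta <- setNames(family$update_theta(theta, common, ss, pm, X = X), nm)
      if (it > config$burn_in)
        draws[it - config$burn_in, ] <- c(theta,
                                          unlist(common[extra], use.names = FALSE))
    }
    chains[[ch]] <- draws
  }
  rhat <- vapply(seq_len(ncol(chains[[1L]])), function(j)
    split_rhat(lapply(chains, function(m) m[, j])), 0)
  names(rhat) <- colnames(chains[[1L]])
  structure(list(chains = chains, rhat = rhat, hypothesis = hypothesis,
                 config = config, seed = seed),
            class = "ppscct_fit")
}

#' @export
print.ppscct_fit <- function(x, ...) {
  pooled <- do.call(rbind, x$chains)
  cat("Posterior fit of hypothesis", x$hypothesis$id, "(",
      length(x$chains), "chains x", nrow(x$chains[[1L]]), "draws )\n")
  print(round(cbind(mean = colMeans(pooled),
                    sd = apply(pooled, 2L, sd),
                    rhat = x$rhat), 4))
  invisible(x)
}

#' Posterior sampling for the hierarchical linear CCE model
#'
#' Conjugate Gibbs updates throughout: cell coefficients, participant
#' intercepts and both variances all have closed-form full conditionals.
#' Non-convergence (any split-R-hat above 1.05) is flagged with a warning,
#' not an error.
#'
#' @param data data.frame with columns `participant`, `cell`, `y`.
#' @param hypothesis a [hypothesis_spec()] whose effects match the cells (or
#'   whose `X` maps effects to cells).
#' @param config an [mcmc_config()].
#' @param seed integer seed.
#' @return a `ppscct_fit`: list of per-chain draw matrices (`chains`, columns
#'   = effects plus `sigma2`, `tau2`), split-R-hat per column (`rhat`).
#' @export
sample_posterior_linear <- function(data, hypothesis,
                                    config = mcmc_config(), seed = 1L) {
  fam <- family_hier_linear()
  ss <- fam$suffstats(normalise_linear_data(data))
  check_hypothesis_cells(hypothesis, ss$cells)
  hypothesis$X <- resolved_X(hypothesis, ss$cells)
  fit <- run_single_model(fam, ss, hypothesis, config, seed)
  warn_rhat(fit)
  fit
}

#' Posterior sampling for the hierarchical cumulative-logit model
#'
#' Metropolis-within-Gibbs: random-walk updates for cell coefficients and
#' participant intercepts, conjugate inverse-gamma update for the intercept
#' variance.
#'
#' @inheritParams sample_posterior_linear
#' @param data data.frame with columns `participant`, `cell`, `score`.
#' @param cutpoints fixed cut-points, see [likert_cutpoints()].
#' @return a `ppscct_fit` (columns = effects plus `tau2`).
#' @export
sample_posterior_logit <- function(data, hypothesis,
                                   config = mcmc_config(), seed = 1L,
                                   cutpoints = likert_cutpoints()) {
  fam <- family_ordinal(cutpoints)
  ss <- fam$suffstats(data)
  check_hypothesis_cells(hypothesis, ss$cells)
  hypothesis$X <- resolved_X(hypothesis, ss$cells)
  fit <- run_single_model(fam, ss, hypothesis, config, seed)
  warn_rhat(fit)
  fit
}

normalise_linear_data <- function(data) {
  d <- as.data.frame(data)
  if (is.null(d$y) && !is.null(d$d_ms)) d$y <- d$d_ms
  if (is.null(d$y) && !is.null(d$cce_ms)) d$y <- d$cce_ms
  if (is.null(d$cell) && !is.null(d$condition)) d$cell <- d$condition
  if (is.null(d$cell) && !is.null(d$group)) d$cell <- d$group
  d
}

check_hypothesis_cells <- function(hypothesis, cells) {
  if (is.null(hypothesis$X)) {
    if (!setequal(names(hypothesis$effects), cells))
      stop_bad_arg("hypothesis effects (",
                   paste(names(hypothesis$effects), collapse = ", "),
                   ") do not match the data cells (",
                   paste(cells, collapse = ", "), ")")
  } else if (nrow(hypothesis$X) != length(cells)) {
    stop_bad_arg("hypothesis design matrix has ", nrow(hypothesis$X),
                 " rows but the data have ", length(cells), " cells")
  }
}

warn_rhat <- function(fit, limit = 1.05) {
  bad <- fit$rhat[is.finite(fit$rhat) & fit$rhat > limit]
  if (length(bad))
    warning("possible non-convergence (split-Rhat > ", limit, "): ",
            paste(names(bad), round(bad, 3), collapse = ", "), call. = FALSE)
  invisible(fit)
}

#' Posterior credible interval from a fit
#'
#' @param fit a `ppscct_fit`.
#' @param param column name (default the first effect).
#' @param level interval mass (default 0.95).
#' @return `c(lower, upper)` equal-tailed interval over pooled draws.
#' @export
credible_interval <- function(fit, param = NULL, level = 0.95) {
  pooled <- do.call(rbind, fit$chains)
  param <- param %||% colnames(pooled)[1L]
  unname(stats::quantile(pooled[, param], c((1 - level) / 2,
                                            1 - (1 - level) / 2)))
}

## ------------------------------------------------------ analytic oracle ----

#' Exact log marginal likelihood: normal data, known sigma, normal prior
#'
#' For `y_i ~ N(mu, known_sigma^2)` i.i.d. with `mu ~ N(prior_mean,
#' prior_sd^2)`, the marginal likelihood of the data is available in closed
#' form; used as the independent oracle for the product-space sampler.
#'
#' @param y numeric observations (may be empty: log marginal 0).
#' @param known_sigma observation SD (> 0).
#' @param prior_mean,prior_sd prior mean and SD of `mu`.
#' @return log marginal likelihood.
#' @export
analytic_log_marginal_normal <- function(y, known_sigma, prior_mean,
                                         prior_sd) {
  check_number(known_sigma, "known_sigma", lower = 0, strict_lower = TRUE)
  check_number(prior_sd, "prior_sd", lower = 0, strict_lower = TRUE)
  n <- length(y)
  if (n == 0L) return(0)
  ybar <- mean(y)
  ssw <- sum((y - ybar)^2)
  s2 <- known_sigma^2
  -n / 2 * log(2 * pi * s2) - 0.5 * log(1 + n * prior_sd^2 / s2) -
    ssw / (2 * s2) - (ybar - prior_mean)^2 / (2 * (s2 / n + prior_sd^2))
}
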