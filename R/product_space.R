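# Transdimensional product-space (Carlin-Chib) sampler.
#
# All candidate hypotheses' effect parameters are kept in the state jointly
# with a categorical model index.  One Gibbs cycle: (i) update the shared
# nuisance block (participant intercepts, variances) and the active model's
# effects against the likelihood; (ii) redraw every inactive model's effects
# from its pseudo-prior (a proper moment-matched normal); (iii) draw the
# index from its full conditional, proportional to
#   model_prior x likelihood x prior(effects) / pseudo-prior(effects),
# computed in log space with max-subtraction.  Posterior model probabilities
# are the kept-draw visit proportions pooled over chains; correctness
# requires (and tests verify) insensitivity to the pseudo-prior choice.

make_family <- function(family, sigma = NULL,
                        cutpoints = likert_cutpoints()) {
  if (is.list(family) && !is.null(family$log_lik)) return(family)
  switch(match.arg(family, c("hier_linear", "normal", "ordinal")),
         hier_linear = family_hier_linear(),
         normal = family_normal(sigma %||%
                                  stop_bad_arg("family 'normal' needs sigma")),
         ordinal = family_ordinal(cutpoints))
}

space_data <- function(family, data) {
  if (family$name == "hier_linear") data <- normalise_linear_data(data)
  family$suffstats(data)
}

#' Fit pseudo-priors by pilot runs
#'
#' Each hypothesis-model is sampled on its own (pilot run) and its posterior
#' mean/SD per effect parameter define a moment-matched normal pseudo-prior.
#' With no data the pseudo-prior equals the prior's moments.
#'
#' @param models list of [hypothesis_spec()] objects.
#' @param data the data all models share (format depends on `family`).
#' @param pilot_config an [mcmc_config()] for the pilot runs.
#' @param family `"hier_linear"`, `"normal"`, `"ordinal"`, or a family
#'   object.
#' @param seed integer seed.
#' @param sigma known observation SD (family `"normal"` only).
#' @param cutpoints cut-points (family `"ordinal"` only).
#' @return a `pseudo_prior_spec`: per model id, named `mean` and `sd`
#'   vectors over that model's effect parameters.
#' @export
fit_pseudo_priors <- function(models, data,
                              pilot_config = mcmc_config(n_chains = 1L,
                                                         burn_in = 500L,
                                                         n_samples = 2000L),
                              family = "hier_linear", seed = 1L,
                              sigma = NULL, cutpoints = likert_cutpoints()) {
  fam <- make_family(family, sigma, cutpoints)
  no_data <- is.null(data) || (is.atomic(data) && length(data) == 0L) ||
    (is.data.frame(data) && nrow(data) == 0L)
  out <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    stopifnot(inherits(m, "hypothesis_spec"))
    pm <- prior_moments(m)
    if (no_data) {
      out[[m$id]] <- list(mean = pm$mean, sd = pm$sd)
      next
    }
    ss <- space_data(fam, data)
    m$X <- resolved_X(m, ss$cells)
    fit <- run_single_model(fam, ss, m, pilot_config,
                            child_seed(seed, 17L * i))
    bad <- fit$rhat[names(m$effects)]
    if (pilot_config$n_chains > 1L &&
        any(is.finite(bad) & bad > 1.2))
      stop_bad_arg("pilot run for model '", m$id, "' did not converge ",
                   "(split-Rhat: ", paste(round(bad, 2), collapse = ", "), ")")
    pooled <- do.call(rbind, fit$chains)[, names(m$effects), drop = FALSE]
    out[[m$id]] <- list(mean = colMeans(pooled),
                        sd = pmax(apply(pooled, 2L, sd), 1e-6))
  }
  structure(out, class = "pseudo_prior_spec")
}

#' Run the product-space sampler
#'
#' @param models list of [hypothesis_spec()] objects (distinct ids).
#' @param data shared data (see the family's sampler for the format).
#' @param pseudo a `pseudo_prior_spec` from [fit_pseudo_priors()]; fitted
#'   automatically when `NULL`.
#' @param config an [mcmc_config()]; the default reproduces the reference
#'   budget of 3 x 10,000 kept draws after 1,000 burn-in.
#' @param model_prior prior probabilities over models (default uniform).
#' @param family,sigma,cutpoints as in [fit_pseudo_priors()].
#' @param seed integer seed.
#' @return a `model_posterior` object: `table` (per hypothesis: visits, `pi`
#'   = visit proportion, batch-means `se`, rank), `visit_counts`
#'   (chain x model), `index_rhat` (max split-R-hat of the per-model visit
#'   indicators), `params` (per-model posterior summaries of its effect
#'   draws while active), plus the inputs needed to reproduce the run.
#' @export
run_product_space <- function(models, data, pseudo = NULL,
                              config = mcmc_config(), model_prior = NULL,
                              family = "hier_linear", seed = 1L,
                              sigma = NULL, cutpoints = likert_cutpoints()) {
  stopifnot(length(models) >= 2L)
  ids <- vapply(models, function(m) m$id, "")
  if (anyDuplicated(ids)) stop_bad_arg("model ids must be distinct")
  J <- length(models)
  model_prior <- model_prior %||% rep(1 / J, J)
  if (length(model_prior) != J || any(model_prior < 0) ||
      abs(sum(model_prior) - 1) > 1e-8)
    stop_bad_arg("model_prior must be ", J, " nonnegative values summing to 1")
  fam <- make_family(family, sigma, cutpoints)
  ss <- space_data(fam, data)
  if (is.null(pseudo))
    pseudo <- fit_pseudo_priors(models, data, family = fam,
                                seed = child_seed(seed, 7L))
  if (!all(ids %in% names(pseudo)))
    stop_bad_arg("pseudo-priors missing for: ",
                 paste(setdiff(ids, names(pseudo)), collapse = ", "))
  pm <- lapply(models, prior_moments)
  Xs <- lapply(models, function(m) resolved_X(m, ss$cells))
  lp_prior <- log(model_prior)

  visit_counts <- matrix(0L, config$n_chains, J,
                         dimnames = list(NULL, ids))
  index_chains <- vector("list", config$n_chains)
  p_sum <- lapply(models, function(m) numeric(length(m$effects)))
  p_sumsq <- p_sum
  p_n <- integer(J)

  for (ch in seq_len(config$n_chains)) {
    set.seed(child_seed(seed, 300L + ch))
    theta <- lapply(seq_len(J), function(j)
      setNames(as.numeric(pseudo[[ids[j]]]$mean), names(models[[j]]$effects)))
    common <- fam$init_common(ss)
    k <- sample.int(J, 1L, prob = model_prior)
    idx <- integer(config$n_samples)
    for (it in seq_len(config$burn_in + config$n_samples)) {
      if (!is.null(common))
        common <- fam$update_common(common, theta[[k]], ss, X = Xs[[k]])
      theta[[k]] <- fam$update_theta(theta[[k]], common, ss, pm[[k]],
                                     X = Xs[[k]])
      lw <- numeric(J)
      for (j in seq_len(J)) {
        ps <- pseudo[[ids[j]]]
        if (j != k)
          theta[[j]] <- rnorm(length(theta[[j]]), ps$mean, ps$sd)
        lw[j] <- lp_prior[j] +
          fam$log_lik(theta[[j]], common, ss, X = Xs[[j]]) +
          sum(dnorm(theta[[j]], pm[[j]]$mean, pm[[j]]$sd, log = TRUE)) -
          sum(dnorm(theta[[j]], ps$mean, ps$sd, log = TRUE))
      }
      w <- exp(lw - max(lw))
      k <- sample.int(J, 1L, prob = w)
      if (it > config$burn_in) {
        i <- it - config$burn_in
        idx[i] <- k
        p_sum[[k]] <- p_sum[[k]] + theta[[k]]
        p_sumsq[[k]] <- p_sumsq[[k]] + theta[[k]]^2
        p_n[k] <- p_n[k] + 1L
      }
    }
    index_chains[[ch]] <- idx
    visit_counts[ch, ] <- tabulate(idx, J)
  }

  total <- config$n_chains * config$n_samples
  pi_hat <- colSums(visit_counts) / total
  se <- vapply(seq_len(J), function(j) {
    v <- vapply(index_chains, function(idx) mc_se(as.numeric(idx == j))^2, 0)
    sqrt(sum(v)) / config$n_chains
  }, 0)
  rhat_j <- vapply(seq_len(J), function(j)
    split_rhat(lapply(index_chains, function(idx) as.numeric(idx == j))), 0)
  params <- lapply(seq_len(J), function(j) {
    if (p_n[j] == 0L) return(NULL)
    m <- p_sum[[j]] / p_n[j]
    v <- pmax(p_sumsq[[j]] / p_n[j] - m^2, 0)
    data.frame(param = names(models[[j]]$effects), mean = m, sd = sqrt(v),
               n_draws = p_n[j], row.names = NULL)
  })
  names(params) <- ids
  tab <- data.table::data.table(hypothesis = ids,
                                visits = colSums(visit_counts),
                                pi = pi_hat, se = se)
  data.table::setorder(tab, -pi)
  tab[, rank := seq_len(.N)]
  stuck <- max(pi_hat) > 0.99 && J > 1L
  if (stuck)
    message("index chain spent >99% of kept draws in one model; ",
            "verify with savage_dickey_bf() or a pseudo-prior change")
  structure(list(table = tab[], visit_counts = visit_counts,
                 index_rhat = max(rhat_j[is.finite(rhat_j)], -Inf),
                 params = params, model_prior = setNames(model_prior, ids),
                 pseudo = pseudo, config = config, seed = seed,
                 stuck = stuck, n_kept = total),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("Product-space posterior over", nrow(x$table), "hypotheses (",
      x$n_kept, "kept draws; max index split-Rhat",
      round(x$index_rhat, 3), ")\n")
  print(x$table[, .(hypothesis, pi = round(pi, 4), se = signif(se, 3),
                    visits, rank)])
  invisible(x)
}

#' Winning hypothesis of a model posterior
#'
#' Highest visit proportion wins; exact ties are all returned.
#' @param posterior a `model_posterior`.
#' @return character vector of hypothesis id(s) with maximal `pi`.
#' @export
top_hypothesis <- function(posterior) {
  tab <- posterior$table
  tab$hypothesis[tab$pi == max(tab$pi)]
}

#' Batch-means Monte-Carlo standard error of a visit proportion
#'
#' @param x numeric series of kept-draw indicators (or any ergodic series).
#' @param n_batches number of batches (default `floor(sqrt(length(x)))`).
#' @return standard error of `mean(x)`.
#' @export
mc_se <- function(x, n_batches = NULL) {
  n <- length(x)
  n_batches <- n_batches %||% floor(sqrt(n))
  if (n_batches < 20L)
    stop_bad_arg("too few batches (", n_batches,
                 "); need at least 20 for a stable batch-means estimate")
  b <- n %/% n_batches
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1L) * b + 1L):(i * b)]), 0)
  sd(means) / sqrt(n_batches)
}

#' Savage-Dickey density-ratio Bayes factor
#'
#' For a hypothesis nested at a point (e.g. "effect = 0") inside an
#' encompassing model, the Bayes factor in favour of the nested hypothesis
#' is the posterior density at the point divided by the prior density at the
#' point.  The posterior density is a Gaussian kernel estimate over the
#' pooled draws.  Used as an independent oracle for the product-space
#' sampler's nested comparisons.
#'
#' @param draws numeric posterior draws of the tested parameter, or a
#'   `ppscct_fit` (combined with `param`).
#' @param prior_mean,prior_sd the encompassing model's prior on the
#'   parameter.
#' @param test_point the nested point (default 0).
#' @param param column name when `draws` is a fit.
#' @return list with `bf` (BF nested : encompassing), `posterior_density`,
#'   `prior_density`, `n_near` (draws within one bandwidth of the point) and
#'   `flagged` (`TRUE` when `n_near < 10`, i.e. the estimate is unstable).
#' @export
savage_dickey_bf <- function(draws, prior_mean, prior_sd, test_point = 0,
                             param = NULL) {
  if (inherits(draws, "ppscct_fit")) {
    pooled <- do.call(rbind, draws$chains)
    param <- param %||% colnames(pooled)[1L]
    draws <- pooled[, param]
  }
  stopifnot(is.numeric(draws), length(draws) >= 100L)
  dens <- density(draws)
  post_at <- stats::approx(dens$x, dens$y, xout = test_point, rule = 2L)$y
  prior_at <- dnorm(test_point, prior_mean, prior_sd)
  n_near <- sum(abs(draws - test_point) <= dens$bw)
  flagged <- n_near < 10L
  if (flagged)
    warning("only ", n_near, " draw(s) within one bandwidth of the test ",
            "point; Savage-Dickey estimate is unstable", call. = FALSE)
  list(bf = post_at / prior_at, posterior_density = post_at,
       prior_density = prior_at, n_near = n_near, flagged = flagged)
}
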