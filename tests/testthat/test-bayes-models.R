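test_that("linear log-likelihood: standard-normal point, invariances", {
  d1 <- data.frame(participant = "p1", cell = "c", y = 0)
  p1 <- list(mu = c(c = 0), tau_p = 0, sigma = 1)
  expect_equal(loglik_linear(d1, p1), -0.5 * log(2 * pi))

  set.seed(1)
  d <- data.frame(participant = rep(sprintf("p%d", 1:4), each = 3L),
                  cell = rep(c("a", "b", "c"), 4L), y = rnorm(12, 10, 5))
  par <- list(mu = c(a = 8, b = 10, c = 12), tau_p = 3, sigma = 5)
  base <- loglik_linear(d, par)
  shifted <- d; shifted$y <- shifted$y + 17.3
  par_sh <- par; par_sh$mu <- par$mu + 17.3
  expect_equal(loglik_linear(shifted, par_sh), base)
  expect_error(loglik_linear(d, list(mu = par$mu, tau_p = 3, sigma = 0)),
               "sigma")
})

test_that("linear log-likelihood matches fine-grid quadrature to 1e-6", {
  set.seed(2)
  d <- data.frame(participant = rep(c("p1", "p2", "p3"), each = 2L),
                  cell = rep(c("a", "b"), 3L), y = rnorm(6, 40, 20))
  par <- list(mu = c(a = 35, b = 50), tau_p = 12, sigma = 18)
  expect_equal(loglik_linear(d, par), quad_loglik_hier(d, par),
               tolerance = 1e-6)
})

test_that("log-likelihood decreases moving away from the modelled mean", {
  d <- data.frame(participant = sprintf("p%d", 1:6), cell = "c",
                  y = rep(40, 6L))
  ll <- vapply(c(40, 60, 90, 150), function(m)
    loglik_linear(d, list(mu = c(c = m), tau_p = 5, sigma = 10)), 0)
  expect_true(all(diff(ll) < 0))
})

test_that("prior-only sampling recovers the prior's moments (normal family)", {
  h <- hypothesis_spec("m", c(mu = "active"), list(active = c(40, 20)))
  fam <- ppscct:::family_normal(sigma = 10)
  fit <- ppscct:::run_single_model(fam, fam$suffstats(numeric(0L)), h,
                                   mcmc_config(n_chains = 2L,
                                               burn_in = 200L,
                                               n_samples = 4000L), seed = 1)
  draws <- do.call(rbind, fit$chains)[, "mu"]
  expect_lt(abs(mean(draws) - 40), 3 * 20 / sqrt(length(draws)))
  expect_lt(abs(sd(draws) - 20), 1.5)
})

test_that("degenerate prior pins the posterior at its mean", {
  set.seed(4)
  dat <- data.frame(participant = sprintf("p%d", 1:10), cell = "c",
                    y = rnorm(10, 100, 10))
  h <- hypothesis_spec("null", c(c = "null"), list(null = c(0, 1e-4)))
  fit <- suppressWarnings(sample_posterior_linear(
    dat, h, mcmc_config(n_chains = 1L, burn_in = 200L, n_samples = 1000L),
    seed = 2))
  draws <- do.call(rbind, fit$chains)[, "c"]
  expect_lt(max(abs(draws)), 0.01)
})

test_that("hierarchical linear sampler recovers a known effect", {
  set.seed(5)
  dat <- data.frame(participant = rep(sprintf("p%02d", 1:20), each = 2L),
                    cell = rep(c("a", "b"), 20L),
                    y = rnorm(40, rep(c(40, 0), 20L), 30) +
                      rep(rnorm(20, 0, 10), each = 2L))
  h <- hypothesis_spec("m", c(a = "active", b = "null"))
  fit <- suppressWarnings(sample_posterior_linear(
    dat, h, mcmc_config(n_chains = 2L, burn_in = 300L, n_samples = 2000L),
    seed = 3))
  draws <- do.call(rbind, fit$chains)
  expect_lt(abs(mean(draws[, "a"]) - 40), 3 * sd(draws[, "a"]))
  expect_named(fit$rhat)
  ci <- credible_interval(fit, "a")
  expect_lt(ci[1L], 40); expect_gt(ci[2L], 0)
})

test_that("ordinal probabilities normalise and respect limits", {
  cuts <- likert_cutpoints()
  p0 <- ordinal_probs(0, cuts)
  expect_equal(sum(p0), 1, tolerance = 1e-12)
  expect_true(all(p0 > 0))
  expect_gt(ordinal_probs(40, cuts)[, 10L], 1 - 1e-12)  # coefficient -> +Inf
  # brute-force category arithmetic on a small dataset
  d <- data.frame(participant = c("p1", "p1", "p2"), cell = c("a", "b", "a"),
                  score = c(3L, 10L, 7L))
  par <- list(coef = c(a = 0.8, b = -1.2), b = c(p1 = 0.3, p2 = -0.1))
  eta <- c(0.8 + 0.3, -1.2 + 0.3, 0.8 - 0.1)
  manual <- sum(log(mapply(brute_ordinal_prob, d$score, eta,
                           MoreArgs = list(cutpoints = cuts))))
  expect_equal(loglik_ordinal_logit(d, par), manual, tolerance = 1e-10)
  expect_error(loglik_ordinal_logit(
    data.frame(participant = "p", cell = "a", score = 11L),
    list(coef = c(a = 0))), "1..10")
})

test_that("logit posterior follows the data direction", {
  d <- data.frame(participant = rep(sprintf("p%d", 1:6), each = 4L),
                  cell = "c", score = 10L)
  pri <- default_logit_priors()
  h <- hypothesis_spec("high", c(c = "high"), pri)
  fit <- suppressWarnings(sample_posterior_logit(
    d, h, mcmc_config(n_chains = 1L, burn_in = 300L, n_samples = 1500L),
    seed = 4))
  draws <- do.call(rbind, fit$chains)[, "c"]
  expect_gt(mean(draws), pri$low[1L])
  expect_gt(mean(draws), 0)
})

test_that("logit posterior is symmetric for mirror-symmetric data", {
  d <- data.frame(participant = rep(sprintf("p%d", 1:10), each = 2L),
                  cell = "c", score = rep(c(3L, 8L), 10L))  # 8 = 11 - 3
  h <- hypothesis_spec("m", c(c = "sym"), list(sym = c(0, 2)))
  fit <- suppressWarnings(sample_posterior_logit(
    d, h, mcmc_config(n_chains = 2L, burn_in = 300L, n_samples = 2000L),
    seed = 5))
  draws <- do.call(rbind, fit$chains)[, "c"]
  expect_lt(abs(mean(draws)), 6 * mc_se(draws))
})

test_that("logit sampler recovers known coefficients (n = 500 records)", {
  set.seed(6)
  cuts <- likert_cutpoints()
  truth <- c(a = 2, b = -1.5)
  cells <- rep(c("a", "b"), each = 250L)
  probs <- ordinal_probs(truth[cells], cuts)
  scores <- vapply(seq_len(500L), function(i)
    sample.int(10L, 1L, prob = probs[i, ]), 0L)
  d <- data.frame(participant = rep(sprintf("p%02d", 1:25), times = 20L),
                  cell = cells, score = scores)
  h <- hypothesis_spec("m", c(a = "wide", b = "wide"), list(wide = c(0, 3)))
  fit <- suppressWarnings(sample_posterior_logit(
    d, h, mcmc_config(n_chains = 1L, burn_in = 400L, n_samples = 2000L),
    seed = 6))
  draws <- do.call(rbind, fit$chains)
  for (p in c("a", "b"))
    expect_lt(abs(mean(draws[, p]) - truth[[p]]), 3 * sd(draws[, p]))
})

test_that("analytic normal marginal: empty, single-obs, quadrature", {
  expect_equal(analytic_log_marginal_normal(numeric(0L), 1, 0, 1), 0)
  y <- 0.7
  expect_equal(analytic_log_marginal_normal(y, 1, 0, 1),
               dnorm(y, 0, sqrt(2), log = TRUE))
  set.seed(7)
  y5 <- rnorm(5, 20, 10)
  expect_equal(analytic_log_marginal_normal(y5, 10, 15, 25),
               quad_log_marginal_normal(y5, 10, 15, 25), tolerance = 1e-8)
  expect_error(analytic_log_marginal_normal(y5, -1, 0, 1), "known_sigma")
})

test_that("hypothesis specs validate their priors and effects", {
  expect_error(hypothesis_spec("h", c(a = "weird")), "no prior")
  expect_error(hypothesis_spec("h", c(a = "null"),
                               list(null = c(0, -1))), "sd > 0")
  h <- hypothesis_spec("h", c(a = "null", b = "active"))
  pm <- ppscct:::prior_moments(h)
  expect_equal(pm$mean, c(a = 0, b = 40))
  expect_equal(pm$sd, c(a = 5, b = 20))
  # effects must match the data cells
  expect_error(sample_posterior_linear(
    data.frame(participant = "p", cell = "x", y = 1), h,
    mcmc_config(1L, 10L, 10L), seed = 1), "do not match")
})
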