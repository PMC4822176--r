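# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain loops, grid quadrature, closed forms.

# Brute-force CCE: base-R loops over (participant, condition, laterality).
brute_cce <- function(trials) {
  tr <- as.data.frame(trials)
  tr <- tr[tr$trial_kind == "experimental" & tr$correct, ]
  tr$congr <- ifelse(tr$tactile_elevation == tr$visual_elevation,
                     "congruent", "incongruent")
  tr$lat <- ifelse(tr$tactile_hand == tr$visual_side,
                   "ipsilateral", "contralateral")
  out <- list()
  for (p in unique(tr$participant)) for (cd in unique(tr$condition))
    for (l in c("contralateral", "ipsilateral")) {
      sel <- tr[tr$participant == p & tr$condition == cd & tr$lat == l, ]
      inc <- sel$rt_ms[sel$congr == "incongruent"]
      con <- sel$rt_ms[sel$congr == "congruent"]
      out[[length(out) + 1L]] <- data.frame(
        participant = p, condition = cd, laterality = l,
        cce_ms = if (length(inc) && length(con)) mean(inc) - mean(con)
                 else NA_real_)
    }
  do.call(rbind, out)
}

# Brute-force accuracy over experimental + false-stimulation trials.
brute_accuracy <- function(trials) {
  tr <- as.data.frame(trials)
  sapply(sort(unique(tr$participant)), function(p) {
    sel <- tr[tr$participant == p &
                tr$trial_kind %in% c("experimental", "false_stimulation"), ]
    ok <- ifelse(sel$trial_kind == "false_stimulation",
                 sel$response == "NIENTE",
                 (sel$response == "TAH" & sel$tactile_elevation == "high") |
                   (sel$response == "TOH" & sel$tactile_elevation == "low"))
    mean(ok)
  })
}

# Fine-grid quadrature of the normal marginal likelihood over a normal prior.
quad_log_marginal_normal <- function(y, sigma, prior_mean, prior_sd,
                                     n_grid = 20001L, width = 12) {
  mu <- seq(prior_mean - width * prior_sd, prior_mean + width * prior_sd,
            length.out = n_grid)
  lp <- vapply(mu, function(m)
    sum(dnorm(y, m, sigma, log = TRUE)) +
      dnorm(m, prior_mean, prior_sd, log = TRUE), 0)
  m <- max(lp)
  m + log(sum(exp(lp - m)) * (mu[2L] - mu[1L]))
}

# Fine-grid quadrature of the hierarchical linear likelihood: integrate the
# participant intercept out numerically, one participant at a time.
quad_loglik_hier <- function(data, params, n_grid = 4001L, width = 10) {
  d <- as.data.frame(data)
  s <- params$sigma; tau <- params$tau_p
  total <- 0
  for (p in unique(d$participant)) {
    sel <- d[d$participant == p, ]
    r <- sel$y - params$mu[as.character(sel$cell)]
    b <- seq(-width * tau, width * tau, length.out = n_grid)
    lp <- vapply(b, function(bb)
      sum(dnorm(r, bb, s, log = TRUE)) + dnorm(bb, 0, tau, log = TRUE), 0)
    m <- max(lp)
    total <- total + m + log(sum(exp(lp - m)) * (b[2L] - b[1L]))
  }
  total
}

# Brute-force ordinal category probability (scalar arithmetic).
brute_ordinal_prob <- function(k, eta, cutpoints) {
  upper <- if (k <= length(cutpoints)) 1 / (1 + exp(-(cutpoints[k] - eta)))
           else 1
  lower <- if (k >= 2L) 1 / (1 + exp(-(cutpoints[k - 1L] - eta))) else 0
  upper - lower
}

# Shared fixture: a small Exp-1-style dataset with PPS only in "real".
make_exp1_fixture <- function(seed, n = 18L, trials_per_combo = 9L,
                              extra = c(real = 70, fake = 0, void = 0)) {
  design <- cct_design("g", c("real", "fake", "void"), n,
                       trials_per_combo = trials_per_combo)
  effects <- cct_effects(cce_contra_ms = 30, cce_ipsi_extra_ms = extra,
                         error_rate = 0.07)
  trials <- generate_cct_dataset(design, effects, seed = seed)
  d <- cce_difference(compute_cce(score_trials(trials)))
  data.frame(participant = d$participant, cell = d$condition, y = d$d_ms)
}

# Conjugate two-model fixture shared by the product-space tests: data with a
# moderate effect so neither hypothesis is overwhelmingly favoured.
conjugate_fixture <- function() {
  set.seed(42)
  y <- rnorm(20, 15, 30)
  list(
    y = y, sigma = 30,
    models = list(
      hypothesis_spec("null", c(mu = "null"), list(null = c(0, 5))),
      hypothesis_spec("active", c(mu = "active"), list(active = c(40, 20)))),
    pi_active = {
      b <- exp(analytic_log_marginal_normal(y, 30, 40, 20) -
                 analytic_log_marginal_normal(y, 30, 0, 5))
      b / (1 + b)
    })
}
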