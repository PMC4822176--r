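# Experiment pipelines: compose generation/ingestion, preprocessing,
# hypothesis building and the product-space sampler into the three CCT
# analyses (feet, hands, passive motion) and the questionnaire analysis,
# driven by a YAML/list configuration.  Reports are plain lists serialised
# to JSON; given (config, seed) a run is fully reproducible and the report
# is byte-identical.

#' Load an experiment configuration
#'
#' @param config a YAML file path or a list.  Recognised fields:
#'   `experiment` (`exp1`, `exp2`, `exp3`, `questionnaire`), `seed`,
#'   `design` (arguments of [cct_design()]), `effects` (arguments of
#'   [cct_effects()], or a named list per group), `profile`
#'   (`"control"` or a cell table for [likert_profile()]),
#'   `trials_csv` / `questionnaire_csv` (ingest instead of simulating),
#'   `mcmc` and `pilot` (arguments of [mcmc_config()]), `priors`
#'   (label -> `c(mean, sd)` overrides), `exclusion_threshold`,
#'   `exp3_variant`, `out` (JSON report path), `summary` (text path).
#' @return validated config list.
#' @export
load_experiment_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$experiment <- match.arg(config$experiment,
                                 c("exp1", "exp2", "exp3", "questionnaire"))
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

config_design <- function(config) {
  d <- config$design %||% stop_bad_arg("config$design is required for ",
                                       "synthetic runs")
  do.call(cct_design, d)
}

config_effects <- function(config, design) {
  ef <- config$effects %||% list()
  per_group <- !is.null(names(ef)) && all(names(ef) %in% design$groups) &&
    length(ef) && all(vapply(ef, is.list, TRUE))
  if (per_group) lapply(ef, function(e) do.call(cct_effects, e))
  else do.call(cct_effects, ef)
}

config_mcmc <- function(x, default = mcmc_config()) {
  if (is.null(x)) default else do.call(mcmc_config, x)
}

config_priors <- function(config, default) {
  pr <- default
  for (nm in names(config$priors)) pr[[nm]] <- as.numeric(config$priors[[nm]])
  pr
}

# One product-space analysis on a prepared (data, models) pair.
analyse_space <- function(models, data, family, mcmc, pilot, seed) {
  pseudo <- fit_pseudo_priors(models, data, pilot_config = pilot,
                              family = family, seed = child_seed(seed, 11L))
  run_product_space(models, data, pseudo = pseudo, config = mcmc,
                    family = family, seed = child_seed(seed, 13L))
}

posterior_report <- function(post) {
  tab <- as.data.frame(post$table)
  list(hypotheses = tab,
       top = top_hypothesis(post),
       index_rhat = post$index_rhat,
       stuck = post$stuck,
       n_kept = post$n_kept,
       params = post$params[!vapply(post$params, is.null, TRUE)])
}

#' Run a full experiment analysis
#'
#' Generates (or ingests) trial/questionnaire tables, scores trials, applies
#' the accuracy exclusion, computes CCE and ipsi-minus-contra differences,
#' builds the experiment's hypothesis space, fits pseudo-priors, runs the
#' product-space sampler, and assembles a report.  Every hypothesis appears
#' in the report with its visit proportion, Monte-Carlo SE and rank.
#'
#' @param config see [load_experiment_config()].
#' @return the report list (also written to `config$out` /
#'   `config$summary` when set), with elements `experiment`, `seed`,
#'   `priors`, `exclusions`, and `analyses` (one entry per group, or per
#'   group x component for the questionnaire).
#' @export
run_experiment <- function(config) {
  config <- load_experiment_config(config)
  seed <- config$seed
  exp <- config$experiment
  mcmc <- config_mcmc(config$mcmc)
  pilot <- config_mcmc(config$pilot,
                       mcmc_config(n_chains = 1L, burn_in = 500L,
                                   n_samples = 2000L))
  report <- list(experiment = exp, seed = seed)

  if (exp == "questionnaire") {
    priors <- config_priors(config, default_logit_priors())
    if (!is.null(config$questionnaire_csv)) {
      q <- read_questionnaire(config$questionnaire_csv)
      if (is.null(q$group)) q$group <- "all"
      conditions <- sort(unique(q$condition))
    } else {
      design <- config_design(config)
      conditions <- design$conditions
      profile <- if (is.null(config$profile) ||
                     identical(config$profile, "control"))
        likert_profile_control(conditions)
      else likert_profile(do.call(rbind.data.frame, config$profile))
      q <- generate_questionnaire(design, profile, seed = seed)
    }
    models <- build_questionnaire_hypotheses(conditions, priors = priors)
    analyses <- list()
    for (g in sort(unique(q$group))) {
      for (comp in sort(unique(q$component))) {
        d <- q[q$group == g & q$component == comp, ]
        dat <- data.frame(participant = d$participant,
                          cell = paste(d$condition, d$time, sep = "."),
                          score = d$score)
        post <- analyse_space(models, dat, "ordinal", mcmc, pilot,
                              child_seed(seed, 1000L + length(analyses)))
        analyses[[paste(g, comp, sep = "/")]] <- posterior_report(post)
      }
    }
    report$priors <- priors
    report$n_hypotheses <- length(models)
    report$analyses <- analyses
    return(finalise_report(report, config))
  }

  # CCE experiments -----------------------------------------------------
  priors <- config_priors(config, default_effect_priors())
  if (!is.null(config$trials_csv)) {
    trials <- read_trials(config$trials_csv)
    if (is.null(trials$group)) trials$group <- "all"
  } else {
    design <- config_design(config)
    trials <- generate_cct_dataset(design, config_effects(config, design),
                                   seed = seed)
  }
  scored <- score_trials(trials)
  excl <- exclude_low_accuracy(scored,
                               threshold = config$exclusion_threshold %||%
                                 0.44)
  cce <- compute_cce(excl$trials)
  d <- cce_difference(cce)
  report$exclusions <- list(threshold = config$exclusion_threshold %||% 0.44,
                            excluded = excl$excluded,
                            accuracy = as.data.frame(excl$accuracy))
  report$priors <- priors
  conditions <- sort(unique(as.character(d$condition)))

  analyses <- list()
  if (exp %in% c("exp1", "exp2")) {
    models <- if (exp == "exp1")
      build_hypothesis_space_exp1(conditions, priors = priors)
    else build_hypothesis_space_exp2(conditions, priors = priors)
    for (g in sort(unique(as.character(d$group)))) {
      dat <- d[d$group == g, ]
      post <- analyse_space(models,
                            data.frame(participant = dat$participant,
                                       cell = dat$condition, y = dat$d_ms),
                            "hier_linear", mcmc, pilot,
                            child_seed(seed, 2000L + length(analyses)))
      analyses[[g]] <- posterior_report(post)
    }
  } else {  # exp3: one joint analysis across the two groups
    variant <- config$exp3_variant %||% "difference"
    groups <- sort(unique(as.character(d$group)))
    models <- build_hypothesis_space_exp3(groups, variant = variant,
                                          priors = priors)
    dat <- if (variant == "difference")
      data.frame(participant = d$participant, cell = d$group, y = d$d_ms)
    else data.frame(participant = cce$participant,
                    cell = paste(cce$group, cce$laterality, sep = "."),
                    y = cce$cce_ms)
    dat <- dat[!is.na(dat$y), ]
    post <- analyse_space(models, dat, "hier_linear", mcmc, pilot,
                          child_seed(seed, 3000L))
    analyses[["joint"]] <- posterior_report(post)
    report$exp3_variant <- variant
  }
  report$n_hypotheses <- length(models)
  report$analyses <- analyses
  finalise_report(report, config)
}

finalise_report <- function(report, config) {
  if (!is.null(config$out)) {
    dir.create(dirname(config$out), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(config$summary)) {
    con <- file(config$summary, "w")
    writeLines(format_report(report), con)
    close(con)
  }
  invisible(report)
}

#' Human-readable experiment summary
#'
#' @param report a report from [run_experiment()].
#' @return character vector of summary lines.
#' @export
format_report <- function(report) {
  lines <- c(sprintf("Experiment: %s (seed %d)", report$experiment,
                     report$seed),
             sprintf("Hypotheses per analysis: %d", report$n_hypotheses))
  if (!is.null(report$exclusions))
    lines <- c(lines, sprintf("Excluded participants (accuracy <= %.0f%%): %s",
                              100 * report$exclusions$threshold,
                              if (length(report$exclusions$excluded))
                                paste(report$exclusions$excluded,
                                      collapse = ", ") else "none"))
  for (nm in names(report$analyses)) {
    a <- report$analyses[[nm]]
    lines <- c(lines, sprintf("-- %s (max index split-Rhat %.3f)", nm,
                              a$index_rhat))
    h <- a$hypotheses
    for (i in seq_len(nrow(h)))
      lines <- c(lines, sprintf("   %-28s pi = %.4f (se %.4f)",
                                h$hypothesis[i], h$pi[i], h$se[i]))
    lines <- c(lines, sprintf("   winner: %s",
                              paste(a$top, collapse = " tied with ")))
  }
  lines
}

## ---------------------------------------------------------------- CLI ------

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  positional <- character(0L)
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      flags[[substring(a, 3L)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

#' Command-line interface
#'
#' Subcommands: `synth trials|questionnaire|audio`, `rtaudio extract`,
#' `preprocess`, `run`, `hypotheses`.  Invoke via
#' `Rscript -e 'ppscct::pps_cli()' <subcommand> --flag value ...` or the
#' wrapper script in `inst/cli/pps`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit-relevant result, invisibly.
#' @export
pps_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: pps <synth|rtaudio|preprocess|run|hypotheses> [--flags]\n")
    return(invisible(NULL))
  }
  p <- parse_cli_flags(args[-1L])
  fl <- p$flags
  seed <- as.integer(fl$seed %||% 1L)
  switch(args[[1L]],
    synth = {
      what <- if (length(p$positional)) p$positional[1L] else "trials"
      cfg <- if (!is.null(fl$config)) yaml::read_yaml(fl$config) else list()
      design <- do.call(cct_design, cfg$design %||%
                          list(groups = "control",
                               conditions = c("real", "fake", "void"),
                               n_participants_per_group = 18L))
      if (what == "trials") {
        ef <- if (is.null(cfg$effects)) cct_effects()
              else do.call(cct_effects, cfg$effects)
        write_trials(generate_cct_dataset(design, ef, seed = seed),
                     fl$out %||% "trials.csv")
      } else if (what == "questionnaire") {
        write_questionnaire(
          generate_questionnaire(design,
                                 likert_profile_control(design$conditions),
                                 seed = seed),
          fl$out %||% "questionnaire.csv")
      } else if (what == "audio") {
        dir.create(fl$out %||% "audio", showWarnings = FALSE,
                   recursive = TRUE)
        n <- as.integer(fl$n %||% 10L)
        set.seed(child_seed(seed, 5L))
        onsets <- runif(n, 300, 900)
        for (i in seq_len(n))
          write_wav(generate_voice_wav(onsets[i], 1500,
                                       seed = child_seed(seed, 50L + i)),
                    file.path(fl$out %||% "audio",
                              sprintf("trial_%03d.wav", i)))
      } else stop_bad_arg("unknown synth target: ", what)
    },
    rtaudio = extract_rts(fl$`in` %||% ".", out = fl$out %||% "rts.csv"),
    preprocess = {
      trials <- score_trials(read_trials(fl$trials))
      excl <- exclude_low_accuracy(trials)
      cce <- compute_cce(excl$trials)
      data.table::fwrite(cce_difference(cce), fl$out %||% "cce.csv")
      if (!is.null(fl$report))
        jsonlite::write_json(list(excluded = excl$excluded,
                                  accuracy = as.data.frame(excl$accuracy)),
                             fl$report, auto_unbox = TRUE, digits = NA)
    },
    run = {
      report <- run_experiment(fl$config)
      cat(format_report(report), sep = "\n")
      return(invisible(report))
    },
    hypotheses = {
      space <- switch(fl$space %||% "exp1",
                      exp1 = build_hypothesis_space_exp1(),
                      exp2 = build_hypothesis_space_exp2(),
                      exp3 = build_hypothesis_space_exp3(),
                      questionnaire = build_questionnaire_hypotheses())
      for (h in space) print(h)
      return(invisible(space))
    },
    stop_bad_arg("unknown subcommand: ", args[[1L]])
  )
  invisible(NULL)
}
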