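# Synthetic crossmodal congruency task (CCT) data generation.
#
# The generator emulates the design of a feet/hands CCT study of peripersonal
# space (PPS): per condition, 9 repetitions of each of the 16 visuo-tactile
# combinations (2 tactile hands x 2 tactile elevations x 2 visual sides x
# 2 visual elevations) plus 9 yellow-LED control trials and 9 false
# stimulations = 162 trials, split over 3 blocks. Verbal response tokens are
# TAH (tactile high), TOH (tactile low), LUCI (control light), NIENTE
# (false stimulation).

RESPONSE_TOKENS <- c("TAH", "TOH", "LUCI", "NIENTE")

# Stimulus timing constants, carried as metadata only (not simulated):
# tactile = three 50 ms vibrations separated by 50 ms gaps; the visual
# distractor train starts 30 ms before the tactile train.
STIMULUS_TIMING <- list(pulse_ms = 50, gap_ms = 50, n_pulses = 3L,
                        visual_lead_ms = 30)

#' Experiment design for a synthetic CCT study
#'
#' @param groups character vector of group labels (e.g. `c("control", "pcl")`).
#' @param conditions character vector of condition labels
#'   (e.g. `c("real", "fake", "void")`).
#' @param n_participants_per_group participants per group.
#' @param n_blocks blocks per condition (default 3).
#' @param trials_per_combo repetitions of each of the 16 visuo-tactile
#'   combinations per condition (default 9, i.e. 144 experimental trials).
#' @param n_control yellow-LED control trials per condition (default 9).
#' @param n_false false stimulations per condition (default 9).
#' @return a `cct_design` object.
#' @export
#' @examples
#' d <- cct_design("control", c("real", "fake", "void"), 18)
#' d$trials_per_condition  # 162
cct_design <- function(groups, conditions, n_participants_per_group,
                       n_blocks = 3L, trials_per_combo = 9L,
                       n_control = 9L, n_false = 9L) {
  stopifnot(is.character(groups), length(groups) >= 1L,
            is.character(conditions), length(conditions) >= 1L,
            !anyDuplicated(groups), !anyDuplicated(conditions))
  d <- list(
    groups = groups,
    conditions = conditions,
    n_participants_per_group = check_count(n_participants_per_group,
                                           "n_participants_per_group"),
    n_blocks = check_count(n_blocks, "n_blocks"),
    trials_per_combo = check_count(trials_per_combo, "trials_per_combo"),
    n_control = check_count(n_control, "n_control", lower = 0L),
    n_false = check_count(n_false, "n_false", lower = 0L)
  )
  d$experimental_per_condition <- d$trials_per_combo * 16L
  d$trials_per_condition <- d$experimental_per_condition + d$n_control + d$n_false
  structure(d, class = "cct_design")
}

#' @export
print.cct_design <- function(x, ...) {
  cat("CCT design:", length(x$groups), "group(s) x",
      x$n_participants_per_group, "participants x",
      length(x$conditions), "condition(s);",
      x$trials_per_condition, "trials/condition (",
      x$experimental_per_condition, "experimental +",
      x$n_control, "control +", x$n_false, "false )\n")
  invisible(x)
}

#' Effect specification for RT generation
#'
#' Trial-level reaction times are drawn (per participant `p`, condition `c`)
#' around `baseline_rt_ms + b_p + shift`, where `b_p ~ N(0, participant_sd_ms)`
#' and the shift is 0 for congruent trials, `cce_contra_ms[c]` for incongruent
#' contralateral trials and `cce_contra_ms[c] + cce_ipsi_extra_ms[c]` for
#' incongruent ipsilateral ones. A PPS representation is "present" in a
#' condition exactly when its `cce_ipsi_extra_ms > 0`.
#'
#' @param baseline_rt_ms mean correct-response RT with no interference (ms).
#' @param participant_sd_ms SD of participant baseline offsets (ms).
#' @param residual_sd_ms trial-level SD (ms); 0 gives noise-free RTs.
#' @param cce_contra_ms contralateral congruency effect per condition; a
#'   scalar or a vector named by condition.
#' @param cce_ipsi_extra_ms ipsilateral-minus-contralateral PPS component per
#'   condition; scalar or named vector.
#' @param error_rate per-trial probability of an incorrect response token.
#' @param rt_family `"lognormal"` (right-skewed, the default) or `"normal"`.
#' @return a `cct_effects` object.
#' @export
cct_effects <- function(baseline_rt_ms = 600, participant_sd_ms = 40,
                        residual_sd_ms = 150, cce_contra_ms = 30,
                        cce_ipsi_extra_ms = 70, error_rate = 0.07,
                        rt_family = c("lognormal", "normal")) {
  check_number(baseline_rt_ms, "baseline_rt_ms", lower = 0, strict_lower = TRUE)
  check_number(participant_sd_ms, "participant_sd_ms", lower = 0)
  check_number(residual_sd_ms, "residual_sd_ms", lower = 0)
  check_number(error_rate, "error_rate", lower = 0, upper = 1)
  # accept named lists (e.g. from YAML configs) as per-condition values
  if (is.list(cce_contra_ms)) cce_contra_ms <- unlist(cce_contra_ms)
  if (is.list(cce_ipsi_extra_ms)) cce_ipsi_extra_ms <- unlist(cce_ipsi_extra_ms)
  stopifnot(is.numeric(cce_contra_ms), is.numeric(cce_ipsi_extra_ms))
  structure(list(
    baseline_rt_ms = baseline_rt_ms, participant_sd_ms = participant_sd_ms,
    residual_sd_ms = residual_sd_ms, cce_contra_ms = cce_contra_ms,
    cce_ipsi_extra_ms = cce_ipsi_extra_ms, error_rate = error_rate,
    rt_family = match.arg(rt_family)
  ), class = "cct_effects")
}

effect_for_condition <- function(x, condition) {
  if (is.null(names(x))) x[[1L]]
  else if (condition %in% names(x)) x[[condition]]
  else stop_bad_arg("no effect value for condition '", condition, "'")
}

# One RT draw per row with exact mean `mean_ms`; for the lognormal family the
# meanlog/sdlog are chosen so that E[RT] = mean_ms and SD[RT] = sd_ms.
draw_rt <- function(n, mean_ms, sd_ms, family) {
  if (sd_ms == 0) return(rep(mean_ms, length.out = n))
  if (family == "normal") return(rnorm(n, mean_ms, sd_ms))
  sdlog2 <- log(1 + (sd_ms / mean_ms)^2)
  rlnorm(n, meanlog = log(mean_ms) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

wrong_token <- function(correct_token) {
  pool <- lapply(correct_token, function(tok) setdiff(RESPONSE_TOKENS, tok))
  vapply(seq_along(correct_token),
         function(i) pool[[i]][sample.int(3L, 1L)], "")
}

#' Generate a synthetic CCT trial table
#'
#' Produces one row per trial with the exact per-condition trial counts and
#' factor balance of the design, for every participant of every group.
#' Incorrect trials (probability `error_rate`, independently per trial)
#' receive a uniformly random wrong response token.
#'
#' @param design a [cct_design()].
#' @param effects a [cct_effects()] applied to all groups, or a named list
#'   with one `cct_effects` per group.
#' @param seed integer seed; output is bit-identical for equal inputs.
#' @return a `data.table` of trials (one row each) with columns
#'   `participant, group, condition, block, trial_kind, tactile_hand,
#'   tactile_elevation, visual_side, visual_elevation, response, rt_ms`.
#' @export
#' @examples
#' d <- cct_design("g", "real", 1)
#' tr <- generate_cct_dataset(d, cct_effects(error_rate = 0), seed = 1)
#' nrow(tr)  # 162
generate_cct_dataset <- function(design, effects, seed) {
  stopifnot(inherits(design, "cct_design"))
  if (inherits(effects, "cct_effects"))
    effects <- setNames(rep(list(effects), length(design$groups)), design$groups)
  if (!all(design$groups %in% names(effects)))
    stop_bad_arg("effects must be provided for every group")
  set.seed(child_seed(seed, 1L))

  # balanced experimental grid; repetitions of each combination are spread
  # as evenly as possible over blocks
  combos <- data.table::CJ(tactile_hand = c("left", "right"),
                           tactile_elevation = c("high", "low"),
                           visual_side = c("left", "right"),
                           visual_elevation = c("high", "low"))
  reps <- design$trials_per_combo
  block_of_rep <- rep(seq_len(design$n_blocks), length.out = reps)

  one_condition <- function(cond) {
    exper <- combos[rep(seq_len(nrow(combos)), each = reps)]
    exper[, `:=`(trial_kind = "experimental",
                 block = rep(block_of_rep, times = nrow(combos)))]
    extras <- function(kind, n) data.table::data.table(
      tactile_hand = NA_character_, tactile_elevation = NA_character_,
      visual_side = sample(c("left", "right"), n, replace = TRUE),
      visual_elevation = sample(c("high", "low"), n, replace = TRUE),
      trial_kind = kind, block = rep(seq_len(design$n_blocks), length.out = n))
    tab <- data.table::rbindlist(list(
      exper,
      extras("control_light", design$n_control),
      extras("false_stimulation", design$n_false)), use.names = TRUE)
    tab[trial_kind != "experimental",
        `:=`(tactile_hand = NA_character_, tactile_elevation = NA_character_)]
    # control lights carry no distractor geometry either
    tab[trial_kind == "control_light",
        `:=`(visual_side = NA_character_, visual_elevation = NA_character_)]
    tab[, condition := cond]
    tab[sample.int(nrow(tab))]  # shuffle presentation order within condition
  }

  rows <- list()
  for (g in design$groups) {
    ef <- effects[[g]]
    stopifnot(inherits(ef, "cct_effects"))
    for (i in seq_len(design$n_participants_per_group)) {
      pid <- sprintf("%s_%02d", g, i)
      b_p <- rnorm(1L, 0, ef$participant_sd_ms)
      tab <- data.table::rbindlist(lapply(design$conditions, one_condition))
      tab[, `:=`(participant = pid, group = g)]
      incong <- tab$trial_kind == "experimental" &
        tab$tactile_elevation != tab$visual_elevation
      ipsi <- tab$trial_kind == "experimental" &
        tab$tactile_hand == tab$visual_side
      shift <- numeric(nrow(tab))
      for (cond in design$conditions) {
        cc <- effect_for_condition(ef$cce_contra_ms, cond)
        ce <- effect_for_condition(ef$cce_ipsi_extra_ms, cond)
        sel <- tab$condition == cond & incong
        shift[sel] <- cc + ce * ipsi[sel]
      }
      mean_ms <- pmax(ef$baseline_rt_ms + b_p + shift, 1)
      tab[, rt_ms := draw_rt(.N, mean_ms, ef$residual_sd_ms, ef$rt_family)]
      truth <- data.table::fcase(
        tab$trial_kind == "control_light", "LUCI",
        tab$trial_kind == "false_stimulation", "NIENTE",
        tab$tactile_elevation == "high", "TAH",
        default = "TOH")
      wrong <- runif(nrow(tab)) < ef$error_rate
      resp <- truth
      if (any(wrong)) resp[wrong] <- wrong_token(truth[wrong])
      tab[, response := resp]
      rows[[length(rows) + 1L]] <- tab
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("participant", "group", "condition", "block",
                                 "trial_kind", "tactile_hand",
                                 "tactile_elevation", "visual_side",
                                 "visual_elevation", "response", "rt_ms"))
  out[]
}

## ---------------------------------------------------------------- Likert ----

#' Equidistant latent cut-points for a 1..n_cat Likert scale
#'
#' @param n_cat number of categories (default 10).
#' @param delta spacing of the cut-points on the logit scale (default 1).
#' @return numeric vector of `n_cat - 1` cut-points centred on 0.
#' @export
likert_cutpoints <- function(n_cat = 10L, delta = 1) {
  n_cat <- check_count(n_cat, "n_cat", lower = 2L)
  delta * (seq_len(n_cat - 1L) - n_cat / 2)
}

# Category probabilities of the latent-logistic cut-point model at a given
# location/dispersion.
likert_probs <- function(location, dispersion = 1,
                         cutpoints = likert_cutpoints()) {
  cdf <- c(plogis((cutpoints - location) / dispersion), 1)
  diff(c(0, cdf))
}

#' Expected Likert score under the latent-logistic model
#'
#' Closed-form expectation `sum(k * P(k))` over the categories; used both to
#' calibrate profiles and as a test oracle.
#' @param location latent location (logit scale).
#' @param dispersion latent logistic scale (> 0).
#' @param cutpoints cut-point vector, see [likert_cutpoints()].
#' @return expected score in `[1, n_cat]`.
#' @export
expected_likert_mean <- function(location, dispersion = 1,
                                 cutpoints = likert_cutpoints()) {
  p <- likert_probs(location, dispersion, cutpoints)
  sum(seq_along(p) * p)
}

# Invert expected_likert_mean in the location (monotone increasing).
likert_location_for_mean <- function(target, dispersion = 1,
                                     cutpoints = likert_cutpoints()) {
  n_cat <- length(cutpoints) + 1L
  target <- min(max(target, 1 + 1e-9), n_cat - 1e-9)
  f <- function(loc) expected_likert_mean(loc, dispersion, cutpoints) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0) return(lo)
  if (f(hi) < 0) return(hi)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Likert response profile
#'
#' One latent (location, dispersion) pair per (component, condition, time)
#' cell of the ownership questionnaire.
#'
#' @param cells a data.frame with columns `component, condition, time,
#'   location, dispersion`; `time` is `"before"` or `"after"`.
#' @return a `likert_profile` object.
#' @export
likert_profile <- function(cells) {
  cells <- as.data.frame(cells)
  need <- c("component", "condition", "time", "location", "dispersion")
  if (!all(need %in% names(cells)))
    stop_bad_arg("profile needs columns ", paste(need, collapse = ", "))
  if (any(cells$dispersion <= 0)) stop_bad_arg("dispersion must be > 0")
  if (!all(cells$time %in% c("before", "after")))
    stop_bad_arg("time must be 'before' or 'after'")
  structure(list(cells = cells, cutpoints = likert_cutpoints()),
            class = "likert_profile")
}

#' Control-like default questionnaire profile
#'
#' A profile whose expected cell means reproduce the pattern reported for
#' healthy controls: near-ceiling embodiment of the own (real) feet, floor
#' embodiment with fake feet or an empty frame, floor loss/perceived-movement
#' everywhere, and uniformly high compliance. Locations are solved
#' numerically so that the expected score of each cell equals its target.
#'
#' @param conditions condition labels; defaults to the feet experiment's
#'   `real`, `fake`, `void`.
#' @param dispersion latent dispersion shared by all cells.
#' @return a [likert_profile()].
#' @export
likert_profile_control <- function(conditions = c("real", "fake", "void"),
                                   dispersion = 1) {
  base <- list(  # target means: before, after for real/fake/void
    embodiment = c(9.56, 8.89, 1.00, 1.89, 1.00, 1.00),
    loss       = c(1.11, 1.78, 1.67, 1.67, 1.44, 1.44),
    movement   = c(1.67, 1.44, 1.00, 1.67, 1.22, 1.00),
    compliance = c(8.11, 7.56, 8.11, 8.00, 7.56, 7.78))
  grid <- expand.grid(time = c("before", "after"),
                      condition = c("real", "fake", "void"),
                      component = names(base),
                      stringsAsFactors = FALSE)
  grid$target <- unlist(base)[(match(grid$component, names(base)) - 1L) * 6L +
                                (match(grid$condition,
                                       c("real", "fake", "void")) - 1L) * 2L +
                                match(grid$time, c("before", "after"))]
  grid <- grid[grid$condition %in% conditions, ]
  grid$location <- vapply(grid$target, likert_location_for_mean, 0,
                          dispersion = dispersion)
  grid$dispersion <- dispersion
  likert_profile(grid[c("component", "condition", "time",
                        "location", "dispersion")])
}

#' Generate a synthetic ownership questionnaire table
#'
#' Two items per component are generated in every (participant, condition,
#' time) cell, matching the averaging scheme in which a component score is
#' the mean of its two item scores.
#'
#' @param design a [cct_design()].
#' @param profile a [likert_profile()] used for all groups, or a named list
#'   with one profile per group.
#' @param seed integer seed.
#' @return a `data.table` with columns `participant, group, condition, time,
#'   component, item, score` (scores are integers 1..10).
#' @export
generate_questionnaire <- function(design, profile, seed) {
  stopifnot(inherits(design, "cct_design"))
  if (inherits(profile, "likert_profile"))
    profile <- setNames(rep(list(profile), length(design$groups)),
                        design$groups)
  if (!all(design$groups %in% names(profile)))
    stop_bad_arg("profile must be provided for every group")
  set.seed(child_seed(seed, 2L))
  rows <- list()
  for (g in design$groups) {
    pr <- profile[[g]]
    stopifnot(inherits(pr, "likert_profile"))
    cells <- pr$cells
    need <- expand.grid(condition = design$conditions,
                        time = c("before", "after"),
                        component = unique(cells$component),
                        stringsAsFactors = FALSE)
    key <- function(d) paste(d$component, d$condition, d$time)
    missing <- setdiff(key(need), key(cells))
    if (length(missing))
      stop_bad_arg("profile is missing cells: ",
                   paste(missing, collapse = "; "))
    cells <- cells[cells$condition %in% design$conditions, ]
    n_cat <- length(pr$cutpoints) + 1L
    for (i in seq_len(design$n_participants_per_group)) {
      pid <- sprintf("%s_%02d", g, i)
      for (r in seq_len(nrow(cells))) {
        p <- likert_probs(cells$location[r], cells$dispersion[r], pr$cutpoints)
        sc <- sample.int(n_cat, 2L, replace = TRUE, prob = p)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          participant = pid, group = g, condition = cells$condition[r],
          time = cells$time[r], component = cells$component[r],
          item = 1:2, score = sc)
      }
    }
  }
  data.table::rbindlist(rows)[]
}

## ----------------------------------------------------------------- audio ----

#' Generate a synthetic voice-response waveform
#'
#' A mono waveform with Gaussian background noise throughout and a voiced
#' (high-energy, harmonic) segment starting at `onset_ms`; emulates the
#' 8 kHz WAV recordings from which verbal-response RTs are extracted.
#'
#' @param onset_ms voice onset time in ms (>= 0).
#' @param duration_ms total duration in ms.
#' @param sample_rate samples per second (default 8000).
#' @param noise_amplitude background-noise SD on the amplitude scale (-1..1);
#'   0 gives an exactly silent pre-onset segment.
#' @param seed integer seed.
#' @param voiced_ms duration of the voiced segment (default: 300 ms, clipped
#'   to the end of the file).
#' @param voiced_amplitude peak amplitude of the voiced segment.
#' @return a `voice_wave` list: `wave` (numeric samples, -1..1),
#'   `sample_rate`, `onset_sample` (0-based index of the first voiced
#'   sample; the test oracle), `onset_ms`.
#' @export
#' @examples
#' w <- generate_voice_wav(500, 1000, seed = 1)
#' w$onset_sample  # 4000
generate_voice_wav <- function(onset_ms, duration_ms, sample_rate = 8000L,
                               noise_amplitude = 0.02, seed = 1L,
                               voiced_ms = 300, voiced_amplitude = 0.5) {
  check_number(onset_ms, "onset_ms", lower = 0)
  check_number(duration_ms, "duration_ms", lower = 0, strict_lower = TRUE)
  check_number(noise_amplitude, "noise_amplitude", lower = 0)
  sample_rate <- check_count(sample_rate, "sample_rate")
  if (onset_ms >= duration_ms)
    stop_bad_arg("onset_ms must fall within duration_ms")
  voiced_ms <- min(voiced_ms, duration_ms - onset_ms)
  set.seed(child_seed(seed, 3L))
  n <- round(duration_ms * sample_rate / 1000)
  onset_sample <- round(onset_ms * sample_rate / 1000)  # 0-based
  wave <- if (noise_amplitude > 0) rnorm(n, 0, noise_amplitude) else numeric(n)
  nv <- round(voiced_ms * sample_rate / 1000)
  t <- seq_len(nv) / sample_rate
  f0 <- 150
  # harmonic weights normalised to unit power, so the voiced RMS is
  # voiced_amplitude / sqrt(2), as for a pure sine of that amplitude
  wgt <- c(0.6, 0.3, 0.1) / sqrt(sum(c(0.6, 0.3, 0.1)^2))
  voiced <- voiced_amplitude *
    (wgt[1L] * sin(2 * pi * f0 * t) + wgt[2L] * sin(2 * pi * 2 * f0 * t) +
       wgt[3L] * sin(2 * pi * 3 * f0 * t))
  # brief linear attack (5 ms) so the segment is not a hard click
  attack <- pmin(seq_len(nv) / (0.005 * sample_rate), 1)
  idx <- onset_sample + seq_len(nv)
  wave[idx] <- wave[idx] + voiced * attack
  wave <- pmin(pmax(wave, -1), 1)
  structure(list(wave = wave, sample_rate = sample_rate,
                 onset_sample = onset_sample, onset_ms = onset_ms),
            class = "voice_wave")
}

## ---------------------------------------------------------------- CSV IO ----

#' Read/write trial and questionnaire tables as CSV
#'
#' Plain-CSV persistence with the documented headers used throughout the
#' package (see [generate_cct_dataset()] and [generate_questionnaire()]).
#' @param x table to write.
#' @param path CSV file path.
#' @return `read_trials`/`read_questionnaire` return a `data.table`.
#' @export
write_trials <- function(x, path) data.table::fwrite(x, path)

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- data.table::fread(path, colClasses = list(character = "participant"),
                          na.strings = c("", "NA"))
  need <- c("participant", "condition", "trial_kind", "response", "rt_ms")
  if (!all(need %in% names(tr)))
    stop_bad_arg("trial CSV must contain columns ",
                 paste(need, collapse = ", "))
  tr
}

#' @rdname write_trials
#' @export
write_questionnaire <- function(x, path) data.table::fwrite(x, path)

#' @rdname write_trials
#' @export
read_questionnaire <- function(path) {
  q <- data.table::fread(path, colClasses = list(character = "participant"),
                         na.strings = c("", "NA"))
  need <- c("participant", "condition", "time", "component", "score")
  if (!all(need %in% names(q)))
    stop_bad_arg("questionnaire CSV must contain columns ",
                 paste(need, collapse = ", "))
  q
}
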