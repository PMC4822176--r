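# Trial scoring, participant exclusion, and crossmodal congruency effects.
#
# The CCE is mean RT(incongruent) - mean RT(congruent), computed from correct
# trials only, separately for ipsilateral trials (visual distractor on the
# side of the stimulated hand) and contralateral trials.  A PPS
# representation is inferred when the ipsilateral CCE exceeds the
# contralateral CCE, so the quantity carried into the Bayesian models is
# d = CCE(ipsi) - CCE(contra).

#' Score trials for correctness
#'
#' An experimental trial is correct iff the token matches the tactile
#' elevation (`TAH` = high, `TOH` = low); a control-light trial iff the token
#' is `LUCI`; a false stimulation iff the token is `NIENTE`.  Congruency and
#' laterality labels are derived at the same time.
#'
#' @param trials a trial table (see [generate_cct_dataset()]).
#' @return a copy of the table with logical `correct` and character
#'   `congruency` (`congruent`/`incongruent`) and `laterality`
#'   (`ipsilateral`/`contralateral`) columns (the latter two `NA` outside
#'   experimental trials).
#' @export
score_trials <- function(trials) {
  tr <- data.table::as.data.table(trials)
  bad <- !(tr$response %in% RESPONSE_TOKENS)
  if (any(bad))
    stop_bad_arg("unknown response token '", tr$response[which(bad)[1L]],
                 "' in row ", which(bad)[1L])
  tr[, correct := data.table::fcase(
    trial_kind == "control_light", response == "LUCI",
    trial_kind == "false_stimulation", response == "NIENTE",
    trial_kind == "experimental",
    (response == "TAH" & tactile_elevation == "high") |
      (response == "TOH" & tactile_elevation == "low"),
    default = NA)]
  if (anyNA(tr$correct))
    stop_bad_arg("unknown trial_kind '",
                 tr$trial_kind[which(is.na(tr$correct))[1L]], "'")
  tr[, congruency := data.table::fifelse(
    trial_kind == "experimental",
    data.table::fifelse(tactile_elevation == visual_elevation,
                        "congruent", "incongruent"),
    NA_character_)]
  tr[, laterality := data.table::fifelse(
    trial_kind == "experimental",
    data.table::fifelse(tactile_hand == visual_side,
                        "ipsilateral", "contralateral"),
    NA_character_)]
  tr[]
}

#' Exclude participants at or below chance accuracy
#'
#' Accuracy is computed per participant over the scorable trials —
#' experimental plus false stimulations, excluding the yellow-LED control
#' trials (the chance level "without control trials") — and participants at
#' or below the threshold are removed entirely.
#'
#' @param trials a scored trial table (see [score_trials()]).
#' @param threshold exclusion threshold as a proportion (default 0.44:
#'   participants with accuracy of 44 percent or less are dropped).
#' @param include_control if `TRUE`, control-light trials also count towards
#'   accuracy (non-default reading of the rule).
#' @return list with `trials` (kept rows), `excluded` (character vector of
#'   participant ids) and `accuracy` (per-participant accuracy table).
#' @export
exclude_low_accuracy <- function(trials, threshold = 0.44,
                                 include_control = FALSE) {
  check_number(threshold, "threshold", lower = 0, upper = 1)
  tr <- data.table::as.data.table(trials)
  if (is.null(tr$correct)) tr <- score_trials(tr)
  kinds <- c("experimental", "false_stimulation",
             if (include_control) "control_light")
  acc <- tr[trial_kind %in% kinds,
            .(n_ok = sum(correct), n_tot = .N), by = participant]
  acc[, accuracy := n_ok / n_tot]
  no_trials <- setdiff(unique(tr$participant), acc$participant)
  out <- acc$participant[acc$accuracy <= threshold]
  excluded <- c(out, no_trials)
  if (length(no_trials))
    warning("participant(s) with no scorable trials excluded: ",
            paste(no_trials, collapse = ", "), call. = FALSE)
  list(trials = tr[!participant %in% excluded],
       excluded = excluded,
       accuracy = acc[])
}

#' Per-participant crossmodal congruency effects
#'
#' For every (participant, condition, laterality) cell: mean RT of correct
#' incongruent trials minus mean RT of correct congruent trials.  Incorrect
#' trials are rejected first; only experimental trials enter.  Cells in
#' which either congruency level has no correct trial yield `NA` with a
#' warning.
#'
#' @param trials a scored trial table.
#' @return a `data.table` (`participant, group, condition, laterality,
#'   cce_ms, n_congruent, n_incongruent`).
#' @export
compute_cce <- function(trials) {
  tr <- data.table::as.data.table(trials)
  if (is.null(tr$correct)) tr <- score_trials(tr)
  if (is.null(tr$group)) tr[, group := "all"]
  use <- tr[trial_kind == "experimental" & correct == TRUE &
              !is.na(rt_ms)]
  cell <- use[, .(mean_rt = mean(rt_ms), n = .N),
              by = .(participant, group, condition, laterality, congruency)]
  wide <- data.table::dcast(cell,
                            participant + group + condition + laterality ~
                              congruency,
                            value.var = c("mean_rt", "n"), fill = NA)
  for (col in c("mean_rt_congruent", "mean_rt_incongruent",
                "n_congruent", "n_incongruent"))
    if (is.null(wide[[col]])) wide[, (col) := NA_real_]
  out <- wide[, .(participant, group, condition, laterality,
                  cce_ms = mean_rt_incongruent - mean_rt_congruent,
                  n_congruent, n_incongruent)]
  if (anyNA(out$cce_ms))
    warning(sum(is.na(out$cce_ms)),
            " CCE cell(s) undefined (no correct trials in a congruency cell)",
            call. = FALSE)
  data.table::setorder(out, participant, condition, laterality)
  out[]
}

#' Ipsilateral-minus-contralateral CCE differences
#'
#' @param cce a CCE table from [compute_cce()].
#' @return a `data.table` (`participant, group, condition, d_ms`) with
#'   `d_ms = cce(ipsilateral) - cce(contralateral)`; rows whose cells are
#'   incomplete are skipped with a warning.
#' @export
cce_difference <- function(cce) {
  cc <- data.table::as.data.table(cce)
  wide <- data.table::dcast(cc, participant + group + condition ~ laterality,
                            value.var = "cce_ms")
  for (col in c("ipsilateral", "contralateral"))
    if (is.null(wide[[col]])) wide[, (col) := NA_real_]
  wide[, d_ms := ipsilateral - contralateral]
  dropped <- wide[is.na(d_ms)]
  if (nrow(dropped))
    warning(nrow(dropped), " (participant, condition) cell(s) dropped: ",
            "missing a laterality", call. = FALSE)
  out <- wide[!is.na(d_ms), .(participant, group, condition, d_ms)]
  data.table::setorder(out, participant, condition)
  out[]
}
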