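# Hypothesis-space builders for the three experiments and the ownership
# questionnaire.  Each builder is a pure function of its arguments and
# returns a list of hypothesis_spec objects.
#
# CCE hypothesis spaces put a prior label on the per-cell
# ipsilateral-minus-contralateral effect: "null" (no PPS, effect pinned near
# 0) or "active" (PPS present, effect near +40 ms).  The questionnaire
# spaces put "high"/"low" labels on log-odds coefficients.

active_id <- function(effects, active_label = "active") {
  on <- names(effects)[effects == active_label]
  if (!length(on)) "none" else paste(on, collapse = "+")
}

enumerate_null_active <- function(cells, priors) {
  grid <- expand.grid(rep(list(c("null", "active")), length(cells)),
                      stringsAsFactors = FALSE)
  names(grid) <- cells
  lapply(seq_len(nrow(grid)), function(i) {
    eff <- unlist(grid[i, , drop = FALSE])
    names(eff) <- cells
    hypothesis_spec(active_id(eff), eff, priors)
  })
}

#' Hypothesis space for the feet experiment (3 conditions, 8 hypotheses)
#'
#' All `2^3` assignments of null/active to the per-condition PPS effect,
#' from the absence of PPS everywhere to its presence in all conditions.
#'
#' @param conditions exactly three condition labels.
#' @param priors prior labels, see [default_effect_priors()].
#' @return list of 8 [hypothesis_spec()] objects (ids name the active
#'   conditions, e.g. `"real"`, `"real+fake"`, `"none"`).
#' @export
build_hypothesis_space_exp1 <- function(conditions = c("real", "fake", "void"),
                                        priors = default_effect_priors()) {
  if (length(conditions) != 3L)
    stop_bad_arg("this space is defined for exactly 3 conditions")
  enumerate_null_active(conditions, priors)
}

#' Hypothesis space for the hands experiment (2 conditions, 4 hypotheses)
#'
#' @param conditions exactly two condition labels.
#' @inheritParams build_hypothesis_space_exp1
#' @return list of 4 [hypothesis_spec()] objects.
#' @export
build_hypothesis_space_exp2 <- function(conditions = c("within", "outside"),
                                        priors = default_effect_priors()) {
  if (length(conditions) != 2L)
    stop_bad_arg("this space is defined for exactly 2 conditions")
  enumerate_null_active(conditions, priors)
}

#' Hypothesis space for the passive-motion experiment (2 groups, 4 hypotheses)
#'
#' The four hypotheses: no PPS in either group, PPS only in the first group,
#' PPS only in the second, PPS in both.  Two parameterisations are offered:
#' \describe{
#'   \item{`"difference"`}{the modelled quantity is the per-participant
#'     ipsi-minus-contra CCE difference, with a null/active prior per group
#'     (data cells = groups).}
#'   \item{`"cell_means"`}{the modelled quantities are the contralateral and
#'     ipsilateral CCE cell means per group (data cells =
#'     `group.laterality`); "absence" pins both means of a group at zero
#'     (null prior on the contralateral mean and on the ipsi-minus-contra
#'     increment), "presence" gives the contralateral mean a vague baseline
#'     prior and the increment the active prior.}
#' }
#'
#' @param groups exactly two group labels.
#' @param variant `"difference"` (default) or `"cell_means"`.
#' @inheritParams build_hypothesis_space_exp1
#' @return list of 4 [hypothesis_spec()] objects.
#' @export
build_hypothesis_space_exp3 <- function(groups = c("motion", "no_motion"),
                                        variant = c("difference",
                                                    "cell_means"),
                                        priors = default_effect_priors()) {
  if (length(groups) != 2L)
    stop_bad_arg("this space is defined for exactly 2 groups")
  variant <- match.arg(variant)
  if (variant == "difference") return(enumerate_null_active(groups, priors))
  # cells are sorted group x laterality labels, matching the sampler's
  # sorted-cell convention
  cells <- sort(as.vector(outer(groups, c("contralateral", "ipsilateral"),
                                paste, sep = ".")))
  build_one <- function(present) {
    eff <- character(0L)
    for (g in groups) {
      lab <- if (g %in% present) c("baseline", "active") else c("null", "null")
      eff[paste0("contra_", g)] <- lab[1L]
      eff[paste0("delta_", g)] <- lab[2L]
    }
    X <- matrix(0, length(cells), length(eff),
                dimnames = list(cells, names(eff)))
    for (g in groups) {
      X[paste(g, "contralateral", sep = "."), paste0("contra_", g)] <- 1
      X[paste(g, "ipsilateral", sep = "."), paste0("contra_", g)] <- 1
      X[paste(g, "ipsilateral", sep = "."), paste0("delta_", g)] <- 1
    }
    hypothesis_spec(if (!length(present)) "none"
                    else paste(present, collapse = "+"),
                    eff, priors, X = X)
  }
  list(build_one(character(0L)), build_one(groups[1L]),
       build_one(groups[2L]), build_one(groups))
}

#' Questionnaire hypothesis space (default size 22)
#'
#' A reconstruction of a constrained enumeration over high/low assignments
#' to the (condition x before/after) cells of one questionnaire component:
#' \enumerate{
#'   \item all `2^k` time-invariant assignments (one shared high/low level
#'     per condition; before = after);
#'   \item assignments in which exactly one condition changes level across
#'     time (2 directions), with the remaining conditions tied to a common
#'     time-invariant level (2 levels);
#'   \item the two global-change assignments (every condition low before and
#'     high after, or the reverse).
#' }
#' With 3 conditions this yields `8 + 12 + 2 = 22` hypotheses.  Cell names
#' follow the `condition.time` convention (sorted), and tied cells share one
#' effect parameter via the hypothesis design matrix.
#'
#' @param conditions condition labels (default `real`, `fake`, `void`).
#' @param times the two time labels (default `before`, `after`).
#' @param priors logit-scale prior labels, see [default_logit_priors()].
#' @param include_tied,include_single_change,include_global_change toggles
#'   for the three blocks of the grammar.
#' @param expected_size if given, an error is raised when the grammar does
#'   not produce exactly this many hypotheses.
#' @return list of [hypothesis_spec()] objects.
#' @export
build_questionnaire_hypotheses <- function(conditions = c("real", "fake",
                                                          "void"),
                                           times = c("before", "after"),
                                           priors = default_logit_priors(),
                                           include_tied = TRUE,
                                           include_single_change = TRUE,
                                           include_global_change = TRUE,
                                           expected_size = NULL) {
  if (length(times) != 2L) stop_bad_arg("exactly two time labels required")
  k <- length(conditions)
  cells <- sort(as.vector(outer(conditions, times, paste, sep = ".")))
  cell_index <- function(cond, time) match(paste(cond, time, sep = "."),
                                           cells)
  lab <- c(low = "L", high = "H")
  out <- list()

  add <- function(id, eff, X) {
    rownames(X) <- cells
    colnames(X) <- names(eff)
    out[[length(out) + 1L]] <<- hypothesis_spec(id, eff, priors, X = X)
  }

  if (include_tied) {
    grid <- expand.grid(rep(list(c("low", "high")), k),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      eff <- setNames(unlist(grid[i, ]), conditions)
      X <- matrix(0, length(cells), k)
      for (j in seq_len(k)) X[cell_index(conditions[j], times), j] <- 1
      add(paste(conditions, lab[eff], sep = "=", collapse = ","), eff, X)
    }
  }
  if (include_single_change) {
    for (cond in conditions) {
      others <- setdiff(conditions, cond)
      for (dir in list(c("low", "high"), c("high", "low"))) {
        for (other_level in c("low", "high")) {
          eff <- setNames(c(dir, other_level),
                          c(paste0(cond, "_", times), "others"))
          X <- matrix(0, length(cells), 3L)
          X[cell_index(cond, times[1L]), 1L] <- 1
          X[cell_index(cond, times[2L]), 2L] <- 1
          for (o in others) X[cell_index(o, times), 3L] <- 1
          add(paste0(cond, ":", lab[dir[1L]], ">", lab[dir[2L]],
                     ",others=", lab[other_level]), eff, X)
        }
      }
    }
  }
  if (include_global_change) {
    for (dir in list(c("low", "high"), c("high", "low"))) {
      eff <- setNames(dir, paste0("all_", times))
      X <- matrix(0, length(cells), 2L)
      X[cell_index(conditions, times[1L]), 1L] <- 1
      X[cell_index(conditions, times[2L]), 2L] <- 1
      add(paste0("all:", lab[dir[1L]], ">", lab[dir[2L]]), eff, X)
    }
  }
  if (!is.null(expected_size) && length(out) != expected_size)
    stop_bad_arg("grammar produced ", length(out), " hypotheses, not the ",
                 "requested ", expected_size)
  out
}
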