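make_trial <- function(kind, elev = NA, response, hand = "left",
                       vside = "left", velev = "high", rt = 500,
                       participant = "p1", condition = "real") {
  data.frame(participant = participant, group = "g", condition = condition,
             block = 1L, trial_kind = kind,
             tactile_hand = if (kind == "experimental") hand else NA,
             tactile_elevation = if (kind == "experimental") elev else NA,
             visual_side = vside, visual_elevation = velev,
             response = response, rt_ms = rt)
}

test_that("scoring follows the token rules", {
  tr <- rbind(make_trial("experimental", "high", "TAH"),
              make_trial("experimental", "low", "TOH"),
              make_trial("experimental", "high", "TOH"),
              make_trial("experimental", "low", "TAH"),
              make_trial("control_light", response = "LUCI"),
              make_trial("control_light", response = "TAH"),
              make_trial("false_stimulation", response = "NIENTE"),
              make_trial("false_stimulation", response = "TAH"))
  sc <- score_trials(tr)
  expect_equal(sc$correct,
               c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("unknown response tokens are rejected with the row number", {
  tr <- rbind(make_trial("experimental", "high", "TAH"),
              make_trial("experimental", "high", "OOPS"))
  expect_error(score_trials(tr), "OOPS")
  expect_error(score_trials(tr), "row 2")
})

test_that("derived congruency and laterality labels are correct", {
  tr <- make_trial("experimental", "high", "TAH", hand = "left",
                   vside = "right", velev = "low")
  sc <- score_trials(tr)
  expect_equal(sc$congruency, "incongruent")
  expect_equal(sc$laterality, "contralateral")
  sc2 <- score_trials(make_trial("experimental", "low", "TOH", hand = "right",
                                 vside = "right", velev = "low"))
  expect_equal(sc2$congruency, "congruent")
  expect_equal(sc2$laterality, "ipsilateral")
  expect_true(is.na(score_trials(
    make_trial("control_light", response = "LUCI"))$congruency))
})

test_that("accuracy exclusion straddles the 44% threshold exactly", {
  # participant accuracies straddling the rule: 43% out, 45% in
  build <- function(p, n_ok, n_tot) {
    correct <- make_trial("experimental", "high", "TAH", participant = p)
    wrong <- make_trial("experimental", "high", "TOH", participant = p)
    rbind(correct[rep(1L, n_ok), ], wrong[rep(1L, n_tot - n_ok), ])
  }
  tr <- rbind(build("p43", 43L, 100L), build("p44", 44L, 100L),
              build("p45", 45L, 100L), build("p100", 10L, 10L))
  res <- exclude_low_accuracy(score_trials(tr))
  expect_setequal(res$excluded, c("p43", "p44"))  # <= 0.44 is out
  expect_setequal(unique(res$trials$participant), c("p45", "p100"))
})

test_that("exclusion equals a brute-force accuracy count on generated data", {
  design <- cct_design("g", c("real", "fake"), 10)
  # error rates spanning the threshold; accuracy ~ 1 - error_rate
  trials <- data.table::rbindlist(lapply(1:10, function(i) {
    er <- seq(0.05, 0.95, length.out = 10)[i]
    tr <- generate_cct_dataset(cct_design("g", c("real", "fake"), 1),
                               cct_effects(error_rate = er), seed = 40L + i)
    tr$participant <- sprintf("p%02d", i)
    tr
  }))
  sc <- score_trials(trials)
  res <- exclude_low_accuracy(sc)
  acc <- brute_accuracy(sc)
  expect_setequal(res$excluded, names(acc)[acc <= 0.44])
  # a participant with no scorable trials is excluded and flagged
  ctrl_only <- sc[sc$trial_kind == "control_light" &
                    sc$participant == "p01", ]
  ctrl_only$participant <- "p_empty"
  expect_warning(res2 <- exclude_low_accuracy(rbind(sc, ctrl_only)),
                 "no scorable")
  expect_true("p_empty" %in% res2$excluded)
})

test_that("nothing is excluded when everyone is at ceiling", {
  tr <- generate_cct_dataset(cct_design("g", "real", 3),
                             cct_effects(error_rate = 0), seed = 1)
  expect_length(exclude_low_accuracy(score_trials(tr))$excluded, 0L)
})

test_that("CCE arithmetic on hand-built cells is exact", {
  two <- function(rt, congruent, participant = "p1") {
    velev <- if (congruent) "high" else "low"
    make_trial("experimental", "high", "TAH", velev = velev, rt = rt)
  }
  tr <- rbind(two(500, TRUE), two(520, TRUE), two(600, FALSE),
              two(640, FALSE))
  cc <- compute_cce(score_trials(tr))
  expect_equal(cc$cce_ms, 110)  # mean(600, 640) - mean(500, 520)
  tr_same <- rbind(two(500, TRUE), two(500, FALSE))
  expect_equal(compute_cce(score_trials(tr_same))$cce_ms, 0)
})

test_that("CCE equals the brute-force aggregation oracle on generated data", {
  tr <- generate_cct_dataset(cct_design("g", c("real", "void"), 3),
                             cct_effects(), seed = 8)
  sc <- score_trials(tr)
  got <- as.data.frame(compute_cce(sc))
  oracle <- brute_cce(sc)
  m <- merge(got, oracle, by = c("participant", "condition", "laterality"),
             suffixes = c("", "_oracle"))
  expect_equal(nrow(m), nrow(got))
  expect_equal(m$cce_ms, m$cce_ms_oracle)
})

test_that("compute_cce is invariant to trial order and to incorrect trials", {
  tr <- generate_cct_dataset(cct_design("g", c("real", "void"), 2),
                             cct_effects(error_rate = 0), seed = 9)
  sc <- score_trials(tr)
  base <- compute_cce(sc)
  shuffled <- compute_cce(sc[sample.int(nrow(sc)), ])
  expect_equal(as.data.frame(base), as.data.frame(shuffled))
  # incorrect trials with absurd RTs must not move any CCE (rejection rule)
  junk <- sc[sc$trial_kind == "experimental", ][1:50, ]
  junk$response <- ifelse(junk$tactile_elevation == "high", "TOH", "TAH")
  junk$correct <- FALSE
  junk$rt_ms <- 1e6
  expect_equal(as.data.frame(compute_cce(rbind(sc, junk))),
               as.data.frame(base))
})

test_that("ipsi-minus-contra difference matches row-wise subtraction", {
  cc <- data.frame(participant = rep(c("p1", "p2"), each = 2L), group = "g",
                   condition = "real",
                   laterality = rep(c("ipsilateral", "contralateral"), 2L),
                   cce_ms = c(92.86, 20.56, 10, 10))
  d <- cce_difference(cc)
  expect_equal(d$d_ms, c(92.86 - 20.56, 0))
  # missing laterality rows are dropped with a warning
  expect_warning(d2 <- cce_difference(cc[-2L, ]), "missing a laterality")
  expect_equal(d2$participant, "p2")
  # random tables: d equals brute-force subtraction
  set.seed(3)
  cc$cce_ms <- rnorm(4)
  d3 <- cce_difference(cc)
  for (p in c("p1", "p2"))
    expect_equal(d3$d_ms[d3$participant == p],
                 cc$cce_ms[cc$participant == p &
                             cc$laterality == "ipsilateral"] -
                   cc$cce_ms[cc$participant == p &
                               cc$laterality == "contralateral"])
})

test_that("noise-free pipeline recovers the generative ipsi-extra exactly", {
  design <- cct_design("g", c("real", "fake"), 3)
  ef <- cct_effects(participant_sd_ms = 20, residual_sd_ms = 0,
                    cce_contra_ms = 30,
                    cce_ipsi_extra_ms = c(real = 70, fake = 0),
                    error_rate = 0)
  d <- cce_difference(compute_cce(score_trials(
    generate_cct_dataset(design, ef, seed = 10))))
  expect_equal(d$d_ms[d$condition == "real"], rep(70, 3))
  expect_equal(d$d_ms[d$condition == "fake"], rep(0, 3))
})
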