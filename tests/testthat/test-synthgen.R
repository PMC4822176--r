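test_that("trial counts and factor balance match the design for any seed", {
  design <- cct_design(c("a", "b"), c("real", "fake", "void"), 2)
  expect_equal(design$experimental_per_condition, 144L)
  expect_equal(design$trials_per_condition, 162L)
  for (seed in c(1L, 99L)) {
    tr <- generate_cct_dataset(design, cct_effects(), seed = seed)
    expect_equal(nrow(tr), 2L * 2L * 3L * 162L)
    counts <- table(tr$participant, tr$condition)
    expect_true(all(counts == 162L))
    ex <- tr[tr$trial_kind == "experimental", ]
    combo <- table(ex$participant, ex$condition, ex$tactile_hand,
                   ex$tactile_elevation, ex$visual_side, ex$visual_elevation)
    expect_true(all(combo == 9L))
    expect_true(all(table(tr$participant, tr$condition,
                          tr$trial_kind)[, , "control_light"] == 9L))
    expect_true(all(table(tr$participant, tr$condition,
                          tr$trial_kind)[, , "false_stimulation"] == 9L))
  }
})

test_that("same seed gives bit-identical output; different seed differs", {
  design <- cct_design("g", "real", 2)
  a <- generate_cct_dataset(design, cct_effects(), seed = 5)
  b <- generate_cct_dataset(design, cct_effects(), seed = 5)
  c <- generate_cct_dataset(design, cct_effects(), seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$rt_ms, c$rt_ms))
})

test_that("noise-free degenerate case: all experimental RTs equal baseline", {
  design <- cct_design("g", "real", 1)
  ef <- cct_effects(baseline_rt_ms = 600, participant_sd_ms = 0,
                    residual_sd_ms = 0, cce_contra_ms = 0,
                    cce_ipsi_extra_ms = 0, error_rate = 0)
  tr <- generate_cct_dataset(design, ef, seed = 1)
  expect_equal(unique(tr$rt_ms[tr$trial_kind == "experimental"]), 600)
  expect_true(all(tr$response[tr$trial_kind == "control_light"] == "LUCI"))
  expect_true(all(tr$response[tr$trial_kind == "false_stimulation"] ==
                    "NIENTE"))
})

test_that("invalid effect specifications are rejected", {
  expect_error(cct_effects(residual_sd_ms = -1), "residual_sd_ms")
  expect_error(cct_effects(error_rate = 1.2), "error_rate")
  expect_error(cct_effects(baseline_rt_ms = 0), "baseline_rt_ms")
  design <- cct_design(c("a", "b"), "real", 1)
  expect_error(generate_cct_dataset(design, list(a = cct_effects()), 1),
               "every group")
})

test_that("noise-free congruency shifts reproduce the specified CCE exactly", {
  design <- cct_design("g", "real", 3)
  ef <- cct_effects(participant_sd_ms = 25, residual_sd_ms = 0,
                    cce_contra_ms = 30, cce_ipsi_extra_ms = 70,
                    error_rate = 0)
  tr <- as.data.frame(generate_cct_dataset(design, ef, seed = 2))
  ex <- tr[tr$trial_kind == "experimental", ]
  ex$congr <- ifelse(ex$tactile_elevation == ex$visual_elevation,
                     "cong", "incong")
  ex$lat <- ifelse(ex$tactile_hand == ex$visual_side, "ipsi", "contra")
  for (p in unique(ex$participant)) for (l in c("contra", "ipsi")) {
    sel <- ex[ex$participant == p & ex$lat == l, ]
    cce <- mean(sel$rt_ms[sel$congr == "incong"]) -
      mean(sel$rt_ms[sel$congr == "cong"])
    expect_equal(cce, if (l == "contra") 30 else 100)
  }
})

test_that("error_rate = 1 makes every response a wrong token", {
  design <- cct_design("g", "real", 1)
  tr <- generate_cct_dataset(design, cct_effects(error_rate = 1), seed = 3)
  truth <- ifelse(tr$trial_kind == "control_light", "LUCI",
                  ifelse(tr$trial_kind == "false_stimulation", "NIENTE",
                         ifelse(tr$tactile_elevation == "high",
                                "TAH", "TOH")))
  expect_true(all(tr$response != truth))
  expect_true(all(tr$response %in% c("TAH", "TOH", "LUCI", "NIENTE")))
})

test_that("likert generation: floor case, missing cells, expectation oracle", {
  design <- cct_design("g", "real", 4)
  floor_profile <- likert_profile(data.frame(
    component = "embodiment", condition = "real",
    time = rep(c("before", "after"), each = 1L),
    location = -30, dispersion = 1))
  q <- generate_questionnaire(design, floor_profile, seed = 1)
  expect_true(all(q$score == 1L))
  expect_equal(nrow(q), 4L * 2L * 2L)  # 2 items x 2 times x 4 participants

  incomplete <- likert_profile(data.frame(
    component = "embodiment", condition = "real", time = "before",
    location = 0, dispersion = 1))
  expect_error(generate_questionnaire(design, incomplete, seed = 1),
               "missing cells")

  # empirical cell means converge to the closed-form categorical expectation
  big <- cct_design("g", "real", 1000)
  prof <- likert_profile(data.frame(
    component = "embodiment", condition = "real",
    time = c("before", "after"), location = c(2.5, -1), dispersion = 1))
  q <- as.data.frame(generate_questionnaire(big, prof, seed = 7))
  cuts <- likert_cutpoints()
  for (i in 1:2) {
    probs <- vapply(1:10, brute_ordinal_prob, 0,
                    eta = prof$cells$location[i] / 1, cutpoints = cuts)
    expected <- sum(1:10 * probs)
    got <- mean(q$score[q$time == prof$cells$time[i]])
    expect_lt(abs(got - expected), 0.1)
  }
})

test_that("control-like profile is calibrated to its target cell means", {
  prof <- likert_profile_control()
  cells <- prof$cells
  emb_real_before <- cells[cells$component == "embodiment" &
                             cells$condition == "real" &
                             cells$time == "before", ]
  expect_lt(abs(expected_likert_mean(emb_real_before$location) - 9.56), 0.02)
  emb_void_before <- cells[cells$component == "embodiment" &
                             cells$condition == "void" &
                             cells$time == "before", ]
  expect_lt(abs(expected_likert_mean(emb_void_before$location) - 1), 0.02)
})

test_that("voice waveform: onset indexing, silence, argfirst oracle", {
  w <- generate_voice_wav(500, 1000, sample_rate = 8000, seed = 1)
  expect_equal(w$onset_sample, 4000)  # 8 samples per ms
  w0 <- generate_voice_wav(500, 1000, noise_amplitude = 0, seed = 1)
  expect_true(all(w0$wave[1:4000] == 0))
  expect_error(generate_voice_wav(1000, 800, seed = 1), "within")

  set.seed(11)
  for (onset in round(runif(25, 50, 900))) {
    w <- generate_voice_wav(onset, 1000, noise_amplitude = 0, seed = onset)
    argfirst <- which(w$wave != 0)[1L] - 1L  # 0-based
    expect_equal(w$onset_sample, argfirst)
  }
})

test_that("empirical CCE converges to the implied CCE (LLN, >= 1e4 per cell)", {
  design <- cct_design("g", "real", 1, trials_per_combo = 2500L)
  ef <- cct_effects(cce_contra_ms = 30, cce_ipsi_extra_ms = 70,
                    error_rate = 0, residual_sd_ms = 150)
  tr <- generate_cct_dataset(design, ef, seed = 13)
  cc <- compute_cce(score_trials(tr))
  n_cell <- 2500L * 4L  # trials per (laterality x congruency) cell
  se <- sqrt(2 * 150^2 / n_cell)
  expect_lt(abs(cc$cce_ms[cc$laterality == "contralateral"] - 30), 3 * se)
  expect_lt(abs(cc$cce_ms[cc$laterality == "ipsilateral"] - 100), 3 * se)
})

test_that("trial tables round-trip through CSV", {
  tr <- generate_cct_dataset(cct_design("g", "real", 1), cct_effects(),
                             seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(tr))
})
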