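---
title: "Models and methods: Bayesian hypothesis comparison for crossmodal congruency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

The crossmodal congruency task (CCT) probes peripersonal space (PPS): the
region around the body in which visual and tactile signals are integrated.
Participants report the elevation (high/low) of a tactile stimulus delivered
to a hand-held device while ignoring visual distractors that flash at a
congruent or incongruent elevation, on the same side as the stimulated hand
(ipsilateral) or the opposite side (contralateral). Incongruent distractors
slow responses; the crossmodal congruency effect is

$$\mathrm{CCE} = \overline{RT}_{\text{incongruent}} -
\overline{RT}_{\text{congruent}},$$

computed from correct trials only, separately per laterality. Contralateral
CCEs arise from purely spatial interference; ipsilateral CCEs additionally
reflect PPS, so a PPS representation is inferred when
$d = \mathrm{CCE}_{\text{ipsi}} - \mathrm{CCE}_{\text{contra}} > 0$.

`ppscct` packages the full analysis chain for such experiments: a synthetic
data generator that emulates the design (so every stage is testable without
participant data), voice-onset RT extraction from WAV recordings, CCE
preprocessing, and Bayesian comparison of hypothesis sets via a
transdimensional product-space (Carlin–Chib) Gibbs sampler.

## Trial design and scoring

Each condition comprises 9 repetitions of the 16 visuo-tactile combinations
(2 tactile hands × 2 tactile elevations × 2 visual sides × 2 visual
elevations; 144 experimental trials), plus 9 control-light trials (a yellow
LED; expected answer "LUCI") and 9 false stimulations (distractor without
touch; expected answer "NIENTE"): 162 trials over 3 blocks. Experimental
answers are "TAH" (felt high) or "TOH" (felt low). A participant whose
accuracy over experimental + false-stimulation trials is ≤ 44% (the chance
level once control trials are set aside) is excluded entirely. We read
"without control trials" as excluding the yellow-LED trials from the
accuracy denominator; the reading is configurable
(`exclude_low_accuracy(include_control = TRUE)`).

Cell means use the arithmetic mean of correct-trial RTs, pooled across
blocks and hands; no outlier trimming is applied. Both choices follow the
minimal reading of the procedure; pooling per condition (rather than per
block) is the simplest defensible aggregation.

## The synthetic-data generator

The generator is a stated world, not a tuning knob. Its defaults:

* baseline RT 600 ms with participant offsets of SD 40 ms (these cancel in
  any CCE);
* trial-level noise SD 150 ms, lognormal by default (RT distributions are
  right-skewed; a normal family is provided for analytic convenience). With
  36 trials per (laterality × congruency) cell this implies a
  between-participant SD of a per-participant CCE of
  $\sqrt{2\cdot150^2/36} \approx 35$ ms, consistent with the 32–44 ms
  group SDs reported for healthy controls in this paradigm; the per-trial
  decomposition is not identifiable from published group summaries, so this
  calibration conflates participant and trial variance deliberately and is
  documented here once;
* contralateral congruency effect 30 ms; ipsilateral surplus
  (`cce_ipsi_extra_ms`) 70 ms where PPS is present and 0 elsewhere,
  matching the ~72 ms ipsi-minus-contra difference reported for the own-feet
  condition in controls;
* 7% incorrect trials (the reported rejection rate), realised as a
  uniformly random wrong token — the error *mechanism* is not described in
  the source, only its rate;
* Likert answers from a latent-logistic cut-point model with fixed
  equidistant cut-points (spacing 1 on the logit scale); the control-like
  default profile inverts the expected-score function so that each
  (component, condition, time) cell hits its published target mean (e.g.
  own-feet embodiment ≈ 9.56 before the task, ≈ 1 with an empty frame).

What a green test on synthetic data establishes: that the pipeline and the
samplers recover the structure they are pointed at, at realistic noise
levels. What it does not establish: anything about apparatus artefacts,
RT-tail physiology, sequential effects, or participant-level effect
heterogeneity (the generator draws a fixed effect per condition).

Stimulus timing (three 50 ms pulses with 50 ms gaps, 30 ms visual lead) is
carried as metadata constants, not simulated.

## Voice-onset RT extraction

Verbal responses are recorded as 8 kHz mono WAV. The detector computes RMS
per 10 ms frame, estimates the noise floor from the first 100 ms, and
declares an onset at the first run of ≥ 3 consecutive frames whose RMS
exceeds 5× the floor, refining to the first sample in that neighbourhood
whose amplitude crosses the same relative threshold. Consequences: detection
is invariant to global gain; in the noise-free case the detected onset
shifts sample-exactly with the signal; responses earlier than the noise
floor window (100 ms) would inflate the floor, which is acceptable because
verbal RTs in this task are far slower. The original study names only the
tooling for this step, not the algorithm, so no numerical agreement with the
original extraction is claimed; accuracy is instead tested against the
generator's stored true onsets (±20 ms at 20 dB SNR).

## Hypothesis models

**Linear (CCE) models.** For per-participant quantities $y_{pc}$ (the
ipsi-minus-contra difference, or a CCE cell mean) in cells $c$:

$$y_{pc} = (X\theta)_c + b_p + \varepsilon_{pc}, \qquad
b_p \sim N(0, \tau^2), \quad \varepsilon_{pc} \sim N(0, \sigma^2),$$

with participant random intercepts as the single level of hierarchy (the
source says "hierarchical" without further detail). Each hypothesis
assigns a prior label per effect: null $N(0, 5\,\text{ms})$ or active
$N(40, 20\,\text{ms})$. The exact prior constants of the original analysis
are in supplementary material that is not available; these defaults are
calibrated to the reported effect magnitudes, are configurable everywhere,
and are echoed in every report. Variances get vague inverse-gamma
(precision-Gamma(0.001, 0.001)) priors. All full conditionals are
conjugate, so single-model posteriors use pure Gibbs; `loglik_linear()`
integrates $b_p$ in closed form (compound-symmetric marginal), giving an
exact, deterministic likelihood used by oracles and tests.

**Ordinal (questionnaire) models.** Scores 1–10 follow a cumulative logit
with fixed equidistant cut-points, cell coefficients on the log-odds scale,
and participant random intercepts; high cells get a $N(+3, 1)$ prior, low
cells $N(-3, 1)$ (the published analysis states only that high and low
coefficients follow two stated distributions whose parameters are not
legible in the main text). Updates are Metropolis-within-Gibbs with a
fixed 0.4 random-walk step. A cumulative (ordered) logit was chosen over a
binary high/low collapse because the frequentist companion analyses were
ordered logistic regressions; the binary collapse can be emulated with
2-category cut-points.

## Hypothesis spaces

* Feet experiment: all $2^3$ null/active assignments over the three viewing
  conditions (8 hypotheses, per group).
* Hands experiment: all $2^2$ assignments over within/outside (4).
* Passive-motion experiment: absence/presence per group (4), in two
  parameterisations. The default models the per-participant difference
  $d$; the `cell_means` variant reproduces the published formulation in
  which "absence" pins *both* the contralateral and ipsilateral CCE means
  at zero. It reparameterises cell means as (contra, delta = ipsi − contra)
  so that absence puts the null prior on both coordinates, and presence
  gives contra a vague baseline prior $N(30, 40)$ and delta the active
  prior.
* Questionnaire: 22 hypotheses per component. The exact generating grammar
  of the original 22 is in unavailable supplementary material; the shipped
  grammar — 8 time-invariant high/low assignments per condition, 12 with
  exactly one condition changing across time (2 directions × 2 tied levels
  for the others), and 2 global before/after flips — is an explicit
  reconstruction that reaches the same count, is configurable, and must not
  be read as the original's.

## Product-space sampling

All hypotheses' parameters are sampled jointly with a categorical index
$M$. One Gibbs cycle updates (i) the shared nuisance block (participant
intercepts, variances) and the active model's effects against the
likelihood, (ii) every inactive model's effects from its pseudo-prior (a
proper normal moment-matched to a single-model pilot run; with no data it
equals the prior), and (iii) the index from its full conditional,

$$P(M = k \mid \cdot) \propto p(M=k)\, L(y \mid \theta_k)\,
\frac{p(\theta_k \mid M = k)}{\tilde p(\theta_k)},$$

computed in log space with max-subtraction. Posterior model probabilities
are kept-draw visit proportions pooled over chains (default budget: 3
chains × 10,000 kept after 1,000 burn-in = 30,000 draws). The defining
correctness property — insensitivity of the visit proportions to the
pseudo-prior choice — is tested directly, alongside an analytic
Bayes-factor oracle on a conjugate fixture and a Savage–Dickey density-ratio
oracle for nested comparisons. Reported diagnostics: batch-means Monte-Carlo
standard errors per probability (always reported, since a printed "1" may
be rounding or genuinely all visits), split-$\hat R$ of the per-model visit
indicators, and a decisiveness note when one model absorbs > 99% of visits.
The model prior is uniform unless specified; ties in the winning hypothesis
are reported as ties.

## Numerical and design choices

* Seeds: every stochastic routine takes an explicit seed; derived seeds are
  kept below $2^{31}$. Identical (config, seed) pairs produce byte-identical
  reports (no timestamps in report files).
* Degenerate inputs: zero noise SDs are honoured exactly (point RTs), an
  all-zero waveform yields a no-onset marker rather than an error, empty
  CCE cells yield `NA` with a warning, and participants with no scorable
  trials are excluded and flagged.
* Pseudo-prior SDs are floored at 1e-6 to remain proper after degenerate
  pilots.
* The accuracy rule uses ≤ (a participant at exactly 44% is excluded).
* WAV I/O is a minimal 16-bit PCM mono RIFF implementation, because no
  suitable audio package is available in the supported dependency set.

## Reduced test budgets

Acceptance checks of the conjugate oracle, symmetry, and pseudo-prior
invariance use the full 30,000-draw budget. The replicated recovery and
coverage checks state wall-clock bounds only; they run at single-chain
budgets (3,000 kept draws per fit; 1,200 for the coverage replicates) so the
whole suite stays within its time budget. The two exp-3-analogue replicates
that are decision-boundary cases under the difference parameterisation were
verified to give the same winner at the full budget — the reduced budgets
change Monte-Carlo error, not decisions.

## Known limitations

* No participant-level heterogeneity of the PPS effect in the generator, and
  no modelling of spasticity, apparatus geometry, or RT-tail physiology.
* The questionnaire grammar and the prior constants are reconstructions (see
  above); conclusions about the original study's exact numbers are out of
  scope, and no headline probability from the original analysis is
  reproducible from synthetic data.
* The ordinal sampler's fixed random-walk step is adequate for the tested
  data sizes; very large datasets would warrant adaptive steps.
* Savage–Dickey estimates degrade when few draws fall near the test point;
  the implementation flags this instead of failing.
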