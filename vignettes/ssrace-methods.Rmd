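---
title: "Modelling response inhibition and locus coeruleus contrast with ssrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling response inhibition and locus coeruleus contrast with ssrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrace)
```

## What the package models

`ssrace` implements a complete analysis chain for asking whether the
integrity of the locus coeruleus — the brain's main noradrenergic nucleus,
visible as a hyperintense structure on neuromelanin-sensitive MRI —
moderates the effect of a noradrenergic drug (atomoxetine) on response
inhibition. The chain has four stages, each usable on its own:

1. **Task engine** — a generative simulator of the stop-signal task and of
   agents performing it (the synthetic-data module);
2. **Race model** — the ex-Gaussian race likelihood with attentional
   failures;
3. **Inference** — hierarchical Bayesian estimation by DE-MCMC, yielding
   posterior distributions of the stop-signal reaction time (SSRT);
4. **Imaging and association** — contrast-to-noise (CNR) quantification of
   the locus coeruleus from 3D volumes, and the mixed-model stage linking
   CNR to the drug effect on SSRT.

## The stop-signal task and its simulator

The task is a two-choice RT task (left/right arrow) interrupted on a
minority of trials by a stop signal. Each run has 4 blocks of 140 trials:
110 go, 10 no-go and 20 stop trials per block. The first 20 trials of every
block are go trials whose mean RT sets the starting stop-signal delay
(SSD): mean lead-in RT minus 200 ms. The remaining trials are pseudorandomly
interleaved under two run-length constraints — at most 7 consecutive go
trials and at most 2 consecutive signal (no-go or stop) trials — enforced
by seeded rejection resampling with a 10,000-attempt cap. After a
successful stop the SSD rises by 50 ms, after a failed stop it falls by
50 ms, clamped to [50, 1500] ms; this staircase tracks 50% stop accuracy.
No-go trials carry an SSD of zero and do not move the staircase (only stop
trials are described as staircased). The staircase restarts at each block
from the lead-in rule by default; `task_config(staircase_continues = TRUE)`
carries it across blocks instead, since the protocol does not pin this
down.

Simulated agents follow the generative race described below. Two
simulation-only conventions are needed that the model itself does not fix:
a response window (default 4.5 s, matching the upper RT plausibility
bound) after which a trial is scored as an omission, and independence of
go-failure draws across trials (matching the model's exchangeability
assumption). Every participant-session gets its own derived random
substream, so any single subject is reproducible in isolation.

`simulate_study()` wires the cohort design: controls tested once, patients
tested twice in a double-blind placebo/atomoxetine crossover with drug
order randomized in permuted blocks of six (three placebo-first, three
atomoxetine-first per block). Each patient carries a latent CNR value; an
optional `cnr_link` shifts the atomoxetine-session stop-runner mean by
`slope * (cnr - cnr_mean)`, planting a drug-by-CNR interaction that the
downstream mixed model should recover. A small practice effect
(`session_shift`, default −20 ms on the stop-runner mean in session two)
emulates the session effect such crossover designs typically show.

Defaults of `study_groups()` place the control group's SSRT near 0.39 s
and the patient group's near 0.46 s, with go RTs, between-subject spread
and attentional-failure rates at levels realistic for older adults. These
are the package's simulated study conditions; they are set once here and
are not tuned per analysis.

```{r, eval = FALSE}
study <- simulate_study(n_controls = 26, n_patients = 19,
                        cnr_link = list(slope = 0.03), seed = 1)
dplyr::count(study$trials, group, drug, kind)
```

## The ex-Gaussian race model

Performance arises from a race between three independent runners: a stop
process and two go processes, one matching and one mismatching the
stimulus. Each runner's finish time is ex-Gaussian — a Gaussian (mean
`mu`, SD `sigma`) plus an independent exponential (mean `tau`) — the
standard positively skewed RT distribution. Two attentional-failure
mixtures complete the model: with probability `p_tf` the stop runner never
launches on a stop/no-go trial ("trigger failure"), and with probability
`p_gf` the go runners never launch ("go failure", an omission). Ignoring
these failures is known to bias SSRT upward, which the package's tests
reproduce.

Per-trial likelihood contributions:

* go response on side *s* at time *t*:
  `(1 - p_gf) f_s(t) S_other(t)`; omission: `p_gf`;
* signal-respond (response despite a stop signal at delay *d*):
  the go term times the censoring factor
  `p_tf + (1 - p_tf) S_stop(t - d)`;
* successful inhibition:
  `p_gf + (1 - p_gf)(1 - p_tf) ∫ f_stop(u) S_match(d+u) S_mismatch(d+u) du`.

No-go trials use the same expressions with `d = 0`. SSRT is the mean of
the stop runner's finish-time distribution, `mu_stop + tau_stop`, computed
per MCMC sample to give a posterior; go RT is `mu_go_match +
tau_go_match`.

Numerical choices: all ex-Gaussian densities are evaluated in log space
(stable for small `tau`); the inhibition integral is evaluated two ways —
an adaptive-quadrature reference (`stop_inhibit_loglik()`, absolute
tolerance 1e-9, errors surfaced with diagnostics) and a composite
Gauss-Legendre fast path used by the sampler (three panels over the stop
finish-time mass; validated against both the adaptive quadrature and
Monte-Carlo race frequencies). Impossible observations return `-Inf`
rather than erroring, so samplers simply reject. Commission errors are
produced by the mismatch runner, not a separate lapse parameter.

Before fitting, `preprocess_rts()` removes implausibly short (< 0.25 s) or
long (> 4.5 s) RTs and then go RTs beyond 2.5 SD of the
participant-session's go-RT mean. The order of operations is sequential
(absolute bounds first, then the SD rule on the survivors) and the SD rule
applies to go RTs only — signal-respond RTs keep their censored
distribution — since the protocol leaves both points open; the choice is
recorded in the trimming report attached to the output.

## Hierarchical inference

Participant parameters are drawn from group-level truncated normals
(probit-scale normals for the two probabilities); each group — controls,
patients on placebo, patients on atomoxetine — is fitted separately with
identical priors. Only three prior locations are study-stated
(`mu_go_match` 1.5 s, `mu_go_mismatch` 1.5 s, `mu_stop` 1 s, reflecting
older participants); every other location and scale is a weakly
informative implementation default recorded in
`inst/priors/default_priors.yaml`, and should not be read as anything
else.

The sampler is DE-MCMC, the family used by the established
stop-signal-model toolboxes: 33 chains by default (three per free
participant-level parameter), thinning 10, and a migration step with
probability 0.05. Within each iteration:

* participant parameters update in three crossover sub-blocks (stop
  runner + trigger failure; matching go runner + go failure; mismatching
  go runner) — smaller blocks keep acceptance healthy at modest trial
  counts, and the stop block touches only the stop/no-go likelihood
  component, which is cached separately from the go component;
* each parameter's group mean and log-SD update as a crossover pair
  (log-scale SDs cannot step below zero);
* interweaved *group-affine* moves, one per runner block, shift the
  group mean and rescale the group SD together with every participant's
  value. These moves are the package's answer to the hierarchical funnel:
  weakly identified parameters (the stop and mismatch runners at reduced
  trial counts) otherwise mix extremely slowly because the group block
  and the participant blocks each pin the other in place. The
  well-identified matching-go block only takes its (comparatively
  expensive) affine move on a random subset of iterations.

Migration runs only during the first burn-in chunks; left on, it
progressively duplicates states and collapses the chain diversity that
drives every crossover proposal (we observed exactly this failure mode).
Burn-in is adaptive: sampling proceeds in chunks until the split-chain
R-hat of every group-level parameter falls below 1.1, evaluated on a
migration-free window, after which 500 retained (thinned) iterations per
chain form the posterior; burn-in draws are discarded. Chains start from
per-participant method-of-moments values (go-RT moments; the integration
SSRT, mean go RT minus mean SSD, for the stop runner) with multiplicative
jitter — initialisation sets the scale, the posterior is determined by
the data and priors.

At the deliberately small "reduced fit" size used in the package's own
checks (8 participants, 2 blocks), several parameters are only weakly
identified and the honest R-hat after a capped burn-in typically lands
close to the 1.1 criterion rather than far below it; the posterior
intervals are correspondingly wide and cover the generating values. Fits
report convergence status rather than masking it: a fit that exhausts its
burn-in budget is flagged `converged = FALSE` and still returns draws.

Posterior-predictive checking simulates datasets from draws of the
participant-level posterior on the observed trial structure (kinds, SSDs
and stimuli fixed; responses regenerated) and overlays observed go-RT
deciles, signal-respond deciles and the inhibition function against 95%
predictive bands (`posterior_predictive()`, `autoplot()`).

Group and drug contrasts subtract matched MCMC sample vectors
(`posterior_contrast()`), reporting the posterior median and 95% quantile
interval; a difference is "reliably different from zero" when that
interval excludes zero. Unequal run lengths are reconciled by
deterministic, evenly spaced subsampling of the longer run.

## Locus coeruleus CNR quantification

All imaging is index-space: volumes are plain 3D arrays on a common grid
with axial slices ordered caudal to rostral, and the registration chain
that would align real acquisitions is out of scope (phantoms are generated
pre-aligned). The CNR map is `(V - Mean_REF) / SD_REF` with the reference
statistics taken from a central pontine reference region per subject; no
bias-field correction or smoothing is applied. CNR is invariant to affine
intensity rescaling, and the reference region of the output map has mean 0
and SD 1 by construction.

Segmentation is the semi-automated rule: within a search region, voxels
whose CNR strictly exceeds 5 are segmented slice by slice ("above" is read
as strict; ties are measure-zero on real data). Instead of an interactive
checking step, `segment_lc()` warns on empty segmentations and the voxel
counts per slice are available for QC. Binary segmentations from N
subjects average into a probabilistic atlas (values on the k/N lattice),
conventionally thresholded at 5% (default) or 25% probability.
`extract_lc_cnr()` averages the CNR map over atlas voxels, reporting each
side and both sides combined, for the whole structure and for
rostral/middle/caudal subdivisions defined as equal thirds of the occupied
slice extent — the anatomical cut planes are not specified in the source
protocol, so equal thirds is the package's convention.

`make_phantom()` builds synthetic volumes for all of this: a noisy
reference block plus two parasagittal hyperintense tubes with a specified
CNR per subdivision. A noise-free phantom carries nominal reference
statistics (its empirical SD would be zero), making planted CNR exactly
recoverable; noisy phantoms use per-subject empirical statistics like real
data. Phantoms emulate geometry and contrast only — no bias fields,
partial-volume effects, motion or registration error — so passing tests
demonstrate the correctness of the quantification arithmetic, not
robustness to real-world artefacts.

## The association stage

`descriptives()` reduces trial tables to stop accuracy, go error rate
(commission + omission over go trials) and its logit. Because error rates
sit near zero, the logit uses the empirical-logit form
`log((k + 0.5) / (n - k + 0.5))`; this zero-count convention is the
package's, recorded here and in the output metadata. The model-free
integration estimate of SSRT (mean go RT minus mean SSD, valid under 50%
tracking) is included for quick summaries and for replicate-heavy
simulation studies where refitting the full hierarchical model per
replicate is not sensible.

`fit_moderation_lmm()` fits `outcome ~ drug * cnr + session +
(1 | subject)` by REML on the patient rows, z-scoring the outcome and CNR
(so coefficients are standardized), coding placebo/first-session as 0.
F tests use Kenward-Roger denominator degrees of freedom, falling back to
Satterthwaite when necessary; the method used is recorded in the result.
Subjects missing one session stay in the model via the random-intercept
structure. `drug_change_correlation()` computes each complete patient's
atomoxetine-minus-placebo change, removes the session effect estimated
from the within-subject session differences, and reports the Pearson
correlation with whole-structure CNR. Bayes-factor columns are
deliberately out of scope; the core results are frequentist.

`subdivision_anova()` runs the group (between) by subdivision (within)
ANOVA on CNR via a multivariate linear model with Greenhouse-Geisser
sphericity correction, with Welch group contrasts per subdivision and
paired subdivision contrasts as follow-ups. When the within-subject error
covariance is degenerate (possible in constructed data), the uncorrected
repeated-measures test is reported and the epsilon column is `NA`.

## Problem sizes used in the package's own checks

The test-suite and acceptance checks run at deliberately reduced scale,
chosen as the smallest sizes at which each property is informative: trial
sequences over 100 seeds; 2,000 stop trials for the staircase's long-run
accuracy; 2×10⁵–10⁶ Monte-Carlo races per likelihood comparison; a
hierarchical fit of 8 participants × 2 blocks with 33 chains and 500
retained iterations; a trigger-failure bias comparison on 5 participants
at shortened iteration counts; and 50 replicate studies of 50 patients (two
blocks each) for sign recovery of the planted drug-by-CNR interaction
through the integration-SSRT pathway. The vignette states these as the
package's chosen designs; all are reproducible from fixed seeds.

## Known limitations

* The generative simulator shares its likelihood's assumptions
  (context independence, exchangeable lapses); it cannot reveal
  misspecification of those assumptions.
* DE-MCMC at very small trial counts mixes slowly in the weakly
  identified stop/mismatch parameters even with the affine interweaving;
  treat near-threshold R-hat values and wide intervals as the honest
  price of small data, not as estimation failure.
* Equal-thirds subdivisions are a convention; anatomically defined cut
  planes would shift subdivision means on real data.
* The LMM stage assumes a single random intercept; richer random
  structures are not identified with two sessions per subject.
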