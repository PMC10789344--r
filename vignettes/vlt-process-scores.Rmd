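---
title: "Process scores, reliability and diagnostic models for the 15-word Verbal Learning Test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process scores, reliability and diagnostic models for the 15-word Verbal Learning Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

The 15-word Verbal Learning Test (15-VLT, a Rey Auditory Verbal Learning
Test adaptation) is a standard instrument for verbal episodic memory in
memory-clinic diagnostics: five immediate learning trials of a 15-word
list, an unannounced delayed free recall after about 20 minutes, and a
30-item yes/no recognition trial.  When the recall phases are audio
recorded and transcribed automatically, the transcript carries much more
than the clinician's three totals: output order, timing, and
trial-to-trial dynamics support a large catalog of *process scores*.

`vltkit` implements that pipeline end to end:

1. **Scoring** — normalize transcripts and classify every recall event as
   first-correct, repetition, or intrusion.
2. **Features** — compute a catalog of ~100 process scores per session.
3. **Reliability** — quantify clinician-vs-ASR agreement with ICC(A,k).
4. **Group statistics** — Mann-Whitney effect sizes and correlation
   structure against other cognitive measures.
5. **Classification** — extra-trees models under leave-one-out
   cross-validation (LOOCV) separating subjective cognitive decline (SCD)
   from mild cognitive impairment (MCI) / dementia.
6. **Simulation** — a generative cohort model so every stage is testable
   without access to clinical data, which is typically shareable only on
   request.

## Scoring contract

Tokens are normalized by lowercasing, stripping punctuation/whitespace and
folding diacritics; matching against the target list is **exact after
normalization**.  No fuzzy or phonetic matching is attempted: transcriber
errors should surface as disagreement between raters, not be silently
absorbed by the scorer.  Within a trial, the first occurrence of a target
is a first-correct recall, later occurrences are repetitions, and
off-list tokens are intrusions; the three classes partition the events.
Clinician records that carry only per-trial counts (the common paper-form
situation) are supported: count-level features are computed and all
token-level features are reported missing.

Word lists are configuration data.  The package ships three synthetic
parallel 15-word lists with matched recognition foils
(`inst/extdata/wordlists_synthetic.json`); the clinical Dutch lists are
proprietary and are not reproduced.

## The feature catalog

With `C_t` the set of list positions recalled at trial `t` and
`c_t = |C_t|`:

* **Counts** — per-trial correct counts, total immediate recall
  (`sum(c_1..c_5)`, range 0–75), delayed recall, recognition true/false
  positives, per-trial repetitions and intrusions.
* **Timing** — first-correct recalls with onset at or below 10 s of the
  recall phase.  Only first-correct events are counted (a repetition adds
  no new word), and the feature is missing when onsets are unavailable;
  it is never imputed.
* **Serial position** — region counts `|C_t ∩ R|` for primacy, midlist and
  recency regions, per trial, totalled, and for the delayed trial, plus
  proportions (count / region size).  Default cut points are primacy 1–4,
  midlist 5–11, recency 12–15 — the common convention for 15-item lists;
  they are configurable via `serial_regions()` because the literature
  names the regions but not universal cuts.
* **Learning slopes** — least-squares slope of `c_t` on `t` over trials
  1–5 (overall), 1–3 (early) and 3–5 (late); the late slope is a
  three-point regression rather than `(c_5 - c_3)/2` for robustness to a
  dip at trial 4.  Peak slope is `max(c_{t+1} - c_t)`; simple gain is
  `c_5 - c_1`.
* **Consistency** — the constancy learning index
  `sum_t |C_t ∩ C_{t+1}| / sum_t c_t` (t = 1..4), the classic
  item-consistency construct; gained/lost counts between consecutive
  trials; savings `= delayed / c_5` (missing when `c_5 = 0`).
* **Organization** — serial clusters: adjacent output pairs whose list
  positions are consecutive (forward chaining by default; a flag enables
  bidirectional counting).  Subjective organization: the pair-frequency
  measure `PF = O - 2c(c-1)/(hk)` between consecutive trials, where `O`
  counts unordered pairs recalled adjacently (either order) in both
  trials, `h`, `k` are the two counts and `c` the shared-item count.  The
  subtracted term is the exact chance expectation, so PF has mean zero
  under random output order — a property the test suite checks by Monte
  Carlo.

Missing inputs propagate to missing features, never zeros; imputation is
an explicit, logged step inside the classifier's cross-validation folds.
Semantic clustering is deliberately absent: the instrument's lists are
unrelated nouns, so semantic-category structure is undefined for it.

## Reliability: ICC(A,k)

Agreement between the clinician's score and the ASR-derived score uses
the two-way, absolute-agreement, mean-of-k-ratings intraclass
correlation (k = 2):

$$\mathrm{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}$$

from the two-way ANOVA mean squares (rows = participants, columns =
raters).  Absolute agreement is the right flavour here because a
systematic undercount by the transcriber *should* depress agreement.
Confidence intervals use the McGraw–Wong F-based interval for the
single-rater coefficient with Satterthwaite degrees of freedom,
transformed to the mean-rating form by the Spearman–Brown step
(alpha = 0.05).  Published ICCs of this design sometimes come with much
wider, software-specific intervals; we document ours and make no attempt
to reproduce any particular variant.  Degenerate inputs are handled
explicitly: duplicated columns give exactly 1; zero between-subject
variance gives 0 with a warning.

Difference summaries are always clinician minus ASR, so positive values
mean missed words; exceedance thresholds (14 words for the 0–75 total,
4 for the 0–15 delayed score) are configurable.

## Group statistics

Feature-level group differences use the Mann-Whitney U test with
midranks, a tie-corrected normal approximation and no continuity
correction — the large-sample behaviour of standard statistical
packages.  The reported effect size is `r = |Z|/sqrt(N)`; because
missingness makes `N` feature-specific, it is reported per feature.  The
univariate AUC falls out of the identity `AUC = U/(n_a n_b)`.
Correlation matrices use Pearson correlations after case-wise deletion
(all-variable complete cases), matching how mixed cognitive batteries
are usually summarized.

## Diagnostic models

The model family crosses four subtests (total immediate recall, delayed
recall, recognition count, and all three "full") with three nested
tiers: (1) the core score only, (2) plus age, (3) plus the entire
feature catalog.  The classifier is an extremely randomized trees
ensemble (ranger with `splitrule = "extratrees"`, one random split per
candidate feature, no bagging), 500 trees by default, fixed seed policy
(fold `i` uses `seed + i`), median imputation fitted inside each
training fold.  Evaluation is LOOCV; AUCs carry DeLong
structural-components variances and normal-theory intervals, tier
differences use the paired DeLong test, and F1 of the impaired class is
reported at a fixed 0.5 probability threshold (the thresholding rule is
a convention, not an optimized cut).  Hyperparameters are deliberately
not tuned: with no held-out validation set, reproducibility beats
squeezing AUC.

One property of LOOCV worth knowing: on small balanced samples it is
*pessimistically* biased, because the held-out case's class is always
under-represented in its training fold.  With uninformative features and
n = 20 the null AUC sits near 0.37, recovering toward 0.5 as n grows
(≈ 0.46 at n = 60).  The package's null-calibration checks therefore run
at cohort scale (n = 60) rather than toy scale.

## The synthetic cohort generator

The generator exists so the pipeline is testable and demonstrable
without patient data.  For word `w` and trial `t`:

$$P(\text{recall}) = \mathrm{logistic}(\alpha + \beta(t-1) +
\pi\,[w \in \text{primacy}] + \rho\,[w \in \text{recency}] + u)$$

with `u ~ N(0, sigma_u)` a participant ability effect.  Delayed recall
keeps trial-5-recalled words with probability
`logistic(logit(theta) + theta_u * u)` and resurrects others with
probability `eps`.  Recognition thresholds Gaussian familiarity (mean
`dprime` targets / 0 foils) at criterion `crit`.  Output order blends
presentation order with the previous trial's output order (`order_mix`,
Gaussian jitter `order_noise`); a pure previous-order regime preserves
the relative order of repeatedly recalled words, while newly recalled
words enter by list position — no mechanism can make arbitrary recall
sets chain in consecutive list order.  Onsets accumulate log-normal
gaps (`gap_mu`, `gap_sigma`), with a participant-level speech-rate trait
(`gap_mu_sd`) making some people habitual fast, unpaused speakers.
Intrusions (Poisson per trial, drawn from a fixed multisyllabic dummy
vocabulary) and repetitions (per-word Bernoulli) are injected into the
output sequence.

The ASR variant is derived from the clinical truth by the word-miss
process: a word whose preceding gap is under `fast_gap_s` seconds is
dropped with probability `fast_miss`, otherwise `base_miss`, and
intrusions are removed entirely (the transcriber cannot identify
off-list words).  This reproduces the mechanism reported for real
recordings — misses concentrate in fast, unpaused recall — and yields
the observed count-dependent agreement pattern: the more words recalled,
the larger the clinician-minus-ASR gap.

### Calibration and its rationale

Defaults were calibrated once, by simulation at n = 500 per group,
against the published group summaries of the ASR scores: total immediate
recall 37.6 (SD 12.9) for SCD vs 24.1 (10.7) for the impaired group, and
delayed recall 8.1 (3.5) vs 3.6 (3.2).  All eight statistics land within
10% across seeds.  Two structural choices fell out of that exercise:

* `theta_u > 0` (ability-linked consolidation).  A fixed retention
  probability cannot produce delayed-recall SDs of 3.2–3.5 while keeping
  total-recall SDs near 11–13; tying retention to ability does, and is
  also the behaviourally plausible direction.
* `gap_mu_sd = 0.8` (speech-rate trait).  With i.i.d. gaps, per-person
  miss rates concentrate and the clinician-ASR agreement stays near
  0.95 with no large misses.  A participant-level rate trait produces
  the realistic pattern: a pooled mean difference of about 7 words on
  the 0–75 total, roughly a tenth of participants losing more than 14
  words, and ICCs near 0.90 (total) / 0.94 (delayed).

The dementia group reuses MCI parameters with a severity shift (lower
baseline and learning, weaker consolidation and discriminability, slower
speech); a 13-person group cannot support separate calibration.
Auxiliary cognitive z-scores, severity and functioning scales are
generated as group-shifted linear functions of `u` plus noise — enough
to reproduce the qualitative low-to-moderate correlation structure of a
cognitive battery, with no claim to model those instruments.

### What the simulator does not emulate

Words are exchangeable (no per-word difficulty); there is no semantic
content in intrusions; the ASR model is a two-level miss process, not an
acoustic engine (no substitutions, no volume effects); diagnosis labels
are exact; and the groups separate more cleanly than clinical reality —
classifier AUCs on the default cohort run around 0.85–0.90 where
clinical studies report 0.7–0.8.  Passing tests therefore demonstrate
the correctness and internal consistency of the computational pipeline
and the direction of its qualitative behaviours, not field performance
on real patients.

## Numerical and testing choices

* All randomized components take explicit seeds; LOOCV score vectors are
  bit-identical across runs with the same configuration.
* Rank computations use midranks throughout, so the AUC-U identity and
  the complementary-orientation identity `U + U' = n_a n_b` hold exactly,
  ties included.
* Degenerate cases are defined, not accidental: constant scores give
  AUC 0.5 with a warning; identical score vectors give a paired-test
  p of exactly 1; `PF` is missing when either trial is empty; savings is
  missing when trial-5 recall is zero.
* Test problem sizes are chosen to make Monte-Carlo checks sharp but
  quick: 1,000 simulated sessions for feature invariants, 500 per group
  for calibration, 50 replicates for null calibration, 25 replicates for
  the tier-comparison property, 2,000 bootstrap resamples against the
  DeLong variance.

## Known limitations

The scorer has no fuzzy matching, so transcription *substitutions*
(rather than omissions) would score as intrusion-plus-miss; the
feature catalog is a reconstruction of the named process-score families
plus systematic region-by-trial expansions, not a certified copy of any
proprietary 102-item list; and the F1 threshold of 0.5 on LOOCV
probabilities is a convention that can sit far from the optimal operating
point when classes are unbalanced.
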