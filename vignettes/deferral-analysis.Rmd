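---
title: "Evaluating physician-AI deferral strategies for ARDS chest X-ray reading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating physician-AI deferral strategies for ARDS chest X-ray reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardsdefer)
library(dplyr)
```

## The problem

Identifying findings of the acute respiratory distress syndrome (ARDS) on a
chest X-ray — bilateral airspace opacities, the imaging criterion of the
Berlin definition — is notoriously unreliable: experienced readers disagree
with each other on a substantial fraction of films. A deep-learning
classifier can beat the average physician on this task overall while still
being the weaker reader on the most ambiguous films. That asymmetry is what
makes *deferral policies* interesting: rather than choosing between human
and machine, route each film to whichever reader is better placed to call
it, using each side's own stated uncertainty as the switch.

`ardsdefer` implements the full analysis pipeline for such a study: the
ordinal rating scale shared by readers and model, consensus reference
standards from multi-reader panels, the deferral and blending strategies,
and a clustered evaluation protocol. Because the motivating study's data
are available only through a data-use agreement, the package also ships a
synthetic reader-study generator calibrated to that study's published
marginal statistics, so every stage is testable end to end.

## The rating scale and its conventions

Everything meets on the ordinal 1–8 scale: 1 is a confident negative, 8 a
confident positive, and the pair {4, 5} is equivocal. A model probability
$p$ is placed on the scale by the linear map $r = 1 + 7p$, whose fixed
points matter:

* $p = 0.5 \mapsto r = 4.5$, the binary decision threshold. The threshold
  is *inclusive*: a score of exactly 4.5 is called positive. The package
  applies this rule uniformly — to consensus tie-breaks, where it is part
  of the labelling rule, and to every blended strategy score, where a
  threshold convention is needed and 4.5 is the only one defined.
* Ratings in $[3.5, 5.5)$ — probabilities in $[2.5/7, 4.5/7) \approx
  [0.357, 0.643)$ — form the AI uncertainty band, closed below and open
  above. Reader uncertainty is the integer pair {4, 5}. These are kept as
  two distinct predicates (`reader_is_uncertain()`, `ai_is_uncertain()`)
  rather than unified, because their edge semantics genuinely differ.
  The exact rational bounds $2.5/7$ and $4.5/7$ are used internally; the
  three-decimal values are display only.

## Reference standards

The per-image label is the strict majority of the panel's binarised reads
(integer rating ≥ 5 ⇔ ≥ 4.5). An exact tie — possible on even panels —
falls through to the mean raw rating, positive iff ≥ 4.5. Panels that a
reader exclusion reduces below two reads raise an error rather than being
dropped silently: a silent drop would desynchronise the per-reader
evaluation subsets. Panels smaller than the study's design size of six
reads warn only, so small fixtures stay usable.

Evaluating a reader against labels their own reads helped define would
flatter them; every reader is therefore scored against leave-one-reader-out
(LOO) labels rebuilt from the other readers (`loo_label_sets()`). The same
exclusion applies to the *difficult* flag: an image is difficult for a
given evaluation when at least two of the retained readers' binary reads
disagree with the consensus.

## Strategies and review burden

Seven policies produce a per-image final score on the 1–8 scale, a binary
decision, and a decision source. Review burden is the percentage of images
needing at least one physician read: 0 for the AI alone, 100 whenever the
physician reads everything, $100 \times$ the deferred fraction for the
AI-first policy, and above 100 for the audit policy (second reads). Two
conventions are worth stating:

* When the AI-first policy does **not** defer, and when the reader-first
  policy does, the final score is the AI's *continuous* rating equivalent,
  not a snapped integer — binary decisions are unaffected and information
  is preserved for downstream blending and plots.
* The audit policy's second reader is drawn uniformly among the other
  panel members who rated that image, from a dedicated seeded substream
  per test reader, so per-reader results replay independently. The second
  reader's read is used unconditionally, even if it is itself equivocal.

The weighted average $w\,y_{\text{physician}} + (1 - w)\,y_{\text{AI}}$
selects $w$ per test reader by maximising the mean validation accuracy of
the *other* readers over the grid $\{0, 0.05, \dots, 1\}$ (21 candidates).
Two open choices were resolved as follows:

* Each validation reader is scored against their **own** LOO labels,
  consistent with the evaluation convention; scoring against the
  all-reader consensus is available via `validation_labels = "all"` but
  not the default.
* Grid ties break toward the smaller $w$ (more AI weight), a deterministic
  rule consistent with the AI carrying the greater validated weight in
  this problem. Ties at the top of the grid are in fact *structural*: for
  any reader whose integer ratings match the labels, a blend with
  $w \ge 0.9$ retains a margin of at least $0.9 \times 0.5 = 0.45$ from
  the threshold while the AI can pull the score by at most
  $(1 - w) \times 3.5 = 0.35$, so the top grid weights tie exactly and
  the smallest tied weight is returned.

## Evaluation protocol

Metrics are computed per (reader, strategy) on the subset of images that
reader reviewed, against that reader's LOO labels, then averaged across
readers. A metric with an empty denominator (no positives in a subset, say)
is `NA`, never 0 — zero-imputation would bias sensitivity in low-prevalence
resamples.

Uncertainty comes from a patient-level cluster bootstrap: chest X-rays from
one patient are correlated, so patients are resampled with replacement and
a patient drawn $k$ times contributes all their images $k$ times. Within
each replicate, per-reader metrics are recomputed from the resampled
confusion counts and then averaged across readers — the ordering matters
(the across-reader mean of per-reader accuracies is not the pooled
accuracy) and is asserted by a test where the two orders differ. The 95%
interval is the 2.5th/97.5th percentile of the replicate means, using R's
default linear-interpolation quantile so intervals are bit-reproducible.
The reported point estimate is the observed (non-bootstrap) across-reader
mean; the bootstrap mean is returned alongside for inspection. Replicates
where a metric is undefined for every reader are dropped for that metric
and counted in the summary.

The one-sided comparison of strategies A and B is paired by default: both
are evaluated on the same patient resamples and the p-value is the
fraction of replicates where A fails to exceed B, ties counting against A
(conservative and deterministic). An independent-resampling variant exists
behind `method = "independent"`; the paired construction is the default
because it respects the within-replicate coupling of the two strategies.

Deliberately absent: AUROC. A physician's ordinal rating cannot rank films
the way a continuous model score can, so an AUROC comparison between the
two would not be a fair summary of reader performance; all comparisons use
threshold metrics.

## The synthetic generator

The generator emulates the *statistical shape* of a 115-patient,
414-image, 9-reader ARDS reader study; it makes no attempt to model images
or the classifier's internals, only their output distributions.

* **Cohort.** Patients are positive with probability $30/115$. Image
  counts per patient are zero-truncated negative binomial with size 3.5
  and mean parameter 3.2, chosen once so that large cohorts reproduce a
  median of 3 images (IQR about 2–4.5) and a mean of ~3.6 ≈ 414/115.
  40% of positive patients (12/30) are "late onset": the first
  $\lceil k/2 \rceil$ of their $k$ images are negative — the simplest
  mechanism consistent with initially ARDS-negative films; patients with a
  single image are not eligible (a late-onset patient with no positive
  image would be vacuous). Per-image difficulty is Beta(0.33, 2.0): most
  films are easy, with a long tail of genuinely ambiguous ones.
* **Readers.** A read is correct with probability
  $\mathrm{clamp}(a_0 - s \cdot d,\ 0.5,\ 1)$ at difficulty $d$. The
  default panel's base accuracies span 0.81–0.96 (slope 0.40),
  reflecting the heterogeneity of a real panel; the mix of stronger and
  weaker readers is what lets the panel disagree enough to flag a
  realistic share of films as difficult while the consensus stays
  accurate. Whether a read is emitted as equivocal depends on
  correctness: incorrect reads are $1 + \kappa$ times as likely to be
  equivocal ($\kappa$ = `calibration`, default 1.5), normalised so the
  marginal equivocal rate equals the 5.6% target exactly in expectation;
  $\kappa = 0$ makes confidence independent of correctness, and the
  remaining confidence levels {2, 3, 4} are tilted toward high confidence
  when correct with strength $\log(1+\kappa)/2$. Because wrong reads
  cluster on difficult films, reader and AI uncertainty co-occur more
  often than independence predicts, as in real panels.
* **AI.** The latent score is $m = (2y - 1)\,\Phi^{-1}(a(d)) + \sigma
  \epsilon$ and the reported probability $\mathrm{logistic}(m/T)$. At the
  default $\sigma = 1$ the accuracy of thresholding at 0.5 equals $a(d)$
  exactly; the temperature $T$ spreads the probabilities without touching
  the ranking and thereby sets the uncertainty-band share. Defaults
  ($a_0 = 0.999$, slope 1.10, $T = 1.095$) put the expected band share at
  20.8% and make the AI clearly stronger than readers on easy films but
  weaker on the difficult tail.
* **Plumbing.** One master seed fans out through named substreams
  (`cohort`, `ratings`, `scores`, `bootstrap`, `audit_<reader>`), so each
  stage replays independently. Panels are assigned at the patient level by
  default (a reader reads all of an assigned patient's films), matching
  random patient assignment of reviewers; per-image assignment is
  available, and neither is asserted to be the original study's exact
  procedure.

**What the generator does and does not reproduce.** With these defaults,
large synthetic cohorts land the published marginal rates (reader
equivocal 5.6%, AI band 20.8%, prevalence, cohort shape) and the
qualitative structure of reader-vs-AI performance: the AI ahead overall
and on non-difficult films, readers ahead on difficult films and inside
the AI's uncertainty band, the AI ahead where readers are equivocal. The
*exact* published quadruple — 25% of films difficult together with reader
accuracies 0.844/0.702 and AI 0.899/0.678 on the two strata — is not
jointly reachable under this generator, and the reason is structural:
reads here are independent given difficulty, whereas a 25% difficult rate
alongside a 15.6% reader error rate on *non-difficult* films requires
readers' errors to be correlated within image (films that genuinely
mislead everyone). The calibrated defaults settle at roughly 31% difficult
with reader ~0.86/0.74 and AI ~0.90/0.70, preserving every ordering.
Passing tests on these cohorts therefore validates the pipeline's
*mechanics and orderings*, not the exact stratified magnitudes of any real
panel — and real reader studies should expect within-image error
correlation that this generator deliberately omits.

## Numerical and degenerate-input choices

* Probabilities, ratings and weights are validated at the boundaries they
  are defined on; out-of-range values are errors, not clamped.
* `base_accuracy = 1` with `score_noise = 0` is a legal degenerate AI: the
  latent separation is infinite and probabilities collapse to {0, 1}.
* Accuracy curves clamp to $[0.5, 1]$ — a reader or model is never worse
  than chance, however difficult the film.
* Bootstrap resampling uses `sample.int` multiplicities via `tabulate`,
  and confusion counts are aggregated per patient once so each replicate
  is a matrix product; B = 1000 on a 115-patient, 9-reader study runs in
  well under a second.
* Quantiles everywhere are R's type-7 (linear interpolation), stated once
  and never varied, so intervals reproduce bit-for-bit under a fixed seed.

## Problem sizes used in the test suite

The suite validates convergence claims at the sizes where their tolerances
are meaningful: marginal-rate and monotonicity checks on cohorts of
~10,000 images; bootstrap coverage on 200 independent 115-patient studies
with B = 1000 (nominal 95% ± 3 points); the deferral-superiority ordering
on 100 seeded 115-patient studies. These sizes were chosen so Monte-Carlo
error is comfortably below each asserted tolerance. On the burden check:
a single 414-image cohort measures the AI-uncertain rate with a sampling
standard deviation of about 2 percentage points
($\sqrt{0.208 \times 0.792 / 414}$), so agreement with the configured
20.8% is asserted on the mean burden across the 100 studies, while the
superiority ordering — which is what deferral buys — is asserted per
study.

## Known limitations

* Reads are independent given difficulty; real panels show within-image
  error correlation (see above), which would be the first extension.
* Strategy evaluation assumes the behavioural model of the original
  readers is unchanged by the existence of an AI backstop; a physician
  told the AI will catch their equivocal calls may rate differently.
* The audit policy uses whatever second read exists, including an
  equivocal one; no escalation beyond one second reader is modelled.
* Labels derive from panel ratings alone; any clinical side-information
  the original readers used is folded into their accuracy parameters, not
  modelled.
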