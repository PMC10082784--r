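# ardsdefer

Tools for analysing how physicians and an AI classifier should share the
work of reading chest X-rays for findings of the acute respiratory distress
syndrome (ARDS). ARDS diagnosis hinges on recognising bilateral airspace
opacities on imaging, a task on which physicians are known to disagree; an
AI model can outperform the average reader overall and still be the wrong
tool for the hardest films. `ardsdefer` is aimed at biostatisticians and
clinical-ML researchers running multi-reader, multi-case evaluations of
such human–AI *deferral* policies: who reads first, who gets the final say
when the first reader is uncertain, and what that costs in physician
workload.

## What it implements

**The assessment scale.** Readers grade each image on an ordinal 1–8 scale
(1 = confident non-ARDS, 8 = confident ARDS; 4/5 = equivocal). Classifier
probabilities are mapped onto the same axis by the linear map
*r* = 1 + 7*p*, so *p* = 0.5 lands on the binary decision threshold
*r* = 4.5 (inclusive). Reader uncertainty is the equivocal pair {4, 5};
AI uncertainty is the band *r* ∈ [3.5, 5.5), i.e. *p* ∈ [0.357, 0.643).

**Reference standards.** The per-image ground truth is the majority vote of
the panel's binarised reads, with exact ties resolved by the mean raw
rating (≥ 4.5 → positive). Each reader is evaluated against
*leave-one-reader-out* (LOO) labels rebuilt without their own reads, so no
reader influences the standard they are judged against. Images where ≥ 2
retained readers disagree with the consensus are flagged *difficult*.

**Collaboration strategies.** Seven per-image decision policies, each with
a decision-source audit trail and a *review burden* (percentage of images
needing at least one physician read):

| strategy | rule | burden |
|---|---|---|
| `physician` | the reader's rating stands | 100 |
| `ai` | the AI's rating equivalent stands | 0 |
| `ai_aided_physician` | reader first; equivocal reads (4/5) defer to AI | 100 |
| `physician_aided_ai` | AI first; band scores defer to the reader | 100 × deferred fraction |
| `average` | mean of rating and rating equivalent | 100 |
| `weighted_average` | *w*·rating + (1 − *w*)·rating-equivalent | 100 |
| `audit` | both read; a random second reader settles disagreements | 100 + 100 × disagreement fraction |

The weight *w* is chosen per test reader by leave-one-physician-out
validation over the grid {0, 0.05, …, 1}.

**Evaluation.** Accuracy, F1, sensitivity, specificity, PPV and NPV per
(reader, strategy), averaged across readers; 95% CIs from a patient-level
cluster bootstrap (chest X-rays are clustered within patients, so patients
— not images — are resampled; default B = 1000, percentile intervals); a
one-sided paired bootstrap test between strategies; and stratified
reader-vs-AI accuracy reports (difficulty, mutual uncertainty, confidence
levels).

**Synthetic reader studies.** The original study's data are not publicly
deposited, so the package ships a seeded generator that emulates its
structure: 115 patients (30 ARDS-positive, 12 of them presenting late),
~3.6 images per patient (median 3), panels of 6–9 of 9 heterogeneous
readers, reader equivocal rate 5.6%, AI uncertainty-band rate 20.8%, and
difficulty-dependent accuracy for both. Every analysis stage is exercised
end-to-end on these cohorts.

## Worked example

```r
library(ardsdefer)
library(dplyr)

study <- simulate_reader_study(seed = 42)
study$cohort
#> <synthetic_cohort> 115 patients (25 positive), 416 images (66 positive)

ev <- evaluate_strategies(study$ratings, study$scores, seed = 42)
cb <- cluster_bootstrap(ev, B = 1000, seed = 42)

cb$summary |>
  filter(metric == "accuracy") |>
  left_join(mean_reader_metrics(ev) |>
              filter(metric == "review_burden") |>
              select(strategy, burden = estimate), by = "strategy") |>
  mutate(across(c(estimate, ci_low, ci_high), ~ round(.x, 3)),
         burden = round(burden, 1)) |>
  select(strategy, accuracy = estimate, ci_low, ci_high, burden) |>
  arrange(desc(accuracy)) |>
  as.data.frame()
#>             strategy accuracy ci_low ci_high burden
#> 1              audit    0.918  0.900   0.938  125.0
#> 2   weighted_average    0.895  0.874   0.916  100.0
#> 3            average    0.876  0.858   0.894  100.0
#> 4 physician_aided_ai    0.875  0.846   0.902   21.7
#> 5 ai_aided_physician    0.840  0.822   0.858  100.0
#> 6                 ai    0.833  0.799   0.868    0.0
#> 7          physician    0.831  0.813   0.849  100.0

one_sided_bootstrap_test(ev, "physician_aided_ai", "physician",
                         B = 1000, seed = 42)$p_value
#> 0.001
```

Reading the table: each accuracy is the across-reader mean against that
reader's LOO labels, with its 95% cluster-bootstrap interval; `burden` is
the physician workload. The AI-first deferral strategy
(`physician_aided_ai`) is within a point of the much costlier blending
strategies while sending only ~21% of images to a physician; reading every
image (`physician`, burden 100) buys no accuracy over it. The p-value is
the one-sided paired bootstrap comparison against the physician-alone
baseline.

The full pipeline (generate → label → strategise → evaluate → report) runs
from one configuration:

```r
run_pipeline(list(seed = 1, out_dir = "out"))        # or a YAML path
```

which writes `ratings.csv`, `labels.csv`, `decisions.csv`, `results.csv`,
`summaries.csv`, `strata.csv`, a Markdown report and a JSON manifest from
which the run is exactly reproducible.

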