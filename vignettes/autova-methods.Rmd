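---
title: "Tariff-based verbal autopsy decision support: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tariff-based verbal autopsy decision support: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autova)
```

## The problem

A large share of deaths in many countries occur outside health facilities
and must still be certified by a physician before burial and registration.
Without medical records, certifying physicians fall back on an interview
with the family, and practice varies widely: ill-defined codes (R99
ill-defined, I46 cardiac arrest, R54 senility) are common and useless for
health policy. A verbal autopsy (VA) standardises that interview into
binary symptom questions, and an algorithm can turn the endorsements into
candidate causes. `autova` implements such an engine together with the
decision-support layer a certifying physician actually interacts with: an
endorsed-symptom summary, the top three candidate causes with likelihood
categories, an explicit abstention ("undetermined"), routing rules for
when the tool is used at all, and the evaluation statistics produced by a
pilot of such a system.

The physician stays in charge throughout: the engine proposes, the
physician certifies, possibly refining a proposal (for example a specific
cancer site the questionnaire cannot resolve) or overriding it entirely.
The package therefore models the physician explicitly in its simulation
layer, and evaluates the *certified* causes of death, not just the
algorithmic ones.

## The tariff model

Let $x_{ij}$ be the fraction of training deaths of cause $j$ that endorsed
symptom $i$, estimated from a gold-standard library of deaths with known
causes (`compute_endorsement_matrix()`). The tariff of symptom $i$ for
cause $j$ is a robust z-score across causes:

$$t_{ij} = \frac{x_{ij} - \mathrm{median}_{j'}(x_{ij'})}
               {\max(\mathrm{IQR}_{j'}(x_{ij'}),\ \varepsilon)}$$

so a symptom only earns a large tariff for a cause when its endorsement
rate for that cause stands out from its rate across all causes. A symptom
endorsed equally by every cause has tariff zero everywhere and cannot move
a diagnosis. The score of a death for cause $j$ is the sum of $t_{ij}$
over its endorsed symptoms; missing responses contribute nothing, matching
the binary checkbox semantics of the instrument.

Numerical choices, all configurable through `va_tariff()`:

* **Quantiles** use linear interpolation between order statistics (type
  7). The test suite checks the whole pipeline against an independent
  brute-force implementation of the same convention.
* **IQR floor** $\varepsilon = 0.001$ guards against degenerate rows where
  more than half the causes share one endorsement rate.
* **Rounding** to granularity 0.5, half away from zero, keeps tariffs
  coarse so single noisy training cells cannot dominate a score.
* **Truncation** keeps the 40 largest-|t| tariffs per cause (ties broken
  by symptom order), zeroing the rest, so each cause is driven by its most
  discriminating symptoms. Toy fixtures in the tests disable truncation.
* No bootstrap significance-zeroing of tariffs is applied; the pipeline is
  fully deterministic given its seeds, and the option is left as a
  configuration extension point.

Raw scores are not comparable across causes, so each score is converted to
a percentile rank against a **resampled training reference**
(`build_rank_reference()`): for each cause, 100 training deaths of that
cause are drawn with replacement (seeded) and scored against that cause.
Resampling to a common size removes training-prevalence effects from the
ranks. Ranks use the mid-rank convention for ties. The PRNG contract is
documented (one `set.seed`, causes in list order, `sample.int` per cause)
so tests can replay the stream independently.

## Decision support and abstention

A cause is shown to the physician only if it is demographically plausible
for the deceased (`restriction_table()`; restrictions are applied before
thresholding), its score clears an absolute floor, and its percentile rank
clears a rank floor (`va_thresholds()`, defaults `min_score = 0`,
`min_rank = 0.5`). These defaults are *artifact defaults*: the engines
this design descends from use unpublished cutoffs, and reports based on
the defaults should label them as such. Qualifying causes are ordered by
score, ties broken by rank and then cause id so output is reproducible
for audit; the top three are reported with likelihood categories
("possible" up to "very likely") read off the rank through configurable
bin edges (`va_likelihood_bins()`, defaults 0.50/0.65/0.80/0.95/1.00).
If no cause qualifies the report is undetermined — the engine abstains
rather than guesses, and the physician certifies unaided.

The default rank floor of 0.5 has a sharp interpretation: a death must
look *at least as typical* of a cause as the median training death of that
cause. Because a field death of cause $j$ has approximately the same score
distribution as the training deaths of cause $j$, its own-cause rank is
close to uniform, and the median rule abstains on roughly half of
individual deaths even when the signal is strong. That is intentional for
decision support — a physician is shown only well-supported suggestions —
but it would be a poor *population* estimator. For population-level CSMF
estimation the package therefore uses the unthresholded top-scoring cause
(`predict(fit, cohort, type = "top1")`, no abstention), and the recovery
analyses in the tests and the acceptance script do the same. With
perfectly separable profiles every training death of a cause ties at the
same score, the own-cause rank is exactly 0.5 under the mid-rank
convention, and the default thresholds recover every death.

## Routing (the SOP)

Each death takes exactly one of three pathways:

1. `RECORDS` — medical records are available *and* sufficient to certify;
2. `NARRATIVE` — otherwise, the open-ended narrative interview alone
   suffices (the narrative always precedes the structured questions,
   matching how physicians reason clinically);
3. `FULL_VA` — otherwise, the structured VA is administered and the
   decision report produced.

Record availability alone does not decide the pathway: records are often
incomplete, so the record carries a separate `records_confident` flag
(defaulting to availability when absent). The three pathways partition any
cohort, which the tests assert.

## The synthetic-data generator

No field data ships with the package; the generator defines the study
conditions under which the pipeline is exercised.

* **Profiles** (`generate_cause_profiles()`): each cause owns a signature
  of 3 symptoms endorsed with probability $0.5 + 0.5s$, all other symptoms
  are background at $0.5(1-s)$, where $s \in [0,1]$ is the sharpness. At
  $s = 1$ causes are perfectly separable; at $s = 0$ every symptom is an
  uninformative coin flip. Signatures are disjoint consecutive blocks when
  the symptom budget allows, random (and logged) otherwise.
* **Demographics**: an adult-module cohort, ages uniform on 20–90 years,
  55% male — the shape of a typical out-of-facility pilot cohort.
* **Pathways**: records available for 33.4% of deaths; given records, the
  physician certifies directly from them 31% of the time; the narrative
  alone suffices for 9.6% of the remainder. These defaults put about 81%
  of deaths on the FULL_VA pathway, the usage level a pilot of this kind
  reports; they are scenario parameters, not estimates.
* **Physician behaviour** (`physician_behaviour()`): accept the top cause
  with probability 0.82; failing that, accept rank 2 or 3 with probability
  0.17; otherwise override from a configurable cause distribution; refine
  an accepted cause into a free-entry child label 5% of the time.
  Undetermined reports always draw from the override distribution — a
  certificate must carry some cause. On the RECORDS and NARRATIVE pathways
  the simulated physician certifies the true cause: the external evidence
  supplied the diagnosis, and no error rate for those pathways is modelled.

Everything is reproducible bit-for-bit from a seed: every generator calls
`set.seed` once on entry and documents its draw order.

What the generator does **not** emulate: correlated symptoms within a
cause (endorsements are conditionally independent), age- or sex-dependent
symptom profiles, interviewer effects, recall bias, or missingness
patterns in the structured questions. Passing recovery tests on this
generator therefore demonstrates that the pipeline's mechanics are
correct — not that the engine achieves any particular accuracy on real
verbal autopsies.

## Evaluation statistics

`agreement_stats()` reports tool usage (share of deaths on the FULL_VA
pathway) and, among those, how often the physician certified one of the
top-3 causes and the top-1 cause. "Used the tool's diagnosis" is
operationalised as any-of-top-3, with top-1 agreement reported separately,
because routine reports of such pilots are ambiguous between the two; the
package computes both, over both the all-FULL_VA and determinate-reports
denominators. `reclassification_matrix()` cross-tabulates the algorithm's
top-1 cause against the physician's certified cause (optionally only where
they disagree) with row percentages; `ill_defined_fraction()` measures the
garbage-code share (R99, I46, R54, plus abstentions);
`map_cause_categories()` collapses specific causes — including free-entry
refinements — into aggregate categories for side-by-side comparison with
external tabulations, with the caveat that externally coded national data
are not strictly comparable to a VA-assisted community cohort.
Human-readable summaries round percentages to integers; machine output
keeps full precision.

Population recovery is measured by CSMF accuracy,
$1 - \sum_j |\hat{f}_j - f_j| \,/\, 2(1 - \min_j f_j)$, which is 1 iff the
estimated cause-fraction distribution matches the truth and 0 for the
worst possible estimate (all mass on the rarest true cause). A degenerate
single-cause truth makes the denominator vanish; the package defines the
accuracy as 1 when the estimate matches exactly and raises an error
otherwise.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full pipeline is exercised end to end in seconds: oracle-equivalence
property tests at up to 5 causes × 10 symptoms × 20 training deaths;
recovery scenarios at 6 causes × 20 symptoms, 200 training deaths per
cause, cohorts of 1,000–2,000 deaths; and one pilot-scale run of 5,649
deaths over 11 causes × 40 symptoms. Behaviour-parameter recovery uses
10,000 simulated reports.

## Known limitations

* The tariff constants (granularity, floor, truncation, reference size)
  are configurable but their defaults are design choices, not values
  fitted to any published engine.
* Likelihood bin edges and qualification thresholds are artifact defaults;
  deployments should calibrate them and say so.
* The conditional-independence generator flattens real symptom
  correlation; CSMF accuracies measured here are optimistic.
* No chance-corrected concordance or uncertainty intervals on CSMFs;
  both are natural extension points.
* Free-text narrative content is out of scope; the narrative enters only
  through the `narrative_confident` routing flag.
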