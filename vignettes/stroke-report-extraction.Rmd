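---
title: "Sentence-level rule-based extraction of stroke attributes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sentence-level rule-based extraction of stroke attributes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokenlp)
```

## The extraction model

`strokenlp` targets the chart-abstraction problem for stroke-protocol
neuroimaging reports: turning each free-text CT/CTA/CTP report into seven
structured attributes (proximal large vessel occlusion, distal anterior
circulation occlusion, basilar occlusion, established ischemia,
intracranial hemorrhage, ASPECTS band, collateral status). The extraction
engine is deliberately simple and fully auditable:

1. **Sentence segmentation.** Rules never see more than one sentence, so
   segmentation defines evidence scope. Boundaries are newlines (radiology
   reports put section headers on their own lines) and runs of `.!?`
   followed by whitespace and an uppercase letter or digit; periods inside
   decimals (`1.5 cm`) and after a configurable abbreviation list (`Dr`,
   `vs`, `e.g`, ...) are protected. Offsets are 0-based half-open so each
   sentence is recoverable from the original text by slicing — an invariant
   the test suite checks on randomized texts.

2. **Weighted rule matching.** A rule is a regular expression with a signed
   weight targeting one class of one attribute; matching is
   case-insensitive unless the rule opts out. Each (rule, sentence) pair
   contributes at most one match — the cap prevents a repeated phrase from
   inflating scores without bound. Rules that need two cues in one
   sentence (an occlusion synonym *and* `M1`) use lookahead conjunction,
   which is what makes the engine *sentence-scoped keyword co-occurrence*
   rather than anything smarter.

3. **Aggregation and classification.** Per attribute, a class's raw score
   is the sum of the weights of its matched rules. Binary attributes map
   the `present` score through the standard logistic
   `p = 1/(1 + exp(-s))` and classify present iff `s > 0` (strictly): the
   underlying tool concept only requires that evidence raise or lower a
   probability estimate, so the logistic is the minimal monotone,
   symmetric mapping with `p(0) = 0.5`, and the strict inequality makes
   the no-evidence report default to absent. Categorical attributes take
   the positively-scoring class with the highest score; ties break
   worst-first (`poor` before `intermediate` before `good`, `lt5` before
   `ge5`), a clinically conservative choice for a screening tool; with no
   positive score the `not_reported` default wins.

4. **ASPECTS by value, not by class score.** An ASPECTS mention requires
   the capitalized token `ASPECTS`/`ASPECT` (case-sensitive) or the phrase
   "aspect score" (any case), followed by an integer; the first mention in
   document order with a value in 0–10 wins, bands at 5, and out-of-range
   integers are skipped. The case-sensitivity guard exists because English
   reuses "aspect" for facets of anatomy; the document-order rule reflects
   that reports state the score once in FINDINGS; the 0–10 guard rejects
   dictation noise. The raw integer is kept in the prediction trace only —
   evaluation uses the banded 3-class variable, which is what report-level
   validation tables compare.

## Weight scheme and the shipped rules

Shipped weights use three magnitudes: **1** for hedged cues, **2** for firm
cues, **4** for negation/exclusion. Consequences:

* a single same-sentence negation (−4) overrides up to two firm cues
  (+2 each), so "No evidence of occlusion of the M1 segment" nets −2 and
  classifies absent;
* a hedge alone (+1) classifies present — "possible subtle hypodensity"
  counts as ischemia unless negated. Whether hedged language *should*
  count as positive is genuinely undecidable from report text (human
  abstractors themselves agree only ~80% of the time on ischemia); we
  chose to count it, at reduced weight, and surface the lower probability
  (0.73 vs 0.88) in the trace rather than hide the threshold effect.

The LVO anatomy vocabulary is M1/A1 tokens, "carotid terminus", and
"proximal MCA/middle cerebral artery" phrasings. Isolated intracranial ICA
occlusion is excluded from LVO by construction — ICA wording is simply not
in the proximal vocabulary. Two documented failure modes of keyword
co-occurrence are deliberately preserved, not patched:

* **False positive:** "near-occlusion of the cavernous internal carotid
  artery with reconstitution of flow in the M1 segment" — occlusion cue
  and `M1` share a sentence, so the engine says present though no proximal
  occlusion exists.
* **False negative:** "occlusion extending from the internal carotid
  artery to the M2 segment" — a human infers M1 involvement from vascular
  anatomy; the engine sees no M1/A1 token and says absent.

`stroke_fixtures()` freezes these (and twelve more) as a behavioral
contract; `discrepancy_report()` shows, for every mismatch, exactly which
rule fired, which is the loop that makes iterative rule refinement
practical.

## The synthetic generator

Real stroke-protocol corpora are private, so the generator produces
labeled corpora with the statistical structure the pipeline needs to be
tested against. Defaults emulate a 1320-report consecutive corpus: LVO
12.2%, distal occlusion 14.2%, basilar occlusion 2.0%, established
ischemia 29.6%, hemorrhage 10.5%; ASPECTS stated in 29.1% of reports
(40/384 of stated values below 5) and collaterals in 16.4% (141:26:49
good:intermediate:poor). Attributes are sampled **independently** because
only marginal prevalences are documented; any correlation structure
(LVO with poor collaterals, say) would be invented. Text is rendered from
a template bank in neutral radiology style with both spelling dialects
(hemorrhage/haemorrhage), one FINDINGS sentence per finding, and a generic
IMPRESSION line. Gold labels always follow the generator's clinical ground
truth, *not* engine capability, so injected failure modes surface as
honest errors.

Five adversarial rewrites are available at configurable per-report rates
(all default 0): `negation_decoy` (pertinent-negative sentences for absent
findings), `hedge_ischemia` (hedged phrasing, gold stays present),
`ica_to_m2_extension` (gold LVO present — and, since the sentence
describes an occlusion reaching M2, gold distal present too — engine
misses it), `cavernous_reconstitution` (gold LVO absent, engine falsely
fires), and `aspect_homonym` (labels unchanged). The two LVO rewrites are
sampled mutually exclusively within a report so error accounting stays
exact: the LVO false-negative count equals the number of
`ica_to_m2_extension` flags and the false-positive count equals the number
of `cavernous_reconstitution` flags, one for one.

What passing tests on this corpus shows — and does not show: template and
rule vocabularies are aligned by construction, so 100% recovery on a clean
corpus validates the *plumbing* (segmentation, matching, aggregation,
negation logic, banding) and not robustness to real reporting variation.
Real reports paraphrase more freely, embed findings in comparative and
historical clauses, and split evidence across sentences; performance there
is an empirical question this package cannot answer without data, which is
exactly why the hard-case machinery exists.

## Evaluation machinery

Metrics are the standard diagnostic-accuracy set: sensitivity
`100·tp/(tp+fn)`, specificity `100·tn/(tn+fp)`, PPV, NPV, accuracy;
categorical attributes get one-vs-rest rows per class plus exact-match
multiclass accuracy. Numerical conventions:

* **Zero denominators give `NA`**, never 0 or 100 and never an exception:
  silently coercing would distort small-cell attributes (basilar occlusion
  at 2% prevalence can easily have no positives in a validation cohort).
* **Rounding is presentation-only**: metrics are carried at full precision
  and rounded to one decimal, half away from zero, only in
  `format_metrics()` / the CSV writer, matching clinical-table style.
* **Percent agreement** (not kappa) implements inter-rater reliability,
  because that is the statistic the duplicate-abstraction workflow
  reports.
* `split_corpus()` uses `round(train_fraction · n)` and a seeded
  `sample.int()`, so the canonical 1320-report corpus at fraction 921/1320
  gives cohorts of exactly 921 and 399, reproducibly; the pipeline script
  materializes membership to a CSV so cohort assignment is auditable.

The implementation of the metric formulas is cross-checked in the test
suite against an independent brute-force recount (an explicit per-item
loop) on 1000 random gold/prediction pairs, and one-vs-rest counts against
relabel-then-recount.

## Problem sizes and determinism

The test and acceptance workloads use corpora of 100–1000 reports for
behavioral checks, 1320 for split and binomial-interval checks, and
20 000 for prevalence-convergence checks (each empirical prevalence within
3 binomial standard errors of its configured value) — sizes at which every
property tested is already tight while the whole suite stays fast on a
single CPU. All randomness flows through explicit seeds
(`withr::with_seed`); corpora are byte-identical given config + seed, and
prediction is fully deterministic, so end-to-end runs reproduce exactly.

## Known limitations

* No cross-sentence inference, coreference, or vascular-anatomy ontology:
  evidence split across sentences is invisible by design.
* No machine-learned weights; the weight scheme is a fixed, interpretable
  convention.
* Report-level labels only: multiple occlusions in one report collapse to
  one positive label, consistent with report-level validation tables.
* The homonym guard assumes the score is dictated with the capitalized
  token or the phrase "aspect score"; a report writing "aspects score of
  8" in lowercase without "score" adjacency variations outside the shipped
  patterns would be missed — the patterns are configuration and can be
  extended per site.
* The synthetic generator does not mimic any real report's wording and
  carries no patient-level or longitudinal structure.
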