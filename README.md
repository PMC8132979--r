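# strokenlp

Rule-based extraction of stroke-related attributes from free-text head and
neck CT / CTA / CTP radiology reports, with the validation machinery needed
to measure how well it works.

## The problem

Population-scale stroke surveillance and thrombectomy research need
structured variables — *is there a proximal large vessel occlusion (LVO)?
an intracranial hemorrhage? what is the ASPECTS?* — but those variables
live in free-text radiology reports, and manual chart abstraction costs
minutes per report. `strokenlp` implements a transparent, auditable
alternative: sentence-level weighted regular-expression rules, the approach
used by iterative rule-refinement abstraction tools in clinical NLP.

The package classifies seven attributes per report:

| attribute | type | classes |
|---|---|---|
| `lvo` (MCA-M1 / ACA-A1 occlusion, ± carotid terminus) | binary | present / absent |
| `distal_occlusion` (M2/A2 or beyond) | binary | present / absent |
| `basilar_occlusion` | binary | present / absent |
| `ischemia` (established) | binary | present / absent |
| `hemorrhage` (any intracranial) | binary | present / absent |
| `aspects` (banded) | categorical | not_reported / lt5 / ge5 |
| `collaterals` | categorical | not_reported / poor / intermediate / good |

## The model

Reports are split into sentences; every rule is a regular expression that
must match **within a single sentence** and carries a signed weight
targeting one class of one attribute. For each attribute the raw score of
class *c* is

```
s_c = Σ  w_r   over rules r targeting c that matched some sentence
```

(one match per rule–sentence pair). For binary attributes the score maps
through the standard logistic, `p = 1 / (1 + exp(−s_present))`, and the
report is classified *present* iff `s_present > 0`; categorical attributes
take the highest positively-scoring class (worst-first tie-break) or the
`not_reported` default. Shipped weights use magnitudes 1 (hedged cue), 2
(firm cue) and 4 (negation), so a same-sentence "no evidence of …" vetoes
up to two firm cues. ASPECTS is extracted by value: a case-sensitive
`ASPECTS`/`ASPECT` token (or the phrase "aspect score") followed by an
integer 0–10, banded at 5 — the lowercase anatomical homonym ("the lateral
aspect of the vessel") never fires.

Sentence scope is a feature *and* a documented limitation: "occlusion" and
"M1 segment" in one sentence classify as LVO even when the occlusion is
actually cavernous-ICA with reconstituted M1 flow, and an "ICA occlusion
extending to the M2 segment" is missed because no M1/A1 token appears.
Both failure modes are preserved in the shipped rules, reproduced by the
fixture suite, and injectable into synthetic corpora at controlled rates.

Validation follows standard diagnostic-accuracy practice: sensitivity,
specificity, PPV, NPV and overall accuracy per attribute (one-vs-rest per
class for the categorical ones), percent agreement, seeded train/validation
splitting, and a discrepancy report pairing every gold-vs-predicted
mismatch with the rules that fired, to drive iterative rule refinement.

Because real stroke-protocol report corpora are private, the package
includes a seeded synthetic generator whose defaults emulate a
1320-report consecutive stroke-protocol corpus (LVO 12.2%, distal 14.2%,
basilar 2.0%, ischemia 29.6%, hemorrhage 10.5%, ASPECTS stated in 29.1%,
collaterals in 16.4%), with adversarial rewrites (negation decoys, hedged
ischemia, the two LVO hard cases, the ASPECT homonym) available at
configurable rates.

## Worked example

```r
library(strokenlp)

report <- list(
  id = "ex-001",
  text = paste0(
    "CT/CTA STROKE PROTOCOL:\nFINDINGS:\n",
    "Loss of opacification of the left M1 segment extending into the M2 segment. ",
    "Possible subtle hypodensity in the left insula. ",
    "No evidence of intracranial hemorrhage. ASPECTS is 7. ",
    "Good collateral circulation is noted.\n",
    "IMPRESSION: Acute left MCA occlusion."
  )
)
predict_report(report)[, 1:9]
#>       id     lvo distal_occlusion basilar_occlusion ischemia hemorrhage aspects
#> 1 ex-001 present          present            absent  present     absent     ge5
#>   collaterals aspects_value
#> 1        good             7
```

The M1 "loss of opacification" sentence fires the proximal-occlusion rule
(`lvo = present`) and, via its M2 mention, the distal rule; the hedged
hypodensity classifies ischemia present at reduced weight; the negated
hemorrhage sentence scores −2 (cue +2, negation −4), i.e. probability
0.119, so hemorrhage is absent; ASPECTS 7 bands to `ge5`.

Corpus-level evaluation with the pipe:

```r
corpus <- generate_corpus(sim_config(n_reports = 300, seed = 42))
ev <- corpus |> predict_corpus() |> (\(p) evaluate_predictions(corpus, p, cohort = "demo"))()
glance(ev)
#>   cohort   n n_attributes n_discrepancies mean_binary_accuracy
#> 1   demo 300            7               0                  100
```

On a clean synthetic corpus (no adversarial rewrites) the shipped rules
recover every gold label, because generator templates and rule vocabulary
are aligned by construction — `tidy(ev)` shows 100.0 in every defined cell.
Inject hard cases to degrade it in a controlled, exactly-countable way:

```r
cfg <- sim_config(n_reports = 800, seed = 1,
                  hard_rates = list(ica_to_m2_extension = 0.05))
hard <- generate_corpus(cfg)
confusion(hard$lvo, predict_corpus(hard)$lvo)$fn
# equals the number of reports carrying the ica_to_m2_extension flag, exactly
```

A command-line pipeline (`simulate`, `split`, `extract`, `evaluate`,
`fixtures`) is installed at `system.file("cli", "strokenlp.R", package =
"strokenlp")`.

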