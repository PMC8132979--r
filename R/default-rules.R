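# Cue vocabularies shared by the default rules. Weights follow a fixed
# magnitude scheme: 1 = weak/hedged cue, 2 = firm cue, 4 = negation or
# exclusion, so a single same-sentence negation overrides up to two firm cues.

# occlusion synonyms, including angiographic phrasing ("loss of opacification")
OCC <- "(?:occlus|occluded|loss of opacification|filling defect|thromb)"
# proximal anterior circulation anatomy defining large vessel occlusion:
# MCA-M1 or ACA-A1, with or without carotid terminus involvement. Isolated
# intracranial ICA wording deliberately does NOT appear here.
LVO_ANAT <- paste0(
  "(?:\\bM1\\b|\\bA1\\b|carotid terminus|",
  "proximal (?:MCA\\b|middle cerebral arter|anterior cerebral arter))"
)
# M2/A2 segments or beyond define distal anterior circulation occlusion
DISTAL_ANAT <- "(?:\\bM2\\b|\\bM3\\b|\\bM4\\b|\\bA2\\b|\\bA3\\b|\\bA4\\b)"
HEM <- paste0(
  "(?:h(?:a?)emorrhage|h(?:a?)ematoma|h(?:a?)emorrhagic|\\bSAH\\b|",
  "subarachnoid blood|intraparenchymal blood|intraventricular blood)"
)
# firm ischemia cues; hypodensity hedged by "possible"/"subtle" is excluded
# here and picked up by the weak-cue rule instead
ISCH_FIRM <- paste0(
  "(?:established isch(?:a?)emia|\\binfarct|",
  "loss of gr[ae]y-white differentiation|(?<!subtle )(?<!possible )hypodensit)"
)
ISCH_HEDGE <- paste0(
  "(?:possible subtle hypodensit|subtle hypodensit|questionable hypodensit|",
  "cannot (?:rule out|exclude) (?:early )?isch|possible early isch)"
)
ISCH_ANY <- "(?:\\binfarct|isch(?:a?)emi|hypodensit|gr[ae]y-white)"
NEG <- "\\b(?:no|not|without|negative for)\\b"

both <- function(a, b) paste0("(?=.*", a, ")(?=.*", b, ")")

default_rule_table <- function() {
  r <- function(rule_id, attribute, target_class, pattern, weight,
                case_sensitive = FALSE, note = "") {
    tibble::tibble(
      rule_id = rule_id, attribute = attribute, target_class = target_class,
      pattern = pattern, weight = weight, case_sensitive = case_sensitive,
      note = note
    )
  }
  dplyr::bind_rows(
    # ---- proximal large vessel occlusion (MCA-M1 / ACA-A1 / terminus) ----
    r(
      "lvo_proximal_occlusion", "lvo", "present", both(OCC, LVO_ANAT), 2,
      note = "occlusion synonym + M1/A1/terminus wording in one sentence"
    ),
    r(
      "lvo_negated", "lvo", "present", both(NEG, LVO_ANAT), -4,
      note = "same-sentence negation of proximal anatomy vetoes the finding"
    ),
    r(
      "lvo_patent", "lvo", "present", both("\\bpatent\\b", LVO_ANAT), -4,
      note = "explicitly patent proximal vessels"
    ),
    # ---- distal anterior circulation occlusion (M2/A2 or beyond) ----
    r(
      "distal_occlusion_cue", "distal_occlusion", "present",
      both(OCC, DISTAL_ANAT), 2,
      note = "occlusion synonym + M2/M3/A2/A3 wording in one sentence"
    ),
    r(
      "distal_negated", "distal_occlusion", "present",
      both(NEG, DISTAL_ANAT), -4
    ),
    r(
      "distal_patent", "distal_occlusion", "present",
      both("\\bpatent\\b", DISTAL_ANAT), -4
    ),
    # ---- basilar occlusion ----
    r(
      "basilar_occlusion_cue", "basilar_occlusion", "present",
      both(OCC, "basilar"), 2
    ),
    r("basilar_negated", "basilar_occlusion", "present", both(NEG, "basilar"), -4),
    r(
      "basilar_patent", "basilar_occlusion", "present",
      both("\\bpatent\\b", "basilar"), -4
    ),
    # ---- intracranial hemorrhage (both spelling dialects) ----
    r(
      "hemorrhage_cue", "hemorrhage", "present", HEM, 2,
      note = "hemorrhage/haemorrhage/hematoma/SAH and blood-product phrasing"
    ),
    r("hemorrhage_negated", "hemorrhage", "present", both(NEG, HEM), -4),
    # ---- established ischemia, firm vs hedged language ----
    r(
      "ischemia_firm", "ischemia", "present", ISCH_FIRM, 2,
      note = "established infarct/ischemia, grey-white loss, frank hypodensity"
    ),
    r(
      "ischemia_hedged", "ischemia", "present", ISCH_HEDGE, 1,
      note = "hedged phrasing carries half weight; alone it still classifies
present, but any same-sentence negation overrides it"
    ),
    r("ischemia_negated", "ischemia", "present", both(NEG, ISCH_ANY), -4),
    # ---- qualitative collateral status ----
    r(
      "collaterals_good", "collaterals", "good",
      both("collateral", "\\b(?:good|robust|excellent)\\b"), 2
    ),
    r(
      "collaterals_intermediate", "collaterals", "intermediate",
      both("collateral", "\\b(?:intermediate|moderate)\\b"), 2
    ),
    r(
      "collaterals_poor", "collaterals", "poor",
      both("collateral", "\\b(?:poor|sparse|scant|absent)\\b"), 2
    ),
    # ---- ASPECTS mentions: value banding happens in extract_aspects(); the
    # target_class field is not consulted for these capture rules ----
    r(
      "aspects_token", "aspects", "ge5",
      "\\bASPECTS?\\b[\\s:=-]{0,3}(?:(?:is|of|was|score)\\b[\\s:=-]{0,3}){0,2}(\\d{1,2})\\b",
      2,
      case_sensitive = TRUE,
      note = "capitalized token only, so the anatomical homonym 'aspect' never fires"
    ),
    r(
      "aspects_score_phrase", "aspects", "ge5",
      "\\baspect\\s+score\\b[\\s:=-]{0,3}(?:(?:is|of|was)\\b[\\s:=-]{0,3}){0,2}(\\d{1,2})\\b",
      2,
      note = "the explicit phrase 'aspect score' is unambiguous in any case"
    )
  )
}

#' Default stroke attribute rule library
#'
#' The shipped rule sets for all seven attributes. They encode, per
#' attribute: a firm positive-evidence rule requiring the finding cue and
#' (where relevant) the defining anatomy in the same sentence; same-sentence
#' negation/patency rules with a weight large enough to override two firm
#' cues; a reduced-weight rule for hedged ischemia language; and
#' case-sensitivity guards for the ASPECT/aspect homonym. Known, documented
#' consequences of sentence-scoped keyword matching are preserved rather
#' than patched: an occlusion word co-occurring with "M1" in one sentence
#' classifies as proximal LVO even when the occlusion is actually cavernous
#' ICA with reconstituted M1 flow, and an "ICA extending to M2" occlusion is
#' missed because neither M1 nor A1 is named.
#'
#' @return A compiled `stroke_ruleset` (see [compile_ruleset()]) with a
#'   `version` attribute.
#' @examples
#' rs <- default_rules()
#' table(rs$attribute)
#' @export
default_rules <- function() {
  rs <- compile_ruleset(default_rule_table())
  attr(rs, "version") <- "1.0.0"
  rs
}

#' Behavioral fixture suite
#'
#' A fixed set of report texts with gold labels and the classification the
#' default rules are expected to produce, covering the documented behaviors:
#' the proximal-occlusion phrasing revision (loss of opacification + M1), the
#' same-sentence false positive (cavernous ICA occlusion with reconstituted
#' M1), the anatomy false negative (ICA-to-M2 extension without an M1/A1
#' token), the ASPECT homonym, hedged ischemia, clean negations, and
#' canonical positives for every attribute. `agrees` marks whether the
#' engine's expected output equals gold; fixtures with `agrees = FALSE` are
#' the known failure modes of sentence-scoped keyword matching.
#'
#' @return A tibble with columns `fixture_id`, `tag`, `text`, list-columns
#'   `gold` and `engine` (full validated label vectors), and `agrees`.
#' @examples
#' fx <- stroke_fixtures()
#' fx[!fx$agrees, c("fixture_id", "tag")]
#' @export
stroke_fixtures <- function() {
  schema <- stroke_schema()
  fx <- function(fixture_id, tag, text, gold, engine = gold) {
    tibble::tibble(
      fixture_id = fixture_id, tag = tag, text = text,
      gold = list(validate_labels(gold, schema)),
      engine = list(validate_labels(engine, schema))
    )
  }
  out <- dplyr::bind_rows(
    fx(
      "proximal_opacification", "revision_case",
      "CTA demonstrates loss of opacification in the left middle cerebral artery, involving the left M1 segment and extending into the M2 segment.",
      gold = list(lvo = "present", distal_occlusion = "present")
    ),
    fx(
      "cavernous_reconstitution", "same_sentence_false_positive",
      "There is near-occlusion of the cavernous internal carotid artery with reconstitution of flow in the M1 segment.",
      gold = list(),
      engine = list(lvo = "present")
    ),
    fx(
      "ica_to_m2_extension", "anatomy_false_negative",
      "There is an occlusion extending from the internal carotid artery to the M2 segment.",
      gold = list(lvo = "present", distal_occlusion = "present"),
      engine = list(distal_occlusion = "present")
    ),
    fx(
      "aspect_homonym", "homonym_guard",
      "Calcification along the lateral aspect of the cavernous carotid artery.",
      gold = list()
    ),
    fx(
      "hedged_ischemia", "hedged_cue",
      "Possible subtle hypodensity in the right insula.",
      gold = list(ischemia = "present")
    ),
    fx(
      "canonical_lvo", "canonical_positive",
      "Occlusion of the M1 segment of the right MCA.",
      gold = list(lvo = "present")
    ),
    fx(
      "isolated_ica_excluded", "exclusion",
      "Occlusion of the intracranial internal carotid artery without involvement of the M1 segment.",
      gold = list()
    ),
    fx(
      "negated_hemorrhage", "clean_negation",
      "No evidence of intracranial hemorrhage.",
      gold = list()
    ),
    fx(
      "basilar_thrombosis", "canonical_positive",
      "Thrombosis of the mid basilar artery.",
      gold = list(basilar_occlusion = "present")
    ),
    fx(
      "good_collaterals", "canonical_positive",
      "Good collateral circulation is noted.",
      gold = list(collaterals = "good")
    ),
    fx(
      "aspects_low_with_infarct", "aspects_banding",
      "ASPECTS of 3 with a large MCA territory infarct.",
      gold = list(aspects = "lt5", ischemia = "present")
    ),
    fx(
      "aspects_high", "aspects_banding",
      "No acute hemorrhage. ASPECTS is 8.",
      gold = list(aspects = "ge5")
    ),
    fx(
      "aspects_out_of_range", "range_guard",
      "ASPECTS 12 was dictated in error.",
      gold = list()
    ),
    fx(
      "distal_m2", "canonical_positive",
      "Occlusion of the left M2 segment of the middle cerebral artery.",
      gold = list(distal_occlusion = "present")
    )
  )
  out$agrees <- purrr::map2_lgl(out$gold, out$engine, identical)
  out
}
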