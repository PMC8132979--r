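#' Configuration for the synthetic report generator
#'
#' Default prevalences reproduce the marginal attribute frequencies of a
#' 1320-report consecutive stroke-protocol imaging corpus: proximal large
#' vessel occlusion 12.2%, distal anterior circulation occlusion 14.2%,
#' basilar occlusion 2.0%, established ischemia 29.6%, intracranial
#' hemorrhage 10.5%; ASPECTS stated in 29.1% of reports (40/384 of those
#' below 5) and collateral status in 16.4% (141/216 good, 26/216
#' intermediate, 49/216 poor). Attributes are sampled independently: only
#' marginal prevalences are documented, and a correlation structure would be
#' invented.
#'
#' `hard_rates` control the per-report probability of five adversarial
#' rewrites (all default 0): `negation_decoy` (explicit pertinent-negative
#' sentences for absent findings), `hedge_ischemia` (hedged ischemia
#' phrasing), `ica_to_m2_extension` (an ICA occlusion extending to M2,
#' worded without M1/A1 -- a proximal occlusion the engine cannot see),
#' `cavernous_reconstitution` (cavernous ICA near-occlusion with
#' reconstituted M1 flow -- not a proximal occlusion, but the engine sees
#' "occlusion" and "M1" in one sentence), and `aspect_homonym` (an
#' anatomical "aspect" sentence). The two LVO rewrites are mutually
#' exclusive within a report.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; corpora are byte-identical given the same
#'   config and seed.
#' @param prevalence Named list overriding any of: `lvo`,
#'   `distal_occlusion`, `basilar_occlusion`, `ischemia`, `hemorrhage`,
#'   `aspects_reported`, `p_lt5_given_reported`, `collaterals_reported`,
#'   `p_collaterals` (named numeric over good/intermediate/poor, summing
#'   to 1).
#' @param hard_rates Named list overriding any of the five hard-case rates.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_reports = 100, seed = 42)
#' cfg$prevalence$lvo
#' @export
sim_config <- function(n_reports = 1320, seed = 1,
                       prevalence = list(), hard_rates = list()) {
  if (!is.numeric(n_reports) || n_reports < 1 || n_reports != round(n_reports)) {
    stop("n_reports must be a positive integer", call. = FALSE)
  }
  prev <- list(
    lvo = 0.122,
    distal_occlusion = 0.142,
    basilar_occlusion = 0.020,
    ischemia = 0.296,
    hemorrhage = 0.105,
    aspects_reported = 0.291,
    p_lt5_given_reported = 40 / 384,
    collaterals_reported = 0.164,
    p_collaterals = c(good = 141, intermediate = 26, poor = 49) / 216
  )
  unknown <- setdiff(names(prevalence), names(prev))
  if (length(unknown) > 0) {
    stop("unknown prevalence field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  prev[names(prevalence)] <- prevalence
  hard <- list(
    negation_decoy = 0, hedge_ischemia = 0, ica_to_m2_extension = 0,
    cavernous_reconstitution = 0, aspect_homonym = 0
  )
  unknown <- setdiff(names(hard_rates), names(hard))
  if (length(unknown) > 0) {
    stop("unknown hard-case tag(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  hard[names(hard_rates)] <- hard_rates
  probs <- c(
    unlist(prev[setdiff(names(prev), "p_collaterals")]),
    prev$p_collaterals, unlist(hard)
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(prev$p_collaterals) - 1) > 1e-8) {
    stop("p_collaterals must sum to 1", call. = FALSE)
  }
  if (hard$ica_to_m2_extension + hard$cavernous_reconstitution > 1) {
    stop("the two LVO hard-case rates must sum to at most 1", call. = FALSE)
  }
  structure(
    list(
      n_reports = as.integer(n_reports), seed = as.integer(seed),
      prevalence = prev, hard_rates = hard
    ),
    class = "sim_config"
  )
}

# ---- template bank -------------------------------------------------------
# Neutral radiology phrasing, both spelling dialects. Every template is
# audited against the default rules so that gold labels and rule behavior
# stay consistent on clean (non-adversarial) text.

sim_templates <- function() {
  list(
    header = c(
      "CT HEAD AND CT ANGIOGRAPHY HEAD AND NECK:",
      "CT/CTA/CTP STROKE PROTOCOL:",
      "CT HEAD WITHOUT CONTRAST AND CTA CIRCLE OF WILLIS:"
    ),
    lvo = c(
      "There is occlusion of the {side} M1 segment.",
      "Loss of opacification of the {side} M1 segment of the middle cerebral artery.",
      "Occlusion of the {side} A1 segment of the anterior cerebral artery.",
      "Occlusive thrombus at the {side} carotid terminus extending into the M1 segment.",
      "Abrupt occlusion of the proximal middle cerebral artery on the {side}."
    ),
    lvo_neg = c(
      "The M1 segments are patent bilaterally.",
      "No occlusion of the M1 or A1 segments.",
      "The proximal middle cerebral arteries are patent."
    ),
    distal = c(
      "Occlusion of the {side} M2 segment of the middle cerebral artery.",
      "There is a filling defect in the {side} M3 branch.",
      "Loss of opacification of the {side} A2 segment.",
      "Occluded {side} M2 branch of the MCA."
    ),
    distal_neg = c(
      "The M2 and M3 branches are patent.",
      "No filling defect in the M2 or M3 branches."
    ),
    basilar = c(
      "Occlusion of the basilar artery.",
      "Thrombosis of the mid basilar artery.",
      "Loss of opacification of the basilar tip."
    ),
    basilar_neg = c(
      "The basilar artery is patent.",
      "No occlusion of the basilar artery."
    ),
    ischemia = c(
      "There is an established infarct in the {side} MCA territory.",
      "Established ischaemia involving the {side} frontal lobe.",
      "Large hypodensity with loss of grey-white differentiation in the {side} MCA territory.",
      "Acute infarction of the {side} basal ganglia."
    ),
    ischemia_hedge = c(
      "Possible subtle hypodensity in the {side} insula.",
      "Cannot rule out early ischemia in the {side} MCA territory."
    ),
    ischemia_neg = c(
      "No established infarct or hypodensity.",
      "No evidence of acute ischemia.",
      "No loss of grey-white differentiation."
    ),
    hemorrhage = c(
      "Acute intraparenchymal hemorrhage in the {side} basal ganglia.",
      "There is a small subdural haematoma along the {side} convexity.",
      "Subarachnoid haemorrhage within the {side} sylvian fissure.",
      "Acute intraventricular hemorrhage is present."
    ),
    hemorrhage_neg = c(
      "No evidence of intracranial hemorrhage.",
      "No acute intracranial haemorrhage."
    ),
    aspects = c(
      "ASPECTS is {v}.",
      "ASPECTS of {v}.",
      "ASPECT score {v}."
    ),
    collaterals = list(
      good = c(
        "Good collateral circulation is noted.",
        "Robust collateral vessels are seen."
      ),
      intermediate = c(
        "Intermediate collateral status.",
        "Moderate collateral circulation is present."
      ),
      poor = c(
        "Poor collateral circulation.",
        "Sparse collateral vessels are seen."
      )
    ),
    hard = list(
      ica_to_m2_extension =
        "There is an occlusion extending from the internal carotid artery to the M2 segment.",
      cavernous_reconstitution =
        "There is near-occlusion of the cavernous internal carotid artery with reconstitution of flow in the M1 segment.",
      aspect_homonym =
        "There is calcification along the lateral aspect of the cavernous carotid artery."
    ),
    impression_pos = "IMPRESSION: Acute findings as described above.",
    impression_neg = "IMPRESSION: No acute intracranial abnormality."
  )
}

pick <- function(x) if (length(x) == 1) x else sample(x, 1)

fill_side <- function(x) sub("{side}", pick(c("left", "right")), x, fixed = TRUE)

# Render one report's text from its gold labels, hard flags, and ASPECTS
# integer. Consumes RNG (template and laterality choices).
render_report_text <- function(labels, flags, aspects_value, templates = sim_templates()) {
  tp <- templates
  sent <- character(0)

  # proximal LVO: hard rewrites replace the finding sentence entirely
  if ("ica_to_m2_extension" %in% flags) {
    sent <- c(sent, tp$hard$ica_to_m2_extension)
  } else if ("cavernous_reconstitution" %in% flags) {
    sent <- c(sent, tp$hard$cavernous_reconstitution)
  } else if (labels[["lvo"]] == "present") {
    sent <- c(sent, fill_side(pick(tp$lvo)))
  } else if ("negation_decoy" %in% flags) {
    sent <- c(sent, pick(tp$lvo_neg))
  }

  if (labels[["distal_occlusion"]] == "present") {
    if (!"ica_to_m2_extension" %in% flags) {
      sent <- c(sent, fill_side(pick(tp$distal)))
    } # the ICA-to-M2 sentence already describes the distal extension
  } else if ("negation_decoy" %in% flags) {
    sent <- c(sent, pick(tp$distal_neg))
  }

  if (labels[["basilar_occlusion"]] == "present") {
    sent <- c(sent, pick(tp$basilar))
  } else if ("negation_decoy" %in% flags) {
    sent <- c(sent, pick(tp$basilar_neg))
  }

  if (labels[["ischemia"]] == "present") {
    bank <- if ("hedge_ischemia" %in% flags) tp$ischemia_hedge else tp$ischemia
    sent <- c(sent, fill_side(pick(bank)))
  } else if ("negation_decoy" %in% flags) {
    sent <- c(sent, pick(tp$ischemia_neg))
  }

  if (labels[["hemorrhage"]] == "present") {
    sent <- c(sent, fill_side(pick(tp$hemorrhage)))
  } else if ("negation_decoy" %in% flags) {
    sent <- c(sent, pick(tp$hemorrhage_neg))
  }

  if (labels[["aspects"]] != "not_reported") {
    sent <- c(sent, sub("{v}", aspects_value, pick(tp$aspects), fixed = TRUE))
  }
  if (labels[["collaterals"]] != "not_reported") {
    sent <- c(sent, pick(tp$collaterals[[labels[["collaterals"]]]]))
  }
  if ("aspect_homonym" %in% flags) {
    sent <- c(sent, tp$hard$aspect_homonym)
  }

  any_pos <- any(vapply(
    c("lvo", "distal_occlusion", "basilar_occlusion", "ischemia", "hemorrhage"),
    function(a) labels[[a]] == "present", logical(1)
  ))
  impression <- if (any_pos) tp$impression_pos else tp$impression_neg

  paste0(
    pick(tp$header), "\nFINDINGS:\n",
    paste(sent, collapse = " "),
    if (length(sent) > 0) "\n" else "",
    impression
  )
}

#' Generate a labeled synthetic report corpus
#'
#' Samples gold labels per attribute from the configured prevalences,
#' optionally applies adversarial rewrites at the configured hard-case
#' rates, and renders each report from a template bank (header, one
#' FINDINGS sentence per finding, an IMPRESSION line). Gold labels follow
#' the generator's clinical ground-truth semantics, independent of whether
#' the rule engine can recover them: the ICA-to-M2 rewrite keeps proximal
#' LVO gold-present (the engine misses it) and the cavernous-reconstitution
#' rewrite keeps it gold-absent (the engine falsely detects it), so
#' documented failure modes surface as honest errors.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `id`, `text`, one gold-label column per
#'   attribute, and a list-column `hard_flags`.
#' @examples
#' corpus <- generate_corpus(sim_config(n_reports = 5, seed = 7))
#' corpus$text[1]
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_reports
  prev <- config$prevalence
  hard <- config$hard_rates
  templates <- sim_templates()

  withr::with_seed(config$seed, {
    labels <- tibble::tibble(
      lvo = ifelse(stats::runif(n) < prev$lvo, "present", "absent"),
      distal_occlusion = ifelse(stats::runif(n) < prev$distal_occlusion, "present", "absent"),
      basilar_occlusion = ifelse(stats::runif(n) < prev$basilar_occlusion, "present", "absent"),
      ischemia = ifelse(stats::runif(n) < prev$ischemia, "present", "absent"),
      hemorrhage = ifelse(stats::runif(n) < prev$hemorrhage, "present", "absent")
    )
    asp_reported <- stats::runif(n) < prev$aspects_reported
    asp_lt5 <- stats::runif(n) < prev$p_lt5_given_reported
    labels$aspects <- ifelse(!asp_reported, "not_reported",
      ifelse(asp_lt5, "lt5", "ge5")
    )
    coll_reported <- stats::runif(n) < prev$collaterals_reported
    coll_class <- sample(names(prev$p_collaterals), n,
      replace = TRUE, prob = prev$p_collaterals
    )
    labels$collaterals <- ifelse(!coll_reported, "not_reported", coll_class)

    # hard-case flags; the two LVO rewrites are mutually exclusive
    u_lvo <- stats::runif(n)
    flag_ica <- u_lvo < hard$ica_to_m2_extension
    flag_cav <- !flag_ica &
      u_lvo < hard$ica_to_m2_extension + hard$cavernous_reconstitution
    flag_decoy <- stats::runif(n) < hard$negation_decoy
    flag_hedge <- stats::runif(n) < hard$hedge_ischemia
    flag_homonym <- stats::runif(n) < hard$aspect_homonym

    # ground-truth overrides implied by the rewrites
    labels$lvo[flag_ica] <- "present"
    labels$distal_occlusion[flag_ica] <- "present"
    labels$lvo[flag_cav] <- "absent"
    labels$ischemia[flag_hedge] <- "present"

    rows <- purrr::map(seq_len(n), function(i) {
      flags <- c(
        if (flag_ica[i]) "ica_to_m2_extension",
        if (flag_cav[i]) "cavernous_reconstitution",
        if (flag_decoy[i]) "negation_decoy",
        if (flag_hedge[i]) "hedge_ischemia",
        if (flag_homonym[i]) "aspect_homonym"
      )
      lab <- as.list(labels[i, ])
      v <- if (lab$aspects == "lt5") {
        sample(0:4, 1)
      } else if (lab$aspects == "ge5") {
        sample(5:10, 1)
      } else {
        NA_integer_
      }
      list(
        text = render_report_text(lab, flags, v, templates),
        flags = flags %||% character(0)
      )
    })

    out <- dplyr::bind_cols(
      tibble::tibble(
        id = sprintf("synth-%05d", seq_len(n)),
        text = vapply(rows, `[[`, character(1), "text")
      ),
      labels
    )
    out$hard_flags <- purrr::map(rows, "flags")
    out
  })
}

#' Rewrite one synthetic report as an adversarial hard case
#'
#' Applies one of the five adversarial rewrites to a single report row:
#' updates the gold labels per clinical ground truth (`ica_to_m2_extension`
#' forces proximal LVO and distal occlusion present;
#' `cavernous_reconstitution` forces proximal LVO absent; `hedge_ischemia`
#' forces ischemia present with hedged wording; the other tags leave labels
#' unchanged), re-renders the text, and appends the tag to `hard_flags`.
#' Template choices consume the current RNG stream; wrap in
#' [withr::with_seed()] for reproducibility.
#'
#' @param report A one-row corpus tibble (as produced by
#'   [generate_corpus()]).
#' @param case_tag One of `"negation_decoy"`, `"hedge_ischemia"`,
#'   `"ica_to_m2_extension"`, `"cavernous_reconstitution"`,
#'   `"aspect_homonym"`.
#' @return The modified one-row tibble.
#' @export
inject_hard_case <- function(report, case_tag) {
  valid <- c(
    "negation_decoy", "hedge_ischemia", "ica_to_m2_extension",
    "cavernous_reconstitution", "aspect_homonym"
  )
  if (!case_tag %in% valid) {
    stop("unknown hard-case tag '", case_tag, "'", call. = FALSE)
  }
  stopifnot(is.data.frame(report), nrow(report) == 1)
  schema <- stroke_schema()
  lab <- as.list(report[1, names(schema)])
  if (case_tag == "ica_to_m2_extension") {
    lab$lvo <- "present"
    lab$distal_occlusion <- "present"
  } else if (case_tag == "cavernous_reconstitution") {
    lab$lvo <- "absent"
  } else if (case_tag == "hedge_ischemia") {
    lab$ischemia <- "present"
  }
  flags <- unique(c(report$hard_flags[[1]] %||% character(0), case_tag))
  v <- if (lab$aspects == "lt5") {
    sample(0:4, 1)
  } else if (lab$aspects == "ge5") {
    sample(5:10, 1)
  } else {
    NA_integer_
  }
  report[1, names(schema)] <- lab
  report$text[1] <- render_report_text(lab, flags, v)
  report$hard_flags <- list(flags)
  report
}
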