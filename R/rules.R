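#' Compile a rule set
#'
#' A rule is a sentence-scoped regular expression with a signed weight that
#' raises (positive weight) or lowers (negative weight) the evidence for one
#' class of one attribute. Matching is case-insensitive unless a rule opts
#' into case sensitivity (used for the ASPECT/aspect homonym). Compilation
#' validates every rule against the schema and rejects malformed patterns and
#' duplicate rule ids.
#'
#' @param rules A data frame with columns `rule_id`, `attribute`,
#'   `target_class`, `pattern`, `weight` and optionally `case_sensitive`
#'   (default `FALSE`) and `note`; or a path to a JSON rule file (a top-level
#'   array of rule objects with those fields).
#' @param schema A [stroke_schema()].
#' @return A tibble of class `stroke_ruleset` with one row per rule and a
#'   `version` attribute.
#' @examples
#' rs <- compile_ruleset(data.frame(
#'   rule_id = "hem_pos", attribute = "hemorrhage", target_class = "present",
#'   pattern = "h(a?)emorrhage", weight = 2
#' ))
#' nrow(rs)
#' @export
compile_ruleset <- function(rules, schema = stroke_schema()) {
  if (is.character(rules) && length(rules) == 1) {
    rules <- read_rules_raw(rules)
  }
  stopifnot(is.data.frame(rules))
  required <- c("rule_id", "attribute", "target_class", "pattern", "weight")
  missing_cols <- setdiff(required, names(rules))
  if (length(missing_cols) > 0) {
    stop("rule set is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  rules <- tibble::as_tibble(rules)
  if (!"case_sensitive" %in% names(rules)) rules$case_sensitive <- FALSE
  if (!"note" %in% names(rules)) rules$note <- ""
  rules$case_sensitive[is.na(rules$case_sensitive)] <- FALSE
  rules$weight <- as.numeric(rules$weight)

  dup <- rules$rule_id[duplicated(rules$rule_id)]
  if (length(dup) > 0) {
    stop("duplicate rule_id(s): ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (is.na(r$weight) || r$weight == 0) {
      stop(sprintf("rule '%s': weight must be nonzero", r$rule_id), call. = FALSE)
    }
    if (!r$attribute %in% names(schema)) {
      stop(sprintf("rule '%s': unknown attribute '%s'", r$rule_id, r$attribute),
        call. = FALSE
      )
    }
    if (!r$target_class %in% schema[[r$attribute]]$classes) {
      stop(sprintf(
        "rule '%s': class '%s' not valid for attribute '%s'",
        r$rule_id, r$target_class, r$attribute
      ), call. = FALSE)
    }
    ok <- tryCatch(
      {
        regexpr(r$pattern, "probe text", perl = TRUE)
        TRUE
      },
      error = function(e) FALSE,
      warning = function(w) FALSE
    )
    if (!ok) {
      stop(sprintf("rule '%s': pattern does not compile: %s", r$rule_id, r$pattern),
        call. = FALSE
      )
    }
  }
  out <- rules[, c(required, "case_sensitive", "note")]
  class(out) <- c("stroke_ruleset", class(out))
  attr(out, "version") <- attr(rules, "version") %||% "custom"
  out
}

#' Match rules against sentences
#'
#' Every (rule, sentence) pair where the pattern matches contributes exactly
#' one match, anchored at the first match position; repeated occurrences of
#' the same pattern within one sentence are not double-counted, so repeated
#' phrases cannot inflate scores without bound. Rules never see text outside
#' a single sentence: evidence split across sentences is invisible, which is
#' a deliberate, documented property of sentence-scoped extraction.
#'
#' @param sentences A sentence tibble from [segment_sentences()] or
#'   [segment_corpus()] (columns `index`, `text`, optionally `id`).
#' @param ruleset A compiled [compile_ruleset()].
#' @return A tibble with columns `id` (if present in `sentences`), `rule_id`,
#'   `attribute`, `target_class`, `weight`, `sentence_index`, `match_start`,
#'   `match_end` (0-based half-open offsets within the sentence).
#' @export
match_rules <- function(sentences, ruleset) {
  stopifnot(is.data.frame(sentences), inherits(ruleset, "stroke_ruleset"))
  has_id <- "id" %in% names(sentences)
  empty <- tibble::tibble(
    id = character(), rule_id = character(), attribute = character(),
    target_class = character(), weight = numeric(),
    sentence_index = integer(), match_start = integer(), match_end = integer()
  )
  if (!has_id) empty$id <- NULL
  if (nrow(sentences) == 0 || nrow(ruleset) == 0) {
    return(empty)
  }
  out <- purrr::pmap_dfr(
    ruleset[, c("rule_id", "attribute", "target_class", "weight", "case_sensitive")],
    function(rule_id, attribute, target_class, weight, case_sensitive) {
      m <- regexpr(ruleset$pattern[ruleset$rule_id == rule_id], sentences$text,
        perl = TRUE, ignore.case = !case_sensitive
      )
      hit <- which(m != -1L)
      if (length(hit) == 0) {
        return(NULL)
      }
      res <- tibble::tibble(
        rule_id = rule_id, attribute = attribute,
        target_class = target_class, weight = weight,
        sentence_index = sentences$index[hit],
        match_start = as.integer(m[hit]) - 1L,
        match_end = as.integer(m[hit]) - 1L + attr(m, "match.length")[hit]
      )
      if (has_id) res <- dplyr::bind_cols(tibble::tibble(id = sentences$id[hit]), res)
      res
    }
  )
  if (nrow(out) == 0) {
    return(empty)
  }
  ord <- if (has_id) order(out$id, out$sentence_index) else order(out$sentence_index)
  out[ord, ]
}

#' Aggregate matched rules into per-class scores
#'
#' The raw score of class `c` is the sum of signed weights of all matches
#' targeting `c`. For binary attributes the score of the `present` class is
#' mapped through the standard logistic to a probability,
#' `p = 1 / (1 + exp(-s))`, so positive evidence raises and negative evidence
#' lowers the estimate; no matches give `s = 0` and `p = 0.5`.
#'
#' @param matches Matches for one report from [match_rules()].
#' @param attribute Attribute name.
#' @param schema A [stroke_schema()].
#' @return A list of class `score_bundle` with elements `attribute`, `scores`
#'   (named numeric, one per class), `probability` (binary attributes only,
#'   otherwise `NA`) and `matches`.
#' @examples
#' sent <- segment_sentences("No evidence of intracranial hemorrhage.")
#' m <- match_rules(sent, default_rules())
#' score_attribute(m, "hemorrhage")
#' @export
score_attribute <- function(matches, attribute, schema = stroke_schema()) {
  stopifnot(attribute %in% names(schema))
  attr_schema <- schema[[attribute]]
  scores <- stats::setNames(numeric(length(attr_schema$classes)), attr_schema$classes)
  rel <- matches[matches$attribute == attribute, , drop = FALSE]
  if (nrow(rel) > 0) {
    agg <- tapply(rel$weight, rel$target_class, sum)
    scores[names(agg)] <- agg
  }
  p <- if (attr_schema$kind == "binary") stats::plogis(scores[["present"]]) else NA_real_
  structure(
    list(attribute = attribute, scores = scores, probability = p, matches = rel),
    class = "score_bundle"
  )
}

#' @export
print.score_bundle <- function(x, ...) {
  cat("<score_bundle> ", x$attribute, "\n", sep = "")
  cat("  scores:", paste(names(x$scores), round(x$scores, 3), sep = "=", collapse = " "), "\n")
  if (!is.na(x$probability)) cat("  probability:", round(x$probability, 4), "\n")
  cat("  matches:", nrow(x$matches), "\n")
  invisible(x)
}

#' Classify an attribute from its score bundle
#'
#' Binary attributes are `present` iff the `present` score is strictly
#' positive, so a report with no evidence (score 0) defaults to `absent`.
#' Categorical attributes pick the positive-scoring class with the highest
#' score, breaking ties by the schema's worst-first priority; with no
#' positive score the schema default (`not_reported`) wins.
#'
#' @param bundle A [score_attribute()] result, or a named numeric vector of
#'   per-class scores.
#' @param attr_schema One attribute's schema entry, e.g.
#'   `stroke_schema()$collaterals`.
#' @return A single class label.
#' @export
classify_score <- function(bundle, attr_schema) {
  scores <- if (inherits(bundle, "score_bundle")) bundle$scores else bundle
  stopifnot(all(names(scores) %in% attr_schema$classes))
  if (attr_schema$kind == "binary") {
    return(if (scores[["present"]] > 0) "present" else "absent")
  }
  pos <- scores[scores > 0]
  if (length(pos) == 0) {
    return(attr_schema$default_class)
  }
  top <- names(pos)[pos == max(pos)]
  # worst-first priority breaks ties
  attr_schema$priority[attr_schema$priority %in% top][1]
}

# Band an ASPECTS integer (0-10) into the 3-class variable.
band_aspects <- function(value) {
  if (is.na(value)) {
    return("not_reported")
  }
  if (value < 5) "lt5" else "ge5"
}

#' Extract the ASPECTS band from sentences
#'
#' Searches for an ASPECTS mention carrying an integer 0-10. A mention
#' requires either the exact capitalized token `ASPECTS`/`ASPECT`
#' (case-sensitive, so the anatomical homonym "the lateral aspect of ..."
#' never qualifies) or the phrase "aspect score" (case-insensitive). The
#' first valid mention in document order wins; integers outside 0-10 are
#' ignored. The raw integer is returned alongside the band and kept in the
#' prediction trace only -- classification uses the banded variable.
#'
#' @param sentences A sentence tibble for one report.
#' @param ruleset Rule set supplying the mention patterns: rules with
#'   `attribute == "aspects"` and positive weight, each pattern containing
#'   one capture group for the integer.
#' @return A list with `class` (`"not_reported"`, `"lt5"` or `"ge5"`) and
#'   `value` (integer or `NA`).
#' @examples
#' extract_aspects(segment_sentences("ASPECTS is 8."))
#' extract_aspects(segment_sentences("Calcification along the lateral aspect of the vessel."))
#' @export
extract_aspects <- function(sentences, ruleset = default_rules()) {
  none <- list(class = "not_reported", value = NA_integer_)
  if (nrow(sentences) == 0) {
    return(none)
  }
  rules <- ruleset[ruleset$attribute == "aspects" & ruleset$weight > 0, , drop = FALSE]
  if (nrow(rules) == 0) {
    return(none)
  }
  for (i in seq_len(nrow(sentences))) {
    txt <- sentences$text[i]
    mentions <- list()
    for (j in seq_len(nrow(rules))) {
      g <- gregexpr(rules$pattern[j], txt,
        perl = TRUE,
        ignore.case = !rules$case_sensitive[j]
      )[[1]]
      if (g[1] == -1L) next
      cs <- attr(g, "capture.start")
      cl <- attr(g, "capture.length")
      for (k in seq_along(g)) {
        val <- suppressWarnings(as.integer(substr(txt, cs[k, 1], cs[k, 1] + cl[k, 1] - 1)))
        mentions[[length(mentions) + 1]] <- list(pos = as.integer(g[k]), value = val)
      }
    }
    if (length(mentions) == 0) next
    mentions <- mentions[order(vapply(mentions, `[[`, integer(1), "pos"))]
    for (m in mentions) {
      if (!is.na(m$value) && m$value >= 0 && m$value <= 10) {
        return(list(class = band_aspects(m$value), value = m$value))
      }
    }
  }
  none
}

#' Predict all stroke attributes for a corpus of reports
#'
#' Runs the full sentence-level pipeline on each report: sentence
#' segmentation, rule matching, signed-weight aggregation and
#' classification for the five binary attributes and collateral status, and
#' value-banded extraction for ASPECTS. Deterministic: identical text and
#' rules always give identical predictions.
#'
#' @param corpus A tibble with columns `id` (unique) and `text`.
#' @param ruleset A compiled rule set, default [default_rules()].
#' @param schema A [stroke_schema()].
#' @param abbreviations Sentence-segmentation abbreviation list.
#' @return A tibble with one row per report (input order): `id`, one column
#'   per attribute holding the predicted class, `aspects_value` (raw integer
#'   or `NA`), and list-columns `scores` (per-attribute named score vectors)
#'   and `trace` (the matched-rule table for the report).
#' @examples
#' corpus <- tibble::tibble(id = "r1", text = "Occlusion of the left M1 segment.")
#' predict_corpus(corpus)$lvo
#' @export
predict_corpus <- function(corpus, ruleset = default_rules(),
                           schema = stroke_schema(),
                           abbreviations = default_abbreviations()) {
  stopifnot(is.data.frame(corpus), all(c("id", "text") %in% names(corpus)))
  if (anyDuplicated(corpus$id)) {
    stop("corpus contains duplicate report id(s): ",
      paste(unique(corpus$id[duplicated(corpus$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  ids <- as.character(corpus$id)
  sentences <- segment_corpus(corpus, abbreviations)
  matches <- match_rules(sentences, ruleset)

  score_attrs <- setdiff(names(schema), "aspects")
  # aggregate signed weights per report x attribute x class
  agg <- if (nrow(matches) > 0) {
    dplyr::summarise(
      dplyr::group_by(
        matches[matches$attribute != "aspects", , drop = FALSE],
        .data$id, .data$attribute, .data$target_class
      ),
      score = sum(.data$weight), .groups = "drop"
    )
  } else {
    tibble::tibble(
      id = character(), attribute = character(),
      target_class = character(), score = numeric()
    )
  }

  agg_by_id <- split(agg, factor(agg$id, levels = ids))
  match_by_id <- if (nrow(matches) > 0) {
    split(matches, factor(matches$id, levels = ids))
  } else {
    rep(list(matches), length(ids))
  }

  # ASPECTS: only sentences that mention the token can carry a score
  asp_sent <- sentences[grepl("aspect", sentences$text, ignore.case = TRUE), , drop = FALSE]
  asp_by_id <- split(asp_sent, factor(asp_sent$id, levels = ids))

  rows <- purrr::map(seq_along(ids), function(i) {
    a <- agg_by_id[[i]]
    scores <- purrr::map(score_attrs, function(at) {
      s <- stats::setNames(numeric(length(schema[[at]]$classes)), schema[[at]]$classes)
      rel <- a[a$attribute == at, , drop = FALSE]
      if (nrow(rel) > 0) s[rel$target_class] <- rel$score
      s
    })
    names(scores) <- score_attrs
    pred <- vapply(score_attrs, function(at) {
      classify_score(scores[[at]], schema[[at]])
    }, character(1))
    asp <- extract_aspects(asp_by_id[[i]], ruleset)
    list(pred = pred, scores = scores, aspects = asp)
  })

  out <- tibble::tibble(id = ids)
  for (at in score_attrs) {
    out[[at]] <- vapply(rows, function(r) r$pred[[at]], character(1))
  }
  out$aspects <- vapply(rows, function(r) r$aspects$class, character(1))
  out$aspects_value <- vapply(rows, function(r) as.integer(r$aspects$value), integer(1))
  out <- out[, c("id", names(schema), "aspects_value")]
  out$scores <- purrr::map(rows, "scores")
  out$trace <- match_by_id
  out
}

#' @rdname predict_corpus
#' @param report A one-row data frame (or named list) with `id` and `text`.
#' @export
predict_report <- function(report, ruleset = default_rules(),
                           schema = stroke_schema(),
                           abbreviations = default_abbreviations()) {
  if (!is.data.frame(report)) {
    report <- tibble::tibble(id = report$id %||% "report", text = report$text)
  }
  stopifnot(nrow(report) == 1)
  predict_corpus(report, ruleset, schema, abbreviations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
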