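# JSON-lines corpus format: one object per report,
# {"id", "text", "labels"?, "hard_flags"?}, UTF-8.

#' Read / write a report corpus (JSON-lines)
#'
#' One JSON object per line with fields `id`, `text`, optional `labels`
#' (attribute -> class; binary classes may be encoded as 1/0 or true/false
#' and are normalized on read) and optional `hard_flags`. Reports without a
#' `labels` object get `NA` in every label column.
#'
#' @param path File path.
#' @param schema A [stroke_schema()].
#' @return A corpus tibble (`id`, `text`, label columns, `hard_flags`).
#' @export
read_corpus <- function(path, schema = stroke_schema()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  ids <- vapply(recs, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) {
    stop("corpus contains duplicate report id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    id = ids,
    text = vapply(recs, function(r) as.character(r$text), character(1))
  )
  labs <- purrr::map(recs, function(r) {
    if (is.null(r$labels)) {
      return(NULL)
    }
    validate_labels(r$labels, schema)
  })
  for (at in names(schema)) {
    out[[at]] <- vapply(labs, function(l) {
      if (is.null(l)) NA_character_ else l[[at]]
    }, character(1))
  }
  out$hard_flags <- purrr::map(recs, function(r) {
    as.character(r$hard_flags %||% character(0))
  })
  out
}

#' @rdname read_corpus
#' @param corpus A corpus tibble.
#' @export
write_corpus <- function(corpus, path, schema = stroke_schema()) {
  label_cols <- intersect(names(schema), names(corpus))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(id = corpus$id[i], text = corpus$text[i])
    if (length(label_cols) > 0 && !any(is.na(unlist(corpus[i, label_cols])))) {
      rec$labels <- as.list(corpus[i, label_cols])
    }
    flags <- corpus$hard_flags[[i]] %||% character(0)
    if (!is.null(corpus$hard_flags) && length(flags) > 0) {
      rec$hard_flags <- flags
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a rule file (JSON)
#'
#' A rule file is a top-level JSON array of rule objects with fields
#' `rule_id`, `attribute`, `target_class`, `pattern`, `weight`, and optional
#' `case_sensitive` and `note`. Reading compiles and validates the rules.
#'
#' @param path File path.
#' @param schema A [stroke_schema()].
#' @return A compiled `stroke_ruleset`.
#' @export
read_rules <- function(path, schema = stroke_schema()) {
  compile_ruleset(read_rules_raw(path), schema)
}

read_rules_raw <- function(path) {
  if (!file.exists(path)) {
    stop("rule file not found: ", path, call. = FALSE)
  }
  df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tibble::as_tibble(df)
}

#' @rdname read_rules
#' @param ruleset A `stroke_ruleset`.
#' @export
write_rules <- function(ruleset, path) {
  df <- as.data.frame(ruleset)
  jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write predictions (JSON-lines)
#'
#' One object per report: `{"id", "pred": {attribute: class}, "scores":
#' {attribute: {class: score}}, "aspects_value"?}`.
#'
#' @param predictions Output of [predict_corpus()].
#' @param path File path.
#' @export
write_predictions <- function(predictions, path, schema = stroke_schema()) {
  attrs <- names(schema)
  lines <- vapply(seq_len(nrow(predictions)), function(i) {
    rec <- list(
      id = predictions$id[i],
      pred = as.list(predictions[i, attrs]),
      scores = purrr::map(predictions$scores[[i]], as.list)
    )
    if (!is.na(predictions$aspects_value[i])) {
      rec$aspects_value <- predictions$aspects_value[i]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path, schema = stroke_schema()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  out <- tibble::tibble(id = vapply(recs, function(r) as.character(r$id), character(1)))
  for (at in names(schema)) {
    out[[at]] <- vapply(recs, function(r) as.character(r$pred[[at]]), character(1))
  }
  out$aspects_value <- vapply(recs, function(r) {
    as.integer(r$aspects_value %||% NA_integer_)
  }, integer(1))
  out$scores <- purrr::map(recs, function(r) purrr::map(r$scores, unlist))
  out
}

#' Write a metrics table as CSV
#'
#' Columns `cohort, attribute, class, prevalence_n, prevalence_pct,
#' sensitivity, specificity, ppv, npv, accuracy`, with percentages rounded
#' to one decimal (half away from zero) and undefined metrics as `NA`.
#'
#' @param eval_or_metrics A `stroke_eval` object or its metrics tibble.
#' @param path File path.
#' @export
write_metrics_csv <- function(eval_or_metrics, path) {
  metrics <- if (inherits(eval_or_metrics, "stroke_eval")) {
    eval_or_metrics$metrics
  } else {
    eval_or_metrics
  }
  readr::write_csv(format_metrics(metrics), path, na = "NA")
  invisible(path)
}

#' Write discrepancy records (JSON-lines)
#'
#' One object per gold-vs-predicted mismatch, with the matched-rule ids in
#' the trace so the offending pattern is visible during review.
#'
#' @param discrepancies Output of [discrepancy_report()].
#' @param path File path.
#' @export
write_discrepancies <- function(discrepancies, path) {
  lines <- vapply(seq_len(nrow(discrepancies)), function(i) {
    tr <- discrepancies$trace[[i]]
    jsonlite::toJSON(
      list(
        report_id = discrepancies$report_id[i],
        attribute = discrepancies$attribute[i],
        gold = discrepancies$gold[i],
        predicted = discrepancies$predicted[i],
        resolution = discrepancies$resolution[i],
        matched_rules = if (nrow(tr) > 0) tr$rule_id else character(0)
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
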