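#' 2x2 confusion counts
#'
#' @param gold,pred Equal-length vectors of class labels.
#' @param positive_class The class treated as positive.
#' @return A one-row tibble of class `confusion_matrix` with integer columns
#'   `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(c("present", "present", "absent", "absent"),
#'           c("present", "absent", "absent", "present"), "present")
#' @export
confusion <- function(gold, pred, positive_class = "present") {
  if (length(gold) != length(pred)) {
    stop("gold and pred have different lengths (", length(gold), " vs ",
      length(pred), ")",
      call. = FALSE
    )
  }
  gp <- gold == positive_class
  pp <- pred == positive_class
  out <- tibble::tibble(
    tp = sum(gp & pp), fp = sum(!gp & pp),
    tn = sum(!gp & !pp), fn = sum(gp & !pp)
  )
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(tn+fp)`, positive
#' predictive value `100*tp/(tp+fp)`, negative predictive value
#' `100*tn/(tn+fn)` and overall accuracy `100*(tp+tn)/n`, all on the 0-100
#' scale and unrounded. A zero denominator yields `NA` (rendered as `NA` in
#' outputs, never coerced to 0 or 100, which would distort small-cell
#' attributes such as basilar occlusion). Rounding to one decimal happens
#' only at presentation time, via [format_metrics()].
#'
#' @param cm A [confusion()] result (or any one-row data frame with columns
#'   `tp`, `fp`, `tn`, `fn`).
#' @return A one-row tibble: the four counts plus `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
binary_metrics <- function(cm) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(cm)), nrow(cm) == 1)
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) {
    stop("empty evaluation: confusion matrix has no observations", call. = FALSE)
  }
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
    sensitivity = rate(cm$tp, cm$tp + cm$fn),
    specificity = rate(cm$tn, cm$tn + cm$fp),
    ppv = rate(cm$tp, cm$tp + cm$fp),
    npv = rate(cm$tn, cm$tn + cm$fn),
    accuracy = 100 * (cm$tp + cm$tn) / n
  )
}

#' One-vs-rest metrics for a categorical attribute
#'
#' Each class is scored against the rest with [binary_metrics()]; the
#' overall multiclass accuracy is the percentage of exact class matches.
#'
#' @param gold,pred Equal-length class vectors.
#' @param classes Class labels to report (default: all observed).
#' @return A tibble with one row per class (column `class` first) plus an
#'   `overall_accuracy` attribute.
#' @export
categorical_metrics <- function(gold, pred, classes = NULL) {
  if (length(gold) != length(pred)) {
    stop("gold and pred have different lengths", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(gold, pred)))
  rows <- purrr::map_dfr(classes, function(cl) {
    dplyr::bind_cols(
      tibble::tibble(class = cl),
      binary_metrics(confusion(gold, pred, cl))
    )
  })
  attr(rows, "overall_accuracy") <- 100 * mean(gold == pred)
  rows
}

#' Prevalence count and percent
#'
#' @param labels Vector of class labels.
#' @param positive_class Class counted as positive.
#' @return A one-row tibble with `count` and `percent` (rounded to one
#'   decimal, half away from zero, matching tabular reporting style).
#' @examples
#' prevalence(rep(c("present", "absent"), c(161, 1159)))
#' @export
prevalence <- function(labels, positive_class = "present") {
  n <- length(labels)
  if (n == 0) {
    stop("prevalence of an empty label vector is undefined", call. = FALSE)
  }
  count <- sum(labels == positive_class)
  tibble::tibble(count = count, percent = round_half_away(100 * count / n, 1))
}

#' Percent agreement between two label vectors
#'
#' The inter-rater reliability statistic used for duplicate chart
#' abstraction: the percentage of positions with identical class labels.
#' Symmetric in its arguments.
#'
#' @param labels_a,labels_b Equal-length class vectors.
#' @return A single percentage in \[0, 100\].
#' @export
percent_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors have different lengths", call. = FALSE)
  }
  if (length(labels_a) == 0) {
    stop("agreement on zero items is undefined", call. = FALSE)
  }
  100 * mean(labels_a == labels_b)
}

# round half away from zero, the convention used in the metric tables;
# a relative epsilon guards against 0.05 stored as 0.049999...
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5 + 1e-9) / m
}

#' Seeded train/validation split
#'
#' Partitions a corpus into disjoint, exhaustive train and validation sets
#' with `round(train_fraction * n)` reports in the training set. The split
#' is deterministic given the seed and is intended to be materialized (see
#' the `split` command of the pipeline script) so cohort membership is
#' auditable.
#'
#' @param corpus A tibble with an `id` column.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return A named list of two tibbles, `train` and `validation`.
#' @examples
#' corpus <- tibble::tibble(id = as.character(1:10), text = "")
#' lengths(lapply(split_corpus(corpus, 0.7, 1), nrow))
#' @export
split_corpus <- function(corpus, train_fraction, seed) {
  stopifnot(is.data.frame(corpus), "id" %in% names(corpus))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(corpus)
  n_train <- round(train_fraction * n)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_train))
  list(
    train = corpus[sort(idx), , drop = FALSE],
    validation = corpus[setdiff(seq_len(n), sort(idx)), , drop = FALSE]
  )
}

#' Gold-vs-predicted discrepancy report
#'
#' One record per (report, attribute) pair where the predicted class differs
#' from the gold label, carrying the matched-rule trace for that attribute
#' so a reviewer can see exactly which pattern fired (or failed to fire).
#' This is the artifact driving iterative rule refinement; the resolution
#' tag starts as `"unresolved"` and is meant to be adjudicated by a human as
#' `"abstractor_error"` or `"tool_error"`.
#'
#' @param corpus A labeled corpus (gold label columns per attribute).
#' @param predictions Output of [predict_corpus()] for the same reports.
#' @param schema A [stroke_schema()].
#' @return A tibble with columns `report_id`, `attribute`, `gold`,
#'   `predicted`, `resolution`, and list-column `trace` (matched rules for
#'   that attribute in that report).
#' @export
discrepancy_report <- function(corpus, predictions, schema = stroke_schema()) {
  stopifnot(all(corpus$id %in% predictions$id))
  pred_idx <- match(corpus$id, predictions$id)
  out <- purrr::map_dfr(names(schema), function(at) {
    if (!at %in% names(corpus)) {
      stop("corpus carries no gold labels for attribute '", at, "'", call. = FALSE)
    }
    gold <- corpus[[at]]
    pred <- predictions[[at]][pred_idx]
    bad <- which(!is.na(gold) & gold != pred)
    if (length(bad) == 0) {
      return(NULL)
    }
    tibble::tibble(
      report_id = corpus$id[bad],
      attribute = at,
      gold = gold[bad],
      predicted = pred[bad],
      resolution = "unresolved",
      trace = purrr::map(pred_idx[bad], function(i) {
        tr <- predictions$trace[[i]]
        tr[tr$attribute == at, , drop = FALSE]
      })
    )
  })
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(
      report_id = character(), attribute = character(), gold = character(),
      predicted = character(), resolution = character(), trace = list()
    ))
  }
  out[order(match(out$report_id, corpus$id), match(out$attribute, names(schema))), ]
}

#' Evaluate predictions against gold labels
#'
#' Builds the full validation report: per-attribute prevalence and
#' sensitivity/specificity/PPV/NPV/accuracy for the five binary attributes,
#' one-vs-rest rows per class plus overall multiclass accuracy for ASPECTS
#' and collateral status, and the discrepancy table.
#'
#' @param corpus Labeled corpus tibble (gold columns per attribute).
#' @param predictions Output of [predict_corpus()] for the same reports.
#' @param schema A [stroke_schema()].
#' @param cohort Optional cohort name recorded in the metrics table (e.g.
#'   `"derivation"` / `"validation"`).
#' @return An object of class `stroke_eval`: a list with `metrics`
#'   (unrounded tibble with columns `cohort`, `attribute`, `class`,
#'   `prevalence_n`, `prevalence_pct`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`), `discrepancies`, `n`, and `cohort`. Categorical
#'   attributes contribute one row per class plus an `overall` row carrying
#'   the multiclass accuracy. Use [generics::tidy()], [generics::glance()]
#'   or [ggplot2::autoplot()] on the result.
#' @examples
#' corpus <- generate_corpus(sim_config(n_reports = 50, seed = 1))
#' ev <- evaluate_predictions(corpus, predict_corpus(corpus))
#' tidy(ev)
#' @export
evaluate_predictions <- function(corpus, predictions, schema = stroke_schema(),
                                 cohort = "all") {
  missing_lab <- setdiff(names(schema), names(corpus))
  if (length(missing_lab) > 0) {
    stop("corpus has no gold labels for: ", paste(missing_lab, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(corpus$id %in% predictions$id)) {
    stop("predictions are missing some corpus ids", call. = FALSE)
  }
  pred_idx <- match(corpus$id, predictions$id)
  n <- nrow(corpus)

  rows <- purrr::map_dfr(names(schema), function(at) {
    gold <- corpus[[at]]
    pred <- predictions[[at]][pred_idx]
    if (schema[[at]]$kind == "binary") {
      prev <- prevalence(gold, "present")
      met <- binary_metrics(confusion(gold, pred, "present"))
      tibble::tibble(
        cohort = cohort, attribute = at, class = "present",
        prevalence_n = prev$count, prevalence_pct = prev$percent,
        sensitivity = met$sensitivity, specificity = met$specificity,
        ppv = met$ppv, npv = met$npv, accuracy = met$accuracy
      )
    } else {
      cm <- categorical_metrics(gold, pred, schema[[at]]$classes)
      per_class <- purrr::map_dfr(seq_len(nrow(cm)), function(i) {
        prev <- prevalence(gold, cm$class[i])
        tibble::tibble(
          cohort = cohort, attribute = at, class = cm$class[i],
          prevalence_n = prev$count, prevalence_pct = prev$percent,
          sensitivity = cm$sensitivity[i], specificity = cm$specificity[i],
          ppv = cm$ppv[i], npv = cm$npv[i], accuracy = NA_real_
        )
      })
      dplyr::bind_rows(per_class, tibble::tibble(
        cohort = cohort, attribute = at, class = "overall",
        prevalence_n = n, prevalence_pct = 100,
        sensitivity = NA_real_, specificity = NA_real_,
        ppv = NA_real_, npv = NA_real_,
        accuracy = attr(cm, "overall_accuracy")
      ))
    }
  })

  structure(
    list(
      metrics = rows,
      discrepancies = discrepancy_report(corpus, predictions, schema),
      n = n,
      cohort = cohort
    ),
    class = "stroke_eval"
  )
}

#' @export
print.stroke_eval <- function(x, ...) {
  cat(
    "<stroke_eval> cohort:", x$cohort, " n =", x$n,
    " discrepancies =", nrow(x$discrepancies), "\n"
  )
  print(format_metrics(x$metrics))
  invisible(x)
}

#' Round a metrics table for presentation
#'
#' Applies the table convention (one decimal, half away from zero) to the
#' percentage columns. Undefined metrics stay `NA`.
#'
#' @param metrics The `metrics` tibble of a `stroke_eval`.
#' @return The tibble with rounded percentage columns.
#' @export
format_metrics <- function(metrics) {
  pct_cols <- intersect(
    c("prevalence_pct", "sensitivity", "specificity", "ppv", "npv", "accuracy"),
    names(metrics)
  )
  for (cl in pct_cols) {
    metrics[[cl]] <- ifelse(is.na(metrics[[cl]]), NA_real_,
      round_half_away(metrics[[cl]], 1)
    )
  }
  metrics
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stroke evaluation
#'
#' @param x A `stroke_eval` object.
#' @param ... Unused.
#' @return The unrounded metrics tibble.
#' @export
tidy.stroke_eval <- function(x, ...) {
  x$metrics
}

#' One-row summary of a stroke evaluation
#'
#' @param x A `stroke_eval` object.
#' @param ... Unused.
#' @return A one-row tibble: `cohort`, `n`, number of attributes, number of
#'   discrepancies, and mean binary accuracy.
#' @export
glance.stroke_eval <- function(x, ...) {
  bin <- x$metrics[x$metrics$class == "present", ]
  tibble::tibble(
    cohort = x$cohort,
    n = x$n,
    n_attributes = length(unique(x$metrics$attribute)),
    n_discrepancies = nrow(x$discrepancies),
    mean_binary_accuracy = mean(bin$accuracy, na.rm = TRUE)
  )
}
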