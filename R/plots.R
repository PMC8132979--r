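#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stroke evaluation
#'
#' Dot plot of sensitivity, specificity, PPV and NPV per attribute (and per
#' class for the categorical attributes), the visual analogue of the
#' accuracy tables. Undefined (NA) metrics are dropped from the panel.
#'
#' @param object A `stroke_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stroke_eval <- function(object, ...) {
  m <- object$metrics[object$metrics$class != "overall", ]
  m$label <- ifelse(m$class == "present", m$attribute,
    paste0(m$attribute, ": ", m$class)
  )
  long <- tidyr::pivot_longer(
    m[, c("label", "sensitivity", "specificity", "ppv", "npv")],
    -"label",
    names_to = "metric", values_to = "value"
  )
  long <- long[!is.na(long$value), ]
  long$metric <- factor(long$metric, c("sensitivity", "specificity", "ppv", "npv"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$label)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), nrow = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 100)) +
    ggplot2::labs(
      x = "percent", y = NULL,
      title = paste0("Extraction accuracy (", object$cohort, ", n = ", object$n, ")")
    ) +
    ggplot2::theme_bw()
}

#' Plot attribute prevalences of a labeled corpus
#'
#' Bar chart of the percentage of reports positive (binary attributes) or
#' reported (categorical attributes) in a corpus, useful for eyeballing a
#' synthetic corpus against its configured prevalences.
#'
#' @param corpus A labeled corpus tibble.
#' @param schema A [stroke_schema()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(corpus, schema = stroke_schema()) {
  rows <- purrr::map_dfr(names(schema), function(at) {
    positive <- if (schema[[at]]$kind == "binary") {
      corpus[[at]] == "present"
    } else {
      corpus[[at]] != "not_reported"
    }
    tibble::tibble(
      attribute = at,
      percent = 100 * mean(positive),
      kind = schema[[at]]$kind
    )
  })
  ggplot2::ggplot(rows, ggplot2::aes(
    x = .data$percent,
    y = stats::reorder(.data$attribute, .data$percent),
    fill = .data$kind
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "% of reports positive / reported", y = NULL,
      title = paste0("Attribute prevalence (n = ", nrow(corpus), ")")
    ) +
    ggplot2::theme_bw()
}
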