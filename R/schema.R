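#' Attribute schema for stroke report abstraction
#'
#' Defines the seven stroke-related attributes abstracted from head/neck
#' CT/CTA/CTP reports: five binary attributes (proximal large vessel
#' occlusion, distal anterior circulation occlusion, basilar occlusion,
#' established ischemia, intracranial hemorrhage) and two categorical ones
#' (ASPECTS band, collateral status). Binary attributes take classes
#' `present`/`absent` with default `absent`; categorical attributes carry a
#' `not_reported` default because most reports do not state them.
#'
#' Proximal large vessel occlusion (`lvo`) means occlusion of the MCA-M1 or
#' ACA-A1 segment, with or without carotid terminus involvement; isolated
#' intracranial ICA occlusion does not count. Distal occlusion means M2/A2
#' segments or beyond. ASPECTS is banded as `lt5` / `ge5` / `not_reported`;
#' the raw 0-10 integer is kept in the prediction trace only.
#'
#' Categorical tie-break priorities are worst-first (`poor` before
#' `intermediate` before `good`; `lt5` before `ge5`), a clinically
#' conservative choice.
#'
#' @return An object of class `stroke_schema`: a named list with one element
#'   per attribute, each a list with fields `name`, `kind` (`"binary"` or
#'   `"categorical"`), `classes`, `default_class` and `priority`.
#' @examples
#' sch <- stroke_schema()
#' names(sch)
#' sch$aspects$classes
#' @export
stroke_schema <- function() {
  binary <- function(name) {
    list(
      name = name, kind = "binary",
      classes = c("present", "absent"),
      default_class = "absent",
      priority = c("present", "absent")
    )
  }
  categorical <- function(name, classes, priority) {
    list(
      name = name, kind = "categorical",
      classes = classes,
      default_class = "not_reported",
      priority = priority
    )
  }
  out <- list(
    lvo = binary("lvo"),
    distal_occlusion = binary("distal_occlusion"),
    basilar_occlusion = binary("basilar_occlusion"),
    ischemia = binary("ischemia"),
    hemorrhage = binary("hemorrhage"),
    aspects = categorical(
      "aspects",
      classes = c("not_reported", "lt5", "ge5"),
      priority = c("lt5", "ge5", "not_reported")
    ),
    collaterals = categorical(
      "collaterals",
      classes = c("not_reported", "poor", "intermediate", "good"),
      priority = c("poor", "intermediate", "good", "not_reported")
    )
  )
  structure(out, class = "stroke_schema")
}

#' @export
print.stroke_schema <- function(x, ...) {
  cat("<stroke_schema> ", length(x), " attributes\n", sep = "")
  for (a in x) {
    cat(sprintf(
      "  %-17s %-11s classes: %s (default %s)\n",
      a$name, a$kind, paste(a$classes, collapse = "/"), a$default_class
    ))
  }
  invisible(x)
}

#' Names of the binary / categorical attributes
#'
#' @param schema A [stroke_schema()].
#' @return Character vector of attribute names.
#' @export
binary_attributes <- function(schema = stroke_schema()) {
  names(schema)[vapply(schema, function(a) a$kind == "binary", logical(1))]
}

#' @rdname binary_attributes
#' @export
categorical_attributes <- function(schema = stroke_schema()) {
  names(schema)[vapply(schema, function(a) a$kind == "categorical", logical(1))]
}

#' Validate and complete a label mapping
#'
#' Fills in schema defaults for attributes missing from `labels` (binary ->
#' `absent`, categorical -> `not_reported`), normalizes common binary
#' encodings (`1`/`0`, `TRUE`/`FALSE`, `yes`/`no` -> `present`/`absent`) and
#' rejects unknown attributes or classes. Idempotent: validating a validated
#' mapping returns it unchanged.
#'
#' @param labels Named list or named character vector, attribute -> class.
#' @param schema A [stroke_schema()].
#' @return Named character vector with one entry per schema attribute, in
#'   schema order.
#' @examples
#' validate_labels(list(lvo = "present"))
#' validate_labels(list(aspects = "lt5", hemorrhage = 1))
#' @export
validate_labels <- function(labels = list(), schema = stroke_schema()) {
  labels <- as.list(labels)
  unknown <- setdiff(names(labels), names(schema))
  if (length(unknown) > 0) {
    stop("unknown attribute(s) in labels: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  out <- vapply(schema, function(a) a$default_class, character(1))
  for (nm in names(labels)) {
    val <- normalize_class(labels[[nm]], schema[[nm]])
    if (!val %in% schema[[nm]]$classes) {
      stop(sprintf(
        "invalid class '%s' for attribute '%s' (allowed: %s)",
        val, nm, paste(schema[[nm]]$classes, collapse = ", ")
      ), call. = FALSE)
    }
    out[[nm]] <- val
  }
  out
}

# Gold files in the wild encode binary attributes as 1/0 or true/false; the
# reader normalizes them to present/absent. Categorical classes pass through.
normalize_class <- function(value, attr_schema) {
  if (length(value) != 1 || is.na(value)) {
    stop("labels must be single non-missing values", call. = FALSE)
  }
  if (attr_schema$kind == "binary") {
    v <- tolower(as.character(value))
    if (v %in% c("1", "true", "yes", "present")) {
      return("present")
    }
    if (v %in% c("0", "false", "no", "absent")) {
      return("absent")
    }
    return(as.character(value))
  }
  as.character(value)
}
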