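#' Default protected abbreviations for sentence segmentation
#'
#' Periods following these tokens never end a sentence. The list is
#' configuration, not code: radiology dialects differ, and pipelines can pass
#' their own list to [segment_sentences()].
#'
#' @return Character vector of abbreviations (without the trailing period).
#' @export
default_abbreviations <- function() {
  c("Dr", "Drs", "Mr", "Mrs", "Ms", "vs", "e.g", "i.e", "approx", "No", "cf")
}

#' Split report text into sentences with character spans
#'
#' Every extraction rule is applied within a single sentence, so segmentation
#' defines the scope of all downstream matching. Boundaries are:
#' \itemize{
#'   \item newlines (hard boundaries; radiology reports put section headers
#'     such as `FINDINGS:` on their own lines), and
#'   \item runs of sentence-final punctuation (`.`, `!`, `?`) followed by
#'     whitespace and an uppercase letter or digit.
#' }
#' A period inside a decimal number (`1.5 cm`) or after a protected
#' abbreviation does not split. Offsets are 0-based half-open into the
#' original text, so `substr(text, start + 1, end)` recovers each sentence
#' verbatim.
#'
#' @param text A single string (possibly empty).
#' @param abbreviations Character vector of protected abbreviations.
#' @return A tibble with columns `index` (0-based sentence index), `text`,
#'   `start`, `end`. Empty or whitespace-only input gives zero rows.
#' @examples
#' segment_sentences("No acute hemorrhage. ASPECTS is 8.")
#' segment_sentences("A 1.5 cm hypodensity is seen.")
#' @export
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- tibble::tibble(
    index = integer(), text = character(),
    start = integer(), end = integer()
  )
  if (is.na(text) || !nzchar(text)) {
    return(empty)
  }

  n <- nchar(text)
  # candidate boundaries: position AFTER which we cut (0-based end offset)
  cut_after <- integer(0)

  # newline runs are hard boundaries
  nl <- gregexpr("\n+", text, perl = TRUE)[[1]]
  if (nl[1] != -1) {
    cut_after <- c(cut_after, as.integer(nl) - 1L)
  }

  # punctuation runs followed by whitespace + uppercase/digit
  pm <- gregexpr("[.!?]+(?=[ \t]+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (pm[1] != -1) {
    starts <- as.integer(pm)
    lens <- attr(pm, "match.length")
    for (k in seq_along(starts)) {
      pos <- starts[k] # 1-based position of first punctuation char
      run_end <- pos + lens[k] - 1L # 1-based position of last punct char
      if (protected_period(text, pos, abbreviations)) next
      cut_after <- c(cut_after, run_end) # cut after the punctuation run
    }
  }

  cut_after <- sort(unique(cut_after))
  bounds <- c(0L, cut_after, n)
  pieces <- tibble::tibble(
    start = utils::head(bounds, -1),
    end = utils::tail(bounds, -1)
  )
  pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]

  # trim leading/trailing whitespace from each piece, keeping offsets honest
  res <- purrr::pmap_dfr(pieces, function(start, end) {
    raw <- substr(text, start + 1, end)
    lead <- nchar(sub("^(\\s*).*$", "\\1", raw))
    trail <- nchar(sub("^.*?(\\s*)$", "\\1", raw))
    s <- start + lead
    e <- end - trail
    if (e <= s) {
      return(NULL)
    }
    tibble::tibble(
      text = substr(text, s + 1, e),
      start = as.integer(s), end = as.integer(e)
    )
  })
  if (nrow(res) == 0) {
    return(empty)
  }
  res$index <- seq_len(nrow(res)) - 1L
  res[, c("index", "text", "start", "end")]
}

# Is the punctuation at 1-based position `pos` protected from splitting?
# Protected: "." directly inside a decimal number, or ending an abbreviation.
protected_period <- function(text, pos, abbreviations) {
  ch <- substr(text, pos, pos)
  if (ch != ".") {
    return(FALSE)
  }
  before <- substr(text, max(1, pos - 20), pos - 1)
  after <- substr(text, pos + 1, pos + 1)
  # decimal number: digit on both sides of the period
  if (grepl("[0-9]$", before) && grepl("^[0-9]", after)) {
    return(TRUE)
  }
  for (ab in abbreviations) {
    pat <- paste0("(?:^|[^A-Za-z])", escape_regex(ab), "$")
    if (grepl(pat, before, perl = TRUE, ignore.case = ab %in% c("vs", "approx"))) {
      return(TRUE)
    }
  }
  FALSE
}

escape_regex <- function(x) {
  gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)
}

#' Segment every report in a corpus
#'
#' @param corpus A tibble with columns `id` and `text` (one row per report).
#' @param abbreviations Passed to [segment_sentences()].
#' @return A tibble of sentences with a leading `id` column.
#' @export
segment_corpus <- function(corpus, abbreviations = default_abbreviations()) {
  stopifnot(is.data.frame(corpus), all(c("id", "text") %in% names(corpus)))
  out <- purrr::map2_dfr(corpus$id, corpus$text, function(id, txt) {
    s <- segment_sentences(txt, abbreviations)
    if (nrow(s) == 0) {
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(id = id), s)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      id = character(), index = integer(), text = character(),
      start = integer(), end = integer()
    )
  }
  out
}
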