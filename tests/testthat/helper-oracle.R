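# Independent brute-force recount of diagnostic accuracy metrics: explicit
# per-item loop, no shared code with the package's vectorized implementation.
oracle_binary <- function(gold, pred, positive_class = "present") {
  tp <- 0L
  fp <- 0L
  tn <- 0L
  fn <- 0L
  for (i in seq_along(gold)) {
    g <- gold[i] == positive_class
    p <- pred[i] == positive_class
    if (g && p) {
      tp <- tp + 1L
    } else if (!g && p) {
      fp <- fp + 1L
    } else if (!g && !p) {
      tn <- tn + 1L
    } else {
      fn <- fn + 1L
    }
  }
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    accuracy = 100 * (tp + tn) / (tp + fp + tn + fn)
  )
}

# Build gold/pred label vectors realizing an exact confusion composition.
labels_from_counts <- function(tp, fp, tn, fn,
                               pos = "present", neg = "absent") {
  list(
    gold = c(rep(pos, tp), rep(neg, fp), rep(neg, tn), rep(pos, fn)),
    pred = c(rep(pos, tp), rep(pos, fp), rep(neg, tn), rep(neg, fn))
  )
}

random_label_pairs <- function(n, classes = c("present", "absent")) {
  list(
    gold = sample(classes, n, replace = TRUE),
    pred = sample(classes, n, replace = TRUE)
  )
}

binary_attrs <- c(
  "lvo", "distal_occlusion", "basilar_occlusion", "ischemia", "hemorrhage"
)
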