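#' Confusion matrix for decision streams
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Ordered class set; defaults to the union of observed labels
#'   in the canonical six-class order where applicable.
#' @return An object of class `eog_confusion`: a list with `classes` and
#'   `counts` (square matrix, rows = truth, columns = predicted).
#' @examples
#' cm <- confusion(c("left", "left", "blink"), c("left", "right", "blink"))
#' glance(cm)$accuracy
#' @export
confusion <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred))
    abort("truth and pred must have equal length")
  if (is.null(classes)) {
    seen <- union(truth, pred)
    classes <- c(intersect(eye_classes(), seen), setdiff(seen, eye_classes()))
  }
  bad <- setdiff(union(truth, pred), classes)
  if (length(bad))
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  counts <- table(factor(truth, levels = classes),
                  factor(pred, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  structure(list(classes = classes, counts = counts),
            class = "eog_confusion")
}

#' @export
print.eog_confusion <- function(x, ...) {
  cat(sprintf("<eog_confusion> %d classes, %d observations, accuracy %.1f%%\n",
              length(x$classes), sum(x$counts), accuracy(x)))
  print(x$counts)
  invisible(x)
}

#' @rdname confusion
#' @param x An `eog_confusion`.
#' @param percent If `TRUE`, row-normalize to percentages (rounded display
#'   convention is left to the caller; values are raw floats).
#' @param ... Unused.
#' @method tidy eog_confusion
#' @export
tidy.eog_confusion <- function(x, percent = FALSE, ...) {
  m <- x$counts
  if (percent) {
    rs <- rowSums(m)
    m <- sweep(m, 1, ifelse(rs > 0, rs, 1), "/") * 100
  }
  out <- as_tibble(as.data.frame.table(m, responseName = "value"))
  names(out) <- c("truth", "predicted", if (percent) "percent" else "n")
  out
}

#' @rdname confusion
#' @method glance eog_confusion
#' @export
glance.eog_confusion <- function(x, ...) {
  tibble(n = sum(x$counts), n_classes = length(x$classes),
         accuracy = accuracy(x),
         chance = chance_level(length(x$classes)))
}

#' Overall accuracy of a confusion matrix, percent
#' @param cm An [confusion()] object.
#' @return Percent correct (trace over total).
#' @export
accuracy <- function(cm) {
  tot <- sum(cm$counts)
  if (tot == 0) return(NA_real_)
  sum(diag(cm$counts)) / tot * 100
}

#' Collapse a confusion matrix onto a coarser class set
#'
#' @param cm An [confusion()] object.
#' @param mapping Named character vector mapping each original class to a
#'   collapsed class, e.g. [game_collapse()]. Identity mapping allowed.
#' @return A collapsed `eog_confusion`.
#' @export
collapse_confusion <- function(cm, mapping) {
  miss <- setdiff(cm$classes, names(mapping))
  if (length(miss))
    abort(paste0("mapping lacks class(es): ", paste(miss, collapse = ", ")))
  long <- tidy(cm)
  long$truth <- unname(mapping[as.character(long$truth)])
  long$predicted <- unname(mapping[as.character(long$predicted)])
  classes <- unique(unname(mapping))
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  for (i in seq_len(nrow(long)))
    counts[long$truth[i], long$predicted[i]] <-
      counts[long$truth[i], long$predicted[i]] + long$n[i]
  structure(list(classes = classes, counts = counts), class = "eog_confusion")
}

#' The three-command game collapse
#'
#' Maps the six decision classes onto the game's command set: left and right
#' stay themselves, everything else (up, down, center, blink) is `idle`.
#' @return A named character vector usable with [collapse_confusion()] and
#'   [class_metrics()].
#' @export
game_collapse <- function() {
  c(up = "idle", down = "idle", left = "left", right = "right",
    center = "idle", blink = "idle")
}

#' One-vs-rest precision, sensitivity and specificity per class
#'
#' Precision = TP/(TP+FP) x 100, Sensitivity (recall) = TP/(TP+FN) x 100,
#' Specificity = TN/(TN+FP) x 100, computed one-vs-rest per class of the
#' (optionally collapsed) confusion matrix. Classes with no positive
#' observations yield `NaN` metrics with a warning.
#'
#' @param cm An [confusion()] object.
#' @param collapse Optional mapping (see [collapse_confusion()]).
#' @return A tibble: `class`, `TP`, `FP`, `TN`, `FN`, `precision`,
#'   `sensitivity`, `specificity` (percent).
#' @examples
#' cm <- confusion(rep(c("left", "right"), 10), rep(c("left", "right"), 10))
#' class_metrics(cm)
#' @export
class_metrics <- function(cm, collapse = NULL) {
  if (!is.null(collapse)) cm <- collapse_confusion(cm, collapse)
  m <- cm$counts
  tot <- sum(m)
  purrr::map_dfr(seq_along(cm$classes), function(i) {
    TP <- m[i, i]
    FP <- sum(m[, i]) - TP
    FN <- sum(m[i, ]) - TP
    TN <- tot - TP - FP - FN
    if (TP + FN == 0)
      warn(paste0("class '", cm$classes[i], "' has no positive observations; metrics undefined"))
    tibble(class = cm$classes[i], TP = TP, FP = FP, TN = TN, FN = FN,
           precision = TP / (TP + FP) * 100,
           sensitivity = TP / (TP + FN) * 100,
           specificity = TN / (TN + FP) * 100)
  })
}

#' Chance level for uniform guessing
#' @param k Number of classes (>= 2).
#' @return Expected accuracy of a uniform random decision stream, percent.
#' @examples
#' chance_level(6)  # 16.67
#' chance_level(5)  # 20
#' @export
chance_level <- function(k) {
  if (k < 2) abort("chance level needs at least 2 classes")
  100 / k
}

#' Command-rate accounting
#'
#' One decision is emitted per 1-s block, so a 60-s recording yields 60
#' decisions per minute; a controller that consumes every `control_decimation`-th
#' decision (the game controller processes the first and ignores the second,
#' i.e. decimation 2) acts at the classification rate divided by the
#' decimation.
#'
#' @param n_blocks Number of decisions emitted.
#' @param duration_s Recording duration in seconds (> 0).
#' @param control_decimation Integer >= 1.
#' @return A tibble with `classification_rate` and `control_rate`, per minute.
#' @examples
#' bit_rates(60, 60, 2)  # 60 and 30 per minute
#' @export
bit_rates <- function(n_blocks, duration_s, control_decimation = 1) {
  if (duration_s <= 0) abort("duration_s must be positive")
  if (control_decimation < 1) abort("control_decimation must be >= 1")
  cr <- n_blocks / duration_s * 60
  tibble(classification_rate = cr, control_rate = cr / control_decimation)
}

#' Score a labeled decision stream
#'
#' Computes the block-level confusion matrix of decisions against labels and,
#' for protocol recordings, the trial-level view in which an event is correct
#' if the dominant decision over its labeled blocks matches the label.
#'
#' @param decisions An `eog_decisions` tibble with a `label` column.
#' @return A list with `confusion` (block-level `eog_confusion`),
#'   `block_accuracy`, and `summary` (a one-row tibble).
#' @export
score_decisions <- function(decisions) {
  if (!"label" %in% names(decisions))
    abort("decision stream has no ground-truth labels")
  cm <- confusion(decisions$label, decisions$decision)
  list(confusion = cm,
       block_accuracy = accuracy(cm),
       summary = glance(cm))
}
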