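# Rejection thresholding: binarized classification, accuracy with
# rejection, and F-beta-driven threshold selection.

#' Threshold configuration
#'
#' @param binarization_threshold Minimum top-class probability to accept a
#'   prediction (default 0.9).
#' @param beta F-beta weighting; values below 1 weight precision over
#'   recall (default 0.3, heavily discouraging false positives).
#' @param threshold_grid Candidate thresholds for [select_threshold()]
#'   (default 0, 0.05, ..., 1).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(binarization_threshold = 0.9, beta = 0.3,
                             threshold_grid = seq(0, 1, by = 0.05)) {
  stopifnot(binarization_threshold >= 0, binarization_threshold <= 1,
            beta > 0, length(threshold_grid) >= 1,
            all(threshold_grid >= 0 & threshold_grid <= 1))
  structure(list(binarization_threshold = binarization_threshold,
                 beta = beta, threshold_grid = threshold_grid),
            class = "threshold_config")
}

#' Binarized classification with rejection
#'
#' A row is labelled with its argmax class when the maximum probability
#' reaches the threshold, and rejected (NA) otherwise. Exact argmax ties
#' resolve to the lowest class index. Rows that are entirely `NA`
#' (e.g. invalid reads skipped by [predict_proba()]) are rejected.
#'
#' @param probs `N x C` probability matrix (rows sum to 1); column names,
#'   if present, are used as labels.
#' @param t Threshold in `[0,1]`.
#' @return Character vector of length `N`: class labels (column names, or
#'   0-based class indices as strings when unnamed), with `NA` for
#'   rejected rows.
#' @export
classify_with_threshold <- function(probs, t) {
  stopifnot(is.matrix(probs), t >= 0, t <= 1)
  if (!nrow(probs)) return(character(0))
  labels <- colnames(probs)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(probs)) - 1L)
  bad <- !stats::complete.cases(probs)
  p <- probs
  p[bad, ] <- 0
  best <- max.col(p, ties.method = "first")
  mx <- p[cbind(seq_len(nrow(p)), best)]
  out <- labels[best]
  out[bad | mx < t] <- NA_character_
  out
}

#' Accuracy over accepted predictions, and discard rate
#'
#' @param pred_labels Predictions with `NA` marking rejected reads.
#' @param truth True labels (no `NA`), same length.
#' @return List with `accuracy` (fraction correct among accepted; `NA`
#'   with `undefined = TRUE` when everything was rejected),
#'   `discard_rate`, `n_accepted`, `n_total`, `undefined`.
#' @export
accuracy_with_rejection <- function(pred_labels, truth) {
  if (length(pred_labels) != length(truth))
    stop("pred_labels and truth must have the same length")
  if (anyNA(truth)) stop("truth must not contain NA")
  acc_idx <- !is.na(pred_labels)
  n <- length(truth)
  list(
    accuracy = if (any(acc_idx)) mean(pred_labels[acc_idx] == truth[acc_idx])
               else NA_real_,
    discard_rate = if (n) sum(!acc_idx) / n else 0,
    n_accepted = sum(acc_idx), n_total = n,
    undefined = !any(acc_idx)
  )
}

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`; 0 when precision and recall
#' are both 0. `beta = 1` gives the harmonic mean (F1); `beta < 1` weights
#' precision more heavily.
#'
#' @param precision,recall Values in `[0,1]`.
#' @param beta Positive weighting parameter.
#' @return The F-beta value.
#' @export
fbeta <- function(precision, recall, beta) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1, beta > 0)
  denom <- beta^2 * precision + recall
  if (denom == 0) return(0)
  (1 + beta^2) * precision * recall / denom
}

#' Select a binarization threshold by F-beta
#'
#' At each candidate threshold, predictions are binarized with rejection;
#' precision = correct accepted / accepted, and recall = correct accepted /
#' all reads (so every rejection costs recall). The threshold maximizing
#' F-beta wins; ties resolve toward the *stricter* (larger) threshold,
#' favouring fewer false positives.
#'
#' @param probs `N x C` probability matrix.
#' @param truth True labels (matching the matrix column names).
#' @param config A [threshold_config()].
#' @return List with `best_t` and `report`, a data.frame with columns
#'   threshold, precision, recall, f_beta, discard_rate.
#' @export
select_threshold <- function(probs, truth, config = threshold_config()) {
  stopifnot(inherits(config, "threshold_config"))
  grid <- sort(config$threshold_grid)
  rows <- lapply(grid, function(t) {
    pred <- classify_with_threshold(probs, t)
    acc_idx <- !is.na(pred)
    correct <- sum(pred[acc_idx] == truth[acc_idx])
    precision <- if (any(acc_idx)) correct / sum(acc_idx) else 0
    recall <- correct / length(truth)
    data.frame(threshold = t, precision = precision, recall = recall,
               f_beta = fbeta(precision, recall, config$beta),
               discard_rate = mean(!acc_idx))
  })
  report <- do.call(rbind, rows)
  best <- report$threshold[max(which(report$f_beta == max(report$f_beta)))]
  list(best_t = best, report = report)
}

#' Write a threshold-selection report as TSV
#' @param report The `report` data.frame from [select_threshold()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
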