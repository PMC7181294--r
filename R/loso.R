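#' Confusion matrix with fixed class order
#'
#' Rows are true classes, columns predicted classes; row sums equal the
#' per-class test counts.
#' @param truth,predicted character vectors of equal length.
#' @param classes class order; defaults to sorted union.
#' @return Integer matrix.
#' @export
confusion_matrix <- function(truth, predicted,
                             classes = sort(unique(c(truth, predicted)))) {
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  mat <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(truth = classes, predicted = classes))
  mat
}

#' Macro-averaged F1 score
#'
#' Per-class F1 = 2PR/(P+R) from the confusion matrix, averaged with equal
#' class weight; a class with no predictions and no test instances
#' contributes F1 = 0 only if it appears in the matrix.
#' @param cm confusion matrix from \code{\link{confusion_matrix}}.
#' @return Macro F1 in [0, 1].
#' @export
macro_f1 <- function(cm) {
  f1 <- vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    prec_den <- sum(cm[, i]); rec_den <- sum(cm[i, ])
    if (tp == 0) return(0)
    p <- tp / prec_den; r <- tp / rec_den
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' Leave-one-subject-out evaluation of HAR-SR
#'
#' One fold per subject: the model (including PCA loading, MCB table and
#' reference histograms) is refitted on all other subjects' recordings and
#' the held-out subject's recordings are classified, so no information from
#' a test subject ever enters training. Metrics are pooled over folds.
#'
#' @param recordings list of \code{\link{har_recording}} objects from at
#'   least 2 subjects.
#' @param control a \code{\link{harsr_control}}.
#' @return An object of class \code{"harsr_loso"}: list with \code{folds}
#'   (per-subject data.frame of accuracy and macro F1), \code{confusion}
#'   (pooled), \code{accuracy}, \code{macro_f1}, \code{truth},
#'   \code{predicted}, \code{subjects}.
#' @export
loso <- function(recordings, control = harsr_control()) {
  subjects <- vapply(recordings, `[[`, character(1), "subject")
  labels <- vapply(recordings, `[[`, character(1), "activity")
  classes <- sort(unique(labels))
  subj_ids <- sort(unique(subjects))
  if (length(subj_ids) < 2L)
    stop("LOSO needs at least 2 subjects")
  truth <- character(0); predicted <- character(0); fold_of <- character(0)
  fold_rows <- list()
  for (s in subj_ids) {
    test_idx <- which(subjects == s)
    train_idx <- which(subjects != s)
    stopifnot(length(intersect(train_idx, test_idx)) == 0L)
    model <- harsr(recordings[train_idx], control)
    pred <- predict(model, recordings[test_idx])
    tr <- labels[test_idx]
    truth <- c(truth, tr); predicted <- c(predicted, pred)
    fold_of <- c(fold_of, rep(s, length(tr)))
    cmf <- confusion_matrix(tr, pred, classes)
    fold_rows[[s]] <- data.frame(subject = s, n = length(tr),
                                 accuracy = mean(pred == tr),
                                 macro_f1 = macro_f1(cmf),
                                 row.names = NULL)
  }
  cm <- confusion_matrix(truth, predicted, classes)
  structure(list(folds = do.call(rbind, fold_rows), confusion = cm,
                 accuracy = mean(predicted == truth),
                 macro_f1 = macro_f1(cm), truth = truth,
                 predicted = predicted, subjects = fold_of,
                 classes = classes, control = control),
            class = "harsr_loso")
}

#' @export
print.harsr_loso <- function(x, ...) {
  cat("HAR-SR leave-one-subject-out evaluation\n")
  cat(sprintf("  %d fold(s), %d recording(s), %d class(es)\n",
              nrow(x$folds), length(x$truth), length(x$classes)))
  cat(sprintf("  pooled accuracy: %.4f   pooled macro F1: %.4f\n",
              x$accuracy, x$macro_f1))
  cat("\nPer-fold metrics:\n")
  print(x$folds, row.names = FALSE)
  cat("\nPooled confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the pooled metrics and per-fold table as JSON and the confusion
#' matrix as CSV.
#' @param report a \code{"harsr_loso"} object.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(accuracy = report$accuracy, macro_f1 = report$macro_f1,
         folds = report$folds, classes = report$classes),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   file.path(dir, "confusion.csv"))
  invisible(dir)
}
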