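#' Control parameters for a HAR-SR model
#'
#' Defaults are the method's standard operating point: concatenation
#' fusion, SAX with word length 6 over a 6-letter alphabet, 128-sample
#' windows with 50\% overlap, and k = 3 cosine-similarity nearest
#' neighbours.
#'
#' @param fusion data-fusion method applied to the multi-axis channels.
#' @param method symbolic encoder, \code{"sax"} or \code{"sfa"}.
#' @param omega word length.
#' @param alpha alphabet size.
#' @param window_length bag-of-patterns sliding-window size in samples.
#' @param overlap fraction of the window shared by consecutive windows;
#'   the hop is \code{window_length * (1 - overlap)} samples.
#' @param k neighbour count for the k-NN vote.
#' @param znorm_epsilon degenerate-window threshold (see
#'   \code{\link{symbolic_config}}).
#' @param drop_dc SFA: drop the DC Fourier coefficient.
#' @param complexity_normalized use normalized entropy inside the
#'   statistical complexity (default).
#' @return A list of class \code{"harsr_control"}.
#' @export
harsr_control <- function(fusion = c("concatenation", "magnitude", "pca"),
                          method = c("sax", "sfa"),
                          omega = 6L, alpha = 6L,
                          window_length = 128L, overlap = 0.5,
                          k = 3L, znorm_epsilon = 1e-8, drop_dc = TRUE,
                          complexity_normalized = TRUE) {
  fusion <- match.arg(fusion)
  method <- match.arg(method)
  if (overlap < 0 || overlap >= 1)
    stop("config error: overlap must be in [0, 1)")
  if (window_length < 1) stop("config error: window_length must be >= 1")
  if (k < 1) stop("config error: k must be >= 1")
  cfg <- symbolic_config(omega, alpha, method,
                         znorm_epsilon = znorm_epsilon, drop_dc = drop_dc)
  step <- max(1L, as.integer(round(window_length * (1 - overlap))))
  structure(list(fusion = fusion, symbolic = cfg,
                 window_length = as.integer(window_length),
                 overlap = overlap, step = step, k = as.integer(k),
                 complexity_normalized = complexity_normalized),
            class = "harsr_control")
}

fused_length <- function(recording, control) {
  n <- n_samples(recording)
  if (control$fusion == "concatenation") n * length(recording$channels) else n
}

# fuse + histogram for one recording, given fitted pca/mcb components
featurize_histogram <- function(recording, control, pca_fit, mcb) {
  fused <- fuse_recording(recording, control$fusion, pca_fit)
  bop_histogram(fused, control$window_length, control$step,
                control$symbolic, mcb = mcb,
                label = recording$activity, subject = recording$subject)
}

#' Fit a HAR-SR activity-recognition model
#'
#' Runs the full training pipeline on labeled recordings: data fusion,
#' bag-of-patterns symbolic encoding (fitting the MCB table on the training
#' windows when the encoder is SFA), construction of the per-class
#' reference histograms, and extraction of one information-theory feature
#' vector per recording. Everything data-dependent (PCA loading, MCB table,
#' reference histograms) is learned from these recordings only, so a model
#' fitted inside a cross-validation fold never sees test data.
#'
#' @param recordings list of \code{\link{har_recording}} objects; at least
#'   one per class and at least \code{control$k} in total.
#' @param control a \code{\link{harsr_control}}.
#' @return An object of class \code{"harsr"} with components
#'   \code{features} (N x (2K+3) matrix), \code{labels}, \code{subjects},
#'   \code{references}, \code{control}, and any fitted \code{pca} /
#'   \code{mcb} components.
#' @export
harsr <- function(recordings, control = harsr_control()) {
  if (!length(recordings)) stop("no training recordings")
  labels <- vapply(recordings, `[[`, character(1), "activity")
  if (length(unique(labels)) < 2L)
    stop("missing class: need recordings from at least 2 classes")
  if (control$k > length(recordings))
    stop("k = ", control$k, " exceeds training size ", length(recordings))
  for (r in recordings)
    if (fused_length(r, control) < control$window_length)
      stop("window-too-long error: a fused recording is shorter than ",
           control$window_length, " samples")

  pca_fit <- if (control$fusion == "pca") fit_pca_fusion(recordings)
             else NULL
  mcb <- NULL
  if (control$symbolic$method == "sfa") {
    rows <- do.call(rbind, lapply(recordings, function(r) {
      fused <- fuse_recording(r, control$fusion, pca_fit)
      mft_sliding(fused, control$window_length, control$symbolic$omega,
                  drop_dc = control$symbolic$drop_dc, step = control$step)
    }))
    mcb <- fit_mcb(rows, control$symbolic)
  }
  hists <- lapply(recordings, featurize_histogram,
                  control = control, pca_fit = pca_fit, mcb = mcb)
  refs <- build_references(hists)
  feats <- t(vapply(hists, function(h)
    feature_vector(normalize_histogram(h), refs),
    numeric(2L * length(refs$classes) + 3L)))
  structure(list(features = feats, labels = labels,
                 subjects = vapply(recordings, `[[`, character(1),
                                   "subject"),
                 references = refs, control = control,
                 pca = pca_fit, mcb = mcb, classes = refs$classes),
            class = "harsr")
}

#' @export
print.harsr <- function(x, ...) {
  cat("HAR-SR model\n")
  cat(sprintf("  %d training vector(s) of length %d, %d class(es): %s\n",
              nrow(x$features), ncol(x$features), length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  fusion=%s  encoder=%s (omega=%d, alpha=%d, eta=%g)\n",
              x$control$fusion, x$control$symbolic$method,
              x$control$symbolic$omega, x$control$symbolic$alpha,
              x$references$eta))
  cat(sprintf("  window=%d samples, step=%d, k=%d, cosine similarity\n",
              x$control$window_length, x$control$step, x$control$k))
  invisible(x)
}

#' @export
summary.harsr <- function(object, ...) {
  print(object)
  cat("\nTraining recordings per class:\n")
  print(table(object$labels))
  cat("\nFeature ranges:\n")
  print(apply(object$features, 2L, range))
  invisible(object)
}

#' Cosine similarity between two vectors
#'
#' dot(u, v) / (||u|| ||v||), in [-1, 1]. A zero-norm vector has no
#' direction, so similarity is undefined and an error is raised rather
#' than silently returning 0.
#'
#' @param u,v numeric vectors of equal length.
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("undefined-similarity error: zero-norm vector")
  sum(u * v) / (nu * nv)
}

# majority vote among the k most similar training vectors; ties between
# classes broken by the single most similar neighbour among tied classes
knn_vote <- function(similarities, labels, k) {
  ord <- order(similarities, decreasing = TRUE)
  top <- ord[seq_len(min(k, length(ord)))]
  tab <- table(labels[top])
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  best <- top[labels[top] %in% winners][1L]  # top is similarity-ordered
  labels[best]
}

#' Predict activity labels for new recordings
#'
#' Each recording is featurized with the model's fitted components and
#' reference histograms, training vectors are ranked by cosine similarity,
#' and the majority label among the k nearest wins (ties go to the class
#' of the single most similar tied-class neighbour).
#'
#' @param object a fitted \code{"harsr"} model.
#' @param newdata a \code{har_recording} or list of them.
#' @param k neighbour count; defaults to the fitted control's k.
#' @param diagnostics also return per-recording neighbour tables.
#' @param ... unused.
#' @return Character vector of predicted labels, or, with
#'   \code{diagnostics = TRUE}, a list with \code{label}, \code{features}
#'   and \code{neighbors} per recording.
#' @export
predict.harsr <- function(object, newdata, k = object$control$k,
                          diagnostics = FALSE, ...) {
  if (inherits(newdata, "har_recording")) newdata <- list(newdata)
  res <- lapply(newdata, function(rec) {
    h <- featurize_histogram(rec, object$control, object$pca, object$mcb)
    fv <- feature_vector(normalize_histogram(h), object$references)
    sims <- apply(object$features, 1L, cosine_similarity, v = fv)
    lab <- knn_vote(sims, object$labels, k)
    if (diagnostics) {
      ord <- order(sims, decreasing = TRUE)[seq_len(min(k, length(sims)))]
      list(label = lab, features = fv,
           neighbors = data.frame(rank = seq_along(ord),
                                  label = object$labels[ord],
                                  subject = object$subjects[ord],
                                  similarity = sims[ord],
                                  row.names = NULL))
    } else lab
  })
  if (diagnostics) res else unlist(res, use.names = FALSE)
}
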