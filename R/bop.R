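#' Bag-of-patterns word histogram of a fused series
#'
#' Slides a window over the univariate series, encodes every window into a
#' symbolic word (SAX or SFA per \code{config$method}) and tallies word
#' frequencies. The histogram is stored sparsely (unobserved words count 0)
#' but is defined over the full word space of size alpha^omega, which every
#' downstream entropy/divergence computation ranges over.
#'
#' @param fused_series numeric vector (already fused to one dimension).
#' @param window_length sliding-window size in samples (default 128).
#' @param step hop between window starts; the default 64 is 50\% overlap.
#' @param config a \code{\link{symbolic_config}}.
#' @param mcb fitted \code{"har_mcb"} table, required when
#'   \code{config$method == "sfa"}.
#' @param label,subject optional activity label / subject id carried along.
#' @return An object of class \code{"word_histogram"}: list with
#'   \code{counts} (named integer vector over observed words), \code{total}
#'   (number of windows), \code{omega}, \code{alpha}, \code{eta}
#'   (= alpha^omega), \code{label}, \code{subject}.
#' @export
bop_histogram <- function(fused_series, window_length = 128L, step = 64L,
                          config = symbolic_config(), mcb = NULL,
                          label = NULL, subject = NULL) {
  n <- length(fused_series)
  if (window_length > n)
    stop("window-too-long error: series length ", n,
         " < window_length ", window_length)
  if (step < 1) stop("parameter error: step must be >= 1")
  starts <- seq.int(1L, n - window_length + 1L, by = step)
  if (config$method == "sax") {
    words <- vapply(starts, function(a)
      sax_word(fused_series[a:(a + window_length - 1L)], config),
      character(1))
  } else {
    if (is.null(mcb))
      stop("config error: SFA encoding requires a fitted MCB table")
    if (mcb$omega != config$omega || mcb$alpha != config$alpha)
      stop("config error: MCB table fitted with different omega/alpha")
    rows <- mft_sliding(fused_series, window_length, config$omega,
                        drop_dc = mcb$drop_dc, step = step)
    words <- encode_sfa_rows(rows, mcb)
  }
  counts <- table(words)
  structure(list(counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 total = length(words),
                 omega = config$omega, alpha = config$alpha,
                 eta = as.numeric(config$alpha)^config$omega,
                 label = label, subject = subject),
            class = "word_histogram")
}

#' @export
print.word_histogram <- function(x, ...) {
  cat(sprintf("<word_histogram> %d window(s), %d distinct word(s) of %g possible\n",
              x$total, length(x$counts), x$eta))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Serialize a word histogram to JSON
#' @param h a \code{"word_histogram"}.
#' @param path JSON file path.
#' @export
write_histogram <- function(h, path) {
  jsonlite::write_json(
    list(omega = h$omega, alpha = h$alpha, counts = as.list(h$counts),
         total = h$total, label = h$label, subject = h$subject),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
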