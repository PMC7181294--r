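#' Probability distribution over the symbolic word space
#'
#' Distributions are stored sparsely: only words with nonzero probability
#' are kept, together with the word-space size eta = alpha^omega that all
#' entropy and divergence computations range over. The uniform distribution
#' is represented analytically so large word spaces stay cheap.
#'
#' @param probs named numeric vector of nonzero probabilities (must sum
#'   to 1 within 1e-12).
#' @param eta word-space size (>= number of listed words).
#' @return An object of class \code{"word_distribution"}.
#' @export
word_distribution <- function(probs, eta) {
  probs <- probs[probs > 0]
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probabilities must sum to 1")
  if (length(probs) > eta)
    stop("more nonzero probabilities than the word space holds")
  structure(list(probs = probs, eta = as.numeric(eta), uniform = FALSE),
            class = "word_distribution")
}

#' @rdname word_distribution
#' @export
uniform_distribution <- function(eta) {
  if (eta < 2) stop("eta must be >= 2")
  structure(list(probs = numeric(0), eta = as.numeric(eta), uniform = TRUE),
            class = "word_distribution")
}

#' @export
print.word_distribution <- function(x, ...) {
  if (x$uniform)
    cat(sprintf("<word_distribution> uniform over eta = %g words\n", x$eta))
  else
    cat(sprintf("<word_distribution> %d nonzero of eta = %g words\n",
                length(x$probs), x$eta))
  invisible(x)
}

#' Normalize a word histogram into a probability distribution
#'
#' Divides every count by the number of windows, keeping the full word
#' space: words never observed have probability zero.
#'
#' @param h a \code{"word_histogram"} with \code{total > 0}.
#' @return A \code{"word_distribution"}.
#' @export
normalize_histogram <- function(h) {
  if (is.null(h$total) || h$total <= 0)
    stop("empty histogram: no windows encoded")
  word_distribution(h$counts / h$total, h$eta)
}

#' Shannon entropy of a word distribution
#'
#' Raw entropy H = -sum p_i ln p_i (with 0 ln 0 = 0) lies in [0, ln eta];
#' the normalized value Hs = H / ln(eta) lies in [0, 1], reaching 0 for a
#' degenerate distribution and 1 for the uniform one.
#'
#' @param P a \code{"word_distribution"}.
#' @return Named numeric vector \code{c(raw = H, normalized = Hs)}.
#' @export
shannon_entropy <- function(P) {
  if (P$uniform) {
    raw <- log(P$eta)
  } else {
    p <- P$probs
    raw <- -sum(p * log(p))
  }
  c(raw = raw, normalized = raw / log(P$eta))
}

#' Normalization constant of the Jensen-Shannon divergence
#'
#' Q0 is the reciprocal of the Jensen-Shannon divergence between a
#' degenerate (single-word) distribution and the uniform distribution over
#' eta words - the maximal, "totally deterministic" case - so the scaled
#' divergence ranges over [0, 1]:
#' Q0 = -2 / ( ((eta+1)/eta) ln(eta+1) - 2 ln(2 eta) + ln(eta) ).
#'
#' @param eta word-space size (>= 2).
#' @return The constant Q0.
#' @export
q0_constant <- function(eta) {
  if (eta < 2) stop("eta must be >= 2")
  -2 / (((eta + 1) / eta) * log(eta + 1) - 2 * log(2 * eta) + log(eta))
}

# probability a distribution assigns to any word outside its listed support
off_support_prob <- function(P) if (P$uniform) 1 / P$eta else 0

#' Normalized Jensen-Shannon divergence between two word distributions
#'
#' Qj = Q0 * ( H[(P+Q)/2] - H[P]/2 - H[Q]/2 ) with raw entropies inside the
#' bracket and Q0 carrying the normalization, so Qj is symmetric, equals 0
#' iff P = Q, and equals 1 for a degenerate distribution against the
#' uniform. Computed sparsely over the union of supports.
#'
#' @param P,Q \code{"word_distribution"} objects sharing the same eta.
#' @param q0 normalization constant; defaults to
#'   \code{\link{q0_constant}(eta)}.
#' @return Divergence in [0, 1].
#' @export
js_divergence <- function(P, Q, q0 = q0_constant(P$eta)) {
  if (!isTRUE(all.equal(P$eta, Q$eta)))
    stop("distributions live on different word spaces")
  eta <- P$eta
  nms <- union(names(P$probs), names(Q$probs))
  p0 <- off_support_prob(P); q0off <- off_support_prob(Q)
  pv <- if (length(nms)) ifelse(nms %in% names(P$probs),
                                P$probs[nms], p0) else numeric(0)
  qv <- if (length(nms)) ifelse(nms %in% names(Q$probs),
                                Q$probs[nms], q0off) else numeric(0)
  pv[is.na(pv)] <- p0; qv[is.na(qv)] <- q0off
  m <- (pv + qv) / 2
  m0 <- (p0 + q0off) / 2
  h_listed <- -sum(m[m > 0] * log(m[m > 0]))
  h_rest <- if (m0 > 0) -(eta - length(nms)) * m0 * log(m0) else 0
  h_mix <- h_listed + h_rest
  js <- h_mix - shannon_entropy(P)[["raw"]] / 2 -
    shannon_entropy(Q)[["raw"]] / 2
  max(q0 * js, 0)
}

#' Statistical complexity of a distribution against a reference
#'
#' C = Qj(P, ref) * Hs(P): the product of the normalized Jensen-Shannon
#' divergence from the reference and the normalized Shannon entropy. Both
#' perfectly ordered (Hs = 0) and perfectly random (Qj(P, Pe) = 0)
#' distributions get complexity 0; intermediate structure scores higher.
#'
#' @param P a \code{"word_distribution"}.
#' @param ref reference \code{"word_distribution"} (same eta).
#' @param q0 normalization constant for the divergence.
#' @param normalized use the normalized entropy Hs (default); set
#'   \code{FALSE} to use the raw entropy for sensitivity analysis.
#' @return Complexity value (in [0, 1] when \code{normalized = TRUE}).
#' @export
statistical_complexity <- function(P, ref, q0 = q0_constant(P$eta),
                                   normalized = TRUE) {
  h <- shannon_entropy(P)[[if (normalized) "normalized" else "raw"]]
  js_divergence(P, ref, q0) * h
}

#' Build the reference set: uniform plus per-class pooled histograms
#'
#' For each class, the word counts of all its histograms are summed
#' word-wise into a single reference histogram, then normalized. The
#' uniform distribution over the word space is always included. Class
#' order is sorted labels and is recorded.
#'
#' @param labeled_histograms list of \code{"word_histogram"} objects, each
#'   with a non-NULL \code{label}; all must share omega and alpha.
#' @return An object of class \code{"har_references"}: list with
#'   \code{uniform}, \code{class_refs} (named list in sorted label order),
#'   \code{classes}, \code{eta} and \code{q0}.
#' @export
build_references <- function(labeled_histograms) {
  labs <- vapply(labeled_histograms, function(h) {
    if (is.null(h$label)) stop("histogram without a class label")
    h$label
  }, character(1))
  etas <- vapply(labeled_histograms, function(h) h$eta, numeric(1))
  if (length(unique(etas)) != 1L)
    stop("histograms use different word spaces")
  eta <- etas[[1L]]
  classes <- sort(unique(labs))
  refs <- lapply(classes, function(cl) {
    hs <- labeled_histograms[labs == cl]
    counts <- unlist(lapply(hs, `[[`, "counts"))
    pooled <- tapply(counts, names(counts), sum)
    pooled <- stats::setNames(as.numeric(pooled), names(pooled))
    word_distribution(pooled / sum(pooled), eta)
  })
  names(refs) <- classes
  structure(list(uniform = uniform_distribution(eta), class_refs = refs,
                 classes = classes, eta = eta, q0 = q0_constant(eta)),
            class = "har_references")
}

#' @export
print.har_references <- function(x, ...) {
  cat(sprintf("<har_references> %d class reference(s) + uniform over eta = %g\n",
              length(x$class_refs), x$eta))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Information-theory feature vector of a distribution
#'
#' Returns, in fixed order: the normalized entropy Hs; the normalized
#' Jensen-Shannon divergence from the uniform reference and from each class
#' reference (sorted class order); then the statistical complexity against
#' the uniform and each class reference. For K classes the vector has
#' length 2K + 3 (15 features for a six-class problem).
#'
#' @param P a \code{"word_distribution"}.
#' @param refs a \code{"har_references"} set with matching eta.
#' @return Named numeric vector
#'   \code{(Hs, Q_ref, Q_<class>..., C_ref, C_<class>...)}.
#' @export
feature_vector <- function(P, refs) {
  if (!isTRUE(all.equal(P$eta, refs$eta)))
    stop("distribution and references use different word spaces")
  hs <- shannon_entropy(P)[["normalized"]]
  qs <- vapply(refs$class_refs, function(r)
    js_divergence(P, r, refs$q0), numeric(1))
  q_ref <- js_divergence(P, refs$uniform, refs$q0)
  out <- c(hs, q_ref, qs, hs * q_ref, hs * qs)
  names(out) <- c("Hs", "Q_ref", paste0("Q_", refs$classes),
                  "C_ref", paste0("C_", refs$classes))
  out
}
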