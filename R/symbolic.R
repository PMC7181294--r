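#' Symbolic discretization configuration
#'
#' Bundles the word length omega, alphabet size alpha and encoder choice
#' shared by SAX and SFA. The word space has exactly alpha^omega words.
#'
#' @param omega word length (>= 1; even for SFA, where each retained complex
#'   DFT coefficient contributes a real and an imaginary part).
#' @param alpha alphabet size (2..26).
#' @param method \code{"sax"} or \code{"sfa"}.
#' @param znorm_epsilon standard-deviation threshold under which a window is
#'   treated as constant and z-normalization is skipped.
#' @param drop_dc SFA only: drop the DC (mean) Fourier coefficient so the
#'   encoding is mean-invariant. Default \code{TRUE}.
#' @return An object of class \code{"har_symbolic_config"}.
#' @export
symbolic_config <- function(omega = 6L, alpha = 6L,
                            method = c("sax", "sfa"),
                            znorm_epsilon = 1e-8, drop_dc = TRUE) {
  method <- match.arg(method)
  omega <- as.integer(omega); alpha <- as.integer(alpha)
  if (omega < 1L) stop("config error: omega must be >= 1")
  if (alpha < 2L || alpha > 26L)
    stop("config error: alpha must be in 2..26")
  if (method == "sfa" && omega %% 2L != 0L)
    stop("parameter error: SFA requires an even omega")
  structure(list(omega = omega, alpha = alpha, method = method,
                 znorm_epsilon = znorm_epsilon, drop_dc = drop_dc),
            class = "har_symbolic_config")
}

#' Piecewise aggregate approximation
#'
#' Reduces a series of length n to omega frame means. When omega does not
#' divide n, fractional frame weighting is used: each frame spans n/omega
#' samples and a sample straddling a frame boundary contributes to both
#' frames in proportion to its overlap, so every sample's mass is kept.
#'
#' @param series numeric vector, length >= omega.
#' @param omega number of frames.
#' @return Numeric vector of length omega.
#' @export
paa <- function(series, omega) {
  n <- length(series)
  if (omega > n) stop("paa error: omega exceeds series length")
  if (omega == n) return(as.numeric(series))
  if (n %% omega == 0L) {
    frame <- n %/% omega
    return(colMeans(matrix(series, nrow = frame)))
  }
  width <- n / omega
  out <- numeric(omega)
  for (j in seq_len(omega)) {
    lo <- (j - 1) * width
    hi <- j * width
    i0 <- floor(lo) + 1     # first sample overlapping the frame
    i1 <- ceiling(hi)       # last sample overlapping the frame
    idx <- i0:i1
    overlap <- pmin(idx, hi) - pmax(idx - 1, lo)
    out[j] <- sum(overlap * series[idx]) / width
  }
  out
}

#' Equiprobable breakpoints under the standard normal
#'
#' The alpha - 1 thresholds that split the standard-normal distribution
#' into alpha equal-probability regions: the normal quantiles at
#' i/alpha, i = 1..alpha-1. Strictly increasing and antisymmetric about 0.
#'
#' @param alpha alphabet size (>= 2).
#' @return Numeric vector of length alpha - 1.
#' @export
gaussian_breakpoints <- function(alpha) {
  if (alpha < 2) stop("alpha must be >= 2")
  stats::qnorm(seq_len(alpha - 1) / alpha)
}

# Map values to 0-based letter indices given sorted breakpoints.
# Convention: value v gets letter k iff b_{k-1} <= v < b_k with
# b_0 = -Inf, b_alpha = +Inf; a value equal to a breakpoint takes the
# higher letter.
encode_indices <- function(values, breakpoints) {
  findInterval(values, breakpoints)
}

letters_for <- function(idx) {
  paste(letters[idx + 1L], collapse = "")
}

#' SAX word of a window
#'
#' Z-normalizes the window (skipped for near-constant windows, which emit
#' the letter whose breakpoint interval contains 0 repeated omega times),
#' reduces it with \code{\link{paa}} and maps each frame mean to a letter
#' via \code{\link{gaussian_breakpoints}}.
#'
#' @param window numeric vector, length >= omega.
#' @param config a \code{\link{symbolic_config}}.
#' @return Single character string of omega letters.
#' @export
sax_word <- function(window, config) {
  bp <- gaussian_breakpoints(config$alpha)
  s <- stats::sd(window)
  if (!is.finite(s) || s < config$znorm_epsilon) {
    k <- encode_indices(0, bp)
    return(letters_for(rep.int(k, config$omega)))
  }
  z <- (window - mean(window)) / s
  letters_for(encode_indices(paa(z, config$omega), bp))
}

#' Leading DFT coefficients of a window
#'
#' Returns the first omega/2 complex Fourier coefficients of the window,
#' interleaved as (re, im, re, im, ...) and scaled by 1/length(window).
#' With \code{drop_dc = TRUE} (the default) coefficients start at frequency
#' index 1, making the representation invariant to the window mean.
#'
#' @param window numeric vector.
#' @param omega even number of real values to return (omega/2 complex
#'   coefficients).
#' @param drop_dc drop the DC coefficient and start at index 1.
#' @return Numeric vector of length omega.
#' @export
dft_coefficients <- function(window, omega, drop_dc = TRUE) {
  if (omega %% 2L != 0L) stop("parameter error: omega must be even")
  n <- length(window)
  if (n < omega) stop("window shorter than omega")
  X <- stats::fft(window) / n
  start <- if (drop_dc) 2L else 1L
  ks <- start:(start + omega %/% 2L - 1L)
  if (max(ks) > n) stop("window too short for requested coefficients")
  co <- X[ks]
  out <- numeric(omega)
  out[seq(1L, omega, by = 2L)] <- Re(co)
  out[seq(2L, omega, by = 2L)] <- Im(co)
  out
}

#' Sliding-window DFT coefficients via the momentary Fourier transform
#'
#' Computes the leading DFT coefficients of every sliding window of the
#' series. The full transform is evaluated only for the first window; each
#' subsequent window is obtained by the O(omega) incremental update
#' X_k <- e^(2*pi*i*k/w) * (X_k - x_out + x_in), then scaled by 1/w.
#'
#' @param series numeric vector.
#' @param window_length window size w.
#' @param omega as in \code{\link{dft_coefficients}}.
#' @param drop_dc as in \code{\link{dft_coefficients}}.
#' @param step output rows are subsampled to windows starting at
#'   0, step, 2*step, ... (the update itself always slides by 1).
#' @return Matrix with one row per returned window and omega columns.
#' @export
mft_sliding <- function(series, window_length, omega, drop_dc = TRUE,
                        step = 1L) {
  n <- length(series)
  w <- as.integer(window_length)
  if (w > n) stop("window-too-long error")
  if (omega %% 2L != 0L) stop("parameter error: omega must be even")
  start <- if (drop_dc) 1L else 0L
  ks <- start:(start + omega %/% 2L - 1L)
  n_win <- n - w + 1L
  keep <- seq.int(1L, n_win, by = step)
  out <- matrix(0, nrow = length(keep), ncol = omega)
  # unnormalized coefficients of the first window
  X <- stats::fft(series[1:w])[ks + 1L]
  twiddle <- exp(2i * pi * ks / w)
  row_of <- match(seq_len(n_win), keep)
  store <- function(t, X) {
    r <- row_of[t]
    if (!is.na(r)) {
      co <- X / w
      out[r, seq(1L, omega, by = 2L)] <<- Re(co)
      out[r, seq(2L, omega, by = 2L)] <<- Im(co)
    }
  }
  store(1L, X)
  if (n_win > 1L) {
    for (t in 2:n_win) {
      X <- twiddle * (X - series[t - 1L] + series[t + w - 1L])
      store(t, X)
    }
  }
  out
}

#' Fit a multiple-coefficient-binning quantization table
#'
#' Learns, for each of the omega coefficient columns, alpha - 1 equi-depth
#' breakpoints: the empirical quantiles at i/alpha (linear interpolation
#' between order statistics). Must be fitted on training data only.
#'
#' @param coefficient_rows numeric matrix of training coefficient rows
#'   (windows x omega), e.g. from \code{\link{mft_sliding}}.
#' @param config a \code{\link{symbolic_config}} with \code{method = "sfa"}.
#' @return An object of class \code{"har_mcb"}: list with \code{breakpoints}
#'   (omega x (alpha - 1) matrix, rows non-decreasing), \code{omega},
#'   \code{alpha}, \code{drop_dc} and a training fingerprint.
#' @export
fit_mcb <- function(coefficient_rows, config) {
  m <- as.matrix(coefficient_rows)
  if (ncol(m) != config$omega)
    stop("config error: coefficient rows have ", ncol(m),
         " columns, expected omega = ", config$omega)
  if (nrow(m) < config$alpha)
    stop("too few training rows: need at least alpha = ", config$alpha)
  probs <- seq_len(config$alpha - 1L) / config$alpha
  bp <- t(apply(m, 2L, stats::quantile, probs = probs, names = FALSE,
                type = 7))
  if (config$alpha == 2L) bp <- matrix(bp, ncol = 1L)
  structure(list(breakpoints = bp, omega = config$omega,
                 alpha = config$alpha, drop_dc = config$drop_dc,
                 fingerprint = sprintf("n=%d;sum=%.10g", nrow(m), sum(m))),
            class = "har_mcb")
}

#' Serialize / deserialize an MCB table to JSON
#' @param mcb a \code{"har_mcb"} object.
#' @param path JSON file path.
#' @return \code{path} (write) or the \code{"har_mcb"} object (read).
#' @export
write_mcb <- function(mcb, path) {
  jsonlite::write_json(
    list(omega = mcb$omega, alpha = mcb$alpha, drop_dc = mcb$drop_dc,
         fingerprint = mcb$fingerprint,
         breakpoints = apply(mcb$breakpoints, 1L, identity,
                             simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mcb
#' @export
read_mcb <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bp <- if (is.matrix(x$breakpoints)) x$breakpoints
        else matrix(unlist(x$breakpoints), nrow = x$omega, byrow = TRUE)
  dimnames(bp) <- NULL
  structure(list(breakpoints = bp, omega = x$omega, alpha = x$alpha,
                 drop_dc = x$drop_dc, fingerprint = x$fingerprint),
            class = "har_mcb")
}

# Encode a matrix of coefficient rows against a fitted MCB table,
# returning a character vector of words.
encode_sfa_rows <- function(rows, mcb) {
  rows <- as.matrix(rows)
  idx <- matrix(0L, nrow = nrow(rows), ncol = ncol(rows))
  for (j in seq_len(ncol(rows)))
    idx[, j] <- findInterval(rows[, j], mcb$breakpoints[j, ])
  apply(idx, 1L, function(k) paste(letters[k + 1L], collapse = ""))
}

#' SFA word of a window
#'
#' Computes the window's leading DFT coefficients and quantizes each one
#' with the per-coefficient breakpoints of a fitted MCB table, using the
#' same tie rule as SAX (value equal to a breakpoint takes the higher
#' letter).
#'
#' @param window numeric vector.
#' @param mcb fitted \code{"har_mcb"} from \code{\link{fit_mcb}}.
#' @param config a \code{\link{symbolic_config}}; omega/alpha must match
#'   the table.
#' @return Single character string of omega letters.
#' @export
sfa_word <- function(window, mcb, config) {
  if (mcb$omega != config$omega || mcb$alpha != config$alpha)
    stop("config error: MCB table fitted with different omega/alpha")
  co <- dft_coefficients(window, config$omega, drop_dc = mcb$drop_dc)
  encode_sfa_rows(matrix(co, nrow = 1L), mcb)[[1L]]
}
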