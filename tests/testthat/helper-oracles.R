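# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# naive O(n^2) DFT, coefficient k (0-based), unscaled
naive_dft_coef <- function(x, k) {
  n <- length(x)
  j <- 0:(n - 1)
  sum(x * exp(-2i * pi * j * k / n))
}

# interleaved (re, im) leading coefficients, scaled by 1/n
naive_dft_vector <- function(x, omega, drop_dc = TRUE) {
  start <- if (drop_dc) 1L else 0L
  ks <- start:(start + omega / 2 - 1)
  co <- vapply(ks, function(k) naive_dft_coef(x, k) / length(x),
               complex(1))
  out <- numeric(omega)
  out[seq(1, omega, by = 2)] <- Re(co)
  out[seq(2, omega, by = 2)] <- Im(co)
  out
}

# entropy of a dense probability vector, 0 ln 0 = 0
dense_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# unnormalized Jensen-Shannon divergence of dense probability vectors
dense_js <- function(p, q) {
  dense_entropy((p + q) / 2) - dense_entropy(p) / 2 - dense_entropy(q) / 2
}

# dense vector -> word_distribution with synthetic word names
dense_to_dist <- function(p) {
  names(p) <- sprintf("w%03d", seq_along(p))
  word_distribution(p[p > 0], length(p))
}

# fractional-frame PAA by per-sample mass enumeration
enum_paa <- function(x, omega) {
  n <- length(x)
  width <- n / omega
  acc <- numeric(omega)
  for (i in seq_len(n)) {            # sample i covers [i-1, i)
    for (j in seq_len(omega)) {      # frame j covers [(j-1)w, jw)
      ov <- min(i, j * width) - max(i - 1, (j - 1) * width)
      if (ov > 0) acc[j] <- acc[j] + ov * x[i]
    }
  }
  acc / width
}

# exhaustive sliding-window start offsets (1-based), discarding partials
enum_window_starts <- function(n, w, step) {
  starts <- integer(0)
  a <- 1
  while (a + w - 1 <= n) {
    starts <- c(starts, a)
    a <- a + step
  }
  starts
}

# full-ranking k-NN vote: majority among top k, ties to the most similar
# neighbour belonging to a tied class
brute_vote <- function(train, labels, query, k) {
  sims <- apply(train, 1, function(u)
    sum(u * query) / sqrt(sum(u^2) * sum(query^2)))
  ord <- order(sims, decreasing = TRUE)
  top <- ord[seq_len(k)]
  tab <- table(labels[top])
  tied <- names(tab)[tab == max(tab)]
  if (length(tied) == 1) return(tied)
  for (i in top) if (labels[i] %in% tied) return(labels[i])
}

# small random 3-axis recording
random_recording <- function(subject = "S1", activity = "walk", n = 300,
                             rate = 50) {
  har_recording(subject, activity, rate,
                list(acc_x = rnorm(n), acc_y = rnorm(n), acc_z = rnorm(n)))
}
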