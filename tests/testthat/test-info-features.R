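mk_hist <- function(counts, omega = 1L, eta = NULL,
                    label = NULL, subject = NULL) {
  # minimal word_histogram for feature tests
  if (is.null(eta)) stop("give eta")
  structure(list(counts = counts, total = sum(counts),
                 omega = omega, alpha = NA_integer_, eta = eta,
                 label = label, subject = subject),
            class = "word_histogram")
}

test_that("histogram normalization keeps zeros and sums to one", {
  h <- mk_hist(c(aa = 3L, ab = 1L), eta = 4)
  P <- normalize_histogram(h)
  expect_equal(unname(P$probs), c(0.75, 0.25))
  expect_equal(sum(P$probs), 1)
  expect_equal(P$eta, 4)
  expect_error(normalize_histogram(mk_hist(integer(0), eta = 4)),
               "empty histogram")
  u <- normalize_histogram(mk_hist(c(aa = 2L, ab = 2L, ba = 2L, bb = 2L),
                                   eta = 4))
  expect_equal(unname(u$probs), rep(0.25, 4))
})

test_that("Shannon entropy hits its stated extremes and values", {
  eta <- 4
  delta <- word_distribution(c(aa = 1), eta)
  expect_equal(shannon_entropy(delta)[["raw"]], 0)
  expect_equal(shannon_entropy(uniform_distribution(eta))[["raw"]],
               log(eta))
  expect_equal(shannon_entropy(uniform_distribution(eta))[["normalized"]],
               1)
  P <- word_distribution(c(aa = 0.75, ab = 0.25), eta)
  expect_equal(shannon_entropy(P)[["raw"]], 0.56233, tolerance = 1e-4)
  expect_equal(shannon_entropy(P)[["normalized"]], 0.40564,
               tolerance = 1e-4)
  # sparse storage agrees with a dense evaluation
  expect_equal(shannon_entropy(P)[["raw"]],
               dense_entropy(c(0.75, 0.25, 0, 0)))
})

test_that("Q0 is the reciprocal of the delta-vs-uniform divergence", {
  expect_equal(q0_constant(4), 2.6288, tolerance = 1e-3)
  expect_equal(q0_constant(2), 4.6347, tolerance = 1e-3)
  for (eta in c(2:20, 50, 137, 500, 1000)) {
    delta <- c(1, rep(0, eta - 1))
    unif <- rep(1 / eta, eta)
    expect_equal(q0_constant(eta) * dense_js(delta, unif), 1,
                 tolerance = 1e-10)
  }
})

test_that("Jensen-Shannon divergence is normalized, symmetric and exact", {
  eta <- 16
  unif <- uniform_distribution(eta)
  delta <- word_distribution(c(w001 = 1), eta)
  expect_equal(js_divergence(delta, unif), 1, tolerance = 1e-12)
  expect_equal(js_divergence(unif, delta), 1, tolerance = 1e-12)
  set.seed(30)
  for (i in 1:30) {
    p <- rgamma(eta, 1); p <- p / sum(p)
    q <- rgamma(eta, 1); q <- q / sum(q)
    P <- dense_to_dist(p); Q <- dense_to_dist(q)
    expect_equal(js_divergence(P, Q),
                 q0_constant(eta) * dense_js(p, q), tolerance = 1e-12)
    expect_equal(js_divergence(P, Q), js_divergence(Q, P),
                 tolerance = 1e-14)
    expect_gte(js_divergence(P, Q), 0)
    expect_lte(js_divergence(P, Q), 1)
    expect_equal(js_divergence(P, P), 0, tolerance = 1e-14)
    expect_equal(js_divergence(P, unif),
                 q0_constant(eta) * dense_js(p, rep(1 / eta, eta)),
                 tolerance = 1e-12)
  }
  expect_error(js_divergence(P, uniform_distribution(8)),
               "different word spaces")
})

test_that("divergence separates distinct distributions", {
  set.seed(31)
  eta <- 9
  for (i in 1:20) {
    p <- rgamma(eta, 1); p <- p / sum(p)
    q <- rgamma(eta, 1); q <- q / sum(q)
    expect_gt(js_divergence(dense_to_dist(p), dense_to_dist(q)), 1e-10)
  }
})

test_that("statistical complexity vanishes at both entropy extremes", {
  eta <- 4
  unif <- uniform_distribution(eta)
  delta <- word_distribution(c(aa = 1), eta)
  expect_equal(statistical_complexity(delta, unif), 0)
  expect_equal(statistical_complexity(unif, unif), 0, tolerance = 1e-14)
  P <- word_distribution(c(aa = 0.75, ab = 0.25), eta)
  oracle <- q0_constant(eta) *
    dense_js(c(0.75, 0.25, 0, 0), rep(0.25, 4)) *
    (dense_entropy(c(0.75, 0.25)) / log(eta))
  expect_equal(statistical_complexity(P, unif), oracle, tolerance = 1e-12)
  # raw-entropy variant scales by ln(eta)
  expect_equal(statistical_complexity(P, unif, normalized = FALSE),
               oracle * log(eta), tolerance = 1e-12)
})

test_that("reference histograms pool word counts per class", {
  h1 <- mk_hist(c(aa = 2L, ab = 2L), eta = 4, label = "A")
  h2 <- mk_hist(c(aa = 1L, ab = 1L), eta = 4, label = "A")
  refs <- build_references(list(h1, h2))
  expect_equal(refs$class_refs$A$probs, c(aa = 0.5, ab = 0.5))
  hA <- mk_hist(c(aa = 1L), eta = 4, label = "A")
  hB <- mk_hist(c(ab = 1L), eta = 4, label = "B")
  refs2 <- build_references(list(hA, hB))
  expect_equal(refs2$classes, c("A", "B"))
  expect_equal(refs2$class_refs$A$probs, c(aa = 1))
  expect_equal(refs2$class_refs$B$probs, c(ab = 1))
  expect_true(refs2$uniform$uniform)
  expect_error(build_references(list(mk_hist(c(aa = 1L), eta = 4))),
               "without a class label")
})

test_that("random pseudo-class splits converge to the pooled reference", {
  set.seed(32)
  eta <- 8
  base <- c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05, 0, 0)
  words <- sprintf("w%d", 1:eta)
  hists <- lapply(1:1000, function(i) {
    draw <- table(factor(sample(words, 50, TRUE, prob = base),
                         levels = words))
    cnt <- c(draw)[c(draw) > 0]
    mk_hist(cnt, eta = eta, label = sample(c("X", "Y"), 1))
  })
  refs <- build_references(hists)
  for (cl in c("X", "Y")) {
    p <- refs$class_refs[[cl]]$probs[words[base > 0]]
    expect_equal(unname(p), base[base > 0], tolerance = 0.05)
  }
})

test_that("feature vectors have length 2K+3 in the documented order", {
  set.seed(33)
  eta <- 16
  mk_class_hists <- function(labels) {
    lapply(labels, function(cl) {
      cnt <- table(sprintf("w%03d", sample(1:eta, 30, TRUE)))
      mk_hist(stats::setNames(as.integer(cnt), names(cnt)), eta = eta,
              label = cl)
    })
  }
  refs6 <- build_references(mk_class_hists(rep(c("a1", "a2", "a3", "a4",
                                                 "a5", "a6"), 2)))
  P <- normalize_histogram(mk_class_hists("a1")[[1]])
  fv <- feature_vector(P, refs6)
  expect_length(fv, 15)
  expect_equal(names(fv)[1:2], c("Hs", "Q_ref"))
  refs2 <- build_references(mk_class_hists(c("A", "B")))
  fv2 <- feature_vector(P, refs2)
  expect_length(fv2, 7)
  expect_equal(names(fv2),
               c("Hs", "Q_ref", "Q_A", "Q_B", "C_ref", "C_A", "C_B"))
  expect_true(all(fv2 >= 0 & fv2 <= 1))
})

test_that("a distribution equal to its class reference scores zero there", {
  hA <- mk_hist(c(aa = 3L, ab = 1L), eta = 4, label = "A")
  hB <- mk_hist(c(ba = 2L, bb = 2L), eta = 4, label = "B")
  refs <- build_references(list(hA, hB))
  fv <- feature_vector(normalize_histogram(hA), refs)
  expect_equal(unname(fv["Q_A"]), 0, tolerance = 1e-12)
  expect_equal(unname(fv["C_A"]), 0, tolerance = 1e-12)
  expect_lt(fv["Q_A"], fv["Q_B"])
  expect_lt(fv["C_A"], fv["C_B"])
})
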