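test_that("PAA reduces by frame means, with fractional weighting", {
  expect_equal(paa(rep(3.5, 12), 4), rep(3.5, 4))
  expect_equal(paa(c(1, 2, 3, 4, 5, 6), 2), c(2, 5))
  set.seed(10)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    omega <- sample(2:min(n, 9), 1)
    x <- rnorm(n)
    expect_equal(paa(x, omega), enum_paa(x, omega), tolerance = 1e-12)
  }
  expect_error(paa(1:3, 4), "omega exceeds")
})

test_that("Gaussian breakpoints are equiprobable normal quantiles", {
  expect_equal(gaussian_breakpoints(2), 0)
  expect_equal(gaussian_breakpoints(4), c(-0.6745, 0, 0.6745),
               tolerance = 1e-4)
  expect_equal(gaussian_breakpoints(3), c(-0.4307, 0.4307),
               tolerance = 1e-4)
  for (a in c(5, 7, 10)) {
    bp <- gaussian_breakpoints(a)
    expect_true(all(diff(bp) > 0))
    expect_equal(bp, -rev(bp))
  }
  expect_error(gaussian_breakpoints(1), ">= 2")
})

test_that("SAX words follow monotone ramps and the degenerate convention", {
  cfg <- symbolic_config(omega = 4, alpha = 4, method = "sax")
  w <- sax_word(seq(0, 1, length.out = 32), cfg)
  lets <- strsplit(w, "")[[1]]
  expect_equal(lets[1], "a")
  expect_equal(lets[4], "d")
  expect_true(all(diff(match(lets, letters)) >= 0))
  # near-constant window: the letter whose interval contains 0, repeated;
  # ties go to the higher letter, so even alphabets take the upper-middle
  expect_equal(sax_word(rep(2.5, 32), cfg), "cccc")
  cfg3 <- symbolic_config(omega = 4, alpha = 3, method = "sax")
  expect_equal(sax_word(rep(-1, 32), cfg3), "bbbb")
})

test_that("SAX is affine-invariant and complements under negation", {
  cfg <- symbolic_config(omega = 5, alpha = 6, method = "sax")
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(64)
    w <- sax_word(x, cfg)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_identical(sax_word(a * x + b, cfg), w)
    k <- match(strsplit(w, "")[[1]], letters) - 1
    neg <- paste(letters[(cfg$alpha - 1 - k) + 1], collapse = "")
    expect_identical(sax_word(-x, cfg), neg)
  }
})

test_that("reachable SAX words stay inside the alpha^omega word space", {
  cfg <- symbolic_config(omega = 3, alpha = 3, method = "sax")
  set.seed(12)
  words <- replicate(3000, sax_word(rnorm(9), cfg))
  expect_true(all(nchar(words) == 3))
  expect_true(all(strsplit(paste(words, collapse = ""), "")[[1]]
                  %in% c("a", "b", "c")))
  expect_lte(length(unique(words)), 27)
  expect_gt(length(unique(words)), 10)  # dense random input covers widely
})

test_that("DFT coefficients match a naive O(n^2) transform", {
  expect_equal(dft_coefficients(rep(4, 16), 4, drop_dc = TRUE), rep(0, 4))
  co <- dft_coefficients(cos(2 * pi * (0:15) / 16), 2, drop_dc = TRUE)
  expect_equal(co[1], 0.5, tolerance = 1e-9)   # re at coefficient 1
  expect_equal(co[2], 0, tolerance = 1e-9)     # im vanishes for cosine
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(16:64, 1))
    for (dc in c(TRUE, FALSE))
      expect_equal(dft_coefficients(x, 6, drop_dc = dc),
                   naive_dft_vector(x, 6, drop_dc = dc),
                   tolerance = 1e-10)
  }
  expect_error(dft_coefficients(rnorm(16), 3), "even")
})

test_that("momentary Fourier transform equals per-window DFT", {
  set.seed(14)
  x <- rnorm(500)
  m <- mft_sliding(x, 64, 6)
  expect_equal(nrow(m), 500 - 64 + 1)
  expect_equal(m[1, ], dft_coefficients(x[1:64], 6), tolerance = 1e-12)
  err <- max(abs(m - t(vapply(1:(500 - 63), function(a)
    naive_dft_vector(x[a:(a + 63)], 6), numeric(6)))))
  expect_lt(err, 1e-8)
  const <- mft_sliding(rep(2, 100), 32, 4)
  expect_true(all(abs(sweep(const, 2, const[1, ])) < 1e-12))
  # subsampled output rows match the corresponding full rows
  sub <- mft_sliding(x, 64, 6, step = 50)
  expect_equal(sub, m[seq(1, nrow(m), by = 50), ], tolerance = 1e-12)
})

test_that("MCB learns equi-depth breakpoints by linear interpolation", {
  cfg <- symbolic_config(omega = 2, alpha = 4, method = "sfa")
  rows <- cbind(1:100, rnorm(100))
  mcb <- fit_mcb(rows, cfg)
  expect_equal(mcb$breakpoints[1, ], c(25.75, 50.5, 75.25))
  expect_equal(mcb$breakpoints[1, ],
               unname(quantile(1:100, c(0.25, 0.5, 0.75))))
  expect_true(all(apply(mcb$breakpoints, 1, function(r)
    all(diff(r) >= 0))))
  # constant column: all breakpoints coincide
  mcb2 <- fit_mcb(cbind(rep(7, 50), rnorm(50)), cfg)
  expect_true(all(mcb2$breakpoints[1, ] == 7))
  expect_error(fit_mcb(rows[1:3, ], cfg), "too few")
})

test_that("MCB letters are close to equifrequent on held-out data", {
  set.seed(15)
  cfg <- symbolic_config(omega = 2, alpha = 4, method = "sfa")
  train <- matrix(rnorm(2 * 10000), ncol = 2)
  mcb <- fit_mcb(train, cfg)
  held <- matrix(rnorm(2 * 10000), ncol = 2)
  words <- harsr:::encode_sfa_rows(held, mcb)
  first_letter <- substr(words, 1, 1)
  freq <- table(first_letter) / length(first_letter)
  expect_true(all(abs(freq - 0.25) < 0.05))
})

test_that("SFA words are deterministic and respect quantile positions", {
  set.seed(16)
  cfg <- symbolic_config(omega = 4, alpha = 4, method = "sfa")
  train <- t(replicate(200, dft_coefficients(rnorm(32), 4)))
  mcb <- fit_mcb(train, cfg)
  x <- rnorm(32)
  expect_identical(sfa_word(x, mcb, cfg), sfa_word(x, mcb, cfg))
  # coefficients below every first breakpoint give the all-'a' word
  lo <- mcb$breakpoints[, 1] - 1
  expect_identical(harsr:::encode_sfa_rows(matrix(lo, nrow = 1), mcb),
                   "aaaa")
  # re-encoding a training row is consistent with its quantile positions
  co <- train[17, ]
  word <- strsplit(harsr:::encode_sfa_rows(matrix(co, nrow = 1), mcb),
                   "")[[1]]
  for (j in 1:4) {
    expected <- sum(mcb$breakpoints[j, ] <= co[j])  # tie to higher letter
    expect_equal(match(word[j], letters) - 1, expected)
  }
  cfg_bad <- symbolic_config(omega = 4, alpha = 5, method = "sfa")
  expect_error(sfa_word(x, mcb, cfg_bad), "config error")
})

test_that("MCB table survives a JSON round trip", {
  set.seed(17)
  cfg <- symbolic_config(omega = 4, alpha = 5, method = "sfa")
  mcb <- fit_mcb(matrix(rnorm(200), ncol = 4), cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_mcb(mcb, f)
  back <- read_mcb(f)
  expect_equal(back$breakpoints, mcb$breakpoints, ignore_attr = TRUE)
  expect_equal(back$omega, mcb$omega)
  expect_equal(back$fingerprint, mcb$fingerprint)
})

test_that("SAX transform time grows roughly linearly in series length", {
  cfg <- symbolic_config()
  x1 <- rnorm(20000); x2 <- rnorm(40000)
  t1 <- system.time(bop_histogram(x1, 128, 1, cfg))[["elapsed"]]
  t2 <- system.time(bop_histogram(x2, 128, 1, cfg))[["elapsed"]]
  expect_lt(t2, 3 * max(t1, 0.05))  # smoke check only
})
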