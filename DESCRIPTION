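Package: harsr
Title: Human Activity Recognition from Inertial Sensors via Symbolic
    Representation and Information-Theory Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lightweight classification of wearable inertial-sensor time
    series. Multi-axis accelerometer/gyroscope/magnetometer recordings are
    fused to a univariate series (concatenation, magnitude or PCA),
    discretized into symbolic words with SAX (piecewise aggregate
    approximation plus Gaussian breakpoints) or SFA (sliding discrete
    Fourier transform plus multiple coefficient binning), summarized as
    bag-of-patterns word histograms, and reduced to a small
    information-theory feature vector: normalized Shannon entropy,
    Jensen-Shannon divergences and statistical complexities against the
    uniform histogram and per-class reference histograms. Classification
    uses cosine-similarity k-nearest neighbours, evaluated with
    leave-one-subject-out cross-validation. Includes a seeded generator of
    multi-subject, multi-class synthetic inertial recordings for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
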