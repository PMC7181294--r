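---
title: "Symbolic representation and information-theory features for activity recognition"
author: "harsr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic representation and information-theory features for activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harsr)
```

## The problem and the model

Body-worn inertial sensors (accelerometer, gyroscope, magnetometer) record
multi-axis time series whose short-term structure differs between physical
activities: walking produces a roughly periodic signal near 1--2 Hz,
running faster and larger oscillations, sitting an almost constant signal.
`harsr` classifies such recordings with a deliberately small feature set
built from a *symbolic* representation of the signal, so that the final
model is a k-nearest-neighbour classifier over vectors of a dozen or so
numbers rather than over thousands of raw samples.

The pipeline behind `harsr()` has five stages:

1. **Fusion.** A recording's channels are collapsed to one univariate
   series. The default simply concatenates the channels (no information is
   lost, no reduction happens); alternatives are the per-sample Euclidean
   magnitude of each x/y/z triplet and projection onto the first principal
   component, both genuine reductions. The PCA loading is always learned
   on training data only and reused at test time, because the evaluation
   protocol (below) forbids test information in training.
2. **Sliding windows.** Windows of $w$ samples are slid over the fused
   series with a configurable hop; with hop 1 a series of length $n$
   yields $n - w + 1$ windows. Trailing partial windows are discarded,
   never padded. Defaults: $w = 128$ samples, 50 % overlap (hop 64).
3. **Symbolic encoding.** Each window becomes a word of length
   $\omega$ over an alphabet of $\alpha$ letters, by either
   * **SAX** --- z-normalize the window, reduce it to $\omega$ frame means
     (piecewise aggregate approximation, PAA), and map each mean to a
     letter using the standard-normal quantile breakpoints at
     $i/\alpha$; or
   * **SFA** --- take the window's leading $\omega/2$ complex DFT
     coefficients and quantize each real/imaginary part with per-column
     equi-depth breakpoints learned from training windows (multiple
     coefficient binning, MCB).
4. **Bag of patterns.** Word frequencies are tallied into a histogram
   over the word space of $\eta = \alpha^\omega$ possible words
   ($46{,}656$ at the default $\omega = \alpha = 6$).
5. **Information-theory features.** The histogram, normalized to a
   distribution $P$, is summarized by entropy, divergence and complexity
   against a set of reference distributions (next section). Cosine
   similarity between feature vectors drives a k-NN vote ($k = 3$ by
   default).

## Entropy, divergence, complexity

For a distribution $P = (p_1, \dots, p_\eta)$ over the word space, the
Shannon entropy $H[P] = -\sum_i p_i \ln p_i$ (with $0 \ln 0 = 0$) ranges
from $0$ for a degenerate distribution to $\ln \eta$ for the uniform
distribution $P_e$; the normalized entropy is
$H_s = H[P] / \ln \eta \in [0, 1]$.

Two different distributions can share an entropy value, so a second
coordinate measures *imbalance*: the Jensen--Shannon divergence

$$Q_J[P, Q] \;=\; Q_0 \left( H\!\left[\tfrac{P+Q}{2}\right]
  - \tfrac{H[P]}{2} - \tfrac{H[Q]}{2} \right),$$

with raw entropies inside the bracket and the constant $Q_0$ carrying the
normalization. $Q_0$ is defined so that the *maximal* divergence --- a
degenerate $\delta$ against the uniform $P_e$, the totally deterministic
extreme --- equals exactly 1:

$$Q_0 \;=\; \frac{1}{JS(\delta, P_e)}
 \;=\; -2\left[\frac{\eta+1}{\eta}\ln(\eta+1) - 2\ln(2\eta)
 + \ln\eta\right]^{-1}.$$

This is the Rosso-style normalization from the statistical-complexity
literature; the factor 2 on the $\ln(2\eta)$ term is required for the
defining property $Q_J(\delta, P_e) = 1$ to hold, and the package tests
verify $Q_0 \cdot JS(\delta, P_e) = 1$ for every $\eta$ from 2 to 1000.

The **statistical complexity** couples the two:
$C[P] = Q_J[P, \mathrm{ref}] \cdot H_s[P]$. It vanishes at both extremes
--- perfectly ordered data ($H_s = 0$) and uncorrelated noise
($Q_J[P, P_e] = 0$) --- and peaks in between, which is exactly where
activity signals live. We use the *normalized* entropy in the product so
that $C \in [0, 1]$; a `normalized = FALSE` switch in
`statistical_complexity()` exposes the raw-entropy variant for
sensitivity analysis.

**Per-class references.** Entropy alone cannot separate more than a few
classes, so divergence and complexity are also computed against one
*reference histogram per class*: the word-wise sum of all training
histograms of that class, normalized. With $K$ classes the feature vector
is

$$[\,H_s,\; Q_{ref},\; Q_{c_1},\dots,Q_{c_K},\;
   C_{ref},\; C_{c_1},\dots,C_{c_K}\,],$$

of length $2K + 3$ --- 15 features for a six-class problem. A histogram
drawn from class $A$ tends to diverge least from $A$'s reference, which
is the signal the k-NN exploits. References are rebuilt inside every
training fold and never see test subjects.

Histograms and references are stored sparsely but all entropy and
divergence computations range over the full $\eta$-word space; the
uniform reference is handled analytically, so even
$\eta = 16{,}777{,}216$ costs nothing.

## Numerical conventions

These conventions are deliberate and frozen; changing any of them changes
words, histograms and features.

* **Breakpoint tie rule.** A value $v$ gets letter $k$ iff
  $b_{k-1} \le v < b_k$ ($b_0 = -\infty$, $b_\alpha = +\infty$): a value
  equal to a breakpoint takes the *higher* letter. The same rule applies
  to SAX breakpoints and to MCB lookups (binary search via
  `findInterval`).
* **Degenerate windows.** A window with standard deviation below
  `znorm_epsilon` ($10^{-8}$) is not z-normalized (that would divide by
  ~0); it emits, $\omega$ times, the letter whose interval contains 0.
  Under the tie rule this is the upper-middle letter for even $\alpha$
  (e.g. `c` for $\alpha = 4$) and the middle letter for odd $\alpha$.
  Stationary activities produce many such windows, and mapping them all
  to one deterministic word is what makes a stationary class's histogram
  nearly degenerate (low entropy), which the features pick up.
* **Fractional PAA.** When $\omega \nmid n$, each frame spans $n/\omega$
  samples and a straddling sample contributes to both frames in
  proportion to its overlap. Every sample's mass is kept.
* **MCB quantiles.** Equi-depth breakpoints are the empirical quantiles
  at $i/\alpha$ with linear interpolation between order statistics
  (R's default type-7 rule), a named rule so tables are reproducible.
* **SFA and z-scoring.** SAX z-normalizes each window; SFA does not.
  Dropping the DC coefficient (the default) makes SFA mean-invariant, and
  the data-learned MCB table absorbs scale. This also keeps the sliding
  (momentary) Fourier transform exact: the DFT is computed once for the
  first window and updated incrementally with
  $X_k \leftarrow e^{2\pi i k/w}(X_k - x_{\text{out}} + x_{\text{in}})$,
  which agrees with per-window DFTs to better than $10^{-8}$ over
  hundreds of updates.
* **Eigenvector sign.** The PCA loading's largest-magnitude coefficient
  is made positive, a convention needed for reproducible projections.
* **Word-space guard.** `wordspace_info()` refuses $\alpha^\omega >
  10^8$ without `force = TRUE`; cost grows with the word space.

## Evaluation protocol

`loso()` implements leave-one-subject-out cross-validation: each fold
holds out *all* recordings of one subject and refits everything
data-dependent --- PCA loading, MCB table, reference histograms, training
feature vectors --- on the remaining subjects. Subject-level splitting is
the honest protocol for wearable data: plain k-fold lets a model memorize
a person's idiosyncrasies and overstates accuracy. Reported metrics are
pooled accuracy and macro-averaged F1 (macro is our recorded convention:
equal class weight, appropriate for the balanced designs the generator
produces), plus a pooled confusion matrix whose row sums equal the
per-class test counts by construction.

## What the synthetic generator does and does not emulate

`simulate_har_dataset()` produces 3-axis accelerometer-like recordings:
gravity offset, plus (for periodic classes) a sum of subject-modulated
sinusoidal harmonics distributed across axes by a fixed orientation
vector, plus independent Gaussian noise. Subject effects --- a lognormal
amplitude factor, an additive frequency jitter and a random phase --- are
drawn from an RNG keyed by (seed, subject id), so datasets are
deterministic and adding subjects never changes existing subjects' data.

Three named scenarios fix the study conditions (6 subjects, 4 classes,
4 recordings per subject and class, 10 s at 50 Hz):

* `separable` --- one stationary class and three periodic classes with
  well-separated fundamentals (1.0, 2.0, 3.2 Hz), mild subject effects
  (10 % amplitude spread, 0.05 Hz jitter), noise sd 0.05 g. The pipeline
  should classify this nearly perfectly under LOSO (macro F1 ≥ 0.90).
* `chance` --- four classes with *identical* parameters; labels carry no
  information and accuracy should sit near $1/K = 0.25$.
* `hard` --- fundamentals 0.2 Hz apart with subject jitter of comparable
  size (0.25 Hz), strong amplitude spread and triple the noise;
  performance lands between the other two.

These sizes were chosen as the smallest design that exercises every
pipeline stage with non-trivial fold counts; a full LOSO run takes a few
seconds. What the generator does **not** emulate: gait biomechanics
(impact transients, asymmetry), sensor drift and saturation,
heavy-tailed or correlated noise, magnetometer/heading physics, or
transitions within a recording. Passing the synthetic acceptance checks
therefore demonstrates that the implementation is correct and that the
feature set separates spectrally distinct activities under subject-level
validation --- not that any particular accuracy will be reached on real
devices.

## Design choices that were genuinely open

* **One histogram per recording.** Features are extracted per labeled
  recording (the classification unit); fixed-duration super-segments can
  be had by splitting recordings upstream.
* **PCA scope.** The loading is fitted globally on the training fold
  (not per segment or per subject), the choice most consistent with
  subject-independent deployment.
* **Multi-sensor magnitude.** With several sensors, magnitude is taken
  per sensor and the magnitude series are concatenated (deterministic
  sensor order), preserving per-sensor structure while staying
  univariate.
* **Window length is in samples.** The default 128 matches the standard
  operating point; callers working in seconds convert with their
  sampling rate.
* **k-NN vote.** Majority among the $k = 3$ nearest by cosine
  similarity; ties go to the most similar neighbour among the tied
  classes. Nearest-neighbour assignment is the $k = 1$ special case.

## Known limitations

* Concatenation fusion slides windows across channel boundaries; the few
  boundary windows mix channels. All classes are affected equally and
  empirically this does not hurt, but it is a property of the
  concatenation design, not of the signal.
* SFA's MCB table is supervised by the training fold; with few, similar
  subjects it can overfit them, which is visible as a SAX/SFA gap under
  LOSO.
* Feature vectors live in $[0,1]$ and are used raw (no standardization);
  with cosine similarity this weights features by magnitude, which is
  intended but worth knowing when adding features.
* The alphabet is capped at 26 letters (single-character words).
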