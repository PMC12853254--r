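---
title: "Temporal dynamics of phoneme encoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal dynamics of phoneme encoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

When listeners hear continuous speech, the articulatory properties of each
phoneme — its *phonetic features* (voicing, manner and place of
articulation, vowel roundness, front-backness) — can be decoded from
scalp EEG for several hundred milliseconds after the phoneme was heard,
far longer than the phoneme itself lasts. Temporal-generalization (TG)
analysis shows that this long-lived trace is not a single sustained
activation: the information is handed between successive neural
configurations roughly every 80 ms, about the duration of one phoneme.
This *dynamic coding* lets the brain keep the last few phonemes
simultaneously decodable while preserving their order, which is what a
lexical-access mechanism needs. Clinical questions follow naturally:
in post-stroke aphasia, is phonetic information encoded more weakly,
for a shorter time, or passed between configurations at a different
speed? And does encoding duration adapt to lexical uncertainty — the
Shannon entropy of the cohort of words compatible with the phonemes
heard so far — as it does in healthy listeners?

phonodyn implements this entire analysis pipeline, and pairs it with a
synthetic-EEG generator in which the ground truth (encoding duration,
dwell time per configuration, group differences, entropy coupling) is
known and configurable, so every stage can be verified quantitatively
without access to any clinical recording.

# The synthetic forward model

`simulate_subject()` builds continuous 64-channel EEG at 128 Hz as

\[
X(t) \;=\; \mathrm{snr}\sum_{i}\sum_{f \in F_i}\sum_{k}
  g\!\left(t-t_i\right)\, e_k\!\left(t - t_i - r_0\right)\, p_{f,k}
  \;+\; N(t),
\]

where \(t_i\) are phoneme onsets, \(F_i\) the features active on
phoneme \(i\), \(p_{f,k}\) unit-norm spatial patterns, \(g\) a per-group
gain step function of time since phoneme onset, and \(N\) an
equal-power pink (1/f) plus white noise mixture, iid across channels
with unit standard deviation — so `snr` is response amplitude divided
by noise standard deviation.

Key choices, and why:

* **Dwell and handoff.** Each feature owns
  \(K=\lceil D/\tau \rceil\) patterns (`encode_duration_s` \(D\),
  `dwell_tau_s` \(\tau\)); pattern \(k\) is active during phase
  \([k\tau, (k{+}1)\tau)\) of the encoding span. Envelopes \(e_k\) are
  plateaus with raised-cosine crossfades of width
  \(\rho=\min(\tau/2, 40\,\mathrm{ms})\) at the handoffs, complementary
  so that total signal power is constant through a handoff. Early
  designs with per-interval half-sine envelopes put notches of zero
  signal at every handoff, gouging chance-level gaps into the TG
  diagonal that no real recording shows; the plateau-crossfade scheme
  keeps the diagonal smooth while leaving the dwell time — the width of
  the generalization peak — exactly \(\tau\).
* **Distinct ensembles.** The \(K\) patterns of a feature are mutually
  orthogonalized, not merely consecutive-orthogonal. Random unit
  vectors in 64 dimensions overlap by \(\approx 0.12\) on average, and
  that incidental overlap between, say, patterns 1 and 3 produced
  spurious long-lag generalization that widened the recovered dwell on
  some seeds. Handing off to a genuinely fresh population is also the
  cleaner reading of the hypothesis being modelled.
* **Entropy coupling.** `entropy_duration_bonus_s` spreads the realized
  encoding duration across the entropy range:
  \(D_i = D + \mathrm{bonus}\cdot(q_i - 1/2)\) with \(q_i\) the
  phoneme's entropy quantile. The bonus is therefore the duration
  difference between the most and least predictable phonemes while the
  mean stays \(D\). A purely additive bonus for high-entropy phonemes
  would place the entire high-minus-low difference after
  \(r_0 + D = 0.35\) s, outside the fixed 0.15–0.35 s window in which
  the group-by-entropy interaction is classically tested; the centered
  form places it at the window's upper edge, where it belongs
  physiologically (encoding persists until identity is resolved).
  A named list gives per-group bonuses, which is how a group lacking
  the adaptive mechanism is simulated.
* **Stimulus structure.** Word sequences are drawn from a generated
  pronunciation lexicon with Zipf token frequencies and heavy
  word-onset sharing (`prefix_reuse`); phoneme durations are log-normal
  with median 70 ms clipped to [29, 359] ms, matching natural narrative
  speech. Prefix sharing is what gives the cohort model graded
  uncertainty. Be aware that token-frequency concentration induces
  phoneme-label autocorrelation between neighbouring phonemes (the same
  frequent words recur), which genuinely widens measured generalization
  and extends decodable time — as co-articulation does in real speech.
  Recovery analyses that target the *injected* parameters therefore use
  a flatter, larger lexicon (`lexicon_zipf = 0.5`,
  `n_lexicon_words = 500`) to keep that autocorrelation below ~0.1.
* **Seeds.** One master seed; per-subject streams derive via an integer
  mixing function (`derive_seed`), keeping every run reproducible
  bit-for-bit.

The generator does **not** model realistic lead fields, artifacts
(blinks, muscle), inter-subject spatial variability (all subjects share
the ground-truth patterns, as they share the stimulus), or phonotactic
constraints beyond prefix reuse. Passing recovery tests on this data
shows the *analysis machinery* is correct and calibrated; it does not
certify performance on any particular clinical recording.

# Preprocessing

The conditioning chain is fixed and mirrors standard continuous-speech
EEG practice: common-average reference → high-pass (least-squares FIR,
pass 0.5 Hz / stop 0.45 Hz) → low-pass (pass 25 Hz / stop 27.5 Hz) →
downsample to 128 Hz → per-channel z-scoring over the whole recording →
phoneme-locked epochs from −0.2 to 0.6 s (103 samples at 128 Hz), with
no baseline correction and no post-epoch normalization.

The least-squares FIR design is the classical band-integral
(Toeplitz-plus-Hankel) closed form, written here because no installed
package provides it; it reproduces `scipy.signal.firls` coefficients to
a relative 2×10⁻⁶. Filters are applied zero-phase (forward–backward),
protecting epoch latencies; attenuation in dB doubles accordingly. The
canonical order is 2000 taps at a 512 Hz processing rate (a 3.9 s
impulse response); when the pipeline runs directly on 128 Hz synthetic
data it scales the order to 500 so the impulse-response *duration* is
unchanged and desk-scale recordings remain much longer than the filter.
Simulations include a 3 s noise-only lead-in/out so filter edge
transients never touch analysed epochs.

One consequence of high-pass filtering worth knowing about: the filter
subtracts a seconds-scale local average, so every event-locked response
acquires faint sign-inverted "compensation lobes" before and after its
true support. These lobes are themselves (weakly) decodable — above
chance on the TG diagonal, below chance when a decoder trained inside
the response is tested on a lobe. With enough statistical power the
above-chance diagonal extent therefore *exceeds* the injected encoding
duration — the same reason full-scale analyses of real recordings find
decodability windows (~0.5 s) well beyond the nominal 0.3 s encoding
time. The dynamic-coding statistic is made robust to this (below).

# Decoding

One-vs-all logistic regression with an L2 penalty (unit inverse
strength; IRLS with warm starts along the time axis, implemented in
C++/Armadillo), stratified five-fold cross-validation, scored with the
AUC of the receiver-operating curve, which is prevalence-insensitive
with chance at 0.5 — important because phonetic features occur in 5–80%
of phonemes and no resampling or class weighting is applied. A decoder
is trained on the 64-channel vector at each train time and tested at
every test time, giving the 103×103 TG matrix. AUCs are computed per held-out fold and
averaged rather than pooled across folds: per-fold scoring keeps fold
boundaries from mixing decision-score scales and its mean is what the
cross-validation seed-invariance test checks. For trial-subset analyses (entropy tertiles,
word positions) training always uses the full training folds and only
the test sets are split, so all subsets share the same fitted decoders.
Per-sensor topographies feed a sensor's whole epoch timecourse to the
decoder. Fold assignment is stratified by label — at 5 folds and 5%
prevalence, unstratified folds regularly lose a class — and shuffled
under a fixed seed; results are reproducible and identical to serial
execution.

# TG summary metrics

* **Decoding duration** is the above-chance extent of the diagonal,
  assessed with the one-sample sign-flip cluster test across subjects
  and reported as the longest significant window (isolated spurious
  clusters elsewhere do not inflate it).
* **Generalization profile**: rows of the TG matrix in the 0–0.35 s
  train window are shifted so the diagonal sits at lag 0, then averaged
  across rows; lags supported by fewer than half the rows are excluded
  (edge bias).
* **Generalization width** (the dwell-time estimate) is, by default,
  the full width at half maximum of the profile above a robust baseline
  (25th percentile across lags), with sub-lag interpolation of the two
  half-maximum crossings. For a triangular generalization peak — which
  is what a dwell-\(\tau\) code produces — this recovers \(\tau\) for
  any \(\tau\), matching the empirical regime in which measured widths
  (~0.08 s) agree with the dwell time and the median phoneme
  duration. The alternative conventions (z-scored profile
  exceeding z(CI); per-lag CI across train rows) are exposed via
  `se_mode`; the z-rule coincides with half-maximum in the narrow-peak
  regime but collapses for peaks occupying a large fraction of the lag
  axis, and the across-rows CI counts nearly the full peak base
  (~2\(\tau\)), so neither recovers the dwell across the tested range.
* **Dynamic-vs-static delta**: per subject and per train time, the TG
  row mean minus the diagonal value — literally comparing the rows of
  the matrix to its diagonal. A static code generalizes across its
  whole encoding span, so row mean ≈ diagonal; a dynamic code
  generalizes only near the diagonal, so the delta is negative.
  Significance comes from the one-sample sign-flip cluster test. Both
  the averaged columns and the tested domain are restricted to the
  *encoding core* — the contiguous span where the group-mean diagonal
  exceeds chance by half the peak effect — because outside it the delta
  mixes in the filter-compensation lobes (sign-inverted generalization)
  and would brand even a perfectly static code "dynamic". The
  restriction is data-dependent; its false-positive behaviour on pure
  noise is checked by Monte-Carlo in the test suite and stays near the
  nominal level.

# Permutation statistics

Cluster tests follow the standard nonparametric recipe: pointwise t
statistics (one-sample on subject data minus the null value; pooled
two-sample for group comparisons), cluster-forming threshold equal to
the two-tailed Student-t quantile at the test's degrees of freedom,
cluster mass = sum of t within a supra-threshold connected component
(positive and negative components kept separate), null distribution of
the maximum |mass| over 10 000 sign-flips or group exchanges, and
p = (b+1)/(m+1) so p is never zero and the test is exactly valid. The
observed labelling is not forced into the null sample. Adjacency is a
1D chain for timecourses, 4-connectivity on the TG grid (corner-touching
blobs stay distinct; 8-connectivity is available through a custom
adjacency), and a distance-threshold graph (1.4 × median
nearest-neighbour distance, the common cap heuristic) on the montage
for sensor-space tests; the montage itself is a synthetic Fibonacci
hemisphere since no manufacturer cap geometry ships with the package.
The max-t test for sensor topographies and the scalar permutation
t-test use the same (b+1)/(m+1) convention; the group-by-entropy
interaction uses parametric per-lag independent-samples t tests with
Benjamini–Hochberg correction across the 0.15–0.35 s window; behavioral
correlations are per-lag Pearson tests, deliberately uncorrected and
labelled exploratory.

Sampled cluster p-values agree with exhaustive enumeration (all 2⁸ sign
patterns; all C(10,5) group splits) within 0.02 in the test suite, and
each cluster test's family-wise error over 500 null simulations lies in
the nominal 3–7% band.

# Problem sizes and numerical choices

Verification runs use desk-scale conditions chosen once: 6 subjects per
group, 80–150 word tokens (≈300–560 phonemes) per subject, 1–6 decoded
features, SNR 2, 128 Hz generation. Width and duration recovery use the
6-feature, 150-word, flat-lexicon configuration (feature averaging
dilutes residual label autocorrelation, as averaging 18 features does at
full scale); discrimination and group-difference checks use 1–2
features at 80–100 words, where their effects are already decisive.
IRLS stops at 30 iterations or an infinity-norm step below 10⁻⁶; AUC
uses midranks for ties; epoch onset rounding is to the nearest sample
(≤3.9 ms latency error at 128 Hz). Degenerate inputs fail loudly and
early: flat channels, single-class folds, all-equal entropy
distributions, upsampling requests, windows outside the matrix.

# Known limitations

The generator shares spatial patterns across subjects and omits
artifacts and realistic head geometry, so between-subject variance is
optimistic. The entropy mechanism is injected at the level of encoding
duration only; real interactions may also modulate gain. Above-chance
decodability beyond the injected encoding span (stimulus
autocorrelation, filter lobes) is a property of the measurement chain,
not a bug, and grows with statistical power; duration-recovery claims
are therefore calibrated at the problem sizes stated above. Forced
alignment, grapheme-to-phoneme conversion, eye-artifact removal and
source-space analyses are out of scope.
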