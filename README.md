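# phonodyn

Temporal-generalization decoding of phonetic features from EEG during
continuous speech, with a fully verifiable synthetic ground truth.

## What this package is for

When people listen to natural speech, the phonetic features of each
phoneme (voicing, manner, place, roundness, front-backness) are
decodable from EEG for ~0.3–0.5 s — far longer than the ~0.07 s phoneme
itself — and the information is handed between successive neural
configurations about every 0.08 s ("dynamic coding"). Quantifying this
requires a long chain of machinery: phoneme-level annotation with
cohort-entropy conditions, careful EEG conditioning, temporal
generalization (TG) decoding, summary metrics, and cluster-based
permutation inference. phonodyn implements the whole chain for R users
(e.g., for comparing clinical groups such as post-stroke aphasia
against controls), and adds a synthetic-EEG generator whose ground
truth — encoding duration *D*, dwell time *τ*, group gain profiles,
entropy coupling — is known and configurable, so every stage can be
validated end to end without any real recording.

The core quantities, in the field's standard notation:

* **TG matrix**: train a one-vs-all L2 logistic decoder on the channel
  vector at each train time *t* and score AUC at every test time *t′*
  under stratified 5-fold cross-validation; chance is AUC = 0.5.
* **Decoding duration**: the above-chance extent of the diagonal
  (matched *t* = *t′*), tested with a one-sample sign-flip cluster
  permutation test across subjects.
* **Generalization width** *w*: roll each row so the diagonal sits at
  lag 0, average rows over the 0–0.35 s train window, and take the full
  width at half maximum of the resulting peak — the dwell time of
  information in one spatial configuration (*w ≈ τ*).
* **Dynamic-vs-static delta**: per train time, the TG row mean minus
  the diagonal; significantly negative clusters mean the code is
  dynamic (moment-matched decoders beat sustained generalization).
* **Cohort entropy**: Shannon entropy (bits) of the frequency-weighted
  set of lexicon words consistent with the phonemes heard so far;
  tertile subsets test whether uncertain phonemes are encoded longer.

## A worked example

Simulate six subjects with the default dynamic code (τ = 0.08 s,
D = 0.3 s, response onset 0.05 s, SNR 2), run the full pipeline, and
look at the recovered dynamics:

```r
library(phonodyn)

summary <- run_pipeline(list(
  simulate = list(n_words = 150L, snr = 2, n_subjects_per_group = 6L,
                  n_lexicon_words = 500L, lexicon_zipf = 0.5,
                  feature_subset = c("voiced", "unvoiced", "occlusive",
                                     "fricative", "coronal", "labial")),
  stats    = list(n_permutations = 2000L),
  run      = list(per_sensor = FALSE, subsets = FALSE)),
  out_dir = "pd_demo", seed = 1)

mean(summary$widths$width_s)
#> [1] 0.08163034
summary$average_diagonal$windows
#>      onset_s   offset_s
#> 1 -0.1093750 -0.046875
#> 2  0.0078125  0.046875
#> 3  0.0625000  0.390625
#> 4  0.4296875  0.468750
#> 5  0.4921875  0.546875
summary$average_diagonal$extent_s
#> [1] 0.328125
summary$dynamic_delta$n_negative_clusters
#> [1] 1
```

Reading the output: the mean generalization width 0.082 s recovers the
injected dwell time τ = 0.08 s — information lives in one spatial
configuration for about one phoneme's duration before moving on. The
longest significant window on the feature-average diagonal (row 3) runs
from ~0.06 to ~0.39 s — `extent_s` 0.33 s — matching the injected
response (onset 0.05 s, duration 0.3 s, plus filter smearing); the
brief satellite windows before onset and after 0.4 s are the faint
high-pass compensation lobes and stimulus autocorrelation that any
sufficiently powered analysis of filtered continuous speech picks up
(the vignette discusses both). The significantly negative delta cluster
says the code is dynamic, not static. The same run writes
`pd_demo/report/summary.json` with per-feature significant windows,
per-subject widths, and (for two-group configurations) group cluster
tests, the permutation width comparison, the sensor max-t topography
test and the FDR-corrected group-by-entropy interaction.

Individual stages are plain functions if you want to compose them
yourself: `generate_lexicon()`, `sample_utterance()`,
`annotate_events()`, `build_feature_table()`, `prune_rare_features()`,
`simulate_subject()`, `preprocess_chain()`, `tg_decode()`,
`decode_all_features()`, `tg_decode_subsets()`, `decode_per_sensor()`,
`tg_reorient()`, `generalization_width()`, `dynamic_delta()`,
`one_sample_cluster_perm()`, `two_sample_cluster_perm()`,
`max_t_sensor_test()`, `entropy_interaction()`,
`behavior_correlation()`. `validate_events()` checks alignment TSVs.
See the vignette (`vignettes/phoneme-decoding-dynamics.Rmd`) for the
model, the estimator conventions and their rationale.

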