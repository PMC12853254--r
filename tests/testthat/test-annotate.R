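test_that("feature indicators match the multi-value system", {
  ev <- events_from_words(c("p", "b"))
  ft <- build_feature_table(ev)
  expect_equal(ncol(ft$matrix), 21)
  p <- ft$matrix[1, ]
  expect_equal(unname(p[c("unvoiced", "occlusive", "labial")]), c(1L, 1L, 1L))
  vowel_feats <- c("short_vowel", "long_vowel", "low_vowel", "mid_vowel",
                   "high_vowel", "front", "central", "back")
  expect_true(all(p[vowel_feats] == 0))
  expect_equal(unname(ft$matrix[2, "voiced"]), 1L)
})

test_that("empty event lists give a 0-row 21-column table", {
  ft <- build_feature_table(data.frame(phoneme = character(0)))
  expect_equal(dim(ft$matrix), c(0L, 21L))
})

test_that("unmapped phonemes fail loudly with the offending labels", {
  ev <- data.frame(phoneme = c("p", "qq", "zz"))
  expect_error(build_feature_table(ev), "qq, zz")
})

test_that("row sums are 4 for consonants and 5 for vowels", {
  fm <- default_feature_map()
  ft <- build_feature_table(data.frame(phoneme = fm$phoneme), fm)
  rs <- rowSums(ft$matrix)
  is_vowel <- !is.na(fm$frontback) & fm$frontback != ""
  expect_true(all(rs[is_vowel] == 5))
  expect_true(all(rs[!is_vowel] == 4))
})

test_that("pruning drops rates strictly below the threshold", {
  M <- cbind(a = c(rep(1L, 49), rep(0L, 951)),
             b = c(rep(1L, 50), rep(0L, 950)),
             c = rep(1L, 1000))
  ft <- phonodyn:::new_feature_table(M)
  pr <- prune_rare_features(ft, threshold = 0.05)
  expect_equal(pr$feature_names, c("b", "c"))  # 0.049 dropped, 0.050 kept
  expect_error(prune_rare_features(ft, threshold = 1.5), "all features")
})

test_that("a study-like stream prunes dental, glottal and low vowel: 21 -> 18", {
  set.seed(5)
  common <- c("p", "t", "k", "s", "n", "m", "r", "l", "E", "I", "e", "o", "u", "@")
  rare <- c("T", "h", "a")  # dental, glottal, low vowel carriers
  ph <- c(sample(common, 970, replace = TRUE), sample(rare, 30, replace = TRUE))
  ft <- build_feature_table(data.frame(phoneme = ph))
  pr <- prune_rare_features(ft)
  expect_equal(ncol(pr$matrix), 18)
  expect_false(any(c("dental", "glottal", "low_vowel") %in% pr$feature_names))
})

test_that("within-word positions count from both word edges", {
  ev <- events_from_words(c("k a t", "a", "p l a n t e r x s"))
  ev <- assign_positions(ev)
  expect_equal(ev$position_from_onset[1:3], 1:3)
  expect_equal(ev$position_from_offset[1:3], 3:1)
  expect_equal(ev$position_from_onset[4], 1L)
  expect_equal(ev$position_from_offset[4], 1L)
  # 9-phoneme word: onset positions 6..9 flagged out of subset
  expect_equal(ev$out_of_subset[5:13], c(rep(FALSE, 5), rep(TRUE, 4)))
  expect_true(all(ev$position_from_onset + ev$position_from_offset ==
                    rep(c(3, 1, 9), c(3, 1, 9)) + 1L))
})

test_that("cohort entropy follows the Shannon formula over the prefix cohort", {
  lex <- toy_lexicon()
  ev <- assign_positions(events_from_words(c("k a t", "k a p")))
  ev <- cohort_entropy(ev, lex)
  # word-initial phonemes carry no entropy
  expect_true(all(is.na(ev$entropy_bits[ev$position_from_onset == 1])))
  # prefix "k a": cohort kat/kap/kan with p = .1/.3/.6 (hand-evaluated)
  h_ka <- -(0.1 * log2(0.1) + 0.3 * log2(0.3) + 0.6 * log2(0.6))
  expect_equal(ev$entropy_bits[2], h_ka, tolerance = 1e-12)
  # full prefix "k a t": cohort is the single word kat -> 0 bits
  expect_equal(ev$entropy_bits[3], 0)
  # uniform cohort of 4 -> 2 bits
  lex4 <- data.frame(word = paste0("w", 1:4),
                     pronunciation = paste("k a", c("t", "p", "n", "s")),
                     frequency = rep(5, 4))
  ev2 <- cohort_entropy(assign_positions(events_from_words("k a t")), lex4)
  expect_equal(ev2$entropy_bits[2], 2)
  # unknown prefix -> empty cohort, absent entropy, logged
  expect_message(
    ev3 <- cohort_entropy(assign_positions(events_from_words("x y")), lex),
    "empty cohort")
  expect_true(is.na(ev3$entropy_bits[2]))
})

test_that("uniform weighting is available and entropy is bounded by log2 cohort", {
  lex <- toy_lexicon()
  ev <- assign_positions(events_from_words("k a"))
  ev_u <- cohort_entropy(ev, lex, weighted = FALSE)
  expect_equal(ev_u$entropy_bits[2], log2(3))
  lex2 <- generate_lexicon(120, seed = 8)
  evs <- assign_positions(sample_utterance(lex2, 150, seed = 9))
  evs <- cohort_entropy(evs, lex2)
  ok <- !is.na(evs$entropy_bits)
  expect_true(all(evs$entropy_bits[ok] >= -1e-12))
  expect_true(all(evs$entropy_bits[ok] <= log2(nrow(lex2)) + 1e-12))
})

test_that("entropy tertiles split at interpolated percentiles, ties to lower", {
  ev <- data.frame(entropy_bits = as.numeric(1:9))
  out <- suppressMessages(entropy_tertiles(ev))
  expect_equal(as.character(out$entropy_tertile),
               rep(c("low", "mid", "high"), each = 3))
  ev3 <- data.frame(entropy_bits = c(0.1, 0.5, 0.9))
  out3 <- suppressMessages(entropy_tertiles(ev3))
  expect_equal(as.character(out3$entropy_tertile), c("low", "mid", "high"))
  # ties straddling the 33rd percentile: checked against quantile() itself
  e <- c(1, 2, 2, 2, 3, 4, 5, 6, 7)
  q <- quantile(e, c(1 / 3, 2 / 3), names = FALSE)
  outt <- suppressMessages(entropy_tertiles(data.frame(entropy_bits = e)))
  expect_equal(as.character(outt$entropy_tertile),
               ifelse(e <= q[1], "low", ifelse(e <= q[2], "mid", "high")))
  expect_error(suppressMessages(
    entropy_tertiles(data.frame(entropy_bits = rep(1, 10)))), "degenerate")
  expect_error(entropy_tertiles(data.frame(entropy_bits = c(1, NA, NA))),
               "at least 3")
})
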