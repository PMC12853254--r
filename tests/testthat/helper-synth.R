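# Small in-code fixtures shared across tests.

# kat/kap/kan toy lexicon with known cohort structure
toy_lexicon <- function() {
  lex <- data.frame(word = c("kat", "kap", "kan"),
                    pronunciation = c("k a t", "k a p", "k a n"),
                    frequency = c(10, 30, 60), stringsAsFactors = FALSE)
  class(lex) <- c("pd_lexicon", "data.frame")
  lex
}

# contiguous event stream for a vector of phoneme sequences (one word each)
events_from_words <- function(words, dur = 0.07, t0 = 0) {
  ph <- unlist(strsplit(words, " ", fixed = TRUE))
  n_ph <- lengths(strsplit(words, " ", fixed = TRUE))
  data.frame(onset_s = t0 + (seq_along(ph) - 1) * dur, duration_s = dur,
             phoneme = ph, word = rep(words, n_ph),
             word_index = rep(seq_along(words) - 1L, n_ph),
             stringsAsFactors = FALSE)
}

# minimal epochs object with pure-noise data (events x channels x times)
noise_epochs <- function(n_events, n_channels = 8, n_times = 15,
                         sfreq = 128, seed = 1) {
  set.seed(seed)
  structure(list(
    data = array(rnorm(n_events * n_channels * n_times),
                 dim = c(n_events, n_channels, n_times)),
    times_s = (seq_len(n_times) - 1) / sfreq,
    sfreq = sfreq,
    events = data.frame(row = seq_len(n_events)),
    labels = paste0("ch", seq_len(n_channels)), montage = NULL),
    class = "eeg_epochs")
}

# inject a channel pattern carrying labels y into given time indices
inject_pattern <- function(epochs, y, time_idx, amp = 3, pattern = NULL,
                           seed = 2) {
  set.seed(seed)
  nc <- dim(epochs$data)[2]
  if (is.null(pattern)) pattern <- rnorm(nc)
  pattern <- pattern / sqrt(sum(pattern^2))
  for (t in time_idx)
    epochs$data[, , t] <- epochs$data[, , t] +
      amp * outer(ifelse(y == 1, 1, -1), pattern)
  epochs
}

# stratified fold vector (same scheme as the package uses internally)
make_folds_for_test <- function(y, k, seed = 1) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  as.integer(fold)
}

# a tg_matrix built directly from a value matrix
tg_from_values <- function(values, sfreq = 128, t0 = -0.2) {
  n <- nrow(values)
  phonodyn:::new_tg_matrix(values, t0 + (seq_len(n) - 1) / sfreq)
}
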