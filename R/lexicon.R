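#' Phoneme inventory of the shipped feature map
#'
#' @param feature_map optional feature map data.frame (defaults to the
#'   shipped Dutch-style map, see [default_feature_map()]).
#' @return character vector of phoneme labels.
#' @export
phoneme_inventory <- function(feature_map = default_feature_map()) {
  feature_map$phoneme
}

#' Generate a synthetic pronunciation lexicon
#'
#' Random unique phoneme sequences with Zipf-distributed token frequencies
#' (frequency of the rank-r word proportional to 1/r^zipf_exponent), the
#' shape observed in corpus frequency lists such as film-subtitle counts.
#'
#' @param n_words number of words (>= 2).
#' @param phoneme_inventory character vector of phoneme labels.
#' @param length_range integer length-2 vector, min/max phonemes per word.
#' @param zipf_exponent Zipf exponent (default 1).
#' @param prefix_reuse probability that a new word is built by extending
#'   or mutating the prefix of an existing word (default 0.7). Natural
#'   lexicons share word onsets heavily, which is what gives the cohort
#'   model its graded uncertainty; fully independent random sequences
#'   would make nearly every cohort a singleton.
#' @param seed integer RNG seed.
#' @return object of class `pd_lexicon`: data.frame with columns `word`,
#'   `pronunciation` (space-separated phonemes) and `frequency`.
#' @export
generate_lexicon <- function(n_words, phoneme_inventory = phonodyn::phoneme_inventory(),
                             length_range = c(2L, 6L), zipf_exponent = 1,
                             prefix_reuse = 0.7, seed = 1L) {
  if (n_words < 2) stop("a lexicon needs at least 2 words")
  if (length_range[1] < 1) stop("minimum word length must be >= 1")
  inv <- as.character(phoneme_inventory)
  lens <- length_range[1]:length_range[2]
  capacity <- sum(length(inv)^as.double(lens))
  if (n_words > capacity)
    stop("phoneme inventory too small to produce ", n_words,
         " unique sequences of length ", length_range[1], "-", length_range[2])
  set.seed(seed)
  rand_len <- function() lens[sample.int(length(lens), 1)]
  rand_word <- function() sample(inv, rand_len(), replace = TRUE)
  words <- list(rand_word())
  tries <- 0L
  while (length(words) < n_words) {
    w <- if (runif(1) < prefix_reuse && length(words) > 0) {
      base <- words[[sample.int(length(words), 1)]]
      L <- rand_len()
      npre <- sample.int(max(1L, min(length(base), L - 1L)), 1)
      c(base[seq_len(npre)], if (L > npre) sample(inv, L - npre, replace = TRUE))
    } else rand_word()
    key <- paste(w, collapse = " ")
    if (!key %in% vapply(words, paste, character(1), collapse = " "))
      words <- c(words, list(w))
    tries <- tries + 1L
    if (tries > 200L * n_words)
      stop("phoneme inventory too small to produce ", n_words, " unique sequences")
  }
  seqs <- vapply(words, paste, character(1), collapse = " ")
  freq <- pmax(1, round(1e5 / seq_len(n_words)^zipf_exponent))
  lex <- data.frame(word = paste0("w", seq_len(n_words)),
                    pronunciation = seqs, frequency = freq,
                    stringsAsFactors = FALSE)
  class(lex) <- c("pd_lexicon", "data.frame")
  lex
}

#' @export
print.pd_lexicon <- function(x, ...) {
  cat("<pd_lexicon> ", nrow(x), " words, total frequency ",
      sum(x$frequency), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

lexicon_phonemes <- function(lexicon) strsplit(lexicon$pronunciation, " ", fixed = TRUE)

#' Sample a phoneme event stream from a lexicon
#'
#' Words are drawn independently with probability proportional to lexicon
#' frequency; phoneme durations come from a log-normal with the given
#' median, clipped to [min, max]; events are contiguous in time.
#'
#' @param lexicon a [generate_lexicon()] result (or data.frame with the
#'   same columns).
#' @param n_words number of word tokens to emit.
#' @param phoneme_duration_model numeric `(median_s, min_s, max_s)`;
#'   default `c(0.070, 0.029, 0.359)` mirrors natural narrative speech.
#' @param seed integer RNG seed.
#' @param t0 onset of the first phoneme (seconds; default 0).
#' @param sdlog log-normal shape parameter of the duration sampler.
#' @return data.frame of phoneme events with columns `onset_s`,
#'   `duration_s`, `phoneme`, `word`, `word_index` (0-based word token).
#' @export
sample_utterance <- function(lexicon, n_words,
                             phoneme_duration_model = c(0.070, 0.029, 0.359),
                             seed = 1L, t0 = 0, sdlog = 0.4) {
  if (nrow(lexicon) == 0) stop("lexicon is empty")
  set.seed(seed)
  med <- phoneme_duration_model[1]
  lo <- phoneme_duration_model[2]
  hi <- phoneme_duration_model[3]
  idx <- sample.int(nrow(lexicon), n_words, replace = TRUE,
                    prob = lexicon$frequency)
  prons <- lexicon_phonemes(lexicon)[idx]
  n_ph <- vapply(prons, length, integer(1))
  total <- sum(n_ph)
  dur <- pmin(hi, pmax(lo, rlnorm(total, meanlog = log(med), sdlog = sdlog)))
  onset <- t0 + c(0, cumsum(dur))[seq_len(total)]
  data.frame(onset_s = onset, duration_s = dur,
             phoneme = unlist(prons),
             word = rep(lexicon$word[idx], n_ph),
             word_index = rep(seq_len(n_words) - 1L, n_ph),
             stringsAsFactors = FALSE)
}

#' Read / write lexicon and event tables (TSV)
#'
#' Plain tab-separated interchange formats: the lexicon has columns
#' `word`, `pronunciation` (space-separated phonemes), `frequency`; event
#' tables have at least `onset_s`, `duration_s`, `phoneme`, `word`,
#' `word_index`.
#'
#' @param path file path.
#' @return the read data.frame, or (for writers) `path` invisibly.
#' @export
read_lexicon <- function(path) {
  lex <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("word", "pronunciation", "frequency") %in% names(lex)))
  if (any(lex$frequency <= 0)) stop("lexicon frequencies must be > 0")
  class(lex) <- c("pd_lexicon", "data.frame")
  lex
}

#' @rdname read_lexicon
#' @param lexicon,events object to write.
#' @export
write_lexicon <- function(lexicon, path) {
  write.table(as.data.frame(lexicon), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname read_lexicon
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "phoneme", "word", "word_index")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event table lacks columns: ", paste(miss, collapse = ", "))
  ev
}

#' @rdname read_lexicon
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
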