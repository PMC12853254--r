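#' Assign within-word phoneme positions
#'
#' Counts `position_from_onset` 1..L and `position_from_offset` L..1
#' within each word token (events chunked by `word_index`). Positions
#' beyond 5 are retained but flagged `out_of_subset`, matching the usual
#' restriction of position analyses to the first/last five phonemes.
#'
#' @param events event data.frame sorted by onset with non-decreasing
#'   `word_index`.
#' @param max_position largest position used in subset analyses (default 5).
#' @return events with `position_from_onset`, `position_from_offset` and
#'   logical `out_of_subset` columns.
#' @export
assign_positions <- function(events, max_position = 5L) {
  if (is.unsorted(events$onset_s)) stop("events must be sorted by onset")
  if (is.unsorted(events$word_index)) stop("word_index must be non-decreasing")
  runs <- rle(events$word_index)$lengths
  pos <- unlist(lapply(runs, seq_len), use.names = FALSE)
  len <- rep(runs, runs)
  events$position_from_onset <- pos
  events$position_from_offset <- len - pos + 1L
  events$out_of_subset <- pos > max_position
  events
}

#' Cohort entropy of phoneme events
#'
#' For each non-word-initial phoneme, the cohort is the set of lexicon
#' words whose pronunciation starts with the phonemes heard so far in the
#' current word (including the current phoneme). Word probabilities are
#' frequency-weighted (or uniform), and `entropy_bits` is the Shannon
#' entropy of that distribution in bits. Word-initial phonemes and
#' phonemes with an empty cohort get `NA`.
#'
#' @param events event data.frame (with positions assigned or not; the
#'   first phoneme of each word token is identified by `word_index` runs).
#' @param lexicon lexicon data.frame ([generate_lexicon()]).
#' @param weighted frequency-weight the cohort (default TRUE).
#' @return events with an `entropy_bits` column.
#' @export
cohort_entropy <- function(events, lexicon, weighted = TRUE) {
  if (nrow(lexicon) == 0) stop("lexicon is empty")
  prons <- vapply(lexicon_phonemes(lexicon),
                  function(p) paste(p, collapse = "\r"), character(1))
  freq <- if (weighted) as.double(lexicon$frequency) else
    rep(1, nrow(lexicon))
  runs <- rle(events$word_index)$lengths
  pos <- unlist(lapply(runs, seq_len), use.names = FALSE)
  ent <- rep(NA_real_, nrow(events))
  # prefix of phonemes heard so far within the current word
  start <- rep(cumsum(c(1L, runs))[seq_along(runs)], runs)
  for (i in which(pos > 1L)) {
    prefix <- paste(events$phoneme[start[i]:i], collapse = "\r")
    hit <- startsWith(prons, prefix) &
      (nchar(prons) == nchar(prefix) |
         substr(prons, nchar(prefix) + 1L, nchar(prefix) + 1L) == "\r")
    if (!any(hit)) next  # empty cohort: entropy stays absent
    p <- freq[hit] / sum(freq[hit])
    ent[i] <- -sum(p * log2(p))
  }
  events$entropy_bits <- ent
  n_empty <- sum(pos > 1L & is.na(ent))
  if (n_empty) message(n_empty, " non-initial events had an empty cohort")
  events
}

#' Split entropy values into tertiles
#'
#' Computes the 33rd and 66th percentiles (linear interpolation) of
#' `entropy_bits` over events where entropy is present and labels events
#' `low` (<= 33rd percentile), `mid`, or `high` (> 66th percentile); ties
#' at a cut point go to the lower tertile. Downstream analyses use only
#' the low and high thirds.
#'
#' @param events event data.frame with `entropy_bits`.
#' @return events with an `entropy_tertile` factor column
#'   (levels low/mid/high, `NA` where entropy is absent).
#' @export
entropy_tertiles <- function(events) {
  e <- events$entropy_bits
  ok <- !is.na(e)
  if (sum(ok) < 3) stop("need at least 3 events with entropy")
  q <- quantile(e[ok], c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (min(e[ok]) == max(e[ok]))
    stop("degenerate entropy distribution: all values equal")
  # heavy ties (e.g. a mass of zero-entropy singleton cohorts) can make
  # the cuts coincide; the mid bin is then empty and the split is 2-way
  lab <- rep(NA_character_, length(e))
  lab[ok] <- ifelse(e[ok] <= q[1], "low", ifelse(e[ok] <= q[2], "mid", "high"))
  events$entropy_tertile <- factor(lab, levels = c("low", "mid", "high"))
  counts <- table(events$entropy_tertile)
  message("entropy tertiles (33rd percentile ", signif(q[1], 4),
          ", 66th percentile ", signif(q[2], 4), "): low=", counts["low"],
          " mid=", counts["mid"], " high=", counts["high"])
  events
}

#' Full annotation pass
#'
#' Positions, cohort entropy and entropy tertiles in one call.
#'
#' @inheritParams cohort_entropy
#' @param tertiles also compute tertile labels (default TRUE).
#' @return annotated events.
#' @export
annotate_events <- function(events, lexicon, weighted = TRUE, tertiles = TRUE) {
  events <- assign_positions(events)
  events <- cohort_entropy(events, lexicon, weighted = weighted)
  if (tertiles) events <- entropy_tertiles(events)
  events
}
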