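#' Default phoneme-to-feature map
#'
#' A Dutch-style (CGN phone set) multi-value phonetic feature system with
#' 21 binary features across five classes: voicing (voiced, unvoiced),
#' manner (nasal, fricative, occlusive, approximant, short_vowel,
#' long_vowel), place (dental, coronal, glottal, labial, velar, low_vowel,
#' mid_vowel, high_vowel), roundness (rounded, unrounded) and
#' front-backness (front, central, back; vowels only). The map is shipped
#' as a TSV resource and can be replaced by the user: the map is data, not
#' algorithm.
#'
#' @param path optional path to a replacement TSV with columns `phoneme`,
#'   `voicing`, `manner`, `place`, `roundness`, `frontback`.
#' @return data.frame, one row per phoneme.
#' @export
default_feature_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dutch_feature_map.tsv", package = "phonodyn")
  read.delim(path, stringsAsFactors = FALSE, na.strings = "",
             colClasses = "character")
}

# Canonical feature order of the 21-feature system.
feature_names_21 <- function() {
  c("voiced", "unvoiced",
    "nasal", "fricative", "occlusive", "approximant", "short_vowel",
    "long_vowel",
    "dental", "coronal", "glottal", "labial", "velar", "low_vowel",
    "mid_vowel", "high_vowel",
    "rounded", "unrounded",
    "front", "central", "back")
}

#' Build the events-by-features indicator table
#'
#' Expands each phoneme event into binary indicators over the 21-feature
#' system; vowel-only features are 0 for consonants and vice versa.
#'
#' @param events event data.frame with a `phoneme` column.
#' @param feature_map phoneme-to-feature map ([default_feature_map()]).
#' @return object of class `pd_feature_table`: list with `matrix`
#'   (events x features, 0/1), `feature_names` and `feature_rates`.
#' @export
build_feature_table <- function(events, feature_map = default_feature_map()) {
  ph <- as.character(events$phoneme)
  unknown <- setdiff(unique(ph), feature_map$phoneme)
  if (length(unknown))
    stop("phonemes not in feature map: ", paste(unknown, collapse = ", "))
  fn <- feature_names_21()
  idx <- match(ph, feature_map$phoneme)
  M <- matrix(0L, nrow = length(ph), ncol = length(fn),
              dimnames = list(NULL, fn))
  for (col in c("voicing", "manner", "place", "roundness", "frontback")) {
    val <- feature_map[[col]][idx]
    ok <- !is.na(val) & val != ""
    if (any(ok)) M[cbind(which(ok), match(val[ok], fn))] <- 1L
  }
  new_feature_table(M)
}

new_feature_table <- function(M) {
  structure(list(matrix = M, feature_names = colnames(M),
                 feature_rates = if (nrow(M)) colMeans(M) else
                   setNames(rep(NA_real_, ncol(M)), colnames(M))),
            class = "pd_feature_table")
}

#' @export
print.pd_feature_table <- function(x, ...) {
  cat("<pd_feature_table> ", nrow(x$matrix), " events x ",
      ncol(x$matrix), " features\n", sep = "")
  r <- sort(x$feature_rates, decreasing = TRUE)
  cat("rates: ", paste0(names(r)[seq_len(min(6, length(r)))], "=",
                        signif(r[seq_len(min(6, length(r)))], 2),
                        collapse = " "), " ...\n", sep = "")
  invisible(x)
}

#' Drop rarely occurring features
#'
#' Removes features whose occurrence rate across events is strictly below
#' `threshold` (default 5% of phonemes); survivor order is preserved.
#'
#' @param table a [build_feature_table()] result.
#' @param threshold minimum fraction of events (default 0.05).
#' @return pruned `pd_feature_table`.
#' @export
prune_rare_features <- function(table, threshold = 0.05) {
  if (nrow(table$matrix) == 0) stop("feature table is empty")
  keep <- table$feature_rates >= threshold
  if (!any(keep)) stop("all features fall below the pruning threshold")
  new_feature_table(table$matrix[, keep, drop = FALSE])
}
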