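#' Decoding configuration
#'
#' @param n_folds cross-validation folds (default 5).
#' @param lambda L2 (ridge) penalty of the one-vs-all logistic decoder;
#'   unit inverse-strength default.
#' @param seed RNG seed for the fold shuffle.
#' @param max_iter,tol IRLS iteration controls.
#' @return list of class `pd_decode_config`.
#' @export
decode_config <- function(n_folds = 5L, lambda = 1, seed = 1L,
                          max_iter = 30L, tol = 1e-6) {
  if (n_folds < 2) stop("need at least 2 folds")
  structure(list(n_folds = n_folds, lambda = lambda, seed = seed,
                 max_iter = max_iter, tol = tol),
            class = "pd_decode_config")
}

# Stratified fold assignment: shuffle within class, deal round-robin.
make_folds <- function(y, n_folds, seed) {
  if (length(y) < n_folds) stop("fewer events than folds")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < n_folds)
    stop("a class has fewer events than folds; cannot stratify")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

new_tg_matrix <- function(values, times, feature = "feature",
                          subject = NA, subset = "all") {
  structure(list(values = values, times_s = times, feature = feature,
                 subject = subject, subset = subset),
            class = "tg_matrix")
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat("<tg_matrix> ", x$feature, " [", x$subset, "] ",
      nrow(x$values), "x", ncol(x$values), " (train x test), mean AUC ",
      round(mean(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.tg_matrix <- function(x, ...) {
  graphics::image(x$times_s, x$times_s, t(x$values),
                  xlab = "test time (s)", ylab = "train time (s)",
                  main = paste("TG:", x$feature), ...)
  graphics::abline(0, 1, lty = 2)
}

#' Temporal-generalization decoding of one binary feature
#'
#' Trains a ridge-logistic decoder on the channel vector at every train
#' time and scores AUC at every test time on held-out folds (stratified
#' cross-validation; per-fold AUCs averaged). The diagonal corresponds to
#' matched train/test time; chance is 0.5 regardless of class prevalence.
#'
#' @param epochs an `eeg_epochs`.
#' @param labels binary (0/1) vector, one per epoch.
#' @param cfg a [decode_config()].
#' @return a `tg_matrix` (train times x test times AUC).
#' @export
tg_decode <- function(epochs, labels, cfg = decode_config()) {
  stopifnot(length(labels) == dim(epochs$data)[1])
  fold <- make_folds(labels, cfg$n_folds, cfg$seed)
  res <- cpp_tg_decode(epochs$data, as.double(labels), as.integer(fold),
                       integer(length(labels)), 0L,
                       cfg$lambda, cfg$max_iter, cfg$tol)
  new_tg_matrix(res$overall, epochs$times_s)
}

#' Decode every retained feature, plus the feature average
#'
#' @param epochs an `eeg_epochs`.
#' @param table a `pd_feature_table` aligned with the epochs.
#' @param cfg a [decode_config()].
#' @return list with `per_feature` (named list of `tg_matrix`) and
#'   `average` (their unweighted mean).
#' @export
decode_all_features <- function(epochs, table, cfg = decode_config()) {
  stopifnot(nrow(table$matrix) == dim(epochs$data)[1])
  mats <- list()
  for (f in table$feature_names) {
    m <- tryCatch(tg_decode(epochs, table$matrix[, f], cfg),
                  error = function(e) {
                    warning("feature ", f, " dropped: ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(m)) { m$feature <- f; mats[[f]] <- m }
  }
  if (!length(mats)) stop("no feature could be decoded")
  avg <- Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats)
  list(per_feature = mats,
       average = new_tg_matrix(avg, epochs$times_s, feature = "average"))
}

#' Temporal generalization with subset-wise test sets
#'
#' Decoders are trained exactly as in [tg_decode()] on the full training
#' folds; AUC is then computed separately on each level of
#' `subset_labels` within the test folds, so all levels share the same
#' fitted decoders. Events with `NA` subset still contribute to training.
#'
#' @param epochs an `eeg_epochs`.
#' @param labels binary feature labels.
#' @param subset_labels factor/character per event (NA = train-only).
#' @param cfg a [decode_config()].
#' @return named list of `tg_matrix`, one per level present.
#' @export
tg_decode_subsets <- function(epochs, labels, subset_labels,
                              cfg = decode_config()) {
  stopifnot(length(labels) == dim(epochs$data)[1],
            length(subset_labels) == length(labels))
  f <- factor(subset_labels)
  lv <- levels(f)
  sub <- as.integer(f)
  sub[is.na(sub)] <- 0L
  fold <- make_folds(labels, cfg$n_folds, cfg$seed)
  res <- cpp_tg_decode(epochs$data, as.double(labels), as.integer(fold),
                       sub, length(lv), cfg$lambda, cfg$max_iter, cfg$tol)
  out <- list()
  for (i in seq_along(lv)) {
    vals <- res$levels[[i]]
    if (all(!is.finite(vals))) {
      warning("subset level ", lv[i], " absent from all test folds; omitted")
      next
    }
    out[[lv[i]]] <- new_tg_matrix(vals, epochs$times_s, subset = lv[i])
  }
  out
}

#' Per-sensor decoding
#'
#' For each sensor, the decoder input is that sensor's full epoch
#' timecourse; the score is the cross-validated AUC averaged over the
#' features in `table`, yielding a topography vector.
#'
#' @param epochs an `eeg_epochs`.
#' @param table a `pd_feature_table`.
#' @param cfg a [decode_config()].
#' @return named numeric vector, one score per sensor.
#' @export
decode_per_sensor <- function(epochs, table, cfg = decode_config()) {
  n_sens <- dim(epochs$data)[2]
  scores <- matrix(NA_real_, n_sens, length(table$feature_names))
  for (j in seq_along(table$feature_names)) {
    y <- table$matrix[, j]
    fold <- make_folds(y, cfg$n_folds, cfg$seed)
    for (s in seq_len(n_sens)) {
      X <- epochs$data[, s, ]
      scores[s, j] <- cpp_cv_auc(X, as.double(y), as.integer(fold),
                                 cfg$lambda, cfg$max_iter, cfg$tol)
    }
  }
  setNames(rowMeans(scores, na.rm = TRUE), epochs$labels)
}
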