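#' Diagonal of a TG matrix
#'
#' Matched train/test time decoding performance ("decoding duration"
#' timecourse).
#'
#' @param tg a `tg_matrix`.
#' @return numeric vector with the epoch time axis as names-free
#'   attribute `times_s`.
#' @export
tg_diagonal <- function(tg) {
  stopifnot(nrow(tg$values) == ncol(tg$values))
  structure(diag(tg$values), times_s = tg$times_s)
}

#' Reorient a TG matrix onto a lag axis
#'
#' Shifts each row of the matrix so that its diagonal element lands at
#' lag 0 (lag = test time minus train time), restricts rows to the train
#' window, and averages across rows per lag. Lags supported by fewer
#' than `min_coverage` of the windowed rows are flagged and excluded
#' from width counting (edge bias). Each row's value multiset is
#' preserved by the shift.
#'
#' @param tg a `tg_matrix`.
#' @param train_window train-time window in seconds (default `c(0, 0.35)`).
#' @param min_coverage minimum fraction of rows contributing (default 0.5).
#' @return object of class `pd_gen_profile`: `lag_s`, `mean` (profile),
#'   `rows` (train rows x lags, NA where out of range), `n_contrib`,
#'   `covered` (logical mask).
#' @export
tg_reorient <- function(tg, train_window = c(0, 0.35), min_coverage = 0.5) {
  times <- tg$times_s
  T_ <- length(times)
  rows <- which(times >= train_window[1] & times <= train_window[2])
  if (!length(rows)) stop("train window lies outside the matrix")
  lags <- -(T_ - 1):(T_ - 1)
  R <- matrix(NA_real_, length(rows), length(lags))
  for (i in seq_along(rows)) {
    t <- rows[i]
    # test index j sits at lag j - t  ->  lag index j - t + T_
    R[i, (1:T_) - t + T_] <- tg$values[t, ]
  }
  n_contrib <- colSums(!is.na(R))
  covered <- n_contrib >= min_coverage * length(rows)
  step <- times[2] - times[1]
  structure(list(lag_s = lags * step,
                 mean = colMeans(R, na.rm = TRUE),
                 rows = R, n_contrib = n_contrib, covered = covered,
                 feature = tg$feature, subject = tg$subject),
            class = "pd_gen_profile")
}

#' @export
print.pd_gen_profile <- function(x, ...) {
  cat("<pd_gen_profile> lags ", signif(min(x$lag_s), 3), " to ",
      signif(max(x$lag_s), 3), " s; peak ",
      round(max(x$mean[x$covered], na.rm = TRUE), 4), " at lag ",
      signif(x$lag_s[x$covered][which.max(x$mean[x$covered])], 3), " s\n",
      sep = "")
  invisible(x)
}

#' Generalization width of a reoriented profile
#'
#' Standardizes the subject's mean generalization profile (z-score across
#' covered lags), attaches a confidence interval to every lag, and counts
#' the lags whose lower CI bound stays above 0; the count times the lag
#' step is the width in seconds, interpreted as the dwell time of
#' information in one spatial configuration.
#'
#' Three conventions are exposed. `"halfmax"` (default) counts the lags
#' whose profile value exceeds the midpoint between a robust baseline
#' (25th percentile across covered lags) and the peak - the full width
#' at half maximum, which recovers the injected dwell time for a
#' triangular generalization peak of any width. `"profile"` uses the
#' profile's own standard deviation across lags as the CI scale, so the
#' rule reduces to z-scored profile > z(ci); it coincides with the
#' half-maximum rule when the peak is narrow relative to the lag window
#' (the empirical regime, dwell ~ 0.08 s against a ~0.7 s lag axis) but
#' degenerates for very broad peaks. `"rows"` uses the per-lag standard
#' error across contributing train rows.
#'
#' @param profile a [tg_reorient()] result.
#' @param ci_level confidence level for the CI-based modes (default 0.95).
#' @param se_mode `"halfmax"`, `"profile"` or `"rows"` (see above).
#' @return list with `width_s`, `z` (standardized profile), `lower`
#'   (distance above the counting threshold), `lag_s`.
#' @export
generalization_width <- function(profile, ci_level = 0.95,
                                 se_mode = c("halfmax", "profile", "rows")) {
  se_mode <- match.arg(se_mode)
  cov <- profile$covered
  if (sum(cov) < 3) stop("too few covered lags")
  v <- profile$mean[cov]
  mu <- mean(v); sg <- sd(v)
  zc <- qnorm(1 - (1 - ci_level) / 2)
  step <- profile$lag_s[2] - profile$lag_s[1]
  if (sg == 0) {
    w <- if (mu > 0) sum(cov) * step else 0
    message("degenerate (zero-variance) profile; width set by sign of mean")
    return(list(width_s = w, z = rep(0, sum(cov)), lower = rep(mu, sum(cov)),
                lag_s = profile$lag_s[cov]))
  }
  z <- (v - mu) / sg
  lower <- switch(se_mode,
    halfmax = {
      baseline <- quantile(v, 0.25, names = FALSE)
      v - (baseline + max(v)) / 2
    },
    profile = z - zc,
    rows = {
      rs <- apply(profile$rows[, cov, drop = FALSE], 2, sd, na.rm = TRUE) / sg
      z - zc * rs / sqrt(profile$n_contrib[cov])
    })
  if (se_mode == "halfmax") {
    # contiguous width around the peak, with sub-lag interpolation of the
    # half-maximum crossings (robust against shoulder noise)
    pk <- which.max(lower)
    left <- pk
    while (left > 1 && lower[left - 1] > 0) left <- left - 1
    right <- pk
    while (right < length(lower) && lower[right + 1] > 0) right <- right + 1
    wl <- if (left > 1)
      lower[left] / (lower[left] - lower[left - 1]) else 0.5
    wr <- if (right < length(lower))
      lower[right] / (lower[right] - lower[right + 1]) else 0.5
    width <- (right - left + wl + wr) * step
  } else {
    width <- sum(lower > 0) * step
  }
  list(width_s = width, z = z, lower = lower, lag_s = profile$lag_s[cov])
}

#' Dynamic-vs-static delta timecourses
#'
#' For each subject and each train time, subtracts the diagonal value
#' (the moment-matched decoder's performance) from that decoder's mean
#' generalization level - its TG row averaged across test times - so the
#' delta compares the rows of the matrix to its diagonal. A sustained
#' (static) code generalizes across the whole encoding span, making the
#' row mean match the diagonal; a dynamic code generalizes only in a
#' narrow band, pushing the row mean below the diagonal. Significantly
#' negative clusters of the delta (one-sample sign-flip cluster test)
#' therefore indicate dynamic coding.
#'
#' The dynamic-vs-static question is only defined where information is
#' actually present, so by default (`select = "core"`) the averaged test
#' columns and the evaluation domain are restricted to the encoding
#' core: the contiguous span where the group-mean diagonal exceeds
#' chance by at least half the peak effect, anchored to the train
#' window. This keeps filter-compensation lobes (sign-inverted decodable
#' copies of the response outside the encoding span, an unavoidable
#' by-product of high-pass filtering) from masquerading as dynamics.
#' `"window"` averages over the train-window columns and evaluates the
#' full axis; `"all"` uses the whole matrix.
#'
#' @param tg_list list of per-subject `tg_matrix` (same axes).
#' @param train_window train-time window anchoring the encoding core.
#' @param select column-selection rule (see above).
#' @param chance chance level (default 0.5).
#' @return list with `delta` (subjects x train-times matrix over the
#'   full axis), `times_s`, `cols_used` (indices of the averaged test
#'   columns) and `domain` (train-time indices on which the delta is
#'   interpretable and should be tested).
#' @export
dynamic_delta <- function(tg_list, train_window = c(0, 0.35),
                          select = c("core", "window", "all"),
                          chance = 0.5) {
  select <- match.arg(select)
  times <- tg_list[[1]]$times_s
  for (tg in tg_list)
    if (!isTRUE(all.equal(tg$times_s, times)))
      stop("TG matrices have mismatching time axes")
  diags <- t(vapply(tg_list, function(tg) diag(tg$values),
                    numeric(length(times))))
  gm <- colMeans(diags)
  w <- which(times >= train_window[1] & times <= train_window[2])
  if (!length(w)) stop("train window lies outside the matrix")
  domain <- seq_along(times)
  cols <- switch(select,
    all = seq_along(times),
    window = w,
    core = {
      thr <- chance + 0.5 * (max(gm[w]) - chance)
      r <- rle(gm > thr)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      runs <- which(r$values)
      if (!length(runs)) w else {
        hit <- runs[vapply(runs, function(k)
          starts[k] <= max(w) && ends[k] >= min(w), logical(1))]
        cand <- if (length(hit)) hit else runs
        k <- cand[which.max(r$lengths[cand])]
        domain <- starts[k]:ends[k]
        domain
      }
    })
  if (!length(cols)) cols <- w
  delta <- t(vapply(tg_list, function(tg) {
    rowMeans(tg$values[, cols, drop = FALSE]) - diag(tg$values)
  }, numeric(length(times))))
  list(delta = delta, times_s = times, cols_used = cols, domain = domain)
}

#' Extent of significant above-chance decoding on the diagonal
#'
#' Runs the one-sample sign-flip cluster test on per-subject diagonal
#' timecourses against chance and returns the total duration covered by
#' significant clusters, plus the cluster detail.
#'
#' @param diags subjects x times matrix of diagonal AUC.
#' @param times_s time axis.
#' @param chance chance level (default 0.5).
#' @param cfg a [test_config()].
#' @return list with `extent_s` (duration of the longest significant
#'   window; isolated spurious clusters elsewhere do not inflate it),
#'   `total_s` (summed duration over all significant clusters), `windows`
#'   (data.frame of significant cluster onsets/offsets), and the
#'   `cluster_result`.
#' @export
diagonal_extent <- function(diags, times_s, chance = 0.5,
                            cfg = test_config()) {
  res <- one_sample_cluster_perm(diags, mu0 = chance, cfg = cfg,
                                 adjacency = adjacency_1d(ncol(diags)))
  sig <- which(res$p <= cfg$alpha & res$masses > 0)
  mask <- res$labels %in% sig
  step <- times_s[2] - times_s[1]
  wins <- NULL
  longest <- 0
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    wins <- data.frame(onset_s = times_s[starts[r$values]],
                       offset_s = times_s[ends[r$values]])
    longest <- max(r$lengths[r$values]) * step
  }
  list(extent_s = longest, total_s = sum(mask) * step, windows = wins,
       clusters = res)
}
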