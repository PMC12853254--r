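#' Permutation-test configuration
#'
#' @param n_permutations number of random permutations (default 10000).
#' @param alpha cluster significance level (default 0.05).
#' @param cluster_alpha two-tailed p defining the cluster-forming t
#'   threshold (inverse Student-t quantile at the test's degrees of
#'   freedom; default 0.05).
#' @param seed RNG seed for the permutation draw.
#' @return list of class `pd_test_config`.
#' @export
test_config <- function(n_permutations = 10000L, alpha = 0.05,
                        cluster_alpha = 0.05, seed = 1L) {
  if (n_permutations < 1) stop("need at least one permutation")
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 cluster_alpha = cluster_alpha, seed = seed),
            class = "pd_test_config")
}

new_cluster_result <- function(res, thr, nperm) {
  ncl <- length(res$masses)
  clusters <- lapply(seq_len(ncl), function(c) which(res$labels == c))
  structure(list(t = as.vector(res$t), labels = as.vector(res$labels),
                 clusters = clusters, masses = as.vector(res$masses),
                 p = as.vector(res$p), null_max = as.vector(res$null_max),
                 threshold = thr, n_permutations = nperm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$clusters), " cluster(s), threshold |t| > ",
      round(x$threshold, 3), ", ", x$n_permutations, " permutations\n", sep = "")
  if (length(x$clusters)) {
    df <- data.frame(size = lengths(x$clusters),
                     mass = round(x$masses, 2), p = signif(x$p, 3))
    print(df)
  }
  invisible(x)
}

#' One-sample sign-flip cluster permutation test
#'
#' t-values on `data - mu0` per domain point; supra-threshold contiguous
#' points (under the given adjacency) form clusters whose mass is the sum
#' of t-values; the null is the maximum absolute cluster mass under
#' random per-subject sign flips; cluster p = (exceedances + 1) /
#' (permutations + 1). Positive and negative clusters are kept separate
#' and compared two-sided against the max-|mass| null.
#'
#' @param data subjects x points matrix (1D timecourse, flattened TG
#'   grid, or any point set matching `adjacency`).
#' @param mu0 null value (0, or 0.5 for AUC data).
#' @param cfg a [test_config()].
#' @param adjacency adjacency object ([adjacency_1d()],
#'   [adjacency_grid()], [sensor_adjacency()]); default 1D chain.
#' @return a `cluster_result`.
#' @export
one_sample_cluster_perm <- function(data, mu0 = 0, cfg = test_config(),
                                    adjacency = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 2) stop("need at least 2 subjects")
  if (is.null(adjacency)) adjacency <- adjacency_1d(ncol(data))
  if (adjacency$n != ncol(data))
    stop("adjacency size does not match the data domain")
  thr <- qt(1 - cfg$cluster_alpha / 2, df = n - 1)
  set.seed(cfg$seed)
  signs <- matrix(sample(c(-1, 1), cfg$n_permutations * n, replace = TRUE),
                  cfg$n_permutations, n)
  res <- cpp_cluster_onesample(data - mu0, signs, thr,
                               adjacency$adj, adjacency$ptr)
  new_cluster_result(res, thr, cfg$n_permutations)
}

#' Two-sample (group-exchange) cluster permutation test
#'
#' Pooled-variance independent-samples t per point, clustering as in
#' [one_sample_cluster_perm()], with the null built by shuffling subjects
#' between groups.
#'
#' @param groupA,groupB subjects x points matrices.
#' @param cfg a [test_config()].
#' @param adjacency adjacency object; default 1D chain.
#' @return a `cluster_result`.
#' @export
two_sample_cluster_perm <- function(groupA, groupB, cfg = test_config(),
                                    adjacency = NULL) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  n1 <- nrow(groupA); n2 <- nrow(groupB)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  if (ncol(groupA) != ncol(groupB)) stop("point sets differ between groups")
  if (is.null(adjacency)) adjacency <- adjacency_1d(ncol(groupA))
  if (adjacency$n != ncol(groupA))
    stop("adjacency size does not match the data domain")
  thr <- qt(1 - cfg$cluster_alpha / 2, df = n1 + n2 - 2)
  set.seed(cfg$seed)
  perms <- t(replicate(cfg$n_permutations,
                       sample.int(n1 + n2, n1) - 1L))
  res <- cpp_cluster_twosample(rbind(groupA, groupB), n1, perms, thr,
                               adjacency$adj, adjacency$ptr)
  new_cluster_result(res, thr, cfg$n_permutations)
}

#' Mass-univariate max-t sensor test
#'
#' Independent-samples t per sensor; the family-wise null distribution is
#' the maximum |t| over the whole sensor array in each group-label
#' permutation; corrected p per sensor is the proportion of the null at
#' or above its observed |t|.
#'
#' @param groupA,groupB subjects x sensors matrices.
#' @param cfg a [test_config()].
#' @return list with `t`, `p_corrected`, `significant` (sensor indices at
#'   `cfg$alpha`), `null_max`.
#' @export
max_t_sensor_test <- function(groupA, groupB, cfg = test_config()) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB)) stop("sensor axes do not match")
  n1 <- nrow(groupA); n2 <- nrow(groupB)
  tfun <- function(A, B) {
    m1 <- colMeans(A); m2 <- colMeans(B)
    sp <- (colSums(sweep(A, 2, m1)^2) + colSums(sweep(B, 2, m2)^2)) /
      (n1 + n2 - 2)
    (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  }
  t_obs <- tfun(groupA, groupB)
  D <- rbind(groupA, groupB)
  set.seed(cfg$seed)
  null <- vapply(seq_len(cfg$n_permutations), function(b) {
    ia <- sample.int(n1 + n2, n1)
    max(abs(tfun(D[ia, , drop = FALSE], D[-ia, , drop = FALSE])))
  }, numeric(1))
  p <- vapply(abs(t_obs), function(v) (sum(null >= v) + 1) /
                (cfg$n_permutations + 1), numeric(1))
  list(t = t_obs, p_corrected = p, significant = which(p <= cfg$alpha),
       null_max = null)
}

#' Scalar permutation t-test (independent samples)
#'
#' @param a,b numeric vectors (length >= 2 each).
#' @param n_permutations permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `t` (pooled-variance statistic) and two-sided
#'   permutation `p`.
#' @export
perm_ttest_scalar <- function(a, b, n_permutations = 10000L, seed = 1L) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  n1 <- length(a); n2 <- length(b)
  tstat <- function(x, y) {
    sp <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
    (mean(x) - mean(y)) / sqrt(sp * (1 / n1 + 1 / n2))
  }
  t_obs <- tstat(a, b)
  z <- c(a, b)
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i) {
    ia <- sample.int(n1 + n2, n1)
    tstat(z[ia], z[-ia])
  }, numeric(1))
  p <- (sum(abs(null) >= abs(t_obs)) + 1) / (n_permutations + 1)
  list(t = t_obs, p = p)
}

#' Group-by-entropy interaction test on decoding timecourses
#'
#' Per subject, the high-entropy minus low-entropy decoding difference;
#' per time lag inside the window, an independent-samples t-test between
#' groups; Benjamini-Hochberg correction over the window lags.
#'
#' @param highA,lowA,highB,lowB subjects x time matrices (groups A and B).
#' @param times_s shared time axis.
#' @param window analysis window in seconds (default `c(0.15, 0.35)`).
#' @param alpha FDR level (default 0.05).
#' @return data.frame with `lag_s`, `t`, `p`, `p_fdr`, `significant`.
#' @export
entropy_interaction <- function(highA, lowA, highB, lowB, times_s,
                                window = c(0.15, 0.35), alpha = 0.05) {
  idx <- which(times_s >= window[1] & times_s <= window[2])
  if (!length(idx)) stop("window lies outside the time axis")
  dA <- highA - lowA
  dB <- highB - lowB
  tt <- vapply(idx, function(j) {
    ht <- t.test(dA[, j], dB[, j], var.equal = TRUE)
    c(ht$statistic, ht$p.value)
  }, numeric(2))
  p_fdr <- p.adjust(tt[2, ], method = "BH")
  data.frame(lag_s = times_s[idx], t = tt[1, ], p = tt[2, ],
             p_fdr = p_fdr, significant = p_fdr <= alpha)
}

#' Lag-wise behavioral correlation
#'
#' Pearson correlation between a per-subject decoding timecourse and a
#' behavioral score at every lag, uncorrected (exploratory), with
#' contiguous significant lags reported as intervals.
#'
#' @param timecourses subjects x time matrix.
#' @param behavior numeric score per subject.
#' @param times_s time axis.
#' @param alpha significance level (default 0.05).
#' @return list with `r`, `p` per lag and `intervals` (data.frame of
#'   contiguous significant spans, or NULL).
#' @export
behavior_correlation <- function(timecourses, behavior, times_s,
                                 alpha = 0.05) {
  timecourses <- as.matrix(timecourses)
  if (nrow(timecourses) < 3) stop("need >= 3 subjects with both measures")
  if (sd(behavior) == 0) stop("behavior score has zero variance")
  r <- p <- rep(NA_real_, ncol(timecourses))
  for (j in seq_len(ncol(timecourses))) {
    x <- timecourses[, j]
    if (sd(x) == 0) next  # absent value, logged below
    ct <- cor.test(x, behavior)
    r[j] <- ct$estimate; p[j] <- ct$p.value
  }
  if (anyNA(r)) message(sum(is.na(r)), " lags with zero variance skipped")
  sig <- !is.na(p) & p <= alpha
  intervals <- NULL
  if (any(sig)) {
    rl <- rle(sig)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    intervals <- data.frame(onset_s = times_s[starts[rl$values]],
                            offset_s = times_s[ends[rl$values]])
  }
  list(r = r, p = p, times_s = times_s, intervals = intervals)
}
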