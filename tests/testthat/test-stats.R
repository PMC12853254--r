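test_that("one-sample cluster test: degenerate and maximal cases", {
  cfg <- test_config(n_permutations = 500, seed = 1)
  res <- one_sample_cluster_perm(matrix(0, 5, 12), mu0 = 0, cfg = cfg)
  expect_length(res$clusters, 0)
  set.seed(2)
  D <- matrix(1 + rnorm(10 * 20, 0, 0.01), 10, 20)
  res2 <- one_sample_cluster_perm(D, cfg = cfg)
  expect_length(res2$clusters, 1)
  expect_equal(sort(res2$clusters[[1]]), 1:20)
  expect_lt(res2$p[1], 0.01)
  expect_error(one_sample_cluster_perm(D[1, , drop = FALSE]), "2 subjects")
  expect_error(one_sample_cluster_perm(D, adjacency = adjacency_1d(5)),
               "adjacency")
})

# exact reference: enumerate all sign patterns / group assignments in R,
# computing max cluster mass with plain loops
exact_onesample_p <- function(D, thr) {
  n <- nrow(D)
  maxmass <- function(t) {
    best <- 0; cur <- 0; sgn <- 0
    for (v in t) {
      s <- if (abs(v) > thr) sign(v) else 0
      if (s != 0 && s == sgn) cur <- cur + v
      else { cur <- if (s != 0) v else 0 }
      sgn <- s
      best <- max(best, abs(cur))
    }
    best
  }
  tstat <- function(X) {
    m <- colMeans(X); s <- apply(X, 2, sd)
    ifelse(s == 0, 0, m / (s / sqrt(n)))
  }
  obs <- maxmass(tstat(D))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- apply(signs, 1, function(s) maxmass(tstat(D * s)))
  mean(null >= obs - 1e-12)
}

test_that("sampled one-sample p matches exhaustive sign-flip enumeration", {
  set.seed(3)
  D <- matrix(rnorm(8 * 5, mean = 0.6), 8, 5)
  thr <- qt(0.975, 7)
  p_exact <- exact_onesample_p(D, thr)
  res <- one_sample_cluster_perm(D, cfg = test_config(n_permutations = 5000,
                                                      seed = 4))
  expect_gt(length(res$clusters), 0)
  expect_lt(abs(min(res$p) - p_exact), 0.02)
})

test_that("two-sample cluster test localizes a boxcar group difference", {
  set.seed(5)
  A <- matrix(rnorm(8 * 30, 0, 0.1), 8, 30)
  B <- matrix(rnorm(8 * 30, 0, 0.1), 8, 30)
  B[, 10:20] <- B[, 10:20] - 0.2
  res <- two_sample_cluster_perm(A, B, test_config(n_permutations = 1000,
                                                   seed = 6))
  sig <- which(res$p <= 0.05)
  expect_gte(length(sig), 1)
  hit <- res$clusters[[sig[which.max(abs(res$masses[sig]))]]]
  expect_true(length(intersect(hit, 10:20)) > 5)
  expect_error(two_sample_cluster_perm(A[1, , drop = FALSE], B), "2 subjects")
})

test_that("sampled two-sample p matches exhaustive group-exchange enumeration", {
  set.seed(7)
  a <- matrix(rnorm(5 * 4, 0.8), 5, 4)
  b <- matrix(rnorm(5 * 4, 0), 5, 4)
  thr <- qt(0.975, 8)
  D <- rbind(a, b)
  tstat <- function(ia) {
    A <- D[ia, , drop = FALSE]; B <- D[-ia, , drop = FALSE]
    sp <- (apply(A, 2, var) * 4 + apply(B, 2, var) * 4) / 8
    (colMeans(A) - colMeans(B)) / sqrt(sp * (2 / 5))
  }
  maxmass <- function(t) {
    best <- 0; cur <- 0; sgn <- 0
    for (v in t) {
      s <- if (abs(v) > thr) sign(v) else 0
      if (s != 0 && s == sgn) cur <- cur + v
      else cur <- if (s != 0) v else 0
      sgn <- s
      best <- max(best, abs(cur))
    }
    best
  }
  combs <- combn(10, 5)
  obs <- maxmass(tstat(1:5))
  null <- apply(combs, 2, function(ia) maxmass(tstat(ia)))
  p_exact <- mean(null >= obs - 1e-12)
  res <- two_sample_cluster_perm(a, b, test_config(n_permutations = 5000,
                                                   seed = 8))
  expect_lt(abs(min(res$p) - p_exact), 0.02)
})

test_that("TG-grid clustering uses 4-connectivity: corner blobs stay apart", {
  set.seed(9)
  n <- 10  # 4x4 grid domain, flattened column-major
  D <- matrix(rnorm(n * 16, 0, 0.05), n, 16)
  blob1 <- c(1, 2, 5, 6)    # cells (1,1),(2,1),(1,2),(2,2)
  blob2 <- c(11, 12, 15, 16)  # cells (3,3),(4,3),(3,4),(4,4)
  D[, blob1] <- D[, blob1] + 1
  D[, blob2] <- D[, blob2] + 1
  res <- one_sample_cluster_perm(D, cfg = test_config(n_permutations = 200),
                                 adjacency = adjacency_grid(4, 4))
  expect_length(res$clusters, 2)
  expect_setequal(res$clusters[[1]], blob1)
  expect_setequal(res$clusters[[2]], blob2)
})

test_that("max-t sensor test controls the family and finds a shifted sensor", {
  set.seed(10)
  A <- matrix(rnorm(20 * 16), 20, 16)
  B <- matrix(rnorm(20 * 16), 20, 16)
  sdp <- sqrt((var(A[, 5]) + var(B[, 5])) / 2)
  B[, 5] <- B[, 5] - 3 * sdp
  res <- max_t_sensor_test(A, B, test_config(n_permutations = 1000, seed = 11))
  expect_true(5 %in% res$significant)
  # identical sensors get identical corrected p
  A2 <- matrix(rnorm(12), 12, 1)[, rep(1, 6)]
  B2 <- matrix(rnorm(12), 12, 1)[, rep(1, 6)]
  res2 <- max_t_sensor_test(A2, B2, test_config(n_permutations = 300, seed = 12))
  expect_equal(length(unique(res2$p_corrected)), 1)
})

test_that("scalar permutation t-test matches exhaustive enumeration", {
  set.seed(13)
  a <- rnorm(5, 1); b <- rnorm(5)
  tstat <- function(x, y) {
    sp <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 8
    (mean(x) - mean(y)) / sqrt(sp * (2 / 5))
  }
  z <- c(a, b)
  null <- apply(combn(10, 5), 2, function(ia) tstat(z[ia], z[-ia]))
  p_exact <- mean(abs(null) >= abs(tstat(a, b)) - 1e-12)
  res <- perm_ttest_scalar(a, b, n_permutations = 5000, seed = 14)
  expect_lt(abs(res$p - p_exact), 0.02)
  # identical multisets: p ~ 1
  expect_gt(perm_ttest_scalar(1:6, 1:6, 2000, 1)$p, 0.9)
  # disjoint supports: minimal attainable p
  expect_lte(perm_ttest_scalar(rnorm(10, 10), rnorm(10), 10000, 1)$p, 0.001)
  expect_error(perm_ttest_scalar(1, 1:3), ">= 2")
})

test_that("entropy interaction flags only the perturbed lags, FDR-corrected", {
  times <- seq(-0.2, 0.6, by = 1 / 128)
  idx_win <- times >= 0.15 & times <= 0.35
  set.seed(15)
  mk <- function(n) matrix(rnorm(n * length(times), 0, 0.05), n)
  hits <- 0L
  for (rep in 1:30) {
    set.seed(rep)
    ei <- entropy_interaction(mk(8), mk(8), mk(8), mk(8), times)
    if (any(ei$significant)) hits <- hits + 1L
  }
  expect_lte(hits, 4)  # null calibration
  hA <- mk(8); per <- times >= 0.2 & times <= 0.25
  hA[, per] <- hA[, per] + 0.1
  ei2 <- entropy_interaction(hA, mk(8), mk(8), mk(8), times)
  expect_true(any(ei2$significant))
  expect_true(all(ei2$lag_s[ei2$significant] >= 0.19 &
                    ei2$lag_s[ei2$significant] <= 0.26))
  # a single-lag window reduces BH to the raw p
  t1 <- times[which.min(abs(times - 0.2))]
  ei3 <- entropy_interaction(hA, mk(8), mk(8), mk(8), times,
                             window = c(t1, t1))
  expect_equal(nrow(ei3), 1)
  expect_equal(ei3$p_fdr, ei3$p)
  expect_error(entropy_interaction(hA, mk(8), mk(8), mk(8), times,
                                   window = c(2, 3)), "window")
})

test_that("behavioral correlations recover exact dependence and stay calibrated", {
  set.seed(16)
  tc <- matrix(rnorm(40 * 25), 40, 25)
  beh <- tc[, 7]
  res <- behavior_correlation(tc, beh, seq_len(25) / 128)
  expect_equal(res$r[7], 1, tolerance = 1e-12)
  expect_true(!is.null(res$intervals))
  # independent draws: |r| < 0.32 for ~95 % of lags at n = 40
  set.seed(17)
  res2 <- behavior_correlation(matrix(rnorm(40 * 200), 40), rnorm(40),
                               seq_len(200) / 128)
  expect_gt(mean(abs(res2$r) < 0.32), 0.9)
  expect_error(behavior_correlation(tc[1:2, ], beh[1:2], seq_len(25) / 128),
               "3 subjects")
  expect_error(behavior_correlation(tc, rep(1, 40), seq_len(25) / 128),
               "variance")
})
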