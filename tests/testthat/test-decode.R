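test_that("AUC agrees with an independent implementation and handles ties", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(60), 1)  # rounding forces ties
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, s, direction = "<", quiet = TRUE))))
    expect_equal(phonodyn:::cpp_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant to strictly monotone transforms of the scores", {
  set.seed(5)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80)
  a <- phonodyn:::cpp_auc(s, y)
  expect_equal(phonodyn:::cpp_auc(exp(2 * s) - 3, y), a)
  expect_equal(phonodyn:::cpp_auc(rank(s), y), a)
})

test_that("ridge logistic matches a general-purpose optimizer", {
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40)
  y <- rbinom(40, 1, plogis(X %*% c(1, -2, 0.5)))
  lam <- 2
  w_cpp <- phonodyn:::cpp_ridge_logistic(X, y, lam, 100L, 1e-10)
  obj <- function(w) {
    eta <- w[1] + X %*% w[-1]
    -sum(y * eta - log1p(exp(eta))) + lam / 2 * sum(w[-1]^2)
  }
  w_ref <- optim(rep(0, 4), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))$par
  expect_equal(as.vector(w_cpp), w_ref, tolerance = 1e-4)
})

test_that("label flips behave antisymmetrically", {
  set.seed(7)
  X <- matrix(rnorm(100 * 5), 100)
  y <- rbinom(100, 1, 0.5)
  # fixed scores: flipping the labels mirrors AUC around chance
  s <- rnorm(100)
  expect_equal(phonodyn:::cpp_auc(s, y) + phonodyn:::cpp_auc(s, 1 - y), 1,
               tolerance = 1e-12)
  # refitting under flipped labels negates the decoder exactly, so the
  # cross-validated AUC is reproduced to machine precision
  w1 <- phonodyn:::cpp_ridge_logistic(X, y, 1, 100L, 1e-10)
  w2 <- phonodyn:::cpp_ridge_logistic(X, 1 - y, 1, 100L, 1e-10)
  expect_equal(as.vector(w1), -as.vector(w2), tolerance = 1e-10)
  fold <- make_folds_for_test(y, 5)
  a <- phonodyn:::cpp_cv_auc(X, y, fold, 1, 30L, 1e-6)
  b <- phonodyn:::cpp_cv_auc(X, 1 - y, fold, 1, 30L, 1e-6)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("chance-level data give chance-level TG matrices", {
  ep <- noise_epochs(400, n_channels = 8, n_times = 12, seed = 8)
  set.seed(9)
  y <- rbinom(400, 1, 0.5)
  tg <- tg_decode(ep, y, decode_config(seed = 1))
  expect_equal(dim(tg$values), c(12, 12))
  expect_true(all(is.finite(tg$values)))
  expect_equal(mean(tg$values), 0.5, tolerance = 0.02)
})

test_that("a time-localized pattern confines the above-chance region", {
  set.seed(10)
  y <- rbinom(300, 1, 0.5)
  ep <- inject_pattern(noise_epochs(300, 10, 14, seed = 11), y, 5:7, amp = 2)
  tg <- tg_decode(ep, y, decode_config(seed = 2))
  inside <- tg$values[5:7, 5:7]
  outside <- tg$values[10:14, 10:14]
  expect_gt(mean(inside), 0.85)
  expect_equal(mean(outside), 0.5, tolerance = 0.03)
  # pattern constant across the epoch -> above chance over the full square
  ep2 <- inject_pattern(noise_epochs(300, 10, 8, seed = 12), y, 1:8, amp = 2)
  tg2 <- tg_decode(ep2, y, decode_config(seed = 2))
  expect_gt(min(tg2$values), 0.8)
})

test_that("single-class labels and tiny folds are refused", {
  ep <- noise_epochs(20, 4, 5)
  expect_error(tg_decode(ep, rep(1, 20)), "single class")
  expect_error(tg_decode(ep, c(1, rep(0, 19))), "stratify|fewer")
  expect_error(tg_decode(noise_epochs(4, 4, 5), c(0, 1, 0, 1)),
               "fewer events than folds")
})

test_that("decode_all_features returns per-feature matrices plus their mean", {
  ep <- noise_epochs(150, 6, 8, seed = 13)
  set.seed(14)
  M <- cbind(f1 = rbinom(150, 1, 0.5), f2 = rbinom(150, 1, 0.3))
  out <- decode_all_features(ep, phonodyn:::new_feature_table(M),
                             decode_config(seed = 3))
  expect_named(out$per_feature, c("f1", "f2"))
  expect_equal(out$average$values,
               (out$per_feature$f1$values + out$per_feature$f2$values) / 2)
  # a feature that cannot be decoded is dropped with a warning, not fatal
  M2 <- cbind(f1 = M[, 1], bad = c(1, rep(0, 149)))
  expect_warning(
    out2 <- decode_all_features(ep, phonodyn:::new_feature_table(M2),
                                decode_config(seed = 3)),
    "bad")
  expect_named(out2$per_feature, "f1")
})

test_that("subset decoding shares decoders and isolates subset signal", {
  set.seed(15)
  n <- 360
  y <- rbinom(n, 1, 0.5)
  lev <- sample(c("A", "B"), n, replace = TRUE)
  ep <- noise_epochs(n, 8, 10, seed = 16)
  # signal present only in level-A events
  idxA <- which(lev == "A")
  set.seed(17)
  pat <- rnorm(8); pat <- pat / sqrt(sum(pat^2))
  for (t in 4:6)
    ep$data[idxA, , t] <- ep$data[idxA, , t] +
      2.5 * outer(ifelse(y[idxA] == 1, 1, -1), pat)
  out <- tg_decode_subsets(ep, y, lev, decode_config(seed = 4))
  expect_named(out, c("A", "B"))
  expect_gt(mean(out$A$values[4:6, 4:6]), 0.8)
  expect_lt(abs(mean(out$B$values[4:6, 4:6]) - 0.5), 0.07)
  # degenerate single-level subsets reproduce plain TG decoding
  one <- tg_decode_subsets(ep, y, rep("A", n), decode_config(seed = 4))
  plain <- tg_decode(ep, y, decode_config(seed = 4))
  expect_equal(one$A$values, plain$values, tolerance = 1e-12)
})

test_that("per-sensor decoding localizes an informative sensor", {
  set.seed(18)
  n <- 240
  y <- rbinom(n, 1, 0.5)
  ep <- noise_epochs(n, 6, 10, seed = 19)
  ep$data[, 4, 3:8] <- ep$data[, 4, 3:8] + 1.5 * ifelse(y == 1, 1, -1)
  M <- cbind(f1 = y)
  sc <- decode_per_sensor(ep, phonodyn:::new_feature_table(M),
                          decode_config(seed = 5))
  expect_length(sc, 6)
  expect_equal(which.max(sc), 4L, ignore_attr = TRUE)
  expect_gt(sc[4], 0.8)
  expect_lt(abs(mean(sc[-4]) - 0.5), 0.06)
})

test_that("the mean TG matrix is stable under fold reshuffling", {
  set.seed(20)
  y <- rbinom(300, 1, 0.5)
  ep <- inject_pattern(noise_epochs(300, 8, 8, seed = 21), y, 3:6, amp = 1.5)
  m1 <- mean(tg_decode(ep, y, decode_config(seed = 1))$values)
  m2 <- mean(tg_decode(ep, y, decode_config(seed = 99))$values)
  expect_equal(m1, m2, tolerance = 0.01)
})
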