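test_that("LDA weights follow the closed-form regularized solution", {
  set.seed(41)
  # 1-D symmetric classes: boundary at the midpoint 0
  x <- matrix(c(rnorm(20, -1, 1), rnorm(20, 1, 1)), ncol = 1)
  lab <- rep(c("L", "R"), each = 20)
  m <- fit_lda(x, lab, lambda = 0)
  expect_gt(m$w[1], 0)
  expect_equal(m$b, m$w[1] * mean(x), tolerance = 1e-9)
  # 2-D: w proportional to solve(S + lambda I, mu1 - mu0)
  x2 <- cbind(rnorm(40, rep(c(0, 2), each = 20)), rnorm(40, 0, 2))
  m2 <- fit_lda(x2, lab, lambda = 0.05)
  y <- as.integer(lab == "R")
  S <- ((crossprod(scale(x2[y == 0, ], scale = FALSE)) +
           crossprod(scale(x2[y == 1, ], scale = FALSE))) / (40 - 2) +
          diag(0.05, 2))
  w_oracle <- solve(S, colMeans(x2[y == 1, ]) - colMeans(x2[y == 0, ]))
  expect_equal(m2$w, unname(w_oracle), tolerance = 1e-9)
})

test_that("regularization defeats singular covariances; lambda = 0 errors", {
  set.seed(42)
  base <- rnorm(20)
  x <- cbind(base, base)  # duplicated feature -> singular pooled covariance
  lab <- rep(c("L", "R"), 10)
  expect_error(fit_lda(x, lab, lambda = 0), "singular")
  expect_silent(m <- fit_lda(x, lab, lambda = 0.05))
  expect_length(m$w, 2)
})

test_that("LOOCV decoding matches an independent R implementation", {
  set.seed(43)
  n <- 24; p <- 5; nb <- 6
  rates <- array(rnorm(n * p * nb, mean = 3), dim = c(n, p, nb))
  lab <- rep(c("L", "R"), n / 2)
  rates[lab == "R", , 3:4] <- rates[lab == "R", , 3:4] + 0.8
  tens <- make_tensor(rates, lab)
  dec <- loocv_decode(tens, lambda = 0.05)

  loocv_oracle <- function(X, y, lambda) {
    mean(vapply(seq_along(y), function(i) {
      Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
      m0 <- colMeans(Xtr[ytr == 0, , drop = FALSE])
      m1 <- colMeans(Xtr[ytr == 1, , drop = FALSE])
      S <- (crossprod(sweep(Xtr[ytr == 0, , drop = FALSE], 2, m0)) +
              crossprod(sweep(Xtr[ytr == 1, , drop = FALSE], 2, m1))) /
        (nrow(Xtr) - 2) + diag(lambda, ncol(X))
      w <- solve(S, m1 - m0)
      pred <- as.integer(sum(w * X[i, ]) > sum(w * (m0 + m1) / 2))
      pred == y[i]
    }, TRUE))
  }
  y <- as.integer(lab == "R")
  oracle <- vapply(1:nb, function(b) loocv_oracle(rates[, , b], y, 0.05), 0)
  expect_equal(dec$cp, oracle, tolerance = 1e-12)
})

test_that("decoding is at chance for label-independent rates and perfect for
           separable ones", {
  set.seed(44)
  rates <- array(rnorm(40 * 6 * 4, mean = 3), dim = c(40, 6, 4))
  lab <- rep(c("L", "R"), 20)
  dec <- loocv_decode(make_tensor(rates, lab))
  expect_lt(abs(mean(dec$cp) - 0.5), 1.96 * sqrt(0.25 / (40 * 4)) + 0.05)
  rates[lab == "R", , ] <- rates[lab == "R", , ] + 10
  expect_true(all(loocv_decode(make_tensor(rates, lab))$cp == 1))
})

test_that("cp is invariant under unit permutation", {
  set.seed(45)
  rates <- array(rnorm(20 * 5 * 3, mean = 3), dim = c(20, 5, 3))
  lab <- rep(c("L", "R"), 10)
  a <- loocv_decode(make_tensor(rates, lab))
  b <- loocv_decode(make_tensor(rates[, c(3, 1, 5, 2, 4), ], lab))
  expect_identical(a$cp, b$cp)
})

test_that("population-size equalization draws K units and averages", {
  set.seed(46)
  ra <- array(rnorm(24 * 4 * 3, 3), dim = c(24, 4, 3))
  rb <- array(rnorm(24 * 9 * 3, 3), dim = c(24, 9, 3))
  lab <- rep(c("L", "R"), 12)
  ra[lab == "R", , ] <- ra[lab == "R", , ] + 1
  rb[lab == "R", , ] <- rb[lab == "R", , ] + 1
  ta <- make_tensor(ra, lab); tb <- make_tensor(rb, lab)
  set.seed(1); r1 <- equalize_and_decode(ta, tb)
  set.seed(1); r2 <- equalize_and_decode(ta, tb)
  expect_identical(r1, r2)                       # seeded draws reproduce
  expect_equal(attr(r1, "k"), 4)
  # equal-size populations decode directly (no draw variability)
  set.seed(2); d1 <- equalize_and_decode(ta, ta)
  expect_identical(d1$cp_a, d1$cp_b)
  # K-subsampling with replacement cannot beat the full population on average
  full_b <- loocv_decode(tb)$cp
  expect_lte(mean(r1$cp_b), mean(full_b) + 0.02)
})

test_that("beta-distribution comparison matches numeric quantiles", {
  r <- compare_cp_beta(0.5, 0.5, 54)
  expect_false(r$sig)
  r2 <- compare_cp_beta(0.5, 0.9, 54)
  expect_equal(r2$threshold, qbeta(0.95, 28, 28), tolerance = 1e-12)
  expect_true(r2$sig)
  # consistency: a fixed gap is always detected as n grows
  expect_true(compare_cp_beta(0.5, 0.6, 5000)$sig)
  expect_error(compare_cp_beta(0.5, 0.6, 0))
})

test_that("correct-trained decoders generalize to identical error trials", {
  set.seed(47)
  rates <- array(rnorm(30 * 4 * 5, 3), dim = c(30, 4, 5))
  lab <- rep(c("L", "R"), 15)
  rates[lab == "R", , ] <- rates[lab == "R", , ] + 2
  tens <- make_tensor(rates, lab)
  tens$trials$outcome <- rep(c("correct", "error"), c(24, 6))
  r <- train_correct_test_error(tens, n_perm = 100)
  expect_false(any(r$sig_drop))
  expect_gt(mean(r$cp_error), 0.8)
})

test_that("label-flipped error trials decode below chance", {
  set.seed(48)
  rates <- array(rnorm(30 * 4 * 3, 3), dim = c(30, 4, 3))
  lab <- rep(c("L", "R"), 15)
  flip <- c(rep(FALSE, 24), rep(TRUE, 6))
  eff <- ifelse(xor(lab == "R", flip), 2, 0)     # rates follow flipped side
  rates <- rates + array(rep(eff, 4 * 3), dim = dim(rates))
  tens <- make_tensor(rates, lab)
  tens$trials$outcome <- ifelse(flip, "error", "correct")
  r <- train_correct_test_error(tens, n_perm = 100)
  expect_lt(mean(r$cp_error), 0.2)
})

test_that("Hotelling T2 reduces to t^2 in one dimension and is F-calibrated", {
  set.seed(49)
  xl <- matrix(rnorm(12, 1), ncol = 1); xr <- matrix(rnorm(12, 2), ncol = 1)
  h <- hotelling_t2(xl, xr, lambda = 0)
  tt <- t.test(xl, xr, var.equal = TRUE)$statistic
  expect_equal(h$t2, unname(tt)^2, tolerance = 1e-9)
  expect_equal(hotelling_t2(xl, xl)$t2, 0)
  # type-I error of the F approximation at lambda = 0
  rej <- mean(replicate(400, {
    a <- matrix(rnorm(60), ncol = 3); b <- matrix(rnorm(60), ncol = 3)
    hotelling_t2(a, b, lambda = 0)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("paired permutation test flags consistent differences only", {
  set.seed(50)
  a <- matrix(rnorm(10 * 4, 0.6), 10)
  b <- matrix(rnorm(10 * 4, 0.5), 10)
  r <- paired_permutation_test(a, a, n_perm = 300)
  expect_false(any(r$sig))
  r2 <- paired_permutation_test(a + 2, b, n_perm = 1000)
  expect_true(all(r2$sig))
})
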