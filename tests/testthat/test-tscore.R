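test_that("per-bin t matches the textbook pooled-SD two-sample t", {
  rates <- array(0, dim = c(6, 1, 1))
  rates[, 1, 1] <- c(1, 2, 3, 4, 5, 6)
  tens <- make_tensor(rates, rep(c("L", "R"), each = 3))
  prof <- tscore_curves(tens)
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)$statistic
  expect_equal(prof$t, unname(oracle), tolerance = 1e-12)
  expect_equal(prof$t, -3.674, tolerance = 1e-3)
})

test_that("t curves are antisymmetric under label swap and 0 for ties", {
  set.seed(21)
  rates <- array(rnorm(20 * 3 * 8, mean = 5), dim = c(20, 3, 8))
  lab <- rep(c("L", "R"), 10)
  a <- tscore_curves(make_tensor(rates, lab))
  b <- tscore_curves(make_tensor(rates, ifelse(lab == "L", "R", "L")))
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  # identical L and R sets -> t = 0
  rates2 <- array(0, dim = c(10, 3, 8))
  rates2[1:5, , ] <- rates[1:5, , ]
  rates2[6:10, , ] <- rates[1:5, , ]
  z <- tscore_curves(make_tensor(rates2, rep(c("L", "R"), each = 5)))
  expect_true(all(abs(z$t) < 1e-9))
})

test_that("zero pooled SD yields flagged zero t", {
  rates <- array(2, dim = c(8, 1, 2))
  prof <- tscore_curves(make_tensor(rates, rep(c("L", "R"), 4)))
  expect_true(all(prof$t == 0))
  expect_true(all(prof$flagged))
})

test_that("the analytic significance criterion at ~54 trials is t > 1.67", {
  expect_equal(round(t_criterion(54, 0.05), 2), 1.67)
})

test_that("shuffle masks flag planted discrimination and respect alpha = 1", {
  set.seed(22)
  n <- 50
  rates <- array(rnorm(n * 2 * 10, mean = 4), dim = c(n, 2, 10))
  lab <- rep(c("L", "R"), n / 2)
  rates[lab == "L", 1, 4:5] <- rates[lab == "L", 1, 4:5] + 3  # planted bump
  tens <- make_tensor(rates, lab)
  prof <- suppressMessages(tscore_curves(tens, n_shuffle = 300))
  m <- matrix(prof$sig, nrow = 2)          # units x bins
  expect_true(all(m[1, 4:5]))
  expect_false(any(m[2, ]))
  all_sig <- suppressMessages(tscore_curves(tens, n_shuffle = 50, alpha = 1,
                                            bonferroni = FALSE))
  expect_true(all(all_sig$sig))
})

test_that("null units are flagged at no more than the corrected rate", {
  set.seed(23)
  fp <- 0; total <- 0
  for (i in 1:25) {
    rates <- array(rnorm(24 * 1 * 8, mean = 4), dim = c(24, 1, 8))
    prof <- suppressMessages(
      tscore_curves(make_tensor(rates, rep(c("L", "R"), 12)),
                    n_shuffle = 200))
    fp <- fp + sum(prof$sig); total <- total + nrow(prof)
  }
  expect_lte(fp / total, 0.05 / 8 + 0.005)
})

test_that("informative units need > 50 ms of significant coding in-window", {
  base <- tibble::tibble(unit_id = "u1", area = "dCA1",
                         time = seq(-5, 4.95, by = 0.05))
  mk <- function(sig_times) {
    p <- base
    p$t <- 0; p$flagged <- FALSE
    p$sig <- vapply(p$time, function(tt)
      any(abs(tt - sig_times) < 1e-9), TRUE)
    attr(p, "bin_s") <- 0.05
    class(p) <- c("tscore_profiles", class(p))
    p
  }
  expect_false(informative_units(mk(0))$informative)            # 1 bin
  expect_true(informative_units(mk(c(0, 0.05)))$informative)    # 2 bins
  expect_false(informative_units(mk(c(4.8, 4.85)))$informative) # outside
  # >= 1 bin reading available
  expect_true(informative_units(mk(0), min_bins = 1)$informative)
})

test_that("tscore summaries report peak and total significant duration", {
  set.seed(24)
  rates <- array(rnorm(30 * 1 * 6, mean = 4), dim = c(30, 1, 6))
  lab <- rep(c("L", "R"), 15)
  rates[lab == "L", 1, 2:4] <- rates[lab == "L", 1, 2:4] + 3
  prof <- suppressMessages(
    tscore_curves(make_tensor(rates, lab), n_shuffle = 300))
  s <- tscore_summary(prof)
  expect_equal(s$duration_s, 0.15, tolerance = 1e-9)  # 3 bins x 50 ms
  expect_equal(s$peak_time_s, prof$time[which.max(abs(prof$t))])
  expect_equal(tscore_summary(prof, duration = "longest_run")$duration_s, 0.15)
})

test_that("coding distance removes offsets and scales by pooled variance", {
  x <- c(1, -1, 2, 0, -2)
  expect_equal(coding_distance(x, x), 0)
  expect_equal(coding_distance(x, x + 5), 0, tolerance = 1e-12)
  expect_warning(d0 <- coding_distance(rep(1, 5), rep(1, 5)), "zero")
  expect_equal(d0, 0)
  # orthogonal unit-variance (population) profiles of length n -> sqrt(2n)
  n <- 64
  a <- rep(c(1, -1), n / 2)
  b <- rep(c(1, 1, -1, -1), n / 4)
  stopifnot(abs(sum(a * b)) < 1e-9)
  expect_equal(coding_distance(a, b), sqrt(2 * n), tolerance = 1e-9)
})

test_that("stronger planted dCA1 tuning yields larger peak t than mPFC", {
  cfg <- simulate_config(n_units = c(dCA1 = 10, mPFC = 10), n_trials = 42,
                         cue_frac = 1, ca1_amp_hz = 7, mpfc_amp_hz = 2,
                         assemblies = list(), rhythm_m = 0)
  sim <- simulate_session(cfg, seed = 19)
  s <- select_units(sim$session)
  tens <- build_rate_tensor(s, "t_sample", c(-2, 2), bandwidth = 0.1)
  pk <- tscore_summary(
    suppressMessages(tscore_curves(tens, n_shuffle = 50)))
  expect_gt(mean(pk$peak_abs_t[pk$area == "dCA1"]),
            mean(pk$peak_abs_t[pk$area == "mPFC"]))
})
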