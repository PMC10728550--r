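test_that("EM factor analysis recovers a planted loading subspace", {
  G <- planted_loadings(30, list(1:6, 11:15), strength = 1.2)
  inp <- model_fa_input(30, loadings = G, seed = 71, n_trials = 50)
  m <- fit_fa(inp, 2)
  expect_true(m$converged)
  # subspace angle between fitted and true loading spans < 5 degrees
  qa <- qr.Q(qr(m$loadings)); qb <- qr.Q(qr(G))
  angle <- acos(min(svd(crossprod(qa, qb))$d)) * 180 / pi
  expect_lt(angle, 5)
  # noise variances near their true value 1
  expect_equal(median(m$psi), 1, tolerance = 0.1)
})

test_that("EM loadings agree with stats::factanal on standardized data", {
  # factanal fits the same ML factor model (correlation metric, different
  # optimizer); the recovered loading subspaces must coincide
  G <- planted_loadings(16, list(1:5, 9:12), strength = 1.2)
  inp <- model_fa_input(16, loadings = G, seed = 70, n_trials = 40)
  z <- t(scale(t(inp$x)))   # standardize units so metrics match
  m <- fit_fa(z, 2)
  fo <- stats::factanal(covmat = cov(t(z)), factors = 2, rotation = "none")
  qa <- qr.Q(qr(m$loadings))
  qb <- qr.Q(qr(matrix(as.numeric(fo$loadings), ncol = 2)))
  angle <- acos(min(svd(crossprod(qa, qb))$d)) * 180 / pi
  expect_lt(angle, 2)
})

test_that("the zero-factor model matches the diagonal-Gaussian closed form", {
  inp <- model_fa_input(10, seed = 72, n_trials = 20)
  m0 <- fit_fa(inp, 0)
  x <- inp$x; M <- ncol(x)
  v <- apply(x, 1, function(r) mean((r - mean(r))^2))
  ll <- -M / 2 * (nrow(x) * log(2 * pi) + sum(log(v)) + nrow(x))
  expect_equal(m0$loglik, ll, tolerance = 1e-6)
})

test_that("EM log likelihood is non-decreasing over iterations", {
  G <- planted_loadings(15, list(1:4))
  inp <- model_fa_input(15, loadings = G, seed = 73, n_trials = 30)
  m <- fit_fa(inp, 2)
  expect_true(all(diff(m$loglik_trace) > -1e-6))
})

test_that("trial shuffling preserves per-unit content and kills correlation", {
  G <- planted_loadings(12, list(1:6), strength = 1.5)
  inp <- model_fa_input(12, loadings = G, seed = 74, n_trials = 30)
  set.seed(1)
  sh <- trial_shuffle(inp)
  # equal-length trials: per-unit marginals are exact permutations
  for (j in c(1, 5, 12))
    expect_equal(sort(sh$x[j, ]), sort(inp$x[j, ]))
  # within-trial autocorrelation of each unit is preserved bit-exactly
  ac_by_trial <- function(x, tr) {
    sapply(split(seq_along(tr), tr), function(ix)
      sum(x[ix[-1]] * x[ix[-length(ix)]]))
  }
  expect_equal(unname(sort(ac_by_trial(sh$x[3, ], sh$trial))),
               unname(sort(ac_by_trial(inp$x[3, ], inp$trial))),
               tolerance = 1e-12)
  # cross-unit correlation of planted co-members collapses
  expect_gt(cor(inp$x[1, ], inp$x[2, ]), 0.4)
  expect_lt(abs(cor(sh$x[1, ], sh$x[2, ])), 0.1)
  # single trial: no-op
  one <- inp; one$trial <- rep(1L, ncol(one$x))
  expect_identical(trial_shuffle(one)$x, one$x)
})

test_that("factor-count selection finds planted factors and rejects noise", {
  set.seed(75)
  null_p <- vapply(1:6, function(i) {
    inp <- model_fa_input(12, seed = 750 + i, n_trials = 30,
                          bins_per_trial = 60)
    suppressMessages(select_n_factors(inp, max_p = 3, n_boot = 60))$p
  }, 0L)
  expect_gte(sum(null_p == 0), 5)

  two_p <- vapply(1:4, function(i) {
    G <- planted_loadings(16, list(1:4, 9:12), strength = 1.3)
    inp <- model_fa_input(16, loadings = G, seed = 760 + i, n_trials = 30,
                          bins_per_trial = 60)
    suppressMessages(select_n_factors(inp, max_p = 4, n_boot = 60))$p
  }, 0L)
  expect_gte(sum(two_p == 2), 3)
})

test_that("loading significance recovers planted membership", {
  set.seed(76)
  prec <- rec <- numeric(0)
  for (i in 1:4) {
    members <- list(1:5, 10:13)
    G <- planted_loadings(20, members, strength = 1.3)
    inp <- model_fa_input(20, loadings = G, seed = 770 + i, n_trials = 40,
                          bins_per_trial = 60)
    sel <- suppressMessages(select_n_factors(inp, max_p = 3, n_boot = 60))
    if (sel$p < 2) { prec <- c(prec, 0); rec <- c(rec, 0); next }
    sl <- significant_loadings(sel$models[[sel$p + 1]],
                               sel$boot_loadings[[sel$p]])
    hit <- which(rowSums(sl$mask) > 0)
    truth <- unlist(members)
    prec <- c(prec, length(intersect(hit, truth)) / max(length(hit), 1))
    rec <- c(rec, length(intersect(hit, truth)) / length(truth))
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})

test_that("sign convention puts each factor's largest loading positive", {
  G <- planted_loadings(12, list(1:4), strength = -2)  # planted negative
  inp <- model_fa_input(12, loadings = G, seed = 78, n_trials = 30)
  m <- fit_fa(inp, 1)
  sl <- significant_loadings(m, abs(rnorm(100, 0, 0.05)))
  i <- which.max(abs(sl$model$loadings[, 1]))
  expect_gt(sl$model$loadings[i, 1], 0)
  expect_warning(significant_loadings(m, rep(0, 50)), "all zero")
})

test_that("assemblies are typed by area and merged by the subset rule", {
  mask <- cbind(c(TRUE, TRUE, FALSE, TRUE, FALSE),   # c1, c2, m2 -> inter
                c(TRUE, TRUE, FALSE, FALSE, FALSE),  # {c1, c2} subset of F1
                c(FALSE, FALSE, TRUE, FALSE, FALSE)) # singleton -> dropped
  rownames(mask) <- c("c1", "c2", "c3", "m2", "m3")
  a <- assemble(mask, c("dCA1", "dCA1", "dCA1", "mPFC", "mPFC"))
  expect_equal(nrow(a), 2)
  expect_equal(a$type, c("inter-area", "within-dCA1"))
  expect_equal(a$merged_into, c(NA, "F1"))
  # within-area typing
  mask2 <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE), ncol = 1,
                  dimnames = list(rownames(mask), NULL))
  expect_equal(assemble(mask2, c("dCA1", "dCA1", "dCA1", "mPFC", "mPFC"))$type,
               "within-dCA1")
})

test_that("activation significance calibrates and saturates at alpha = 1", {
  G <- planted_loadings(12, list(1:5), strength = 1.5)
  inp <- model_fa_input(12, loadings = G, seed = 79, n_trials = 30)
  m <- fit_fa(inp, 1)
  set.seed(2)
  # scoring a trial-shuffled input through the model calibrates to ~alpha
  act0 <- activation_significance(m, trial_shuffle(inp), alpha = 0.05,
                                  n_boot = 10)
  expect_equal(mean(act0$mask), 0.05, tolerance = 0.2)
  # real (factor-driven) input exceeds the shuffled floor more often
  act <- activation_significance(m, inp, alpha = 0.05, n_boot = 10)
  expect_gt(mean(act$mask), mean(act0$mask))
  act1 <- activation_significance(m, inp, alpha = 1 - 1e-12, n_boot = 3)
  expect_gt(mean(act1$mask), 0.98)
})

test_that("overlap scores follow the Jaccard identities", {
  expect_equal(overlap_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_score(c("a"), c("b")), 0)
  expect_equal(overlap_score(c("1", "2", "3"), c("2", "3", "4")), 0.5)
  expect_equal(overlap_score(character(), character()), 1)
  # symmetry
  expect_equal(overlap_score(c("a", "b", "c"), c("b")),
               overlap_score(c("b"), c("a", "b", "c")))
  # set-level matching
  expect_equal(match_overlap(list(c("a", "b")), list(c("a", "b"))), 1)
  expect_equal(match_overlap(list(c("a", "b")), list(c("x", "y"))), 0)
  expect_equal(match_overlap(list(), list(c("a"))), 0)
})

test_that("ICA detects a strongly planted assembly and rejects independence", {
  set.seed(80)
  G <- planted_loadings(40, list(5:8), strength = 1.5)
  inp <- model_fa_input(40, loadings = G, seed = 81, n_trials = 40,
                        bins_per_trial = 60)
  ica <- ica_assemblies(inp)
  expect_equal(nrow(ica), 1)
  expect_equal(sort(ica$members[[1]]), sprintf("u%02d", 5:8))
  # independent units: no eigenvalue clears the Marchenko-Pastur bound
  inp0 <- model_fa_input(40, seed = 82, n_trials = 40, bins_per_trial = 60)
  expect_equal(nrow(ica_assemblies(inp0)), 0)
})
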