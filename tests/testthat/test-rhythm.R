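test_that("autocorrelograms are flat at 1 for Poisson and periodic for
           cosine-modulated trains", {
  set.seed(101)
  flat <- poisson_train(function(t) rep(20, length(t)), 200)
  acg <- autocorrelogram(flat, bin_s = 0.02, max_lag = 1, duration_s = 200)
  expect_equal(mean(acg$value), 1, tolerance = 0.05)
  expect_equal(acg$value, rev(acg$value), tolerance = 1e-12)  # symmetry
  expect_lt(acg_modulation_index(acg), 0.2)

  mod <- poisson_train(function(t) 20 * (1 + 0.6 * cos(2 * pi * 4.5 * t)), 200)
  acg_m <- autocorrelogram(mod, bin_s = 0.02, max_lag = 1, duration_s = 200)
  # cosine-modulated Poisson: ACG peaks at multiples of 1/4.5 s ~ 222 ms
  side <- acg_m[acg_m$lag > 0.1 & acg_m$lag < 0.35, ]
  expect_equal(side$lag[which.max(side$value)], 1 / 4.5, tolerance = 0.03)
  expect_gt(acg_modulation_index(acg_m), 0.5)
  # modulation index is monotone in the planted depth
  weak <- poisson_train(function(t) 20 * (1 + 0.2 * cos(2 * pi * 4.5 * t)), 200)
  acg_w <- autocorrelogram(weak, bin_s = 0.02, max_lag = 1, duration_s = 200)
  expect_lt(acg_modulation_index(acg_w), acg_modulation_index(acg_m))
  # full-band normalization saturates at 1
  expect_equal(acg_modulation_index(acg_m, band = c(1, 15)), 1,
               tolerance = 1e-9)
  expect_true(attr(autocorrelogram(flat[1:10], 0.02, 1, duration_s = 200),
                   "low_confidence"))
})

test_that("multitaper coherence separates shared from independent modulation", {
  set.seed(102)
  epochs <- tibble::tibble(t0 = seq(0, 116, by = 4), t1 = seq(4, 120, by = 4))
  shared <- function(t) 1 + 0.6 * cos(2 * pi * 4.5 * t)
  a <- poisson_train(function(t) 15 * shared(t), 120)
  b <- poisson_train(function(t) 15 * shared(t), 120)
  x <- poisson_train(function(t) rep(15, length(t)), 120)
  y <- poisson_train(function(t) rep(15, length(t)), 120)
  co_shared <- pair_coherence(a, b, epochs)
  co_ind <- pair_coherence(x, y, epochs)
  expect_gt(co_shared$band_mean, 3 * co_ind$band_mean)
  expect_true(all(co_shared$spectrum$coherence >= 0 &
                    co_shared$spectrum$coherence <= 1))
})

test_that("rate-matched cross-correlograms localize a planted lag", {
  set.seed(103)
  a <- sort(runif(3000, 0, 300))
  b <- sort(a + 0.025 + rnorm(3000, sd = 0.003))  # B follows A by 25 ms
  epochs <- tibble::tibble(t0 = seq(0, 290, by = 10), t1 = seq(10, 300, by = 10))
  ccg <- crosscorrelogram(a, b, epochs, bin_s = 0.02, max_lag = 0.2,
                          n_draws = 5)
  # positive lag = reference train a fires first; +25 ms -> the +0.02 bin
  expect_equal(ccg$lag[which.max(ccg$value)], 0.02, tolerance = 1e-9)
  # independent trains: flat
  set.seed(104)
  x <- sort(runif(2000, 0, 200)); y <- sort(runif(2000, 0, 200))
  ep2 <- tibble::tibble(t0 = seq(0, 190, by = 10), t1 = seq(10, 200, by = 10))
  ccg0 <- crosscorrelogram(x, y, ep2, bin_s = 0.02, max_lag = 0.2, n_draws = 5)
  expect_lt(sd(ccg0$value) / mean(ccg0$value), 0.5)
  # antisymmetry of the lag convention under argument swap (equal counts so
  # no subsampling randomness)
  ccg_ab <- crosscorrelogram(a, b, epochs, 0.02, 0.2, n_draws = 1)
  ccg_ba <- crosscorrelogram(b, a, epochs, 0.02, 0.2, n_draws = 1)
  expect_equal(ccg_ab$value, rev(ccg_ba$value), tolerance = 0.25)
  # a pair empty in all windows is skipped
  expect_message(
    out <- crosscorrelogram(numeric(0), y, ep2, 0.02, 0.2), "skipped")
  expect_null(out)
})

test_that("CCG spectra expose planted rhythms and detect condition drops", {
  set.seed(105)
  mk_ccgs <- function(m, n_pairs) {
    t(replicate(n_pairs, {
      shift <- runif(1, 0, 2 * pi)
      lag <- seq(-1, 1, by = 0.02)
      0.05 * (1 + m * cos(2 * pi * 4.5 * lag + shift * 0)) +
        rnorm(length(lag), sd = 0.004)
    }))
  }
  strong <- mk_ccgs(0.5, 12); weak <- mk_ccgs(0.05, 12)
  sp <- ccg_spectrum(tibble::tibble(lag = seq(-1, 1, by = 0.02),
                                    value = strong[1, ]))
  sub <- sp[sp$freq >= 1 & sp$freq <= 15, ]
  expect_equal(sub$freq[which.max(sub$power)], 4.5, tolerance = 0.6)
  bt <- ccg_band_test(strong, weak, n_perm = 1000)
  inb <- bt$freq >= 3.5 & bt$freq <= 5.5
  expect_true(any(bt$sig[inb]))
  expect_true(all(bt$power_a[inb] > bt$power_b[inb]))
  bt0 <- ccg_band_test(strong, strong, n_perm = 200)
  expect_false(any(bt0$sig))
})

test_that("lead/lag balance has the documented sign convention", {
  lag <- seq(-1, 1, by = 0.1)
  sym <- tibble::tibble(lag = lag, value = dnorm(lag, 0, 0.3))
  expect_equal(lead_lag_balance(sym), 0, tolerance = 1e-9)
  pos <- tibble::tibble(lag = lag, value = as.numeric(lag > 0))
  expect_equal(lead_lag_balance(pos), 1)
  neg <- tibble::tibble(lag = lag, value = as.numeric(lag < 0))
  expect_equal(lead_lag_balance(neg), -1)
})

test_that("phase locking requires spikes and a live band", {
  lfp <- tibble::tibble(time_s = seq(0, 10, by = 1 / 200),
                        voltage = sin(2 * pi * 9 * seq(0, 10, by = 1 / 200)))
  attr(lfp, "fs_hz") <- 200
  expect_null(spike_phase_locking(runif(10, 0, 10), lfp, c(8, 12)))
  flat <- dplyr::mutate(lfp, voltage = 0)
  attr(flat, "fs_hz") <- 200
  expect_error(spike_phase_locking(runif(100, 0, 10), flat, c(8, 12)), "flat")
})

test_that("assembly phase classification separates sample- and choice-active", {
  cfg <- simulate_config(n_units = c(dCA1 = 8, mPFC = 8), n_trials = 42,
                         cue_frac = 0,
                         assemblies = list(list(n_dca1 = 3, n_mpfc = 3)))
  sim <- simulate_session(cfg, seed = 106)
  s <- select_units(sim$session)
  inp <- build_fa_input(s, "joint")
  set.seed(1)
  aset <- suppressMessages(detect_assemblies(inp, max_p = 2, n_boot = 50))
  expect_gte(aset$selection$p, 1)
  cls <- classify_assembly_phase(aset, s, factor = 1)
  expect_true(cls$phase_class %in% c("sample-active", "choice-active", "none"))
  al <- align_activation(aset, s, 1, "t_sample", c(-2, 1))
  expect_equal(dim(al$activation),
               c(sum(!is.na(s$trials$t_sample)), 60))
  ec <- error_activation_contrast(al, n_perm = 200)
  expect_equal(nrow(ec), 60)
  expect_true(all(ec$p >= 0 & ec$p <= 1))
})
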