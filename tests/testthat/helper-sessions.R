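`%||%` <- function(a, b) if (is.null(a)) b else a

# Small sessions used across test files. Everything is generated in code at
# test time; fixture sizes trade statistical power against suite runtime.

tiny_session <- function(seed = 42, n_trials = 30, ...) {
  cfg <- simulate_config(n_units = c(dCA1 = 8, mPFC = 8), n_trials = n_trials,
                         assemblies = list(list(n_dca1 = 3, n_mpfc = 3)), ...)
  simulate_session(cfg, seed = seed)
}

null_session <- function(seed, n_trials = 30, n_per_area = 8) {
  cfg <- simulate_config(n_units = c(dCA1 = n_per_area, mPFC = n_per_area),
                         n_trials = n_trials, cue_frac = 0,
                         assemblies = list(), rhythm_m = 0,
                         error_frac = c(`4` = 0, `8` = 0, `16` = 0))
  simulate_session(cfg, seed = seed)
}

# hand-built two-unit session with exactly known spikes/trials
toy_session <- function() {
  trials <- tibble::tibble(
    trial = 1:3, cue_side = c("L", "R", "L"), delay_s = c(4, 4, 8),
    outcome = c("correct", "correct", "error"),
    t_cue = c(10, 40, 70), t_sample = c(12, 42, 72),
    t_tone = c(16, 46, 80), t_nosepoke = c(17, 47, 81),
    t_choice = c(18.5, 48.5, 82.5), t_reward = c(19, 49, NA))
  spikes <- tibble::tibble(
    unit_id = rep(c("u1", "u2"), c(5, 4)),
    area = rep(c("dCA1", "mPFC"), c(5, 4)),
    spike_time_s = c(11, 12.2, 15, 41.9, 73, 12.1, 42.1, 46.5, 72.5))
  new_session(spikes, trials, duration_s = 100)
}

# fa_input built directly from a known factor model with equal-length trials
model_fa_input <- function(n_units = 20, n_trials = 40, bins_per_trial = 100,
                           loadings = NULL, psi = NULL, seed = 1) {
  set.seed(seed)
  M <- n_trials * bins_per_trial
  p <- if (is.null(loadings)) 0 else ncol(loadings)
  psi <- psi %||% rep(1, n_units)
  mu <- runif(n_units, 2, 6)
  x <- matrix(rnorm(n_units * M, sd = sqrt(psi)), n_units, M) + mu
  if (p > 0) x <- x + loadings %*% matrix(rnorm(p * M), p, M)
  rownames(x) <- sprintf("u%02d", seq_len(n_units))
  structure(list(x = x, unit_id = rownames(x),
                 area = rep(c("dCA1", "mPFC"), length.out = n_units),
                 time = (seq_len(M) - 1) * 0.05,
                 trial = rep(seq_len(n_trials), each = bins_per_trial),
                 bin_s = 0.05),
            class = "fa_input")
}

# planted-loading matrix: `members` load `strength` on one factor
planted_loadings <- function(n_units, member_idx, strength = 1) {
  G <- matrix(0, n_units, length(member_idx))
  for (k in seq_along(member_idx)) G[member_idx[[k]], k] <- strength
  G
}

# hand-built rate tensor (trials x units x bins array plus labels)
make_tensor <- function(rates, labels, times = NULL, areas = NULL) {
  d <- dim(rates)
  structure(list(
    rates = rates, times = times %||% (seq_len(d[3]) - 1) * 0.05,
    unit_id = sprintf("u%02d", seq_len(d[2])),
    area = areas %||% rep("dCA1", d[2]),
    trials = tibble::tibble(trial = seq_len(d[1]), cue_side = labels,
                            outcome = "correct"),
    align = "t_sample", bin_s = 0.05,
    bandwidths = rep(0.05, d[2])), class = "rate_tensor")
}

# inhomogeneous Poisson draw on a fine grid (independent oracle for the
# package's own simulator)
poisson_train <- function(rate_fn, duration, dt = 0.001) {
  tt <- seq(dt / 2, duration, by = dt)
  n <- rpois(length(tt), rate_fn(tt) * dt)
  sort(rep(tt[n > 0], n[n > 0]) + runif(sum(n), -dt / 2, dt / 2))
}
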