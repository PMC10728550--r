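#' Configuration for the DNMTS session simulator
#'
#' Defaults emulate the recorded study conditions: ~30 well-isolated units per
#' area, 150 trials per session (50 each at 4/8/16 s delays, equal left/right
#' counts per delay, presented in shuffled blocks of 10), log-normal baseline
#' rates (median 2 Hz), planted within- and inter-area cell assemblies driven
#' by a shared multiplicative gain on 50-ms bins, 4.5 Hz co-modulation of
#' inter-area assembly members confined to the 4 s before the sample press,
#' sequential delay-tiling side-selective mPFC tuning, and error trials on
#' which mPFC delay tuning and the rhythm depth are attenuated.
#'
#' @param n_units named vector, units per area.
#' @param n_trials total trials (multiple of `3 * 2` for balance).
#' @param delays_s delay lengths (s).
#' @param baseline_median_hz,baseline_sigma_log log-normal baseline firing.
#' @param cue_frac fraction of units given side-selective tuning.
#' @param ca1_amp_hz,mpfc_amp_hz cue-bump amplitudes (dCA1 stronger, as in the
#'   recorded data); `tuning_width_s` is the bump SD.
#' @param delay_code `"sequential"` (bumps tiling the delay) or `"stable"`
#'   (constant side-selective offset across the delay) for tuned mPFC units.
#' @param assemblies list of planted assemblies, each
#'   `list(n_dca1 =, n_mpfc =)`; members are drawn from the unit pools and get
#'   `assembly_baseline_hz` baseline.
#' @param gain_sd SD of the shared log-gain per 50-ms bin (0 = no
#'   co-fluctuation).
#' @param rhythm_f_hz,rhythm_m rhythm frequency and modulation depth `m` in
#'   `[0, 1]`; applied as `1 + m*cos(2*pi*f*t + phi)` with a common phase per
#'   trial, to inter-area assembly members, in the 4 s pre-sample window only.
#' @param error_frac error probability per delay (named by delay).
#' @param miss_frac miss probability per trial.
#' @param error_attenuation multipliers applied on error trials to mPFC delay
#'   tuning amplitude and to rhythm depth.
#' @param iti_s inter-trial interval after correct trials (errors/misses add
#'   10 s time-out).
#' @param dt_s simulation grid step for the inhomogeneous Poisson draw.
#' @return a `sim_config` list.
#' @export
simulate_config <- function(n_units = c(dCA1 = 30, mPFC = 30),
                            n_trials = 150,
                            delays_s = c(4, 8, 16),
                            baseline_median_hz = 2,
                            baseline_sigma_log = 0.5,
                            cue_frac = 0.5,
                            ca1_amp_hz = 6,
                            mpfc_amp_hz = 3,
                            tuning_width_s = 0.6,
                            delay_code = c("sequential", "stable"),
                            assemblies = list(
                              list(n_dca1 = 3, n_mpfc = 3),
                              list(n_dca1 = 3, n_mpfc = 3),
                              list(n_dca1 = 3, n_mpfc = 0)),
                            assembly_baseline_hz = 5,
                            gain_sd = 0.8,
                            rhythm_f_hz = 4.5,
                            rhythm_m = 0.3,
                            error_frac = c(`4` = 0.10, `8` = 0.15, `16` = 0.35),
                            miss_frac = 0,
                            error_attenuation = c(mpfc_delay = 0.3, rhythm = 0.3),
                            iti_s = 5,
                            dt_s = 0.005) {
  delay_code <- match.arg(delay_code)
  stopifnot(rhythm_m >= 0, rhythm_m <= 1, n_trials %% (2 * length(delays_s)) == 0)
  need <- vapply(assemblies, function(a) c(a$n_dca1 %||% 0, a$n_mpfc %||% 0),
                 numeric(2))
  if (length(assemblies) > 0 &&
      (sum(need[1, ]) > n_units[["dCA1"]] || sum(need[2, ]) > n_units[["mPFC"]]))
    abort("planted assemblies need more units than the area pools contain")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a DNMTS session with planted ground truth
#'
#' Draws inhomogeneous-Poisson spike trains whose intensity for unit i on
#' trial k is baseline x side-dependent Gaussian cue bump x shared assembly
#' gain (members only, 50-ms resolution) x rhythmic factor (inter-area
#' assembly members, pre-sample window only), with mPFC delay tuning and
#' rhythm depth attenuated on error trials.
#'
#' @param config a [simulate_config()].
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @return list with elements `session` (a `dnmts_session`) and `truth`
#'   (assembly memberships, tuned-unit table, rhythm and attenuation
#'   parameters, seed).
#' @export
simulate_session <- function(config = simulate_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config

  ## ---- trial schedule -----------------------------------------------------
  per_delay <- cfg$n_trials / length(cfg$delays_s)
  sched <- tidyr::expand_grid(delay_s = cfg$delays_s,
                              cue_side = c("L", "R"),
                              rep = seq_len(per_delay / 2))
  sched <- sched[sample.int(nrow(sched)), c("delay_s", "cue_side")]
  sched$trial <- seq_len(nrow(sched))
  sched$outcome <- "correct"
  miss <- runif(nrow(sched)) < cfg$miss_frac
  sched$outcome[miss] <- "miss"
  for (d in cfg$delays_s) {             # exact error counts per delay
    pool <- which(sched$delay_s == d & !miss)
    n_err <- round(cfg$error_frac[[as.character(d)]] * length(pool))
    if (n_err > 0) sched$outcome[sample(pool, n_err)] <- "error"
  }

  t0 <- 10
  n_tr <- nrow(sched)
  t_cue <- t_sample <- t_tone <- t_nosepoke <- t_choice <- t_reward <-
    rep(NA_real_, n_tr)
  cursor <- t0
  # latencies log-normal, independent of delay and outcome; quantized to
  # 0.25 s as behavioral timestamps effectively are
  lat <- function(median_s, sdlog = 0.3)
    max(0.25, round(rlnorm(1, log(median_s), sdlog) * 4) / 4)
  for (k in seq_len(n_tr)) {
    t_cue[k] <- cursor
    t_sample[k] <- t_cue[k] + lat(1.5)
    t_tone[k] <- t_sample[k] + sched$delay_s[k]
    if (sched$outcome[k] == "miss") {
      cursor <- t_tone[k] + 10 + cfg$iti_s
      next
    }
    t_nosepoke[k] <- t_tone[k] + 0.5 + lat(0.8)
    t_choice[k] <- t_nosepoke[k] + lat(1.5)
    t_reward[k] <- if (sched$outcome[k] == "correct") t_choice[k] + 0.5 else NA_real_
    cursor <- t_choice[k] + cfg$iti_s + if (sched$outcome[k] == "error") 10 else 0
  }
  trials <- tibble(trial = sched$trial, cue_side = sched$cue_side,
                   delay_s = sched$delay_s, outcome = sched$outcome,
                   t_cue = t_cue, t_sample = t_sample, t_tone = t_tone,
                   t_nosepoke = t_nosepoke, t_choice = t_choice,
                   t_reward = t_reward)
  duration <- cursor + 5

  ## ---- unit pools and ground truth ---------------------------------------
  unit_ids <- c(sprintf("c%02d", seq_len(cfg$n_units[["dCA1"]])),
                sprintf("m%02d", seq_len(cfg$n_units[["mPFC"]])))
  areas <- rep(c("dCA1", "mPFC"), cfg$n_units[c("dCA1", "mPFC")])
  baseline <- rlnorm(length(unit_ids), log(cfg$baseline_median_hz),
                     cfg$baseline_sigma_log)

  ca1_pool <- unit_ids[areas == "dCA1"]
  pfc_pool <- unit_ids[areas == "mPFC"]
  asm <- list()
  free_c <- ca1_pool; free_m <- pfc_pool
  for (j in seq_along(cfg$assemblies)) {
    a <- cfg$assemblies[[j]]
    mc <- if ((a$n_dca1 %||% 0) > 0) sample(free_c, a$n_dca1) else character()
    mm <- if ((a$n_mpfc %||% 0) > 0) sample(free_m, a$n_mpfc) else character()
    free_c <- setdiff(free_c, mc); free_m <- setdiff(free_m, mm)
    type <- if (length(mc) > 0 && length(mm) > 0) "inter-area"
            else if (length(mc) > 0) "within-dCA1" else "within-mPFC"
    asm[[j]] <- list(id = paste0("A", j), members = c(mc, mm), type = type)
  }
  asm_members <- unique(unlist(lapply(asm, `[[`, "members")))
  baseline[unit_ids %in% asm_members] <- cfg$assembly_baseline_hz
  inter_members <- unique(unlist(lapply(asm[vapply(asm, `[[`, "", "type") ==
                                               "inter-area"], `[[`, "members")))

  tuned <- tibble(unit_id = character(), area = character(),
                  pref_side = character(), amp_hz = numeric(),
                  center_s = numeric(), width_s = numeric(),
                  ref_event = character(), kind = character())
  for (i in seq_along(unit_ids)) {
    if (runif(1) >= cfg$cue_frac) next
    side <- sample(c("L", "R"), 1)
    if (areas[i] == "dCA1") {
      ref <- sample(c("t_sample", "t_choice"), 1)
      tuned <- bind_rows(tuned, tibble(
        unit_id = unit_ids[i], area = areas[i], pref_side = side,
        amp_hz = cfg$ca1_amp_hz * runif(1, 0.7, 1.3),
        center_s = runif(1, -0.5, 0.5), width_s = cfg$tuning_width_s,
        ref_event = ref, kind = "press"))
    } else {
      kind <- if (cfg$delay_code == "stable") "delay_stable" else "delay_tile"
      tuned <- bind_rows(tuned, tibble(
        unit_id = unit_ids[i], area = areas[i], pref_side = side,
        amp_hz = cfg$mpfc_amp_hz * runif(1, 0.7, 1.3),
        center_s = runif(1, 0, max(cfg$delays_s)),
        width_s = cfg$tuning_width_s,
        ref_event = "t_sample", kind = kind))
    }
  }

  ## ---- shared gain and spike draw -----------------------------------------
  dt <- cfg$dt_s
  n_grid <- ceiling(duration / dt)
  tgrid <- (seq_len(n_grid) - 0.5) * dt
  gain_bin <- 0.05
  n_gbin <- ceiling(duration / gain_bin)
  up <- round(gain_bin / dt)
  gains <- lapply(asm, function(a) {
    g <- exp(cfg$gain_sd * rnorm(n_gbin) - cfg$gain_sd^2 / 2)
    rep(g, each = up)[seq_len(n_grid)]
  })
  phi <- runif(n_tr, 0, 2 * pi)  # common rhythm phase per trial
  done <- !is.na(trials$t_choice)
  # index range of grid midpoints falling in [a, b)
  win <- function(a, b) {
    i0 <- max(1L, as.integer(floor(a / dt + 0.5)) + 1L)
    i1 <- min(n_grid, as.integer(ceiling(b / dt - 0.5)))
    if (i1 < i0) integer() else i0:i1
  }

  spikes_list <- vector("list", length(unit_ids))
  for (i in seq_along(unit_ids)) {
    uid <- unit_ids[i]
    rate <- rep(baseline[i], n_grid)
    tu <- tuned[tuned$unit_id == uid, ]
    if (nrow(tu) == 1) {
      pref <- trials$cue_side == tu$pref_side
      for (k in which(pref)) {
        amp <- tu$amp_hz
        if (tu$kind == "press") {
          ref <- trials[[tu$ref_event]][k]
          if (is.na(ref)) next
          ctr <- ref + tu$center_s
          idx <- win(ctr - 4 * tu$width_s, ctr + 4 * tu$width_s)
          rate[idx] <- rate[idx] +
            amp * exp(-(tgrid[idx] - ctr)^2 / (2 * tu$width_s^2))
        } else {
          if (trials$outcome[k] == "error")
            amp <- amp * cfg$error_attenuation[["mpfc_delay"]]
          d0 <- trials$t_sample[k]; d1 <- trials$t_tone[k]
          if (tu$kind == "delay_stable") {
            idx <- win(d0, d1)
            rate[idx] <- rate[idx] + amp
          } else {
            ctr <- d0 + tu$center_s
            if (tu$center_s <= trials$delay_s[k] + 1) {
              idx <- win(ctr - 4 * tu$width_s,
                         min(ctr + 4 * tu$width_s, d1 + 1))
              rate[idx] <- rate[idx] +
                amp * exp(-(tgrid[idx] - ctr)^2 / (2 * tu$width_s^2))
            }
          }
        }
      }
    }
    for (j in seq_along(asm))
      if (uid %in% asm[[j]]$members) rate <- rate * gains[[j]]
    if (uid %in% inter_members && cfg$rhythm_m > 0) {
      for (k in which(done)) {
        m <- cfg$rhythm_m
        if (trials$outcome[k] == "error") m <- m * cfg$error_attenuation[["rhythm"]]
        idx <- win(trials$t_sample[k] - 4, trials$t_sample[k])
        rate[idx] <- rate[idx] *
          (1 + m * cos(2 * pi * cfg$rhythm_f_hz * tgrid[idx] + phi[k]))
      }
    }
    counts <- rpois(n_grid, pmax(rate, 0) * dt)
    hit <- which(counts > 0)
    st <- rep(tgrid[hit] - dt / 2, counts[hit]) + runif(sum(counts[hit]), 0, dt)
    spikes_list[[i]] <- tibble(unit_id = uid, area = areas[i],
                               spike_time_s = sort(st))
  }

  session <- new_session(bind_rows(spikes_list), trials, duration_s = duration)
  truth <- list(
    assemblies = asm,
    cue_tuned = tuned,
    baseline_hz = setNames(baseline, unit_ids),
    rhythm = list(f_hz = cfg$rhythm_f_hz, m = cfg$rhythm_m,
                  epoch = "4 s pre-sample", members = inter_members,
                  phase = phi),
    error_attenuation = cfg$error_attenuation,
    seed = seed)
  list(session = session, truth = truth)
}

#' Simulate a per-area LFP and optionally phase-lock selected units
#'
#' LFP per area is 1/f background noise plus a theta (9 Hz) sinusoid and an
#' optional low-frequency (4.5 Hz) component. Units listed in `lock` have
#' their spike trains regenerated as inhomogeneous Poisson with intensity
#' proportional to a von Mises function of the instantaneous phase of the
#' requested component, planting phase locking of known concentration.
#'
#' @param session a `dnmts_session`.
#' @param fs_hz LFP sample rate.
#' @param theta_amp,low_amp,noise_sd component amplitudes (a.u.).
#' @param theta_f_hz,low_f_hz component frequencies.
#' @param lock optional tibble `unit_id`, `freq_hz` (which component),
#'   `kappa` (von Mises concentration), `phase` (preferred phase, rad).
#' @param seed RNG seed.
#' @return the session with an `lfp` element attached (attribute `fs_hz`).
#' @export
simulate_lfp <- function(session, fs_hz = 250, theta_amp = 1, low_amp = 0.3,
                         noise_sd = 0.5, theta_f_hz = 9, low_f_hz = 4.5,
                         lock = NULL, seed = 1) {
  set.seed(seed)
  n <- ceiling(session$duration_s * fs_hz)
  tt <- (seq_len(n) - 1) / fs_hz
  one_over_f <- function(n) {
    z <- fft(complex(real = rnorm(n), imaginary = rnorm(n)))
    f <- pmax(seq(0, 1, length.out = n), 1 / n)
    x <- Re(fft(z / sqrt(f), inverse = TRUE)) / n
    x / sd(x)
  }
  comp <- function() theta_amp * cos(2 * pi * theta_f_hz * tt) +
    low_amp * cos(2 * pi * low_f_hz * tt) + noise_sd * one_over_f(n)
  lfp <- bind_rows(
    tibble(area = "dCA1", time_s = tt, voltage = comp()),
    tibble(area = "mPFC", time_s = tt, voltage = comp()))
  attr(lfp, "fs_hz") <- fs_hz
  if (!is.null(lock)) {
    u <- session_units(session)
    for (r in seq_len(nrow(lock))) {
      uid <- lock$unit_id[r]
      base <- u$mean_rate_hz[u$unit_id == uid]
      ph <- 2 * pi * lock$freq_hz[r] * tt  # phase of the pure component
      k <- lock$kappa[r]
      lam <- base * exp(k * cos(ph - lock$phase[r])) / besselI(k, 0)
      counts <- rpois(n, lam / fs_hz)
      hit <- which(counts > 0)
      st <- sort(rep(tt[hit], counts[hit]) + runif(sum(counts[hit]), 0, 1 / fs_hz))
      ar <- as.character(session$spikes$area[session$spikes$unit_id == uid][1])
      session$spikes <- session$spikes[session$spikes$unit_id != uid, ]
      session$spikes <- arrange(
        bind_rows(session$spikes,
                  tibble(unit_id = uid, area = ar, spike_time_s = st)),
        .data$unit_id, .data$spike_time_s)
    }
  }
  session$lfp <- lfp
  session
}
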