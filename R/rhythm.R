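#' Event-locked epoch windows
#'
#' Helper returning `[t0, t1)` windows around a trial event, used to restrict
#' spike-pair analyses to e.g. the 4 s preceding sample presses.
#'
#' @param session a `dnmts_session`.
#' @param align event column.
#' @param window `c(pre, post)` seconds relative to the event.
#' @param outcomes restrict to these outcomes (default correct + error).
#' @return tibble `trial`, `t0`, `t1`.
#' @export
event_epochs <- function(session, align = "t_sample", window = c(-4, 0),
                         outcomes = c("correct", "error")) {
  tr <- session$trials
  tr <- tr[tr$outcome %in% outcomes & !is.na(tr[[align]]), ]
  tibble(trial = tr$trial, t0 = tr[[align]] + window[1],
         t1 = tr[[align]] + window[2])
}

spikes_in <- function(st, t0, t1) st[st >= t0 & st < t1]

#' Rate-normalized spike-train autocorrelogram
#'
#' Coincidence counts at lag bins (zero-lag self-pairs excluded), divided by
#' the count expected from a homogeneous Poisson train of the same rate, so
#' the asymptote is ~1. Computed over the supplied epochs (or the whole
#' recording when `epochs` is `NULL`).
#'
#' @param spike_times numeric vector (s).
#' @param bin_s lag bin width (s).
#' @param max_lag maximum lag (s).
#' @param epochs optional tibble `t0`, `t1`; `duration_s` is required when
#'   `epochs` is `NULL`.
#' @param duration_s recording length (s).
#' @param rate_normalized divide by the Poisson expectation.
#' @return a `correlogram` tibble `lag`, `value` (attribute
#'   `low_confidence` when under 50 spikes).
#' @export
autocorrelogram <- function(spike_times, bin_s = 0.02, max_lag = 1,
                            epochs = NULL, duration_s = NULL,
                            rate_normalized = TRUE) {
  if (is.null(epochs)) {
    stopifnot(!is.null(duration_s))
    epochs <- tibble(t0 = 0, t1 = duration_s)
  }
  nb <- 2 * round(max_lag / bin_s) + 1
  lags <- seq(-max_lag, max_lag, by = bin_s)
  counts <- numeric(nb)
  expected <- numeric(nb)
  n_total <- 0
  for (k in seq_len(nrow(epochs))) {
    st <- spikes_in(spike_times, epochs$t0[k], epochs$t1[k])
    n <- length(st)
    n_total <- n_total + n
    if (n < 2) next
    counts <- counts + as.numeric(correlogram_cpp(st, st, bin_s, max_lag, TRUE))
    Tk <- epochs$t1[k] - epochs$t0[k]
    # finite-window overlap: pairs at lag tau only arise over Tk - |tau|
    expected <- expected + n * (n / Tk) * bin_s * pmax(1 - abs(lags) / Tk, 0)
  }
  value <- if (rate_normalized && all(expected > 0)) counts / expected
           else counts
  out <- tibble(lag = lags, value = value)
  attr(out, "low_confidence") <- n_total < 50
  attr(out, "bin_s") <- bin_s
  class(out) <- c("correlogram", class(out))
  out
}

#' Band-power modulation index of an autocorrelogram
#'
#' Fraction of the mean-removed ACG's spectral power (lags up to
#' `max_lag_s`) falling in `band`, relative to the total over `total_band`.
#' This band-fraction definition is this package's own; an alternative
#' (peak - trough) / (peak + trough) over 150-300 ms lags is available via
#' `method`.
#'
#' @param acg a [autocorrelogram()] result.
#' @param band frequency band of interest (Hz).
#' @param total_band normalizing band (Hz).
#' @param max_lag_s lags entering the spectrum.
#' @param method `"band_fraction"` or `"peak_trough"`.
#' @return scalar in `[0, 1]`.
#' @export
acg_modulation_index <- function(acg, band = c(3.5, 5.5),
                                 total_band = c(1, 15), max_lag_s = 1,
                                 method = c("band_fraction", "peak_trough")) {
  method <- match.arg(method)
  bin_s <- attr(acg, "bin_s") %||% diff(acg$lag[1:2])
  if (method == "peak_trough") {
    seg <- acg$value[abs(acg$lag) >= 0.15 & abs(acg$lag) <= 0.3]
    pk <- max(seg); tr <- min(seg)
    return(if (pk + tr <= 0) 0 else (pk - tr) / (pk + tr))
  }
  v <- acg$value[abs(acg$lag) <= max_lag_s]
  v <- v - mean(v)
  sp <- series_spectrum(v, 1 / bin_s)
  num <- sum(sp$power[sp$freq >= band[1] & sp$freq <= band[2]])
  den <- sum(sp$power[sp$freq >= total_band[1] & sp$freq <= total_band[2]])
  if (den == 0) 0 else min(num / den, 1)
}

# zero-padded periodogram of a short series; Hann taper suppresses sidelobe
# leakage from broad envelope components
series_spectrum <- function(v, fs, pad = 512, taper = TRUE) {
  if (taper) {
    L <- length(v)
    v <- v * 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  }
  n <- max(pad, length(v))
  z <- fft(c(v, rep(0, n - length(v))))
  freq <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2))
  tibble(freq = freq[half], power = Mod(z[half])^2)
}

# discrete prolate spheroidal sequences via the symmetric tridiagonal form
dpss_tapers <- function(n, nw = 3, k = 5) {
  W <- nw / n
  d <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- diag(d)
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper coherence between two spike trains
#'
#' Magnitude-squared coherence between mean-subtracted binned spike counts
#' over the supplied epochs, estimated by averaging multitaper cross- and
#' auto-spectra over tapers and epochs (Slepian tapers, `NW = 3`, `k = 5`).
#'
#' @param spikes_a,spikes_b spike-time vectors (s).
#' @param epochs tibble `t0`, `t1` of equal-length windows.
#' @param bin_s count bin (default 10 ms).
#' @param band band over which `band_mean` is taken (Hz).
#' @param nw,k multitaper parameters.
#' @return list `spectrum` (tibble `freq`, `coherence`), `band_mean`.
#' @export
pair_coherence <- function(spikes_a, spikes_b, epochs, bin_s = 0.01,
                           band = c(3.5, 5.5), nw = 3, k = 5) {
  stopifnot(nrow(epochs) > 0)
  len <- min(epochs$t1 - epochs$t0)
  n <- floor(len / bin_s)
  tap <- dpss_tapers(n, nw, k)
  sxx <- syy <- numeric(n)
  sxy <- complex(real = numeric(n), imaginary = numeric(n))
  for (e in seq_len(nrow(epochs))) {
    br <- epochs$t0[e] + (0:n) * bin_s
    xa <- tabulate(findInterval(spikes_in(spikes_a, epochs$t0[e], br[n + 1]), br),
                   nbins = n)
    xb <- tabulate(findInterval(spikes_in(spikes_b, epochs$t0[e], br[n + 1]), br),
                   nbins = n)
    xa <- xa - mean(xa); xb <- xb - mean(xb)
    for (j in seq_len(k)) {
      fa <- fft(xa * tap[, j]); fb <- fft(xb * tap[, j])
      sxx <- sxx + Mod(fa)^2
      syy <- syy + Mod(fb)^2
      sxy <- sxy + fa * Conj(fb)
    }
  }
  half <- seq_len(floor(n / 2))
  freq <- (half - 1) / (n * bin_s)
  coh <- Mod(sxy[half])^2 / pmax(sxx[half] * syy[half], 1e-300)
  inb <- freq >= band[1] & freq <= band[2]
  list(spectrum = tibble(freq = freq, coherence = coh),
       band_mean = mean(coh[inb]))
}

#' Rate-matched pairwise cross-correlogram
#'
#' For every draw, within each event window the higher-count train is
#' randomly subsampled to the lower count before coincidences are tallied,
#' removing firing-rate offsets between the cells; counts are averaged over
#' draws and divided by the per-draw matched total spike count. Positive lag
#' means the reference train `spikes_a` (dCA1 by convention) fires first.
#'
#' @param spikes_a,spikes_b spike-time vectors; `spikes_a` is the reference.
#' @param epochs tibble `t0`, `t1`.
#' @param bin_s lag bin (20 or 100 ms).
#' @param max_lag maximum lag (s).
#' @param n_draws subsampling draws (default 100).
#' @return a `correlogram` tibble `lag`, `value` (coincidences per spike),
#'   or `NULL` when either train is empty in every window.
#' @export
crosscorrelogram <- function(spikes_a, spikes_b, epochs, bin_s = 0.02,
                             max_lag = 1, n_draws = 100) {
  nb <- 2 * round(max_lag / bin_s) + 1
  per_win <- map(seq_len(nrow(epochs)), function(e) {
    list(a = spikes_in(spikes_a, epochs$t0[e], epochs$t1[e]),
         b = spikes_in(spikes_b, epochs$t0[e], epochs$t1[e]))
  })
  per_win <- per_win[vapply(per_win, function(w)
    length(w$a) > 0 && length(w$b) > 0, TRUE)]
  if (length(per_win) == 0) {
    inform("no window contains spikes from both trains; pair skipped")
    return(NULL)
  }
  lags <- seq(-max_lag, max_lag, by = bin_s)
  # finite-window overlap correction so raw count decline with |lag| does
  # not masquerade as low-frequency structure
  win_len <- median(epochs$t1 - epochs$t0)
  overlap <- pmax(1 - abs(lags) / win_len, 1e-3)
  acc <- numeric(nb)
  for (d in seq_len(n_draws)) {
    counts <- numeric(nb)
    n_spk <- 0
    for (w in per_win) {
      m <- min(length(w$a), length(w$b))
      a <- if (length(w$a) > m) sort(sample(w$a, m)) else w$a
      b <- if (length(w$b) > m) sort(sample(w$b, m)) else w$b
      counts <- counts + as.numeric(correlogram_cpp(a, b, bin_s, max_lag, FALSE))
      n_spk <- n_spk + 2 * m
    }
    acc <- acc + counts / overlap / n_spk
  }
  out <- tibble(lag = lags, value = acc / n_draws)
  attr(out, "bin_s") <- bin_s
  class(out) <- c("correlogram", class(out))
  out
}

#' Power spectrum of a cross-correlogram
#'
#' Spectrum of the mean-removed CCG values; with two condition groups a
#' per-frequency permutation test (Bonferroni over frequencies) flags
#' significant power changes.
#'
#' @param ccg a [crosscorrelogram()] result (20-ms bins typical).
#' @return tibble `freq`, `power`.
#' @export
ccg_spectrum <- function(ccg) {
  bin_s <- attr(ccg, "bin_s") %||% diff(ccg$lag[1:2])
  series_spectrum(ccg$value - mean(ccg$value), 1 / bin_s)
}

#' Permutation test for condition differences in CCG band power
#'
#' Rows of `ccgs_a` / `ccgs_b` are per-pair CCG value vectors under the two
#' conditions. Per frequency, condition labels are permuted across pairs;
#' p values are Bonferroni-corrected over frequencies.
#'
#' @param ccgs_a,ccgs_b matrices (pairs x lags) of CCG values.
#' @param bin_s CCG lag bin (s).
#' @param n_perm permutations.
#' @param alpha level after Bonferroni correction.
#' @param max_freq analyse frequencies up to this (Hz).
#' @return tibble `freq`, `power_a`, `power_b`, `p`, `sig`.
#' @export
ccg_band_test <- function(ccgs_a, ccgs_b, bin_s = 0.02, n_perm = 1000,
                          alpha = 0.05, max_freq = 15) {
  # native spectral resolution (no zero padding): the Bonferroni correction
  # then runs over genuinely distinct frequency bins
  np <- ncol(ccgs_a)
  spec_rows <- function(m) {
    t(apply(m, 1, function(v)
      series_spectrum(v - mean(v), 1 / bin_s, pad = np)$power))
  }
  sa <- spec_rows(ccgs_a); sb <- spec_rows(ccgs_b)
  freq <- series_spectrum(ccgs_a[1, ] - mean(ccgs_a[1, ]), 1 / bin_s,
                          pad = np)$freq
  keep <- freq <= max_freq
  sa <- sa[, keep, drop = FALSE]; sb <- sb[, keep, drop = FALSE]
  obs <- colMeans(sa) - colMeans(sb)
  pool <- rbind(sa, sb)
  na <- nrow(sa)
  exceed <- numeric(ncol(sa))
  for (i in seq_len(n_perm)) {
    ix <- sample.int(nrow(pool))
    d <- colMeans(pool[ix[seq_len(na)], , drop = FALSE]) -
         colMeans(pool[ix[-seq_len(na)], , drop = FALSE])
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p <- pmin((exceed + 1) / (n_perm + 1) * sum(keep), 1)  # Bonferroni
  tibble(freq = freq[keep], power_a = colMeans(sa), power_b = colMeans(sb),
         p = p, sig = p < alpha)
}

#' Lead/lag balance of a cross-correlogram
#'
#' `(sum positive lags - sum negative lags) / sum all`; positive values mean
#' the reference (dCA1) train tends to fire first.
#'
#' @param ccg a [crosscorrelogram()] result.
#' @param max_lag lags entering the balance (s).
#' @return scalar in `[-1, 1]`.
#' @export
lead_lag_balance <- function(ccg, max_lag = 1) {
  v <- ccg$value[abs(ccg$lag) <= max_lag]
  l <- ccg$lag[abs(ccg$lag) <= max_lag]
  tot <- sum(v)
  if (tot == 0) return(0)
  (sum(v[l > 0]) - sum(v[l < 0])) / tot
}

#' Align assembly activation scores to a trial event
#'
#' Maps FA factor scores (defined on the concatenated task-epoch bins) onto
#' a trial x bin grid around a named event.
#'
#' @param aset an `assembly_set` (with activation computed).
#' @param session the session the FA input came from.
#' @param factor factor index.
#' @param align event column.
#' @param window `c(pre, post)` seconds.
#' @return list `activation` (trials x bins), `sig` (same shape),
#'   `times`, `trials`.
#' @export
align_activation <- function(aset, session, factor, align = "t_sample",
                             window = c(-4, 1)) {
  input <- aset$input
  bin_s <- input$bin_s
  tr <- session$trials[!is.na(session$trials[[align]]), ]
  times <- seq(window[1], window[2] - bin_s / 2, by = bin_s)
  z <- aset$model$scores[factor, ]
  sig <- aset$activation$mask[factor, ]
  act <- matrix(NA_real_, nrow(tr), length(times))
  sg <- matrix(NA, nrow(tr), length(times))
  bins <- as.integer(round(input$time / bin_s))
  for (k in seq_len(nrow(tr))) {
    want <- as.integer(round((tr[[align]][k] + times) / bin_s))
    hit <- match(want, bins)
    ok <- !is.na(hit)
    act[k, ok] <- z[hit[ok]]
    sg[k, ok] <- sig[hit[ok]]
  }
  list(activation = act, sig = sg, times = times, trials = tr)
}

#' Classify an assembly as sample- or choice-active
#'
#' Trial-averaged activation is aligned to the sample and the choice press;
#' the class is the pre-press window holding the global peak of the mean
#' activation (ties break to sample, flagged). Assemblies without
#' significant activation in either pre-press window are classed `"none"`.
#'
#' @param aset an `assembly_set`.
#' @param session the session.
#' @param factor factor index.
#' @param window pre-press window `c(pre, post)`.
#' @return list `phase_class`, `peak_sample`, `peak_choice`, `tie`.
#' @export
classify_assembly_phase <- function(aset, session, factor,
                                    window = c(-4, 0)) {
  a_s <- align_activation(aset, session, factor, "t_sample", window)
  a_c <- align_activation(aset, session, factor, "t_choice", window)
  any_sig <- any(a_s$sig, na.rm = TRUE) || any(a_c$sig, na.rm = TRUE)
  if (!any_sig)
    return(list(phase_class = "none", peak_sample = NA, peak_choice = NA,
                tie = FALSE))
  pk_s <- max(colMeans(a_s$activation, na.rm = TRUE), na.rm = TRUE)
  pk_c <- max(colMeans(a_c$activation, na.rm = TRUE), na.rm = TRUE)
  tie <- isTRUE(all.equal(pk_s, pk_c))
  cls <- if (tie || pk_s >= pk_c) "sample-active" else "choice-active"
  list(phase_class = cls, peak_sample = pk_s, peak_choice = pk_c, tie = tie)
}

#' Correct-versus-error contrast of assembly activation
#'
#' Per 50-ms bin, the difference in mean z-scored activation between correct
#' and error trials is permutation-tested (outcome labels permuted across
#' trials), Bonferroni-corrected over bins.
#'
#' @param aligned an [align_activation()] result.
#' @param n_perm permutations.
#' @param alpha level after correction.
#' @return tibble `time`, `mean_correct`, `mean_error`, `p`, `sig`.
#' @export
error_activation_contrast <- function(aligned, n_perm = 1000, alpha = 0.05) {
  out_lbl <- aligned$trials$outcome
  keep <- out_lbl %in% c("correct", "error")
  A <- aligned$activation[keep, , drop = FALSE]
  A <- scale(A)  # z-score per bin across trials
  lbl <- out_lbl[keep]
  is_c <- lbl == "correct"
  stat <- function(flag) colMeans(A[flag, , drop = FALSE], na.rm = TRUE) -
    colMeans(A[!flag, , drop = FALSE], na.rm = TRUE)
  obs <- stat(is_c)
  exceed <- numeric(length(obs))
  for (i in seq_len(n_perm))
    exceed <- exceed + (abs(stat(sample(is_c))) >= abs(obs))
  p <- pmin((exceed + 1) / (n_perm + 1) * length(obs), 1)
  tibble(time = aligned$times, mean_correct = colMeans(A[is_c, , drop = FALSE]),
         mean_error = colMeans(A[!is_c, , drop = FALSE]), p = p,
         sig = p < alpha)
}

# FFT analytic-signal phase
analytic_phase <- function(x) {
  n <- length(x)
  z <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(z * h, inverse = TRUE) / n)
}

rayleigh_p <- function(n, mrl) {
  R <- n * mrl
  z <- R^2 / n
  # Zar's approximation to the exact Rayleigh distribution
  exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
}

#' Spike phase locking to a band-filtered LFP
#'
#' Zero-phase 4th-order Butterworth band-pass, analytic-signal phase sampled
#' at spike times; mean resultant length, Rayleigh circular-uniformity p and
#' preferred phase are returned. Units with fewer than `min_spikes` spikes
#' are excluded (`NULL`).
#'
#' @param spike_times spike times (s).
#' @param lfp tibble `time_s`, `voltage` (one area), attribute `fs_hz` or
#'   `fs_hz` argument.
#' @param band frequency band (Hz), e.g. `c(3.5, 5.5)` or `c(8, 12)`.
#' @param fs_hz LFP sample rate (overrides the attribute).
#' @param min_spikes exclusion threshold.
#' @return list `mrl`, `rayleigh_p`, `preferred_phase`, `n_spikes`.
#' @export
spike_phase_locking <- function(spike_times, lfp, band, fs_hz = NULL,
                                min_spikes = 50) {
  fs <- fs_hz %||% attr(lfp, "fs_hz")
  stopifnot(!is.null(fs))
  if (length(spike_times) < min_spikes) return(NULL)
  v <- lfp$voltage
  if (sd(v) == 0 || all(v == 0)) abort("flat LFP: phase undefined")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, v)
  if (sd(filt) < 1e-12 * sd(v)) abort("zero-amplitude band: phase undefined")
  ph <- analytic_phase(filt)
  idx <- pmin(pmax(round(spike_times * fs) + 1, 1), length(ph))
  sp <- ph[idx]
  C <- mean(cos(sp)); S <- mean(sin(sp))
  mrl <- sqrt(C^2 + S^2)
  list(mrl = mrl, rayleigh_p = rayleigh_p(length(sp), mrl),
       preferred_phase = atan2(S, C), n_spikes = length(sp))
}

#' Theta-to-low-band tuning ratio
#'
#' For units significantly phase locked in both the 4-5 Hz and theta bands,
#' the ratio of theta MRL to low-band MRL.
#'
#' @param spike_times spike times.
#' @param lfp area LFP tibble.
#' @param low_band,theta_band the two bands (Hz).
#' @param fs_hz sample rate.
#' @param alpha Rayleigh significance required in both bands.
#' @return ratio, or `NA` if not significant in both bands / excluded.
#' @export
mrl_ratio <- function(spike_times, lfp, low_band = c(3.5, 5.5),
                      theta_band = c(8, 12), fs_hz = NULL, alpha = 0.05) {
  lo <- spike_phase_locking(spike_times, lfp, low_band, fs_hz)
  th <- spike_phase_locking(spike_times, lfp, theta_band, fs_hz)
  if (is.null(lo) || is.null(th)) return(NA_real_)
  if (lo$rayleigh_p >= alpha || th$rayleigh_p >= alpha) return(NA_real_)
  th$mrl / lo$mrl
}
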