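#' The two-sample t criterion at a given trial count
#'
#' Upper-tail criterion: discrimination at level `alpha` requires
#' `t > qt(1 - alpha, n_trials - 2)`. At the typical ~54 trials per session
#' this evaluates to 1.67.
#'
#' @param n_trials total trials pooled over the two cue conditions.
#' @param alpha significance level.
#' @return the criterion value of t.
#' @export
t_criterion <- function(n_trials = 54, alpha = 0.05) {
  qt(1 - alpha, df = n_trials - 2)
}

# Pooled-SD two-sample t per column of M (trials x features); labels logical
# (TRUE = first group, i.e. t > 0 when group L fires more). Zero pooled SD
# gives t = 0, flagged.
tstat_columns <- function(M, is_l) {
  nL <- sum(is_l); nR <- sum(!is_l)
  mL <- colMeans(M[is_l, , drop = FALSE]); mR <- colMeans(M[!is_l, , drop = FALSE])
  vL <- colSums(sweep(M[is_l, , drop = FALSE], 2, mL)^2) / (nL - 1)
  vR <- colSums(sweep(M[!is_l, , drop = FALSE], 2, mR)^2) / (nR - 1)
  sp <- sqrt(((nL - 1) * vL + (nR - 1) * vR) / (nL + nR - 2))
  denom <- sp * sqrt(1 / nL + 1 / nR)
  flagged <- denom == 0 | is.na(denom)
  t <- ifelse(flagged, 0, (mL - mR) / denom)
  list(t = t, flagged = flagged)
}

#' Time-resolved left/right t-score profiles per unit
#'
#' For every unit and 50-ms bin, the two-sample pooled-SD t statistic between
#' left-trial and right-trial firing rates (positive = stronger on left
#' trials). With `n_shuffle > 0` a label-shuffle null is built (permutations
#' shared across bins and units) and each bin is marked significant when the
#' observed |t| exceeds the `1 - alpha/n_bins` (Bonferroni) quantile of its
#' shuffled |t| distribution.
#'
#' @param tensor a [build_rate_tensor()] result.
#' @param labels optional character vector of per-trial labels; defaults to
#'   the tensor's `cue_side`.
#' @param n_shuffle number of label permutations (0 = no significance mask).
#' @param alpha significance level before Bonferroni correction.
#' @param bonferroni correct over time bins.
#' @return a `tscore_profiles` tibble: `unit_id`, `area`, `time`, `t`,
#'   `flagged`, and `sig` when shuffles were run.
#' @export
tscore_curves <- function(tensor, labels = NULL, n_shuffle = 0, alpha = 0.05,
                          bonferroni = TRUE) {
  labels <- labels %||% tensor$trials$cue_side
  lev <- sort(unique(labels))
  stopifnot(length(lev) == 2)
  is_l <- labels == lev[1]
  if (sum(is_l) < 3 || sum(!is_l) < 3)
    abort("need at least 3 trials per side")
  d <- dim(tensor$rates)
  M <- matrix(tensor$rates, nrow = d[1])  # trials x (units*bins)
  obs <- tstat_columns(M, is_l)
  # columns of M run over units fastest, then bins
  out <- tibble(
    unit_id = rep(tensor$unit_id, times = d[3]),
    area = rep(tensor$area, times = d[3]),
    time = rep(tensor$times, each = d[2]),
    t = unname(obs$t),
    flagged = unname(obs$flagged))

  if (n_shuffle > 0) {
    if (n_shuffle < 500)
      inform("fewer than 500 shuffles; significance quantiles will be coarse")
    Tnull <- matrix(NA_real_, n_shuffle, ncol(M))
    for (s in seq_len(n_shuffle))
      Tnull[s, ] <- abs(tstat_columns(M, sample(is_l))$t)
    a_corr <- if (bonferroni) alpha / d[3] else alpha
    # exact permutation p value per bin (conservative at any shuffle count)
    cnt <- colSums(Tnull >= rep(abs(obs$t), each = n_shuffle))
    out$p <- (1 + cnt) / (n_shuffle + 1)
    out$sig <- out$p <= a_corr
    attr(out, "alpha_corrected") <- a_corr
  }
  attr(out, "align") <- tensor$align
  attr(out, "bin_s") <- tensor$bin_s
  attr(out, "n_shuffle") <- n_shuffle
  class(out) <- c("tscore_profiles", class(out))
  out
}

#' Per-unit summary of t-score profiles
#'
#' Duration of encoding is the total significant time (bin count times bin
#' width); `duration = "longest_run"` instead reports the longest contiguous
#' significant stretch.
#'
#' @param profiles a [tscore_curves()] result with a `sig` column.
#' @param duration `"total"` or `"longest_run"`.
#' @return tibble `unit_id`, `area`, `peak_abs_t`, `peak_time_s`,
#'   `duration_s`.
#' @export
tscore_summary <- function(profiles, duration = c("total", "longest_run")) {
  duration <- match.arg(duration)
  bin_s <- attr(profiles, "bin_s")
  has_sig <- "sig" %in% names(profiles)
  profiles |>
    as_tibble() |>
    group_by(.data$unit_id, .data$area) |>
    summarise(
      peak_abs_t = max(abs(.data$t)),
      peak_time_s = .data$time[which.max(abs(.data$t))],
      duration_s = if (!has_sig) NA_real_
        else if (duration == "total") sum(.data$sig) * bin_s
        else longest_run(.data$sig) * bin_s,
      .groups = "drop")
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Informative-unit classification
#'
#' A unit is informative when its significant bins within `window_s` of the
#' sample or choice press total more than 50 ms (at 50-ms bins: at least
#' `min_bins = 2`; set `min_bins = 1` for the weaker ">= 50 ms" reading).
#'
#' @param profiles_sample,profiles_choice [tscore_curves()] results (with
#'   `sig`) aligned to the sample and choice presses.
#' @param window_s half-width of the window around each press.
#' @param min_bins minimum number of significant bins.
#' @return tibble `unit_id`, `area`, `n_sig_bins`, `informative`.
#' @export
informative_units <- function(profiles_sample, profiles_choice = NULL,
                              window_s = 4, min_bins = 2) {
  stopifnot("sig" %in% names(profiles_sample))
  pool <- bind_rows(as_tibble(profiles_sample),
                    if (!is.null(profiles_choice)) as_tibble(profiles_choice))
  pool |>
    filter(abs(.data$time) <= window_s) |>
    group_by(.data$unit_id, .data$area) |>
    summarise(n_sig_bins = sum(.data$sig), .groups = "drop") |>
    mutate(informative = .data$n_sig_bins >= min_bins)
}

#' Coding distance between two t-score profiles
#'
#' Euclidean distance after dividing both profiles by their pooled SD and
#' removing each profile's mean, so a constant offset or common rescaling
#' does not contribute. Zero pooled variance returns 0 with a warning.
#'
#' @param t1,t2 numeric t-score vectors on the same time grid.
#' @return nonnegative scalar.
#' @export
coding_distance <- function(t1, t2) {
  stopifnot(length(t1) == length(t2))
  n <- length(t1)
  v <- (var(t1) + var(t2)) / 2 * (n - 1) / n  # population-style pooled variance
  if (is.na(v) || v == 0) {
    warn("zero pooled variance; coding distance set to 0")
    return(0)
  }
  a <- (t1 - mean(t1)) / sqrt(v)
  b <- (t2 - mean(t2)) / sqrt(v)
  sqrt(sum((a - b)^2))
}
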