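#' Bandwidth grid for KDE cross-validation
#'
#' Log-spaced grid from 1 ms to 2 s (60 points) over which the unbiased
#' cross-validation error is minimized.
#' @param from,to,n grid bounds (s) and size.
#' @return numeric vector of bandwidths (Gaussian kernel SD, s).
#' @export
bandwidth_grid <- function(from = 0.001, to = 2, n = 60) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Unbiased cross-validation error of a Gaussian-kernel rate KDE
#'
#' Least-squares cross-validation score
#' `CVE(h) = int f_hat^2 - (2/n) sum_i f_hat_{-i}(x_i)`, either through the
#' closed form available for Gaussian kernels (`method = "closed_form"`,
#' the implementation used throughout the pipeline) or by direct numerical
#' leave-one-out evaluation (`method = "loo"`, an independent route kept for
#' verification).
#'
#' @param spike_times numeric vector (s).
#' @param bandwidths candidate kernel SDs (s).
#' @param method `"closed_form"` or `"loo"`.
#' @return tibble `bandwidth_s`, `cve`.
#' @export
kde_cve <- function(spike_times, bandwidths = bandwidth_grid(),
                    method = c("closed_form", "loo")) {
  method <- match.arg(method)
  x <- sort(spike_times)
  n <- length(x)
  stopifnot(n >= 2)
  if (method == "closed_form") {
    cve <- kde_cve_grid_cpp(x, bandwidths)
  } else {
    cve <- vapply(bandwidths, function(h) {
      d <- outer(x, x, "-")
      K2 <- exp(-d^2 / (4 * h^2)) / (2 * h * sqrt(pi))     # kernel at sqrt(2) h
      K1 <- exp(-d^2 / (2 * h^2)) / (h * sqrt(2 * pi))     # kernel at h
      int_f2 <- sum(K2) / n^2
      loo <- vapply(seq_len(n), function(i) sum(K1[i, -i]) / (n - 1), 0)
      int_f2 - 2 * mean(loo)
    }, 0)
  }
  tibble(bandwidth_s = bandwidths, cve = as.numeric(cve))
}

#' Optimal KDE bandwidth by unbiased cross-validation
#'
#' Grid minimizer of [kde_cve()]; ties break toward the smaller bandwidth.
#' Fewer than 5 spikes fall back to 100 ms with a warning.
#'
#' @inheritParams kde_cve
#' @return bandwidth (s), with the CVE table as attribute `"cve"`.
#' @export
optimal_bandwidth <- function(spike_times, bandwidths = bandwidth_grid()) {
  if (length(spike_times) < 5) {
    warn("fewer than 5 spikes; falling back to 100 ms bandwidth")
    return(0.1)
  }
  tab <- kde_cve(spike_times, bandwidths)
  h <- tab$bandwidth_s[which.min(tab$cve)]  # which.min takes the first = smallest h
  attr(h, "cve") <- tab
  h
}

#' Instantaneous firing rate by Gaussian-kernel density estimation
#'
#' Sum over spikes of Gaussian kernels of SD `bandwidth_s`; units Hz, so the
#' integral over the whole line equals the spike count.
#'
#' @param spike_times numeric vector (s).
#' @param bandwidth_s kernel SD (s).
#' @param times evaluation times (s).
#' @return tibble `time`, `rate`.
#' @export
estimate_rate <- function(spike_times, bandwidth_s, times) {
  stopifnot(bandwidth_s > 0)
  if (length(spike_times) == 0)
    return(tibble(time = times, rate = 0))
  tibble(time = times,
         rate = as.numeric(kde_eval_cpp(sort(spike_times), times, bandwidth_s)))
}

#' Event-aligned trial x unit x bin rate tensor
#'
#' KDE rates sampled at 50-ms bin left edges on a grid aligned to a named
#' trial event (bin offset 0 starts at the event). One bandwidth per unit is
#' used for every alignment: either supplied, a single fixed value, or
#' selected per unit by unbiased cross-validation over the task period.
#'
#' @param session a `dnmts_session` (after [select_units()]).
#' @param align event column of the trial table (e.g. `"t_sample"`).
#' @param window `c(pre, post)` seconds around the event (pre negative).
#' @param bin_s bin width (s).
#' @param bandwidth `"cv"`, a single number (s), or a named vector per unit.
#' @param trials optional trial indices to include; trials missing the event
#'   are dropped with a message.
#' @return a `rate_tensor`: list with `rates` (array trials x units x bins),
#'   `times` (bin left edges, s, relative), `unit_id`, `area`, `trials`
#'   (tibble), `align`, `bin_s`, `bandwidths`.
#' @export
build_rate_tensor <- function(session, align = "t_sample", window = c(-5, 5),
                              bin_s = 0.05, bandwidth = "cv", trials = NULL) {
  u <- session_units(session)
  tr <- session$trials
  if (!is.null(trials)) tr <- tr[tr$trial %in% trials, ]
  has_ev <- !is.na(tr[[align]])
  if (any(!has_ev))
    inform(sprintf("dropping %d trial(s) without %s", sum(!has_ev), align))
  tr <- tr[has_ev, ]
  times_rel <- seq(window[1], window[2] - bin_s / 2, by = bin_s)
  nb <- length(times_rel)

  bw <- resolve_bandwidths(session, u$unit_id, bandwidth)
  arr <- array(0, dim = c(nrow(tr), nrow(u), nb),
               dimnames = list(NULL, u$unit_id, NULL))
  for (j in seq_len(nrow(u))) {
    st <- unit_spikes(session, u$unit_id[j])
    for (k in seq_len(nrow(tr))) {
      tt <- tr[[align]][k] + times_rel
      arr[k, j, ] <- kde_eval_cpp(st, tt, bw[j])
    }
  }
  structure(list(rates = arr, times = times_rel, unit_id = u$unit_id,
                 area = as.character(u$area), trials = tr, align = align,
                 bin_s = bin_s, bandwidths = bw),
            class = "rate_tensor")
}

resolve_bandwidths <- function(session, unit_ids, bandwidth) {
  if (is.character(bandwidth) && identical(bandwidth, "cv")) {
    vapply(unit_ids, function(id)
      as.numeric(optimal_bandwidth(unit_spikes(session, id))), 0)
  } else if (is.numeric(bandwidth) && length(bandwidth) == 1) {
    setNames(rep(bandwidth, length(unit_ids)), unit_ids)
  } else {
    stopifnot(all(unit_ids %in% names(bandwidth)))
    bandwidth[unit_ids]
  }
}

#' @export
print.rate_tensor <- function(x, ...) {
  cat(sprintf("<rate_tensor> %d trials x %d units x %d bins, aligned to %s\n",
              dim(x$rates)[1], dim(x$rates)[2], dim(x$rates)[3], x$align))
  invisible(x)
}

#' @rdname tidy.tscore_profiles
#' @export
tidy.rate_tensor <- function(x, ...) {
  d <- dim(x$rates)
  tibble(trial = rep(x$trials$trial, times = d[2] * d[3]),
         unit_id = rep(rep(x$unit_id, each = d[1]), times = d[3]),
         time = rep(x$times, each = d[1] * d[2]),
         rate = as.numeric(x$rates))
}

#' Subset a rate tensor by units and/or trials
#' @param tensor a `rate_tensor`.
#' @param units unit ids to keep.
#' @param trials trial indices to keep.
#' @return a `rate_tensor`.
#' @export
tensor_subset <- function(tensor, units = NULL, trials = NULL) {
  jj <- if (is.null(units)) seq_along(tensor$unit_id)
        else match(units, tensor$unit_id)
  kk <- if (is.null(trials)) seq_len(nrow(tensor$trials))
        else which(tensor$trials$trial %in% trials)
  tensor$rates <- tensor$rates[kk, jj, , drop = FALSE]
  tensor$unit_id <- tensor$unit_id[jj]
  tensor$area <- tensor$area[jj]
  tensor$trials <- tensor$trials[kk, ]
  tensor$bandwidths <- tensor$bandwidths[jj]
  tensor
}

#' Event responsiveness of units
#'
#' A unit is responsive if its trial-averaged z-scored rate exceeds |z| > 3
#' anywhere in the 2 s after the event. The baseline mean comes from the
#' 500 ms preceding the event; the z denominator is the standard error of the
#' trial-averaged rate (across-trial SD pooled over the baseline bins divided
#' by sqrt(n_trials)), which keeps the nominal tail of the |z| > 3 criterion.
#' Units whose baseline SE is zero are flagged indeterminate.
#'
#' @param session a `dnmts_session`.
#' @param align event column name.
#' @param post_s,baseline_s analysis and baseline window lengths (s).
#' @param bin_s bin width (s).
#' @param z_thresh threshold on |z|.
#' @param bandwidth as in [build_rate_tensor()].
#' @return tibble `unit_id`, `area`, `responsive`, `indeterminate`, `peak_z`,
#'   plus a nested `z_profile` (tibble `time`, `z`).
#' @export
detect_responsive <- function(session, align = "t_sample", post_s = 2,
                              baseline_s = 0.5, bin_s = 0.05, z_thresh = 3,
                              bandwidth = 0.05) {
  tr <- session$trials[!is.na(session$trials[[align]]), ]
  stopifnot(nrow(tr) >= 10)
  tensor <- build_rate_tensor(session, align, window = c(-baseline_s, post_s),
                              bin_s = bin_s, bandwidth = bandwidth)
  base_bins <- tensor$times < 0
  post_bins <- tensor$times >= 0
  n_tr <- dim(tensor$rates)[1]
  out <- map(seq_along(tensor$unit_id), function(j) {
    m <- tensor$rates[, j, , drop = FALSE][, 1, ]
    avg <- colMeans(m)
    mu <- mean(avg[base_bins])
    # SE of the trial average: across-trial SD pooled over baseline bins
    s <- sqrt(mean(apply(m[, base_bins, drop = FALSE], 2, var))) / sqrt(n_tr)
    indet <- is.na(s) || s == 0
    if (indet) s <- NA_real_
    z <- (avg - mu) / s
    tibble(unit_id = tensor$unit_id[j], area = tensor$area[j],
           responsive = !indet && any(abs(z[post_bins]) > z_thresh),
           indeterminate = indet,
           peak_z = if (indet) NA_real_ else max(abs(z[post_bins])),
           z_profile = list(tibble(time = tensor$times, z = z)))
  })
  bind_rows(out)
}
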