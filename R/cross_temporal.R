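#' Cross-temporal decoding grid
#'
#' Decoders are trained at one time bin and tested at every other. Per
#' resample, `n_per_class` trials are drawn from each cue condition; within
#' the draw, one trial of each class is held out in turn (leave-one-pair-out)
#' so training and testing sets are disjoint; performance is averaged over
#' folds and resamples. Resample-group means are retained so condition
#' differences can be permutation-tested ([ct_difference()]).
#'
#' @param tensor a [build_rate_tensor()] result.
#' @param labels per-trial labels (default `cue_side`).
#' @param n_per_class trials drawn per class and resample (default 8).
#' @param n_resamples number of random draws (default 500; the full-scale
#'   convention is 500 draws x 10 folds ~ 5000 cross-validations).
#' @param lambda regularization.
#' @param stride use every `stride`-th bin of the tensor for the grid.
#' @param n_groups resample groups stored for permutation testing.
#' @return a `ct_matrix`: `perf` (train x test), `times`, `group_perf`
#'   (train x test x group), metadata; `sig_mask`/`smoothed` filled by
#'   [ct_significance()] / [ct_smooth()].
#' @export
cross_temporal_decode <- function(tensor, labels = NULL, n_per_class = 8,
                                  n_resamples = 500, lambda = 0.05,
                                  stride = 1, n_groups = 20) {
  labels <- labels %||% tensor$trials$cue_side
  li <- labels_to_int(labels)
  i0 <- which(li$y == 0); i1 <- which(li$y == 1)
  if (length(i0) < n_per_class || length(i1) < n_per_class)
    abort(sprintf("need >= %d trials per class; have %d / %d",
                  n_per_class, length(i0), length(i1)))
  keep <- seq(1, dim(tensor$rates)[3], by = stride)
  R <- tensor$rates[, , keep, drop = FALSE]
  times <- tensor$times[keep]
  n_groups <- min(n_groups, n_resamples)
  per_group <- ceiling(n_resamples / n_groups)
  gp <- array(NA_real_, dim = c(length(times), length(times), n_groups))
  for (g in seq_len(n_groups)) {
    ng <- min(per_group, n_resamples - (g - 1) * per_group)
    if (ng <= 0) break
    draws <- vapply(seq_len(ng), function(r)
      c(sample(i0, n_per_class), sample(i1, n_per_class)) - 1L,
      integer(2 * n_per_class))
    gp[, , g] <- cross_temporal_cpp(R, li$y, draws, lambda)
  }
  structure(list(perf = apply(gp, c(1, 2), mean, na.rm = TRUE),
                 group_perf = gp, times = times,
                 n_per_class = n_per_class, n_resamples = n_resamples,
                 lambda = lambda, stride = stride,
                 sig_mask = NULL, smoothed = FALSE),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d x %d grid, %d resamples, mean cp %.3f\n",
              length(x$times), length(x$times), x$n_resamples, mean(x$perf)))
  invisible(x)
}

#' Shuffle-label significance of a cross-temporal grid
#'
#' Each cell is flagged significant when observed performance exceeds the
#' `1 - alpha` quantile of grids computed on label-shuffled data.
#'
#' @param matrix a [cross_temporal_decode()] result.
#' @param tensor,labels the inputs it was computed from.
#' @param n_boot shuffled-label grids (each at `null_resamples` resamples).
#' @param alpha level.
#' @param null_resamples resamples per shuffled grid.
#' @return the `ct_matrix` with `sig_mask` (logical train x test) filled in.
#' @export
ct_significance <- function(matrix, tensor, labels = NULL, n_boot = 100,
                            alpha = 0.05, null_resamples = 10) {
  labels <- labels %||% tensor$trials$cue_side
  li <- labels_to_int(labels)
  keep <- seq(1, dim(tensor$rates)[3], by = matrix$stride)
  R <- tensor$rates[, , keep, drop = FALSE]
  k <- matrix$n_per_class
  null <- array(NA_real_, dim = c(dim(matrix$perf), n_boot))
  for (b in seq_len(n_boot)) {
    yp <- sample(li$y)
    j0 <- which(yp == 0); j1 <- which(yp == 1)
    draws <- vapply(seq_len(null_resamples), function(r)
      c(sample(j0, k), sample(j1, k)) - 1L, integer(2 * k))
    null[, , b] <- cross_temporal_cpp(R, yp, draws, matrix$lambda)
  }
  cnt <- apply(sweep(null, c(1, 2), matrix$perf, ">="), c(1, 2), sum)
  p <- (1 + cnt) / (n_boot + 1)
  matrix$sig_mask <- p <= alpha
  matrix$null_p <- p
  matrix
}

#' Gaussian smoothing of a cross-temporal grid (visualization only)
#'
#' A 250-ms Gaussian kernel (read as FWHM, so sigma = 0.25 / 2.355 s) is
#' applied across both the training and testing dimensions after significance
#' testing; the significance mask is never smoothed.
#'
#' @param matrix a `ct_matrix`.
#' @param fwhm_s kernel full width at half maximum (s).
#' @return the `ct_matrix` with smoothed `perf` and `smoothed = TRUE`.
#' @export
ct_smooth <- function(matrix, fwhm_s = 0.25) {
  bin <- diff(matrix$times[1:2])
  sigma_bins <- fwhm_s / 2.355 / bin
  matrix$perf <- gauss_smooth_2d(matrix$perf, sigma_bins)
  matrix$smoothed <- TRUE
  matrix
}

gauss_smooth_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    # normalized convolution with zero padding: preserves constants and
    # total mass up to the renormalized edges
    n <- length(v)
    pad <- rep(0, half)
    num <- as.numeric(stats::filter(c(pad, v, pad), k, sides = 2))
    den <- as.numeric(stats::filter(c(pad, rep(1, n), pad), k, sides = 2))
    (num / den)[half + seq_len(n)]
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Permutation difference between two cross-temporal grids
#'
#' Per-cell difference `A - B` with a permutation test across the stored
#' resample groups of the two conditions.
#'
#' @param ma,mb `ct_matrix` objects on the same grid.
#' @param n_perm group-label permutations.
#' @param alpha two-sided level.
#' @return list `diff` (matrix), `sig_mask`, `times`.
#' @export
ct_difference <- function(ma, mb, n_perm = 1000, alpha = 0.05) {
  stopifnot(identical(ma$times, mb$times))
  ga <- ma$group_perf; gb <- mb$group_perf
  na <- dim(ga)[3]; nb <- dim(gb)[3]
  pool <- array(c(ga, gb), dim = c(dim(ga)[1:2], na + nb))
  obs <- ma$perf - mb$perf
  exceed <- array(0L, dim = dim(obs))
  for (i in seq_len(n_perm)) {
    ix <- sample.int(na + nb)
    d <- apply(pool[, , ix[seq_len(na)], drop = FALSE], c(1, 2), mean) -
         apply(pool[, , ix[na + seq_len(nb)], drop = FALSE], c(1, 2), mean)
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p <- (exceed + 1) / (n_perm + 1)
  list(diff = obs, p = p, sig_mask = p < alpha, times = ma$times)
}
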