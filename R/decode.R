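labels_to_int <- function(labels) {
  lev <- sort(unique(as.character(labels)))
  stopifnot(length(lev) == 2)
  list(y = as.integer(labels == lev[2]), levels = lev)
}

#' Fit a regularized linear discriminant at one time bin
#'
#' Two-class LDA on trial x unit rates with the pooled covariance moved
#' toward the identity, `Sigma_reg = Sigma + lambda I`. Equal priors; the
#' decision boundary passes through the midpoint of the class means.
#'
#' @param x matrix, trials x units.
#' @param labels two-level vector per trial.
#' @param lambda ridge added to the pooled covariance diagonal (default 0.05).
#' @return an `lda_model`: weights `w`, bias `b`, class means, `lambda`,
#'   label `levels`.
#' @export
fit_lda <- function(x, labels, lambda = 0.05) {
  li <- labels_to_int(labels)
  stopifnot(lambda >= 0, length(unique(li$y)) == 2)
  if (lambda == 0) {
    S <- pooled_cov(x, li$y)
    if (rcond(S) < 1e-12)
      abort(paste("pooled covariance is numerically singular with lambda = 0;",
                  "use lambda > 0 (the pipeline default is 0.05)"))
  }
  f <- lda_fit_cpp(x, li$y, lambda)
  structure(list(w = as.numeric(f$w), b = as.numeric(f$b),
                 means = rbind(colMeans(x[li$y == 0, , drop = FALSE]),
                               colMeans(x[li$y == 1, , drop = FALSE])),
                 lambda = lambda, levels = li$levels),
            class = "lda_model")
}

pooled_cov <- function(x, y) {
  c0 <- scale(x[y == 0, , drop = FALSE], scale = FALSE)
  c1 <- scale(x[y == 1, , drop = FALSE], scale = FALSE)
  (crossprod(c0) + crossprod(c1)) / max(nrow(x) - 2, 1)
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  sc <- drop(as.matrix(newdata) %*% object$w)
  object$levels[(sc > object$b) + 1L]
}

#' Leave-one-out population decoding over time
#'
#' Per 50-ms bin, each trial is held out in turn, a regularized LDA fit on
#' the rest, and the held-out label predicted; `cp` is the correct-prediction
#' fraction (1 - CVE). With `n_shuffle > 0` a label-shuffle null is computed
#' (same LOOCV on permuted labels; permutations shared across bins) giving a
#' per-bin upper confidence bound and a Bonferroni-corrected significance
#' mask.
#'
#' @param tensor a [build_rate_tensor()] result.
#' @param labels per-trial labels (default: the tensor's `cue_side`).
#' @param lambda covariance regularization.
#' @param n_shuffle label permutations for the null (0 = none).
#' @param alpha level before Bonferroni correction over bins.
#' @param bonferroni logical.
#' @return a `decoding_result` tibble `time`, `cp` (+ `null_hi`, `sig`),
#'   with attributes `n_units`, `n_trials`, `lambda`.
#' @export
loocv_decode <- function(tensor, labels = NULL, lambda = 0.05, n_shuffle = 0,
                         alpha = 0.05, bonferroni = TRUE) {
  labels <- labels %||% tensor$trials$cue_side
  li <- labels_to_int(labels)
  if (min(table(li$y)) < 6)
    warn("fewer than 6 trials in a class; LOOCV estimates will be unstable")
  cp <- as.numeric(lda_loocv_curve_cpp(tensor$rates, li$y, lambda))
  out <- tibble(time = tensor$times, cp = cp)
  if (n_shuffle > 0) {
    n <- length(li$y)
    perms <- vapply(seq_len(n_shuffle), function(i) sample.int(n) - 1L,
                    integer(n))
    null <- lda_loocv_null_cpp(tensor$rates, li$y, perms, lambda)
    a_corr <- if (bonferroni) alpha / length(cp) else alpha
    out$null_hi <- apply(null, 1, quantile, probs = 1 - a_corr, names = FALSE)
    # exact permutation p value: conservative at any shuffle count
    out$p <- (1 + rowSums(null >= cp)) / (n_shuffle + 1)
    out$sig <- out$p <= a_corr
    attr(out, "alpha_corrected") <- a_corr
  }
  attr(out, "n_units") <- dim(tensor$rates)[2]
  attr(out, "n_trials") <- length(li$y)
  attr(out, "lambda") <- lambda
  attr(out, "levels") <- li$levels
  class(out) <- c("decoding_result", class(out))
  out
}

#' Decode two populations at equalized size
#'
#' K is fixed to the smaller population's unit count; the larger population
#' is decoded on 10 independent draws of K units with replacement and the
#' per-bin correct-prediction fractions averaged; the smaller population is
#' decoded once.
#'
#' @param tensor_a,tensor_b [build_rate_tensor()] results on the same trials.
#' @param labels per-trial labels (default `cue_side` of `tensor_a`).
#' @param lambda regularization.
#' @param n_draws number of K-unit draws for the larger population.
#' @return tibble `time`, `cp_a`, `cp_b`, `k` (attribute `k` also set).
#' @export
equalize_and_decode <- function(tensor_a, tensor_b, labels = NULL,
                                lambda = 0.05, n_draws = 10) {
  labels <- labels %||% tensor_a$trials$cue_side
  li <- labels_to_int(labels)
  pa <- dim(tensor_a$rates)[2]; pb <- dim(tensor_b$rates)[2]
  if (pa < 2 || pb < 2) abort("need at least 2 units per population")
  k <- min(pa, pb)
  one <- function(tensor, p) {
    if (p == k)
      return(as.numeric(lda_loocv_curve_cpp(tensor$rates, li$y, lambda)))
    draws <- replicate(n_draws, sample.int(p, k, replace = TRUE),
                       simplify = FALSE)
    rowMeans(vapply(draws, function(ix)
      as.numeric(lda_loocv_curve_cpp(tensor$rates[, ix, , drop = FALSE],
                                     li$y, lambda)),
      numeric(dim(tensor$rates)[3])))
  }
  out <- tibble(time = tensor_a$times, cp_a = one(tensor_a, pa),
                cp_b = one(tensor_b, pb))
  attr(out, "k") <- k
  out
}

#' Beta-distribution comparison of two correct-prediction fractions
#'
#' The smaller CP defines the reference distribution Beta(k + 1, n - k + 1)
#' with `k = round(cp_small * n_trials)`; the larger CP is significant when
#' it exceeds the 95th percentile of that reference.
#'
#' @param cp_small,cp_large per-bin CP vectors in `[0, 1]`.
#' @param n_trials trial count behind the CP estimates.
#' @param alpha upper-tail level.
#' @return tibble `cp_small`, `cp_large`, `threshold`, `sig`.
#' @export
compare_cp_beta <- function(cp_small, cp_large, n_trials, alpha = 0.05) {
  stopifnot(n_trials > 0, all(cp_small <= cp_large + 1e-12))
  k <- round(cp_small * n_trials)
  thr <- qbeta(1 - alpha, k + 1, n_trials - k + 1)
  tibble(cp_small = cp_small, cp_large = cp_large, threshold = thr,
         sig = cp_large > thr)
}

#' Decode error trials with decoders trained on correct trials
#'
#' Per bin, a decoder is fit on all correct trials and evaluated on error
#' trials. Significance of the performance drop relative to correct-trial
#' LOOCV is assessed by permuting the correct/error outcome assignment across
#' trials (preserving counts), recomputing the train/test CP per permutation,
#' and flagging bins whose observed error CP falls below the Bonferroni-
#' corrected `alpha` quantile of the permutation null.
#'
#' @param tensor a tensor containing both correct and error trials.
#' @param labels cue labels per trial (default `cue_side`).
#' @param outcomes per-trial `"correct"`/`"error"` (default from the tensor).
#' @param lambda regularization.
#' @param n_perm outcome permutations.
#' @param alpha level before Bonferroni correction.
#' @return tibble `time`, `cp_correct` (LOOCV on correct trials), `cp_error`,
#'   `null_lo`, `sig_drop`.
#' @export
train_correct_test_error <- function(tensor, labels = NULL, outcomes = NULL,
                                     lambda = 0.05, n_perm = 200,
                                     alpha = 0.05) {
  labels <- labels %||% tensor$trials$cue_side
  outcomes <- outcomes %||% tensor$trials$outcome
  li <- labels_to_int(labels)
  is_err <- outcomes == "error"
  if (sum(is_err) < 3) {
    inform("fewer than 3 error trials; skipping error generalization")
    return(NULL)
  }
  tr_idx <- which(!is_err) - 1L
  te_idx <- which(is_err) - 1L
  cp_err <- as.numeric(lda_train_test_curve_cpp(tensor$rates, li$y,
                                                tr_idx, te_idx, lambda))
  sub_corr <- tensor$rates[!is_err, , , drop = FALSE]
  cp_corr <- as.numeric(lda_loocv_curve_cpp(sub_corr, li$y[!is_err], lambda))
  null <- vapply(seq_len(n_perm), function(i) {
    fake_err <- sample(is_err)
    as.numeric(lda_train_test_curve_cpp(tensor$rates, li$y,
                                        which(!fake_err) - 1L,
                                        which(fake_err) - 1L, lambda))
  }, numeric(length(cp_err)))
  a_corr <- alpha / length(cp_err)
  lo <- apply(null, 1, quantile, probs = a_corr, names = FALSE)
  tibble(time = tensor$times, cp_correct = cp_corr, cp_error = cp_err,
         null_lo = lo, sig_drop = cp_err < lo)
}

#' Session-level paired permutation test of two condition curves
#'
#' Given per-session time curves under two conditions (e.g. correct-trial
#' versus error-trial decoding, with sessions as rows), tests per time bin
#' whether condition A exceeds condition B by randomly flipping the sign of
#' each session's difference (the permutation distribution of the mean
#' paired difference), Bonferroni-corrected over bins.
#'
#' @param mat_a,mat_b sessions x bins matrices.
#' @param n_perm sign-flip permutations.
#' @param alpha level after correction.
#' @param bonferroni correct over bins.
#' @param alternative `"greater"` (A > B) or `"two.sided"`.
#' @return tibble `bin`, `mean_a`, `mean_b`, `p`, `sig`.
#' @export
paired_permutation_test <- function(mat_a, mat_b, n_perm = 1000, alpha = 0.05,
                                    bonferroni = TRUE,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(identical(dim(mat_a), dim(mat_b)))
  d <- mat_a - mat_b
  n <- nrow(d)
  obs <- colMeans(d)
  exceed <- numeric(ncol(d))
  for (i in seq_len(n_perm)) {
    flip <- sample(c(-1, 1), n, replace = TRUE)
    perm <- colMeans(d * flip)
    exceed <- exceed +
      if (alternative == "greater") (perm >= obs) else (abs(perm) >= abs(obs))
  }
  p <- (exceed + 1) / (n_perm + 1)
  if (bonferroni) p <- pmin(p * ncol(d), 1)
  tibble(bin = seq_len(ncol(d)), mean_a = colMeans(mat_a),
         mean_b = colMeans(mat_b), p = p, sig = p < alpha)
}

#' Hotelling's T-squared contrast of two population conditions
#'
#' T2 relates the class mean difference to the (regularized) pooled
#' covariance; scaled by its degrees of freedom it is approximately
#' F(p, n1 + n2 - p - 1) distributed, which supplies the p value (exact when
#' `lambda = 0`).
#'
#' @param x_l,x_r trials x units matrices for the two conditions.
#' @param lambda regularization added to the pooled covariance.
#' @return list `t2`, `f`, `df1`, `df2`, `p_value`.
#' @export
hotelling_t2 <- function(x_l, x_r, lambda = 0.05) {
  x_l <- as.matrix(x_l); x_r <- as.matrix(x_r)
  n1 <- nrow(x_l); n2 <- nrow(x_r); p <- ncol(x_l)
  stopifnot(n1 >= 2, n2 >= 2, ncol(x_r) == p)
  y <- c(rep(0L, n1), rep(1L, n2))
  S <- pooled_cov(rbind(x_l, x_r), y)
  Sreg <- S + diag(lambda, p)
  if (lambda == 0 && rcond(Sreg) < 1e-12)
    abort("singular pooled covariance with lambda = 0")
  d <- colMeans(x_l) - colMeans(x_r)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(crossprod(d, solve(Sreg, d)))
  df2 <- n1 + n2 - p - 1
  f <- if (df2 > 0) t2 * df2 / ((n1 + n2 - 2) * p) else NA_real_
  pv <- if (df2 > 0) pf(f, p, df2, lower.tail = FALSE) else NA_real_
  list(t2 = t2, f = f, df1 = p, df2 = df2, p_value = pv)
}
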