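#' Build the factor-analysis input matrix
#'
#' Units x time-bins matrix of KDE firing rates over the concatenated task
#' epochs (cue onset - 5 s to choice press + 5 s per completed trial, merged
#' where they overlap), for mPFC only, dCA1 only, or both areas concatenated.
#'
#' @param session a `dnmts_session` (after [select_units()]).
#' @param variant `"joint"`, `"dca1"` or `"mpfc"`.
#' @param pre_s,post_s epoch padding around cue / choice.
#' @param bin_s bin width (s).
#' @param bandwidth as in [build_rate_tensor()]; default 50 ms.
#' @return an `fa_input`: list `x` (units x bins), `unit_id`, `area`,
#'   `time` (bin left edges, s), `trial` (owning trial per column), `bin_s`.
#' @export
build_fa_input <- function(session, variant = c("joint", "dca1", "mpfc"),
                           pre_s = 5, post_s = 5, bin_s = 0.05,
                           bandwidth = 0.05) {
  variant <- match.arg(variant)
  epochs <- excise_task_epochs(session, pre_s, post_s, bin_s)
  if (nrow(epochs) == 0) abort("no task epochs available")
  u <- session_units(session)
  keep <- switch(variant, joint = rep(TRUE, nrow(u)),
                 dca1 = u$area == "dCA1", mpfc = u$area == "mPFC")
  u <- u[keep, ]
  bw <- resolve_bandwidths(session, u$unit_id, bandwidth)
  x <- matrix(0, nrow(u), nrow(epochs),
              dimnames = list(u$unit_id, NULL))
  for (j in seq_len(nrow(u)))
    x[j, ] <- kde_eval_cpp(unit_spikes(session, u$unit_id[j]),
                           epochs$time, bw[j])
  structure(list(x = x, unit_id = u$unit_id, area = as.character(u$area),
                 time = epochs$time, trial = epochs$trial, bin_s = bin_s),
            class = "fa_input")
}

#' Maximum-likelihood factor analysis by EM
#'
#' Fits the latent model `v_t = mu + Gamma z_t + eps`, `eps ~ N(0, Psi)`
#' diagonal, `z ~ N(0, I)`, to the columns of an `fa_input` (or any
#' units x bins matrix). `p = 0` fits the independent-noise null model.
#' Noise variances collapsing toward zero (Heywood cases) are floored at
#' `1e-6` of each unit's variance with a warning flag. The log likelihood is
#' non-decreasing over EM iterations.
#'
#' @param input `fa_input` or numeric matrix (units x bins).
#' @param p number of factors.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return an `fa_model`: `mu`, `loadings` (units x p), `psi`, `p`,
#'   `scores` (p x bins, posterior means), `loglik`, `loglik_trace`,
#'   `converged`, `heywood`.
#' @export
fit_fa <- function(input, p, tol = 1e-6, max_iter = 500) {
  x <- if (inherits(input, "fa_input")) input$x else as.matrix(input)
  N <- nrow(x); M <- ncol(x)
  stopifnot(p >= 0, p < N, M >= 10 * max(p, 1))
  mu <- rowMeans(x)
  xc <- x - mu
  S <- tcrossprod(xc) / M                     # ML covariance
  em <- fa_em(S, M, p, tol, max_iter)
  if (!em$converged) warn("factor analysis EM did not converge; returning best fit")
  if (em$heywood) warn("Heywood case: noise variance floored for some unit(s)")
  scores <- if (p == 0) matrix(0, 0, M) else {
    Sigma <- tcrossprod(em$loadings) + diag(em$psi, N)
    t(solve(Sigma, em$loadings)) %*% xc
  }
  structure(list(mu = mu, loadings = em$loadings, psi = em$psi,
                 p = as.integer(p), scores = scores, loglik = em$loglik,
                 loglik_trace = em$trace, converged = em$converged,
                 heywood = em$heywood, unit_id = rownames(x)),
            class = "fa_model")
}

# EM on a covariance matrix alone (M = number of observations behind S)
fa_em <- function(S, M, p, tol = 1e-6, max_iter = 500) {
  N <- nrow(S)
  dS <- pmax(diag(S), 1e-12)
  if (p == 0) {
    ll <- fa_loglik(diag(dS, N), S, M, N)
    return(list(loadings = matrix(0, N, 0), psi = dS, loglik = ll,
                trace = ll, converged = TRUE, heywood = FALSE))
  }
  # initialize from the correlation eigenstructure (scaled back to the
  # covariance metric): a single-unit variance direction is likelihood-
  # equivalent to noise variance, so factors must start where correlation,
  # not variance, lives
  psi <- 0.5 * dS
  R <- stats::cov2cor(S)
  eR <- eigen(R, symmetric = TRUE)
  lamR <- pmax(eR$values[seq_len(p)] - 1, 0.05)
  G <- diag(sqrt(dS), N) %*% eR$vectors[, seq_len(p), drop = FALSE] %*%
    diag(sqrt(lamR), p)
  heywood <- FALSE
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    Sigma <- tcrossprod(G) + diag(psi, N)
    ll <- fa_loglik(Sigma, S, M, N)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
    delta <- t(solve(Sigma, G))               # p x N: E[z|x] projection
    H <- diag(p) - delta %*% G + delta %*% S %*% t(delta)
    G <- S %*% t(delta) %*% solve(H)
    psi <- diag(S - G %*% delta %*% S)
    low <- psi < 1e-6 * dS
    if (any(low)) { heywood <- TRUE; psi[low] <- 1e-6 * dS[low] }
  }
  Sigma <- tcrossprod(G) + diag(psi, N)
  list(loadings = G, psi = psi, loglik = fa_loglik(Sigma, S, M, N),
       trace = trace, converged = it < max_iter, heywood = heywood)
}

fa_loglik <- function(Sigma, S, M, N) {
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  -M / 2 * (N * log(2 * pi) + logdet + sum(diag(chol2inv(ch) %*% S)))
}

#' @export
print.fa_model <- function(x, ...) {
  cat(sprintf("<fa_model> %d units, %d factor(s), loglik %.1f%s\n",
              length(x$mu), x$p, x$loglik,
              if (x$heywood) " [Heywood-floored]" else ""))
  invisible(x)
}

#' Trial-shuffle surrogate of an FA input
#'
#' For each unit independently, whole-trial rate segments are permuted
#' across trials, preserving every unit's within-trial structure and
#' autocorrelation (and the event-locked rate structure shared across
#' trials) while destroying instantaneous cross-unit dependencies. Trials of
#' exactly equal segment length exchange directly; remaining trials are
#' permuted within blocks of nearest segment length, the donor segment being
#' truncated or recycled to the recipient length. With a single trial the
#' input is returned unchanged.
#'
#' @param input an `fa_input`.
#' @param block_size nearest-length block size for unequal-length trials.
#' @return an `fa_input` with shuffled `x`.
#' @export
trial_shuffle <- function(input, block_size = 8) {
  x <- input$x
  segs <- split(seq_along(input$trial), input$trial)
  lens <- lengths(segs)
  # partition trials into shuffle groups: exact-length groups, then
  # nearest-length blocks over the leftover singletons
  groups <- list()
  for (L in unique(lens)) {
    same <- which(lens == L)
    if (length(same) >= 2) groups[[length(groups) + 1]] <- same
  }
  single <- setdiff(seq_along(segs), unlist(groups))
  if (length(single) >= 2) {
    ord <- single[order(lens[single])]
    cuts <- split(ord, ceiling(seq_along(ord) / block_size))
    groups <- c(groups, cuts[lengths(cuts) >= 2])
  }
  for (j in seq_len(nrow(x))) {
    for (grp in groups) {
      perm <- grp[sample(length(grp))]
      rows <- lapply(segs[perm], function(src) x[j, src])
      for (gi in seq_along(grp)) {
        dst <- segs[[grp[gi]]]
        v <- rows[[gi]]
        x[j, dst] <- rep_len(v, length(dst))
      }
    }
  }
  input$x <- x
  input
}

#' Bootstrap selection of the number of significant factors
#'
#' For l = 1..max_p the incremental log-likelihood ratio
#' `LLR(l) = 2 (ll_l - ll_{l-1})` on the real data is compared against the
#' 99th percentile of the same statistic over `n_boot` trial-shuffled
#' surrogates; the selected `p` is the largest l whose increments 1..l are
#' all significant (stopping at the first failure). Bootstrap loading
#' distributions at the selected p are retained for
#' [significant_loadings()].
#'
#' @param input an `fa_input`.
#' @param max_p largest factor count considered.
#' @param n_boot number of trial-shuffled surrogates (the full-scale
#'   convention is 500).
#' @param q bootstrap quantile defining the upper confidence limit.
#' @param tol,max_iter EM settings.
#' @return list `p`, `llr` (tibble `l`, `llr`, `threshold`, `significant`),
#'   `boot_loadings` (|loading| draws at each l, list over l),
#'   `models` (real-data ladder fits).
#' @export
select_n_factors <- function(input, max_p = 6, n_boot = 500, q = 0.99,
                             tol = 1e-6, max_iter = 500) {
  stopifnot(max_p < nrow(input$x))
  if (n_boot < 100)
    inform("fewer than 100 bootstraps; confidence limits will be coarse")
  M <- ncol(input$x)
  ladder_on <- function(x) {
    S <- tcrossprod(x - rowMeans(x)) / ncol(x)
    lls <- numeric(max_p + 1)
    loads <- vector("list", max_p)
    for (l in 0:max_p) {
      em <- fa_em(S, ncol(x), l, tol = tol, max_iter = max_iter)
      lls[l + 1] <- em$loglik
      if (l > 0) loads[[l]] <- abs(em$loadings)
    }
    list(lls = lls, loads = loads)
  }
  real_models <- vector("list", max_p + 1)
  for (l in 0:max_p)
    real_models[[l + 1]] <- suppressWarnings(fit_fa(input, l, tol = tol,
                                                    max_iter = max_iter))
  ll_real <- vapply(real_models, `[[`, 0, "loglik")
  llr_real <- 2 * diff(ll_real)

  boot_llr <- matrix(NA_real_, n_boot, max_p)
  boot_loads <- vector("list", max_p)
  for (b in seq_len(n_boot)) {
    lad <- ladder_on(trial_shuffle(input)$x)
    boot_llr[b, ] <- 2 * diff(lad$lls)
    for (l in seq_len(max_p))
      boot_loads[[l]] <- c(boot_loads[[l]], as.numeric(lad$loads[[l]]))
  }
  thr <- apply(boot_llr, 2, quantile, probs = q, names = FALSE)
  sig <- llr_real > thr
  p_sel <- if (!sig[1]) 0L else {
    first_fail <- which(!sig)
    if (length(first_fail) == 0) max_p else first_fail[1] - 1L
  }
  list(p = as.integer(p_sel),
       llr = tibble(l = seq_len(max_p), llr = llr_real, threshold = thr,
                    significant = sig),
       boot_loadings = boot_loads,
       models = real_models)
}

#' Significant factor loadings
#'
#' Unit i is assigned to factor l when |loading| exceeds the `q` quantile of
#' the pooled bootstrap |loading| distribution at the same factor count
#' (`per_factor = TRUE` thresholds each factor column separately). Factor
#' signs are aligned so each factor's largest-|loading| unit loads
#' positively.
#'
#' @param model an `fa_model` with `p >= 1`.
#' @param boot_loadings numeric vector (pooled) or matrix of bootstrap
#'   |loadings| at the same p (from [select_n_factors()]).
#' @param q quantile (default 0.99, the 1% upper confidence limit).
#' @param per_factor threshold per factor instead of pooled.
#' @return list `mask` (units x factors logical), `threshold`, `model`
#'   (sign-aligned).
#' @export
significant_loadings <- function(model, boot_loadings, q = 0.99,
                                 per_factor = FALSE) {
  stopifnot(model$p >= 1)
  G <- model$loadings
  # sign convention: largest-|loading| member positive
  for (l in seq_len(ncol(G))) {
    i <- which.max(abs(G[, l]))
    if (G[i, l] < 0) {
      G[, l] <- -G[, l]
      if (nrow(model$scores) >= l) model$scores[l, ] <- -model$scores[l, ]
    }
  }
  model$loadings <- G
  bl <- abs(as.numeric(unlist(boot_loadings)))
  if (all(bl == 0)) {
    warn("bootstrap loadings are all zero; every loading flagged significant")
    thr <- 0
  } else thr <- quantile(bl, q, names = FALSE)
  if (per_factor && is.matrix(boot_loadings))
    thr <- apply(abs(boot_loadings), 2, quantile, probs = q, names = FALSE)
  mask <- abs(G) > rep(thr, each = nrow(G))
  rownames(mask) <- model$unit_id
  list(mask = mask, threshold = thr, model = model)
}

#' Assemble detected factors into cell assemblies
#'
#' One assembly per factor with at least 2 significantly loading units;
#' typed by its members' areas. A within-area assembly whose member set is a
#' subset of an inter-area assembly's members is reported as part of the
#' larger assembly (`merged_into` set, not listed separately among active
#' assemblies).
#'
#' @param mask units x factors logical matrix (rownames = unit ids).
#' @param areas character vector of areas matching the mask rows.
#' @return tibble `id`, `factor`, `type`, `members` (list-column),
#'   `n_members`, `merged_into`.
#' @export
assemble <- function(mask, areas) {
  stopifnot(nrow(mask) == length(areas))
  rows <- list()
  for (l in seq_len(ncol(mask))) {
    mem <- rownames(mask)[mask[, l]]
    if (length(mem) < 2) next
    ar <- unique(areas[mask[, l]])
    type <- if (length(ar) == 2) "inter-area"
            else if (ar == "dCA1") "within-dCA1" else "within-mPFC"
    rows[[length(rows) + 1]] <- tibble(
      id = paste0("F", l), factor = l, type = type,
      members = list(sort(mem)), n_members = length(mem))
  }
  if (length(rows) == 0)
    return(tibble(id = character(), factor = integer(), type = character(),
                  members = list(), n_members = integer(),
                  merged_into = character()))
  out <- bind_rows(rows)
  out$merged_into <- NA_character_
  inter <- which(out$type == "inter-area")
  for (i in which(out$type != "inter-area")) {
    for (j in inter) {
      if (all(out$members[[i]] %in% out$members[[j]])) {
        out$merged_into[i] <- out$id[j]
        break
      }
    }
  }
  out
}

#' Significant assembly activation times
#'
#' A factor score is significant at a time bin when it exceeds the
#' `1 - alpha` quantile of scores obtained by projecting trial-shuffled
#' inputs through the fitted model.
#'
#' @param model a sign-aligned `fa_model`.
#' @param input the `fa_input` to score (normally the one the model was fit
#'   on; scores are recomputed by projecting `input` through the model).
#' @param alpha level (default 0.01).
#' @param n_boot shuffled projections.
#' @return list `mask` (factors x bins logical), `threshold` (per factor),
#'   `scores`.
#' @export
activation_significance <- function(model, input, alpha = 0.01, n_boot = 20) {
  stopifnot(model$p >= 1)
  Sigma <- tcrossprod(model$loadings) + diag(model$psi, length(model$mu))
  delta <- t(solve(Sigma, model$loadings))
  scores <- delta %*% (input$x - model$mu)
  null <- vector("list", n_boot)
  for (b in seq_len(n_boot))
    null[[b]] <- delta %*% (trial_shuffle(input)$x - model$mu)
  nullmat <- do.call(cbind, null)              # p x (bins * n_boot)
  thr <- apply(nullmat, 1, quantile, probs = 1 - alpha, names = FALSE)
  mask <- sweep(scores, 1, thr, ">")
  list(mask = mask, threshold = thr, scores = scores)
}

#' End-to-end FA assembly detection
#'
#' Runs the full ladder: factor-count selection against trial-shuffle
#' bootstraps, loading significance, sign alignment, assembly typing and the
#' subset-merge rule, and activation significance.
#'
#' @param input an `fa_input`.
#' @param max_p,n_boot,q_llr see [select_n_factors()].
#' @param q_load loading-significance quantile.
#' @param alpha_act activation-significance level.
#' @param n_boot_act shuffled projections for activation significance.
#' @return an `assembly_set`: list `assemblies` (tibble), `model`,
#'   `selection`, `activation`, `input`.
#' @export
detect_assemblies <- function(input, max_p = 6, n_boot = 500, q_llr = 0.99,
                              q_load = 0.99, alpha_act = 0.01,
                              n_boot_act = 20) {
  sel <- select_n_factors(input, max_p = max_p, n_boot = n_boot, q = q_llr)
  if (sel$p == 0) {
    return(structure(list(assemblies = assemble(matrix(FALSE, nrow(input$x), 0,
                                     dimnames = list(input$unit_id, NULL)),
                                     input$area),
                          model = sel$models[[1]], selection = sel,
                          activation = NULL, input = input),
                     class = "assembly_set"))
  }
  model <- sel$models[[sel$p + 1]]
  sl <- significant_loadings(model, sel$boot_loadings[[sel$p]], q = q_load)
  act <- activation_significance(sl$model, input, alpha = alpha_act,
                                 n_boot = n_boot_act)
  structure(list(assemblies = assemble(sl$mask, input$area),
                 model = sl$model, selection = sel, activation = act,
                 loading_mask = sl$mask, input = input),
            class = "assembly_set")
}

#' @export
print.assembly_set <- function(x, ...) {
  a <- x$assemblies
  cat(sprintf("<assembly_set> %d factor(s) selected, %d assemblies (%s)\n",
              x$selection$p, nrow(a),
              if (nrow(a) > 0) paste(a$type, collapse = ", ") else "none"))
  invisible(x)
}
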