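#' Jaccard overlap between two member sets
#'
#' `O = |A intersect B| / |A union B|`: 1 for identical sets, 0 iff
#' disjoint, symmetric.
#'
#' @param a,b character vectors of unit ids.
#' @return scalar in `[0, 1]`.
#' @export
overlap_score <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Mean best-pair overlap between two assembly sets
#'
#' For each assembly in `set_a` the highest-overlap assembly in `set_b` is
#' found; the mean of those best overlaps is returned (0 if either set is
#' empty while the other is not, 1 if both are empty).
#'
#' @param set_a,set_b lists of member-id character vectors (or `assemblies`
#'   tibbles from [detect_assemblies()] / [ica_assemblies()]).
#' @return scalar in `[0, 1]`.
#' @export
match_overlap <- function(set_a, set_b) {
  get_sets <- function(s) if (is.data.frame(s)) s$members else s
  a <- get_sets(set_a); b <- get_sets(set_b)
  if (length(a) == 0 && length(b) == 0) return(1)
  if (length(a) == 0 || length(b) == 0) return(0)
  mean(vapply(a, function(m) max(vapply(b, overlap_score, 0, a = m)), 0))
}

# symmetric-decorrelation fixed-point ICA (logcosh contrast) on whitened rows
fast_ica_w <- function(Z, max_iter = 200, tol = 1e-6) {
  k <- nrow(Z); M <- ncol(Z)
  sym <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), k) %*%
      t(s$vectors) %*% W
  }
  W <- sym(matrix(rnorm(k * k), k))
  for (it in seq_len(max_iter)) {
    Y <- W %*% Z
    G <- tanh(Y)
    W1 <- sym(G %*% t(Z) / M - diag(rowMeans(1 - G^2), k) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Independent-component cell-assembly detection
#'
#' The classical PCA/ICA route used to cross-check the factor-analysis
#' assemblies: the number of co-activation components is the count of
#' correlation-matrix eigenvalues of the z-scored 50-ms rates exceeding the
#' Marchenko-Pastur upper bound `(1 + sqrt(N/M))^2`; ICA is run on the
#' retained subspace; a unit belongs to a component when its |weight|
#' exceeds that component's mean + `threshold_sd` SD; assemblies require at
#' least 3 members.
#'
#' @param input an `fa_input`.
#' @param threshold_sd weight threshold in SD (default 2.5).
#' @param min_members minimum assembly size (default 3).
#' @return tibble like [assemble()]'s output (plus `weights` list-column);
#'   empty when no eigenvalue clears the bound.
#' @export
ica_assemblies <- function(input, threshold_sd = 2.5, min_members = 3) {
  x <- input$x
  N <- nrow(x); M <- ncol(x)
  sds <- apply(x, 1, sd)
  ok <- sds > 0
  z <- (x[ok, , drop = FALSE] - rowMeans(x[ok, , drop = FALSE])) / sds[ok]
  C <- tcrossprod(z) / M
  mp_hi <- (1 + sqrt(nrow(z) / M))^2
  e <- eigen(C, symmetric = TRUE)
  n_sig <- sum(e$values > mp_hi)
  empty <- tibble(id = character(), factor = integer(), type = character(),
                  members = list(), n_members = integer(),
                  merged_into = character(), weights = list())
  if (n_sig == 0) return(empty)
  V <- e$vectors[, seq_len(n_sig), drop = FALSE]
  lam <- e$values[seq_len(n_sig)]
  Zw <- diag(1 / sqrt(lam), n_sig) %*% t(V) %*% z     # whitened projections
  W <- fast_ica_w(Zw)
  patterns <- V %*% diag(sqrt(lam), n_sig) %*% t(W)   # units x components
  for (kk in seq_len(n_sig)) {
    w <- patterns[, kk] / sqrt(sum(patterns[, kk]^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    patterns[, kk] <- w
  }
  if (threshold_sd <= 0)
    warn("non-positive weight threshold: every unit becomes a member")
  ids <- input$unit_id[ok]
  areas <- input$area[ok]
  rows <- list()
  for (kk in seq_len(n_sig)) {
    w <- patterns[, kk]
    mem <- abs(w) > mean(abs(w)) + threshold_sd * sd(abs(w))
    if (sum(mem) < min_members) next
    ar <- unique(areas[mem])
    rows[[length(rows) + 1]] <- tibble(
      id = paste0("IC", kk), factor = kk,
      type = if (length(ar) == 2) "inter-area"
             else if (ar == "dCA1") "within-dCA1" else "within-mPFC",
      members = list(sort(ids[mem])), n_members = sum(mem),
      merged_into = NA_character_, weights = list(setNames(w, ids)))
  }
  if (length(rows) == 0) empty else bind_rows(rows)
}

#' Rank-ordered synthetic assembly decoding curves
#'
#' Units are ranked in descending order of their individual peak decoding
#' performance (LOOCV peak CP over the supplied alignment windows). For each
#' group size the 1st, 2nd, ... ranked consecutive blocks of that size are
#' decoded jointly and their peak CP recorded; blocks running past the unit
#' pool are omitted.
#'
#' @param tensors list of [build_rate_tensor()] results sharing trials
#'   (e.g. sample +-5 s and the 5 s before choice).
#' @param labels per-trial labels (default `cue_side` of the first tensor).
#' @param sizes group sizes (default 2:20).
#' @param ranks block ranks (default 1:10).
#' @param lambda regularization.
#' @return list `ranking` (tibble `unit_id`, `peak_cp`, `rank`) and `curve`
#'   (tibble `size`, `rank`, `peak_cp`).
#' @export
synthetic_assembly_curve <- function(tensors, labels = NULL, sizes = 2:20,
                                     ranks = 1:10, lambda = 0.05) {
  if (inherits(tensors, "rate_tensor")) tensors <- list(tensors)
  labels <- labels %||% tensors[[1]]$trials$cue_side
  li <- labels_to_int(labels)
  units <- tensors[[1]]$unit_id
  peak_cp_of <- function(unit_idx) {
    max(vapply(tensors, function(tensor)
      max(lda_loocv_curve_cpp(tensor$rates[, unit_idx, , drop = FALSE],
                              li$y, lambda)), 0))
  }
  single <- vapply(seq_along(units), function(j) peak_cp_of(j), 0)
  ord <- order(single, decreasing = TRUE)
  ranking <- tibble(unit_id = units[ord], peak_cp = single[ord],
                    rank = seq_along(ord))
  rows <- list()
  for (s in sizes) {
    for (r in ranks) {
      ix <- ((r - 1) * s + 1):(r * s)
      if (max(ix) > length(units)) break
      rows[[length(rows) + 1]] <-
        tibble(size = s, rank = r, peak_cp = peak_cp_of(ord[ix]))
    }
  }
  list(ranking = ranking, curve = bind_rows(rows))
}

#' Rank of the closest-performing synthetic assembly
#'
#' Matches a detected assembly's peak CP to the synthetic curve at the same
#' (or nearest available) size and returns the rank of the
#' closest-performing block.
#'
#' @param peak_cp observed assembly peak CP.
#' @param size assembly size.
#' @param curve the `curve` tibble from [synthetic_assembly_curve()].
#' @return integer rank.
#' @export
match_synthetic_rank <- function(peak_cp, size, curve) {
  sz <- curve$size[which.min(abs(curve$size - size))]
  sub <- curve[curve$size == sz, ]
  sub$rank[which.min(abs(sub$peak_cp - peak_cp))]
}

#' Decoding after destroying noise correlations
#'
#' Within each cue condition, trial order is permuted so the label (signal)
#' structure is preserved while trial-by-trial co-fluctuations are
#' destroyed: `mode = "within-area"` permutes every unit independently
#' (removing all noise correlations); `mode = "between-area"` applies one
#' permutation per area shared by its units (removing only inter-area noise
#' correlations). CP curves are averaged over `n_perm` permutations.
#'
#' @param tensor a [build_rate_tensor()] result.
#' @param labels per-trial labels.
#' @param n_perm permutations to average (default 50).
#' @param mode which correlations to destroy.
#' @param lambda regularization.
#' @return tibble `time`, `cp_observed`, `cp_shuffled`.
#' @export
noise_shuffle_decoding <- function(tensor, labels = NULL, n_perm = 50,
                                   mode = c("within-area", "between-area"),
                                   lambda = 0.05) {
  mode <- match.arg(mode)
  labels <- labels %||% tensor$trials$cue_side
  li <- labels_to_int(labels)
  obs <- as.numeric(lda_loocv_curve_cpp(tensor$rates, li$y, lambda))
  d <- dim(tensor$rates)
  cls <- split(seq_len(d[1]), li$y)
  acc <- numeric(d[3])
  for (i in seq_len(n_perm)) {
    R <- tensor$rates
    if (mode == "within-area") {
      for (j in seq_len(d[2]))
        for (ix in cls) R[ix, j, ] <- R[sample(ix), j, ]
    } else {
      for (ar in unique(tensor$area)) {
        jj <- which(tensor$area == ar)
        for (ix in cls) R[ix, jj, ] <- R[sample(ix), jj, ]
      }
    }
    acc <- acc + as.numeric(lda_loocv_curve_cpp(R, li$y, lambda))
  }
  tibble(time = tensor$times, cp_observed = obs, cp_shuffled = acc / n_perm)
}
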