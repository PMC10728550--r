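#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_hline
#'   geom_ribbon labs scale_fill_viridis_c facet_wrap theme_minimal geom_col
#' @export
ggplot2::autoplot

#' Tidy and summary methods for pipeline result objects
#'
#' `tidy()` returns the long per-bin (or per-cell / per-loading) tibble
#' behind a result object; `glance()` a one-row summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @name tidy.tscore_profiles
NULL

#' @rdname tidy.tscore_profiles
#' @export
tidy.tscore_profiles <- function(x, ...) as_tibble(x)

#' @rdname tidy.tscore_profiles
#' @export
glance.tscore_profiles <- function(x, ...) {
  s <- tscore_summary(x)
  tibble(n_units = nrow(s), mean_peak_abs_t = mean(s$peak_abs_t),
         mean_duration_s = mean(s$duration_s))
}

#' @rdname tidy.tscore_profiles
#' @export
tidy.decoding_result <- function(x, ...) as_tibble(x)

#' @rdname tidy.tscore_profiles
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(peak_cp = max(x$cp), peak_time_s = x$time[which.max(x$cp)],
         mean_cp = mean(x$cp),
         frac_sig = if ("sig" %in% names(x)) mean(x$sig) else NA_real_,
         n_units = attr(x, "n_units"), n_trials = attr(x, "n_trials"),
         lambda = attr(x, "lambda"))
}

#' @rdname tidy.tscore_profiles
#' @export
tidy.ct_matrix <- function(x, ...) {
  tibble(train_time = rep(x$times, times = length(x$times)),
         test_time = rep(x$times, each = length(x$times)),
         cp = as.numeric(x$perf),
         sig = if (!is.null(x$sig_mask)) as.logical(x$sig_mask) else NA)
}

#' @rdname tidy.tscore_profiles
#' @export
glance.ct_matrix <- function(x, ...) {
  off <- abs(row(x$perf) - col(x$perf)) > 1
  tibble(mean_cp = mean(x$perf), mean_diag_cp = mean(diag(x$perf)),
         mean_offdiag_cp = mean(x$perf[off]),
         frac_sig = if (!is.null(x$sig_mask)) mean(x$sig_mask) else NA_real_,
         n_resamples = x$n_resamples)
}

#' @rdname tidy.tscore_profiles
#' @export
tidy.fa_model <- function(x, ...) {
  if (x$p == 0)
    return(tibble(unit_id = character(), factor = integer(),
                  loading = numeric()))
  tibble(unit_id = rep(x$unit_id %||% as.character(seq_along(x$mu)),
                       times = x$p),
         factor = rep(seq_len(x$p), each = length(x$mu)),
         loading = as.numeric(x$loadings))
}

#' @rdname tidy.tscore_profiles
#' @export
glance.fa_model <- function(x, ...) {
  tibble(p = x$p, loglik = x$loglik, converged = x$converged,
         heywood = x$heywood, n_units = length(x$mu))
}

#' @rdname tidy.tscore_profiles
#' @export
tidy.assembly_set <- function(x, ...) {
  a <- x$assemblies
  if (nrow(a) == 0) return(a)
  tidyr::unnest(mutate(a, unit_id = .data$members), "unit_id") |>
    select("id", "factor", "type", "unit_id", "merged_into")
}

#' @rdname tidy.tscore_profiles
#' @export
glance.assembly_set <- function(x, ...) {
  a <- x$assemblies
  tibble(p_selected = x$selection$p, n_assemblies = nrow(a),
         n_inter = sum(a$type == "inter-area"),
         n_within = sum(a$type != "inter-area"))
}

#' @rdname tidy.tscore_profiles
#' @param object a result object (autoplot convention).
#' @export
autoplot.decoding_result <- function(object, ...) {
  g <- ggplot(as_tibble(object), aes(.data$time, .data$cp)) +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    geom_line() +
    labs(x = "time from event (s)", y = "correct-prediction fraction") +
    theme_minimal()
  if ("null_hi" %in% names(object))
    g <- g + geom_line(aes(y = .data$null_hi), colour = "grey60")
  g
}

#' @rdname tidy.tscore_profiles
#' @export
autoplot.ct_matrix <- function(object, ...) {
  ggplot(tidy(object), aes(.data$train_time, .data$test_time,
                           fill = .data$cp)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "training time (s)", y = "testing time (s)", fill = "CP") +
    theme_minimal()
}

#' @rdname tidy.tscore_profiles
#' @export
autoplot.tscore_profiles <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$time, .data$t, group = .data$unit_id)) +
    geom_line(alpha = 0.4) +
    facet_wrap(~area) +
    labs(x = "time from event (s)", y = "t score (L - R)") +
    theme_minimal()
}

#' @rdname tidy.tscore_profiles
#' @export
autoplot.correlogram <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$lag, .data$value)) +
    geom_col(width = attr(object, "bin_s") %||% NULL) +
    labs(x = "lag (s)", y = "normalized coincidences") +
    theme_minimal()
}

#' @rdname tidy.tscore_profiles
#' @export
autoplot.assembly_set <- function(object, ...) {
  d <- tidy.fa_model(object$model)
  if (nrow(d) == 0) abort("no factors to plot")
  d$significant <- as.logical(object$loading_mask)
  ggplot(d, aes(factor(.data$factor), .data$unit_id, fill = .data$loading)) +
    geom_tile(aes(alpha = ifelse(.data$significant, 1, 0.4))) +
    scale_fill_viridis_c() +
    labs(x = "factor", y = "unit", alpha = NULL) +
    theme_minimal()
}
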