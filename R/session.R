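#' DNMTS recording sessions
#'
#' A session bundles the two raw inputs of the pipeline: a spike table
#' (one row per spike: `unit_id`, `area`, `spike_time_s`) and a trial/event
#' table (one row per trial: `trial`, `cue_side`, `delay_s`, `outcome` and the
#' event timestamps `t_cue`, `t_sample`, `t_tone`, `t_nosepoke`, `t_choice`,
#' `t_reward`). All times are absolute seconds from session start.
#'
#' @param spikes tibble with columns `unit_id`, `area`, `spike_time_s`.
#' @param trials tibble with the trial/event columns listed above.
#' @param duration_s session duration in seconds; defaults to the last event
#'   or spike plus 1 s.
#' @param lfp optional tibble `area`, `time_s`, `voltage` with attribute
#'   `fs_hz` giving the sample rate.
#' @return An object of class `dnmts_session`.
#' @export
new_session <- function(spikes, trials, duration_s = NULL, lfp = NULL) {
  spikes <- as_tibble(spikes)
  trials <- as_tibble(trials)
  req_sp <- c("unit_id", "area", "spike_time_s")
  req_tr <- c("trial", "cue_side", "delay_s", "outcome",
              "t_cue", "t_sample", "t_tone", "t_nosepoke", "t_choice", "t_reward")
  missing_sp <- setdiff(req_sp, names(spikes))
  missing_tr <- setdiff(req_tr, names(trials))
  if (length(missing_sp) > 0)
    abort(paste0("spike table is missing column(s): ",
                 paste(missing_sp, collapse = ", ")))
  if (length(missing_tr) > 0)
    abort(paste0("event table is missing column(s): ",
                 paste(missing_tr, collapse = ", ")))

  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$area <- normalize_area(spikes$area)
  bad <- !complete.cases(spikes[req_sp])
  if (any(bad)) {
    warn(sprintf("dropping %d unparsable spike row(s)", sum(bad)))
    spikes <- spikes[!bad, ]
  }
  if (is.unsorted(spikes$spike_time_s)) {
    # per-unit sort is what matters downstream; sort globally for tidiness
    ord <- order(spikes$unit_id, spikes$spike_time_s)
    if (any(tapply(spikes$spike_time_s, spikes$unit_id, is.unsorted)))
      warn("spike times were not sorted within unit; sorting")
    spikes <- spikes[ord, ]
  } else {
    spikes <- arrange(spikes, .data$unit_id, .data$spike_time_s)
  }
  if (any(spikes$spike_time_s < 0)) abort("negative spike times")

  trials$trial <- as.integer(trials$trial)
  trials <- arrange(trials, .data$trial)
  validate_trials(trials)

  if (is.null(duration_s)) {
    duration_s <- max(c(spikes$spike_time_s, unlist(trials[grep("^t_", names(trials))])),
                      na.rm = TRUE) + 1
  }
  completed <- trials$outcome != "miss"
  if (mean(completed) < 2 / 3)
    warn(sprintf("only %.0f%% of trials completed (< 67%%); session would be excluded upstream",
                 100 * mean(completed)))

  structure(list(spikes = spikes, trials = trials,
                 duration_s = duration_s, lfp = lfp),
            class = "dnmts_session")
}

normalize_area <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))
  map <- c(DCA1 = "dCA1", CA1 = "dCA1", HPC = "dCA1", HIPPOCAMPUS = "dCA1",
           MPFC = "mPFC", PFC = "mPFC", PL = "mPFC", PRELIMBIC = "mPFC")
  out <- unname(map[key])
  if (anyNA(out))
    abort(paste0("unrecognized area label(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  factor(out, levels = c("dCA1", "mPFC"))
}

validate_trials <- function(trials) {
  ev <- c("t_cue", "t_sample", "t_tone", "t_nosepoke", "t_choice")
  for (i in seq_len(nrow(trials))) {
    tt <- as.numeric(trials[i, ev])
    tt <- tt[!is.na(tt)]
    if (is.unsorted(tt))
      abort(sprintf("trial %d: event timestamps out of order", trials$trial[i]))
  }
  d <- trials$t_tone - trials$t_sample - trials$delay_s
  off <- which(!is.na(d) & abs(d) > 0.5)
  if (length(off) > 0)
    warn(sprintf("trial(s) %s: tone-sample interval deviates from nominal delay by > 0.5 s",
                 paste(trials$trial[off], collapse = ", ")))
  bad_side <- !trials$cue_side %in% c("L", "R")
  if (any(bad_side)) abort("cue_side must be 'L' or 'R'")
  bad_out <- !trials$outcome %in% c("correct", "error", "miss")
  if (any(bad_out)) abort("outcome must be correct/error/miss")
  invisible(trials)
}

#' Read a session from spike and event CSV files
#'
#' @param spikes_path CSV with header `unit_id,area,spike_time_s`.
#' @param events_path CSV with header
#'   `trial,cue_side,delay_s,outcome,t_cue,t_sample,t_tone,t_nosepoke,t_choice,t_reward`;
#'   empty cells mark absent events (miss trials).
#' @param lfp_path optional CSV `area,time_s,voltage`.
#' @return A [new_session()] object.
#' @export
read_session <- function(spikes_path, events_path, lfp_path = NULL) {
  spikes <- readr::read_csv(spikes_path, show_col_types = FALSE, progress = FALSE)
  trials <- readr::read_csv(events_path, show_col_types = FALSE, progress = FALSE)
  lfp <- NULL
  if (!is.null(lfp_path)) {
    lfp <- readr::read_csv(lfp_path, show_col_types = FALSE, progress = FALSE)
    fs <- 1 / median(diff(sort(unique(lfp$time_s))))
    attr(lfp, "fs_hz") <- fs
  }
  new_session(spikes, trials, lfp = lfp)
}

#' Write a session back to CSV files
#'
#' Inverse of [read_session()]; spike times are written with microsecond
#' precision so a read/write round trip is lossless at 1e-6 s.
#'
#' @param session a `dnmts_session`.
#' @param spikes_path,events_path output paths.
#' @export
write_session <- function(session, spikes_path, events_path) {
  sp <- session$spikes
  sp$spike_time_s <- sprintf("%.6f", sp$spike_time_s)
  readr::write_csv(sp, spikes_path, progress = FALSE)
  readr::write_csv(session$trials, events_path, progress = FALSE)
  invisible(session)
}

#' @export
print.dnmts_session <- function(x, ...) {
  u <- session_units(x)
  cat(sprintf("<dnmts_session> %d units (%d dCA1, %d mPFC), %d trials, %.0f s\n",
              nrow(u), sum(u$area == "dCA1"), sum(u$area == "mPFC"),
              nrow(x$trials), x$duration_s))
  invisible(x)
}

#' Per-unit summary table
#'
#' @param session a `dnmts_session`.
#' @return tibble `unit_id`, `area`, `n_spikes`, `mean_rate_hz` (spike count
#'   divided by session duration).
#' @export
session_units <- function(session) {
  session$spikes |>
    group_by(.data$unit_id, .data$area) |>
    summarise(n_spikes = n(), .groups = "drop") |>
    mutate(mean_rate_hz = .data$n_spikes / session$duration_s) |>
    arrange(.data$unit_id)
}

#' Spike times of one unit
#' @param session a `dnmts_session`.
#' @param unit_id unit identifier.
#' @return sorted numeric vector of spike times (s).
#' @export
unit_spikes <- function(session, unit_id) {
  session$spikes$spike_time_s[session$spikes$unit_id == unit_id]
}

#' Drop units below a mean-rate threshold
#'
#' Units with task-period mean firing rate below `min_rate_hz` (default
#' 0.5 Hz, the standard inclusion criterion) are removed.
#'
#' @param session a `dnmts_session`.
#' @param min_rate_hz inclusion threshold in Hz.
#' @return the filtered session.
#' @export
select_units <- function(session, min_rate_hz = 0.5) {
  stopifnot(session$duration_s > 0)
  u <- session_units(session)
  keep <- u$unit_id[u$mean_rate_hz >= min_rate_hz]
  if (length(keep) == 0) warn("no units pass the rate threshold")
  session$spikes <- filter(session$spikes, .data$unit_id %in% keep)
  session
}

#' Concatenated task-epoch time bins
#'
#' Collects 50-ms bins covering cue onset minus `pre_s` to choice press plus
#' `post_s` for every completed trial, merging overlapping windows so no bin
#' is duplicated. Bins live on the absolute session grid (bin k covers
#' `[k*bin_s, (k+1)*bin_s)`); each bin is labelled with its owning trial
#' (earliest trial on overlap).
#'
#' @param session a `dnmts_session`.
#' @param pre_s,post_s seconds before cue / after choice press.
#' @param bin_s bin width, default 0.05 s.
#' @return tibble `bin` (absolute index), `time` (left edge, s), `trial`.
#' @export
excise_task_epochs <- function(session, pre_s = 5, post_s = 5, bin_s = 0.05) {
  tr <- session$trials
  skip <- is.na(tr$t_choice)
  if (any(skip))
    inform(sprintf("skipping %d miss trial(s) without a choice press", sum(skip)))
  tr <- tr[!skip, ]
  if (nrow(tr) == 0) {
    warn("no completed trials; empty epoch set")
    return(tibble(bin = integer(), time = numeric(), trial = integer()))
  }
  pieces <- map(seq_len(nrow(tr)), function(i) {
    b0 <- floor((tr$t_cue[i] - pre_s) / bin_s)
    b1 <- ceiling((tr$t_choice[i] + post_s) / bin_s) - 1L
    tibble(bin = as.integer(b0:b1), trial = tr$trial[i])
  })
  out <- bind_rows(pieces) |>
    group_by(.data$bin) |>
    summarise(trial = min(.data$trial), .groups = "drop") |>
    arrange(.data$bin)
  out$time <- out$bin * bin_s
  select(out, "bin", "time", "trial")
}
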