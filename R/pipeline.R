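#' Pipeline run configuration
#'
#' Bundles the inputs (paths to spike/event CSVs, or a simulation config),
#' stage toggles and the numeric parameters of every stage, with the
#' pipeline defaults: lambda 0.05, 50-ms bins, 500 FA bootstraps, 1000 label
#' shuffles, 500 cross-temporal resamples of 8 trials per class, 100 CCG
#' draws, 50 noise permutations.
#'
#' @param spikes_path,events_path input CSVs; ignored when `simulate` given.
#' @param simulate a [simulate_config()] to generate the session instead.
#' @param stages character subset of
#'   `c("rates", "units", "decoding", "cross_temporal", "assemblies",
#'   "rhythm")`.
#' @param lambda,bin_s,bandwidth,n_shuffle,n_boot_fa,n_resamples,n_per_class,ccg_draws,noise_perms
#'   stage parameters (see the stage functions).
#' @param max_p FA factor-count ceiling.
#' @param seed master seed; every stage RNG derives from it.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(spikes_path = NULL, events_path = NULL,
                            simulate = NULL,
                            stages = c("rates", "units", "decoding",
                                       "cross_temporal", "assemblies",
                                       "rhythm"),
                            lambda = 0.05, bin_s = 0.05, bandwidth = "cv",
                            n_shuffle = 1000, n_boot_fa = 500,
                            n_resamples = 500, n_per_class = 8, max_p = 6,
                            ccg_draws = 100, noise_perms = 50, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> unit selection -> rate tensors -> single-unit
#' coding -> population decoding (correct, and correct->error when error
#' trials exist) -> cross-temporal decoding -> FA assembly detection (+ ICA
#' cross-check) -> rhythm physiology, writing each stage's output as plain
#' CSV/JSON into `out_dir` together with the resolved configuration and
#' seed. Stages not in `config$stages` are skipped; later stages that need a
#' skipped stage fail with a clear message.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list of stage results; summary written to
#'   `summary.json` and `summary.md`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  started <- Sys.time()
  log <- character()
  note <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    log <<- c(log, msg)
    inform(msg)
  }

  cfg_out <- config
  cfg_out$simulate <- if (!is.null(config$simulate)) unclass(config$simulate)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  if (!is.null(config$simulate)) {
    note("simulating session (seed %d)", config$seed)
    sim <- simulate_session(config$simulate, seed = config$seed)
    session <- sim$session
    jsonlite::write_json(
      list(assemblies = lapply(sim$truth$assemblies, function(a)
        list(id = a$id, type = a$type, members = a$members)),
        rhythm = sim$truth$rhythm[c("f_hz", "m", "epoch")],
        seed = sim$truth$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    write_session(session, file.path(out_dir, "spikes.csv"),
                  file.path(out_dir, "events.csv"))
  } else {
    note("reading session")
    session <- read_session(config$spikes_path, config$events_path)
  }
  session <- select_units(session)
  res <- list(session = session)
  on <- function(stage) stage %in% config$stages
  need <- function(stage, from_stage, what) {
    if (is.null(res[[what]]))
      abort(sprintf("stage '%s' needs stage '%s' (missing '%s'); enable it",
                    stage, from_stage, what))
  }

  if (on("rates")) {
    note("building rate tensors (bandwidth: %s)",
         paste(config$bandwidth, collapse = ","))
    res$tensor_sample <- build_rate_tensor(session, "t_sample", c(-5, 5),
                                           config$bin_s, config$bandwidth)
    res$tensor_choice <- build_rate_tensor(session, "t_choice", c(-5, 5),
                                           config$bin_s, config$bandwidth)
    readr::write_csv(tibble(unit_id = names(res$tensor_sample$bandwidths),
                            bandwidth_s = res$tensor_sample$bandwidths),
                     file.path(out_dir, "bandwidths.csv"), progress = FALSE)
  }

  if (on("units")) {
    need("units", "rates", "tensor_sample")
    note("single-unit coding (%d shuffles)", config$n_shuffle)
    ps <- tscore_curves(res$tensor_sample, n_shuffle = config$n_shuffle)
    pc <- tscore_curves(res$tensor_choice, n_shuffle = config$n_shuffle)
    info <- informative_units(ps, pc)
    report <- left_join(tscore_summary(ps), info,
                        by = c("unit_id", "area"))
    readr::write_csv(report, file.path(out_dir, "unit_report.csv"),
                     progress = FALSE)
    res$profiles_sample <- ps; res$profiles_choice <- pc
    res$informative <- info
  }

  if (on("decoding")) {
    need("decoding", "rates", "tensor_sample")
    note("population decoding (lambda = %g)", config$lambda)
    corr <- session$trials$outcome[match(res$tensor_sample$trials$trial,
                                         session$trials$trial)] == "correct"
    dec <- loocv_decode(tensor_subset(res$tensor_sample,
                                      trials = res$tensor_sample$trials$trial[corr]),
                        lambda = config$lambda,
                        n_shuffle = min(config$n_shuffle, 200))
    readr::write_csv(tidy(dec), file.path(out_dir, "decoding_sample.csv"),
                     progress = FALSE)
    res$decoding <- dec
    if (any(!corr)) {
      tce <- train_correct_test_error(res$tensor_sample, lambda = config$lambda)
      if (!is.null(tce))
        readr::write_csv(tce, file.path(out_dir, "decoding_error.csv"),
                         progress = FALSE)
      res$error_decoding <- tce
    }
  }

  if (on("cross_temporal")) {
    need("cross_temporal", "rates", "tensor_sample")
    note("cross-temporal decoding (%d resamples)", config$n_resamples)
    ct <- cross_temporal_decode(res$tensor_sample,
                                n_per_class = config$n_per_class,
                                n_resamples = config$n_resamples,
                                lambda = config$lambda, stride = 4)
    readr::write_csv(tidy(ct), file.path(out_dir, "cross_temporal.csv"),
                     progress = FALSE)
    res$ct <- ct
  }

  if (on("assemblies")) {
    note("FA assembly detection (%d bootstraps)", config$n_boot_fa)
    input <- build_fa_input(session, "joint", bandwidth = 0.05)
    aset <- detect_assemblies(input, max_p = config$max_p,
                              n_boot = config$n_boot_fa)
    ica <- ica_assemblies(input)
    jsonlite::write_json(
      list(fa = lapply(seq_len(nrow(aset$assemblies)), function(i)
             list(id = aset$assemblies$id[i], type = aset$assemblies$type[i],
                  members = aset$assemblies$members[[i]])),
           ica = lapply(seq_len(nrow(ica)), function(i)
             list(id = ica$id[i], type = ica$type[i],
                  members = ica$members[[i]])),
           fa_ica_overlap = match_overlap(ica, aset$assemblies)),
      file.path(out_dir, "assemblies.json"), auto_unbox = TRUE, digits = NA)
    if (aset$selection$p > 0) {
      act <- tibble(time = input$time,
                    as_tibble(t(aset$model$scores),
                              .name_repair = ~ paste0("F", seq_len(aset$selection$p))))
      readr::write_csv(act, file.path(out_dir, "activations.csv"),
                       progress = FALSE)
    }
    res$assemblies <- aset; res$ica <- ica
  }

  if (on("rhythm")) {
    need("rhythm", "assemblies", "assemblies")
    note("rhythm physiology")
    aset <- res$assemblies
    inter <- aset$assemblies[aset$assemblies$type == "inter-area", ]
    pairs <- list()
    epochs <- event_epochs(session, "t_sample", c(-4, 0), "correct")
    if (nrow(inter) > 0) {
      mem <- inter$members[[1]]
      areas <- session_units(session)
      ca1 <- intersect(mem, areas$unit_id[areas$area == "dCA1"])
      pfc <- intersect(mem, areas$unit_id[areas$area == "mPFC"])
      for (a in ca1) for (b in pfc) {
        coh <- pair_coherence(unit_spikes(session, a),
                              unit_spikes(session, b), epochs)
        pairs[[length(pairs) + 1]] <-
          tibble(unit_a = a, unit_b = b, same_assembly = TRUE,
                 band_coherence = coh$band_mean)
      }
    }
    if (length(pairs) > 0)
      readr::write_csv(bind_rows(pairs), file.path(out_dir, "pair_coherence.csv"),
                       progress = FALSE)
    res$pairs <- if (length(pairs) > 0) bind_rows(pairs)
  }

  elapsed <- as.numeric(difftime(Sys.time(), started, units = "secs"))
  summary <- list(
    seed = config$seed,
    elapsed_s = elapsed,
    n_units = nrow(session_units(session)),
    n_trials = nrow(session$trials),
    stages = config$stages,
    peak_cp = if (!is.null(res$decoding)) max(res$decoding$cp),
    n_assemblies = if (!is.null(res$assemblies))
      nrow(res$assemblies$assemblies),
    fa_ica_overlap = if (!is.null(res$assemblies) && !is.null(res$ica))
      match_overlap(res$ica, res$assemblies$assemblies))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c("# Pipeline run", "",
               sprintf("- seed: %d", config$seed),
               sprintf("- elapsed: %.1f s", elapsed),
               sprintf("- units: %d, trials: %d", summary$n_units,
                       summary$n_trials),
               "", "## Log", log),
             file.path(out_dir, "summary.md"))
  invisible(res)
}
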