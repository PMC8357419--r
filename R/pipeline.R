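#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full synthetic-pipeline
#' run. Unknown keys in any section raise an error before any computation.
#' All stochastic stages derive their seeds from the single `seed`, so a
#' run is a pure function of its configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @param stages subset of the canonical stage sequence
#'   `simulate`, `score_states`, `detect_spindles`, `characterize`,
#'   `comodulate`, `spikes`, `trajectory`.
#' @param lfp named list of overrides for [synth_lfp_spec()].
#' @param emg named list: `wake` (data.frame of bouts), `twitches`
#'   (times, s), `fs`; defaults lay out two wake bouts and five twitches
#'   over the recording.
#' @param spikes named list of overrides for [synth_spikes_spec()].
#' @param cohort named list of overrides for [cohort_spec()].
#' @param detection named list: `variant`, `mad_multiplier`.
#' @param n_boot bootstrap resamples for the trajectory stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, stages = NULL,
                            lfp = list(), emg = list(), spikes = list(),
                            cohort = list(), detection = list(),
                            n_boot = 2000L) {
  all_stages <- c("simulate", "score_states", "detect_spindles",
                  "characterize", "comodulate", "spikes", "trajectory")
  if (is.null(stages)) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  check_keys <- function(lst, allowed, what) {
    bad <- setdiff(names(lst), allowed)
    if (length(bad))
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(lfp, names(formals(synth_lfp_spec)), "lfp")
  check_keys(emg, c("wake", "twitches", "fs"), "emg")
  check_keys(spikes, names(formals(synth_spikes_spec)), "spikes")
  check_keys(cohort, names(formals(cohort_spec)), "cohort")
  check_keys(detection, c("variant", "mad_multiplier"), "detection")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, lfp = lfp, emg = emg, spikes = spikes,
                 cohort = cohort, detection = detection,
                 n_boot = as.integer(n_boot)),
            class = "pipeline_config")
}

# deterministic polynomial hash of a string (base-31 over a large prime),
# used to fingerprint the configuration
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  p <- 34359738337                   # < 2^35, so h * 31 stays exact
  for (b in bytes) h <- (h * 31 + b) %% p
  sprintf("%05x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the synthetic analysis pipeline
#'
#' Executes the requested stages in their canonical order, writing one CSV
#' per result table plus a JSON run manifest (configuration, derived seeds,
#' configuration hash, and per-stage event counts). Outputs contain no
#' timestamps, so identical configuration and seed give byte-identical
#' files.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  log_lines <- character(0)
  note <- function(stage, ...) {
    line <- paste0("stage=", stage, " ", paste0(..., collapse = ""))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seeds <- config$seed + c(simulate = 101L, emg = 211L, spikes = 307L,
                           cohort = 401L)
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  want <- function(s) s %in% config$stages

  lfp_spec <- do.call(synth_lfp_spec, config$lfp)
  sim <- NULL
  if (want("simulate") || want("detect_spindles") || want("comodulate") ||
      want("spikes")) {
    sim <- run_stage("simulate", function()
      generate_lfp(lfp_spec, seeds[["simulate"]]))
    if (want("simulate")) {
      write_table(sim$events, file.path(config$out_dir, "ground_truth_events.csv"))
      note("simulate", "n_events=", nrow(sim$events),
           " duration_s=", lfp_spec$duration)
    }
  }

  states <- NULL
  if (want("score_states") || want("detect_spindles")) {
    emg_fs <- config$emg$fs %||% 2000
    dur <- lfp_spec$duration
    wake <- config$emg$wake %||%
      data.frame(start_s = c(0.02, 0.52) * dur, end_s = c(0.10, 0.60) * dur)
    twitches <- config$emg$twitches %||%
      (0.62 * dur + seq_len(5L) * 0.06 * dur)
    plan <- emg_bout_plan(dur, wake = wake, twitches = twitches)
    emg <- run_stage("score_states", function()
      generate_emg(plan, fs = emg_fs, seed = seeds[["emg"]]))
    env <- emg_envelope(emg$emg, emg$fs)
    states <- score_states(env)
    if (want("score_states")) {
      write_table(states$intervals, file.path(config$out_dir, "states.csv"))
      write_table(data.frame(twitch_s = twitch_times(states)),
                  file.path(config$out_dir, "twitches.csv"))
      note("score_states", "n_intervals=", nrow(states$intervals),
           " threshold_uV=", signif(env$threshold, 6))
    }
  }

  events <- NULL
  if (want("detect_spindles") || want("characterize") || want("comodulate") ||
      want("spikes")) {
    variant <- config$detection$variant %||% "rodent"
    madm <- config$detection$mad_multiplier %||% 3
    x <- sim$recording$signal[1L, ]
    fs <- sim$recording$fs
    mask <- if (!is.null(states)) sleep_mask(states) else
      data.frame(start_s = 0, end_s = lfp_spec$duration)
    if (!nrow(mask)) mask <- data.frame(start_s = 0, end_s = lfp_spec$duration)
    events_by_channel <- run_stage("detect_spindles", function()
      lapply(seq_len(nrow(sim$recording$signal)), function(ch) {
        prc <- compute_par(sim$recording$signal[ch, ], fs, variant = variant)
        detect_spindle_events(prc, mask, mad_multiplier = madm,
                              channel = ch)
      }))
    events <- events_by_channel[[1L]]
    if (want("detect_spindles")) {
      write_table(events, file.path(config$out_dir, "events.csv"))
      note("detect_spindles", "n_detected=", nrow(events))
    }
  }

  if (want("characterize")) {
    char <- run_stage("characterize", function()
      characterize_events(events, sim$recording$signal[1L, ],
                          sim$recording$fs))
    n_fun <- sum(sim$recording$channel_meta$functional)
    char$extent <- vapply(seq_len(nrow(char)), function(k)
      spatial_extent(char[k, ], events_by_channel, ref_channel = 1L,
                     n_functional = n_fun,
                     functional = sim$recording$channel_meta$functional), 0)
    write_table(char, file.path(config$out_dir, "events_characterized.csv"))
    note("characterize", "n_events=", nrow(char))
  }

  if (want("comodulate")) {
    centers <- (events$start_s + events$end_s) / 2
    if (length(centers) >= 5L) {
      cmg <- run_stage("comodulate", function()
        comodulogram(sim$recording$signal[1L, ], sim$recording$fs, centers))
      curve <- spindle_coupling_curve(cmg)
      peaks <- detect_coupling_peaks(curve)
      write_table(data.frame(freq_hz = curve$freqs, coupling = curve$curve,
                             excluded = curve$excluded),
                  file.path(config$out_dir, "coupling_curve.csv"))
      write_table(peaks, file.path(config$out_dir, "coupling_peaks.csv"))
      note("comodulate", "n_events=", length(centers),
           " n_peaks=", nrow(peaks))
    } else {
      note("comodulate", "skipped: only ", length(centers), " events")
    }
  }

  if (want("spikes")) {
    sp_spec <- do.call(synth_spikes_spec, config$spikes)
    dur <- lfp_spec$duration
    gt <- sim$events[sim$events$channel == 1L, , drop = FALSE]
    gt$phi0 <- 0
    sp <- run_stage("spikes", function()
      generate_spikes(sp_spec, dur, events = gt, seed = seeds[["spikes"]]))
    hb <- inject_spike_transients(sp, dur, n_channels = 2L,
                                  seed = seeds[["spikes"]])
    det <- detect_spikes(hb$highband, hb$fs,
                         zones = unname(unlist(sp_spec$zones))[1:2])
    write_table(as.data.frame(det), file.path(config$out_dir, "spikes.csv"))
    if (nrow(det) >= 50L) {
      acg <- autocorrelogram_ci(det$time_s)
      write_table(data.frame(lag_s = acg$lags, count = acg$counts,
                             ci_low = acg$ci_low, ci_high = acg$ci_high,
                             flag = acg$flags),
                  file.path(config$out_dir, "acg.csv"))
    }
    note("spikes", "n_spikes=", nrow(det))
  }

  if (want("trajectory")) {
    co_spec <- do.call(cohort_spec, config$cohort)
    co <- run_stage("trajectory", function()
      generate_cohort(co_spec, seeds[["cohort"]]))
    fit <- fit_trajectory(co)
    traj <- list(best_degree = fit$best$degree,
                 loocv_mse = fit$candidates$loocv_mse,
                 coefficients = fit$best$coefficients,
                 rule = "per-animal LOOCV")
    if (fit$best$degree >= 2L) {
      nad <- bootstrap_nadir(co, fit$best$degree, n_boot = config$n_boot,
                             seed = config$seed + 503L)
      write_table(data.frame(age_bin = nad$bins,
                             within_mass = nad$within_mass,
                             null_mass = nad$null_mass),
                  file.path(config$out_dir, "nadir_distribution.csv"))
      traj$mode_age <- nad$mode_age
      traj$exceedance <- nad$exceedance
    }
    writeLines(jsonlite::toJSON(traj, auto_unbox = TRUE, digits = NA),
               file.path(config$out_dir, "trajectory.json"))
    note("trajectory", "best_degree=", fit$best$degree)
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(as.character(cfg_json)),
                   derived_seeds = as.list(seeds),
                   log = log_lines)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))
  invisible(res)
}
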