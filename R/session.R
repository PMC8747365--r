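#' Session configuration for the end-to-end pipeline
#'
#' Bundles everything one monitoring session needs: channel mode, the
#' synthetic source (beat schedule for ECG, activation profile for EMG),
#' interference, AFE model, adaptive filtering policy, analysis
#' parameters, logging cadence (24 ms chunks consolidated every 5 min of
#' signal time, emulating local logging plus periodic server sync) and
#' one seed that fixes every random draw.
#'
#' @param mode \code{"ECG"} or \code{"EMG"}.
#' @param duration session length in seconds.
#' @param fs sampling rate in Hz; \code{fs * 0.024} must be integral.
#' @param seed integer master seed.
#' @param schedule a \code{\link{beat_schedule}} (ECG mode); default 60 bpm.
#' @param profile an \code{\link{emg_activation}} (EMG mode).
#' @param interference an \code{\link{interference_spec}} or NULL for a
#'   clean session.
#' @param afe an \code{\link{afe_config}}; its fs/channel are forced to
#'   match the session.
#' @param policy an \code{\link{adaptive_policy}}.
#' @param analysis named list of analysis parameters:
#'   \code{bpm_window} (s), \code{rms_window} (s), \code{long_window} (s),
#'   \code{trim_start} (s of warm-up excluded from analysis, default 0 --
#'   set to ~8 s when comparing sessions whose adaptive filters engage at
#'   different times, so the causal startup window does not bias counts).
#' @param log_chunk chunk duration of the append-only log in seconds
#'   (default 0.024).
#' @param sync_period consolidation period in seconds (default 300); must
#'   be an integer multiple of \code{log_chunk} bursts.
#' @return object of class \code{session_config}.
#' @export
session_config <- function(mode = c("ECG", "EMG"), duration = 600, fs = 1000,
                           seed = 1L, schedule = NULL, profile = NULL,
                           interference = NULL, afe = NULL, policy = NULL,
                           analysis = list(), log_chunk = 0.024,
                           sync_period = 300) {
  mode <- match.arg(mode)
  if (abs(fs * 0.024 - round(fs * 0.024)) > 1e-9)
    stop("fs * 24 ms must be an integral number of samples")
  if (abs(sync_period / log_chunk - round(sync_period / log_chunk)) > 1e-9)
    stop("sync_period must be an integral multiple of log_chunk")
  if (mode == "ECG" && is.null(schedule))
    schedule <- beat_schedule(duration = duration, mean_hr = 60)
  if (mode == "EMG" && is.null(profile))
    profile <- emg_activation(times = 0, levels = 1, duration = duration)
  if (is.null(afe)) afe <- afe_config(mode, fs = fs)
  afe$fs <- fs
  afe$channel <- mode
  if (afe$lp_cutoff >= fs / 2)
    stop("AFE low-pass cutoff must be below Nyquist at the session fs")
  if (is.null(policy)) policy <- adaptive_policy()
  defaults <- list(bpm_window = 1800, rms_window = 0.2, long_window = 1800,
                   trim_start = 0)
  analysis <- utils::modifyList(defaults, analysis)
  structure(list(mode = mode, duration = duration, fs = fs,
                 seed = as.integer(seed), schedule = schedule,
                 profile = profile, interference = interference, afe = afe,
                 policy = policy, analysis = analysis,
                 log_chunk = log_chunk, sync_period = sync_period),
            class = "session_config")
}

#' Run a full monitoring session
#'
#' Executes the whole pipeline deterministically from the config seed:
#' synthesize the biopotential -> add interference -> AFE (filtering,
#' gain, quantization) -> 24 ms burst packetization -> append-only burst
#' log plus per-sync-period consolidated logs -> host-side adaptive
#' filtering with a noise-report log -> channel analysis (R-peaks, R-R,
#' windowed BPM and HRV for ECG; windowed RMS and normalized intensity
#' for EMG) -> report JSON.
#'
#' @param config a \code{\link{session_config}}.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with \code{paths} (named file paths),
#'   \code{report} (the analysis report list) and \code{noise_reports}.
#' @export
run_session <- function(config, out_dir) {
  stopifnot(inherits(config, "session_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("session stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }
  # --- synthesize --------------------------------------------------------
  src <- stage("synth", {
    if (config$mode == "ECG") {
      generate_ecg(config$schedule, fs = config$fs,
                   duration = config$duration)$signal
    } else {
      generate_emg(config$profile, fs = config$fs, seed = config$seed)$signal
    }
  })
  noisy <- stage("interference", {
    if (is.null(config$interference)) src
    else add_interference(src, config$interference, seed = config$seed + 1L)
  })
  # --- device ------------------------------------------------------------
  conditioned <- stage("afe", apply_afe(noisy, config$afe))
  codes <- stage("quantize", quantize(conditioned, config$afe))
  bursts <- stage("packetize",
                  packetize(codes, config$fs, mode = config$mode))
  paths <- list(burst_log = file.path(out_dir, "bursts.jsonl"))
  stage("burst_log", write_bursts_jsonl(bursts, paths$burst_log))
  # consolidated per-sync-period logs: the chunk log split on sync bounds
  bursts_per_sync <- round(config$sync_period / 0.024)
  lines <- readLines(paths$burst_log, warn = FALSE)
  nsync <- ceiling(length(lines) / bursts_per_sync)
  paths$sync_logs <- character(0)
  for (k in seq_len(nsync)) {
    i0 <- (k - 1L) * bursts_per_sync + 1L
    i1 <- min(k * bursts_per_sync, length(lines))
    p <- file.path(out_dir, sprintf("bursts_sync_%04d.jsonl", k))
    writeLines(lines[i0:i1], p)
    paths$sync_logs <- c(paths$sync_logs, p)
  }
  # --- host --------------------------------------------------------------
  filt <- stage("host_filter", stream_filter(bursts, config$policy, config$afe))
  paths$filtered = file.path(out_dir, "filtered.csv")
  stage("filtered_csv", write_signal_csv(filt$signal, paths$filtered))
  paths$noise_log <- file.path(out_dir, "noise.jsonl")
  writeLines(vapply(filt$reports, function(r)
    as.character(jsonlite::toJSON(unclass(r), auto_unbox = TRUE, digits = NA)),
    character(1)), paths$noise_log)
  # --- analysis ----------------------------------------------------------
  report <- stage("analysis", {
    if (config$mode == "ECG") {
      peaks <- detect_r_peaks(filt$signal)
      keep <- peaks$peak_times >= config$analysis$trim_start
      peaks$peak_times <- peaks$peak_times[keep]
      peaks$peak_indices <- peaks$peak_indices[keep]
      rr <- rr_intervals(peaks)
      bw <- windowed_bpm(rr, window = config$analysis$bpm_window)
      ht <- hrv_time(rr)
      span <- max(rr$t_mid) - min(rr$t_mid)
      hf <- if (span >= 300) hrv_freq(rr) else NULL
      paths$bpm <- file.path(out_dir, "bpm.csv")
      utils::write.csv(bw, paths$bpm, row.names = FALSE)
      rep <- list(mode = "ECG", seed = config$seed, fs = config$fs,
                  duration = config$duration,
                  n_peaks = length(peaks$peak_times),
                  mean_bpm = 60000 / mean(rr$intervals),
                  sdnn = ht$sdnn, rmssd = ht$rmssd)
      if (!is.null(hf)) {
        rep$lf_nu <- hf$lf_nu; rep$hf_nu <- hf$hf_nu; rep$lf_hf <- hf$lf_hf
      }
      rep
    } else {
      rms <- windowed_rms(filt$signal, window = config$analysis$rms_window)
      ni <- normalized_intensity(rms, long_window = config$analysis$long_window)
      paths$intensity <- file.path(out_dir, "intensity.csv")
      utils::write.csv(as.data.frame(rms), paths$intensity, row.names = FALSE)
      paths$intensity_long <- file.path(out_dir, "intensity_long.csv")
      utils::write.csv(ni, paths$intensity_long, row.names = FALSE)
      list(mode = "EMG", seed = config$seed, fs = config$fs,
           duration = config$duration,
           mean_rms = mean(rms$rms), max_rms = max(rms$rms),
           n_long_windows = nrow(ni))
    }
  })
  paths$report <- file.path(out_dir, "report.json")
  write_report_json(report, paths$report)
  invisible(list(paths = paths, report = report, noise_reports = filt$reports))
}
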