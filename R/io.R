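#' Write a signal to CSV with a JSON sidecar header
#'
#' Two columns (\code{time_s}, \code{amplitude_mV}); a one-line JSON
#' sidecar (\code{<path>.meta.json}) records fs, channel, units, t0 and
#' any generator metadata so a run is reproducible from the header alone.
#'
#' @param sig a \code{sampled_signal}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "sampled_signal"))
  df <- data.frame(time_s = signal_times(sig), amplitude_mV = sig$x)
  utils::write.csv(df, path, row.names = FALSE)
  hdr <- list(fs = sig$fs, channel = sig$channel, units = sig$units,
              t0 = sig$t0, meta = sig$meta)
  writeLines(as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' Read a signal CSV written by \code{\link{write_signal_csv}}
#'
#' @param path CSV path; the sidecar \code{<path>.meta.json} must exist
#'   (without it the sampling rate is inferred from the time column and a
#'   warning is raised).
#' @return a \code{sampled_signal}.
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_mV") %in% names(df)))
    stop(sprintf("%s line 1: expected columns time_s, amplitude_mV", path))
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    hdr <- jsonlite::fromJSON(readLines(side, warn = FALSE))
    sampled_signal(df$amplitude_mV, fs = hdr$fs, units = hdr$units,
                   channel = hdr$channel, t0 = hdr$t0,
                   meta = if (is.null(hdr$meta)) list() else hdr$meta)
  } else {
    warning("no sidecar header found; inferring fs from the time column")
    fs <- 1 / stats::median(diff(df$time_s))
    sampled_signal(df$amplitude_mV, fs = fs, t0 = df$time_s[1])
  }
}

#' Write a burst stream as JSON-lines
#'
#' One JSON object per burst: seq, mode, t_start, partial, n_pad, codes.
#'
#' @param bursts list of \code{packet_burst}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bursts_jsonl <- function(bursts, path) {
  # hand-rolled serialization of this fixed flat schema: orders of magnitude
  # faster than per-burst toJSON on long sessions, byte-compatible with it
  lines <- vapply(bursts, function(b) {
    sprintf('{"seq":%d,"mode":"%s","t_start":%s,"partial":%s,"n_pad":%d,"codes":[%s]}',
            b$seq, b$mode, format(b$t_start, digits = 17, scientific = FALSE),
            if (b$partial) "true" else "false", b$n_pad,
            paste(b$samples, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines burst stream
#'
#' @param path path written by \code{\link{write_bursts_jsonl}}.
#' @return list of \code{packet_burst}.
#' @export
read_bursts_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(seq_along(lines), function(i) {
    o <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e)
                    stop(sprintf("%s line %d: malformed JSON (%s)",
                                 path, i, conditionMessage(e))))
    need <- c("seq", "mode", "t_start", "partial", "n_pad", "codes")
    if (!all(need %in% names(o)))
      stop(sprintf("%s line %d: missing fields %s", path, i,
                   paste(setdiff(need, names(o)), collapse = ", ")))
    structure(list(seq = as.integer(o$seq), mode = o$mode,
                   samples = as.integer(o$codes), t_start = o$t_start,
                   partial = isTRUE(o$partial), n_pad = as.integer(o$n_pad)),
              class = "packet_burst")
  })
}

#' Write an analysis report as JSON
#' @param report a named list (HRV report, agreement report, ...).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read an analysis report JSON
#' @param path path written by \code{\link{write_report_json}}.
#' @return named list.
#' @export
read_report_json <- function(path) jsonlite::fromJSON(path)

#' Validate a session report against the shipped schema
#'
#' Structural validation (required fields and types) of a session report
#' against the schema shipped at
#' \code{system.file("extdata/report-schema.json", package = "wearbiosig")}.
#'
#' @param report a named list as produced by \code{\link{run_session}}.
#' @return TRUE invisibly; stops with the first violation otherwise.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::fromJSON(system.file("extdata", "report-schema.json",
                                           package = "wearbiosig"),
                               simplifyVector = FALSE)
  req <- unlist(schema$required)
  miss <- setdiff(req, names(report))
  if (length(miss))
    stop("report is missing required fields: ", paste(miss, collapse = ", "))
  for (fld in names(schema$properties)) {
    if (!fld %in% names(report)) next
    want <- schema$properties[[fld]]$type
    val <- report[[fld]]
    ok <- switch(want,
                 number = is.numeric(val),
                 string = is.character(val),
                 integer = is.numeric(val) && all(val == round(val)),
                 object = is.list(val),
                 array = is.vector(val) || is.list(val),
                 TRUE)
    if (!ok) stop(sprintf("report field '%s' should have type %s", fld, want))
  }
  invisible(TRUE)
}
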