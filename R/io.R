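## Plain-text trace and event I/O. Traces are two-column TSV
## (time_s, current_pA) with a structured-text (YAML) sidecar holding the
## sampling rate, protocol segments and provenance; events are CSV with two
## comment lines carrying total time and baseline.

.sidecarPath <- function(path) paste0(path, ".meta.yaml")

#' Write and read current traces
#'
#' \code{writeTrace} stores a trace as two-column TSV (\code{time_s},
#' \code{current_pA}, full double precision) with a YAML sidecar
#' (\code{<path>.meta.yaml}) containing the sampling rate, protocol segments
#' and metadata; \code{readTrace} reconstructs the
#' [CurrentTrace-class] losslessly.
#'
#' @param trace A [CurrentTrace-class].
#' @param path Output TSV path.
#' @return \code{writeTrace}: the path, invisibly. \code{readTrace}: a
#'   [CurrentTrace-class].
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "CurrentTrace"))
  x <- currentSamples(trace)
  df <- data.frame(time_s = sprintf("%.17g", traceTimes(trace)),
                   current_pA = sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    sampling_rate_Hz = samplingRate(trace),
    protocol = lapply(seq_len(nrow(protocol(trace)@segments)), function(i)
      as.list(protocol(trace)@segments[i, ])),
    metadata = traceMetadata(trace)
  )
  yaml::write_yaml(meta, .sidecarPath(path))
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  df <- utils::read.delim(path, colClasses = "numeric")
  meta <- yaml::read_yaml(.sidecarPath(path))
  segs <- do.call(rbind, lapply(meta$protocol, function(s)
    data.frame(kind = s$kind, start_mV = s$start_mV, end_mV = s$end_mV,
               duration_s = s$duration_s)))
  md <- meta$metadata
  if (is.null(md)) md <- list()
  new("CurrentTrace", current = df$current_pA,
      samplingRate = meta$sampling_rate_Hz,
      protocol = voltageProtocol(segs),
      metadata = md)
}

#' Write and read idealized event tables
#'
#' Events are stored as CSV with columns \code{class} (if present),
#' \code{level}, \code{start_s}, \code{duration_s},
#' \code{mean_amplitude_pA}; total record time and baseline travel in
#' \code{#}-prefixed comment lines.
#'
#' @param record An [IdealizedRecord-class].
#' @param path Output CSV path.
#' @return \code{writeEvents}: the path, invisibly. \code{readEvents}: an
#'   [IdealizedRecord-class].
#' @export
writeEvents <- function(record, path) {
  stopifnot(is(record, "IdealizedRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_time_s: %.17g", totalTime(record)), con)
  writeLines(sprintf("# baseline_pA: %.17g", baseline(record)), con)
  utils::write.csv(dwells(record), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  hdr <- readLines(path, n = 2L)
  getNum <- function(key) {
    line <- grep(key, hdr, value = TRUE, fixed = TRUE)
    if (!length(line)) stop("missing header line: ", key)
    as.numeric(sub(paste0("# ", key, ":"), "", line, fixed = TRUE))
  }
  d <- utils::read.csv(path, comment.char = "#")
  d$level <- as.integer(d$level)
  new("IdealizedRecord", dwells = d,
      totalTime = getNum("total_time_s"),
      baseline = getNum("baseline_pA"))
}
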