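#' Read a marker-block (RPM-style) VXP trace file
#'
#' Parses the minimal VXP text dialect: `key=value` header lines up to a
#' `[Data]` marker, then one CSV record per sample with fields
#' `amplitude,phase,timestamp_ms,valid,ttlin,mark`. The TTL-in field
#' carries the scanner's X-RAY ON flag; timestamps are integer
#' milliseconds and are converted to seconds. Unknown header keys are
#' accepted silently; a `samples_per_second` header overrides the default
#' 30 Hz nominal rate.
#'
#' @param path Path to a VXP-dialect text file.
#' @return A [surrogate_trace] labelled `"rpm"`.
#' @seealso [read_bellows_export()], [write_trace()]
#' @export
read_rpm_vxp <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  data_at <- match("[Data]", trimws(lines))
  if (is.na(data_at)) {
    stop(sprintf("malformed VXP header in %s: no [Data] marker", path),
         call. = FALSE)
  }
  header <- lines[seq_len(data_at - 1L)]
  header <- header[nzchar(trimws(header))]
  if (!all(grepl("=", header, fixed = TRUE))) {
    bad <- which(!grepl("=", header, fixed = TRUE))[1L]
    stop(sprintf("malformed VXP header in %s at line %d: expected key=value",
                 path, bad), call. = FALSE)
  }
  keys <- vapply(strsplit(header, "=", fixed = TRUE),
                 function(kv) trimws(kv[[1L]]), character(1L))
  vals <- vapply(strsplit(header, "=", fixed = TRUE),
                 function(kv) trimws(paste(kv[-1L], collapse = "=")),
                 character(1L))
  rate <- 30
  if ("samples_per_second" %in% keys) {
    rate <- suppressWarnings(as.numeric(vals[match("samples_per_second",
                                                   keys)]))
    if (is.na(rate) || rate <= 0) {
      stop(sprintf("malformed VXP header in %s: bad samples_per_second",
                   path), call. = FALSE)
    }
  }
  data_lines <- lines[seq.int(data_at + 1L, length.out = length(lines) -
                                data_at)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0L) {
    stop(sprintf("empty trace: %s has no data lines", path), call. = FALSE)
  }
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop(sprintf("parse error in %s at data line %d: expected 6 fields, got %d",
                 path, bad, nf[bad]), call. = FALSE)
  }
  m <- suppressWarnings(
    matrix(as.numeric(trimws(unlist(fields))), ncol = 6L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop(sprintf("parse error in %s at data line %d: non-numeric field",
                 path, bad), call. = FALSE)
  }
  surrogate_trace(times = m[, 3L] / 1000,
                  amplitudes = m[, 1L],
                  beam_on = m[, 5L] != 0,
                  label = "rpm",
                  nominal_rate = rate,
                  phase = m[, 2L])
}

#' Read a bellows-style trace export
#'
#' Parses the bellows CSV dialect: a header line
#' `time_s,displacement,xray_on`, then one row per sample. Displacement is
#' in arbitrary pressure units; `xray_on` is 0/1. The nominal sampling
#' rate is estimated as `(n - 1) / (t_last - t_first)`.
#'
#' @param path Path to a bellows CSV export.
#' @return A [surrogate_trace] labelled `"bellows"`.
#' @seealso [read_rpm_vxp()], [write_trace()]
#' @export
read_bellows_export <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L ||
      gsub("\\s", "", lines[1L]) != "time_s,displacement,xray_on") {
    stop(sprintf("malformed bellows header in %s at line 1", path),
         call. = FALSE)
  }
  if (length(lines) < 2L) {
    stop(sprintf("empty trace: %s has no data lines", path), call. = FALSE)
  }
  fields <- strsplit(lines[-1L], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1L]
    stop(sprintf("parse error in %s at data line %d: expected 3 fields",
                 path, bad), call. = FALSE)
  }
  m <- suppressWarnings(
    matrix(as.numeric(trimws(unlist(fields))), ncol = 3L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop(sprintf("parse error in %s at data line %d: non-numeric field",
                 path, bad), call. = FALSE)
  }
  tt <- m[, 1L]
  if (length(tt) > 1L && any(diff(tt) <= 0)) {
    bad <- which(diff(tt) <= 0)[1L] + 1L
    stop(sprintf("ordering error in %s at data line %d: timestamps not strictly increasing",
                 path, bad), call. = FALSE)
  }
  rate <- if (length(tt) > 1L) (length(tt) - 1) / (tt[length(tt)] - tt[1L])
          else 38
  surrogate_trace(times = tt, amplitudes = m[, 2L], beam_on = m[, 3L] != 0,
                  label = "bellows", nominal_rate = rate)
}

#' Write a surrogate trace to disk
#'
#' Writes either the VXP dialect (read back with [read_rpm_vxp()]) or the
#' bellows CSV dialect (read back with [read_bellows_export()]). Numeric
#' values keep at least 10 significant digits, so a write/read round trip
#' preserves amplitudes and times to well below 1e-6.
#'
#' @param trace A [surrogate_trace].
#' @param path Output file path.
#' @param dialect `"rpm"` for the VXP dialect or `"bellows"` for the CSV
#'   dialect.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path, dialect = c("rpm", "bellows")) {
  stopifnot_trace(trace)
  dialect <- match.arg(dialect)
  num <- function(x) formatC(x, format = "g", digits = 12)
  if (dialect == "rpm") {
    phase <- if (is.null(trace$phase)) rep(0, length(trace$times))
             else trace$phase
    lines <- c(
      sprintf("samples_per_second=%s", num(trace$nominal_rate)),
      "[Data]",
      sprintf("%s,%s,%s,1,%d,0",
              num(trace$amplitudes), num(phase),
              num(trace$times * 1000), as.integer(trace$beam_on)))
  } else {
    lines <- c("time_s,displacement,xray_on",
               sprintf("%s,%s,%d", num(trace$times), num(trace$amplitudes),
                       as.integer(trace$beam_on)))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
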