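#' Construct a surrogate respiratory trace
#'
#' A `surrogate_trace` holds one external-surrogate respiratory channel:
#' sample times in seconds, amplitudes in the channel's native units
#' (millimetres for a marker-block channel, arbitrary pressure units for a
#' bellows channel), the per-sample X-RAY ON beam flag used for
#' synchronization, and an optional advisory phase column carried through
#' from the source file but never used for sorting.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param amplitudes Numeric vector of signal amplitudes, same length as
#'   `times`.
#' @param beam_on Logical vector flagging samples acquired while the
#'   scanner beam was on (X-RAY ON), same length as `times`.
#' @param label Channel label, one of `"rpm"`, `"bellows"`, `"other"`.
#' @param nominal_rate Nominal sampling rate in Hz (must be positive).
#' @param phase Optional numeric vector of per-sample phase values from
#'   the source file (advisory only).
#' @return An object of class `surrogate_trace`.
#' @export
#' @examples
#' tr <- surrogate_trace(times = seq(0, 1, by = 0.1),
#'                       amplitudes = sin(seq(0, 1, by = 0.1)),
#'                       beam_on = rep(TRUE, 11),
#'                       label = "rpm", nominal_rate = 10)
#' tr
surrogate_trace <- function(times, amplitudes, beam_on,
                            label = "other",
                            nominal_rate, phase = NULL) {
  label <- match.arg(label, c("rpm", "bellows", "other"))
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  beam_on <- as.logical(beam_on)
  n <- length(times)
  if (n < 1L) {
    stop("empty trace: at least one sample is required", call. = FALSE)
  }
  if (length(amplitudes) != n || length(beam_on) != n) {
    stop("times, amplitudes and beam_on must have identical length",
         call. = FALSE)
  }
  if (!is.null(phase)) {
    phase <- as.numeric(phase)
    if (length(phase) != n) {
      stop("phase must have the same length as times", call. = FALSE)
    }
  }
  if (anyNA(times) || anyNA(amplitudes) || anyNA(beam_on)) {
    stop("trace fields must not contain missing values", call. = FALSE)
  }
  if (n > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L ||
      !is.finite(nominal_rate) || nominal_rate <= 0) {
    stop("nominal_rate must be a single positive number", call. = FALSE)
  }
  structure(
    list(times = times, amplitudes = amplitudes, beam_on = beam_on,
         label = label, nominal_rate = as.numeric(nominal_rate),
         phase = phase),
    class = "surrogate_trace"
  )
}

#' @export
print.surrogate_trace <- function(x, ...) {
  cat(sprintf("<surrogate_trace> %s channel, %d samples @ %.3g Hz\n",
              x$label, length(x$times), x$nominal_rate))
  cat(sprintf("  time span: %.3f .. %.3f s; beam on: %d samples\n",
              x$times[1L], x$times[length(x$times)], sum(x$beam_on)))
  cat(sprintf("  amplitude: [%.4g, %.4g]%s\n",
              min(x$amplitudes), max(x$amplitudes),
              if (is.null(x$phase)) "" else "; phase column present"))
  invisible(x)
}

#' @export
length.surrogate_trace <- function(x) length(x$times)

#' Coerce a surrogate trace to a data frame
#'
#' @param x A `surrogate_trace`.
#' @param ... Unused.
#' @return A data frame with columns `time_s`, `amplitude`, `beam_on` and,
#'   when present, `phase`.
#' @export
as.data.frame.surrogate_trace <- function(x, ...) {
  d <- data.frame(time_s = x$times, amplitude = x$amplitudes,
                  beam_on = x$beam_on)
  if (!is.null(x$phase)) d$phase <- x$phase
  d
}

is_surrogate_trace <- function(x) inherits(x, "surrogate_trace")

stopifnot_trace <- function(x, arg = deparse(substitute(x))) {
  if (!is_surrogate_trace(x)) {
    stop(sprintf("`%s` must be a surrogate_trace", arg), call. = FALSE)
  }
  invisible(x)
}
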