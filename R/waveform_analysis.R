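#' Crop a trace to its first contiguous beam-on interval
#'
#' The scanner's X-RAY ON flag is the mutual reference point between the
#' two surrogate channels: all waveform analysis is restricted to beam-on
#' samples, and the first beam-on sample becomes the time origin. The
#' wall-clock time of the new origin is kept in the `"time_offset"`
#' attribute so that externally timestamped events (e.g. simulated slice
#' acquisitions) can be moved onto the same axis.
#'
#' @param trace A [surrogate_trace] with at least one beam-on sample.
#' @return A [surrogate_trace] containing only the first contiguous
#'   beam-on run, with times starting at 0.
#' @export
crop_to_beam_on <- function(trace) {
  stopifnot_trace(trace)
  if (!any(trace$beam_on)) {
    stop("synchronization error: trace has no beam-on (X-RAY ON) samples",
         call. = FALSE)
  }
  first_on <- which(trace$beam_on)[1L]
  run_end <- first_on
  while (run_end < length(trace$times) && trace$beam_on[run_end + 1L]) {
    run_end <- run_end + 1L
  }
  keep <- seq.int(first_on, run_end)
  offset <- trace$times[first_on]
  out <- surrogate_trace(times = trace$times[keep] - offset,
                         amplitudes = trace$amplitudes[keep],
                         beam_on = trace$beam_on[keep],
                         label = trace$label,
                         nominal_rate = trace$nominal_rate,
                         phase = trace$phase[keep])
  attr(out, "time_offset") <- offset
  out
}

#' Resample a trace at reference time points
#'
#' Used to downsample the faster bellows channel (~38 Hz) onto the
#' marker-block channel's 30 Hz timestamps before comparison. Amplitudes
#' are linearly interpolated; the beam flag is taken from the nearest
#' original sample.
#'
#' @param trace A [surrogate_trace].
#' @param reference_times Numeric vector of query times (seconds), all
#'   within the trace's time span.
#' @return A [surrogate_trace] sampled at `reference_times`.
#' @export
resample_to <- function(trace, reference_times) {
  stopifnot_trace(trace)
  reference_times <- as.numeric(reference_times)
  span <- range(trace$times)
  if (any(reference_times < span[1L] | reference_times > span[2L])) {
    stop("extrapolation error: reference times outside the trace time span",
         call. = FALSE)
  }
  amp <- stats::approx(trace$times, trace$amplitudes,
                       xout = reference_times, method = "linear")$y
  nearest <- vapply(reference_times, function(tt) {
    which.min(abs(trace$times - tt))
  }, integer(1L))
  rate <- if (length(reference_times) > 1L) {
    (length(reference_times) - 1) /
      (reference_times[length(reference_times)] - reference_times[1L])
  } else {
    trace$nominal_rate
  }
  surrogate_trace(times = reference_times, amplitudes = amp,
                  beam_on = trace$beam_on[nearest], label = trace$label,
                  nominal_rate = rate)
}

#' Peak-search configuration
#'
#' Parameters for end-inhale peak detection. Defaults are sized to detect
#' breathing between roughly 7 and 22 breaths per minute: minimum peak
#' prominence 10% of the amplitude range, minimum separation 1.5 s,
#' plateau tolerance 2% of the amplitude range, and a 0.3 s minimum run
#' duration before a flattened top is reported at its midpoint.
#'
#' @param min_prominence_frac Minimum peak prominence as a fraction of the
#'   trace amplitude range.
#' @param min_separation_s Minimum time between retained peaks, seconds.
#' @param plateau_tol_frac Amplitude tolerance (fraction of range) used to
#'   delimit a flattened peak region.
#' @param plateau_min_s Minimum duration of a flattened region before the
#'   midpoint rule replaces the sample maximum.
#' @param refine_quadratic Refine sharp peak times by a three-point
#'   quadratic fit around the discrete maximum.
#' @param smoothing_s Moving-average window (seconds) applied to the
#'   amplitude series before peak localization; 0 disables it. Smoothing
#'   only steers the search — reported peak kinds and times come from the
#'   smoothed series, but normalization always uses raw amplitudes.
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(min_prominence_frac = 0.10,
                        min_separation_s = 1.5,
                        plateau_tol_frac = 0.02,
                        plateau_min_s = 0.3,
                        refine_quadratic = TRUE,
                        smoothing_s = 0.4) {
  stopifnot(min_prominence_frac >= 0, min_separation_s >= 0,
            plateau_tol_frac >= 0, plateau_min_s >= 0, smoothing_s >= 0)
  structure(list(min_prominence_frac = min_prominence_frac,
                 min_separation_s = min_separation_s,
                 plateau_tol_frac = plateau_tol_frac,
                 plateau_min_s = plateau_min_s,
                 refine_quadratic = isTRUE(refine_quadratic),
                 smoothing_s = smoothing_s),
            class = "peak_config")
}

# Prominence of the local maximum at index i: height above the higher of
# the two lowest points separating it from higher terrain on each side.
peak_prominence <- function(a, i) {
  h <- a[i]
  left_min <- h
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (a[j] > h) break
    if (a[j] < left_min) left_min <- a[j]
  }
  if (j == 1L && a[j] <= h && a[j] < left_min) left_min <- a[j]
  right_min <- h
  j <- i
  n <- length(a)
  while (j < n) {
    j <- j + 1L
    if (a[j] > h) break
    if (a[j] < right_min) right_min <- a[j]
  }
  if (j == n && a[j] <= h && a[j] < right_min) right_min <- a[j]
  h - max(left_min, right_min)
}

#' Detect end-inhale peaks in a respiratory trace
#'
#' Local maximum displacements are located by a prominence-filtered
#' search with a minimum temporal separation (a bounding-box criterion in
#' time and amplitude). Where the curve has no distinct peak — a
#' truncated or plateau top — the maximal run of samples within the
#' plateau tolerance of the local maximum, when longer than the minimum
#' plateau duration, is reported as a single peak at the run's temporal
#' midpoint. Sharp peaks are otherwise refined to sub-sample precision by
#' a quadratic fit through the maximum and its neighbours.
#'
#' @param trace A [surrogate_trace], normally already cropped to beam-on.
#' @param cfg A [peak_config].
#' @return A `peak_list`: list with `peak_times` (seconds, increasing),
#'   `peak_kind` (`"sharp"` or `"plateau_midpoint"`) and `search_config`.
#'   A monotone trace yields an empty peak list.
#' @export
detect_end_inhale_peaks <- function(trace, cfg = peak_config()) {
  stopifnot_trace(trace)
  stopifnot(inherits(cfg, "peak_config"))
  a <- trace$amplitudes
  tt <- trace$times
  n <- length(a)
  empty <- structure(list(peak_times = numeric(0),
                          peak_kind = character(0),
                          search_config = cfg),
                     class = "peak_list")
  if (cfg$smoothing_s > 0 && n > 2L) {
    dt <- stats::median(diff(tt))
    w <- max(1L, round(cfg$smoothing_s / dt))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L && w < n) {
      a <- stats::filter(a, rep(1 / w, w), sides = 2)
      h <- (w - 1L) %/% 2L
      # shrink the window near the edges instead of dropping samples
      for (i in seq_len(h)) {
        a[i] <- mean(trace$amplitudes[seq_len(2L * i - 1L)])
        a[n - i + 1L] <- mean(trace$amplitudes[seq.int(n - 2L * i + 2L, n)])
      }
      a <- as.numeric(a)
    }
  }
  rng <- max(a) - min(a)
  if (n < 3L || rng == 0) return(empty)

  # candidate maxima: runs of equal value with a strict rise before and a
  # strict fall after (interior runs only)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (a[i] > a[i - 1L]) {
      j <- i
      while (j < n && a[j + 1L] == a[j]) j <- j + 1L
      if (j < n && a[j + 1L] < a[j]) {
        cand <- c(cand, as.integer(round((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L) return(empty)

  prom <- vapply(cand, function(ix) peak_prominence(a, ix), numeric(1L))
  cand <- cand[prom >= cfg$min_prominence_frac * rng]
  if (length(cand) == 0L) return(empty)

  # enforce separation, keeping higher peaks first
  ord <- cand[order(a[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (ix in ord) {
    if (all(abs(tt[ix] - tt[kept]) >= cfg$min_separation_s)) {
      kept <- c(kept, ix)
    }
  }
  kept <- sort(kept)

  peak_times <- numeric(length(kept))
  peak_kind <- character(length(kept))
  tol <- cfg$plateau_tol_frac * rng
  for (k in seq_along(kept)) {
    ix <- kept[k]
    lo <- ix
    while (lo > 1L && a[lo - 1L] >= a[ix] - tol) lo <- lo - 1L
    hi <- ix
    while (hi < n && a[hi + 1L] >= a[ix] - tol) hi <- hi + 1L
    if (tt[hi] - tt[lo] > cfg$plateau_min_s) {
      peak_times[k] <- (tt[lo] + tt[hi]) / 2
      peak_kind[k] <- "plateau_midpoint"
    } else {
      pt <- tt[ix]
      if (cfg$refine_quadratic && ix > 1L && ix < n) {
        y1 <- a[ix - 1L]; y2 <- a[ix]; y3 <- a[ix + 1L]
        denom <- y1 - 2 * y2 + y3
        if (denom < 0) {
          # vertex of the parabola through the three samples, assuming a
          # locally uniform sample spacing
          dt <- (tt[ix + 1L] - tt[ix - 1L]) / 2
          shift <- 0.5 * (y1 - y3) / denom
          pt <- tt[ix] + max(-0.5, min(0.5, shift)) * dt
        }
      }
      peak_times[k] <- pt
      peak_kind[k] <- "sharp"
    }
  }
  o <- order(peak_times)
  structure(list(peak_times = peak_times[o], peak_kind = peak_kind[o],
                 search_config = cfg),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks (%d plateau midpoints)\n",
              length(x$peak_times),
              sum(x$peak_kind == "plateau_midpoint")))
  invisible(x)
}

#' Normalize a trace to its maximum end-inhale peak
#'
#' All amplitudes are divided by the largest amplitude attained at a
#' detected end-inhale peak (evaluated by linear interpolation at the
#' peak times), so the tallest peak becomes exactly 1. This makes
#' channels with different native units (mm vs arbitrary pressure units)
#' directly comparable.
#'
#' @param trace A [surrogate_trace].
#' @param peaks A non-empty `peak_list` for `trace`.
#' @return The normalized [surrogate_trace].
#' @export
normalize_to_max_peak <- function(trace, peaks) {
  stopifnot_trace(trace)
  stopifnot(inherits(peaks, "peak_list"))
  if (length(peaks$peak_times) == 0L) {
    stop("normalization error: empty peak list", call. = FALSE)
  }
  peak_amp <- stats::approx(trace$times, trace$amplitudes,
                            xout = peaks$peak_times, rule = 2)$y
  m <- max(peak_amp)
  if (m == 0) {
    stop("normalization error: maximum peak amplitude is zero",
         call. = FALSE)
  }
  out <- trace
  out$amplitudes <- trace$amplitudes / m
  out
}

#' Pair end-inhale peaks between two channels
#'
#' Greedy nearest-neighbour matching in time: the globally closest
#' remaining pair is matched first, each peak is used at most once, and
#' candidate pairs further apart than `max_offset_s` are discarded.
#'
#' @param a,b `peak_list` objects (or numeric vectors of peak times).
#' @param max_offset_s Largest admissible time offset between matched
#'   peaks, seconds.
#' @return A data frame with columns `time_a`, `time_b`, ordered by
#'   `time_a`, with attributes `n_unmatched_a` and `n_unmatched_b`.
#' @export
pair_peaks <- function(a, b, max_offset_s) {
  ta <- if (inherits(a, "peak_list")) a$peak_times else as.numeric(a)
  tb <- if (inherits(b, "peak_list")) b$peak_times else as.numeric(b)
  stopifnot(is.numeric(max_offset_s), max_offset_s >= 0)
  pairs <- data.frame(time_a = numeric(0), time_b = numeric(0))
  if (length(ta) > 0L && length(tb) > 0L) {
    d <- abs(outer(ta, tb, "-"))
    d[d > max_offset_s] <- NA_real_
    while (any(!is.na(d))) {
      ij <- arrayInd(which.min(d), dim(d))
      pairs <- rbind(pairs, data.frame(time_a = ta[ij[1L]],
                                       time_b = tb[ij[2L]]))
      d[ij[1L], ] <- NA_real_
      d[, ij[2L]] <- NA_real_
    }
  }
  pairs <- pairs[order(pairs$time_a), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "n_unmatched_a") <- length(ta) - nrow(pairs)
  attr(pairs, "n_unmatched_b") <- length(tb) - nrow(pairs)
  pairs
}

#' Summarize inter-surrogate latency from matched peak pairs
#'
#' The per-pair latency is `time_b - time_a` in milliseconds. With the
#' marker-block (RPM) channel passed as `a` and the bellows as `b`, a
#' positive latency means the marker-block end-inhale occurred before the
#' bellows end-inhale, i.e. the RPM channel leads.
#'
#' @param pairs Data frame from [pair_peaks()] (columns `time_a`,
#'   `time_b`), with at least one row.
#' @param hist_bin_ms Histogram bin width in milliseconds.
#' @return A `latency_summary`: `pair_deltas` (ms), `mean_ms`, `sd_ms`
#'   (sample SD), `min_ms`, `max_ms`, `histogram` (data frame `bin_left`,
#'   `bin_right`, `count`), `n_unmatched_a`, `n_unmatched_b`.
#' @export
latency_summary <- function(pairs, hist_bin_ms = 25) {
  stopifnot(is.data.frame(pairs),
            all(c("time_a", "time_b") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    stop("insufficient data: no matched peak pairs", call. = FALSE)
  }
  stopifnot(hist_bin_ms > 0)
  deltas <- (pairs$time_b - pairs$time_a) * 1000
  lo <- floor(min(deltas) / hist_bin_ms) * hist_bin_ms
  hi <- floor(max(deltas) / hist_bin_ms) * hist_bin_ms + hist_bin_ms
  breaks <- seq(lo, hi, by = hist_bin_ms)
  counts <- vapply(seq_len(length(breaks) - 1L), function(i) {
    sum(deltas >= breaks[i] & deltas < breaks[i + 1L])
  }, integer(1L))
  structure(list(
    pair_deltas = deltas,
    mean_ms = mean(deltas),
    sd_ms = if (length(deltas) > 1L) stats::sd(deltas) else NA_real_,
    min_ms = min(deltas),
    max_ms = max(deltas),
    histogram = data.frame(bin_left = breaks[-length(breaks)],
                           bin_right = breaks[-1L], count = counts),
    n_unmatched_a = attr(pairs, "n_unmatched_a") %||% NA_integer_,
    n_unmatched_b = attr(pairs, "n_unmatched_b") %||% NA_integer_),
    class = "latency_summary")
}

#' @export
print.latency_summary <- function(x, ...) {
  cat(sprintf(
    "<latency_summary> %d pairs: mean %.1f ms, sd %.1f ms, range [%.1f, %.1f] ms\n",
    length(x$pair_deltas), x$mean_ms, x$sd_ms, x$min_ms, x$max_ms))
  invisible(x)
}

#' Amplitude and rate statistics of a cropped trace
#'
#' Mean and sample standard deviation of the beam-on amplitudes, the
#' coefficient of variation (%CV = SD / mean x 100) characterizing
#' breathing-amplitude irregularity, and the breathing rate in breaths
#' per minute (detected end-inhale peaks per beam-on minute).
#'
#' @param trace A beam-on-cropped [surrogate_trace].
#' @param peaks A `peak_list` for `trace`.
#' @return A list of class `trace_stats`: `mean_amp`, `sd_amp`,
#'   `cv_percent`, `bpm`, `duration_s`.
#' @export
trace_stats <- function(trace, peaks) {
  stopifnot_trace(trace)
  stopifnot(inherits(peaks, "peak_list"))
  amps <- trace$amplitudes[trace$beam_on]
  tts <- trace$times[trace$beam_on]
  if (length(amps) < 2L) {
    stop("trace too short for statistics", call. = FALSE)
  }
  m <- mean(amps)
  s <- stats::sd(amps)
  if (m == 0) {
    stop("CV undefined: mean amplitude is zero", call. = FALSE)
  }
  dur <- tts[length(tts)] - tts[1L]
  structure(list(mean_amp = m, sd_amp = s, cv_percent = s / m * 100,
                 bpm = if (dur > 0) length(peaks$peak_times) / dur * 60
                       else 0,
                 duration_s = dur),
            class = "trace_stats")
}

#' @export
print.trace_stats <- function(x, ...) {
  cat(sprintf(
    "<trace_stats> amplitude %.3f +/- %.3f (CV %.1f%%), %.1f BPM over %.1f s\n",
    x$mean_amp, x$sd_amp, x$cv_percent, x$bpm, x$duration_s))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used to test agreement between the two
#' normalized surrogate waveforms (and between tabulated study
#' statistics).
#'
#' @param x,y Numeric vectors of equal length (at least 3) with nonzero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("pearson_r needs two equal-length vectors of length >= 3",
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("pearson_r inputs must not contain missing values", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic for the first sample (midranks under ties), with
#' a two-sided p-value: exact when the combined sample size is at most 20
#' and no ties are present, otherwise a normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Nonempty numeric vectors.
#' @return A list: `U` (statistic for `x`), `p_value`, `n_x`, `n_y`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("mann_whitney_u requires two nonempty samples", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (nx + ny) <= 20L && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(U), p_value = unname(wt$p.value), n_x = nx, n_y = ny,
       method = if (exact) "exact" else "normal_approx")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
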