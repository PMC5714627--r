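#' Generate a programmable breathing motion program
#'
#' Produces superior-inferior target displacement and the coupled
#' anterior-posterior chest-wall displacement driving the external
#' surrogates. The `regular` kind is a raised-cosine-power cycle (a
#' standard breathing model that dwells near end-exhale); end-inhale
#' maxima occur at cycle boundaries. The `irregular` kind draws each
#' cycle's period and peak amplitude from mean-one lognormal jitter and
#' adds a linear baseline drift, emulating erratic patient breathing.
#'
#' @param kind `"regular"` or `"irregular"`.
#' @param params List of generator parameters:
#'   \describe{
#'     \item{period_s}{Mean breathing period, seconds (default 4).}
#'     \item{amplitude_cm}{Mean S-I peak amplitude, cm, expected in
#'       `[0.5, 3]`; values outside only raise a warning (default 1).}
#'     \item{duration_s}{Program length, seconds (default 90).}
#'     \item{power}{Half the cosine exponent `2n` (default 2, i.e.
#'       cos^4).}
#'     \item{period_jitter_pct}{Irregular only: lognormal CV of the
#'       per-cycle period, percent (default 15).}
#'     \item{amplitude_jitter_pct}{Irregular only: lognormal CV of the
#'       per-cycle amplitude, percent (default 30).}
#'     \item{drift_cm_per_min}{Irregular only: linear baseline drift
#'       (default 0).}
#'     \item{surface_ratio}{A-P chest-wall amplitude as a fraction of the
#'       S-I amplitude (default 0.3).}
#'     \item{sample_rate_hz}{Program sampling rate (default 100).}
#'   }
#' @param seed Integer seed; the program is bit-reproducible for a fixed
#'   seed.
#' @return A `motion_program`: `times` (s), `si_cm`, `ap_cm`,
#'   `cycle_starts` (end-inhale times, s), `cycle_amplitudes_cm`,
#'   `metadata`.
#' @export
make_breathing_curve <- function(kind = c("regular", "irregular"),
                                 params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(
    period_s = 4, amplitude_cm = 1, duration_s = 90, power = 2,
    period_jitter_pct = 15, amplitude_jitter_pct = 30,
    drift_cm_per_min = 0, surface_ratio = 0.3, sample_rate_hz = 100),
    params)
  if (p$amplitude_cm < 0.5 || p$amplitude_cm > 3) {
    warning(sprintf(
      "amplitude %.2f cm is outside the studied 0.5-3 cm excursion range",
      p$amplitude_cm))
  }
  set.seed(as.integer(seed))
  n_cycles <- 2L * ceiling(p$duration_s / p$period_s) + 5L
  if (kind == "regular") {
    periods <- rep(p$period_s, n_cycles)
    amps <- rep(p$amplitude_cm, n_cycles + 1L)
    drift_rate <- 0
  } else {
    sig_t <- sqrt(log(1 + (p$period_jitter_pct / 100)^2))
    sig_a <- sqrt(log(1 + (p$amplitude_jitter_pct / 100)^2))
    periods <- p$period_s * stats::rlnorm(n_cycles, -sig_t^2 / 2, sig_t)
    amps <- p$amplitude_cm * stats::rlnorm(n_cycles + 1L,
                                           -sig_a^2 / 2, sig_a)
    drift_rate <- p$drift_cm_per_min / 60
  }
  starts <- c(0, cumsum(periods))
  # fallback: extend with mean cycles if jitter left the span uncovered
  while (starts[length(starts)] <= p$duration_s) {
    periods <- c(periods, p$period_s)
    amps <- c(amps, p$amplitude_cm)
    starts <- c(starts, starts[length(starts)] + p$period_s)
  }
  times <- seq(0, p$duration_s, by = 1 / p$sample_rate_hz)
  ci <- findInterval(times, starts)
  u <- (times - starts[ci]) / periods[ci]
  # amplitude envelope interpolates between consecutive end-inhale peaks
  # so the displacement is continuous across cycle boundaries
  env <- amps[ci] * (1 - u) + amps[ci + 1L] * u
  si <- env * cos(pi * u)^(2 * p$power) + drift_rate * times
  ap <- p$surface_ratio * si
  structure(list(times = times, si_cm = si, ap_cm = ap,
                 cycle_starts = starts[starts <= p$duration_s],
                 cycle_amplitudes_cm =
                   amps[seq_along(starts[starts <= p$duration_s])],
                 metadata = list(kind = kind, params = p,
                                 seed = as.integer(seed))),
            class = "motion_program")
}

#' @export
print.motion_program <- function(x, ...) {
  cat(sprintf(
    "<motion_program> %s, %.0f s @ %g Hz, S-I range [%.2f, %.2f] cm, %d cycles\n",
    x$metadata$kind, x$times[length(x$times)],
    x$metadata$params$sample_rate_hz, min(x$si_cm), max(x$si_cm),
    length(x$cycle_starts)))
  invisible(x)
}

#' Describe an external surrogate channel
#'
#' Parameters of the transfer from chest-wall displacement to one
#' recorded surrogate signal: a gain (signal units per cm), a small lag,
#' additive white Gaussian amplitude noise, an optional low-amplitude
#' plateau floor (the bellows truncates extreme low positions), and the
#' channel's sampling rate.
#'
#' @param gain Signal units per cm of A-P displacement.
#' @param lag_ms Channel lag in milliseconds (signal is delayed by this
#'   much relative to the motion).
#' @param noise_sd Additive Gaussian noise SD, signal units.
#' @param plateau_floor Optional floor (signal units) below which the
#'   output is clamped.
#' @param sampling_rate_hz Channel sampling rate, Hz.
#' @return A list of class `surrogate_model`.
#' @export
surrogate_model <- function(gain = 1, lag_ms = 0, noise_sd = 0,
                            plateau_floor = NULL, sampling_rate_hz = 30) {
  stopifnot(sampling_rate_hz > 0, noise_sd >= 0)
  structure(list(gain = gain, lag_ms = lag_ms, noise_sd = noise_sd,
                 plateau_floor = plateau_floor,
                 sampling_rate_hz = sampling_rate_hz),
            class = "surrogate_model")
}

#' Synthesize a synchronized dual-surrogate recording
#'
#' Samples the motion program's A-P chest-wall channel through two
#' surrogate models (typically a 30 Hz marker-block channel and a ~38 Hz
#' bellows channel), each applying its own gain, lag, noise and optional
#' plateau clamping. Both channels carry the X-RAY ON flag, true exactly
#' inside `beam_window`, with an identical wall-clock rising edge.
#'
#' @param program A `motion_program`.
#' @param rpm_model,bellows_model [surrogate_model()] descriptions of the
#'   two channels.
#' @param beam_window Length-2 numeric: beam-on start and stop times
#'   (seconds) within the program span. Defaults to 1 s after start
#'   through 1 s before the end. Choosing an integer-second start keeps
#'   the rising edge on a sample of both channels.
#' @param seed Integer seed for the noise streams.
#' @return A list with elements `rpm` and `bellows`, each a
#'   [surrogate_trace].
#' @export
synthesize_surrogates <- function(program,
                                  rpm_model = surrogate_model(
                                    gain = 10, sampling_rate_hz = 30),
                                  bellows_model = surrogate_model(
                                    gain = 2.5, sampling_rate_hz = 38),
                                  beam_window = NULL, seed = 1L) {
  stopifnot(inherits(program, "motion_program"))
  span <- range(program$times)
  if (is.null(beam_window)) {
    beam_window <- c(ceiling(span[1L]) + 1, floor(span[2L]) - 1)
  }
  stopifnot(length(beam_window) == 2L, beam_window[1L] < beam_window[2L])
  if (beam_window[1L] < span[1L] || beam_window[2L] > span[2L]) {
    stop("beam window must lie within the program span", call. = FALSE)
  }
  set.seed(as.integer(seed))
  channel <- function(model, label) {
    lag_s <- model$lag_ms / 1000
    if (abs(lag_s) >= diff(span)) {
      stop("parameter error: lag exceeds the program span", call. = FALSE)
    }
    tt <- seq(span[1L], span[2L], by = 1 / model$sampling_rate_hz)
    src_t <- tt - lag_s
    amp <- stats::approx(program$times, program$ap_cm, xout = src_t,
                         rule = 2)$y * model$gain
    if (model$noise_sd > 0) {
      amp <- amp + stats::rnorm(length(amp), 0, model$noise_sd)
    }
    if (!is.null(model$plateau_floor)) {
      amp <- pmax(amp, model$plateau_floor)
    }
    surrogate_trace(times = tt, amplitudes = amp,
                    beam_on = tt >= beam_window[1L] & tt <= beam_window[2L],
                    label = label,
                    nominal_rate = model$sampling_rate_hz)
  }
  list(rpm = channel(rpm_model, "rpm"),
       bellows = channel(bellows_model, "bellows"))
}

#' Build a digital lung-mimicking phantom
#'
#' A uniform low-density slab (default -800 HU, within the lung-like
#' -900 to -600 HU band) containing high-contrast inserts. Insert voxels
#' are set by a center-of-voxel inclusion test.
#'
#' @param dim_vox Grid size, length 3 (x, y, z voxels).
#' @param spacing_mm Voxel spacing, mm, length 3.
#' @param origin_mm Grid corner position, mm.
#' @param background_hu Slab HU (default -800).
#' @param inserts List of inserts; each a list with `shape` (`"sphere"`
#'   or `"box"`), `center_mm` (length 3), `size_mm` (sphere diameter or
#'   box edge lengths), `hu`.
#' @return A `digital_phantom`: a [volume3d] plus the insert definitions.
#' @export
build_phantom <- function(dim_vox = c(32, 32, 40),
                          spacing_mm = c(3, 3, 2.5),
                          origin_mm = c(0, 0, 0),
                          background_hu = -800,
                          inserts = list(list(shape = "sphere",
                                              center_mm = NULL,
                                              size_mm = 30, hu = 50))) {
  dim_vox <- as.integer(dim_vox)
  vol <- volume3d(array(background_hu, dim = dim_vox), spacing_mm,
                  origin_mm)
  extent <- origin_mm + dim_vox * vol$spacing
  xs <- axis_centers(dim_vox[1L], vol$spacing[1L], vol$origin[1L])
  ys <- axis_centers(dim_vox[2L], vol$spacing[2L], vol$origin[2L])
  zs <- axis_centers(dim_vox[3L], vol$spacing[3L], vol$origin[3L])
  for (k in seq_along(inserts)) {
    ins <- inserts[[k]]
    if (is.null(ins$center_mm)) {
      ins$center_mm <- vol$origin + dim_vox * vol$spacing / 2
      inserts[[k]] <- ins
    }
    half <- if (identical(ins$shape, "sphere")) rep(ins$size_mm / 2, 3L)
            else rep(ins$size_mm, length.out = 3L) / 2
    if (any(ins$center_mm - half < origin_mm) ||
        any(ins$center_mm + half > extent)) {
      stop("geometry error: insert extends outside the phantom grid",
           call. = FALSE)
    }
    vol$data[insert_mask(ins, xs, ys, zs)] <- ins$hu
  }
  structure(list(data = vol$data, spacing = vol$spacing,
                 origin = vol$origin, background_hu = background_hu,
                 inserts = inserts),
            class = c("digital_phantom", "volume3d"))
}

# logical 3D array of voxels whose centers fall inside the insert,
# with the insert displaced by dz_mm in z
insert_mask <- function(ins, xs, ys, zs, dz_mm = 0) {
  cx <- ins$center_mm[1L]; cy <- ins$center_mm[2L]
  cz <- ins$center_mm[3L] + dz_mm
  if (identical(ins$shape, "sphere")) {
    r2 <- (ins$size_mm / 2)^2
    dx2 <- (xs - cx)^2; dy2 <- (ys - cy)^2; dz2 <- (zs - cz)^2
    outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
  } else if (identical(ins$shape, "box")) {
    half <- rep(ins$size_mm, length.out = 3L) / 2
    inx <- abs(xs - cx) <= half[1L]
    iny <- abs(ys - cy) <= half[2L]
    inz <- abs(zs - cz) <= half[3L]
    outer(outer(inx, iny, "&"), inz, "&")
  } else {
    stop(sprintf("unknown insert shape '%s'", ins$shape), call. = FALSE)
  }
}

#' @export
print.digital_phantom <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<digital_phantom> %d x %d x %d @ (%g, %g, %g) mm, background %g HU, %d inserts\n",
    d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L],
    x$background_hu, length(x$inserts)))
  invisible(x)
}

#' Helical acquisition configuration
#'
#' @param slice_thickness_mm Reconstructed slice thickness (defaults to
#'   the phantom z spacing at simulation time if `NULL`).
#' @param rotation_period_s Gantry rotation period, seconds.
#' @param couch_pitch Table advance per rotation as a fraction of the
#'   detector width; 4D CT uses a very low pitch (~0.06-0.08) so each
#'   position is imaged across at least one breathing period.
#' @param detector_width_mm Detector z coverage, mm.
#' @param scan_start_s,scan_stop_s Acquisition window, seconds; when
#'   `scan_stop_s` is `NULL` the scan runs until the couch has covered
#'   the phantom.
#' @return A list of class `acquisition_config`.
#' @export
acquisition_config <- function(slice_thickness_mm = NULL,
                               rotation_period_s = 0.5,
                               couch_pitch = 0.07,
                               detector_width_mm = 20,
                               scan_start_s = 1,
                               scan_stop_s = NULL) {
  stopifnot(rotation_period_s > 0, couch_pitch > 0, couch_pitch <= 1.5,
            detector_width_mm > 0)
  structure(list(slice_thickness_mm = slice_thickness_mm,
                 rotation_period_s = rotation_period_s,
                 couch_pitch = couch_pitch,
                 detector_width_mm = detector_width_mm,
                 scan_start_s = scan_start_s,
                 scan_stop_s = scan_stop_s),
            class = "acquisition_config")
}

#' Simulate an oversampled helical 4D CT acquisition
#'
#' The couch advances continuously at `detector_width x pitch /
#' rotation_period`. At each gantry rotation every reconstruction slice
#' position currently under the detector yields one `slice_record`
#' imaging the phantom translated superior-inferiorly by the program's
#' S-I displacement at that instant (nearest-neighbour resampling of the
#' shifted grid; no projection physics). With a low pitch each couch
#' position stays under the detector for at least one breathing period,
#' providing the oversampling retrospective sorting requires.
#'
#' @param phantom A `digital_phantom`.
#' @param program A `motion_program` spanning the scan duration.
#' @param config An [acquisition_config()].
#' @return List of `slice_record`s: `couch_z` (slice position, mm),
#'   `acquisition_time` (s), `pixels` (2D HU array), `in_plane_spacing`.
#' @export
simulate_acquisition <- function(phantom, program,
                                 config = acquisition_config()) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(program, "motion_program"),
            inherits(config, "acquisition_config"))
  dz <- config$slice_thickness_mm %||% phantom$spacing[3L]
  nz <- dim(phantom$data)[3L]
  z_slices <- axis_centers(nz, phantom$spacing[3L], phantom$origin[3L])
  advance_per_s <- config$detector_width_mm * config$couch_pitch /
    config$rotation_period_s
  z0 <- phantom$origin[3L] - config$detector_width_mm
  z_end <- phantom$origin[3L] + nz * phantom$spacing[3L]
  stop_t <- config$scan_stop_s %||%
    (config$scan_start_s + (z_end - z0) / advance_per_s)
  if (stop_t > program$times[length(program$times)]) {
    stop(sprintf(
      "coverage error: program ends at %.1f s but the scan needs %.1f s",
      program$times[length(program$times)], stop_t), call. = FALSE)
  }
  rot_times <- seq(config$scan_start_s, stop_t,
                   by = config$rotation_period_s)
  si_at <- stats::approx(program$times, program$si_cm, xout = rot_times,
                         rule = 2)$y * 10  # cm -> mm
  records <- vector("list", 0L)
  for (r in seq_along(rot_times)) {
    det_lo <- z0 + advance_per_s * (rot_times[r] - config$scan_start_s)
    det_hi <- det_lo + config$detector_width_mm
    active <- which(z_slices >= det_lo & z_slices < det_hi)
    if (length(active) == 0L) next
    # object shifted by +si in z: image at z is the phantom at z - si
    src_z <- z_slices[active] - si_at[r]
    src_k <- round((src_z - phantom$origin[3L]) / phantom$spacing[3L] +
                     0.5)
    for (a in seq_along(active)) {
      k <- src_k[a]
      px <- if (k >= 1L && k <= nz) phantom$data[, , k] else
        matrix(phantom$background_hu, dim(phantom$data)[1L],
               dim(phantom$data)[2L])
      records[[length(records) + 1L]] <- structure(
        list(couch_z = z_slices[active[a]],
             acquisition_time = rot_times[r],
             pixels = px,
             in_plane_spacing = phantom$spacing[1:2]),
        class = "slice_record")
    }
  }
  if (length(records) == 0L) {
    stop("coverage error: acquisition produced no slices", call. = FALSE)
  }
  records
}

#' Ground-truth internal target volume of a moving phantom
#'
#' The ITV ground truth is the union of the insert masks with the
#' phantom held at end-inhale (maximum S-I displacement), end-exhale
#' (minimum), and the midpoint displacement, mirroring static
#' acquisitions with the motion platform paused. It represents the
#' maximum envelope free of sorting artifacts and interplay.
#'
#' @param phantom A `digital_phantom` with at least one insert.
#' @param program A `motion_program`.
#' @param beam_window Optional length-2 window (seconds); displacement
#'   extremes are taken over this window when supplied, else over the
#'   whole program.
#' @return A [voxel_mask] labelled `"itv_true"` on the phantom grid.
#' @export
ground_truth_itv <- function(phantom, program, beam_window = NULL) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(program, "motion_program"))
  if (length(phantom$inserts) == 0L) {
    stop("phantom has no inserts to form a target volume", call. = FALSE)
  }
  si <- program$si_cm
  if (!is.null(beam_window)) {
    keep <- program$times >= beam_window[1L] &
      program$times <= beam_window[2L]
    si <- si[keep]
  }
  dz_set <- c(max(si), min(si), (max(si) + min(si)) / 2) * 10  # cm -> mm
  d <- dim(phantom$data)
  xs <- axis_centers(d[1L], phantom$spacing[1L], phantom$origin[1L])
  ys <- axis_centers(d[2L], phantom$spacing[2L], phantom$origin[2L])
  zs <- axis_centers(d[3L], phantom$spacing[3L], phantom$origin[3L])
  acc <- array(FALSE, dim = d)
  for (dz in dz_set) {
    for (ins in phantom$inserts) {
      acc <- acc | insert_mask(ins, xs, ys, zs, dz_mm = dz)
    }
  }
  voxel_mask(acc, phantom$spacing, phantom$origin, label = "itv_true")
}

#' Insert mask of a static phantom at a given displacement
#'
#' Convenience helper: the voxel mask covered by the phantom's inserts
#' when the object is translated by `dz_mm` superior-inferiorly.
#'
#' @param phantom A `digital_phantom`.
#' @param dz_mm S-I displacement in mm.
#' @return A [voxel_mask].
#' @export
phantom_object_mask <- function(phantom, dz_mm = 0) {
  stopifnot(inherits(phantom, "digital_phantom"))
  d <- dim(phantom$data)
  xs <- axis_centers(d[1L], phantom$spacing[1L], phantom$origin[1L])
  ys <- axis_centers(d[2L], phantom$spacing[2L], phantom$origin[2L])
  zs <- axis_centers(d[3L], phantom$spacing[3L], phantom$origin[3L])
  acc <- array(FALSE, dim = d)
  for (ins in phantom$inserts) {
    acc <- acc | insert_mask(ins, xs, ys, zs, dz_mm = dz_mm)
  }
  voxel_mask(acc, phantom$spacing, phantom$origin, label = "object")
}

#' Default study-like breathing programs
#'
#' Eight frozen parameter sets spanning the range of clinical scenarios
#' the digital study emulates: S-I amplitudes from 0.5 to 2.5 cm and
#' per-cycle amplitude irregularity from nearly regular (5% jitter) to
#' erratic (65% jitter), all with 15% period jitter over 75 s programs.
#' Case `i` pairs with seed `i` by convention.
#'
#' @param case Integer in 1..8.
#' @return A parameter list for [make_breathing_curve()] (kind
#'   `"irregular"`).
#' @export
study_program_params <- function(case) {
  stopifnot(length(case) == 1L, case %in% 1:8)
  amps <- c(0.5, 1, 1.5, 2, 2.5, 1, 1.5, 2)
  jit <- c(5, 12, 20, 28, 36, 45, 55, 65)
  list(amplitude_cm = amps[case], amplitude_jitter_pct = jit[case],
       period_jitter_pct = 15, duration_s = 75)
}
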