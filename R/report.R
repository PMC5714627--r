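#' Bundled reference-study tables
#'
#' Per-case statistics from a published dual-surrogate 4D CT evaluation,
#' shipped with the package so the derivable population statistics can be
#' recomputed offline: eight phantom breathing curves (amplitude mean/SD,
#' %CV, breathing rate, inter-surrogate Pearson r), the corresponding
#' phantom ITV comparison (percent volume change, OI, Dice, centroid
#' differences, percent differences from the ground-truth ITV), ten
#' patient cases (waveform statistics plus lung-volume agreement), and
#' the study's printed population summary values.
#'
#' @return A list of data frames: `phantom_waveforms`, `phantom_itv`,
#'   `patients`, `population_summary`.
#' @export
reference_tables <- function() {
  rd <- function(f) {
    utils::read.csv(system.file("extdata", f, package = "surro4dct",
                                mustWork = TRUE))
  }
  list(phantom_waveforms = rd("phantom_waveform_stats.csv"),
       phantom_itv = rd("phantom_itv_comparison.csv"),
       patients = rd("patient_study_stats.csv"),
       population_summary = rd("reference_population_summary.csv"))
}

#' Recompute population statistics from the bundled reference tables
#'
#' Derives every population-level statistic that follows from the
#' bundled per-case rows — cross-table Pearson correlations between
#' amplitude %CV (and breathing rate) and the percent difference from
#' the ground-truth ITV, and the phantom/patient population means — and
#' reports each next to the study's printed reference value.
#'
#' @return A data frame with columns `statistic`, `value` (recomputed),
#'   `reference_value` (printed), `n` (cases used).
#' @export
reference_study_stats <- function() {
  tb <- reference_tables()
  pw <- tb$phantom_waveforms
  pi_ <- tb$phantom_itv
  pa <- tb$patients
  rpm <- pw[pw$surrogate == "rpm", ]
  bel <- pw[pw$surrogate == "bellows", ]
  pa_b <- pa[pa$surrogate == "bellows", ]
  stopifnot(all(rpm$case == pi_$case), all(bel$case == pi_$case))
  # breathing rate is per curve (identical in both channel rows); its
  # association with the ITV shortfall is averaged over the two channels
  bpm_r <- mean(c(pearson_r(bel$breathing_rate_bpm,
                            pi_$itv_true_diff_rpm_percent),
                  pearson_r(bel$breathing_rate_bpm,
                            pi_$itv_true_diff_bellows_percent)))
  vals <- c(
    phantom_rpm_cv_vs_itv_true_diff_r =
      pearson_r(rpm$amp_cv_percent, pi_$itv_true_diff_rpm_percent),
    phantom_bellows_cv_vs_itv_true_diff_r =
      pearson_r(bel$amp_cv_percent, pi_$itv_true_diff_bellows_percent),
    phantom_bpm_vs_itv_true_diff_r = bpm_r,
    phantom_mean_volume_change_percent = mean(pi_$volume_change_percent),
    phantom_mean_itv_true_diff_bellows_percent =
      mean(pi_$itv_true_diff_bellows_percent),
    phantom_mean_itv_true_diff_rpm_percent =
      mean(pi_$itv_true_diff_rpm_percent),
    phantom_mean_pearson_r = mean(bel$pearson_r),
    patient_mean_volume_change_percent =
      mean(pa_b$volume_change_percent),
    patient_mean_overlap_index = mean(pa_b$overlap_index),
    patient_mean_dice = mean(pa_b$dice),
    patient_mean_pearson_r = mean(pa_b$pearson_r))
  ns <- c(rep(nrow(pi_), 7L), rep(nrow(pa_b), 4L))
  ref <- tb$population_summary
  out <- data.frame(statistic = names(vals), value = unname(vals),
                    reference_value =
                      ref$reference_value[match(names(vals),
                                                ref$statistic)],
                    n = ns)
  rownames(out) <- NULL
  out
}

#' End-to-end waveform comparison report
#'
#' Runs the full dual-channel waveform chain: crop both channels to the
#' beam-on window, downsample the bellows onto the marker-block
#' timestamps, detect end-inhale peaks, normalize each channel to its
#' maximum peak, pair peaks, and summarize latency, per-channel
#' amplitude statistics and the inter-channel Pearson correlation.
#'
#' @param rpm,bellows [surrogate_trace] objects for the two channels.
#' @param cfg A [peak_config].
#' @param hist_bin_ms Latency histogram bin width, ms.
#' @param max_offset_s Peak-pairing window; defaults to half the median
#'   breathing period of the marker-block channel.
#' @param out_dir Optional directory; when given, writes
#'   `waveform_stats.csv`, `latency_histogram.csv` and
#'   `latency_summary.json`.
#' @return A list: `stats` (data frame, one row per channel), `latency`
#'   (a `latency_summary`), `pearson_r`, `rpm`, `bellows` (the processed
#'   normalized traces), `peaks_rpm`, `peaks_bellows`.
#' @export
compare_waveforms_report <- function(rpm, bellows, cfg = peak_config(),
                                     hist_bin_ms = 25,
                                     max_offset_s = NULL,
                                     out_dir = NULL) {
  stopifnot_trace(rpm); stopifnot_trace(bellows)
  rpm_c <- crop_to_beam_on(rpm)
  bel_c <- crop_to_beam_on(bellows)
  common <- rpm_c$times[rpm_c$times <= max(bel_c$times)]
  bel_r <- resample_to(bel_c, common)
  rpm_r <- if (length(common) < length(rpm_c$times)) {
    resample_to(rpm_c, common)
  } else {
    rpm_c
  }
  pk_r <- detect_end_inhale_peaks(rpm_r, cfg)
  pk_b <- detect_end_inhale_peaks(bel_r, cfg)
  rpm_n <- normalize_to_max_peak(rpm_r, pk_r)
  bel_n <- normalize_to_max_peak(bel_r, pk_b)
  if (is.null(max_offset_s)) {
    max_offset_s <- if (length(pk_r$peak_times) > 1L) {
      stats::median(diff(pk_r$peak_times)) / 2
    } else {
      1
    }
  }
  pairs <- pair_peaks(pk_r, pk_b, max_offset_s)
  lat <- latency_summary(pairs, hist_bin_ms)
  st_r <- trace_stats(rpm_n, pk_r)
  st_b <- trace_stats(bel_n, pk_b)
  r <- pearson_r(rpm_n$amplitudes, bel_n$amplitudes)
  stats_df <- data.frame(
    surrogate = c("rpm", "bellows"),
    amp_mean = c(st_r$mean_amp, st_b$mean_amp),
    amp_sd = c(st_r$sd_amp, st_b$sd_amp),
    cv_percent = c(st_r$cv_percent, st_b$cv_percent),
    bpm = c(st_r$bpm, st_b$bpm),
    pearson_r = r)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(stats_df, file.path(out_dir, "waveform_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(lat$histogram,
                     file.path(out_dir, "latency_histogram.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(mean_ms = lat$mean_ms, sd_ms = lat$sd_ms, min_ms = lat$min_ms,
           max_ms = lat$max_ms, n_pairs = length(lat$pair_deltas),
           n_unmatched_a = lat$n_unmatched_a,
           n_unmatched_b = lat$n_unmatched_b,
           sign_convention = "positive = first channel (rpm) leads"),
      file.path(out_dir, "latency_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(stats = stats_df, latency = lat, pearson_r = r,
       rpm = rpm_n, bellows = bel_n, peaks_rpm = pk_r, peaks_bellows = pk_b)
}

#' Run one synthetic dual-surrogate phantom study
#'
#' Full end-to-end experiment on the digital phantom: generate a
#' breathing program and the two surrogate channels, simulate the
#' oversampled helical acquisition, sort slices into ten phase volumes
#' independently with each channel's end-inhale tags, build the two
#' MIPs, segment the target on each, and compare the resulting ITVs with
#' each other and with the ground-truth ITV.
#'
#' @param seed Integer seed driving the program and noise streams.
#' @param program_kind `"regular"` or `"irregular"`.
#' @param program_params Parameters for [make_breathing_curve()].
#' @param rpm_model,bellows_model [surrogate_model()] descriptions.
#' @param phantom A `digital_phantom` (default [build_phantom()]).
#' @param acq An [acquisition_config()].
#' @param object_window HU window segmenting the high-contrast target on
#'   the MIP (the lung-density slab lies outside it).
#' @param cfg A [peak_config].
#' @param out_dir Optional output directory for the report CSV and the
#'   MIP difference map NIfTI.
#' @return A list: `comparison` (a `similarity_report`,
#'   bellows-accepted), `itv_true_cc`, `diff_bellows_percent`,
#'   `diff_rpm_percent`, `mip_rpm`, `mip_bellows`, `itv_rpm`,
#'   `itv_bellows`, `itv_true`, `study_rpm`, `study_bellows`,
#'   `waveforms` (the [compare_waveforms_report()] result), `seed`.
#' @export
run_phantom_study <- function(seed = 1L,
                              program_kind = "irregular",
                              program_params = list(),
                              rpm_model = surrogate_model(
                                gain = 10, sampling_rate_hz = 30),
                              bellows_model = surrogate_model(
                                gain = 2.5, sampling_rate_hz = 38),
                              phantom = build_phantom(),
                              acq = acquisition_config(),
                              object_window = c(-300, 300),
                              cfg = peak_config(),
                              out_dir = NULL) {
  program <- make_breathing_curve(program_kind, program_params,
                                  seed = seed)
  span <- range(program$times)
  beam <- c(ceiling(span[1L]) + 1, floor(span[2L]) - 1)
  traces <- synthesize_surrogates(program, rpm_model, bellows_model,
                                  beam_window = beam, seed = seed + 1L)
  wf <- compare_waveforms_report(traces$rpm, traces$bellows, cfg = cfg)
  slices <- simulate_acquisition(phantom, program, acq)

  sort_with <- function(trace_n, peaks) {
    tags <- auto_tag(peaks)
    offset <- attr(trace_n, "time_offset") %||% beam[1L]
    acq_t <- vapply(slices, function(s) s$acquisition_time, numeric(1L))
    pm <- assign_phase(acq_t - offset, tags)
    pm$times <- acq_t  # back on the wall clock for slice lookup
    suppressWarnings(sort_slices(slices, pm))
  }
  st_r <- sort_with(wf$rpm, wf$peaks_rpm)
  st_b <- sort_with(wf$bellows, wf$peaks_bellows)
  mip_r <- compute_mip(st_r)
  mip_b <- compute_mip(st_b)
  itv_r <- segment_threshold(mip_r, object_window[1L], object_window[2L])
  itv_r$label <- "itv_rpm"
  itv_b <- segment_threshold(mip_b, object_window[1L], object_window[2L])
  itv_b$label <- "itv_bellows"
  itv_true <- ground_truth_itv(phantom, program, beam_window = beam)
  # ground truth lives on the phantom grid; the sorted volumes share it
  cmp <- similarity_report(itv_b, itv_r)
  out <- list(comparison = cmp,
              itv_true_cc = mask_volume(itv_true),
              diff_bellows_percent = percent_diff_from_true(itv_true,
                                                            itv_b),
              diff_rpm_percent = percent_diff_from_true(itv_true, itv_r),
              mip_rpm = mip_r, mip_bellows = mip_b,
              itv_rpm = itv_r, itv_bellows = itv_b, itv_true = itv_true,
              study_rpm = st_r, study_bellows = st_b, waveforms = wf,
              seed = as.integer(seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(phantom_study_row(out),
                     file.path(out_dir, "phantom_study.csv"),
                     row.names = FALSE)
    dm <- difference_map(mip_b, mip_r)
    dm$data[is.na(dm$data)] <- 0
    write_volume(dm, file.path(out_dir, "mip_difference_map.nii.gz"))
  }
  out
}

phantom_study_row <- function(res) {
  cmp <- res$comparison
  data.frame(seed = res$seed,
             volume_change_percent = cmp$percent_volume_change,
             overlap_index = cmp$oi,
             dice = cmp$dsc,
             centroid_dx_mm = cmp$centroid_delta_mm[1L],
             centroid_dy_mm = cmp$centroid_delta_mm[2L],
             centroid_dz_mm = cmp$centroid_delta_mm[3L],
             itv_true_diff_bellows_percent = res$diff_bellows_percent,
             itv_true_diff_rpm_percent = res$diff_rpm_percent,
             itv_bellows_cc = cmp$volume_accepted_cc,
             itv_rpm_cc = cmp$volume_test_cc,
             itv_true_cc = res$itv_true_cc,
             latency_mean_ms = res$waveforms$latency$mean_ms,
             pearson_r = res$waveforms$pearson_r,
             cv_rpm_percent =
               res$waveforms$stats$cv_percent[
                 res$waveforms$stats$surrogate == "rpm"])
}

#' Batch phantom study over several seeds
#'
#' Runs [run_phantom_study()] for each seed and stacks the per-seed
#' comparison rows, appending a population mean and SD row.
#'
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [run_phantom_study()].
#' @param out_dir Optional directory for `phantom_study_batch.csv`.
#' @return A data frame with one row per seed plus `mean` and `sd` rows.
#' @export
run_phantom_batch <- function(seeds = 1:8, ..., out_dir = NULL) {
  rows <- lapply(seeds, function(s) {
    phantom_study_row(run_phantom_study(seed = s, ...))
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1L))
  mrow <- df[1L, ]; srow <- df[1L, ]
  mrow[num] <- lapply(df[num], mean)
  srow[num] <- lapply(df[num], stats::sd)
  mrow$seed <- NA_integer_; srow$seed <- NA_integer_
  df$summary <- ""
  mrow$summary <- "mean"; srow$summary <- "sd"
  out <- rbind(df, mrow, srow)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "phantom_study_batch.csv"),
                     row.names = FALSE)
  }
  out
}

#' Load a study configuration file
#'
#' Reads a YAML configuration with optional blocks `program`
#' (breathing-curve parameters), `rpm_model` / `bellows_model`
#' (surrogate channels), `acquisition`, `peaks` (peak search), `seed`
#' and `out_dir`, and returns the assembled argument list for
#' [run_phantom_study()].
#'
#' @param path Path to a YAML file.
#' @return A named list of arguments.
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$seed)) args$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$program$kind)) args$program_kind <- cfg$program$kind
  pp <- cfg$program
  pp$kind <- NULL
  if (length(pp)) args$program_params <- pp
  if (!is.null(cfg$rpm_model)) {
    args$rpm_model <- do.call(surrogate_model, cfg$rpm_model)
  }
  if (!is.null(cfg$bellows_model)) {
    args$bellows_model <- do.call(surrogate_model, cfg$bellows_model)
  }
  if (!is.null(cfg$acquisition)) {
    args$acq <- do.call(acquisition_config, cfg$acquisition)
  }
  if (!is.null(cfg$peaks)) args$cfg <- do.call(peak_config, cfg$peaks)
  if (!is.null(cfg$out_dir)) args$out_dir <- cfg$out_dir
  args
}
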