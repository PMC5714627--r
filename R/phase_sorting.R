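#' Create end-inhale (0% phase) tags from detected peaks
#'
#' Retrospective phase sorting anchors the 0% (end-inhale) phase at the
#' detected end-inhale peaks. Clinical software tags these automatically
#' and allows manual correction; here the automatic tags are the peak
#' times from [detect_end_inhale_peaks()], and [edit_tags()] provides the
#' manual-correction path.
#'
#' @param peaks A `peak_list` with at least two peaks.
#' @return A `tag_list`: `tag_times` (seconds, strictly increasing, more
#'   than 1 s apart), `provenance` per tag (`"auto"` or `"manual_add"`),
#'   and `removed_times` (audit trail).
#' @export
auto_tag <- function(peaks) {
  stopifnot(inherits(peaks, "peak_list"))
  tt <- peaks$peak_times
  if (length(tt) < 2L) {
    stop("insufficient cycles: at least two end-inhale peaks are required",
         call. = FALSE)
  }
  if (any(diff(tt) <= 1)) {
    stop("tagging error: consecutive end-inhale tags must be more than 1 s apart",
         call. = FALSE)
  }
  structure(list(tag_times = tt,
                 provenance = rep("auto", length(tt)),
                 removed_times = numeric(0)),
            class = "tag_list")
}

#' Manually edit end-inhale tags
#'
#' Adds tags for missed breathing cycles and removes improperly placed
#' ones; removals are logged in the audit list. An addition that would
#' leave two tags 1 s or less apart is rejected.
#'
#' @param tags A `tag_list`.
#' @param add Numeric vector of tag times to add (seconds).
#' @param remove Numeric vector of existing tag times to remove (matched
#'   within 1e-6 s).
#' @return The edited `tag_list`.
#' @export
edit_tags <- function(tags, add = numeric(0), remove = numeric(0)) {
  stopifnot(inherits(tags, "tag_list"))
  tt <- tags$tag_times
  prov <- tags$provenance
  removed <- tags$removed_times
  for (rm in as.numeric(remove)) {
    hit <- which(abs(tt - rm) < 1e-6)
    if (length(hit) == 0L) {
      stop(sprintf("edit rejected: no tag at %.6f s to remove", rm),
           call. = FALSE)
    }
    hit <- hit[1L]
    removed <- c(removed, tt[hit])
    tt <- tt[-hit]
    prov <- prov[-hit]
  }
  for (ad in as.numeric(add)) {
    if (length(tt) > 0L && any(abs(tt - ad) <= 1)) {
      stop(sprintf(
        "edit rejected: tag at %.3f s would be within 1 s of an existing tag",
        ad), call. = FALSE)
    }
    tt <- c(tt, ad)
    prov <- c(prov, "manual_add")
  }
  o <- order(tt)
  tt <- tt[o]; prov <- prov[o]
  if (length(tt) > 1L && any(diff(tt) <= 1)) {
    stop("edit rejected: resulting tags violate the 1 s separation rule",
         call. = FALSE)
  }
  structure(list(tag_times = tt, provenance = prov,
                 removed_times = removed),
            class = "tag_list")
}

#' Assign continuous respiratory phase from end-inhale tags
#'
#' Phase advances linearly in time between consecutive end-inhale tags:
#' `phase_fraction = (t - T_i) / (T_(i+1) - T_i)`, 0 at end-inhale and
#' approximately 0.5 at end-exhale for symmetric cycles. Each time is
#' also binned to the nearest of the ten phase bins {0%, 10%, ..., 90%}
#' with circular wraparound (fractions of 0.95 or more are nearer to the
#' cycle start and fall in bin 0); an exact interior midpoint is broken
#' toward the lower bin. Times before the first or after the last tag
#' have no cycle context and are marked invalid.
#'
#' @param times Numeric vector of query times, seconds.
#' @param tags A `tag_list` with at least two tags.
#' @return A `phase_map`: `times`, `phase_fraction` in `[0, 1)`,
#'   `phase_bin` (percent, one of 0, 10, ..., 90), `valid`.
#' @export
assign_phase <- function(times, tags) {
  stopifnot(inherits(tags, "tag_list"))
  tt <- tags$tag_times
  if (length(tt) < 2L) {
    stop("insufficient cycles: at least two tags are required",
         call. = FALSE)
  }
  times <- as.numeric(times)
  n <- length(times)
  frac <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  iv <- findInterval(times, tt)
  inside <- iv >= 1L & iv < length(tt)
  frac[inside] <- (times[inside] - tt[iv[inside]]) /
    (tt[iv[inside] + 1L] - tt[iv[inside]])
  at_last <- times == tt[length(tt)]
  frac[at_last] <- 0
  valid <- inside | at_last
  bin <- rep(NA_integer_, n)
  bin[valid] <- bin_fraction(frac[valid], 10L)
  structure(list(times = times, phase_fraction = frac, phase_bin = bin,
                 valid = valid),
            class = "phase_map")
}

# nearest-bin (circular) label in percent for phase fractions in [0, 1):
# interior midpoints break toward the lower bin; fractions within half a
# bin of 1 wrap to bin 0
bin_fraction <- function(f, n_bins) {
  b <- ifelse(f >= 1 - 0.5 / n_bins, 0L,
              as.integer(ceiling(f * n_bins - 0.5)))
  b[b < 0L] <- 0L
  as.integer(round(b * 100 / n_bins))
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d samples, %d valid\n",
              length(x$times), sum(x$valid)))
  invisible(x)
}

#' Sort simulated slices into per-phase volumes
#'
#' Retrospective phase sorting of an oversampled helical acquisition:
#' slices are grouped by couch position; each slice belongs to the phase
#' bin of its continuous phase (nearest bin center, circular, ties as in
#' [assign_phase()]), and for each position and bin the member slice
#' circularly closest to the bin center is selected. A (position, bin)
#' pair with no member slice is flagged as a sorting artifact and left
#' empty. Slices acquired outside the tagged interval are excluded and
#' counted.
#'
#' @param slices List of `slice_record` objects
#'   (see [simulate_acquisition()]).
#' @param phase_map A `phase_map` evaluated on a time grid covering the
#'   slice acquisition times (the continuous phase of each slice is read
#'   from the nearest phase-map sample).
#' @param n_bins Number of phase bins (default 10).
#' @return A `phase_study`: `volumes` (one [volume3d] per bin, voxels
#'   `NA` where no slice was admissible), `bins` (percent labels),
#'   `provenance` (data frame: couch_z, bin_percent, acquisition time,
#'   continuous phase), `artifact_flags` (data frame: couch_z,
#'   bin_percent), `n_excluded`.
#' @export
sort_slices <- function(slices, phase_map, n_bins = 10L) {
  stopifnot(inherits(phase_map, "phase_map"), length(slices) > 0L,
            n_bins >= 1L)
  acq_t <- vapply(slices, function(s) s$acquisition_time, numeric(1L))
  couch <- vapply(slices, function(s) s$couch_z, numeric(1L))
  idx <- vapply(acq_t, function(tt) {
    which.min(abs(phase_map$times - tt))
  }, integer(1L))
  frac <- phase_map$phase_fraction[idx]
  ok <- phase_map$valid[idx]
  slice_bin <- rep(NA_integer_, length(frac))
  slice_bin[ok] <- bin_fraction(frac[ok], n_bins)
  n_excluded <- sum(!ok)
  if (n_excluded > 0L) {
    warning(sprintf("%d slices at untagged times excluded from sorting",
                    n_excluded))
  }
  zs <- sort(unique(couch))
  centers <- (seq_len(n_bins) - 1L) / n_bins
  circ_dist <- function(f, c) pmin(abs(f - c), 1 - abs(f - c))

  sl1 <- slices[[1L]]
  nxy <- dim(sl1$pixels)
  vols <- lapply(seq_len(n_bins), function(b) {
    array(NA_real_, dim = c(nxy[1L], nxy[2L], length(zs)))
  })
  prov <- list()
  flags <- list()
  for (zi in seq_along(zs)) {
    here <- which(couch == zs[zi] & ok)
    for (b in seq_len(n_bins)) {
      bin_pct <- (b - 1L) * 100L / n_bins
      cand <- here[slice_bin[here] == bin_pct]
      if (length(cand) == 0L) {
        flags[[length(flags) + 1L]] <-
          data.frame(couch_z = zs[zi], bin_percent = bin_pct)
        next
      }
      dc <- circ_dist(frac[cand], centers[b])
      pick <- cand[order(dc, acq_t[cand])][1L]
      vols[[b]][, , zi] <- slices[[pick]]$pixels
      prov[[length(prov) + 1L]] <-
        data.frame(couch_z = zs[zi],
                   bin_percent = (b - 1L) * 100L / n_bins,
                   acquisition_time = acq_t[pick],
                   phase_fraction = frac[pick])
    }
  }
  dz <- if (length(zs) > 1L) min(diff(zs)) else sl1$in_plane_spacing[1L]
  spacing <- c(sl1$in_plane_spacing, dz)
  origin <- c(0, 0, zs[1L] - dz / 2)
  volumes <- lapply(vols, volume3d, spacing = spacing, origin = origin)
  structure(list(
    volumes = volumes,
    bins = (seq_len(n_bins) - 1L) * 100L / n_bins,
    provenance = if (length(prov)) do.call(rbind, prov) else
      data.frame(couch_z = numeric(0), bin_percent = numeric(0),
                 acquisition_time = numeric(0), phase_fraction = numeric(0)),
    artifact_flags = if (length(flags)) do.call(rbind, flags) else
      data.frame(couch_z = numeric(0), bin_percent = numeric(0)),
    n_excluded = n_excluded,
    selection_rule = "closest-phase"),
    class = "phase_study")
}

#' @export
print.phase_study <- function(x, ...) {
  cat(sprintf(
    "<phase_study> %d bins, %d couch positions, %d artifact flags, %d excluded slices\n",
    length(x$volumes), dim(x$volumes[[1L]]$data)[3L],
    nrow(x$artifact_flags), x$n_excluded))
  invisible(x)
}

#' Write a phase study to NIfTI files
#'
#' One file per phase bin (`phase_00.nii.gz`, `phase_10.nii.gz`, ...)
#' plus `artifact_flags.csv` (couch_z_mm, bin_percent). Unfilled voxels
#' are written as the `fill` value.
#'
#' @param study A `phase_study`.
#' @param dir Output directory (created if needed).
#' @param fill Value replacing `NA` voxels on disk.
#' @return Invisibly, the written file paths.
#' @export
write_phase_study <- function(study, dir, fill = -1000) {
  stopifnot(inherits(study, "phase_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(study$volumes)) {
    v <- study$volumes[[i]]
    v$data[is.na(v$data)] <- fill
    p <- file.path(dir, sprintf("phase_%02d.nii.gz", study$bins[i]))
    write_volume(v, p)
    paths <- c(paths, p)
  }
  fcsv <- file.path(dir, "artifact_flags.csv")
  flags <- study$artifact_flags
  names(flags) <- c("couch_z_mm", "bin_percent")
  utils::write.csv(flags, fcsv, row.names = FALSE)
  invisible(c(paths, fcsv))
}
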