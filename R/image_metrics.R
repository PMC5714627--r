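#' Maximum intensity projection over phase volumes
#'
#' Voxelwise maximum over all phase volumes of a 4D CT study. `NA`
#' voxels (e.g. flagged empty sorting bins) are ignored; a voxel that is
#' `NA` in every phase stays `NA`.
#'
#' @param phases List of [volume3d] objects on identical grids, or a
#'   `phase_study`.
#' @return A [volume3d] MIP.
#' @export
compute_mip <- function(phases) {
  if (inherits(phases, "phase_study")) phases <- phases$volumes
  stopifnot(length(phases) >= 1L)
  ref <- phases[[1L]]
  for (p in phases) {
    if (!same_grid(ref, p)) {
      stop("geometry error: phase volumes are not on the same grid",
           call. = FALSE)
    }
  }
  dat <- do.call(pmax, c(lapply(phases, function(p) p$data),
                         list(na.rm = TRUE)))
  dat[is.infinite(dat)] <- NA_real_
  volume3d(array(dat, dim = dim(ref$data)), ref$spacing, ref$origin)
}

# --- 3D connectivity helpers ------------------------------------------

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) {
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  } else if (connectivity != 26L) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  as.matrix(g)
}

# label connected components of a logical 3D array; returns an integer
# array (0 = background). Frontier-batch BFS keeps this fast in plain R.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  no <- nrow(offs)
  lin_offs <- offs[, 1L] + offs[, 2L] * d[1L] + offs[, 3L] * d[1L] * d[2L]
  lab <- array(0L, dim = d)
  unvisited <- mask
  ix <- array(rep(seq_len(d[1L]), times = d[2L] * d[3L]), dim = d)
  iy <- array(rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
              dim = d)
  current <- 0L
  repeat {
    seed <- which(unvisited)
    if (length(seed) == 0L) break
    seed <- seed[1L]
    current <- current + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    lab[seed] <- current
    while (length(frontier) > 0L) {
      nf <- length(frontier)
      cand <- rep(frontier, each = no) + rep(lin_offs, times = nf)
      src_x <- rep(ix[frontier], each = no)
      src_y <- rep(iy[frontier], each = no)
      dx <- rep(offs[, 1L], times = nf)
      dy <- rep(offs[, 2L], times = nf)
      keep <- cand >= 1L & cand <= length(mask)
      cand <- cand[keep]
      # reject neighbours that wrapped around the x or y axis
      ok <- ix[cand] == src_x[keep] + dx[keep] &
        iy[cand] == src_y[keep] + dy[keep]
      cand <- unique(cand[ok])
      cand <- cand[unvisited[cand]]
      if (length(cand) > 0L) {
        unvisited[cand] <- FALSE
        lab[cand] <- current
      }
      frontier <- cand
    }
  }
  lab
}

#' Threshold segmentation within a region of interest
#'
#' Selects voxels whose HU value lies in `[hu_lo, hu_hi]` inside an
#' optional box ROI, then keeps the largest 26-connected component. The
#' default window (-900 to -600 HU) targets lung-density material.
#'
#' @param volume A [volume3d].
#' @param hu_lo,hu_hi Threshold window bounds (inclusive).
#' @param roi Optional list with `lo` and `hi`, each length-3 1-based
#'   voxel index bounds of the search box.
#' @return A [voxel_mask].
#' @export
segment_threshold <- function(volume, hu_lo = -900, hu_hi = -600,
                              roi = NULL) {
  stopifnot(inherits(volume, "volume3d"))
  d <- dim(volume$data)
  sel <- !is.na(volume$data) & volume$data >= hu_lo & volume$data <= hu_hi
  if (!is.null(roi)) {
    lo <- pmax(1L, as.integer(roi$lo)); hi <- pmin(d, as.integer(roi$hi))
    if (any(lo > hi)) {
      stop("geometry error: ROI outside the volume grid", call. = FALSE)
    }
    box <- array(FALSE, dim = d)
    box[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- TRUE
    sel <- sel & box
  }
  if (!any(sel)) {
    stop("empty segmentation: no voxels inside the threshold window",
         call. = FALSE)
  }
  lab <- label_components(sel, connectivity = 26L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  voxel_mask(lab == keep, volume$spacing, volume$origin,
             label = sprintf("threshold[%g,%g]", hu_lo, hu_hi))
}

#' Simplified automatic lung segmentation
#'
#' Emulates the clinical auto-segmentation flow: find the axial slice
#' holding the largest two connected air areas that are enclosed by the
#' body (air that reaches the volume boundary is outside air and is
#' rejected), then grow the lung volume from those seed regions by a 3D
#' flood fill (6-connected) over air-range voxels.
#'
#' @param volume A [volume3d] containing a body region (HU > -300)
#'   enclosing air (HU < -600).
#' @param air_hu Upper HU bound for air-like voxels.
#' @return A [voxel_mask] of the lungs. A single enclosed air region
#'   yields a warning; none is an error.
#' @export
segment_lungs_simple <- function(volume, air_hu = -600) {
  stopifnot(inherits(volume, "volume3d"))
  d <- dim(volume$data)
  air <- !is.na(volume$data) & volume$data < air_hu
  if (!any(air)) {
    stop("empty segmentation: no air-range voxels in the volume",
         call. = FALSE)
  }
  lab <- label_components(air, connectivity = 6L)
  # components touching the grid boundary are open to the exterior
  boundary <- array(FALSE, dim = d)
  boundary[c(1L, d[1L]), , ] <- TRUE
  boundary[, c(1L, d[2L]), ] <- TRUE
  boundary[, , c(1L, d[3L])] <- TRUE
  open_ids <- unique(lab[boundary & lab > 0L])
  enclosed <- lab
  enclosed[enclosed %in% open_ids] <- 0L
  if (!any(enclosed > 0L)) {
    stop("empty segmentation: no enclosed air region found",
         call. = FALSE)
  }
  # seed slice: largest total enclosed-air area over its top-two regions
  best_k <- 0L; best_area <- -1
  per_slice <- integer(d[3L])
  for (k in seq_len(d[3L])) {
    ids <- enclosed[, , k]
    if (!any(ids > 0L)) next
    areas <- sort(tabulate(ids[ids > 0L]), decreasing = TRUE)
    score <- sum(utils::head(areas[areas > 0L], 2L))
    per_slice[k] <- score
    if (score > best_area) { best_area <- score; best_k <- k }
  }
  seed_ids <- enclosed[, , best_k]
  seed_ids <- unique(seed_ids[seed_ids > 0L])
  areas <- vapply(seed_ids, function(id) sum(enclosed[, , best_k] == id),
                  integer(1L))
  seed_ids <- seed_ids[order(areas, decreasing = TRUE)]
  seed_ids <- utils::head(seed_ids, 2L)
  if (length(seed_ids) == 1L) {
    warning("single enclosed air region: one-lung segmentation")
  }
  # the 6-connected flood fill from the seed regions is exactly the
  # union of the enclosed components carrying the seeds
  voxel_mask(array(enclosed %in% seed_ids, dim = d), volume$spacing,
             volume$origin, label = "lungs")
}

#' Mask volume in cubic centimetres
#'
#' @param mask A [voxel_mask].
#' @return Voxel count times voxel volume, in cc.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Mask centroid in physical coordinates
#'
#' Unweighted mean of the member voxel centers, in mm, ordered
#' (x lateral, y anterior-posterior, z superior-inferior).
#'
#' @param mask A nonempty [voxel_mask].
#' @return Numeric length-3 vector, mm.
#' @export
centroid <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("undefined centroid: empty mask", call. = FALSE)
  }
  unname(colMeans(sweep(sweep(idx - 0.5, 2L, mask$spacing, "*"), 2L,
                        mask$origin, "+")))
}

count_overlap <- function(a, b) {
  if (!same_grid(a, b)) {
    stop("geometry error: masks are not on the same grid", call. = FALSE)
  }
  c(na = sum(a$data), nb = sum(b$data), nab = sum(a$data & b$data))
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)` by voxel counts; 1 iff the
#' masks are identical, 0 for disjoint masks.
#'
#' @param a,b [voxel_mask] objects on the same grid, not both empty.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  n <- count_overlap(a, b)
  if (n[["na"]] + n[["nb"]] == 0L) {
    stop("undefined DSC: both masks are empty", call. = FALSE)
  }
  2 * n[["nab"]] / (n[["na"]] + n[["nb"]])
}

#' Overlap index
#'
#' `OI = |accepted intersect test| / |accepted|`: the inclusion of the
#' accepted volume within the test volume. Not symmetric — swapping the
#' arguments changes the denominator.
#'
#' @param accepted Nonempty reference [voxel_mask] (the clinically
#'   accepted volume).
#' @param test Comparison [voxel_mask] on the same grid.
#' @return OI in `[0, 1]`.
#' @export
oi <- function(accepted, test) {
  n <- count_overlap(accepted, test)
  if (n[["na"]] == 0L) {
    stop("undefined OI: accepted mask is empty", call. = FALSE)
  }
  n[["nab"]] / n[["na"]]
}

#' Percent volume change relative to an accepted mask
#'
#' `(V_accepted - V_test) / V_accepted x 100`; negative when the test
#' volume is the larger one.
#'
#' @param accepted Nonempty accepted [voxel_mask].
#' @param test Test [voxel_mask].
#' @return Percent volume change.
#' @export
percent_volume_change <- function(accepted, test) {
  va <- mask_volume(accepted)
  if (va == 0) {
    stop("undefined volume change: accepted volume is zero",
         call. = FALSE)
  }
  (va - mask_volume(test)) / va * 100
}

#' Percent difference from a ground-truth mask
#'
#' `(V_true - V_test) / V_true x 100`; non-negative whenever the test
#' volume is contained in the truth.
#'
#' @param true_mask Nonempty ground-truth [voxel_mask].
#' @param test Test [voxel_mask].
#' @return Percent difference.
#' @export
percent_diff_from_true <- function(true_mask, test) {
  vt <- mask_volume(true_mask)
  if (vt == 0) {
    stop("undefined difference: ground-truth volume is zero",
         call. = FALSE)
  }
  (vt - mask_volume(test)) / vt * 100
}

#' Voxelwise difference map
#'
#' `a - b` on identical grids, used to visualize local density changes
#' between two MIP reconstructions.
#'
#' @param a,b [volume3d] objects on the same grid.
#' @return A [volume3d] of differences.
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "volume3d"), inherits(b, "volume3d"))
  if (!same_grid(a, b)) {
    stop("geometry error: volumes are not on the same grid",
         call. = FALSE)
  }
  volume3d(a$data - b$data, a$spacing, a$origin)
}

#' Full similarity report between two masks
#'
#' Bundles volumes, percent volume change, DSC, OI and the centroid
#' difference (test minus accepted) into one record.
#'
#' @param accepted,test [voxel_mask] objects on the same grid.
#' @return A `similarity_report` list: `volume_accepted_cc`,
#'   `volume_test_cc`, `percent_volume_change`, `dsc`, `oi`,
#'   `centroid_delta_mm` (x, y, z).
#' @export
similarity_report <- function(accepted, test) {
  structure(list(
    volume_accepted_cc = mask_volume(accepted),
    volume_test_cc = mask_volume(test),
    percent_volume_change = percent_volume_change(accepted, test),
    dsc = dsc(accepted, test),
    oi = oi(accepted, test),
    centroid_delta_mm = centroid(test) - centroid(accepted)),
    class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report> %.2f vs %.2f cc (%+.2f%%), DSC %.3f, OI %.3f\n",
    x$volume_accepted_cc, x$volume_test_cc, x$percent_volume_change,
    x$dsc, x$oi))
  cat(sprintf("  centroid delta (x, y, z): (%.2f, %.2f, %.2f) mm\n",
              x$centroid_delta_mm[1L], x$centroid_delta_mm[2L],
              x$centroid_delta_mm[3L]))
  invisible(x)
}
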