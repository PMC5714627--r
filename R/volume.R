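#' 3D image volume
#'
#' Minimal container for a 3D voxel grid with physical geometry. Axis
#' convention: x is lateral, y anterior-posterior, z superior-inferior.
#' Voxel indices are 0-based in the geometry model: the physical center
#' of voxel `(i, j, k)` (0-based) is `origin + (index + 0.5) * spacing`.
#'
#' @param data A 3D numeric or logical array.
#' @param spacing Voxel spacing in mm, length 3, all positive.
#' @param origin Physical position (mm) of the grid corner, length 3.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("geometry error: spacing must be three positive numbers",
         call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("geometry error: origin must be three finite numbers",
         call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ (%.2f, %.2f, %.2f) mm\n",
              d[1L], d[2L], d[3L],
              x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  invisible(x)
}

#' Binary voxel mask
#'
#' A segmentation result on the same grid as its source volume.
#'
#' @param data A 3D logical array.
#' @param spacing,origin Grid geometry as in [volume3d()].
#' @param label Text label for reports.
#' @return An object of class `voxel_mask` (also `volume3d`).
#' @export
voxel_mask <- function(data, spacing, origin = c(0, 0, 0), label = "") {
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data)) data[is.na(data)] <- FALSE
  v <- volume3d(data, spacing, origin)
  v$label <- as.character(label)
  class(v) <- c("voxel_mask", "volume3d")
  v
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> '%s': %d voxels set (%.2f cc)\n",
              x$label, sum(x$data), mask_volume(x)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Write a volume or mask to a NIfTI file
#'
#' @param vol A [volume3d] or [voxel_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  dat <- vol$data
  if (is.logical(dat)) dat <- array(as.integer(dat), dim = dim(dat))
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  # NIfTI affine maps 0-based voxel indices to voxel-center world
  # coordinates: center of voxel 0 is origin + spacing / 2
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4L] <- vol$origin + vol$spacing / 2
  img <- RNifti::`sform<-`(img, value = structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a volume
#'
#' @param path Path to a NIfTI file.
#' @param as_mask Interpret nonzero voxels as a [voxel_mask].
#' @return A [volume3d] (or [voxel_mask]).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) == 2L) {
    dat <- array(dat, dim = c(dim(dat), 1L))  # single-slice volume
  }
  if (length(dim(dat)) != 3L) {
    stop("geometry error: expected a 3D NIfTI volume", call. = FALSE)
  }
  pd <- abs(RNifti::pixdim(img))
  spacing <- if (length(pd) >= 3L) pd[1:3] else c(pd, 1)[1:3]
  m <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  org <- if (is.matrix(m) && all(is.finite(m[1:3, 4L]))) {
    m[1:3, 4L] - spacing / 2
  } else {
    c(0, 0, 0)
  }
  if (as_mask) {
    voxel_mask(dat != 0, spacing, org, label = basename(path))
  } else {
    volume3d(dat, spacing, org)
  }
}

# physical centers (mm) along one axis; idx is 1-based
axis_centers <- function(n, spacing, origin) {
  origin + (seq_len(n) - 0.5) * spacing
}
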