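#' Masked 4D time-series volume
#'
#' Container for a 4D functional acquisition: an `x * y * z * t` intensity
#' array, the repetition time, voxel geometry, and a binary analysis mask.
#' All graph construction downstream operates on the voxels inside `mask`.
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param tr repetition time in seconds.
#' @param voxel_mm length-3 numeric, voxel edge lengths in mm.
#' @param mask logical 3D array matching the spatial dimensions; voxels
#'   entering the analysis. Must be non-empty.
#' @param origin_mm mm coordinate of voxel (1,1,1); with `voxel_mm` this
#'   defines the (diagonal) affine used to report mm coordinates.
#' @return An object of class `ts_volume`.
#' @export
ts_volume <- function(data, tr, voxel_mm = c(4, 4, 4), mask = NULL,
                      origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (dim(data)[4] < 2) stop("time dimension must have at least 2 frames")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be a positive number of seconds")
  if (any(voxel_mm <= 0)) stop("voxel sizes must be positive")
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  stopifnot(identical(dim(mask), dim(data)[1:3]))
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("analysis mask is empty")
  structure(
    list(data = data, tr = tr, voxel_mm = as.numeric(voxel_mm),
         origin_mm = as.numeric(origin_mm), mask = mask),
    class = "ts_volume"
  )
}

#' @export
print.ts_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_volume> %d x %d x %d voxels x %d frames, TR %.3g s, %d in mask\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

n_frames <- function(v) dim(v$data)[4]

# 4x4 diagonal affine mapping 0-based voxel indices to mm
volume_affine <- function(v) {
  A <- diag(c(v$voxel_mm, 1))
  A[1:3, 4] <- v$origin_mm
  A
}

# 1-based voxel coordinates (n x 3) -> mm coordinates (n x 3)
voxel_to_mm <- function(coords, voxel_mm, origin_mm) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  sweep(sweep(coords - 1, 2, voxel_mm, `*`), 2, origin_mm, `+`)
}

#' Write / read a time-series volume as NIfTI
#'
#' Thin wrappers around \pkg{RNifti}. The mask travels as a separate 3D
#' NIfTI file; TR is stored in the NIfTI time-step field.
#'
#' @param v a [ts_volume()].
#' @param path output path for the 4D image (`.nii` / `.nii.gz`).
#' @param mask_path optional path for the binary mask image.
#' @return `write_volume_nifti` returns `path` invisibly; `read_volume_nifti`
#'   returns a [ts_volume()].
#' @export
write_volume_nifti <- function(v, path, mask_path = NULL) {
  img <- RNifti::asNifti(v$data)
  img <- RNifti::`pixdim<-`(img, c(v$voxel_mm, v$tr))
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    m <- RNifti::asNifti(array(as.numeric(v$mask), dim(v$mask)))
    m <- RNifti::`pixdim<-`(m, v$voxel_mm)
    RNifti::writeNifti(m, mask_path)
  }
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, mask_path = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  dat <- array(as.numeric(img), dim(img))
  if (length(dim(dat)) == 3) dim(dat) <- c(dim(dat), 1)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(m), dim(m)[1:3]) > 0.5
  }
  ts_volume(dat, tr = tr %||% (if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1),
            voxel_mm = pd[1:3], mask = mask)
}

#' Write a per-node map back into grid space as NIfTI
#'
#' @param values numeric vector, one value per node.
#' @param nodes a `node_ts` lookup (from [mask_and_downsample()]) or a matrix
#'   of 1-based voxel coordinates.
#' @param dim grid dimensions of the target image.
#' @param path output path.
#' @param voxel_mm voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, nodes, dim, path, voxel_mm = c(4, 4, 4)) {
  coords <- if (is.matrix(nodes)) nodes else nodes$coords
  stopifnot(length(values) == nrow(coords))
  arr <- array(0, dim)
  arr[cbind(coords[, 1], coords[, 2], coords[, 3])] <- values
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}
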