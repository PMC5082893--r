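#' Confound regressor set
#'
#' Per-time-point nuisance regressors: six motion parameters, the global
#' signal, and surrogate ventricle (CSF) and white-matter region means.
#' Any component may be flagged absent by passing `NULL`.
#'
#' @param motion `T x 6` matrix of motion parameters, or `NULL`.
#' @param global,csf,wm length-`T` numeric regressors, or `NULL`.
#' @return An object of class `confound_set`.
#' @export
confound_set <- function(motion = NULL, global = NULL, csf = NULL, wm = NULL) {
  lens <- c(if (!is.null(motion)) nrow(motion),
            length(global) %||% NULL, length(csf) %||% NULL,
            length(wm) %||% NULL,
            if (!is.null(global)) length(global),
            if (!is.null(csf)) length(csf),
            if (!is.null(wm)) length(wm))
  lens <- lens[lens > 0]
  if (length(unique(lens)) > 1) stop("confound regressors differ in length")
  for (nm in c("global", "csf", "wm")) {
    x <- get(nm)
    if (!is.null(x) && all(x == 0)) stop(nm, " regressor is constant zero; flag it absent with NULL")
  }
  structure(list(motion = motion, global = global, csf = csf, wm = wm),
            class = "confound_set")
}

confound_matrix <- function(c, n) {
  cols <- list()
  if (!is.null(c$motion)) {
    m <- as.matrix(c$motion)
    colnames(m) <- colnames(m) %||% paste0("mot", seq_len(ncol(m)))
    cols <- c(cols, list(m))
  }
  for (nm in c("global", "csf", "wm"))
    if (!is.null(c[[nm]])) cols <- c(cols, list(setNames(data.frame(c[[nm]]), nm)))
  X <- if (length(cols)) as.matrix(do.call(cbind, cols)) else matrix(0, n, 0)
  if (nrow(X) != n && ncol(X) > 0) stop("confound length does not match time series")
  X
}

#' Extract region-mean confounds from a volume
#'
#' Computes the global signal (mean over all brain voxels: analysis mask
#' plus WM/CSF regions) and the WM and CSF region means from the data.
#'
#' @param v a [ts_volume()].
#' @param wm_region,csf_region voxel-coordinate matrices of the surrogate
#'   regions.
#' @param motion optional `T x 6` motion matrix.
#' @return A [confound_set()].
#' @export
extract_confounds <- function(v, wm_region, csf_region, motion = NULL) {
  d <- dim(v$data)
  flat <- matrix(v$data, prod(d[1:3]), d[4])
  wm_i <- coords_to_idx(wm_region, d[1:3])
  csf_i <- coords_to_idx(csf_region, d[1:3])
  brain_i <- sort(unique(c(which(v$mask), wm_i, csf_i)))
  confound_set(
    motion = motion,
    global = colMeans(flat[brain_i, , drop = FALSE]),
    csf = colMeans(flat[csf_i, , drop = FALSE]),
    wm = colMeans(flat[wm_i, , drop = FALSE]))
}

#' Read / write confounds as TSV
#'
#' Columns `mot1..mot6`, `global`, `csf`, `wm`; missing columns are flagged
#' absent in the resulting [confound_set()].
#' @param path TSV file path.
#' @param c a [confound_set()] (for writing).
#' @return A [confound_set()] (reading) or `path` invisibly (writing).
#' @export
read_confounds_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  motcols <- paste0("mot", 1:6)
  confound_set(
    motion = if (all(motcols %in% names(d))) as.matrix(d[motcols]) else NULL,
    global = if ("global" %in% names(d)) d$global else NULL,
    csf = if ("csf" %in% names(d)) d$csf else NULL,
    wm = if ("wm" %in% names(d)) d$wm else NULL)
}

#' @rdname read_confounds_tsv
#' @export
write_confounds_tsv <- function(c, path) {
  n <- nrow(confound_matrix(c, n = if (!is.null(c$global)) length(c$global) else nrow(c$motion)))
  utils::write.table(as.data.frame(confound_matrix(c, n)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discard initial frames
#'
#' Removes the first `k` frames of a 4D acquisition (magnetisation
#' equilibration period); all metadata is preserved.
#'
#' @param v a [ts_volume()].
#' @param k number of frames to drop (`0 <= k < T`).
#' @return The shortened [ts_volume()].
#' @export
discard_initial_volumes <- function(v, k) {
  stopifnot(inherits(v, "ts_volume"))
  T <- n_frames(v)
  if (k >= T) stop("empty series: cannot discard ", k, " of ", T, " frames")
  if (k == 0) return(v)
  v$data <- v$data[, , , (k + 1):T, drop = FALSE]
  v
}

#' Regress confounds out of every voxel time series
#'
#' Replaces each voxel series by its ordinary-least-squares residual on the
#' confound regressors plus an intercept. With a rank-deficient confound
#' matrix a warning is raised and the minimum-norm (pseudoinverse) fit is
#' used; residuals are identical either way.
#'
#' @param v a [ts_volume()].
#' @param confounds a [confound_set()].
#' @return The residualised [ts_volume()].
#' @export
regress_confounds <- function(v, confounds) {
  stopifnot(inherits(v, "ts_volume"), inherits(confounds, "confound_set"))
  d <- dim(v$data)
  T <- d[4]
  X <- cbind(intercept = 1, confound_matrix(confounds, T))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using pseudoinverse fit")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  flat <- matrix(v$data, prod(d[1:3]), T)
  res <- t(qr.resid(qrX, t(flat)))
  v$data <- array(res, d)
  v
}

#' High-pass temporal filter (discrete-cosine basis projection)
#'
#' Removes fluctuations slower than `cutoff_s` by projecting out the
#' low-order discrete cosine basis functions with frequency below
#' `1/cutoff_s` (the SPM-style cutoff-matched DCT set). A pure sinusoid of
#' period `2 * cutoff_s` is attenuated by at least 90\% in amplitude; one of
#' period `cutoff_s / 4` is retained within 10\%.
#'
#' @param v a [ts_volume()].
#' @param cutoff_s cutoff period in seconds; must exceed `2 * TR`.
#' @param preserve_mean if `TRUE` the temporal mean is added back after
#'   filtering; by default the mean (DC component) is removed too.
#' @return The filtered [ts_volume()].
#' @export
highpass_filter <- function(v, cutoff_s, preserve_mean = FALSE) {
  stopifnot(inherits(v, "ts_volume"))
  if (cutoff_s <= 2 * v$tr) stop("invalid parameter: cutoff must exceed 2 * TR")
  d <- dim(v$data)
  T <- d[4]
  K <- floor(2 * T * v$tr / cutoff_s)   # basis k has frequency k / (2 T TR)
  flat <- matrix(v$data, prod(d[1:3]), T)
  mu <- rowMeans(flat)
  flat <- flat - mu
  if (K >= 1) {
    t0 <- seq_len(T) - 0.5
    B <- sapply(seq_len(K), function(k) cos(pi * k * t0 / T))
    B <- sweep(B, 2, sqrt(colSums(B^2)), `/`)        # orthonormal over time
    flat <- flat - (flat %*% B) %*% t(B)
  }
  if (preserve_mean) flat <- flat + mu
  v$data <- array(flat, d)
  v
}

# row-normalized truncated 1D Gaussian kernel matrix for one axis
gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma_vox^2)))
  r <- ceiling(4 * sigma_vox)
  K[abs(outer(idx, idx, `-`)) > r] <- 0
  K / rowSums(K)                                     # edge renormalization
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, truncated at 4 sigma and
#' edge-renormalized so that total intensity is conserved to within 1\%.
#' `fwhm_mm = 0` is the identity.
#'
#' @param v a [ts_volume()].
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @return The smoothed [ts_volume()].
#' @export
spatial_smooth <- function(v, fwhm_mm) {
  stopifnot(inherits(v, "ts_volume"))
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(v)
  d <- dim(v$data)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / v$voxel_mm   # sigma in voxels, per axis
  Kx <- gauss_kernel_matrix(d[1], sig[1])
  Ky <- gauss_kernel_matrix(d[2], sig[2])
  Kz <- gauss_kernel_matrix(d[3], sig[3])
  X <- matrix(v$data, d[1], prod(d[2:4]))              # x first
  X <- Kx %*% X
  A <- array(X, d)
  A <- aperm(A, c(2, 1, 3, 4))                         # y first
  X <- Ky %*% matrix(A, d[2], prod(d[c(1, 3, 4)]))
  A <- aperm(array(X, d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  A <- aperm(A, c(3, 1, 2, 4))                         # z first
  X <- Kz %*% matrix(A, d[3], prod(d[c(1, 2, 4)]))
  A <- aperm(array(X, d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  v$data <- A
  v
}

#' Mask and down-sample to a node-by-time matrix
#'
#' Aggregates `factor^3` blocks of source voxels (intersected with the mask)
#' into nodes by block-mean, returning one time series per surviving node
#' plus a node-to-coordinate lookup used to report mm coordinates.
#'
#' @param v a [ts_volume()].
#' @param mask logical 3D array (defaults to the volume's own mask).
#' @param factor integer down-sampling factor (`>= 1`).
#' @return An object of class `node_ts`: list with `series` (nodes x time),
#'   `coords` (1-based block coordinates in the down-sampled grid), `mm`
#'   (block-centre mm coordinates), `n_src` (source voxels per node),
#'   `factor`, `dim` (down-sampled grid dimensions), `voxel_mm`.
#' @export
mask_and_downsample <- function(v, mask = v$mask, factor = 1L) {
  stopifnot(inherits(v, "ts_volume"), factor >= 1)
  factor <- as.integer(factor)
  d <- dim(v$data)
  if (!any(mask)) stop("empty mask: no voxels survive")
  dd <- ceiling(d[1:3] / factor)
  src <- which(mask)
  co <- arrayInd(src, d[1:3])
  blk <- (co - 1L) %/% factor + 1L
  key <- blk[, 1] + dd[1] * (blk[, 2] - 1L) + dd[1] * dd[2] * (blk[, 3] - 1L)
  ukey <- sort(unique(key))
  grp <- match(key, ukey)
  n_node <- length(ukey)
  flat <- matrix(v$data, prod(d[1:3]), d[4])[src, , drop = FALSE]
  cnt <- tabulate(grp, n_node)
  series <- rowsum(flat, grp) / cnt
  bco <- arrayInd(ukey, dd)
  ctr_src <- (bco - 1) * factor + (factor + 1) / 2        # block centre in source voxels
  mm <- voxel_to_mm(ctr_src, v$voxel_mm, v$origin_mm)
  structure(list(series = unname(series), coords = bco, mm = mm,
                 n_src = cnt, factor = factor, dim = dd,
                 voxel_mm = v$voxel_mm * factor),
            class = "node_ts")
}

#' @export
print.node_ts <- function(x, ...) {
  cat(sprintf("<node_ts> %d nodes x %d frames (factor %d)\n",
              nrow(x$series), ncol(x$series), x$factor))
  invisible(x)
}
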