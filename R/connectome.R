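#' Pearson correlation matrix of node time series
#'
#' Correlates all node pairs. Constant series yield undefined coefficients;
#' the affected nodes are recorded in the `excluded` attribute and their
#' rows/columns set to `NA` (they can never enter a thresholded graph).
#' Pairwise correlations may be computed in node blocks; the result is
#' independent of block size.
#'
#' @param ts nodes x time numeric matrix (or a `node_ts`).
#' @param block optional block size (number of nodes per block) for
#'   memory-bounded computation; `NULL` computes in one shot.
#' @return An N x N symmetric matrix of class `correlation_matrix` with unit
#'   diagonal and an `excluded` integer attribute.
#' @export
correlation_matrix <- function(ts, block = NULL) {
  if (inherits(ts, "node_ts")) ts <- ts$series
  stopifnot(is.matrix(ts))
  if (ncol(ts) < 3) stop("insufficient data: need at least 3 time points")
  sds <- apply(ts, 1, sd)
  excluded <- which(sds == 0 | !is.finite(sds))
  Z <- ts - rowMeans(ts)
  nrm <- sqrt(rowSums(Z^2))
  nrm[nrm == 0] <- NA
  Z <- Z / nrm
  n <- nrow(Z)
  if (is.null(block) || block >= n) {
    R <- tcrossprod(Z)
  } else {
    R <- matrix(NA_real_, n, n)
    starts <- seq(1, n, by = block)
    for (a in starts) {
      ia <- a:min(a + block - 1, n)
      for (b in starts) {
        if (b < a) next
        ib <- b:min(b + block - 1, n)
        blk <- tcrossprod(Z[ia, , drop = FALSE], Z[ib, , drop = FALSE])
        R[ia, ib] <- blk
        R[ib, ia] <- t(blk)
      }
    }
  }
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  if (length(excluded)) {
    R[excluded, ] <- NA
    R[, excluded] <- NA
    diag(R)[excluded] <- 1
  }
  structure(R, class = c("correlation_matrix", "matrix"),
            excluded = as.integer(excluded))
}

# number of edges retained at density d for an N-node graph (round-half-even)
edges_at_density <- function(N, d) as.integer(round(d * N * (N - 1) / 2))

# upper-triangle pair indices ordered by decreasing |R| with deterministic
# tie-break by ascending (i, j); returns list(i, j, absr) for all pairs
ordered_pairs <- function(R) {
  N <- nrow(R)
  ut <- which(upper.tri(R))
  a <- abs(R[ut])
  a[is.na(a)] <- -Inf                     # excluded nodes never enter
  j <- ((ut - 1L) %/% N) + 1L
  i <- ut - (j - 1L) * N
  o <- order(-a, i, j)
  list(i = i[o], j = j[o], absr = a[o])
}

#' Threshold a correlation matrix at a fixed link density
#'
#' Keeps exactly `M = round(d * N * (N - 1) / 2)` edges with the largest
#' absolute correlation (positive and negative correlations both count);
#' ties at the cut are broken by ascending node-index pair order. The
#' realized threshold `t_d` (smallest retained `|R|`) is subject-specific.
#'
#' @param R a [correlation_matrix()].
#' @param d link density in `(0, 1]`.
#' @return An object of class `density_graph`: list with `density`,
#'   `threshold`, `M`, `edges` (M x 2 matrix, i < j), `n_nodes`.
#' @export
threshold_at_density <- function(R, d) {
  if (d <= 0 || d > 1) stop("invalid density: must be in (0, 1]")
  N <- nrow(R)
  M <- edges_at_density(N, d)
  op <- ordered_pairs(R)
  keep <- seq_len(M)
  structure(list(density = d, threshold = if (M > 0) op$absr[M] else Inf,
                 M = M, edges = cbind(i = op$i[keep], j = op$j[keep]),
                 n_nodes = N),
            class = "density_graph")
}

#' @export
print.density_graph <- function(x, ...) {
  cat(sprintf("<density_graph> N = %d, density %.3g, M = %d edges, |R| threshold %.4f\n",
              x$n_nodes, x$density, x$M, x$threshold))
  invisible(x)
}

#' Nodal degree map of a thresholded graph
#'
#' @param g a [threshold_at_density()] result.
#' @return Integer vector: the number of incident edges per node.
#' @export
degree_map <- function(g) {
  stopifnot(inherits(g, "density_graph"))
  tabulate(c(g$edges[, 1], g$edges[, 2]), g$n_nodes)
}

#' Degree maps across a density sweep
#'
#' Computes the correlation matrix once, orders all node pairs once, and
#' cuts the ordered edge list at each density, so edge sets are nested
#' across densities and each node's degree is non-decreasing in density.
#'
#' @param ts nodes x time matrix (or `node_ts`), or a precomputed
#'   [correlation_matrix()].
#' @param densities ascending density grid, e.g. [density_grid()].
#' @return Object of class `degree_sweep`: list with `degree` (nodes x
#'   densities integer matrix), `densities`, `M` (edges per density),
#'   `thresholds` (realized `t_d` per density).
#' @export
degree_sweep <- function(ts, densities = density_grid()) {
  if (length(densities) == 0 || is.unsorted(densities))
    stop("density grid must be nonempty and ascending")
  R <- if (inherits(ts, "correlation_matrix")) ts else correlation_matrix(ts)
  N <- nrow(R)
  op <- ordered_pairs(R)
  M <- vapply(densities, function(d) {
    if (d <= 0 || d > 1) stop("invalid density: must be in (0, 1]")
    edges_at_density(N, d)
  }, integer(1))
  deg <- matrix(0L, N, length(densities),
                dimnames = list(NULL, paste0("d", densities)))
  thr <- numeric(length(densities))
  for (k in seq_along(densities)) {
    keep <- seq_len(M[k])
    deg[, k] <- tabulate(c(op$i[keep], op$j[keep]), N)
    thr[k] <- if (M[k] > 0) op$absr[M[k]] else Inf
  }
  structure(list(degree = deg, densities = densities, M = M, thresholds = thr),
            class = "degree_sweep")
}

#' @export
print.degree_sweep <- function(x, ...) {
  cat(sprintf("<degree_sweep> %d nodes x %d densities (%.3g..%.3g)\n",
              nrow(x$degree), length(x$densities),
              min(x$densities), max(x$densities)))
  invisible(x)
}

#' Mean degree count over a region of interest
#'
#' @param s a [degree_sweep()] result (or a nodes x densities matrix).
#' @param roi integer node indices of the region.
#' @param d density at which to read the sweep; must be on the grid.
#' @return Mean per-voxel degree count over the ROI at density `d`.
#' @export
roi_mean_degree <- function(s, roi, d) {
  deg <- if (inherits(s, "degree_sweep")) s$degree else s
  dens <- if (inherits(s, "degree_sweep")) s$densities else NULL
  if (length(roi) == 0) stop("empty roi")
  if (any(roi < 1 | roi > nrow(deg))) stop("roi indices outside node set")
  k <- if (is.null(dens)) d else {
    kk <- which(abs(dens - d) < 1e-9)
    if (length(kk) != 1) stop("density ", d, " not on the sweep grid")
    kk
  }
  mean(deg[roi, k])
}
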