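#' TFCE parameters
#'
#' @param E extent exponent (> 0).
#' @param H height exponent (> 0).
#' @param n_steps number of height-integration steps (>= 10).
#' @param connectivity neighbourhood: 6, 18 or 26.
#' @return An object of class `tfce_params`. Defaults are the standard
#'   published TFCE settings (E = 0.5, H = 2, 26-connectivity).
#' @export
tfce_params <- function(E = 0.5, H = 2, n_steps = 100L, connectivity = 26L) {
  if (E <= 0 || H <= 0) stop("TFCE exponents must be positive")
  if (n_steps < 10) stop("need at least 10 height steps")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Neighbourhood structure over a node set
#'
#' Builds the (CSR) adjacency of grid neighbours among a set of voxel nodes,
#' used by TFCE and connected-component labelling.
#'
#' @param coords n x 3 matrix of 1-based voxel coordinates (e.g. the
#'   `coords` of a `node_ts`).
#' @param connectivity 6, 18 or 26.
#' @return An object of class `node_neighbors`.
#' @export
node_neighbors <- function(coords, connectivity = 26L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  nb <- build_neighbors_cpp(coords, as.integer(connectivity))
  structure(list(idx = nb$idx, ptr = nb$ptr, n = nb$n, coords = coords,
                 connectivity = as.integer(connectivity)),
            class = "node_neighbors")
}

#' Two-sample t statistic map
#'
#' Pooled-variance two-sample t per voxel (df = nA + nB - 2), sign
#' convention A - B. Voxels with zero pooled variance get t = 0 and are
#' listed in the `zero_variance` attribute.
#'
#' @param groupA,groupB nodes x subjects matrices of per-subject maps.
#' @return Numeric t map with attributes `df` and `zero_variance`.
#' @export
tstat_map <- function(groupA, groupB) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  nA <- ncol(groupA); nB <- ncol(groupB)
  if (nA < 2 || nB < 2) stop("need at least 2 subjects per group")
  if (nrow(groupA) != nrow(groupB)) stop("groups must share the node set")
  mA <- rowMeans(groupA); mB <- rowMeans(groupB)
  vA <- rowSums((groupA - mA)^2); vB <- rowSums((groupB - mB)^2)
  sp2 <- (vA + vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  zv <- which(se == 0)
  t[zv] <- 0
  attr(t, "df") <- nA + nB - 2
  attr(t, "zero_variance") <- zv
  t
}

#' Threshold-free cluster enhancement
#'
#' TFCE integrates, over height steps h from 0 to the map maximum,
#' `e(v, h)^E * h^H * dh`, where `e(v, h)` is the extent of the
#' suprathreshold connected component containing v at height h. Negative
#' map values are enhanced by applying the same integral to the negated
#' map; the result is returned signed.
#'
#' @param stat numeric statistic map over the node set.
#' @param nbr a [node_neighbors()] structure.
#' @param params a [tfce_params()].
#' @return Signed TFCE map (positive part minus the enhancement of the
#'   negated map's positive part).
#' @export
tfce_enhance <- function(stat, nbr, params = tfce_params()) {
  stopifnot(inherits(nbr, "node_neighbors"), inherits(params, "tfce_params"))
  if (length(stat) != nbr$n) stop("map length does not match neighbour structure")
  if (any(!is.finite(stat))) stop("statistic map must be finite")
  pos <- tfce_cpp(pmax(stat, 0), nbr$idx, nbr$ptr, params$E, params$H, params$n_steps)
  neg <- tfce_cpp(pmax(-stat, 0), nbr$idx, nbr$ptr, params$E, params$H, params$n_steps)
  pos - neg
}

# all two-group label arrangements as a logical matrix (subjects x arrangements);
# TRUE marks membership of group A. First column is the observed labelling.
all_arrangements <- function(labels_A, n) {
  nA <- length(labels_A)
  combs <- combn(n, nA)
  obs <- which(apply(combs, 2, function(cc) identical(sort(cc), sort(labels_A))))
  ord <- c(obs, setdiff(seq_len(ncol(combs)), obs))
  combs[, ord, drop = FALSE]
}

#' Permutation FWE-corrected group inference with TFCE
#'
#' For each voxel, compares the observed TFCE score against the permutation
#' distribution of the image-wide maximum TFCE score (max-statistic FWE
#' correction). Both contrast signs are evaluated as one-sided max-null
#' tests; the reported corrected p is `min(1, 2 * min(p_pos, p_neg))`, so
#' `p < alpha` corresponds to one-sided significance at `alpha / 2`. When
#' the number of distinct group-A assignments is at most `n_perm`, all
#' arrangements are enumerated (exhaustive mode, p = count / total);
#' otherwise `n_perm` random permutations are drawn and the add-one
#' estimator `p = (1 + #exceedances) / (n_perm + 1)` is used.
#'
#' @param maps nodes x subjects matrix of per-subject degree maps.
#' @param labels length-`n_subjects` two-level grouping (factor, character
#'   or logical); the first level / `TRUE` is group A.
#' @param nbr a [node_neighbors()].
#' @param n_perm number of permutations (>= 100 recommended).
#' @param params a [tfce_params()].
#' @param seed integer seed for the permutation stream (required for
#'   reproducible p-maps).
#' @return Object of class `group_contrast`: `t`, `tfce`, `p` (corrected,
#'   two-sided), `p_pos`, `p_neg`, `sign` (+1 where A > B direction is the
#'   more extreme), `n_perm`, `exhaustive`, `max_null_pos/neg`.
#' @export
permutation_fwe <- function(maps, labels, nbr, n_perm = 5000L,
                            params = tfce_params(), seed) {
  maps <- as.matrix(maps)
  if (missing(seed)) stop("a permutation seed is required")
  lab <- as.factor(labels)
  if (nlevels(lab) != 2) stop("labels must have exactly two levels")
  n <- ncol(maps)
  if (length(lab) != n) stop("one label per subject required")
  idxA <- which(lab == levels(lab)[1])
  nA <- length(idxA); nB <- n - nA
  if (nA < 1 || nB < 1) stop("degenerate labels: one group is empty")
  if (nA < 2 || nB < 2) stop("need at least 2 subjects per group")

  n_arr <- choose(n, nA)
  if (n_arr < 2) stop("fewer than 2 distinct label arrangements")
  exhaustive <- n_arr <= n_perm

  tfce_of <- function(ia) {
    t <- tstat_map(maps[, ia, drop = FALSE], maps[, -ia, drop = FALSE])
    tfce_enhance(as.numeric(t), nbr, params)
  }
  t_obs <- tstat_map(maps[, idxA, drop = FALSE], maps[, -idxA, drop = FALSE])
  f_obs <- tfce_enhance(as.numeric(t_obs), nbr, params)

  if (exhaustive) {
    arr <- all_arrangements(idxA, n)
    K <- ncol(arr)
    maxpos <- maxneg <- numeric(K)
    for (k in seq_len(K)) {
      f <- if (k == 1) f_obs else tfce_of(arr[, k])
      maxpos[k] <- max(f, 0)
      maxneg[k] <- max(-f, 0)
    }
    p_pos <- vapply(pmax(f_obs, 0), function(x) sum(maxpos >= x) / K, numeric(1))
    p_neg <- vapply(pmax(-f_obs, 0), function(x) sum(maxneg >= x) / K, numeric(1))
  } else {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
    maxpos <- maxneg <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      ia <- sample.int(n, nA)
      f <- tfce_of(ia)
      maxpos[k] <- max(f, 0)
      maxneg[k] <- max(-f, 0)
    }
    p_pos <- vapply(pmax(f_obs, 0), function(x) (1 + sum(maxpos >= x)) / (n_perm + 1), numeric(1))
    p_neg <- vapply(pmax(-f_obs, 0), function(x) (1 + sum(maxneg >= x)) / (n_perm + 1), numeric(1))
  }
  structure(list(t = as.numeric(t_obs), tfce = f_obs,
                 p = pmin(1, 2 * pmin(p_pos, p_neg)),
                 p_pos = p_pos, p_neg = p_neg,
                 sign = ifelse(p_pos <= p_neg, 1L, -1L),
                 n_perm = if (exhaustive) n_arr else n_perm,
                 exhaustive = exhaustive,
                 max_null_pos = maxpos, max_null_neg = maxneg),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast> %d voxels, %s%d permutations, min corrected p = %.4g\n",
              length(x$t), if (x$exhaustive) "exhaustive " else "", x$n_perm,
              min(x$p)))
  invisible(x)
}

#' Cross-density conjunction mask
#'
#' A voxel enters the conjunction when its corrected p is below `alpha`
#' with a consistent contrast sign in at least `min_count` of the supplied
#' density-wise contrasts.
#'
#' @param contrasts list of [permutation_fwe()] results (one per density),
#'   or a list with elements `p` and `sign`.
#' @param alpha FWE level.
#' @param min_count minimum number of densities (e.g. 8 of 10).
#' @return List with `mask` (logical per voxel), `hits` (per-voxel count of
#'   significant densities in the dominant sign), `sign`.
#' @export
conjunction_mask <- function(contrasts, alpha = 0.05, min_count = 8L) {
  if (min_count > length(contrasts))
    stop("min_count exceeds the number of density maps")
  P <- sapply(contrasts, `[[`, "p")
  S <- sapply(contrasts, `[[`, "sign")
  if (is.null(dim(P))) { P <- matrix(P, ncol = length(contrasts)); S <- matrix(S, ncol = length(contrasts)) }
  sigpos <- rowSums(P < alpha & S > 0)
  signeg <- rowSums(P < alpha & S < 0)
  hits <- pmax(sigpos, signeg)
  list(mask = hits >= min_count, hits = hits,
       sign = ifelse(sigpos >= signeg, 1L, -1L))
}

#' Cluster table of a mask
#'
#' Labels connected components of a voxel mask and reports, per cluster,
#' the extent, peak |t| and the peak's mm coordinates.
#'
#' @param mask logical vector over the node set.
#' @param stat the statistic map used for peaks (e.g. a t map).
#' @param nbr a [node_neighbors()].
#' @param mm optional nodes x 3 matrix of mm coordinates (e.g. `node_ts$mm`);
#'   voxel coordinates are reported if absent.
#' @return data.frame with columns `cluster`, `extent`, `peak_stat`,
#'   `peak_x`, `peak_y`, `peak_z` (mm), sorted by decreasing extent. Empty
#'   mask yields an empty table.
#' @export
cluster_report <- function(mask, stat, nbr, mm = NULL) {
  stopifnot(inherits(nbr, "node_neighbors"))
  lab <- label_components_cpp(as.logical(mask), nbr$idx, nbr$ptr)
  if (all(lab == 0))
    return(data.frame(cluster = integer(0), extent = integer(0),
                      peak_stat = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0)))
  if (is.null(mm)) mm <- nbr$coords
  rows <- lapply(sort(unique(lab[lab > 0])), function(cl) {
    vv <- which(lab == cl)
    pk <- vv[which.max(abs(stat[vv]))]
    data.frame(cluster = cl, extent = length(vv), peak_stat = stat[pk],
               peak_x = mm[pk, 1], peak_y = mm[pk, 2], peak_z = mm[pk, 3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$extent), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
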