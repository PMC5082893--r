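#' Additive placebo/drug decomposition of drug-arm responses
#'
#' Under the additive model (empirical analgesia = predicted placebo
#' response + drug response + error, with the error taken as zero), the
#' per-subject drug component is the empirical analgesia minus the placebo
#' response predicted from the discovery fit. Subjects are categorized as
#' `enhanced` (delta > epsilon), `diminished` (delta < -epsilon) or
#' `neutral`.
#'
#' @param model a [fit_discovery_model()] result (fitted on discovery data
#'   only).
#' @param empirical per-subject empirical percent analgesia (drug arm).
#' @param degree per-subject ROI degree counts feeding the placebo
#'   prediction.
#' @param ids optional subject identifiers.
#' @param epsilon neutrality half-width in percent analgesia (default 10).
#' @return Object of class `placebo_decomposition`: data.frame with `id`,
#'   `empirical`, `predicted`, `delta`, `category`; `epsilon` attribute.
#'   Subjects with a missing degree count are excluded with a warning.
#' @export
decompose <- function(model, empirical, degree, ids = NULL, epsilon = 10) {
  stopifnot(inherits(model, "prediction_model"))
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(empirical))
  miss <- is.na(degree) | is.na(empirical)
  if (any(miss)) {
    warning(sum(miss), " subject(s) excluded for missing degree or outcome")
    ids <- ids[!miss]; empirical <- empirical[!miss]; degree <- degree[!miss]
  }
  predicted <- predict_outcome(model, degree)
  delta <- empirical - predicted
  category <- ifelse(delta > epsilon, "enhanced",
                     ifelse(delta < -epsilon, "diminished", "neutral"))
  out <- data.frame(id = ids, empirical = empirical, predicted = predicted,
                    delta = delta, category = category,
                    stringsAsFactors = FALSE)
  structure(out, epsilon = epsilon,
            class = c("placebo_decomposition", "data.frame"))
}

#' Select mostly-drug responders
#'
#' Subjects whose empirical analgesia clears the responder threshold while
#' their predicted placebo response stays below the ceiling: their response
#' is attributed mostly to the drug.
#'
#' @param d a [decompose()] result.
#' @param resp_threshold empirical analgesia threshold, percent (default 20).
#' @param placebo_ceiling maximum predicted placebo response, percent
#'   (default 5).
#' @return The selected rows of `d` (possibly empty).
#' @export
select_pure_drug_responders <- function(d, resp_threshold = 20,
                                        placebo_ceiling = 5) {
  stopifnot(inherits(d, "placebo_decomposition"))
  d[d$empirical >= resp_threshold & d$predicted < placebo_ceiling, ,
    drop = FALSE]
}

#' Exact two-sided Mann-Whitney test
#'
#' Enumerates every assignment of the combined (mid-)ranks to the smaller
#' group and computes the two-sided p as `min(1, 2 * min(P(U <= u),
#' P(U >= u)))` from the exact null distribution. Falls back to the normal
#' approximation when the arrangement count exceeds `max_arrangements`.
#'
#' @param x,y the two samples.
#' @param max_arrangements enumeration cap (default 20000).
#' @return List with `u` (U statistic of `x`), `p`, `exact`,
#'   `n_arrangements`.
#' @export
mann_whitney_exact <- function(x, y, max_arrangements = 20000) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be nonempty")
  n_arr <- choose(nx + ny, nx)
  if (n_arr < 2) stop("fewer than 2 distinct arrangements")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (n_arr <= max_arrangements) {
    combs <- combn(nx + ny, nx)
    us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
    list(u = u_obs, p = p, exact = TRUE, n_arrangements = n_arr)
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sig <- sqrt(nx * ny / 12 * ((nx + ny + 1) -
      sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))))
    z <- (u_obs - mu) / sig
    list(u = u_obs, p = min(1, 2 * pnorm(-abs(z))), exact = FALSE,
         n_arrangements = n_arr)
  }
}

#' Search for a drug-predictive region
#'
#' Voxel-wise exact two-sided Mann-Whitney contrast between the
#' mostly-drug responders and the remaining responders. The candidate
#' region is the largest connected component among the voxels attaining
#' the top rank statistic in the drug-predictive direction (degree counts
#' higher in the mostly-drug responders); the reported p is the exact
#' two-sided test on the region's mean degree counts.
#'
#' @param pure_maps nodes x subjects degree maps of the mostly-drug
#'   responders.
#' @param other_maps nodes x subjects degree maps of the other responders.
#' @param nbr a [node_neighbors()].
#' @return Object of class `drug_region_result`: `region` (node indices),
#'   `voxel_p` (per-voxel exact two-sided p), `voxel_u` (per-voxel U of the
#'   mostly-drug group), `u`, `p` (exact two-sided MW p on the region mean
#'   degrees), `pure_degrees`, `other_degrees`.
#' @export
drug_region_search <- function(pure_maps, other_maps, nbr) {
  pure_maps <- as.matrix(pure_maps); other_maps <- as.matrix(other_maps)
  n1 <- ncol(pure_maps); n2 <- ncol(other_maps)
  if (n1 < 1 || n2 < 1) stop("both subsets must be nonempty")
  if (choose(n1 + n2, n1) < 2) stop("too few subjects for any permutation")
  nv <- nrow(pure_maps)
  mw_all <- lapply(seq_len(nv), function(v)
    mann_whitney_exact(pure_maps[v, ], other_maps[v, ]))
  voxel_p <- vapply(mw_all, `[[`, numeric(1), "p")
  voxel_u <- vapply(mw_all, `[[`, numeric(1), "u")
  cand <- voxel_u >= max(voxel_u) - 1e-9
  lab <- label_components_cpp(cand, nbr$idx, nbr$ptr)
  sizes <- tabulate(lab[lab > 0])
  region <- which(lab == which.max(sizes))
  pure_deg <- colMeans(pure_maps[region, , drop = FALSE])
  other_deg <- colMeans(other_maps[region, , drop = FALSE])
  mw <- mann_whitney_exact(pure_deg, other_deg)
  structure(list(region = region, voxel_p = voxel_p, voxel_u = voxel_u,
                 u = mw$u, p = mw$p,
                 pure_degrees = pure_deg, other_degrees = other_deg),
            class = "drug_region_result")
}

#' @export
print.drug_region_result <- function(x, ...) {
  cat(sprintf("<drug_region_result> %d-voxel region, exact MW p = %.4g\n",
              length(x$region), x$p))
  invisible(x)
}

#' Validate a drug region against placebo-corrected responses
#'
#' Pearson correlation (with p-value) between the region's degree counts
#' and the per-subject delta (empirical minus predicted placebo), per
#' outcome scale, over all drug-arm subjects.
#'
#' @param region_degrees per-subject region mean degree counts.
#' @param deltas named list of per-subject delta vectors, one per scale
#'   (e.g. `list(VAS = ..., WOMAC = ...)`).
#' @return Named list per scale: `r`, `p`, `n` (or `flag` when degrees are
#'   constant).
#' @export
validate_drug_region <- function(region_degrees, deltas) {
  if (!is.list(deltas)) deltas <- list(delta = deltas)
  lapply(deltas, function(dd) {
    ok <- complete.cases(region_degrees, dd)
    if (sum(ok) < 4) stop("need at least 4 subjects")
    x <- region_degrees[ok]; y <- dd[ok]
    if (sd(x) == 0)
      return(list(r = NA_real_, p = NA_real_, n = sum(ok),
                  flag = "constant degrees"))
    ct <- cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
}

#' Category counts of a decomposition
#'
#' @param d a [decompose()] result.
#' @return Named integer vector with counts for `enhanced`, `neutral`,
#'   `diminished`.
#' @export
categorize_arm <- function(d) {
  stopifnot(inherits(d, "placebo_decomposition"))
  cnt <- table(factor(d$category, levels = c("enhanced", "neutral", "diminished")))
  setNames(as.integer(cnt), names(cnt))
}
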