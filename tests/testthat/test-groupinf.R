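test_that("two-sample t maps match the textbook formula and are antisymmetric", {
  set.seed(41)
  A <- matrix(rnorm(10 * 4, mean = 1), 10, 4)
  B <- matrix(rnorm(10 * 5), 10, 5)
  t_ab <- tstat_map(A, B)
  # per-voxel hand-computed pooled-variance t
  for (v in c(1, 5, 10)) {
    nA <- 4; nB <- 5
    sp2 <- ((nA - 1) * var(A[v, ]) + (nB - 1) * var(B[v, ])) / (nA + nB - 2)
    t_hand <- (mean(A[v, ]) - mean(B[v, ])) / sqrt(sp2 * (1 / nA + 1 / nB))
    expect_equal(as.numeric(t_ab[v]), t_hand, tolerance = 1e-10)
    expect_equal(as.numeric(t_ab[v]),
                 unname(t.test(A[v, ], B[v, ], var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
  }
  expect_equal(attr(t_ab, "df"), 7)
  expect_equal(as.numeric(tstat_map(B, A)), -as.numeric(t_ab), tolerance = 1e-12)
  expect_equal(as.numeric(tstat_map(A, A)), rep(0, 10))
  # zero pooled variance flagged, not NaN
  A2 <- A; A2[3, ] <- 2; B2 <- B; B2[3, ] <- 2
  t2 <- tstat_map(A2, B2)
  expect_equal(as.numeric(t2[3]), 0)
  expect_equal(attr(t2, "zero_variance"), 3L)
})

test_that("TFCE of an isolated voxel approaches the closed-form h^3/3", {
  nbr <- grid_neighbors(3)
  st <- numeric(27)
  st[14] <- 2
  f <- tfce_enhance(st, nbr, tfce_params(E = 0.5, H = 2, n_steps = 20000L))
  expect_equal(f[14], 2^3 / 3, tolerance = 1e-3)
  expect_equal(tfce_enhance(numeric(27), nbr), numeric(27))
})

test_that("TFCE agrees with the naive per-threshold labelling oracle", {
  nbr <- grid_neighbors(5)
  co <- nbr$coords
  set.seed(42)
  for (rep in 1:2) {
    st <- pmax(rnorm(125, 0.3, 1), 0)
    p <- tfce_params(n_steps = 40L)
    f <- tfce_enhance(st, nbr, p)
    oracle <- tfce_naive(st, co, E = 0.5, H = 2, nsteps = 40)
    expect_equal(f, oracle, tolerance = 1e-8)
  }
  # two-voxel plateau
  st2 <- numeric(125); st2[c(62, 63)] <- 1.5
  f2 <- tfce_enhance(st2, nbr, tfce_params(n_steps = 50L))
  o2 <- tfce_naive(st2, co, nsteps = 50)
  expect_equal(f2, o2, tolerance = 1e-8)
  # negative lobes are enhanced on the negated map
  st3 <- rnorm(125)
  f3 <- tfce_enhance(st3, nbr, tfce_params(n_steps = 30L))
  expect_equal(f3[st3 > 0 | f3 > 0],
               tfce_naive(pmax(st3, 0), co, nsteps = 30)[st3 > 0 | f3 > 0],
               tolerance = 1e-8)
  expect_equal(-f3[f3 < 0],
               tfce_naive(pmax(-st3, 0), co, nsteps = 30)[f3 < 0],
               tolerance = 1e-8)
})

test_that("scaling a statistic map up never decreases TFCE values", {
  nbr <- grid_neighbors(4)
  set.seed(43)
  st <- rnorm(64)
  f1 <- abs(tfce_enhance(st, nbr))
  f2 <- abs(tfce_enhance(2.5 * st, nbr))
  expect_true(all(f2 >= f1 - 1e-10))
})

test_that("exhaustive permutation p-values equal full enumeration", {
  set.seed(44)
  nbr <- grid_neighbors(3)
  maps <- matrix(rnorm(27 * 8), 27, 8)
  maps[1:4, 1:4] <- maps[1:4, 1:4] + 2
  labels <- rep(c("g1", "g2"), each = 4)
  params <- tfce_params(n_steps = 20L)
  res <- permutation_fwe(maps, labels, nbr, n_perm = 100, params = params, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(8, 4))
  # independent enumeration oracle over all 70 arrangements
  combs <- combn(8, 4)
  mx_pos <- mx_neg <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    t_k <- tstat_map(maps[, combs[, k], drop = FALSE],
                     maps[, -combs[, k], drop = FALSE])
    f_k <- tfce_enhance(as.numeric(t_k), nbr, params)
    mx_pos[k] <- max(f_k, 0); mx_neg[k] <- max(-f_k, 0)
  }
  t_obs <- tstat_map(maps[, 1:4], maps[, 5:8])
  f_obs <- tfce_enhance(as.numeric(t_obs), nbr, params)
  p_pos_oracle <- sapply(pmax(f_obs, 0), function(x) mean(mx_pos >= x))
  p_neg_oracle <- sapply(pmax(-f_obs, 0), function(x) mean(mx_neg >= x))
  expect_equal(res$p_pos, p_pos_oracle, tolerance = 1e-12)
  expect_equal(res$p_neg, p_neg_oracle, tolerance = 1e-12)
  expect_equal(res$p, pmin(1, 2 * pmin(p_pos_oracle, p_neg_oracle)),
               tolerance = 1e-12)
})

test_that("sampled permutation p-values respect the add-one lower bound", {
  set.seed(45)
  nbr <- grid_neighbors(3)
  maps <- matrix(rnorm(27 * 14), 27, 14)
  maps[10:14, 1:7] <- maps[10:14, 1:7] + 4
  labels <- rep(c("a", "b"), each = 7)
  res <- permutation_fwe(maps, labels, nbr, n_perm = 199,
                         params = tfce_params(n_steps = 20L), seed = 3)
  expect_false(res$exhaustive)
  expect_true(all(res$p_pos >= 1 / 200))
  expect_true(all(res$p_neg >= 1 / 200))
  expect_equal(min(res$p_pos), 1 / 200)   # the planted effect attains the floor
  # reproducible given the seed
  res2 <- permutation_fwe(maps, labels, nbr, n_perm = 199,
                          params = tfce_params(n_steps = 20L), seed = 3)
  expect_identical(res$p, res2$p)
  expect_error(permutation_fwe(maps, rep("a", 14), nbr, n_perm = 99, seed = 1),
               "two levels")
})

test_that("conjunction mask counts consistent-sign significant densities", {
  mk <- function(p, s) list(p = p, sign = s)
  n <- 6
  set.seed(46)
  maps <- lapply(1:10, function(k)
    mk(runif(n), sample(c(-1L, 1L), n, replace = TRUE)))
  cj <- conjunction_mask(maps, alpha = 0.4, min_count = 8)
  # direct counting oracle
  P <- sapply(maps, `[[`, "p"); S <- sapply(maps, `[[`, "sign")
  hits_oracle <- pmax(rowSums(P < 0.4 & S > 0), rowSums(P < 0.4 & S < 0))
  expect_equal(cj$hits, hits_oracle)
  expect_equal(cj$mask, hits_oracle >= 8)
  # significant at 7/10 densities is excluded at min_count 8
  p7 <- c(rep(0.01, 7), rep(0.9, 3))
  maps7 <- lapply(seq_len(10), function(k) mk(p7[k], 1L))
  expect_false(conjunction_mask(maps7, 0.05, 8)$mask)
  expect_true(conjunction_mask(lapply(1:10, function(k) mk(0.01, 1L)), 0.05, 8)$mask)
  # a sign flip breaks the conjunction even when p is small
  s8 <- c(rep(1L, 8), -1L, -1L)
  maps8 <- lapply(seq_len(10), function(k) mk(0.01, s8[k]))
  expect_false(conjunction_mask(maps8, 0.05, 9)$mask)
  # shrinks with min_count
  cj1 <- conjunction_mask(maps, 0.4, 5)
  cj2 <- conjunction_mask(maps, 0.4, 6)
  expect_true(all(which(cj2$mask) %in% which(cj1$mask)))
  expect_error(conjunction_mask(maps, 0.05, 11), "exceeds")
})

test_that("cluster reports label components with peak statistics and mm coordinates", {
  nbr <- grid_neighbors(5)
  stat <- rnorm(125)
  mask <- rep(FALSE, 125)
  expect_equal(nrow(cluster_report(mask, stat, nbr)), 0)
  mask[3] <- TRUE
  r1 <- cluster_report(mask, stat, nbr)
  expect_equal(r1$extent, 1)
  expect_equal(r1$peak_stat, stat[3])
  # two disjoint blobs: corners of the grid
  co <- nbr$coords
  blob1 <- which(co[, 1] <= 2 & co[, 2] <= 2 & co[, 3] <= 2)
  blob2 <- which(co[, 1] >= 4 & co[, 2] >= 4 & co[, 3] >= 4)
  mask2 <- rep(FALSE, 125)
  mask2[c(blob1, blob2)] <- TRUE
  stat2 <- numeric(125)
  stat2[blob1] <- 2; stat2[blob1[1]] <- 5
  stat2[blob2] <- -3; stat2[blob2[4]] <- -7
  r2 <- cluster_report(mask2, stat2, nbr, mm = co * 4)
  expect_equal(nrow(r2), 2)
  expect_setequal(r2$extent, c(8, 8))
  expect_setequal(r2$peak_stat, c(5, -7))
  expect_equal(unlist(r2[r2$peak_stat == 5, c("peak_x", "peak_y", "peak_z")]),
               co[blob1[1], ] * 4, ignore_attr = TRUE)
})
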