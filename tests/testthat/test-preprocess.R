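test_that("initial-volume discarding trims frames and preserves metadata", {
  v <- ts_volume(array(rnorm(2 * 2 * 2 * 300), c(2, 2, 2, 300)), tr = 2.5)
  out <- discard_initial_volumes(v, 5)
  expect_equal(dim(out$data)[4], 295)
  expect_equal(out$data[, , , 1], v$data[, , , 6])
  expect_equal(out$tr, v$tr)
  expect_identical(discard_initial_volumes(v, 0), v)
  v10 <- ts_volume(array(rnorm(8 * 10), c(2, 2, 2, 10)), tr = 2.5)
  expect_error(discard_initial_volumes(v10, 10), "empty series")
})

test_that("confound regression leaves residuals orthogonal to regressors", {
  set.seed(11)
  T <- 40
  conf <- confound_set(motion = matrix(rnorm(T * 6), T, 6),
                       global = rnorm(T), csf = rnorm(T), wm = rnorm(T))
  v <- ts_volume(array(rnorm(3 * 3 * 3 * T), c(3, 3, 3, T)), tr = 2)
  out <- regress_confounds(v, conf)
  X <- cbind(1, placebonet:::confound_matrix(conf, T))
  flat <- matrix(out$data, 27, T)
  for (j in seq_len(ncol(X))) {
    ip <- abs(flat %*% X[, j])
    expect_true(all(ip <= 1e-8 * sqrt(rowSums(flat^2)) * sqrt(sum(X[, j]^2)) + 1e-12))
  }
})

test_that("a voxel equal to a confound is annihilated; residuals match the normal equations", {
  set.seed(12)
  T <- 30
  g <- rnorm(T)
  conf <- confound_set(global = g)
  dat <- array(rnorm(8 * T), c(2, 2, 2, T))
  dat[1, 1, 1, ] <- 3 * g + 2
  v <- ts_volume(dat, tr = 2)
  out <- regress_confounds(v, conf)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-10)
  # independent normal-equations oracle
  X <- cbind(1, g)
  beta <- solve(t(X) %*% X, t(X) %*% t(matrix(dat, 8, T)))
  res_oracle <- t(matrix(dat, 8, T)) - X %*% beta
  expect_equal(matrix(out$data, 8, T), t(res_oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-deficient confounds fall back to a pseudoinverse fit with a warning", {
  T <- 25
  g <- rnorm(T)
  conf <- confound_set(motion = cbind(g, g, matrix(0, T, 4)), wm = rnorm(T))
  v <- ts_volume(array(rnorm(8 * T), c(2, 2, 2, T)), tr = 2)
  expect_warning(out <- regress_confounds(v, conf), "rank-deficient")
  # zero columns only: output equals the mean-centred input
  conf0 <- confound_set(motion = matrix(0, T, 6))
  expect_warning(out0 <- regress_confounds(v, conf0), "rank-deficient")
  flat <- matrix(v$data, 8, T)
  expect_equal(matrix(out0$data, 8, T), flat - rowMeans(flat),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("high-pass filter removes slow fluctuations and keeps fast ones", {
  T <- 295; tr <- 2.5
  # constant series: DC removed (or preserved on request)
  vc <- sine_volume(rep(3, T), tr)
  expect_lt(max(abs(highpass_filter(vc, 150)$data)), 1e-10)
  expect_equal(as.numeric(highpass_filter(vc, 150, preserve_mean = TRUE)$data),
               rep(3, T), tolerance = 1e-10)
  # period 300 s (= 2 x cutoff): amplitude at the driving frequency down >= 90%
  x_slow <- sin(2 * pi * (1:T) * tr / 300 + 0.4)
  y_slow <- as.numeric(highpass_filter(sine_volume(x_slow, tr), 150)$data)
  expect_lte(amp_at(y_slow, 1 / 300, tr) / amp_at(x_slow, 1 / 300, tr), 0.1)
  # period 37.5 s (= cutoff / 4): retained within 10%
  x_fast <- sin(2 * pi * (1:T) * tr / 37.5 + 1.1)
  y_fast <- as.numeric(highpass_filter(sine_volume(x_fast, tr), 150)$data)
  expect_gte(amp_at(y_fast, 1 / 37.5, tr) / amp_at(x_fast, 1 / 37.5, tr), 0.9)
  expect_error(highpass_filter(sine_volume(rnorm(T), tr), 4), "invalid parameter")
})

test_that("Gaussian smoothing matches the closed-form kernel and conserves intensity", {
  d <- c(9, 9, 9)
  v0 <- ts_volume(array(100 + rnorm(prod(d) * 2), c(d, 2)), tr = 2,
                  voxel_mm = c(4, 4, 4))
  expect_identical(spatial_smooth(v0, 0), v0)
  # unit impulse in the centre: compare against the sampled-Gaussian product
  imp <- array(0, c(d, 2))
  imp[5, 5, 5, 1] <- 1
  vi <- ts_volume(imp, tr = 2, voxel_mm = c(4, 4, 4))
  out <- spatial_smooth(vi, 5)
  sig <- 5 / (2 * sqrt(2 * log(2))) / 4
  k1 <- exp(-((1:9) - 5)^2 / (2 * sig^2))
  k1[abs((1:9) - 5) > ceiling(4 * sig)] <- 0
  k1 <- k1 / sum(k1)
  expected <- outer(outer(k1, k1), k1)
  expect_equal(out$data[, , , 1], expected, tolerance = 1e-6)
  # total intensity conserved within 1% frame-wise
  sm <- spatial_smooth(v0, 6)
  for (t in 1:2)
    expect_lt(abs(sum(sm$data[, , , t]) - sum(v0$data[, , , t])) /
                abs(sum(v0$data[, , , t])), 0.01)
})

test_that("masking and down-sampling compute block means with a coordinate lookup", {
  d <- c(4, 4, 4)
  arr <- array(rnorm(prod(d) * 3), c(d, 3))
  v <- ts_volume(arr, tr = 2, voxel_mm = c(2, 2, 2))
  # factor 1, full mask: node count equals mask voxel count
  nts <- mask_and_downsample(v, factor = 1)
  expect_equal(nrow(nts$series), prod(d))
  # uniform volume: every node series constant
  vu <- ts_volume(array(rep(seq_len(3), each = prod(d)), c(d, 3)), tr = 2)
  ntu <- mask_and_downsample(vu, factor = 2)
  expect_true(all(apply(ntu$series, 1, function(x) all(x == x[1] + c(0, 1, 2)))))
  # checkerboard mask, factor 2: brute-force block means
  co <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  mask <- array((co[, 1] + co[, 2] + co[, 3]) %% 2 == 0, d)
  nts2 <- mask_and_downsample(v, mask, factor = 2)
  for (n in seq_len(nrow(nts2$coords))) {
    b <- nts2$coords[n, ]
    ix <- (b - 1) * 2 + 1
    vals <- sapply(1:3, function(t) {
      blk <- arr[ix[1]:(ix[1] + 1), ix[2]:(ix[2] + 1), ix[3]:(ix[3] + 1), t]
      m <- mask[ix[1]:(ix[1] + 1), ix[2]:(ix[2] + 1), ix[3]:(ix[3] + 1)]
      mean(blk[m])
    })
    expect_equal(unname(nts2$series[n, ]), vals, tolerance = 1e-12)
  }
  expect_error(mask_and_downsample(v, array(FALSE, d)), "empty mask")
})

test_that("after confound regression node series are uncorrelated with the global signal", {
  spec <- small_spec()
  v <- generate_volume(spec, pi = 1, seed = 77)
  v <- discard_initial_volumes(v, 5)
  conf <- extract_confounds(v, spec$wm, spec$csf)
  g <- conf$global
  out <- regress_confounds(v, conf)
  nts <- mask_and_downsample(out, out$mask, 1)
  cors <- abs(apply(nts$series, 1, function(x)
    if (sd(x) == 0) 0 else cor(x, g)))
  expect_lt(max(cors), 1e-6)
})

test_that("confound TSV round-trips with absent components flagged", {
  T <- 20
  conf <- confound_set(motion = matrix(rnorm(T * 6), T, 6), global = rnorm(T),
                       csf = rnorm(T), wm = rnorm(T))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_confounds_tsv(conf, path)
  back <- read_confounds_tsv(path)
  expect_equal(back$global, conf$global, tolerance = 1e-12)
  expect_equal(unname(as.matrix(back$motion)), unname(conf$motion), tolerance = 1e-12)
  expect_error(confound_set(global = rep(0, 5)), "constant zero")
})
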