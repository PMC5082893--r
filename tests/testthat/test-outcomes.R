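test_that("percent analgesia follows the baseline-normalized formula", {
  expect_equal(percent_analgesia(6, 3), 50)
  expect_equal(percent_analgesia(6, 6), 0)
  expect_equal(percent_analgesia(5, 4), 20)
  expect_equal(percent_analgesia(4, 6), -50)      # worsening allowed
  # scale invariance
  expect_equal(percent_analgesia(6.2, 2.7), percent_analgesia(62, 27))
  expect_error(percent_analgesia(0, 1), "undefined baseline")
})

test_that("responder classification is inclusive at the threshold and rounds half away", {
  # pre 5 -> post 4 is exactly 20%: a responder under the inclusive rule
  cr <- classify_responders(percent_analgesia(5, 4), 20)
  expect_true(cr$flags)
  x <- c(rep(30, 8), rep(5, 9))
  cr2 <- classify_responders(x, 20)
  expect_equal(cr2$n_responders, 8)
  expect_equal(cr2$percent, 47)                   # 8/17 prints as 47%
  expect_equal(classify_responders(c(rep(25, 8), rep(0, 11)), 20)$percent, 42)
  expect_equal(classify_responders(rep(0, 5), 20)$n_responders, 0)
  expect_equal(classify_responders(c(0.01, -3, 2), 1e-9)$n_responders, 2)
  expect_error(classify_responders(x, 0), "threshold")
})

test_that("discovery fit recovers exact lines and exposes diagnostics", {
  x <- c(1, 2, 3, 5, 8)
  m <- suppressWarnings(fit_discovery_model(x, 2 * x + 1))  # exact fit
  expect_equal(m$a, 2, tolerance = 1e-12)
  expect_equal(m$b, 1, tolerance = 1e-12)
  expect_equal(m$r2, 1)
  expect_false(m$underdetermined)
  m2 <- fit_discovery_model(c(1, 4), c(3, 9))
  expect_true(m2$underdetermined)
  expect_equal(m2$a, 2, tolerance = 1e-12)
  expect_error(fit_discovery_model(rep(2, 5), rnorm(5)), "zero variance")
  # prediction transfer y2 = a x2 + b
  expect_equal(predict_outcome(m, c(0, 10)), c(1, 21))
  m0 <- suppressWarnings(fit_discovery_model(x, rep(7, 5) + 0 * x))
  expect_equal(predict_outcome(m0, c(-5, 100)), c(7, 7), tolerance = 1e-9)
})

test_that("ROC AUC equals the concordant-pair count and pROC agrees", {
  # perfectly separated
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  # 3 vs 3 toy: exhaustive concordant-pair oracle with tie credit
  s <- c(3, 5, 7, 4, 5, 9); f <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pairs <- expand.grid(p = s[f], n = s[!f])
  oracle <- mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  expect_equal(roc_auc(s, f)$auc, oracle)
  skip_if_not_installed("pROC")
  set.seed(51)
  for (i in 1:3) {
    sc <- rnorm(40); fl <- rbinom(40, 1, 0.4) == 1
    expect_equal(roc_auc(sc, fl)$auc,
                 as.numeric(pROC::auc(pROC::roc(fl, sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
  expect_error(roc_auc(rnorm(5), rep(TRUE, 5)), "both classes")
})

test_that("labels independent of scores give chance-level AUC", {
  set.seed(52)
  sc <- rnorm(400)
  fl <- rbinom(400, 1, 0.5) == 1
  expect_lt(abs(roc_auc(sc, fl)$auc - 0.5), 0.08)
})

test_that("ROC comparison implements Hanley-McNeil with the stated CI formula", {
  eq <- roc_compare(0.8, 10, 10, 0.8, 12, 15)
  expect_equal(eq$diff, 0)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  cmp <- roc_compare(1.0, 15, 15, 0.5, 15, 15)
  expect_lt(cmp$p, 0.05)
  # CI = Z_(alpha/2) * sigma / sqrt(n): sigma 0.1, n 25, Z 1.96 -> 0.0392
  expect_equal(ci_halfwidth(0.1, 25), qnorm(0.975) * 0.1 / 5, tolerance = 1e-12)
  expect_equal(round(ci_halfwidth(0.1, 25), 4), 0.0392)
  # Hanley-McNeil SE oracle at AUC 0.5: sqrt((npos+nneg+1)/(12*npos*nneg))
  se0 <- roc_compare(0.5, 10, 12, 0.5, 10, 12)$se1
  expect_equal(se0, sqrt((0.25 + 9 * (1 / 3 - 0.25) + 11 * (1 / 3 - 0.25)) / 120),
               tolerance = 1e-12)
  expect_error(roc_compare(0.9, 0, 10, 0.8, 5, 5), "degenerate")
})

test_that("Fisher exact p matches stats::fisher.test across sampled tables", {
  # printed-style worked example: equal-rate responder tables give p near 1
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p, 2 / choose(10, 5))
  expect_equal(fisher_exact_2x2(3, 6, 2, 4)$p, 1)   # identical row proportions
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p, 1)   # zero margin flag
  set.seed(53)
  for (i in 1:200) {
    r1 <- sample(0:15, 1); a <- sample(0:r1, 1)
    r2 <- sample(0:15, 1); c <- sample(0:r2, 1)
    p_ref <- stats::fisher.test(matrix(c(a, r1 - a, c, r2 - c), 2,
                                       byrow = TRUE))$p.value
    expect_equal(fisher_exact_2x2(a, r1 - a, c, r2 - c)$p, min(1, p_ref),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("stepwise selection keeps informative predictors and prunes noise", {
  set.seed(54)
  n <- 60
  X <- data.frame(degree = rnorm(n), age = rnorm(n), bdi = rnorm(n),
                  pcs = rnorm(n))
  y <- 3 * X$degree + rnorm(n, sd = 0.8)
  res <- stepwise_regression(y, X)
  expect_equal(res$selected, "degree")
  expect_gt(res$unique_variance[["degree"]], 0.5)
  # exact linear in two orthogonal candidates: both selected, unique
  # variances partition R^2
  Q <- qr.Q(qr(cbind(X$degree, X$age))) * sqrt(n)
  X$degree <- Q[, 1]; X$age <- Q[, 2]
  y2 <- 2 * X$degree - 1.5 * X$age + rnorm(n, sd = 0.05)
  res2 <- stepwise_regression(y2, X)
  expect_true(all(c("degree", "age") %in% res2$selected))
  expect_lte(sum(res2$unique_variance[c("degree", "age")]), res2$r2 + 1e-2)
  expect_gt(res2$r2, 0.99)
  # pure-noise candidates: empty model in most runs
  empty <- sum(sapply(1:10, function(i) {
    set.seed(540 + i)
    Xn <- data.frame(matrix(rnorm(40 * 4), 40, 4))
    length(stepwise_regression(rnorm(40), Xn)$selected) == 0
  }))
  expect_gte(empty, 7)
  # collinear candidate dropped with a warning
  X3 <- X; X3$degree2 <- X$degree
  expect_warning(res3 <- stepwise_regression(y, X3), "collinear")
  expect_true("degree" %in% res3$selected || "degree2" %in% res3$selected)
})

test_that("pre/post correlation check separates marker-response from baseline severity", {
  set.seed(55)
  n <- 40
  deg <- rnorm(n, 100, 20)
  pre <- runif(n, 4, 9)
  post <- pre - 3 * (deg - 100) / 20 + rnorm(n, 0, 0.5)  # degree-driven response
  res <- pre_post_correlation_check(deg, pre, post)
  expect_lt(abs(res$pre$r), 0.35)
  expect_gt(abs(res$post$r), 0.4)
  same <- pre_post_correlation_check(deg, pre, pre)
  expect_equal(same$pre$r, same$post$r)
  const <- pre_post_correlation_check(rep(5, 10), runif(10, 4, 9), runif(10, 2, 9))
  expect_true(any(grepl("undefined", const$flag)))
  expect_error(pre_post_correlation_check(1:3, 1:3, 1:3), "at least 4")
})

test_that("subject outcome records derive entry score, analgesia and flags", {
  beh <- data.frame(id = c("a", "b"), arm = "placebo",
                    vas_pre_1 = c(6, 5), vas_pre_2 = c(7, 5), vas_pre_3 = c(5, 5),
                    vas_post = c(3, 4.5), womac_pre = c(50, 40),
                    womac_post = c(25, 40))
  out <- subject_outcomes(beh)
  expect_equal(out$vas_entry, c(6, 5))
  expect_equal(out$analgesia_vas, c(50, 10))
  expect_equal(out$analgesia_womac, c(50, 0))
  expect_equal(out$responder, c(TRUE, FALSE))
})

test_that("responder summary matches the t-interval oracle", {
  set.seed(56)
  x <- c(rnorm(12, 50, 15), rnorm(8, 5, 5))
  rs <- responder_summary(x, 20)
  resp <- x[x >= 20]
  tt <- t.test(resp)
  expect_equal(rs$mean, mean(resp))
  expect_equal(rs$ci, as.numeric(tt$conf.int), tolerance = 1e-10)
})
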