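#' Percent analgesia from pre/post pain scores
#'
#' `100 * (pre - post) / pre`. Negative values (worsening) are allowed;
#' a non-positive baseline is an error. Scale-invariant: rescaling pre and
#' post together leaves the result unchanged.
#'
#' @param pre baseline score (> 0); for VAS, the mean of up to three
#'   pre-treatment measurements.
#' @param post post-treatment score.
#' @return Percent analgesia (vectorised).
#' @export
percent_analgesia <- function(pre, post) {
  if (any(pre <= 0)) stop("undefined baseline: pre-treatment score must be > 0")
  100 * (pre - post) / pre
}

#' Build per-subject outcome records from a behavioral table
#'
#' Computes the VAS entry score (mean of available `vas_pre_1..3` columns),
#' percent analgesia on the VAS and WOMAC scales, and the responder flag
#' (inclusive threshold: analgesia >= `threshold`).
#'
#' @param behavior data.frame with columns `id`, `arm`, `vas_pre_1..3`,
#'   `vas_post`, `womac_pre`, `womac_post` and covariates.
#' @param threshold responder threshold, percent (default 20).
#' @return The table augmented with `vas_entry`, `analgesia_vas`,
#'   `analgesia_womac`, `responder`.
#' @export
subject_outcomes <- function(behavior, threshold = 20) {
  b <- behavior
  pre_cols <- intersect(paste0("vas_pre_", 1:3), names(b))
  b$vas_entry <- rowMeans(b[pre_cols], na.rm = TRUE)
  b$analgesia_vas <- ifelse(is.na(b$vas_post), NA,
                            percent_analgesia(b$vas_entry, b$vas_post))
  b$analgesia_womac <- ifelse(is.na(b$womac_post) | is.na(b$womac_pre), NA,
                              100 * (b$womac_pre - b$womac_post) / b$womac_pre)
  b$responder <- b$analgesia_vas >= threshold
  b
}

#' Classify responders at an analgesia threshold
#'
#' Inclusive rule: a subject with percent analgesia greater than or equal
#' to the threshold is a responder. The summary percentage is rounded half
#' away from zero to an integer (8/17 prints as 47\%).
#'
#' @param analgesia numeric vector of percent analgesia values.
#' @param threshold percent threshold in (0, 100].
#' @return List with `flags` (logical), `n_responders`, `n`, `percent`.
#' @export
classify_responders <- function(analgesia, threshold = 20) {
  if (threshold <= 0 || threshold > 100) stop("threshold must be in (0, 100]")
  flags <- analgesia >= threshold
  n_ok <- sum(!is.na(flags))
  list(flags = flags, n_responders = sum(flags, na.rm = TRUE), n = n_ok,
       percent = round_half_away(100 * sum(flags, na.rm = TRUE) / n_ok))
}

#' Fit the discovery linear model y = a x + b
#'
#' Ordinary least squares of percent analgesia on ROI degree counts in the
#' discovery cohort. The fitted slope/intercept are later applied unchanged
#' to validation-cohort degree counts.
#'
#' @param degree per-subject ROI degree counts (x).
#' @param analgesia per-subject percent analgesia (y).
#' @param scale outcome scale label ("VAS" or "WOMAC").
#' @return Object of class `prediction_model`: `a`, `b`, `r2`, `p`, `n`,
#'   `scale`, `se_a`, `ci_a` (95\% CI of the slope), `underdetermined`.
#' @export
fit_discovery_model <- function(degree, analgesia, scale = "VAS") {
  ok <- complete.cases(degree, analgesia)
  x <- degree[ok]; y <- analgesia[ok]
  if (length(x) < 2) stop("need at least 2 subjects to fit")
  if (var(x) == 0) stop("zero variance in degree counts")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  underdet <- length(x) < 3
  se_a <- if (underdet) NA_real_ else sm$coefficients["x", "Std. Error"]
  p_a <- if (underdet) NA_real_ else sm$coefficients["x", "Pr(>|t|)"]
  tcrit <- if (underdet) NA_real_ else qt(0.975, df = length(x) - 2)
  structure(list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                 r2 = sm$r.squared, p = p_a, n = length(x), scale = scale,
                 se_a = se_a,
                 ci_a = c(coef(fit)[2] - tcrit * se_a, coef(fit)[2] + tcrit * se_a),
                 underdetermined = underdet),
            class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("<prediction_model %s> y = %.4g x %+.4g (n = %d, R2 = %.3f, p = %.3g)\n",
              x$scale, x$a, x$b, x$n, x$r2, x$p))
  invisible(x)
}

#' Predict percent analgesia from degree counts
#'
#' Applies the discovery fit `y2 = a * x2 + b` to new ROI degree counts.
#'
#' @param m a [fit_discovery_model()] result.
#' @param degree new per-subject degree counts.
#' @return Predicted percent analgesia.
#' @export
predict_outcome <- function(m, degree) {
  stopifnot(inherits(m, "prediction_model"))
  m$a * degree + m$b
}

#' ROC AUC by the rank (Mann-Whitney) formula
#'
#' AUC equals the probability that a random positive outranks a random
#' negative; ties receive half credit. Higher scores are taken to indicate
#' the positive class. Accuracy is reported at the Youden-optimal cut
#' (maximising sensitivity + specificity - 1).
#'
#' @param scores numeric classifier scores.
#' @param flags logical (or 0/1) class labels; `TRUE` = positive.
#' @return List with `auc`, `threshold` (Youden cut), `accuracy`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, flags) {
  flags <- as.logical(flags)
  ok <- complete.cases(scores, flags)
  scores <- scores[ok]; flags <- flags[ok]
  n_pos <- sum(flags); n_neg <- sum(!flags)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)                      # midranks: ties get half credit
  auc <- (sum(r[flags]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  cuts <- sort(unique(scores))
  cuts <- c(cuts[1] - 1, (cuts[-1] + cuts[-length(cuts)]) / 2, cuts[length(cuts)] + 1)
  best <- NULL
  for (cc in cuts) {
    sens <- mean(scores[flags] > cc)
    spec <- mean(scores[!flags] <= cc)
    if (is.null(best) || sens + spec - 1 > best$j + 1e-12)
      best <- list(j = sens + spec - 1, cut = cc, sens = sens, spec = spec)
  }
  acc <- (best$sens * n_pos + best$spec * n_neg) / (n_pos + n_neg)
  list(auc = auc, threshold = best$cut, accuracy = acc,
       sensitivity = best$sens, specificity = best$spec,
       n_pos = n_pos, n_neg = n_neg)
}

# Hanley-McNeil standard error of an AUC
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Confidence-interval half-width, CI = Z_(alpha/2) * sigma / sqrt(n)
#'
#' @param sigma standard error.
#' @param n sample size.
#' @param conf confidence level (default 0.95, Z = 1.96).
#' @return Half-width of the interval.
#' @export
ci_halfwidth <- function(sigma, n, conf = 0.95) {
  qnorm(1 - (1 - conf) / 2) * sigma / sqrt(n)
}

#' Compare two independent ROC curves
#'
#' z test on the AUC difference with Hanley-McNeil standard errors; the
#' confidence interval uses the half-width formula of [ci_halfwidth()] with
#' `sigma` the standard error of the difference and `n` the total number of
#' subjects.
#'
#' @param auc1,auc2 the two AUCs.
#' @param n1_pos,n1_neg,n2_pos,n2_neg class counts of the two samples.
#' @param conf confidence level.
#' @return List with `diff`, `se1`, `se2`, `se_diff`, `z`, `p` (two-sided
#'   normal), `ci` (difference +/- half-width).
#' @export
roc_compare <- function(auc1, n1_pos, n1_neg, auc2, n2_pos, n2_neg, conf = 0.95) {
  if (min(n1_pos, n1_neg, n2_pos, n2_neg) < 1) stop("degenerate class counts")
  se1 <- hanley_mcneil_se(auc1, n1_pos, n1_neg)
  se2 <- hanley_mcneil_se(auc2, n2_pos, n2_neg)
  se_d <- sqrt(se1^2 + se2^2)
  d <- auc1 - auc2
  z <- if (se_d == 0) 0 else d / se_d
  n <- n1_pos + n1_neg + n2_pos + n2_neg
  hw <- ci_halfwidth(se_d, n, conf)
  list(diff = d, se1 = se1, se2 = se2, se_diff = se_d, z = z,
       p = 2 * pnorm(-abs(z)), ci = c(d - hw, d + hw))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exhaustive hypergeometric enumeration: the two-sided p sums the
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table (the common
#' exact-test convention).
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome:
#'   `[[a, b], [c, d]]`.
#' @return List with `p` (two-sided), `table`, `flag` (set when a margin is
#'   zero, where p = 1 by convention).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be nonnegative integers")
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0)
    return(list(p = 1, table = matrix(cnt, 2, byrow = TRUE), flag = "zero margin"))
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(1, p), table = matrix(cnt, 2, byrow = TRUE), flag = NULL)
}

#' Stepwise forward regression with backward pruning
#'
#' Adds the candidate with the smallest entry p-value while it is below
#' `p_enter`, then removes any retained predictor whose p-value exceeds
#' `p_remove`, repeating until stable. Collinear candidates (which cannot
#' be estimated given the current model) are dropped with a warning.
#' Unique variance per retained predictor is the squared semipartial
#' correlation (R^2 of the full model minus R^2 without that predictor).
#'
#' @param y response (percent analgesia).
#' @param X data.frame or matrix of candidate predictors (covariates plus
#'   the ROI degree count).
#' @param p_enter entry criterion (default 0.05).
#' @param p_remove removal criterion (default 0.10).
#' @return List with `selected` (names), `model` (the final `lm`, or `NULL`
#'   for the empty model), `unique_variance` (named), `r2`, `steps` (log of
#'   add/remove actions).
#' @export
stepwise_regression <- function(y, X, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(X)
  ok <- complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (nrow(X) <= ncol(X) + 2)
    warning("few observations relative to candidates; selection may be unstable")
  vars <- names(X)
  sel <- character(0)
  steps <- character(0)
  coef_p <- function(vs) {
    dat <- data.frame(y = y, X[vs])
    fit <- lm(y ~ ., data = dat)
    cf <- summary(fit)$coefficients
    list(fit = fit, p = cf[-1, "Pr(>|t|)", drop = TRUE])
  }
  repeat {
    changed <- FALSE
    cand <- setdiff(vars, sel)
    if (length(cand)) {
      entry <- vapply(cand, function(vn) {
        dat <- data.frame(y = y, X[c(sel, vn)])
        fit <- tryCatch(lm(y ~ ., data = dat), error = function(e) NULL)
        if (is.null(fit) || anyNA(coef(fit))) return(NA_real_)
        cf <- summary(fit)$coefficients
        row <- grep(vn, rownames(cf), fixed = TRUE)
        if (!length(row)) NA_real_ else cf[row[1], "Pr(>|t|)"]
      }, numeric(1))
      drop_coll <- cand[is.na(entry)]
      if (length(drop_coll)) {
        warning("dropping collinear candidate(s): ", paste(drop_coll, collapse = ", "))
        vars <- setdiff(vars, drop_coll)
        entry <- entry[!is.na(entry)]
        cand <- setdiff(vars, sel)
      }
      if (length(entry) && min(entry, na.rm = TRUE) < p_enter) {
        add <- cand[which.min(entry)]
        sel <- c(sel, add)
        steps <- c(steps, paste("add", add))
        changed <- TRUE
      }
    }
    if (length(sel)) {
      p <- coef_p(sel)$p
      names(p) <- sel
      if (max(p) > p_remove) {
        rm_v <- names(which.max(p))
        sel <- setdiff(sel, rm_v)
        steps <- c(steps, paste("remove", rm_v))
        changed <- TRUE
      }
    }
    if (!changed) break
    if (length(steps) > 4 * length(vars) + 8) break   # cycle guard
  }
  if (!length(sel))
    return(list(selected = character(0), model = NULL,
                unique_variance = numeric(0), r2 = 0, steps = steps))
  full <- coef_p(sel)$fit
  r2_full <- summary(full)$r.squared
  uv <- vapply(sel, function(vn) {
    others <- setdiff(sel, vn)
    r2_red <- if (length(others)) summary(coef_p(others)$fit)$r.squared else 0
    r2_full - r2_red
  }, numeric(1))
  list(selected = sel, model = full, unique_variance = uv, r2 = r2_full,
       steps = steps)
}

#' Pre/post correlation check (regression-to-the-mean guard)
#'
#' Correlates ROI degree counts with symptom scores before and after
#' treatment. A marker that reflects treatment response (rather than
#' regression to the mean) should be uncorrelated with pre-treatment
#' severity but correlated with the post-treatment score.
#'
#' @param degree per-subject ROI degree counts.
#' @param pre,post per-subject scores before/after treatment.
#' @return List with `pre` and `post` (each `r`, `p`, `n`), and `flag` set
#'   when a correlation is undefined (constant input).
#' @export
pre_post_correlation_check <- function(degree, pre, post) {
  ok <- complete.cases(degree, pre, post)
  if (sum(ok) < 4) stop("need at least 4 complete triplets")
  degree <- degree[ok]; pre <- pre[ok]; post <- post[ok]
  flag <- NULL
  one <- function(x, y, lab) {
    if (sd(x) == 0 || sd(y) == 0) {
      flag <<- c(flag, paste("undefined correlation:", lab))
      return(list(r = NA_real_, p = NA_real_, n = length(x)))
    }
    ct <- cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  list(pre = one(degree, pre, "degree vs pre"),
       post = one(degree, post, "degree vs post"),
       flag = flag)
}

#' Responder-group mean analgesia with confidence interval
#'
#' Mean percent analgesia among responders with the normal-theory
#' confidence interval (mean +/- t * SE).
#'
#' @param analgesia per-subject percent analgesia.
#' @param threshold responder threshold (default 20).
#' @param conf confidence level.
#' @return List with `mean`, `ci`, `n`.
#' @export
responder_summary <- function(analgesia, threshold = 20, conf = 0.95) {
  x <- analgesia[!is.na(analgesia) & analgesia >= threshold]
  n <- length(x)
  if (n < 2) stop("need at least 2 responders")
  se <- sd(x) / sqrt(n)
  tcrit <- qt(1 - (1 - conf) / 2, df = n - 1)
  list(mean = mean(x), ci = c(mean(x) - tcrit * se, mean(x) + tcrit * se), n = n)
}
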