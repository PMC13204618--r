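test_that("zscore_by_fold: analytic values, moments, rank preservation", {
  pr <- data.frame(slide_id = letters[1:3], fold = 1, risk_raw = c(1, 2, 3),
                   risk_std = NA_real_)
  z <- zscore_by_fold(pr)$risk_std
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(round(z, 4), c(-1.2247, 0, 1.2247))
  set.seed(8)
  pr2 <- data.frame(slide_id = as.character(1:40),
                    fold = rep(1:4, each = 10), risk_raw = rnorm(40, 5, 3),
                    risk_std = NA_real_)
  z2 <- zscore_by_fold(pr2)
  for (f in 1:4) {
    zi <- z2$risk_std[z2$fold == f]
    ri <- z2$risk_raw[z2$fold == f]
    expect_equal(mean(zi), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(zi^2)), 1, tolerance = 1e-9)
    expect_equal(cor(zi, ri, method = "spearman"), 1)
  }
  prc <- data.frame(slide_id = c("a", "b"), fold = 1, risk_raw = c(2, 2),
                    risk_std = NA_real_)
  expect_warning(zc <- zscore_by_fold(prc), "zero")
  expect_equal(zc$risk_std, c(0, 0))
})

test_that("harrell_c: analytic orderings and exact oracle agreement", {
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_equal(harrell_c(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  set.seed(21)
  for (trial in 1:10) {
    n <- 120
    r <- sample(rnorm(40), n, replace = TRUE)       # force risk ties
    tt <- sample(1:30, n, replace = TRUE)
    dd <- rbinom(n, 1, 0.5); dd[1] <- 1
    expect_identical(harrell_c(r, tt, dd), oracle_harrell_c(r, tt, dd))
  }
  expect_error(harrell_c(1, 5, 0), "comparable")
})

test_that("harrell_c properties: reversal symmetry, monotone invariance, survival pkg", {
  set.seed(22)
  r <- rnorm(60); tt <- rexp(60); dd <- rbinom(60, 1, 0.6); dd[1] <- 1
  expect_equal(harrell_c(r, tt, dd) + harrell_c(-r, tt, dd), 1)
  expect_equal(harrell_c(exp(2 * r) + 5, tt, dd), harrell_c(r, tt, dd))
  if (requireNamespace("survival", quietly = TRUE)) {
    cf <- survival::concordance(survival::Surv(tt, dd) ~ r, reverse = TRUE)
    expect_equal(harrell_c(r, tt, dd), unname(cf$concordance), tolerance = 1e-12)
  }
})

test_that("km_estimate: product limit by hand", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(wsisurv:::km_eval(km2, 1), 2 / 3)
  expect_equal(wsisurv:::km_eval(km2, 2.5), 2 / 3)
  expect_equal(wsisurv:::km_eval(km2, 3), 0)
  km3 <- km_estimate(c(2, 4, 9), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_true(all(diff(km_estimate(rexp(50), rbinom(50, 1, .5))$surv) <= 0))
  # zero censoring: KM equals empirical survival at every observed time
  set.seed(23)
  tt <- sample(1:20, 100, replace = TRUE)
  km4 <- km_estimate(tt, rep(1, 100))
  expect_equal(km4$surv, vapply(km4$time, function(u) mean(tt > u), 0))
})

test_that("stratify_quantile: splits, subsets, degenerate input", {
  g <- stratify_quantile(1:8, 0.5)
  expect_length(g$low_ids, 4); expect_length(g$high_ids, 4)
  g75 <- stratify_quantile(1:8, 0.75)
  expect_length(g75$low_ids, 6); expect_length(g75$high_ids, 2)
  # subgroup use: restricting to a subset partitions only that subset
  r <- setNames(1:10, letters[1:10])
  sub <- r[3:8]
  gs <- stratify_quantile(sub, 0.75)
  expect_setequal(c(gs$low_ids, gs$high_ids), letters[3:8])
  expect_error(stratify_quantile(rep(2, 5), 0.5), "identical")
  expect_error(stratify_quantile(1:5, 1.2), "q must")
})

test_that("cox_hr_binary: null, grid oracle, separation flag", {
  # duplicated survival data in both groups -> HR exactly 1
  tt <- c(1, 3, 5, 8, 1, 3, 5, 8); dd <- c(1, 1, 0, 1, 1, 1, 0, 1)
  ids <- as.character(1:8)
  gr <- structure(list(q = 0.5, cutoff = 0, low_ids = ids[1:4],
                       high_ids = ids[5:8]), class = "risk_groups")
  names(tt) <- names(dd) <- ids
  hr <- cox_hr_binary(gr, tt, dd)
  expect_false(hr$diverged)
  expect_equal(hr$hr, 1, tolerance = 1e-6)
  # alternating groups: matches the grid maximizer of the partial likelihood
  tt2 <- setNames(c(1, 2, 3, 4), ids[1:4]); dd2 <- setNames(rep(1, 4), ids[1:4])
  gr2 <- structure(list(q = 0.5, cutoff = 0, low_ids = c("2", "4"),
                        high_ids = c("1", "3")), class = "risk_groups")
  hr2 <- cox_hr_binary(gr2, tt2, dd2)
  # subject order low-then-high: times (2,4,1,3), group (0,0,1,1)
  b_star <- oracle_binary_cox_beta(c(0, 0, 1, 1), c(2, 4, 1, 3), rep(1, 4))
  expect_equal(hr2$beta, b_star, tolerance = 1e-4)
  if (requireNamespace("survival", quietly = TRUE)) {
    x <- c(0, 0, 1, 1)
    fit <- survival::coxph(survival::Surv(c(2, 4, 1, 3), rep(1, 4)) ~ x,
                           ties = "breslow")
    expect_equal(hr2$beta, unname(coef(fit)), tolerance = 1e-6)
  }
  # all early deaths in one group: monotone likelihood
  gr3 <- structure(list(q = 0.5, cutoff = 0, low_ids = c("3", "4"),
                        high_ids = c("1", "2")), class = "risk_groups")
  hr3 <- cox_hr_binary(gr3, tt2, dd2)
  expect_true(hr3$diverged)
  expect_equal(hr3$hr, Inf)
})

test_that("ipcw_auc: separation, tie handling, rank-sum reduction", {
  expect_equal(ipcw_auc(c(4, 3, 2, 1), c(1, 2, 3, 4), rep(1, 4), 2.5), 1)
  expect_equal(ipcw_auc(rep(1, 6), 1:6, rep(1, 6), 3.5), 0.5)
  # no censoring: equals the plain rank-sum AUC of indicator(time <= t)
  set.seed(24)
  r <- rnorm(80); tt <- rexp(80, 0.1)
  for (h in c(5, 10, 20)) {
    lab <- as.numeric(tt <= h)
    w <- suppressWarnings(wilcox.test(r[lab == 1], r[lab == 0])$statistic)
    auc_rank <- unname(w) / (sum(lab) * sum(1 - lab))
    expect_equal(ipcw_auc(r, tt, rep(1, 80), h), auc_rank, tolerance = 1e-12)
  }
  expect_error(ipcw_auc(r, tt, rep(1, 80), 1e6), "no controls")
})

test_that("ipcw_auc is invariant to monotone risk transforms", {
  set.seed(25)
  r <- rnorm(60); tt <- rexp(60, 0.08); dd <- rbinom(60, 1, 0.7)
  a1 <- ipcw_auc(r, tt, dd, 8)
  expect_equal(ipcw_auc(3 * r - 1, tt, dd, 8), a1, tolerance = 1e-12)
  expect_equal(ipcw_auc(exp(r), tt, dd, 8), a1, tolerance = 1e-12)
})

test_that("timepoint_auc_panel: contract and per-horizon errors", {
  set.seed(26)
  r <- rnorm(100); tt <- rexp(100, 1 / 40); dd <- rbinom(100, 1, 0.7)
  panel <- timepoint_auc_panel(r, tt, dd)
  expect_named(panel, c("t12", "t36", "t60"))
  expect_true(all(panel >= 0 & panel <= 1))
  expect_error(timepoint_auc_panel(r, tt, dd, horizons = c(12, 1e7)),
               "horizon 1e\\+07")
})

test_that("bootstrap_delta_c: identical models, extremes, determinism", {
  set.seed(27)
  tt <- rexp(40); dd <- rbinom(40, 1, 0.8); dd[1] <- 1
  r <- rnorm(40)
  b0 <- bootstrap_delta_c(r, r, tt, dd, n_iter = 50, seed = 3)
  expect_equal(b0$delta, 0)
  expect_equal(b0$ci, c(0, 0))
  expect_equal(b0$p_value, 1)
  # uncensored, A perfect and B reversed: every resampled delta is 1
  tt2 <- 1:30; dd2 <- rep(1, 30); rA <- 30:1; rB <- 1:30
  b1 <- bootstrap_delta_c(rA, rB, tt2, dd2, n_iter = 50, seed = 4)
  expect_equal(b1$ci, c(1, 1))
  expect_true(all(b1$deltas == 1))
  b2 <- bootstrap_delta_c(r, rev(r), tt, dd, n_iter = 100, seed = 9)
  b3 <- bootstrap_delta_c(r, rev(r), tt, dd, n_iter = 100, seed = 9)
  expect_identical(b2, b3)
})

test_that("fold standardization aligns distorted folds without hurting pooled C", {
  # two folds scored on different scales: pooling raw risks scrambles the
  # ordering, pooling standardized risks restores it
  set.seed(28)
  n <- 60
  eta <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(eta)); dd <- rep(1, n)
  fold <- rep(1:2, each = n / 2)
  raw <- ifelse(fold == 1, 100 + 0.2 * eta, -50 + 5 * eta)
  pr <- data.frame(slide_id = as.character(1:n), fold = fold, risk_raw = raw,
                   risk_std = NA_real_)
  z <- zscore_by_fold(pr)$risk_std
  c_raw <- harrell_c(raw, tt, dd)
  c_std <- harrell_c(z, tt, dd)
  expect_gt(c_std, c_raw)
  # the same affine map applied to every fold leaves the standardized
  # scores (hence the pooled C) unchanged
  pr_orig <- data.frame(slide_id = as.character(1:n), fold = fold,
                        risk_raw = eta, risk_std = NA_real_)
  pr_aff <- transform(pr_orig, risk_raw = 2 * eta + 7)
  expect_equal(zscore_by_fold(pr_aff)$risk_std,
               zscore_by_fold(pr_orig)$risk_std, tolerance = 1e-12)
})
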