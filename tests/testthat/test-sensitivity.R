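test_that("Cochran's Q matches direct summation and its degenerate cases", {
  # consensus instruments: all ratios equal -> Q = 0, p = 1
  hc <- harmonized_set(c("a", "b", "c"), c(0.1, 0.2, 0.3), 0.01,
                       0.4 * c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.2))
  q <- cochran_q(hc, "IVW")
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
  expect_equal(q$df, 2L)

  # Egger on exactly-linear points -> Q = 0 with df = n - 2
  hl <- harmonized_set(sprintf("rs%d", 1:4), c(0.1, 0.2, 0.3, 0.4), 0.01,
                       0.1 + 0.4 * c(0.1, 0.2, 0.3, 0.4), 0.05)
  qe <- cochran_q(hl, "MR-Egger")
  expect_equal(qe$q, 0, tolerance = 1e-18)
  expect_equal(qe$df, 2L)

  # random sets: brute-force summation oracle, both methods
  for (seed in 1:5) {
    h <- random_instruments(8, seed + 300)
    w <- 1 / h$se_out^2
    theta <- mr_ivw(h, "fixed")$theta
    expect_equal(cochran_q(h, "IVW")$q,
                 sum(w * (h$beta_out - theta * h$beta_exp)^2),
                 tolerance = 1e-10)
    fit <- mr_egger(h)$fit
    # oracle residuals on the oriented (beta_exp >= 0) scale Egger fits on
    flip <- ifelse(h$beta_exp < 0, -1, 1)
    expect_equal(cochran_q(h, "MR-Egger")$q,
                 sum(w * (h$beta_out * flip - fit$intercept -
                            fit$slope * h$beta_exp * flip)^2),
                 tolerance = 1e-10)
    # reordering invariance and non-negativity
    perm <- withr::with_seed(seed, sample(nrow(h)))
    expect_equal(cochran_q(h[perm, ], "IVW")$q, cochran_q(h, "IVW")$q,
                 tolerance = 1e-12)
    expect_gte(cochran_q(h, "IVW")$q, 0)
  }

  expect_true(is.na(cochran_q(random_instruments(2, 1), "MR-Egger")$q))
})

test_that("Egger intercept test recovers a constructed intercept", {
  withr::with_seed(21, {
    n <- 20
    bx <- runif(n, 0.05, 0.3)
    se_y <- rep(0.005, n)
    by <- 0.1 + 0.4 * bx + rnorm(n, 0, se_y)  # true intercept 0.1
    h <- harmonized_set(sprintf("rs%d", 1:n), bx, 0.001, by, se_y)
  })
  pt <- egger_intercept_test(mr_egger(h)$fit)
  expect_equal(pt$intercept, 0.1, tolerance = 0.02)
  expect_lt(pt$pval, 0.05)
  expect_false(pt$no_pleiotropy_at_0.05)
  expect_equal(pt$df, 18L)
})

test_that("Egger intercept p is near-uniform under the no-pleiotropy null", {
  pvals <- vapply(1:200, function(s) {
    h <- withr::with_seed(s, {
      n <- 15
      bx <- runif(n, 0.05, 0.3)
      se_y <- runif(n, 0.05, 0.15)
      by <- 0.3 * bx + rnorm(n, 0, se_y)
      harmonized_set(sprintf("rs%d", 1:n), bx, 0.001, by, se_y)
    })
    egger_intercept_test(mr_egger(h)$fit)$pval
  }, numeric(1))
  # rejection near the nominal rate (binomial 2 SE band around 0.05);
  # the max(1, .) dispersion floor makes the test mildly conservative
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  expect_gt(mean(pvals < 0.5), 0.25)  # not degenerate either
})

test_that("nsnp = 3 Egger uses df = 1", {
  h <- random_instruments(3, 17)
  expect_equal(mr_egger(h)$fit$df, 1L)
  expect_equal(egger_intercept_test(mr_egger(h)$fit)$df, 1L)
})

test_that("leave-one-out equals fresh IVW fits on reduced sets", {
  h <- random_instruments(7, 41)
  loo <- leave_one_out(h, model = "fixed")
  expect_equal(nrow(loo), 8L)  # 7 exclusions + all-SNP row
  expect_true(all(loo$nsnp[1:7] == 6L))
  for (j in 1:7) {
    fresh <- mr_ivw(h[-j, , drop = FALSE], model = "fixed")
    expect_equal(loo$theta[j], fresh$theta, tolerance = 1e-12)
    expect_equal(loo$se[j], fresh$se, tolerance = 1e-12)
  }
  expect_identical(loo$excluded[8], "(none)")

  # consensus instruments: all leave-one-out estimates identical
  hc <- harmonized_set(c("a", "b", "c"), c(0.1, 0.2, 0.3), 0.01,
                       0.4 * c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.2))
  lc <- leave_one_out(hc)
  expect_equal(diff(range(lc$theta)), 0, tolerance = 1e-12)

  # a gross outlier moves the estimate most when excluded
  ho <- random_instruments(8, 43)
  ho$beta_out[4] <- 10 * 0.3 * ho$beta_exp[4]
  ho$se_out[4] <- 0.01
  lo <- leave_one_out(ho, model = "fixed")
  full <- lo$theta[lo$excluded == "(none)"]
  shifts <- abs(lo$theta[1:8] - full)
  expect_equal(which.max(shifts), 4L)

  expect_error(leave_one_out(random_instruments(2, 1)), ">= 3")
})

presso_fixture <- function(seed, n = 10, theta = 0.3, outlier_ratio = 3) {
  withr::with_seed(seed, {
    bx <- rnorm(n, 0.15, 0.03)
    se_y <- rep(0.01, n)
    by <- theta * bx + rnorm(n, 0, se_y)
    by[1] <- outlier_ratio * bx[1]  # ratio 10x the consensus
    harmonized_set(sprintf("rs%d", 1:n), bx, 0.002, by, se_y)
  })
}

test_that("MR-PRESSO flags a constructed outlier and corrects the fit", {
  h <- presso_fixture(1)
  res <- mr_presso(h, n_sim = 1000, seed = 7)
  # the injected outlier is always among the flagged SNPs; a gross outlier
  # distorts the leave-one-out fits enough that neighbours may be swept up
  expect_true("rs1" %in% res$outliers)
  expect_lt(res$global_pval, 0.05)
  expect_false("rs1" %in% res$corrected_snps)
  expect_lt(abs(res$corrected$theta - 0.3), 0.1)
  expect_false(is.na(res$distortion_pval))
  expect_lte(res$corrected$nsnp, 9L)
})

test_that("MR-PRESSO is seed-reproducible with bounded global p", {
  h <- presso_fixture(2)
  a <- mr_presso(h, n_sim = 500, seed = 11)
  b <- mr_presso(h, n_sim = 500, seed = 11)
  expect_identical(a$global_pval, b$global_pval)
  expect_identical(a$outlier_pvals, b$outlier_pvals)
  expect_gte(a$global_pval, 1 / 501)
  expect_lte(a$global_pval, 1)
})

test_that("MR-PRESSO under the null finds no outliers at ~nominal rate", {
  hits <- vapply(1:40, function(s) {
    h <- withr::with_seed(s + 500, {
      n <- 10
      bx <- rnorm(n, 0.15, 0.03)
      se_y <- runif(n, 0.05, 0.15)
      by <- 0.3 * bx + rnorm(n, 0, se_y)
      harmonized_set(sprintf("rs%d", 1:n), bx, 0.002, by, se_y)
    })
    res <- mr_presso(h, n_sim = 300, seed = s)
    c(length(res$outliers) > 0, res$global_pval > 0.05)
  }, logical(2))
  expect_lte(mean(hits[1, ]), 0.15)   # outliers rarely flagged
  expect_gte(mean(hits[2, ]), 0.75)   # global test mostly quiet
})

test_that("MR-PRESSO below 4 instruments is not estimable; small n_sim warns", {
  res <- mr_presso(random_instruments(3, 1), seed = 1)
  expect_true(is.na(res$global_pval))
  expect_length(res$outliers, 0)
  expect_warning(mr_presso(random_instruments(6, 2), n_sim = 50, seed = 1),
                 "n_sim")
})
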