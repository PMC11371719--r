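test_that("wald_ratio is the delta-method ratio", {
  h <- harmonized_set("rs1", 0.5, 0.01, 0.25, 0.1)
  est <- wald_ratio(h)
  expect_equal(est$theta, 0.5)
  expect_equal(est$se, 0.2)
  # sign symmetry and the null
  expect_equal(wald_ratio(harmonized_set("rs1", -0.5, 0.01, 0.25,
                                         0.1))$theta, -0.5)
  expect_equal(wald_ratio(harmonized_set("rs1", 0.5, 0.01, 0, 0.1))$theta, 0)
  expect_error(wald_ratio(harmonized_set("rs1", 0, 0.01, 0.1, 0.1)),
               "nonzero")
})

test_that("IVW equals the weighted zero-intercept regression oracle", {
  # spec example triple
  h <- harmonized_set(c("a", "b", "c"), c(0.1, 0.2, 0.15), 0.01,
                      c(0.05, 0.08, 0.09), c(0.01, 0.02, 0.015))
  est <- mr_ivw(h, model = "fixed")
  o <- ivw_oracle(h, "fixed")
  expect_equal(est$theta, o$theta, tolerance = 1e-12)
  expect_equal(est$se, o$se, tolerance = 1e-12)

  # consensus instruments: ratio identical regardless of weights
  hc <- harmonized_set(c("a", "b"), c(0.1, 0.3), 0.01,
                       c(0.03, 0.09), c(0.05, 0.2))
  expect_equal(mr_ivw(hc)$theta, 0.3, tolerance = 1e-12)

  # single instrument degenerates to the Wald ratio
  h1 <- harmonized_set("a", 0.5, 0.01, 0.25, 0.1)
  est1 <- mr_ivw(h1)
  expect_equal(est1$theta, 0.5)
  expect_match(est1$note, "single instrument")

  expect_error(mr_ivw(harmonized_set(c("a", "b"), c(0, 0), 0.01,
                                     c(0.1, 0.2), 0.1)),
               "degenerate")
})

test_that("fixed and random IVW share the point estimate; SEs differ only", {
  for (seed in 1:8) {
    h <- random_instruments(10, seed)
    f <- mr_ivw(h, "fixed")
    r <- mr_ivw(h, "multiplicative_random")
    expect_identical(f$theta, r$theta)
    expect_gte(r$se, f$se)
    expect_equal(r$se, ivw_oracle(h, "random")$se, tolerance = 1e-10)
  }
})

test_that("MR-Egger matches the free-intercept WLS oracle", {
  # exact linear fixture: intercept 0.1, slope 0.4
  h <- harmonized_set(sprintf("rs%d", 1:4), c(0.1, 0.2, 0.3, 0.4), 0.01,
                      0.1 + 0.4 * c(0.1, 0.2, 0.3, 0.4), 0.05)
  fit <- mr_egger(h)$fit
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$slope, 0.4, tolerance = 1e-10)

  for (seed in 1:8) {
    hr <- random_instruments(10, seed + 100)
    fit <- mr_egger(hr)$fit
    o <- egger_oracle(hr)
    expect_equal(fit$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(fit$slope_se, o$slope_se, tolerance = 1e-10)
    expect_equal(fit$intercept_se, o$intercept_se, tolerance = 1e-10)
  }
})

test_that("MR-Egger below 3 instruments is not estimable (the '/' case)", {
  h <- random_instruments(2, 1)
  res <- mr_egger(h)
  expect_true(is_not_estimable(res$estimate))
  expect_null(res$fit)
  expect_true(is.na(res$estimate$or_))
})

test_that("weighted median interpolates the 50% weight point", {
  # symmetric equal-weight case
  h <- harmonized_set(c("a", "b", "c"), c(0.1, 0.1, 0.1), 0.01,
                      0.1 * c(0.1, 0.2, 0.3), rep(0.05, 3))
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$theta, 0.2, tolerance = 1e-12)

  # majority weight: the dominant instrument's ratio wins (up to the
  # interpolation between ratio midpoints, negligible at 99.5% weight)
  hw <- harmonized_set(c("a", "b", "c"), c(1, 0.05, 0.05), 0.01,
                       c(0.5, 0.02, 0.01), c(0.05, 0.05, 0.05))
  w <- hw$beta_exp^2 / hw$se_out^2
  expect_gt(w[1] / sum(w), 0.5)
  est <- mr_weighted_median(hw, n_boot = 50, seed = 1)
  expect_lt(abs(est$theta - 0.5), 0.001)

  # brute-force oracle on random sets
  for (seed in 1:10) {
    hr <- random_instruments(5 + seed %% 4, seed + 200)
    est <- mr_weighted_median(hr, n_boot = 50, seed = 1)
    expect_equal(est$theta,
                 wme_oracle(hr$beta_out / hr$beta_exp,
                            hr$beta_exp^2 / hr$se_out^2),
                 tolerance = 1e-12)
  }

  expect_true(is_not_estimable(
    mr_weighted_median(random_instruments(2, 1), seed = 1)))
})

test_that("equal-weight WME equals the ordinary interpolated median", {
  h <- random_instruments(9, 77)
  h$beta_exp <- abs(h$beta_exp)
  h$se_out <- h$beta_exp  # makes weights bx^2/se^2 identical
  ratios <- h$beta_out / h$beta_exp
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$theta, wme_oracle(ratios, rep(1, 9)), tolerance = 1e-12)
})

test_that("WME bootstrap SE is seed-reproducible and seed-stable", {
  h <- random_instruments(12, 31)
  a <- mr_weighted_median(h, n_boot = 1000, seed = 42)
  b <- mr_weighted_median(h, n_boot = 1000, seed = 42)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(h, n_boot = 1000, seed = 43)
  expect_lt(abs(a$se - c_$se) / a$se, 0.1)
})

test_that("estimators are equivariant under per-SNP exposure sign flips", {
  h <- random_instruments(8, 55)
  flipped <- h
  idx <- c(2, 5, 7)
  flipped$beta_exp[idx] <- -flipped$beta_exp[idx]
  flipped$beta_out[idx] <- -flipped$beta_out[idx]
  expect_equal(mr_ivw(h)$theta, mr_ivw(flipped)$theta, tolerance = 1e-12)
  expect_equal(mr_egger(h)$fit$slope, mr_egger(flipped)$fit$slope,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$theta,
               mr_weighted_median(flipped, n_boot = 10, seed = 1)$theta,
               tolerance = 1e-12)
})

test_that("odds-ratio conversion uses the 1.959964 normal quantile", {
  res <- to_odds_ratio(0.5, 0.25)
  expect_equal(unname(res),
               c(exp(0.5), exp(0.5 - 1.959964 * 0.25),
                 exp(0.5 + 1.959964 * 0.25)), tolerance = 1e-12)
  expect_equal(round(unname(res), 4), c(1.6487, 1.0101, 2.6912))

  null <- to_odds_ratio(0, 0.3)
  expect_equal(unname(null["or_"]), 1)
  expect_equal(null[["ci_low"]] * null[["ci_high"]], 1, tolerance = 1e-12)

  tight <- to_odds_ratio(log(2), 1e-12)
  expect_equal(unname(tight), rep(2, 3), tolerance = 1e-9)

  # every estimate keeps or_ = exp(theta) and an ordered CI
  h <- random_instruments(6, 9)
  for (est in list(mr_ivw(h), mr_egger(h)$estimate,
                   mr_weighted_median(h, n_boot = 20, seed = 1))) {
    expect_equal(est$or_, exp(est$theta), tolerance = 1e-12)
    expect_lt(est$ci_low, est$or_)
    expect_gt(est$ci_high, est$or_)
  }
})
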