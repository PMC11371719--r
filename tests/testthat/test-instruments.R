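tab_with_p <- function(p) {
  association_table(
    make_assoc_df(SNP = sprintf("rs%d", seq_along(p)),
                  effect_allele = "A", other_allele = "G", eaf = 0.3,
                  beta = 0.1, se = 0.02, pval = p, n = 18340),
    meta_cont())
}

test_that("filter_by_pvalue keeps rows strictly below the threshold", {
  tab <- tab_with_p(c(2e-6, 5e-5, 1e-8))
  out <- suppressMessages(filter_by_pvalue(tab, 1e-5))
  expect_identical(out$SNP, c("rs1", "rs3"))
  expect_equal(nrow(suppressMessages(filter_by_pvalue(tab, 1))), 3L)
  empty <- suppressMessages(filter_by_pvalue(tab_with_p(numeric()), 1e-5))
  expect_equal(nrow(empty), 0L)
})

test_that("ld_clump follows the greedy p-ranked rule", {
  # exhaustive trace: p1 < p2 < p3; rs2 is linked to rs1, rs3 is not
  tab <- tab_with_p(c(1e-8, 1e-7, 1e-6))
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  r2[1, 3] <- r2[3, 1] <- 0.0005
  r2[2, 3] <- r2[3, 2] <- 0.0002
  ld <- ld_matrix(c("rs1", "rs2", "rs3"), r2)
  out <- suppressMessages(ld_clump(tab, ld, r2_threshold = 0.001))
  expect_identical(out$SNP, c("rs1", "rs3"))

  # all independent -> all kept; single candidate -> kept
  ld0 <- ld_matrix(c("rs1", "rs2", "rs3"), diag(3))
  expect_equal(nrow(suppressMessages(ld_clump(tab, ld0))), 3L)
  one <- suppressMessages(ld_clump(
    tab_with_p(1e-8), ld_matrix("rs1", matrix(1))))
  expect_equal(nrow(one), 1L)

  expect_error(suppressMessages(
    ld_clump(tab, ld_matrix(c("rs1", "rs2"), diag(2)))), "rs3")
})

test_that("ld_clump output is an independent set retaining the top SNP", {
  for (seed in 1:5) {
    n <- 12
    tab <- withr::with_seed(seed, tab_with_p(runif(n, 1e-10, 1e-5)))
    ld <- withr::with_seed(seed, {
      a <- matrix(runif(n * n, 0, 0.05), n)
      r2 <- (a + t(a)) / 2
      diag(r2) <- 1
      ld_matrix(tab$SNP, r2)
    })
    out <- suppressMessages(ld_clump(tab, ld, r2_threshold = 0.03))
    # invariant: every retained pair is below the threshold
    sub <- ld$r2[out$SNP, out$SNP, drop = FALSE]
    diag(sub) <- 0
    expect_lt(max(sub), 0.03)
    # invariant: the smallest-p candidate always survives
    expect_true(tab$SNP[which.min(tab$pval)] %in% out$SNP)
  }
})

test_that("ld_clump honors the distance window when positions exist", {
  tab <- tab_with_p(c(1e-8, 1e-7))
  tab$pos <- c(1e6, 1e6 + 2e7)  # 20 Mb apart
  tab <- mrpipe::association_table(as.data.frame(tab), meta_cont())
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2)  # nominally linked
  ld <- ld_matrix(c("rs1", "rs2"), r2)
  # outside the 10 Mb window the pair counts as unlinked
  out <- suppressMessages(ld_clump(tab, ld, r2_threshold = 0.001,
                                   window_kb = 10000))
  expect_equal(nrow(out), 2L)
  # a window wide enough to cover the pair lets the r2 rule prune
  out2 <- suppressMessages(ld_clump(tab, ld, r2_threshold = 0.001,
                                    window_kb = 1e9))
  expect_equal(nrow(out2), 1L)
  # an infinite window disables position handling entirely (r2 rules)
  out3 <- suppressMessages(ld_clump(tab, ld, r2_threshold = 0.001,
                                    window_kb = Inf))
  expect_equal(nrow(out3), 1L)
})

test_that("exclude_snps removes listed ids and warns on unknowns", {
  tab <- tab_with_p(rep(1e-6, 5))
  out <- suppressMessages(exclude_snps(tab, c("rs2", "rs4"), "confounder"))
  expect_identical(out$SNP, c("rs1", "rs3", "rs5"))
  d <- table_diagnostics(out)
  expect_true(all(c("rs2", "rs4") %in% d$SNP[d$action == "row excluded"]))

  expect_identical(
    suppressMessages(exclude_snps(tab, character(0)))$SNP, tab$SNP)
  expect_warning(suppressMessages(exclude_snps(tab, "rs999")),
                 "not present")
})

test_that("p-value filter and exclusion commute", {
  tab <- tab_with_p(c(1e-8, 1e-4, 1e-6, 1e-7, 0.5))
  excl <- c("rs1", "rs5")
  # rs5 fails the p filter first in route (a), so exclude_snps warns there
  a <- suppressWarnings(suppressMessages(
    exclude_snps(filter_by_pvalue(tab, 1e-5), excl)))
  b <- suppressMessages(
    filter_by_pvalue(exclude_snps(tab, excl), 1e-5))
  expect_identical(a$SNP, b$SNP)
})

test_that("variance_explained matches its closed form", {
  # beta = 0.1, se = 0.02, n = 18340: t = 5, r2 = 25/(25 + 18338)
  expect_equal(variance_explained(0.1, 0.02, 18340), 25 / (25 + 18338))
  expect_equal(variance_explained(0, 0.02, 1000), 0)
  # r2 -> 1 as t -> infinity
  expect_gt(variance_explained(10, 1e-6, 100), 0.999999)
  expect_error(variance_explained(0.1, 0.02, 2), "n must exceed 2")
  # eaf-based alternative
  expect_equal(variance_explained(0.1, 0.02, 1000, eaf = 0.3,
                                  method = "eaf"),
               2 * 0.3 * 0.7 * 0.01)
})

test_that("f_statistic evaluates the printed formula exactly", {
  expect_equal(f_statistic(0.01, 18340, 1), 0.01 * 18338 / 0.99)
  expect_equal(f_statistic(0, 1000, 1), 0)
  expect_equal(f_statistic(0.5, 102, 50), 0.5 * 51 / (50 * 0.5))
  expect_error(f_statistic(1, 100, 1), "r2")
  expect_error(f_statistic(0.1, 2, 1), "n must exceed")
})

test_that("f_statistic is monotone in r2 and n", {
  withr::with_seed(11, {
    r2 <- sort(runif(20, 0, 0.9))
    expect_true(all(diff(f_statistic(r2, 5000, 3)) > 0))
    n <- sort(sample(100:100000, 20))
    expect_true(all(diff(f_statistic(0.02, n, 3)) > 0))
  })
})

test_that("screen_weak_instruments gates on F > threshold with k = 1", {
  # rs1: t = 5 on n = 18340 -> F ~ 25; rs2: t = 2 -> F ~ 4 (weak)
  df <- make_assoc_df(SNP = c("rs1", "rs2"), effect_allele = "A",
                      other_allele = "G", eaf = 0.3,
                      beta = c(0.10, 0.04), se = 0.02, n = 18340)
  tab <- association_table(df, meta_cont())
  res <- suppressMessages(screen_weak_instruments(tab, f_threshold = 10))
  expect_identical(res$table$SNP, "rs1")
  expect_equal(nrow(res$diagnostics), 2L)
  expect_false(res$diagnostics$retained[res$diagnostics$SNP == "rs2"])
  expect_true(all(res$diagnostics$k == 1L))
  # per-SNP F agrees with the formula applied to the t-based r2
  r2 <- variance_explained(df$beta, df$se, df$n)
  expect_equal(res$diagnostics$f_stat, f_statistic(r2, df$n, 1))

  empty <- suppressMessages(
    screen_weak_instruments(tab_with_p(numeric())))
  expect_equal(nrow(empty$table), 0L)
})
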