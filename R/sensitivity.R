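# Sensitivity diagnostics on a fitted instrument set: heterogeneity
# (Cochran's Q), pleiotropy (Egger intercept), influence (leave-one-out),
# and outliers (MR-PRESSO).

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (beta_out_j - yhat_j)^2)` with `w_j = 1/se_out_j^2` and
#' `yhat_j` the fitted prediction: `theta * beta_exp_j` for IVW (fixed-effect
#' point estimate), plus the intercept for MR-Egger. The p-value uses a
#' chi-square with `nsnp - 1` (IVW) or `nsnp - 2` (Egger) degrees of
#' freedom; `p > 0.05` is conventionally read as "no heterogeneity".
#'
#' @param insts A `harmonized_set` or compatible data frame.
#' @param method `"IVW"` or `"MR-Egger"`.
#' @param fit Optional: an `mr_estimate` (IVW) or `egger_fit` already
#'   computed on `insts`; refitted when absent.
#' @return A `heterogeneity_result`: list with `method`, `q`, `df`, `pval`,
#'   `nsnp`. Not-estimable (all-`NA` q) below the method's minimum nsnp.
#' @export
cochran_q <- function(insts, method = c("IVW", "MR-Egger"), fit = NULL) {
  method <- match.arg(method)
  h <- kept(insts)
  n <- nrow(h)
  min_n <- if (method == "IVW") 2L else 3L
  if (n < min_n) {
    return(structure(list(method = method, q = NA_real_, df = NA_integer_,
                          pval = NA_real_, nsnp = n,
                          note = "not_estimable: too few instruments"),
                     class = "heterogeneity_result"))
  }
  w <- 1 / h$se_out^2
  if (method == "IVW") {
    if (is.null(fit)) fit <- mr_ivw(h, model = "fixed")
    stopifnot(inherits(fit, "mr_estimate"))
    yhat <- fit$theta * h$beta_exp
    df <- n - 1L
  } else {
    if (is.null(fit)) fit <- mr_egger(h)$fit
    stopifnot(inherits(fit, "egger_fit"))
    # Egger orients exposure effects non-negative before fitting; apply the
    # same orientation so predictions line up.
    flip <- sign(h$beta_exp)
    flip[flip == 0] <- 1
    yhat <- (fit$intercept + fit$slope * (h$beta_exp * flip)) * flip
    df <- n - 2L
  }
  q <- sum(w * (h$beta_out - yhat)^2)
  pval <- stats::pchisq(q, df = df, lower.tail = FALSE)
  structure(list(method = method, q = q, df = df, pval = pval, nsnp = n,
                 note = ""),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  if (is.na(x$q)) {
    cat(sprintf("<heterogeneity> %s: not estimable (nsnp = %d)\n",
                x$method, x$nsnp))
  } else {
    cat(sprintf("<heterogeneity> %s: Q = %.3f on %d df, p = %.3g%s\n",
                x$method, x$q, x$df, x$pval,
                if (x$pval > 0.05) " (no heterogeneity at 0.05)" else ""))
  }
  invisible(x)
}

#' Egger-intercept test for directional pleiotropy
#'
#' Two-sided t test of intercept = 0 on `nsnp - 2` degrees of freedom. By
#' the conventional rule, `p > 0.05` is read as no evidence of horizontal
#' pleiotropy.
#'
#' @param fit An `egger_fit` from [mr_egger()].
#' @return A `pleiotropy_test`: list with `intercept`, `se`, `pval`, `df`,
#'   `no_pleiotropy_at_0.05`.
#' @export
egger_intercept_test <- function(fit) {
  stopifnot(inherits(fit, "egger_fit"))
  structure(list(intercept = fit$intercept, se = fit$intercept_se,
                 pval = fit$intercept_pval, df = fit$df,
                 no_pleiotropy_at_0.05 = fit$intercept_pval > 0.05),
            class = "pleiotropy_test")
}

#' @export
print.pleiotropy_test <- function(x, ...) {
  cat(sprintf(
    "<pleiotropy_test> Egger intercept %.4f (se %.4f), p = %.3g -> %s\n",
    x$intercept, x$se, x$pval,
    if (x$no_pleiotropy_at_0.05) "no evidence of directional pleiotropy"
    else "directional pleiotropy indicated"))
  invisible(x)
}

#' Leave-one-out IVW series
#'
#' Re-estimates the IVW effect `nsnp` times, each time excluding one SNP,
#' to reveal instruments that drive the pooled estimate.
#'
#' @param insts A `harmonized_set` or compatible data frame; >= 3
#'   instruments.
#' @param model IVW model passed to [mr_ivw()].
#' @return A `loo_series`: data frame with one row per excluded SNP
#'   (`excluded`, `nsnp`, `theta`, `se`, `pval`, `or_`, `ci_low`,
#'   `ci_high`) plus a final `"(none)"` row holding the all-SNP estimate.
#' @export
leave_one_out <- function(insts, model = "multiplicative_random") {
  h <- kept(insts)
  n <- nrow(h)
  if (n < 3) {
    stop("leave_one_out: needs >= 3 instruments", call. = FALSE)
  }
  one <- function(est, label) {
    data.frame(excluded = label, nsnp = est$nsnp, theta = est$theta,
               se = est$se, pval = est$pval, or_ = est$or_,
               ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(n), function(j) {
    one(mr_ivw(h[-j, , drop = FALSE], model = model), h$SNP[j])
  })
  rows[[n + 1L]] <- one(mr_ivw(h, model = model), "(none)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("loo_series", "data.frame"))
}

# Leave-one-out fixed-effect IVW thetas via sum updates; y is a matrix with
# one simulated outcome vector per row (or a plain vector).
loo_theta_matrix <- function(x, y, w) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  sxx <- sum(w * x^2)
  wx <- w * x                      # length n
  sxy <- y %*% wx                  # nrep x 1
  num <- matrix(sxy, nrow(y), length(x)) - sweep(y, 2L, wx, `*`)
  den <- sxx - w * x^2             # length n
  sweep(num, 2L, den, `/`)         # nrep x n: theta excluding SNP j
}

#' MR-PRESSO: global heterogeneity, outlier, and distortion tests
#'
#' Simulation-based outlier diagnostic on the IVW regression. The observed
#' residual sum of squares uses leave-one-out IVW predictions: for each SNP
#' j, `rss_j = w_j * (beta_out_j - theta_hat_(-j) * beta_exp_j)^2`. The null
#' distribution is built by parametric simulation (`beta_out* ~
#' Normal(theta_hat_(-j) * beta_exp_j, se_out_j)`, leave-one-out thetas
#' recomputed per replicate). The global p-value is
#' `(1 + #[RSS* >= RSS]) / (n_sim + 1)`. Per-SNP observed contributions are
#' compared with their simulated distributions and Bonferroni-adjusted by
#' the set size; SNPs with adjusted p below `outlier_alpha` are flagged.
#' Because one gross outlier contaminates every leave-one-out fit (and
#' would drag clean neighbours over the threshold), flagged SNPs are
#' removed sequentially — worst contribution first, test repeated on the
#' remainder — until a pass comes back clean. When outliers are found, the
#' distortion test compares the estimate shift after outlier removal with
#' shifts from removing random subsets of the same size, and `corrected`
#' holds the IVW fit on the clean subset.
#'
#' @param insts A `harmonized_set` or compatible data frame; >= 4
#'   instruments.
#' @param n_sim Simulation replicates; default 1000 (values < 100 warn).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-SNP outlier test; default 0.05.
#' @param seed Seed for the simulations (required).
#' @return A `presso_result`: list with `global_rss`, `global_pval`,
#'   `outlier_pvals` (named, Bonferroni-adjusted), `outliers`,
#'   `distortion_pval` (`NA` when no outliers), `corrected` (an
#'   `mr_estimate` or `NULL`), `corrected_snps` (ids the corrected fit
#'   used), `n_sim`, `seed`, `nsnp`.
#' @export
mr_presso <- function(insts, n_sim = 1000, outlier_alpha = 0.05, seed = 1L) {
  h <- kept(insts)
  n <- nrow(h)
  if (n < 4) {
    return(structure(list(global_rss = NA_real_, global_pval = NA_real_,
                          outlier_pvals = stats::setNames(numeric(0),
                                                          character(0)),
                          outliers = character(0),
                          distortion_pval = NA_real_, corrected = NULL,
                          corrected_snps = character(0),
                          n_sim = n_sim, seed = seed, nsnp = n,
                          note = "not_estimable: needs >= 4 instruments"),
                     class = "presso_result"))
  }
  if (n_sim < 100) {
    warning("mr_presso: n_sim < 100 gives a coarse p-value", call. = FALSE)
  }

  # One simulation pass: leave-one-out IVW residual contributions for the
  # observed data, plus their null distribution from parametric replicates.
  presso_pass <- function(hh, pass_seed) {
    x <- hh$beta_exp
    y <- hh$beta_out
    w <- 1 / hh$se_out^2
    m <- nrow(hh)
    theta_loo <- drop(loo_theta_matrix(x, y, w))
    obs_contrib <- w * (y - theta_loo * x)^2
    sim <- with_seed(pass_seed, {
      mu <- theta_loo * x
      ystar <- matrix(stats::rnorm(n_sim * m, mean = rep(mu, each = n_sim),
                                   sd = rep(hh$se_out, each = n_sim)),
                      nrow = n_sim)
      tl <- loo_theta_matrix(x, ystar, w)
      contrib <- sweep((ystar - sweep(tl, 2L, x, `*`))^2, 2L, w, `*`)
      list(rss = rowSums(contrib), contrib = contrib)
    })
    raw_p <- vapply(seq_len(m), function(j) {
      (1 + sum(sim$contrib[, j] >= obs_contrib[j])) / (n_sim + 1)
    }, numeric(1))
    list(obs_contrib = obs_contrib, obs_rss = sum(obs_contrib),
         sim_rss = sim$rss, raw_p = raw_p)
  }

  # First pass on the full set defines the global test and the reported
  # per-SNP p-values.
  first <- presso_pass(h, seed)
  obs_rss <- first$obs_rss
  global_pval <- (1 + sum(first$sim_rss >= obs_rss)) / (n_sim + 1)
  adj_p <- stats::setNames(pmin(first$raw_p * n, 1), h$SNP)

  # Outlier removal is sequential: a gross outlier distorts every
  # leave-one-out fit, so flagged SNPs are peeled off worst-first and the
  # test repeated on the remainder until it comes back clean.
  outliers <- character(0)
  current <- h
  pass <- first
  iter <- 0L
  repeat {
    m <- nrow(current)
    flagged <- which(pmin(pass$raw_p * m, 1) < outlier_alpha)
    if (length(flagged) == 0 || m <= 3) break
    worst <- flagged[which.max(pass$obs_contrib[flagged])]
    outliers <- c(outliers, current$SNP[worst])
    current <- current[-worst, , drop = FALSE]
    iter <- iter + 1L
    if (nrow(current) < 4) break
    pass <- presso_pass(current, child_seed(seed, 100L + iter))
  }

  distortion_pval <- NA_real_
  corrected <- NULL
  corrected_snps <- character(0)
  if (length(outliers) > 0) {
    keep_idx <- !(h$SNP %in% outliers)
    corrected_snps <- h$SNP[keep_idx]
    if (sum(keep_idx) >= 2) {
      theta_all <- mr_ivw(h, model = "fixed")$theta
      corrected <- mr_ivw(h[keep_idx, , drop = FALSE],
                          model = "multiplicative_random")
      d_obs <- corrected$theta - theta_all
      n_out <- length(outliers)
      d_null <- with_seed(child_seed(seed, 1L), {
        vapply(seq_len(min(n_sim, 1000L)), function(b) {
          drop_idx <- sample.int(n, n_out)
          mr_ivw(h[-drop_idx, , drop = FALSE], model = "fixed")$theta -
            theta_all
        }, numeric(1))
      })
      distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) /
        (length(d_null) + 1)
    } else {
      corrected <- mr_not_estimable("IVW", sum(keep_idx),
                                    "fewer than 2 non-outlier instruments")
    }
  }
  structure(list(global_rss = obs_rss, global_pval = global_pval,
                 outlier_pvals = adj_p, outliers = outliers,
                 distortion_pval = distortion_pval, corrected = corrected,
                 corrected_snps = corrected_snps,
                 n_sim = n_sim, seed = seed, nsnp = n, note = ""),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  if (is.na(x$global_rss)) {
    cat(sprintf("<mr_presso> not estimable (nsnp = %d)\n", x$nsnp))
    return(invisible(x))
  }
  cat(sprintf("<mr_presso> global RSS = %.3f, p = %.3g (n_sim = %d)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outliers) > 0) {
    cat("  outliers:", paste(x$outliers, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_pval))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}
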