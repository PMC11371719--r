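# Causal estimators on a harmonized instrument set: Wald ratio, IVW,
# MR-Egger, weighted median, and odds-ratio reporting.
#
# Notation: per instrument j, beta_Xj (exposure effect), beta_Yj (outcome
# effect), se_Yj; IVW weight w_j = 1/se_Yj^2. The outcome scale is log-odds
# for binary traits, so exp(theta) is an odds ratio.

#' Construct an MR causal-effect estimate
#'
#' Usually produced by [mr_ivw()], [mr_egger()], [mr_weighted_median()] or
#' [wald_ratio()] rather than called directly. Not-estimable results (too
#' few instruments) carry `NA` fields and a `note`.
#'
#' @param method One of `"IVW"`, `"MR-Egger"`, `"WME"`, `"Wald"`.
#' @param theta Causal effect on the outcome scale (log-odds for binary).
#' @param se Standard error of `theta`.
#' @param pval Two-sided p-value.
#' @param nsnp Number of instruments used.
#' @param model `"fixed"`, `"multiplicative_random"`, or `NA`.
#' @param note Free-text annotation (e.g. degeneracy notes).
#' @param ci_multiplier Half-width multiplier on the log scale; the normal
#'   97.5th percentile by default, a t quantile for MR-Egger.
#' @return An `mr_estimate`: list with `method`, `theta`, `se`, `pval`,
#'   `or_`, `ci_low`, `ci_high`, `nsnp`, `model`, `note`.
#' @export
mr_estimate <- function(method, theta, se, pval, nsnp, model = NA_character_,
                        note = "", ci_multiplier = Z_CI) {
  est <- list(method = method, theta = theta, se = se, pval = pval,
              or_ = exp(theta),
              ci_low = exp(theta - ci_multiplier * se),
              ci_high = exp(theta + ci_multiplier * se),
              nsnp = nsnp, model = model, note = note)
  structure(est, class = "mr_estimate")
}

# A not-estimable placeholder (mirrors "/" cells in reported tables).
mr_not_estimable <- function(method, nsnp, why) {
  structure(list(method = method, theta = NA_real_, se = NA_real_,
                 pval = NA_real_, or_ = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, nsnp = nsnp, model = NA_character_,
                 note = paste0("not_estimable: ", why)),
            class = "mr_estimate")
}

#' Is an estimate not estimable?
#'
#' @param x An `mr_estimate`.
#' @return `TRUE` when the method could not be run (e.g. too few SNPs).
#' @export
is_not_estimable <- function(x) {
  inherits(x, "mr_estimate") && startsWith(x$note %||% "", "not_estimable")
}

#' @export
print.mr_estimate <- function(x, ...) {
  if (is_not_estimable(x)) {
    cat(sprintf("<mr_estimate> %s (nsnp = %d): not estimable (%s)\n",
                x$method, x$nsnp, sub("^not_estimable: ", "", x$note)))
    return(invisible(x))
  }
  cat(sprintf(
    "<mr_estimate> %s (nsnp = %d%s)\n  theta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$method, x$nsnp,
    if (!is.na(x$model)) paste0(", ", x$model) else "",
    x$theta, x$se, x$or_, x$ci_low, x$ci_high, x$pval))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$nsnp, theta = x$theta, se = x$se,
             or_ = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval, model = x$model, note = x$note,
             stringsAsFactors = FALSE)
}

# Pull the kept instruments out of a harmonized set, with guards.
kept <- function(insts) {
  if (inherits(insts, "harmonized_set")) {
    insts <- harmonized_instruments(insts)
  }
  stopifnot(is.data.frame(insts),
            all(c("SNP", "beta_exp", "se_exp", "beta_out", "se_out")
                %in% names(insts)))
  if (any(insts$se_out <= 0) || any(insts$se_exp <= 0)) {
    stop("instrument standard errors must be > 0", call. = FALSE)
  }
  insts
}

#' Wald ratio estimate from a single instrument
#'
#' `theta = beta_out / beta_exp` with first-order delta-method standard
#' error `se_out / |beta_exp|` (adequate for strong instruments, F > 10).
#'
#' @param inst One harmonized instrument (single-row `harmonized_set` or a
#'   list/row with `beta_exp`, `beta_out`, `se_out`, `SNP`).
#' @return An `mr_estimate` with `method = "Wald"`.
#' @export
wald_ratio <- function(inst) {
  if (is.data.frame(inst)) {
    stopifnot(nrow(inst) == 1L)
    inst <- as.list(inst)
  }
  if (inst$beta_exp == 0) {
    stop("wald_ratio: beta_exp must be nonzero", call. = FALSE)
  }
  theta <- inst$beta_out / inst$beta_exp
  se <- inst$se_out / abs(inst$beta_exp)
  mr_estimate("Wald", theta, se, pval_from_z(theta / se), nsnp = 1L)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Zero-intercept weighted least squares of outcome effects on exposure
#' effects with weights `1/se_out^2`:
#' `theta = sum(w * bx * by) / sum(w * bx^2)`. The fixed-effect standard
#' error is `1/sqrt(sum(w * bx^2))`; under the multiplicative random-effects
#' model (default) it is inflated by `max(1, sqrt(Q / (nsnp - 1)))` where Q
#' is Cochran's heterogeneity statistic. The point estimate is identical
#' under both models. A single instrument degenerates to the Wald ratio.
#'
#' @param insts A `harmonized_set` (dropped rows ignored) or compatible data
#'   frame; at least 2 instruments (1 returns the Wald ratio with a note).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with extra fields `se_fixed`, `se_random` and
#'   `q` (Cochran's Q of the fit).
#' @export
mr_ivw <- function(insts, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  h <- kept(insts)
  n <- nrow(h)
  if (n == 0) return(mr_not_estimable("IVW", 0L, "no instruments"))
  if (n == 1) {
    est <- wald_ratio(h)
    est$method <- "IVW"
    est$note <- "single instrument: Wald ratio"
    return(est)
  }
  if (all(h$beta_exp == 0)) {
    stop("mr_ivw: all exposure effects are zero (degenerate design)",
         call. = FALSE)
  }
  w <- 1 / h$se_out^2
  sxx <- sum(w * h$beta_exp^2)
  theta <- sum(w * h$beta_exp * h$beta_out) / sxx
  se_fixed <- 1 / sqrt(sxx)
  q <- sum(w * (h$beta_out - theta * h$beta_exp)^2)
  se_random <- se_fixed * max(1, sqrt(q / (n - 1)))
  se <- if (model == "fixed") se_fixed else se_random
  est <- mr_estimate("IVW", theta, se, pval_from_z(theta / se),
                     nsnp = n, model = model)
  est$se_fixed <- se_fixed
  est$se_random <- se_random
  est$q <- q
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept and weights `1/se_out^2`. Instruments are first oriented so all
#' exposure effects are non-negative (flipping the outcome effect sign in
#' step). The slope estimates the causal effect under the InSIDE assumption
#' (pleiotropy independent of instrument strength); the intercept estimates
#' average directional pleiotropy. Standard errors use a multiplicative
#' over-dispersion scale `max(1, sqrt(Q' / (nsnp - 2)))`; p-values use a t
#' distribution with `nsnp - 2` degrees of freedom.
#'
#' @param insts A `harmonized_set` or compatible data frame; needs >= 3
#'   instruments with spread in the exposure effects.
#' @return List with `estimate` (an `mr_estimate`, slope) and `fit` (an
#'   `egger_fit`: `slope`, `slope_se`, `slope_pval`, `intercept`,
#'   `intercept_se`, `intercept_pval`, `nsnp`, `df`, `q`). Not-estimable
#'   below 3 instruments (`fit` is `NULL`).
#' @export
mr_egger <- function(insts) {
  h <- kept(insts)
  n <- nrow(h)
  if (n < 3) {
    return(list(estimate = mr_not_estimable("MR-Egger", n,
                                            "needs >= 3 instruments"),
                fit = NULL))
  }
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  x <- h$beta_exp * flip
  y <- h$beta_out * flip
  w <- 1 / h$se_out^2
  sw <- sum(w)
  sx <- sum(w * x)
  sxx <- sum(w * x^2)
  sy <- sum(w * y)
  sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  if (det <= .Machine$double.eps * sw * sxx) {
    stop("mr_egger: no spread in exposure effects (degenerate design)",
         call. = FALSE)
  }
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  resid <- y - intercept - slope * x
  q <- sum(w * resid^2)
  df <- n - 2L
  scale <- max(1, sqrt(q / df))
  slope_se <- sqrt(sw / det) * scale
  intercept_se <- sqrt(sxx / det) * scale
  slope_p <- max(2 * stats::pt(-abs(slope / slope_se), df), 1e-300)
  intercept_p <- max(2 * stats::pt(-abs(intercept / intercept_se), df),
                     1e-300)
  t_mult <- stats::qt(0.975, df)
  est <- mr_estimate("MR-Egger", slope, slope_se, slope_p, nsnp = n,
                     model = "multiplicative_random",
                     ci_multiplier = t_mult)
  fit <- structure(list(slope = slope, slope_se = slope_se,
                        slope_pval = slope_p, intercept = intercept,
                        intercept_se = intercept_se,
                        intercept_pval = intercept_p,
                        nsnp = n, df = df, q = q),
                   class = "egger_fit")
  list(estimate = est, fit = fit)
}

#' @export
print.egger_fit <- function(x, ...) {
  cat(sprintf(
    "<egger_fit> nsnp = %d\n  slope     %.4f (se %.4f), p = %.3g\n  intercept %.4f (se %.4f), p = %.3g\n",
    x$nsnp, x$slope, x$slope_se, x$slope_pval,
    x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

# Interpolated weighted median of values `theta` with weights `w`.
# Sort by theta; with normalized weights p_j, the abscissa of theta_(j) is
# cumsum(p)_j - p_j/2; the estimate is linear interpolation at 0.5.
weighted_median_point <- function(theta, w) {
  stopifnot(length(theta) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(theta)
  theta <- theta[ord]
  p <- w[ord] / sum(w)
  cum <- cumsum(p) - p / 2
  if (0.5 <= cum[1]) return(theta[1])
  if (0.5 >= cum[length(cum)]) return(theta[length(theta)])
  stats::approx(cum, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' The 50%-weight quantile of the per-SNP Wald ratios with weights
#' `beta_exp^2 / se_out^2` (inverse variance of each ratio, first order).
#' Consistent even when invalid instruments contribute up to half the
#' weight. The standard error comes from a parametric bootstrap: exposure
#' and outcome effects are resampled from
#' `Normal(beta, se)` and the estimate recomputed.
#'
#' @param insts A `harmonized_set` or compatible data frame; >= 3
#'   instruments.
#' @param n_boot Bootstrap replicates; default 1000.
#' @param seed Seed for the bootstrap (required for reproducibility).
#' @return An `mr_estimate` with `method = "WME"`.
#' @export
mr_weighted_median <- function(insts, n_boot = 1000, seed = 1L) {
  h <- kept(insts)
  n <- nrow(h)
  if (n < 3) return(mr_not_estimable("WME", n, "needs >= 3 instruments"))
  ratio <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  theta <- weighted_median_point(ratio, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, h$beta_exp, h$se_exp)
      by <- stats::rnorm(n, h$beta_out, h$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / h$se_out[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_estimate("WME", theta, se, pval_from_z(theta / se), nsnp = n)
}

#' Convert a log-scale effect to an odds ratio with 95% CI
#'
#' @param theta Effect on the log-odds scale.
#' @param se Standard error (> 0 unless `theta` is exact).
#' @param ci_multiplier Half-width multiplier; normal 97.5th percentile by
#'   default.
#' @return Named numeric vector `or_`, `ci_low`, `ci_high`.
#' @examples
#' to_odds_ratio(0.5, 0.25)  # 1.6487, 1.0101, 2.6912
#' @export
to_odds_ratio <- function(theta, se, ci_multiplier = Z_CI) {
  stopifnot(se >= 0)
  c(or_ = exp(theta),
    ci_low = exp(theta - ci_multiplier * se),
    ci_high = exp(theta + ci_multiplier * se))
}
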