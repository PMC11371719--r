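# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# The generator emulates the study design the pipeline targets: a
# continuous exposure (e.g. genus-level gut-microbiota abundance measured
# in ~18,000 people) and a rare binary outcome (e.g. an inflammatory
# myopathy with a few hundred cases against ~213,000 controls), observed in
# non-overlapping cohorts. Effects are drawn per-instrument, measurement
# noise independently per cohort (two-sample design, no overlap), and the
# known generating parameters are returned for recovery tests.

#' Generating parameters for a synthetic exposure/outcome pair
#'
#' Defaults mirror the motivating study scale: exposure GWAS of 18,340
#' individuals; binary outcome with 208 cases and 213,145 controls.
#'
#' @param theta_true True causal effect of the exposure on the outcome
#'   (log-odds per SD of exposure).
#' @param n_instruments Number of instruments to simulate.
#' @param n_exp Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome case/control counts (binary outcome);
#'   set `outcome_type = "continuous"` to use `n_cases + n_controls` as a
#'   plain sample size.
#' @param outcome_type `"binary"` (default) or `"continuous"`.
#' @param beta_exp_mean,beta_exp_sd Mean and SD of the true per-allele
#'   instrument effects on the exposure (SD units).
#' @param pleiotropy `"none"`, `"balanced"` (direct effects centred at 0) or
#'   `"directional"` (centred at `pleiotropy_mean`).
#' @param pleiotropy_mean,pleiotropy_sd Location/spread of the direct
#'   (pleiotropic) SNP-outcome effects.
#' @param inside_violated When `TRUE`, direct effects are correlated with
#'   instrument strength (violating the InSIDE assumption behind MR-Egger).
#' @param inside_cor Target correlation used when `inside_violated`.
#' @param n_outliers Number of instruments whose outcome effect is
#'   multiplied by `outlier_multiplier` (gross pleiotropic outliers).
#' @param outlier_multiplier Multiplier applied to outlier outcome effects.
#' @param maf_range Range the minor-allele frequencies are drawn from;
#'   must lie in (0, 0.5\].
#' @param palindrome_fraction Fraction of SNPs given A/T or C/G allele
#'   pairs.
#' @param seed RNG seed; required so a truth object fully determines its
#'   dataset.
#' @return A `simulation_truth` object (named list).
#' @export
simulation_truth <- function(theta_true = 0,
                             n_instruments = 30L,
                             n_exp = 18340L,
                             n_cases = 208L,
                             n_controls = 213145L,
                             outcome_type = c("binary", "continuous"),
                             beta_exp_mean = 0.1,
                             beta_exp_sd = 0.03,
                             pleiotropy = c("none", "balanced",
                                            "directional"),
                             pleiotropy_mean = 0,
                             pleiotropy_sd = 0,
                             inside_violated = FALSE,
                             inside_cor = 0.6,
                             n_outliers = 0L,
                             outlier_multiplier = 10,
                             maf_range = c(0.05, 0.5),
                             palindrome_fraction = 0.2,
                             seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(n_instruments >= 1, beta_exp_sd >= 0, pleiotropy_sd >= 0,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            n_outliers >= 0, n_outliers <= n_instruments,
            !is.null(seed))
  structure(list(theta_true = theta_true,
                 n_instruments = as.integer(n_instruments),
                 n_exp = n_exp, n_cases = n_cases, n_controls = n_controls,
                 outcome_type = outcome_type,
                 beta_exp_mean = beta_exp_mean, beta_exp_sd = beta_exp_sd,
                 pleiotropy = pleiotropy, pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 inside_violated = inside_violated, inside_cor = inside_cor,
                 n_outliers = as.integer(n_outliers),
                 outlier_multiplier = outlier_multiplier,
                 maf_range = maf_range,
                 palindrome_fraction = palindrome_fraction,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

# GWAS standard-error approximations given MAF and sample size.
# Continuous (standardized) trait: se = 1/sqrt(n * v), v = 2*maf*(1-maf).
# Binary trait (log-odds): se = 1/sqrt(n * v * cp * (1 - cp)) with cp the
# case proportion — reproduces the very large SEs implied by a handful of
# cases against >200k controls.
se_gwas <- function(maf, n, case_prop = NULL) {
  v <- 2 * maf * (1 - maf)
  if (is.null(case_prop)) 1 / sqrt(n * v)
  else 1 / sqrt(n * v * case_prop * (1 - case_prop))
}

#' Simulate a harmonizable exposure/outcome summary-statistics pair
#'
#' For each instrument j: a MAF and a true exposure effect are drawn; a
#' direct (pleiotropic) outcome effect `alpha_j` is drawn per the
#' pleiotropy regime; the true outcome effect is
#' `theta_true * beta_xj + alpha_j`. Observed effects add independent
#' Gaussian noise with the standard GWAS standard-error approximation for
#' each cohort; p-values come from the normal approximation. Alleles are
#' assigned randomly with a configurable palindromic fraction and identical
#' orientation in both files (harmonization behaviour on flipped files is
#' exercised separately in tests). Outliers multiply the observed outcome
#' effect of randomly chosen instruments.
#'
#' @param truth A [simulation_truth()].
#' @return List with `exposure` and `outcome` (validated `assoc_table`s) and
#'   `truth` (the input, with element `generated` appended: per-SNP true
#'   effects, direct effects, and outlier flags).
#' @export
simulate_pair <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  m <- truth$n_instruments
  with_seed(truth$seed, {
    maf <- stats::runif(m, truth$maf_range[1], truth$maf_range[2])
    bx_true <- stats::rnorm(m, truth$beta_exp_mean, truth$beta_exp_sd)

    alpha <- switch(truth$pleiotropy,
      none = rep(0, m),
      balanced = stats::rnorm(m, 0, truth$pleiotropy_sd),
      directional = stats::rnorm(m, truth$pleiotropy_mean,
                                 truth$pleiotropy_sd))
    if (truth$inside_violated && truth$pleiotropy != "none" &&
        truth$pleiotropy_sd > 0 && truth$beta_exp_sd > 0) {
      # Mix in instrument strength to induce cor(alpha, bx) ~ inside_cor.
      rho <- truth$inside_cor
      z <- (bx_true - truth$beta_exp_mean) / truth$beta_exp_sd
      alpha_centred <- (alpha - mean(alpha))
      alpha <- mean(alpha) +
        truth$pleiotropy_sd * (rho * z +
                                 sqrt(1 - rho^2) * alpha_centred /
                                   truth$pleiotropy_sd)
    }
    by_true <- truth$theta_true * bx_true + alpha

    se_x <- se_gwas(maf, truth$n_exp)
    n_out_total <- truth$n_cases + truth$n_controls
    se_y <- if (truth$outcome_type == "binary") {
      se_gwas(maf, n_out_total, truth$n_cases / n_out_total)
    } else {
      se_gwas(maf, n_out_total)
    }

    bx_obs <- stats::rnorm(m, bx_true, se_x)
    by_obs <- stats::rnorm(m, by_true, se_y)

    is_outlier <- rep(FALSE, m)
    if (truth$n_outliers > 0) {
      idx <- sample.int(m, truth$n_outliers)
      by_obs[idx] <- by_obs[idx] * truth$outlier_multiplier
      is_outlier[idx] <- TRUE
    }

    # Allele pairs: palindromic (A/T or C/G) for a configurable fraction.
    pal <- stats::runif(m) < truth$palindrome_fraction
    ea <- character(m)
    oa <- character(m)
    pal_pairs <- list(c("A", "T"), c("C", "G"))
    nonpal_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                         c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    for (j in seq_len(m)) {
      pair <- if (pal[j]) {
        p <- pal_pairs[[sample.int(2L, 1L)]]
        if (stats::runif(1) < 0.5) rev(p) else p
      } else {
        nonpal_pairs[[sample.int(8L, 1L)]]
      }
      ea[j] <- pair[1]
      oa[j] <- pair[2]
    }

    snp <- sprintf("rs%06d", seq_len(m))
    mk <- function(beta, se, n) {
      data.frame(SNP = snp, effect_allele = ea, other_allele = oa,
                 eaf = maf, beta = beta, se = se,
                 pval = pval_from_z(beta / se), n = n,
                 stringsAsFactors = FALSE)
    }
    exp_meta <- study_meta("synthetic_exposure", "continuous",
                           n_total = truth$n_exp)
    out_meta <- if (truth$outcome_type == "binary") {
      study_meta("synthetic_outcome", "binary", n_total = n_out_total,
                 n_cases = truth$n_cases, n_controls = truth$n_controls)
    } else {
      study_meta("synthetic_outcome", "continuous", n_total = n_out_total)
    }
    truth$generated <- data.frame(SNP = snp, maf = maf, beta_exp_true = bx_true,
                                  alpha = alpha, beta_out_true = by_true,
                                  se_exp = se_x, se_out = se_y,
                                  outlier = is_outlier,
                                  stringsAsFactors = FALSE)
    list(exposure = association_table(mk(bx_obs, se_x, truth$n_exp),
                                      exp_meta),
         outcome = association_table(mk(by_obs, se_y, n_out_total),
                                     out_meta),
         truth = truth)
  })
}

#' Simulate a block-diagonal LD matrix
#'
#' r-squared equals `within_r2` inside each block of consecutive SNPs and 0
#' between blocks; SNP ids match [simulate_pair()]'s naming
#' (`rs000001`, ...). The final block is truncated when `block_size` does
#' not divide `n_snps`.
#'
#' @param n_snps Number of SNPs.
#' @param block_size SNPs per LD block.
#' @param within_r2 r-squared inside a block, in \[0, 1\].
#' @param seed Unused for the matrix itself (kept for interface symmetry).
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(n_snps, block_size, within_r2, seed = 1L) {
  stopifnot(n_snps >= 1, block_size >= 1)
  if (within_r2 < 0 || within_r2 > 1) {
    stop("simulate_ld: within_r2 must be in [0, 1]", call. = FALSE)
  }
  block <- rep(seq_len(ceiling(n_snps / block_size)),
               each = block_size)[seq_len(n_snps)]
  r2 <- outer(block, block, function(a, b) ifelse(a == b, within_r2, 0))
  diag(r2) <- 1
  ld_matrix(sprintf("rs%06d", seq_len(n_snps)), r2)
}

#' Write a simulation truth object as JSON
#'
#' @param truth A [simulation_truth()] (with or without generated per-SNP
#'   values).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
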