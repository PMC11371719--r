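# Shared fixtures and independent oracles.
# The oracles deliberately take a different route from the package code:
# estimator checks go through lm()/explicit interpolation, not the
# closed-form sums used in R/estimators.R.

make_assoc_df <- function(SNP, effect_allele, other_allele, eaf, beta, se,
                          pval = NULL, n = 10000) {
  if (length(SNP) == 0) {
    return(data.frame(SNP = character(), effect_allele = character(),
                      other_allele = character(), eaf = numeric(),
                      beta = numeric(), se = numeric(), pval = numeric(),
                      n = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(SNP = SNP, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, stringsAsFactors = FALSE)
}

meta_cont <- function(name = "exposure", n = 18340) {
  study_meta(name, "continuous", n_total = n)
}

meta_bin <- function(name = "outcome", cases = 208, controls = 213145) {
  study_meta(name, "binary", n_total = cases + controls,
             n_cases = cases, n_controls = controls)
}

# Random harmonized instrument set for estimator property tests.
random_instruments <- function(n, seed, theta = 0.3) {
  withr::with_seed(seed, {
    bx <- rnorm(n, 0.1, 0.05)
    bx[abs(bx) < 0.01] <- 0.05
    se_x <- runif(n, 0.005, 0.02)
    se_y <- runif(n, 0.02, 0.2)
    by <- theta * bx + rnorm(n, 0, se_y)
    harmonized_set(sprintf("rs%03d", seq_len(n)), bx, se_x, by, se_y)
  })
}

# Independent IVW oracle: zero-intercept weighted lm. Fixed-effect SE is
# the lm coefficient SE with the estimated dispersion divided back out;
# the multiplicative random-effects SE re-inflates by max(1, sigma).
ivw_oracle <- function(h, model = "fixed") {
  w <- 1 / h$se_out^2
  f <- lm(beta_out ~ 0 + beta_exp, data = h, weights = w)
  s <- summary(f)
  theta <- unname(coef(f)[1])
  se_fixed <- s$coefficients[1, 2] / s$sigma
  se <- if (model == "fixed") se_fixed else se_fixed * max(1, s$sigma)
  list(theta = theta, se = se)
}

# Independent MR-Egger oracle: free-intercept weighted lm on instruments
# oriented to non-negative exposure effects, multiplicative dispersion
# floored at 1.
egger_oracle <- function(h) {
  flip <- ifelse(h$beta_exp < 0, -1, 1)
  x <- h$beta_exp * flip
  y <- h$beta_out * flip
  w <- 1 / h$se_out^2
  f <- lm(y ~ x, weights = w)
  s <- summary(f)
  scale <- max(1, s$sigma)
  list(intercept = unname(coef(f)[1]), slope = unname(coef(f)[2]),
       intercept_se = s$coefficients[1, 2] / s$sigma * scale,
       slope_se = s$coefficients[2, 2] / s$sigma * scale)
}

# Brute-force interpolated weighted median: walk the sorted ratios and
# interpolate at cumulative weight one half, straight from the definition.
wme_oracle <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  p <- w[ord] / sum(w)
  absc <- numeric(length(p))
  run <- 0
  for (j in seq_along(p)) {
    absc[j] <- run + p[j] / 2
    run <- run + p[j]
  }
  if (0.5 <= absc[1]) return(theta[1])
  if (0.5 >= absc[length(absc)]) return(theta[length(theta)])
  j <- max(which(absc < 0.5))
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - absc[j]) /
    (absc[j + 1] - absc[j])
}

# Write an assoc_table fixture to a temp file; caller owns cleanup via
# withr::local_tempfile or deferred unlink.
write_fixture <- function(df, meta, path = tempfile(fileext = ".tsv")) {
  write_association_table(association_table(df, meta), path)
  path
}
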