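# Harmonization: align exposure and outcome effects onto a common effect
# allele, resolving strand flips and palindromic SNPs, and drop what cannot
# be resolved.

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand orientation
#' cannot be inferred from the alleles alone.
#'
#' @param effect_allele,other_allele Single bases (A/C/G/T); vectors recycle.
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(ALLELE_COMPLEMENT[toupper(effect_allele)] == toupper(other_allele))
}

#' Harmonize exposure and outcome association tables
#'
#' Pairs each exposure SNP with its outcome record on a common effect allele.
#' Per SNP the outcome is (in order of attempt): matched as-is; flipped when
#' the outcome lists the alleles in swapped orientation (outcome beta
#' negated, `eaf_out` replaced by `1 - eaf_out`); strand-complemented and
#' re-matched; for palindromic pairs, oriented by allele-frequency agreement
#' when both frequencies lie outside the ambiguity band
#' `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`, else dropped. SNPs
#' absent from the outcome or with irreconcilable alleles are dropped. Every
#' exposure SNP appears exactly once in the output, harmonized or dropped
#' with a reason.
#'
#' @param exposure,outcome `assoc_table`s; the exposure table is the
#'   post-selection instrument set. Duplicate SNP ids in either are an error
#'   (enforced at table construction).
#' @param palindrome_eaf_limit Half-width of frequency decidability: a
#'   palindrome is resolvable only when both eafs are `< limit` or
#'   `> 1 - limit`. Default 0.42.
#' @return A `harmonized_set`: data frame with columns `SNP`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `action`
#'   (`kept_as_is`, `outcome_flipped`, `palindrome_resolved`, `dropped`) and
#'   `drop_reason` (non-empty iff dropped). Attributes `exposure_meta` and
#'   `outcome_meta` carry the study metadata.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "assoc_table"), inherits(outcome, "assoc_table"),
            palindrome_eaf_limit > 0, palindrome_eaf_limit < 0.5)
  if (anyDuplicated(exposure$SNP) || anyDuplicated(outcome$SNP)) {
    stop("harmonize_pair: duplicate SNP ids", call. = FALSE)
  }
  out_idx <- match(exposure$SNP, outcome$SNP)

  n <- nrow(exposure)
  res <- data.frame(
    SNP = exposure$SNP,
    beta_exp = exposure$beta, se_exp = exposure$se,
    beta_out = NA_real_, se_out = NA_real_,
    eaf_exp = exposure$eaf, eaf_out = NA_real_,
    action = rep("dropped", n), drop_reason = rep("", n),
    stringsAsFactors = FALSE)

  band_lo <- palindrome_eaf_limit
  band_hi <- 1 - palindrome_eaf_limit
  decidable <- function(f) !is.na(f) && (f < band_lo || f > band_hi)

  for (i in seq_len(n)) {
    j <- out_idx[i]
    if (is.na(j)) {
      res$drop_reason[i] <- "missing_in_outcome"
      next
    }
    e1 <- exposure$effect_allele[i]
    o1 <- exposure$other_allele[i]
    e2 <- outcome$effect_allele[j]
    o2 <- outcome$other_allele[j]
    b_out <- outcome$beta[j]
    f_out <- outcome$eaf[j]

    if (is_palindromic(e1, o1)) {
      # Alleles cannot reveal strand; require the same pair, then orient by
      # frequency agreement.
      if (!setequal(c(e1, o1), c(e2, o2))) {
        res$drop_reason[i] <- "allele_mismatch"
        next
      }
      if (e2 != e1) {            # label alignment first
        b_out <- -b_out
        f_out <- if (is.na(f_out)) NA_real_ else 1 - f_out
      }
      f_exp <- exposure$eaf[i]
      if (!decidable(f_exp) || !decidable(f_out)) {
        res$drop_reason[i] <- "ambiguous_palindrome"
        next
      }
      if ((f_exp < 0.5) != (f_out < 0.5)) {  # opposite strands: flip again
        b_out <- -b_out
        f_out <- 1 - f_out
      }
      action <- "palindrome_resolved"
    } else if (e2 == e1 && o2 == o1) {
      action <- "kept_as_is"
    } else if (e2 == o1 && o2 == e1) {
      b_out <- -b_out
      f_out <- if (is.na(f_out)) NA_real_ else 1 - f_out
      action <- "outcome_flipped"
    } else {
      ce2 <- ALLELE_COMPLEMENT[[e2]]
      co2 <- ALLELE_COMPLEMENT[[o2]]
      if (ce2 == e1 && co2 == o1) {
        action <- "kept_as_is"
      } else if (ce2 == o1 && co2 == e1) {
        b_out <- -b_out
        f_out <- if (is.na(f_out)) NA_real_ else 1 - f_out
        action <- "outcome_flipped"
      } else {
        res$drop_reason[i] <- "allele_mismatch"
        next
      }
    }
    res$action[i] <- action
    res$beta_out[i] <- b_out
    res$se_out[i] <- outcome$se[j]
    res$eaf_out[i] <- f_out
  }

  structure(res,
            exposure_meta = table_meta(exposure),
            outcome_meta = table_meta(outcome),
            palindrome_eaf_limit = palindrome_eaf_limit,
            class = c("harmonized_set", "data.frame"))
}

#' Retained (non-dropped) instruments of a harmonized set
#'
#' @param h A `harmonized_set`.
#' @return The subset of rows with `action != "dropped"`, same class.
#' @export
harmonized_instruments <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  keep <- h$action != "dropped"
  out <- as.data.frame(h, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes_to_keep <- c("exposure_meta", "outcome_meta",
                          "palindrome_eaf_limit")
  for (a in attributes_to_keep) attr(out, a) <- attr(h, a, exact = TRUE)
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' Write the harmonization audit trail
#'
#' One row per exposure SNP with its action and drop reason, tab-delimited.
#'
#' @param h A `harmonized_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_harmonization_audit <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  audit <- as.data.frame(h)[, c("SNP", "action", "drop_reason")]
  utils::write.table(audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.harmonized_set <- function(x, ...) {
  kept <- sum(x$action != "dropped")
  cat(sprintf("<harmonized_set> %d SNPs (%d harmonized, %d dropped)\n",
              nrow(x), kept, nrow(x) - kept))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Build a harmonized set from already-aligned effect vectors
#'
#' For data whose exposure and outcome effects are already expressed on a
#' common effect allele (e.g. simulation output or pre-harmonized exports),
#' bypassing the allele bookkeeping of [harmonize_pair()].
#'
#' @param snp SNP ids.
#' @param beta_exp,se_exp Exposure effects and standard errors.
#' @param beta_out,se_out Outcome effects and standard errors.
#' @param eaf_exp,eaf_out Optional effect-allele frequencies.
#' @return A `harmonized_set` with all rows marked `kept_as_is`.
#' @export
harmonized_set <- function(snp, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, eaf_out = NA_real_) {
  n <- length(snp)
  structure(data.frame(
    SNP = as.character(snp),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    eaf_exp = rep_len(eaf_exp, n), eaf_out = rep_len(eaf_out, n),
    action = rep("kept_as_is", n), drop_reason = rep("", n),
    stringsAsFactors = FALSE),
    class = c("harmonized_set", "data.frame"))
}
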