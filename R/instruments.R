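# Instrument selection: significance filter, LD clumping, confounder
# exclusion, and weak-instrument screening via the F statistic.

#' Construct an LD matrix of squared correlations
#'
#' @param snp_ids Character vector of SNP ids, one per row/column.
#' @param r2 Square symmetric matrix of r-squared values in \[0, 1\] with a
#'   unit diagonal.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != nrow(r2) || nrow(r2) != ncol(r2)) {
    stop("ld_matrix: r2 must be square with one row/column per snp_id",
         call. = FALSE)
  }
  if (anyDuplicated(snp_ids)) stop("ld_matrix: duplicate snp_ids",
                                   call. = FALSE)
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("ld_matrix: r2 values must be finite and in [0, 1]", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) {
    stop("ld_matrix: r2 must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    stop("ld_matrix: diagonal must be 1", call. = FALSE)
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from a delimited text file
#'
#' Expects a square matrix with SNP ids as both the header row and the first
#' column.
#'
#' @param path Path to a tab- or comma-delimited matrix file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  m <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE)
  ld_matrix(rownames(m), as.matrix(m))
}

#' Write an LD matrix to tab-delimited text
#'
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- data.frame(SNP = ld$snp_ids, ld$r2, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter association records by p-value
#'
#' Retains rows with `pval < threshold` (strict), preserving input order.
#' The conventional instrument-selection threshold for microbiome exposures
#' is 1e-5.
#'
#' @param table An `assoc_table`.
#' @param threshold P-value threshold in (0, 1\]; default `1e-5`.
#' @return Filtered `assoc_table`; the number of removed rows is reported
#'   via `message()`.
#' @export
filter_by_pvalue <- function(table, threshold = 1e-5) {
  stopifnot(inherits(table, "assoc_table"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  keep <- table$pval < threshold
  message(sprintf("filter_by_pvalue: removed %d of %d SNPs at p >= %g",
                  sum(!keep), nrow(table), threshold))
  retable(table[keep, , drop = FALSE], table)
}

#' Greedy LD clumping by p-value rank
#'
#' Ranks candidates by ascending p-value and accepts a SNP iff its r-squared
#' with every previously accepted SNP is below `r2_threshold`. When the table
#' carries a numeric `pos` column (base pairs) and `window_kb` is finite,
#' pairs farther apart than `window_kb` (or on different `chr`) are treated
#' as unlinked (r-squared 0). Output rows keep the original table order.
#'
#' @param candidates An `assoc_table`; every SNP must appear in `ld`.
#' @param ld An [ld_matrix()].
#' @param r2_threshold Independence threshold; default 0.001.
#' @param window_kb Clumping window in kilobases; default 10000. Ignored when
#'   the table has no `pos` column.
#' @return The accepted subset as an `assoc_table`.
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001,
                     window_kb = 10000) {
  stopifnot(inherits(candidates, "assoc_table"), inherits(ld, "ld_matrix"))
  if (nrow(candidates) == 0) return(candidates)
  missing_ids <- setdiff(candidates$SNP, ld$snp_ids)
  if (length(missing_ids) > 0) {
    stop("ld_clump: candidate SNP(s) absent from LD matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  has_pos <- "pos" %in% names(candidates) &&
    all(is.finite(as.numeric(candidates$pos))) && is.finite(window_kb)
  ord <- order(candidates$pval)
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      r2 <- ld$r2[candidates$SNP[i], candidates$SNP[j]]
      if (has_pos) {
        same_chr <- !("chr" %in% names(candidates)) ||
          identical(candidates$chr[i], candidates$chr[j])
        far <- abs(as.numeric(candidates$pos[i]) -
                     as.numeric(candidates$pos[j])) > window_kb * 1000
        if (!same_chr || far) r2 <- 0
      }
      if (r2 >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  keep <- sort(accepted)
  message(sprintf("ld_clump: kept %d of %d SNPs at r2 < %g",
                  length(keep), nrow(candidates), r2_threshold))
  retable(candidates[keep, , drop = FALSE], candidates)
}

#' Remove SNPs on an exclusion list
#'
#' Stands in for a confounder screen (e.g. a PhenoScanner-derived list):
#' removes listed SNPs and logs each removal with the supplied reason.
#' Listed ids absent from the table are ignored with a warning.
#'
#' @param table An `assoc_table`.
#' @param exclusion_list Character vector of SNP ids to drop.
#' @param reason Free-text reason recorded in the table's diagnostics.
#' @return Filtered `assoc_table`.
#' @export
exclude_snps <- function(table, exclusion_list, reason = "on exclusion list") {
  stopifnot(inherits(table, "assoc_table"))
  exclusion_list <- as.character(exclusion_list)
  hit <- table$SNP %in% exclusion_list
  unknown <- setdiff(exclusion_list, table$SNP)
  if (length(unknown) > 0) {
    warning("exclude_snps: ", length(unknown),
            " listed id(s) not present in table (ignored)", call. = FALSE)
  }
  diags <- if (any(hit)) {
    data.frame(SNP = table$SNP[hit], field = "SNP", problem = reason,
               action = "row excluded", stringsAsFactors = FALSE)
  } else NULL
  message(sprintf("exclude_snps: removed %d SNP(s) (%s)", sum(hit), reason))
  retable(table[!hit, , drop = FALSE], table, extra_diags = diags)
}

#' Read a SNP exclusion list from text
#'
#' One SNP id per line; an optional second tab- or comma-separated column
#' holds a reason and is ignored here.
#'
#' @param path File path.
#' @return Character vector of SNP ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "[\t,]"), `[[`, character(1), 1L)
}

#' Variance in the exposure explained by one SNP
#'
#' Computed from the t statistic: `r2 = t^2 / (t^2 + n - 2)` with
#' `t = beta/se`. This form is scale-free and does not need the effect-allele
#' frequency; the frequency-based alternative `2*eaf*(1-eaf)*beta^2` is
#' available via `method = "eaf"` (it assumes a standardized trait).
#'
#' @param beta,se,n Per-SNP effect, standard error, sample size (vectors
#'   recycle).
#' @param eaf Effect-allele frequency, required for `method = "eaf"`.
#' @param method `"tstat"` (default) or `"eaf"`.
#' @return Fraction(s) in \[0, 1).
#' @export
variance_explained <- function(beta, se, n, eaf = NULL,
                               method = c("tstat", "eaf")) {
  method <- match.arg(method)
  if (method == "eaf") {
    if (is.null(eaf) || anyNA(eaf)) {
      stop("variance_explained: eaf required for method = 'eaf'",
           call. = FALSE)
    }
    return(pmin(2 * eaf * (1 - eaf) * beta^2, 1 - 1e-12))
  }
  if (any(n <= 2)) stop("variance_explained: n must exceed 2", call. = FALSE)
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Instrument-strength F statistic
#'
#' `F = r2 * (n - k - 1) / (k * (1 - r2))` where `r2` is the variance
#' explained by the `k` instrument(s) in a sample of size `n`. The
#' conventional weak-instrument cutoff is F > 10.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of instruments; default 1.
#' @return F value(s) >= 0.
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) {
    stop("f_statistic: r2 must be in [0, 1)", call. = FALSE)
  }
  if (any(k < 1)) stop("f_statistic: k must be >= 1", call. = FALSE)
  if (any(n <= k + 1)) {
    stop("f_statistic: n must exceed k + 1", call. = FALSE)
  }
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Screen out weak instruments by per-SNP F statistic
#'
#' Computes each SNP's variance explained and F (with `k = 1`), removes SNPs
#' with `F <= f_threshold`, and returns full diagnostics for every candidate,
#' including the joint F of the retained set (`k` = set size) as an
#' attribute.
#'
#' @param table An `assoc_table`.
#' @param f_threshold Weak-instrument cutoff; default 10.
#' @param r2_method Passed to [variance_explained()].
#' @return List with elements `table` (survivors, an `assoc_table`) and
#'   `diagnostics` (data frame: `SNP`, `r2_exposure`, `f_stat`, `n`, `k`,
#'   `retained`); attribute `joint_f` on the diagnostics holds the joint F.
#' @export
screen_weak_instruments <- function(table, f_threshold = 10,
                                    r2_method = c("tstat", "eaf")) {
  stopifnot(inherits(table, "assoc_table"))
  r2_method <- match.arg(r2_method)
  if (nrow(table) == 0) {
    diags <- data.frame(SNP = character(), r2_exposure = numeric(),
                        f_stat = numeric(), n = numeric(), k = integer(),
                        retained = logical())
    return(list(table = table, diagnostics = diags))
  }
  r2 <- variance_explained(table$beta, table$se, table$n, eaf = table$eaf,
                           method = r2_method)
  f <- f_statistic(r2, table$n, k = 1)
  keep <- f > f_threshold
  diags <- data.frame(SNP = table$SNP, r2_exposure = r2, f_stat = f,
                      n = table$n, k = 1L, retained = keep,
                      stringsAsFactors = FALSE)
  if (any(keep)) {
    r2_joint <- sum(r2[keep])
    k_joint <- sum(keep)
    n_min <- min(table$n[keep])
    attr(diags, "joint_f") <- if (r2_joint < 1 && n_min > k_joint + 1) {
      f_statistic(r2_joint, n_min, k = k_joint)
    } else NA_real_
  }
  message(sprintf("screen_weak_instruments: removed %d of %d SNPs at F <= %g",
                  sum(!keep), nrow(table), f_threshold))
  list(table = retable(table[keep, , drop = FALSE], table),
       diagnostics = diags)
}
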