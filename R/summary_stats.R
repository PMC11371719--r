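# GWAS summary-statistics data model: study metadata, association tables,
# validation, and delimited-text readers/writers.

#' Canonical column names for association tables
#'
#' On-disk and in-memory association tables use these columns, in this order:
#' `SNP`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' Extra columns (e.g. `chr`, `pos`) are carried through untouched.
#'
#' @return Character vector of the eight canonical column names.
#' @export
canonical_columns <- function() {
  c("SNP", "effect_allele", "other_allele", "eaf", "beta", "se", "pval", "n")
}

#' Study metadata for one GWAS
#'
#' @param trait_name Trait label, e.g. a bacterial genus or a disease.
#' @param trait_type `"continuous"` (e.g. genus abundance, effects in SD
#'   units) or `"binary"` (case/control, effects on the log-odds scale).
#' @param n_total Total sample size.
#' @param n_cases,n_controls Case/control counts for binary traits; `NA`
#'   when unknown or not applicable. When both are present they must sum to
#'   `n_total`.
#' @return A `study_meta` object (named list).
#' @examples
#' study_meta("dermatomyositis", "binary", 213353, 208, 213145)
#' @export
study_meta <- function(trait_name, trait_type = c("continuous", "binary"),
                       n_total, n_cases = NA_integer_,
                       n_controls = NA_integer_) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_name), length(trait_name) == 1L,
            nzchar(trait_name))
  n_total <- as.numeric(n_total)
  stopifnot(length(n_total) == 1L, is.finite(n_total), n_total >= 1)
  n_cases <- as.numeric(n_cases %||% NA_real_)
  n_controls <- as.numeric(n_controls %||% NA_real_)
  if (length(n_cases) == 0) n_cases <- NA_real_
  if (length(n_controls) == 0) n_controls <- NA_real_
  if (!is.na(n_cases) && !is.na(n_controls) &&
      n_cases + n_controls != n_total) {
    stop("study_meta: n_cases + n_controls must equal n_total (",
         n_cases, " + ", n_controls, " != ", n_total, ")", call. = FALSE)
  }
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 n_total = n_total, n_cases = n_cases,
                 n_controls = n_controls),
            class = "study_meta")
}

#' @export
print.study_meta <- function(x, ...) {
  cc <- if (!is.na(x$n_cases)) {
    sprintf(" (%d cases / %d controls)", x$n_cases, x$n_controls)
  } else ""
  cat(sprintf("<study_meta> %s [%s], n = %s%s\n", x$trait_name, x$trait_type,
              format(x$n_total, big.mark = ","), cc))
  invisible(x)
}

#' Build a validated association table
#'
#' Wraps a data frame of per-SNP association records into an `assoc_table`:
#' alleles are upper-cased, rows violating hard invariants are dropped with
#' one diagnostic each, and study metadata is attached. Hard invariants:
#' alleles are single bases in A/C/G/T and differ from each other (indels and
#' multi-allelic records are rejected), `se > 0`, `pval` in (0, 1], `eaf` in
#' [0, 1] or missing, `n >= 1`. A `pval` inconsistent with `|beta/se|` under
#' the normal approximation by more than two orders of magnitude produces a
#' warning diagnostic but keeps the row. Duplicate SNP ids are an error.
#'
#' @param df Data frame with the columns of [canonical_columns()].
#' @param meta A [study_meta()] object.
#' @return An `assoc_table` (data frame subclass) with attributes `meta` and
#'   `diagnostics` (data frame: `SNP`, `field`, `problem`, `action`).
#' @export
association_table <- function(df, meta) {
  stopifnot(inherits(meta, "study_meta"), is.data.frame(df))
  missing_cols <- setdiff(canonical_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("association_table: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df$SNP <- as.character(df$SNP)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  dup <- unique(df$SNP[duplicated(df$SNP)])
  if (length(dup) > 0) {
    stop("association_table: duplicate SNP id(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }

  diags <- list()
  note <- function(snp, field, problem, action) {
    diags[[length(diags) + 1L]] <<- data.frame(
      SNP = snp, field = field, problem = problem, action = action,
      stringsAsFactors = FALSE)
  }

  bases <- c("A", "C", "G", "T")
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!(r$effect_allele %in% bases)) {
      note(r$SNP, "effect_allele",
           paste0("not a single base A/C/G/T: '", r$effect_allele, "'"),
           "row dropped")
      keep[i] <- FALSE
      next
    }
    if (!(r$other_allele %in% bases)) {
      note(r$SNP, "other_allele",
           paste0("not a single base A/C/G/T: '", r$other_allele, "'"),
           "row dropped")
      keep[i] <- FALSE
      next
    }
    if (r$effect_allele == r$other_allele) {
      note(r$SNP, "other_allele", "effect and other allele identical",
           "row dropped")
      keep[i] <- FALSE
      next
    }
    if (is.na(r$beta)) {
      note(r$SNP, "beta", "not a finite number", "row dropped")
      keep[i] <- FALSE
      next
    }
    if (is.na(r$se) || r$se <= 0) {
      note(r$SNP, "se", "must be a finite number > 0", "row dropped")
      keep[i] <- FALSE
      next
    }
    if (is.na(r$pval) || r$pval <= 0 || r$pval > 1) {
      note(r$SNP, "pval", "must be in (0, 1]", "row dropped")
      keep[i] <- FALSE
      next
    }
    if (is.na(r$n) || r$n < 1) {
      note(r$SNP, "n", "must be >= 1", "row dropped")
      keep[i] <- FALSE
      next
    }
    if (!is.na(r$eaf) && (r$eaf < 0 || r$eaf > 1)) {
      note(r$SNP, "eaf", "must be in [0, 1] or NA", "row dropped")
      keep[i] <- FALSE
      next
    }
    # Soft check: reported p consistent with |beta/se| within 2 orders of
    # magnitude on the log10 scale.
    p_expect <- pval_from_z(r$beta / r$se)
    if (abs(log10(p_expect) - log10(r$pval)) > 2) {
      note(r$SNP, "pval",
           sprintf("reported p (%.3g) differs from normal-approximation p (%.3g) by > 2 orders of magnitude",
                   r$pval, p_expect),
           "warning only")
    }
  }

  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  diagnostics <- if (length(diags) > 0) {
    do.call(rbind, diags)
  } else {
    data.frame(SNP = character(), field = character(), problem = character(),
               action = character(), stringsAsFactors = FALSE)
  }
  structure(out,
            meta = meta,
            diagnostics = diagnostics,
            class = c("assoc_table", "data.frame"))
}

#' Retrieve metadata or validation diagnostics from an association table
#'
#' @param table An `assoc_table`.
#' @return `table_meta()`: the [study_meta()]; `table_diagnostics()`: the
#'   row-level diagnostics data frame collected at validation time.
#' @export
table_meta <- function(table) attr(table, "meta", exact = TRUE)

#' @rdname table_meta
#' @export
table_diagnostics <- function(table) attr(table, "diagnostics", exact = TRUE)

# Rebuild an assoc_table around a row subset, preserving meta and appending
# diagnostics. Used by filters so attributes survive subsetting.
retable <- function(df, template, extra_diags = NULL) {
  d <- attr(template, "diagnostics", exact = TRUE)
  if (!is.null(extra_diags) && nrow(extra_diags) > 0) d <- rbind(d, extra_diags)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, meta = attr(template, "meta", exact = TRUE),
            diagnostics = d, class = c("assoc_table", "data.frame"))
}

#' @export
print.assoc_table <- function(x, ...) {
  m <- table_meta(x)
  cat(sprintf("<assoc_table> %s [%s]: %d SNPs\n",
              m$trait_name, m$trait_type, nrow(x)))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table with a header row, renames source
#' columns to the canonical names via `column_map`, and validates the result
#' with [association_table()]. Rows that violate hard invariants are dropped,
#' each with one diagnostic retrievable via [table_diagnostics()].
#'
#' @param path Path to the delimited file. The delimiter is sniffed from the
#'   header line (tab wins over comma) unless `sep` is given.
#' @param meta A [study_meta()] for the study the file came from.
#' @param column_map Named character vector mapping canonical names to source
#'   header names, e.g. `c(SNP = "rsid", beta = "Effect")`. Canonical names
#'   absent from the map are assumed to appear verbatim in the file.
#' @param sep Field separator; `NULL` (default) to sniff.
#' @return A validated `assoc_table`.
#' @export
read_association_table <- function(path, meta, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop("read_association_table: file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA", quote = "\"",
                           comment.char = "")
  wanted <- canonical_columns()
  src <- stats::setNames(wanted, wanted)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
      stop("column_map must be a named vector (canonical = source)",
           call. = FALSE)
    }
    bad <- setdiff(names(column_map), wanted)
    if (length(bad) > 0) {
      stop("column_map names must be canonical columns; unknown: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    src[names(column_map)] <- column_map
  }
  missing_src <- src[!(src %in% names(raw))]
  if (length(missing_src) > 0) {
    stop("read_association_table: mapped column(s) absent from file: ",
         paste(sprintf("%s (for %s)", missing_src, names(missing_src)),
               collapse = ", "), call. = FALSE)
  }
  df <- raw[, src, drop = FALSE]
  names(df) <- wanted
  # carry extra columns (e.g. chr/pos) through untouched
  extras <- setdiff(names(raw), src)
  for (e in extras) df[[e]] <- raw[[e]]
  for (e in intersect(extras, c("pos", "chr_pos"))) {
    df[[e]] <- suppressWarnings(as.numeric(df[[e]]))
  }
  association_table(df, meta)
}

#' Write an association table to canonical tab-delimited text
#'
#' Writes the canonical columns (plus any extras) tab-delimited with `NA` as
#' the missing-value sentinel. `read_association_table()` on the result
#' reproduces the table field-for-field.
#'
#' @param table An `assoc_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_association_table <- function(table, path) {
  stopifnot(inherits(table, "assoc_table"))
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("write_association_table: cannot write '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}
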