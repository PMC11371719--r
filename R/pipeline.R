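# Pipeline orchestration: run configuration, the forward/reverse stage
# chain over exposure-outcome pairs, and paper-shaped report exports.

#' Build and validate a pipeline run configuration
#'
#' An exposure or outcome spec is a list with `name`, `path` (canonical or
#' mapped summary-statistics file), optional `column_map`, optional
#' `ld_path` (square LD matrix for clumping; omitted means instruments are
#' treated as independent), and `meta` (a [study_meta()] or a plain list of
#' its fields).
#'
#' @param exposures,outcomes Lists of study specs as above.
#' @param iv_pval Instrument p-value threshold for forward runs (default
#'   1e-5).
#' @param reverse_iv_pval Threshold for reverse runs (default 1e-5).
#' @param ld_r2 LD clumping threshold (default 0.001).
#' @param clump_window_kb Clumping window in kb (default 10000).
#' @param f_threshold Weak-instrument F cutoff (default 10).
#' @param palindrome_eaf_limit Palindrome ambiguity band edge (default
#'   0.42).
#' @param ivw_model `"multiplicative_random"` (default) or `"fixed"`.
#' @param n_boot Weighted-median bootstrap replicates (default 1000).
#' @param presso_n_sim MR-PRESSO simulation replicates (default 1000).
#' @param outlier_alpha MR-PRESSO outlier significance level (default
#'   0.05).
#' @param seed Integer seed; mandatory (all stochastic steps derive
#'   per-pair child seeds from it).
#' @param exclusion_list_path Optional path to a confounder-SNP exclusion
#'   list (one id per line).
#' @param output_dir Directory reports are written into.
#' @return A `run_config` object (named list).
#' @export
run_config <- function(exposures, outcomes,
                       iv_pval = 1e-5, reverse_iv_pval = 1e-5,
                       ld_r2 = 0.001, clump_window_kb = 10000,
                       f_threshold = 10, palindrome_eaf_limit = 0.42,
                       ivw_model = "multiplicative_random",
                       n_boot = 1000, presso_n_sim = 1000,
                       outlier_alpha = 0.05, seed = 1L,
                       exclusion_list_path = NULL,
                       output_dir = "mr_output") {
  norm_spec <- function(s) {
    stopifnot(is.list(s), !is.null(s$name), !is.null(s$path),
              !is.null(s$meta))
    if (!inherits(s$meta, "study_meta")) {
      s$meta <- do.call(study_meta, s$meta)
    }
    s
  }
  stopifnot(is.list(exposures), length(exposures) >= 1,
            is.list(outcomes), length(outcomes) >= 1,
            iv_pval > 0, iv_pval <= 1, reverse_iv_pval > 0,
            reverse_iv_pval <= 1,
            ld_r2 > 0, ld_r2 <= 1, f_threshold >= 0,
            palindrome_eaf_limit > 0, palindrome_eaf_limit < 0.5,
            ivw_model %in% c("multiplicative_random", "fixed"),
            n_boot >= 1, presso_n_sim >= 1,
            outlier_alpha > 0, outlier_alpha < 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(exposures = lapply(exposures, norm_spec),
                 outcomes = lapply(outcomes, norm_spec),
                 iv_pval = iv_pval, reverse_iv_pval = reverse_iv_pval,
                 ld_r2 = ld_r2, clump_window_kb = clump_window_kb,
                 f_threshold = f_threshold,
                 palindrome_eaf_limit = palindrome_eaf_limit,
                 ivw_model = ivw_model, n_boot = n_boot,
                 presso_n_sim = presso_n_sim,
                 outlier_alpha = outlier_alpha, seed = as.integer(seed),
                 exclusion_list_path = exclusion_list_path,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read or write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_run_config()`: a [run_config()]; `write_run_config()`:
#'   invisibly, `path`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  raw$exclusion_list_path <- raw$exclusion_list_path %||% NULL
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$exposures <- lapply(out$exposures, function(s) {
    s$meta <- unclass(s$meta)
    s
  })
  out$outcomes <- lapply(out$outcomes, function(s) {
    s$meta <- unclass(s$meta)
    s
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

# Load one study spec into an assoc_table (+ optional LD matrix).
load_study <- function(spec) {
  tab <- read_association_table(spec$path, meta = spec$meta,
                                column_map = spec$column_map)
  ld <- if (!is.null(spec$ld_path)) read_ld_matrix(spec$ld_path) else NULL
  list(table = tab, ld = ld)
}

#' Run the full MR stage chain on one exposure-outcome pair
#'
#' p-value filter -> exclusion list -> LD clump -> F screen -> harmonize ->
#' IVW + MR-Egger + weighted median -> Cochran's Q (both fits), Egger
#' intercept, leave-one-out, MR-PRESSO. Methods whose instrument count falls
#' below their minimum return not-estimable results rather than errors.
#'
#' @param exposure,outcome `assoc_table`s.
#' @param config A [run_config()] (thresholds and estimator settings).
#' @param ld Optional [ld_matrix()] for the exposure SNPs; `NULL` skips
#'   clumping (instruments treated as independent).
#' @param exclusion_list Optional character vector of confounder SNP ids.
#' @param seed Seed for the stochastic steps of this pair.
#' @param iv_pval Instrument p-value threshold (defaults to
#'   `config$iv_pval`; reverse runs pass `config$reverse_iv_pval`).
#' @return An `mr_report`: list with `exposure`, `outcome` (trait names),
#'   `stage_counts`, `harmonized`, `estimates` (list of `mr_estimate`),
#'   `heterogeneity`, `pleiotropy`, `loo`, `presso`, `significant` (IVW
#'   p < 0.05), `error` (`NULL` on success).
#' @export
run_pair <- function(exposure, outcome, config, ld = NULL,
                     exclusion_list = NULL, seed = config$seed,
                     iv_pval = config$iv_pval) {
  stopifnot(inherits(config, "run_config"))
  counts <- c(input = nrow(exposure))

  sel <- suppressMessages(filter_by_pvalue(exposure, iv_pval))
  counts["pval_filter"] <- nrow(sel)

  if (!is.null(exclusion_list) && length(exclusion_list) > 0) {
    sel <- suppressWarnings(suppressMessages(
      exclude_snps(sel, exclusion_list, reason = "confounder-associated")))
  }
  counts["confounder_exclusion"] <- nrow(sel)

  if (!is.null(ld) && nrow(sel) > 0) {
    present <- sel$SNP %in% ld$snp_ids
    if (!all(present)) {
      # SNPs missing from the LD panel cannot be cleared for independence.
      sel <- retable(sel[present, , drop = FALSE], sel)
    }
    sel <- suppressMessages(ld_clump(sel, ld, r2_threshold = config$ld_r2,
                                     window_kb = config$clump_window_kb))
  }
  counts["ld_clump"] <- nrow(sel)

  scr <- suppressMessages(
    screen_weak_instruments(sel, f_threshold = config$f_threshold))
  sel <- scr$table
  counts["f_screen"] <- nrow(sel)

  harm <- harmonize_pair(sel, outcome,
                         palindrome_eaf_limit = config$palindrome_eaf_limit)
  hk <- harmonized_instruments(harm)
  counts["harmonized"] <- nrow(hk)

  nsnp <- nrow(hk)
  estimates <- list(
    ivw = if (nsnp >= 1) mr_ivw(hk, model = config$ivw_model)
          else mr_not_estimable("IVW", 0L, "no harmonized instruments"),
    egger = mr_egger(hk)$estimate,
    wme = mr_weighted_median(hk, n_boot = config$n_boot,
                             seed = child_seed(seed, 2L)))
  egger_fit <- if (nsnp >= 3) mr_egger(hk)$fit else NULL

  heterogeneity <- list(ivw = cochran_q(hk, "IVW"),
                        egger = cochran_q(hk, "MR-Egger"))
  pleiotropy <- if (!is.null(egger_fit)) egger_intercept_test(egger_fit)
                else NULL
  loo <- if (nsnp >= 3) leave_one_out(hk, model = config$ivw_model)
         else NULL
  presso <- mr_presso(hk, n_sim = config$presso_n_sim,
                      outlier_alpha = config$outlier_alpha,
                      seed = child_seed(seed, 3L))

  ivw_p <- estimates$ivw$pval
  structure(list(exposure = table_meta(exposure)$trait_name,
                 outcome = table_meta(outcome)$trait_name,
                 stage_counts = counts,
                 instrument_diagnostics = scr$diagnostics,
                 harmonized = harm,
                 estimates = estimates,
                 egger_fit = egger_fit,
                 heterogeneity = heterogeneity,
                 pleiotropy = pleiotropy,
                 loo = loo,
                 presso = presso,
                 significant = isTRUE(!is.na(ivw_p) && ivw_p < 0.05),
                 error = NULL),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %s -> %s%s\n", x$exposure, x$outcome,
              if (!is.null(x$error)) " [FAILED]" else
                if (x$significant) " [significant]" else ""))
  if (!is.null(x$error)) {
    cat("  error:", conditionMessage(x$error), "\n")
    return(invisible(x))
  }
  cat("  stages:", paste(sprintf("%s=%d", names(x$stage_counts),
                                 x$stage_counts), collapse = " "), "\n")
  for (e in x$estimates) print(e)
  invisible(x)
}

# One failed pair report, so a batch survives per-pair errors.
failed_report <- function(exp_name, out_name, err) {
  structure(list(exposure = exp_name, outcome = out_name,
                 stage_counts = c(input = NA_integer_), harmonized = NULL,
                 estimates = list(), heterogeneity = list(),
                 pleiotropy = NULL, loo = NULL, presso = NULL,
                 significant = FALSE, error = err),
            class = "mr_report")
}

#' Run forward MR over every exposure-outcome pair in a config
#'
#' Each pair runs in isolation: an error in one pair is captured on its
#' report and the batch continues. Pairs with IVW p < 0.05 are flagged
#' `significant` (the conventional raw-p criterion; an FDR column is added
#' at export but never gates significance).
#'
#' @param config A [run_config()].
#' @return List of `mr_report`s, one per exposure x outcome combination.
#' @export
run_forward <- function(config) {
  stopifnot(inherits(config, "run_config"))
  excl <- if (!is.null(config$exclusion_list_path)) {
    read_exclusion_list(config$exclusion_list_path)
  } else NULL
  reports <- list()
  idx <- 0L
  for (espec in config$exposures) {
    estudy <- tryCatch(load_study(espec), error = function(e) e)
    for (ospec in config$outcomes) {
      idx <- idx + 1L
      reports[[idx]] <- if (inherits(estudy, "error")) {
        failed_report(espec$name, ospec$name, estudy)
      } else {
        tryCatch({
          ostudy <- load_study(ospec)
          run_pair(estudy$table, ostudy$table, config, ld = estudy$ld,
                   exclusion_list = excl,
                   seed = child_seed(config$seed, idx))
        }, error = function(e) failed_report(espec$name, ospec$name, e))
      }
    }
  }
  reports
}

#' Run reverse MR for flagged pairs
#'
#' Swaps exposure and outcome roles for each named pair and reruns the
#' identical stage chain ([run_pair()]) with the reverse instrument
#' threshold. With very few disease-associated SNPs surviving selection,
#' MR-Egger and the weighted median are frequently not estimable; their
#' entries come back flagged accordingly (exported as "/" sentinels).
#'
#' @param config A [run_config()].
#' @param significant_pairs Either the output of [run_forward()] (only
#'   pairs with `significant = TRUE` are reversed) or a list of
#'   `list(exposure =, outcome =)` name pairs. Empty input yields an empty
#'   list.
#' @return List of `mr_report`s with roles swapped (the disease is the
#'   exposure).
#' @export
run_reverse <- function(config, significant_pairs) {
  stopifnot(inherits(config, "run_config"))
  pairs <- Filter(Negate(is.null), lapply(significant_pairs, function(p) {
    if (inherits(p, "mr_report")) {
      if (!isTRUE(p$significant)) return(NULL)
      list(exposure = p$exposure, outcome = p$outcome)
    } else p
  }))
  if (length(pairs) == 0) return(list())
  find_spec <- function(specs, name) {
    for (s in specs) if (s$name == name) return(s)
    stop("run_reverse: no spec named '", name, "' in config", call. = FALSE)
  }
  excl <- if (!is.null(config$exclusion_list_path)) {
    read_exclusion_list(config$exclusion_list_path)
  } else NULL
  reports <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    reports[[i]] <- tryCatch({
      # Role swap: the original outcome (disease) becomes the exposure.
      espec <- find_spec(config$outcomes, p$outcome)
      ospec <- find_spec(config$exposures, p$exposure)
      estudy <- load_study(espec)
      ostudy <- load_study(ospec)
      run_pair(estudy$table, ostudy$table, config, ld = estudy$ld,
               exclusion_list = excl,
               seed = child_seed(config$seed, 1000L + i),
               iv_pval = config$reverse_iv_pval)
    }, error = function(e) failed_report(p$outcome, p$exposure, e))
  }
  reports
}

# "/" sentinel formatting for not-estimable cells.
fmt_cell <- function(x, digits = 6) {
  ifelse(is.na(x), "/", formatC(x, digits = digits, format = "g"))
}

estimates_table <- function(reports) {
  rows <- list()
  for (r in reports) {
    if (!is.null(r$error)) {
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = r$exposure, outcome = r$outcome, method = "/",
        nsnp = "/", OR = "/", lower = "/", upper = "/", pval = "/",
        significant = "", stringsAsFactors = FALSE)
      next
    }
    for (e in r$estimates) {
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = r$exposure, outcome = r$outcome, method = e$method,
        nsnp = as.character(e$nsnp),
        OR = fmt_cell(e$or_), lower = fmt_cell(e$ci_low),
        upper = fmt_cell(e$ci_high), pval = fmt_cell(e$pval),
        significant = if (e$method == "IVW" && isTRUE(r$significant))
          "yes" else "", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(exposure = character(), outcome = character(),
                      method = character(), nsnp = character(),
                      OR = character(), lower = character(),
                      upper = character(), pval = character(),
                      significant = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # FDR over IVW p-values across pairs (informational only).
  ivw <- out$method == "IVW" & out$pval != "/"
  out$ivw_fdr <- ""
  if (any(ivw)) {
    out$ivw_fdr[ivw] <- fmt_cell(stats::p.adjust(as.numeric(out$pval[ivw]),
                                                 method = "BH"))
  }
  out
}

sensitivity_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (!is.null(r$error)) {
      return(data.frame(exposure = r$exposure, outcome = r$outcome,
                        q_ivw = "/", p_q_ivw = "/", q_egger = "/",
                        p_q_egger = "/", intercept = "/",
                        p_intercept = "/", presso_global_p = "/",
                        presso_outliers = "/", stringsAsFactors = FALSE))
    }
    hi <- r$heterogeneity$ivw
    he <- r$heterogeneity$egger
    data.frame(
      exposure = r$exposure, outcome = r$outcome,
      q_ivw = fmt_cell(hi$q), p_q_ivw = fmt_cell(hi$pval),
      q_egger = fmt_cell(he$q), p_q_egger = fmt_cell(he$pval),
      intercept = if (!is.null(r$pleiotropy))
        fmt_cell(r$pleiotropy$intercept) else "/",
      p_intercept = if (!is.null(r$pleiotropy))
        fmt_cell(r$pleiotropy$pval) else "/",
      presso_global_p = if (!is.null(r$presso))
        fmt_cell(r$presso$global_pval) else "/",
      presso_outliers = if (!is.null(r$presso) &&
                              length(r$presso$outliers) > 0)
        paste(r$presso$outliers, collapse = ",") else "",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export pipeline reports as delimited tables plus a run manifest
#'
#' Writes into `outdir`: `estimates.tsv` (method, nsnp, OR, CI, p — the
#' shape of a published MR results table, with "/" sentinels for
#' not-estimable cells), `sensitivity.tsv` (Q statistics, Egger intercept,
#' MR-PRESSO), per-pair `harmonization_<i>.tsv` audits,
#' `leave_one_out_<i>.tsv` series, `scatter_<i>.tsv` per-SNP effect pairs
#' (for scatter plots), and `manifest.json` (config + seed + package
#' version; re-readable with [read_run_config()]).
#'
#' @param reports List of `mr_report`s (forward and/or reverse).
#' @param outdir Output directory, created if needed.
#' @param config The [run_config()] that produced the reports.
#' @param prefix File-name prefix (e.g. `"forward"` / `"reverse"`).
#' @return Invisibly, the paths written.
#' @export
export_reports <- function(reports, outdir, config, prefix = "forward") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, file) {
    p <- file.path(outdir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(estimates_table(reports), paste0(prefix, "_estimates.tsv"))
  if (length(reports) > 0) {
    wr(sensitivity_table(reports), paste0(prefix, "_sensitivity.tsv"))
  }
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    if (!is.null(r$error)) next
    tag <- sprintf("%s_%02d", prefix, i)
    if (!is.null(r$harmonized)) {
      wr(as.data.frame(r$harmonized)[, c("SNP", "action", "drop_reason")],
         paste0("harmonization_", tag, ".tsv"))
      hk <- harmonized_instruments(r$harmonized)
      if (nrow(hk) > 0) {
        wr(hk[, c("SNP", "beta_exp", "se_exp", "beta_out", "se_out")],
           paste0("scatter_", tag, ".tsv"))
      }
    }
    if (!is.null(r$loo)) {
      wr(as.data.frame(r$loo), paste0("leave_one_out_", tag, ".tsv"))
    }
  }
  manifest <- file.path(outdir, "manifest.json")
  cfg <- unclass(config)
  cfg$exposures <- lapply(cfg$exposures, function(s) {
    s$meta <- unclass(s$meta)
    s
  })
  cfg$outcomes <- lapply(cfg$outcomes, function(s) {
    s$meta <- unclass(s$meta)
    s
  })
  jsonlite::write_json(
    list(config = cfg,
         package = "mrpipe",
         version = as.character(utils::packageVersion("mrpipe")),
         n_reports = length(reports)),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
    na = "null")
  paths <- c(paths, manifest)
  invisible(paths)
}
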