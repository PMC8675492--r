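# Summary-statistics I/O: validated association tables, SE reconstruction
# from p-values, and result-table serialization.

STANDARD_FIELDS <- c("variant_id", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pvalue", "n")

#' Construct a validated GWAS association table
#'
#' An association table holds one row per variant: identifier, effect and
#' other allele, effect-allele frequency (EAF), effect size, standard error,
#' p-value and sample size, for a single trait. Effect sizes for binary
#' traits are log-odds per effect allele.
#'
#' @param records data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n` (missing `eaf`/`n`
#'   columns are added as `NA`).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_cases,n_noncases case/non-case counts (binary traits only).
#' @param unit_sd phenotypic standard deviation in measurement units
#'   (e.g. 20.1 mm Hg for systolic blood pressure), or `NA`.
#' @param validate reject rows violating the row invariants (`se > 0`,
#'   `pvalue` in (0,1], `eaf` in \[0,1\], distinct single-base upper-case
#'   alleles are not enforced here beyond case-normalization and
#'   effect != other).
#' @return An object of class `assoc_table` (a data.frame with trait
#'   metadata attributes and a `read_log` attribute recording rejected rows).
#' @export
assoc_table <- function(records, trait_id, trait_type = c("continuous", "binary"),
                        n_cases = NA_integer_, n_noncases = NA_integer_,
                        unit_sd = NA_real_, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(records)) stop_data("`records` must be a data.frame")
  for (f in c("eaf", "n")) if (!f %in% names(records)) records[[f]] <- NA_real_
  miss <- setdiff(STANDARD_FIELDS, names(records))
  if (length(miss))
    stop_config("association table is missing required columns: ",
                paste(miss, collapse = ", "))
  records <- records[STANDARD_FIELDS]
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (f in c("eaf", "beta", "se", "pvalue", "n"))
    records[[f]] <- suppressWarnings(as.numeric(records[[f]]))

  rejected <- data.frame(variant_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (validate && nrow(records)) {
    reasons <- rep(NA_character_, nrow(records))
    bad <- function(cond, why) {
      cond[is.na(cond)] <- FALSE
      reasons[cond & is.na(reasons)] <<- why
    }
    bad(is.na(records$beta), "non-numeric or missing beta")
    bad(!is.na(records$se) & records$se <= 0, "non-positive se")
    bad(is.na(records$se), "missing se")
    bad(is.na(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1,
        "pvalue outside (0,1]")
    bad(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1),
        "eaf outside [0,1]")
    bad(records$effect_allele == records$other_allele, "identical alleles")
    bad(!grepl("^[ACGT]+$", records$effect_allele) |
          !grepl("^[ACGT]+$", records$other_allele), "non-ACGT allele")
    keep <- is.na(reasons)
    rejected <- data.frame(variant_id = records$variant_id[!keep],
                           reason = reasons[!keep], stringsAsFactors = FALSE)
    records <- records[keep, , drop = FALSE]
  }
  if (anyDuplicated(records$variant_id))
    stop_data("duplicate variant_id in association table for trait ", trait_id)
  if (trait_type == "binary" && !is.na(n_cases) && !is.na(n_noncases)) {
    ntot <- records$n[!is.na(records$n)]
    if (length(ntot) && any(abs(ntot - (n_cases + n_noncases)) > 0.5))
      warning("per-variant N differs from n_cases + n_noncases for trait ",
              trait_id, call. = FALSE)
  }
  rownames(records) <- NULL
  structure(records,
            class = c("assoc_table", "data.frame"),
            trait_id = trait_id, trait_type = trait_type,
            n_cases = n_cases, n_noncases = n_noncases, unit_sd = unit_sd,
            read_log = list(accepted = nrow(records), rejected = nrow(rejected),
                            rejects = rejected))
}

#' @export
print.assoc_table <- function(x, ...) {
  log <- attr(x, "read_log")
  cat(sprintf("GWAS association table: %s (%s), %d variants (%d rejected on read)\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x),
              log$rejected %||% 0L))
  if (!is.na(attr(x, "unit_sd")))
    cat(sprintf("  phenotype SD: %g\n", attr(x, "unit_sd")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read a GWAS summary-association table from a delimited text file
#'
#' Heterogeneous sources (consortium files, biobank downloads) are funnelled
#' through one reader by mapping standard field names onto source column
#' names. Rows violating the row invariants are rejected individually and
#' recorded in the table's read log, not fatal. `"."`, `""` and `"NA"` are
#' treated as missing. P-values are parsed from text, preserving magnitudes
#' down to 1e-300.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map named character vector, `standard_field = source_column`;
#'   unmapped standard names are looked up verbatim.
#' @param trait_id,trait_type,n_cases,n_noncases,unit_sd trait metadata,
#'   see [assoc_table()].
#' @param effect_is_or set `TRUE` when the source reports odds ratios; effects
#'   are log-transformed on read.
#' @param sep field separator (default tab).
#' @return A validated [assoc_table()].
#' @export
read_association_table <- function(path, column_map = NULL, trait_id,
                                   trait_type = c("continuous", "binary"),
                                   n_cases = NA_integer_, n_noncases = NA_integer_,
                                   unit_sd = NA_real_, effect_is_or = FALSE,
                                   sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop_config("summary-statistics file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c(".", "", "NA"), quote = "",
                           comment.char = "")
  if (!nrow(raw)) stop_data("empty summary-statistics table: ", path)
  cmap <- stats::setNames(STANDARD_FIELDS, STANDARD_FIELDS)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), STANDARD_FIELDS)
    if (length(unknown))
      stop_config("column_map refers to unknown standard fields: ",
                  paste(unknown, collapse = ", "))
    cmap[names(column_map)] <- column_map
  }
  required <- cmap[c("variant_id", "effect_allele", "other_allele",
                     "beta", "se", "pvalue")]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop_config("mapped column(s) absent from ", path, ": ",
                paste(missing_cols, collapse = ", "))
  get_col <- function(std) {
    if (cmap[[std]] %in% names(raw)) raw[[cmap[[std]]]] else NA_character_
  }
  rec <- data.frame(variant_id = get_col("variant_id"),
                    effect_allele = get_col("effect_allele"),
                    other_allele = get_col("other_allele"),
                    eaf = get_col("eaf"), beta = get_col("beta"),
                    se = get_col("se"), pvalue = get_col("pvalue"),
                    n = get_col("n"), stringsAsFactors = FALSE)
  if (effect_is_or) {
    or <- suppressWarnings(as.numeric(rec$beta))
    rec$beta <- ifelse(!is.na(or) & or > 0, log(or), NA_real_)
  }
  assoc_table(rec, trait_id = trait_id, trait_type = trait_type,
              n_cases = n_cases, n_noncases = n_noncases, unit_sd = unit_sd)
}

#' Reconstruct a standard error from an effect size and p-value
#'
#' Some outcome sources report effect and p-value but no SE. Assuming the
#' p-value came from a two-sided normal test, the SE is `|beta| / z` with
#' `z = qnorm(1 - p/2)`. Round-tripping the p-value from `beta` and the
#' returned SE reproduces the input to 1e-10 relative accuracy.
#'
#' @param beta nonzero effect size(s).
#' @param pvalue p-value(s) strictly inside (0,1), not below 1e-300 (below
#'   that the normal quantile saturates; supply a z-score instead).
#' @return positive SE, vectorized over inputs.
#' @export
se_from_pvalue <- function(beta, pvalue) {
  if (any(is.na(beta)) || any(is.na(pvalue)))
    stop_data("SE not recoverable: missing beta or pvalue")
  if (any(beta == 0)) stop_data("SE not recoverable: beta = 0")
  if (any(pvalue <= 0 | pvalue >= 1))
    stop_data("pvalue must be strictly inside (0,1)")
  if (any(pvalue < 1e-300))
    stop_data("pvalue below 1e-300; supply a z-score directly")
  z <- stats::qnorm(pvalue / 2, lower.tail = FALSE)
  abs(beta) / z
}

results_columns <- c("exposure", "outcome", "method", "n_snps", "beta", "se",
                     "ci_low", "ci_high", "or", "or_ci_low", "or_ci_high",
                     "pvalue", "Q", "Q_pvalue", "egger_intercept",
                     "egger_intercept_p", "passes_bonferroni")

method_labels <- c(wald = "Wald", ivw_fixed = "IVW-FE", ivw_mre = "IVW-MRE",
                   weighted_median = "weighted-median", egger = "MR-Egger",
                   mv_ivw = "MV-IVW", mv_egger = "MV-Egger")

#' Flatten MR estimates to a results data.frame
#'
#' @param estimates a list of [mr_estimate] objects (or a single one).
#' @param bonferroni optional p-value threshold used to fill
#'   `passes_bonferroni`.
#' @return data.frame with one row per estimate.
#' @export
estimates_to_frame <- function(estimates, bonferroni = NA_real_) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  if (!length(estimates)) stop_data("no estimates to tabulate")
  rows <- lapply(estimates, function(e) {
    or <- to_odds_ratio(e)
    label <- unname(method_labels[e$method])
    if (is.na(label)) label <- e$method
    data.frame(exposure = e$exposure %||% NA_character_,
               outcome = e$outcome %||% NA_character_,
               method = label,
               n_snps = e$n_snps, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high,
               or = or[["or"]], or_ci_low = or[["or_ci_low"]],
               or_ci_high = or[["or_ci_high"]], pvalue = e$pvalue,
               Q = e$q %||% NA_real_, Q_pvalue = e$q_pvalue %||% NA_real_,
               egger_intercept = e$intercept %||% NA_real_,
               egger_intercept_p = e$intercept_p %||% NA_real_,
               passes_bonferroni = if (is.na(bonferroni)) NA
                                   else e$pvalue < bonferroni,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write MR estimates to a tab-separated results table
#'
#' Numbers are serialized at full double precision so that re-reading the
#' file reproduces the values exactly.
#'
#' @param estimates list of [mr_estimate] objects or a data.frame from
#'   [estimates_to_frame()].
#' @param path output path.
#' @param bonferroni optional threshold for the `passes_bonferroni` column.
#' @export
write_results_table <- function(estimates, path, bonferroni = NA_real_) {
  df <- if (is.data.frame(estimates)) estimates
        else estimates_to_frame(estimates, bonferroni)
  if (!nrow(df)) stop_data("refusing to write an empty results table")
  ser <- df
  for (col in names(ser))
    if (is.numeric(ser[[col]]))
      ser[[col]] <- ifelse(is.na(ser[[col]]), "NA", fmt_num(ser[[col]]))
  ok <- tryCatch({
    utils::write.table(ser, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_data("cannot write results table to ", path, ": ",
                             conditionMessage(ok))
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path path to the TSV.
#' @return data.frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  num <- setdiff(results_columns, c("exposure", "outcome", "method",
                                    "passes_bonferroni"))
  for (col in intersect(num, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}
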