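# Instrument selection and strength diagnostics: significance filtering,
# greedy LD clumping, per-SNP and mean F, I2 for the NOME assumption,
# variance explained, and power for binary-outcome MR.

#' Keep genome-wide significant variants
#'
#' @param table an [assoc_table()].
#' @param p_max exclusive p-value threshold (default 5e-8).
#' @return the filtered table (order preserved); warns when empty.
#' @export
significance_filter <- function(table, p_max = 5e-8) {
  keep <- !is.na(table$pvalue) & table$pvalue < p_max
  out <- table[keep, , drop = FALSE]
  if (!nrow(out))
    warning("no variant passes p < ", format(p_max), call. = FALSE)
  attributes(out)[c("trait_id", "trait_type", "n_cases", "n_noncases",
                    "unit_sd")] <-
    attributes(table)[c("trait_id", "trait_type", "n_cases", "n_noncases",
                        "unit_sd")]
  class(out) <- class(table)
  out
}

#' Greedy LD clumping
#'
#' Repeatedly retains the remaining variant with the smallest p-value and
#' removes all variants correlated with it at `r2 >= r2_max`. Ties on
#' p-value break lexicographically on `variant_id`, making the selection
#' deterministic.
#'
#' @param table an [assoc_table()].
#' @param ld square symmetric matrix of pairwise r2 with unit diagonal;
#'   dimnames, if present, must cover the table's variant ids, otherwise
#'   rows are matched by position.
#' @param r2_max exclusive independence threshold (default 0.001).
#' @return the clumped table, in the original row order.
#' @export
ld_clump <- function(table, ld, r2_max = 0.001) {
  L <- nrow(table)
  if (!is.matrix(ld) || nrow(ld) != L || ncol(ld) != L)
    stop_data("LD matrix dimensions do not match the table")
  if (max(abs(ld - t(ld))) > 1e-8) stop_data("LD matrix is not symmetric")
  if (any(abs(diag(ld) - 1) > 1e-8)) stop_data("LD matrix diagonal must be 1")
  if (!is.null(rownames(ld))) {
    if (!all(table$variant_id %in% rownames(ld)))
      stop_data("LD matrix dimnames do not cover the table's variants")
    ld <- ld[table$variant_id, table$variant_id, drop = FALSE]
  }
  ord <- order(table$pvalue, table$variant_id)
  alive <- rep(TRUE, L)
  kept <- logical(L)
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[ld[i, ] >= r2_max] <- FALSE
  }
  out <- table[kept, , drop = FALSE]
  class(out) <- class(table)
  out
}

#' Per-SNP F statistic
#'
#' Approximated by the squared SNP-phenotype association divided by its
#' variance, `(beta/se)^2`; values below 10 flag potentially weak
#' instruments.
#'
#' @param beta,se effect size(s) and positive SE(s); vectorized.
#' @return F statistic(s).
#' @export
per_snp_f <- function(beta, se) {
  if (any(is.na(se) | se <= 0)) stop_data("se must be positive")
  (beta / se)^2
}

#' I-squared of instrument strength (NOME diagnostic)
#'
#' Heterogeneity of the SNP-exposure associations relative to their SEs:
#' `Q = sum(w*(bx - bbar)^2)` with inverse-variance weights and
#' `I2 = max(0, (Q - (L-1))/Q)`. Values below 0.90 indicate likely NOME
#' violation (diluted MR-Egger estimates); above 0.97, minimal bias.
#'
#' @param beta_x,se_x SNP-exposure effects and SEs (length >= 2).
#' @return I2 in \[0,1\].
#' @export
i2_gx <- function(beta_x, se_x) {
  L <- length(beta_x)
  if (L < 2L) stop_data("I2 requires at least 2 variants")
  if (any(se_x <= 0)) stop_data("se_x must be positive")
  w <- 1 / se_x^2
  bbar <- sum(w * beta_x) / sum(w)
  q <- sum(w * (beta_x - bbar)^2)
  if (q <= 0) return(0)
  max(0, (q - (L - 1)) / q)
}

#' Phenotypic variance explained by a set of instruments
#'
#' Per SNP, `r2 = (beta/sd)^2 * 2*MAF*(1-MAF)` with the effect standardized
#' by the phenotypic SD and `MAF = min(eaf, 1-eaf)`; summed over SNPs.
#'
#' @param beta per-allele effects in phenotype units.
#' @param eaf effect-allele frequencies strictly inside (0,1).
#' @param phenotype_sd phenotypic standard deviation in the same units
#'   (use 1 if `beta` is already standardized).
#' @return total proportion of variance explained.
#' @export
variance_explained <- function(beta, eaf, phenotype_sd = 1) {
  if (any(is.na(eaf) | eaf <= 0 | eaf >= 1))
    stop_data("eaf must lie strictly inside (0,1)")
  if (is.na(phenotype_sd) || phenotype_sd <= 0)
    stop_data("phenotype_sd must be positive")
  maf <- pmin(eaf, 1 - eaf)
  sum((beta / phenotype_sd)^2 * 2 * maf * (1 - maf))
}

#' Instrument-strength diagnostics for an instrument set
#'
#' @param beta_x,se_x SNP-exposure effects and SEs.
#' @param eaf effect-allele frequencies (optional; needed for r2).
#' @param phenotype_sd phenotypic SD for standardization (optional).
#' @return object of class `instrument_diagnostics`: per-SNP F, mean/min/max
#'   F, I2, and variance explained (NA when eaf or SD is missing).
#' @export
instrument_diagnostics <- function(beta_x, se_x, eaf = NULL,
                                   phenotype_sd = NA_real_) {
  f <- per_snp_f(beta_x, se_x)
  r2 <- if (!is.null(eaf) && !anyNA(eaf) && !is.na(phenotype_sd))
    variance_explained(beta_x, eaf, phenotype_sd) else NA_real_
  structure(list(n_snps = length(beta_x), f_per_snp = f, f_mean = mean(f),
                 f_min = min(f), f_max = max(f),
                 i2_gx = if (length(beta_x) >= 2) i2_gx(beta_x, se_x)
                         else NA_real_,
                 r2_explained = r2),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("Instrument diagnostics over %d SNPs\n", x$n_snps))
  cat(sprintf("  mean F %.1f (range %.1f - %.1f), I2 %.1f%%",
              x$f_mean, x$f_min, x$f_max, 100 * x$i2_gx))
  if (!is.na(x$r2_explained))
    cat(sprintf(", r2 explained %.2f%%", 100 * x$r2_explained))
  cat("\n")
  invisible(x)
}

#' Power and detectable effect for binary-outcome MR
#'
#' Normal-approximation power: the effective sample size of an MR study is
#' the outcome sample size scaled by the variance in the exposure explained
#' by the instruments, giving non-centrality
#' `NCP = n_total * r2 * cf*(1-cf) * log(OR)^2` and
#' `power = pnorm(sqrt(NCP) - z_{1-alpha/2})`. In `detectable_or` mode the
#' OR (> 1) giving `power_target` is returned.
#'
#' @param n_total total outcome sample size.
#' @param case_fraction proportion of cases among `n_total`.
#' @param r2 variance in the exposure explained by the instruments.
#' @param alpha two-sided significance level.
#' @param mode `"detectable_or"` or `"power_at_or"`.
#' @param or_value odds ratio at which to evaluate power
#'   (`mode = "power_at_or"`).
#' @param power_target target power (`mode = "detectable_or"`, default 0.8).
#' @return power, or the detectable odds ratio.
#' @export
mr_power_binary <- function(n_total, case_fraction, r2, alpha = 0.05,
                            mode = c("detectable_or", "power_at_or"),
                            or_value = NULL, power_target = 0.8) {
  mode <- match.arg(mode)
  if (r2 <= 0) stop_data("r2 must be positive (r2 = 0 implies infinite ",
                         "sample size)")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop_data("case_fraction must lie in (0,1)")
  za <- stats::qnorm(1 - alpha / 2)
  info <- n_total * r2 * case_fraction * (1 - case_fraction)
  if (mode == "power_at_or") {
    if (is.null(or_value)) stop_config("or_value required for power_at_or")
    stats::pnorm(sqrt(info * log(or_value)^2) - za)
  } else {
    if (power_target <= 0 || power_target >= 1)
      stop_data("power_target must lie in (0,1)")
    exp((za + stats::qnorm(power_target)) / sqrt(info))
  }
}
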