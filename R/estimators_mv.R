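# Multivariable MR: joint estimation of direct effects of K exposures,
# Sanderson-Windmeijer conditional instrument strength, and a modified Q
# statistic accounting for the phenotypic correlation between exposures.

#' Construct a multivariable harmonized set
#'
#' @param exposures character vector of K >= 2 exposure ids.
#' @param variant_id character vector of L variant ids.
#' @param beta_x,se_x L x K matrices of SNP-exposure effects and SEs
#'   (columns ordered as `exposures`).
#' @param beta_y,se_y SNP-outcome effects and SEs (length L).
#' @param pheno_corr K x K symmetric phenotypic correlation matrix with
#'   unit diagonal.
#' @param outcome_id outcome trait id.
#' @return object of class `mv_harmonized_set`.
#' @export
mv_harmonized_set <- function(exposures, variant_id, beta_x, se_x,
                              beta_y, se_y, pheno_corr = NULL,
                              outcome_id = "outcome") {
  K <- length(exposures)
  beta_x <- as.matrix(beta_x)
  se_x <- as.matrix(se_x)
  L <- length(beta_y)
  if (K < 2L) stop_data("multivariable MR needs at least 2 exposures")
  if (nrow(beta_x) != L || ncol(beta_x) != K ||
      nrow(se_x) != L || ncol(se_x) != K || length(se_y) != L)
    stop_data("dimension mismatch in multivariable set")
  if (any(se_x <= 0) || any(se_y <= 0)) stop_data("all SEs must be positive")
  pheno_corr <- pheno_corr %||% diag(K)
  pheno_corr <- as.matrix(pheno_corr)
  if (nrow(pheno_corr) != K || ncol(pheno_corr) != K ||
      max(abs(pheno_corr - t(pheno_corr))) > 1e-8 ||
      any(abs(diag(pheno_corr) - 1) > 1e-8) || any(abs(pheno_corr) > 1 + 1e-12))
    stop_data("pheno_corr must be symmetric with unit diagonal and entries ",
              "in [-1,1]")
  colnames(beta_x) <- colnames(se_x) <- exposures
  structure(list(exposures = exposures, outcome_id = outcome_id,
                 variant_id = as.character(variant_id), beta_x = beta_x,
                 se_x = se_x, beta_y = beta_y, se_y = se_y,
                 pheno_corr = pheno_corr),
            class = "mv_harmonized_set")
}

#' @export
print.mv_harmonized_set <- function(x, ...) {
  cat(sprintf("Multivariable harmonized set: %s -> %s, %d variants\n",
              paste(x$exposures, collapse = " + "), x$outcome_id,
              length(x$beta_y)))
  invisible(x)
}

#' Build a multivariable harmonized set from association tables
#'
#' Takes the union of the per-exposure instrument lists, optionally drops
#' instruments shared between exposures (or cross-correlated at
#' `r2 >= shared_r2` according to `ld_info`), and harmonizes every retained
#' variant across all exposures and the outcome onto the first exposure's
#' effect allele using the univariable harmonization rules.
#'
#' @param exposure_tables named list of [assoc_table()]s, first entry is the
#'   primary exposure whose allele orientation is the reference.
#' @param outcome an [assoc_table()].
#' @param instruments optional named list of instrument id vectors per
#'   exposure (default: all variants in each exposure table).
#' @param ld_info optional data.frame `id_a`, `id_b`, `r2` of cross-exposure
#'   LD; pairs at `r2 >= shared_r2` are treated as shared and dropped.
#' @param pheno_corr K x K phenotypic correlation matrix (default identity).
#' @param drop_shared drop variants instrumenting more than one exposure
#'   (default `TRUE`).
#' @param shared_r2 LD threshold for the shared-predictor rule (default
#'   0.001, the same threshold used for instrument independence).
#' @param ambiguity_window palindromic ambiguity window.
#' @return an [mv_harmonized_set()].
#' @export
build_mv_set <- function(exposure_tables, outcome, instruments = NULL,
                         ld_info = NULL, pheno_corr = NULL,
                         drop_shared = TRUE, shared_r2 = 0.001,
                         ambiguity_window = c(0.42, 0.58)) {
  K <- length(exposure_tables)
  if (K < 2L) stop_data("build_mv_set needs at least 2 exposure tables")
  ids <- names(exposure_tables) %||%
    vapply(exposure_tables, function(t) attr(t, "trait_id"), "")
  instruments <- instruments %||% lapply(exposure_tables, `[[`, "variant_id")
  inst_union <- unique(unlist(instruments))

  shared <- character()
  if (drop_shared) {
    counts <- table(unlist(lapply(instruments, unique)))
    shared <- names(counts)[counts > 1L]
    if (!is.null(ld_info) && nrow(ld_info)) {
      hot <- ld_info$r2 >= shared_r2
      for (i in which(hot)) {
        a <- ld_info$id_a[i]; b <- ld_info$id_b[i]
        in_lists <- vapply(instruments, function(v) a %in% v || b %in% v,
                           TRUE)
        cross <- vapply(instruments, function(v) a %in% v, TRUE) !=
                 vapply(instruments, function(v) b %in% v, TRUE)
        if (sum(in_lists) > 1L || any(cross))
          shared <- union(shared, c(a, b))
      }
    }
  }

  ref <- as.data.frame(exposure_tables[[1]])
  rownames(ref) <- ref$variant_id
  dropped <- list()
  rows <- list()
  for (v in inst_union) {
    if (v %in% shared) { dropped[[v]] <- "shared predictor"; next }
    present <- vapply(exposure_tables, function(t) v %in% t$variant_id, TRUE)
    if (!all(present)) { dropped[[v]] <- "missing in an exposure table"; next }
    if (!v %in% outcome$variant_id) { dropped[[v]] <- "missing in outcome"; next }
    # Reference orientation: the variant's record in the first table where
    # it appears as an instrument; for simplicity, the first exposure table.
    rrec <- as.data.frame(exposure_tables[[1]])[
      exposure_tables[[1]]$variant_id == v, ]
    pal <- classify_palindromic(rrec$effect_allele, rrec$other_allele,
                                rrec$eaf, ambiguity_window)
    if (pal == "palindromic_ambiguous") {
      dropped[[v]] <- "ambiguous palindromic"; next
    }
    bx <- numeric(K); sx <- numeric(K)
    ok <- TRUE
    for (j in seq_len(K)) {
      erec <- as.data.frame(exposure_tables[[j]])[
        exposure_tables[[j]]$variant_id == v, ]
      al <- align_alleles(rrec$effect_allele, rrec$other_allele,
                          erec$effect_allele, erec$other_allele,
                          erec$beta, erec$se, erec$eaf)
      if (!is.null(al$failure)) { dropped[[v]] <- al$failure; ok <- FALSE; break }
      bx[j] <- al$beta; sx[j] <- al$se
    }
    if (!ok) next
    orec <- as.data.frame(outcome)[outcome$variant_id == v, ]
    al <- align_alleles(rrec$effect_allele, rrec$other_allele,
                        orec$effect_allele, orec$other_allele,
                        orec$beta, orec$se, orec$eaf)
    if (!is.null(al$failure)) { dropped[[v]] <- al$failure; next }
    rows[[v]] <- c(bx, sx, al$beta, al$se)
  }
  L <- length(rows)
  if (L < K + 1L) stop_data("underidentified: ", L, " usable variants for ",
                            K, " exposures")
  m <- do.call(rbind, rows)
  set <- mv_harmonized_set(ids, names(rows),
                           beta_x = m[, 1:K, drop = FALSE],
                           se_x = m[, (K + 1):(2 * K), drop = FALSE],
                           beta_y = m[, 2 * K + 1], se_y = m[, 2 * K + 2],
                           pheno_corr = pheno_corr,
                           outcome_id = attr(outcome, "trait_id") %||% "outcome")
  attr(set, "dropped") <- data.frame(variant_id = names(dropped),
                                     reason = unlist(dropped) %||% character(),
                                     stringsAsFactors = FALSE)
  set
}

mv_wls <- function(X, y, w, labels, set, method, q_df_extra = 0L) {
  fit <- stats::lm.wfit(X, y, w)
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  if (any(aliased))
    warning("rank-deficient design: exposure(s) ",
            paste(labels[aliased], collapse = ", "),
            " aliased; coefficients set to NA", call. = FALSE)
  res <- y - X[, !aliased, drop = FALSE] %*% coefs[!aliased]
  q <- sum(w * res^2)
  df <- length(y) - sum(!aliased)
  phi <- if (df >= 1) max(1, q / df) else 1
  xtwx <- crossprod(X[, !aliased, drop = FALSE],
                    w * X[, !aliased, drop = FALSE])
  vc <- solve(xtwx) * phi
  se <- rep(NA_real_, length(coefs))
  se[!aliased] <- sqrt(diag(vc))
  list(coefs = coefs, se = se, q = q, df = df, phi = phi, aliased = aliased)
}

#' Multivariable IVW
#'
#' Weighted least squares of the SNP-outcome effects on the K columns of
#' SNP-exposure effects, no intercept, weights `1/se_y^2`. Coefficient j is
#' exposure j's direct effect on the outcome, holding the other exposures
#' fixed. SEs are inflated by `sqrt(max(1, Q/(L-K)))`. An all-zero exposure
#' column is aliased: its coefficient is `NA` (with a warning) and the
#' remaining coefficients reduce to the lower-dimensional fit.
#'
#' @param set an [mv_harmonized_set()].
#' @param effects `"multiplicative_random"` (default) or `"fixed"`.
#' @return named list of [mr_estimate()]s, one per exposure.
#' @export
mv_ivw <- function(set, effects = c("multiplicative_random", "fixed")) {
  effects <- match.arg(effects)
  K <- length(set$exposures)
  L <- length(set$beta_y)
  if (L <= K) stop_data("need more variants than exposures")
  w <- 1 / set$se_y^2
  f <- mv_wls(set$beta_x, set$beta_y, w, set$exposures, set, "mv_ivw")
  phi <- if (effects == "fixed") 1 else f$phi
  scale <- if (effects == "fixed") sqrt(1 / f$phi) else 1
  out <- lapply(seq_len(K), function(j) {
    if (f$aliased[j]) return(NULL)
    mr_estimate("mv_ivw", beta = unname(f$coefs[j]),
                se = unname(f$se[j]) * scale, n_snps = L, q = f$q,
                q_df = f$df, dispersion = phi,
                exposure = set$exposures[j], outcome = set$outcome_id)
  })
  names(out) <- set$exposures
  out
}

#' Multivariable MR-Egger
#'
#' As [mv_ivw()] plus an intercept column, after orienting every variant so
#' the primary (first) exposure's effect is non-negative. A nonzero
#' intercept indicates directional pleiotropy not captured by the modelled
#' exposures.
#'
#' @param set an [mv_harmonized_set()].
#' @param fit_intercept with `FALSE`, reproduces [mv_ivw()].
#' @return list with `estimates` (per-exposure [mr_estimate()]s, each
#'   carrying the shared intercept fields) and `intercept` (estimate, se, p).
#' @export
mv_egger <- function(set, fit_intercept = TRUE) {
  K <- length(set$exposures)
  L <- length(set$beta_y)
  if (L <= K + as.integer(fit_intercept))
    stop_data("need more variants than coefficients")
  flip <- sign(set$beta_x[, 1])
  flip[flip == 0] <- 1
  bx <- set$beta_x * flip
  by <- set$beta_y * flip
  w <- 1 / set$se_y^2
  X <- if (fit_intercept) cbind(`(intercept)` = 1, bx) else bx
  labels <- if (fit_intercept) c("(intercept)", set$exposures)
            else set$exposures
  f <- mv_wls(X, by, w, labels, set, "mv_egger")
  off <- as.integer(fit_intercept)
  intercept <- if (fit_intercept)
    list(estimate = unname(f$coefs[1]), se = unname(f$se[1]),
         pvalue = 2 * stats::pnorm(-abs(f$coefs[1] / f$se[1])))
  else NULL
  est <- lapply(seq_len(K), function(j) {
    if (f$aliased[j + off]) return(NULL)
    mr_estimate("mv_egger", beta = unname(f$coefs[j + off]),
                se = unname(f$se[j + off]), n_snps = L, q = f$q,
                q_df = f$df, dispersion = f$phi,
                intercept = intercept$estimate, intercept_se = intercept$se,
                intercept_p = intercept$pvalue,
                exposure = set$exposures[j], outcome = set$outcome_id)
  })
  names(est) <- set$exposures
  list(estimates = est, intercept = intercept)
}

#' Sanderson-Windmeijer conditional F statistic
#'
#' Conditional instrument strength of exposure j given the other exposure
#' (two-exposure case): minimizes over delta
#' `Q_j(delta) = sum((bx_j - delta*bx_m)^2 / (se_j^2 + delta^2*se_m^2 -
#' 2*delta*rho*se_j*se_m))`, with `rho` the phenotypic correlation between
#' the exposures, and returns `Q_j(delta_hat)/(L-1)`. Values well above 10
#' indicate the instruments retain predictive strength for exposure j
#' beyond what they share with exposure m.
#'
#' @param set an [mv_harmonized_set()] with K = 2.
#' @param j index of the exposure whose conditional strength is assessed.
#' @param interval search interval for delta (default \[-10, 10\]).
#' @return the conditional F statistic.
#' @export
conditional_f <- function(set, j = 1L, interval = c(-10, 10)) {
  K <- length(set$exposures)
  if (K != 2L) stop_data("conditional_f supports exactly 2 exposures")
  L <- length(set$beta_y)
  if (L < 3L) stop_data("need at least 3 variants")
  m <- if (j == 1L) 2L else 1L
  rho <- set$pheno_corr[j, m]
  bj <- set$beta_x[, j]; bm <- set$beta_x[, m]
  sj <- set$se_x[, j]; sm <- set$se_x[, m]
  # With no cross signal at all the profiled denominator is unbounded in
  # delta; the natural limit is delta = 0, the marginal mean-F analogue.
  if (all(bm == 0)) return(sum((bj / sj)^2) / (L - 1))
  qfun <- function(delta) {
    den <- sj^2 + delta^2 * sm^2 - 2 * delta * rho * sj * sm
    if (any(den <= 0)) return(Inf)
    sum((bj - delta * bm)^2 / den)
  }
  opt <- stats::optimize(qfun, interval = interval, tol = 1e-8)
  if (!is.finite(opt$objective))
    stop_data("conditional F minimization failed (degenerate denominator)")
  opt$objective / (L - 1)
}

#' Modified Q statistic for multivariable MR
#'
#' Residual heterogeneity at causal effects `theta`, with per-variant
#' variances propagating the exposure-effect uncertainty and the
#' phenotypic correlation between the two exposures:
#' `den_k = se_y^2 + t1^2 se_x1^2 + t2^2 se_x2^2 + 2 t1 t2 rho se_x1 se_x2`.
#' Called without `theta`, the statistic is minimized over theta and
#' reported at the minimizer.
#'
#' @param set an [mv_harmonized_set()] with K = 2.
#' @param theta length-2 vector of causal effects, or `NULL` to minimize.
#' @return list `q`, `df` (`L - 2`), `pvalue`, `theta`.
#' @export
modified_q <- function(set, theta = NULL) {
  K <- length(set$exposures)
  if (K != 2L) stop_data("modified_q supports exactly 2 exposures")
  L <- length(set$beta_y)
  rho <- set$pheno_corr[1, 2]
  qfun <- function(th) {
    den <- set$se_y^2 + th[1]^2 * set$se_x[, 1]^2 +
      th[2]^2 * set$se_x[, 2]^2 +
      2 * th[1] * th[2] * rho * set$se_x[, 1] * set$se_x[, 2]
    if (any(den <= 0))
      stop_data("non-positive variance in modified Q (pathological ",
                "correlation input)")
    sum((set$beta_y - th[1] * set$beta_x[, 1] - th[2] * set$beta_x[, 2])^2 /
          den)
  }
  if (is.null(theta)) {
    start <- vapply(mv_ivw(set), function(e) if (is.null(e)) 0 else e$beta, 0)
    opt <- stats::optim(start, qfun, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    theta <- opt$par
  }
  q <- qfun(theta)
  df <- L - K
  list(q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE),
       theta = theta)
}
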