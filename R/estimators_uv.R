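# Univariable two-sample MR estimators: Wald ratio, IVW (fixed and
# multiplicative random effects), weighted median, MR-Egger, plus Cochran's
# Q, unit rescaling and odds-ratio conversion.

#' Construct an MR estimate object
#'
#' @param method one of `wald`, `ivw_fixed`, `ivw_mre`, `weighted_median`,
#'   `egger`, `mv_ivw`, `mv_egger`.
#' @param beta,se causal estimate (log-odds of the outcome per exposure
#'   unit for binary outcomes) and its SE.
#' @param n_snps number of instruments used.
#' @param q,q_df heterogeneity statistic and degrees of freedom.
#' @param dispersion multiplicative overdispersion actually applied
#'   (`>= 1`).
#' @param intercept,intercept_se,intercept_p Egger intercept terms.
#' @param exposure,outcome trait identifiers.
#' @param exposure_unit `"per_sd"` or `"per_custom"`.
#' @param seed,n_boot bootstrap metadata (weighted median).
#' @return object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snps, q = NA_real_,
                        q_df = NA_integer_, dispersion = 1,
                        intercept = NULL, intercept_se = NULL,
                        intercept_p = NULL, exposure = NULL, outcome = NULL,
                        exposure_unit = "per_sd", seed = NULL,
                        n_boot = NULL) {
  if (is.na(se) || se <= 0) stop_data("mr_estimate requires se > 0")
  if (!is.na(dispersion) && dispersion < 1)
    stop_data("dispersion must be >= 1")
  qnorm95 <- stats::qnorm(0.975)
  est <- list(method = method, beta = beta, se = se,
              ci_low = beta - qnorm95 * se, ci_high = beta + qnorm95 * se,
              pvalue = 2 * stats::pnorm(-abs(beta / se)),
              n_snps = n_snps, q = q, q_df = q_df,
              q_pvalue = if (is.na(q) || is.na(q_df) || q_df < 1) NA_real_
                         else stats::pchisq(q, q_df, lower.tail = FALSE),
              dispersion = dispersion, intercept = intercept,
              intercept_se = intercept_se, intercept_p = intercept_p,
              exposure = exposure, outcome = outcome,
              exposure_unit = exposure_unit, seed = seed, n_boot = n_boot)
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- to_odds_ratio(x)
  cat(sprintf("%s estimate (%d SNPs): beta = %.4g (SE %.4g), p = %.3g\n",
              unname(method_labels[x$method] %||% x$method), x$n_snps,
              x$beta, x$se, x$pvalue))
  cat(sprintf("  OR %.3f (95%% CI %.3f, %.3f)\n",
              or[["or"]], or[["or_ci_low"]], or[["or_ci_high"]]))
  if (!is.na(x$q) && !is.na(x$q_df) && x$q_df >= 1)
    cat(sprintf("  Q = %.3g on %d df (p = %.3g), dispersion %.3g\n",
                x$q, x$q_df, x$q_pvalue, x$dispersion))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

set_vectors <- function(set) {
  v <- set$variants
  list(bx = v$beta_x, sx = v$se_x, by = v$beta_y, sy = v$se_y,
       L = nrow(v))
}

#' Wald ratio for a single instrument
#'
#' The SNP-outcome association divided by the SNP-exposure association,
#' with the first-order delta-method SE `se_y / |beta_x|`.
#'
#' @param beta_x,se_x,beta_y,se_y per-variant exposure and outcome effects
#'   and SEs.
#' @param exposure,outcome optional trait ids.
#' @return an [mr_estimate()] with `method = "wald"`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, exposure = NULL,
                       outcome = NULL) {
  if (beta_x == 0) stop_data("undefined ratio: beta_x = 0")
  mr_estimate("wald", beta = beta_y / beta_x, se = se_y / abs(beta_x),
              n_snps = 1L, dispersion = 1, exposure = exposure,
              outcome = outcome)
}

#' Inverse-variance weighted MR estimate
#'
#' Precision-weighted combination of per-SNP Wald ratios, equivalently the
#' no-intercept weighted regression of outcome on exposure effects with
#' weights `1/se_y^2`. With multiplicative random effects (the default,
#' which assumes balanced pleiotropy) the fixed-effect SE is inflated by
#' `sqrt(max(1, Q/(L-1)))`, so it never shrinks below the fixed-effect SE.
#' A single-SNP set reduces to the Wald ratio.
#'
#' @param set a [harmonized_set()].
#' @param effects `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [mr_estimate()].
#' @export
mr_ivw <- function(set, effects = c("multiplicative_random", "fixed")) {
  effects <- match.arg(effects)
  d <- set_vectors(set)
  if (d$L < 1L) stop_data("empty harmonized set")
  if (d$L == 1L) {
    est <- wald_ratio(d$bx, d$sx, d$by, d$sy, set$exposure_id, set$outcome_id)
    return(est)
  }
  w <- 1 / d$sy^2
  theta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fixed <- 1 / sqrt(sum(w * d$bx^2))
  q <- sum(w * (d$by - theta * d$bx)^2)
  df <- d$L - 1L
  phi <- if (effects == "multiplicative_random") max(1, q / df) else 1
  mr_estimate(if (effects == "fixed") "ivw_fixed" else "ivw_mre",
              beta = theta, se = se_fixed * sqrt(phi), n_snps = d$L,
              q = q, q_df = df, dispersion = phi,
              exposure = set$exposure_id, outcome = set$outcome_id)
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimate
#'
#' Consistent when at least 50% of the weight comes from valid instruments.
#' The point estimate interpolates the inverse-variance-weighted empirical
#' quantile function of the per-SNP Wald ratios at probability 0.5 (weights
#' `beta_x^2 / se_y^2`). The SE is the standard deviation of the estimate
#' over parametric-bootstrap replicates resampling both exposure and
#' outcome effects from their reported SEs; the seed is required so results
#' are reproducible.
#'
#' @param set a [harmonized_set()] with at least 3 variants.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed (required).
#' @return an [mr_estimate()].
#' @export
weighted_median <- function(set, n_boot = 1000L, seed) {
  if (missing(seed)) stop_config("weighted_median requires an explicit seed")
  d <- set_vectors(set)
  if (d$L < 3L) stop_data("weighted median requires at least 3 variants")
  ratios <- d$by / d$bx
  weights <- d$bx^2 / d$sy^2
  est <- weighted_median_point(ratios, weights)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxs <- stats::rnorm(d$L, d$bx, d$sx)
      bys <- stats::rnorm(d$L, d$by, d$sy)
      weighted_median_point(bys / bxs, bxs^2 / d$sy^2)
    }, 0)
  })
  se <- stats::sd(boot)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  mr_estimate("weighted_median", beta = est, se = se, n_snps = d$L,
              dispersion = 1, exposure = set$exposure_id,
              outcome = set$outcome_id, seed = seed, n_boot = n_boot)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' an intercept, after orienting every SNP so the exposure effect is
#' non-negative. The slope estimates the causal effect under the InSIDE
#' assumption; a nonzero intercept indicates average directional
#' pleiotropy. SEs are inflated by `sqrt(max(1, Q'/(L-2)))`.
#'
#' @param set a [harmonized_set()] with at least 3 variants.
#' @param fit_intercept fit the pleiotropy intercept (default). With
#'   `FALSE` the fit is the reference no-intercept model, which reproduces
#'   the IVW point estimate.
#' @return an [mr_estimate()] with intercept fields.
#' @export
mr_egger <- function(set, fit_intercept = TRUE) {
  d <- set_vectors(set)
  if (d$L < 3L) stop_data("MR-Egger requires at least 3 variants")
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  bx <- d$bx * flip
  by <- d$by * flip
  w <- 1 / d$sy^2
  X <- if (fit_intercept) cbind(intercept = 1, slope = bx)
       else cbind(slope = bx)
  if (fit_intercept && stats::var(bx) == 0)
    stop_data("slope unidentifiable: no spread in oriented exposure effects")
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * by))
  res <- by - X %*% coefs
  q <- sum(w * res^2)
  df <- d$L - ncol(X)
  phi <- max(1, q / df)
  vc <- solve(xtwx) * phi
  slope_i <- ncol(X)
  se_slope <- sqrt(vc[slope_i, slope_i])
  if (fit_intercept) {
    i_se <- sqrt(vc[1, 1])
    mr_estimate("egger", beta = coefs[slope_i], se = se_slope, n_snps = d$L,
                q = q, q_df = df, dispersion = phi,
                intercept = unname(coefs[1]), intercept_se = i_se,
                intercept_p = 2 * stats::pnorm(-abs(coefs[1] / i_se)),
                exposure = set$exposure_id, outcome = set$outcome_id)
  } else {
    mr_estimate("egger", beta = coefs[slope_i], se = se_slope, n_snps = d$L,
                q = q, q_df = df, dispersion = phi,
                exposure = set$exposure_id, outcome = set$outcome_id)
  }
}

#' Cochran's Q for a harmonized set at a given causal effect
#'
#' @param set a [harmonized_set()] with at least 2 variants.
#' @param theta causal effect at which residual heterogeneity is evaluated.
#' @return list with `q`, `df` (`L - 1`) and chi-square `pvalue`.
#' @export
cochran_q <- function(set, theta) {
  d <- set_vectors(set)
  if (d$L < 2L) stop_data("Cochran's Q requires at least 2 variants")
  w <- 1 / d$sy^2
  q <- sum(w * (d$by - theta * d$bx)^2)
  df <- d$L - 1L
  list(q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Rescale an estimate from per-SD to a custom exposure increment
#'
#' Multiplies the estimate, SE and CI bounds by `target_unit/phenotype_sd`
#' (e.g. from per-SD of systolic BP, SD 20.1 mm Hg, to per 10 mm Hg). The
#' p-value is scale-invariant and unchanged.
#'
#' @param est an [mr_estimate()] expressed per SD of the exposure.
#' @param phenotype_sd phenotypic SD in measurement units.
#' @param target_unit desired exposure increment in the same units.
#' @return the rescaled [mr_estimate()] (`exposure_unit = "per_custom"`).
#' @export
rescale_estimate <- function(est, phenotype_sd, target_unit) {
  if (phenotype_sd <= 0 || target_unit <= 0)
    stop_data("phenotype_sd and target_unit must be positive")
  k <- target_unit / phenotype_sd
  out <- est
  out$beta <- est$beta * k
  out$se <- est$se * k
  out$ci_low <- est$ci_low * k
  out$ci_high <- est$ci_high * k
  out$exposure_unit <- "per_custom"
  out
}

#' Convert a log-odds MR estimate to an odds-ratio scale
#'
#' @param est an [mr_estimate()] on the log-odds scale.
#' @return named numeric vector `or`, `or_ci_low`, `or_ci_high`
#'   (exponentiated estimate and normal 95% CI).
#' @export
to_odds_ratio <- function(est) {
  c(or = exp(est$beta), or_ci_low = exp(est$ci_low),
    or_ci_high = exp(est$ci_high))
}
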