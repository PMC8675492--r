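# Synthetic two-sample GWAS summary statistics with known ground truth.
# The outcome is binary and effects are generated directly on the log-odds
# scale: per-SNP standardized exposure effects gamma_k are rescaled so the
# instruments explain exactly target_r2 of the exposure variance, SEs follow
# the standard frequency-dependent analytic forms, and pleiotropy can be
# balanced, directional, and/or correlated with instrument strength
# (an InSIDE violation).

#' Define a simulation scenario
#'
#' Defaults describe a desk-scale version of a large biobank analysis:
#' 100 independent instruments explaining 2.6% of the exposure variance in
#' an exposure GWAS of 450,000, applied to a binary outcome GWAS of 400,000
#' with 9% cases.
#'
#' @param n_snps number of instruments L (>= 3).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_fraction proportion of cases in the outcome GWAS.
#' @param maf_range minor-allele-frequency range, inside (0, 0.5].
#' @param target_r2 exposure variance explained by the L instruments.
#' @param theta true causal effect (log-odds per exposure SD).
#' @param mu_alpha,sigma_alpha mean and SD of per-SNP pleiotropic effects
#'   on the outcome (log-odds), applied to the invalid fraction.
#' @param inside_rho correlation between pleiotropy and instrument strength
#'   (nonzero violates InSIDE).
#' @param invalid_fraction fraction of SNPs carrying pleiotropy.
#' @param palindromic_fraction fraction of SNPs assigned A/T or C/G allele
#'   pairs.
#' @param unit_sd phenotypic SD used to express exposure effects in
#'   measurement units (1 keeps them per-SD).
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_snps = 100L, n_exposure = 450000L,
                         n_outcome = 400000L, case_fraction = 0.09,
                         maf_range = c(0.05, 0.5), target_r2 = 0.026,
                         theta = 0, mu_alpha = 0, sigma_alpha = 0,
                         inside_rho = 0, invalid_fraction = 0,
                         palindromic_fraction = 0.2, unit_sd = 1,
                         seed = 1L) {
  s <- list(n_snps = as.integer(n_snps), n_exposure = n_exposure,
            n_outcome = n_outcome, case_fraction = case_fraction,
            maf_range = maf_range, target_r2 = target_r2, theta = theta,
            mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
            inside_rho = inside_rho, invalid_fraction = invalid_fraction,
            palindromic_fraction = palindromic_fraction, unit_sd = unit_sd,
            seed = as.integer(seed))
  if (s$n_snps < 3L) stop_data("scenario needs at least 3 SNPs")
  if (s$target_r2 <= 0) stop_data("target_r2 must be positive")
  if (s$case_fraction <= 0 || s$case_fraction >= 1)
    stop_data("case_fraction must lie in (0,1)")
  if (s$maf_range[1] <= 0 || s$maf_range[2] > 0.5 ||
      s$maf_range[1] > s$maf_range[2])
    stop_data("maf_range must lie inside (0, 0.5]")
  if (abs(s$inside_rho) > 1) stop_data("inside_rho must lie in [-1,1]")
  if (s$invalid_fraction < 0 || s$invalid_fraction > 1)
    stop_data("invalid_fraction must lie in [0,1]")
  structure(s, class = "sim_scenario")
}

#' Read a scenario from a YAML or JSON file
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a [sim_scenario()].
#' @export
read_scenario <- function(path) {
  vals <- read_config_file(path)
  known <- names(formals(sim_scenario))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop_config("unknown scenario fields: ",
                                   paste(unknown, collapse = ", "))
  if (!is.null(vals$maf_range)) vals$maf_range <- unlist(vals$maf_range)
  do.call(sim_scenario, vals)
}

# Effect magnitudes for a significance-selected instrument panel: half-normal
# left-truncated at 0.5, so the weakest SNP retains ~25-35% of the panel's
# mean F, matching the floor that genome-wide significance plus external
# replication imposes on real instrument lists.
rtrunc_halfnorm <- function(L, min = 0.5) {
  p0 <- 2 * stats::pnorm(min) - 1
  u <- stats::runif(L, p0, 1)
  stats::qnorm((u + 1) / 2)
}

NONPALIN_PAIRS <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                       c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
PALIN_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

assign_alleles <- function(L, palindromic_fraction) {
  palin <- stats::runif(L) < palindromic_fraction
  pick <- function(pairs, n) {
    idx <- sample.int(length(pairs), n, replace = TRUE)
    do.call(rbind, pairs[idx])
  }
  ea <- oa <- character(L)
  if (any(palin)) {
    p <- pick(PALIN_PAIRS, sum(palin))
    ea[palin] <- p[, 1]; oa[palin] <- p[, 2]
  }
  if (any(!palin)) {
    p <- pick(NONPALIN_PAIRS, sum(!palin))
    ea[!palin] <- p[, 1]; oa[!palin] <- p[, 2]
  }
  data.frame(effect_allele = ea, other_allele = oa,
             stringsAsFactors = FALSE)
}

#' Simulate an exposure/outcome pair of summary-association tables
#'
#' Generative model (deterministic given the scenario seed): MAFs uniform
#' on `maf_range`; true standardized effect magnitudes drawn from a
#' half-normal left-truncated at 0.5 (mimicking a significance-selected
#' panel, where every SNP retains a sizeable fraction of the mean F) and
#' rescaled so `sum(2*maf*(1-maf)*gamma^2) = target_r2` (effect alleles
#' oriented to be exposure-increasing, as in a curated instrument list);
#' `se_x = (2*maf*(1-maf)*n_exposure)^(-1/2)`;
#' `se_y = (2*maf*(1-maf)*n_outcome*cf*(1-cf))^(-1/2)` (log-odds scale);
#' observed effects are the truth plus normal noise at those SEs, with
#' pleiotropy `alpha_k` added to the outcome effects of the invalid SNPs.
#' P-values are two-sided normal. A configurable fraction of SNPs receives
#' palindromic allele pairs; the effect-allele frequency is `maf` or
#' `1-maf` at random.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `exposure` and `outcome` [assoc_table()]s and `truth`
#'   (gamma, alpha, maf, theta, invalid flags).
#' @export
simulate_pair <- function(scenario) {
  s <- scenario
  with_local_seed(s$seed, {
    L <- s$n_snps
    maf <- stats::runif(L, s$maf_range[1], s$maf_range[2])
    het <- 2 * maf * (1 - maf)
    g0 <- rtrunc_halfnorm(L)
    gamma <- g0 * sqrt(s$target_r2 / sum(het * g0^2))
    se_x <- 1 / sqrt(het * s$n_exposure)
    bx <- gamma + stats::rnorm(L, 0, se_x)
    cf <- s$case_fraction
    se_y <- 1 / sqrt(het * s$n_outcome * cf * (1 - cf))
    n_invalid <- round(s$invalid_fraction * L)
    invalid <- rep(FALSE, L)
    if (n_invalid > 0) invalid[sample.int(L, n_invalid)] <- TRUE
    alpha <- numeric(L)
    if (n_invalid > 0) {
      z <- stats::rnorm(n_invalid)
      gs <- (gamma - mean(gamma)) / stats::sd(gamma)
      alpha[invalid] <- s$mu_alpha + s$sigma_alpha *
        (sqrt(1 - s$inside_rho^2) * z + s$inside_rho * gs[invalid])
    }
    by <- s$theta * gamma + alpha + stats::rnorm(L, 0, se_y)
    al <- assign_alleles(L, s$palindromic_fraction)
    eaf <- ifelse(stats::runif(L) < 0.5, maf, 1 - maf)
    ids <- sprintf("rs%06d", seq_len(L))
    pv <- function(b, se) pmax(2 * stats::pnorm(-abs(b / se)), 1e-300)
    exposure <- assoc_table(
      data.frame(variant_id = ids, effect_allele = al$effect_allele,
                 other_allele = al$other_allele, eaf = eaf,
                 beta = bx * s$unit_sd, se = se_x * s$unit_sd,
                 pvalue = pv(bx, se_x), n = s$n_exposure,
                 stringsAsFactors = FALSE),
      trait_id = "sim_exposure", trait_type = "continuous",
      unit_sd = s$unit_sd)
    n_cases <- round(s$n_outcome * cf)
    outcome <- assoc_table(
      data.frame(variant_id = ids, effect_allele = al$effect_allele,
                 other_allele = al$other_allele, eaf = eaf, beta = by,
                 se = se_y, pvalue = pv(by, se_y), n = s$n_outcome,
                 stringsAsFactors = FALSE),
      trait_id = "sim_outcome", trait_type = "binary",
      n_cases = n_cases, n_noncases = s$n_outcome - n_cases)
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = s$theta, gamma = gamma, alpha = alpha,
                      maf = maf, invalid = invalid, seed = s$seed))
  })
}

#' Simulate a negative-control outcome for an existing exposure table
#'
#' Builds an outcome table for the same variants with a true causal effect
#' of zero and no pleiotropy: observed effects are pure noise at the
#' frequency-dependent analytic SE. A pipeline run against it should give
#' confidence intervals covering OR 1 at the nominal rate.
#'
#' @param exposure an [assoc_table()].
#' @param n_outcome,case_fraction outcome GWAS size and case fraction.
#' @param seed RNG seed.
#' @return a binary-outcome [assoc_table()].
#' @export
make_negative_control <- function(exposure, n_outcome = 400000L,
                                  case_fraction = 0.09, seed = 1L) {
  with_local_seed(seed, {
    maf <- pmin(exposure$eaf, 1 - exposure$eaf)
    if (anyNA(maf)) stop_data("negative control needs eaf for every variant")
    het <- 2 * maf * (1 - maf)
    cf <- case_fraction
    se_y <- 1 / sqrt(het * n_outcome * cf * (1 - cf))
    by <- stats::rnorm(nrow(exposure), 0, se_y)
    n_cases <- round(n_outcome * cf)
    assoc_table(
      data.frame(variant_id = exposure$variant_id,
                 effect_allele = exposure$effect_allele,
                 other_allele = exposure$other_allele, eaf = exposure$eaf,
                 beta = by, se = se_y,
                 pvalue = 2 * stats::pnorm(-abs(by / se_y)), n = n_outcome,
                 stringsAsFactors = FALSE),
      trait_id = "negative_control", trait_type = "binary",
      n_cases = n_cases, n_noncases = n_outcome - n_cases)
  })
}

#' Simulate a two-exposure multivariable MR dataset
#'
#' Exposure 1 follows `scenario`. A second exposure (a BMI-like co-exposure)
#' has `n_snps2` instruments of its own; in addition, every exposure-1
#' instrument carries an effect on exposure 2 with correlation
#' `cross_corr` to its exposure-1 effect, scaled so exposure 2's own
#' instruments plus the cross effects explain `target_r2_2` of its
#' variance. The outcome is `theta1*gamma1 + theta2*gamma2` plus noise, so
#' univariable MR of exposure 1 is biased through the exposure-2 pathway
#' while multivariable MR is not.
#'
#' @param scenario a [sim_scenario()] for exposure 1 (its `theta` is
#'   theta1).
#' @param theta2 causal effect of exposure 2 (log-odds per SD).
#' @param n_snps2 number of instruments exclusive to exposure 2.
#' @param target_r2_2 variance of exposure 2 explained by all its SNPs.
#' @param n_exposure2 exposure-2 GWAS sample size.
#' @param cross_corr correlation between exposure-1 and exposure-2 true
#'   effects over exposure-1's instruments (drives the confounding and
#'   lowers conditional F as it approaches 1).
#' @param pheno_corr phenotypic correlation between the two exposures.
#' @return list: `exposure1`, `exposure2`, `outcome` tables, `instruments`
#'   (id vectors per exposure), `pheno_corr`, `truth`.
#' @export
simulate_mv <- function(scenario, theta2 = 0.1, n_snps2 = 100L,
                        target_r2_2 = 0.04, n_exposure2 = 700000L,
                        cross_corr = 0.5, pheno_corr = 0.2) {
  s <- scenario
  with_local_seed(s$seed + 1L, {
    L1 <- s$n_snps
    L2 <- as.integer(n_snps2)
    L <- L1 + L2
    maf <- stats::runif(L, s$maf_range[1], s$maf_range[2])
    het <- 2 * maf * (1 - maf)
    i1 <- seq_len(L1)
    i2 <- L1 + seq_len(L2)

    g0 <- rtrunc_halfnorm(L1)
    gamma1 <- numeric(L)
    gamma1[i1] <- g0 * sqrt(s$target_r2 / sum(het[i1] * g0^2))

    # Exposure-2 effects: own instruments plus correlated cross effects on
    # exposure-1's instruments; split target_r2_2 between the two blocks.
    own0 <- rtrunc_halfnorm(L2)
    z <- stats::rnorm(L1)
    g1s <- (gamma1[i1] - mean(gamma1[i1])) / stats::sd(gamma1[i1])
    cross0 <- cross_corr * g1s + sqrt(1 - cross_corr^2) * z
    cross0 <- cross0 - min(cross0) + 0.1 # keep cross effects one-signed
    gamma2 <- numeric(L)
    gamma2[i2] <- own0 * sqrt(0.5 * target_r2_2 / sum(het[i2] * own0^2))
    gamma2[i1] <- cross0 * sqrt(0.5 * target_r2_2 / sum(het[i1] * cross0^2))

    se_x1 <- 1 / sqrt(het * s$n_exposure)
    se_x2 <- 1 / sqrt(het * n_exposure2)
    bx1 <- gamma1 + stats::rnorm(L, 0, se_x1)
    bx2 <- gamma2 + stats::rnorm(L, 0, se_x2)
    cf <- s$case_fraction
    se_y <- 1 / sqrt(het * s$n_outcome * cf * (1 - cf))
    by <- s$theta * gamma1 + theta2 * gamma2 + stats::rnorm(L, 0, se_y)

    al <- assign_alleles(L, s$palindromic_fraction)
    eaf <- ifelse(stats::runif(L) < 0.5, maf, 1 - maf)
    ids <- sprintf("rs%06d", seq_len(L))
    pv <- function(b, se) pmax(2 * stats::pnorm(-abs(b / se)), 1e-300)
    mk <- function(beta, se, trait, type = "continuous", ncase = NA, nnon = NA,
                   n = s$n_exposure)
      assoc_table(data.frame(variant_id = ids,
                             effect_allele = al$effect_allele,
                             other_allele = al$other_allele, eaf = eaf,
                             beta = beta, se = se, pvalue = pv(beta, se),
                             n = n, stringsAsFactors = FALSE),
                  trait_id = trait, trait_type = type, n_cases = ncase,
                  n_noncases = nnon)
    n_cases <- round(s$n_outcome * cf)
    list(exposure1 = mk(bx1, se_x1, "sim_exposure1"),
         exposure2 = mk(bx2, se_x2, "sim_exposure2", n = n_exposure2),
         outcome = mk(by, se_y, "sim_outcome", "binary", n_cases,
                      s$n_outcome - n_cases, s$n_outcome),
         instruments = list(sim_exposure1 = ids[i1], sim_exposure2 = ids[i2]),
         pheno_corr = matrix(c(1, pheno_corr, pheno_corr, 1), 2),
         truth = list(theta1 = s$theta, theta2 = theta2, gamma1 = gamma1,
                      gamma2 = gamma2, maf = maf, seed = s$seed))
  })
}
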