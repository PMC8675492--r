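# Univariable estimators: Wald, IVW, weighted median, Egger, Q, rescaling.

test_that("Wald ratio carries sign and the delta-method SE", {
  est <- wald_ratio(0.05, 0.005, 0.01, 0.004)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.08)
  expect_equal(est$n_snps, 1L)
  expect_equal(wald_ratio(0.05, 0.005, 0, 0.004)$beta, 0)
  expect_equal(wald_ratio(-0.05, 0.005, 0.01, 0.004)$beta, -0.2)
  expect_error(wald_ratio(0, 0.005, 0.01, 0.004), "undefined ratio")
})

test_that("IVW reproduces the hand-computed worked example", {
  set <- make_set(beta_x = c(0.1, 0.1), beta_y = c(0.02, 0.04),
                  se_y = c(0.01, 0.01))
  est <- mr_ivw(set)
  expect_equal(est$beta, 0.3)
  expect_equal(est$q, 2)
  expect_equal(est$q_df, 1L)
  expect_equal(est$dispersion, 2)
  expect_equal(est$se, 0.1)
  fixed <- mr_ivw(set, effects = "fixed")
  expect_equal(fixed$se, 1 / sqrt(200))
  # Cochran's Q at the IVW estimate matches
  q <- cochran_q(set, est$beta)
  expect_equal(q$q, 2)
  expect_equal(q$df, 1L)
})

test_that("single-variant IVW reduces to the Wald ratio", {
  set <- make_set(beta_x = 0.05, beta_y = 0.01, se_y = 0.004)
  est <- mr_ivw(set)
  w <- wald_ratio(0.05, 0.005, 0.01, 0.004)
  expect_equal(est$beta, w$beta)
  expect_equal(est$se, w$se)
  expect_equal(est$dispersion, 1)
})

test_that("IVW fixed equals the precision-weighted mean of Wald ratios", {
  for (seed in 1:25) {
    set <- random_set(sample(3:10, 1), seed)
    est <- mr_ivw(set, effects = "fixed")
    v <- set$variants
    w <- v$beta_x^2 / v$se_y^2
    expect_equal(est$beta, sum(w * (v$beta_y / v$beta_x)) / sum(w),
                 tolerance = 1e-12)
    # MRE SE never shrinks below fixed-effect SE
    expect_gte(mr_ivw(set)$se, est$se)
  }
})

test_that("IVW and Egger are invariant to jointly negating any SNP", {
  set <- random_set(8, 13)
  flipped <- set
  flipped$variants$beta_x[3] <- -set$variants$beta_x[3]
  flipped$variants$beta_y[3] <- -set$variants$beta_y[3]
  expect_equal(mr_ivw(set)$beta, mr_ivw(flipped)$beta)
  e1 <- mr_egger(set); e2 <- mr_egger(flipped)
  expect_equal(e1$beta, e2$beta)
  expect_equal(e1$intercept, e2$intercept)
})

test_that("weighted median interpolates the weighted ratio quantile", {
  set <- make_set(beta_x = c(0.1, 0.1, 0.1), beta_y = c(0.01, 0.02, 0.03),
                  se_y = c(0.01, 0.01, 0.01))
  est <- weighted_median(set, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.2)

  # all ratios equal: estimate exact, bootstrap SE small
  setc <- make_set(beta_x = c(0.1, 0.2, 0.3), beta_y = c(0.02, 0.04, 0.06),
                   se_y = rep(1e-5, 3), se_x = rep(1e-5, 3))
  estc <- weighted_median(setc, n_boot = 100, seed = 1)
  expect_equal(estc$beta, 0.2, tolerance = 1e-8)
  expect_lt(estc$se, 0.01)

  # dominant weight: estimate equals that SNP's Wald ratio
  setd <- make_set(beta_x = c(1, 0.001, 0.001), beta_y = c(0.5, 0.01, -0.02),
                   se_y = c(0.01, 0.01, 0.01))
  expect_equal(weighted_median(setd, n_boot = 50, seed = 2)$beta, 0.5,
               tolerance = 1e-3)

  # reproducible given the seed, error without enough SNPs
  expect_equal(weighted_median(set, n_boot = 100, seed = 9)$se,
               weighted_median(set, n_boot = 100, seed = 9)$se)
  expect_error(weighted_median(make_set(c(0.1, 0.1), c(0.01, 0.02),
                                        c(0.01, 0.01)), seed = 1),
               "at least 3")
  expect_error(weighted_median(set, n_boot = 10), "seed")
})

test_that("weighted median resists <50% invalid weight", {
  # 5 valid SNPs with ratios near 0.2, 2 outliers carrying <50% of weight
  bx <- c(rep(0.1, 5), 0.08, 0.08)
  by <- c(0.1 * c(0.18, 0.19, 0.2, 0.21, 0.22), 0.08 * 5, 0.08 * 6)
  set <- make_set(beta_x = bx, beta_y = by, se_y = rep(0.01, 7))
  est <- weighted_median(set, n_boot = 100, seed = 3)
  expect_gte(est$beta, 0.18)
  expect_lte(est$beta, 0.22)
})

test_that("Egger recovers exact linear data and nests IVW", {
  bx <- c(0.1, 0.2, 0.3)
  set <- make_set(beta_x = bx, beta_y = 0.01 + 0.5 * bx,
                  se_y = rep(0.01, 3))
  est <- mr_egger(set)
  expect_equal(est$beta, 0.5)
  expect_equal(est$intercept, 0.01)
  expect_equal(est$q, 0, tolerance = 1e-20)
  # constrained (no-intercept) fit reproduces the IVW point estimate
  for (seed in c(2, 17, 31)) {
    rset <- random_set(7, seed)
    expect_equal(mr_egger(rset, fit_intercept = FALSE)$beta,
                 mr_ivw(rset)$beta, tolerance = 1e-12)
  }
  # no spread in oriented exposure effects -> slope unidentifiable
  flat <- make_set(beta_x = c(0.1, 0.1, -0.1), beta_y = c(0.01, 0.02, 0.01),
                   se_y = rep(0.01, 3))
  expect_error(mr_egger(flat), "unidentifiable")
  expect_error(mr_egger(make_set(c(0.1, 0.2), c(0.01, 0.02), c(0.01, 0.01))),
               "at least 3")
})

test_that("Egger intercept is near zero without pleiotropy (simulation)", {
  means <- vapply(1:40, function(r) {
    sim <- simulate_pair(sim_scenario(n_snps = 60, theta = 0.2,
                                      seed = 1000 + r))
    hs <- harmonize_dataset(sim$exposure, sim$outcome)
    mr_egger(hs)$intercept
  }, 0)
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)) + 1e-4)
})

test_that("Cochran's Q grows quadratically away from the fit", {
  set <- make_set(beta_x = c(0.1, 0.2, 0.3), beta_y = c(0.03, 0.06, 0.09),
                  se_y = rep(0.01, 3))
  expect_equal(cochran_q(set, 0.3)$q, 0, tolerance = 1e-20)
  expect_equal(cochran_q(set, 0.3)$pvalue, 1)
  qs <- vapply(c(0.31, 0.35, 0.4, 0.5), function(t) cochran_q(set, t)$q, 0)
  expect_true(all(diff(qs) > 0))
})

test_that("rescaling and odds-ratio conversion behave linearly", {
  set <- make_set(beta_x = c(0.1, 0.1), beta_y = c(0.02, 0.04),
                  se_y = c(0.01, 0.01))
  est <- mr_ivw(set)
  est$beta <- log(0.98); # ln OR per SD as in a per-SD analysis
  est$ci_low <- est$beta - qnorm(0.975) * est$se
  est$ci_high <- est$beta + qnorm(0.975) * est$se
  r <- rescale_estimate(est, 20.1, 10)
  expect_equal(r$beta, log(0.98) * 10 / 20.1)
  expect_equal(r$pvalue, est$pvalue)
  ident <- rescale_estimate(est, 20.1, 20.1)
  expect_equal(ident$beta, est$beta)

  expect_equal(unname(to_odds_ratio(mr_estimate("wald", 0, 1, 1L))["or"]), 1)
  tight <- mr_estimate("wald", log(2), 1e-12, 1L)
  expect_equal(unname(to_odds_ratio(tight)), rep(2, 3), tolerance = 1e-9)
})
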