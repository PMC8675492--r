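# Multivariable MR: set construction, joint IVW/Egger, conditional F,
# modified Q.

make_mv <- function(L = 10, theta = c(0.2, 0.1), seed = 21, sy = 0.01,
                    noise = 0, pheno_corr = 0.3) {
  set.seed(seed)
  bx <- cbind(runif(L, 0.05, 0.2), runif(L, 0.05, 0.2))
  by <- drop(bx %*% theta) + noise * rnorm(L, 0, sy)
  mv_harmonized_set(c("x1", "x2"), sprintf("rs%d", 1:L), bx,
                    matrix(0.005, L, 2), by, rep(sy, L),
                    pheno_corr = matrix(c(1, pheno_corr, pheno_corr, 1), 2))
}

test_that("build_mv_set unions instruments and drops shared predictors", {
  mv <- simulate_mv(sim_scenario(n_snps = 20, theta = 0.15, seed = 31,
                                 palindromic_fraction = 0),
                    theta2 = 0.1, n_snps2 = 15)
  set <- build_mv_set(list(x1 = mv$exposure1, x2 = mv$exposure2),
                      mv$outcome, instruments = mv$instruments,
                      pheno_corr = mv$pheno_corr)
  # disjoint lists: the full union is retained
  expect_equal(length(set$beta_y), 35L)
  expect_equal(set$exposures, c("x1", "x2"))

  # a variant instrumenting both exposures is dropped
  inst2 <- mv$instruments
  inst2[[2]] <- c(inst2[[2]], inst2[[1]][1])
  set2 <- build_mv_set(list(x1 = mv$exposure1, x2 = mv$exposure2),
                       mv$outcome, instruments = inst2,
                       pheno_corr = mv$pheno_corr)
  expect_false(inst2[[1]][1] %in% set2$variant_id)
  expect_equal(length(set2$beta_y), 34L)

  # cross-exposure LD at r2 >= threshold drops both partners
  ld <- data.frame(id_a = mv$instruments[[1]][2], id_b = mv$instruments[[2]][3],
                   r2 = 0.5, stringsAsFactors = FALSE)
  set3 <- build_mv_set(list(x1 = mv$exposure1, x2 = mv$exposure2),
                       mv$outcome, instruments = mv$instruments,
                       ld_info = ld, pheno_corr = mv$pheno_corr)
  expect_false(any(c(mv$instruments[[1]][2], mv$instruments[[2]][3]) %in%
                     set3$variant_id))

  # K = 2 with one usable variant is underidentified
  tiny <- lapply(mv$instruments, `[`, 1)
  expect_error(build_mv_set(list(x1 = mv$exposure1, x2 = mv$exposure2),
                            mv$outcome, instruments = tiny,
                            pheno_corr = mv$pheno_corr),
               "underidentified")
})

test_that("mv_ivw solves exact data and degenerates gracefully", {
  set <- make_mv(L = 12, theta = c(0.2, 0.1))
  est <- mv_ivw(set)
  expect_equal(est$x1$beta, 0.2, tolerance = 1e-10)
  expect_equal(est$x2$beta, 0.1, tolerance = 1e-10)
  expect_equal(est$x1$q, 0, tolerance = 1e-16)

  # an all-zero second column is aliased; exposure 1 matches univariable IVW
  set0 <- set
  set0$beta_x[, 2] <- 0
  expect_warning(est0 <- mv_ivw(set0), "aliased")
  uni <- mr_ivw(make_set(beta_x = set0$beta_x[, 1], beta_y = set0$beta_y,
                         se_y = set0$se_y))
  expect_equal(est0$x1$beta, uni$beta, tolerance = 1e-12)
  expect_null(est0$x2)

  expect_error(mv_ivw(make_mv(L = 2)), "more variants")
})

test_that("mv_egger nests mv_ivw and finds no intercept in clean data", {
  set <- make_mv(L = 15, theta = c(0.2, 0.1), noise = 1, seed = 4)
  fit <- mv_egger(set)
  expect_lt(abs(fit$intercept$estimate), 3 * fit$intercept$se)
  exact <- make_mv(L = 15, theta = c(0.2, 0.1), noise = 0, seed = 4)
  fit0 <- mv_egger(exact)
  expect_equal(fit0$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(fit0$estimates$x1$beta, 0.2, tolerance = 1e-8)

  constrained <- mv_egger(set, fit_intercept = FALSE)
  ivw <- mv_ivw(set)
  expect_equal(constrained$estimates$x1$beta, ivw$x1$beta, tolerance = 1e-12)
  expect_equal(constrained$estimates$x2$beta, ivw$x2$beta, tolerance = 1e-12)
})

test_that("mv_ivw recovers truth in the simulated confounded design", {
  reps <- lapply(1:25, function(r) {
    mv <- simulate_mv(sim_scenario(n_snps = 60, theta = 0.15,
                                   seed = 600 + r, palindromic_fraction = 0),
                      theta2 = 0.1, n_snps2 = 60, cross_corr = 0.6)
    set <- build_mv_set(list(x1 = mv$exposure1, x2 = mv$exposure2),
                        mv$outcome, instruments = mv$instruments,
                        pheno_corr = mv$pheno_corr)
    uni <- mr_ivw(harmonize_dataset(mv$exposure1[mv$exposure1$variant_id %in%
                                                   mv$instruments[[1]], ],
                                    mv$outcome))
    c(mv = mv_ivw(set)$x1$beta, uni = uni$beta)
  })
  m <- do.call(rbind, reps)
  mv_bias <- mean(m[, "mv"]) - 0.15
  uni_bias <- mean(m[, "uni"]) - 0.15
  # univariable IVW inherits the exposure-2 pathway; MVMR removes most of it
  expect_gt(abs(uni_bias), 3 * abs(mv_bias))
  expect_lt(abs(mv_bias), 3 * sd(m[, "mv"]) / sqrt(nrow(m)) + 0.005)
})

test_that("conditional F tracks independent instrument strength", {
  set <- make_mv(L = 20, seed = 9)
  # second exposure irrelevant: reduces to the mean-F analogue
  set0 <- set
  set0$beta_x[, 2] <- 0
  f <- conditional_f(set0, 1)
  expect_equal(f, sum((set0$beta_x[, 1] / set0$se_x[, 1])^2) / 19,
               tolerance = 1e-6)
  # perfectly proportional exposures with tiny SEs: no independent strength
  setc <- set
  setc$beta_x[, 2] <- 2 * setc$beta_x[, 1]
  expect_lt(conditional_f(setc, 1), 1e-6)
  # invariance to rescaling the other exposure's units
  sets <- set
  sets$beta_x[, 2] <- set$beta_x[, 2] * 3.7
  sets$se_x[, 2] <- set$se_x[, 2] * 3.7
  expect_equal(conditional_f(sets, 1), conditional_f(set, 1),
               tolerance = 1e-4)
})

test_that("modified Q is zero at truth on clean data and minimized properly", {
  exact <- make_mv(L = 12, theta = c(0.2, 0.1), noise = 0, seed = 5)
  expect_equal(modified_q(exact, c(0.2, 0.1))$q, 0, tolerance = 1e-12)
  # seX -> 0 reduces to the IVW Q form
  small <- make_mv(L = 12, theta = c(0.2, 0.1), noise = 1, seed = 6)
  small$se_x[] <- 1e-12
  mq <- modified_q(small, c(0.2, 0.1))
  ivw_q <- sum((small$beta_y - small$beta_x %*% c(0.2, 0.1))^2 / small$se_y^2)
  expect_equal(mq$q, ivw_q, tolerance = 1e-6)
  # the reported minimum beats a surrounding grid (grid-search oracle)
  for (seed in c(7, 8)) {
    s <- make_mv(L = 15, noise = 1, seed = seed)
    opt <- modified_q(s)
    grid <- expand.grid(t1 = opt$theta[1] + seq(-0.05, 0.05, length.out = 7),
                        t2 = opt$theta[2] + seq(-0.05, 0.05, length.out = 7))
    qs <- apply(grid, 1, function(t) modified_q(s, t)$q)
    expect_lte(opt$q, min(qs) + 1e-6)
  }
})
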