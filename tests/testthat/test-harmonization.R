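# Allele alignment, palindromic classification, proxy substitution, and the
# composed harmonization with its invariants.

test_that("align_alleles resolves the four cases and fails on mismatch", {
  direct <- align_alleles("A", "G", "A", "G", 0.02, 0.01, 0.3)
  expect_equal(direct$action, "direct")
  expect_equal(direct$beta, 0.02)

  sw <- align_alleles("A", "G", "G", "A", 0.02, 0.01, 0.3)
  expect_equal(sw$action, "swapped")
  expect_equal(sw$beta, -0.02)
  expect_equal(sw$eaf, 0.7)

  # reverse-complement pair: A/G on the other strand reads T/C
  fl <- align_alleles("A", "G", "T", "C", 0.02, 0.01, 0.3)
  expect_equal(fl$action, "strand_flipped")
  expect_equal(fl$beta, 0.02)

  swfl <- align_alleles("A", "G", "C", "T", 0.02, 0.01, 0.3)
  expect_equal(swfl$action, "swapped_and_flipped")
  expect_equal(swfl$beta, -0.02)

  expect_equal(align_alleles("A", "G", "A", "C", 0.02, 0.01)$failure,
               "allele mismatch")
  expect_match(align_alleles("A", "G", "AT", "G", 0.02, 0.01)$failure,
               "multi-base")
})

test_that("swap rule is an involution on sign and frequency", {
  set.seed(7)
  for (i in 1:50) {
    b <- rnorm(1); f <- runif(1)
    once <- align_alleles("A", "G", "G", "A", b, 0.01, f)
    # applying the swap rule to the once-swapped record restores the original
    twice <- align_alleles("A", "G", "G", "A", once$beta, 0.01, once$eaf)
    expect_equal(twice$beta, b)
    expect_equal(twice$eaf, f)
  }
})

test_that("palindromic classification honours the exclusive window", {
  expect_equal(classify_palindromic("A", "G", 0.50), "not_palindromic")
  expect_equal(classify_palindromic("A", "T", 0.50), "palindromic_ambiguous")
  expect_equal(classify_palindromic("C", "G", 0.30), "palindromic_inferable")
  # endpoints are exclusive: exactly 0.42 / 0.58 is inferable
  expect_equal(classify_palindromic("A", "T", 0.42), "palindromic_inferable")
  expect_equal(classify_palindromic("G", "C", 0.58), "palindromic_inferable")
  expect_equal(classify_palindromic("A", "T", 0.421), "palindromic_ambiguous")
  # missing EAF on a palindromic variant is conservatively ambiguous
  expect_equal(classify_palindromic("A", "T", NA), "palindromic_ambiguous")
})

test_that("proxy substitution picks the best admissible proxy", {
  pm <- proxy_map(data.frame(
    missing_id = c("rs1", "rs2", "rs3", "rs3", "rs4"),
    proxy_id = c("rs9", "rs8", "rs7a", "rs7b", "rs6"),
    r2 = c(0.95, 0.7, 0.85, 0.92, 0.9),
    allele_map = c("A=G,C=T", "A=G,C=T", "A=G,C=T", "A=G,C=T", "A=G,C=G"),
    stringsAsFactors = FALSE))
  avail <- c("rs9", "rs8", "rs7a", "rs7b", "rs6")
  plan <- substitute_proxies(c("rs1", "rs2", "rs3", "rs4"), avail, pm)
  expect_equal(plan$substitutions$proxy_id[plan$substitutions$variant_id == "rs1"],
               "rs9")
  # rs2's only proxy is below r2 >= 0.8
  expect_true("rs2" %in% plan$dropped$variant_id)
  # two admissible proxies: the higher r2 wins
  expect_equal(plan$substitutions$proxy_id[plan$substitutions$variant_id == "rs3"],
               "rs7b")
  # rs4's allele map is not bijective -> skipped, no other candidate
  expect_true("rs4" %in% plan$dropped$variant_id)
  expect_true(all(plan$dropped$reason == "no proxy"))
})

test_that("harmonize_dataset composes the rules and keeps exposure order", {
  p <- make_pair(3)
  hs <- harmonize_dataset(p$exposure, p$outcome)
  expect_equal(n_snps(hs), 3L)
  expect_true(all(hs$variants$action == "direct"))
  expect_equal(hs$variants$variant_id, p$exposure$variant_id)

  # an ambiguous palindromic variant without a proxy is dropped
  p2 <- make_pair(3)
  p2$exposure$effect_allele[2] <- p2$outcome$effect_allele[2] <- "A"
  p2$exposure$other_allele[2] <- p2$outcome$other_allele[2] <- "T"
  p2$exposure$eaf[2] <- p2$outcome$eaf[2] <- 0.5
  hs2 <- harmonize_dataset(p2$exposure, p2$outcome)
  expect_equal(n_snps(hs2), 2L)
  expect_equal(hs2$dropped$reason, "ambiguous palindromic")
  # retained + dropped partitions the requested list
  expect_setequal(c(hs2$variants$variant_id, hs2$dropped$variant_id),
                  p2$exposure$variant_id)

  # inferable palindromic variants align by frequency matching
  p3 <- make_pair(2)
  p3$exposure$effect_allele[1] <- "A"; p3$exposure$other_allele[1] <- "T"
  p3$outcome$effect_allele[1] <- "A"; p3$outcome$other_allele[1] <- "T"
  p3$exposure$eaf[1] <- 0.2
  p3$outcome$eaf[1] <- 0.81  # other side of 0.5: outcome reported for T
  hs3 <- harmonize_dataset(p3$exposure, p3$outcome)
  expect_equal(hs3$variants$action[1], "swapped")
  expect_equal(hs3$variants$beta_y[1], -p3$outcome$beta[1])

  expect_error(harmonize_dataset(p2$exposure[2, ], p2$outcome),
               "no usable instruments")
})

test_that("harmonization substitutes proxies for missing and ambiguous variants", {
  p <- make_pair(4)
  # rs2 missing from outcome; rs9 is a proxy carrying G/C with swapped sense
  outcome <- p$outcome[-2, ]
  proxy_row <- p$outcome[2, ]
  proxy_row$variant_id <- "rs9"
  proxy_row$effect_allele <- "G"; proxy_row$other_allele <- "C"
  proxy_row$beta <- 0.0123; proxy_row$eaf <- 0.25
  outcome <- assoc_table(rbind(as.data.frame(outcome),
                               as.data.frame(proxy_row)),
                         trait_id = "outc", trait_type = "binary")
  pm <- proxy_map(data.frame(missing_id = "rs2", proxy_id = "rs9", r2 = 0.9,
                             allele_map = "A=G,G=C", stringsAsFactors = FALSE))
  hs <- harmonize_dataset(p$exposure, outcome, proxy_map = pm)
  expect_equal(n_snps(hs), 4L)
  row <- hs$variants[hs$variants$variant_id == "rs2", ]
  expect_equal(row$action, "proxy_substituted")
  expect_equal(row$beta_y, 0.0123)
  expect_true(any(grepl("proxied by rs9", hs$audit)))

  # without the proxy map the variant is dropped with "no proxy"
  hs2 <- harmonize_dataset(p$exposure, outcome)
  expect_equal(hs2$dropped$reason, "no proxy")
})

test_that("harmonization is idempotent on an already-harmonized pair", {
  set.seed(11)
  sim <- simulate_pair(sim_scenario(n_snps = 40, seed = 5))
  hs1 <- harmonize_dataset(sim$exposure, sim$outcome)
  # rebuild tables from the harmonized set and harmonize again
  rebuild <- function(hs, side) {
    v <- hs$variants
    assoc_table(data.frame(variant_id = v$variant_id, effect_allele = "A",
                           other_allele = "G", eaf = v$eaf,
                           beta = if (side == "x") v$beta_x else v$beta_y,
                           se = if (side == "x") v$se_x else v$se_y,
                           pvalue = 0.5, n = 1e5, stringsAsFactors = FALSE),
                trait_id = side)
  }
  hs2 <- harmonize_dataset(rebuild(hs1, "x"), rebuild(hs1, "y"))
  expect_equal(hs2$variants$beta_y, hs1$variants$beta_y)
  expect_equal(hs2$variants$beta_x, hs1$variants$beta_x)
  expect_true(all(hs2$variants$action == "direct"))
  expect_equal(nrow(hs2$dropped), 0L)
})

test_that("retained + dropped always partitions the request (property)", {
  for (seed in 1:10) {
    sim <- simulate_pair(sim_scenario(n_snps = 30, seed = seed,
                                      palindromic_fraction = 0.5,
                                      maf_range = c(0.3, 0.5)))
    hs <- harmonize_dataset(sim$exposure, sim$outcome)
    expect_setequal(c(hs$variants$variant_id, hs$dropped$variant_id),
                    sim$exposure$variant_id)
    expect_equal(n_snps(hs) + nrow(hs$dropped), nrow(sim$exposure))
  }
})
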