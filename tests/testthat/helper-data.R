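# Shared fixture builders. Everything is generated in code; no stored data.

make_assoc_df <- function(n = 3, ids = sprintf("rs%d", seq_len(n)),
                          ea = rep("A", n), oa = rep("G", n),
                          eaf = rep(0.3, n), beta = seq_len(n) / 100,
                          se = rep(0.01, n), pvalue = rep(1e-10, n),
                          nn = rep(1e5, n)) {
  data.frame(variant_id = ids, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = nn,
             stringsAsFactors = FALSE)
}

make_table <- function(..., trait_id = "trait", trait_type = "continuous") {
  assoc_table(make_assoc_df(...), trait_id = trait_id,
              trait_type = trait_type)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A concordant exposure/outcome pair sharing ids and alleles.
make_pair <- function(n = 5, beta_x = seq(0.02, 0.1, length.out = n),
                      beta_y = 0.3 * beta_x, se_x = rep(0.005, n),
                      se_y = rep(0.01, n), eaf = seq(0.1, 0.4, length.out = n)) {
  ids <- sprintf("rs%d", seq_len(n))
  exposure <- assoc_table(
    make_assoc_df(n, ids = ids, eaf = eaf, beta = beta_x, se = se_x),
    trait_id = "expo")
  outcome <- assoc_table(
    make_assoc_df(n, ids = ids, eaf = eaf, beta = beta_y, se = se_y),
    trait_id = "outc", trait_type = "binary")
  list(exposure = exposure, outcome = outcome)
}

make_set <- function(beta_x, beta_y, se_y, se_x = rep(0.005, length(beta_x)),
                     eaf = rep(0.3, length(beta_x))) {
  harmonized_set("expo", "outc", data.frame(
    variant_id = sprintf("rs%d", seq_along(beta_x)), beta_x = beta_x,
    se_x = se_x, beta_y = beta_y, se_y = se_y, eaf = eaf,
    action = "direct", stringsAsFactors = FALSE))
}

random_set <- function(L, seed) {
  set.seed(seed)
  make_set(beta_x = runif(L, 0.02, 0.2) * sample(c(-1, 1), L, TRUE),
           beta_y = rnorm(L, 0, 0.05),
           se_y = runif(L, 0.005, 0.05),
           se_x = runif(L, 0.002, 0.01))
}
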