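# Internal helpers shared across modules.

# Reverse-complement single-base alleles (no reversal needed for length-1).
revcomp <- function(a) chartr("ACGT", "TGCA", a)

is_snp_allele <- function(a) {
  !is.na(a) & nchar(a) == 1L & a %in% c("A", "C", "G", "T")
}

is_palindromic_pair <- function(ea, oa) {
  is_snp_allele(ea) & is_snp_allele(oa) & revcomp(ea) == oa
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-replicate seed from a master seed, staying inside 32-bit range.
derive_seed <- function(master, i) {
  as.integer((as.double(master) + 104729 * as.double(i)) %% 2147483587)
}

stop_config <- function(...) {
  stop(structure(class = c("gwasmr_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("gwasmr_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")
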