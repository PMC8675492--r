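# Allele harmonization: align exposure and outcome summary statistics to a
# common effect allele, resolve strand flips and palindromic ambiguity, and
# substitute file-based proxies for variants missing from the outcome.

#' Align one outcome record onto the exposure's effect allele
#'
#' Four resolutions are possible: identical allele pair (`direct`), swapped
#' alleles (outcome beta negated, EAF reflected), reverse-complement pair
#' (`strand_flipped`, values unchanged), and reverse-complement of the
#' swapped pair (`swapped_and_flipped`, beta negated, EAF reflected). Any
#' other combination fails with reason `"allele mismatch"`. Multi-base
#' (indel) alleles are rejected: only biallelic SNPs are harmonized.
#'
#' @param exp_ea,exp_oa exposure effect/other allele (single bases).
#' @param out_ea,out_oa outcome effect/other allele.
#' @param beta_y,se_y,eaf_y outcome effect, SE and effect-allele frequency.
#' @return list with `beta`, `se`, `eaf`, `action` on success, or
#'   `list(failure = reason)`.
#' @export
align_alleles <- function(exp_ea, exp_oa, out_ea, out_oa,
                          beta_y, se_y, eaf_y = NA_real_) {
  if (!all(is_snp_allele(c(exp_ea, exp_oa, out_ea, out_oa))))
    return(list(failure = "non-SNP or multi-base allele"))
  if (out_ea == exp_ea && out_oa == exp_oa) {
    list(beta = beta_y, se = se_y, eaf = eaf_y, action = "direct")
  } else if (out_ea == exp_oa && out_oa == exp_ea) {
    list(beta = -beta_y, se = se_y, eaf = 1 - eaf_y, action = "swapped")
  } else if (revcomp(out_ea) == exp_ea && revcomp(out_oa) == exp_oa) {
    list(beta = beta_y, se = se_y, eaf = eaf_y, action = "strand_flipped")
  } else if (revcomp(out_ea) == exp_oa && revcomp(out_oa) == exp_ea) {
    list(beta = -beta_y, se = se_y, eaf = 1 - eaf_y,
         action = "swapped_and_flipped")
  } else {
    list(failure = "allele mismatch")
  }
}

#' Classify a variant's palindromic status
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' resolved from the alleles alone. If the effect-allele frequency is far
#' from 0.5 the orientation can be inferred by frequency matching; inside
#' the ambiguity window (default strictly above 0.42 and strictly below
#' 0.58) it cannot. A palindromic variant with missing EAF is conservatively
#' classified ambiguous.
#'
#' @param effect_allele,other_allele single-base alleles.
#' @param eaf effect-allele frequency, possibly `NA`.
#' @param window exclusive ambiguity window endpoints.
#' @return `"not_palindromic"`, `"palindromic_inferable"` or
#'   `"palindromic_ambiguous"`.
#' @export
classify_palindromic <- function(effect_allele, other_allele, eaf = NA_real_,
                                 window = c(0.42, 0.58)) {
  if (!all(is_snp_allele(c(effect_allele, other_allele))))
    stop_data("palindromic classification needs single-base SNP alleles")
  if (!is_palindromic_pair(effect_allele, other_allele))
    return("not_palindromic")
  if (is.na(eaf)) return("palindromic_ambiguous")
  if (eaf > window[1] && eaf < window[2]) "palindromic_ambiguous"
  else "palindromic_inferable"
}

#' Read a proxy map from a TSV file
#'
#' Columns: `missing_id`, `proxy_id`, `r2`, `allele_map` (e.g. `"A=G,C=T"`:
#' missing-variant allele `=` corresponding proxy allele).
#' @param path file path.
#' @return data.frame of class `proxy_map`.
#' @export
read_proxy_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("missing_id", "proxy_id", "r2", "allele_map")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("proxy map lacks columns: ",
                                paste(miss, collapse = ", "))
  proxy_map(df)
}

#' Construct a proxy map
#' @param entries data.frame with `missing_id`, `proxy_id`, `r2`,
#'   `allele_map` columns.
#' @return the validated `proxy_map`.
#' @export
proxy_map <- function(entries) {
  entries$r2 <- as.numeric(entries$r2)
  if (any(is.na(entries$r2) | entries$r2 < 0 | entries$r2 > 1))
    stop_data("proxy r2 must lie in [0,1]")
  structure(entries, class = c("proxy_map", "data.frame"))
}

# "A=G,C=T" -> c(A = "G", C = "T"); NULL on malformed input.
parse_allele_map <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) return(NULL)
  m <- stats::setNames(toupper(vapply(kv, `[`, "", 2L)),
                       toupper(vapply(kv, `[`, "", 1L)))
  if (anyDuplicated(names(m)) || anyDuplicated(unname(m))) return(NULL)
  m
}

#' Plan proxy substitutions for instruments missing from an outcome
#'
#' Each missing variant maps to its highest-r2 proxy that clears `r2_min`
#' and is present in the outcome set; variants with no admissible proxy are
#' dropped with reason `"no proxy"`. Proxies with an inconsistent allele
#' correspondence are skipped in favour of the next candidate.
#'
#' @param requested character vector of instrument variant ids needing a proxy.
#' @param available character vector of variant ids present in the outcome.
#' @param proxy_map a [proxy_map()] (may be `NULL`/empty).
#' @param r2_min minimum linkage r2 for an acceptable proxy (default 0.8).
#' @return list with `substitutions` (data.frame `variant_id`, `proxy_id`,
#'   `r2`, `allele_map`) and `dropped` (data.frame `variant_id`, `reason`).
#' @export
substitute_proxies <- function(requested, available, proxy_map = NULL,
                               r2_min = 0.8) {
  subs <- data.frame(variant_id = character(), proxy_id = character(),
                     r2 = numeric(), allele_map = character(),
                     stringsAsFactors = FALSE)
  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (v in requested) {
    cand <- if (is.null(proxy_map) || !nrow(proxy_map)) NULL
            else proxy_map[proxy_map$missing_id == v &
                           proxy_map$r2 >= r2_min &
                           proxy_map$proxy_id %in% available, , drop = FALSE]
    chosen <- NULL
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(-cand$r2, cand$proxy_id), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        if (!is.null(parse_allele_map(cand$allele_map[i]))) {
          chosen <- cand[i, , drop = FALSE]
          break
        }
      }
    }
    if (is.null(chosen)) {
      dropped <- rbind(dropped, data.frame(variant_id = v, reason = "no proxy",
                                           stringsAsFactors = FALSE))
    } else {
      subs <- rbind(subs, data.frame(variant_id = v,
                                     proxy_id = chosen$proxy_id,
                                     r2 = chosen$r2,
                                     allele_map = chosen$allele_map,
                                     stringsAsFactors = FALSE))
    }
  }
  list(substitutions = subs, dropped = dropped)
}

#' Construct a harmonized exposure/outcome variant set
#'
#' @param exposure_id,outcome_id trait identifiers.
#' @param variants data.frame with `variant_id`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `eaf`, `action`.
#' @param dropped data.frame with `variant_id`, `reason`.
#' @param audit optional character vector of per-variant log lines.
#' @return object of class `harmonized_set`.
#' @export
harmonized_set <- function(exposure_id, outcome_id, variants, dropped = NULL,
                           audit = character()) {
  dropped <- dropped %||% data.frame(variant_id = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)
  if (nrow(variants)) {
    ok <- is.finite(variants$beta_x) & variants$se_x > 0 &
      is.finite(variants$beta_y) & variants$se_y > 0
    if (!all(ok)) stop_data("harmonized set contains non-finite effects or ",
                            "non-positive SEs")
  }
  rownames(variants) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 variants = variants, dropped = dropped, audit = audit),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s, %d variants retained, %d dropped\n",
              x$exposure_id, x$outcome_id, nrow(x$variants), nrow(x$dropped)))
  if (nrow(x$variants)) {
    tab <- table(x$variants$action)
    cat("  actions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of variants in a harmonized set
#' @param set a `harmonized_set`.
#' @export
n_snps <- function(set) nrow(set$variants)

#' Harmonize an exposure instrument table against an outcome table
#'
#' Composition of the three harmonization rules: proxy substitution for
#' variants missing from the outcome (and for ambiguous palindromic
#' variants, tried before dropping them), allele alignment with strand
#' resolution, and palindromic classification. Palindromic-but-inferable
#' variants are aligned by frequency matching (EAF vs 1-EAF closeness);
#' ambiguous ones without a usable proxy are dropped. Retained variants keep
#' the exposure table's order; every decision is recorded in the audit log.
#'
#' @param exposure an [assoc_table()] restricted to the instrument variants.
#' @param outcome an [assoc_table()] for the outcome trait.
#' @param proxy_map optional [proxy_map()].
#' @param ambiguity_window palindromic EAF ambiguity window (exclusive).
#' @param r2_min minimum proxy r2.
#' @param infer_palindromic align inferable palindromic variants by
#'   frequency matching (`TRUE`, default) or drop all palindromic variants.
#' @return a [harmonized_set()].
#' @export
harmonize_dataset <- function(exposure, outcome, proxy_map = NULL,
                              ambiguity_window = c(0.42, 0.58), r2_min = 0.8,
                              infer_palindromic = TRUE) {
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  rownames(ou) <- ou$variant_id
  requested <- ex$variant_id
  audit <- character()
  keep <- list()
  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop_var <- function(v, why) {
    dropped <<- rbind(dropped, data.frame(variant_id = v, reason = why,
                                          stringsAsFactors = FALSE))
    audit <<- c(audit, sprintf("%s: dropped (%s)", v, why))
  }

  # Which variants need a proxy: absent from outcome, or palindromic-ambiguous.
  palin_class <- vapply(seq_len(nrow(ex)), function(i) {
    classify_palindromic(ex$effect_allele[i], ex$other_allele[i], ex$eaf[i],
                         ambiguity_window)
  }, "")
  needs_proxy <- !(requested %in% ou$variant_id) |
    palin_class == "palindromic_ambiguous"
  plan <- substitute_proxies(requested[needs_proxy], ou$variant_id,
                             proxy_map, r2_min)
  sub_of <- stats::setNames(plan$substitutions$proxy_id,
                            plan$substitutions$variant_id)
  amap_of <- stats::setNames(plan$substitutions$allele_map,
                             plan$substitutions$variant_id)

  for (i in seq_len(nrow(ex))) {
    v <- ex$variant_id[i]
    action_prefix <- NULL
    if (needs_proxy[i]) {
      if (!v %in% names(sub_of)) {
        drop_var(v, if (v %in% ou$variant_id) "ambiguous palindromic"
                    else "no proxy")
        next
      }
      p <- sub_of[[v]]
      orec <- ou[p, ]
      amap <- parse_allele_map(amap_of[[v]])
      # Translate proxy alleles back into the missing variant's allele space.
      inv <- stats::setNames(names(amap), unname(amap))
      if (!all(c(orec$effect_allele, orec$other_allele) %in% names(inv))) {
        drop_var(v, "proxy allele correspondence inconsistent")
        next
      }
      # A proxy that is itself palindromic-ambiguous cannot be oriented.
      pclass <- classify_palindromic(orec$effect_allele, orec$other_allele,
                                     orec$eaf, ambiguity_window)
      if (pclass == "palindromic_ambiguous") {
        drop_var(v, "proxy palindromic-ambiguous")
        next
      }
      orec$effect_allele <- unname(inv[orec$effect_allele])
      orec$other_allele <- unname(inv[orec$other_allele])
      action_prefix <- "proxy_substituted"
      audit <- c(audit, sprintf("%s: proxied by %s (r2=%g)", v, p,
                                plan$substitutions$r2[
                                  plan$substitutions$variant_id == v]))
    } else {
      orec <- ou[v, ]
    }

    pal <- classify_palindromic(ex$effect_allele[i], ex$other_allele[i],
                                ex$eaf[i], ambiguity_window)
    if (pal == "palindromic_inferable" && !infer_palindromic) {
      drop_var(v, "palindromic (inference disabled)")
      next
    }
    if (pal == "palindromic_inferable" && is.null(action_prefix)) {
      # Strand is unresolvable from alleles; orient by frequency matching.
      if (is.na(orec$eaf)) { drop_var(v, "palindromic, outcome eaf missing"); next }
      same_side <- (ex$eaf[i] - 0.5) * (orec$eaf - 0.5) >= 0
      al <- if (same_side)
        list(beta = orec$beta, se = orec$se, eaf = orec$eaf, action = "direct")
      else
        list(beta = -orec$beta, se = orec$se, eaf = 1 - orec$eaf,
             action = "swapped")
    } else {
      al <- align_alleles(ex$effect_allele[i], ex$other_allele[i],
                          orec$effect_allele, orec$other_allele,
                          orec$beta, orec$se, orec$eaf)
    }
    if (!is.null(al$failure)) { drop_var(v, al$failure); next }
    if (!is.finite(ex$beta[i]) || !is.finite(al$beta) ||
        is.na(ex$se[i]) || ex$se[i] <= 0 || is.na(al$se) || al$se <= 0) {
      drop_var(v, "non-finite effect or SE")
      next
    }
    action <- if (is.null(action_prefix)) al$action else action_prefix
    audit <- c(audit, sprintf("%s: retained (%s)", v, action))
    keep[[length(keep) + 1L]] <- data.frame(
      variant_id = v, beta_x = ex$beta[i], se_x = ex$se[i],
      beta_y = al$beta, se_y = al$se, eaf = ex$eaf[i], action = action,
      stringsAsFactors = FALSE)
  }

  variants <- if (length(keep)) do.call(rbind, keep)
              else data.frame(variant_id = character(), beta_x = numeric(),
                              se_x = numeric(), beta_y = numeric(),
                              se_y = numeric(), eaf = numeric(),
                              action = character(), stringsAsFactors = FALSE)
  if (!nrow(variants)) stop_data("no usable instruments after harmonization")
  harmonized_set(attr(exposure, "trait_id") %||% "exposure",
                 attr(outcome, "trait_id") %||% "outcome",
                 variants, dropped, audit)
}
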