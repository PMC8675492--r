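# Study orchestration: run a configured exposure x outcome grid through
# harmonization, all estimators, diagnostics, power and multiplicity
# correction, and write result tables.

read_config_file <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_config("config must be .yaml/.yml or .json: ", path)
}

#' Bonferroni-corrected significance threshold for an analysis grid
#'
#' @param alpha family-wise error rate.
#' @param n_exposures,n_outcomes grid dimensions (>= 1).
#' @return `alpha / (n_exposures * n_outcomes)`; e.g. 0.05 over 2 exposures
#'   and 18 outcomes gives 0.0014 (2 s.f.). Comparisons should use the
#'   exact value; the rounding is display-only.
#' @export
bonferroni_threshold <- function(alpha, n_exposures, n_outcomes) {
  if (alpha <= 0 || alpha >= 1) stop_data("alpha must lie in (0,1)")
  if (n_exposures < 1 || n_outcomes < 1)
    stop_data("exposure and outcome counts must be >= 1")
  alpha / (n_exposures * n_outcomes)
}

#' Read and validate a study configuration
#'
#' The configuration (YAML or JSON) lists exposures (trait id, summary-
#' statistics path, phenotype SD, optional instrument-list path or selection
#' thresholds, optional rescale target), outcomes (trait id, path, trait
#' type, case counts, optional `effect_is_or`), an optional proxy map path,
#' optional MVMR covariates with a phenotypic correlation, `alpha`,
#' `correction` (`bonferroni` or `none`), `n_boot`, `seed` and
#' `output_dir`. Relative paths resolve against the config file's
#' directory.
#'
#' @param path config file path.
#' @return validated config list of class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- read_config_file(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(p)
    if (file.exists(p)) p else file.path(base, p)
  }
  if (!length(cfg$exposures %||% list()) || !length(cfg$outcomes %||% list()))
    stop_config("config needs at least one exposure and one outcome")
  as_rows <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i)
      as.list(x[i, , drop = FALSE]))
    else x
  }
  cfg$exposures <- lapply(as_rows(cfg$exposures), function(e) {
    if (is.null(e$trait_id) || is.null(e$path))
      stop_config("each exposure needs trait_id and path")
    e$path <- resolve(e$path)
    if (!is.null(e$instruments)) e$instruments <- resolve(e$instruments)
    e$p_max <- e$p_max %||% 5e-8
    e
  })
  cfg$outcomes <- lapply(as_rows(cfg$outcomes), function(o) {
    if (is.null(o$trait_id) || is.null(o$path))
      stop_config("each outcome needs trait_id and path")
    o$path <- resolve(o$path)
    o$trait_type <- o$trait_type %||% "binary"
    o
  })
  if (!is.null(cfg$proxy_map)) cfg$proxy_map <- resolve(cfg$proxy_map)
  cfg$alpha <- cfg$alpha %||% 0.05
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_config("alpha must lie in (0,1)")
  cfg$correction <- match.arg(cfg$correction %||% "bonferroni",
                              c("bonferroni", "none"))
  cfg$n_boot <- cfg$n_boot %||% 1000L
  cfg$seed <- cfg$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% "results"
  if (!grepl("^/", cfg$output_dir)) cfg$output_dir <- file.path(base, cfg$output_dir)
  structure(cfg, class = "study_config")
}

load_exposure <- function(e) {
  tab <- read_association_table(e$path, column_map = e$column_map,
                                trait_id = e$trait_id,
                                trait_type = "continuous",
                                unit_sd = e$phenotype_sd %||% NA_real_)
  if (!is.null(e$instruments)) {
    ids <- readLines(e$instruments)
    ids <- ids[nzchar(ids)]
    tab <- tab[tab$variant_id %in% ids, , drop = FALSE]
    class(tab) <- c("assoc_table", "data.frame")
  } else if (!is.null(e$p_max)) {
    tab <- significance_filter(tab, e$p_max)
  }
  tab
}

load_outcome <- function(o) {
  read_association_table(o$path, column_map = o$column_map,
                         trait_id = o$trait_id, trait_type = o$trait_type,
                         n_cases = o$n_cases %||% NA_integer_,
                         n_noncases = o$n_noncases %||% NA_integer_,
                         effect_is_or = isTRUE(o$effect_is_or))
}

run_cell <- function(exp_tab, out_tab, ecfg, ocfg, cfg, pmap, threshold) {
  hs <- harmonize_dataset(exp_tab, out_tab, proxy_map = pmap)
  ests <- list(mr_ivw(hs))
  if (n_snps(hs) >= 3L) {
    ests <- c(ests, list(
      weighted_median(hs, n_boot = cfg$n_boot, seed = cfg$seed),
      mr_egger(hs)))
  }
  sd <- ecfg$phenotype_sd %||% NA_real_
  target <- ecfg$rescale_unit %||% NA_real_
  rescaled <- if (!is.na(sd) && !is.na(target))
    lapply(ests, function(e) {
      r <- rescale_estimate(e, sd, target)
      r$method <- paste0(unname(method_labels[r$method]), "_rescaled")
      r
    }) else list()
  diag <- instrument_diagnostics(hs$variants$beta_x, hs$variants$se_x,
                                 eaf = hs$variants$eaf, phenotype_sd = sd)
  power <- if (identical(ocfg$trait_type, "binary") &&
               !is.null(ocfg$n_cases) && !is.null(ocfg$n_noncases) &&
               !is.na(diag$r2_explained)) {
    nt <- ocfg$n_cases + ocfg$n_noncases
    mr_power_binary(nt, ocfg$n_cases / nt, diag$r2_explained,
                    alpha = cfg$alpha, mode = "detectable_or",
                    power_target = cfg$power_target %||% 0.8)
  } else NA_real_
  frame <- estimates_to_frame(c(ests, rescaled), bonferroni = threshold)
  list(harmonized = hs, estimates = frame, diagnostics = diag,
       detectable_or = power)
}

#' Run a configured MR study grid
#'
#' For every exposure x outcome cell: harmonize (with proxy substitution if
#' configured), estimate with IVW (multiplicative random effects, the main
#' analysis) plus weighted-median and MR-Egger sensitivity analyses,
#' rescale to a custom exposure increment when configured, compute
#' instrument diagnostics and the detectable OR at the target power, and
#' flag estimates passing the Bonferroni-corrected threshold. Failures are
#' isolated per cell. Writes one results TSV per outcome, a combined table,
#' and a run log into the configured output directory.
#'
#' @param config a `study_config` or a path to one.
#' @return (invisibly) list with `combined` results data.frame, per-cell
#'   `cells`, the exact `threshold`, and `failures`.
#' @export
run_study <- function(config) {
  cfg <- if (inherits(config, "study_config")) config
         else read_study_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  pmap <- if (!is.null(cfg$proxy_map)) read_proxy_map(cfg$proxy_map) else NULL
  threshold <- if (cfg$correction == "bonferroni")
    bonferroni_threshold(cfg$alpha, length(cfg$exposures),
                         length(cfg$outcomes))
  else cfg$alpha
  cells <- list()
  failures <- list()
  combined <- list()
  exp_tabs <- lapply(cfg$exposures, function(e)
    tryCatch(load_exposure(e), error = function(err) err))
  for (oi in seq_along(cfg$outcomes)) {
    ocfg <- cfg$outcomes[[oi]]
    out_tab <- tryCatch(load_outcome(ocfg), error = function(err) err)
    per_outcome <- list()
    for (ei in seq_along(cfg$exposures)) {
      ecfg <- cfg$exposures[[ei]]
      key <- paste(ecfg$trait_id, ocfg$trait_id, sep = ":")
      res <- tryCatch({
        if (inherits(exp_tabs[[ei]], "error")) stop(exp_tabs[[ei]])
        if (inherits(out_tab, "error")) stop(out_tab)
        run_cell(exp_tabs[[ei]], out_tab, ecfg, ocfg, cfg, pmap, threshold)
      }, error = function(err) err)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
      } else {
        cells[[key]] <- res
        per_outcome[[key]] <- res$estimates
        combined[[key]] <- res$estimates
      }
    }
    if (length(per_outcome))
      write_results_table(do.call(rbind, per_outcome),
                          file.path(cfg$output_dir,
                                    paste0(ocfg$trait_id, "_results.tsv")))
  }
  if (!length(cells))
    stop_data("all cells failed: ",
              paste(names(failures), unlist(failures), collapse = "; "))
  combined <- do.call(rbind, combined)
  rownames(combined) <- NULL
  write_results_table(combined, file.path(cfg$output_dir, "combined_results.tsv"))
  log <- c(sprintf("gwasmr %s", as.character(utils::packageVersion("gwasmr"))),
           sprintf("seed: %d", cfg$seed),
           sprintf("alpha: %g, correction: %s, exact threshold: %.10g",
                   cfg$alpha, cfg$correction, threshold),
           sprintf("cells: %d ok, %d failed", length(cells), length(failures)),
           if (length(failures))
             sprintf("FAILED %s: %s", names(failures), unlist(failures)))
  writeLines(log, file.path(cfg$output_dir, "run_log.txt"))
  invisible(list(combined = combined, cells = cells, threshold = threshold,
                 failures = failures))
}
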