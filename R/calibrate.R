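# Calibration experiments: repeated simulate -> harmonize -> estimate runs
# summarising bias, RMSE, coverage and rejection for each estimator.

#' Run a calibration experiment for one scenario
#'
#' Replicates are seeded independently from a master seed, so any single
#' replicate can be reproduced in isolation. Each replicate simulates a
#' summary-statistics pair, harmonizes it through the standard rules, and
#' applies the requested estimators; failures are recorded and the
#' replicate excluded for that method.
#'
#' @param scenario a [sim_scenario()]; its `seed` field is ignored in
#'   favour of `seed`.
#' @param methods subset of `"ivw"`, `"ivw_fixed"`, `"weighted_median"`,
#'   `"egger"`.
#' @param n_reps number of replicates (>= 100 recommended).
#' @param seed master seed.
#' @param n_boot bootstrap replicates for the weighted median.
#' @param alpha nominal test size for the rejection rate.
#' @param stream_path optional TSV path receiving per-replicate estimates
#'   for audit.
#' @return data.frame of class `calibration_result`, one row per method:
#'   mean estimate, bias against the scenario's true effect, empirical and
#'   mean model SE, RMSE, 95% coverage, rejection rate at `alpha`, failure
#'   count. The Egger row's `intercept_mean` averages the fitted intercepts.
#' @export
calibrate <- function(scenario, methods = "ivw", n_reps = 200L, seed = 1L,
                      n_boot = 200L, alpha = 0.05, stream_path = NULL) {
  methods <- match.arg(methods, c("ivw", "ivw_fixed", "weighted_median",
                                  "egger"), several.ok = TRUE)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- scenario
    s$seed <- derive_seed(seed, r)
    sim <- simulate_pair(s)
    hs <- tryCatch(harmonize_dataset(sim$exposure, sim$outcome),
                   error = function(e) NULL)
    one <- lapply(methods, function(m) {
      est <- tryCatch(switch(m,
        ivw = mr_ivw(hs),
        ivw_fixed = mr_ivw(hs, effects = "fixed"),
        weighted_median = weighted_median(hs, n_boot = n_boot,
                                          seed = derive_seed(seed, r) + 7L),
        egger = mr_egger(hs)),
        error = function(e) NULL)
      if (is.null(hs) || is.null(est))
        data.frame(rep = r, method = m, beta = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   pvalue = NA_real_, intercept = NA_real_,
                   stringsAsFactors = FALSE)
      else
        data.frame(rep = r, method = m, beta = est$beta, se = est$se,
                   ci_low = est$ci_low, ci_high = est$ci_high,
                   pvalue = est$pvalue,
                   intercept = est$intercept %||% NA_real_,
                   stringsAsFactors = FALSE)
    })
    rows[[r]] <- do.call(rbind, one)
  }
  per_rep <- do.call(rbind, rows)
  if (!is.null(stream_path))
    utils::write.table(per_rep, stream_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  truth <- scenario$theta
  out <- do.call(rbind, lapply(methods, function(m) {
    d <- per_rep[per_rep$method == m & !is.na(per_rep$beta), ]
    n_fail <- n_reps - nrow(d)
    data.frame(method = m, n_reps = nrow(d), n_fail = n_fail,
               true_theta = truth,
               mean_estimate = mean(d$beta),
               bias = mean(d$beta) - truth,
               empirical_se = stats::sd(d$beta),
               mean_model_se = mean(d$se),
               rmse = sqrt(mean((d$beta - truth)^2)),
               coverage_95 = mean(d$ci_low <= truth & truth <= d$ci_high),
               rejection_rate = mean(d$pvalue < alpha),
               intercept_mean = if (m == "egger") mean(d$intercept)
                                else NA_real_,
               seed = seed, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "per_rep") <- per_rep
  class(out) <- c("calibration_result", "data.frame")
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration over %d replicates (true effect %.3g)\n",
              max(x$n_reps + x$n_fail), x$true_theta[1]))
  print.data.frame(x[c("method", "mean_estimate", "bias", "empirical_se",
                       "mean_model_se", "coverage_95", "rejection_rate",
                       "n_fail")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Monte-Carlo standard error of a calibration mean estimate
#' @param result a [calibrate()] result row or data.frame.
#' @return `empirical_se / sqrt(n_reps)` per row.
#' @export
mc_se <- function(result) result$empirical_se / sqrt(result$n_reps)
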