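#' Bayesian multilevel relevance analysis
#'
#' High-level entry point: builds a [bn_dataset()] from a data frame,
#' resolves missing codes (complete-case by default), runs the
#' Metropolis-coupled structure sampler and returns the posterior
#' relevance summary.  Use [tidy()] for the per-pair posterior table,
#' [glance()] for run-level diagnostics, [mbs_posterior_table()] and
#' [k_mbs_aggregate()] for set-level relevance.
#'
#' @param data A data frame of categorical columns, or a [bn_dataset()].
#' @param targets Target column names.
#' @param score A [score_config()].
#' @param mcmc An [mcmc_config()].
#' @param missing Missing-data policy passed to [complete_case_filter()].
#' @param ... Passed to [mc3_run()].
#' @return A `bnbmla_run`.
#' @export
#' @examples
#' sim <- simulate_dataset(scenario_asthma(n = 300, seed = 7))
#' fit <- bnbmla(sim$dataset, targets = "asthma",
#'               mcmc = mcmc_config(burn_in = 1000, n_steps = 10000,
#'                                  feature_eval_interval = 1, seed = 7))
#' tidy(fit)
bnbmla <- function(data, targets = NULL, score = score_config(),
                   mcmc = mcmc_config(), missing = "drop_rows", ...) {
  ds <- if (inherits(data, "bn_dataset")) data
        else bn_dataset(data, targets = targets %||% character(0))
  cc <- complete_case_filter(ds, policy = missing)
  if (cc$report$rows_removed > 0 || cc$report$cells_imputed > 0)
    inform(sprintf("missing data: %d rows removed, %d cells imputed",
                   cc$report$rows_removed, cc$report$cells_imputed))
  mc3_run(cc$dataset, targets = targets, score = score, mcmc = mcmc, ...)
}

#' Tidy posterior table of a relevance run
#'
#' One row per (predictor, target) pair with the model-averaged posterior
#' of each dependency type and the Monte Carlo standard error of the
#' strong-relevance estimate.
#'
#' @param x A `bnbmla_run` or `bnbmla_exact`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bnbmla_run
#' @export
tidy.bnbmla_run <- function(x, ...) {
  out <- dplyr::transmute(x$pairwise,
    predictor = .data$predictor, target = .data$target,
    associated = .data$assoc, d_relevant = .data$dcr,
    s_relevant = .data$sr, interaction = .data$pir,
    transitive = .data$tcr, confounded = .data$confr,
    relevant = relevance_call(.data$sr))
  if (!inherits(x, "bnbmla_exact"))
    out$mc_se <- sqrt(out$s_relevant * (1 - out$s_relevant) / x$n_samples)
  out
}

#' Run-level summary of a relevance run
#'
#' @param x A `bnbmla_run`.
#' @param ... Unused.
#' @return One-row tibble: sample counts, acceptance and swap rates, the
#'   number of distinct blanket sets visited, and the top posterior mass.
#' @method glance bnbmla_run
#' @export
glance.bnbmla_run <- function(x, ...) {
  if (inherits(x, "bnbmla_exact")) {
    return(tibble::tibble(n_dags = x$n_dags, log_z = x$log_z,
                          n_targets = length(x$targets),
                          n_predictors = length(x$predictors)))
  }
  swaps <- if (length(x$stats$swap_attempts) > 0 &&
               sum(x$stats$swap_attempts) > 0)
    sum(x$stats$swap_accepts) / sum(x$stats$swap_attempts) else NA_real_
  tibble::tibble(
    n_samples = x$n_samples,
    n_targets = length(x$targets), n_predictors = length(x$predictors),
    acceptance_cold = x$stats$acceptance_rate[1],
    swap_rate = swaps,
    n_mbs_sets = nrow(x$mbs[[1]]),
    top_mbs_mass = max(x$mbs[[1]]$prob))
}

#' @method autoplot bnbmla_run
#' @export
autoplot.bnbmla_run <- function(object, feature = "s_relevant",
                                threshold = 0.5, ...) {
  d <- tidy(object)
  d$predictor <- factor(d$predictor,
                        levels = rev(sort(unique(d$predictor))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[feature]], y = .data$predictor)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::facet_wrap(~target) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = paste("posterior of", feature), y = NULL) +
    ggplot2::theme_minimal()
}

#' Full analysis pipeline
#'
#' Load, quality-control, frequentist baseline, structure MCMC and
#' posterior reports, writing every artifact plus a reproducibility
#' manifest to `out_dir`.  Controls for the Hardy-Weinberg filter are the
#' individuals with code 0 on the first target.
#'
#' @param data_path Delimited genotype/phenotype table
#'   (see [load_genotype_table()]).
#' @param targets Target column names.
#' @param out_dir Output directory.
#' @param score,mcmc Configurations.
#' @param hwe_p_max,callrate_min QC thresholds (see [qc_filter()]).
#' @param run_qc Apply the QC filter (default TRUE).
#' @return Invisibly, the paths of the written artifacts.
#' @export
run_pipeline <- function(data_path, targets, out_dir,
                         score = score_config(), mcmc = mcmc_config(),
                         hwe_p_max = 0.005, callrate_min = 0.90,
                         run_qc = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- load_genotype_table(data_path, target_names = targets)
  paths <- character(0)
  if (run_qc) {
    controls <- !is.na(ds$data[[targets[1]]]) & ds$data[[targets[1]]] == 0
    qc <- qc_filter(ds, controls, hwe_p_max = hwe_p_max,
                    callrate_min = callrate_min)
    ds <- qc$dataset
    qc_path <- file.path(out_dir, "qc_report.json")
    jsonlite::write_json(unclass(qc$report)[1:4], qc_path, auto_unbox = FALSE)
    paths <- c(paths, qc_path)
  }
  cc <- complete_case_filter(ds, "drop_rows")
  ds <- cc$dataset
  assoc <- association_report(ds, target = targets[1])
  assoc_path <- file.path(out_dir, "association.tsv")
  readr::write_tsv(assoc, assoc_path)
  paths <- c(paths, assoc_path)
  run <- mc3_run(ds, targets = targets, score = score, mcmc = mcmc)
  paths <- c(paths, write_report(run, out_dir))
  manifest <- list(
    data_path = data_path, targets = targets,
    n_rows = ds$n_rows, n_variables = nrow(ds$meta),
    rows_removed_missing = cc$report$rows_removed,
    score = unclass(run$score), mcmc = unclass(run$mcmc),
    acceptance_rate = run$stats$acceptance_rate,
    swap_accepts = run$stats$swap_accepts,
    n_recorded = run$n_samples,
    package_version = as.character(utils::packageVersion("bnbmla")))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, man_path)
  invisible(paths)
}
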