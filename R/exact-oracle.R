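#' Count labeled DAGs on a small domain
#'
#' Exhaustive count of directed acyclic graphs on `n` nodes respecting a
#' parent limit, by recursive parent-set assignment with cycle pruning.
#' Without a parent limit the counts follow the known sequence
#' 1, 3, 25, 543, 29281, 3781503.
#'
#' @param n Number of nodes (1..6).
#' @param max_parents Parent limit (default 8 = effectively none for
#'   `n <= 6`).
#' @return Number of DAGs.
#' @export
count_dags <- function(n, max_parents = 8) {
  cpp_count_dags(as.integer(n), as.integer(max_parents))
}

#' Enumerate labeled DAGs
#'
#' Materializes every DAG on `n <= 5` nodes as [bn_dag()] objects (29,281
#' graphs at n = 5).  For n = 6 use [count_dags()] or
#' [exact_posteriors()], which enumerate without materializing.
#'
#' @param n Number of nodes (1..5).
#' @param max_parents Parent limit.
#' @param names Optional node names (defaults to `V1..Vn`).
#' @return List of `bn_dag` objects.
#' @export
enumerate_dags <- function(n, max_parents = 8, names = NULL) {
  if (is.null(names)) names <- paste0("V", seq_len(n))
  raw <- cpp_enumerate_dags(as.integer(n), as.integer(max_parents))
  lapply(raw, function(ps) {
    g <- bn_dag(names)
    g$parents <- lapply(ps, as.integer)
    g
  })
}

#' Exact feature posteriors by exhaustive enumeration
#'
#' Computes every feature posterior and Markov blanket set posterior by
#' summing over all DAG structures on the domain, weighting each structure
#' by its normalized marginal likelihood (uniform structure prior,
#' log-sum-exp stabilized).  Tractable for up to 6 variables; the ground
#' truth against which the MCMC sampler is validated.
#'
#' @param ds A complete [bn_dataset()] with at most 6 variables.
#' @param targets Target names; defaults to the dataset's target columns.
#' @param score A [score_config()].
#' @return A `bnbmla_exact` object with the same tables as [mc3_run()].
#' @export
exact_posteriors <- function(ds, targets = NULL, score = score_config()) {
  if (is.null(targets)) targets <- target_names(ds)
  if (length(targets) == 0) abort("no target variables specified")
  if (nrow(ds$meta) > 6) abort("exact enumeration supports at most 6 variables")
  ti <- match(targets, ds$meta$name)
  if (anyNA(ti)) abort("unknown target variable(s)")
  preds <- setdiff(ds$meta$name, targets)
  pi <- match(preds, ds$meta$name)
  raw <- cpp_oracle_posteriors(dataset_matrix(ds), ds$meta$arity,
                               as.integer(ti), as.integer(pi),
                               as.integer(score$max_parents),
                               prior_code(score), score$ess)
  build_result(raw, ds, targets, preds, score, mcmc = NULL, kind = "exact")
}
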