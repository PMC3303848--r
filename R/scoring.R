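#' Scoring configuration
#'
#' The marginal likelihood of a complete multinomial dataset given a DAG
#' has a closed form under Dirichlet parameter priors.  Two hyperparameter
#' schemes are supported: `"ch"` sets every Dirichlet hyperparameter to 1
#' (the classical closed form; the default), `"bdeu"` sets
#' `alpha_ijk = ess / (r_child * q_parents)`, which makes the score
#' equivalent across Markov-equivalent structures.
#'
#' @param prior `"ch"` or `"bdeu"`.
#' @param ess Equivalent sample size (BDeu only, > 0).
#' @param max_parents Parent limit per node (default 8); the uniform
#'   structure prior ranges over DAGs respecting this limit.
#' @return A `score_config` list.
#' @export
score_config <- function(prior = c("ch", "bdeu"), ess = 1, max_parents = 8) {
  prior <- match.arg(prior)
  if (prior == "bdeu" && ess <= 0) abort("ess must be positive for BDeu")
  structure(list(prior = prior, ess = ess, max_parents = as.integer(max_parents)),
            class = "score_config")
}

prior_code <- function(cfg) if (cfg$prior == "ch") 0L else 1L

#' Family log marginal likelihood
#'
#' Closed-form log marginal likelihood of one child variable given a parent
#' set, for complete multinomial data:
#' \deqn{\prod_j \frac{\Gamma(\alpha_{ij})}{\Gamma(\alpha_{ij}+N_{ij})}
#'       \prod_k \frac{\Gamma(\alpha_{ijk}+N_{ijk})}{\Gamma(\alpha_{ijk})}}
#' where `j` ranges over parent configurations and `k` over child states.
#' An empty dataset scores 0 (all Gamma terms cancel).
#'
#' @param ds A complete [bn_dataset()].
#' @param child Child variable name.
#' @param parents Character vector of parent names (excludes the child).
#' @param config A [score_config()].
#' @return Log probability (finite).
#' @export
#' @examples
#' ds <- bn_dataset(data.frame(x = c(1, 1)))
#' family_log_marginal(ds, "x")          # log(1/3)
family_log_marginal <- function(ds, child, parents = character(0),
                                config = score_config()) {
  ci <- match(child, ds$meta$name)
  if (is.na(ci)) abort(paste0("unknown child: ", child))
  pi <- match(parents, ds$meta$name)
  if (anyNA(pi)) abort("unknown parent variable(s)")
  if (ci %in% pi) abort("parent set must exclude the child")
  if (length(pi) > config$max_parents)
    abort(sprintf("parent set exceeds the limit of %d", config$max_parents))
  cpp_family_log_marginal(dataset_matrix(ds), ds$meta$arity,
                          ci - 1L, as.integer(pi - 1L),
                          prior_code(config), config$ess)
}

#' DAG log score
#'
#' Decomposable score of a structure: the sum of family log marginal
#' likelihoods over all variables.  Under the uniform structure prior the
#' prior contributes a constant, which is omitted, so the posterior ratio
#' of two structures is `exp(score difference)`.
#'
#' @param ds A complete [bn_dataset()] whose variables match `g`.
#' @param g A [bn_dag()] over the dataset variables.
#' @param config A [score_config()].
#' @return Log score.
#' @export
dag_log_score <- function(ds, g, config = score_config()) {
  if (!setequal(g$names, ds$meta$name))
    abort("DAG variables must match dataset variables")
  if (!dag_is_acyclic(g)) abort("structure contains a directed cycle")
  if (any(lengths(g$parents) > config$max_parents))
    abort(sprintf("a node exceeds the parent limit of %d", config$max_parents))
  idx <- match(g$names, ds$meta$name)   # dag var -> dataset column
  parent_sets <- vector("list", nrow(ds$meta))
  for (v in seq_along(g$names))
    parent_sets[[idx[v]]] <- as.integer(idx[g$parents[[v]]] - 1L)
  cpp_dag_log_score(dataset_matrix(ds), ds$meta$arity, parent_sets,
                    prior_code(config), config$ess)
}

#' Incremental score change of an edge operation
#'
#' Exploits decomposability: adding or deleting an edge `from -> to`
#' re-scores only the family of `to`; reversing re-scores the families of
#' both endpoints.  Equals `dag_log_score(g') - dag_log_score(g)` exactly.
#'
#' @param ds A complete [bn_dataset()].
#' @param g A [bn_dag()].
#' @param move List with `op` (`"add"`, `"delete"` or `"reverse"`), `from`,
#'   `to`.
#' @param config A [score_config()].
#' @return List with `delta` (log-score change) and `dag` (the structure
#'   after the move).
#' @export
score_delta <- function(ds, g, move, config = score_config()) {
  op <- match.arg(move$op, c("add", "delete", "reverse"))
  from <- move$from; to <- move$to
  fam <- function(child_idx, parent_idx)
    family_log_marginal(ds, g$names[child_idx], g$names[parent_idx], config)
  u <- var_index(g, from); v <- var_index(g, to)
  if (op == "add") {
    g2 <- dag_add_edge(g, from, to)
    if (length(g2$parents[[v]]) > config$max_parents)
      abort("move violates the parent limit")
    delta <- fam(v, g2$parents[[v]]) - fam(v, g$parents[[v]])
  } else if (op == "delete") {
    g2 <- dag_remove_edge(g, from, to)
    delta <- fam(v, g2$parents[[v]]) - fam(v, g$parents[[v]])
  } else {
    g2 <- dag_add_edge(dag_remove_edge(g, from, to), to, from)
    if (length(g2$parents[[u]]) > config$max_parents)
      abort("move violates the parent limit")
    delta <- (fam(v, g2$parents[[v]]) - fam(v, g$parents[[v]])) +
             (fam(u, g2$parents[[u]]) - fam(u, g$parents[[u]]))
  }
  list(delta = delta, dag = g2)
}
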