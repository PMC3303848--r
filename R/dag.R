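#' Directed acyclic graph over dataset variables
#'
#' Lightweight DAG structure used as the unit of MCMC state and for
#' evaluating structural relevance features.  Variables are identified by
#' name; parent sets are stored per variable.
#'
#' @param names Character vector of variable names.
#' @param edges Optional two-column data frame or matrix of edges
#'   (`from`, `to`).
#' @return An object of class `bn_dag`.
#' @export
#' @examples
#' g <- bn_dag(c("x", "z", "y"), edges = data.frame(from = c("x", "z"),
#'                                                  to   = c("z", "y")))
#' markov_blanket(g, "z")
bn_dag <- function(names, edges = NULL) {
  if (anyDuplicated(names)) abort("variable names must be unique")
  g <- structure(list(names = names,
                      parents = rep(list(integer(0)), length(names))),
                 class = "bn_dag")
  if (!is.null(edges)) {
    edges <- as.data.frame(edges)
    for (i in seq_len(nrow(edges)))
      g <- dag_add_edge(g, edges[i, 1], edges[i, 2])
  }
  g
}

var_index <- function(g, x) {
  if (is.character(x)) {
    i <- match(x, g$names)
    if (anyNA(i)) abort(paste0("unknown variable(s): ",
                               paste(x[is.na(i)], collapse = ", ")))
    i
  } else as.integer(x)
}

#' @rdname bn_dag
#' @param g A `bn_dag`.
#' @param from,to Variable names (or indices) of the edge endpoints.
#' @export
dag_add_edge <- function(g, from, to) {
  u <- var_index(g, from); v <- var_index(g, to)
  if (u == v) abort("self-loops are not allowed")
  if (u %in% g$parents[[v]]) abort("edge already present")
  g$parents[[v]] <- sort(c(g$parents[[v]], u))
  if (!dag_is_acyclic(g)) abort("edge would create a directed cycle")
  g
}

#' @rdname bn_dag
#' @export
dag_remove_edge <- function(g, from, to) {
  u <- var_index(g, from); v <- var_index(g, to)
  if (!(u %in% g$parents[[v]])) abort("edge not present")
  g$parents[[v]] <- setdiff(g$parents[[v]], u)
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat("<bn_dag> ", length(x$names), " nodes, ", ne, " edges\n", sep = "")
  for (v in seq_along(x$names))
    if (length(x$parents[[v]]) > 0)
      cat("  ", paste(x$names[x$parents[[v]]], collapse = ", "),
          " -> ", x$names[v], "\n", sep = "")
  invisible(x)
}

dag_n_edges <- function(g) sum(lengths(g$parents))

adjacency <- function(g) {
  n <- length(g$names)
  a <- matrix(FALSE, n, n, dimnames = list(g$names, g$names))
  for (v in seq_len(n)) a[g$parents[[v]], v] <- TRUE
  a
}

dag_is_acyclic <- function(g) {
  a <- adjacency(g)
  n <- nrow(a)
  indeg <- colSums(a)
  removed <- 0L
  queue <- which(indeg == 0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    removed <- removed + 1L
    ch <- which(a[v, ])
    a[v, ch] <- FALSE
    indeg[ch] <- indeg[ch] - 1L
    queue <- c(queue, ch[indeg[ch] == 0])
  }
  removed == n
}

# reflexive-free transitive closure: closure[u, v] TRUE iff directed path u ~> v
dag_closure <- function(g) {
  a <- adjacency(g)
  n <- nrow(a)
  cl <- a
  repeat {
    nxt <- cl | (cl %*% a > 0)
    if (identical(nxt, cl)) break
    cl <- nxt
  }
  cl
}

#' Markov blanket of a target variable
#'
#' The Markov blanket set of `y` — its parents, its children, and the other
#' parents of its children — contains exactly the variables that are
#' strongly relevant to `y`: conditioned on the blanket, `y` is independent
#' of everything else.
#'
#' @param g A [bn_dag()].
#' @param y Target variable name.
#' @return Character vector of blanket members (sorted).
#' @export
markov_blanket <- function(g, y) {
  a <- adjacency(g)
  yi <- var_index(g, y)
  pa <- which(a[, yi])
  ch <- which(a[yi, ])
  sp <- if (length(ch) > 0) which(rowSums(a[, ch, drop = FALSE]) > 0) else integer(0)
  mb <- setdiff(sort(unique(c(pa, ch, sp))), yi)
  sort(g$names[mb])
}

#' Joint Markov blanket of a set of targets
#'
#' Union of the member blankets, minus the target set itself: the variables
#' strongly relevant to at least one target.
#'
#' @param g A [bn_dag()].
#' @param targets Character vector of target names (nonempty).
#' @return Character vector of blanket members (sorted).
#' @export
markov_blanket_of_set <- function(g, targets) {
  if (length(targets) == 0) abort("target set must be nonempty")
  mb <- unique(unlist(lapply(targets, function(t) markov_blanket(g, t))))
  sort(setdiff(mb, targets))
}

#' Pairwise dependency features of a DAG
#'
#' Classifies the structural relation between a predictor `x` and a target
#' `y` in a single DAG:
#' * `dcr` — direct relevance: an edge between `x` and `y` (either direction);
#' * `tcr` — transitive relevance: a directed path between `x` and `y`
#'   (a direct edge counts as a length-1 path);
#' * `confr` — confounded relevance: a proper common ancestor;
#' * `assoc` — association: `dcr | tcr | confr`;
#' * `pir` — pure interactionist relevance: a common child and no direct
#'   edge (the epistasis-like relation);
#' * `sr` — strong relevance: `dcr | pir`, equivalently membership in the
#'   Markov blanket of `y`;
#' * `mediated_only` — a directed path exists but no direct edge.
#'
#' `pir` excludes the direct edge so that strong relevance decomposes
#' additively: `P(sr) = P(dcr) + P(pir)` when averaged over structures.
#'
#' @param g A [bn_dag()].
#' @param x,y Distinct variable names.
#' @return One-row tibble of logical features.
#' @export
pairwise_features <- function(g, x, y) {
  xi <- var_index(g, x); yi <- var_index(g, y)
  if (xi == yi) abort("x and y must be distinct")
  a <- adjacency(g)
  cl <- dag_closure(g)
  dcr <- a[xi, yi] || a[yi, xi]
  tcr <- cl[xi, yi] || cl[yi, xi]
  confr <- any(cl[, xi] & cl[, yi] & !(seq_len(nrow(a)) %in% c(xi, yi)))
  pir <- any(a[xi, ] & a[yi, ]) && !dcr
  tibble::tibble(x = g$names[xi], y = g$names[yi],
                 dcr = dcr, tcr = tcr, confr = confr,
                 assoc = dcr || tcr || confr,
                 pir = pir, sr = dcr || pir,
                 mediated_only = tcr && !dcr)
}

#' Multi-target relevance features of a DAG
#'
#' For a predictor `x` and a set of targets, reports per-target strong
#' relevance (`exist`), exclusive relevance (`only`: strongly relevant to
#' that target and no other), relevance to any other target (`other_than`),
#' and the scalar summaries `mt` (strongly relevant to at least one target)
#' and `edge_to_any` (direct edge to at least one target).
#'
#' @param g A [bn_dag()].
#' @param x Predictor name (not a target).
#' @param targets Character vector of target names.
#' @return Tibble with one row per target.
#' @export
multi_target_features <- function(g, x, targets) {
  if (x %in% targets) abort("x must not be one of the targets")
  feats <- lapply(targets, function(t) pairwise_features(g, x, t))
  exist <- vapply(feats, function(f) f$sr, logical(1))
  edge <- vapply(feats, function(f) f$dcr, logical(1))
  other <- vapply(seq_along(targets),
                  function(i) any(exist[-i]), logical(1))
  tibble::tibble(x = x, target = targets,
                 exist = exist,
                 only = exist & !other,
                 other_than = other,
                 mt = any(exist),
                 edge_to_any = any(edge))
}
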