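# Shared fixtures and independent oracles for the test suite.

# Dataset with declared arities (categories may be unobserved), built from
# integer codes already in 0..arity-1.
coded_dataset <- function(df, targets = character(), arity = NULL) {
  ds <- bn_dataset(df, targets = targets)
  if (!is.null(arity)) {
    idx <- match(names(arity), ds$meta$name)
    ds$meta$arity[idx] <- as.integer(arity)
    for (nm in names(arity)) {
      # identity coding when categories are declared explicitly
      ds$data[[nm]] <- df[[nm]]
      ds$levels[[nm]] <- seq_len(arity[[nm]]) - 1L
    }
  }
  ds
}

empty_binary_dataset <- function(n_vars, names = paste0("V", seq_len(n_vars))) {
  df <- as.data.frame(setNames(rep(list(integer(0)), n_vars), names))
  coded_dataset(df, targets = names[n_vars],
                arity = setNames(rep(2L, n_vars), names))
}

# Independent CH-score oracle: the sequential predictive product
# prod_i (N_{x_i} + 1) / (i - 1 + r) for a no-parent family, applied per
# parent configuration for a family with parents.
seq_pred_log_score <- function(x, r) {
  counts <- rep(0, r)
  out <- 0
  for (i in seq_along(x)) {
    k <- x[i] + 1
    out <- out + log((counts[k] + 1) / (i - 1 + r))
    counts[k] <- counts[k] + 1
  }
  out
}

seq_pred_family_score <- function(child_codes, parent_config, r) {
  out <- 0
  for (cfg in unique(parent_config))
    out <- out + seq_pred_log_score(child_codes[parent_config == cfg], r)
  out
}

# Brute-force operator neighborhood on adjacency matrices, independent of
# the package's dag_neighborhood(): validity checked by trace-of-powers
# acyclicity and explicit parent counting.
brute_is_dag <- function(a) {
  n <- nrow(a)
  m <- a
  for (k in seq_len(n)) {
    if (sum(diag(m)) > 0) return(FALSE)
    m <- m %*% a
  }
  TRUE
}

brute_neighborhood <- function(a, max_parents = 8) {
  n <- nrow(a)
  moves <- list()
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    if (a[u, v] == 1) {
      a2 <- a; a2[u, v] <- 0
      moves[[length(moves) + 1]] <- c("delete", u, v)
      a3 <- a2; a3[v, u] <- 1
      if (brute_is_dag(a3) && sum(a3[, u]) <= max_parents)
        moves[[length(moves) + 1]] <- c("reverse", u, v)
    } else if (a[v, u] == 0) {
      a2 <- a; a2[u, v] <- 1
      if (brute_is_dag(a2) && sum(a2[, v]) <= max_parents)
        moves[[length(moves) + 1]] <- c("add", u, v)
    }
  }
  if (length(moves) == 0)
    return(data.frame(op = character(0), from = integer(0), to = integer(0)))
  m <- do.call(rbind, moves)
  data.frame(op = m[, 1], from = as.integer(m[, 2]), to = as.integer(m[, 3]))
}

# Small 5-variable generating model (4 SNPs + 1 binary target) for
# oracle-equivalence checks.
tiny_scenario <- function(seed, n = 200) {
  simulation_config(
    n_individuals = n,
    maf = c(snpA = 0.3, snpB = 0.5, snpC = 0.5, snpD = 0.2),
    effects = tibble::tibble(target = "pheno", snp = "snpA", beta = 0.9),
    epistasis = tibble::tibble(target = "pheno", snp1 = "snpB",
                               snp2 = "snpC", beta = 1.3),
    intercepts = c(pheno = -0.8),
    targets = "pheno", seed = seed)
}

random_dag <- function(n_nodes, p_edge = 0.3) {
  names <- paste0("N", seq_len(n_nodes))
  g <- bn_dag(names)
  ord <- sample(n_nodes)
  for (i in seq_len(n_nodes - 1)) for (j in (i + 1):n_nodes)
    if (runif(1) < p_edge)
      g <- dag_add_edge(g, names[ord[i]], names[ord[j]])
  g
}

expect_setequal_chr <- function(x, y) expect_setequal(as.character(x),
                                                      as.character(y))
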