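#' MCMC configuration
#'
#' Settings for the Metropolis-coupled structure sampler.  The defaults
#' reproduce the published analysis scale (10^6 burn-in steps, 5x10^6
#' post-burn-in steps, parent limit 8); chain count, temperature ladder and
#' swap schedule follow conventional MC^3 practice and are configurable.
#'
#' @param burn_in Burn-in steps discarded before recording (default 1e6).
#' @param n_steps Post-burn-in steps (default 5e6).
#' @param n_chains Number of tempered chains (default 4).
#' @param inverse_temperatures Descending vector starting at 1.0; chain 1
#'   is the cold chain and is the only chain recorded.
#' @param swap_interval Steps between state-swap attempts of a uniformly
#'   chosen adjacent chain pair (default 10).
#' @param feature_eval_interval Record the cold chain every this many
#'   post-burn-in steps (default 10; 1 evaluates every visited structure).
#' @param max_parents Parent limit per node (default 8).
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(burn_in = 1e6, n_steps = 5e6, n_chains = 4,
                        inverse_temperatures = c(1, 0.8, 0.6, 0.4),
                        swap_interval = 10, feature_eval_interval = 10,
                        max_parents = 8, seed = 1) {
  n_chains <- as.integer(n_chains)
  inverse_temperatures <- inverse_temperatures[seq_len(n_chains)]
  if (abs(inverse_temperatures[1] - 1) > 1e-12)
    abort("the first inverse temperature must be 1.0 (cold chain)")
  if (n_chains > 1 && any(diff(inverse_temperatures) >= 0))
    abort("inverse temperatures must be strictly decreasing")
  if (burn_in < 0 || n_steps < 1) abort("invalid step counts")
  structure(list(burn_in = burn_in, n_steps = n_steps, n_chains = n_chains,
                 inverse_temperatures = inverse_temperatures,
                 swap_interval = swap_interval,
                 feature_eval_interval = feature_eval_interval,
                 max_parents = as.integer(max_parents),
                 seed = as.numeric(seed)),
            class = "mcmc_config")
}

#' Neighborhood of a structure under the three operators
#'
#' Enumerates every valid instantiation of the three local operators on a
#' DAG — edge addition, edge reversal, edge deletion — respecting
#' acyclicity and the parent limit.  Used by [propose_move()] and by tests
#' that verify the Hastings correction against brute-force counts.
#'
#' @param g A [bn_dag()].
#' @param max_parents Parent limit.
#' @return Tibble with columns `op`, `from`, `to`.
#' @export
dag_neighborhood <- function(g, max_parents = 8) {
  a <- adjacency(g)
  cl <- dag_closure(g)
  n <- nrow(a)
  npar <- lengths(g$parents)
  rows <- list()
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    if (a[u, v]) {
      rows[[length(rows) + 1]] <- c("delete", u, v)
      # reversal: u gains parent v; invalid if an alternative u ~> v path survives
      g2 <- g; g2$parents[[v]] <- setdiff(g2$parents[[v]], u)
      if (npar[u] < max_parents && !dag_closure(g2)[u, v])
        rows[[length(rows) + 1]] <- c("reverse", u, v)
    } else if (!a[v, u]) {
      if (npar[v] < max_parents && !cl[v, u])
        rows[[length(rows) + 1]] <- c("add", u, v)
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(op = character(0), from = character(0),
                          to = character(0)))
  m <- do.call(rbind, rows)
  tibble::tibble(op = m[, 1], from = g$names[as.integer(m[, 2])],
                 to = g$names[as.integer(m[, 3])])
}

#' Propose a structure move
#'
#' Draws an operator uniformly among addition, reversal and deletion
#' (resampling, with a count, when the chosen operator has no valid
#' instantiation), then an instantiation uniformly among that operator's
#' valid moves.  The log Hastings correction is the log ratio of reverse to
#' forward proposal probabilities, computed from exact neighborhood sizes
#' on the current and proposed structures.
#'
#' @param g A [bn_dag()].
#' @param max_parents Parent limit.
#' @return List with `move` (`op`, `from`, `to`), `log_hastings`, and
#'   `n_resampled`.  Uses R's RNG stream.
#' @export
propose_move <- function(g, max_parents = 8) {
  nb <- dag_neighborhood(g, max_parents)
  if (nrow(nb) == 0) abort("no valid move exists (single-node domain)")
  ops <- c("add", "delete", "reverse")
  counts <- vapply(ops, function(o) sum(nb$op == o), integer(1))
  avail <- sum(counts > 0)
  n_res <- 0L
  repeat {
    op <- ops[sample.int(3, 1)]
    if (counts[[op]] > 0) break
    n_res <- n_res + 1L
  }
  pool <- nb[nb$op == op, ]
  pick <- pool[sample.int(nrow(pool), 1), ]
  g2 <- switch(op,
    add = dag_add_edge(g, pick$from, pick$to),
    delete = dag_remove_edge(g, pick$from, pick$to),
    reverse = dag_add_edge(dag_remove_edge(g, pick$from, pick$to),
                           pick$to, pick$from))
  nb2 <- dag_neighborhood(g2, max_parents)
  counts2 <- vapply(ops, function(o) sum(nb2$op == o), integer(1))
  avail2 <- sum(counts2 > 0)
  rev_op <- switch(op, add = "delete", delete = "add", reverse = "reverse")
  log_fwd <- -log(avail) - log(counts[[op]])
  log_rev <- -log(avail2) - log(counts2[[rev_op]])
  list(move = list(op = op, from = pick$from, to = pick$to),
       log_hastings = log_rev - log_fwd, n_resampled = n_res,
       dag = g2)
}

#' One Metropolis-Hastings step over structures
#'
#' Reference R implementation of a single tempered MH step: propose via
#' [propose_move()], accept with probability
#' `min(1, exp(beta * delta_score + log_hastings))`.  The compiled sampler
#' in [mc3_run()] performs the same computation; this function exists for
#' inspection and testing on small problems.
#'
#' @param ds A complete [bn_dataset()].
#' @param g Current [bn_dag()].
#' @param config A [score_config()].
#' @param beta Inverse temperature (1 = target posterior).
#' @return List with `dag` (new state) and `accepted`.
#' @export
mh_step <- function(ds, g, config = score_config(), beta = 1) {
  prop <- propose_move(g, config$max_parents)
  delta <- score_delta(ds, g, prop$move, config)$delta
  log_alpha <- beta * delta + prop$log_hastings
  if (log_alpha >= 0 || log(runif(1)) < log_alpha)
    list(dag = prop$dag, accepted = TRUE)
  else list(dag = g, accepted = FALSE)
}

#' Metropolis-coupled MCMC over DAG structures
#'
#' Runs `n_chains` tempered chains whose stationary distributions are
#' powered versions of the structure posterior `P(G | D)`; adjacent chains
#' periodically propose state swaps, and the cold chain's states are
#' recorded after burn-in.  Structural feature indicators (direct,
#' transitive, confounded, pure-interaction, strong relevance; Markov
#' blanket sets; multi-target relevance) are accumulated over the recorded
#' samples, so their means estimate the corresponding posteriors.
#'
#' @param ds A complete [bn_dataset()] with at least one target.
#' @param targets Target variable names; defaults to the dataset's
#'   target-role columns.
#' @param score A [score_config()].
#' @param mcmc An [mcmc_config()].
#' @param store_series Keep per-sample strong-relevance indicator series
#'   (needed for [rhat_diagnostic()]).
#' @param store_dags Keep every recorded structure (memory-heavy; for
#'   diagnostics and tests on small runs only).
#' @return An object of class `bnbmla_run`; see [tidy.bnbmla_run()],
#'   [mbs_posterior_table()], [relevance_report()].
#' @export
mc3_run <- function(ds, targets = NULL, score = score_config(),
                    mcmc = mcmc_config(), store_series = FALSE,
                    store_dags = FALSE) {
  if (is.null(targets)) targets <- target_names(ds)
  if (length(targets) == 0) abort("no target variables specified")
  ti <- match(targets, ds$meta$name)
  if (anyNA(ti)) abort("unknown target variable(s)")
  preds <- setdiff(ds$meta$name, targets)
  pi <- match(preds, ds$meta$name)
  cfg <- list(burn_in = mcmc$burn_in, n_steps = mcmc$n_steps,
              n_chains = mcmc$n_chains,
              inverse_temperatures = mcmc$inverse_temperatures,
              swap_interval = mcmc$swap_interval,
              feature_eval_interval = mcmc$feature_eval_interval,
              max_parents = mcmc$max_parents, seed = mcmc$seed,
              prior = prior_code(score), ess = score$ess,
              store_series = store_series, store_dags = store_dags)
  raw <- cpp_mc3_run(dataset_matrix(ds), ds$meta$arity, cfg,
                     as.integer(ti), as.integer(pi))
  build_result(raw, ds, targets, preds, score, mcmc, kind = "mcmc")
}

# Shape the C++ accumulator output (sampler or exact oracle) into tibbles.
build_result <- function(raw, ds, targets, preds, score, mcmc, kind) {
  nm <- ds$meta$name
  n_rec <- raw$total
  pair_mat <- function(f) as.vector(t(raw[[f]]))  # pred-major -> long
  grid <- tidyr::expand_grid(predictor = preds, target = targets)
  pairwise <- dplyr::bind_cols(grid, tibble::tibble(
    dcr = pair_mat("dcr"), tcr = pair_mat("tcr"), confr = pair_mat("confr"),
    assoc = pair_mat("assoc"), pir = pair_mat("pir"), sr = pair_mat("sr"),
    mediated_only = pair_mat("mediated_only")))
  multitarget <- dplyr::bind_cols(grid, tibble::tibble(
    exist = pair_mat("mt_exist"), only = pair_mat("mt_only"),
    other_than = pair_mat("mt_other")))
  predictor_summary <- tibble::tibble(
    predictor = preds, mt = as.numeric(raw$mt_any),
    edge_to_any = as.numeric(raw$edge_to_any))
  predictor_summary$ap <- unname(vapply(preds, function(p) {
    ap_approximation(multitarget$exist[multitarget$predictor == p])
  }, numeric(1)))
  shape_mbs <- function(tbl, target_label) {
    sets <- lapply(tbl$sets, function(ix) sort(nm[ix]))
    out <- tibble::tibble(set = sets, prob = tbl$prob)
    out <- out[order(-out$prob), ]
    out$rank <- seq_len(nrow(out))
    attr(out, "target") <- target_label
    class(out) <- c("mbs_table", class(out))
    out
  }
  mbs <- lapply(seq_along(targets),
                function(i) shape_mbs(raw$mbs_tables[[i]], targets[i]))
  names(mbs) <- targets
  mbs_joint <- if (length(raw$mbs_joint) == 2)
    shape_mbs(raw$mbs_joint, paste(targets, collapse = "+")) else NULL
  out <- list(pairwise = pairwise, multitarget = multitarget,
              predictor_summary = predictor_summary,
              mbs = mbs, mbs_joint = mbs_joint,
              targets = targets, predictors = preds,
              n_samples = n_rec, score = score, mcmc = mcmc,
              kind = kind)
  if (kind == "mcmc") {
    out$stats <- list(acceptance_rate = raw$acceptance_rate,
                      swap_attempts = raw$swap_attempts,
                      swap_accepts = raw$swap_accepts,
                      operator_resamples = raw$operator_resamples,
                      cache_size = raw$cache_size)
    out$score_trace <- raw$score_trace
    if (!is.null(raw$sr_series)) {
      s <- matrix(as.integer(raw$sr_series), nrow = nrow(raw$sr_series))
      rownames(s) <- paste0(grid$predictor, "~", grid$target)
      out$sr_series <- s
    }
    if (!is.null(raw$dags)) {
      out$dags <- lapply(raw$dags, function(ps) {
        g <- bn_dag(nm)
        g$parents <- lapply(ps, as.integer)
        g
      })
    }
    class(out) <- "bnbmla_run"
  } else {
    out$n_dags <- raw$n_dags
    out$log_z <- raw$log_z
    class(out) <- c("bnbmla_exact", "bnbmla_run")
  }
  out
}

#' @export
print.bnbmla_run <- function(x, ...) {
  cat("<", if (inherits(x, "bnbmla_exact")) "bnbmla_exact" else "bnbmla_run",
      "> ", length(x$predictors), " predictors, ",
      length(x$targets), " target(s): ",
      paste(x$targets, collapse = ", "), "\n", sep = "")
  if (inherits(x, "bnbmla_exact"))
    cat("  exact enumeration over ", format(x$n_dags, big.mark = ","),
        " DAGs\n", sep = "")
  else
    cat("  ", format(x$n_samples, big.mark = ","),
        " recorded cold-chain samples\n", sep = "")
  top <- dplyr::arrange(x$pairwise, dplyr::desc(.data$sr))
  print(head(top, 8))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic for feature indicators
#'
#' Potential scale reduction factor computed from two or more independent
#' runs' strong-relevance indicator series (run [mc3_run()] with
#' `store_series = TRUE` and different seeds).  Values near 1 indicate the
#' runs agree; values well above 1.1 indicate non-convergence.
#'
#' @param runs List of at least two `bnbmla_run` objects with stored
#'   series, or a list of equal-length numeric vectors/matrices.
#' @return Tibble with columns `feature` and `rhat`, plus the maximum as
#'   attribute `max_rhat`.
#' @export
rhat_diagnostic <- function(runs) {
  if (length(runs) < 2) abort("at least two independent runs are required")
  mats <- lapply(runs, function(r) {
    if (inherits(r, "bnbmla_run")) {
      if (is.null(r$sr_series))
        abort("run has no stored series; use store_series = TRUE")
      r$sr_series
    } else if (is.matrix(r)) r else matrix(r, nrow = 1)
  })
  len <- vapply(mats, ncol, integer(1))
  if (length(unique(len)) != 1) abort("runs must have equal length")
  feats <- rownames(mats[[1]]) %||% paste0("f", seq_len(nrow(mats[[1]])))
  rhat1 <- function(chains) {     # list of numeric vectors
    m <- length(chains); n <- length(chains[[1]])
    means <- vapply(chains, mean, numeric(1))
    w <- mean(vapply(chains, var, numeric(1)))
    b_over_n <- var(means)
    if (w == 0 && b_over_n == 0) return(1)
    if (w == 0) return(Inf)
    sqrt(((n - 1) / n * w + b_over_n) / w)
  }
  rh <- vapply(seq_along(feats), function(i) {
    rhat1(lapply(mats, function(m) as.numeric(m[i, ])))
  }, numeric(1))
  out <- tibble::tibble(feature = feats, rhat = rh)
  attr(out, "max_rhat") <- max(rh)
  out
}
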