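#' Posterior of a single structural feature
#'
#' The posterior probability of a structural feature is the model-averaged
#' indicator: the fraction of recorded cold-chain structures (or exact
#' posterior mass) in which the feature holds.  A binomial Monte Carlo
#' standard error accompanies sampled estimates.
#'
#' @param run A `bnbmla_run` or `bnbmla_exact` object.
#' @param feature One of `"dcr"`, `"tcr"`, `"confr"`, `"assoc"`, `"pir"`,
#'   `"sr"`, `"mediated_only"`.
#' @param predictor,target Variable names selecting the pair.
#' @return One-row tibble: `feature`, `predictor`, `target`, `estimate`,
#'   `n_samples`, `mc_se`.
#' @export
estimate_feature_posterior <- function(run, feature, predictor, target) {
  feature <- match.arg(feature, c("dcr", "tcr", "confr", "assoc", "pir",
                                  "sr", "mediated_only"))
  row <- run$pairwise[run$pairwise$predictor == predictor &
                      run$pairwise$target == target, ]
  if (nrow(row) == 0) abort("no such predictor/target pair in the run")
  p <- row[[feature]]
  n <- run$n_samples
  se <- if (inherits(run, "bnbmla_exact")) 0 else sqrt(p * (1 - p) / n)
  tibble::tibble(feature = feature, predictor = predictor, target = target,
                 estimate = p, n_samples = n, mc_se = se)
}

#' Markov blanket set posterior table
#'
#' The distribution over Markov blanket sets of a target observed in the
#' run: each visited set with its estimated posterior mass, ranked by
#' probability.  Probabilities sum to 1 over the observed sets by
#' construction.
#'
#' @param run A `bnbmla_run`.
#' @param target A single target name, or `NULL` for the joint blanket of
#'   all targets (multi-target runs).
#' @return A tibble of class `mbs_table` with list-column `set`, `prob` and
#'   `rank`.
#' @export
mbs_posterior_table <- function(run, target = NULL) {
  if (is.null(target)) {
    if (length(run$targets) == 1) return(run$mbs[[1]])
    if (is.null(run$mbs_joint)) abort("run has no joint blanket table")
    return(run$mbs_joint)
  }
  if (!target %in% names(run$mbs)) abort(paste0("unknown target: ", target))
  run$mbs[[target]]
}

#' k-subset partial relevance aggregation
#'
#' The posterior that a k-sized set `s` is jointly strongly relevant is the
#' total Markov-blanket-set mass over supersets of `s`:
#' `P(k-MBS = s) = sum over observed m >= s of P(MBS = m)`.  Aggregation is
#' over the observed (visited) sets, so the result is a lower bound whose
#' truncation error is bounded by the unobserved mass.
#'
#' @param table An `mbs_table` from [mbs_posterior_table()].
#' @param k Subset size (>= 1).
#' @return Tibble with list-column `set` (size-k subsets), `prob`, `rank`.
#'   Empty when no observed blanket reaches size `k`.
#' @export
#' @examples
#' tbl <- tibble::tibble(set = list(c("A","B"), "A", c("B","C")),
#'                       prob = c(0.6, 0.3, 0.1))
#' k_mbs_aggregate(tbl, 1)   # A 0.9, B 0.7, C 0.1
k_mbs_aggregate <- function(table, k) {
  if (k < 1) abort("k must be >= 1")
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(table))) {
    members <- table$set[[i]]
    if (length(members) < k) next
    subs <- combn(sort(members), k, simplify = FALSE)
    for (s in subs) {
      key <- paste(s, collapse = "\r")
      acc[[key]] <- (acc[[key]] %||% 0) + table$prob[i]
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0)
    return(tibble::tibble(set = list(), prob = numeric(0),
                          rank = integer(0)))
  out <- tibble::tibble(
    set = unname(lapply(keys, function(k2) strsplit(k2, "\r")[[1]])),
    prob = unname(vapply(keys, function(k2) acc[[k2]], numeric(1))))
  out <- out[order(-out$prob), ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("mbs_table", class(out))
  out
}

#' Independence approximation of multi-target strong relevance
#'
#' Approximates the probability of strong relevance to at least one of
#' several targets from the individual per-target posteriors, assuming the
#' targets independent: `1 - prod(1 - p)`.  The exact multi-target
#' posterior accounts for dependencies between targets; comparing the two
#' reveals how strongly the targets interact.
#'
#' @param p Vector of per-target strong-relevance posteriors in `[0, 1]`.
#' @return A probability.
#' @export
#' @examples
#' ap_approximation(c(0.09, 0.04, 0.05, 0.61))  # ~0.68
ap_approximation <- function(p) {
  if (any(p < 0 | p > 1)) abort("posteriors must lie in [0, 1]")
  1 - prod(1 - p)
}

#' Relevance decision at a posterior threshold
#'
#' A variable is called relevant when its posterior is greater than or
#' equal to the threshold (0.5 by default, i.e. "more probable than not").
#'
#' @param p Posterior probability (vectorized).
#' @param threshold Decision threshold, inclusive.
#' @return Logical vector.
#' @export
relevance_call <- function(p, threshold = 0.5) {
  if (any(p < 0 | p > 1)) abort("posteriors must lie in [0, 1]")
  p >= threshold
}

#' Peakness of a posterior over sets
#'
#' Ranked posterior mass of the most probable sets.  A peaked curve (mass
#' concentrated at low ranks) indicates the data suffice to identify the
#' relevant set; a flat curve indicates many weakly supported alternatives.
#'
#' @param table An `mbs_table` (full or k-aggregated).
#' @param top_n Number of ranks to keep (default 100).
#' @return Tibble `(rank, prob)` with non-increasing `prob`, of class
#'   `peakness_curve`.
#' @export
peakness_curve <- function(table, top_n = 100) {
  if (nrow(table) == 0) abort("empty posterior table")
  out <- tibble::tibble(rank = table$rank, prob = table$prob)
  out <- out[order(out$rank), ]
  out <- head(out, top_n)
  class(out) <- c("peakness_curve", class(out))
  out
}

#' @method autoplot peakness_curve
#' @export
autoplot.peakness_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$prob)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank of set", y = "posterior probability",
                  title = "Peakness of the set posterior") +
    ggplot2::theme_minimal()
}

#' Posterior relevance report
#'
#' Collects the run's posteriors into the two standard report layouts: a
#' pairwise table per predictor and target (Associated, D-Relevant,
#' S-Relevant, Interaction, Transitive) and, for multi-target runs, a
#' decomposition per predictor (Exist / Only / OtherThan per target, the
#' independence approximation AP, and the multi-target posterior MT).
#'
#' @param run A `bnbmla_run` or `bnbmla_exact`.
#' @return List with `pairwise` and (when more than one target) `multitarget`
#'   tibbles.
#' @export
relevance_report <- function(run) {
  pw <- dplyr::transmute(run$pairwise,
    predictor = .data$predictor, target = .data$target,
    associated = .data$assoc, d_relevant = .data$dcr,
    s_relevant = .data$sr, interaction = .data$pir,
    transitive = .data$tcr)
  out <- list(pairwise = pw)
  if (length(run$targets) > 1) {
    wide <- tidyr::pivot_wider(run$multitarget,
      names_from = "target",
      values_from = c("exist", "only", "other_than"))
    out$multitarget <- dplyr::left_join(wide, run$predictor_summary,
                                        by = "predictor")
  }
  out
}

#' Write relevance reports as TSV
#'
#' @param run A `bnbmla_run`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- relevance_report(run)
  paths <- character(0)
  p1 <- file.path(dir, "pairwise_posteriors.tsv")
  readr::write_tsv(rep$pairwise, p1); paths <- p1
  if (!is.null(rep$multitarget)) {
    p2 <- file.path(dir, "multitarget_posteriors.tsv")
    readr::write_tsv(rep$multitarget, p2); paths <- c(paths, p2)
  }
  for (t in names(run$mbs)) {
    pt <- file.path(dir, paste0("mbs_", t, ".tsv"))
    tbl <- run$mbs[[t]]
    flat <- tibble::tibble(rank = tbl$rank,
                           set = vapply(tbl$set, paste, "", collapse = ","),
                           prob = tbl$prob)
    readr::write_tsv(flat, pt); paths <- c(paths, pt)
  }
  invisible(paths)
}
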