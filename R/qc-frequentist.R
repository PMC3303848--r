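#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed
#' genotype counts against the p^2 / 2pq / q^2 expectation at the estimated
#' allele frequency.  Deviation in controls flags likely genotyping error.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return One-row tibble with `chi2`, `df` and `p`.
#' @export
#' @examples
#' hwe_test(49, 42, 9)   # exact HWE proportions: chi2 = 0
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) abort("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1)
    abort("monomorphic input: Hardy-Weinberg test undefined (no expected heterozygotes)")
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_AA, n_Aa, n_aa)
  chi2 <- sum((o - e)^2 / e)
  tibble::tibble(chi2 = chi2, df = 1, p = pchisq(chi2, df = 1,
                                                 lower.tail = FALSE))
}

woolf_ci <- function(a, b, c, d, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  lo <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  exp(c(lo - z * se, lo + z * se))
}

#' Allele-level case-control association test
#'
#' Pearson chi-square (no continuity correction) on the 2x2 allele count
#' table with cross-product odds ratio and Woolf (log-OR) 95% confidence
#' interval.  A zero cell triggers the Haldane correction: 0.5 is added to
#' every cell for the OR/CI and the result is flagged.
#'
#' @param a,b,c,d Counts: case-exposed, case-unexposed, control-exposed,
#'   control-unexposed.
#' @return One-row tibble: `chi2`, `p`, `or`, `ci_low`, `ci_high`,
#'   `haldane_corrected`.
#' @export
allele_association_test <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("counts must be non-negative")
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("a margin of the 2x2 table is zero")
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  corrected <- any(tab == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  ci <- woolf_ci(a, b, c, d)
  tibble::tibble(chi2 = chi2,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 or = a * d / (b * c),
                 ci_low = ci[1], ci_high = ci[2],
                 haldane_corrected = corrected)
}

#' Genotype-level case-control association tests
#'
#' Overall 2-df chi-square on the 2x3 genotype table plus the collapsed
#' 1-df recessive (minor homozygote vs rest) and dominant (carrier vs
#' non-carrier) tests, which identify the genetic model: a recessive effect
#' gives a smaller recessive p than overall p.  An empty genotype column is
#' collapsed with a warning and only the defined 1-df test is returned.
#'
#' @param counts 2x3 matrix of genotype counts, rows = (case, control),
#'   columns = (AA, Aa, aa) with `aa` the minor homozygote.
#' @return Tibble with one row per model (`overall`, `recessive`,
#'   `dominant`): `chi2`, `df`, `p`, and OR/CI for the collapsed models.
#' @export
genotype_association_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 3))) abort("counts must be a 2x3 matrix")
  if (any(rowSums(counts) == 0)) abort("each row must have positive total")
  chi2_of <- function(tab) {
    keep <- colSums(tab) > 0
    tab <- tab[, keep, drop = FALSE]
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    list(chi2 = sum((tab - e)^2 / e), df = ncol(tab) - 1L)
  }
  empty_col <- any(colSums(counts) == 0)
  if (empty_col)
    warn("empty genotype class: overall test collapsed to 1 df")
  rows <- list()
  ov <- chi2_of(counts)
  rows$overall <- tibble::tibble(model = "overall", chi2 = ov$chi2,
                                 df = ov$df,
                                 p = pchisq(ov$chi2, ov$df, lower.tail = FALSE),
                                 or = NA_real_, ci_low = NA_real_,
                                 ci_high = NA_real_)
  collapse <- function(model, exposed_cols) {
    tab <- cbind(rowSums(counts[, exposed_cols, drop = FALSE]),
                 rowSums(counts[, -exposed_cols, drop = FALSE]))
    if (any(colSums(tab) == 0))
      return(tibble::tibble(model = model, chi2 = NA_real_, df = NA_integer_,
                            p = NA_real_, or = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_))
    res <- chi2_of(tab)
    haldane <- any(tab == 0)
    t2 <- if (haldane) tab + 0.5 else tab
    ci <- woolf_ci(t2[1, 1], t2[1, 2], t2[2, 1], t2[2, 2])
    tibble::tibble(model = model, chi2 = res$chi2, df = res$df,
                   p = pchisq(res$chi2, res$df, lower.tail = FALSE),
                   or = t2[1, 1] * t2[2, 2] / (t2[1, 2] * t2[2, 1]),
                   ci_low = ci[1], ci_high = ci[2])
  }
  dplyr::bind_rows(rows$overall,
                   collapse("recessive", 3L),
                   collapse("dominant", 2:3))
}

genotype_counts <- function(ds, snp, rows = NULL) {
  v <- ds$data[[snp]]
  if (!is.null(rows)) v <- v[rows]
  lev <- ds$levels[[snp]]
  orig <- lev[v + 1L]
  c(n_AA = sum(orig == 0, na.rm = TRUE),
    n_Aa = sum(orig == 1, na.rm = TRUE),
    n_aa = sum(orig == 2, na.rm = TRUE))
}

#' Quality-control filter for SNP columns
#'
#' Removes, in order: monomorphic SNPs (a single observed genotype),
#' SNPs deviating from Hardy-Weinberg equilibrium *in controls* at
#' `p < hwe_p_max`, and SNPs with genotyping call rate at or below
#' `callrate_min` (computed before any complete-case filtering).  The three
#' removal lists plus the retained list partition the input SNPs.
#'
#' @param ds A [bn_dataset()]; genotype-kind predictor columns are filtered.
#' @param controls Logical vector (length `n_rows`) marking control
#'   individuals, used for the Hardy-Weinberg test.
#' @param hwe_p_max Hardy-Weinberg p-value threshold (default 0.005).
#' @param callrate_min Minimum call rate; SNPs at or below are removed
#'   (default 0.90).
#' @return List with `dataset` (filtered) and `report` (class `qc_report`).
#' @export
qc_filter <- function(ds, controls, hwe_p_max = 0.005, callrate_min = 0.90) {
  if (length(controls) != ds$n_rows)
    abort("controls mask length must equal the number of rows")
  if (!any(controls)) abort("controls mask selects no rows")
  snps <- ds$meta$name[ds$meta$role == "predictor" &
                       ds$meta$kind == "genotype"]
  removed_mono <- character(0)
  removed_hwe <- character(0)
  removed_call <- character(0)
  for (s in snps) {
    v <- ds$data[[s]]
    obs <- v[!is.na(v)]
    if (length(unique(obs)) <= 1) { removed_mono <- c(removed_mono, s); next }
    gc <- genotype_counts(ds, s, rows = which(controls))
    hwe_p <- tryCatch(hwe_test(gc[1], gc[2], gc[3])$p, error = function(e) NA)
    if (!is.na(hwe_p) && hwe_p < hwe_p_max) {
      removed_hwe <- c(removed_hwe, s); next
    }
    cr <- mean(!is.na(v))
    if (cr <= callrate_min) removed_call <- c(removed_call, s)
  }
  removed <- c(removed_mono, removed_hwe, removed_call)
  retained <- setdiff(snps, removed)
  keep <- setdiff(ds$meta$name, removed)
  out <- ds
  out$data <- ds$data[, keep, drop = FALSE]
  out$meta <- ds$meta[ds$meta$name %in% keep, , drop = FALSE]
  out$levels <- ds$levels[keep]
  report <- structure(list(removed_monomorphic = removed_mono,
                           removed_hwe = removed_hwe,
                           removed_callrate = removed_call,
                           retained = retained,
                           hwe_p_max = hwe_p_max,
                           callrate_min = callrate_min),
                      class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n",
      "  monomorphic removed: ", length(x$removed_monomorphic), "\n",
      "  HWE (controls, p<", x$hwe_p_max, ") removed: ",
      length(x$removed_hwe), "\n",
      "  call rate <=", x$callrate_min, " removed: ",
      length(x$removed_callrate), "\n",
      "  retained: ", length(x$retained), "\n", sep = "")
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (>= 1).
#' @return List with `threshold` (`alpha / m`) and `display` (threshold
#'   rounded to one significant figure, as conventionally reported).
#' @export
#' @examples
#' bonferroni_threshold(0.05, 102)$display  # 5e-4
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) abort("m must be >= 1")
  th <- alpha / m
  list(threshold = th, display = signif(th, 1))
}

#' Haplotype odds ratio from published frequencies
#'
#' Reconstructs the 2x2 haplotype-count table from case/control haplotype
#' frequencies and chromosome counts (2 per individual), rounding to the
#' nearest count, and reports the cross-product odds ratio with a Woolf CI.
#' This count-based OR can differ in the last digit from one estimated by
#' conditional logistic regression on haplotype probabilities.
#'
#' @param f_case,f_control Haplotype frequency in cases / controls, in (0,1).
#' @param n_case_chrom,n_control_chrom Chromosome counts (2 x individuals).
#' @return One-row tibble: `or`, `ci_low`, `ci_high` and the reconstructed
#'   counts.
#' @export
haplotype_or_from_frequencies <- function(f_case, f_control,
                                          n_case_chrom, n_control_chrom) {
  if (f_case <= 0 || f_case >= 1 || f_control <= 0 || f_control >= 1)
    abort("haplotype frequencies must lie strictly between 0 and 1")
  a <- round(f_case * n_case_chrom)
  b <- n_case_chrom - a
  c <- round(f_control * n_control_chrom)
  d <- n_control_chrom - c
  ci <- woolf_ci(a, b, c, d)
  tibble::tibble(or = a * d / (b * c), ci_low = ci[1], ci_high = ci[2],
                 case_with = a, case_without = b,
                 control_with = c, control_without = d)
}

#' Logistic regression with forced interaction terms
#'
#' Maximum-likelihood logistic fit (IRLS via [glm()]) of a binary response
#' on main-effect and product terms, with Wald confidence intervals and
#' p-values per term.  Genotype predictors enter numerically (0/1/2 allele
#' counts).  Complete separation or non-convergence raises an error naming
#' the offending term.
#'
#' @param data Data frame holding the response and predictors.
#' @param response Name of the binary (0/1) response column.
#' @param terms Character vector of model terms; products as `"a:b"`.
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `exp_estimate`, `ci_low`, `ci_high`, `p`.
#' @export
logistic_interaction_fit <- function(data, response, terms, level = 0.95) {
  if (nrow(data) <= length(terms) + 1)
    abort("more model terms than observations")
  f <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(glm(f, data = data, family = binomial()))
  sm <- summary(fit)$coefficients
  big <- abs(coef(fit)) > 15
  if (!fit$converged || any(big, na.rm = TRUE)) {
    bad <- names(coef(fit))[which(big)]
    abort(paste0("logistic fit unstable (separation or non-convergence)",
                 if (length(bad) > 0)
                   paste0(" in term(s): ", paste(bad, collapse = ", "))))
  }
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(term = rownames(sm),
                 estimate = sm[, "Estimate"],
                 exp_estimate = exp(sm[, "Estimate"]),
                 ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
                 ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
                 p = sm[, "Pr(>|z|)"])
}

#' Per-SNP allele association report
#'
#' Computes the allele-level chi-square test, odds ratio and confidence
#' interval for every genotype predictor against a binary target, with a
#' Bonferroni significance flag at `alpha` over the number of SNPs tested.
#'
#' @param ds A complete [bn_dataset()].
#' @param target Binary target column name (cases = code 1).
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return Tibble with one row per SNP.
#' @export
association_report <- function(ds, target = NULL, alpha = 0.05) {
  if (is.null(target)) target <- target_names(ds)[1]
  y <- ds$data[[target]]
  cases <- which(y == 1)
  controls <- which(y == 0)
  snps <- ds$meta$name[ds$meta$role == "predictor" &
                       ds$meta$kind == "genotype"]
  th <- bonferroni_threshold(alpha, length(snps))$threshold
  rows <- lapply(snps, function(s) {
    gc_case <- genotype_counts(ds, s, cases)
    gc_ctrl <- genotype_counts(ds, s, controls)
    # minor allele counts
    a <- 2 * gc_case[["n_aa"]] + gc_case[["n_Aa"]]
    b <- 2 * gc_case[["n_AA"]] + gc_case[["n_Aa"]]
    c <- 2 * gc_ctrl[["n_aa"]] + gc_ctrl[["n_Aa"]]
    d <- 2 * gc_ctrl[["n_AA"]] + gc_ctrl[["n_Aa"]]
    res <- tryCatch(allele_association_test(a, b, c, d),
                    error = function(e) tibble::tibble(
                      chi2 = NA_real_, p = NA_real_, or = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      haldane_corrected = NA))
    dplyr::bind_cols(tibble::tibble(snp = s), res)
  })
  out <- dplyr::bind_rows(rows)
  out$bonferroni_significant <- !is.na(out$p) & out$p < th
  attr(out, "bonferroni_threshold") <- th
  out
}
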