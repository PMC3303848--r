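#' Discrete genotype/phenotype dataset
#'
#' The analysis operates on a complete-case table of categorical variables:
#' rows are individuals, columns are SNP genotypes (coded 0/1/2 as minor
#' allele counts), discretized clinical measurements, and one or more target
#' phenotypes.  Each column carries an arity (number of observed category
#' codes), a role (`predictor` or `target`) and a kind (`genotype`,
#' `phenotype` or `covariate`).
#'
#' Observed values of every column are recoded to dense integer codes
#' `0 .. arity-1`; the original values are retained in the `levels` attribute
#' so that genotype-level statistics (Hardy-Weinberg tests, allele counts)
#' can be computed on the original coding.  Missing values are permitted at
#' construction and must be resolved by [complete_case_filter()] before
#' scoring or sampling.
#'
#' @param data A data frame of categorical columns (integer, factor or
#'   character).  `NA` marks a missing observation.
#' @param targets Character vector of target column names.
#' @param kinds Optional named character vector giving the kind of each
#'   column; unnamed columns default to `"genotype"` for predictors and
#'   `"phenotype"` for targets.
#'
#' @return An object of class `bn_dataset`: a list with elements `data`
#'   (tibble of dense integer codes), `meta` (tibble with columns `name`,
#'   `arity`, `role`, `kind`, `call_rate`), `levels` (named list of original
#'   values per column) and `n_rows`.
#' @export
#' @examples
#' d <- data.frame(snp1 = c(0, 1, 2, 1), snp2 = c(0, 0, 1, 1),
#'                 asthma = c(0, 1, 1, 0))
#' ds <- bn_dataset(d, targets = "asthma")
#' ds$meta
bn_dataset <- function(data, targets = character(), kinds = NULL) {
  data <- tibble::as_tibble(data)
  nm <- names(data)
  if (anyDuplicated(nm)) abort("duplicate column names in dataset")
  missing_targets <- setdiff(targets, nm)
  if (length(missing_targets) > 0)
    abort(paste0("unknown target column(s): ",
                 paste(missing_targets, collapse = ", ")))
  levels_list <- list()
  coded <- data
  for (j in nm) {
    v <- data[[j]]
    if (is.factor(v)) v <- as.character(v)
    if (is.double(v)) {
      if (any(is.finite(v) & v != round(v)))
        abort(paste0("column '", j, "' has non-categorical (non-integer) values; ",
                     "discretize it first (see discretize_continuous())"))
      v <- as.integer(v)
    }
    lev <- sort(unique(v[!is.na(v)]))
    levels_list[[j]] <- lev
    coded[[j]] <- match(v, lev) - 1L
  }
  arity <- vapply(levels_list, length, integer(1))
  role <- ifelse(nm %in% targets, "target", "predictor")
  kind <- ifelse(role == "target", "phenotype", "genotype")
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), nm)
    if (length(bad) > 0) abort(paste0("kinds refer to unknown columns: ",
                                      paste(bad, collapse = ", ")))
    kind[match(names(kinds), nm)] <- unname(kinds)
  }
  call_rate <- vapply(coded, function(v) mean(!is.na(v)), numeric(1))
  mono <- nm[arity <= 1]
  if (length(mono) > 0)
    inform(paste0("monomorphic column(s) (single observed code): ",
                  paste(mono, collapse = ", ")))
  structure(
    list(data = coded,
         meta = tibble::tibble(name = nm, arity = unname(arity),
                               role = role, kind = kind,
                               call_rate = unname(call_rate)),
         levels = levels_list,
         n_rows = nrow(coded)),
    class = "bn_dataset")
}

#' @export
print.bn_dataset <- function(x, ...) {
  n_tar <- sum(x$meta$role == "target")
  cat("<bn_dataset> ", x$n_rows, " individuals x ", nrow(x$meta),
      " variables (", n_tar, " target", if (n_tar != 1) "s", ")\n", sep = "")
  n_miss <- sum(is.na(as.matrix(x$data)))
  if (n_miss > 0) cat("  ", n_miss, " missing cells (complete_case_filter() required before analysis)\n", sep = "")
  print(x$meta, n = 10)
  invisible(x)
}

variable_names <- function(ds) ds$meta$name
target_names <- function(ds) ds$meta$name[ds$meta$role == "target"]
predictor_names <- function(ds) ds$meta$name[ds$meta$role == "predictor"]

# dense integer matrix for the compiled core; refuses missing codes
dataset_matrix <- function(ds) {
  m <- as.matrix(ds$data)
  if (anyNA(m))
    abort("dataset contains missing codes; apply complete_case_filter() first")
  storage.mode(m) <- "integer"
  m
}

#' Read a delimited genotype/phenotype table
#'
#' Reads a header-rowed CSV/TSV file of genotype codes (0/1/2 minor-allele
#' counts) and phenotype columns into a [bn_dataset()].  Missing cells
#' (empty, `NA`, `?`, `-9`) are kept as `NA` and reported; resolve them with
#' [complete_case_filter()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param target_names Character vector naming the target column(s).
#' @param delim Field delimiter; guessed from the file when `NULL`.
#' @param meta_path Optional JSON sidecar with per-column `role`/`kind`
#'   written by [write_genotype_table()].
#' @return A [bn_dataset()].
#' @export
load_genotype_table <- function(path, target_names = character(),
                                delim = NULL, meta_path = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA", "?", "-9"),
                           show_col_types = FALSE, name_repair = "minimal")
  if (anyDuplicated(names(raw))) abort("duplicate column names in input file")
  kinds <- NULL
  if (!is.null(meta_path)) {
    side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (length(target_names) == 0 && !is.null(side$role))
      target_names <- side$name[side$role == "target"]
    if (!is.null(side$kind)) kinds <- setNames(side$kind, side$name)
  }
  ds <- bn_dataset(raw, targets = target_names, kinds = kinds)
  n_miss <- sum(is.na(as.matrix(ds$data)))
  inform(sprintf("read %d rows x %d columns from %s (%d missing cells)",
                 ds$n_rows, ncol(ds$data), path, n_miss))
  ds
}

#' Write a dataset back to delimited text
#'
#' Writes original (pre-recoding) category values; a write/read round trip
#' reproduces the codes exactly.  Roles and kinds can be stored in a JSON
#' sidecar so the file is self-describing.
#'
#' @param ds A [bn_dataset()].
#' @param path Output file path (comma-delimited).
#' @param meta_path Optional path for the JSON role/kind sidecar.
#' @export
write_genotype_table <- function(ds, path, meta_path = NULL) {
  orig <- ds$data
  for (j in names(orig)) {
    lev <- ds$levels[[j]]
    orig[[j]] <- lev[orig[[j]] + 1L]
  }
  readr::write_csv(orig, path, na = "NA")
  if (!is.null(meta_path))
    jsonlite::write_json(ds$meta[, c("name", "role", "kind")], meta_path,
                         auto_unbox = FALSE)
  invisible(path)
}

#' Import genotypes from a VCF file
#'
#' Biallelic records are coded as alt-allele counts 0/1/2 (phase is
#' ignored); multi-allelic records are skipped with a warning.  Sample order
#' is preserved.  The returned dataset has no target column; join phenotype
#' columns and rebuild with [bn_dataset()].
#'
#' @param path Path to a VCF 4.x file.
#' @return A [bn_dataset()] of genotype predictors.
#' @export
load_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("load_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) abort("VCF contains no sample columns")
  alt <- vcfR::getALT(v)
  biallelic <- !is.na(alt) & !grepl(",", alt)
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    warn(sprintf("skipped %d multi-allelic record(s)", n_skip))
  if (!any(biallelic)) abort("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  ids <- vcfR::getID(v)[biallelic]
  ids[is.na(ids)] <- paste0("site", which(is.na(ids)))
  code_gt <- function(g) {
    alleles <- strsplit(g, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) == 0 || any(a == ".") || any(is.na(a))) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  mat <- apply(gt, 1, code_gt)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  df <- tibble::as_tibble(mat, .name_repair = "minimal")
  names(df) <- ids
  bn_dataset(df)
}

#' Discretize a continuous measurement
#'
#' The multinomial model requires categorical variables, so continuous
#' clinical measurements (serum IgE, eosinophil counts, ...) must be binned.
#' Ties on a cutpoint are assigned to the lower bin; cutpoints are returned
#' for reproducibility.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @param scheme `"median"` (2 bins), `"tertile"` (3 rank-based bins) or
#'   `"fixed_cutpoints"`.
#' @param cutpoints Numeric cutpoints, required for `"fixed_cutpoints"`.
#' @return A list with `code` (integer codes `0..k-1`) and `cutpoints`.
#' @export
#' @examples
#' discretize_continuous(c(1, 2, 3, 4), "median")$code  # 0 0 1 1
discretize_continuous <- function(values,
                                  scheme = c("median", "tertile",
                                             "fixed_cutpoints"),
                                  cutpoints = NULL) {
  scheme <- match.arg(scheme)
  finite <- values[is.finite(values)]
  if (length(unique(finite)) < 2)
    abort("cannot discretize: fewer than 2 distinct finite values")
  cp <- switch(scheme,
    median = median(finite),
    # type-1 quantiles sit on order statistics, giving exact n/3 splits
    # for distinct values
    tertile = unname(quantile(finite, c(1 / 3, 2 / 3), type = 1)),
    fixed_cutpoints = {
      if (is.null(cutpoints)) abort("fixed_cutpoints scheme requires cutpoints")
      sort(cutpoints)
    })
  code <- rowSums(outer(values, cp, ">"))
  code[is.na(values)] <- NA
  list(code = as.integer(code), cutpoints = cp)
}

#' Resolve missing codes
#'
#' The closed-form marginal likelihood assumes a complete dataset, yet
#' genotyping call rates below 100% leave missing cells.  Two policies are
#' offered: `drop_rows` removes every row with at least one missing analysis
#' variable (the default: it preserves the completeness assumption exactly),
#' `mode_impute` fills each missing cell with the column's most frequent
#' code.
#'
#' @param ds A [bn_dataset()], possibly with missing codes.
#' @param policy `"drop_rows"` or `"mode_impute"`.
#' @return A list with `dataset` (complete [bn_dataset()]) and `report`
#'   (tibble with `rows_removed` and `cells_imputed`).
#' @export
complete_case_filter <- function(ds, policy = c("drop_rows", "mode_impute")) {
  policy <- match.arg(policy)
  m <- as.matrix(ds$data)
  any_missing <- anyNA(m)
  if (!any_missing) {
    return(list(dataset = ds,
                report = tibble::tibble(policy = policy, rows_removed = 0L,
                                        cells_imputed = 0L)))
  }
  if (policy == "drop_rows") {
    keep <- complete.cases(m)
    if (!any(keep)) abort("drop_rows policy removed every row")
    out <- ds
    out$data <- ds$data[keep, , drop = FALSE]
    out$n_rows <- sum(keep)
    report <- tibble::tibble(policy = policy,
                             rows_removed = sum(!keep), cells_imputed = 0L)
  } else {
    out <- ds
    imputed <- 0L
    for (j in names(out$data)) {
      v <- out$data[[j]]
      if (anyNA(v)) {
        tab <- tabulate(v + 1L, nbins = max(v, na.rm = TRUE) + 1L)
        mode_code <- which.max(tab) - 1L
        imputed <- imputed + sum(is.na(v))
        v[is.na(v)] <- mode_code
        out$data[[j]] <- v
      }
    }
    report <- tibble::tibble(policy = policy, rows_removed = 0L,
                             cells_imputed = imputed)
  }
  list(dataset = out, report = report)
}
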