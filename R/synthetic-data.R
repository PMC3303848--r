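#' Simulation configuration for genotype-phenotype data
#'
#' Describes a generating model with known ground-truth relevance
#' structure: founder SNPs in Hardy-Weinberg equilibrium, LD proxy SNPs
#' that copy a source allele with given fidelity, direct logistic genotype
#' effects on binary phenotypes, purely epistatic SNP pairs with no
#' marginal effect, continuous phenotypes driven by other variables, and a
#' directed wiring among phenotypes (so a SNP can reach a target only
#' through an intermediate phenotype).
#'
#' The epistatic interaction is the exclusive-or of the two SNPs'
#' heterozygosity indicators; at minor allele frequency 0.5 each SNP's
#' marginal effect is exactly zero while the pair is jointly predictive.
#'
#' @param n_individuals Number of individuals.
#' @param maf Named numeric vector of founder SNP minor allele frequencies
#'   in (0, 0.5].
#' @param ld Optional tibble `(proxy, source, fidelity)`: each proxy SNP
#'   copies each source allele with probability `fidelity`, else redraws
#'   from the population frequency (allelic correlation = fidelity).
#' @param effects Optional tibble `(target, snp, beta)`: per-minor-allele
#'   log-odds on a binary phenotype.
#' @param epistasis Optional tibble `(target, snp1, snp2, beta)`:
#'   heterozygosity-XOR interaction log-odds.
#' @param phenotype_edges Optional tibble `(from, to, beta)` of directed
#'   phenotype-phenotype effects (acyclic).
#' @param continuous Optional tibble `(name, driver, delta, sigma)`:
#'   standard-normal-scale continuous phenotypes
#'   `delta * driver + N(0, sigma)`.
#' @param intercepts Named numeric vector of binary phenotype intercepts.
#' @param targets Character vector of target phenotypes (defaults to every
#'   phenotype).
#' @param seed Integer seed for reproducibility.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_individuals, maf, ld = NULL, effects = NULL,
                              epistasis = NULL, phenotype_edges = NULL,
                              continuous = NULL, intercepts = NULL,
                              targets = NULL, seed = 1) {
  if (any(maf <= 0 | maf > 0.5)) abort("minor allele frequencies must lie in (0, 0.5]")
  if (is.null(names(maf))) abort("maf must be a named vector")
  phen_binary <- unique(c(effects$target, epistasis$target,
                          phenotype_edges$from, phenotype_edges$to))
  phen_binary <- setdiff(phen_binary, continuous$name)
  phen_all <- c(phen_binary, continuous$name)
  if (!is.null(phenotype_edges)) {
    g <- bn_dag(phen_all)
    for (i in seq_len(nrow(phenotype_edges)))
      g <- dag_add_edge(g, phenotype_edges$from[i], phenotype_edges$to[i])
  }
  if (is.null(targets)) targets <- phen_all
  structure(list(n_individuals = as.integer(n_individuals), maf = maf,
                 ld = ld, effects = effects, epistasis = epistasis,
                 phenotype_edges = phenotype_edges, continuous = continuous,
                 intercepts = intercepts %||%
                   setNames(numeric(length(phen_binary)), phen_binary),
                 targets = targets, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate genotypes
#'
#' Founder SNPs draw two independent Bernoulli(maf) alleles per individual
#' (genotype frequencies `(1-p)^2, 2p(1-p), p^2`); LD proxies copy each
#' source allele with the configured fidelity and redraw from the
#' population frequency otherwise.
#'
#' @param cfg A [simulation_config()].
#' @return Tibble of 0/1/2 genotype codes, one column per SNP, with the
#'   allele matrices in attribute `"alleles"` (used by proxy generation).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  alleles <- list()
  for (s in names(cfg$maf)) {
    p <- cfg$maf[[s]]
    alleles[[s]] <- matrix(rbinom(2 * n, 1, p), n, 2)
  }
  if (!is.null(cfg$ld)) {
    for (i in seq_len(nrow(cfg$ld))) {
      src <- cfg$ld$source[i]; f <- cfg$ld$fidelity[i]
      if (is.null(alleles[[src]])) abort(paste0("unknown LD source: ", src))
      p <- mean(alleles[[src]])
      copy <- matrix(rbinom(2 * n, 1, f), n, 2)
      fresh <- matrix(rbinom(2 * n, 1, p), n, 2)
      alleles[[cfg$ld$proxy[i]]] <- copy * alleles[[src]] + (1 - copy) * fresh
    }
  }
  out <- tibble::as_tibble(lapply(alleles, function(a) as.integer(rowSums(a))))
  attr(out, "alleles") <- alleles
  out
}

#' Simulate phenotypes with ground truth
#'
#' Generates phenotypes in topological order of the declared wiring:
#' binary phenotypes from a logistic model in their genotype, epistatic and
#' phenotype parents; continuous phenotypes as linear-Gaussian in their
#' driver.  Returns the answer key labeling each (SNP, target) pair as
#' `direct`, `pure_interaction`, `transitive_only` or `null`.
#'
#' @param genotypes Genotype tibble from [simulate_genotypes()].
#' @param cfg A [simulation_config()].
#' @return List with `phenotypes` (tibble) and `ground_truth` (tibble
#'   `snp`, `target`, `label`).
#' @export
simulate_phenotypes <- function(genotypes, cfg) {
  set.seed(cfg$seed + 1L)
  n <- nrow(genotypes)
  phen_names <- unique(c(names(cfg$intercepts), cfg$continuous$name))
  # dependency order over phenotypes
  dep <- bn_dag(phen_names)
  add_dep <- function(g, from, to)
    if (from %in% phen_names) dag_add_edge(g, from, to) else g
  if (!is.null(cfg$phenotype_edges))
    for (i in seq_len(nrow(cfg$phenotype_edges)))
      dep <- add_dep(dep, cfg$phenotype_edges$from[i], cfg$phenotype_edges$to[i])
  if (!is.null(cfg$continuous))
    for (i in seq_len(nrow(cfg$continuous)))
      dep <- add_dep(dep, cfg$continuous$driver[i], cfg$continuous$name[i])
  order <- topological_order(dep)
  values <- list()
  value_of <- function(x) {
    if (x %in% names(genotypes)) as.numeric(genotypes[[x]])
    else values[[x]]
  }
  for (ph in phen_names[order]) {
    if (!is.null(cfg$continuous) && ph %in% cfg$continuous$name) {
      row <- cfg$continuous[cfg$continuous$name == ph, ]
      values[[ph]] <- row$delta * value_of(row$driver) + rnorm(n, 0, row$sigma)
    } else {
      eta <- rep(cfg$intercepts[[ph]] %||% 0, n)
      if (!is.null(cfg$effects)) {
        ef <- cfg$effects[cfg$effects$target == ph, ]
        for (i in seq_len(nrow(ef)))
          eta <- eta + ef$beta[i] * value_of(ef$snp[i])
      }
      if (!is.null(cfg$epistasis)) {
        ep <- cfg$epistasis[cfg$epistasis$target == ph, ]
        for (i in seq_len(nrow(ep))) {
          h1 <- genotypes[[ep$snp1[i]]] == 1
          h2 <- genotypes[[ep$snp2[i]]] == 1
          eta <- eta + ep$beta[i] * as.numeric(xor(h1, h2))
        }
      }
      if (!is.null(cfg$phenotype_edges)) {
        pe <- cfg$phenotype_edges[cfg$phenotype_edges$to == ph, ]
        for (i in seq_len(nrow(pe)))
          eta <- eta + pe$beta[i] * value_of(pe$from[i])
      }
      values[[ph]] <- rbinom(n, 1, plogis(eta))
    }
  }
  list(phenotypes = tibble::as_tibble(values[phen_names]),
       ground_truth = ground_truth_labels(cfg, phen_names))
}

topological_order <- function(g) {
  a <- adjacency(g)
  indeg <- colSums(a)
  order <- integer(0)
  avail <- which(indeg == 0)
  while (length(avail) > 0) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    ch <- which(a[v, ])
    a[v, ch] <- FALSE
    indeg[ch] <- indeg[ch] - 1
    avail <- c(avail, ch[indeg[ch] == 0])
  }
  if (length(order) != nrow(a)) abort("phenotype wiring contains a cycle")
  order
}

# Answer key: mutually exclusive labels per (snp, target) pair.
ground_truth_labels <- function(cfg, phen_names) {
  snps <- c(names(cfg$maf), cfg$ld$proxy)
  direct_on <- function(s, t) {
    (!is.null(cfg$effects) &&
       any(cfg$effects$snp == s & cfg$effects$target == t)) ||
    (!is.null(cfg$continuous) &&
       any(cfg$continuous$driver == s & cfg$continuous$name == t))
  }
  epi_on <- function(s, t)
    !is.null(cfg$epistasis) &&
      any(cfg$epistasis$target == t &
            (cfg$epistasis$snp1 == s | cfg$epistasis$snp2 == s))
  # phenotype ancestry closure
  dep <- bn_dag(phen_names)
  safe_add <- function(g, from, to)
    if (from %in% phen_names && to %in% phen_names) dag_add_edge(g, from, to) else g
  if (!is.null(cfg$phenotype_edges))
    for (i in seq_len(nrow(cfg$phenotype_edges)))
      dep <- safe_add(dep, cfg$phenotype_edges$from[i], cfg$phenotype_edges$to[i])
  if (!is.null(cfg$continuous))
    for (i in seq_len(nrow(cfg$continuous)))
      dep <- safe_add(dep, cfg$continuous$driver[i], cfg$continuous$name[i])
  cl <- dag_closure(dep)
  reaches_target <- function(s, t) {
    # any phenotype p with a SNP effect whose descendants include t
    for (p in phen_names) {
      if (p == t) next
      if ((direct_on(s, p) || epi_on(s, p)) && cl[p, t]) return(TRUE)
    }
    FALSE
  }
  source_of <- function(s) {
    if (!is.null(cfg$ld) && s %in% cfg$ld$proxy)
      cfg$ld$source[match(s, cfg$ld$proxy)] else NA_character_
  }
  rows <- list()
  for (s in snps) for (t in cfg$targets) {
    label <- if (direct_on(s, t)) "direct"
      else if (epi_on(s, t)) "pure_interaction"
      else if (reaches_target(s, t)) "transitive_only"
      else {
        src <- source_of(s)
        if (!is.na(src) && (direct_on(src, t) || epi_on(src, t) ||
                            reaches_target(src, t)))
          "transitive_only" else "null"
      }
    rows[[length(rows) + 1]] <- tibble::tibble(snp = s, target = t,
                                               label = label)
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete analysis dataset
#'
#' Runs [simulate_genotypes()] and [simulate_phenotypes()], discretizes
#' continuous phenotypes by median split, and assembles a [bn_dataset()]
#' with the configured targets.
#'
#' @param cfg A [simulation_config()].
#' @return List with `dataset` (a complete [bn_dataset()]), `ground_truth`,
#'   `genotypes` and raw `phenotypes`.
#' @export
simulate_dataset <- function(cfg) {
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  phen <- sim$phenotypes
  kinds <- setNames(rep("genotype", ncol(geno)), names(geno))
  for (ph in names(phen)) {
    if (is.double(phen[[ph]]) && any(phen[[ph]] != round(phen[[ph]]))) {
      phen[[ph]] <- discretize_continuous(phen[[ph]], "median")$code
    }
    kinds[[ph]] <- "phenotype"
  }
  ds <- bn_dataset(dplyr::bind_cols(geno, phen), targets = cfg$targets,
                   kinds = kinds)
  list(dataset = ds, ground_truth = sim$ground_truth,
       genotypes = geno, phenotypes = sim$phenotypes)
}

default_mafs <- function(n_snps)
  setNames(rep(c(0.1, 0.2, 0.3, 0.4, 0.5), length.out = n_snps),
           sprintf("snp%02d", seq_len(n_snps)))

#' Bundled simulation scenarios
#'
#' Three ready-made generating models mirroring a staged association
#' analysis: a single binary target (`scenario_asthma`, n = 1201 by
#' default), two wired targets (`scenario_asthma_rhinitis`, n = 1100), and
#' four targets including two continuous measurements
#' (`scenario_clinical`, n = 200).  Each plants one directly relevant SNP
#' (`snp05`, minor allele frequency 0.5, per-allele log-odds 0.7), an LD
#' proxy of it (`snp06`, allele-copy fidelity 0.9 — genotype r^2 of 0.81,
#' matching the tag-SNP selection convention — with no own effect), and a
#' purely epistatic pair (`snp10`, `snp15`, both at frequency 0.5,
#' heterozygosity-XOR log-odds 1.2, zero marginal effect).
#'
#' @param n Number of individuals.
#' @param n_snps Number of SNPs (>= 15).
#' @param seed Seed.
#' @return A [simulation_config()].
#' @export
scenario_asthma <- function(n = 1201, n_snps = 20, seed = 1) {
  maf <- default_mafs(n_snps)
  maf["snp05"] <- 0.5; maf["snp10"] <- 0.5; maf["snp15"] <- 0.5
  maf <- maf[setdiff(names(maf), "snp06")]   # snp06 becomes the proxy
  simulation_config(
    n_individuals = n, maf = maf,
    ld = tibble::tibble(proxy = "snp06", source = "snp05", fidelity = 0.9),
    effects = tibble::tibble(target = "asthma", snp = "snp05", beta = 0.7),
    epistasis = tibble::tibble(target = "asthma", snp1 = "snp10",
                               snp2 = "snp15", beta = 1.2),
    intercepts = c(asthma = -1.3),
    targets = "asthma", seed = seed)
}

#' @rdname scenario_asthma
#' @export
scenario_asthma_rhinitis <- function(n = 1100, n_snps = 20, seed = 1) {
  cfg <- scenario_asthma(n = n, n_snps = n_snps, seed = seed)
  simulation_config(
    n_individuals = n, maf = cfg$maf, ld = cfg$ld,
    effects = dplyr::bind_rows(
      cfg$effects,
      tibble::tibble(target = "rhinitis", snp = "snp03", beta = 0.8)),
    epistasis = cfg$epistasis,
    phenotype_edges = tibble::tibble(from = "rhinitis", to = "asthma",
                                     beta = 1.0),
    intercepts = c(asthma = -1.8, rhinitis = -0.8),
    targets = c("asthma", "rhinitis"), seed = seed)
}

#' @rdname scenario_asthma
#' @export
scenario_clinical <- function(n = 200, n_snps = 20, seed = 1) {
  cfg <- scenario_asthma_rhinitis(n = n, n_snps = n_snps, seed = seed)
  simulation_config(
    n_individuals = n, maf = cfg$maf, ld = cfg$ld,
    effects = cfg$effects, epistasis = cfg$epistasis,
    phenotype_edges = dplyr::bind_rows(
      cfg$phenotype_edges,
      tibble::tibble(from = "eosinophil", to = "asthma", beta = 0.9)),
    continuous = tibble::tibble(
      name = c("ige", "eosinophil"), driver = c("snp08", "ige"),
      delta = c(0.8, 0.6), sigma = c(1, 0.8)),
    intercepts = c(asthma = -1.8, rhinitis = -0.8),
    targets = c("ige", "eosinophil", "rhinitis", "asthma"), seed = seed)
}

#' Worked example DAG of the dependency types
#'
#' A fixed 12-node DAG over three phenotypes (`Y1`, `Y2`, `Y3`) and nine
#' SNPs exhibiting every dependency type at once: a direct edge
#' (`SNP1 -> Y1`), a transitive relation (two directed paths from `SNP5`
#' to `Y3`), a confounded relation (`SNP1` is a common ancestor of `Y2`
#' and `SNP3`), and a pure interaction (`Y1` and `SNP7` share the child
#' `Y3` without an edge).  Its blankets are
#' `MBS(Y2) = {Y1, SNP9, Y3, SNP7}` and
#' `MBS({Y1,Y2,Y3}) = {SNP1, SNP4, SNP7, SNP9}`.
#'
#' @return A [bn_dag()].
#' @export
relevance_demo_dag <- function() {
  nodes <- c("Y1", "Y2", "Y3", paste0("SNP", 1:9))
  bn_dag(nodes, edges = data.frame(
    from = c("SNP1", "SNP4", "SNP5", "SNP5", "SNP1", "Y1", "SNP9", "Y1",
             "Y2", "SNP7"),
    to   = c("Y1",   "Y1",   "SNP1", "SNP4", "SNP3", "Y2", "Y2",  "Y3",
             "Y3", "Y3")))
}
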