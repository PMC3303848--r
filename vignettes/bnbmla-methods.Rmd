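---
title: "Bayesian multilevel relevance analysis: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian multilevel relevance analysis: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnbmla)
```

## The problem

Case-control association studies test each SNP against the phenotype one at
a time. That viewpoint cannot distinguish a causal variant from a proxy in
linkage disequilibrium with it, silently misses purely epistatic variants
(no marginal effect, strong joint effect), and gives no coherent account of
relevance to several correlated phenotypes at once. This package addresses
those gaps by modeling the joint distribution of all genotypes and
phenotypes as a Bayesian network and asking *structural* questions about the
posterior over networks.

## Model and posterior

Variables are multinomial; a structure $G$ is a DAG over them. For complete
data with Dirichlet parameter priors the marginal likelihood $P(D \mid G)$
decomposes per family into the closed form

$$\prod_j \frac{\Gamma(\alpha_{ij})}{\Gamma(\alpha_{ij}+N_{ij})}
  \prod_k \frac{\Gamma(\alpha_{ijk}+N_{ijk})}{\Gamma(\alpha_{ijk})},$$

with $N_{ijk}$ the count of child state $k$ under parent configuration $j$.
With a uniform prior over structures (restricted to a parent limit, 8 by
default), $P(G \mid D) \propto P(D \mid G)$. The default hyperparameter
scheme sets every $\alpha_{ijk} = 1$; a BDeu scheme
($\alpha_{ijk} = \mathrm{ess}/(r q)$) is available because the
hyperparameters of the original analyses are not recorded and BDeu is the
standard score-equivalent alternative. Only observed parent configurations
contribute, and all arithmetic is in the log domain via `lgamma`, so large
counts cannot overflow.

The quantity of interest is never a single best network but the posterior
of a structural feature $f$:
$P(f \mid D) = \sum_G f(G)\, P(G \mid D)$. Features evaluated per structure:

* **direct relevance** (edge between $X$ and $Y$, either orientation),
* **transitive relevance** (directed path; a direct edge is a length-1
  path),
* **confounded relevance** (a proper common ancestor),
* **association** (any of the above),
* **pure interaction** (common child *and no direct edge*),
* **strong relevance** (direct or pure interaction — exactly membership in
  the Markov blanket of $Y$),
* Markov blanket sets, their $k$-subsets, and multi-target combinations
  (Exist / Only / OtherThan / MT).

Two definitional points were genuinely open and were fixed as follows.
First, pure interaction *excludes* the direct edge: this makes strong
relevance decompose additively, $P(SR) = P(DCR) + P(PIR)$, which is the
identity the reported relevance tables satisfy row by row; the package
asserts it exactly on every run. Second, transitive relevance *includes*
length-1 paths (an edge is a directed path), which keeps transitive
posteriors at least as large as direct ones; the stricter "mediated only"
reading (path but no edge) is reported as an auxiliary column because the
discussion of transitive association often intends that sense.
"Common ancestor" means a proper ancestor of both endpoints via directed
paths of length at least one, excluding the endpoints themselves.

## Sampling

Exact summation over structures is super-exponential, so posteriors are
estimated by Metropolis-coupled MCMC (MC^3). Each chain proposes one of
three operators — add, reverse, delete an edge — chosen uniformly, with the
instantiation uniform among that operator's valid moves (acyclicity and the
parent limit respected). Because neighborhood sizes differ between states,
detailed balance requires the exact Hastings correction; it is computed
from exhaustive neighborhood counts on the current and proposed states
rather than assumed symmetric. If the chosen operator has no valid
instantiation (e.g. deletion on an empty graph) the operator is resampled
and the event counted.

The published analysis scale — burn-in $10^6$ steps, $5\times 10^6$
post-burn-in steps, parent limit 8 — is the default configuration. The
original chain count, temperature ladder and swap schedule are not
recorded; the package defaults to four chains at inverse temperatures
(1.0, 0.8, 0.6, 0.4) with a swap attempt between a uniformly chosen
adjacent pair every 10 steps, which is conventional MC^3 practice, and all
three are configurable. Tempered chains target $P(D \mid G)^\beta$; only
the cold chain ($\beta = 1$) is recorded. Feature indicators are evaluated
every 10th cold-chain state by default (interval 1 evaluates every visited
structure, matching the original evaluation). All chains start from the
empty graph: the starting state is not recorded in the original account,
and the empty graph is deterministic and unbiased under the uniform prior.
A run is fully reproducible from its seed; the sampler uses its own
Mersenne-Twister stream, so results are independent of R's RNG state.

Convergence is monitored with the Gelman-Rubin potential scale reduction
factor on feature indicator series across independent seeded runs
(`rhat_diagnostic()`), and data sufficiency with the peakness of the
ranked blanket-set posterior (`peakness_curve()`): a flat curve means many
weakly supported candidate sets, i.e. the sample is too small for a full
multivariate answer — which is precisely the situation the $k$-subset
aggregation (`k_mbs_aggregate()`) is designed for, since
$P(k\text{-MBS} = s) = \sum_{m \supseteq s} P(\mathrm{MBS} = m)$
concentrates mass on small, well-supported subsets. Aggregation runs over
the *visited* sets only; the truncation error is bounded by the mass of
unvisited sets, which the normalized table makes visible.

## Exact oracle

For domains of up to six variables the package computes the same
posteriors by exhaustive enumeration (`exact_posteriors()`), sharing the
scoring code verbatim so that tests isolate the sampler, not the score.
Enumeration assigns parent sets node by node with early cycle pruning and
normalizes with log-sum-exp. The test suite requires every sampled
pairwise and blanket-set posterior on three seeded five-variable datasets
(200 rows, $2\times 10^5$ recorded samples) to be within 0.02 absolute of
the enumeration value, and reproduces the analytic no-data limit
($P(\text{edge}) = 2/3$ on two variables).

## Quality control and frequentist baselines

The companion frequentist layer reproduces the standard screening
pipeline: monomorphic SNPs removed; Hardy-Weinberg equilibrium tested by
1-df chi-square goodness of fit *in controls only* with removal at
$p < 0.005$; call-rate filter at 90% (computed before complete-case
filtering); allele and genotype chi-square tests with cross-product odds
ratios and Woolf confidence intervals; Bonferroni threshold
$\alpha/m$ displayed at one significant figure; logistic regression with
forced interaction terms on numeric 0/1/2 genotype codings. Chi-square
tests use no continuity correction — the original software defaults are
unknowable, and the uncorrected statistic is the simplest documented
choice. Zero cells receive the Haldane 0.5 correction and are flagged.
Haplotype odds ratios are reconstructed from published haplotype
frequencies and chromosome counts by rounding to integer count tables;
this count-based estimate can differ in the last digit from a
conditional-logistic estimate on haplotype probabilities (1.42 vs 1.41 in
one published row), which is documented rather than forced.

Missing genotypes are resolved before scoring because the closed form
assumes complete data. How the original analysis handled cells below 100%
call rate is not recorded; the default policy drops incomplete rows (it
preserves the completeness assumption exactly and is reported), with
mode imputation as the alternative. Continuous measurements (IgE,
eosinophil counts) are discretized — median split by default, rank-based
tertiles and fixed cutpoints available — with ties assigned to the lower
bin and cutpoints reported.

## The synthetic generator

No genotype data accompany the original study, so validation rests on a
generator with known ground truth. It emulates: biallelic SNPs in
Hardy-Weinberg equilibrium at configured minor allele frequencies; LD
proxies that copy each source allele with fidelity $f$ (allelic
correlation $f$, genotype $r^2 = f^2$ in closed form); direct logistic
genotype effects; purely epistatic pairs via the exclusive-or of
heterozygosity indicators, which at MAF 0.5 has exactly zero marginal
effect per SNP; continuous phenotypes as linear-Gaussian children of a
driver; and an acyclic wiring among phenotypes so that a SNP can reach a
target only through an intermediate phenotype. Copy-fidelity LD is
deliberately simpler than haplotype-block realism: the tests need the
*structure* (transitive but not direct relevance), not population-genetic
fidelity, and the copy model has an analytic correlation to test against.
The generator does not model population stratification, admixture, or
genotyping error.

Three bundled scenarios mirror a staged analysis: one binary target
(n = 1201 by default), two wired targets (n = 1100), and four targets
including two continuous measurements (n = 200) — the sample sizes of the
three embedded datasets the method was originally demonstrated on. Each
plants one direct SNP (per-allele log-odds 0.7 at MAF 0.5), one LD proxy
(allele-copy fidelity 0.9, no own effect) and one epistatic pair
(log-odds 1.2). These effect sizes were chosen once as
realistic-but-detectable at the scenario sample sizes; they are properties
of the simulator, not reproductions of unknowable real effect sizes. The
proxy fidelity deserves a note: 0.9 gives genotype $r^2 \approx 0.8$, the
conventional tag-SNP threshold used when the study's SNP panels are
designed, and it sits below the identifiability ceiling — at fidelity 0.95
the causal SNP's expected family-score advantage over its proxy shrinks to
a few nats at n = 1500 and the posterior picks the proxy on a substantial
fraction of realizations, so "proxy not strongly relevant" would not be a
property of that generator at all. Separating a causal SNP from a proxy in
near-perfect LD is impossible for any method at these sample sizes; the
scenario tests the distinction at the LD level the field's tagging
convention implies. The recovery suite runs the
scenarios at n = 1500 with a reduced sampler ($10^5$ burn-in,
$5\times 10^5$ steps, thinning 10) and requires: the direct SNP called
strongly relevant at the 0.5 threshold; the proxy associated ($\ge 0.5$)
but not strongly relevant ($< 0.5$); the epistatic pair among the top five
2-subsets; and the phenotype-mediated SNP relevant to its own phenotype
but not to the downstream one. Passing these shows the machinery separates
the four relevance types under the generator's assumptions — it does not
certify performance on real cohorts with fine-scale LD, stratification or
measurement error.

## Numerical and engineering notes

The sampler, scorer and enumerator are compiled (Rcpp). Family scores are
cached by (child, parent-set) key, so the incremental score of a move
costs one or two family recomputations; the cache is exact (tested against
full rescoring to 1e-10). Problem sizes used in the shipped tests —
five-variable oracles at 200 rows, 22-variable recovery runs at 1500 rows —
were chosen so the whole suite runs on a single CPU in minutes while still
exercising the study-scale step counts; the defaults remain the full
published scale. Structures are stored as bitsets; domains beyond a few
hundred variables would need a different representation. Ties in ranked
tables are broken by insertion order after a stable sort on probability;
set keys are canonical sorted name vectors.

## Known limitations

* Estimates are Monte Carlo: rare features (posterior below a few times
  $1/\sqrt{n_{\text{samples}}}$) carry large relative error.
* The blanket-set table and its $k$-aggregation see only visited sets;
  with flat posteriors the tail mass is spread over many unvisited sets.
* The uniform structure prior combined with a parent limit is not uniform
  over *sparsity* classes; with the default hyperparameters the score is
  not score-equivalent across Markov-equivalent DAGs (use BDeu if that
  matters for your question).
* Complete-case filtering assumes missingness unrelated to structure;
  informative missingness is not modeled.
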