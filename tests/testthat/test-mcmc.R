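test_that("operator neighborhoods match brute-force enumeration", {
  # empty 3-node DAG: only additions, 6 of them
  g0 <- bn_dag(c("a", "b", "c"))
  nb0 <- dag_neighborhood(g0)
  expect_equal(nrow(nb0), 6)
  expect_true(all(nb0$op == "add"))

  set.seed(3)
  for (rep in 1:15) {
    g <- random_dag(4, 0.4)
    nb <- dag_neighborhood(g, max_parents = 2)
    a <- adjacency(g) * 1
    bf <- brute_neighborhood(a, max_parents = 2)
    expect_equal(nrow(nb), nrow(bf))
    key <- function(op, f, t) paste(op, f, t)
    expect_setequal(key(nb$op, match(nb$from, g$names),
                        match(nb$to, g$names)),
                    key(bf$op, bf$from, bf$to))
  }
})

test_that("no proposed addition ever creates a cycle", {
  set.seed(6)
  for (rep in 1:10) {
    g <- random_dag(5, 0.4)
    nb <- dag_neighborhood(g)
    adds <- nb[nb$op == "add", ]
    for (i in seq_len(nrow(adds))) {
      g2 <- dag_add_edge(g, adds$from[i], adds$to[i])  # errors on a cycle
      expect_true(dag_is_acyclic(g2))
    }
  }
})

test_that("the Hastings correction uses exact neighborhood sizes", {
  g <- bn_dag(c("a", "b", "c"), edges = data.frame(from = "a", to = "b"))
  set.seed(1)
  prop <- propose_move(g)
  nb <- dag_neighborhood(g)
  counts <- table(factor(nb$op, c("add", "delete", "reverse")))
  nb2 <- dag_neighborhood(prop$dag)
  counts2 <- table(factor(nb2$op, c("add", "delete", "reverse")))
  rev_op <- c(add = "delete", delete = "add", reverse = "reverse")[prop$move$op]
  log_fwd <- -log(sum(counts > 0)) - log(counts[[prop$move$op]])
  log_rev <- -log(sum(counts2 > 0)) - log(counts2[[rev_op]])
  expect_equal(prop$log_hastings, log_rev - log_fwd, tolerance = 1e-12)
})

test_that("a higher-scoring symmetric proposal is always accepted", {
  set.seed(44)
  x <- sample(0:1, 120, TRUE)
  y <- ifelse(runif(120) < 0.95, x, 1 - x)
  ds <- coded_dataset(data.frame(x = x, y = y, z = sample(0:1, 120, TRUE)),
                      targets = "y", arity = c(x = 2, y = 2, z = 2))
  g <- bn_dag(c("x", "y", "z"))
  # adding x -> y has a large positive delta; repeat until that move is drawn
  for (i in 1:200) {
    st <- mh_step(ds, g)
    if (dag_n_edges(st$dag) > 0 &&
        ("x" %in% st$dag$names[st$dag$parents[[2]]])) break
  }
  expect_true(st$accepted)
})

test_that("same seed gives an identical sample stream", {
  sim <- simulate_dataset(tiny_scenario(seed = 2, n = 120))
  mc <- mcmc_config(burn_in = 500, n_steps = 4000, seed = 99,
                    feature_eval_interval = 1)
  r1 <- mc3_run(sim$dataset, mcmc = mc, store_series = TRUE)
  r2 <- mc3_run(sim$dataset, mcmc = mc, store_series = TRUE)
  expect_identical(r1$sr_series, r2$sr_series)
  expect_identical(r1$pairwise, r2$pairwise)
  r3 <- mc3_run(sim$dataset, mcmc = mcmc_config(burn_in = 500, n_steps = 4000,
                                                seed = 100,
                                                feature_eval_interval = 1))
  expect_false(identical(r3$pairwise$sr, r1$pairwise$sr))
})

test_that("with no data the chain visits the three 2-node DAGs uniformly", {
  ds <- empty_binary_dataset(2, c("x", "y"))
  run <- mc3_run(ds, targets = "y",
                 mcmc = mcmc_config(burn_in = 1000, n_steps = 60000,
                                    n_chains = 1, inverse_temperatures = 1,
                                    feature_eval_interval = 1, seed = 7))
  expect_equal(run$pairwise$dcr, 2 / 3, tolerance = 0.01)
  # single chain: plain Metropolis-Hastings, no swap statistics
  expect_length(run$stats$swap_attempts, 0)
})

test_that("planted-edge posteriors match exact enumeration", {
  set.seed(51)
  x <- sample(0:2, 150, TRUE, c(.4, .4, .2))
  y <- rbinom(150, 1, plogis(-1 + 1.3 * x))
  z <- sample(0:1, 150, TRUE)
  ds <- coded_dataset(data.frame(x = x, z = z, y = y), targets = "y",
                      arity = c(x = 3, z = 2, y = 2))
  ex <- exact_posteriors(ds, targets = "y")
  run <- mc3_run(ds, mcmc = mcmc_config(burn_in = 20000, n_steps = 200000,
                                        feature_eval_interval = 1, seed = 13))
  for (f in c("dcr", "sr", "assoc", "pir"))
    expect_lt(max(abs(run$pairwise[[f]] - ex$pairwise[[f]])), 0.02)
})

test_that("every recorded structure is acyclic and within the parent limit", {
  sim <- simulate_dataset(tiny_scenario(seed = 9, n = 100))
  run <- mc3_run(sim$dataset,
                 mcmc = mcmc_config(burn_in = 200, n_steps = 2000,
                                    feature_eval_interval = 2,
                                    max_parents = 2, seed = 3),
                 store_dags = TRUE)
  expect_gt(length(run$dags), 0)
  for (g in run$dags) {
    expect_true(dag_is_acyclic(g))
    expect_true(all(lengths(g$parents) <= 2))
  }
})

test_that("swaps preserve each chain's stationary distribution", {
  # empty data: every tempered target is the same uniform distribution,
  # so the cold chain must stay uniform despite frequent swap moves
  ds <- empty_binary_dataset(2, c("x", "y"))
  run <- mc3_run(ds, targets = "y",
                 mcmc = mcmc_config(burn_in = 1000, n_steps = 60000,
                                    n_chains = 4, swap_interval = 5,
                                    feature_eval_interval = 1, seed = 21))
  expect_equal(run$pairwise$dcr, 2 / 3, tolerance = 0.015)
  expect_gt(sum(run$stats$swap_accepts), 0)
})

test_that("the potential scale reduction factor matches a hand computation", {
  s1 <- matrix(rep(c(0, 1), 500), 1)
  # identical chains: B = 0, so rhat = sqrt((n-1)/n), i.e. 1 at long n
  expect_equal(rhat_diagnostic(list(s1, s1))$rhat, 1, tolerance = 1e-3)

  stuck1 <- matrix(rep(0, 50), 1); stuck2 <- matrix(rep(1, 50), 1)
  expect_gt(rhat_diagnostic(list(stuck1, stuck2))$rhat, 1.1)

  set.seed(2)
  a <- rbinom(40, 1, 0.3); b <- rbinom(40, 1, 0.6)
  got <- rhat_diagnostic(list(matrix(a, 1), matrix(b, 1)))$rhat
  n <- 40
  w <- mean(c(var(a), var(b)))
  bn <- var(c(mean(a), mean(b)))
  expect_equal(got, sqrt(((n - 1) / n * w + bn) / w), tolerance = 1e-12)

  expect_error(rhat_diagnostic(list(s1)), "two")
})

test_that("independent seeded runs converge to the same posteriors", {
  sim <- simulate_dataset(tiny_scenario(seed = 4, n = 150))
  mk <- function(seed) mc3_run(sim$dataset,
    mcmc = mcmc_config(burn_in = 5000, n_steps = 40000,
                       feature_eval_interval = 1, seed = seed),
    store_series = TRUE)
  runs <- list(mk(101), mk(202))
  rh <- rhat_diagnostic(runs)
  expect_lt(attr(rh, "max_rhat"), 1.1)
})
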