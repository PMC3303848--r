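test_that("feature posterior estimates carry binomial MC error", {
  ds <- empty_binary_dataset(2, c("x", "y"))
  run <- mc3_run(ds, targets = "y",
                 mcmc = mcmc_config(burn_in = 500, n_steps = 30000,
                                    feature_eval_interval = 1, seed = 2))
  est <- estimate_feature_posterior(run, "dcr", "x", "y")
  expect_equal(est$estimate, 2 / 3, tolerance = 0.01)
  expect_equal(est$mc_se,
               sqrt(est$estimate * (1 - est$estimate) / est$n_samples))
  expect_error(estimate_feature_posterior(run, "dcr", "nope", "y"), "pair")
})

test_that("k-subset aggregation sums superset mass", {
  tbl <- tibble::tibble(set = list(c("A", "B"), "A", c("B", "C")),
                        prob = c(0.6, 0.3, 0.1))
  k1 <- k_mbs_aggregate(tbl, 1)
  get <- function(t, s) t$prob[vapply(t$set, identical, TRUE, s)]
  expect_equal(get(k1, "A"), 0.9)
  expect_equal(get(k1, "B"), 0.7)
  expect_equal(get(k1, "C"), 0.1)
  k2 <- k_mbs_aggregate(tbl, 2)
  expect_equal(get(k2, c("A", "B")), 0.6)
  expect_equal(get(k2, c("B", "C")), 0.1)
  expect_equal(nrow(k_mbs_aggregate(tbl, 3)), 0)
  expect_error(k_mbs_aggregate(tbl, 0), ">= 1")
})

test_that("k = 1 aggregation equals blanket-membership posteriors", {
  sim <- simulate_dataset(tiny_scenario(seed = 6, n = 150))
  run <- mc3_run(sim$dataset,
                 mcmc = mcmc_config(burn_in = 2000, n_steps = 20000,
                                    feature_eval_interval = 1, seed = 8))
  tbl <- mbs_posterior_table(run)
  expect_equal(sum(tbl$prob), 1, tolerance = 1e-9)
  k1 <- k_mbs_aggregate(tbl, 1)
  for (i in seq_len(nrow(k1))) {
    v <- k1$set[[i]][1]
    sr <- run$pairwise$sr[run$pairwise$predictor == v]
    expect_equal(k1$prob[i], sr, tolerance = 1e-9)
  }
  # subset monotonicity: any pair's mass never exceeds either member's
  k2 <- k_mbs_aggregate(tbl, 2)
  get1 <- function(v) k1$prob[vapply(k1$set, identical, TRUE, v)]
  for (i in seq_len(min(nrow(k2), 20))) {
    pair <- k2$set[[i]]
    expect_lte(k2$prob[i], get1(pair[1]) + 1e-9)
    expect_lte(k2$prob[i], get1(pair[2]) + 1e-9)
  }
})

test_that("independence approximation of joint relevance", {
  expect_equal(round(ap_approximation(c(0.09, 0.04, 0.05, 0.61)), 2), 0.68)
  expect_equal(round(ap_approximation(c(0.31, 0.47, 0.37, 0.43)), 2), 0.87)
  expect_equal(ap_approximation(0.3), 0.3)  # single target: identity
  expect_error(ap_approximation(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the relevance threshold is inclusive at 0.5", {
  expect_true(relevance_call(0.5))
  expect_false(relevance_call(0.49))
  expect_true(relevance_call(1.0))
  expect_equal(relevance_call(c(0.2, 0.5, 0.9)), c(FALSE, TRUE, TRUE))
})

test_that("peakness curves are non-increasing and sharpen with sample size", {
  tbl <- tibble::tibble(set = list("A"), prob = 1, rank = 1L)
  pc <- peakness_curve(tbl)
  expect_equal(nrow(pc), 1)

  run_at <- function(n) {
    sim <- simulate_dataset(tiny_scenario(seed = 3, n = n))
    run <- mc3_run(sim$dataset,
                   mcmc = mcmc_config(burn_in = 3000, n_steps = 30000,
                                      feature_eval_interval = 1, seed = 5))
    peakness_curve(mbs_posterior_table(run))
  }
  small <- run_at(60)
  large <- run_at(1200)
  expect_true(all(diff(small$prob) <= 1e-12))
  expect_true(all(diff(large$prob) <= 1e-12))
  expect_gt(large$prob[1], small$prob[1])   # more data, more peaked
})

test_that("report tables satisfy the disjoint-union identity per row", {
  sim <- simulate_dataset(tiny_scenario(seed = 12, n = 200))
  run <- mc3_run(sim$dataset,
                 mcmc = mcmc_config(burn_in = 2000, n_steps = 20000,
                                    feature_eval_interval = 1, seed = 12))
  rep <- relevance_report(run)
  pw <- rep$pairwise
  expect_equal(pw$s_relevant, pw$d_relevant + pw$interaction,
               tolerance = 1e-12)
  expect_true(all(pw$associated >= pw$d_relevant - 1e-12))
  expect_true(all(pw$s_relevant >= 0 & pw$s_relevant <= 1))

  td <- tidy(run)
  expect_true(all(c("predictor", "target", "s_relevant", "mc_se") %in%
                  names(td)))
  gl <- glance(run)
  expect_equal(gl$n_samples, run$n_samples)
})

test_that("multi-target reports expose Exist/Only/OtherThan/AP/MT columns", {
  cfg <- simulation_config(
    n_individuals = 250,
    maf = c(s1 = 0.4, s2 = 0.5),
    effects = tibble::tibble(target = c("t1", "t2"), snp = c("s1", "s1"),
                             beta = c(1.0, 1.0)),
    intercepts = c(t1 = -0.6, t2 = -0.6),
    targets = c("t1", "t2"), seed = 19)
  sim <- simulate_dataset(cfg)
  run <- mc3_run(sim$dataset,
                 mcmc = mcmc_config(burn_in = 2000, n_steps = 20000,
                                    feature_eval_interval = 1, seed = 19))
  rep <- relevance_report(run)
  mt <- rep$multitarget
  expect_true(all(c("exist_t1", "exist_t2", "only_t1", "other_than_t1",
                    "ap", "mt") %in% names(mt)))
  r1 <- mt[mt$predictor == "s1", ]
  # only[t] <= exist[t]; mt >= each exist
  expect_lte(r1$only_t1, r1$exist_t1 + 1e-12)
  expect_gte(r1$mt, max(r1$exist_t1, r1$exist_t2) - 1e-9)
  # AP is computed from the exist columns
  expect_equal(r1$ap, 1 - (1 - r1$exist_t1) * (1 - r1$exist_t2),
               tolerance = 1e-9)
  # joint-target blanket table exists and normalizes
  joint <- mbs_posterior_table(run)
  expect_equal(sum(joint$prob), 1, tolerance = 1e-9)
})
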