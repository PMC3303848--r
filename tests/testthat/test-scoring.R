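test_that("family score matches the sequential predictive oracle", {
  # binary child, no parents, two identical observations: (1/2)(2/3) = 1/3
  ds <- coded_dataset(data.frame(x = c(1L, 1L)), arity = c(x = 2))
  expect_equal(family_log_marginal(ds, "x"), log(1 / 3), tolerance = 1e-12)

  # empty dataset scores 0: every Gamma term cancels
  ds0 <- empty_binary_dataset(2)
  expect_equal(family_log_marginal(ds0, "V1"), 0)

  # family with one parent equals the product of per-parent-configuration
  # no-parent scores
  set.seed(4)
  for (rep in 1:5) {
    x <- sample(0:1, 40, TRUE)
    p <- sample(0:2, 40, TRUE)
    ds2 <- coded_dataset(data.frame(x = x, p = p), arity = c(x = 2, p = 3))
    expect_equal(family_log_marginal(ds2, "x", "p"),
                 seq_pred_family_score(x, p, 2), tolerance = 1e-10)
    expect_equal(family_log_marginal(ds2, "x"),
                 seq_pred_log_score(x, 2), tolerance = 1e-10)
  }
})

test_that("BDeu score responds to the equivalent sample size", {
  ds <- coded_dataset(data.frame(x = rep(c(0L, 1L), c(15, 5))),
                      arity = c(x = 2))
  ch <- family_log_marginal(ds, "x", config = score_config("ch"))
  bd1 <- family_log_marginal(ds, "x", config = score_config("bdeu", ess = 1))
  bd100 <- family_log_marginal(ds, "x",
                               config = score_config("bdeu", ess = 100))
  expect_false(isTRUE(all.equal(ch, bd1)))
  # a large ess pulls the marginal toward the uniform-parameter prediction
  expect_lt(bd100, bd1)
  expect_error(score_config("bdeu", ess = 0), "positive")
})

test_that("DAG score is decomposable and matches the enumeration oracle", {
  set.seed(8)
  x <- sample(0:1, 30, TRUE)
  y <- ifelse(runif(30) < 0.8, x, 1 - x)
  ds <- coded_dataset(data.frame(x = x, y = y), targets = "y",
                      arity = c(x = 2, y = 2))
  g_empty <- bn_dag(c("x", "y"))
  expect_equal(dag_log_score(ds, g_empty),
               family_log_marginal(ds, "x") + family_log_marginal(ds, "y"),
               tolerance = 1e-12)
  g_xy <- dag_add_edge(g_empty, "x", "y")
  g_yx <- dag_add_edge(g_empty, "y", "x")
  expect_equal(dag_log_score(ds, g_xy),
               seq_pred_log_score(x, 2) + seq_pred_family_score(y, x, 2),
               tolerance = 1e-10)
  expect_equal(dag_log_score(ds, g_yx),
               seq_pred_log_score(y, 2) + seq_pred_family_score(x, y, 2),
               tolerance = 1e-10)
  # posterior ratio of two structures is exp(score difference)
  ratio <- exp(dag_log_score(ds, g_xy) - dag_log_score(ds, g_empty))
  expect_gt(ratio, 1)  # dependent data favor the edge
})

test_that("score is invariant to row order", {
  set.seed(12)
  df <- data.frame(a = sample(0:2, 50, TRUE), b = sample(0:1, 50, TRUE),
                   c = sample(0:1, 50, TRUE))
  ds1 <- coded_dataset(df, arity = c(a = 3, b = 2, c = 2))
  ds2 <- coded_dataset(df[sample(50), ], arity = c(a = 3, b = 2, c = 2))
  g <- bn_dag(c("a", "b", "c"),
              edges = data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(dag_log_score(ds1, g), dag_log_score(ds2, g),
               tolerance = 1e-12)
})

test_that("incremental deltas equal full rescore differences", {
  set.seed(21)
  df <- as.data.frame(lapply(setNames(rep(2, 4), c("a", "b", "c", "d")),
                             function(r) sample(0:(r - 1), 60, TRUE)))
  ds <- coded_dataset(df, arity = c(a = 2, b = 2, c = 2, d = 2))
  for (rep in 1:10) {
    g <- random_dag(4)
    g$names <- c("a", "b", "c", "d")
    nb <- dag_neighborhood(g, max_parents = 8)
    if (nrow(nb) == 0) next
    mv <- nb[sample(nrow(nb), 1), ]
    res <- score_delta(ds, g, list(op = mv$op, from = mv$from, to = mv$to))
    expect_equal(res$delta,
                 dag_log_score(ds, res$dag) - dag_log_score(ds, g),
                 tolerance = 1e-10)
  }
  # add then delete the same edge nets to zero
  g <- bn_dag(c("a", "b", "c", "d"))
  added <- score_delta(ds, g, list(op = "add", from = "a", to = "b"))
  removed <- score_delta(ds, added$dag,
                         list(op = "delete", from = "a", to = "b"))
  expect_equal(added$delta + removed$delta, 0, tolerance = 1e-12)
})

test_that("more data sharpens the preference for the generating structure", {
  set.seed(33)
  n <- 80
  a <- sample(0:1, n, TRUE)
  b <- sample(0:1, n, TRUE)
  collider <- ifelse(runif(n) < 0.9, as.integer(xor(a, b)), sample(0:1, n, TRUE))
  df <- data.frame(a = a, b = b, c = collider)
  truth <- bn_dag(c("a", "b", "c"),
                  edges = data.frame(from = c("a", "b"), to = c("c", "c")))
  rival <- bn_dag(c("a", "b", "c"))
  margin <- function(d) {
    ds <- coded_dataset(d, arity = c(a = 2, b = 2, c = 2))
    dag_log_score(ds, truth) - dag_log_score(ds, rival)
  }
  expect_gt(margin(rbind(df, df)), margin(df))   # doubled rows widen the gap
  expect_gt(margin(df), 0)
})
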