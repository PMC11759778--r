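test_that("separable data and k = 1 closed forms are recovered exactly", {
  fit <- kmeans1d(c(0, 0, 10, 10), k = 2, seed = 1)
  expect_equal(fit$centroids, c(0, 10))
  expect_equal(fit$sse, 0)
  expect_equal(fit$cluster, c(1L, 1L, 2L, 2L))

  set.seed(42)
  x <- rnorm(37)
  fit1 <- kmeans1d(x, k = 1, seed = 1)
  expect_equal(fit1$centroids, mean(x))
  expect_equal(fit1$sse, sum((x - mean(x))^2))
})

test_that("input validation rejects impossible requests", {
  expect_error(kmeans1d(c(1, 1, 1), k = 2), "distinct")
  expect_error(kmeans1d(numeric(0), k = 1), "non-empty")
  expect_error(kmeans1d(c(1, NA), k = 1), "finite")
  expect_error(kmeans1d(1:5, k = 0), "positive integer")
  expect_error(kmeans1d_dp(1:3, k = 4), "distinct")
})

test_that("fits are bit-reproducible under a fixed seed and leave the RNG alone", {
  x <- c(rnorm(40), rnorm(40, 6), rnorm(40, 13))
  f1 <- kmeans1d(x, 3, seed = 7)
  f2 <- kmeans1d(x, 3, seed = 7)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(f1$sse, f2$sse)

  set.seed(99); before <- runif(1)
  set.seed(99); invisible(kmeans1d(x, 2, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("centroids equal member means and SSE is self-consistent", {
  set.seed(5)
  for (rep in 1:5) {
    x <- runif(80, 0, 10)
    k <- sample(2:4, 1)
    fit <- kmeans1d(x, k, seed = rep)
    expect_true(all(fit$cluster %in% seq_len(k)))
    expect_length(fit$cluster, length(x))
    for (u in seq_len(k))
      expect_equal(fit$centroids[u], mean(x[fit$cluster == u]), tolerance = 1e-9)
    expect_equal(fit$sse, sum((x - fit$centroids[fit$cluster])^2),
                 tolerance = 1e-9)
    expect_true(all(diff(fit$centroids) > 0))
  }
})

test_that("DP oracle matches exhaustive contiguous-partition enumeration (n <= 12)", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    x <- round(runif(n, 0, 20), 2)
    for (k in 1:min(4, length(unique(x)))) {
      dp <- kmeans1d_dp(x, k)
      expect_equal(dp$sse, enum_contiguous_sse(x, k), tolerance = 1e-9)
    }
  }
})

test_that("DP oracle handles obvious optima and SSE nests in k", {
  dp <- kmeans1d_dp(c(1, 2, 100), 2)
  expect_equal(sort(unname(dp$cluster)), c(1, 1, 2))
  expect_equal(dp$centroids, c(1.5, 100))

  set.seed(21)
  x <- rnorm(60, 0, 4)
  sses <- vapply(1:5, function(k) kmeans1d_dp(x, k)$sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-9))
})

test_that("Lloyd with restarts attains the DP optimum on well-separated bumps", {
  set.seed(31)
  x <- c(rnorm(20, 0, 0.3), rnorm(20, 5, 0.3), rnorm(20, 11, 0.3))
  fit <- kmeans1d(x, 3, n_restarts = 10, seed = 1)
  dp <- kmeans1d_dp(x, 3)
  expect_equal(fit$sse, dp$sse, tolerance = 1e-9)
  expect_identical(fit$cluster, dp$cluster)
})

test_that("heuristic SSE never beats the DP optimum", {
  set.seed(41)
  for (rep in 1:10) {
    x <- runif(50, 0, 1)
    k <- sample(1:4, 1)
    fit <- kmeans1d(x, k, n_restarts = 3, seed = rep)
    dp <- kmeans1d_dp(x, k)
    expect_gte(fit$sse, dp$sse - 1e-9 * (1 + dp$sse))
  }
})

test_that("independent library implementation agrees on the optimum", {
  # cross-check against stats::kmeans on an easy, well-separated dataset
  set.seed(51)
  x <- c(rnorm(30, 0, 0.2), rnorm(30, 3, 0.2))
  fit <- kmeans1d(x, 2, seed = 1)
  ref <- stats::kmeans(x, centers = 2, nstart = 10)
  expect_equal(fit$sse, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(fit$centroids, sort(as.numeric(ref$centers)), tolerance = 1e-8)
})

test_that("random init also works and converges", {
  set.seed(61)
  x <- c(rnorm(30, 0), rnorm(30, 8))
  fit <- kmeans1d(x, 2, init = "random", n_restarts = 5, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$sse, kmeans1d_dp(x, 2)$sse, tolerance = 1e-9)
})

test_that("model methods behave like a classed fit should", {
  set.seed(71)
  x <- c(rnorm(25, 0, 0.5), rnorm(25, 6, 0.5))
  fit <- kmeans1d(x, 2, seed = 1)
  expect_named(coef(fit), c("cluster1", "cluster2"))
  expect_identical(predict(fit), fit$cluster)
  expect_equal(predict(fit, c(min(x), max(x))), c(1L, 2L))
  expect_equal(fitted(fit), fit$centroids[fit$cluster])
  expect_equal(sum(residuals(fit)^2), fit$sse)
  expect_output(print(fit), "1-D k-means")
  s <- summary(fit)
  expect_equal(sum(s$within_sse), fit$sse)
  # midpoint ties go to the lower-indexed (smaller-centroid) cluster
  tie <- kmeans1d(c(0, 0, 2, 2), 2, seed = 1)
  expect_equal(predict(tie, 1), 1L)
})

test_that("pooling concatenates with provenance and round-trips", {
  a <- make_instance("a", "PD", 2, c(1, 2, 3))
  b <- make_instance("b", "HC", 0, c(0.1, 0.2, 0.3, 0.4, 0.5))
  pooled <- pool_instances(list(a, b))
  expect_equal(nrow(pooled), 8)
  expect_equal(as.vector(table(pooled$instance_id)[c("a", "b")]), c(3L, 5L))
  expect_equal(pooled$modulus[pooled$instance_id == "a"], a$moduli)
  expect_equal(pooled$modulus[pooled$instance_id == "b"], b$moduli)
  expect_equal(pooled$j[pooled$instance_id == "b"], 1:5)
  expect_error(pool_instances(list()), "non-empty")
  expect_error(pool_instances(list(a, a)), "duplicate")
})
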