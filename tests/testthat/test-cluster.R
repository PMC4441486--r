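test_that("pearson_correlation matches the closed formula and flags degeneracy", {
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  # direct evaluation of E[(X-mux)(Y-muy)]/(sx sy) with sample moments
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), manual, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x + 10), -1)
  expect_warning(r <- pearson_correlation(c(1, 1, 1), y), "zero variance")
  expect_true(is.na(r))
})

test_that("vectorized leave-one-out correlations equal a plain cor() loop", {
  set.seed(42)
  X <- matrix(rpois(30 * 12, 8), 30, 12)
  assign <- sample(rep_len(1:2, 30))
  C <- hiscl:::.loo_correlations(X, assign, 2L)
  for (i in 1:30) {
    for (c in 1:2) {
      M <- colSums(X[assign == c, , drop = FALSE])
      if (assign[i] == c) M <- M - X[i, ]
      expect_equal(C[i, c], cor(X[i, ], M), tolerance = 1e-10,
                   info = sprintf("cell %d cluster %d", i, c))
    }
  }
})

test_that("duplicated distinct profiles separate perfectly", {
  a <- c(40, 1, 1, 30, 2, 9, 0, 3, 1, 5)
  b <- c(1, 35, 22, 0, 18, 1, 7, 0, 4, 2)
  X <- rbind(matrix(a, 6, 10, byrow = TRUE),
             matrix(b, 5, 10, byrow = TRUE))
  truth <- rep(1:2, c(6, 5))
  cl <- correlation_kmeans(X, seed = 3)
  expect_equal(clustering_accuracy(cl, truth), 1)
  expect_true(cl$converged)
})

test_that("the converged state is a fixed point of the update rule", {
  set.seed(5)
  ex <- simulate_two_population_experiment(seed = 5, n_per_population = c(40, 25),
                                           n_genes = 120)
  cl <- correlation_kmeans(ex$counts, seed = 6)
  after <- oracle_loo_sweep(unclass(ex$counts), cl$assignments)
  expect_identical(unname(after), unname(cl$assignments))
})

test_that("full run matches an independent step-by-step re-implementation", {
  set.seed(8)
  X <- matrix(rpois(8 * 20, 10), 8, 20)
  X[1:4, 1:6] <- X[1:4, 1:6] + 15   # two weakly separated groups
  for (seed in c(1, 2, 9)) {
    cl <- correlation_kmeans(X, seed = seed)
    ref <- oracle_corr_kmeans(X, seed = seed)
    expect_identical(unname(cl$assignments), unname(ref$assignments),
                     info = paste("seed", seed))
    expect_equal(cl$switch_history, ref$history, info = paste("seed", seed))
  }
})

test_that("clustering is deterministic given its seed", {
  ex <- simulate_two_population_experiment(seed = 2, n_per_population = c(30, 20),
                                           n_genes = 100)
  c1 <- correlation_kmeans(ex$counts, seed = 11)
  c2 <- correlation_kmeans(ex$counts, seed = 11)
  expect_identical(c1$assignments, c2$assignments)
  expect_identical(c1$switch_history, c2$switch_history)
})

test_that("inject_foreign preserves totals and is the identity at m = 0", {
  ex <- simulate_two_population_experiment(seed = 3, n_per_population = c(20, 15),
                                           n_genes = 80)
  X <- ex$counts
  expect_equal(inject_foreign(X, 0, seed = 1), unclass(X), ignore_attr = TRUE)
  for (m in c(10, 50, 120)) {
    Xp <- inject_foreign(X, m, seed = m)
    expect_identical(unname(rowSums(Xp)), unname(rowSums(X)))
    expect_true(all(Xp >= 0))
  }
  expect_error(inject_foreign(rbind(c(2, 1), c(5, 5)), 10), "cannot replace")
})

test_that("correlation to the aggregate increases with m on average", {
  # well-separated populations so the baseline aggregate correlation is
  # low and the pull toward the aggregate is visible at each step
  tx <- make_transcriptome(100, divergence = 2.5, seed = 44)
  X <- simulate_population_counts(c(30, 20), tx, 340, seed = 45)
  agg <- colSums(X)
  m_grid <- floor(min(rowSums(X)) * c(0, 0.3, 0.6, 0.9))
  mean_cor <- sapply(m_grid, function(m) {
    Xp <- inject_foreign(X, m, seed = 5)
    mean(apply(Xp, 1, cor, y = agg))
  })
  expect_true(all(diff(mean_cor) > 0))
})

test_that("accuracy is invariant to label permutation", {
  truth <- rep(c("a", "b"), c(12, 8))
  assign <- rep(c(1L, 2L), c(12, 8))
  expect_equal(clustering_accuracy(assign, truth), 1)
  expect_equal(clustering_accuracy(3L - assign, truth), 1)
  expect_equal(clustering_accuracy(assign, rev(truth)),
               clustering_accuracy(3L - assign, rev(truth)))
})

test_that("robustness curve: separable at m = 0, chance at full replacement", {
  ex <- simulate_two_population_experiment(seed = 6, n_per_population = c(30, 30),
                                           n_genes = 100,
                                           intermediate_fraction = 0)
  X <- ex$counts
  rc0 <- robustness_curve(X, ex$labels, m_grid = 0, n_trials = 3, seed = 7)
  expect_gt(rc0$mean_accuracy, 0.95)

  # complete replacement (m = each cell's total) destroys all signal:
  # accuracy near chance
  accF <- sapply(1:5, function(s) {
    Xp <- inject_foreign(X, rowSums(X), seed = 80 + s)
    clustering_accuracy(correlation_kmeans(Xp, seed = 90 + s), ex$labels)
  })
  expect_lt(mean(accF), 0.75)
  expect_gte(mean(accF), 0.5)  # best-permutation floor
})
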