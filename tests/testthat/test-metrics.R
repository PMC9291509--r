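# Population quality metrics: ratios, Wasserstein distance, hypervolume.

test_that("validity, uniqueness and novelty follow their definitions", {
  expect_equal(validity_ratio(c("CC", "CC")), 1.0)
  expect_equal(uniqueness_ratio(c("CC", "CC")), 0.5)
  expect_equal(novelty_ratio(c("CC", "CC"), training_set = "CC"), 0.0)

  fresh <- c("c1ccccc1", "CCO", "CCN")
  expect_equal(validity_ratio(fresh), 1.0)
  expect_equal(uniqueness_ratio(fresh), 1.0)
  expect_equal(novelty_ratio(fresh, training_set = "CCCCCCCC"), 1.0)

  # planted composition: 2 invalid, 2 duplicated, 2 from training, of 8
  train <- c("CCO", "CCN")
  batch <- c("CCO", "CCN", "c1ccccc1", "c1ccccc1", "CCC", NA, "xx((", "CCCC")
  expect_equal(validity_ratio(batch), 6 / 8)
  expect_equal(uniqueness_ratio(batch), 5 / 8)
  expect_equal(novelty_ratio(batch, train), 3 / 5)
  expect_error(validity_ratio(character(0)), class = "delfrag_metric_error")
  expect_error(novelty_ratio(character(0), train), class = "delfrag_metric_error")
})

test_that("canonicalization governs duplicate detection in the ratios", {
  expect_equal(uniqueness_ratio(c("OCC", "CCO", "C(C)O")), 1 / 3)
  expect_equal(novelty_ratio(c("OCC"), training_set = "CCO"), 0.0)
})

test_that("W1 matches closed-form cases and the sorted-matching oracle", {
  expect_equal(wasserstein1(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein1(0, 1), 1.0)
  expect_equal(wasserstein1(c(0, 1), c(2, 3)), 2.0)
  set.seed(3)
  a <- stats::rnorm(40); b <- stats::rnorm(25, mean = 1)
  # translation property
  expect_equal(wasserstein1(a, a + 1.7), 1.7, tolerance = 1e-12)
  # symmetry, non-negativity, triangle inequality
  cc <- stats::rexp(33)
  expect_equal(wasserstein1(a, b), wasserstein1(b, a))
  expect_gte(wasserstein1(a, b), 0)
  expect_lte(wasserstein1(a, cc),
             wasserstein1(a, b) + wasserstein1(b, cc) + 1e-12)
  # equal sizes: mean absolute difference of the sorted samples
  b2 <- stats::rnorm(40)
  expect_equal(wasserstein1(a, b2), mean(abs(sort(a) - sort(b2))))
  # unequal sizes: exact CDF integral equals the replication oracle
  expect_equal(wasserstein1(a[1:6], b[1:4]), oracle_w1(a[1:6], b[1:4]))
  expect_equal(wasserstein1(a, b), oracle_w1(a, b))
  expect_error(wasserstein1(numeric(0), a), class = "delfrag_metric_error")
})

test_that("hypervolume matches hand computations and is union-like", {
  expect_equal(hypervolume(c(1, 1), c(2, 2)), 1.0)
  expect_equal(hypervolume(rbind(c(0, 1), c(1, 0)), c(2, 2)), 3.0)
  front <- rbind(c(0, 1), c(1, 0))
  with_dominated <- rbind(front, c(1, 1))  # inside the union already
  expect_equal(hypervolume(with_dominated, c(2, 2)), 3.0)
  # adding a non-dominated point grows the volume
  expect_gt(hypervolume(rbind(front, c(0.25, 0.25)), c(2, 2)), 3.0)
  # 3-D hand case: inclusion-exclusion gives 4 + 2 - 1
  expect_equal(hypervolume(c(1, 1, 1), c(2, 2, 2)), 1.0)
  expect_equal(hypervolume(rbind(c(0, 0, 1), c(1, 1, 0)), c(2, 2, 2)), 5.0)
  expect_error(hypervolume(c(3, 1), c(2, 2)),
               class = "delfrag_invalid_reference")
  expect_error(hypervolume(c(1, 1), c(2, 2, 2)), class = "delfrag_shape_error")
})

test_that("hypervolume is strictly monotone under front domination", {
  set.seed(6)
  ref <- c(1, 1, 1)
  pts <- matrix(stats::runif(30), ncol = 3)
  hv1 <- hypervolume(pts, ref)
  better <- pts * 0.9  # dominates the original front
  expect_gt(hypervolume(better, ref), hv1)
})

test_that("3-D hypervolume agrees with Monte-Carlo integration", {
  set.seed(8)
  for (k in 1:3) {
    pts <- matrix(stats::runif(3 * 12), ncol = 3)
    ref <- c(1.1, 1.1, 1.1)
    mc <- oracle_hv_mc(pts, ref, n = 2e5, seed = k)
    expect_lt(abs(hypervolume(pts, ref) - mc$hv), 3 * mc$se + 1e-9)
  }
})

test_that("generation report is reproducible and zero for identical data", {
  run <- tiny_del_run()
  init <- run$initial
  pop <- run$populations[[1]]
  ref <- run$reference_point
  rep1 <- generation_report(pop, init, ref, training_set = run$training_set)
  rep2 <- generation_report(pop, init, ref, training_set = run$training_set)
  expect_identical(rep1, rep2)
  expect_equal(rep1$w1_sas, 0)
  expect_equal(rep1$w1_logp, 0)
  expect_equal(rep1$w1_bas, 0)
  expect_true(all(run$metrics$validity >= 0 & run$metrics$validity <= 1))
  expect_true(all(run$metrics$uniqueness >= 0 & run$metrics$uniqueness <= 1))
  expect_true(all(run$metrics$novelty >= 0 & run$metrics$novelty <= 1))
})
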