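# Multi-objective machinery and the generation loop.

test_that("Pareto dominance is strict and dimension-checked", {
  expect_true(dominates(c(1, 1, 1), c(2, 2, 2)))
  expect_false(dominates(c(1, 1, 1), c(1, 1, 1)))
  expect_false(dominates(c(1, 3, 2), c(3, 1, 2)))
  expect_false(dominates(c(3, 1, 2), c(1, 3, 2)))
  expect_true(dominates(c(1, 1, 2), c(1, 1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), class = "delfrag_shape_error")
})

test_that("non-dominated sorting matches the peeling oracle", {
  expect_identical(non_dominated_sort(matrix(c(1, 2), 1)), 1L)
  chain <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_identical(non_dominated_sort(chain), c(1L, 2L, 3L))
  set.seed(14)
  for (k in 1:20) {
    objs <- matrix(stats::rnorm(3 * 40), ncol = 3)
    expect_identical(non_dominated_sort(objs), oracle_pareto_ranks(objs))
  }
  # ranks partition the set: every point in exactly one front
  objs <- matrix(stats::rnorm(90), ncol = 3)
  r <- non_dominated_sort(objs)
  expect_true(all(r >= 1) && !anyNA(r))
})

test_that("crowding distance follows the normalized-gap convention", {
  expect_identical(crowding_distance(rbind(c(0, 1))), Inf)
  expect_identical(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  d <- crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_identical(d[c(1, 3)], c(Inf, Inf))
  expect_equal(d[2], 2)
  # order invariance after matching points
  front <- rbind(c(0, 5), c(1, 3), c(2, 2), c(4, 1), c(7, 0))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(crowding_distance(front[perm, ]), crowding_distance(front)[perm])
  # a zero-range objective contributes nothing
  flat <- rbind(c(0, 1), c(1, 1), c(2, 1))
  expect_equal(crowding_distance(flat)[2], 1)
})

test_that("tournament selection respects rank, crowding and the seed", {
  members <- data.frame(smiles = c("a", "b"), sas = c(1, 2), logp = c(1, 2),
                        bas = c(-5, -4), mw = c(100, 100),
                        rank = c(1L, 2L), crowding = c(Inf, Inf))
  pop <- del_population(members)
  set.seed(123)
  seq1 <- replicate(50, tournament_select(pop, p = 0.95))
  set.seed(123)
  seq2 <- replicate(50, tournament_select(pop, p = 0.95))
  expect_identical(seq1, seq2)
  # symmetric ties fall to a fair coin
  members$rank <- c(1L, 1L); members$crowding <- c(1, 1)
  pop <- del_population(members)
  set.seed(5)
  picks <- replicate(4000, tournament_select(pop, p = 1))
  expect_gt(mean(picks == 1), 0.45)
  expect_lt(mean(picks == 1), 0.55)
  expect_error(tournament_select(del_population(members[1, , drop = FALSE])),
               class = "delfrag_population_error")
})

test_that("uniform crossover conserves coordinates; mutation respects its rate", {
  z <- stats::rnorm(64)
  set.seed(2)
  same <- crossover_latent(z, z)
  expect_identical(same$child1, z)
  expect_identical(same$child2, z)
  z2 <- stats::rnorm(64)
  cx <- crossover_latent(z, z2)
  expect_equal(cx$child1 + cx$child2, z + z2)
  expect_true(all(cx$child1 == z | cx$child1 == z2))
  expect_error(crossover_latent(z, z2[1:10]), class = "delfrag_shape_error")

  expect_identical(mutate_latent(z, rate = 0), z)
  expect_identical(mutate_latent(z, rate = 1, sigma = 0), z)
  expect_error(mutate_latent(z, rate = 0.1, sigma = -1),
               class = "delfrag_config_error")
  expect_error(mutate_latent(z, rate = 2), class = "delfrag_config_error")
})

test_that("one evolution step is seeded, deduplicated and size-bounded", {
  run <- tiny_del_run()
  pop0 <- run$populations[[1]]
  model <- run$model
  cfg <- run$config
  pop0 <- delfrag:::refresh_latents(pop0, model)
  set.seed(77)
  nxt1 <- evolve_generation(pop0, model, cfg)
  set.seed(77)
  nxt2 <- evolve_generation(pop0, model, cfg)
  expect_identical(nxt1$members, nxt2$members)
  expect_identical(nxt1$generation, pop0$generation + 1L)
  expect_lte(nrow(nxt1$members), nxt1$size_target)
  expect_false(any(duplicated(nxt1$members$smiles)))
  expect_true(all(is_valid_smiles(nxt1$members$smiles)))
  # ranks partition the population
  expect_false(anyNA(nxt1$members$rank))
  expect_error(evolve_generation(del_population(nxt1$members), model, cfg),
               class = "delfrag_population_error")
})

test_that("elitist truncation preserves the first front under a closed loop", {
  # without mutation and with selection pressure 1, front-1 members of the
  # previous population can only be displaced by dominating offspring, so
  # the front never gets worse
  run <- tiny_del_run()
  pop <- delfrag:::refresh_latents(run$populations[[2]], run$model)
  cfg <- run$config
  cfg$mutation_rate <- 0
  ref <- run$reference_point
  hv_before <- hypervolume(front1_clipped(pop$members, ref), ref)
  set.seed(11)
  nxt <- evolve_generation(pop, run$model, cfg)
  hv_after <- hypervolume(front1_clipped(nxt$members, ref), ref)
  expect_gte(hv_after, hv_before - 1e-12)
})

test_that("a seeded run is reproducible and improves its front", {
  fx <- fixture_library(100)
  cfg <- del_config(generations = 2, population_size = 30,
                    initial_epochs = 8, subsequent_epochs = 3, seed = 21)
  r1 <- run_del(fx[1:60], cfg, tiny_model_config(), variant = "jt")
  r2 <- run_del(fx[1:60], cfg, tiny_model_config(), variant = "jt")
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$populations[[3]]$members, r2$populations[[3]]$members)

  run <- surrogate_del_run()
  init <- run$populations[[1]]$members
  fin <- run$populations[[length(run$populations)]]$members
  mean_front <- function(m) {
    colMeans(m[m$rank == 1, c("sas", "logp", "bas")])
  }
  improved <- mean_front(fin) <= mean_front(init)
  expect_gte(sum(improved), 2)
})

test_that("a zero-generation run returns the pretrained state only", {
  fx <- fixture_library(100)[1:30]
  cfg <- del_config(generations = 0, population_size = 20,
                    initial_epochs = 4, seed = 3)
  run <- run_del(fx, cfg, tiny_model_config(), variant = "jt")
  expect_length(run$populations, 1)
  expect_identical(nrow(run$metrics), 1L)
  expect_identical(run$metrics$generation, 0L)
  expect_s3_class(run$model, "fragment_vae")
  expect_output(print(run), "DEL run")
})
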