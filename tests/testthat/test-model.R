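# Generative model: loss functions, training, encoding, guarded decoding.

test_that("Gaussian KL matches closed form and quadrature", {
  expect_equal(kl_gaussian(rep(0, 8), rep(0, 8)), 0)
  expect_equal(kl_gaussian(1, 0), 0.5)
  expect_error(kl_gaussian(c(0, 0), 0), class = "delfrag_shape_error")
  set.seed(1)
  for (k in 1:5) {
    mu <- stats::rnorm(1); lv <- stats::rnorm(1, sd = 0.5)
    # numeric quadrature of the 1-D KL integral
    f <- function(x) {
      q <- stats::dnorm(x, mu, exp(lv / 2))
      ifelse(q > 0, q * (stats::dnorm(x, mu, exp(lv / 2), log = TRUE) -
                           stats::dnorm(x, log = TRUE)), 0)
    }
    num <- stats::integrate(f, -30, 30, rel.tol = 1e-10)$value
    expect_equal(kl_gaussian(mu, lv), num, tolerance = 1e-6)
  }
  # matrix input gives per-row values
  m <- matrix(stats::rnorm(6), 2, 3)
  lv <- matrix(stats::rnorm(6), 2, 3)
  expect_equal(kl_gaussian(m, lv),
               c(kl_gaussian(m[1, ], lv[1, ]), kl_gaussian(m[2, ], lv[2, ])))
})

test_that("loss composition follows the weighted variational objective", {
  lb <- elbo_loss(1, 2, 3, beta = 0.1, alpha = 0.5)
  expect_equal(lb$total, 2.7)
  expect_equal(elbo_loss(4.2, 9, 99, beta = 0, alpha = 0)$total, 4.2)
  expect_equal(elbo_loss(1.5, 2.5, 0, beta = 1, alpha = 0)$total, 4.0)
  expect_error(elbo_loss(1, 1, 1, beta = -0.1, alpha = 0),
               class = "delfrag_config_error")

  expect_equal(jtvae_reconstruction(0, 0, 0, 0), 0)
  expect_equal(jtvae_reconstruction(1, 2, 3, 0), 6)
  expect_error(jtvae_reconstruction(-1, 0, 0, 0), class = "delfrag_loss_error")
})

test_that("training reduces the loss and records a consistent breakdown", {
  m <- tiny_jt_model()
  h <- m$history
  expect_lt(h$total[nrow(h)], h$total[1])
  expect_equal(h$total,
               h$reconstruction + m$spec$beta * h$kl + m$spec$alpha * h$property_se,
               tolerance = 1e-12)
  expect_equal(h$reconstruction, h$topology + h$label, tolerance = 1e-12)
  expect_error(fragment_vae(character(0)), class = "delfrag_invalid_input")
})

test_that("identical config and seed give identical loss trajectories", {
  fx <- fixture_library(200)[1:30]
  m1 <- fragment_vae(fx, variant = "jt", config = tiny_model_config(),
                     epochs = 5, seed = 9)
  m2 <- fragment_vae(fx, variant = "jt", config = tiny_model_config(),
                     epochs = 5, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("encoding is deterministic in the mean and names OOV fragments", {
  m <- tiny_jt_model()
  smis <- m$train_smiles[1:5]
  e1 <- encode(m, smis)
  e2 <- encode(m, smis)
  expect_identical(e1$mean, e2$mean)
  expect_identical(ncol(e1$mean), m$config$latent_size)
  expect_equal(e1$sample, e1$mean + exp(e1$log_variance / 2) * e1$epsilon)
  expect_error(encode(m, "CN1CCC[C@H]1c1cccnc1"), class = "delfrag_oov_error")
  err <- tryCatch(encode(m, "CN1CCC[C@H]1c1cccnc1"), error = function(e) e)
  expect_match(conditionMessage(err), "\\*")  # names the offending cluster
})

test_that("an overfit model reconstructs a memorized training set", {
  fx <- fixture_library(200)[21:30]
  m <- fragment_vae(fx, variant = "jt",
                    config = model_config(16, 64, 16, 1, 1e-2, 5),
                    epochs = 150, seed = 4)
  dec <- decode(m, encode(m, fx)$mean)
  expect_gte(sum(dec == fx), 8)
  expect_identical(decode(m, encode(m, fx)$mean), dec)  # deterministic
})

test_that("guarded junction-tree decoding only ever emits valid molecules", {
  m <- tiny_jt_model()
  s <- sample_prior(m, 200, seed = 31)
  expect_length(s, 200)
  expect_false(anyNA(s))
  expect_equal(validity_ratio(s), 1.0)
  expect_identical(sample_prior(m, 200, seed = 31), s)
  expect_false(identical(sample_prior(m, 200, seed = 32), s))
  expect_identical(sample_prior(m, 0, seed = 1), character(0))
})

test_that("aggregate posterior approaches the prior under the unweighted ELBO", {
  fx <- fixture_library(200)
  m <- fragment_vae(fx, variant = "jt",
                    config = model_config(16, 64, 16, 1, 5e-3, 32,
                                          beta = 1, alpha = 0.1),
                    epochs = 20, seed = 42)
  set.seed(99)
  z <- encode(m, fx)$sample
  pvals <- vapply(seq_len(ncol(z)), function(j) {
    stats::ks.test(z[, j], "pnorm")$p.value
  }, numeric(1))
  # family-wise check at level 0.01 (Bonferroni across coordinates)
  expect_true(all(pvals > 0.01 / length(pvals)))
  expect_gt(stats::median(pvals), 0.05)
})

test_that("fine-tuning anneals the learning rate as base * rate^generation", {
  m <- tiny_jt_model()
  m2 <- finetune(m, m$train_smiles[1:20], epochs = 2, generation = 2,
                 annealing_rate = 0.8)
  h <- m2$history
  expect_equal(utils::tail(h$lr, 1), m$config$learning_rate * 0.8^2)
  expect_equal(0.0001 * 0.8^2, 0.000064)  # the reference schedule
})

test_that("property regularization shrinks the latent property error", {
  fx <- fixture_library(200)[1:60]
  cfg0 <- model_config(16, 64, 16, 1, 5e-3, 16, beta = 0.1, alpha = 0)
  cfg1 <- model_config(16, 64, 16, 1, 5e-3, 16, beta = 0.1, alpha = 0.5)
  m0 <- fragment_vae(fx, variant = "jt", config = cfg0, epochs = 15, seed = 3)
  m1 <- fragment_vae(fx, variant = "jt", config = cfg1, epochs = 15, seed = 3)
  expect_lt(utils::tail(m1$history$property_se, 1),
            utils::tail(m0$history$property_se, 1))
})

test_that("model methods print, predict, simulate and plot", {
  m <- tiny_jt_model()
  expect_output(print(m), "junction-tree")
  expect_output(summary(m), "Loss history")
  expect_true(is.list(coef(m)) && "emb" %in% names(coef(m)))
  z <- predict(m, m$train_smiles[1:3], type = "latent")
  expect_identical(dim(z), c(3L, m$config$latent_size))
  p <- predict(m, m$train_smiles[1:3], type = "properties")
  expect_identical(colnames(p), c("sas", "logp", "bas"))
  expect_identical(simulate(m, nsim = 5, seed = 2), sample_prior(m, 5, seed = 2))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(m); grDevices::dev.off()
  expect_true(file.size(f) > 0)
})

test_that("the unguarded SMILES variant flags rather than raises invalid decodes", {
  fx <- fixture_library(200)[1:40]
  m <- fragment_vae(fx, variant = "smiles", config = tiny_model_config(),
                    epochs = 10, seed = 6)
  set.seed(8)
  z <- matrix(stats::rnorm(50 * m$spec$D, sd = 3), 50)
  dec <- decode(m, z)   # may contain NA, must not error
  expect_length(dec, 50)
  ok <- dec[!is.na(dec)]
  if (length(ok)) expect_true(all(is_valid_smiles(ok)))
})
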