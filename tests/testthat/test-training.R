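test_that("KL weight ramps linearly then plateaus", {
  expect_equal(kl_weight_schedule(0, 300), 0)
  expect_equal(kl_weight_schedule(100, 300), 1e-7)
  expect_equal(kl_weight_schedule(50, 300), 5e-8)
  expect_equal(kl_weight_schedule(299, 300), 1e-7)
  # conventional-ELBO mode is the same ramp with unit plateau
  expect_equal(kl_weight_schedule(30, 90, kl_max_weight = 1), 1)
  expect_error(kl_weight_schedule(-1, 10))
})

test_that("training reduces the loss and is seed-deterministic", {
  sim <- cached("train_sim",
                simulate_sc_dataset(D = 600, V = 120, K = 4, L = 8, seed = 21))
  f1 <- sctopic(sim$data, K = 4, L = 8, hidden = 16, epochs = 25,
                minibatch = 150, seed = 13)
  h <- f1$history
  expect_lt(mean(tail(h$loss, 3)), h$loss[1])
  expect_true(all(is.finite(h$loss)))
  expect_equal(nrow(h), 25)
  f2 <- sctopic(sim$data, K = 4, L = 8, hidden = 16, epochs = 25,
                minibatch = 150, seed = 13)
  expect_equal(f1$history$loss[25], f2$history$loss[25], tolerance = 1e-9)
  expect_identical(f1$params$alpha, f2$params$alpha)
})

test_that("a fixed gene embedding is never updated", {
  sim <- tiny_sim()
  sets <- split(paste0("gene", 1:80), rep(1:8, each = 10))
  names(sets) <- paste0("path", 1:8)
  rho <- build_pathway_rho(sets, sim$data$gene_ids)
  fit <- sctopic(sim$data, K = 4, hidden = 16, epochs = 5, minibatch = 100,
                 rho_fixed = rho, seed = 1)
  expect_identical(fit$params$rho, rho)
  expect_true(fit$params$rho_fixed)
  expect_equal(fit$params$L, 8)
})

test_that("adversarial training validates batches and trains a discriminator", {
  sim <- tiny_sim()
  one_batch <- sc_counts(sim$data$counts, batch = rep(1, 300),
                         cell_type = sim$data$cell_type)
  expect_error(sctopic(one_batch, K = 4, epochs = 2, adversarial = TRUE),
               "at least 2 batches")
  fit <- sctopic(sim$data, K = 4, L = 8, hidden = 16, epochs = 5,
                 minibatch = 100, adversarial = TRUE, seed = 1)
  expect_length(fit$disc$b2, 2)
  expect_true(all(is.finite(fit$history$disc_loss)))
  # discriminator-only updates reduce cross-entropy on fixed embeddings
  set.seed(2)
  delta <- rbind(matrix(rnorm(200, -1), 50), matrix(rnorm(200, 1), 50))
  lab <- rep(1:2, each = 50)
  disc <- sctopic:::.init_discriminator(4, 16, 2)
  st <- sctopic:::.adam_init(disc)
  ce0 <- sctopic:::.disc_ce(disc, delta, lab)$ce
  for (i in 1:50) {
    ce <- sctopic:::.disc_ce(disc, delta, lab)
    up <- sctopic:::.adam_step(disc, ce$grads, st, 0.005)
    disc <- up$params; st <- up$state
  }
  expect_lt(sctopic:::.disc_ce(disc, delta, lab)$ce, ce0)
})

test_that("cell embeddings are deterministic and batch-free", {
  fit <- tiny_fit()
  sim <- tiny_sim()
  e1 <- predict(fit, sim$data)
  e2 <- predict(fit, sim$data)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(300, 4))
  th <- predict(fit, sim$data, type = "theta")
  expect_equal(unname(rowSums(th)), rep(1, 300), tolerance = 1e-9)
  # the batch intercept plays no role in encoding: flipping batch labels
  # leaves the embedding unchanged
  flipped <- sim$data
  flipped$batch <- 3L - flipped$batch
  expect_equal(unname(predict(fit, flipped)), unname(e1))
  # adaptive normalization is deterministic too
  a1 <- predict(fit, sim$data, bn_stats = "dataset")
  expect_identical(a1, predict(fit, sim$data, bn_stats = "dataset"))
  # ... and once the running averages have converged (they lag the batch
  # statistics early in training), the two modes agree on training-like data
  fit40 <- sctopic(sim$data, K = 4, L = 8, hidden = 16, epochs = 40,
                   minibatch = 100, seed = 2)
  expect_gt(cor(as.vector(predict(fit40, sim$data, bn_stats = "dataset")),
                as.vector(predict(fit40, sim$data))), 0.95)
  wrong <- sc_counts(sim$data$counts[, 1:60], gene_ids = sim$data$gene_ids[1:60])
  expect_error(predict(fit, wrong), "genes do not match")
})

test_that("held-out NLL equals log V for a uniform-rate model and is stable", {
  V <- 50
  set.seed(3)
  p <- sctopic:::.init_params(V, 3, 4, 1, 8)
  p$alpha[] <- 0; p$rho[] <- 0; p$lam[] <- 0
  m <- structure(list(params = p, gene_ids = paste0("gene", 1:V),
                      batch_levels = "batch1",
                      config = list(dropout = 0.1,
                                    recon_target = "normalized")),
                 class = "sctopic")
  held <- simulate_cells(simulate_truth(3, 4, V, seed = 4), 40, 200, seed = 5)
  expect_equal(heldout_nll(m, held), log(V), tolerance = 1e-9)
  expect_identical(heldout_nll(m, held), heldout_nll(m, held))
})

test_that("training improves held-out likelihood over a random initialization", {
  sim <- cached("train_sim",
                simulate_sc_dataset(D = 600, V = 120, K = 4, L = 8, seed = 21))
  sp <- holdout_split(sim$data, 0.1, seed = 2)
  fit0 <- sctopic(sp$train, K = 4, L = 8, hidden = 16, epochs = 1,
                  minibatch = 600, seed = 1)   # near-initialization model
  fit1 <- sctopic(sp$train, K = 4, L = 8, hidden = 16, epochs = 40,
                  minibatch = 150, seed = 1)
  expect_lt(heldout_nll(fit1, sp$held), heldout_nll(fit0, sp$held))
})

test_that("checkpoints round-trip bit-exactly", {
  fit <- tiny_fit()
  d <- withr::local_tempdir()
  write_sctopic(fit, d)
  back <- read_sctopic(d)
  expect_identical(back$params$alpha, fit$params$alpha)
  expect_identical(back$params$rho, fit$params$rho)
  expect_identical(back$params$lam, fit$params$lam)
  for (nm in names(fit$params$encoder))
    expect_identical(back$params$encoder[[nm]], fit$params$encoder[[nm]],
                     label = paste("encoder", nm))
  expect_identical(back$gene_ids, fit$gene_ids)
  # a reloaded model predicts identically
  sim <- tiny_sim()
  expect_identical(predict(back, sim$data), predict(fit, sim$data))
  expect_error(read_sctopic(file.path(d, "nope")), "not a checkpoint")
})

test_that("model methods expose the fit coherently", {
  fit <- tiny_fit()
  expect_output(print(fit), "K = 4 topics")
  expect_silent(cf <- coef(fit))
  expect_equal(dim(cf$beta), c(4, 80))
  expect_equal(unname(cf$beta), unname(cf$alpha %*% cf$rho))
  expect_s3_class(logLik(fit), "logLik")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  out <- capture.output(s <- summary(fit))
  expect_true(any(grepl("Top genes", out)))
  simd <- simulate(fit, nsim = 30, seed = 9, library_mean = 200)
  expect_s3_class(simd, "sc_counts")
  expect_equal(dim(simd), c(30, 80))
  res <- residuals(fit, tiny_sim()$data)
  expect_equal(dim(res), c(300, 80))
  expect_true(all(is.finite(res)))
})
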