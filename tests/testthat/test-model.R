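zero_model <- function(V = 6, K = 3, L = 4, S = 2, H = 8) {
  set.seed(1)
  p <- sctopic:::.init_params(V, K, L, S, H)
  p$encoder[c("W1", "b1", "be1", "W2", "b2", "be2",
              "Wmu", "bmu", "Wlv", "blv")] <-
    lapply(p$encoder[c("W1", "b1", "be1", "W2", "b2", "be2",
                       "Wmu", "bmu", "Wlv", "blv")], function(x) x * 0)
  structure(list(params = p, gene_ids = paste0("g", seq_len(V)),
                 batch_levels = as.character(seq_len(S)),
                 config = list(dropout = 0.1, recon_target = "normalized")),
            class = "sctopic")
}

test_that("softmax mixing is stable, shift-invariant and order-preserving", {
  expect_equal(mix_topics(c(0, 0, 0)), rep(1 / 3, 3))
  d <- c(-2, 1, 0.5, 3)
  expect_equal(mix_topics(d), mix_topics(d + 57.3))
  expect_equal(which.max(mix_topics(d)), which.max(d))
  expect_equal(sum(mix_topics(c(1000, -1000, 0))), 1)
})

test_that("a zeroed encoder maps every cell to mu = 0, log_var = 0 in eval mode", {
  m <- zero_model()
  X <- matrix(runif(5 * 6), 5); X <- X / rowSums(X)
  post <- encode_cells(m, X, mode = "eval")
  expect_equal(post$mu, matrix(0, 5, 3))
  expect_equal(post$log_var, matrix(0, 5, 3))
  # eval mode is deterministic
  fit <- tiny_fit()
  X2 <- normalize_profiles(tiny_sim()$data)$profiles
  expect_identical(encode_cells(fit, X2), encode_cells(fit, X2))
  expect_error(encode_cells(fit, cbind(X2, 0)), "genes")
})

test_that("reparameterized draws match the posterior moments", {
  post <- list(mu = matrix(c(1, -2), 1), log_var = matrix(c(-60, -60), 1))
  expect_equal(sample_delta(post, seed = 1), post$mu, tolerance = 1e-10)
  post <- list(mu = matrix(rep(c(0.5, -1), each = 1e5), 1e5),
               log_var = matrix(rep(c(log(0.64), log(2.25)), each = 1e5), 1e5))
  dr <- sample_delta(post, seed = 7)
  sd_true <- c(0.8, 1.5)
  expect_lt(max(abs(colMeans(dr) - c(0.5, -1)) / (sd_true / sqrt(1e5))), 3)
  expect_lt(max(abs(apply(dr, 2, var) / sd_true^2 - 1)), 0.05)
})

test_that("decoded rates form a simplex and obey the intercept structure", {
  m <- zero_model()
  p <- m$params
  p$alpha[] <- 0; p$lam[] <- 0
  r <- decode_rates(c(5, -1, 0), p, 1)
  expect_equal(as.numeric(r), rep(1 / 6, 6))
  # boosting one gene's intercept sends its rate toward 1 monotonically
  rates_for <- function(boost) {
    p2 <- p; p2$lam[1, 3] <- boost
    decode_rates(c(0, 0, 0), p2, 1)[1, 3]
  }
  v <- vapply(c(0, 2, 5, 10), rates_for, 0)
  expect_true(all(diff(v) > 0))
  expect_gt(v[4], 0.99)
  expect_error(decode_rates(c(0, 0, 0), p, 9), "out of range")
  # K = 1: rate is softmax(alpha rho + lam) regardless of theta
  set.seed(2)
  p1 <- sctopic:::.init_params(V = 5, K = 1, L = 3, S = 1, H = 4)
  p1$alpha <- matrix(rnorm(3), 1); p1$rho <- matrix(rnorm(15), 3)
  p1$lam <- matrix(rnorm(5), 1)
  oracle <- exp(p1$alpha %*% p1$rho + p1$lam)
  oracle <- oracle / sum(oracle)
  expect_equal(as.numeric(decode_rates(1, p1, 1)), as.numeric(oracle),
               tolerance = 1e-12)
  # without the intercept, rates ignore the batch index
  p$use_batch_intercept <- FALSE
  p$lam[2, ] <- rnorm(6)
  expect_equal(decode_rates(c(1, 0, 2), p, 1), decode_rates(c(1, 0, 2), p, 2))
  # simplex property on random inputs
  set.seed(3)
  r <- decode_rates(matrix(rnorm(30), 10), m$params, sample(1:2, 10, TRUE))
  expect_equal(rowSums(r), rep(1, 10), tolerance = 1e-9)
  expect_gte(min(r), 0)
})

test_that("reconstruction log-likelihood matches elementwise oracle and bounds", {
  V <- 7
  expect_equal(reconstruction_loglik(rep(1 / V, V), rep(1 / V, V)), -log(V))
  r <- mix_topics(rnorm(V))
  e3 <- replace(numeric(V), 3, 1)
  expect_equal(reconstruction_loglik(e3, r), log(r[3]))
  set.seed(4)
  t <- abs(rnorm(V)); r <- mix_topics(rnorm(V))
  expect_equal(reconstruction_loglik(t, r), sum(t * log(r)),
               tolerance = 1e-12)
  # Gibbs inequality: cross-entropy >= entropy of the target
  for (i in 1:20) {
    t <- mix_topics(rnorm(V))
    r <- mix_topics(rnorm(V))
    expect_gte(-reconstruction_loglik(t, r), -sum(t * log(t)) - 1e-12)
  }
  expect_warning(reconstruction_loglik(c(1, 1), c(1, 0)), "underflow")
})

test_that("closed-form KL matches known values and a Monte-Carlo oracle", {
  expect_equal(kl_normal(list(mu = rep(0, 4), log_var = rep(0, 4))), 0)
  expect_equal(kl_normal(list(mu = 1, log_var = 0)), 0.5)
  set.seed(5)
  for (i in 1:5) {
    mu <- rnorm(2, sd = 0.7); lv <- rnorm(2, sd = 0.4)
    kl <- kl_normal(list(mu = mu, log_var = lv))
    expect_gte(kl, 0)
    z <- matrix(rnorm(2e5), 1e5) %*% diag(exp(lv / 2))
    z <- sweep(z, 2, mu, "+")
    logq <- -0.5 * rowSums(sweep(z, 2, mu, "-")^2 %*% diag(exp(-lv))) -
      0.5 * sum(lv) - log(2 * pi)
    logp <- -0.5 * rowSums(z^2) - log(2 * pi)
    expect_lt(abs(kl - mean(logq - logp)), 0.01)
  }
})

test_that("topic-gene scores are the product of the two embeddings", {
  p <- list(alpha = rbind(c(1, 2), c(0, 0)), rho = rbind(c(3, 0, 1), c(1, 1, 0)),
            K = 2, L = 2, V = 3)
  beta <- topic_gene_matrix(p)
  expect_equal(unname(beta), rbind(c(5, 2, 1), c(0, 0, 0)))
  set.seed(6)
  p2 <- list(alpha = matrix(rnorm(12), 6), rho = matrix(rnorm(16), 2))
  expect_lte(qr(topic_gene_matrix(p2))$rank, 2)
})

test_that("pathway gene embedding is standardized binary membership", {
  sets <- list(s1 = c("a", "b"), s2 = c("b", "c"))
  genes <- c("a", "b", "c", "d")
  rho <- build_pathway_rho(sets, genes)
  expect_equal(dim(rho), c(2, 4))
  expect_equal(unname(colMeans(rho)), rep(0, 4))
  # gene in no set -> zero column; membership column b has zero variance too
  expect_equal(unname(rho[, "d"]), c(0, 0))
  expect_equal(unname(rho[, "b"]), c(0, 0))
  sds <- apply(rho, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_true(all(abs(sds[c("a", "c")] - 1) < 1e-12))
  expect_error(build_pathway_rho(list(s = "zz"), genes), "no gene overlaps")
})

test_that("discriminator cross-entropy matches hand computation", {
  disc <- sctopic:::.init_discriminator(3, 4, 2)
  disc$W1[] <- 0; disc$W2[] <- 0; disc$b1[] <- 0; disc$b2[] <- 0
  X <- matrix(rnorm(6), 2)
  expect_equal(discriminator_loss(X, c(1L, 2L), disc), log(2))
  # near-one-hot logits -> loss near 0
  disc$b2 <- c(50, -50)
  expect_lt(discriminator_loss(X, c(1L, 1L), disc), 1e-10)
  # manual two-cell oracle with random weights
  set.seed(7)
  disc <- sctopic:::.init_discriminator(3, 4, 2)
  lab <- c(2L, 1L)
  fw <- sctopic:::.disc_forward(disc, X)
  pr <- t(apply(fw$logits, 1, function(z) exp(z - max(z)) / sum(exp(z - max(z)))))
  expect_equal(discriminator_loss(X, lab, disc),
               -mean(log(pr[cbind(1:2, lab)])), tolerance = 1e-12)
  expect_error(discriminator_loss(X, c(1L, 3L), disc), "out of range")
})

test_that("analytic gradients match finite differences on a toy batch", {
  # deterministic loss: no dropout, fixed reparameterization noise
  set.seed(8)
  V <- 6; K <- 3; L <- 4; S <- 2; H <- 5; B <- 4
  p <- sctopic:::.init_params(V, K, L, S, H)
  X <- matrix(rexp(B * V), B); X <- X / rowSums(X)
  bi <- c(1L, 2L, 1L, 2L)
  eps <- matrix(rnorm(B * K), B)
  w <- 0.3
  loss_fn <- function(p) {
    fw <- sctopic:::.encoder_forward(p$encoder, X, train = TRUE, dropout = 0)
    delta <- fw$mu + exp(fw$lv / 2) * eps
    Theta <- softmax_rows(delta)
    eta <- Theta %*% p$alpha %*% p$rho + p$lam[bi, ]
    R <- softmax_rows(eta)
    recon <- rowSums(X * log(pmax(R, 1e-30)))
    klv <- 0.5 * rowSums(fw$mu^2 + exp(fw$lv) - fw$lv - 1)
    mean(-recon + w * klv)
  }
  # analytic gradients via the package's backward pass
  fw <- sctopic:::.encoder_forward(p$encoder, X, train = TRUE, dropout = 0)
  sig <- exp(fw$lv / 2)
  delta <- fw$mu + sig * eps
  Theta <- softmax_rows(delta)
  M <- p$alpha %*% p$rho
  R <- softmax_rows(Theta %*% M + p$lam[bi, ])
  G <- (rowSums(X) * R - X) / B
  gTheta <- tcrossprod(G, M)
  gM <- crossprod(Theta, G)
  galpha <- tcrossprod(gM, p$rho)
  grho <- crossprod(p$alpha, gM)
  glam <- matrix(0, S, V)
  agg <- rowsum(G, bi); glam[as.integer(rownames(agg)), ] <- agg
  gdelta <- Theta * (gTheta - rowSums(gTheta * Theta))
  gmu <- gdelta + w * fw$mu / B
  glv <- gdelta * eps * 0.5 * sig + w * 0.5 * (exp(fw$lv) - 1) / B
  genc <- sctopic:::.encoder_backward(p$encoder, fw$cache, gmu, glv)
  num_grad <- function(get, set, analytic, n_probe = 6) {
    vals <- get(p)
    set.seed(9)
    probes <- sample(length(vals), min(n_probe, length(vals)))
    h <- 1e-5
    for (ix in probes) {
      pp <- p; vp <- vals; vp[ix] <- vp[ix] + h; pp <- set(pp, vp)
      pm <- p; vm <- vals; vm[ix] <- vm[ix] - h; pm <- set(pm, vm)
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      expect_lt(abs(analytic[ix] - fd), 1e-6 + 1e-4 * abs(fd))
    }
  }
  num_grad(function(p) p$alpha, function(p, v) { p$alpha[] <- v; p }, galpha)
  num_grad(function(p) p$rho, function(p, v) { p$rho[] <- v; p }, grho)
  num_grad(function(p) p$lam, function(p, v) { p$lam[] <- v; p }, glam)
  for (nm in c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2",
               "Wmu", "bmu", "Wlv", "blv")) {
    num_grad(function(p) p$encoder[[nm]],
             function(p, v) { p$encoder[[nm]][] <- v; p }, genc[[nm]],
             n_probe = 4)
  }
})
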