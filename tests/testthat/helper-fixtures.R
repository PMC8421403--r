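# Shared fixtures and independent oracles. Expensive fits used by several
# acceptance checks are built lazily once per test run and cached here.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

# ---- study conditions for the recovery / ablation / transfer experiments ----
# 3000 cells x 500 genes, 8 planted topics, 2 batches with unit-scale
# intercepts; models trained 300 epochs (K = 8, L = 32, H = 64) with
# minibatch 250 (~3.6k steps, inside the typical convergence range).

acc_sim <- function() cached("acc_sim", simulate_sc_dataset(seed = 11L))

acc_fit <- function(kind = c("full", "nolam", "adv")) {
  kind <- match.arg(kind)
  cached(paste0("acc_fit_", kind), {
    sim <- acc_sim()
    sctopic(sim$data, K = 8, L = 32, hidden = 64, epochs = 300,
            minibatch = 250, seed = 4,
            batch_intercept = (kind != "nolam"),
            adversarial = (kind == "adv"))
  })
}

acc_metrics <- function(kind) {
  cached(paste0("acc_metrics_", kind), {
    sim <- acc_sim()
    emb <- predict(acc_fit(kind), sim$data)
    list(ari = leiden_sweep(emb, attr(sim$data, "cluster"), seed = 1)$ari,
         kbet = as.numeric(kbet(emb, sim$data$batch, seed = 1)))
  })
}

# zero-shot transfer target: a fresh draw from the same truth with redrawn
# batch intercepts (same alpha/rho/cluster structure, new lambda)
acc_transfer_target <- function() {
  cached("acc_transfer_target", {
    truth <- acc_sim()$truth
    truth2 <- simulate_truth(truth$K, truth$L, truth$V, truth$S, truth$C,
                             truth$topic_separation, truth$batch_scale,
                             seed = 99L, rho = truth$rho,
                             alpha = truth$alpha)
    simulate_cells(truth2, D = 3000L, seed = 100L)
  })
}

# pathway-informed recovery experiment: data generated from a fixed
# pathways-by-genes gene embedding with one dominant pathway per topic
pathway_recovery_setup <- function() {
  cached("pathway_recovery_setup", {
    K <- 8L; P <- 16L; V <- 500L
    genes <- paste0("gene", seq_len(V))
    sets <- lapply(seq_len(P), function(i)
      genes[((i - 1L) * 25L + 1L):(i * 25L)])
    names(sets) <- paste0("path", seq_len(P))
    rho_fixed <- build_pathway_rho(sets, genes)
    set.seed(41)
    alpha_true <- matrix(rnorm(K * P, sd = 0.05), K, P)
    alpha_true[cbind(seq_len(K), seq_len(K))] <- 1
    truth <- simulate_truth(K = K, L = P, V = V, S = 1L, C = K,
                            topic_separation = 4, batch_scale = 0,
                            seed = 42L, rho = rho_fixed, alpha = alpha_true)
    data <- simulate_cells(truth, D = 3000L, seed = 43L)
    list(truth = truth, data = data, rho_fixed = rho_fixed, K = K)
  })
}

pathway_recovery_fit <- function() {
  cached("pathway_recovery_fit", {
    s <- pathway_recovery_setup()
    sctopic(s$data, K = s$K, hidden = 64, epochs = 300, minibatch = 250,
            rho_fixed = s$rho_fixed, seed = 44L)
  })
}

# fraction of planted cell types whose dominant fitted topic ranks the
# generating pathway among its top-5 topic-embedding scores
pathway_recovery_rate <- function(fit, setup) {
  theta <- predict(fit, setup$data, type = "theta")
  cl <- attr(setup$data, "cluster")
  rep5 <- pathway_topic_report(fit, top_n = 5)
  hits <- vapply(seq_len(setup$K), function(c) {
    dom <- which.max(colMeans(theta[cl == c, , drop = FALSE]))
    paste0("path", c) %in% rep5$pathway[rep5$topic == dom]
  }, TRUE)
  mean(hits)
}

# quick low-cost fit for interface-level tests
tiny_sim <- function() cached("tiny_sim",
  simulate_sc_dataset(D = 300L, V = 80L, K = 4L, L = 8L, S = 2L, seed = 5L))

tiny_fit <- function() cached("tiny_fit", {
  sctopic(tiny_sim()$data, K = 4, L = 8, hidden = 16, epochs = 8,
          minibatch = 100, seed = 2)
})

# ---- independent oracles ----

# pair-counting ARI over all C(n,2) pairs
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1 else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1 else s01 <- s01 + 1
  }
  total <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / total
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# entropy-based NMI with arithmetic-mean normalization
brute_nmi <- function(a, b) {
  n <- length(a)
  h <- function(x) {
    p <- table(x) / n
    -sum(p * log(p))
  }
  tab <- table(a, b) / n
  mi <- 0
  pa <- rowSums(tab); pb <- colSums(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  unname(mi / ((h(a) + h(b)) / 2))
}

# exhaustive GSEA running sum evaluated at every index
brute_es <- function(scores, genes, set, classic = FALSE) {
  o <- order(-scores, genes, method = "radix")
  s <- abs(scores[o]); g <- genes[o]
  hit <- g %in% set
  V <- length(s)
  best <- -Inf
  for (i in seq_len(V)) {
    ph <- sum(s[seq_len(i)][hit[seq_len(i)]]) / sum(s[hit])
    pm <- if (classic) sum(!hit[seq_len(i)]) / sum(!hit) else
      sum(s[seq_len(i)][!hit[seq_len(i)]]) / sum(s[!hit])
    if (ph - pm > best) best <- ph - pm
  }
  best
}

# BH step-up computed literally from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# silhouette widths from the definition (Euclidean)
brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- as.matrix(dist(X))
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
}
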