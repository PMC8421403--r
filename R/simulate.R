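# Simulator for the model's own generative process, extended with planted
# cell-type clusters (Gaussian-mixture means on delta) and batch intercepts
# so that recovery, ablation and transfer behaviour can be tested without
# any external dataset. With topic_separation = 0 and batch_scale = 0 it
# reduces exactly to the generative process the model assumes
# (delta ~ N(0, I), theta = softmax(delta), rates = softmax(theta alpha rho),
# counts ~ Multinomial).

#' Ground-truth parameters for a synthetic dataset
#'
#' Draws decoder parameters and planted-cluster means. `alpha` is scaled by
#' `1/sqrt(L)` so the rows of `beta = alpha %*% rho` have approximately unit
#' variance regardless of the embedding dimension; cluster separation is
#' then governed solely by `topic_separation`. Cluster `c` gets mean
#' `topic_separation * e_c` on `delta` (one-hot on topic `c`, cycling if
#' `C > K`), so each planted cell type expresses predominantly one topic.
#'
#' @param K,L,V,S topics, embedding dimension, genes, batches.
#' @param C number of planted cell-type clusters (recommended `C <= K`).
#' @param topic_separation scale of the planted cluster means on `delta`
#'   (0 = unclustered null; default 4, i.e. a dominant-topic proportion of
#'   about 0.9 at K = 8).
#' @param batch_scale sd of the batch intercepts `lambda` (0 = no batch
#'   effect).
#' @param seed integer seed.
#' @param rho optional fixed gene-embedding matrix (L x V), e.g. from
#'   [build_pathway_rho()]; when supplied only `alpha`, `lambda` and the
#'   cluster means are drawn.
#' @param alpha optional fixed topic-embedding matrix (K x L).
#' @return an object of class `sc_truth`: list with `alpha`, `rho`, `lam`,
#'   `cluster_means` (C x K), dims, and the arguments used.
#' @export
simulate_truth <- function(K, L, V, S = 1L, C = K, topic_separation = 4,
                           batch_scale = 0, seed = 1L, rho = NULL,
                           alpha = NULL) {
  stopifnot(K >= 1, V >= 1, S >= 1, C >= 1)
  set.seed(seed)
  if (is.null(rho)) rho <- matrix(stats::rnorm(L * V), L, V)
  L <- nrow(rho)
  if (is.null(alpha)) alpha <- matrix(stats::rnorm(K * L) / sqrt(L), K, L)
  lam <- matrix(stats::rnorm(S * V, sd = batch_scale), S, V)
  if (batch_scale == 0) lam[] <- 0
  cm <- matrix(0, C, K)
  for (c in seq_len(C)) cm[c, ((c - 1L) %% K) + 1L] <- topic_separation
  structure(list(alpha = alpha, rho = rho, lam = lam, cluster_means = cm,
                 K = K, L = L, V = V, S = S, C = C,
                 topic_separation = topic_separation,
                 batch_scale = batch_scale, seed = seed),
            class = "sc_truth")
}

#' Draw cells from a synthetic truth
#'
#' For each cell: cluster and batch uniform, `delta ~ N(cluster_mean, I)`,
#' `theta = softmax(delta)`, rates
#' `softmax(theta %*% alpha %*% rho + lambda[batch, ])`, library size
#' `N ~ Poisson(library_mean)` (floored at 1), counts
#' `Multinomial(N, rates)`.
#'
#' @param truth an `sc_truth` from [simulate_truth()].
#' @param D number of cells.
#' @param library_mean mean library size (default 1500).
#' @param seed integer seed.
#' @return an [sc_counts] object whose `cell_type` holds the planted
#'   cluster labels (`"type1"`, ...), with attribute `truth_delta` (D x K
#'   true latent activities) and `cluster` (integer labels).
#' @export
simulate_cells <- function(truth, D, library_mean = 1500, seed = 1L) {
  stopifnot(inherits(truth, "sc_truth"), D >= 1, library_mean > 0)
  set.seed(seed)
  cl <- sample.int(truth$C, D, replace = TRUE)
  bi <- sample.int(truth$S, D, replace = TRUE)
  delta <- truth$cluster_means[cl, , drop = FALSE] +
    matrix(stats::rnorm(D * truth$K), D)
  theta <- softmax_rows(delta)
  eta <- theta %*% truth$alpha %*% truth$rho + truth$lam[bi, , drop = FALSE]
  R <- softmax_rows(eta)
  n <- pmax(stats::rpois(D, library_mean), 1L)
  counts <- matrix(0L, D, truth$V)
  for (i in seq_len(D))
    counts[i, ] <- stats::rmultinom(1L, n[i], R[i, ])[, 1L]
  out <- sc_counts(counts, gene_ids = paste0("gene", seq_len(truth$V)),
                   cell_ids = paste0("cell", seq_len(D)),
                   batch = paste0("batch", bi),
                   cell_type = paste0("type", cl))
  # keep batch codes aligned with the truth's lambda rows (sc_counts encodes
  # by first appearance, which would permute them)
  out$batch <- bi
  out$batch_levels <- paste0("batch", seq_len(truth$S))
  attr(out, "truth_delta") <- delta
  attr(out, "cluster") <- cl
  out
}

#' Planted and null gene sets for enrichment testing
#'
#' For each requested topic, the set of its `set_size` top-scoring genes
#' under `beta = alpha %*% rho` (a maximally enriched "planted" set), plus
#' `n_null_sets` gene sets drawn uniformly without replacement.
#'
#' @param truth an `sc_truth`.
#' @param topics integer topic indices to plant sets for.
#' @param set_size genes per set (>= 5).
#' @param n_null_sets number of random control sets.
#' @param seed integer seed.
#' @return named list of gene-symbol vectors (`planted_topic<k>` and
#'   `null<i>`), as accepted by [gsea_topics()].
#' @export
simulate_gene_sets <- function(truth, topics = seq_len(truth$K),
                               set_size = 25L, n_null_sets = 10L,
                               seed = 1L) {
  stopifnot(set_size >= 5L, set_size <= truth$V)
  set.seed(seed)
  beta <- truth$alpha %*% truth$rho
  genes <- paste0("gene", seq_len(truth$V))
  sets <- list()
  for (k in topics)
    sets[[paste0("planted_topic", k)]] <-
      genes[order(-beta[k, ])[seq_len(set_size)]]
  for (i in seq_len(n_null_sets))
    sets[[paste0("null", i)]] <- sample(genes, set_size)
  sets
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: [simulate_truth()] + [simulate_cells()] +
#' [simulate_gene_sets()], with per-stage seeds derived from one master
#' seed.
#'
#' @param D,V,K,L,S,C dataset dimensions (defaults: 3000 cells, 500 genes,
#'   8 topics, embedding 32, 2 batches, one cluster per topic).
#' @param topic_separation,batch_scale,library_mean see [simulate_truth()]
#'   and [simulate_cells()].
#' @param seed master seed.
#' @return list with `truth`, `data` (an [sc_counts]) and `gene_sets`.
#' @export
simulate_sc_dataset <- function(D = 3000L, V = 500L, K = 8L, L = 32L,
                                S = 2L, C = K, topic_separation = 4,
                                batch_scale = 1, library_mean = 1500,
                                seed = 1L) {
  truth <- simulate_truth(K, L, V, S, C, topic_separation, batch_scale,
                          seed = .derive_seed(seed, 1L))
  data <- simulate_cells(truth, D, library_mean,
                         seed = .derive_seed(seed, 2L))
  sets <- simulate_gene_sets(truth, seed = .derive_seed(seed, 3L))
  list(truth = truth, data = data, gene_sets = sets)
}
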