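# Clustering and batch-mixing evaluation: ARI (via mclust), NMI
# (arithmetic-mean normalization), the kBET-style chi-square neighborhood
# test, average silhouette width (via cluster::silhouette), and a Leiden
# resolution sweep on a kNN graph.

#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement between two partitions
#' (Hubert-Arabie form). Symmetric and invariant to label renaming;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) .stopf("label vectors differ in length")
  if (length(a) < 2L) .stopf("need at least 2 observations")
  mclust::adjustedRandIndex(a, b)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their entropies, `I(a; b) / ((H(a) + H(b)) / 2)`. Two identical
#' single-cluster partitions (both entropies zero) return 1 by convention.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) .stopf("label vectors differ in length")
  n <- length(a)
  tab <- table(a, b)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  pjk <- tab / n
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / outer(pj, pk)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pj) + h(pk)) / 2
  if (denom == 0) return(1)
  mi / denom
}

# squared Euclidean distances from rows of A to rows of B
.sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' kBET-style batch-mixing acceptance rate
#'
#' For randomly sampled cells, compares the batch composition of the k
#' nearest neighbors (Euclidean, excluding the cell itself) against the
#' global batch proportions with a Pearson chi-square test on `S - 1`
#' degrees of freedom. The acceptance rate is the fraction of tested
#' neighborhoods with `p > alpha`; near `1 - alpha` for perfectly mixed
#' batches, near 0 when batches separate in the embedding.
#'
#' @param embeddings cells x d numeric matrix.
#' @param batch per-cell batch labels (>= 2 distinct values).
#' @param k neighborhood size (default 15).
#' @param alpha test level (default 0.05).
#' @param n_test number of cells to test (default 500; capped at the number
#'   of cells).
#' @param seed integer seed for the cell sample.
#' @return scalar acceptance rate in `[0, 1]`, with attribute `pvals`.
#' @export
kbet <- function(embeddings, batch, k = 15L, alpha = 0.05, n_test = 500L,
                 seed = 1L) {
  embeddings <- as.matrix(embeddings)
  d <- nrow(embeddings)
  batch <- as.integer(factor(batch))
  S <- max(batch)
  if (S < 2L) .stopf("kbet needs at least 2 batches")
  if (k >= d) .stopf("k must be smaller than the number of cells")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_idx <- sample.int(d, min(n_test, d))
  glob <- tabulate(batch, S) / d
  pv <- numeric(length(test_idx))
  block <- 256L
  for (s0 in seq(1L, length(test_idx), by = block)) {
    ii <- test_idx[s0:min(s0 + block - 1L, length(test_idx))]
    d2 <- .sqdist(embeddings[ii, , drop = FALSE], embeddings)
    for (j in seq_along(ii)) {
      ord <- order(d2[j, ])
      nb <- setdiff(ord, ii[j])[seq_len(k)]
      obs <- tabulate(batch[nb], S)
      expd <- pmax(k * glob, 1e-12)
      stat <- sum((obs - expd)^2 / expd)
      pv[s0 + j - 1L] <- stats::pchisq(stat, df = S - 1, lower.tail = FALSE)
    }
  }
  structure(mean(pv > alpha), pvals = pv)
}

#' Average silhouette width
#'
#' Mean silhouette (cohesion vs nearest-other-cluster separation,
#' normalized by the larger of the two; Euclidean distance) of an embedding
#' under given labels, optionally averaged only over cells carrying one
#' label.
#'
#' @param embeddings cells x d numeric matrix.
#' @param labels per-cell labels (>= 2 distinct values overall).
#' @param restrict_to optional single label: average only those cells'
#'   silhouettes (computed against all cells).
#' @return scalar in `[-1, 1]`.
#' @export
asw <- function(embeddings, labels, restrict_to = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) .stopf("asw needs at least 2 labels")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(as.matrix(embeddings)))
  widths <- sil[, "sil_width"]
  if (is.null(restrict_to)) return(mean(widths))
  sel <- labels == restrict_to
  if (!any(sel)) .stopf("no cell carries label '%s'", restrict_to)
  mean(widths[sel])
}

# undirected kNN graph (Euclidean); block-wise distance computation
.knn_graph <- function(embeddings, k = 15L) {
  d <- nrow(embeddings)
  k <- min(k, d - 1L)
  edges <- matrix(0L, d * k, 2L)
  row <- 1L
  block <- 512L
  for (s0 in seq(1L, d, by = block)) {
    ii <- s0:min(s0 + block - 1L, d)
    d2 <- .sqdist(embeddings[ii, , drop = FALSE], embeddings)
    for (j in seq_along(ii)) {
      i <- ii[j]
      nb <- order(d2[j, ])
      nb <- nb[nb != i][seq_len(k)]
      edges[row:(row + k - 1L), ] <- cbind(i, nb)
      row <- row + k
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Leiden clustering with a resolution sweep
#'
#' Builds a k-nearest-neighbor graph on the embedding (Euclidean,
#' unweighted), runs Leiden community detection (modularity objective) at
#' each resolution, and returns the clustering with the highest ARI against
#' the reference labels; ties go to the smallest resolution.
#'
#' @param embeddings cells x d numeric matrix.
#' @param truth_labels reference labels for ARI selection.
#' @param resolutions numeric vector of resolution parameters.
#' @param knn neighborhood size for the graph (default 15).
#' @param seed integer seed (Leiden refinement is stochastic).
#' @return list with `membership`, `ari`, `resolution`, and `ari_by_resolution`.
#' @export
leiden_sweep <- function(embeddings, truth_labels,
                         resolutions = c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2),
                         knn = 15L, seed = 1L) {
  if (!length(resolutions)) .stopf("resolutions must be non-empty")
  g <- .knn_graph(as.matrix(embeddings), knn)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  best <- list(ari = -Inf)
  all_ari <- setNames(numeric(length(resolutions)),
                      format(resolutions))
  for (ri in seq_along(resolutions)) {
    r <- resolutions[ri]
    set.seed(seed)
    cm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = r, n_iterations = 3L)
    memb <- igraph::membership(cm)
    a <- ari(memb, truth_labels)
    all_ari[ri] <- a
    if (a > best$ari)       # strict: ties keep the smallest resolution
      best <- list(membership = as.integer(memb), ari = a, resolution = r)
  }
  best$ari_by_resolution <- all_ari
  best
}

#' Clustering and batch-mixing report for an embedding
#'
#' One-call evaluation: Leiden-sweep ARI and NMI against cell-type labels,
#' kBET acceptance against batch labels, and average silhouette width.
#'
#' @param embeddings cells x d numeric matrix (e.g. `predict(fit, data)`).
#' @param cell_type per-cell reference labels (optional).
#' @param batch per-cell batch labels (optional; needs >= 2 batches for
#'   kBET).
#' @param resolutions,knn,kbet_k,n_test,seed tuning knobs passed through.
#' @return list of class `sc_metrics` with elements `ari`, `nmi`,
#'   `best_resolution`, `kbet_acceptance`, `asw` (NA where not computable).
#' @export
evaluate_embeddings <- function(embeddings, cell_type = NULL, batch = NULL,
                                resolutions = c(0.1, 0.25, 0.5, 0.75, 1,
                                                1.5, 2),
                                knn = 15L, kbet_k = 15L, n_test = 500L,
                                seed = 1L) {
  out <- list(ari = NA_real_, nmi = NA_real_, best_resolution = NA_real_,
              kbet_acceptance = NA_real_, asw = NA_real_)
  if (!is.null(cell_type)) {
    sw <- leiden_sweep(embeddings, cell_type, resolutions, knn, seed)
    out$ari <- sw$ari
    out$nmi <- nmi(sw$membership, cell_type)
    out$best_resolution <- sw$resolution
    out$asw <- asw(embeddings, cell_type)
  }
  if (!is.null(batch) && length(unique(batch)) >= 2L)
    out$kbet_acceptance <- as.numeric(kbet(embeddings, batch, k = kbet_k,
                                           n_test = n_test, seed = seed))
  class(out) <- "sc_metrics"
  out
}

#' @export
print.sc_metrics <- function(x, ...) {
  cat(sprintf(
    "ARI %.3f | NMI %.3f | kBET acceptance %.3f | ASW %.3f (Leiden res %s)\n",
    x$ari, x$nmi, x$kbet_acceptance, x$asw,
    format(x$best_resolution)))
  invisible(x)
}
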