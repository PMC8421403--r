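# Topic interpretation: ranked topic-gene scores, weighted GSEA with a
# gene-shuffle permutation null, BH correction, and per-topic pathway
# reports for pathway-informed fits.

#' Rank genes by topic score
#'
#' Stable descending sort of one topic's gene scores; ties are broken by
#' gene identifier in C-locale lexicographic order, so the ranking is
#' independent of input order.
#'
#' @param scores numeric vector of gene scores (one row of
#'   [topic_gene_matrix()]).
#' @param gene_ids character vector of the same length.
#' @return data.frame with columns `gene` and `score`, sorted.
#' @export
rank_genes <- function(scores, gene_ids) {
  stopifnot(length(scores) == length(gene_ids))
  o <- order(-scores, gene_ids, method = "radix")
  data.frame(gene = gene_ids[o], score = scores[o],
             stringsAsFactors = FALSE)
}

#' Enrichment score of a gene set on a ranked list
#'
#' Walks down the score-ranked gene list accumulating
#' `P_hit(i)` — the fraction of the set's total (absolute) score mass seen
#' up to position `i` — and `P_miss(i)`, the same for genes outside the set
#' (also score-weighted; set `classic = TRUE` for the unweighted
#' equal-step miss convention). The enrichment score is
#' `ES = max_i (P_hit(i) - P_miss(i))`, the signed one-sided maximum; the
#' leading edge is the set genes at or before the argmax.
#'
#' @param ranked data.frame from [rank_genes()] (columns `gene`, `score`).
#' @param set character vector of gene symbols.
#' @param classic use unweighted misses (each miss steps `1/(V - m)`).
#' @return list with `es`, `leading_edge` and the argmax `position`.
#' @export
gsea_es <- function(ranked, set, classic = FALSE) {
  h <- ranked$gene %in% set
  if (!any(h)) .stopf("gene set has no overlap with the ranked list")
  if (all(h)) .stopf("gene set covers the whole ranked list; P_miss undefined")
  w <- abs(ranked$score)
  .es_from_hits(w, h, classic, genes = ranked$gene)
}

# core running-sum; `h` logical hit indicator over the sorted positions
.es_from_hits <- function(w, h, classic = FALSE, genes = NULL) {
  wh <- sum(w[h])
  p_hit <- if (wh > 0) cumsum(w * h) / wh else cumsum(h) / sum(h)
  if (classic) {
    p_miss <- cumsum(!h) / sum(!h)
  } else {
    wm <- sum(w[!h])
    p_miss <- if (wm > 0) cumsum(w * (!h)) / wm else cumsum(!h) / sum(!h)
  }
  diff <- p_hit - p_miss
  pos <- which.max(diff)
  list(es = diff[pos], position = pos,
       leading_edge = if (is.null(genes)) NULL else
         genes[seq_len(pos)][h[seq_len(pos)]])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} m p_(j) / j`, capped at 1),
#' stable with respect to input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Weighted GSEA over topics with a gene-shuffle permutation null
#'
#' For each topic, ranks genes by their topic score, computes the observed
#' enrichment score of every gene set, and builds a null by shuffling the
#' gene symbols over the (fixed, sorted) score list `n_perm` times. The
#' empirical p-value is `(N' + 1) / (N + 1)` where `N'` counts null
#' enrichment scores strictly greater than the observed one; q-values are
#' BH-adjusted across the sets tested within each topic.
#'
#' @param object a fitted [sctopic] model, or a topics x genes score matrix
#'   with gene ids as column names.
#' @param gene_sets named list of gene-symbol vectors ([read_gmt()] or
#'   [simulate_gene_sets()]).
#' @param topics integer topic indices (default: all).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param classic unweighted-miss convention (see [gsea_es()]).
#' @param bh_family `"per_topic"` (default) adjusts within each topic;
#'   `"global"` across all (topic, set) pairs.
#' @return data.frame of class `sc_gsea` with columns `topic`, `set`, `es`,
#'   `p`, `q`, `leading_edge` (comma-joined); the per-topic null ES draws
#'   are kept in `attr(, "null_es")` (a list of `n_perm` x sets matrices).
#' @export
gsea_topics <- function(object, gene_sets, topics = NULL, n_perm = 1000L,
                        seed = 1L, classic = FALSE,
                        bh_family = c("per_topic", "global")) {
  bh_family <- match.arg(bh_family)
  beta <- if (inherits(object, "sctopic")) topic_gene_matrix(object) else
    as.matrix(object)
  gene_ids <- colnames(beta)
  if (is.null(gene_ids)) .stopf("score matrix needs gene ids as column names")
  if (is.null(topics)) topics <- seq_len(nrow(beta))
  sizes <- vapply(gene_sets, function(s) sum(gene_ids %in% s), 1L)
  usable <- sizes > 0 & sizes < length(gene_ids)
  if (!all(usable))
    .warnf("skipping %d gene set(s) with empty or full overlap",
           sum(!usable))
  gene_sets <- gene_sets[usable]
  if (!length(gene_sets)) .stopf("no usable gene set")
  sizes <- sizes[usable]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  V <- length(gene_ids)
  rows <- list(); nulls <- list()
  for (k in topics) {
    ranked <- rank_genes(beta[k, ], gene_ids)
    w <- abs(ranked$score)
    obs <- lapply(gene_sets, function(s) gsea_es(ranked, s, classic))
    # null ES depends only on the set size once symbols are shuffled
    null_by_size <- list()
    for (m in unique(sizes)) {
      es <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        h <- logical(V)
        h[sample.int(V, m)] <- TRUE
        es[b] <- .es_from_hits(w, h, classic)$es
      }
      null_by_size[[as.character(m)]] <- es
    }
    null_mat <- vapply(as.character(sizes), function(m) null_by_size[[m]],
                       numeric(n_perm))
    colnames(null_mat) <- names(gene_sets)
    es_obs <- vapply(obs, `[[`, 0, "es")
    p <- (colSums(null_mat > matrix(es_obs, n_perm, length(es_obs),
                                    byrow = TRUE)) + 1) / (n_perm + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      topic = k, set = names(gene_sets), es = es_obs, p = p,
      leading_edge = vapply(obs, function(o)
        paste(o$leading_edge, collapse = ","), ""),
      stringsAsFactors = FALSE, row.names = NULL)
    nulls[[as.character(k)]] <- null_mat
  }
  res <- do.call(rbind, rows)
  res$q <- if (bh_family == "per_topic")
    stats::ave(res$p, res$topic, FUN = bh_adjust) else bh_adjust(res$p)
  res <- res[, c("topic", "set", "es", "p", "q", "leading_edge")]
  attr(res, "null_es") <- nulls
  class(res) <- c("sc_gsea", "data.frame")
  res
}

#' Top-scoring genes of a topic
#'
#' @param object a fitted [sctopic] model or a topics x genes score matrix
#'   with gene-id column names.
#' @param topic topic index.
#' @param n number of genes (default 10).
#' @return character vector: the first `n` genes of [rank_genes()].
#' @export
top_genes <- function(object, topic, n = 10L) {
  beta <- if (inherits(object, "sctopic")) topic_gene_matrix(object) else
    as.matrix(object)
  if (n > ncol(beta)) .stopf("n exceeds the number of genes")
  rank_genes(beta[topic, ], colnames(beta))$gene[seq_len(n)]
}

#' Per-topic top pathways of a pathway-informed fit
#'
#' For a model fitted with a fixed pathways-by-genes gene embedding, each
#' row of the learned topic embedding `alpha` scores the pathways directly;
#' this reports the `top_n` pathways per topic.
#'
#' @param object a fitted [sctopic] model with `rho_fixed = TRUE`.
#' @param top_n pathways per topic (default 5).
#' @return data.frame with columns `topic`, `rank`, `pathway`, `score`.
#' @export
pathway_topic_report <- function(object, top_n = 5L) {
  if (!object$params$rho_fixed || is.null(object$pathway_names))
    .stopf("model was not fitted with a fixed pathway gene embedding")
  al <- object$params$alpha
  top_n <- min(top_n, ncol(al))
  out <- do.call(rbind, lapply(seq_len(nrow(al)), function(k) {
    o <- order(-al[k, ])[seq_len(top_n)]
    data.frame(topic = k, rank = seq_len(top_n),
               pathway = object$pathway_names[o], score = al[k, o],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
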