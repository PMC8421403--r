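#' Differential topic activity by permutation test
#'
#' For every topic `k` and label `j`, computes the observed difference of
#' mean topic activity between cells with and without the label, builds a
#' one-sided (upregulation) null by reshuffling the label assignments among
#' cells, and reports `p = (N' + 1) / (N + 1)` with `N'` the number of
#' permuted differences at least as large as the observed one (set
#' `strict = TRUE` to count strictly greater ones). Bonferroni correction
#' multiplies by the number of (topic, label) hypotheses, `K * J`. A topic
#' is flagged differentially expressed when `q < q_max` and the observed
#' difference exceeds `diff_min` — use 2 for cell-type labels and 0.2 for
#' condition labels on the unnormalized `delta`-scale activities (the `mu`
#' embedding from [predict.sctopic()]), whose range makes those thresholds
#' meaningful, unlike the simplex-bounded topic proportions.
#'
#' @param activities cells x K matrix of topic activities (the `mu`
#'   embedding).
#' @param labels per-cell categorical labels; every level must be present
#'   in at least one cell and absent from at least one.
#' @param n_perm permutations (default 1000; raise to 1e5 for publication-
#'   grade q-values — cost is `O(n_perm * cells * K)`).
#' @param seed integer seed.
#' @param q_max,diff_min DE thresholds (defaults 0.01 and 2).
#' @param strict count only strictly greater permuted differences.
#' @return data.frame of class `sc_de` with columns `topic`, `label`,
#'   `diff`, `p`, `q`, `de`; permuted differences are kept in
#'   `attr(, "null_diff")` (an `n_perm` x (K*J) matrix, columns
#'   `topic.label`).
#' @export
de_topic_test <- function(activities, labels, n_perm = 1000L, seed = 1L,
                          q_max = 0.01, diff_min = 2, strict = FALSE) {
  A <- as.matrix(activities)
  D <- nrow(A); K <- ncol(A)
  labels <- as.character(labels)
  if (length(labels) != D) .stopf("labels length mismatch")
  lev <- unique(labels)
  J <- length(lev)
  cnt <- table(factor(labels, levels = lev))
  if (any(cnt == 0) || any(cnt == D))
    .stopf("every label must be present in >= 1 cell and absent in >= 1")
  tot <- colSums(A)
  diff_for <- function(lab) {
    # K x J matrix of mean(label) - mean(not label)
    sums <- rowsum(A, factor(lab, levels = lev))    # J x K
    nj <- as.numeric(table(factor(lab, levels = lev)))
    m_in <- sums / nj
    m_out <- (matrix(tot, J, K, byrow = TRUE) - sums) / (D - nj)
    t(m_in - m_out)                                  # K x J
  }
  d_obs <- diff_for(labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- matrix(0L, K, J)
  null_store <- matrix(NA_real_, n_perm, K * J)
  for (b in seq_len(n_perm)) {
    d_p <- diff_for(labels[sample.int(D)])
    exceed <- exceed + if (strict) (d_p > d_obs) else (d_p >= d_obs)
    null_store[b, ] <- as.vector(d_p)
  }
  p <- (exceed + 1) / (n_perm + 1)
  q <- pmin(1, p * K * J)
  out <- data.frame(topic = rep(seq_len(K), J),
                    label = rep(lev, each = K),
                    diff = as.vector(d_obs), p = as.vector(p),
                    q = as.vector(q),
                    de = as.vector(q < q_max & d_obs > diff_min),
                    stringsAsFactors = FALSE)
  colnames(null_store) <- paste(rep(seq_len(K), J), rep(lev, each = K),
                                sep = ".")
  attr(out, "null_diff") <- null_store
  class(out) <- c("sc_de", "data.frame")
  out
}
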