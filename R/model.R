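# Core model quantities: the variational encoder pass, reparameterized
# sampling, the softmax topic mixture, the tri-factorized decoder
# r = softmax(theta alpha rho + lambda), the multinomial reconstruction
# log-likelihood, and the closed-form Gaussian KL.

# fresh parameter set; rho_fixed (P x V) switches on the pathway-informed
# variant, in which L = P and rho is frozen
.init_params <- function(V, K, L, S, H, use_batch_intercept = TRUE,
                         rho_fixed = NULL, init_scale = 0.02) {
  if (!is.null(rho_fixed)) {
    stopifnot(ncol(rho_fixed) == V)
    L <- nrow(rho_fixed)
    rho <- rho_fixed
  } else {
    rho <- matrix(stats::rnorm(L * V, sd = init_scale), L, V)
  }
  list(alpha = matrix(stats::rnorm(K * L, sd = init_scale), K, L),
       rho = rho,
       lam = matrix(0, S, V),
       encoder = .init_encoder(V, H, K),
       use_batch_intercept = use_batch_intercept,
       rho_fixed = !is.null(rho_fixed),
       K = K, L = L, V = V, S = S, H = H)
}

#' Encode expression profiles into the variational posterior
#'
#' Runs the two-hidden-layer encoder (128-unit ReLU layers with 1D batch
#' normalization and 0.1 dropout by default) on normalized profiles and
#' returns the per-cell posterior mean and log-variance of the unnormalized
#' topic mixture. In `"eval"` mode dropout is disabled and batch
#' normalization uses running statistics, so the output is a deterministic
#' function of the input.
#'
#' @param object a fitted [sctopic] model.
#' @param profiles numeric matrix of row-normalized profiles (cells x genes,
#'   same genes as the model).
#' @param mode `"eval"` (default) or `"train"`.
#' @param bn_stats batch-normalization statistics in eval mode: `"running"`
#'   (default; the averages accumulated during training, so each cell's
#'   embedding depends on its own profile only) or `"dataset"` (recompute
#'   mean/variance over the supplied profiles — adaptive normalization for
#'   zero-shot transfer to datasets whose technical shifts differ from the
#'   training data; deterministic, but cells are no longer encoded
#'   independently).
#' @return list with matrices `mu` and `log_var` (cells x K).
#' @export
encode_cells <- function(object, profiles, mode = c("eval", "train"),
                         bn_stats = c("running", "dataset")) {
  mode <- match.arg(mode)
  bn_stats <- match.arg(bn_stats)
  p <- object$params
  if (ncol(profiles) != p$V)
    .stopf("profiles have %d genes but the model expects %d",
           ncol(profiles), p$V)
  if (mode == "eval" && bn_stats == "dataset") {
    # full-dataset batch statistics, dropout off: deterministic adaptive pass
    fw <- .encoder_forward(p$encoder, profiles, train = TRUE, dropout = 0)
  } else {
    fw <- .encoder_forward(p$encoder, profiles, train = (mode == "train"),
                           dropout = object$config$dropout)
  }
  list(mu = fw$mu, log_var = fw$lv)
}

#' Reparameterized draws from the variational posterior
#'
#' Draws `delta = mu + exp(log_var / 2) * eps` with standard-normal `eps`.
#'
#' @param posterior list with `mu` and `log_var` matrices (cells x K).
#' @param seed optional integer seed for reproducible draws.
#' @return matrix of the same shape as `mu`.
#' @export
sample_delta <- function(posterior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(stats::rnorm(length(posterior$mu)), nrow(posterior$mu))
  posterior$mu + exp(posterior$log_var / 2) * eps
}

#' Topic mixture from unnormalized activities
#'
#' `theta = softmax(delta)`, the logistic-normal link from the latent cell
#' embedding to the topic-proportion simplex.
#'
#' @param delta numeric vector (length K) or matrix (cells x K).
#' @return simplex vector/matrix of the same shape.
#' @export
mix_topics <- function(delta) softmax_rows(delta)

#' Decoder: per-cell transcription rates
#'
#' Computes `r = softmax_genes(theta %*% alpha %*% rho + lambda[s, ])`, the
#' tri-factorized linear decoder with a batch-specific gene intercept. With
#' the intercept disabled (the "-lambda" ablation) rates are independent of
#' the batch index.
#'
#' @param theta topic-mixture matrix (cells x K) or vector.
#' @param params model parameter list (element `params` of a fitted model).
#' @param batch_index integer batch label in `1..S`, recycled over cells.
#' @return rate matrix (cells x V); each row is a simplex over genes.
#' @export
decode_rates <- function(theta, params, batch_index = 1L) {
  if (is.null(dim(theta))) theta <- matrix(theta, 1L)
  if (any(batch_index < 1L | batch_index > params$S))
    .stopf("batch index out of range 1..%d", params$S)
  eta <- theta %*% params$alpha %*% params$rho
  if (params$use_batch_intercept) {
    bi <- rep_len(as.integer(batch_index), nrow(eta))
    eta <- eta + params$lam[bi, , drop = FALSE]
  }
  softmax_rows(eta)
}

#' Multinomial reconstruction log-likelihood
#'
#' `sum_g target_g * log(r_g)` — the multinomial log-likelihood up to the
#' count-only combinatorial constant. Rates are floored at 1e-30 before the
#' log; a warning is raised if the floor is hit where the target is positive.
#'
#' @param target non-negative vector/matrix (normalized profile or raw
#'   counts), same shape as `rates`.
#' @param rates simplex vector/matrix over genes.
#' @return scalar (vector input) or per-cell vector (matrix input).
#' @export
reconstruction_loglik <- function(target, rates) {
  if (any(target < 0)) .stopf("negative target")
  hit_floor <- rates < .LOG_EPS & target > 0
  if (any(hit_floor))
    .warnf("rate underflow at %d positive-target entries; log floored",
           sum(hit_floor))
  lr <- log(pmax(rates, .LOG_EPS))
  if (is.null(dim(target))) sum(target * lr) else rowSums(target * lr)
}

#' Closed-form KL divergence from the standard-normal prior
#'
#' Per-cell `KL[N(mu, diag(sigma^2)) || N(0, I)] =
#' 0.5 * sum_k (mu_k^2 + sigma_k^2 - log sigma_k^2 - 1)`.
#'
#' @param posterior list with `mu` and `log_var` (vectors or cells x K
#'   matrices).
#' @return per-cell numeric vector (or scalar).
#' @export
kl_normal <- function(posterior) {
  mu <- posterior$mu; lv <- posterior$log_var
  term <- mu^2 + exp(lv) - lv - 1
  if (is.null(dim(mu))) 0.5 * sum(term) else 0.5 * rowSums(term)
}

#' Unnormalized topics-by-genes score matrix
#'
#' `beta = alpha %*% rho` (K x V): each row assigns every gene an
#' unnormalized score under that topic; rank at most L. These scores are the
#' association statistic used by [gsea_topics()] and [top_genes()].
#'
#' @param object a fitted [sctopic] model, or a raw parameter list.
#' @return numeric matrix K x V with gene ids as column names when known.
#' @export
topic_gene_matrix <- function(object) {
  p <- if (!is.null(object$params)) object$params else object
  beta <- p$alpha %*% p$rho
  if (!is.null(object$gene_ids)) colnames(beta) <- object$gene_ids
  rownames(beta) <- paste0("topic", seq_len(nrow(beta)))
  beta
}

#' Pathways-by-genes fixed gene embedding
#'
#' Builds the binary membership matrix (`1` if the pathway contains the
#' gene) restricted to `gene_ids`, then standardizes each gene column to
#' mean 0 / sd 1 across pathways for numerical stability. Columns with zero
#' variance (genes in no pathway, or in all) are set to all zeros and
#' counted in a message. Used as the frozen `rho` of a pathway-informed fit.
#'
#' @param gene_sets named list of gene-symbol vectors (see [read_gmt()]),
#'   already filtered to the minimum set size.
#' @param gene_ids model gene identifiers (the V columns).
#' @return standardized matrix P x V with pathway names as row names.
#' @export
build_pathway_rho <- function(gene_sets, gene_ids) {
  memb <- vapply(gene_sets, function(s) as.numeric(gene_ids %in% s),
                 numeric(length(gene_ids)))
  memb <- t(memb)                        # pathways x genes
  if (all(memb == 0)) .stopf("no gene overlaps any gene set")
  out <- .standardize_cols(memb)
  nzv <- attr(out, "n_zero_variance")
  if (nzv > 0)
    message(sprintf("%d gene column(s) with zero variance set to 0", nzv))
  dimnames(out) <- list(names(gene_sets), gene_ids)
  out
}

#' Discriminator cross-entropy on cell embeddings
#'
#' Mean categorical cross-entropy of the two-layer batch discriminator's
#' logits against the true batch labels. Exposed for inspection; training
#' uses it internally for both the adversarial generator term and the
#' discriminator updates.
#'
#' @param delta cell embedding matrix (cells x K).
#' @param batch integer batch labels in `1..S`.
#' @param disc discriminator weights (element `disc` of an adversarial fit).
#' @return scalar mean cross-entropy.
#' @export
discriminator_loss <- function(delta, batch, disc) {
  S <- length(disc$b2)
  if (any(batch < 1L | batch > S)) .stopf("batch label out of range 1..%d", S)
  .disc_ce(disc, delta, as.integer(batch))$ce
}
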