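#' @export
print.sctopic <- function(x, ...) {
  p <- x$params
  variant <- c(if (p$rho_fixed) "pathway-informed",
               if (!p$use_batch_intercept) "no batch intercept",
               if (x$config$adversarial) "adversarial")
  cat(sprintf("Embedded topic model: K = %d topics, L = %d, V = %d genes, S = %d batch(es)\n",
              p$K, p$L, p$V, p$S))
  if (length(variant)) cat("Variant:", paste(variant, collapse = ", "), "\n")
  h <- x$history
  cat(sprintf("Trained %d epochs (final loss %.5f, reconstruction %.5f)\n",
              nrow(h), h$loss[nrow(h)], h$recon[nrow(h)]))
  invisible(x)
}

#' Summarize a fitted embedded topic model
#'
#' @param object a fitted [sctopic] model.
#' @param n_top number of top-scoring genes to show per topic.
#' @param ... ignored.
#' @return invisibly, a list with the training history tail and the
#'   top-gene table.
#' @export
summary.sctopic <- function(object, n_top = 5L, ...) {
  print(object)
  beta <- topic_gene_matrix(object)
  tops <- t(apply(beta, 1L, function(r)
    object$gene_ids[order(-r)[seq_len(n_top)]]))
  colnames(tops) <- paste0("gene", seq_len(n_top))
  cat("\nTop genes per topic:\n")
  print(utils::head(tops, 10L))
  if (nrow(tops) > 10L) cat(sprintf("... and %d more topics\n",
                                    nrow(tops) - 10L))
  invisible(list(history = utils::tail(object$history, 5L),
                 top_genes = tops))
}

#' Model coefficients: the decoder factors
#'
#' @param object a fitted [sctopic] model.
#' @param ... ignored.
#' @return list with `alpha` (topics x embedding), `rho` (embedding x
#'   genes), `lambda` (batches x genes, rows named by batch level) and
#'   `beta = alpha %*% rho` (topics x genes).
#' @export
coef.sctopic <- function(object, ...) {
  p <- object$params
  lam <- p$lam
  rownames(lam) <- object$batch_levels
  colnames(lam) <- object$gene_ids
  rho <- p$rho
  colnames(rho) <- object$gene_ids
  if (!is.null(object$pathway_names)) rownames(rho) <- object$pathway_names
  list(alpha = p$alpha, rho = rho, lambda = lam,
       beta = topic_gene_matrix(object))
}

#' Cell embeddings and rates for (new) data
#'
#' Runs the trained encoder in evaluation mode (deterministic: no dropout,
#' running batch-normalization statistics) on data whose genes match the
#' model — align foreign data first with [align_to_reference()]. This is the
#' zero-shot transfer path: no parameter is updated, and the batch intercept
#' plays no role in encoding.
#'
#' @param object a fitted [sctopic] model.
#' @param newdata an [sc_counts] object or a cells x genes count matrix.
#' @param type `"delta"` (default; the variational mean `mu`, the cell
#'   embedding used for clustering), `"theta"` (topic proportions
#'   `softmax(mu)`), or `"rates"` (decoded gene rates; uses `batch`).
#' @param batch batch labels for `type = "rates"` (must be levels seen in
#'   training; defaults to the first level).
#' @param bn_stats `"running"` (default) or `"dataset"`; see
#'   [encode_cells()]. Use `"dataset"` when transferring to data whose
#'   technical shifts were not seen in training.
#' @param ... ignored.
#' @return a cells x K matrix (`delta`/`theta`) or cells x V (`rates`).
#' @export
predict.sctopic <- function(object, newdata,
                            type = c("delta", "theta", "rates"),
                            batch = NULL,
                            bn_stats = c("running", "dataset"), ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "sc_counts")) newdata <- sc_counts(newdata)
  if (!identical(newdata$gene_ids, object$gene_ids))
    .stopf("newdata genes do not match the model; use align_to_reference()")
  norm <- normalize_profiles(newdata)
  post <- encode_cells(object, norm$profiles, mode = "eval",
                       bn_stats = match.arg(bn_stats))
  rownames(post$mu) <- newdata$cell_ids[norm$kept]
  if (type == "delta") return(post$mu)
  theta <- softmax_rows(post$mu)
  if (type == "theta") return(theta)
  bi <- if (is.null(batch)) 1L else {
    m <- match(as.character(batch), object$batch_levels)
    if (anyNA(m)) .stopf("unknown batch level")
    m
  }
  decode_rates(theta, object$params, bi)
}

#' Mean per-cell training log-likelihood
#' @param object a fitted [sctopic] model.
#' @param ... ignored.
#' @return `logLik` object holding the final-epoch mean reconstruction
#'   log-likelihood (the multinomial constant is omitted).
#' @export
logLik.sctopic <- function(object, ...) {
  ll <- -object$history$recon[nrow(object$history)]
  structure(ll, df = with(object$params,
                          K * L + if (rho_fixed) 0 else L * V) ,
            class = "logLik")
}

#' Plot training history
#'
#' Base-graphics trace of the total loss and reconstruction term per epoch.
#'
#' @param x a fitted [sctopic] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sctopic <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, h$recon), type = "l", lty = 1,
                    col = c("black", "steelblue"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", c("total", "reconstruction"), lty = 1,
                   col = c("black", "steelblue"), bty = "n")
  invisible(x)
}

#' Simulate counts from a fitted model
#'
#' Draws cells from the fitted generative process: `delta ~ N(0, I)`,
#' `theta = softmax(delta)`, rates through the fitted decoder with a
#' uniformly drawn training batch, Poisson library sizes, multinomial
#' counts.
#'
#' @param object a fitted [sctopic] model.
#' @param nsim number of cells to draw.
#' @param seed optional integer seed.
#' @param library_mean mean Poisson library size.
#' @param ... ignored.
#' @return an [sc_counts] object with the model's genes.
#' @export
simulate.sctopic <- function(object, nsim = 100L, seed = NULL,
                             library_mean = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  delta <- matrix(stats::rnorm(nsim * p$K), nsim)
  bi <- sample.int(p$S, nsim, replace = TRUE)
  R <- decode_rates(softmax_rows(delta), p, bi)
  n <- pmax(stats::rpois(nsim, library_mean), 1L)
  counts <- t(vapply(seq_len(nsim),
                     function(i) stats::rmultinom(1L, n[i], R[i, ])[, 1L],
                     numeric(p$V)))
  sc_counts(counts, gene_ids = object$gene_ids,
            batch = object$batch_levels[bi])
}

#' Pearson residuals of counts under the fitted rates
#'
#' `(y - N r) / sqrt(N r (1 - r))` per cell and gene, with rates decoded at
#' the variational mean and the cell's own batch intercept.
#'
#' @param object a fitted [sctopic] model.
#' @param newdata an [sc_counts] object (defaults require explicit data; the
#'   model does not store its training matrix).
#' @param ... ignored.
#' @return cells x genes matrix of Pearson residuals.
#' @export
residuals.sctopic <- function(object, newdata, ...) {
  if (!inherits(newdata, "sc_counts")) newdata <- sc_counts(newdata)
  theta <- predict(object, newdata, type = "theta")
  bi <- match(newdata$batch_levels[newdata$batch], object$batch_levels)
  if (anyNA(bi)) bi[is.na(bi)] <- 1L
  R <- decode_rates(theta, object$params, bi)
  n <- library_sizes(newdata)
  mu <- n * R
  (as.matrix(newdata$counts) - mu) / sqrt(pmax(mu * (1 - R), .LOG_EPS))
}
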