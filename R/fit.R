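#' Linear KL-annealing schedule
#'
#' The KL weight starts at zero and rises linearly to `kl_max_weight` over
#' the first `warmup_fraction` of training, then stays constant — the usual
#' warm-up that prevents early posterior collapse under the multinomial
#' reconstruction term.
#'
#' @param epoch 0-based epoch index (0 = before any update).
#' @param total_epochs total number of training epochs.
#' @param kl_max_weight plateau weight (default `1e-7`).
#' @param warmup_fraction fraction of epochs spent ramping (default 1/3).
#' @return the KL weight for that epoch.
#' @examples
#' kl_weight_schedule(0, 300)            # 0
#' kl_weight_schedule(100, 300)          # 1e-7
#' kl_weight_schedule(50, 300)           # 5e-8
#' @export
kl_weight_schedule <- function(epoch, total_epochs, kl_max_weight = 1e-7,
                               warmup_fraction = 1 / 3) {
  stopifnot(epoch >= 0, epoch <= total_epochs,
            warmup_fraction > 0, warmup_fraction <= 1)
  kl_max_weight * min(1, epoch / (warmup_fraction * total_epochs))
}

#' Fit an embedded topic model to single-cell counts
#'
#' Fits the tri-factorized topic model by amortized variational inference:
#' a two-hidden-layer encoder maps each cell's library-size-normalized
#' profile to a Gaussian posterior over its unnormalized topic mixture
#' `delta`; the decoder reconstructs expression rates as
#' `softmax(softmax(delta) %*% alpha %*% rho + lambda[batch, ])` under a
#' multinomial likelihood. All parameters are optimized with Adam on the
#' negative ELBO with a linearly annealed KL weight.
#'
#' Variants: `batch_intercept = FALSE` drops the `lambda` term (the
#' "-lambda" ablation); `adversarial = TRUE` adds a two-layer batch
#' discriminator on `delta` — each iteration performs one generator update
#' that also maximizes the discriminator's cross-entropy (weighted by
#' `adv_weight`), followed by `disc_updates` discriminator updates on the
#' frozen embedding; a `rho_fixed` matrix (see [build_pathway_rho()])
#' freezes the gene embedding to pathway memberships so the learned topic
#' embedding `alpha` directly associates topics with pathways.
#'
#' @param x an [sc_counts] object, or a counts matrix (cells x genes).
#' @param batch per-cell batch labels when `x` is a bare matrix.
#' @param K number of topics (default 50).
#' @param L gene/topic embedding dimension (default 400; ignored when
#'   `rho_fixed` is given).
#' @param hidden encoder hidden width (default 128).
#' @param epochs training epochs.
#' @param lr Adam learning rate (default 0.005).
#' @param minibatch minibatch size (default 2000); the last short minibatch
#'   of an epoch is kept.
#' @param kl_max_weight,kl_warmup_fraction see [kl_weight_schedule()]. Set
#'   `kl_max_weight = 1` for a conventionally weighted ELBO.
#' @param batch_intercept include the per-batch gene intercept `lambda`.
#' @param adversarial train the adversarial batch-correction variant
#'   (requires at least two batches).
#' @param adv_weight weight of the adversarial term in the generator loss
#'   (default 1).
#' @param adv_objective how the generator fools the discriminator:
#'   `"confusion"` (default) minimizes the cross-entropy between the
#'   discriminator's prediction and the uniform distribution over batches
#'   (fixed point: an uninformative discriminator); `"gated_ce"` maximizes
#'   the discriminator's label cross-entropy, active only while the
#'   discriminator beats chance (an unbounded cross-entropy ascent settles
#'   into a label-flip equilibrium in which batches remain separable).
#' @param adv_warmup two fractions of training: the adversarial weight is 0
#'   before the first, ramps linearly to `adv_weight` at the second, then
#'   stays constant (default `c(1/3, 2/3)`). Letting the topic structure
#'   form before applying batch pressure preserves clustering quality.
#' @param disc_lr discriminator Adam learning rate (default 0.02; faster
#'   than the generator so the discriminator tracks the moving embedding).
#' @param disc_updates discriminator updates per generator update (default 8).
#' @param disc_hidden discriminator hidden width (default 128).
#' @param rho_fixed optional pathways-by-genes matrix; when given, `rho` is
#'   frozen to it and `L` becomes its row count.
#' @param recon_target `"normalized"` (default) reconstructs the
#'   row-normalized profile; `"counts"` weights the likelihood by raw counts.
#' @param dropout encoder dropout rate (default 0.1).
#' @param drop_empty drop zero-library cells (default) or error.
#' @param seed integer seed governing initialization, minibatch order,
#'   dropout and the reparameterization draws; two runs with the same seed
#'   and configuration are identical.
#' @param verbose print per-epoch losses every `verbose` epochs (0 = quiet).
#' @return An object of class `"sctopic"`: a list with `params` (alpha, rho,
#'   lam, encoder weights, dims and flags), `disc` (adversarial fits only),
#'   `history` (per-epoch data.frame of loss, reconstruction and KL terms,
#'   KL weight, discriminator loss), `gene_ids`, `batch_levels`, `config`
#'   and `call`. Use [predict.sctopic()] for cell embeddings,
#'   [topic_gene_matrix()] for topic-gene scores, [heldout_nll()] for
#'   held-out likelihood.
#' @seealso [simulate_sc_dataset()] to generate data this model can be
#'   tested on; [evaluate_embeddings()] for clustering metrics.
#' @export
sctopic <- function(x, batch = NULL, K = 50L, L = 400L, hidden = 128L,
                    epochs = 50L, lr = 0.005, minibatch = 2000L,
                    kl_max_weight = 1e-7, kl_warmup_fraction = 1 / 3,
                    batch_intercept = TRUE, adversarial = FALSE,
                    adv_weight = 1,
                    adv_objective = c("confusion", "gated_ce"),
                    adv_warmup = c(1 / 3, 2 / 3), disc_lr = 0.02,
                    disc_updates = 8L, disc_hidden = 128L,
                    rho_fixed = NULL,
                    recon_target = c("normalized", "counts"),
                    dropout = 0.1, drop_empty = TRUE, seed = 1L,
                    verbose = 0L) {
  recon_target <- match.arg(recon_target)
  adv_objective <- match.arg(adv_objective)
  if (!inherits(x, "sc_counts")) x <- sc_counts(x, batch = batch)
  stopifnot(K >= 1, epochs >= 1, lr > 0, minibatch >= 1)
  norm <- normalize_profiles(x, drop_empty = drop_empty)
  if (norm$n_dropped > 0) x <- x[norm$kept]
  D <- nrow(x$counts); V <- ncol(x$counts); S <- length(x$batch_levels)
  if (adversarial && S < 2)
    .stopf("adversarial training needs at least 2 batches, got %d", S)
  cfg <- list(K = K, L = if (is.null(rho_fixed)) L else nrow(rho_fixed),
              hidden = hidden, epochs = epochs, lr = lr,
              minibatch = min(minibatch, D), kl_max_weight = kl_max_weight,
              kl_warmup_fraction = kl_warmup_fraction,
              batch_intercept = batch_intercept, adversarial = adversarial,
              adv_weight = adv_weight, adv_objective = adv_objective,
              adv_warmup = adv_warmup, disc_lr = disc_lr,
              disc_updates = disc_updates,
              disc_hidden = disc_hidden, recon_target = recon_target,
              dropout = dropout, seed = as.integer(seed))

  set.seed(cfg$seed)
  params <- .init_params(V, K, cfg$L, S, hidden,
                         use_batch_intercept = batch_intercept,
                         rho_fixed = rho_fixed)
  disc <- if (adversarial) .init_discriminator(K, disc_hidden, S) else NULL

  fit <- .train_loop(x, params, disc, cfg, verbose)
  obj <- structure(list(params = fit$params, disc = fit$disc,
                        history = fit$history, gene_ids = x$gene_ids,
                        batch_levels = x$batch_levels,
                        pathway_names = rownames(rho_fixed),
                        config = cfg, call = match.call()),
                   class = "sctopic")
  obj
}

# normalized sparse profiles for a row subset, densified on demand
.dense_profiles <- function(counts, n, idx) {
  x <- as.matrix(counts[idx, , drop = FALSE]) / n[idx]
  dimnames(x) <- NULL
  x
}

.train_loop <- function(x, params, disc, cfg, verbose) {
  D <- nrow(x$counts)
  n <- library_sizes(x)
  bi_all <- x$batch
  dec <- list(alpha = params$alpha, rho = params$rho, lam = params$lam)
  st_dec <- .adam_init(dec)
  st_enc <- .adam_init(params$encoder[!grepl("^r[mv]", names(params$encoder))])
  st_disc <- if (!is.null(disc)) .adam_init(disc) else NULL
  skip_dec <- c(if (params$rho_fixed) "rho",
                if (!params$use_batch_intercept) "lam")
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                     recon = NA_real_, kl = NA_real_, kl_weight = NA_real_,
                     disc_loss = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    w <- kl_weight_schedule(ep - 1L, cfg$epochs, cfg$kl_max_weight,
                            cfg$kl_warmup_fraction)
    aw <- if (is.null(disc)) 0 else {
      f <- (ep - 1L) / cfg$epochs
      cfg$adv_weight * min(1, max(0, (f - cfg$adv_warmup[1]) /
                                    (cfg$adv_warmup[2] - cfg$adv_warmup[1])))
    }
    ord <- sample.int(D)
    starts <- seq(1L, D, by = cfg$minibatch)
    acc <- c(loss = 0, recon = 0, kl = 0, dl = 0); nb <- 0L
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + cfg$minibatch - 1L, D)]
      B <- length(idx)
      X <- .dense_profiles(x$counts, n, idx)
      bi <- bi_all[idx]
      fw <- .encoder_forward(params$encoder, X, train = TRUE,
                             dropout = cfg$dropout)
      params$encoder <- fw$enc
      mu <- fw$mu; lv <- fw$lv
      eps <- matrix(stats::rnorm(B * cfg$K), B)
      sig <- exp(lv / 2)
      delta <- mu + sig * eps
      Theta <- softmax_rows(delta)
      M <- dec$alpha %*% dec$rho
      eta <- Theta %*% M
      if (params$use_batch_intercept) eta <- eta + dec$lam[bi, , drop = FALSE]
      R <- softmax_rows(eta)
      Tgt <- if (cfg$recon_target == "normalized") X else
        unname(as.matrix(x$counts[idx, , drop = FALSE]))
      recon <- rowSums(Tgt * log(pmax(R, .LOG_EPS)))
      klv <- 0.5 * rowSums(mu^2 + exp(lv) - lv - 1)
      loss <- mean(-recon + w * klv)
      if (!is.finite(loss))
        .stopf("non-finite loss at epoch %d (recon %.3g, kl %.3g)",
               ep, mean(recon), mean(klv))
      # backward: d(-recon)/d_eta, scaled by the minibatch mean
      G <- (rowSums(Tgt) * R - Tgt) / B
      gTheta <- tcrossprod(G, M)
      gM <- crossprod(Theta, G)
      grads_dec <- list(alpha = tcrossprod(gM, dec$rho),
                        rho = if (params$rho_fixed) NULL else
                          crossprod(dec$alpha, gM),
                        lam = NULL)
      if (params$use_batch_intercept) {
        glam <- matrix(0, params$S, params$V)
        agg <- rowsum(G, bi)
        glam[as.integer(rownames(agg)), ] <- agg
        grads_dec$lam <- glam
      }
      gdelta <- Theta * (gTheta - rowSums(gTheta * Theta))
      dl <- NA_real_
      if (!is.null(disc)) {
        ce <- .disc_ce(disc, delta, bi)
        dl <- ce$ce
        if (aw > 0) {
          if (cfg$adv_objective == "confusion") {
            # push the discriminator's prediction toward uniform
            dlogits <- (ce$probs - 1 / params$S) / B
            dH1 <- tcrossprod(dlogits, disc$W2) * (ce$Z1 > 0)
            gdelta <- gdelta + aw * tcrossprod(dH1, disc$W1)
          } else if (ce$ce < log(params$S)) {
            gdelta <- gdelta - aw * ce$dX
          }
        }
      }
      gmu <- gdelta + w * mu / B
      glv <- gdelta * eps * 0.5 * sig + w * 0.5 * (exp(lv) - 1) / B
      grads_enc <- .encoder_backward(params$encoder, fw$cache, gmu, glv)
      up <- .adam_step(dec, grads_dec, st_dec, cfg$lr, skip = skip_dec)
      dec <- up$params; st_dec <- up$state
      up <- .adam_step(params$encoder, grads_enc, st_enc, cfg$lr)
      params$encoder[names(grads_enc)] <- up$params[names(grads_enc)]
      st_enc <- up$state
      if (!is.null(disc)) {
        for (j in seq_len(cfg$disc_updates)) {
          ce <- .disc_ce(disc, delta, bi)
          up <- .adam_step(disc, ce$grads, st_disc, cfg$disc_lr)
          disc <- up$params; st_disc <- up$state
        }
      }
      acc <- acc + c(loss, mean(-recon), mean(klv),
                     if (is.na(dl)) 0 else dl)
      nb <- nb + 1L
    }
    hist[ep, 2:6] <- c(acc[["loss"]] / nb, acc[["recon"]] / nb,
                       acc[["kl"]] / nb, w,
                       if (is.null(disc)) NA_real_ else acc[["dl"]] / nb)
    if (verbose > 0 && (ep %% verbose == 0 || ep == cfg$epochs))
      message(sprintf("epoch %d/%d loss %.5f recon %.5f kl %.4g",
                      ep, cfg$epochs, hist$loss[ep], hist$recon[ep],
                      hist$kl[ep]))
  }
  params$alpha <- dec$alpha; params$rho <- dec$rho; params$lam <- dec$lam
  list(params = params, disc = disc, history = hist)
}

#' Held-out negative log-likelihood
#'
#' Mean per-cell negative multinomial reconstruction log-likelihood on
#' held-out cells, evaluated at the variational mean (`delta = mu`,
#' `theta = softmax(mu)`). Cells whose batch was seen in training use their
#' own batch intercept; unseen batches fall back to a zero intercept with a
#' warning. The count-only multinomial constant is omitted, as in training.
#'
#' @param object a fitted [sctopic] model.
#' @param held an [sc_counts] object with the model's genes.
#' @return scalar mean NLL (natural log units per cell).
#' @export
heldout_nll <- function(object, held) {
  if (!identical(held$gene_ids, object$gene_ids))
    .stopf("held-out genes do not match the model; align first")
  norm <- normalize_profiles(held)
  post <- encode_cells(object, norm$profiles, mode = "eval")
  Theta <- softmax_rows(post$mu)
  p <- object$params
  eta <- Theta %*% p$alpha %*% p$rho
  if (p$use_batch_intercept) {
    sm <- match(held$batch_levels[held$batch[norm$kept]],
                object$batch_levels)
    if (anyNA(sm)) {
      .warnf("%d cell(s) from batches unseen in training; using zero intercept",
             sum(is.na(sm)))
    }
    known <- !is.na(sm)
    eta[known, ] <- eta[known, , drop = FALSE] +
      p$lam[sm[known], , drop = FALSE]
  }
  R <- softmax_rows(eta)
  tgt <- if (object$config$recon_target == "normalized") norm$profiles else
    as.matrix(held$counts[norm$kept, , drop = FALSE])
  -mean(reconstruction_loglik(tgt, R))
}
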