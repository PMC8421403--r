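# Internal feed-forward machinery for the amortized encoder and the
# adversarial discriminator: linear layers, 1D batch normalization, inverted
# dropout, ReLU, manual backpropagation, and Adam. Written against base R
# matrix ops; minibatches are dense (cells x features).

.BN_EPS <- 1e-5

.glorot <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

# two shared hidden layers (Linear -> BatchNorm -> ReLU -> Dropout), then
# parallel linear heads for mu and log sigma^2
.init_encoder <- function(V, H, K) {
  list(W1 = .glorot(V, H), b1 = numeric(H),
       g1 = rep(1, H), be1 = numeric(H), rm1 = numeric(H), rv1 = rep(1, H),
       W2 = .glorot(H, H), b2 = numeric(H),
       g2 = rep(1, H), be2 = numeric(H), rm2 = numeric(H), rv2 = rep(1, H),
       Wmu = .glorot(H, K), bmu = numeric(K),
       Wlv = .glorot(H, K), blv = numeric(K))
}

# returns list(mu, lv, cache); `train` toggles batch statistics + dropout.
# Running statistics are updated in place on the returned `enc` element
# (momentum convention: running <- (1 - mom) * running + mom * batch).
.encoder_forward <- function(enc, X, train = FALSE, dropout = 0.1,
                             bn_momentum = 0.1) {
  B <- nrow(X)
  layer <- function(Xin, W, b, g, be, rm, rv) {
    Z <- Xin %*% W
    Z <- sweep(Z, 2L, b, "+")
    if (train) {
      m <- colMeans(Z)
      v <- colMeans(Z^2) - m^2
      v <- pmax(v, 0)
    } else {
      m <- rm; v <- rv
    }
    xh <- sweep(sweep(Z, 2L, m, "-"), 2L, sqrt(v + .BN_EPS), "/")
    A <- sweep(sweep(xh, 2L, g, "*"), 2L, be, "+")
    Hout <- A * (A > 0)
    mask <- NULL
    if (train && dropout > 0) {
      mask <- matrix(stats::runif(length(Hout)) >= dropout, B) / (1 - dropout)
      Hout <- Hout * mask
    }
    list(Z = Z, m = m, v = v, xh = xh, A = A, Hout = Hout, mask = mask)
  }
  l1 <- layer(X, enc$W1, enc$b1, enc$g1, enc$be1, enc$rm1, enc$rv1)
  l2 <- layer(l1$Hout, enc$W2, enc$b2, enc$g2, enc$be2, enc$rm2, enc$rv2)
  mu <- sweep(l2$Hout %*% enc$Wmu, 2L, enc$bmu, "+")
  lv <- sweep(l2$Hout %*% enc$Wlv, 2L, enc$blv, "+")
  if (train) {
    ub <- if (B > 1) B / (B - 1) else 1       # running var stores unbiased
    enc$rm1 <- (1 - bn_momentum) * enc$rm1 + bn_momentum * l1$m
    enc$rv1 <- (1 - bn_momentum) * enc$rv1 + bn_momentum * l1$v * ub
    enc$rm2 <- (1 - bn_momentum) * enc$rm2 + bn_momentum * l2$m
    enc$rv2 <- (1 - bn_momentum) * enc$rv2 + bn_momentum * l2$v * ub
  }
  list(mu = mu, lv = lv, enc = enc,
       cache = list(X = X, l1 = l1, l2 = l2, train = train))
}

# gradient of loss wrt encoder parameters given dmu, dlv (B x K each)
.encoder_backward <- function(enc, cache, dmu, dlv) {
  l1 <- cache$l1; l2 <- cache$l2; X <- cache$X
  gr <- list()
  gr$Wmu <- crossprod(l2$Hout, dmu); gr$bmu <- colSums(dmu)
  gr$Wlv <- crossprod(l2$Hout, dlv); gr$blv <- colSums(dlv)
  dH <- tcrossprod(dmu, enc$Wmu) + tcrossprod(dlv, enc$Wlv)
  back_layer <- function(l, W, g, dHout, Xin) {
    if (!is.null(l$mask)) dHout <- dHout * l$mask
    dA <- dHout * (l$A > 0)
    dg <- colSums(dA * l$xh); dbe <- colSums(dA)
    dxh <- sweep(dA, 2L, g, "*")
    # batch-statistics backward (biased variance)
    inv_sd <- 1 / sqrt(l$v + .BN_EPS)
    dZ <- sweep(dxh, 2L, colMeans(dxh), "-") -
      l$xh * matrix(colMeans(dxh * l$xh), nrow(dxh), ncol(dxh), byrow = TRUE)
    dZ <- sweep(dZ, 2L, inv_sd, "*")
    list(dW = crossprod(Xin, dZ), db = colSums(dZ), dg = dg, dbe = dbe,
         dXin = tcrossprod(dZ, W))
  }
  b2 <- back_layer(l2, enc$W2, enc$g2, dH, l1$Hout)
  gr$W2 <- b2$dW; gr$b2 <- b2$db; gr$g2 <- b2$dg; gr$be2 <- b2$dbe
  b1 <- back_layer(l1, enc$W1, enc$g1, b2$dXin, X)
  gr$W1 <- b1$dW; gr$b1 <- b1$db; gr$g1 <- b1$dg; gr$be1 <- b1$dbe
  gr
}

# note: .encoder_backward assumes eval-mode was not used (batch statistics)

.init_discriminator <- function(K, Dh, S) {
  list(W1 = .glorot(K, Dh), b1 = numeric(Dh),
       W2 = .glorot(Dh, S), b2 = numeric(S))
}

.disc_forward <- function(disc, X) {
  Z1 <- sweep(X %*% disc$W1, 2L, disc$b1, "+")
  H1 <- Z1 * (Z1 > 0)
  logits <- sweep(H1 %*% disc$W2, 2L, disc$b2, "+")
  list(logits = logits, cache = list(X = X, Z1 = Z1, H1 = H1))
}

# mean categorical cross-entropy and its gradients; labels in 1..S
.disc_ce <- function(disc, X, labels) {
  fw <- .disc_forward(disc, X)
  P <- softmax_rows(fw$logits)
  B <- nrow(X)
  idx <- cbind(seq_len(B), labels)
  ce <- -mean(log(pmax(P[idx], .LOG_EPS)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B
  dH1 <- tcrossprod(dlogits, disc$W2) * (fw$cache$Z1 > 0)
  list(ce = ce,
       grads = list(W1 = crossprod(X, dH1), b1 = colSums(dH1),
                    W2 = crossprod(fw$cache$H1, dlogits),
                    b2 = colSums(dlogits)),
       dX = tcrossprod(dH1, disc$W1),
       probs = P, Z1 = fw$cache$Z1)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# one Adam step over the named parameter list; `skip` names are left frozen
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, skip = character()) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (nm %in% skip || is.null(grads[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
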