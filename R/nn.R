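# Minimal fully-connected network machinery for the adversarial model:
# forward/backward passes with leaky-ReLU hidden units, optional tanh
# output, logistic loss on logits, and Adam updates. Matrices are
# batch-rows by units-columns; weights W[[l]] map layer l-1 to layer l.

nn_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    # He-style scaling for the leaky-ReLU stack
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                  sqrt(2 / sizes[l])),
                     nrow = sizes[l], ncol = sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

# branch-free formulations: markedly faster than ifelse() on large matrices
lrelu <- function(x, alpha = 0.2) alpha * x + (1 - alpha) * (x > 0) * x
dlrelu <- function(x, alpha = 0.2) alpha + (1 - alpha) * (x > 0)

# Forward pass; returns activations and pre-activations for backprop.
# out_act: "linear" (logits) or "tanh" (bounded generator output).
nn_forward <- function(net, X, out_act = "linear") {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  Z <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- H[[l]] %*% net$W[[l]] + rep(net$b[[l]], each = nrow(X))
    H[[l + 1L]] <- if (l < L) lrelu(Z[[l]])
                   else if (out_act == "tanh") tanh(Z[[l]])
                   else Z[[l]]
  }
  list(H = H, Z = Z, out = H[[L + 1L]], out_act = out_act)
}

# Backward pass from dOut (gradient w.r.t. the network output). Returns
# per-parameter gradients and the gradient w.r.t. the input (for chaining
# discriminator -> generator).
nn_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- db <- vector("list", L)
  d <- if (cache$out_act == "tanh") dOut * (1 - cache$out^2) else dOut
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d * dlrelu(cache$Z[[l]])
    dW[[l]] <- crossprod(cache$H[[l]], d)
    db[[l]] <- colSums(d)
    d <- d %*% t(net$W[[l]])
  }
  list(dW = dW, db = db, dX = d)
}

# Numerically stable binary cross-entropy on logits.
# target is 0 (fake) or 1 (real); returns mean loss and d(loss)/d(logit).
bce_logits <- function(logits, target) {
  p <- 1 / (1 + exp(-logits))
  loss <- mean(ifelse(logits > 0,
                      logits * (1 - target) + log1p(exp(-logits)),
                      -logits * target + log1p(exp(logits))))
  list(loss = loss, dlogits = (p - target) / length(logits))
}

adam_init <- function(net) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(mW = zeros(net$W), vW = zeros(net$W),
       mb = zeros(net$b), vb = zeros(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}
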