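# Compact exact t-SNE (quadratic in n; adequate for feature tables of a few
# hundred rows). Standard formulation: per-point Gaussian bandwidths found
# by bisection on the perplexity, symmetrized input affinities, Student-t
# low-dimensional kernel, gradient descent with momentum and early
# exaggeration.

tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_embed <- function(X, perplexity = 10, max_iter = 400, seed = 1,
                       eta = 100) {
  n <- nrow(X)
  if (perplexity >= (n - 1) / 3) perplexity <- max(2, floor((n - 1) / 3))
  P <- tsne_affinities(X, perplexity)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
    V <- matrix(0, n, 2)
    for (iter in seq_len(max_iter)) {
      Pit <- if (iter <= 100) P * 4 else P      # early exaggeration
      D2y <- as.matrix(stats::dist(Y))^2
      W <- 1 / (1 + D2y); diag(W) <- 0
      Q <- pmax(W / sum(W), 1e-12)
      M <- (Pit - Q) * W
      grad <- 4 * (diag(rowSums(M)) %*% Y - M %*% Y)
      mom <- if (iter <= 250) 0.5 else 0.8
      V <- mom * V - eta * grad
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
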