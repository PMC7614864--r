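# Exact (quadratic-cost) t-distributed stochastic neighbour embedding.
# Suited to the population sizes here (a few hundred models); pairwise
# Gaussian affinities with per-point perplexity calibration, symmetrized,
# embedded by gradient descent with momentum and early exaggeration.

tsne_exact <- function(x, dims = 2, perplexity = 15, max_iter = 500,
                       seed = 1, eta = 100) {
  n <- nrow(x)
  if (n - 1 < 3 * perplexity) perplexity <- max(2, floor((n - 1) / 3))
  d2 <- as.matrix(dist(x))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < 1e-300) { H <- 0 } else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi))
        (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo))
        (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  y <- withr_seed(seed, matrix(rnorm(n * dims, sd = 1e-4), n, dims))
  inc <- matrix(0, n, dims)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1
    mom <- if (iter <= 250) 0.5 else 0.8
    yd2 <- as.matrix(dist(y))^2
    num <- 1 / (1 + yd2); diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% y
    inc <- mom * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}
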