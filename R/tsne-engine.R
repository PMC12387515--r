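# Exact (non-approximated) t-SNE, suitable for the cohort sizes this
# package targets (n up to a few thousand). Dense O(n^2) affinities and
# gradients; deterministic given the initialization.

# squared Euclidean distance matrix
sq_dist <- function(x) {
  s <- rowSums(x^2)
  d <- outer(s, s, "+") - 2 * tcrossprod(x)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# symmetrized input affinities P at a given perplexity; per-point precision
# found by binary search on the Shannon entropy of the conditional
# distribution (50 iterations bring the entropy within ~1e-12 of target)
tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  d2 <- sq_dist(x)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf
    hi <- Inf
    beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
        pi_ <- rep(0, length(di))
      } else {
        pi_ <- w / sw
        h <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(h - target) < 1e-12) break
      if (h > target) { # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    p[i, -i] <- pi_
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, .Machine$double.xmin)
}

# gradient-descent embedding with momentum and adaptive gains
tsne_optimize <- function(p, y0, max_iter = 500, learning_rate = 200,
                          exaggeration = 12, exaggeration_iter = 125,
                          momentum = 0.5, final_momentum = 0.8,
                          momentum_switch_iter = 125) {
  n <- nrow(y0)
  y <- y0
  vel <- matrix(0, n, ncol(y))
  gains <- matrix(1, n, ncol(y))
  for (iter in seq_len(max_iter)) {
    pe <- if (iter <= exaggeration_iter) p * exaggeration else p
    num <- 1 / (1 + sq_dist(y))
    diag(num) <- 0
    q <- num / sum(num)
    m <- (pe - q) * num
    grad <- 4 * (diag(rowSums(m)) %*% y - m %*% y)
    same_sign <- sign(grad) == sign(vel)
    gains <- ifelse(same_sign, gains * 0.8, gains + 0.2)
    gains[gains < 0.01] <- 0.01
    mom <- if (iter <= momentum_switch_iter) momentum else final_momentum
    vel <- mom * vel - learning_rate * gains * grad
    y <- y + vel
    y <- sweep(y, 2, colMeans(y)) # keep the embedding centred
  }
  y
}
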