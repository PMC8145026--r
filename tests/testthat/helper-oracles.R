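# Independent brute-force oracles and fixture generators shared by the tests.
# Everything here is a literal, unoptimized transcription of the defining
# formulas, kept deliberately separate from the package's stabilized
# implementations.

rand_spd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d, d)
  scale * (crossprod(A) / d + diag(d) * 0.5)
}

rand_theta <- function(K, d, spread = 4) {
  cluster_params(
    centers = matrix(rnorm(K * d, sd = spread), K, d),
    covariances = replicate(K, rand_spd(d), simplify = FALSE),
    proportions = { p <- runif(K) + 0.2; p / sum(p) })
}

rand_blobs <- function(n, K, d, spread = 5, sd = 1) {
  mu <- matrix(rnorm(K * d, sd = spread), K, d)
  g <- sample.int(K, n, replace = TRUE)
  list(X = mu[g, , drop = FALSE] + matrix(rnorm(n * d, sd = sd), n, d),
       labels = g, centers = mu)
}

# --- direct transcriptions of the energy formulas ------------------------

oracle_w <- function(x, mu, sigma, tau, beta) {
  m <- drop(t(x - mu) %*% solve(sigma) %*% (x - mu))
  if (beta == 0) det(sigma)^(-0.5) * exp(-tau * m)
  else det(sigma)^(-0.5) * (1 + tau * beta * m)^(-1 / beta)
}

oracle_pareto_energy <- function(X, theta, tau, beta) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    A <- 0
    for (k in seq_len(theta$K))
      A <- A + theta$proportions[k] *
        oracle_w(X[i, ], theta$centers[k, ], theta$covariances[[k]], tau, beta)
    tot <- tot + if (beta == 0) -log(A) / tau else (A^(-beta) - 1) / (tau * beta)
  }
  tot
}

oracle_kn_energy <- function(X, centers, S, Sinv, tau) {
  tot <- 0
  K <- nrow(centers)
  for (i in seq_len(nrow(X))) {
    avg <- mean(vapply(seq_len(K), function(k)
      S(tau * sum((X[i, ] - centers[k, ])^2)), 0))
    tot <- tot + Sinv(avg) / tau
  }
  tot
}

oracle_fuzzy_energy <- function(X, centers, beta) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    d2 <- apply(centers, 1, function(mu) sum((X[i, ] - mu)^2))
    tot <- tot + if (any(d2 == 0)) 0 else mean(d2^(-1 / beta))^(-beta)
  }
  tot
}

oracle_frechet_energy <- function(X, centers, tau, gamma) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    d2 <- apply(centers, 1, function(mu) sum((X[i, ] - mu)^2))
    B <- -log(mean(exp(-(tau * d2)^gamma)))
    tot <- tot + (B / tau^gamma)^(1 / gamma)
  }
  tot
}

# --- one textbook Gaussian-mixture EM step -------------------------------

oracle_em_step <- function(X, theta) {
  n <- nrow(X); K <- theta$K; d <- ncol(X)
  dens <- sapply(seq_len(K), function(k) {
    S <- theta$covariances[[k]]
    Xc <- sweep(X, 2, theta$centers[k, ])
    (2 * pi)^(-d / 2) * det(S)^(-0.5) *
      exp(-0.5 * rowSums((Xc %*% solve(S)) * Xc))
  })
  num <- sweep(dens, 2, theta$proportions, "*")
  Q <- num / rowSums(num)
  mu <- t(sapply(seq_len(K), function(k)
    colSums(Q[, k] * X) / sum(Q[, k])))
  covs <- lapply(seq_len(K), function(k) {
    Xc <- sweep(X, 2, mu[k, ])
    crossprod(sqrt(Q[, k]) * Xc) / sum(Q[, k])
  })
  list(Q = Q, centers = mu, covariances = covs, proportions = colMeans(Q))
}

oracle_gmm_nll <- function(X, theta) {
  d <- ncol(X)
  dens <- sapply(seq_len(theta$K), function(k) {
    S <- theta$covariances[[k]]
    Xc <- sweep(X, 2, theta$centers[k, ])
    (2 * pi)^(-d / 2) * det(S)^(-0.5) *
      exp(-0.5 * rowSums((Xc %*% solve(S)) * Xc))
  })
  -sum(log(drop(dens %*% theta$proportions)))
}

# --- brute-force metric oracles ------------------------------------------

oracle_purity <- function(pred, truth) {
  n <- length(pred)
  tot <- 0
  for (k in unique(pred)) {
    best <- max(vapply(unique(truth), function(l)
      sum(pred == k & truth == l) / sum(pred == k), 0))
    tot <- tot + sum(pred == k) / n * best
  }
  tot
}

oracle_f_value <- function(pred, truth) {
  n <- length(pred)
  tot <- 0
  for (k in unique(truth)) {
    best <- 0
    for (l in unique(pred)) {
      inter <- sum(truth == k & pred == l)
      if (inter == 0) next
      P <- inter / sum(truth == k)
      R <- inter / sum(pred == l)
      best <- max(best, 2 * P * R / (P + R))
    }
    tot <- tot + sum(truth == k) / n * best
  }
  tot
}

oracle_ci <- function(A, B) {
  oneway <- function(A, B) {
    q <- apply(A, 1, function(a)
      which.min(colSums((t(B) - a)^2)))
    sum(!(seq_len(nrow(B)) %in% q))
  }
  max(oneway(A, B), oneway(B, A))
}

oracle_mse_perm <- function(mu_hat, mu_star) {
  # exhaustive search over permutations; K <= 7 only
  K <- nrow(mu_hat)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(K)))
    best <- min(best, mean(rowSums((mu_hat[p, , drop = FALSE] - mu_star)^2)))
  best
}

# numerical central-difference gradient of f at x
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}
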