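test_that("Ward initialization recovers separated blob structure deterministically", {
  set.seed(31)
  b <- rand_blobs(120, 2, 2, spread = 8)
  th1 <- init_params(b$X, 2)
  th2 <- init_params(b$X, 2)
  expect_identical(th1$centers, th2$centers)
  # within 3 SE of the generating means (SE ~ sd/sqrt(n_k))
  expect_lt(sqrt(mse_centers(th1$centers, b$centers)), 3 / sqrt(40))
  expect_equal(sum(th1$proportions), 1)
  # n = K: every point its own center, uniform proportions
  Xs <- matrix(rnorm(8), 4, 2)
  ths <- init_params(Xs, 4)
  expect_equal(ths$proportions, rep(0.25, 4))
  expect_equal(ths$centers[order(ths$centers[, 1]), ],
               Xs[order(Xs[, 1]), ], ignore_attr = TRUE)
  expect_error(init_params(Xs, 5), "exceed")
})

test_that("responsibilities match the closed form and FCM memberships", {
  set.seed(17)
  X <- matrix(rnorm(30, sd = 3), 15, 2)
  theta <- rand_theta(3, 2)
  tau <- 0.8; beta <- 0.6
  Q <- responsibilities(X, theta, tau, beta)
  expect_equal(rowSums(Q), rep(1, 15))
  for (i in c(1, 7)) {
    wv <- vapply(1:3, function(k)
      theta$proportions[k] *
        oracle_w(X[i, ], theta$centers[k, ], theta$covariances[[k]], tau, beta),
      0)
    expect_equal(Q[i, ], wv / sum(wv), tolerance = 1e-10)
  }
  # equidistant point with equal Sigma and pi: uniform row
  sym <- cluster_params(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
  Qs <- responsibilities(matrix(0, 1, 2), sym, 0.5, 1)
  expect_equal(drop(Qs), rep(0.25, 4))
  # tau = Inf branch reproduces classic FCM memberships (beta = m - 1)
  m <- 2
  th0 <- cluster_params(theta$centers)
  Qi <- responsibilities(X, th0, Inf, m - 1)
  U <- paretoclust:::.fcm_membership(X, theta$centers, m)
  expect_equal(Qi, U, tolerance = 1e-6)
  # and q^(1+beta) renormalized equals u^m renormalized
  qb <- Qi^m / rowSums(Qi^m)
  ub <- U^m / rowSums(U^m)
  expect_equal(qb, ub, tolerance = 1e-6)
})

test_that("center update: uniform memberships give the grand mean; oracle check", {
  set.seed(23)
  X <- matrix(rnorm(40), 20, 2)
  Qu <- matrix(1 / 3, 20, 3)
  mu <- update_centers(X, Qu, beta = 0.7)
  for (k in 1:3) expect_equal(mu[k, ], colMeans(X), ignore_attr = TRUE)
  Q <- matrix(runif(60), 20, 3); Q <- Q / rowSums(Q)
  mu1 <- update_centers(X, Q, beta = 1)
  for (k in 1:3)
    expect_equal(mu1[k, ], colSums(Q[, k]^2 * X) / sum(Q[, k]^2),
                 ignore_attr = TRUE, tolerance = 1e-12)
  # convex hull: each coordinate within the data range
  expect_true(all(mu1 >= rep(apply(X, 2, min), each = 3) - 1e-12))
  expect_true(all(mu1 <= rep(apply(X, 2, max), each = 3) + 1e-12))
  # empty component
  Q0 <- Q; Q0[, 2] <- 0
  expect_error(update_centers(X, Q0, 0), class = "paretoclust_empty_cluster")
})

test_that("covariance update: GMM reduction, degenerate scale, oracle", {
  set.seed(29)
  X <- matrix(rnorm(60, sd = 2), 30, 2)
  Q1 <- matrix(1, 30, 1)
  # beta=0, tau=1/2: coefficient 1, plain weighted scatter about the mean
  S <- update_covariances(X, Q1, matrix(colMeans(X), 1), tau = 0.5, beta = 0,
                          ridge_alpha = 1)[[1]]
  expect_equal(S, cov(X) * (29 / 30), tolerance = 1e-12, ignore_attr = TRUE)
  # d=2, beta=1 makes the scale factor vanish
  expect_error(update_covariances(X, Q1, matrix(0, 1, 2), 0.5, 1),
               class = "paretoclust_degenerate_scale")
  # transcription at d=2, beta=0.5, tau=0.5: coefficient 0.5
  Q <- matrix(runif(60), 30, 2); Q <- Q / rowSums(Q)
  mu <- update_centers(X, Q, 0.5)
  Ss <- update_covariances(X, Q, mu, 0.5, 0.5, ridge_alpha = 1)
  w <- Q[, 1]^1.5
  Xc <- sweep(X, 2, mu[1, ])
  expect_equal(Ss[[1]], 0.5 * crossprod(Xc * sqrt(w)) / sum(w),
               tolerance = 1e-12, ignore_attr = TRUE)
  # ridge blend keeps symmetry and positive definiteness
  Sr <- update_covariances(X, Q, mu, 0.5, 0.5, ridge_alpha = 0.95)
  for (Sk in Sr) {
    expect_equal(Sk, t(Sk))
    expect_gt(min(eigen(Sk, symmetric = TRUE)$values), 0)
  }
})

test_that("proportion update: beta=0 column means; symmetry; oracle", {
  set.seed(37)
  X <- matrix(rnorm(40), 20, 2)
  Q <- matrix(runif(40), 20, 2); Q <- Q / rowSums(Q)
  th <- rand_theta(2, 2)
  expect_equal(update_proportions(X, Q, th, 0.5, 0), colMeans(Q))
  # mirror-symmetric configuration gives (1/2, 1/2)
  Xs <- rbind(c(2, 0), c(-2, 0), c(3, 1), c(-3, -1))
  ths <- cluster_params(rbind(c(2.5, 0.5), c(-2.5, -0.5)))
  Qs <- responsibilities(Xs, ths, 0.5, 1)
  expect_equal(update_proportions(Xs, Qs, ths, 0.5, 1), c(0.5, 0.5))
  # transcription with beta = 1 (square-root aggregation)
  beta <- 1; tau <- 0.5
  num <- vapply(1:2, function(k) {
    s <- sum(vapply(seq_len(nrow(X)), function(i)
      Q[i, k]^(1 + beta) *
        oracle_w(X[i, ], th$centers[k, ], th$covariances[[k]], tau,
                 beta)^(-beta), 0))
    s^(1 / (1 + beta))
  }, 0)
  expect_equal(update_proportions(X, Q, th, tau, beta), num / sum(num),
               tolerance = 1e-10)
})

test_that("assignment is the row-wise argmax with lowest-index ties", {
  expect_identical(assign_clusters(rbind(c(0.7, 0.3), c(0.5, 0.5))), c(1L, 1L))
  set.seed(41)
  Q <- matrix(runif(60), 20, 3)
  expect_identical(assign_clusters(Q), apply(Q, 1, which.max))
})

test_that("monotone descent holds across random data and random inits", {
  set.seed(53)
  for (rep in 1:25) {
    b <- rand_blobs(80, 3, 2, spread = runif(1, 1, 6))
    init <- cluster_params(b$X[sample.int(80, 3), , drop = FALSE])
    fit <- pareto_cluster(b$X, 3, mode = "pareto", tau = 0.5, beta = 0.5,
                          ridge_alpha = 1, init = init, max_iter = 100)
    tr <- fit$energy_trace
    expect_true(all(diff(tr) <= 1e-10 * (1 + abs(tr[-length(tr)]))))
    expect_length(tr, fit$n_iter + 1)
    expect_identical(fit$labels, assign_clusters(fit$membership))
  }
})

test_that("K=1 gmm fit gives the sample mean and (ridged) sample covariance", {
  set.seed(59)
  X <- matrix(rnorm(100, sd = 2), 50, 2)
  fit <- pareto_cluster(X, 1, mode = "gmm", ridge_alpha = 0.95,
                        init = cluster_params(matrix(rnorm(2), 1, 2)))
  expect_equal(fit$params$centers[1, ], colMeans(X), ignore_attr = TRUE,
               tolerance = 1e-9)
  Sraw <- cov(X) * (49 / 50)
  Sridge <- 0.95 * Sraw + 0.05 * max(diag(Sraw)) * diag(2)
  expect_equal(fit$params$covariances[[1]], Sridge, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("one gmm sweep equals a textbook EM step exactly", {
  set.seed(61)
  b <- rand_blobs(100, 2, 2, spread = 4)
  theta <- init_params(b$X, 2)
  em <- oracle_em_step(b$X, theta)
  Q <- responsibilities(b$X, theta, 0.5, 0)
  expect_equal(Q, em$Q, tolerance = 1e-8)
  mu <- update_centers(b$X, Q, 0)
  expect_equal(mu, em$centers, tolerance = 1e-8, ignore_attr = TRUE)
  Sg <- update_covariances(b$X, Q, mu, 0.5, 0, ridge_alpha = 1)
  for (k in 1:2)
    expect_equal(Sg[[k]], em$covariances[[k]], tolerance = 1e-8,
                 ignore_attr = TRUE)
  expect_equal(update_proportions(b$X, Q, cluster_params(mu, Sg), 0.5, 0),
               em$proportions, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("separated blobs are recovered with near-pure labels", {
  set.seed(67)
  n <- 400
  g <- rep(1:2, each = n / 2)
  X <- cbind(rnorm(n, mean = c(-5, 5)[g]), rnorm(n))
  fit <- pareto_cluster(X, 2, mode = "pareto", tau = 0.5, beta = 0.5)
  expect_lt(mse_centers(fit$params$centers, rbind(c(-5, 0), c(5, 0))), 0.25)
  expect_gt(purity(fit$labels, g), 0.95)
  expect_true(fit$converged)
})

test_that("tau = Inf analytic branch reproduces classic FCM fixed points", {
  set.seed(71)
  b <- rand_blobs(120, 2, 2, spread = 6)
  init <- init_params(b$X, 2)
  fit <- pareto_cluster(b$X, 2, mode = "fuzzy", m = 2, init = init)
  ref <- fcm_reference(b$X, 2, m = 2, init_centers = init$centers)
  expect_equal(fit$params$centers, ref$centers, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(fit$membership, ref$memberships, tolerance = 1e-3,
               ignore_attr = TRUE)
  # operator-level coincidence on identical state
  U <- paretoclust:::.fcm_membership(b$X, init$centers, 2)
  Q <- responsibilities(b$X, cluster_params(init$centers), Inf, 1)
  expect_equal(Q, U, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(update_centers(b$X, Q, 1),
               crossprod(U^2, b$X) / colSums(U^2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("kmeans mode performs Lloyd's iteration", {
  set.seed(73)
  b <- rand_blobs(150, 3, 2, spread = 7)
  init <- init_params(b$X, 3)
  fit <- pareto_cluster(b$X, 3, mode = "kmeans", init = init)
  # independent Lloyd iteration from the same start
  centers <- init$centers
  for (it in 1:200) {
    lab <- apply(b$X, 1, function(x) which.min(colSums((t(centers) - x)^2)))
    new_centers <- t(sapply(1:3, function(k)
      colMeans(b$X[lab == k, , drop = FALSE])))
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  expect_equal(fit$params$centers, centers, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(kmeans_energy(b$X, fit$params$centers),
               tail(fit$energy_trace, 1))
})

test_that("fit is equivariant under row permutation and component relabeling", {
  set.seed(79)
  b <- rand_blobs(90, 2, 2, spread = 6)
  init <- init_params(b$X, 2)
  f1 <- pareto_cluster(b$X, 2, beta = 0.5, init = init)
  perm <- sample.int(90)
  f2 <- pareto_cluster(b$X[perm, ], 2, beta = 0.5, init = init)
  expect_equal(f1$params$centers, f2$params$centers, tolerance = 1e-8)
  expect_equal(f1$labels[perm], f2$labels)
  # swapping the initial component order swaps the fitted components
  init_sw <- cluster_params(init$centers[2:1, ], init$covariances[2:1],
                            init$proportions[2:1])
  f3 <- pareto_cluster(b$X, 2, beta = 0.5, init = init_sw)
  expect_equal(f3$params$centers, f1$params$centers[2:1, ], tolerance = 1e-8)
})

test_that("guards: covariance estimation needs d*beta < 2", {
  X <- matrix(rnorm(60), 30, 2)
  expect_error(pareto_cluster(X, 2, beta = 1),
               class = "paretoclust_degenerate_scale")
  # same beta is fine with fixed covariances
  fit <- pareto_cluster(X, 2, beta = 1, estimate_cov = FALSE)
  expect_s3_class(fit, "pareto_fit")
})

test_that("fcm_reference agrees with an external FCM implementation", {
  skip_if_not_installed("e1071")
  set.seed(5)
  X <- rbind(matrix(rnorm(80), ncol = 2), matrix(rnorm(80, 4), ncol = 2))
  init <- init_params(X, 2)
  ref <- fcm_reference(X, 2, m = 2, init_centers = init$centers)
  cm <- e1071::cmeans(X, centers = init$centers, m = 2, iter.max = 500)
  expect_equal(ref$centers, cm$centers, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(ref$memberships, cm$membership, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("fcm_reference approaches hard assignment as m -> 1+", {
  set.seed(83)
  b <- rand_blobs(100, 2, 2, spread = 10)
  init <- init_params(b$X, 2)
  ref <- fcm_reference(b$X, 2, m = 1.05, init_centers = init$centers)
  expect_gt(mean(apply(ref$memberships, 1, max)), 0.99)
  expect_equal(rowSums(ref$memberships), rep(1, 100))
})
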