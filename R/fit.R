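#' Hierarchical initialization of cluster parameters
#'
#' Initial values for the MM iteration, from a Ward-linkage (Euclidean)
#' agglomerative tree on the raw coordinates. Because a Ward cut at exactly
#' K groups is easily captured by a handful of extreme points when the data
#' are heavy-tailed (a remote branch absorbs one of the K groups and two
#' genuine clusters get merged), the tree is over-cut at `n_groups > K`
#' groups, the K most populous groups seed the components, and every
#' observation is then assigned to its nearest seed center. Centers are the
#' resulting group means, covariances the ridge-stabilized group sample
#' covariances, proportions the group size fractions. The procedure is
#' deterministic given `(X, K)`.
#'
#' @param X n x d data matrix.
#' @param K number of components, `K <= n`.
#' @param seed unused (the Ward tree is deterministic); kept so that callers
#'   can treat all initializers uniformly.
#' @param ridge_alpha ridge blending weight used to stabilize the group
#'   covariances, as in [update_covariances()].
#' @param n_groups number of Ward groups to over-cut into before keeping the
#'   K largest; default `min(n, max(4K, 16))`.
#' @return a [cluster_params()] object.
#' @export
init_params <- function(X, K, seed = NULL, ridge_alpha = 0.95,
                        n_groups = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (K > n) stop("K must not exceed the number of observations")
  if (is.null(n_groups)) n_groups <- min(n, max(4L * K, 16L))
  n_groups <- max(K, min(n, n_groups))
  if (K == n) {
    g <- seq_len(n)
  } else {
    g0 <- stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"),
                        n_groups)
    sizes0 <- tabulate(g0, nbins = n_groups)
    keep <- order(sizes0, decreasing = TRUE)[seq_len(K)]
    seeds <- (rowsum(X, g0) / sizes0)[keep, , drop = FALSE]
    g <- max.col(-.sqdist_matrix(X, seeds), ties.method = "first")
  }
  sizes <- tabulate(g, nbins = K)
  centers <- rowsum(X, g) / sizes
  overall <- mean(apply(X, 2, stats::var))
  if (!is.finite(overall) || overall <= 0) overall <- 1
  covs <- lapply(seq_len(K), function(k) {
    if (sizes[k] < 2) return(diag(overall, d))
    S <- stats::cov(X[g == k, , drop = FALSE])
    s2 <- max(diag(S))
    if (s2 <= 0) return(diag(overall, d))
    ridge_alpha * S + (1 - ridge_alpha) * s2 * diag(d)
  })
  cluster_params(centers, covs, sizes / n)
}

#' Membership (responsibility) matrix
#'
#' The E-type step of the MM iteration:
#' \deqn{q_k(x_i) = \frac{\pi_k w(x_i, \mu_k, \Sigma_k)}
#'   {\sum_\ell \pi_\ell w(x_i, \mu_\ell, \Sigma_\ell)},}
#' computed via log-weights and a max-shifted softmax. `tau = Inf` selects the
#' analytic large-temperature branch: for `beta > 0` the common
#' \eqn{(\tau\beta)^{-1/\beta}} factor cancels and
#' \eqn{q_k \propto \pi_k |\Sigma_k|^{-1/2} (\|x_i-\mu_k\|^2_{\Sigma_k^{-1}})^{-1/\beta}}
#' (the fuzzy c-means regime); for `beta = 0` the rows are hard indicators of
#' the nearest center (the k-means regime). A point coinciding exactly with a
#' center receives full membership in that component (lowest index first).
#'
#' @param X n x d data matrix.
#' @param theta a [cluster_params()] object.
#' @param tau positive temperature, or `Inf` for the analytic branch.
#' @param beta nonnegative shape.
#' @return an n x K row-stochastic matrix.
#' @export
responsibilities <- function(X, theta, tau, beta) {
  theta <- .as_cluster_params(theta)
  X <- as.matrix(X)
  if (is.infinite(tau)) {
    M <- .mahalanobis_matrix(X, theta)
    if (beta == 0) {
      Q <- matrix(0, nrow(X), theta$K)
      Q[cbind(seq_len(nrow(X)), max.col(-M, ties.method = "first"))] <- 1
      return(Q)
    }
    lq <- sweep(-log(M) / beta, 2,
                log(theta$proportions) - .logdets(theta) / 2, "+")
    hit <- which(apply(M, 1, min) == 0)
    if (length(hit)) {
      lq[hit, ] <- -Inf
      lq[cbind(hit, apply(M[hit, , drop = FALSE], 1, which.min))] <- 0
    }
  } else {
    lw <- .log_weight_matrix(X, theta, tau, beta)
    lq <- sweep(lw, 2, log(theta$proportions), "+")
  }
  tot <- .row_logsumexp(lq)
  if (any(!is.finite(tot)))
    stop("membership underflow for observation ", which(!is.finite(tot))[1])
  exp(lq - tot)
}

#' Center update of the MM iteration
#'
#' \deqn{\mu_k \leftarrow \frac{\sum_i q_k(x_i)^{1+\beta} x_i}
#'   {\sum_i q_k(x_i)^{1+\beta}}.}
#' Each updated center is a convex combination of data points.
#'
#' @param X n x d data matrix.
#' @param Q n x K membership matrix.
#' @param beta nonnegative shape.
#' @return K x d matrix of updated centers.
#' @export
update_centers <- function(X, Q, beta) {
  X <- as.matrix(X)
  W <- Q^(1 + beta)
  cs <- colSums(W)
  if (any(cs < 1e-300)) {
    k <- which(cs < 1e-300)[1]
    stop(errorCondition(
      paste0("component ", k, " has effectively no members"),
      class = c("paretoclust_empty_cluster", "error", "condition"),
      component = k))
  }
  crossprod(W, X) / cs
}

#' Covariance update of the MM iteration, with ridge regularization
#'
#' The raw update is
#' \deqn{\Sigma_k \leftarrow \tau(2 - d\beta) \frac{\sum_i q_k(x_i)^{1+\beta}
#'   (x_i - \mu_k)(x_i - \mu_k)^\top}{\sum_i q_k(x_i)^{1+\beta}},}
#' using the freshly updated centers; the scale factor \eqn{\tau(2-d\beta)}
#' must be strictly positive, so covariance estimation requires
#' \eqn{d\beta < 2}. The raw update is then blended with a spherical target,
#' \eqn{\Sigma_k(\alpha) = \alpha \Sigma_k + (1-\alpha)\hat\sigma_k^2 I} with
#' \eqn{\hat\sigma_k^2} the largest diagonal entry of the raw update;
#' `ridge_alpha = 1` disables the blend. At \eqn{\beta = 0, \tau = 1/2} the
#' raw update is exactly the Gaussian-mixture EM M-step scatter.
#'
#' @param X n x d data matrix.
#' @param Q n x K membership matrix.
#' @param centers K x d matrix of freshly updated centers.
#' @param tau positive temperature.
#' @param beta nonnegative shape with `d * beta < 2`.
#' @param ridge_alpha blending weight in (0, 1].
#' @return list of K updated d x d covariance matrices.
#' @export
update_covariances <- function(X, Q, centers, tau, beta, ridge_alpha = 0.95) {
  X <- as.matrix(X)
  d <- ncol(X)
  coef <- tau * (2 - d * beta)
  if (coef <= 0)
    stop(errorCondition(
      paste0("degenerate covariance scale: tau*(2 - d*beta) = ", coef,
             "; lower beta below 2/d or disable covariance estimation"),
      class = c("paretoclust_degenerate_scale", "error", "condition")))
  if (ridge_alpha <= 0 || ridge_alpha > 1) stop("ridge_alpha must be in (0, 1]")
  W <- Q^(1 + beta)
  cs <- colSums(W)
  lapply(seq_len(ncol(Q)), function(k) {
    if (cs[k] < 1e-300)
      stop(errorCondition(
        paste0("component ", k, " has effectively no members"),
        class = c("paretoclust_empty_cluster", "error", "condition"),
        component = k))
    Xc <- sweep(X, 2, centers[k, ]) * sqrt(W[, k])
    S <- coef * crossprod(Xc) / cs[k]
    if (ridge_alpha == 1) return(S)
    s2 <- max(diag(S))
    if (s2 <= 0) s2 <- max(mean(apply(X, 2, stats::var)), .Machine$double.eps)
    ridge_alpha * S + (1 - ridge_alpha) * s2 * diag(d)
  })
}

#' Mixing-proportion update of the MM iteration
#'
#' \deqn{\pi_k \leftarrow \frac{\{\sum_i q_k(x_i)^{1+\beta}
#'   w(x_i, \mu_k, \Sigma_k)^{-\beta}\}^{1/(1+\beta)}}
#'   {\sum_\ell \{\cdot\}^{1/(1+\beta)}},}
#' evaluated at the freshly updated centers and covariances. At
#' \eqn{\beta = 0} this reduces to the Gaussian-mixture M-step
#' \eqn{\pi_k = \frac{1}{n}\sum_i q_k(x_i)}.
#'
#' @param X n x d data matrix.
#' @param Q n x K membership matrix.
#' @param theta_new a [cluster_params()] holding the updated centers and
#'   covariances (its proportions slot is ignored).
#' @param tau positive temperature.
#' @param beta nonnegative shape.
#' @return length-K simplex vector.
#' @export
update_proportions <- function(X, Q, theta_new, tau, beta) {
  if (beta == 0) return(colMeans(Q))
  theta_new <- .as_cluster_params(theta_new)
  X <- as.matrix(X)
  lw <- .log_weight_matrix(X, theta_new, tau, beta)
  lt <- (1 + beta) * log(Q) - beta * lw          # n x K, log of the summands
  mx <- apply(lt, 2, max)
  lognum <- (mx + log(colSums(exp(sweep(lt, 2, mx))))) / (1 + beta)
  p <- exp(lognum - max(lognum))
  p / sum(p)
}

#' Hard cluster assignment from memberships
#'
#' Each observation is assigned to the component with the largest
#' membership; ties are broken deterministically toward the lowest component
#' index.
#'
#' @param Q n x K membership matrix.
#' @return integer vector of labels in 1..K.
#' @export
assign_clusters <- function(Q) {
  max.col(as.matrix(Q), ties.method = "first")
}

#' Pareto clustering by minorize-maximization
#'
#' Fits the Kolmogorov-Nagumo / generalized-Pareto clustering model by the MM
#' iteration: membership step, then center, covariance and proportion updates
#' in that order (the ordering is required for the monotone-descent
#' guarantee). The generalized energy is recorded after every full sweep and
#' is non-increasing along the iteration.
#'
#' @param X n x d numeric data matrix (rows are observations).
#' @param K number of clusters.
#' @param mode preset selecting the regime:
#'   \describe{
#'     \item{`"pareto"`}{free \eqn{(\tau, \beta)}; defaults
#'       \eqn{\tau = 0.5, \beta = 1}.}
#'     \item{`"gmm"`}{\eqn{\beta = 0, \tau = 1/2}: exactly the EM algorithm
#'       for a Gaussian mixture (modulo the ridge blend).}
#'     \item{`"rose"`}{\eqn{\beta = 0}, free \eqn{\tau}: maximum-entropy
#'       (deterministic-annealing) clustering.}
#'     \item{`"fuzzy"`}{analytic \eqn{\tau = \infty} branch with
#'       \eqn{\beta = m - 1}, \eqn{\Sigma_k = I}, \eqn{\pi_k = 1/K} held
#'       fixed: fuzzy c-means with fuzzifier `m`.}
#'     \item{`"kmeans"`}{analytic \eqn{\tau = \infty}, \eqn{\beta = 0}:
#'       Lloyd's algorithm.}
#'   }
#' @param tau positive temperature (ignored by the presets that fix it).
#' @param beta nonnegative shape (ignored by the presets that fix it).
#' @param m fuzzifier for `mode = "fuzzy"` (`beta = m - 1`).
#' @param estimate_cov estimate per-component covariances? Requires
#'   `d * beta < 2`. Forced off in the `"fuzzy"` and `"kmeans"` modes.
#' @param estimate_pi estimate mixing proportions? Forced off in the
#'   `"fuzzy"` and `"kmeans"` modes.
#' @param ridge_alpha ridge blending weight in (0, 1]; 1 disables the ridge.
#' @param max_iter maximum number of MM sweeps.
#' @param rel_tol stop when the relative energy change falls below this.
#' @param init optional [cluster_params()] initial values; default is the
#'   Ward-linkage initialization of [init_params()].
#' @param seed optional integer; only consulted by the empty-cluster
#'   re-seeding fallback, so fits are deterministic given `(X, K, init)`.
#' @return an object of class `"pareto_fit"`: a list with `params`
#'   ([cluster_params()]), `membership` (n x K), `labels`, `energy_trace`
#'   (length `n_iter + 1`, the energy at the initial and after each sweep),
#'   `n_iter`, `converged`, `mode`, `tau`, `beta`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100), ncol = 2),
#'            matrix(rnorm(100, mean = 5), ncol = 2))
#' fit <- pareto_cluster(X, K = 2, beta = 0.5)
#' table(fit$labels)
#' @export
pareto_cluster <- function(X, K,
                           mode = c("pareto", "gmm", "fuzzy", "kmeans", "rose"),
                           tau = 0.5, beta = 1, m = 2,
                           estimate_cov = TRUE, estimate_pi = TRUE,
                           ridge_alpha = 0.95, max_iter = 500, rel_tol = 1e-8,
                           init = NULL, seed = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (K >= n) stop("need more observations than clusters")
  if (tau <= 0) stop("tau must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  if (mode == "gmm") { beta <- 0; tau <- 0.5 }
  if (mode == "rose") beta <- 0
  if (mode == "fuzzy") {
    if (m <= 1) stop("fuzzifier m must be > 1")
    tau <- Inf; beta <- m - 1
    estimate_cov <- FALSE; estimate_pi <- FALSE
  }
  if (mode == "kmeans") {
    tau <- Inf; beta <- 0
    estimate_cov <- FALSE; estimate_pi <- FALSE
  }
  if (estimate_cov && beta > 0 && d * beta >= 2)
    stop(errorCondition(
      paste0("covariance estimation requires d * beta < 2 (here ", d * beta,
             "); lower beta or set estimate_cov = FALSE"),
      class = c("paretoclust_degenerate_scale", "error", "condition")))

  theta <- if (is.null(init)) init_params(X, K, ridge_alpha = ridge_alpha)
           else .as_cluster_params(init)
  if (theta$K != K || theta$d != d) stop("init does not match (K, d)")
  if (mode %in% c("fuzzy", "kmeans"))
    theta <- cluster_params(theta$centers) # identity Sigma, uniform pi

  energy_fun <- switch(mode,
    pareto = function(th) if (beta > 0) pareto_energy(X, th, tau, beta)
                          else rose_energy(X, th, tau),
    gmm = , rose = function(th) rose_energy(X, th, tau),
    fuzzy = function(th) fuzzy_energy(X, th$centers, beta),
    kmeans = function(th) kmeans_energy(X, th$centers))

  trace <- energy_fun(theta)
  converged <- FALSE
  n_iter <- 0L
  last_reseeded <- NA_integer_
  t <- 1L
  while (t <= max_iter) {
    Q <- responsibilities(X, theta, tau, beta)
    cs <- colSums(Q^(1 + beta))
    if (any(cs < 1e-300)) {
      k <- which(cs < 1e-300)[1]
      if (identical(last_reseeded, k))
        stop(errorCondition(
          paste0("component ", k, " emptied twice in a row; cannot recover"),
          class = c("paretoclust_convergence_error", "error", "condition")))
      theta <- .reseed_component(X, theta, k, tau, beta)
      last_reseeded <- k
      next
    }
    last_reseeded <- NA_integer_
    mu <- update_centers(X, Q, beta)
    Sig <- if (estimate_cov)
      update_covariances(X, Q, mu, tau, beta, ridge_alpha)
    else theta$covariances
    th_new <- cluster_params(mu, Sig, theta$proportions)
    prop <- if (estimate_pi) update_proportions(X, Q, th_new, tau, beta)
            else theta$proportions
    theta <- cluster_params(mu, Sig, prop)
    e <- energy_fun(theta)
    trace <- c(trace, e)
    n_iter <- t
    prev <- trace[length(trace) - 1]
    if (abs(e - prev) <= rel_tol * (abs(prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    t <- t + 1L
  }
  Q <- responsibilities(X, theta, tau, beta)
  structure(list(params = theta, membership = Q,
                 labels = assign_clusters(Q), energy_trace = trace,
                 n_iter = n_iter, converged = converged,
                 mode = mode, tau = tau, beta = beta,
                 estimate_cov = estimate_cov, estimate_pi = estimate_pi,
                 ridge_alpha = ridge_alpha, seed = seed,
                 call = match.call()),
            class = "pareto_fit")
}

# Move an emptied component to the least well-explained observation: the one
# with the lowest mixture log-density (finite tau), or the one farthest from
# every center (analytic tau = Inf branch).
.reseed_component <- function(X, theta, k, tau, beta) {
  if (is.infinite(tau)) {
    M <- .sqdist_matrix(X, theta$centers)
    i <- which.max(apply(M, 1, min))
  } else {
    lw <- .log_weight_matrix(X, theta, tau, beta)
    i <- which.min(.row_logsumexp(sweep(lw, 2, log(theta$proportions), "+")))
  }
  centers <- theta$centers
  centers[k, ] <- X[i, ]
  cluster_params(centers, theta$covariances, theta$proportions)
}

#' @export
print.pareto_fit <- function(x, ...) {
  cat("Pareto clustering fit (mode = ", x$mode, ")\n", sep = "")
  cat("  K = ", x$params$K, ", d = ", x$params$d,
      ", tau = ", format(x$tau), ", beta = ", format(x$beta), "\n", sep = "")
  cat("  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  final energy:", format(utils::tail(x$energy_trace, 1)), "\n")
  cat("  cluster sizes:", tabulate(x$labels, x$params$K), "\n")
  invisible(x)
}

#' Classic fuzzy c-means (reference implementation)
#'
#' The textbook Bezdek fixed-point iteration, used as the in-package
#' equivalence oracle for the analytic large-temperature branch of
#' [pareto_cluster()]: memberships
#' \deqn{u_{ik} = \Big[\sum_\ell \big(\|x_i - \mu_k\|^2 /
#'   \|x_i - \mu_\ell\|^2\big)^{1/(m-1)}\Big]^{-1}}
#' (row-stochastic) and centers \eqn{\mu_k = \sum_i u_{ik}^m x_i / \sum_i
#' u_{ik}^m}. A point coinciding with a center receives full membership
#' there. Under the parameter mapping \eqn{\beta = m - 1} these operators
#' coincide with [responsibilities()] / [update_centers()] in the
#' \eqn{\tau = \infty} branch with identity covariances and uniform
#' proportions: the MM membership \eqn{q} equals \eqn{u}, and the MM weight
#' \eqn{q^{1+\beta}} equals \eqn{u^m}.
#'
#' @param X n x d data matrix.
#' @param K number of clusters.
#' @param m fuzzifier, `m > 1`.
#' @param init_centers K x d matrix of starting centers.
#' @param max_iter,tol iteration controls (stop when the largest center
#'   displacement falls below `tol`).
#' @return list with `centers`, `memberships` (n x K, row-stochastic),
#'   `n_iter`.
#' @export
fcm_reference <- function(X, K, m = 2, init_centers, max_iter = 500,
                          tol = 1e-10) {
  if (m <= 1) stop("fuzzifier m must be > 1")
  X <- as.matrix(X)
  centers <- as.matrix(init_centers)
  if (nrow(centers) != K || ncol(centers) != ncol(X))
    stop("init_centers must be K x d")
  u <- NULL
  for (it in seq_len(max_iter)) {
    u <- .fcm_membership(X, centers, m)
    W <- u^m
    new_centers <- crossprod(W, X) / colSums(W)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  list(centers = centers, memberships = .fcm_membership(X, centers, m),
       n_iter = it)
}

.fcm_membership <- function(X, centers, m) {
  D <- .sqdist_matrix(X, centers)
  le <- -log(D) / (m - 1)
  u <- exp(le - .row_logsumexp(le))
  hit <- which(apply(D, 1, min) == 0)
  if (length(hit)) {
    u[hit, ] <- 0
    u[cbind(hit, apply(D[hit, , drop = FALSE], 1, which.min))] <- 1
  }
  u
}
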