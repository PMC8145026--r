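#' Generalized Kolmogorov-Nagumo clustering energy
#'
#' Evaluates the center-only clustering objective
#' \deqn{L_S(\mu) = \frac{1}{\tau} \sum_{i=1}^n S^{-1}\Big(\frac{1}{K}
#'   \sum_{k=1}^K S(\tau \|x_i - \mu_k\|^2)\Big),}
#' the Kolmogorov-Nagumo (quasi-arithmetic) average of the per-cluster
#' energies under the survival function \eqn{S}. Depending on \eqn{S} and the
#' temperature \eqn{\tau} this objective interpolates between k-means
#' (\eqn{\tau \to \infty} with light tails), fuzzy c-means (\eqn{\tau \to
#' \infty}, Pareto tails), maximum-entropy clustering (exponential \eqn{S})
#' and the mean-of-all-distances objective (\eqn{\tau \to 0}).
#'
#' @param X n x d data matrix.
#' @param centers K x d matrix of centers.
#' @param model a [survival_model()].
#' @param tau positive temperature parameter.
#' @return the scalar energy. All inner averages are accumulated in log space
#'   with max-shift stabilization, so extreme values of `tau` (e.g. `1e8`) are
#'   handled without overflow.
#' @export
kn_energy <- function(X, centers, model, tau) {
  .check_surv_model(model)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) stop("tau must be > 0")
  xc <- .check_matrix_centers(X, centers)
  D <- .sqdist_matrix(xc$X, xc$centers)
  K <- nrow(xc$centers)
  switch(model$family,
    pareto = {
      b <- model$shape
      logS <- -log1p(b * tau * D) / b            # n x K
      logmean <- .row_logsumexp(logS) - log(K)
      sum(expm1(-b * logmean)) / (b * tau)
    },
    exponential = {
      logmean <- .row_logsumexp(-tau * D) - log(K)
      -sum(logmean) / tau
    },
    frechet = {
      g <- model$shape
      a <- exp(g * (log(tau) + log(D)))          # (tau * d^2)^gamma; d=0 -> Inf
      B <- .neg_log_mean_exp(a)                  # -log mean exp(-a)
      term <- exp(log(B) / g)                    # B^(1/gamma); B=Inf -> 0
      sum(term) / tau
    })
}

#' Pareto clustering energy with covariances and mixing proportions
#'
#' The full-parameter objective
#' \deqn{L_{\tau,\beta}(\theta) = \frac{1}{\tau\beta} \sum_{i=1}^n \Big[
#'   \Big(\sum_k \pi_k w(x_i, \mu_k, \Sigma_k)\Big)^{-\beta} - 1 \Big],}
#' with the component weight \eqn{w} of [component_weight()]. At \eqn{\beta =
#' 0} it dispatches to the analytic limit [rose_energy()]. With identity
#' covariances and uniform proportions it coincides with
#' `kn_energy(X, centers, survival_model("pareto", beta), tau)`.
#'
#' @param X n x d data matrix.
#' @param theta a [cluster_params()] object.
#' @param tau positive temperature.
#' @param beta nonnegative Pareto shape.
#' @return the scalar energy.
#' @export
pareto_energy <- function(X, theta, tau, beta) {
  if (beta < 0) stop("beta must be >= 0")
  if (beta == 0) return(rose_energy(X, theta, tau))
  if (tau <= 0) stop("tau must be > 0")
  theta <- .as_cluster_params(theta)
  X <- as.matrix(X)
  lw <- .log_weight_matrix(X, theta, tau, beta)
  logA <- .row_logsumexp(sweep(lw, 2, log(theta$proportions), "+"))
  sum(expm1(-beta * logA)) / (tau * beta)
}

#' Maximum-entropy (Rose) clustering energy
#'
#' The analytic \eqn{\beta \to 0} branch of [pareto_energy()]:
#' \deqn{-\frac{1}{\tau} \sum_i \log \sum_k \pi_k |\Sigma_k|^{-1/2}
#'   \exp(-\tau \|x_i - \mu_k\|^2_{\Sigma_k^{-1}}).}
#' At \eqn{\tau = 1/2} this equals \eqn{2\{\mathrm{NLL} - n \log
#' (2\pi)^{d/2}\}} where NLL is the Gaussian-mixture negative log-likelihood,
#' so its minimizers are exactly the Gaussian-mixture MLE.
#'
#' @inheritParams pareto_energy
#' @return the scalar energy.
#' @export
rose_energy <- function(X, theta, tau) {
  if (tau <= 0) stop("tau must be > 0")
  theta <- .as_cluster_params(theta)
  X <- as.matrix(X)
  lw <- .log_weight_matrix(X, theta, tau, 0)
  logA <- .row_logsumexp(sweep(lw, 2, log(theta$proportions), "+"))
  -sum(logA) / tau
}

#' Fuzzy c-means energy (the tau -> infinity Pareto limit)
#'
#' \deqn{\sum_{i=1}^n \Big[\frac{1}{K} \sum_{k=1}^K
#'   (\|x_i - \mu_k\|^2)^{-1/\beta}\Big]^{-\beta},}
#' the negative-exponent power mean of squared distances; with \eqn{\beta =
#' m - 1} its stationary points are those of fuzzy c-means with fuzzifier
#' \eqn{m}. A point coinciding exactly with a center contributes 0 (the
#' analytic limit: the zero distance dominates the negative-power mean).
#'
#' @param X n x d data matrix.
#' @param centers K x d matrix of centers.
#' @param beta positive shape (fuzzifier minus one).
#' @return the scalar energy.
#' @export
fuzzy_energy <- function(X, centers, beta) {
  if (beta <= 0) stop("beta must be > 0")
  xc <- .check_matrix_centers(X, centers)
  D <- .sqdist_matrix(xc$X, xc$centers)
  K <- nrow(xc$centers)
  hit <- apply(D, 1, min) == 0
  terms <- numeric(nrow(D))
  if (any(!hit)) {
    li <- -log(D[!hit, , drop = FALSE]) / beta
    logmean <- .row_logsumexp(li) - log(K)
    terms[!hit] <- exp(-beta * logmean)
  }
  sum(terms)
}

#' k-means energy
#'
#' \eqn{\sum_i \min_k \|x_i - \mu_k\|^2}, the joint \eqn{\tau \to \infty},
#' \eqn{\beta \to 0} limit of the Pareto family.
#'
#' @param X n x d data matrix.
#' @param centers K x d matrix of centers.
#' @return the scalar energy.
#' @export
kmeans_energy <- function(X, centers) {
  xc <- .check_matrix_centers(X, centers)
  sum(apply(.sqdist_matrix(xc$X, xc$centers), 1, min))
}

#' Frechet-family clustering energy
#'
#' \deqn{L_{\gamma,\tau}(\mu) = \sum_{i=1}^n \Big[-\frac{1}{\tau^\gamma}
#'   \log \frac{1}{K} \sum_k \exp\{-(\tau \|x_i - \mu_k\|^2)^\gamma\}
#'   \Big]^{1/\gamma}, \qquad \gamma < 0,}
#' the Kolmogorov-Nagumo energy under the Fréchet survival function
#' \eqn{S(t) = 1 - e^{-t^\gamma}}. For \eqn{K = 1} it reduces exactly to
#' \eqn{\sum_i \|x_i - \mu_1\|^2}. As \eqn{\tau \to \infty} it converges to
#' the power-mean energy [fuzzy_energy()] with \eqn{\beta = -1/\gamma}
#' (equivalently \eqn{\gamma = 1/(1-m)}). As \eqn{\tau \to 0} it converges to
#' the farthest-center energy \eqn{\sum_i \max_k \|x_i - \mu_k\|^2}: the
#' smallest exponent \eqn{(\tau d^2)^\gamma} — the farthest center, since
#' \eqn{\gamma < 0} — dominates the inner log-mean-exp, and the decreasing
#' outer power \eqn{t^{1/\gamma}} maps that minimum back to the maximal
#' squared distance. (The k-means minimum-distance objective is instead
#' approached by letting \eqn{\gamma \to -\infty} in the large-\eqn{\tau}
#' power mean.)
#'
#' @param X n x d data matrix.
#' @param centers K x d matrix of centers.
#' @param tau positive temperature.
#' @param gamma negative shape.
#' @return the scalar energy. Points coinciding exactly with a center
#'   contribute 0 (analytic limit).
#' @export
frechet_energy <- function(X, centers, tau, gamma) {
  if (gamma >= 0) stop("gamma must be < 0")
  if (tau <= 0) stop("tau must be > 0")
  xc <- .check_matrix_centers(X, centers)
  kn_energy(xc$X, xc$centers, survival_model("frechet", gamma), tau)
}

#' Estimating-equation weight of the Frechet energy
#'
#' The weight \eqn{\omega_k(x, \tau, \gamma)} in the stationarity condition
#' \eqn{\partial L_{\gamma,\tau} / \partial \mu_k = \sum_i \omega_k(x_i)
#' (\mu_k - x_i) = 0}, obtained by differentiating the [frechet_energy()] of
#' a single point:
#' \deqn{\omega_k(x) = 2 A(x)^{1/\gamma - 1}
#'   \frac{e^{-a_k}}{\sum_\ell e^{-a_\ell}} \|x - \mu_k\|^{2(\gamma - 1)},}
#' where \eqn{a_k = (\tau\|x-\mu_k\|^2)^\gamma} and \eqn{A(x) =
#' -\tau^{-\gamma} \log \frac{1}{K}\sum_\ell e^{-a_\ell}}. The printed
#' closed form in the source derivation is typographically ambiguous, so the
#' implementation is defined (and unit-tested) as the exact gradient of
#' [frechet_energy()].
#'
#' @param x a single d-vector.
#' @param centers K x d matrix of centers.
#' @param k component index in 1..K.
#' @param tau positive temperature.
#' @param gamma negative shape.
#' @return a nonnegative scalar weight.
#' @export
frechet_weight <- function(x, centers, k, tau, gamma) {
  if (gamma >= 0) stop("gamma must be < 0")
  if (tau <= 0) stop("tau must be > 0")
  if (!is.matrix(centers)) centers <- matrix(centers, ncol = length(x))
  K <- nrow(centers)
  if (k < 1 || k > K) stop("component index k out of range")
  d2 <- colSums((t(centers) - as.numeric(x))^2)
  a <- exp(gamma * (log(tau) + log(d2)))
  amin <- min(a)
  lsm <- -(a - amin) - log(sum(exp(-(a - amin)))) # log softmax of -a
  B <- .neg_log_mean_exp(matrix(a, nrow = 1))     # -log mean exp(-a)
  A <- B / tau^gamma
  2 * A^(1 / gamma - 1) * exp(lsm[k]) * d2[k]^(gamma - 1)
}

#' Pareto component weight
#'
#' The mixture component weight of the Pareto clustering model,
#' \deqn{w(x, \mu, \Sigma) = |\Sigma|^{-1/2} \{1 + \tau\beta
#'   \|x - \mu\|^2_{\Sigma^{-1}}\}^{-1/\beta},}
#' with the analytic \eqn{\beta = 0} branch \eqn{|\Sigma|^{-1/2}
#' \exp(-\tau \|x - \mu\|^2_{\Sigma^{-1}})}. Computed through a log-weight
#' path so that large Mahalanobis distances do not underflow prematurely.
#'
#' @param x a single d-vector.
#' @param mu a d-vector center.
#' @param sigma d x d SPD covariance.
#' @param tau positive temperature.
#' @param beta nonnegative shape.
#' @return a positive scalar.
#' @export
component_weight <- function(x, mu, sigma, tau, beta) {
  if (tau <= 0) stop("tau must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  theta <- cluster_params(matrix(mu, nrow = 1), as.matrix(sigma))
  lw <- .log_weight_matrix(matrix(x, nrow = 1), theta, tau, beta)
  exp(lw[1, 1])
}

# Row-wise -log mean(exp(-a)) for a >= 0, accurate both when the entries are
# huge (max-shift regime) and when they are all tiny (where the naive form
# degenerates to log(1 - epsilon) and loses all relative precision): anchor at
# the row minimum and accumulate the remainder through expm1/log1p.
.neg_log_mean_exp <- function(a) {
  amin <- apply(a, 1, min)
  B <- amin - log1p(rowMeans(expm1(-(a - amin))))
  B[!is.finite(amin)] <- Inf
  B
}

# n x K matrix of log component weights log w(x_i, mu_k, Sigma_k)
.log_weight_matrix <- function(X, theta, tau, beta) {
  M <- .mahalanobis_matrix(X, theta)
  ld <- .logdets(theta)
  if (beta == 0) lw <- -tau * M else lw <- -log1p(tau * beta * M) / beta
  sweep(lw, 2, ld / 2, "-")
}
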