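#' Cluster parameters (centers, covariances, mixing proportions)
#'
#' Container for the parameter triple \eqn{\theta = (\mu_k, \Sigma_k,
#' \pi_k)_{k=1}^K} of a K-component clustering model in d dimensions.
#'
#' @param centers K x d numeric matrix of component centers (a vector is
#'   taken as a single d-dimensional center when `d` is known from
#'   `covariances`, otherwise as a K x 1 matrix).
#' @param covariances list of K symmetric positive-definite d x d matrices,
#'   or a single matrix recycled to all components, or `NULL` for identity
#'   covariances.
#' @param proportions length-K vector of nonnegative mixing proportions
#'   summing to 1, or `NULL` for uniform 1/K.
#' @return an object of class `"cluster_params"` with elements `centers`,
#'   `covariances` (list of matrices), `proportions`, and `K`, `d`.
#' @examples
#' cluster_params(rbind(c(0, 0), c(5, 5)))
#' @export
cluster_params <- function(centers, covariances = NULL, proportions = NULL) {
  if (!is.matrix(centers)) centers <- matrix(centers, nrow = 1)
  storage.mode(centers) <- "double"
  if (any(!is.finite(centers))) stop("centers must be finite")
  K <- nrow(centers); d <- ncol(centers)

  if (is.null(covariances)) covariances <- replicate(K, diag(d), simplify = FALSE)
  if (is.matrix(covariances)) covariances <- replicate(K, covariances, simplify = FALSE)
  if (length(covariances) != K) stop("need one covariance per component")
  covariances <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    if (!all(dim(S) == d)) stop("covariance dimension does not match centers")
    if (max(abs(S - t(S))) > 1e-10 * max(1, max(abs(S))))
      stop("covariance matrix is not symmetric")
    S
  })
  ev <- vapply(covariances, function(S) min(eigen(S, symmetric = TRUE,
                                                  only.values = TRUE)$values), 0)
  if (any(ev <= 0))
    stop("covariance of component ", which(ev <= 0)[1], " is not positive definite")

  if (is.null(proportions)) proportions <- rep(1 / K, K)
  if (length(proportions) != K) stop("need one mixing proportion per component")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-10)
    stop("proportions must be nonnegative and sum to 1")

  structure(list(centers = centers, covariances = covariances,
                 proportions = as.numeric(proportions), K = K, d = d),
            class = "cluster_params")
}

#' @export
print.cluster_params <- function(x, ...) {
  cat("Cluster parameters: K =", x$K, ", d =", x$d, "\n")
  cat("Proportions:", format(x$proportions, digits = 4), "\n")
  cat("Centers:\n"); print(x$centers)
  invisible(x)
}

.as_cluster_params <- function(theta) {
  if (inherits(theta, "cluster_params")) theta
  else cluster_params(theta$centers, theta$covariances, theta$proportions)
}

# row-wise log-sum-exp with max shift; m is a numeric matrix
.row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Cholesky factor and log-determinant of an SPD matrix, with a clear error
.chol_logdet <- function(S, what = "covariance") {
  U <- tryCatch(chol(S), error = function(e)
    stop("singular or non-positive-definite ", what, call. = FALSE))
  list(U = U, logdet = 2 * sum(log(diag(U))))
}

# n x K matrix of squared Mahalanobis distances of rows of X to each component
.mahalanobis_matrix <- function(X, theta) {
  n <- nrow(X)
  M <- matrix(0, n, theta$K)
  for (k in seq_len(theta$K)) {
    cl <- .chol_logdet(theta$covariances[[k]],
                       paste0("covariance (component ", k, ")"))
    Xc <- sweep(X, 2, theta$centers[k, ])
    Z <- Xc %*% backsolve(cl$U, diag(theta$d))
    M[, k] <- rowSums(Z * Z)
  }
  M
}

.logdets <- function(theta) {
  vapply(theta$covariances, function(S) .chol_logdet(S)$logdet, 0)
}

.check_matrix_centers <- function(X, centers) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(centers)) centers <- matrix(centers, ncol = ncol(X))
  if (ncol(X) != ncol(centers))
    stop("data and centers must have the same number of columns")
  list(X = X, centers = centers)
}

# n x K squared Euclidean distance matrix
.sqdist_matrix <- function(X, centers) {
  n2x <- rowSums(X * X)
  n2c <- rowSums(centers * centers)
  D <- outer(n2x, n2c, "+") - 2 * X %*% t(centers)
  D <- pmax(D, 0)
  dimnames(D) <- NULL
  D
}
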