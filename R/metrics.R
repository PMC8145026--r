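#' Pairwise precision and recall of a cluster against a reference class
#'
#' \eqn{\mathrm{Precision}(C_k, D_\ell) = |C_k \cap D_\ell| / |C_k|} and
#' \eqn{\mathrm{Recall}(C_k, D_\ell) = |C_k \cap D_\ell| / |D_\ell|}.
#'
#' @param pred integer vector of predicted cluster labels.
#' @param truth integer vector of reference class labels (same length).
#' @param k cluster index evaluated.
#' @param l reference class index evaluated.
#' @return named numeric vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(pred, truth, k, l) {
  .check_partitions(pred, truth)
  nk <- sum(pred == k); nl <- sum(truth == l)
  if (nk == 0) stop("cluster ", k, " is empty; precision undefined")
  if (nl == 0) stop("class ", l, " is empty; recall undefined")
  inter <- sum(pred == k & truth == l)
  c(precision = inter / nk, recall = inter / nl)
}

#' Purity of a clustering against reference classes
#'
#' \eqn{\mathrm{Purity} = \sum_k \frac{|C_k|}{n} \max_\ell
#' \mathrm{Precision}(C_k, D_\ell)}: the fraction of points that belong to
#' their cluster's majority class. Empty clusters are dropped with a warning.
#'
#' @inheritParams precision_recall
#' @return a value in (0, 1]; 1 iff every cluster is class-pure.
#' @export
purity <- function(pred, truth) {
  .check_partitions(pred, truth)
  tab <- table(pred, truth)
  sum(apply(tab, 1, max)) / length(pred)
}

#' F-value of a clustering against reference classes
#'
#' \eqn{\mathrm{F} = \sum_k \frac{|D_k|}{n} \max_\ell F(D_k, C_\ell)} where
#' \eqn{F(D, C)} is the harmonic mean of \eqn{\mathrm{Precision}(D, C) =
#' |D \cap C|/|D|} and \eqn{\mathrm{Recall}(D, C) = |D \cap C|/|C|}; the
#' outer sum runs over the reference classes, each matched to its best
#' cluster.
#'
#' @inheritParams precision_recall
#' @return a value in (0, 1]; 1 iff the partitions coincide.
#' @export
f_value <- function(pred, truth) {
  .check_partitions(pred, truth)
  n <- length(pred)
  tab <- table(truth, pred)               # classes x clusters counts
  class_sizes <- rowSums(tab)
  clus_sizes <- colSums(tab)
  P <- tab / class_sizes                  # Precision(D_k, C_l)
  R <- sweep(tab, 2, clus_sizes, "/")     # Recall(D_k, C_l)
  Fm <- 2 * P * R / (P + R)
  Fm[tab == 0] <- 0
  sum(class_sizes / n * apply(Fm, 1, max))
}

.check_partitions <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("label vectors must have the same length")
  if (length(pred) == 0) stop("empty label vectors")
  emptyc <- setdiff(seq_len(max(pred)), unique(pred))
  if (length(emptyc))
    warning("dropping empty cluster(s): ", paste(emptyc, collapse = ", "))
  invisible(NULL)
}

#' Centroid index between two center sets
#'
#' The cluster-level dissimilarity
#' \eqn{\mathrm{CI}(\hat\mu, \mu^*) = \max\{\mathrm{CI}'(\hat\mu, \mu^*),
#' \mathrm{CI}'(\mu^*, \hat\mu)\}}, where \eqn{\mathrm{CI}'(A, B)} counts the
#' members of B that are not the nearest neighbour of any member of A
#' ("orphans"). CI = 0 means the nearest-neighbour map covers every target
#' center in both directions, i.e. the two sets describe the same cluster
#' locations. The two sets may have different sizes. Nearest-neighbour ties
#' break toward the lowest index.
#'
#' @param mu_hat K1 x d matrix of estimated centers.
#' @param mu_star K2 x d matrix of reference centers.
#' @return a nonnegative integer, at most `max(K1, K2)`.
#' @export
centroid_index <- function(mu_hat, mu_star) {
  mu_hat <- .as_center_matrix(mu_hat)
  mu_star <- .as_center_matrix(mu_star)
  if (ncol(mu_hat) != ncol(mu_star)) stop("center sets must share d")
  max(.ci_oneway(mu_hat, mu_star), .ci_oneway(mu_star, mu_hat))
}

.ci_oneway <- function(A, B) {
  D <- .sqdist_matrix(A, B)
  q <- max.col(-D, ties.method = "first")  # nearest member of B for each row of A
  sum(!(seq_len(nrow(B)) %in% q))          # orphans of B
}

.as_center_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("centers must be finite")
  m
}

#' Matched mean squared error between center sets
#'
#' \eqn{\mathrm{MSE} = \frac{1}{K} \sum_k \|\hat\mu_{\sigma(k)} -
#' \mu^*_k\|^2} where the correspondence \eqn{\sigma} is the minimum-cost
#' bipartite matching (Hungarian algorithm) on squared distances. Fitted
#' components come in arbitrary order, so index-wise pairing would be
#' label-dependent; the optimal matching is the only label-invariant
#' reading and never exceeds the MSE of any fixed pairing.
#'
#' @param mu_hat K x d matrix of estimated centers.
#' @param mu_star K x d matrix of reference centers (same K and d).
#' @return nonnegative scalar; 0 iff the sets are equal up to ordering.
#' @export
mse_centers <- function(mu_hat, mu_star) {
  mu_hat <- .as_center_matrix(mu_hat)
  mu_star <- .as_center_matrix(mu_star)
  if (!all(dim(mu_hat) == dim(mu_star)))
    stop("center sets must have identical dimensions")
  cost <- .sqdist_matrix(mu_hat, mu_star)
  sigma <- .hungarian(cost)
  mean(cost[cbind(seq_len(nrow(cost)), sigma)])
}

# Minimum-cost perfect matching on a square cost matrix via the standard
# potential-based shortest-augmenting-path (Jonker-Volgenant) scheme, O(K^3).
# Returns sigma with sigma[i] = column assigned to row i.
.hungarian <- function(cost) {
  n <- nrow(cost)
  # arrays indexed 0..n stored at offset +1; p[j] = row matched to column j
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  sigma <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) sigma[p[j + 1]] <- j
  sigma
}
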