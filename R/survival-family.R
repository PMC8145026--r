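#' Survival-function families for Kolmogorov-Nagumo clustering energies
#'
#' Constructs a survival-function model \eqn{S(t) = P(T > t)} from one of the
#' three families the clustering energies are built on:
#'
#' \describe{
#'   \item{pareto}{generalized Pareto, \eqn{S(t) = (1 + \beta t)^{-1/\beta}}
#'     with shape \eqn{\beta > 0}; heavy (polynomial) tail. \eqn{\beta = 0} is
#'     accepted as an exact alias for the exponential family, avoiding the
#'     catastrophic cancellation of evaluating \eqn{(u^{-\beta}-1)/\beta} at
#'     tiny \eqn{\beta}.}
#'   \item{exponential}{\eqn{S(t) = e^{-t}}, the \eqn{\beta \to 0} limit of the
#'     Pareto family; the shape argument is ignored.}
#'   \item{frechet}{\eqn{S(t) = 1 - \exp(-t^\gamma)} with shape
#'     \eqn{\gamma < 0}.}
#' }
#'
#' Pareto/exponential survival functions are convex and decreasing on
#' \eqn{t \ge 0}, which is what guarantees the minorization used by the MM
#' clustering algorithm; the Fréchet survival function is decreasing but not
#' globally convex.
#'
#' @param family one of `"pareto"`, `"exponential"`, `"frechet"`.
#' @param shape shape parameter: \eqn{\beta \ge 0} for `"pareto"` (0 aliases
#'   the exponential branch), \eqn{\gamma < 0} for `"frechet"`, ignored for
#'   `"exponential"`.
#' @return an object of class `"survival_model"`.
#' @examples
#' m <- survival_model("pareto", 1)
#' surv(m, 1)          # (1 + 1)^(-1) = 0.5
#' surv_inv(m, 0.5)    # 1
#' @export
survival_model <- function(family = c("pareto", "exponential", "frechet"),
                           shape = NULL) {
  family <- match.arg(family)
  if (family == "pareto") {
    if (is.null(shape)) stop("pareto family requires a shape parameter beta")
    if (!is.finite(shape) || shape < 0)
      stop("pareto shape beta must be >= 0 (0 aliases the exponential family)")
    if (shape == 0) family <- "exponential"
  } else if (family == "frechet") {
    if (is.null(shape)) stop("frechet family requires a shape parameter gamma")
    if (!is.finite(shape) || shape >= 0)
      stop("frechet shape gamma must be < 0")
  } else {
    shape <- NA_real_
  }
  structure(list(family = family, shape = shape), class = "survival_model")
}

#' @export
print.survival_model <- function(x, ...) {
  cat("Survival model:", x$family,
      if (!is.na(x$shape)) paste0("(shape = ", format(x$shape), ")"), "\n")
  invisible(x)
}

.check_surv_model <- function(model) {
  if (!inherits(model, "survival_model"))
    stop("'model' must be a survival_model object")
}

#' Evaluate a survival function
#'
#' @param model a [survival_model()].
#' @param t nonnegative evaluation points.
#' @return \eqn{S(t)} in \eqn{(0, 1]}; vectorized over `t`.
#' @details The Pareto branch is evaluated in log space,
#'   \eqn{\exp\{-\log(1+\beta t)/\beta\}}, which is stable for large
#'   \eqn{\beta t}.
#' @export
surv <- function(model, t) {
  .check_surv_model(model)
  if (any(!is.finite(t) | t < 0)) stop("t must be finite and >= 0")
  switch(model$family,
    pareto = exp(-log1p(model$shape * t) / model$shape),
    exponential = exp(-t),
    frechet = {
      out <- -expm1(-t^model$shape)
      out[t == 0] <- 1 # t^gamma -> +Inf as t -> 0+ (gamma < 0)
      out
    })
}

#' Inverse survival function
#'
#' For the Pareto and exponential families the inverse is evaluated on the
#' convex extension of its domain, i.e. any \eqn{u > 0} is accepted (values
#' \eqn{u > 1} map to negative "times"); this extension is what lets the
#' mixture-weighted energy use \eqn{S^{-1}} on sums exceeding 1. The Fréchet
#' inverse is only defined for \eqn{u \in (0, 1)} (and \eqn{u = 1 \mapsto 0}).
#'
#' @param model a [survival_model()].
#' @param u positive values (see Details for the per-family domain).
#' @return \eqn{S^{-1}(u)}; vectorized over `u`.
#' @details Pareto: \eqn{S^{-1}(u) = (u^{-\beta} - 1)/\beta}, computed as
#'   `expm1(-beta*log(u))/beta`. Exponential: \eqn{-\log u}. Fréchet:
#'   \eqn{(-\log(1-u))^{1/\gamma}}.
#' @export
surv_inv <- function(model, u) {
  .check_surv_model(model)
  if (any(!is.finite(u) | u <= 0)) stop("u must be finite and > 0")
  switch(model$family,
    pareto = expm1(-model$shape * log(u)) / model$shape,
    exponential = -log(u),
    frechet = {
      if (any(u > 1)) stop("frechet inverse survival requires u in (0, 1]")
      out <- (-log1p(-u))^(1 / model$shape)
      out[u == 1] <- 0
      out
    })
}

#' Density of the survival model
#'
#' The density is \eqn{f(t) = -S'(t)}.
#'
#' @param model a [survival_model()].
#' @param t nonnegative evaluation points.
#' @return \eqn{f(t) \ge 0}; vectorized over `t`. For the Fréchet family the
#'   value at `t = 0` is the analytic limit 0 (the direct expression is an
#'   indeterminate `Inf * 0` product there).
#' @export
surv_density <- function(model, t) {
  .check_surv_model(model)
  if (any(!is.finite(t) | t < 0)) stop("t must be finite and >= 0")
  switch(model$family,
    pareto = exp(-(1 / model$shape + 1) * log1p(model$shape * t)),
    exponential = exp(-t),
    frechet = {
      g <- model$shape
      out <- -g * t^(g - 1) * exp(-t^g)
      out[t == 0] <- 0 # limit of t^(g-1) * exp(-t^g) as t -> 0+
      out
    })
}
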