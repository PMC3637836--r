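#' Model structure specification
#'
#' The default model is the common-slope, common-variance, linear-trend
#' mixture: components differ only in the level (intercept) of linear
#' growth.  Extensions allow component-specific slopes, component-specific
#' variances, and a quadratic time trend (common slope/curvature only).
#'
#' @param slope `"common"` (one slope shared by all components) or
#'   `"component"` (one slope per component).
#' @param variance `"common"` or `"component"`.
#' @param mean `"linear"` or `"quadratic"` (adds a common curvature term).
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(slope = c("common", "component"),
                       variance = c("common", "component"),
                       mean = c("linear", "quadratic")) {
  slope <- match.arg(slope)
  variance <- match.arg(variance)
  mean <- match.arg(mean)
  if (mean == "quadratic" && slope == "component")
    stop("quadratic trend is only supported with a common slope",
         call. = FALSE)
  structure(list(slope = slope, variance = variance, mean = mean),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model spec: %s slope, %s variance, %s trend\n",
              x$slope, x$variance, x$mean))
  invisible(x)
}

#' Mixture parameter container
#'
#' Holds the weights, intercepts, slope(s), optional curvature and
#' variance(s) of a J-component mixture of growth lines.  Weights must be
#' non-negative and sum to one (tolerance 1e-12); variances must be
#' strictly positive.  For reporting, components are conventionally ordered
#' by ascending intercept (see [sort_components()]), which resolves label
#' switching.
#'
#' @param weights J-vector of mixing weights p_j.
#' @param intercepts J-vector of component intercepts alpha_j (outcome
#'   units).
#' @param slope Scalar common slope beta, or J-vector of component slopes
#'   (outcome units per time step), matching `spec$slope`.
#' @param sigma2 Scalar common error variance, or J-vector, matching
#'   `spec$variance` (squared outcome units).
#' @param curvature Scalar quadratic coefficient; required iff
#'   `spec$mean == "quadratic"`.
#' @param spec A [model_spec()].
#' @return An object of class `"mixture_params"`.
#' @export
mixture_params <- function(weights, intercepts, slope, sigma2,
                           curvature = NULL, spec = model_spec()) {
  J <- length(intercepts)
  if (J < 1L) stop("need at least one component", call. = FALSE)
  weights <- as.numeric(weights)
  intercepts <- as.numeric(intercepts)
  slope <- as.numeric(slope)
  sigma2 <- as.numeric(sigma2)
  if (length(weights) != J)
    stop("weights and intercepts must have equal length", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1 (|sum - 1| <= 1e-12); got sum = ",
         format(sum(weights), digits = 17), call. = FALSE)
  want_slopes <- if (spec$slope == "common") 1L else J
  if (length(slope) != want_slopes)
    stop("slope must have length ", want_slopes, " for spec slope '",
         spec$slope, "'", call. = FALSE)
  want_var <- if (spec$variance == "common") 1L else J
  if (length(sigma2) != want_var)
    stop("sigma2 must have length ", want_var, " for spec variance '",
         spec$variance, "'", call. = FALSE)
  if (any(sigma2 <= 0))
    stop("sigma2 must be strictly positive", call. = FALSE)
  if (spec$mean == "quadratic") {
    if (is.null(curvature) || length(curvature) != 1L)
      stop("quadratic spec requires a scalar curvature", call. = FALSE)
    curvature <- as.numeric(curvature)
  } else if (!is.null(curvature)) {
    stop("curvature given but spec mean is 'linear'", call. = FALSE)
  }
  structure(list(J = J, weights = weights, intercepts = intercepts,
                 slope = slope, sigma2 = sigma2, curvature = curvature,
                 spec = spec),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, digits = 4, ...) {
  cat(sprintf("%d-component growth-line mixture (%s slope, %s variance, %s trend)\n",
              x$J, x$spec$slope, x$spec$variance, x$spec$mean))
  tab <- data.frame(weight = x$weights, intercept = x$intercepts)
  if (x$spec$slope == "component") tab$slope <- x$slope
  if (x$spec$variance == "component") tab$sigma2 <- x$sigma2
  print(round(tab, digits))
  if (x$spec$slope == "common")
    cat("common slope:", round(x$slope, digits), "\n")
  if (!is.null(x$curvature))
    cat("curvature:", round(x$curvature, digits), "\n")
  if (x$spec$variance == "common")
    cat("common sigma2:", round(x$sigma2, digits), "\n")
  invisible(x)
}

#' Reorder mixture components by ascending intercept
#'
#' @param params A [mixture_params()] object.
#' @return The same object with components sorted by ascending intercept
#'   (plus the permutation used, as attribute `"perm"`).
#' @export
sort_components <- function(params) {
  perm <- order(params$intercepts)
  params$weights <- params$weights[perm]
  params$intercepts <- params$intercepts[perm]
  if (params$spec$slope == "component") params$slope <- params$slope[perm]
  if (params$spec$variance == "component") params$sigma2 <- params$sigma2[perm]
  attr(params, "perm") <- perm
  params
}

# component mean mu_t = alpha + beta * t (+ curvature * t^2)
component_mean <- function(tindex, intercept, slope, curvature = NULL) {
  mu <- intercept + slope * tindex
  if (!is.null(curvature)) mu <- mu + curvature * tindex^2
  mu
}

#' Log density of one region's trajectory under one component
#'
#' The component density is a product over time of univariate normal
#' densities around the component's growth line (a multivariate normal with
#' diagonal covariance).  Computed as a sum of log densities, never as a
#' product, so that long series with poor parameter values do not underflow.
#'
#' @param y Numeric T-vector of one region's outcomes.
#' @param intercept,slope Component line parameters (scalars).
#' @param sigma2 Error variance (> 0, scalar).
#' @param curvature Optional quadratic coefficient (scalar or `NULL`).
#' @param tindex Time index; defaults to `seq_along(y)`.
#' @return The log density (scalar).
#' @export
component_logdens <- function(y, intercept, slope, sigma2,
                              curvature = NULL, tindex = seq_along(y)) {
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  mu <- component_mean(tindex, intercept, slope, curvature)
  sum(stats::dnorm(y, mean = mu, sd = sqrt(sigma2), log = TRUE))
}

# n x J matrix of component log densities for a whole panel
logdens_matrix <- function(panel, params) {
  y <- panel$y
  tindex <- panel$time_index
  n <- nrow(y); J <- params$J
  out <- matrix(NA_real_, n, J)
  for (j in seq_len(J)) {
    bj <- if (params$spec$slope == "common") params$slope else params$slope[j]
    s2 <- if (params$spec$variance == "common") params$sigma2 else params$sigma2[j]
    mu <- component_mean(tindex, params$intercepts[j], bj, params$curvature)
    res <- sweep(y, 2L, mu)  # y - mu, row-wise
    out[, j] <- -0.5 * ncol(y) * log(2 * pi * s2) -
      rowSums(res^2) / (2 * s2)
  }
  out
}

# numerically stable log(sum(exp(x))) by row
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Observed-data mixture log-likelihood
#'
#' Sum over regions of the log of the weighted mixture of component
#' densities, evaluated with a per-region log-sum-exp.
#'
#' @param panel A `"growth_panel"`.
#' @param params A [mixture_params()] object.
#' @return The log-likelihood (scalar).
#' @export
mixture_loglik <- function(panel, params) {
  if (abs(sum(params$weights) - 1) > 1e-12)
    stop("weights must sum to 1", call. = FALSE)
  lw <- ifelse(params$weights > 0, log(params$weights), -Inf)
  lm <- sweep(logdens_matrix(panel, params), 2L, lw, `+`)
  sum(row_logsumexp(lm))
}

#' Free-parameter count and information criteria
#'
#' Counts the free parameters r of a J-component model (intercepts, slope(s),
#' optional curvature, variance(s), and J-1 free weights) and computes two
#' BIC variants: one penalising by the number of regions n, the other by the
#' total number of observations n*T.  For the default model r = 2J + 1, so
#' the two criteria always differ by (2J + 1) * log(T).
#'
#' @param loglik Maximised log-likelihood.
#' @param J Number of components.
#' @param n Number of regions.
#' @param T Number of time points.
#' @param spec A [model_spec()].
#' @return A list with `r`, `BIC` (= -2 loglik + r log n) and `BIC2`
#'   (= -2 loglik + r log(nT)).
#' @export
information_criteria <- function(loglik, J, n, T, spec = model_spec()) {
  stopifnot(J >= 1, n >= 1, T >= 1)
  n_mean <- J +
    (if (spec$slope == "common") 1L else J) +
    (if (spec$mean == "quadratic") 1L else 0L)
  n_var <- if (spec$variance == "common") 1L else J
  r <- as.integer(n_mean + n_var + (J - 1L))
  list(r = r,
       BIC = -2 * loglik + r * log(n),
       BIC2 = -2 * loglik + r * log(n * T))
}
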